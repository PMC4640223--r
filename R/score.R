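#' Scoring configuration for structure learning
#'
#' Collects the Dirichlet prior strength (equivalent sample size), the
#' seed-network structure-prior strength and the parent cap used by the BDe
#' score and the Tabu search.
#'
#' The BDeu convention is used: a family with r child states and q joint
#' parent configurations gets per-cell pseudo-count ESS / (r * q), so every
#' prior cell exceeds zero and Markov-equivalent structures score equally.
#' The structure prior multiplies the marginal likelihood by kappa once per
#' edge in the symmetric difference between a candidate structure and the
#' seed DAG; kappa = 1 disables the bias.
#'
#' @param ess equivalent sample size (> 0; default 1).
#' @param kappa per-edge-difference prior factor in (0, 1\]; default 0.5.
#' @param max_parents in-degree cap during search (default 3).
#' @return an object of class `score_config`.
#' @export
score_config <- function(ess = 1, kappa = 0.5, max_parents = 3L) {
  if (!is.numeric(ess) || ess <= 0) stop("ess must be positive")
  if (!is.numeric(kappa) || kappa <= 0 || kappa > 1)
    stop("kappa must be in (0, 1]")
  if (max_parents < 0L) stop("max_parents must be >= 0")
  structure(list(ess = ess, kappa = kappa,
                 max_parents = as.integer(max_parents)),
            class = "score_config")
}

# counts N[j, k]: child state k (1..B) within parent configuration j (1..q)
family_counts <- function(child, parents, data) {
  B <- data$n_bins
  st <- data$states
  q <- B^length(parents)
  if (nrow(st) == 0L) return(matrix(0L, nrow = q, ncol = B))
  cfg <- config_index(st[, parents, drop = FALSE], B)
  idx <- (st[, child] ) * q + cfg          # child-major blocks of length q
  matrix(tabulate(idx, nbins = q * B), nrow = q, ncol = B)
}

#' Log BDe marginal likelihood of one family
#'
#' Closed-form log marginal likelihood of a child's column given its
#' parents' columns under a Dirichlet prior with BDeu pseudo-counts
#' ESS / (r * q) per cell: for each parent configuration j,
#' `lgamma(a_j) - lgamma(a_j + N_j) + sum_k [lgamma(a_jk + N_jk) -
#' lgamma(a_jk)]` with a_jk = ESS/(r q) and a_j = ESS/q. An empty data set
#' scores 0 (marginal likelihood 1).
#'
#' @param child child node name (a panel analyte).
#' @param parents character vector of parent names (may be empty); must not
#'   contain the child.
#' @param data a `discretized_panel`.
#' @param config a [score_config()].
#' @return log marginal likelihood (scalar).
#' @export
family_bde_score <- function(child, parents, data, config = score_config()) {
  if (child %in% parents) stop("a node cannot be its own parent")
  stopifnot(inherits(data, "discretized_panel"))
  if (!all(c(child, parents) %in% colnames(data$states)))
    stop("child and parents must be panel analytes")
  B <- data$n_bins
  q <- B^length(parents)
  N <- family_counts(child, parents, data)
  a_cell <- config$ess / (B * q)
  a_row <- config$ess / q
  nj <- rowSums(N)
  sum(lgamma(a_row) - lgamma(a_row + nj)) +
    sum(lgamma(a_cell + N) - lgamma(a_cell))
}

edge_key <- function(edges) {
  if (NROW(edges) == 0L) return(character(0))
  paste(edges[, 1L], edges[, 2L], sep = "\r")
}

# number of directed edges in the symmetric difference of two structures
edge_difference <- function(dag, seed_dag) {
  a <- edge_key(dag$edges)
  b <- edge_key(seed_dag$edges)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Seed-biased network score
#'
#' Total log score of a structure: the sum of its family BDe scores plus a
#' multiplicative structure prior, `delta * log(kappa)`, where delta is the
#' number of directed edges by which the structure differs from the seed DAG
#' (symmetric difference). Structures close to the seed thereby score
#' higher; kappa = 1 (or a `NULL` seed) reduces to the plain BDe score,
#' which decomposes over families.
#'
#' @param dag a `bn_dag` (acyclic by construction).
#' @param data a `discretized_panel` covering the DAG's nodes.
#' @param seed_dag optional seed `bn_dag`; `NULL` for no structure prior.
#' @param config a [score_config()].
#' @return log score (scalar).
#' @export
network_score <- function(dag, data, seed_dag = NULL,
                          config = score_config()) {
  fam <- sum(vapply(dag$nodes, function(v)
    family_bde_score(v, dag_parents(dag, v), data, config), numeric(1)))
  if (is.null(seed_dag) || config$kappa == 1) return(fam)
  fam + edge_difference(dag, seed_dag) * log(config$kappa)
}

#' Fit conditional probability tables by Dirichlet posterior mean
#'
#' Given a structure and discretized data, each CPT row is the posterior
#' mean under the same BDeu pseudo-counts as the score:
#' `(N_jk + ESS/(r q)) / (N_j + ESS/q)`. Rows start from the uniform prior
#' and move with the data; no entry is ever zero, and a parent configuration
#' never observed stays uniform.
#'
#' @param dag a `bn_dag`.
#' @param data a `discretized_panel` whose analytes include the DAG's nodes.
#' @param config a [score_config()].
#' @return a `bn_cpts`.
#' @export
fit_cpts <- function(dag, data, config = score_config()) {
  stopifnot(inherits(data, "discretized_panel"))
  B <- data$n_bins
  cpts <- lapply(dag$nodes, function(v) {
    parents <- dag_parents(dag, v)
    q <- B^length(parents)
    N <- family_counts(v, parents, data)
    a_cell <- config$ess / (B * q)
    prob <- (N + a_cell) / (rowSums(N) + config$ess / q)
    list(parents = parents, prob = prob)
  })
  names(cpts) <- dag$nodes
  new_bn_cpts(cpts, B)
}
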