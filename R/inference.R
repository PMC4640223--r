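# Exact inference on categorical Bayesian networks: factor algebra, variable
# elimination, point-mass interventions (graph surgery or conditioning), and
# a brute-force joint-enumeration oracle for testing.

# A factor is list(vars, card, vals) with vals linearized so the FIRST
# variable in `vars` varies fastest.

new_factor <- function(vars, card, vals) {
  stopifnot(length(vals) == prod(card))
  list(vars = vars, card = card, vals = as.numeric(vals))
}

# linear index (1-based) into a sub-factor for every cell of the union scope
sub_index <- function(vars, card, sub_vars, sub_card) {
  n <- prod(card)
  idx <- rep(1, n)
  stride <- 1
  for (k in seq_along(sub_vars)) {
    pos <- match(sub_vars[k], vars)
    lower <- if (pos == 1L) 1 else prod(card[seq_len(pos - 1L)])
    a <- (floor((seq_len(n) - 1) / lower)) %% card[pos]
    idx <- idx + a * stride
    stride <- stride * sub_card[k]
  }
  idx
}

factor_product <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  card <- integer(length(vars))
  card[match(f1$vars, vars)] <- f1$card
  card[match(f2$vars, vars)] <- f2$card
  i1 <- sub_index(vars, card, f1$vars, f1$card)
  i2 <- sub_index(vars, card, f2$vars, f2$card)
  new_factor(vars, card, f1$vals[i1] * f2$vals[i2])
}

factor_marginalize <- function(f, var) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  arr <- array(f$vals, dim = f$card)
  perm <- c(pos, setdiff(seq_along(f$card), pos))
  arr <- aperm(arr, perm)
  vals <- colSums(matrix(arr, nrow = f$card[pos]))
  new_factor(f$vars[-pos], f$card[-pos], vals)
}

# condition a factor on var = state (0-based); var leaves the scope
factor_reduce <- function(f, var, state) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  arr <- array(f$vals, dim = f$card)
  perm <- c(pos, setdiff(seq_along(f$card), pos))
  arr <- matrix(aperm(arr, perm), nrow = f$card[pos])
  new_factor(f$vars[-pos], f$card[-pos], arr[state + 1L, ])
}

cpt_factor <- function(node, cpts) {
  tab <- cpts$tables[[node]]
  B <- cpts$n_bins
  # prob is q x B (rows parent configs, cols child states); linearize with
  # the child fastest, then parents in listed order
  new_factor(c(node, tab$parents),
             rep(B, 1L + length(tab$parents)),
             as.vector(t(tab$prob)))
}

point_mass_factor <- function(node, state, B) {
  v <- rep(0, B)
  v[state + 1L] <- 1
  new_factor(node, B, v)
}

#' Point-mass intervention specification
#'
#' Forces one or more nodes into a fixed concentration bin. Under the
#' default `surgical` mode (graph surgery, the do-operator) the intervened
#' nodes' incoming edges are cut and their distributions replaced by point
#' masses, so only descendants can change; the underlying CPTs themselves
#' are untouched. Under `observational` mode the forced states are instead
#' treated as evidence and the network is conditioned on them.
#'
#' @param targets named integer vector or list: node -> forced bin index
#'   (0 = low, 1 = medium, 2 = high for 3 bins). Each node at most once.
#' @param mode `"surgical"` or `"observational"`.
#' @return an object of class `intervention_spec`.
#' @export
intervention_spec <- function(targets, mode = c("surgical", "observational")) {
  mode <- match.arg(mode)
  targets <- unlist(targets)
  if (length(targets) == 0L) stop("intervention needs at least one target")
  if (is.null(names(targets)) || any(names(targets) == ""))
    stop("targets must be named by node")
  if (anyDuplicated(names(targets))) stop("a node may appear at most once")
  structure(list(targets = targets, mode = mode),
            class = "intervention_spec")
}

#' Full joint probability table by enumeration
#'
#' Brute-force oracle: enumerates every joint configuration and multiplies
#' the CPT entries, P(x) = prod_i P(x_i | pa(x_i)). Guarded to state spaces
#' of at most one million cells.
#'
#' @param dag a `bn_dag`.
#' @param cpts a matching `bn_cpts`.
#' @return data frame with one 0-based state column per node plus `prob`;
#'   probabilities sum to 1.
#' @export
joint_enumeration_oracle <- function(dag, cpts) {
  B <- cpts$n_bins
  n_cells <- B^length(dag$nodes)
  if (n_cells > 1e6)
    stop("state space too large for enumeration: ", n_cells, " cells")
  grid <- as.matrix(expand.grid(rep(list(0:(B - 1L)), length(dag$nodes))))
  colnames(grid) <- dag$nodes
  prob <- rep(1, nrow(grid))
  for (v in dag$nodes) {
    tab <- cpts$tables[[v]]
    cfg <- config_index(grid[, tab$parents, drop = FALSE], B)
    prob <- prob * tab$prob[cbind(cfg, grid[, v] + 1L)]
  }
  out <- as.data.frame(grid)
  out$prob <- prob
  out
}

# greedy min-degree elimination order over the moralized interaction graph
elimination_order <- function(factors, keep) {
  vars <- setdiff(sort(unique(unlist(lapply(factors, `[[`, "vars")))), keep)
  scopes <- lapply(factors, `[[`, "vars")
  order <- character(0)
  while (length(vars) > 0L) {
    deg <- vapply(vars, function(v) {
      nb <- unique(unlist(scopes[vapply(scopes, function(s) v %in% s, TRUE)]))
      length(setdiff(nb, v))
    }, numeric(1))
    v <- vars[order(deg, vars)][1L]
    order <- c(order, v)
    touching <- vapply(scopes, function(s) v %in% s, TRUE)
    merged <- setdiff(unique(unlist(scopes[touching])), v)
    scopes <- c(scopes[!touching], list(merged))
    vars <- setdiff(vars, v)
  }
  order
}

run_elimination <- function(factors, keep) {
  for (v in elimination_order(factors, keep)) {
    touching <- vapply(factors, function(f) v %in% f$vars, TRUE)
    prod <- Reduce(factor_product, factors[touching])
    factors <- c(factors[!touching], list(factor_marginalize(prod, v)))
  }
  res <- Reduce(factor_product, factors)
  # order scope as requested
  if (length(keep) > 0L && !identical(res$vars, keep)) {
    perm <- match(keep, res$vars)
    arr <- aperm(array(res$vals, dim = res$card), perm)
    res <- new_factor(keep, res$card[perm], as.vector(arr))
  }
  res
}

#' Exact node marginals, optionally under intervention
#'
#' Computes every node's marginal distribution over its concentration bins
#' by variable elimination. With a surgical intervention the intervened
#' nodes' CPT factors are replaced by point masses (their incoming edges
#' are cut), so perturbation propagates only downstream; with an
#' observational intervention the forced states are conditioned on and the
#' result renormalized. Without an intervention both modes coincide.
#'
#' @param dag a `bn_dag`.
#' @param cpts a matching `bn_cpts`.
#' @param intervention optional [intervention_spec()].
#' @return a `marginal_report`: matrix nodes x bins of marginal
#'   probabilities (rows sum to 1) with a `labels` attribute from
#'   [classify_state()].
#' @export
exact_marginals <- function(dag, cpts, intervention = NULL) {
  B <- cpts$n_bins
  nodes <- dag$nodes
  if (!is.null(intervention)) {
    stopifnot(inherits(intervention, "intervention_spec"))
    unknown <- setdiff(names(intervention$targets), nodes)
    if (length(unknown) > 0L)
      stop("intervention on unknown node(s): ", paste(unknown, collapse = ", "))
    if (any(intervention$targets < 0L | intervention$targets >= B))
      stop("forced bin index out of range")
  }
  base_factors <- lapply(nodes, cpt_factor, cpts = cpts)
  names(base_factors) <- nodes
  surgical <- !is.null(intervention) && intervention$mode == "surgical"
  observational <- !is.null(intervention) && intervention$mode == "observational"
  if (surgical) {
    for (v in names(intervention$targets))
      base_factors[[v]] <- point_mass_factor(v, intervention$targets[[v]], B)
  }
  if (observational) {
    for (v in names(intervention$targets))
      base_factors <- lapply(base_factors, factor_reduce, var = v,
                             state = intervention$targets[[v]])
  }
  marg <- matrix(NA_real_, length(nodes), B,
                 dimnames = list(nodes, seq_len(B) - 1L))
  for (v in nodes) {
    if (observational && v %in% names(intervention$targets)) {
      marg[v, ] <- point_mass_factor(v, intervention$targets[[v]], B)$vals
      next
    }
    res <- run_elimination(base_factors, keep = v)
    p <- res$vals
    marg[v, ] <- p / sum(p)
  }
  structure(marg, class = c("marginal_report", "matrix"),
            labels = apply(marg, 1L, classify_state))
}

#' Qualitative label of a marginal distribution
#'
#' Maps a probability vector over the low/medium/high bins to its dominant
#' bin's label, prefixed with "moderately" when the dominant probability is
#' below 0.5 (no bin clearly dominates). Ties between equal maxima resolve
#' toward the medium bin, then toward the lower bin; the medium label never
#' carries the modifier (it already denotes the mid-range bin).
#'
#' @param marginal probability vector summing to 1 (length 3 for the
#'   standard low/medium/high binning; other lengths use bin names
#'   `bin0`, `bin1`, ...).
#' @return character label, e.g. `"high"` or `"moderately high"`.
#' @export
classify_state <- function(marginal) {
  stopifnot(abs(sum(marginal) - 1) < 1e-6)
  B <- length(marginal)
  labels <- if (B == 3L) c("low", "medium", "high") else paste0("bin", 0:(B - 1L))
  best <- which(marginal == max(marginal))
  if (length(best) > 1L) {
    mid <- ceiling(B / 2)
    best <- if (mid %in% best) mid else min(best)
  }
  lab <- labels[best]
  if (marginal[best] < 0.5 && best != ceiling(B / 2))
    lab <- paste("moderately", lab)
  lab
}

#' Perturbation report in low/medium/high table form
#'
#' Tabulates, for a baseline (no intervention) and each perturbation
#' scenario, the marginal probability of every node falling into each
#' concentration bin, one row per (scenario, node), in the layout of the
#' study's perturbation tables: columns `node`, `scenario`, `P_low`,
#' `P_medium`, `P_high` (or `P_bin<k>` for other bin counts) and the
#' qualitative `label`.
#'
#' @param dag a `bn_dag`.
#' @param cpts a matching `bn_cpts`.
#' @param scenarios named list of [intervention_spec()]s; names become the
#'   scenario column (e.g. `"-PRL+IL-13"`).
#' @param baseline include baseline rows (default TRUE).
#' @return data frame.
#' @export
perturbation_table <- function(dag, cpts, scenarios = list(),
                               baseline = TRUE) {
  if (length(scenarios) == 0L && !baseline)
    stop("nothing to report: no scenarios and no baseline")
  if (length(scenarios) > 0L && is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  B <- cpts$n_bins
  bin_cols <- if (B == 3L) c("P_low", "P_medium", "P_high") else
    paste0("P_bin", 0:(B - 1L))
  one <- function(name, spec) {
    m <- exact_marginals(dag, cpts, spec)
    df <- data.frame(node = rownames(m), scenario = name,
                     as.data.frame(unclass(m)))
    names(df)[-(1:2)] <- bin_cols
    df$label <- attr(m, "labels")
    df
  }
  blocks <- list()
  if (baseline) blocks <- c(blocks, list(one("baseline", NULL)))
  for (nm in names(scenarios))
    blocks <- c(blocks, list(one(nm, scenarios[[nm]])))
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
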