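# Tabu search over DAG space: add / delete / reverse single-edge moves,
# greedy best-admissible-move steps with a tabu list of forbidden inverse
# moves, deterministic lexicographic tie-breaking.

move_key <- function(type, i, j) paste(type, i, j, sep = "\r")

inverse_move <- function(type, i, j) {
  switch(type,
         add = move_key("delete", i, j),
         delete = move_key("add", i, j),
         reverse = move_key("reverse", j, i))
}

#' Tabu search structure learning
#'
#' Local search over DAG structures maximizing the seed-biased BDe score
#' ([network_score()]). Starting from the seed structure, each step
#' evaluates all admissible single-edge moves -- adding, removing or
#' reversing an edge -- subject to acyclicity and the parent cap, applies
#' the best one (even when it worsens the score, which lets the search walk
#' out of local optima), and forbids its inverse for the next `tabu_length`
#' steps unless undoing it would beat the best structure seen (aspiration).
#' Ties between equal-scoring moves break lexicographically by
#' (move type, parent, child), so the search is fully deterministic. The
#' best structure visited is returned; it never scores below the seed
#' structure because the seed is the starting incumbent.
#'
#' @param data a `discretized_panel`.
#' @param seed_dag starting (and prior) structure, a `bn_dag` over the
#'   panel's analytes; `NULL` for the empty graph.
#' @param config a [score_config()].
#' @param tabu_length number of recent moves whose inverses are forbidden
#'   (default 10).
#' @param max_iterations hard step cap (default 1000; must be positive).
#' @param patience stop after this many consecutive non-improving steps
#'   (default 100).
#' @return the best `bn_dag` found, with attributes `score` and
#'   `seed_score`.
#' @export
tabu_search <- function(data, seed_dag = NULL, config = score_config(),
                        tabu_length = 10L, max_iterations = 1000L,
                        patience = 100L) {
  stopifnot(inherits(data, "discretized_panel"))
  if (max_iterations <= 0L) stop("max_iterations must be positive")
  nodes <- colnames(data$states)
  n <- length(nodes)
  if (is.null(seed_dag)) seed_dag <- bn_dag(nodes)
  if (!setequal(seed_dag$nodes, nodes))
    stop("seed_dag must be defined over the panel's analytes")
  amat <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(seed_dag$edges) > 0L) amat[seed_dag$edges] <- TRUE
  if (any(colSums(amat) > config$max_parents))
    stop("seed structure exceeds the parent cap")
  seed_amat <- amat
  log_kappa <- log(config$kappa)

  cache <- new.env(parent = emptyenv())
  fam <- function(child, parent_set) {
    key <- paste(child, paste(sort(parent_set), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- family_bde_score(child, parent_set, data, config)
      cache[[key]] <- got
    }
    got
  }
  fam_of <- function(a, v) fam(v, rownames(a)[a[, v]])
  # structure-prior contribution of toggling edge i -> j: the edge-difference
  # count delta moves by one, toward the seed (bonus) or away (penalty)
  prior_term <- function(i, j, adding) {
    if (log_kappa == 0) return(0)
    agree <- seed_amat[i, j]
    if (adding) {
      if (agree) -log_kappa else log_kappa   # delta falls or grows by 1
    } else {
      if (agree) log_kappa else -log_kappa
    }
  }

  current_family <- structure(vapply(nodes, function(v) fam_of(amat, v),
                                     numeric(1)), names = nodes)
  current_score <- sum(current_family) +
    edge_difference(amat_to_dag(amat), seed_dag) * log_kappa
  best_amat <- amat
  best_score <- current_score
  seed_score <- current_score
  tabu <- character(0)
  stale <- 0L

  for (iter in seq_len(max_iterations)) {
    reach <- amat_reachability(amat)
    indeg <- colSums(amat)
    cand_type <- character(0); cand_i <- character(0); cand_j <- character(0)
    cand_delta <- numeric(0)
    push <- function(type, i, j, delta) {
      cand_type[length(cand_type) + 1L] <<- type
      cand_i[length(cand_i) + 1L] <<- i
      cand_j[length(cand_j) + 1L] <<- j
      cand_delta[length(cand_delta) + 1L] <<- delta
    }
    for (i in nodes) for (j in nodes) {
      if (i == j) next
      if (!amat[i, j]) {
        # add i -> j: no reverse path j ~> i, cap respected, no 2-cycle
        if (!amat[j, i] && !reach[j, i] && indeg[j] < config$max_parents) {
          pa <- rownames(amat)[amat[, j]]
          delta <- fam(j, c(pa, i)) - current_family[[j]] +
            prior_term(i, j, adding = TRUE)
          push("add", i, j, delta)
        }
      } else {
        pa <- rownames(amat)[amat[, j]]
        d_del <- fam(j, setdiff(pa, i)) - current_family[[j]] +
          prior_term(i, j, adding = FALSE)
        push("delete", i, j, d_del)
        # reverse i -> j  =>  j -> i: needs no other path i ~> j
        if (indeg[i] < config$max_parents) {
          a2 <- amat; a2[i, j] <- FALSE
          if (!amat_reachability(a2)[i, j]) {
            pa_i <- rownames(amat)[amat[, i]]
            delta <- d_del + fam(i, c(pa_i, j)) - current_family[[i]] +
              prior_term(j, i, adding = TRUE)
            push("reverse", i, j, delta)
          }
        }
      }
    }
    if (length(cand_delta) == 0L) break
    keys <- mapply(move_key, cand_type, cand_i, cand_j, USE.NAMES = FALSE)
    admissible <- !(keys %in% tabu) |
      (current_score + cand_delta > best_score + 1e-12)
    if (!any(admissible)) break
    ord <- order(-cand_delta, match(cand_type, c("add", "delete", "reverse")),
                 cand_i, cand_j)
    pick <- ord[admissible[ord]][1L]
    type <- cand_type[pick]; i <- cand_i[pick]; j <- cand_j[pick]
    if (type == "add") {
      amat[i, j] <- TRUE
      current_family[[j]] <- fam_of(amat, j)
    } else if (type == "delete") {
      amat[i, j] <- FALSE
      current_family[[j]] <- fam_of(amat, j)
    } else {
      amat[i, j] <- FALSE
      amat[j, i] <- TRUE
      current_family[[j]] <- fam_of(amat, j)
      current_family[[i]] <- fam_of(amat, i)
    }
    current_score <- current_score + cand_delta[pick]
    tabu <- c(inverse_move(type, i, j), tabu)
    if (length(tabu) > tabu_length) tabu <- tabu[seq_len(tabu_length)]
    if (current_score > best_score + 1e-12) {
      best_score <- current_score
      best_amat <- amat
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  out <- amat_to_dag(best_amat)
  attr(out, "score") <- best_score
  attr(out, "seed_score") <- seed_score
  out
}

#' Bootstrap edge confidence by model averaging
#'
#' Standard non-parametric bootstrap over samples: each replicate resamples
#' the panel's rows with replacement to the original size, relearns a
#' structure by [tabu_search()], and the confidence of a directed edge is
#' the fraction of replicate networks containing it. Replicate sub-seeds are
#' derived from the master seed up front, so the result is reproducible and
#' independent of execution order.
#'
#' @param data a `discretized_panel`.
#' @param seed_dag seed structure passed to every replicate (may be `NULL`).
#' @param config a [score_config()].
#' @param n_bootstrap number of replicates (default 100).
#' @param seed master integer seed.
#' @param ... further arguments passed to [tabu_search()].
#' @return an `edge_confidence` object: a node x node frequency matrix
#'   `freq` plus `n_bootstrap`.
#' @export
bootstrap_edge_confidence <- function(data, seed_dag = NULL,
                                      config = score_config(),
                                      n_bootstrap = 100L, seed = 1L, ...) {
  stopifnot(inherits(data, "discretized_panel"))
  if (n_bootstrap < 1L) stop("n_bootstrap must be >= 1")
  nodes <- colnames(data$states)
  counts <- matrix(0, length(nodes), length(nodes),
                   dimnames = list(nodes, nodes))
  n <- nrow(data$states)
  seeds <- derive_seeds(seed, n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    rows <- withr::with_seed(seeds[b],
                             sample.int(n, n, replace = TRUE))
    boot <- new_discretized_panel(data$states[rows, , drop = FALSE],
                                  data$n_bins)
    g <- tabu_search(boot, seed_dag = seed_dag, config = config, ...)
    if (nrow(g$edges) > 0L) counts[g$edges] <- counts[g$edges] + 1
  }
  structure(list(freq = counts / n_bootstrap,
                 n_bootstrap = as.integer(n_bootstrap)),
            class = "edge_confidence")
}

#' @export
print.edge_confidence <- function(x, ...) {
  cat("Bootstrap edge confidence over", x$n_bootstrap, "replicates;",
      sum(x$freq > 0), "edges ever seen\n")
  invisible(x)
}

#' Threshold a bootstrap-averaged network
#'
#' Keeps exactly the directed edges whose bootstrap confidence reaches the
#' threshold (default 0.9, the high-stringency cut). Model averaging can in
#' principle retain a directed cycle; if so, the lowest-confidence edge on
#' each remaining cycle (ties broken lexicographically by parent then
#' child) is dropped until the result is acyclic.
#'
#' @param confidences an `edge_confidence`.
#' @param threshold minimum confidence in (0, 1\] (default 0.9).
#' @return a `bn_dag` with a `confidence` attribute: a data frame of the
#'   kept edges and their confidences.
#' @export
threshold_network <- function(confidences, threshold = 0.9) {
  stopifnot(inherits(confidences, "edge_confidence"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  freq <- confidences$freq
  keep <- freq >= threshold
  repeat {
    cyc <- find_cycle(keep)
    if (is.null(cyc)) break
    conf <- freq[cyc]
    drop <- cyc[order(conf, cyc[, 1L], cyc[, 2L])[1L], , drop = FALSE]
    keep[drop] <- FALSE
  }
  dag <- amat_to_dag(keep)
  if (nrow(dag$edges) > 0L) {
    attr(dag, "confidence") <- data.frame(
      parent = dag$edges[, 1L], child = dag$edges[, 2L],
      confidence = freq[dag$edges])
  } else {
    attr(dag, "confidence") <- data.frame(parent = character(0),
                                          child = character(0),
                                          confidence = numeric(0))
  }
  dag
}

# one directed cycle of a logical adjacency matrix as an edge matrix, or
# NULL when acyclic; deterministic DFS in node order
find_cycle <- function(amat) {
  nodes <- rownames(amat)
  state <- structure(rep(0L, length(nodes)), names = nodes)
  parent <- structure(rep(NA_character_, length(nodes)), names = nodes)
  found <- NULL
  dfs <- function(v) {
    state[v] <<- 1L
    for (w in nodes[amat[v, ]]) {
      if (!is.null(found)) return()
      if (state[w] == 1L) {
        path <- v
        u <- v
        while (u != w) { u <- parent[[u]]; path <- c(u, path) }
        # path runs w, ..., v; the cycle closes with the edge v -> w
        found <<- cbind(parent = path, child = c(path[-1L], w))
        return()
      } else if (state[w] == 0L) {
        parent[w] <<- v
        dfs(w)
      }
    }
    state[v] <<- 2L
  }
  for (v in nodes) {
    if (!is.null(found)) break
    if (state[v] == 0L) dfs(v)
  }
  found
}
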