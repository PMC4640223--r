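#' Directed-edge confusion counts between two networks
#'
#' Classifies every slot of an edge universe over the shared node set: TP =
#' edges present in both networks, FP = in the test network only, FN = in
#' the truth network only, TN = the remaining slots. The universe convention
#' is explicit because published totals differ: `"directed"` counts the
#' n(n-1) ordered pairs without self-loops (the default), `"directed-self"`
#' all n^2 ordered pairs, and `"undirected"` the n(n-1)/2 unordered pairs,
#' under which edges are compared as adjacencies regardless of direction.
#'
#' @param test the network under evaluation (`bn_dag`).
#' @param truth the network taken as the standard of truth (`bn_dag`).
#' @param universe `"directed"`, `"directed-self"` or `"undirected"`.
#' @param nodes node-universe policy: `"union"` (default) or
#'   `"intersection"` of the two node sets, or an explicit character vector.
#' @return a `comparison_result`: list with counts `TP`, `FP`, `FN`, `TN`,
#'   the metrics from [confusion_metrics()], `universe` and `node_universe`.
#' @export
edge_confusion <- function(test, truth,
                           universe = c("directed", "directed-self",
                                        "undirected"),
                           nodes = "union") {
  universe <- match.arg(universe)
  shared <- if (identical(nodes, "union")) {
    union(test$nodes, truth$nodes)
  } else if (identical(nodes, "intersection")) {
    intersect(test$nodes, truth$nodes)
  } else as.character(nodes)
  if (length(shared) == 0L) stop("empty shared node universe")
  n <- length(shared)
  restrict <- function(g) {
    e <- g$edges
    e[e[, 1L] %in% shared & e[, 2L] %in% shared, , drop = FALSE]
  }
  canon <- function(e) {
    if (universe == "undirected" && nrow(e) > 0L) {
      e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    }
    unique(paste(e[, 1L], e[, 2L], sep = "\r"))
  }
  a <- canon(restrict(test))
  b <- canon(restrict(truth))
  total <- switch(universe,
                  directed = n * (n - 1L),
                  `directed-self` = n * n,
                  undirected = n * (n - 1L) / 2L)
  tp <- length(intersect(a, b))
  fp <- length(setdiff(a, b))
  fn <- length(setdiff(b, a))
  tn <- total - tp - fp - fn
  metrics <- confusion_metrics(tp, fp, fn, tn)
  structure(c(list(TP = tp, FP = fp, FN = fn, TN = tn), metrics,
              list(universe = universe, node_universe = shared)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Edge confusion (%s universe, %d nodes): TP=%d FP=%d FN=%d TN=%d\n",
              x$universe, length(x$node_universe), x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("  specificity %.3f  sensitivity %.3f  F-score %.3f\n",
              x$specificity, x$sensitivity, x$f_score))
  invisible(x)
}

#' Specificity, sensitivity and F-score from confusion counts
#'
#' Computes specificity = TN / (TN + FP), sensitivity = TP / (TP + FN) and
#' F-score = 2 * specificity * sensitivity / (specificity + sensitivity) on
#' the unrounded ratios. A zero denominator leaves the affected ratio (and
#' the F-score) undefined (`NA`); when both ratios are zero the F-score is
#' defined as 0.
#'
#' @param TP,FP,FN,TN non-negative counts.
#' @return list with `specificity`, `sensitivity`, `f_score`.
#' @export
confusion_metrics <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  spec <- if (TN + FP == 0) NA_real_ else TN / (TN + FP)
  sens <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  f <- if (is.na(spec) || is.na(sens)) {
    NA_real_
  } else if (spec + sens == 0) {
    0
  } else {
    2 * spec * sens / (spec + sens)
  }
  list(specificity = spec, sensitivity = sens, f_score = f)
}

#' Parent-category network complexity
#'
#' A node with k parents whose category counts are c_1, ..., c_k has
#' complexity c_1 * c_2 * ... * c_k (the node's own category count does not
#' enter; an orphan's empty product is 1), and the network's total
#' complexity is the sum over nodes. This counts the parent configurations
#' each conditional table must cover, so it grows with both connectivity
#' and categorization.
#'
#' @param dag a `bn_dag`.
#' @param categories per-node category counts: a single integer applied to
#'   all nodes (default 3) or a named vector covering every node; all
#'   counts >= 2.
#' @return a `complexity_report`: data frame (node, n_parents, complexity)
#'   with attribute `total`.
#' @export
network_complexity <- function(dag, categories = 3L) {
  if (length(categories) == 1L && is.null(names(categories))) {
    categories <- structure(rep(as.integer(categories), length(dag$nodes)),
                            names = dag$nodes)
  }
  missing <- setdiff(dag$nodes, names(categories))
  if (length(missing) > 0L)
    stop("missing category count for: ", paste(missing, collapse = ", "))
  if (any(categories[dag$nodes] < 2L)) stop("category counts must be >= 2")
  comp <- vapply(dag$nodes, function(v) {
    pa <- dag_parents(dag, v)
    prod(categories[pa])
  }, numeric(1))
  out <- data.frame(node = dag$nodes,
                    n_parents = vapply(dag$nodes, function(v)
                      length(dag_parents(dag, v)), integer(1)),
                    complexity = comp, row.names = NULL)
  structure(out, total = sum(comp), class = c("complexity_report",
                                              "data.frame"))
}

#' @export
print.complexity_report <- function(x, ...) {
  NextMethod()
  cat("Total network complexity:", attr(x, "total"), "\n")
  invisible(x)
}
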