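#' Directed acyclic graph over a set of named nodes
#'
#' Constructs the graph object used throughout the package to represent a
#' Bayesian network structure: an ordered node set plus a set of directed
#' edges (parent, child). The constructor validates acyclicity, rejects
#' self-loops and duplicate edges, and stores edges in a canonical
#' (lexicographic) order so that identical structures compare identical.
#'
#' @param nodes character vector of unique node names.
#' @param edges two-column character matrix (or data frame) with columns
#'   parent, child; `NULL` or zero rows for an empty graph.
#' @return an object of class `bn_dag` with elements `nodes` and `edges`
#'   (always a two-column character matrix with columns `parent`, `child`).
#' @examples
#' g <- bn_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' dag_parents(g, "C")
#' @export
bn_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("a DAG needs at least one node")
  if (anyDuplicated(nodes)) stop("duplicate node names")
  edges <- as_edge_matrix(edges)
  if (nrow(edges) > 0L) {
    if (!all(edges %in% nodes)) {
      bad <- setdiff(unique(as.vector(edges)), nodes)
      stop("edge endpoints not in node set: ", paste(bad, collapse = ", "))
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges")
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  g <- structure(list(nodes = nodes, edges = edges), class = "bn_dag")
  if (is.null(topological_order(g))) stop("graph contains a directed cycle")
  g
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      (is.data.frame(edges) && nrow(edges) == 0L) || length(edges) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child"))))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (is.vector(edges) && length(edges) == 2L) edges <- matrix(edges, ncol = 2L)
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child")))
  edges
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("Bayesian network structure:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0L) {
    cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L]), sep = "\n")
  }
  invisible(x)
}

#' @rdname bn_dag
#' @param dag a `bn_dag`.
#' @param node node name.
#' @export
dag_parents <- function(dag, node) {
  unname(dag$edges[dag$edges[, 2L] == node, 1L])
}

#' @rdname bn_dag
#' @export
dag_children <- function(dag, node) {
  unname(dag$edges[dag$edges[, 1L] == node, 2L])
}

# logical adjacency matrix, amat[parent, child]
dag_amat <- function(dag) {
  n <- length(dag$nodes)
  a <- matrix(FALSE, n, n, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$edges) > 0L) a[dag$edges] <- TRUE
  a
}

amat_to_edges <- function(amat) {
  idx <- which(amat, arr.ind = TRUE)
  e <- cbind(parent = rownames(amat)[idx[, 1L]],
             child = colnames(amat)[idx[, 2L]])
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

amat_to_dag <- function(amat) bn_dag(rownames(amat), amat_to_edges(amat))

# Kahn's algorithm; ties broken by the node order given. Returns NULL when a
# cycle makes a full order impossible (used as the acyclicity test).
topological_order_amat <- function(amat) {
  n <- ncol(amat)
  indeg <- colSums(amat)
  order <- integer(0)
  avail <- which(indeg == 0L)
  alive <- rep(TRUE, n)
  while (length(avail) > 0L) {
    v <- avail[1L]
    order <- c(order, v)
    alive[v] <- FALSE
    ch <- which(amat[v, ])
    indeg[ch] <- indeg[ch] - 1L
    avail <- which(alive & indeg == 0L)
  }
  if (length(order) < n) return(NULL)
  order
}

#' Topological order of a DAG
#'
#' Deterministic (Kahn's algorithm, ties broken by node order) ordering with
#' every parent before its children; `NULL` if the edge set is cyclic.
#'
#' @param dag a `bn_dag` (or anything with `$nodes` and `$edges`).
#' @return character vector of node names, or `NULL` for cyclic input.
#' @export
topological_order <- function(dag) {
  amat <- local({
    n <- length(dag$nodes)
    a <- matrix(FALSE, n, n, dimnames = list(dag$nodes, dag$nodes))
    e <- dag$edges
    if (!is.null(e) && nrow(e) > 0L) a[e] <- TRUE
    a
  })
  ord <- topological_order_amat(amat)
  if (is.null(ord)) NULL else dag$nodes[ord]
}

# transitive closure by repeated boolean squaring; reach[i, j] is TRUE when a
# directed path (length >= 1) runs i -> ... -> j
amat_reachability <- function(amat) {
  r <- amat
  step <- amat
  repeat {
    step <- (step %*% amat) > 0
    new <- r | step
    if (identical(new, r)) break
    r <- new
  }
  r
}

#' Descendants of a node
#'
#' @param dag a `bn_dag`.
#' @param nodes character vector of node names.
#' @return names of all strict descendants of any node in `nodes`.
#' @export
dag_descendants <- function(dag, nodes) {
  amat <- dag_amat(dag)
  seen <- structure(rep(FALSE, length(dag$nodes)), names = dag$nodes)
  frontier <- intersect(nodes, dag$nodes)
  out <- character(0)
  while (length(frontier) > 0L) {
    ch <- unique(unlist(lapply(frontier, function(v)
      colnames(amat)[amat[v, ]]), use.names = FALSE))
    ch <- ch[!seen[ch]]
    seen[ch] <- TRUE
    out <- c(out, ch)
    frontier <- ch
  }
  setdiff(unique(out), nodes)
}
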