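#' Seed (prior-knowledge) networks
#'
#' A seed network collects literature-derived interactions among the panel
#' analytes. Edges may be directed or undirected; before it can bias
#' structure learning it must be turned into a DAG by [orient_seed_edges()]
#' and [remove_cycles()].
#'
#' @param nodes character vector: the node universe.
#' @param edges data frame (or matrix) with columns `from`, `to` and
#'   optionally logical `directed` (default `TRUE` per edge when absent).
#' @return an object of class `seed_network`.
#' @export
seed_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("seed network needs a non-empty node universe")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        directed = logical(0))
  } else {
    edges <- as.data.frame(edges)
    if (!"directed" %in% names(edges)) edges$directed <- TRUE
    edges <- data.frame(from = as.character(edges[[1L]]),
                        to = as.character(edges[[2L]]),
                        directed = as.logical(edges$directed))
    if (!all(c(edges$from, edges$to) %in% nodes))
      stop("seed edge endpoint outside the node universe")
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  }
  structure(list(nodes = nodes, edges = edges), class = "seed_network")
}

#' Orient undirected seed edges by depth-first traversal
#'
#' Undirected literature edges are given the direction in which a
#' deterministic depth-first search first traverses them; already-directed
#' edges are kept. The DFS starts from `roots` in the order given (then any
#' still-unvisited nodes in lexicographic order) and scans neighbours
#' lexicographically, so orientation is reproducible. The traversal walks the
#' undirected skeleton, so directed edges are crossed in either direction.
#' An undirected edge between two already-visited nodes is oriented away from
#' the node whose adjacency list is scanned first. The result may still
#' contain cycles contributed by pre-directed edges; pass it through
#' [remove_cycles()].
#'
#' @param seed a [seed_network()].
#' @param roots optional character vector of preferred DFS start nodes.
#' @return a `bn_dag` over the seed's node universe.
#' @export
orient_seed_edges <- function(seed, roots = NULL) {
  stopifnot(inherits(seed, "seed_network"))
  nodes <- seed$nodes
  ed <- seed$edges
  n_edge <- nrow(ed)
  oriented <- ed$directed          # TRUE once the edge has a final direction
  from <- ed$from
  to <- ed$to
  # adjacency lists over the skeleton: edge indices incident to each node
  inc <- lapply(nodes, function(v) which(from == v | to == v))
  names(inc) <- nodes
  visited <- structure(rep(FALSE, length(nodes)), names = nodes)
  starts <- unique(c(as.character(roots), sort(nodes)))
  dfs <- function(v) {
    visited[v] <<- TRUE
    for (ei in inc[[v]]) {
      w <- if (from[ei] == v) to[ei] else from[ei]
      if (!oriented[ei]) {          # first traversal orients the edge
        from[ei] <<- v
        to[ei] <<- w
        oriented[ei] <<- TRUE
      }
      if (!visited[w]) dfs(w)
    }
  }
  for (s in starts) if (!visited[s]) dfs(s)
  edges <- unique(cbind(parent = from, child = to))
  g <- remove_cycles(edges, nodes = nodes)
  g
}

#' Remove cycle-causing edges from a directed graph
#'
#' Conflicting prior-knowledge edges that close feedback cycles are dropped:
#' a depth-first search over the nodes in lexicographic order (neighbours
#' scanned lexicographically) classifies edges, and exactly the back-edges --
#' edges pointing at a node on the current recursion stack -- are removed.
#' The procedure is deterministic, and acyclic input passes unchanged.
#'
#' @param edges two-column matrix/data frame of directed edges
#'   (parent, child), or a `bn_dag`.
#' @param nodes optional node universe (defaults to the edge endpoints).
#' @return a `bn_dag`.
#' @export
remove_cycles <- function(edges, nodes = NULL) {
  if (inherits(edges, "bn_dag")) {
    nodes <- edges$nodes
    edges <- edges$edges
  }
  edges <- as_edge_matrix(edges)
  if (is.null(nodes)) nodes <- sort(unique(as.vector(edges)))
  nodes <- as.character(nodes)
  if (nrow(edges) == 0L) return(bn_dag(nodes))
  edges <- unique(edges)
  # order each node's out-edges lexicographically by child
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  out <- split(seq_len(nrow(edges)), factor(edges[, 1L], levels = nodes))
  state <- structure(rep(0L, length(nodes)), names = nodes) # 0 new 1 stack 2 done
  drop <- logical(nrow(edges))
  dfs <- function(v) {
    state[v] <<- 1L
    for (ei in out[[v]]) {
      w <- edges[ei, 2L]
      if (state[w] == 1L) {
        drop[ei] <<- TRUE            # back-edge: closes a cycle
      } else if (state[w] == 0L) {
        dfs(w)
      }
    }
    state[v] <<- 2L
  }
  for (v in sort(nodes)) if (state[v] == 0L) dfs(v)
  bn_dag(nodes, edges[!drop, , drop = FALSE])
}
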