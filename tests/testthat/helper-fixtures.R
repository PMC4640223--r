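# Fixtures built in code: small reference networks, CPT builders and an
# exhaustive DAG enumerator used as an oracle.

# five-node worked-example topology: A -> B, A -> C, B -> D, C -> D, orphan E
worked_example_dag <- function() {
  bn_dag(c("A", "B", "C", "D", "E"),
         rbind(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D")))
}

# the chain CPTs quoted in the worked example: given A low, B is high with
# probability 0.8 and C is low with probability 0.75
worked_example_cpts <- function() {
  pa <- matrix(c(0.2, 0.5, 0.3), nrow = 1)
  pb <- matrix(c(0.10, 0.10, 0.80,
                 0.30, 0.40, 0.30,
                 0.60, 0.30, 0.10), nrow = 3, byrow = TRUE)
  pc <- matrix(c(0.75, 0.15, 0.10,
                 0.20, 0.60, 0.20,
                 0.10, 0.20, 0.70), nrow = 3, byrow = TRUE)
  pd <- matrix(rep(1 / 3, 27), nrow = 9)
  pd[1, ] <- c(0.8, 0.1, 0.1)
  pd[9, ] <- c(0.05, 0.15, 0.8)
  pe <- matrix(c(0.5, 0.3, 0.2), nrow = 1)
  new_bn_cpts(list(A = list(parents = character(0), prob = pa),
                   B = list(parents = "A", prob = pb),
                   C = list(parents = "A", prob = pc),
                   D = list(parents = c("B", "C"), prob = pd),
                   E = list(parents = character(0), prob = pe)), 3L)
}

worked_example_model <- function() {
  ground_truth_model(worked_example_dag(), worked_example_cpts())
}

# every labelled DAG over the given nodes (no self-loops, no duplicates);
# exhaustive-enumeration oracle for search tests -- 3 nodes give 25
all_dags <- function(nodes) {
  pairs <- expand.grid(parent = nodes, child = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$parent != pairs$child, ]
  n_pairs <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^n_pairs - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n_pairs) - 1)))
    g <- tryCatch(bn_dag(nodes, as.matrix(pairs[sel, , drop = FALSE])),
                  error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

# marginal of one node from the joint-enumeration table
oracle_marginal <- function(joint, node, n_bins = 3L) {
  p <- vapply(0:(n_bins - 1L),
              function(s) sum(joint$prob[joint[[node]] == s]), numeric(1))
  p / sum(p)
}

# discretized panel wrapper around a plain state matrix
panel_from_states <- function(states, n_bins = 3L) {
  new_discretized_panel(states, n_bins)
}
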