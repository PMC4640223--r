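test_that("independent nodes yield the empty graph, confirmed exhaustively", {
  withr::with_seed(41, {
    st <- matrix(sample(0:2, 3 * 500, replace = TRUE), ncol = 3,
                 dimnames = list(NULL, c("A", "B", "C")))
  })
  d <- panel_from_states(st, 3L)
  cfg <- score_config(ess = 1, kappa = 1)
  space <- all_dags(c("A", "B", "C"))
  expect_length(space, 25L)
  scores <- vapply(space, network_score, numeric(1), data = d, config = cfg)
  best <- space[[which.max(scores)]]
  expect_identical(nrow(best$edges), 0L)
  learned <- tabu_search(d, config = cfg)
  expect_identical(nrow(learned$edges), 0L)
})

test_that("a planted dependent pair is recovered as an adjacency", {
  withr::with_seed(42, {
    a <- sample(0:2, 500, replace = TRUE)
    b <- ifelse(stats::runif(500) < 0.9, a, sample(0:2, 500, replace = TRUE))
  })
  d <- panel_from_states(cbind(A = a, B = b), 3L)
  learned <- tabu_search(d, config = score_config(kappa = 1))
  expect_identical(nrow(learned$edges), 1L)
  expect_setequal(as.vector(learned$edges), c("A", "B"))

  # the seed prior splits the score-equivalent orientations
  seed_dag <- bn_dag(c("A", "B"), rbind(c("A", "B")))
  oriented <- tabu_search(d, seed_dag = seed_dag,
                          config = score_config(kappa = 0.5))
  expect_identical(unname(oriented$edges), cbind("A", "B"))
})

test_that("search output never scores below the seed structure", {
  for (seed in 1:5) {
    g_data <- sample_random_dag(5, 2, 0.4, seed = seed)
    m <- ground_truth_model(g_data, strong_cpts(g_data))
    d <- sample_discrete_records(m, 120, seed = seed + 100)
    seed_dag <- sample_random_dag(5, 2, 0.3, seed = seed + 200,
                                  nodes = g_data$nodes)
    out <- tabu_search(d, seed_dag = seed_dag, config = score_config())
    expect_gte(attr(out, "score"), attr(out, "seed_score") - 1e-9)
    expect_true(all(table(out$edges[, 2]) <= 3))   # parent cap respected
  }
  expect_error(tabu_search(panel_from_states(cbind(A = 0L), 3L),
                           max_iterations = 0), "positive")
})

test_that("tabu search attains the exhaustive optimum on three-node spaces", {
  nodes <- c("A", "B", "C")
  space <- all_dags(nodes)
  cfg <- score_config(ess = 1, kappa = 1)
  for (i in c(1, 7, 14, 21, 25)) {     # a spread of generating structures
    truth <- space[[i]]
    m <- ground_truth_model(truth, strong_cpts(truth))
    d <- sample_discrete_records(m, 150, seed = 500 + i)
    best <- max(vapply(space, network_score, numeric(1),
                       data = d, config = cfg))
    learned <- tabu_search(d, config = cfg)
    expect_equal(network_score(learned, d, config = cfg), best,
                 tolerance = 1e-9)
  }
})

test_that("bootstrap confidences are frequencies over relearned replicates", {
  withr::with_seed(43, {
    a <- sample(0:2, 200, replace = TRUE)
    b <- ifelse(stats::runif(200) < 0.95, a, sample(0:2, 200, replace = TRUE))
    u <- sample(0:2, 200, replace = TRUE)
    v <- sample(0:2, 200, replace = TRUE)
  })
  d <- panel_from_states(cbind(A = a, B = b), 3L)

  # single replicate: confidences can only be 0 or 1
  one <- bootstrap_edge_confidence(d, n_bootstrap = 1, seed = 7)
  expect_true(all(one$freq %in% c(0, 1)))

  # strong pair with an orienting seed prior: high confidence for A -> B
  seed_dag <- bn_dag(c("A", "B"), rbind(c("A", "B")))
  conf <- bootstrap_edge_confidence(d, seed_dag = seed_dag,
                                    config = score_config(kappa = 0.5),
                                    n_bootstrap = 30, seed = 8)
  expect_gte(conf$freq["A", "B"], 0.9)

  # independent pair: nothing sticks
  d_ind <- panel_from_states(cbind(U = u, V = v), 3L)
  conf_ind <- bootstrap_edge_confidence(d_ind, n_bootstrap = 30, seed = 9)
  expect_lte(max(conf_ind$freq), 0.2)

  # reproducible under a fixed master seed
  again <- bootstrap_edge_confidence(d, seed_dag = seed_dag,
                                     config = score_config(kappa = 0.5),
                                     n_bootstrap = 30, seed = 8)
  expect_identical(conf$freq, again$freq)
})

test_that("thresholding keeps exactly the confident edges and stays acyclic", {
  mk <- function(entries, nodes) {
    f <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (e in entries) f[e[[1]], e[[2]]] <- e[[3]]
    structure(list(freq = f, n_bootstrap = 100L), class = "edge_confidence")
  }
  conf <- mk(list(list("A", "B", 0.95), list("B", "C", 0.89)),
             c("A", "B", "C"))
  g <- threshold_network(conf, 0.9)
  expect_identical(unname(g$edges), cbind("A", "B"))
  expect_equal(attr(g, "confidence")$confidence, 0.95)

  # full keep at threshold met everywhere
  conf1 <- mk(list(list("A", "B", 1), list("B", "C", 1)), c("A", "B", "C"))
  expect_identical(nrow(threshold_network(conf1, 0.9)$edges), 2L)

  # two-cycle above threshold: the lower-confidence edge is dropped
  conf2 <- mk(list(list("A", "B", 0.95), list("B", "A", 0.92)), c("A", "B"))
  g2 <- threshold_network(conf2, 0.9)
  expect_identical(unname(g2$edges), cbind("A", "B"))

  expect_error(threshold_network(conf, 1.01), "in \\(0, 1\\]")
})
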