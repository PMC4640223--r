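test_that("random DAGs are acyclic, capped and reproducible", {
  g1 <- sample_random_dag(1, max_parents = 3, edge_density = 1, seed = 7)
  expect_identical(nrow(g1$edges), 0L)

  g0 <- sample_random_dag(5, max_parents = 0, edge_density = 1, seed = 7)
  expect_identical(nrow(g0$edges), 0L)

  expect_error(sample_random_dag(0), ">= 1")

  # acyclicity and parent cap verified node by node via the topological
  # order (parents must all precede their children)
  g <- sample_random_dag(26, max_parents = 3, edge_density = 0.15, seed = 1,
                         nodes = cytokine_analytes())
  ord <- topological_order(g)
  expect_false(is.null(ord))
  pos <- structure(match(g$nodes, ord), names = g$nodes)
  for (v in g$nodes) {
    pa <- dag_parents(g, v)
    expect_lte(length(pa), 3L)
    if (length(pa) > 0) expect_true(all(pos[pa] < pos[v]))
  }

  g_again <- sample_random_dag(26, max_parents = 3, edge_density = 0.15,
                               seed = 1, nodes = cytokine_analytes())
  expect_identical(g$edges, g_again$edges)
})

test_that("sampled CPTs are normalized with one row per parent configuration", {
  g <- worked_example_dag()
  cp <- sample_cpts(g, n_bins = 3, concentration = 1, seed = 3)
  expect_identical(nrow(cp$tables$A$prob), 1L)   # orphan
  expect_identical(nrow(cp$tables$D$prob), 9L)   # two 3-state parents
  for (v in g$nodes) {
    expect_equal(rowSums(cp$tables[[v]]$prob),
                 rep(1, nrow(cp$tables[[v]]$prob)))
  }
  expect_error(sample_cpts(g, n_bins = 1), ">= 2")

  # symmetric Dirichlet mean: rows approach uniform as concentration grows
  cp_flat <- sample_cpts(g, n_bins = 3, concentration = 1e6, seed = 3)
  expect_equal(as.vector(cp_flat$tables$D$prob),
               rep(1 / 3, 27), tolerance = 0.02)
})

test_that("strong CPTs are peaked, normalized and parent-sensitive", {
  g <- bn_dag(c("P1", "P2", "C"), rbind(c("P1", "C"), c("P2", "C")))
  cp <- strong_cpts(g, peak = 0.9)
  expect_equal(rowSums(cp$tables$C$prob), rep(1, 9))
  expect_true(all(apply(cp$tables$C$prob, 1, max) >= 0.8))
  # both-low row peaks low, both-high row peaks high
  expect_identical(which.max(cp$tables$C$prob[1, ]), 1L)
  expect_identical(which.max(cp$tables$C$prob[9, ]), 3L)
})

test_that("ancestral sampling is deterministic and matches the CPTs", {
  # deterministic chain: all mass propagates
  g <- bn_dag(c("A", "B"), rbind(c("A", "B")))
  pb <- diag(3)  # P(B = s | A = s) = 1
  cp <- new_bn_cpts(list(A = list(parents = character(0),
                                  prob = matrix(c(0, 0, 1), 1)),
                         B = list(parents = "A", prob = pb)), 3L)
  m <- ground_truth_model(g, cp)
  d <- sample_discrete_records(m, 50, seed = 4)
  expect_true(all(d$states[, "A"] == 2L))
  expect_true(all(d$states[, "B"] == 2L))

  # orphan frequencies converge to the planted distribution
  g1 <- bn_dag("A")
  cp1 <- new_bn_cpts(list(A = list(parents = character(0),
                                   prob = matrix(c(0.2, 0.3, 0.5), 1))), 3L)
  m1 <- ground_truth_model(g1, cp1)
  d1 <- sample_discrete_records(m1, 10000, seed = 5)
  freq <- tabulate(d1$states[, "A"] + 1L, 3) / 10000
  expect_equal(freq, c(0.2, 0.3, 0.5), tolerance = 0.02)

  expect_identical(sample_discrete_records(m1, 100, seed = 6)$states,
                   sample_discrete_records(m1, 100, seed = 6)$states)
  expect_error(sample_discrete_records(m1, 0), ">= 1")
})

test_that("sampling frequencies agree with exact marginals on the worked example", {
  m <- worked_example_model()
  d <- sample_discrete_records(m, 10000, seed = 8)
  marg <- exact_marginals(m$dag, m$cpts)
  for (v in m$dag$nodes) {
    freq <- tabulate(d$states[, v] + 1L, 3) / 10000
    se <- sqrt(marg[v, ] * (1 - marg[v, ]) / 10000)
    expect_true(all(abs(freq - marg[v, ]) <= 3 * se + 1e-12))
  }
})

test_that("emission is truncated, exact at zero scale, and invertible", {
  g <- bn_dag("A")
  cp <- new_bn_cpts(list(A = list(parents = character(0),
                                  prob = matrix(rep(1 / 3, 3), 1))), 3L)

  # zero scale: values equal bin locations exactly
  m0 <- ground_truth_model(g, cp, emission = list(
    A = list(locations = c(10, 100, 1000), scales = c(0, 0, 0))))
  d <- sample_discrete_records(m0, 30, seed = 9)
  p0 <- emit_continuous_panel(d, m0, seed = 10)
  expect_identical(unname(p0$values[, "A"]),
                   c(10, 100, 1000)[d$states[, "A"] + 1L])

  # tight locations near zero: truncation keeps the panel non-negative
  mt <- ground_truth_model(g, cp, emission = list(
    A = list(locations = c(0.1, 1, 2), scales = c(5, 5, 5))))
  pt <- emit_continuous_panel(sample_discrete_records(mt, 500, seed = 11),
                              mt, seed = 12)
  expect_gte(min(pt$values), 0)

  # balanced planted states, well-separated locations: equal-frequency
  # re-discretization recovers the planted states
  m1 <- ground_truth_model(g, cp, emission = list(
    A = list(locations = c(10, 100, 1000), scales = c(1, 1, 1))))
  balanced <- new_discretized_panel(
    matrix(rep(0:2, each = 100), ncol = 1, dimnames = list(NULL, "A")), 3L)
  p1 <- emit_continuous_panel(balanced, m1, seed = 13)
  redisc <- discretize_equal_frequency(p1$values, n_bins = 3)
  expect_gte(mean(redisc$states == balanced$states), 0.99)

  # missing emission is a configuration error
  expect_error(ground_truth_model(g, cp, emission = list()), "missing emission")
  expect_error(ground_truth_model(g, cp, emission = list(
    A = list(locations = c(5, 4, 3), scales = c(1, 1, 1)))),
    "strictly increase")
})

test_that("round trip plant -> emit -> discretize -> learn recovers the skeleton", {
  g <- sample_random_dag(8, max_parents = 2, edge_density = 0.3, seed = 11)
  m <- ground_truth_model(g, strong_cpts(g))
  d <- sample_discrete_records(m, 500, seed = 12)
  panel <- emit_continuous_panel(d, m, seed = 13)
  disc <- discretize_equal_frequency(zscore_normalize(panel))
  learned <- tabu_search(disc, config = score_config())
  planted <- paste(pmin(g$edges[, 1], g$edges[, 2]),
                   pmax(g$edges[, 1], g$edges[, 2]))
  found <- paste(pmin(learned$edges[, 1], learned$edges[, 2]),
                 pmax(learned$edges[, 1], learned$edges[, 2]))
  expect_true(all(planted %in% found))
})

test_that("timecourse panels have the designed shape and cluster structure", {
  design <- default_lactation_design(noise_sd = 0.1)
  out <- make_timecourse_panel(design, seed = 14)
  expect_identical(nrow(out$panel$values), 53L)   # 8+8+8+7+8+7+7
  expect_identical(ncol(out$panel$values), 26L)
  expect_identical(nrow(out$summary), 26L * 7L)
  expect_true(all(c("analyte", "timepoint", "mean", "sem", "n") %in%
                  names(out$summary)))

  # cluster-mates' per-timepoint mean profiles correlate strongly
  profiles <- do.call(cbind, lapply(split(out$summary, out$summary$analyte),
                                    function(d) d$mean))
  assign <- design$cluster_assignment
  for (k in 1:3) {
    members <- names(assign)[assign == k]
    cm <- stats::cor(profiles[, members])
    expect_gte(min(cm), 0.8)
  }

  # zero noise: a flat profile gives identical replicate values, hence
  # per-timepoint means constant across the course (no heterogeneity)
  flat <- timecourse_design(1:4, rep(3L, 4),
                            list(rep(0.5, 4)),
                            structure(1L, names = "X"), noise_sd = 0)
  out_flat <- make_timecourse_panel(flat,
                                    amplitudes = c(X = 100), seed = 15)
  expect_equal(diff(range(out_flat$panel$values)), 0)

  expect_error(timecourse_design(1:4, rep(3L, 4), list(rep(0.5, 3)),
                                 structure(1L, names = "X")),
               "one value per timepoint")
})
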