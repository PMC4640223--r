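test_that("joint enumeration multiplies CPT entries and sums to one", {
  # single orphan: joint equals its CPT row
  g1 <- bn_dag("A")
  cp1 <- new_bn_cpts(list(A = list(parents = character(0),
                                   prob = matrix(c(0.2, 0.3, 0.5), 1))), 3L)
  j1 <- joint_enumeration_oracle(g1, cp1)
  expect_equal(j1$prob, c(0.2, 0.3, 0.5))

  # two independent binary uniform nodes: all four joints 0.25
  g2 <- bn_dag(c("A", "B"))
  cp2 <- new_bn_cpts(list(A = list(parents = character(0),
                                   prob = matrix(c(0.5, 0.5), 1)),
                          B = list(parents = character(0),
                                   prob = matrix(c(0.5, 0.5), 1))), 2L)
  expect_equal(joint_enumeration_oracle(g2, cp2)$prob, rep(0.25, 4))

  # worked-example topology with sampled CPTs sums to 1
  g <- worked_example_dag()
  cp <- sample_cpts(g, seed = 51)
  expect_equal(sum(joint_enumeration_oracle(g, cp)$prob), 1,
               tolerance = 1e-12)

  big <- bn_dag(paste0("N", 1:20))
  expect_error(joint_enumeration_oracle(
    big, sample_cpts(big, seed = 1)), "too large")
})

test_that("variable elimination reproduces the worked example's statement", {
  m <- worked_example_model()
  res <- exact_marginals(m$dag, m$cpts, intervention_spec(c(A = 0L)))
  expect_equal(res["B", "2"], 0.8)   # P(B = high | do A = low)
  expect_equal(res["C", "0"], 0.75)  # P(C = low  | do A = low)
  expect_equal(unname(res["A", ]), c(1, 0, 0))  # point mass on forced bin
  expect_error(exact_marginals(m$dag, m$cpts, intervention_spec(c(Z = 0L))),
               "unknown node")
  expect_error(exact_marginals(m$dag, m$cpts, intervention_spec(c(A = 3L))),
               "out of range")
})

test_that("elimination agrees with the enumeration oracle, with and without do()", {
  for (seed in 1:12) {
    g <- sample_random_dag(5, 3, 0.5, seed = seed)
    cp <- sample_cpts(g, concentration = 0.8, seed = seed + 60)
    joint <- joint_enumeration_oracle(g, cp)
    base <- exact_marginals(g, cp)
    for (v in g$nodes) {
      expect_equal(unname(base[v, ]), oracle_marginal(joint, v),
                   tolerance = 1e-9)
    }
    # surgical intervention: replace the target's CPT by a point mass in
    # the oracle too (graph surgery), then compare all marginals
    target <- g$nodes[(seed %% 5) + 1]
    cp_do <- cp
    q <- nrow(cp$tables[[target]]$prob)
    pm <- matrix(0, 1, 3); pm[1, 2] <- 1
    cp_do$tables[[target]] <- list(parents = character(0), prob = pm)
    g_do <- bn_dag(g$nodes,
                   g$edges[g$edges[, 2] != target, , drop = FALSE])
    joint_do <- joint_enumeration_oracle(g_do, cp_do)
    res <- exact_marginals(g, cp, intervention_spec(c(structure(1L, names = target))))
    for (v in g$nodes) {
      expect_equal(unname(res[v, ]), oracle_marginal(joint_do, v),
                   tolerance = 1e-9)
    }
  }
})

test_that("surgical intervention leaves non-descendants untouched", {
  for (seed in 1:8) {
    g <- sample_random_dag(6, 3, 0.4, seed = seed)
    cp <- sample_cpts(g, seed = seed + 70)
    base <- exact_marginals(g, cp)
    target <- g$nodes[(seed %% 6) + 1]
    res <- exact_marginals(g, cp,
                           intervention_spec(structure(2L, names = target)))
    untouched <- setdiff(g$nodes, c(target, dag_descendants(g, target)))
    for (v in untouched) {
      expect_equal(unname(res[v, ]), unname(base[v, ]), tolerance = 1e-9)
    }
  }
})

test_that("conditioning on a root coincides with surgery on it", {
  m <- worked_example_model()
  surg <- exact_marginals(m$dag, m$cpts,
                          intervention_spec(c(A = 0L), mode = "surgical"))
  obs <- exact_marginals(m$dag, m$cpts,
                         intervention_spec(c(A = 0L), mode = "observational"))
  expect_equal(unclass(surg), unclass(obs), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("every reported marginal row is normalized", {
  g <- sample_random_dag(6, 3, 0.5, seed = 77)
  cp <- sample_cpts(g, seed = 78)
  res <- exact_marginals(g, cp, intervention_spec(c(X1 = 1L, X2 = 2L)))
  expect_equal(unname(rowSums(res)), rep(1, 6), tolerance = 1e-9)
})

test_that("qualitative labels follow the dominant-bin rule", {
  expect_identical(classify_state(c(0.1, 0.1, 0.8)), "high")
  expect_identical(classify_state(c(0.30, 0.33, 0.37)), "moderately high")
  expect_identical(classify_state(c(0.4, 0.4, 0.2)), "medium")
  expect_identical(classify_state(c(0.6, 0.3, 0.1)), "low")
  expect_identical(classify_state(c(0.45, 0.2, 0.35)), "moderately low")
})

test_that("perturbation tables report baseline and scenario marginals", {
  m <- worked_example_model()
  tab <- perturbation_table(m$dag, m$cpts,
                            scenarios = list("-A" = intervention_spec(c(A = 0L))))
  expect_identical(nrow(tab), 10L)   # 5 nodes x (baseline + 1 scenario)
  expect_true(all(c("node", "scenario", "P_low", "P_medium", "P_high",
                    "label") %in% names(tab)))
  expect_equal(tab$P_high[tab$node == "B" & tab$scenario == "-A"], 0.8)
  rs <- rowSums(tab[, c("P_low", "P_medium", "P_high")])
  expect_equal(rs, rep(1, 10), tolerance = 1e-9)

  # forcing nodes to their modal states leaves ancestors at baseline
  base <- exact_marginals(m$dag, m$cpts)
  modal <- which.max(base["D", ]) - 1L
  tab2 <- perturbation_table(m$dag, m$cpts,
                             scenarios = list(s = intervention_spec(
                               structure(modal, names = "D"))))
  for (v in c("A", "B", "C", "E")) {
    expect_equal(unlist(tab2[tab2$node == v & tab2$scenario == "s",
                             c("P_low", "P_medium", "P_high")],
                        use.names = FALSE),
                 unname(base[v, ]), tolerance = 1e-9)
  }
  expect_error(perturbation_table(m$dag, m$cpts, scenarios = list(),
                                  baseline = FALSE), "nothing to report")
})

test_that("a collider child can respond synergistically to joint perturbation", {
  g <- bn_dag(c("P1", "P2", "C"), rbind(c("P1", "C"), c("P2", "C")))
  # child is high only when both parents are high
  prob <- matrix(rep(c(0.8, 0.15, 0.05), 9), ncol = 3, byrow = TRUE)
  prob[9, ] <- c(0.05, 0.15, 0.8)
  cp <- new_bn_cpts(list(P1 = list(parents = character(0),
                                   prob = matrix(rep(1 / 3, 3), 1)),
                         P2 = list(parents = character(0),
                                   prob = matrix(rep(1 / 3, 3), 1)),
                         C = list(parents = c("P1", "P2"), prob = prob)), 3L)
  single1 <- exact_marginals(g, cp, intervention_spec(c(P1 = 2L)))["C", "2"]
  single2 <- exact_marginals(g, cp, intervention_spec(c(P2 = 2L)))["C", "2"]
  joint <- exact_marginals(g, cp,
                           intervention_spec(c(P1 = 2L, P2 = 2L)))["C", "2"]
  expect_gt(joint, single1 + 0.1)
  expect_gt(joint, single2 + 0.1)
})
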