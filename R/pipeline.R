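#' Pipeline configuration
#'
#'
#' Bundles every tunable of the end-to-end analysis with the study's
#' standard defaults: 3 equal-frequency bins, Dirichlet equivalent sample
#' size 1, seed-prior strength 0.5, at most 3 parents per node during
#' search, 100 bootstrap replicates thresholded at confidence 0.9, directed
#' edge universe for comparisons, and FDR level 0.05 for the trend test.
#'
#' @param n_bins category bins per analyte (default 3).
#' @param ess Dirichlet equivalent sample size (default 1).
#' @param kappa seed-prior factor per differing edge, in (0, 1\] (default 0.5).
#' @param max_parents in-degree cap during search (default 3).
#' @param tabu_length tabu list length (default 10).
#' @param max_iterations Tabu step cap (default 1000).
#' @param patience non-improving steps before stopping (default 100).
#' @param n_bootstrap bootstrap replicates (default 100).
#' @param threshold bootstrap confidence threshold in (0, 1\] (default 0.9).
#' @param universe edge-universe convention for comparisons.
#' @param alpha FDR level (default 0.05).
#' @param seed master integer seed (default 1).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_bins = 3L, ess = 1, kappa = 0.5,
                            max_parents = 3L, tabu_length = 10L,
                            max_iterations = 1000L, patience = 100L,
                            n_bootstrap = 100L, threshold = 0.9,
                            universe = c("directed", "directed-self",
                                         "undirected"),
                            alpha = 0.05, seed = 1L) {
  universe <- match.arg(universe)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (n_bootstrap < 1L) stop("n_bootstrap must be >= 1")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  score <- score_config(ess = ess, kappa = kappa, max_parents = max_parents)
  structure(list(n_bins = as.integer(n_bins), score = score,
                 tabu_length = as.integer(tabu_length),
                 max_iterations = as.integer(max_iterations),
                 patience = as.integer(patience),
                 n_bootstrap = as.integer(n_bootstrap),
                 threshold = threshold, universe = universe, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full network-learning pipeline
#'
#' Executes normalize -> discretize -> learn (bootstrap Tabu search) ->
#' threshold -> fit CPTs on a continuous panel, optionally biased by a seed
#' network, and writes the artifacts (learned network TSV with confidences,
#' CPT JSON, baseline-marginal DOT rendering) into `out_dir`. Every file is
#' stamped with the configuration hash and master seed, and re-running with
#' the same inputs and seed reproduces the outputs byte for byte.
#'
#' @param panel an `analyte_panel` or path to a panel CSV.
#' @param seed_net optional [seed_network()], `bn_dag`, or path to a seed
#'   TSV; undirected seed edges are oriented and cycle-causing edges
#'   removed before learning.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return invisibly, a list with the discretized panel, the seed DAG, the
#'   `edge_confidence` map, the thresholded `network`, its fitted `cpts`
#'   and baseline `marginals`.
#' @export
run_pipeline <- function(panel, seed_net = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(panel)) panel <- read_panel(panel)
  stopifnot(inherits(panel, "analyte_panel"))
  if (is.character(seed_net)) seed_net <- read_seed_network(seed_net)
  seed_dag <- if (is.null(seed_net)) {
    bn_dag(panel$analyte_names)
  } else if (inherits(seed_net, "seed_network")) {
    full <- seed_network(union(seed_net$nodes, panel$analyte_names),
                         seed_net$edges)
    orient_seed_edges(full)
  } else if (inherits(seed_net, "bn_dag")) {
    bn_dag(union(seed_net$nodes, panel$analyte_names), seed_net$edges)
  } else stop("seed_net must be a seed_network, bn_dag or file path")

  z <- zscore_normalize(panel)
  disc <- discretize_equal_frequency(z, n_bins = config$n_bins)
  conf <- bootstrap_edge_confidence(disc, seed_dag = seed_dag,
                                    config = config$score,
                                    n_bootstrap = config$n_bootstrap,
                                    seed = config$seed,
                                    tabu_length = config$tabu_length,
                                    max_iterations = config$max_iterations,
                                    patience = config$patience)
  network <- threshold_network(conf, threshold = config$threshold)
  cpts <- fit_cpts(network, disc, config$score)
  marginals <- exact_marginals(network, cpts)
  result <- list(discretized = disc, seed_dag = seed_dag, confidences = conf,
                 network = network, cpts = cpts, marginals = marginals)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- list(config = config_hash(config), seed = config$seed)
    write_network(network, file.path(out_dir, "network.tsv"),
                  provenance = prov)
    write_cpts(cpts, file.path(out_dir, "cpts.json"))
    utils::write.csv(
      data.frame(parent = rep(rownames(conf$freq), ncol(conf$freq)),
                 child = rep(colnames(conf$freq),
                             each = nrow(conf$freq)),
                 confidence = as.vector(conf$freq))[
                   as.vector(conf$freq) > 0, ],
      file.path(out_dir, "edge_confidence.csv"), row.names = FALSE,
      quote = FALSE)
    export_dot(network, file.path(out_dir, "network.dot"),
               marginals = marginals, threshold = config$threshold)
  }
  invisible(result)
}
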