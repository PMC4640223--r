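#' The serum analyte panel measured in the lactation study design
#'
#' Names for the 23 cytokines plus prolactin (PRL), estradiol (E2) and
#' progesterone (P4) that make up a 26-analyte serum panel; used as default
#' node names by the synthetic generator. Greek letters and subscripts are
#' transliterated to plain ASCII.
#'
#' @return character vector of 26 analyte names.
#' @export
cytokine_analytes <- function() {
  c("IL-1a", "IL-1b", "IL-2", "IL-3", "IL-4", "IL-5", "IL-6", "IL-9",
    "IL-10", "IL-12p40", "IL-12p70", "IL-13", "IL-17", "Eotaxin", "G-CSF",
    "GM-CSF", "IFN-g", "KC", "MCP-1", "MIP-1a", "MIP-1b", "RANTES", "TNF-a",
    "E2", "P4", "PRL")
}

# master seed -> k reproducible sub-seeds, all < 2^31; replicate sub-seeds
# are drawn up front so consumers are order-independent
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(2147483646L, k))
}

#' Sample a random DAG with bounded in-degree
#'
#' Draws a uniformly random topological order, then includes each
#' earlier-node -> later-node edge independently with probability
#' `edge_density`, trimming each node's parent set to at most `max_parents`
#' (a uniformly chosen subset when over the cap). Identical seeds give
#' identical graphs.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param max_parents in-degree cap (default 3, the conventional cap for
#'   categorical network learning).
#' @param edge_density probability in \[0, 1\] of each admissible edge.
#' @param seed integer seed.
#' @param nodes optional node names (default `"X1"`, `"X2"`, ...;
#'   [cytokine_analytes()] is a natural choice for 26 nodes).
#' @return a `bn_dag`.
#' @export
sample_random_dag <- function(n_nodes, max_parents = 3L, edge_density = 0.15,
                              seed = 1L, nodes = NULL) {
  if (!is.numeric(n_nodes) || n_nodes < 1L) stop("n_nodes must be >= 1")
  if (max_parents < 0L) stop("max_parents must be >= 0")
  if (edge_density < 0 || edge_density > 1) stop("edge_density must be in [0, 1]")
  n_nodes <- as.integer(n_nodes)
  if (is.null(nodes)) nodes <- paste0("X", seq_len(n_nodes))
  stopifnot(length(nodes) == n_nodes)
  withr::with_seed(seed, {
    ord <- sample(nodes)
    edges <- NULL
    if (n_nodes >= 2L && max_parents > 0L) {
      for (i in 2:n_nodes) {
        cand <- ord[seq_len(i - 1L)]
        sel <- cand[stats::runif(length(cand)) < edge_density]
        if (length(sel) > max_parents)
          sel <- sample(sel, max_parents)
        if (length(sel) > 0L)
          edges <- rbind(edges, cbind(sel, ord[i]))
      }
    }
    bn_dag(nodes, edges)
  })
}

#' Sample conditional probability tables for a DAG
#'
#' Each node receives one probability row per joint parent configuration,
#' drawn from a symmetric Dirichlet with the given concentration parameter.
#' Large concentrations shrink rows toward the uniform distribution; small
#' ones give near-deterministic rows.
#'
#' @param dag a `bn_dag`.
#' @param n_bins number of category bins per node (>= 2; default 3:
#'   low/medium/high).
#' @param concentration positive Dirichlet concentration per cell.
#' @param seed integer seed.
#' @return a `bn_cpts` object: per node a list with `parents` and `prob`, a
#'   q x n_bins matrix whose rows (one per parent configuration, first
#'   parent's state varying fastest) sum to 1.
#' @export
sample_cpts <- function(dag, n_bins = 3L, concentration = 1, seed = 1L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (concentration <= 0) stop("concentration must be positive")
  withr::with_seed(seed, {
    cpts <- lapply(dag$nodes, function(v) {
      parents <- dag_parents(dag, v)
      q <- n_bins^length(parents)
      g <- matrix(stats::rgamma(q * n_bins, shape = concentration), nrow = q)
      list(parents = parents, prob = g / rowSums(g))
    })
    names(cpts) <- dag$nodes
    new_bn_cpts(cpts, n_bins)
  })
}

#' Conditional probability table set
#'
#' Constructor for the CPT container used throughout the package: one entry
#' per node holding its ordered parent list and a q x n_bins probability
#' matrix with one row per joint parent configuration (first parent's state
#' varying fastest) summing to 1.
#'
#' @param cpts named list: node -> list(parents, prob).
#' @param n_bins number of category bins shared by all nodes.
#' @return an object of class `bn_cpts`.
#' @export
new_bn_cpts <- function(cpts, n_bins) {
  n_bins <- as.integer(n_bins)
  for (v in names(cpts)) {
    tab <- cpts[[v]]
    if (!is.matrix(tab$prob) || ncol(tab$prob) != n_bins ||
        nrow(tab$prob) != n_bins^length(tab$parents))
      stop("CPT for ", v, " must have one row per parent configuration ",
           "and one column per bin")
    if (any(abs(rowSums(tab$prob) - 1) > 1e-9))
      stop("CPT rows for ", v, " must sum to 1")
  }
  structure(list(tables = cpts, n_bins = n_bins), class = "bn_cpts")
}

#' @export
print.bn_cpts <- function(x, ...) {
  cat("CPT set:", length(x$tables), "nodes,", x$n_bins, "bins per node\n")
  invisible(x)
}

#' Deterministic strong CPTs for recovery benchmarks
#'
#' A preset that makes every planted edge statistically loud: for each parent
#' configuration the child's dominant state is the parents' state sum,
#' re-centred and clamped to the bin range
#' (`clamp(sum(states) - (k - 1), 0, n_bins - 1)` for k parents) -- an
#' additive activation-with-saturation rule -- and carries probability
#' `peak` (default 0.9, so row maxima are >= 0.8); remaining mass is spread
#' evenly. Each parent thereby shifts the child's distribution both
#' marginally and conditionally, so greedy edge addition can find every
#' edge, and child marginals stay near-uniform so equal-frequency re-binning
#' of emitted concentrations is approximately label-preserving. Orphan nodes
#' get uniform rows for the same reason.
#'
#' @inheritParams sample_cpts
#' @param peak dominant-state probability, in (1/n_bins, 1].
#' @return a `bn_cpts`.
#' @export
strong_cpts <- function(dag, n_bins = 3L, peak = 0.9) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  stopifnot(peak > 1 / n_bins, peak <= 1)
  cpts <- lapply(dag$nodes, function(v) {
    parents <- dag_parents(dag, v)
    np <- length(parents)
    if (np == 0L) {
      prob <- matrix(1 / n_bins, nrow = 1L, ncol = n_bins)
    } else {
      configs <- parent_config_grid(np, n_bins)   # q x np, 0-based states
      dominant <- pmin(pmax(rowSums(configs) - (np - 1L), 0L), n_bins - 1L)
      prob <- matrix((1 - peak) / (n_bins - 1L),
                     nrow = nrow(configs), ncol = n_bins)
      prob[cbind(seq_len(nrow(configs)), dominant + 1L)] <- peak
    }
    list(parents = parents, prob = prob)
  })
  names(cpts) <- dag$nodes
  new_bn_cpts(cpts, n_bins)
}

# all joint parent states as a q x np integer matrix (0-based), first parent
# varying fastest -- the row order every CPT in the package uses
parent_config_grid <- function(np, n_bins) {
  if (np == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  as.matrix(expand.grid(rep(list(0:(n_bins - 1L)), np)))
}

# row index (1-based) into a CPT for given 0-based parent states
config_index <- function(states, n_bins) {
  if (NCOL(states) == 0L) return(rep(1L, NROW(states)))
  states <- as.matrix(states)
  idx <- rep(0L, nrow(states))
  mult <- 1L
  for (j in seq_len(ncol(states))) {
    idx <- idx + states[, j] * mult
    mult <- mult * n_bins
  }
  idx + 1L
}

#' Ground-truth generative model
#'
#' Bundles a planted DAG, its CPTs and a per-analyte emission model mapping
#' category bins to continuous concentrations. The emission for bin b of an
#' analyte is a Gaussian with the given location and scale, truncated at 0
#' (concentrations are non-negative); locations must increase strictly with
#' bin index so that discretization is approximately invertible.
#'
#' @param dag a `bn_dag`.
#' @param cpts a `bn_cpts` over the same nodes.
#' @param emission named list per node: list(locations = length-B increasing
#'   numeric, scales = length-B non-negative numeric); `NULL` for the default
#'   geometric ladder from [default_emission()].
#' @param seed integer seed recorded for provenance.
#' @return an object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(dag, cpts, emission = NULL, seed = 1L) {
  stopifnot(inherits(dag, "bn_dag"), inherits(cpts, "bn_cpts"))
  if (!setequal(dag$nodes, names(cpts$tables)))
    stop("every node of the DAG needs a CPT")
  if (is.null(emission)) emission <- default_emission(dag$nodes, cpts$n_bins)
  for (v in dag$nodes) {
    em <- emission[[v]]
    if (is.null(em)) stop("missing emission model for node ", v)
    if (length(em$locations) != cpts$n_bins ||
        length(em$scales) != cpts$n_bins)
      stop("emission for ", v, " must give one location/scale per bin")
    if (any(diff(em$locations) <= 0))
      stop("emission locations must strictly increase with bin index (", v, ")")
  }
  structure(list(dag = dag, cpts = cpts, emission = emission,
                 seed = as.integer(seed)),
            class = "ground_truth_model")
}

#' @rdname ground_truth_model
#' @param nodes analyte names.
#' @param n_bins bins per analyte.
#' @param locations baseline bin concentrations shared by all analytes
#'   (default a geometric ladder 25/100/400 concentration units).
#' @param cv coefficient of variation of the within-bin emission noise
#'   (default 0.15).
#' @export
default_emission <- function(nodes, n_bins = 3L,
                             locations = 25 * 4^(seq_len(n_bins) - 1L),
                             cv = 0.15) {
  stopifnot(length(locations) == n_bins)
  em <- lapply(nodes, function(v)
    list(locations = locations, scales = cv * locations))
  names(em) <- nodes
  em
}

#' Ancestral sampling of categorical records from a ground-truth model
#'
#' Draws records parents-before-children along a topological order of the
#' planted DAG, so each node is sampled from its CPT row for the already
#' drawn parent configuration.
#'
#' @param model a [ground_truth_model()].
#' @param n_samples number of records (>= 1).
#' @param seed integer seed.
#' @return a `discretized_panel` (states in 0..n_bins-1).
#' @export
sample_discrete_records <- function(model, n_samples, seed = 1L) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  n_samples <- as.integer(n_samples)
  dag <- model$dag
  B <- model$cpts$n_bins
  ord <- topological_order(dag)
  states <- matrix(NA_integer_, nrow = n_samples, ncol = length(dag$nodes),
                   dimnames = list(NULL, dag$nodes))
  withr::with_seed(seed, {
    for (v in ord) {
      tab <- model$cpts$tables[[v]]
      if (length(tab$parents) == 0L) {
        states[, v] <- sample.int(B, n_samples, replace = TRUE,
                                  prob = tab$prob[1L, ]) - 1L
      } else {
        cfg <- config_index(states[, tab$parents, drop = FALSE], B)
        for (j in sort(unique(cfg))) {
          rows <- which(cfg == j)
          states[rows, v] <- sample.int(B, length(rows), replace = TRUE,
                                        prob = tab$prob[j, ]) - 1L
        }
      }
    }
  })
  new_discretized_panel(states, n_bins = B, bin_edges = NULL)
}

#' Emit a continuous concentration panel from planted categorical states
#'
#' Each cell's concentration is drawn from the emission distribution of its
#' planted bin: a Gaussian at the bin's location/scale truncated at zero
#' (drawn by inverse-CDF, so a zero scale returns the location exactly).
#' With well-separated locations and small scales, equal-frequency
#' re-discretization recovers the planted states with high probability.
#'
#' @param discrete a `discretized_panel` of planted states.
#' @param model the [ground_truth_model()] that produced it.
#' @param seed integer seed.
#' @return an `analyte_panel`.
#' @export
emit_continuous_panel <- function(discrete, model, seed = 1L) {
  states <- discrete$states
  nodes <- colnames(states)
  values <- matrix(NA_real_, nrow = nrow(states), ncol = ncol(states),
                   dimnames = dimnames(states))
  withr::with_seed(seed, {
    for (v in nodes) {
      em <- model$emission[[v]]
      if (is.null(em)) stop("missing emission model for node ", v)
      loc <- em$locations[states[, v] + 1L]
      sc <- em$scales[states[, v] + 1L]
      x <- loc
      pos <- sc > 0
      if (any(pos)) {
        # truncated-at-zero Gaussian via inverse CDF
        plo <- stats::pnorm(0, mean = loc[pos], sd = sc[pos])
        u <- plo + stats::runif(sum(pos)) * (1 - plo)
        x[pos] <- stats::qnorm(u, mean = loc[pos], sd = sc[pos])
      }
      values[, v] <- x
    }
  })
  analyte_panel(values)
}

#' Timecourse design for a synthetic lactation-like study
#'
#' Describes the sampling schedule (timepoint labels and replicate counts)
#' and the temporal cluster profiles: each analyte belongs to one cluster,
#' and cluster-mates share a profile of relative means over the timepoints.
#' The default mirrors a 7-timepoint lactation series (days 1, 2, 4, 10, 16,
#' 21, 24; n = 8, 8, 8, 7, 8, 7, 7, i.e. 53 samples) with three profile
#' shapes: an early peak near day 5, a saturating rise to plateau, and a
#' broad peak centred on day 10.
#'
#' @param timepoints ordered numeric or character labels.
#' @param n_per_timepoint integer replicate counts (all >= 1).
#' @param cluster_profiles list of numeric vectors, one value per timepoint.
#' @param cluster_assignment named integer vector: analyte -> cluster index.
#' @param noise_sd replicate noise standard deviation on the relative-profile
#'   scale (default 0.1, i.e. ~10% of the profile dynamic range).
#' @return an object of class `timecourse_design`.
#' @export
timecourse_design <- function(timepoints, n_per_timepoint, cluster_profiles,
                              cluster_assignment, noise_sd = 0.1) {
  stopifnot(length(timepoints) == length(n_per_timepoint),
            all(n_per_timepoint >= 1))
  for (p in cluster_profiles)
    if (length(p) != length(timepoints))
      stop("each cluster profile needs one value per timepoint")
  if (any(is.na(cluster_assignment)) ||
      any(!cluster_assignment %in% seq_along(cluster_profiles)))
    stop("every analyte needs a valid cluster assignment")
  structure(list(timepoints = timepoints,
                 n_per_timepoint = as.integer(n_per_timepoint),
                 cluster_profiles = cluster_profiles,
                 cluster_assignment = cluster_assignment,
                 noise_sd = noise_sd),
            class = "timecourse_design")
}

#' @rdname timecourse_design
#' @param analytes analyte names to assign to the three default clusters
#'   (default the 26-analyte panel, with the hormone/early cluster holding
#'   IL-9, E2, P4 and PRL as observed in the study system).
#' @export
default_lactation_design <- function(analytes = cytokine_analytes(),
                                     noise_sd = 0.1) {
  days <- c(1, 2, 4, 10, 16, 21, 24)
  profiles <- list(
    early_peak = 0.2 + 0.8 * exp(-((days - 5) / 4)^2),
    plateau = 0.2 + 0.8 * days / (days + 4),
    broad_peak = 0.2 + 0.8 * exp(-((days - 10) / 8)^2)
  )
  cluster1 <- c("IL-9", "E2", "P4", "PRL")
  cluster2 <- c("IL-1a", "IL-1b", "IL-12p40", "IL-12p70", "IL-17",
                "MIP-1b", "RANTES")
  assignment <- ifelse(analytes %in% cluster1, 1L,
                       ifelse(analytes %in% cluster2, 2L, 3L))
  names(assignment) <- analytes
  timecourse_design(days, c(8L, 8L, 8L, 7L, 8L, 7L, 7L), profiles,
                    assignment, noise_sd = noise_sd)
}

#' Generate a timecourse panel with planted temporal clusters
#'
#' Produces per-replicate continuous concentrations
#' `amplitude * (profile(t) + noise)` for each analyte, together with the
#' per-timepoint mean/SEM summary table the trend test consumes. Analytes in
#' the same cluster share a mean profile up to amplitude, so their
#' per-timepoint mean series are strongly correlated by construction.
#'
#' @param design a [timecourse_design()].
#' @param amplitudes named per-analyte positive scale factors (concentration
#'   units); default log-normal draws around 100 units.
#' @param seed integer seed.
#' @return list with `panel` (an `analyte_panel` whose sample labels are the
#'   timepoints) and `summary` (a data frame: analyte, timepoint, mean, sem,
#'   n).
#' @export
make_timecourse_panel <- function(design, amplitudes = NULL, seed = 1L) {
  stopifnot(inherits(design, "timecourse_design"))
  analytes <- names(design$cluster_assignment)
  seeds <- derive_seeds(seed, 2L)
  if (is.null(amplitudes)) {
    amplitudes <- withr::with_seed(seeds[1L],
      structure(stats::rlnorm(length(analytes), log(100), 0.8),
                names = analytes))
  }
  stopifnot(all(analytes %in% names(amplitudes)))
  tp <- rep(seq_along(design$timepoints), design$n_per_timepoint)
  n <- length(tp)
  values <- matrix(NA_real_, n, length(analytes),
                   dimnames = list(NULL, analytes))
  withr::with_seed(seeds[2L], {
    for (a in analytes) {
      prof <- design$cluster_profiles[[design$cluster_assignment[[a]]]]
      raw <- prof[tp] + stats::rnorm(n, 0, design$noise_sd)
      values[, a] <- amplitudes[[a]] * pmax(raw, 0)
    }
  })
  panel <- analyte_panel(values,
                         sample_labels = as.character(design$timepoints)[tp])
  summary <- do.call(rbind, lapply(analytes, function(a) {
    m <- tapply(values[, a], tp, mean)
    s <- tapply(values[, a], tp, stats::sd)
    nn <- as.vector(table(tp))
    data.frame(analyte = a,
               timepoint = as.character(design$timepoints),
               mean = as.vector(m), sem = as.vector(s) / sqrt(nn), n = nn)
  }))
  rownames(summary) <- NULL
  list(panel = panel, summary = summary)
}
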