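#' Continuous analyte panel
#'
#' A samples x analytes matrix of non-negative concentrations with optional
#' per-sample group/timepoint labels. Missing cells are rejected: the
#' downstream learner assumes complete records.
#'
#' @param values numeric matrix, samples in rows, analytes in columns
#'   (column names are the analyte identifiers).
#' @param sample_labels optional character vector, one label per sample.
#' @return an object of class `analyte_panel` with elements `values`,
#'   `sample_labels`, `analyte_names`.
#' @export
analyte_panel <- function(values, sample_labels = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("X", seq_len(ncol(values)))
  if (anyNA(values)) stop("panel contains missing cells")
  if (!is.numeric(values)) stop("panel values must be numeric")
  if (any(values < 0)) stop("concentrations must be non-negative")
  if (!is.null(sample_labels)) {
    sample_labels <- as.character(sample_labels)
    if (length(sample_labels) != nrow(values))
      stop("one sample label per row required")
  }
  structure(list(values = values, sample_labels = sample_labels,
                 analyte_names = colnames(values)),
            class = "analyte_panel")
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat("Analyte panel:", nrow(x$values), "samples x",
      ncol(x$values), "analytes\n")
  invisible(x)
}

#' Discretized (categorical) panel
#'
#' Integer states in `0..n_bins-1` (0 = low), one column per analyte, plus
#' the per-analyte cut points used (when known).
#'
#' @param states integer matrix of states.
#' @param n_bins number of bins.
#' @param bin_edges optional named list of increasing numeric cut points.
#' @return an object of class `discretized_panel`.
#' @export
new_discretized_panel <- function(states, n_bins, bin_edges = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (anyNA(states) || any(states < 0L) || any(states >= n_bins))
    stop("states must lie in 0..n_bins-1")
  structure(list(states = states, n_bins = as.integer(n_bins),
                 bin_edges = bin_edges),
            class = "discretized_panel")
}

#' @export
print.discretized_panel <- function(x, ...) {
  cat("Discretized panel:", nrow(x$states), "samples x",
      ncol(x$states), "analytes,", x$n_bins, "bins\n")
  invisible(x)
}

#' Z-score normalization of a panel
#'
#' Standardizes each analyte column to mean 0 and unit sample standard
#' deviation (n - 1 denominator). Constant columns, whose standard deviation
#' is zero, map to all-zero columns rather than NaN.
#'
#' @param panel an `analyte_panel` or numeric matrix.
#' @return numeric matrix of standardized values, same shape and dimnames.
#' @export
zscore_normalize <- function(panel) {
  values <- if (inherits(panel, "analyte_panel")) panel$values else as.matrix(panel)
  if (nrow(values) < 2L) stop("z-scoring needs at least 2 samples")
  ctr <- scale(values, center = TRUE, scale = FALSE)
  s <- apply(values, 2L, stats::sd)
  out <- sweep(ctr, 2L, ifelse(s > 0, s, 1), "/")
  out[, s == 0] <- 0
  dimnames(out) <- dimnames(values)
  out
}

#' Equal-frequency discretization
#'
#' Assigns each analyte's samples to `n_bins` ordered categories (0 = low)
#' so that bin occupancies differ by at most one. Assignment is rank-based:
#' with stable ranks r = 1..n (ties broken by original sample order), the
#' state is `floor((r - 1) * n_bins / n)`, which puts any occupancy deficit
#' in the highest bins and never splits a tie block across non-adjacent
#' bins. Because only ranks enter, any strictly increasing transform of a
#' column leaves its states unchanged.
#'
#' @param panel numeric matrix (typically z-scored) or `analyte_panel`.
#' @param n_bins number of bins (default 3: low/medium/high).
#' @return a `discretized_panel`; `bin_edges` holds, per analyte, the
#'   midpoints between the extreme order statistics of adjacent bins.
#' @export
discretize_equal_frequency <- function(panel, n_bins = 3L) {
  values <- if (inherits(panel, "analyte_panel")) panel$values else as.matrix(panel)
  n <- nrow(values)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (n < n_bins) stop("need at least as many samples as bins")
  states <- matrix(NA_integer_, n, ncol(values), dimnames = dimnames(values))
  edges <- vector("list", ncol(values))
  names(edges) <- colnames(values)
  for (j in seq_len(ncol(values))) {
    r <- rank(values[, j], ties.method = "first")
    st <- as.integer(floor((r - 1) * n_bins / n))
    states[, j] <- st
    srt <- sort(values[, j])
    cuts <- which(diff(st[order(r)]) > 0)        # last rank of each lower bin
    edges[[j]] <- (srt[cuts] + srt[cuts + 1L]) / 2
  }
  new_discretized_panel(states, n_bins, edges)
}

#' Pearson correlation matrix of a panel
#'
#' Pairwise product-moment correlations between analytes; the basis for the
#' correlation heat map. Correlations involving a constant (zero-variance)
#' analyte are undefined and reported as `NA`; the diagonal is 1 by
#' definition.
#'
#' @param panel an `analyte_panel` or numeric matrix with >= 3 samples.
#' @return symmetric analyte x analyte matrix with unit diagonal.
#' @export
pearson_correlation_matrix <- function(panel) {
  values <- if (inherits(panel, "analyte_panel")) panel$values else as.matrix(panel)
  if (nrow(values) < 3L) stop("correlation needs at least 3 samples")
  cm <- suppressWarnings(stats::cor(values))
  diag(cm) <- 1
  cm
}

#' Weighted-mean trend heterogeneity test
#'
#' Tests, per analyte, the null hypothesis that the mean concentration is
#' constant over the timecourse at the inverse-variance weighted mean. With
#' per-timepoint means m_t and standard errors SE_t, the weights are
#' w_t = SE_t^-2, the weighted mean is sum(w m) / sum(w) and the statistic
#' Q = sum(w_t (m_t - weighted_mean)^2) is referred to the upper tail of a
#' chi-square with T - 1 degrees of freedom. Per-timepoint z-scores
#' z_t = (m_t - weighted_mean) * sqrt(w_t) are returned alongside, and the
#' p-values are Benjamini-Hochberg adjusted across analytes.
#'
#' @param summary data frame with columns `analyte`, `timepoint`, `mean`,
#'   `sem` (as produced by [make_timecourse_panel()]); every SEM must be
#'   finite and positive.
#' @param alpha FDR level for the rejection flags (default 0.05).
#' @return data frame, one row per analyte: `analyte`, `weighted_mean`, `Q`,
#'   `df`, `p_value`, `fdr_adjusted_p`, `reject`; attribute `z_scores` holds
#'   the per-timepoint z-score matrix.
#' @export
trend_heterogeneity_test <- function(summary, alpha = 0.05) {
  stopifnot(all(c("analyte", "mean", "sem") %in% names(summary)))
  if (any(!is.finite(summary$sem)) || any(summary$sem <= 0))
    stop("every SEM must be finite and positive")
  split_rows <- split(seq_len(nrow(summary)), summary$analyte)
  res <- lapply(split_rows, function(rows) {
    m <- summary$mean[rows]
    w <- summary$sem[rows]^-2
    if (length(m) < 2L) stop("need >= 2 timepoints per analyte")
    wm <- sum(w * m) / sum(w)
    q <- sum(w * (m - wm)^2)
    z <- (m - wm) * sqrt(w)
    list(wm = wm, q = q, df = length(m) - 1L, z = z)
  })
  out <- data.frame(
    analyte = names(split_rows),
    weighted_mean = vapply(res, `[[`, numeric(1), "wm"),
    Q = vapply(res, `[[`, numeric(1), "q"),
    df = vapply(res, `[[`, integer(1), "df"),
    row.names = NULL
  )
  out$p_value <- stats::pchisq(out$Q, out$df, lower.tail = FALSE)
  bh <- benjamini_hochberg(out$p_value, alpha = alpha)
  out$fdr_adjusted_p <- bh$adjusted
  out$reject <- bh$reject
  attr(out, "z_scores") <- lapply(res, `[[`, "z")
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment over one family of p-values (delegates the
#' adjustment to [stats::p.adjust()]): the rejected set is the largest k
#' such that the k-th smallest p-value is at most k * alpha / m, together
#' with all smaller ranks, which is exactly `adjusted <= alpha`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list with `adjusted` p-values and logical `reject` flags, in the
#'   input order.
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}
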