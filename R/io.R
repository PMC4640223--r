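# Plain-text formats: CSV panels and summary tables, TSV edge lists, JSON
# CPTs, DOT rendering. Files written by the pipeline carry a provenance
# comment with a hash of the configuration so artifacts from different runs
# cannot be mixed silently.

# polynomial rolling hash of the deparsed configuration, as 8 hex digits;
# only used to detect accidental mixing of artifacts across configs
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)[sort(names(config))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read and write analyte panels
#'
#' Panels are CSV files with a header row of analyte names and an optional
#' leading `label` column carrying the group/timepoint of each sample.
#' Missing cells are a hard error: the learner requires complete records.
#'
#' @param path file path.
#' @return `read_panel()` returns an `analyte_panel`.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  labels <- NULL
  if (names(df)[1L] == "label") {
    labels <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  m <- as.matrix(df)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))
    stop("panel has missing cells (rows ", paste(bad, collapse = ", "),
         " of ", path, ")")
  }
  analyte_panel(m, sample_labels = labels)
}

#' @rdname read_panel
#' @param panel an `analyte_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "analyte_panel"))
  df <- as.data.frame(panel$values, check.names = FALSE)
  if (!is.null(panel$sample_labels))
    df <- cbind(label = panel$sample_labels, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write network edge lists
#'
#' Learned networks are TSV files `parent<TAB>child<TAB>confidence` (the
#' confidence column is optional on read and omitted when unknown), with
#' `#`-prefixed provenance comments. Self-loops are rejected on read with
#' the offending line number.
#'
#' @param path file path.
#' @param nodes optional node universe for isolated nodes.
#' @param config optional `pipeline_config`; when given and the file
#'   carries a `# config=` provenance stamp, a mismatch is refused so that
#'   artifacts from different runs cannot be mixed silently.
#' @return `read_network()` returns a `bn_dag` (with a `confidence`
#'   attribute when the file has one).
#' @export
read_network <- function(path, nodes = NULL, config = NULL) {
  lines <- readLines(path)
  if (!is.null(config)) {
    stamp <- grep("^# config=", lines, value = TRUE)
    if (length(stamp) > 0L &&
        sub("^# config=", "", stamp[1L]) != config_hash(config))
      stop("configuration mismatch: ", path,
           " was written under a different pipeline configuration")
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  df <- utils::read.delim(text = lines[keep], header = TRUE,
                          check.names = FALSE)
  if (!all(c("parent", "child") %in% names(df)))
    stop("network file needs 'parent' and 'child' columns: ", path)
  loops <- which(df$parent == df$child)
  if (length(loops) > 0L)
    stop("self-loop at data line ", loops[1L], " of ", path)
  if (is.null(nodes)) nodes <- sort(unique(c(df$parent, df$child)))
  g <- bn_dag(nodes, cbind(df$parent, df$child))
  if ("confidence" %in% names(df)) {
    ord <- order(df$parent, df$child)
    attr(g, "confidence") <- data.frame(parent = df$parent[ord],
                                        child = df$child[ord],
                                        confidence = df$confidence[ord])
  }
  g
}

#' @rdname read_network
#' @param dag a `bn_dag`.
#' @param confidences optional `edge_confidence` or data frame
#'   (parent, child, confidence); defaults to the DAG's own `confidence`
#'   attribute when present.
#' @param provenance optional named list written as `# key=value` comments.
#' @export
write_network <- function(dag, path, confidences = NULL, provenance = NULL) {
  stopifnot(inherits(dag, "bn_dag"))
  if (is.null(confidences)) confidences <- attr(dag, "confidence")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(provenance))
    writeLines(sprintf("# %s=%s", k, provenance[[k]]), con)
  e <- dag$edges
  conf <- rep(NA_real_, nrow(e))
  if (!is.null(confidences)) {
    if (inherits(confidences, "edge_confidence")) {
      if (nrow(e) > 0L) conf <- confidences$freq[e]
    } else {
      key <- paste(e[, 1L], e[, 2L])
      m <- match(key, paste(confidences$parent, confidences$child))
      conf <- confidences$confidence[m]
    }
  }
  has_conf <- !all(is.na(conf))
  writeLines(if (has_conf) "parent\tchild\tconfidence" else "parent\tchild",
             con)
  if (nrow(e) > 0L) {
    body <- if (has_conf) {
      paste(e[, 1L], e[, 2L], format(conf, trim = TRUE), sep = "\t")
    } else paste(e[, 1L], e[, 2L], sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a seed network from a TSV edge list
#'
#' Columns `from` and `to`, plus an optional logical `directed` column
#' (default TRUE). Undirected rows are oriented later by
#' [orient_seed_edges()].
#'
#' @param path file path.
#' @param nodes optional node universe (defaults to the edge endpoints).
#' @return a [seed_network()].
#' @export
read_seed_network <- function(path, nodes = NULL) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          check.names = FALSE)
  if (!all(c("from", "to") %in% names(df)))
    stop("seed file needs 'from' and 'to' columns: ", path)
  if (is.null(nodes)) nodes <- sort(unique(c(df$from, df$to)))
  seed_network(nodes, df)
}

#' Read and write CPT sets as JSON
#'
#' Each node maps to its parent list and a row-per-parent-configuration
#' probability table (first parent's state varying fastest).
#'
#' @param path file path.
#' @return `read_cpts()` returns a `bn_cpts`.
#' @export
read_cpts <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tables <- lapply(obj$nodes, function(x) {
    prob <- if (is.matrix(x$prob)) x$prob else
      matrix(unlist(x$prob), ncol = obj$n_bins, byrow = TRUE)
    parents <- as.character(unlist(x$parents))
    if (length(parents) == 0L) parents <- character(0)
    list(parents = parents, prob = unname(prob))
  })
  new_bn_cpts(tables, obj$n_bins)
}

#' @rdname read_cpts
#' @param cpts a `bn_cpts`.
#' @export
write_cpts <- function(cpts, path) {
  stopifnot(inherits(cpts, "bn_cpts"))
  nodes <- lapply(cpts$tables, function(x)
    list(parents = I(x$parents),
         prob = lapply(seq_len(nrow(x$prob)), function(i) x$prob[i, ])))
  jsonlite::write_json(list(n_bins = cpts$n_bins, nodes = nodes), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a summary table (per-analyte, per-timepoint mean/SEM) as CSV
#'
#' @param summary data frame with columns analyte, timepoint, mean, sem, n.
#' @param path file path.
#' @export
write_summary_table <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, comment.char = "#")
}

#' Export a network to Graphviz DOT
#'
#' Nodes are coloured by their qualitative marginal state (high = green,
#' low = red, medium = white, "moderately" shades lighter); edges at or
#' above the confidence threshold are green, the rest grey.
#'
#' @param dag a `bn_dag`.
#' @param path file path.
#' @param marginals optional `marginal_report` from [exact_marginals()].
#' @param confidences optional `edge_confidence` or the DAG's `confidence`
#'   attribute (used by default).
#' @param threshold confidence cut for green edges (default 0.9).
#' @return the path, invisibly.
#' @export
export_dot <- function(dag, path, marginals = NULL, confidences = NULL,
                       threshold = 0.9) {
  stopifnot(inherits(dag, "bn_dag"))
  if (is.null(confidences)) confidences <- attr(dag, "confidence")
  fill <- function(label) {
    switch(sub("^moderately ", "", label),
           high = if (grepl("^moderately", label)) "palegreen" else "green",
           low = if (grepl("^moderately", label)) "lightpink" else "red",
           "white")
  }
  lines <- c("digraph cytokine_network {", "  node [style=filled];")
  labs <- if (is.null(marginals)) NULL else attr(marginals, "labels")
  for (v in dag$nodes) {
    col <- if (is.null(labs)) "white" else fill(labs[[v]])
    lines <- c(lines, sprintf("  \"%s\" [fillcolor=%s];", v, col))
  }
  e <- dag$edges
  if (nrow(e) > 0L) {
    conf <- rep(NA_real_, nrow(e))
    if (!is.null(confidences)) {
      if (inherits(confidences, "edge_confidence")) {
        conf <- confidences$freq[e]
      } else {
        m <- match(paste(e[, 1L], e[, 2L]),
                   paste(confidences$parent, confidences$child))
        conf <- confidences$confidence[m]
      }
    }
    col <- ifelse(!is.na(conf) & conf >= threshold, "green", "grey")
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [color=%s];",
                              e[, 1L], e[, 2L], col))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
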