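# Readers and writers for the package's plain-text dialects. One canonical
# orientation throughout: time-series TSVs are rows = time, columns = nodes,
# with a header row. Numbers are written with full double precision so every
# round-trip reproduces the in-memory object to better than 1e-12.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write / read a time-series matrix as TSV
#'
#' @param mat Numeric matrix (rows = time, columns = labelled nodes).
#' @param path Output file.
#' @return `read_series_tsv` returns the numeric matrix with column names.
#' @export
write_series_tsv <- function(mat, path) {
  mat <- as.matrix(mat)
  df <- as.data.frame(apply(mat, 2, fmt_num))
  names(df) <- colnames(mat)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  as.matrix(df)
}

#' Write / read a BIDS-style events table
#'
#' Columns: `onset`, `duration`, `trial_type`, `rating`.
#'
#' @param design A `synthetic_design` or block data frame.
#' @param path Output file.
#' @param tr,n_volumes Run geometry attached on read.
#' @return `read_events_tsv` returns a `synthetic_design`.
#' @export
write_events_tsv <- function(design, path) {
  df <- as.data.frame(design)[, c("onset", "duration", "trial_type", "rating")]
  df$onset <- fmt_num(df$onset); df$duration <- fmt_num(df$duration)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path, tr, n_volumes) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_design(df, tr = tr, n_volumes = n_volumes)
}

#' Write / read a Fisher-z connectivity matrix as square TSV
#'
#' Square layout with node labels as both header row and first column.
#'
#' @param conn A `conn_matrix`.
#' @param path Output file.
#' @param condition Condition label attached on read (default from the
#'   file's sidecar-free name: `"condition"`).
#' @return `read_conn_tsv` returns a `conn_matrix`.
#' @export
write_conn_tsv <- function(conn, path) {
  stopifnot(inherits(conn, "conn_matrix"))
  z <- conn$z
  df <- data.frame(node = rownames(z), apply(z, 2, fmt_num),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conn_tsv
#' @export
read_conn_tsv <- function(path, condition = "condition") {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- df[[1]]
  z <- as.matrix(df[, -1, drop = FALSE])
  rownames(z) <- labels
  conn_matrix(z, condition = condition, node_labels = labels,
              mode = "file")
}

#' Write / read a binary graph as edge-list TSV plus sidecar
#'
#' Edge list columns `node_i`, `node_j` (labels); the sidecar
#' (`<path>.meta.yaml`) records density and the full node-label set so
#' isolated nodes survive the round trip.
#'
#' @param g A `bin_graph`.
#' @param path Output file.
#' @return `read_graph_tsv` returns a `bin_graph`.
#' @export
write_graph_tsv <- function(g, path) {
  stopifnot(inherits(g, "bin_graph"))
  idx <- which(upper.tri(g$adj) & g$adj > 0, arr.ind = TRUE)
  df <- data.frame(node_i = g$node_labels[idx[, 1]],
                   node_j = g$node_labels[idx[, 2]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(density = g$density, node_labels = g$node_labels),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  labels <- unlist(meta$node_labels)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  n <- length(labels)
  adj <- matrix(0L, n, n, dimnames = list(labels, labels))
  if (nrow(df)) {
    i <- match(df$node_i, labels); j <- match(df$node_j, labels)
    adj[cbind(i, j)] <- 1L
    adj[cbind(j, i)] <- 1L
  }
  bin_graph(adj, density = meta$density, node_labels = labels)
}

#' Write / read a long-format metric table
#'
#' @param table A `metric_table`.
#' @param path Output file.
#' @return `read_metric_table` returns a `metric_table`.
#' @export
write_metric_table <- function(table, path) {
  df <- as.data.frame(table)
  df$value <- fmt_num(df$value)
  df$density <- fmt_num(df$density)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("metric_table", "data.frame")
  df
}

#' Write a generic results data frame as TSV
#' @param df Data frame.
#' @param path Output file.
#' @export
write_results_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a provenance sidecar
#'
#' Records the configuration, master seed and package version next to a
#' command's outputs.
#'
#' @param dir Output directory.
#' @param config Named list (flat key-value configuration).
#' @param extra Optional additional named entries.
#' @export
write_provenance <- function(dir, config, extra = list()) {
  prov <- c(list(package = "netreconfig",
                 version = as.character(utils::packageVersion("netreconfig")),
                 written = "provenance"),
            config, extra)
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(file.path(dir, "provenance.yaml"))
}
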