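# Density sweep over subject x condition connectivity matrices, long-format
# metric table assembly, and per-density / pooled paired contrasts.

#' Run the density sweep over a cohort of connectivity matrices
#'
#' Thresholds every subject x condition Fisher-z matrix at each density of
#' the grid, computes the metric bundle, and assembles a long-format table.
#' The design must be complete: every subject must provide every condition.
#'
#' @param conn_by_subject Named list (one element per subject) of named
#'   lists (one `conn_matrix` per condition).
#' @param densities Density grid, strictly increasing in `(0, 1]`
#'   (default `c(0.10, 0.15, 0.20, 0.25)`).
#' @param target_nodes Node labels to profile with nodal metrics.
#' @param threshold_mode Passed to [threshold_proportional()].
#' @param fine_tune Passed to [modularity_spectral()].
#' @return Data frame of class `metric_table` with columns `subject`,
#'   `condition`, `density`, `metric`, `scope`, `value`. Global metrics get
#'   scope `"global"`; nodal metrics `"node:<label>"`.
#' @export
metric_sweep <- function(conn_by_subject,
                         densities = c(0.10, 0.15, 0.20, 0.25),
                         target_nodes = character(),
                         threshold_mode = "signed", fine_tune = TRUE) {
  validate_density_grid(densities)
  subjects <- names(conn_by_subject)
  if (is.null(subjects) || any(!nzchar(subjects)))
    stop("conn_by_subject must be a named list of subjects", call. = FALSE)
  cond_sets <- lapply(conn_by_subject, names)
  conditions <- cond_sets[[1]]
  bad <- vapply(cond_sets, function(s) !setequal(s, conditions), TRUE)
  if (any(bad))
    stop("asymmetric design: subject(s) ",
         paste(subjects[bad], collapse = ", "),
         " do not provide conditions ", paste(conditions, collapse = ", "),
         call. = FALSE)

  rows <- vector("list", length(subjects) * length(conditions) *
                   length(densities))
  r <- 0L
  for (sub in subjects) for (cond in conditions) {
    conn <- conn_by_subject[[sub]][[cond]]
    for (k in densities) {
      g <- threshold_proportional(conn, k, mode = threshold_mode)
      mb <- metric_bundle(g, target_nodes = target_nodes,
                          fine_tune = fine_tune)
      glob <- data.frame(subject = sub, condition = cond, density = k,
                         metric = names(mb$global), scope = "global",
                         value = unname(mb$global), stringsAsFactors = FALSE)
      r <- r + 1L
      if (!is.null(mb$nodes)) {
        nd <- mb$nodes
        node_rows <- do.call(rbind, lapply(seq_len(nrow(nd)), function(j)
          data.frame(subject = sub, condition = cond, density = k,
                     metric = c("betweenness", "flow", "participation",
                                "local_efficiency"),
                     scope = paste0("node:", nd$node[j]),
                     value = as.numeric(nd[j, c("betweenness", "flow",
                                                "participation",
                                                "local_efficiency")]),
                     stringsAsFactors = FALSE)))
        rows[[r]] <- rbind(glob, node_rows)
      } else rows[[r]] <- glob
    }
  }
  tbl <- do.call(rbind, rows[seq_len(r)])
  rownames(tbl) <- NULL
  class(tbl) <- c("metric_table", "data.frame")
  tbl
}

validate_density_grid <- function(densities) {
  if (!length(densities) || any(densities <= 0) || any(densities > 1))
    stop("densities must lie in (0, 1]", call. = FALSE)
  if (is.unsorted(densities, strictly = TRUE))
    stop("densities must be strictly increasing", call. = FALSE)
  invisible(densities)
}

extract_pairs <- function(table, metric, scope, condA, condB, densities) {
  sel <- table$metric == metric & table$scope == scope &
    table$density %in% densities
  a <- table[sel & table$condition == condA, c("subject", "density", "value")]
  b <- table[sel & table$condition == condB, c("subject", "density", "value")]
  m <- merge(a, b, by = c("subject", "density"), suffixes = c("_a", "_b"))
  if (!nrow(m) || nrow(m) < nrow(a) || nrow(m) < nrow(b) ||
      nrow(a) != nrow(b))
    stop("paired values missing for some subject x density cells", call. = FALSE)
  m[order(m$subject, m$density), , drop = FALSE]
}

contrast_row <- function(diffs, metric, scope, condA, condB, density_label) {
  df <- length(diffs) - 1L
  if (stats::sd(diffs) < 1e-14) {
    t_val <- NA_real_; p_val <- NA_real_; degenerate <- TRUE
  } else {
    tt <- stats::t.test(diffs)
    t_val <- unname(tt$statistic); p_val <- tt$p.value; degenerate <- FALSE
  }
  data.frame(metric = metric, scope = scope, condA = condA, condB = condB,
             density = density_label, t = t_val, df = df, p = p_val,
             direction = sign(mean(diffs)), degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Paired contrast at one density
#'
#' Classical paired-samples t-test on the per-subject differences
#' `condA - condB` of one metric at one density; two-sided p-value.
#' Zero-variance differences are flagged (`degenerate = TRUE`, t and p
#' `NA`) rather than raising an error.
#'
#' @param table A `metric_table` from [metric_sweep()].
#' @param metric Metric name (e.g. `"q"`).
#' @param scope `"global"` or `"node:<label>"`.
#' @param condA,condB Condition labels; positive t means A > B.
#' @param density Density value at which to contrast.
#' @return One-row data frame: metric, scope, condA, condB, density, t,
#'   df (`n_subjects - 1`), p, direction, degenerate.
#' @export
paired_contrast <- function(table, metric, scope, condA, condB, density) {
  m <- extract_pairs(table, metric, scope, condA, condB, density)
  contrast_row(m$value_a - m$value_b, metric, scope, condA, condB,
               as.character(density))
}

#' Pooled summary contrast across the density grid
#'
#' Collapses across all densities by pooling the subject x density
#' observations as exchangeable pairs and running one paired t-test, so a
#' 14-subject, 4-density sweep yields df = 55. With a single density this
#' reduces exactly to [paired_contrast()].
#'
#' @inheritParams paired_contrast
#' @param densities Densities to pool; default all present in the table.
#' @return One-row data frame as in [paired_contrast()] with
#'   `density = "summary"` and df = `n_subjects * n_densities - 1`.
#' @export
summary_contrast <- function(table, metric, scope, condA, condB,
                             densities = sort(unique(table$density))) {
  m <- extract_pairs(table, metric, scope, condA, condB, densities)
  contrast_row(m$value_a - m$value_b, metric, scope, condA, condB, "summary")
}

#' Pool nodal scopes into a mean scope
#'
#' Averages a set of `node:<label>` scopes (for example the left and right
#' hippocampal hubs) into a single pooled scope per subject x condition x
#' density x metric, appended to the table. Bilateral averaging before the
#' contrast is the usual treatment for paired ROI nodes.
#'
#' @param table A `metric_table`.
#' @param nodes Node labels to pool.
#' @param new_scope Name of the pooled scope (default `"node:hub_mean"`).
#' @return The table with the pooled rows appended.
#' @export
pool_node_scopes <- function(table, nodes, new_scope = "node:hub_mean") {
  scopes <- paste0("node:", nodes)
  sel <- table[table$scope %in% scopes, , drop = FALSE]
  if (!nrow(sel)) stop("no rows for the requested nodes", call. = FALSE)
  agg <- stats::aggregate(
    value ~ subject + condition + density + metric, data = sel, FUN = mean)
  agg$scope <- new_scope
  out <- rbind(as.data.frame(table),
               agg[, c("subject", "condition", "density", "metric", "scope",
                       "value")])
  class(out) <- c("metric_table", "data.frame")
  out
}

#' Full contrast report for a metric table
#'
#' Per-density plus pooled summary contrasts for every metric x scope
#' combination present in the table.
#'
#' @inheritParams paired_contrast
#' @return Data frame of stacked contrast rows.
#' @export
contrast_report <- function(table, condA, condB) {
  combos <- unique(table[, c("metric", "scope")])
  densities <- sort(unique(table$density))
  out <- list()
  for (j in seq_len(nrow(combos))) {
    met <- combos$metric[j]; sc <- combos$scope[j]
    for (k in densities)
      out[[length(out) + 1L]] <- paired_contrast(table, met, sc, condA,
                                                 condB, k)
    out[[length(out) + 1L]] <- summary_contrast(table, met, sc, condA, condB)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
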