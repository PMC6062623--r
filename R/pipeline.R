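# End-to-end analyses over an in-memory cohort: the encoding-phase density
# sweep (filter -> nuisance regression -> condition connectivity -> graph
# metrics -> paired contrasts) and the ROI-level gPPI analysis.

#' Prepare one subject's time series
#'
#' High-pass filter then CompCor nuisance regression (skipped when the
#' dataset carries no noise sources or `n_compcor = 0`).
#'
#' @param dataset An `roi_ts`.
#' @param cutoff_seconds High-pass cutoff (default 90 s).
#' @param n_compcor Number of nuisance components to remove (default 3,
#'   the generator emits 3 noise sources).
#' @return The prepared `roi_ts`.
#' @export
prepare_subject <- function(dataset, cutoff_seconds = 90, n_compcor = 3) {
  ts <- highpass_filter(dataset, cutoff_seconds)
  if (n_compcor > 0 && !is.null(ts$noise_sources) &&
      ncol(as.matrix(ts$noise_sources)) > 0)
    ts <- compcor_regress(ts, min(n_compcor, ncol(as.matrix(ts$noise_sources))))
  ts
}

#' Condition connectivity matrices for one subject
#'
#' Bins the subject's blocks by rating, builds the per-condition weights
#' (HRF-convolved or binary block masks) and estimates one Fisher-z matrix
#' per condition.
#'
#' @param dataset A prepared `roi_dataset` (must carry its `design`).
#' @param bin_rule,drop Passed to [bin_blocks()].
#' @param conn_mode `"weighted"` (HRF-weighted, default) or `"concat"`
#'   (binary block masks).
#' @param clip_eps Passed to [condition_connectivity()].
#' @return Named list of `conn_matrix`, one per condition.
#' @export
subject_connectivity <- function(dataset,
                                 bin_rule = c("2" = "low", "4" = "high"),
                                 drop = c(1L, 3L), conn_mode = "weighted",
                                 clip_eps = 1e-6) {
  design <- dataset$design
  if (is.null(design)) stop("dataset carries no design", call. = FALSE)
  nv <- attr(design, "n_volumes")
  binned <- bin_blocks(design, bin_rule, drop)
  kernel <- hrf_double_gamma(dataset$tr)
  out <- lapply(names(binned$conditions), function(cond) {
    blocks <- binned$conditions[[cond]]
    w <- if (conn_mode == "weighted")
      condition_weights(blocks, dataset$tr, nv, kernel, condition = cond)
    else block_weights(blocks, dataset$tr, nv, condition = cond)
    cm <- condition_connectivity(dataset, w, clip_eps)
    cm$mode <- conn_mode
    cm
  })
  names(out) <- names(binned$conditions)
  out
}

#' Encoding-phase network sweep over a cohort
#'
#' Runs preparation, condition connectivity, the density sweep and the
#' full per-density plus pooled contrast report for a simulated (or
#' loaded) cohort.
#'
#' @param cohort Named list of `roi_dataset`s (see [simulate_cohort()]).
#' @param densities Density grid (default `c(0.10, 0.15, 0.20, 0.25)`).
#' @param bin_rule,drop Passed to [bin_blocks()].
#' @param cutoff_seconds,n_compcor Passed to [prepare_subject()].
#' @param conn_mode Passed to [subject_connectivity()].
#' @param threshold_mode Passed to [threshold_proportional()].
#' @param target_nodes Node labels to profile; default the cohort's hub
#'   nodes.
#' @param condA,condB Conditions contrasted (default `"low"` vs `"high"`).
#' @return List with `table` (metric table), `contrasts` (contrast report),
#'   and `target_nodes`.
#' @export
run_network_sweep <- function(cohort, densities = c(0.10, 0.15, 0.20, 0.25),
                              bin_rule = c("2" = "low", "4" = "high"),
                              drop = c(1L, 3L), cutoff_seconds = 90,
                              n_compcor = 3, conn_mode = "weighted",
                              threshold_mode = "signed",
                              target_nodes = NULL,
                              condA = "low", condB = "high") {
  if (is.null(target_nodes)) {
    d1 <- cohort[[1]]
    target_nodes <- if (!is.null(d1$hub_nodes))
      d1$node_labels[d1$hub_nodes] else character()
  }
  conn <- lapply(cohort, function(d) {
    prep <- prepare_subject(d, cutoff_seconds, n_compcor)
    prep$design <- d$design
    subject_connectivity(prep, bin_rule, drop, conn_mode)
  })
  tbl <- metric_sweep(conn, densities, target_nodes, threshold_mode)
  if (length(target_nodes) > 1L)
    tbl <- pool_node_scopes(tbl, target_nodes)
  list(table = tbl, contrasts = contrast_report(tbl, condA, condB),
       target_nodes = target_nodes)
}

#' ROI-level gPPI analysis over a cohort
#'
#' For each subject: prepares the series, builds the seed x condition
#' interaction design and fits every target node, then tests the
#' `ppi_<condA> - ppi_<condB>` contrast across subjects.
#'
#' @param cohort Named list of `roi_dataset`s.
#' @param seed_label Seed node label; default the first hub node.
#' @param target_labels Target node labels; default all nodes except the
#'   seed.
#' @param bin_rule,drop Passed to [bin_blocks()].
#' @param cutoff_seconds,n_compcor Passed to [prepare_subject()].
#' @param condA,condB PPI conditions contrasted (default `"high"` vs
#'   `"low"`).
#' @param method,n_perm,seed Passed to [group_ppi_contrast()].
#' @return A `gppi_result` data frame.
#' @export
run_gppi <- function(cohort, seed_label = NULL, target_labels = NULL,
                     bin_rule = c("2" = "low", "4" = "high"),
                     drop = c(1L, 3L), cutoff_seconds = 90, n_compcor = 3,
                     condA = "high", condB = "low",
                     method = "t_fdr", n_perm = 1000, seed = 1L) {
  d1 <- cohort[[1]]
  if (is.null(seed_label))
    seed_label <- d1$node_labels[d1$hub_nodes[1]]
  if (is.null(target_labels))
    target_labels <- setdiff(d1$node_labels, seed_label)
  betas <- lapply(cohort, function(d) {
    prep <- prepare_subject(d, cutoff_seconds, n_compcor)
    design <- d$design
    nv <- attr(design, "n_volumes")
    binned <- bin_blocks(design, bin_rule, drop)
    x <- build_gppi_design(prep$series[, seed_label],
                           binned$conditions, d$tr, nv)
    fit_gppi(prep$series[, target_labels, drop = FALSE], x)
  })
  contrast <- stats::setNames(c(1, -1),
                              paste0("ppi_", c(condA, condB)))
  group_ppi_contrast(betas, contrast, method = method, n_perm = n_perm,
                     seed = seed)
}
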