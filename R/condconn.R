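# Condition-binned connectivity: rating-based block binning, canonical
# double-gamma HRF regressors, and condition-specific Fisher-z correlation
# matrices estimated by HRF-weighted (or block-concatenated) correlation.

#' Bin blocks by behavioural rating
#'
#' Assigns every block of a design to an analysis condition according to a
#' rating -> condition rule; ratings listed in `drop` are excluded. Every
#' rating present in the design must be either mapped or dropped.
#'
#' @param design A `synthetic_design` (or data frame with `onset`,
#'   `duration`, `trial_type`, `rating`).
#' @param bin_rule Named character vector mapping rating (as character) to
#'   condition, e.g. `c("2" = "low", "4" = "high")`.
#' @param drop Integer ratings to exclude (default: every rating not named
#'   in `bin_rule` triggers an error unless listed here).
#' @return List with `conditions` (named list of block data frames) and
#'   `dropped` (data frame of excluded blocks).
#' @export
bin_blocks <- function(design, bin_rule = c("2" = "low", "4" = "high"),
                       drop = c(1L, 3L)) {
  stopifnot(is.data.frame(design))
  rat <- as.character(design$rating)
  unmapped <- setdiff(unique(rat), c(names(bin_rule), as.character(drop)))
  if (length(unmapped))
    stop("rating(s) ", paste(unmapped, collapse = ", "),
         " neither mapped by bin_rule nor listed in `drop`", call. = FALSE)
  keep <- rat %in% names(bin_rule)
  cond <- ifelse(keep, bin_rule[rat], NA_character_)
  conditions <- lapply(unique(unname(bin_rule)), function(cn)
    design[!is.na(cond) & cond == cn, , drop = FALSE])
  names(conditions) <- unique(unname(bin_rule))
  empty <- names(conditions)[vapply(conditions, nrow, 0L) == 0L]
  if (length(empty))
    stop("condition(s) empty after binning: ", paste(empty, collapse = ", "),
         call. = FALSE)
  list(conditions = conditions, dropped = design[!keep, , drop = FALSE])
}

#' Canonical double-gamma HRF kernel
#'
#' Samples the canonical haemodynamic response (peak delay 6 s, undershoot
#' delay 16 s, dispersions 1 s, peak:undershoot ratio 6, 32 s support) at
#' the repetition time, scaled to unit peak.
#'
#' @param tr Repetition time in seconds.
#' @param duration_s Kernel support in seconds (default 32).
#' @return Numeric vector of `ceiling(duration_s / tr)` samples.
#' @export
hrf_double_gamma <- function(tr, duration_s = 32) {
  assert_scalar_num(tr, "tr", 1e-9)
  t <- (seq_len(ceiling(duration_s / tr)) - 1) * tr
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

#' Per-volume boxcar for a set of blocks
#' @keywords internal
block_boxcar <- function(blocks, tr, n_volumes) {
  t0 <- (seq_len(n_volumes) - 1) * tr
  box <- numeric(n_volumes)
  for (b in seq_len(nrow(blocks))) {
    on <- blocks$onset[b]; off <- on + blocks$duration[b]
    box[t0 >= on - 1e-9 & t0 < off - 1e-9] <- 1
  }
  box
}

#' HRF-convolved condition weights
#'
#' Convolves the blocks' boxcar with an HRF kernel, truncates to the run
#' length and rectifies the undershoot to zero, producing the nonnegative
#' per-volume weights used by the weighted-correlation estimator.
#'
#' @param blocks Data frame of blocks (`onset`, `duration`).
#' @param tr Repetition time in seconds.
#' @param n_volumes Run length in volumes.
#' @param kernel HRF samples; default [hrf_double_gamma()] at `tr`. Use
#'   `kernel = 1` for the raw boxcar.
#' @param condition Condition label carried on the result.
#' @return Object of class `condition_weights`: list(`condition`,
#'   `weights`).
#' @export
condition_weights <- function(blocks, tr, n_volumes,
                              kernel = hrf_double_gamma(tr),
                              condition = "condition") {
  box <- block_boxcar(blocks, tr, n_volumes)
  w <- stats::convolve(box, rev(kernel), type = "open")[seq_len(n_volumes)]
  w <- pmax(w, 0)
  structure(list(condition = condition, weights = w),
            class = "condition_weights")
}

#' Binary block-membership weights ("concat" mode)
#'
#' @inheritParams condition_weights
#' @return A `condition_weights` whose weights are 0/1 block indicators.
#' @export
block_weights <- function(blocks, tr, n_volumes, condition = "condition") {
  structure(list(condition = condition,
                 weights = block_boxcar(blocks, tr, n_volumes)),
            class = "condition_weights")
}

#' Condition-specific Fisher-z connectivity
#'
#' Weighted Pearson correlation between every node pair, using the
#' condition's per-volume weights (weighted means and variances), followed
#' by clipping at `1 - clip_eps` and the Fisher z = atanh(r) transform.
#' With uniform weights this reduces exactly to the ordinary Pearson
#' correlation; with binary weights it equals the Pearson correlation of
#' the selected volumes.
#'
#' @param ts An `roi_ts`.
#' @param w A `condition_weights` with at least 10 positive weights.
#' @param clip_eps Clipping margin for |r| (default 1e-6).
#' @return Object of class `conn_matrix`: list(`z` node x node Fisher-z
#'   matrix with zero diagonal, `condition`, `node_labels`, `mode`).
#' @export
condition_connectivity <- function(ts, w, clip_eps = 1e-6) {
  stopifnot(inherits(ts, "roi_ts"), inherits(w, "condition_weights"))
  wt <- w$weights
  if (length(wt) != nrow(ts$series))
    stop("weights length must equal the number of volumes", call. = FALSE)
  if (sum(wt > 0) < 10L)
    stop("need at least 10 positively weighted volumes", call. = FALSE)
  cw <- stats::cov.wt(ts$series, wt = wt / sum(wt), cor = FALSE,
                      method = "ML")
  v <- diag(cw$cov)
  bad <- which(v <= 1e-14)
  if (length(bad))
    stop("zero variance under the condition weighting for node(s): ",
         paste(ts$node_labels[bad], collapse = ", "), call. = FALSE)
  r <- cw$cov / sqrt(outer(v, v))
  r <- pmin(pmax(r, -(1 - clip_eps)), 1 - clip_eps)
  z <- atanh(r)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  dimnames(z) <- list(ts$node_labels, ts$node_labels)
  structure(list(z = z, condition = w$condition,
                 node_labels = ts$node_labels, mode = "weighted"),
            class = "conn_matrix")
}

#' Construct a connectivity matrix object from a Fisher-z matrix
#'
#' @param z Symmetric node x node matrix of Fisher-z values, zero diagonal.
#' @param condition Condition label.
#' @param node_labels Node labels; default from `dimnames(z)`.
#' @param mode Estimation mode tag.
#' @return A `conn_matrix`.
#' @export
conn_matrix <- function(z, condition = "condition",
                        node_labels = rownames(z), mode = "external") {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("z must be square", call. = FALSE)
  if (max(abs(z - t(z))) > 1e-8) stop("z must be symmetric", call. = FALSE)
  if (!all(is.finite(z))) stop("z must be finite", call. = FALSE)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  if (is.null(node_labels))
    node_labels <- sprintf("roi_%03d", seq_len(nrow(z)))
  dimnames(z) <- list(node_labels, node_labels)
  structure(list(z = z, condition = condition, node_labels = node_labels,
                 mode = mode), class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %d x %d Fisher-z, condition '%s' (%s mode)\n",
              nrow(x$z), ncol(x$z), x$condition, x$mode))
  invisible(x)
}
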