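# ROI-level generalized psychophysiological interaction (gPPI) modelling:
# seed x condition interaction designs, per-target OLS fits, and
# group-level inference on condition-dependent coupling contrasts.

#' Build a gPPI design matrix
#'
#' Columns: intercept; one HRF-convolved psychological regressor per
#' condition; the standardised seed time series (physiological); one PPI
#' regressor per condition (element-wise product of the standardised seed
#' and that condition's psychological regressor, formed at signal level
#' without deconvolution); then any confound columns.
#'
#' @param seed_ts Numeric vector, the seed node's time series.
#' @param blocks_by_condition Named list of block data frames (one per
#'   condition, each with `onset`, `duration`).
#' @param tr Repetition time in seconds.
#' @param n_volumes Run length in volumes.
#' @param confounds Optional matrix of confound columns (named).
#' @param kernel HRF kernel; default [hrf_double_gamma()] at `tr`.
#' @return Numeric matrix of class `gppi_design` with unique column labels
#'   (`intercept`, `psy_<cond>`, `physio`, `ppi_<cond>`, confounds), full
#'   column rank.
#' @export
build_gppi_design <- function(seed_ts, blocks_by_condition, tr, n_volumes,
                              confounds = NULL,
                              kernel = hrf_double_gamma(tr)) {
  stopifnot(length(seed_ts) == n_volumes)
  if (!length(blocks_by_condition) || is.null(names(blocks_by_condition)))
    stop("blocks_by_condition must be a named non-empty list", call. = FALSE)
  empty <- names(blocks_by_condition)[
    vapply(blocks_by_condition, nrow, 0L) == 0L]
  if (length(empty))
    stop("condition(s) with no blocks: ", paste(empty, collapse = ", "),
         call. = FALSE)
  psy <- sapply(blocks_by_condition, function(b)
    condition_weights(b, tr, n_volumes, kernel)$weights)
  seed_z <- as.numeric(scale(seed_ts))
  ppi <- psy * seed_z
  x <- cbind(intercept = 1, psy, physio = seed_z, ppi)
  colnames(x) <- c("intercept", paste0("psy_", names(blocks_by_condition)),
                   "physio", paste0("ppi_", names(blocks_by_condition)))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (is.null(colnames(confounds)))
      colnames(confounds) <- paste0("confound_", seq_len(ncol(confounds)))
    x <- cbind(x, confounds)
  }
  if (anyDuplicated(colnames(x)))
    stop("design column labels must be unique", call. = FALSE)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop("rank-deficient gPPI design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  class(x) <- c("gppi_design", class(x))
  x
}

#' Fit target time series against a gPPI design
#'
#' Ordinary least squares of one or more target columns on the design;
#' residuals are orthogonal to every design column.
#'
#' @param target_ts Numeric vector or volumes x targets matrix.
#' @param design A `gppi_design`.
#' @return Named beta vector (single target) or columns x targets beta
#'   matrix.
#' @export
fit_gppi <- function(target_ts, design) {
  y <- as.matrix(target_ts)
  stopifnot(nrow(y) == nrow(design))
  fit <- stats::lm.fit(unclass(design), y)
  b <- fit$coefficients
  if (ncol(y) == 1L) {
    b <- drop(b)
    names(b) <- colnames(design)
  } else rownames(b) <- colnames(design)
  b
}

#' Group-level test of a gPPI contrast
#'
#' Applies a contrast vector to each subject's per-node betas and tests the
#' resulting values against zero across subjects per node, either with a
#' one-sample t-test plus Benjamini-Hochberg FDR, or with a sign-flip
#' permutation test.
#'
#' @param betas_by_subject List (length >= 3) of columns x nodes beta
#'   matrices, identical dimnames across subjects.
#' @param contrast Named or positional numeric contrast over design
#'   columns (e.g. +1 on `ppi_high`, -1 on `ppi_low`).
#' @param method `"t_fdr"` (default) or `"sign_permutation"`.
#' @param n_perm Number of sign flips for the permutation method
#'   (default 1000).
#' @param seed Seed for the permutation draws.
#' @return Object of class `gppi_result`: data frame with one row per node
#'   (`node`, `contrast` mean across subjects, `t`, `df`, `p`, `q`).
#' @export
group_ppi_contrast <- function(betas_by_subject, contrast,
                               method = c("t_fdr", "sign_permutation"),
                               n_perm = 1000, seed = 1L) {
  method <- match.arg(method)
  n_sub <- length(betas_by_subject)
  if (n_sub < 3L) stop("need at least 3 subjects", call. = FALSE)
  b1 <- betas_by_subject[[1]]
  cvec <- numeric(nrow(b1))
  if (!is.null(names(contrast))) {
    miss <- setdiff(names(contrast), rownames(b1))
    if (length(miss))
      stop("contrast names not in design: ", paste(miss, collapse = ", "),
           call. = FALSE)
    cvec[match(names(contrast), rownames(b1))] <- contrast
  } else {
    stopifnot(length(contrast) == nrow(b1))
    cvec <- as.numeric(contrast)
  }
  # subjects x nodes matrix of contrast values
  cv <- t(vapply(betas_by_subject, function(b) drop(crossprod(cvec, b)),
                 numeric(ncol(b1))))
  means <- colMeans(cv)
  sds <- apply(cv, 2, stats::sd)
  t_vals <- ifelse(sds > 0, means / (sds / sqrt(n_sub)), NA_real_)
  df <- n_sub - 1L
  if (method == "t_fdr") {
    p <- 2 * stats::pt(abs(t_vals), df, lower.tail = FALSE)
    p[is.na(p)] <- 1
  } else {
    p <- with_seed(seed, {
      flips <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                      n_perm, n_sub)
      obs <- abs(means)
      perm_means <- abs(flips %*% cv / n_sub)
      (colSums(sweep(perm_means, 2, obs, ">=")) + 1) / (n_perm + 1)
    })
  }
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(node = colnames(b1), contrast = means, t = t_vals,
                    df = df, p = p, q = q, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("gppi_result", "data.frame")
  res
}
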