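# Time-series preparation: discrete-cosine high-pass filtering and
# component-based (CompCor-style) nuisance regression. Both stages are
# linear projections, hence exactly idempotent.

#' Construct an ROI time-series object
#'
#' @param series Numeric matrix, volumes x nodes, all finite.
#' @param tr Repetition time in seconds.
#' @param node_labels Unique column labels; defaults to `colnames(series)`.
#' @param noise_sources Optional volumes x components matrix of nuisance
#'   signals (drift estimates, tissue components).
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(series, tr, node_labels = colnames(series),
                   noise_sources = NULL) {
  series <- as.matrix(series)
  if (!all(is.finite(series))) stop("series must be finite", call. = FALSE)
  assert_scalar_num(tr, "tr", 1e-9)
  if (is.null(node_labels))
    node_labels <- sprintf("roi_%03d", seq_len(ncol(series)))
  if (length(node_labels) != ncol(series) || anyDuplicated(node_labels))
    stop("node_labels must be unique and match the column count", call. = FALSE)
  colnames(series) <- node_labels
  if (!is.null(noise_sources)) noise_sources <- as.matrix(noise_sources)
  structure(list(series = series, tr = tr, node_labels = node_labels,
                 noise_sources = noise_sources),
            class = "roi_ts")
}

# residualise columns of y against [1, X] via QR
project_out <- function(y, x) {
  X <- cbind(1, x)
  qr_x <- qr(X)
  y - X %*% qr.coef(qr_x, y)
}

#' Discrete-cosine basis with periods longer than a cutoff
#' @keywords internal
dct_basis <- function(n_volumes, tr, cutoff_seconds) {
  # DCT-II regressor k has period 2 * n * tr / k
  k_max <- floor(2 * n_volumes * tr / cutoff_seconds)
  if (k_max < 1L) return(matrix(numeric(0), n_volumes, 0))
  v <- seq_len(n_volumes) - 0.5
  sapply(seq_len(k_max), function(k) cos(pi * k * v / n_volumes))
}

#' Temporal high-pass filter
#'
#' Removes the mean and all discrete-cosine drift regressors with period
#' longer than `cutoff_seconds` from every node column (the standard fMRI
#' DCT high-pass). The operation is a fixed linear projection and therefore
#' idempotent.
#'
#' @param ts An `roi_ts`.
#' @param cutoff_seconds High-pass cutoff period in seconds (default 90;
#'   must exceed `2 * tr`).
#' @return The filtered `roi_ts` (noise sources passed through untouched).
#' @export
highpass_filter <- function(ts, cutoff_seconds = 90) {
  stopifnot(inherits(ts, "roi_ts"))
  nv <- nrow(ts$series)
  if (cutoff_seconds <= 2 * ts$tr)
    stop("cutoff_seconds must exceed 2 * tr", call. = FALSE)
  basis <- dct_basis(nv, ts$tr, cutoff_seconds)
  if (ncol(basis) >= nv / 2)
    stop("cutoff too small for this series length: the drift basis would ",
         "span at least half the spectrum", call. = FALSE)
  ts$series <- project_out(ts$series, basis)
  colnames(ts$series) <- ts$node_labels
  ts
}

#' Component-based nuisance regression (CompCor style)
#'
#' Computes the top principal components of the column-standardised noise
#' sources and regresses them (plus an intercept) out of every node column.
#' Residuals are exactly orthogonal to the retained components.
#'
#' @param ts An `roi_ts` with non-empty `noise_sources`.
#' @param n_components Number of components to remove (default 5, capped
#'   nowhere: must be at most the number of noise columns and less than the
#'   number of volumes).
#' @return The cleaned `roi_ts`; removed components are stored in attribute
#'   `compcor_components` of the series.
#' @export
compcor_regress <- function(ts, n_components = 5) {
  stopifnot(inherits(ts, "roi_ts"))
  if (is.null(ts$noise_sources) || ncol(as.matrix(ts$noise_sources)) == 0L)
    stop("no noise_sources available; skip the CompCor stage explicitly ",
         "instead of calling compcor_regress()", call. = FALSE)
  ns <- as.matrix(ts$noise_sources)
  if (n_components > ncol(ns))
    stop("n_components exceeds the number of noise components", call. = FALSE)
  if (n_components >= nrow(ns))
    stop("n_components must be less than the number of volumes", call. = FALSE)
  pcs <- stats::prcomp(ns, center = TRUE, scale. = TRUE)$x[, seq_len(n_components),
                                                           drop = FALSE]
  ts$series <- project_out(ts$series, pcs)
  colnames(ts$series) <- ts$node_labels
  attr(ts$series, "compcor_components") <- pcs
  ts
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d volumes x %d nodes, TR = %gs, %d noise source(s)\n",
              nrow(x$series), ncol(x$series), x$tr,
              if (is.null(x$noise_sources)) 0L else ncol(x$noise_sources)))
  invisible(x)
}
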