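# Synthetic multi-subject ROI time-series generator.
#
# Emulates a condition-switching functional scan: node signals follow a
# modular covariance whose integration level and hub wiring differ between
# task conditions, plus slow scanner drift and white measurement noise.
# Ground truth (module partition, hub identity, state specs) travels with
# the dataset so every downstream stage can be validated offline.

#' Define a network state
#'
#' A state is a parameterisation of the node covariance active during blocks
#' of one condition: correlations within and between modules, and how the
#' designated hub nodes split their correlation mass between their own and
#' foreign modules.
#'
#' @param label Condition name (matched against block `trial_type`).
#' @param rho_within Correlation between nodes sharing a module, in `[0, 1)`.
#' @param rho_between Correlation between nodes of different modules, in
#'   `[0, 1)`; must not exceed `rho_within`.
#' @param hub_cross Fraction in `[0, 1]` of a hub node's correlation mass
#'   directed to foreign modules (1 = fully integrative connector hub).
#' @param hub_local Correlation magnitude of a hub to its neighbourhood,
#'   in `[0, 1)`; split between own and foreign modules by `hub_cross`.
#' @return An object of class `state_spec`.
#' @export
state_spec <- function(label, rho_within, rho_between, hub_cross = 0,
                       hub_local = 0) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  assert_scalar_num(rho_within, "rho_within", 0, 1 - 1e-9)
  assert_scalar_num(rho_between, "rho_between", 0, 1 - 1e-9)
  assert_scalar_num(hub_cross, "hub_cross", 0, 1)
  assert_scalar_num(hub_local, "hub_local", 0, 1 - 1e-9)
  if (rho_between > rho_within)
    stop("`rho_between` must not exceed `rho_within`", call. = FALSE)
  structure(list(label = label, rho_within = rho_within,
                 rho_between = rho_between, hub_cross = hub_cross,
                 hub_local = hub_local),
            class = "state_spec")
}

#' Default two-state condition specifications
#'
#' The `low` (low-confidence, high encoding demand) condition is globally
#' integrated: appreciable between-module correlation and hubs wired mostly
#' across modules. The `high` condition is modular/segregated: strong
#' within-module, weak between-module correlation, hubs wired locally.
#' Distractor ratings 1 and 3 map to a neutral intermediate state.
#'
#' @return Named list of `state_spec` objects (`low`, `high`, `guess`, `mid`).
#' @export
default_states <- function() {
  list(
    low   = state_spec("low",   rho_within = 0.35, rho_between = 0.20,
                       hub_cross = 0.85, hub_local = 0.50),
    high  = state_spec("high",  rho_within = 0.45, rho_between = 0.05,
                       hub_cross = 0.05, hub_local = 0.75),
    guess = state_spec("guess", rho_within = 0.30, rho_between = 0.12,
                       hub_cross = 0.50, hub_local = 0.30),
    mid   = state_spec("mid",   rho_within = 0.30, rho_between = 0.12,
                       hub_cross = 0.50, hub_local = 0.30)
  )
}

#' Condition-independent states (coupling-null cohort)
#'
#' Assigns one shared `state_spec` to every condition label, so the node
#' covariance does not depend on condition. Used to validate the gPPI
#' stage: with a single planted seed-by-condition coupling, all remaining
#' nodes are genuinely null (under the two-state defaults every node's
#' seed coupling is condition-dependent, which is a real effect, not a
#' false positive).
#'
#' @param spec The shared `state_spec` (default a neutral intermediate
#'   state).
#' @param labels Condition labels to cover.
#' @return Named list of identical `state_spec`s.
#' @export
uniform_states <- function(spec = state_spec("uniform", 0.30, 0.12,
                                             hub_cross = 0.5,
                                             hub_local = 0.3),
                           labels = c("low", "high", "guess", "mid")) {
  stats::setNames(rep(list(spec), length(labels)), labels)
}

#' Default block design
#'
#' 15-s task blocks separated by 10-s rest, cycling deterministically
#' through ratings 2, 4, 1, 2, 4, 3 so that the low/high contrast conditions
#' get equal numbers of blocks and ratings are an invertible function of the
#' condition label (1 = "guess", 2 = "low", 3 = "mid", 4 = "high").
#'
#' @param n_volumes Number of volumes (default 300).
#' @param tr Repetition time in seconds (default 2).
#' @param block_s Block duration in seconds (default 15).
#' @param gap_s Inter-block rest in seconds (default 10).
#' @param start_s Onset of the first block (default 10).
#' @return A `synthetic_design`: data frame of blocks (`onset`, `duration`,
#'   `trial_type`, `rating`) with attributes `tr` and `n_volumes`.
#' @export
default_design <- function(n_volumes = 300, tr = 2, block_s = 15, gap_s = 10,
                           start_s = 10) {
  total <- n_volumes * tr
  onsets <- seq(start_s, total - block_s, by = block_s + gap_s)
  ratings <- rep_len(c(2L, 4L, 1L, 2L, 4L, 3L), length(onsets))
  lab <- c("guess", "low", "mid", "high")[ratings]
  design <- data.frame(onset = onsets, duration = block_s, trial_type = lab,
                       rating = ratings, stringsAsFactors = FALSE)
  as_design(design, tr = tr, n_volumes = n_volumes)
}

#' Construct a validated block design
#'
#' @param blocks Data frame with columns `onset`, `duration`, `trial_type`,
#'   `rating` (seconds / condition label / integer 1-4).
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes in the run.
#' @return A `synthetic_design` object.
#' @export
as_design <- function(blocks, tr, n_volumes) {
  need <- c("onset", "duration", "trial_type", "rating")
  if (!all(need %in% names(blocks)))
    stop("design needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  assert_scalar_num(tr, "tr", 1e-9)
  stopifnot(n_volumes >= 1)
  blocks <- blocks[order(blocks$onset), , drop = FALSE]
  rownames(blocks) <- NULL
  if (any(blocks$duration <= 0)) stop("block durations must be > 0", call. = FALSE)
  if (!all(blocks$rating %in% 1:4))
    stop("ratings must be integers in 1..4", call. = FALSE)
  ends <- blocks$onset + blocks$duration
  if (nrow(blocks) > 1 && any(blocks$onset[-1] < ends[-nrow(blocks)] - 1e-9))
    stop("blocks must not overlap", call. = FALSE)
  if (max(ends) > n_volumes * tr + 1e-9)
    stop("blocks extend past the end of the run", call. = FALSE)
  structure(blocks, class = c("synthetic_design", "data.frame"),
            tr = tr, n_volumes = as.integer(n_volumes))
}

#' Map each volume to the block (row index) covering it, 0 if rest
#' @keywords internal
volume_blocks <- function(design) {
  tr <- attr(design, "tr"); nv <- attr(design, "n_volumes")
  t0 <- (seq_len(nv) - 1L) * tr  # frame onset times
  idx <- integer(nv)
  for (b in seq_len(nrow(design))) {
    on <- design$onset[b]; off <- on + design$duration[b]
    idx[t0 >= on - 1e-9 & t0 < off - 1e-9] <- b
  }
  idx
}

#' Build a state covariance (correlation) matrix
#'
#' Assembles the node-by-node correlation matrix implied by a
#' [state_spec()]: `rho_within` inside modules, `rho_between` across
#' modules, with each hub node's row/column replaced by
#' `(1 - hub_cross) * hub_local` toward its own module and
#' `hub_cross * hub_local` toward foreign modules. If the result is not
#' positive semidefinite it is repaired with the smallest uniform ridge
#' `lambda <= 0.1` (bisection) followed by renormalisation to unit
#' diagonal; the applied ridge is recorded in attribute `ridge`.
#'
#' @param partition Integer vector, node -> module id.
#' @param spec A `state_spec`.
#' @param hub_nodes Integer node indices acting as hubs (possibly empty).
#' @return Correlation matrix with attribute `ridge` (0 when no repair
#'   was needed).
#' @export
build_state_covariance <- function(partition, spec, hub_nodes = integer()) {
  stopifnot(inherits(spec, "state_spec"))
  partition <- as.integer(partition)
  n <- length(partition)
  mods <- sort(unique(partition))
  if (length(mods) < 2L) stop("need at least 2 modules", call. = FALSE)
  if (any(tabulate(match(partition, mods)) < 2L))
    stop("every module needs at least 2 nodes", call. = FALSE)
  hub_nodes <- as.integer(hub_nodes)
  if (length(hub_nodes) && (any(hub_nodes < 1L) || any(hub_nodes > n)))
    stop("hub_nodes outside the node set", call. = FALSE)

  same <- outer(partition, partition, "==")
  cmat <- ifelse(same, spec$rho_within, spec$rho_between)
  for (h in hub_nodes) {
    hv <- ifelse(partition == partition[h],
                 (1 - spec$hub_cross) * spec$hub_local,
                 spec$hub_cross * spec$hub_local)
    cmat[h, ] <- hv
    cmat[, h] <- hv
  }
  if (length(hub_nodes) > 1L) {
    for (h in hub_nodes) for (g in hub_nodes) if (h != g) {
      v <- if (partition[h] == partition[g])
        (1 - spec$hub_cross) * spec$hub_local
      else spec$hub_cross * spec$hub_local
      cmat[h, g] <- v; cmat[g, h] <- v
    }
  }
  diag(cmat) <- 1

  ridge <- 0
  ev_min <- min(eigen(cmat, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10) {
    # smallest lambda with min eig((C + lambda I)/(1 + lambda)) >= 0 by bisection
    psd_at <- function(l)
      min(eigen((cmat + diag(l, n)) / (1 + l), symmetric = TRUE,
                only.values = TRUE)$values) >= -1e-12
    if (!psd_at(0.1))
      stop("state_spec infeasible: not positive semidefinite within ridge 0.1",
           call. = FALSE)
    lo <- 0; hi <- 0.1
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (psd_at(mid)) hi <- mid else lo <- mid
    }
    ridge <- hi
    cmat <- (cmat + diag(ridge, n)) / (1 + ridge)
    diag(cmat) <- 1
  }
  attr(cmat, "ridge") <- ridge
  cmat
}

#' Simulate one subject's ROI time series
#'
#' Draws each in-block volume from a zero-mean multivariate Gaussian with
#' the covariance of that block's condition; rest volumes come from an
#' uncorrelated baseline. Slow drift components (shared into
#' `noise_sources`) and white measurement noise are then added. The same
#' `(configuration, seed)` pair always yields bit-identical output.
#'
#' @param design A `synthetic_design` (see [default_design()]).
#' @param states Named list of `state_spec`s covering every `trial_type`
#'   appearing in the design.
#' @param n_nodes Number of ROIs (default 60).
#' @param n_modules Number of equally sized modules (default 4).
#' @param hub_nodes Node indices of the designated hubs; default the first
#'   node of each of the first two modules (hippocampus-like seeds).
#' @param noise_sd Standard deviation of additive white noise (default 0.5,
#'   signal units; block signals have unit variance).
#' @param drift_amplitude Amplitude of the slow drift mixed into every node
#'   (default 1).
#' @param seed Integer seed (required).
#' @return An object of class `roi_dataset` (inherits `roi_ts`): list with
#'   `series` (volumes x nodes), `tr`, `node_labels`, `noise_sources`
#'   (volumes x 3 drift/noise regressors), `partition_truth`, `hub_nodes`,
#'   `states`, `design`, `seed`.
#' @export
simulate_subject <- function(design, states = default_states(), n_nodes = 60,
                             n_modules = 4, hub_nodes = NULL, noise_sd = 0.5,
                             drift_amplitude = 1, seed) {
  stopifnot(inherits(design, "synthetic_design"))
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)
  nv <- attr(design, "n_volumes"); tr <- attr(design, "tr")
  labs <- unique(design$trial_type)
  missing_states <- setdiff(labs, names(states))
  if (length(missing_states))
    stop("no state_spec for condition(s): ",
         paste(missing_states, collapse = ", "), call. = FALSE)

  partition <- rep(seq_len(n_modules), each = ceiling(n_nodes / n_modules),
                   length.out = n_nodes)
  if (is.null(hub_nodes)) {
    firsts <- match(unique(partition), partition)
    hub_nodes <- firsts[seq_len(min(2L, length(firsts)))]
  }
  chols <- lapply(states[labs], function(s)
    chol(build_state_covariance(partition, s, hub_nodes) +
           diag(1e-9, n_nodes)))
  vb <- volume_blocks(design)

  with_seed(seed, {
    z <- matrix(stats::rnorm(nv * n_nodes), nv, n_nodes)
    series <- z  # rest volumes: uncorrelated baseline
    for (b in seq_len(nrow(design))) {
      rows <- which(vb == b)
      if (length(rows))
        series[rows, ] <- z[rows, , drop = FALSE] %*%
          chols[[design$trial_type[b]]]
    }
    tt <- (seq_len(nv) - 1) * tr
    total <- nv * tr
    drift1 <- cos(2 * pi * tt / total + stats::runif(1, 0, 2 * pi))
    drift2 <- cos(2 * pi * tt * 3 / total + stats::runif(1, 0, 2 * pi))
    walk <- cumsum(stats::rnorm(nv))
    walk <- (walk - mean(walk)) / max(stats::sd(walk), 1e-12)
    noise_sources <- cbind(drift1 = drift1, drift2 = drift2, slow_walk = walk)
    loadings <- matrix(stats::runif(n_nodes * 3, 0.5, 1.5), 3, n_nodes,
                       byrow = FALSE)
    series <- series + drift_amplitude * (noise_sources %*% loadings)
    if (noise_sd > 0)
      series <- series + matrix(stats::rnorm(nv * n_nodes, sd = noise_sd),
                                nv, n_nodes)
    node_labels <- sprintf("roi_%03d", seq_len(n_nodes))
    colnames(series) <- node_labels
    structure(list(series = series, tr = tr, node_labels = node_labels,
                   noise_sources = noise_sources,
                   partition_truth = partition, hub_nodes = hub_nodes,
                   states = states[labs], design = design,
                   seed = as.integer(seed)),
              class = c("roi_dataset", "roi_ts"))
  })
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from the master seed;
#' all subjects share the design template and ground-truth partition.
#'
#' @param n_subjects Number of subjects (default 14, >= 2).
#' @param design Design template, shared across subjects.
#' @param states Named list of `state_spec`s.
#' @param seed Master integer seed.
#' @param ... Passed to [simulate_subject()].
#' @return Named list (`sub01`, ...) of `roi_dataset` objects.
#' @export
simulate_cohort <- function(n_subjects = 14, design = default_design(),
                            states = default_states(), seed, ...) {
  if (n_subjects < 2) stop("need n_subjects >= 2", call. = FALSE)
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)
  seeds <- derive_seeds(seed, n_subjects)
  out <- lapply(seeds, function(s)
    simulate_subject(design, states, seed = s, ...))
  names(out) <- sprintf("sub%02d", seq_len(n_subjects))
  out
}

#' Plant a seed-by-condition coupling effect in target nodes
#'
#' Adds `amplitude * standardised(seed signal) * condition weight` to the
#' chosen target columns, creating ground-truth condition-dependent coupling
#' for validating the gPPI stage.
#'
#' @param dataset An `roi_dataset`.
#' @param seed_label Node label of the seed region.
#' @param target_labels Node labels receiving the planted coupling.
#' @param condition Condition whose blocks carry the coupling.
#' @param amplitude Coupling amplitude in signal units.
#' @param kernel HRF kernel; default `hrf_double_gamma(dataset$tr)`.
#' @return The modified `roi_dataset`.
#' @export
inject_ppi_effect <- function(dataset, seed_label, target_labels, condition,
                              amplitude, kernel = NULL) {
  stopifnot(inherits(dataset, "roi_ts"))
  if (is.null(kernel)) kernel <- hrf_double_gamma(dataset$tr)
  design <- dataset$design
  blocks <- design[design$trial_type == condition, , drop = FALSE]
  if (!nrow(blocks)) stop("no blocks for condition ", condition, call. = FALSE)
  w <- condition_weights(blocks, dataset$tr, attr(design, "n_volumes"),
                         kernel, condition = condition)
  sd_seed <- as.numeric(scale(dataset$series[, seed_label]))
  bump <- amplitude * sd_seed * w$weights
  for (lab in target_labels)
    dataset$series[, lab] <- dataset$series[, lab] + bump
  dataset
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("<roi_dataset> %d volumes x %d nodes, TR = %gs, %d modules, hubs: %s\n",
              nrow(x$series), ncol(x$series), x$tr,
              length(unique(x$partition_truth)),
              paste(x$node_labels[x$hub_nodes], collapse = ", ")))
  invisible(x)
}
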