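#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded generators do not perturb the session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive child seeds from a master seed
#'
#' Deterministically expands one master seed into `n` distinct 31-bit seeds,
#' used to give each subject (or replicate) an independent but reproducible
#' random stream.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, all in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes;
#' 1 means identical partitions (up to label permutation), 0 is the
#' expected agreement of random partitions.
#'
#' @param a,b Membership vectors of equal length.
#' @return Scalar adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)  # both partitions trivial
  (nij - expected) / (mx - expected)
}

# shared argument checks -------------------------------------------------

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
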