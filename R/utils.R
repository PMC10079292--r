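#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the caller's RNG
#' state, so seeded generators do not disturb the global random stream.
#' With `seed = NULL` the expression runs against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  code
}

# Scalar validation helpers -------------------------------------------------

stop_if_not_scalar_number <- function(x, name, positive = FALSE,
                                      nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_probability <- function(x, name) {
  stop_if_not_scalar_number(x, name)
  if (x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' Nearest-sample index on a uniform time grid, ties toward the earlier sample
#'
#' @param t_query Times to snap (seconds).
#' @param t0 Time of the first sample.
#' @param dt Sampling interval.
#' @param n Number of samples.
#' @return Integer indices in `1:n` (may fall outside; caller checks bounds).
#' @keywords internal
#' @noRd
snap_to_sample <- function(t_query, t0, dt, n) {
  k <- (t_query - t0) / dt
  kf <- floor(k)
  frac <- k - kf
  # half-sample ties resolve to the earlier sample
  idx <- ifelse(frac <= 0.5 + 1e-9, kf, kf + 1) + 1L
  as.integer(idx)
}

#' Check that a time vector is uniformly sampled
#' @keywords internal
#' @noRd
assert_uniform_sampling <- function(t_s, what = "series") {
  if (length(t_s) < 2L) return(invisible(NA_real_))
  dt <- diff(t_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop(sprintf("%s must be uniformly sampled with increasing timestamps",
                 what), call. = FALSE)
  }
  invisible(stats::median(dt))
}

#' Trapezoidal integral of y over t
#' @keywords internal
#' @noRd
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}
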