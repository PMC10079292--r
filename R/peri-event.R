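#' Align a processed trace to behavioral events
#'
#' Builds a peri-event matrix: one row per event, columns spanning lags
#' from `-window[1]` to `+window[2]` seconds around the event, with each
#' event snapped to the nearest trace sample (half-sample ties resolve to
#' the earlier sample). Events whose window would extend beyond the session
#' bounds are dropped with a warning carrying the count; if all events are
#' out of bounds this is an error.
#'
#' @param trace A `processed_trace` (from [process_session()] or
#'   [processed_trace()]).
#' @param event_times Event times (s), sorted ascending.
#' @param window Numeric `c(pre_s, post_s)`, both positive extents.
#' @return A `peri_event_matrix`: list with `z` (events x lags matrix),
#'   `lags_s`, `event_ids`, `window`, and `n_dropped`.
#' @examples
#' tr <- processed_trace(seq(0, 20, by = 0.1), sin(seq(0, 20, by = 0.1)))
#' pem <- align_events(tr, c(5, 10, 15), window = c(2, 2))
#' dim(pem$z)
#' @export
align_events <- function(trace, event_times, window = c(2, 2)) {
  stopifnot(inherits(trace, "processed_trace"))
  if (length(window) != 2L || any(!is.finite(window)) || any(window <= 0)) {
    stop("`window` must be two positive extents c(pre_s, post_s)")
  }
  event_times <- as.numeric(event_times)
  if (length(event_times) == 0L) stop("no events supplied")
  if (is.unsorted(event_times)) stop("`event_times` must be sorted ascending")
  n <- length(trace$z)
  dt <- 1 / trace$sample_rate_hz
  n_pre <- as.integer(round(window[1] / dt))
  n_post <- as.integer(round(window[2] / dt))
  centers <- snap_to_sample(event_times, trace$t_s[1L], dt, n)
  ok <- centers - n_pre >= 1L & centers + n_post <= n
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("all events fall outside the session bounds")
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d event(s) whose window exceeds session bounds",
                    n_dropped))
  }
  centers <- centers[ok]
  offs <- seq.int(-n_pre, n_post)
  z <- t(vapply(centers, function(ci) trace$z[ci + offs],
                numeric(length(offs))))
  structure(list(z = z, lags_s = offs * dt,
                 event_ids = which(ok), window = window,
                 n_dropped = as.integer(n_dropped)),
            class = "peri_event_matrix")
}

#' @export
print.peri_event_matrix <- function(x, ...) {
  cat(sprintf(
    "<peri_event_matrix> %d events x %d lags (%.2f..%.2f s), %d dropped\n",
    nrow(x$z), ncol(x$z), min(x$lags_s), max(x$lags_s), x$n_dropped))
  invisible(x)
}

nearest_lag_index <- function(pem, t_s) {
  dt <- pem$lags_s[2L] - pem$lags_s[1L]
  idx <- snap_to_sample(t_s, pem$lags_s[1L], dt, length(pem$lags_s))
  if (idx < 1L || idx > length(pem$lags_s)) {
    stop(sprintf("time %g s lies outside the peri-event window", t_s))
  }
  idx
}

#' Mean z-score over three consecutive time points
#'
#' Averages the processed signal over three consecutive samples centered on
#' the lag nearest `t_center_s` (ties toward the earlier sample), per event
#' row and across rows. `placement` moves the 3-sample window so the target
#' lag is its center, first, or last sample.
#'
#' @param pem A `peri_event_matrix`.
#' @param t_center_s Target lag (s) within the window.
#' @param placement One of `"center"` (default), `"leading"`, `"trailing"`.
#' @return A `window_stat`: list with `t_center_s` (the snapped lag),
#'   `mean_z`, `n_samples = 3`, and per-event `row_means`.
#' @export
window_mean <- function(pem, t_center_s, placement = "center") {
  stopifnot(inherits(pem, "peri_event_matrix"))
  placement <- match.arg(placement, c("center", "leading", "trailing"))
  ci <- nearest_lag_index(pem, t_center_s)
  cols <- switch(placement,
                 center = (ci - 1L):(ci + 1L),
                 leading = ci:(ci + 2L),
                 trailing = (ci - 2L):ci)
  if (min(cols) < 1L || max(cols) > length(pem$lags_s)) {
    stop("three-sample window falls outside the peri-event window edge")
  }
  row_means <- rowMeans(pem$z[, cols, drop = FALSE])
  structure(list(t_center_s = pem$lags_s[ci], mean_z = mean(row_means),
                 n_samples = 3L, row_means = row_means),
            class = "window_stat")
}

#' @export
print.window_stat <- function(x, ...) {
  cat(sprintf("<window_stat> mean z %.4f over %d samples at lag %.3f s (%d events)\n",
              x$mean_z, x$n_samples, x$t_center_s, length(x$row_means)))
  invisible(x)
}

#' Change in z-score between two peri-event times
#'
#' Difference of the three-sample [window_mean()] at `t1_s` minus at
#' `t0_s`, per event and averaged across events.
#'
#' @param pem A `peri_event_matrix`.
#' @param t0_s,t1_s Lags (s) inside the window.
#' @inheritParams window_mean
#' @return List with `per_row` (per-event differences), `mean`, and the two
#'   `window_stat`s.
#' @export
delta_z <- function(pem, t0_s, t1_s, placement = "center") {
  w0 <- window_mean(pem, t0_s, placement)
  w1 <- window_mean(pem, t1_s, placement)
  per_row <- w1$row_means - w0$row_means
  list(per_row = per_row, mean = mean(per_row), from = w0, to = w1)
}

#' Area under the processed trace between two times
#'
#' Trapezoidal integral of the z-scored signal between the samples nearest
#' `t0_s` and `t1_s` (units: z-score seconds).
#'
#' @param trace A `processed_trace`.
#' @param t0_s,t1_s Integration bounds (s), `t0_s < t1_s`, inside the
#'   session.
#' @return Numeric scalar.
#' @export
trace_auc <- function(trace, t0_s, t1_s) {
  stopifnot(inherits(trace, "processed_trace"))
  if (!is.finite(t0_s) || !is.finite(t1_s) || t0_s >= t1_s) {
    stop("`t0_s` must be strictly less than `t1_s`")
  }
  n <- length(trace$z)
  dt <- 1 / trace$sample_rate_hz
  i0 <- snap_to_sample(t0_s, trace$t_s[1L], dt, n)
  i1 <- snap_to_sample(t1_s, trace$t_s[1L], dt, n)
  if (i0 < 1L || i1 > n) stop("integration bounds fall outside the session")
  idx <- i0:i1
  trapz(trace$t_s[idx], trace$z[idx])
}

#' Equalize event counts across compared categories
#'
#' When comparing signal averages between categories (e.g. trial outcomes),
#' the category with more events is subsampled without replacement, seeded,
#' down to the smallest category size, so every compared average rests on
#' the same number of events.
#'
#' @param groups Named list; each element a matrix (rows = events) or a
#'   vector/list of events.
#' @param seed Integer seed for the subsampling.
#' @return The list with every element reduced to the minimum group size.
#' @export
standardize_counts <- function(groups, seed = 1L) {
  if (!is.list(groups) || length(groups) == 0L) {
    stop("`groups` must be a nonempty list")
  }
  sizes <- vapply(groups, function(g) {
    if (is.matrix(g)) nrow(g) else length(g)
  }, integer(1))
  if (any(sizes == 0L)) {
    stop("empty group(s): ",
         paste(names(groups)[sizes == 0L], collapse = ", "))
  }
  m <- min(sizes)
  with_seed(seed, {
    lapply(groups, function(g) {
      n <- if (is.matrix(g)) nrow(g) else length(g)
      if (n == m) return(g)
      keep <- sort(sample.int(n, m))
      if (is.matrix(g)) g[keep, , drop = FALSE] else g[keep]
    })
  })
}

#' Pearson correlation with Fisher 95% confidence interval
#'
#' Two-sided Pearson product-moment correlation with the Fisher
#' z-transform 95% confidence interval, via [stats::cor.test()].
#'
#' @param x,y Numeric vectors, equal length `n >= 4`, finite, each with
#'   nonzero variance.
#' @return A `correlation_result`: list with `r`, `ci_low`, `ci_high`, `n`,
#'   `p`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (length(x) < 4L) stop("need at least 4 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("`x` and `y` must be finite")
  }
  if (stats::var(x) <= 0 || stats::var(y) <= 0) {
    stop("zero variance in `x` or `y`")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  structure(list(r = unname(ct$estimate),
                 ci_low = ct$conf.int[1L], ci_high = ct$conf.int[2L],
                 n = length(x), p = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (95%% CI %.3f to %.3f), n = %d, p = %.3g\n",
              x$r, x$ci_low, x$ci_high, x$n, x$p))
  invisible(x)
}
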