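#' Construct a raw photometry session
#'
#' A `photometry_session` stores the per-frame scalar intensities of a
#' multiplexed two-laser recording: for every camera frame, the mean pixel
#' intensity over the implanted-fiber ROI (`roi_signal`) and over the
#' control-fluorophore-fiber ROI (`roi_control`), together with the frame
#' time and which laser was on (`"405"`, `"473"`, or `"off"` for background
#' frames acquired without laser transmission).
#'
#' @param frames Data frame with columns `frame_index`, `t_s`, `channel`,
#'   `roi_signal`, `roi_control`.
#' @param rate_hz Per-channel multiplex rate; one of 10 or 15 Hz.
#' @return The validated frames, class `photometry_session`, with attribute
#'   `rate_hz`.
#' @export
photometry_session <- function(frames, rate_hz) {
  need <- c("frame_index", "t_s", "channel", "roi_signal", "roi_control")
  miss <- setdiff(need, names(frames))
  if (length(miss)) {
    stop("session frames missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!rate_hz %in% c(10, 15)) stop("`rate_hz` must be 10 or 15")
  if (is.unsorted(frames$t_s, strictly = TRUE)) {
    stop("frame timestamps must be strictly increasing")
  }
  bad <- setdiff(unique(frames$channel), c("405", "473", "off"))
  if (length(bad)) stop("unknown channel label(s): ", paste(bad, collapse = ", "))
  structure(frames, class = c("photometry_session", "data.frame"),
            rate_hz = rate_hz)
}

#' @export
print.photometry_session <- function(x, ...) {
  tab <- table(x$channel)
  cat(sprintf(
    "<photometry_session> %d frames (%s), %g Hz per channel, %.1f s\n",
    nrow(x),
    paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
    attr(x, "rate_hz"), diff(range(x$t_s))))
  invisible(x)
}

new_channel_pair <- function(t_s, s473, s405, c473, c405, rate_hz,
                             n_dropped = 0L, background = NULL,
                             background_subtracted = FALSE, r2 = list()) {
  structure(list(t_s = t_s, s473 = s473, s405 = s405, c473 = c473,
                 c405 = c405, rate_hz = rate_hz, n_dropped = n_dropped,
                 background = background,
                 background_subtracted = background_subtracted, r2 = r2),
            class = "channel_pair")
}

#' @export
print.channel_pair <- function(x, ...) {
  cat(sprintf(
    "<channel_pair> %d paired samples at %g Hz (%d frame(s) dropped)%s\n",
    length(x$t_s), x$rate_hz, x$n_dropped,
    if (x$background_subtracted) ", background-subtracted" else ""))
  invisible(x)
}

#' Demultiplex an interleaved frame stream into paired 405/473 samples
#'
#' Splits the laser-on frames into the isosbestic (405 nm) and
#' calcium-dependent (473 nm) channels and pairs each 473 frame with the
#' immediately preceding 405 frame, so both channels share one sample grid
#' timestamped at the 473 frame. Unpaired leading/trailing frames are
#' dropped with a warning carrying the count. Two consecutive laser-on
#' frames with the same channel label violate the multiplexing contract and
#' raise an error naming the frame index.
#'
#' @param session A [photometry_session()].
#' @return A `channel_pair`: per-sample times `t_s` and the four series
#'   `s473`, `s405` (signal fiber) and `c473`, `c405` (control fiber).
#' @export
demultiplex <- function(session) {
  stopifnot(inherits(session, "photometry_session"))
  on <- session[session$channel != "off", , drop = FALSE]
  if (nrow(on) < 2L) stop("session contains fewer than two laser-on frames")
  ch <- on$channel
  same <- which(ch[-1L] == ch[-length(ch)])
  if (length(same)) {
    stop(sprintf(
      "channel alternation violated: consecutive %s frames at frame index %d",
      ch[same[1L] + 1L], on$frame_index[same[1L] + 1L]))
  }
  i473 <- which(ch == "473")
  keep <- i473[i473 > 1L]
  n_dropped <- nrow(on) - 2L * length(keep)
  if (length(keep) == 0L) stop("no 405/473 frame pairs found")
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d unpaired laser-on frame(s) at session edges",
                    n_dropped))
  }
  new_channel_pair(
    t_s = on$t_s[keep],
    s473 = on$roi_signal[keep], s405 = on$roi_signal[keep - 1L],
    c473 = on$roi_control[keep], c405 = on$roi_control[keep - 1L],
    rate_hz = attr(session, "rate_hz"), n_dropped = as.integer(n_dropped))
}

#' Subtract the laser-off background from both fibers
#'
#' Averages the frames acquired without laser transmission (`channel ==
#' "off"`) and subtracts the mean background of the signal-fiber ROI from
#' both signal channels, and of the control-fiber ROI from both control
#' channels. Negative values are permitted (with a warning) when the
#' background exceeds a sample.
#'
#' @param pair A `channel_pair` from [demultiplex()].
#' @param session The originating [photometry_session()] (source of the
#'   background frames).
#' @return The pair with background-subtracted series and the background
#'   means recorded.
#' @export
subtract_background <- function(pair, session) {
  stopifnot(inherits(pair, "channel_pair"),
            inherits(session, "photometry_session"))
  off <- session[session$channel == "off", , drop = FALSE]
  if (nrow(off) == 0L) {
    stop("no background ('off') frames present; cannot subtract background")
  }
  bg_sig <- mean(off$roi_signal)
  bg_ctl <- mean(off$roi_control)
  out <- pair
  out$s473 <- pair$s473 - bg_sig
  out$s405 <- pair$s405 - bg_sig
  out$c473 <- pair$c473 - bg_ctl
  out$c405 <- pair$c405 - bg_ctl
  if (any(out$s473 < 0) || any(out$s405 < 0)) {
    warning("background exceeds some signal frames; negative values retained")
  }
  out$background <- c(signal = bg_sig, control = bg_ctl)
  out$background_subtracted <- TRUE
  out
}

ols_residuals <- function(y, x) {
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(residuals = unname(fit$residuals), r2 = r2)
}

#' Stage 1: regress each signal channel on its control-fluorophore channel
#'
#' Removes laser-power fluctuation by ordinary least squares (with
#' intercept) of the 473 and 405 nm signal-fiber series on their
#' time-matched control-fiber series; each series is replaced by its
#' regression residuals. A zero-variance control series is an error unless
#' `fallback = TRUE`, in which case the channel is mean-centered instead
#' (intercept-only fit).
#'
#' @param pair A background-subtracted `channel_pair`.
#' @param fallback Use mean-subtraction when a control series is constant.
#' @return The pair with `s473`/`s405` replaced by residuals; stage R^2
#'   stored in `$r2`.
#' @export
regress_out_control <- function(pair, fallback = FALSE) {
  stopifnot(inherits(pair, "channel_pair"))
  out <- pair
  for (chan in c("473", "405")) {
    y <- pair[[paste0("s", chan)]]
    x <- pair[[paste0("c", chan)]]
    if (stats::var(x) <= 0) {
      if (!fallback) {
        stop(sprintf(paste0(
          "control series for the %s channel has zero variance; ",
          "set `fallback = TRUE` to mean-center instead"), chan))
      }
      out[[paste0("s", chan)]] <- y - mean(y)
      out$r2[[paste0("control_", chan)]] <- 0
    } else {
      fit <- ols_residuals(y, x)
      out[[paste0("s", chan)]] <- fit$residuals
      out$r2[[paste0("control_", chan)]] <- fit$r2
    }
  }
  out
}

#' Stage 2: regress the 473 nm residuals on the 405 nm residuals
#'
#' Removes motion and other shared artifacts by ordinary least squares
#' (with intercept) of the calcium-dependent residuals on the isosbestic
#' residuals; under the isosbestic assumption the 405 nm channel carries
#' the artifacts but none of the calcium signal, so the residuals of this
#' regression retain the transients.
#'
#' @param pair A `channel_pair` after [regress_out_control()].
#' @return Numeric residual series with attribute `r2`.
#' @export
regress_out_isosbestic <- function(pair) {
  stopifnot(inherits(pair, "channel_pair"))
  if (stats::var(pair$s405) <= 0) {
    stop("405 nm residual series has zero variance; cannot regress")
  }
  fit <- ols_residuals(pair$s473, pair$s405)
  structure(fit$residuals, r2 = fit$r2)
}

#' Session-level z-scoring
#'
#' Standardizes a residual series over the whole session:
#' `(x - mean(x)) / sd(x)`.
#'
#' @param residuals Numeric series (>= 2 samples, nonzero variance).
#' @return Numeric z-score series with mean 0 and SD 1.
#' @export
zscore_session <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 2L) stop("need at least 2 samples to z-score")
  s <- stats::sd(residuals)
  if (!is.finite(s) || s <= 0) {
    stop("residual series has zero variance; cannot z-score")
  }
  (residuals - mean(residuals)) / s
}

new_processed_trace <- function(t_s, z, sample_rate_hz, diagnostics = list()) {
  structure(list(t_s = t_s, z = z, sample_rate_hz = sample_rate_hz,
                 diagnostics = diagnostics),
            class = "processed_trace")
}

#' Assemble a processed trace from a time grid and signal values
#'
#' Mainly for constructing reference traces in analyses and tests; the
#' pipeline builds its traces through [process_session()].
#'
#' @param t_s Uniform sample times (s).
#' @param z Signal values (one per sample).
#' @param sample_rate_hz Sampling rate; inferred from `t_s` when missing.
#' @return A `processed_trace`.
#' @export
processed_trace <- function(t_s, z, sample_rate_hz = NULL) {
  if (length(t_s) != length(z)) stop("`t_s` and `z` lengths differ")
  dt <- assert_uniform_sampling(t_s, "trace")
  if (is.null(sample_rate_hz)) sample_rate_hz <- 1 / dt
  new_processed_trace(t_s, as.numeric(z), sample_rate_hz)
}

#' Full photometry processing chain
#'
#' Runs the four-stage chain on a raw session: demultiplex the interleaved
#' 405/473 frame stream, subtract the laser-off background, regress each
#' channel on its control-fluorophore series (laser-power correction),
#' regress the 473 nm residuals on the 405 nm residuals (shared-artifact
#' correction), and z-score the final residuals over the session. Two
#' sequential regressions rather than one multiple regression keep each
#' noise source's correction interpretable and match the order in which
#' the artifacts enter the optical path. Bleaching is absorbed by the
#' regression stages; an optional linear pre-detrend is available but off
#' by default.
#'
#' @param session A [photometry_session()].
#' @param detrend Remove a linear trend from both signal channels before the
#'   regressions (default `FALSE`).
#' @param control_fallback Passed to [regress_out_control()]: mean-center a
#'   channel whose control series is constant instead of failing.
#' @return A `processed_trace` with elements `t_s`, `z` (mean 0, SD 1),
#'   `sample_rate_hz`, and `diagnostics` (per-stage R^2, dropped-frame
#'   count, background means).
#' @examples
#' sim <- simulate_standard_session(seed = 1, duration_s = 60)
#' tr <- process_session(sim$session)
#' tr
#' @export
process_session <- function(session, detrend = FALSE,
                            control_fallback = FALSE) {
  pair <- demultiplex(session)
  pair <- subtract_background(pair, session)
  if (detrend) {
    pair$s473 <- ols_residuals(pair$s473, pair$t_s)$residuals
    pair$s405 <- ols_residuals(pair$s405, pair$t_s)$residuals
  }
  pair <- regress_out_control(pair, fallback = control_fallback)
  res <- regress_out_isosbestic(pair)
  z <- zscore_session(res)
  diagnostics <- list(
    n_dropped_frames = pair$n_dropped,
    background_signal = unname(pair$background["signal"]),
    background_control = unname(pair$background["control"]),
    r2_control_473 = pair$r2$control_473,
    r2_control_405 = pair$r2$control_405,
    r2_isosbestic = unname(attr(res, "r2")))
  new_processed_trace(pair$t_s, z, pair$rate_hz, diagnostics)
}

#' @export
print.processed_trace <- function(x, ...) {
  cat(sprintf("<processed_trace> %d samples at %g Hz (%.1f s)\n",
              length(x$z), x$sample_rate_hz, diff(range(x$t_s))))
  if (length(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf(
      "  stage R^2: control 473 %.3f, control 405 %.3f, isosbestic %.3f\n",
      d$r2_control_473, d$r2_control_405, d$r2_isosbestic))
    cat(sprintf("  dropped frames: %d, background (signal/control): %.3g/%.3g\n",
                d$n_dropped_frames, d$background_signal, d$background_control))
  }
  invisible(x)
}

#' @export
summary.processed_trace <- function(object, ...) {
  z <- object$z
  out <- c(n = length(z), mean = mean(z), sd = stats::sd(z),
           min = min(z), max = max(z))
  cat(sprintf(
    "Processed photometry trace: %d samples, mean %.2e, sd %.6f, range [%.2f, %.2f]\n",
    out["n"], out["mean"], out["sd"], out["min"], out["max"]))
  invisible(out)
}

#' @export
as.data.frame.processed_trace <- function(x, ...) {
  data.frame(t_s = x$t_s, z = x$z)
}

#' @export
plot.processed_trace <- function(x, events = NULL, xlab = "time (s)",
                                 ylab = "z-score", type = "l", ...) {
  graphics::plot(x$t_s, x$z, type = type, xlab = xlab, ylab = ylab, ...)
  if (!is.null(events)) graphics::abline(v = events, col = "red", lty = 3)
  invisible(x)
}
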