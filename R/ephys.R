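#' Construct a current-clamp sweep
#'
#' @param t_s Sample times (s), uniform, >= 10 kHz recommended for action
#'   potential work.
#' @param vm_mv Membrane potential (mV).
#' @param i_pa Injected current (pA), one value per sample.
#' @param step List with `onset_s`, `offset_s`, `amplitude_pa` describing
#'   the current step.
#' @return An object of class `current_clamp_sweep`.
#' @export
current_clamp_sweep <- function(t_s, vm_mv, i_pa, step) {
  if (length(t_s) != length(vm_mv) || length(t_s) != length(i_pa)) {
    stop("`t_s`, `vm_mv`, `i_pa` must have equal length")
  }
  dt <- assert_uniform_sampling(t_s, "sweep")
  if (!all(c("onset_s", "offset_s", "amplitude_pa") %in% names(step))) {
    stop("`step` needs onset_s, offset_s, amplitude_pa")
  }
  if (step$offset_s <= step$onset_s) stop("step offset must follow onset")
  structure(list(t_s = t_s, vm_mv = vm_mv, i_pa = i_pa, step = step,
                 fs_hz = 1 / dt),
            class = "current_clamp_sweep")
}

#' @export
print.current_clamp_sweep <- function(x, ...) {
  cat(sprintf(
    "<current_clamp_sweep> %.3f s at %.0f kHz, %+g pA step %.3f-%.3f s\n",
    diff(range(x$t_s)), x$fs_hz / 1000, x$step$amplitude_pa,
    x$step$onset_s, x$step$offset_s))
  invisible(x)
}

# Additive action-potential template: piecewise-linear waveform (ms from
# peak -> mV above local baseline) with a slow depolarizing foot (10 mV/ms)
# ending 20 mV above baseline, a fast upstroke (100 mV/ms) to a peak 90 mV
# above baseline, repolarization with a 5 mV afterhyperpolarization.
ap_template <- function(fs_hz, threshold_delta_mv = 20) {
  knots_ms <- c(-2.7, -0.7, 0, 1.5, 3.5)
  knots_mv <- c(0, threshold_delta_mv, 90, -5, 0)
  tt <- seq(-2.7e-3, 3.5e-3, by = 1 / fs_hz)
  stats::approx(knots_ms / 1000, knots_mv, xout = tt, rule = 2)$y
}

#' Simulate a current-clamp sweep with template action potentials
#'
#' Membrane response to a square current step (exponential charging toward
#' a steady-state deflection of `step_pa * rin_mohm / 1000` mV) with
#' stereotyped action potentials superposed so that their peaks land at
#' `spike_times_s` (snapped to the sample grid). The template's
#' depolarizing foot turns into its fast upstroke 20 mV above the local
#' baseline, which defines the ground-truth threshold voltage.
#'
#' @param spike_times_s Action-potential peak times (s); spikes closer than
#'   2 ms are rejected.
#' @param step_onset_s,step_offset_s Current-step window (s).
#' @param step_pa Step amplitude (pA).
#' @param rin_mohm Input resistance (megaohm).
#' @param duration_s Sweep length (s), default covers the step plus 0.4 s.
#' @param tau_m_s Membrane time constant (s), default 0.02.
#' @param rest_mv Resting potential (mV), default -60.
#' @param noise_sd_mv Gaussian voltage noise SD (mV), default 0.
#' @param fs_hz Sampling rate (Hz), default 10000.
#' @param seed Optional integer seed.
#' @return A `current_clamp_sweep` with attribute `truth`: list with the
#'   grid-snapped `spike_times_s`, `threshold_mv`, `rin_mohm`, `rest_mv`.
#' @export
simulate_current_clamp <- function(spike_times_s = numeric(),
                                   step_onset_s = 0.1, step_offset_s = 0.6,
                                   step_pa = 0, rin_mohm = 100,
                                   duration_s = NULL, tau_m_s = 0.02,
                                   rest_mv = -60, noise_sd_mv = 0,
                                   fs_hz = 10000, seed = NULL) {
  if (is.null(duration_s)) duration_s <- step_offset_s + 0.4
  spike_times_s <- sort(as.numeric(spike_times_s))
  if (length(spike_times_s)) {
    if (min(spike_times_s) < 0.005 ||
        max(spike_times_s) > duration_s - 0.005) {
      stop("spike times must lie inside the sweep (5 ms margin)")
    }
    if (length(spike_times_s) > 1L && min(diff(spike_times_s)) < 0.002) {
      stop("overlapping spikes: times closer than 2 ms")
    }
  }
  with_seed(seed, {
    n <- as.integer(round(duration_s * fs_hz))
    t_s <- (seq_len(n) - 1L) / fs_hz
    defl <- step_pa * rin_mohm / 1000  # pA * Mohm = uV; /1000 -> mV
    h <- numeric(n)
    during <- t_s >= step_onset_s & t_s < step_offset_s
    after <- t_s >= step_offset_s
    h[during] <- 1 - exp(-(t_s[during] - step_onset_s) / tau_m_s)
    h_end <- 1 - exp(-(step_offset_s - step_onset_s) / tau_m_s)
    h[after] <- h_end * exp(-(t_s[after] - step_offset_s) / tau_m_s)
    vm <- rest_mv + defl * h
    tpl <- ap_template(fs_hz)
    n_pre <- as.integer(round(2.7e-3 * fs_hz))
    snapped <- numeric(length(spike_times_s))
    for (j in seq_along(spike_times_s)) {
      pk <- as.integer(round(spike_times_s[j] * fs_hz)) + 1L
      snapped[j] <- t_s[pk]
      idx <- (pk - n_pre):(pk - n_pre + length(tpl) - 1L)
      keep <- idx >= 1L & idx <= n
      vm[idx[keep]] <- vm[idx[keep]] + tpl[keep]
    }
    if (noise_sd_mv > 0) vm <- vm + stats::rnorm(n, 0, noise_sd_mv)
    i_pa <- ifelse(during, step_pa, 0)
    sweep <- current_clamp_sweep(t_s, vm, i_pa,
                                 list(onset_s = step_onset_s,
                                      offset_s = step_offset_s,
                                      amplitude_pa = step_pa))
    attr(sweep, "truth") <- list(spike_times_s = snapped,
                                 threshold_mv = rest_mv + defl *
                                   h[pmax(as.integer(round(snapped * fs_hz)) + 1L, 1L)] + 20,
                                 rin_mohm = rin_mohm, rest_mv = rest_mv)
    sweep
  })
}

#' Detect action potentials
#'
#' Finds local voltage maxima above `vm_threshold_mv` whose preceding 2 ms
#' contain a depolarization rate of at least `dvdt_threshold` mV/ms, and
#' enforces a refractory period.
#'
#' @param sweep A `current_clamp_sweep`.
#' @param vm_threshold_mv Peak must exceed this voltage (mV), default -20.
#' @param dvdt_threshold Upstroke criterion (mV/ms), default 20.
#' @param refractory_s Minimum spacing between detected spikes (s),
#'   default 0.002.
#' @return Numeric vector of spike (peak) times (s).
#' @export
detect_spikes <- function(sweep, vm_threshold_mv = -20, dvdt_threshold = 20,
                          refractory_s = 0.002) {
  stopifnot(inherits(sweep, "current_clamp_sweep"))
  v <- sweep$vm_mv
  n <- length(v)
  dt_ms <- 1000 / sweep$fs_hz
  peaks <- which(v[-c(1L, 2L)] < v[-c(1L, n)] &
                 v[-c(n - 1L, n)] <= v[-c(1L, n)]) + 1L
  peaks <- peaks[v[peaks] > vm_threshold_mv]
  if (length(peaks) == 0L) return(numeric())
  dvdt <- c(0, diff(v)) / dt_ms
  w <- as.integer(round(0.002 * sweep$fs_hz))
  keep <- vapply(peaks, function(p) {
    lo <- max(2L, p - w)
    max(dvdt[lo:p]) >= dvdt_threshold
  }, logical(1))
  peaks <- peaks[keep]
  if (length(peaks) == 0L) return(numeric())
  times <- sweep$t_s[peaks]
  out <- times[1L]
  for (tm in times[-1L]) {
    if (tm - out[length(out)] >= refractory_s) out <- c(out, tm)
  }
  out
}

#' Action-potential threshold voltage
#'
#' Voltage at the first sample, scanning toward the spike peak, at which
#' the depolarization rate reaches `dvdt_criterion` mV/ms.
#'
#' @param sweep A `current_clamp_sweep`.
#' @param spike_time_s Peak time of the spike (s).
#' @param dvdt_criterion Threshold criterion (mV/ms), default 20.
#' @param search_window_s How far before the peak to search (s),
#'   default 0.005.
#' @return Threshold voltage (mV).
#' @export
ap_threshold <- function(sweep, spike_time_s, dvdt_criterion = 20,
                         search_window_s = 0.005) {
  stopifnot(inherits(sweep, "current_clamp_sweep"))
  fs <- sweep$fs_hz
  pk <- as.integer(round((spike_time_s - sweep$t_s[1L]) * fs)) + 1L
  lo <- max(1L, pk - as.integer(round(search_window_s * fs)))
  # forward difference: dV/dt attributed to the sample where the upstroke
  # begins, so the returned voltage is the kink itself
  dvdt <- diff(sweep$vm_mv[lo:pk]) * fs / 1000
  hit <- which(dvdt >= dvdt_criterion)
  if (length(hit) == 0L) {
    stop(sprintf("dV/dt never reaches %g mV/ms before the spike at %.4f s",
                 dvdt_criterion, spike_time_s))
  }
  sweep$vm_mv[lo + hit[1L] - 1L]
}

#' Maximum firing rate from the first six action potentials
#'
#' Rate over the first six spikes of the current step: five inter-spike
#' intervals spanning `t6 - t1`, i.e. `5 / (t6 - t1)` Hz. With fewer than
#' six spikes in the step the rate is undefined and flagged.
#'
#' @param spike_times_s Spike times (s).
#' @param step_window Numeric `c(onset_s, offset_s)` of the current step;
#'   `NULL` uses all supplied spikes.
#' @return List with `rate_hz` (`NA` when undefined), `defined`, `n_aps`.
#' @export
max_firing_rate <- function(spike_times_s, step_window = NULL) {
  st <- sort(as.numeric(spike_times_s))
  if (!is.null(step_window)) {
    st <- st[st >= step_window[1L] & st <= step_window[2L]]
  }
  if (length(st) < 6L) {
    return(list(rate_hz = NA_real_, defined = FALSE, n_aps = length(st)))
  }
  list(rate_hz = 5 / (st[6L] - st[1L]), defined = TRUE, n_aps = length(st))
}

#' Spike-frequency accommodation index
#'
#' Mean local contrast of successive inter-spike intervals over the current
#' step that elicited maximum firing:
#' `A = mean over i of (ISI_i - ISI_(i-1)) / (ISI_i + ISI_(i-1))`.
#' Positive values indicate spike-frequency adaptation (lengthening
#' intervals); a constant-rate train gives 0.
#'
#' @param isis_s Inter-spike intervals (s), at least 3.
#' @param excluded_depol_block Set `TRUE` when the sweep failed to maintain
#'   sustained firing (depolarization block); such sweeps are excluded and
#'   raise an error.
#' @return Dimensionless index in `[-1, 1]`.
#' @export
accommodation_index <- function(isis_s, excluded_depol_block = FALSE) {
  if (isTRUE(excluded_depol_block)) {
    stop("sweep excluded: depolarization block (no sustained firing)")
  }
  isis_s <- as.numeric(isis_s)
  if (length(isis_s) < 3L) stop("need at least 3 inter-spike intervals")
  if (any(isis_s <= 0)) stop("inter-spike intervals must be positive")
  n <- length(isis_s)
  contrasts <- (isis_s[-1L] - isis_s[-n]) / (isis_s[-1L] + isis_s[-n])
  mean(contrasts)
}

#' Flag a sweep that fails to maintain sustained firing
#'
#' Heuristic for depolarization block on a current step: firing is
#' considered sustained when the last spike falls within the final
#' `max_silent_frac` of the step. No spikes at all also flags the sweep.
#'
#' @param spike_times_s Spike times (s).
#' @param step_onset_s,step_offset_s Step window (s).
#' @param max_silent_frac Tolerated silent tail as a fraction of the step
#'   duration, default 0.3.
#' @return Logical flag.
#' @export
is_depolarization_block <- function(spike_times_s, step_onset_s,
                                    step_offset_s, max_silent_frac = 0.3) {
  st <- spike_times_s[spike_times_s >= step_onset_s &
                      spike_times_s <= step_offset_s]
  if (length(st) == 0L) return(TRUE)
  (step_offset_s - max(st)) > max_silent_frac * (step_offset_s - step_onset_s)
}

#' Input resistance from a hyperpolarizing current step
#'
#' Steady-state voltage deflection (mean over the last 20% of the step,
#' relative to the 50 ms pre-step baseline) divided by the step current:
#' `|dV| (mV) / |I| (nA)` in megaohms. The sweep's step amplitude must
#' match `expected_step_pa`.
#'
#' @param sweep A `current_clamp_sweep` containing the hyperpolarizing
#'   step.
#' @param expected_step_pa Required step amplitude (pA), default -140.
#' @return Input resistance (megaohm).
#' @export
input_resistance <- function(sweep, expected_step_pa = -140) {
  stopifnot(inherits(sweep, "current_clamp_sweep"))
  if (abs(sweep$step$amplitude_pa - expected_step_pa) > 1e-6) {
    stop(sprintf("step amplitude is %g pA, expected %g pA",
                 sweep$step$amplitude_pa, expected_step_pa))
  }
  on <- sweep$step$onset_s
  off <- sweep$step$offset_s
  base <- mean(sweep$vm_mv[sweep$t_s >= on - 0.05 & sweep$t_s < on])
  ss <- mean(sweep$vm_mv[sweep$t_s >= off - 0.2 * (off - on) &
                         sweep$t_s < off])
  if (!is.finite(base) || !is.finite(ss)) {
    stop("sweep lacks baseline or steady-state samples around the step")
  }
  abs(ss - base) / (abs(expected_step_pa) / 1000)
}

#' Post-hyperpolarization rebound burst
#'
#' Counts action potentials within a window after the offset of a
#' hyperpolarizing step and reports their mean inter-spike interval.
#'
#' @param sweep A `current_clamp_sweep` with a hyperpolarizing step.
#' @param window_s Post-offset window (s), default 0.3 (inclusive upper
#'   bound).
#' @param ... Passed to [detect_spikes()].
#' @return List with `n_aps` and `mean_isi_s` (`NA` with fewer than two
#'   spikes).
#' @export
rebound_burst <- function(sweep, window_s = 0.3, ...) {
  stopifnot(inherits(sweep, "current_clamp_sweep"))
  if (sweep$step$amplitude_pa >= 0) {
    stop("rebound burst requires a hyperpolarizing step")
  }
  st <- detect_spikes(sweep, ...)
  off <- sweep$step$offset_s
  st <- st[st > off & st <= off + window_s]
  list(n_aps = length(st),
       mean_isi_s = if (length(st) >= 2L) mean(diff(st)) else NA_real_)
}

#' Intrinsic-feature table for one cell
#'
#' Convenience wrapper running the feature extractors over a family of
#' current-step sweeps from one cell: spikes are detected on every sweep,
#' the depolarizing step with the most action potentials supplies the
#' maximum firing rate, accommodation index, and AP threshold (first
#' spike); a -140 pA sweep, when present, supplies input resistance and
#' the rebound burst.
#'
#' @param sweeps List of `current_clamp_sweep` objects.
#' @param cell_id Label for the output row.
#' @return One-row data frame of features.
#' @export
extract_spike_features <- function(sweeps, cell_id = "cell") {
  stopifnot(length(sweeps) >= 1L)
  spk <- lapply(sweeps, detect_spikes)
  in_step <- function(i) {
    s <- sweeps[[i]]
    spk[[i]][spk[[i]] >= s$step$onset_s & spk[[i]] <= s$step$offset_s]
  }
  depol <- which(vapply(sweeps, function(s) s$step$amplitude_pa > 0,
                        logical(1)))
  best <- if (length(depol)) {
    depol[which.max(vapply(depol, function(i) length(in_step(i)),
                           integer(1)))]
  } else NA_integer_
  thr <- NA_real_; rate <- list(rate_hz = NA_real_, defined = FALSE)
  acc <- NA_real_; block <- NA
  if (!is.na(best)) {
    st <- in_step(best)
    s <- sweeps[[best]]
    block <- is_depolarization_block(st, s$step$onset_s, s$step$offset_s)
    if (length(st)) thr <- ap_threshold(s, st[1L])
    rate <- max_firing_rate(st)
    if (length(st) >= 4L && !block) acc <- accommodation_index(diff(st))
  }
  hyp <- which(vapply(sweeps, function(s)
    abs(s$step$amplitude_pa + 140) < 1e-6, logical(1)))
  rin <- NA_real_; reb <- list(n_aps = NA_integer_, mean_isi_s = NA_real_)
  if (length(hyp)) {
    rin <- input_resistance(sweeps[[hyp[1L]]])
    reb <- rebound_burst(sweeps[[hyp[1L]]])
  }
  data.frame(cell_id = cell_id,
             n_sweeps = length(sweeps),
             ap_threshold_mv = thr,
             max_rate_hz = rate$rate_hz,
             max_rate_defined = rate$defined,
             accommodation_index = acc,
             excluded_depol_block = block,
             input_resistance_mohm = rin,
             rebound_n_aps = reb$n_aps,
             rebound_mean_isi_s = reb$mean_isi_s)
}
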