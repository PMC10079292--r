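#' Calcium-transient kernel (difference of exponentials)
#'
#' Unit-peak-amplitude impulse response used to model the fluorescence
#' transient evoked by a burst of activity under a slow calcium indicator
#' (GCaMP6s-like kinetics by default). The kernel is zero for `t < 0`,
#' rises with time constant `rise_s` and decays with `decay_s`, and is
#' normalized so its maximum equals 1.
#'
#' @param t Times in seconds relative to the event onset.
#' @param rise_s Rise time constant (s), default 0.2.
#' @param decay_s Decay time constant (s), default 1.5; must exceed `rise_s`.
#' @return Numeric vector of kernel values, peak value 1.
#' @examples
#' tt <- seq(0, 6, by = 0.01)
#' k <- transient_kernel(tt)
#' max(k)  # 1
#' @export
transient_kernel <- function(t, rise_s = 0.2, decay_s = 1.5) {
  stop_if_not_scalar_number(rise_s, "rise_s", positive = TRUE)
  stop_if_not_scalar_number(decay_s, "decay_s", positive = TRUE)
  if (decay_s <= rise_s) stop("`decay_s` must exceed `rise_s`")
  raw <- ifelse(t < 0, 0, exp(-t / decay_s) - exp(-t / rise_s))
  t_peak <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
  peak <- exp(-t_peak / decay_s) - exp(-t_peak / rise_s)
  raw / peak
}

#' Shared motion/noise artifact series (sinusoid plus random walk)
#'
#' Generates the artifact waveform injected identically into the 405 and
#' 473 nm channels by the session simulator: a slow sinusoid (cable sway)
#' superposed on a Gaussian random walk (slow baseline wander).
#'
#' @param n Number of channel-rate samples.
#' @param dt Sampling interval (s) at the channel rate.
#' @param sin_amplitude Sinusoid amplitude (fluorescence units), default 0.5.
#' @param sin_freq_hz Sinusoid frequency (Hz), default 0.3.
#' @param walk_sd Per-step standard deviation of the random walk, default 0.01.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
sim_artifact <- function(n, dt, sin_amplitude = 0.5, sin_freq_hz = 0.3,
                         walk_sd = 0.01, seed = NULL) {
  stop_if_not_scalar_number(dt, "dt", positive = TRUE)
  with_seed(seed, {
    tt <- (seq_len(n) - 1L) * dt
    sin_amplitude * sin(2 * pi * sin_freq_hz * tt) +
      cumsum(stats::rnorm(n, 0, walk_sd))
  })
}

#' Configuration for the photometry session simulator
#'
#' Bundles and validates all parameters of [simulate_photometry_session()].
#' Defaults describe the reference synthetic condition used throughout the
#' package's tests: a GCaMP6s-like transient kernel, slow single-exponential
#' photobleaching, moderate frame noise, and a bright control fluorophore.
#'
#' @param duration_s Session duration in seconds (> 0).
#' @param rate_hz Per-channel multiplex rate; one of 10 or 15 Hz (the frame
#'   train alternates the two lasers at twice this rate).
#' @param transient_amplitude Peak amplitude of each calcium transient
#'   (fluorescence units above the bleaching baseline).
#' @param kernel_rise_s,kernel_decay_s Transient kernel time constants (s).
#' @param artifact Additive artifact shared sample-for-sample by the 405 and
#'   473 channels: `NULL` (none), a numeric vector at the channel rate, or a
#'   function of time `f(t_s)`.
#' @param laser_drift Multiplicative laser-power series applied to the signal
#'   and control fibers: `NULL` (constant 1), a numeric vector at the channel
#'   rate, or a function of time.
#' @param bleach_tau_s Photobleaching time constant (s), default 600.
#' @param bleach_amplitude Initial bleachable fluorescence (units), default 2.
#' @param noise_sd Per-frame Gaussian noise SD (units), default 0.05.
#' @param background_level Camera background level (units), default 1.
#' @param control_level Control-fluorophore brightness (units), default 5.
#' @param background_s Duration of the leading laser-off background block (s),
#'   default 2 (at least 1 s of background frames is always emitted).
#' @param seed Optional integer seed; a fixed seed makes the simulated
#'   session byte-identical across calls.
#' @return An object of class `photometry_sim_config`.
#' @seealso [simulate_photometry_session()]
#' @export
photometry_sim_config <- function(duration_s, rate_hz = 15,
                                  transient_amplitude = 1,
                                  kernel_rise_s = 0.2, kernel_decay_s = 1.5,
                                  artifact = NULL, laser_drift = NULL,
                                  bleach_tau_s = 600, bleach_amplitude = 2,
                                  noise_sd = 0.05, background_level = 1,
                                  control_level = 5, background_s = 2,
                                  seed = NULL) {
  stop_if_not_scalar_number(duration_s, "duration_s", positive = TRUE)
  if (!rate_hz %in% c(10, 15)) {
    stop("`rate_hz` must be 10 or 15 (per-channel multiplex rate)")
  }
  stop_if_not_scalar_number(transient_amplitude, "transient_amplitude",
                            nonnegative = TRUE)
  stop_if_not_scalar_number(bleach_tau_s, "bleach_tau_s", positive = TRUE)
  stop_if_not_scalar_number(bleach_amplitude, "bleach_amplitude",
                            nonnegative = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  stop_if_not_scalar_number(background_s, "background_s", positive = TRUE)
  if (background_s < 1) stop("`background_s` must be at least 1 s")
  cfg <- list(duration_s = duration_s, rate_hz = rate_hz,
              transient_amplitude = transient_amplitude,
              kernel_rise_s = kernel_rise_s, kernel_decay_s = kernel_decay_s,
              artifact = artifact, laser_drift = laser_drift,
              bleach_tau_s = bleach_tau_s, bleach_amplitude = bleach_amplitude,
              noise_sd = noise_sd, background_level = background_level,
              control_level = control_level, background_s = background_s,
              seed = seed)
  class(cfg) <- "photometry_sim_config"
  cfg
}

#' Frame counts of a simulated session
#'
#' Number of leading background frames and of per-channel (405/473 pair)
#' samples a session of the given duration contains. Useful for sizing a
#' user-supplied `artifact` or `laser_drift` vector.
#'
#' @param duration_s Session duration (s).
#' @param rate_hz Per-channel multiplex rate (10 or 15 Hz).
#' @param background_s Leading laser-off block duration (s).
#' @return List with `n_background` (frames) and `n_channel` (samples per
#'   channel).
#' @export
session_frame_counts <- function(duration_s, rate_hz = 15, background_s = 2) {
  n_frames <- as.integer(floor(duration_s * 2 * rate_hz + 1e-9))
  n_bg <- as.integer(ceiling(background_s * 2 * rate_hz - 1e-9))
  list(n_background = n_bg,
       n_channel = as.integer((n_frames - n_bg) %/% 2L))
}

eval_series <- function(x, t_s, n, name) {
  if (is.null(x)) return(NULL)
  if (is.function(x)) return(x(t_s))
  if (is.numeric(x)) {
    if (length(x) == 1L) return(rep(x, n))
    if (length(x) != n) {
      stop(sprintf("`%s` must have one value per channel sample (%d), got %d",
                   name, n, length(x)))
    }
    return(x)
  }
  stop(sprintf("`%s` must be NULL, a numeric vector, or a function of time",
               name))
}

#' Simulate a multiplexed two-wavelength photometry session
#'
#' Emits a frame stream emulating a dual-laser photometry rig: a leading
#' block of laser-off background frames, then frames alternating 405 nm /
#' 473 nm at twice the per-channel rate. The 473 nm (calcium-dependent)
#' channel carries kernel-convolved transients at the requested event times
#' plus bleaching, the shared artifact, and noise; the 405 nm (isosbestic)
#' channel carries everything except the transients; the control-fluorophore
#' fiber sees only laser power (drift) and noise. Ground truth (the clean
#' unit-amplitude transient trace and the artifact) is returned alongside.
#'
#' @param cfg A [photometry_sim_config()].
#' @param events Transient onset times (s); all must lie in
#'   `[0, duration_s]`. Events falling inside the leading background block
#'   contribute nothing to the laser-on frames before the block ends.
#' @return A list with elements
#'   \describe{
#'     \item{session}{a `photometry_session`: data frame of frames
#'       (`frame_index`, `t_s`, `channel` in \{"405","473","off"\},
#'       `roi_signal`, `roi_control`) with the per-channel rate attached,}
#'     \item{truth}{a list with `t_s` (473-frame times),
#'       `clean_transient_trace` (unit amplitude), `artifact_trace`,
#'       `laser_drift`, and `event_times_s`.}
#'   }
#' @export
simulate_photometry_session <- function(cfg, events = numeric()) {
  stopifnot(inherits(cfg, "photometry_sim_config"))
  events <- sort(as.numeric(events))
  if (length(events) && (min(events) < 0 || max(events) > cfg$duration_s)) {
    stop("all event times must lie within [0, duration_s]")
  }
  with_seed(cfg$seed, {
    dt_frame <- 1 / (2 * cfg$rate_hz)
    counts <- session_frame_counts(cfg$duration_s, cfg$rate_hz,
                                   cfg$background_s)
    n_bg <- counts$n_background
    n_ch <- counts$n_channel
    t_bg <- (seq_len(n_bg) - 1L) * dt_frame
    t_laser0 <- n_bg * dt_frame
    if (n_ch < 2L) stop("`duration_s` too short for the background block")
    t405 <- t_laser0 + (seq_len(n_ch) - 1L) * 2 * dt_frame
    t473 <- t405 + dt_frame

    clean <- rep(0, n_ch)
    for (e in events) {
      clean <- clean + transient_kernel(t473 - e, cfg$kernel_rise_s,
                                        cfg$kernel_decay_s)
    }
    art <- eval_series(cfg$artifact, t473, n_ch, "artifact")
    if (is.null(art)) art <- rep(0, n_ch)
    drift <- eval_series(cfg$laser_drift, t473, n_ch, "laser_drift")
    if (is.null(drift)) drift <- rep(1, n_ch)

    bleach405 <- cfg$bleach_amplitude * exp(-t405 / cfg$bleach_tau_s)
    bleach473 <- cfg$bleach_amplitude * exp(-t473 / cfg$bleach_tau_s)
    noise <- function(n) stats::rnorm(n, 0, cfg$noise_sd)

    sig405 <- cfg$background_level + drift * (bleach405 + art) + noise(n_ch)
    sig473 <- cfg$background_level +
      drift * (bleach473 + cfg$transient_amplitude * clean + art) +
      noise(n_ch)
    ctl405 <- cfg$background_level + drift * cfg$control_level + noise(n_ch)
    ctl473 <- cfg$background_level + drift * cfg$control_level + noise(n_ch)
    bg_sig <- cfg$background_level + noise(n_bg)
    bg_ctl <- cfg$background_level + noise(n_bg)

    t_all <- c(t_bg, as.vector(rbind(t405, t473)))
    ch_all <- c(rep("off", n_bg), rep(c("405", "473"), n_ch))
    sig_all <- c(bg_sig, as.vector(rbind(sig405, sig473)))
    ctl_all <- c(bg_ctl, as.vector(rbind(ctl405, ctl473)))

    frames <- data.frame(frame_index = seq_along(t_all) - 1L, t_s = t_all,
                         channel = ch_all, roi_signal = sig_all,
                         roi_control = ctl_all)
    session <- photometry_session(frames, rate_hz = cfg$rate_hz)
    truth <- list(t_s = t473, clean_transient_trace = clean,
                  artifact_trace = art, laser_drift = drift,
                  event_times_s = events)
    list(session = session, truth = truth)
  })
}

#' Reference synthetic session at the package's default signal-to-noise
#'
#' Convenience wrapper wiring [simulate_photometry_session()] to the
#' package's standard synthetic condition: transient onsets drawn as a
#' Poisson process (mean rate 0.2 Hz, with the transient amplitude and frame
#' noise of [photometry_sim_config()] defaults), the shared sinusoid plus
#' random-walk artifact of [sim_artifact()], and a slow +/-2 % laser-power
#' drift. Used by the artifact-rejection recovery checks.
#'
#' @param seed Integer seed (required; the condition is defined seeded).
#' @param duration_s Session length (s), default 300.
#' @param rate_hz Per-channel rate, default 15.
#' @param event_rate_hz Mean transient rate (Hz), default 0.2.
#' @return As [simulate_photometry_session()].
#' @export
simulate_standard_session <- function(seed, duration_s = 300, rate_hz = 15,
                                      event_rate_hz = 0.2) {
  stop_if_not_scalar_number(seed, "seed")
  with_seed(seed, {
    n_ev <- stats::rpois(1L, event_rate_hz * duration_s)
    events <- sort(stats::runif(n_ev, 3, duration_s - 3))
    n_ch <- session_frame_counts(duration_s, rate_hz)$n_channel
    art <- sim_artifact(n_ch, dt = 1 / rate_hz)
    cfg <- photometry_sim_config(
      duration_s = duration_s, rate_hz = rate_hz,
      artifact = art,
      laser_drift = function(t) 1 + 0.02 * sin(2 * pi * 0.05 * t))
    simulate_photometry_session(cfg, events)
  })
}
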