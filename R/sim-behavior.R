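#' Parse a fixed-ratio schedule name
#'
#' Schedule names follow `FR<N>-<limit>`: `FR5-5s` requires five presses
#' within 5 s of lever extension; `FR1-NTL` requires one press with no time
#' limit.
#'
#' @param schedule Character scalar, e.g. `"FR5-5s"`, `"FR3-NTL"`.
#' @return List with `ratio` (presses required) and `limit_s` (`Inf` for
#'   NTL).
#' @export
parse_schedule <- function(schedule) {
  m <- regmatches(schedule,
                  regexec("^FR([0-9]+)-(NTL|[0-9]+(\\.[0-9]+)?s)$", schedule))[[1L]]
  if (length(m) == 0L) {
    stop(sprintf("unrecognized schedule '%s' (expected e.g. FR5-5s, FR1-NTL)",
                 schedule))
  }
  limit <- if (m[3L] == "NTL") Inf else as.numeric(sub("s$", "", m[3L]))
  list(ratio = as.integer(m[2L]), limit_s = limit)
}

#' Configuration for the operant session simulator
#'
#' @param schedule Fixed-ratio schedule name; one of `FR1-NTL`, `FR3-NTL`,
#'   `FR5-NTL`, `FR5-30s`, `FR5-15s`, `FR5-10s`, `FR5-7.5s`, `FR5-5s`.
#' @param n_trials Number of trials.
#' @param iti_s Inter-trial interval before each lever extension (s),
#'   default 3.
#' @param consumption_s Consumption period after a completed trial (s),
#'   default 8.
#' @param press_rate_hz Rate of the Poisson press process while the animal
#'   is engaged, default 2.
#' @param p_engage Probability a trial has any pressing, default 0.9.
#' @param light_fraction Fraction of trials flagged as light-delivery
#'   trials, default 0 (0.33 in the optogenetic design). The exact
#'   proportion is enforced by seeded shuffling of a fixed label vector.
#' @param light_effect Additive shift of `p_engage` on light trials
#'   (clamped to `[0, 1]`), default 0.
#' @param max_trial_s Cap on lever availability for no-time-limit
#'   schedules, default 60.
#' @param retrieval_mean_s Mean pellet-retrieval latency (s), default 1.
#' @param premature_entry_rate_hz Rate of head entries during the press
#'   sequence, default 0.
#' @param seed Optional integer seed.
#' @return An object of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(schedule = "FR5-5s", n_trials = 50,
                                iti_s = 3, consumption_s = 8,
                                press_rate_hz = 2, p_engage = 0.9,
                                light_fraction = 0, light_effect = 0,
                                max_trial_s = 60, retrieval_mean_s = 1,
                                premature_entry_rate_hz = 0, seed = NULL) {
  allowed <- c("FR1-NTL", "FR3-NTL", "FR5-NTL", "FR5-30s", "FR5-15s",
               "FR5-10s", "FR5-7.5s", "FR5-5s")
  if (!schedule %in% allowed) {
    stop("`schedule` must be one of: ", paste(allowed, collapse = ", "))
  }
  stop_if_not_scalar_number(n_trials, "n_trials", positive = TRUE)
  stop_if_not_scalar_number(iti_s, "iti_s", positive = TRUE)
  stop_if_not_scalar_number(press_rate_hz, "press_rate_hz", positive = TRUE)
  stop_if_not_probability(p_engage, "p_engage")
  stop_if_not_probability(light_fraction, "light_fraction")
  structure(list(schedule = schedule, n_trials = as.integer(n_trials),
                 iti_s = iti_s, consumption_s = consumption_s,
                 press_rate_hz = press_rate_hz, p_engage = p_engage,
                 light_fraction = light_fraction, light_effect = light_effect,
                 max_trial_s = max_trial_s,
                 retrieval_mean_s = retrieval_mean_s,
                 premature_entry_rate_hz = premature_entry_rate_hz,
                 seed = seed),
            class = "behavior_sim_config")
}

#' Simulate a fixed-ratio operant session
#'
#' Generates a timestamped event log for an operant session: each trial is
#' an inter-trial interval, lever extension, a (possibly empty) Poisson
#' press sequence, pellet delivery after the Nth press if it lands within
#' the schedule's time limit, a head entry retrieving the pellet, lever
#' retraction (at retrieval for completed trials, at time-limit expiry
#' otherwise), and a consumption period after rewarded trials. Light-trial
#' labels are assigned by seeded shuffling of a fixed-proportion vector, so
#' a session carries exactly `round(light_fraction * n_trials)` light
#' trials.
#'
#' @param cfg A [behavior_sim_config()].
#' @return An `event_log` data frame (`t_s`, `label`, `trial_index`,
#'   `light_flag`) with attribute `truth`: a data frame of per-trial ground
#'   truth (`trial_index`, `t_extension_s`, `n_presses`, `outcome`,
#'   `light_flag`).
#' @export
simulate_fr_session <- function(cfg) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  sch <- parse_schedule(cfg$schedule)
  with_seed(cfg$seed, {
    n_light <- as.integer(round(cfg$light_fraction * cfg$n_trials))
    light <- sample(rep(c(TRUE, FALSE),
                        c(n_light, cfg$n_trials - n_light)))
    limit_eff <- min(sch$limit_s, cfg$max_trial_s)
    rows <- vector("list", cfg$n_trials)
    truth <- vector("list", cfg$n_trials)
    t <- 0
    for (i in seq_len(cfg$n_trials)) {
      t_ext <- t + cfg$iti_s
      ev_t <- t_ext
      ev_l <- "lever_extension"
      p <- min(max(cfg$p_engage + if (light[i]) cfg$light_effect else 0, 0), 1)
      presses <- numeric()
      if (stats::runif(1L) < p) {
        gaps <- stats::rexp(sch$ratio, cfg$press_rate_hz)
        cand <- t_ext + cumsum(gaps)
        presses <- cand[cand <= t_ext + limit_eff]
      }
      # premature head entries during the press sequence
      if (cfg$premature_entry_rate_hz > 0 && length(presses) > 0) {
        span <- max(presses) - t_ext
        n_pre <- stats::rpois(1L, cfg$premature_entry_rate_hz * span)
        if (n_pre > 0) {
          pre_t <- sort(stats::runif(n_pre, t_ext, max(presses)))
          ev_t <- c(ev_t, pre_t)
          ev_l <- c(ev_l, rep("head_entry", n_pre))
        }
      }
      if (length(presses)) {
        ev_t <- c(ev_t, presses)
        ev_l <- c(ev_l, rep("press", length(presses)))
      }
      completed <- length(presses) >= sch$ratio
      if (completed) {
        t_del <- presses[sch$ratio] + 0.01
        t_he <- t_del + stats::rexp(1L, 1 / cfg$retrieval_mean_s)
        t_ret <- t_he + 0.05
        ev_t <- c(ev_t, t_del, t_he, t_ret)
        ev_l <- c(ev_l, "pellet_delivery", "head_entry", "lever_retraction")
        t <- t_ret + cfg$consumption_s
      } else {
        t_ret <- t_ext + limit_eff
        ev_t <- c(ev_t, t_ret)
        ev_l <- c(ev_l, "lever_retraction")
        t <- t_ret
      }
      ord <- order(ev_t)
      rows[[i]] <- data.frame(t_s = ev_t[ord], label = ev_l[ord],
                              trial_index = i, light_flag = light[i])
      outcome <- if (completed) "completed"
                 else if (length(presses) > 0) "incomplete" else "omission"
      truth[[i]] <- data.frame(trial_index = i, t_extension_s = t_ext,
                               n_presses = length(presses),
                               outcome = outcome, light_flag = light[i])
    }
    log <- do.call(rbind, rows)
    rownames(log) <- NULL
    structure(log, class = c("event_log", "data.frame"),
              schedule = cfg$schedule, truth = do.call(rbind, truth))
  })
}

#' Simulate a structured lick train
#'
#' Builds lick timestamps forming exactly `n_bouts` bouts under the bout
#' rule (two or more licks with all inter-lick intervals under 2 s):
#' within-bout licks are spaced `intra_ili_s` apart and bouts are separated
#' by `inter_bout_gap_s`.
#'
#' @param n_bouts Number of bouts (0 gives an empty train).
#' @param licks_per_bout Licks per bout.
#' @param intra_ili_s Within-bout inter-lick interval (s); must be < 2.
#' @param inter_bout_gap_s Gap between bouts (s); must be > 2.
#' @param t0_s Time of the first lick, default 0.
#' @return Sorted numeric vector of lick times (s).
#' @export
simulate_lick_train <- function(n_bouts, licks_per_bout, intra_ili_s = 0.2,
                                inter_bout_gap_s = 5, t0_s = 0) {
  if (n_bouts < 0 || licks_per_bout < 1) {
    stop("`n_bouts` must be >= 0 and `licks_per_bout` >= 1")
  }
  if (!(intra_ili_s < 2) || !(inter_bout_gap_s > 2)) {
    stop("need `intra_ili_s` < 2 < `inter_bout_gap_s` for valid bout structure")
  }
  if (n_bouts == 0) return(numeric())
  within <- (seq_len(licks_per_bout) - 1L) * intra_ili_s
  starts <- t0_s +
    (seq_len(n_bouts) - 1L) *
      ((licks_per_bout - 1L) * intra_ili_s + inter_bout_gap_s)
  sort(as.vector(outer(within, starts, `+`)))
}

#' Simulate an open-field trajectory with movement epochs
#'
#' Piecewise trajectory alternating stationary periods and straight runs at
#' constant speed, optionally passing through target locations. Intended as
#' a construction oracle for movement-epoch and approach detection.
#'
#' @param segments Data frame with columns `duration_s` and `speed_cm_s`
#'   (0 for stationary), and optional `heading_rad`.
#' @param dt_s Sampling interval (s), default 1/30.
#' @param x0,y0 Starting position (cm).
#' @return Data frame `t_s`, `x_cm`, `y_cm`.
#' @export
simulate_trajectory <- function(segments, dt_s = 1 / 30, x0 = 0, y0 = 0) {
  if (!all(c("duration_s", "speed_cm_s") %in% names(segments))) {
    stop("`segments` needs columns duration_s and speed_cm_s")
  }
  if (is.null(segments$heading_rad)) segments$heading_rad <- 0
  x <- x0; y <- y0
  xs <- x0; ys <- y0; ts <- 0
  t <- 0
  for (i in seq_len(nrow(segments))) {
    n <- round(segments$duration_s[i] / dt_s)
    if (n < 1) next
    vx <- segments$speed_cm_s[i] * cos(segments$heading_rad[i])
    vy <- segments$speed_cm_s[i] * sin(segments$heading_rad[i])
    tt <- t + seq_len(n) * dt_s
    xs <- c(xs, x + seq_len(n) * dt_s * vx)
    ys <- c(ys, y + seq_len(n) * dt_s * vy)
    ts <- c(ts, tt)
    x <- xs[length(xs)]; y <- ys[length(ys)]; t <- ts[length(ts)]
  }
  data.frame(t_s = ts, x_cm = xs, y_cm = ys)
}
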