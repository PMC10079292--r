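#' Parse an operant event log into trials
#'
#' Segments the log at lever extension/retraction pairs and classifies each
#' trial: `completed` when the press count reaches the schedule's ratio
#' within the time limit (measured from lever extension), `incomplete` when
#' the animal pressed at least once but fewer than the required number
#' (one to four times on FR5), and `omission` when it never pressed.
#' Initiation latency is first press minus extension; retrieval latency is
#' the first head entry after pellet delivery minus the delivery time.
#'
#' @param log An `event_log` data frame (`t_s`, `label`, `trial_index`,
#'   `light_flag`).
#' @param schedule Schedule name, e.g. `"FR5-5s"`; defaults to the log's
#'   `schedule` attribute.
#' @return Data frame of class `trial_table`, one row per trial:
#'   `trial_index`, `schedule`, `t_extension_s`, `t_retraction_s`,
#'   `n_presses`, `outcome`, `initiation_latency_s`, `retrieval_latency_s`,
#'   `light_flag`, `reinforced_flag`.
#' @export
parse_trials <- function(log, schedule = NULL) {
  if (is.null(schedule)) schedule <- attr(log, "schedule")
  if (is.null(schedule)) stop("`schedule` must be given (log carries none)")
  sch <- parse_schedule(schedule)
  if (is.unsorted(log$t_s)) stop("event log timestamps must be nondecreasing")
  ext <- log[log$label == "lever_extension", , drop = FALSE]
  ret <- log[log$label == "lever_retraction", , drop = FALSE]
  if (nrow(ext) == 0L) stop("event log contains no lever_extension events")
  if (nrow(ext) != nrow(ret)) {
    stop("unbalanced lever_extension/lever_retraction events")
  }
  presses <- log[log$label == "press", , drop = FALSE]
  in_trial <- vapply(presses$t_s, function(tp) {
    any(tp >= ext$t_s & tp <= ret$t_s)
  }, logical(1))
  if (any(!in_trial)) {
    stop(sprintf("press at t = %.3f s falls outside any trial",
                 presses$t_s[which(!in_trial)[1L]]))
  }
  out <- lapply(seq_len(nrow(ext)), function(i) {
    t0 <- ext$t_s[i]
    t1 <- ret$t_s[i]
    seg <- log[log$t_s >= t0 & log$t_s <= t1, , drop = FALSE]
    p <- seg$t_s[seg$label == "press"]
    # presses counted toward the ratio must land within the time limit
    p_valid <- p[p - t0 <= sch$limit_s]
    completed <- length(p_valid) >= sch$ratio
    outcome <- if (completed) "completed"
               else if (length(p) > 0) "incomplete" else "omission"
    t_del <- seg$t_s[seg$label == "pellet_delivery"]
    retrieval <- NA_real_
    if (length(t_del)) {
      he <- seg$t_s[seg$label == "head_entry" & seg$t_s > t_del[1L]]
      if (length(he)) retrieval <- he[1L] - t_del[1L]
    }
    data.frame(
      trial_index = ext$trial_index[i], schedule = schedule,
      t_extension_s = t0, t_retraction_s = t1,
      n_presses = length(p), outcome = outcome,
      initiation_latency_s = if (length(p)) p[1L] - t0 else NA_real_,
      retrieval_latency_s = retrieval,
      light_flag = isTRUE(ext$light_flag[i]),
      reinforced_flag = length(t_del) > 0)
  })
  trials <- do.call(rbind, out)
  class(trials) <- c("trial_table", "data.frame")
  trials
}

#' Session performance rates
#'
#' Percentage of completed, incomplete, and omitted trials, overall and
#' split by light-delivery flag when both strata are present. Each row sums
#' to 100.
#'
#' @param trials A `trial_table` from [parse_trials()].
#' @return Data frame with columns `stratum`, `n_trials`, `pct_completed`,
#'   `pct_incomplete`, `pct_omission`.
#' @export
session_performance <- function(trials) {
  if (nrow(trials) == 0L) stop("no trials")
  rate_row <- function(tr, stratum) {
    n <- nrow(tr)
    data.frame(stratum = stratum, n_trials = n,
               pct_completed = 100 * sum(tr$outcome == "completed") / n,
               pct_incomplete = 100 * sum(tr$outcome == "incomplete") / n,
               pct_omission = 100 * sum(tr$outcome == "omission") / n)
  }
  out <- rate_row(trials, "all")
  if (length(unique(trials$light_flag)) > 1L) {
    out <- rbind(out,
                 rate_row(trials[trials$light_flag, , drop = FALSE], "light"),
                 rate_row(trials[!trials$light_flag, , drop = FALSE],
                          "no_light"))
  }
  out
}

#' Segment a lick train into bouts
#'
#' A bout is a maximal run of two or more licks in which every inter-lick
#' interval is strictly under 2 s; an interval of exactly 2 s splits the
#' run, and isolated licks are discarded.
#'
#' @param licks Sorted lick times (s).
#' @param max_ili_s Bout-defining inter-lick interval (s), default 2.
#' @return Data frame with one row per bout: `start_s`, `end_s`, `n_licks`.
#' @export
detect_bouts <- function(licks, max_ili_s = 2) {
  licks <- as.numeric(licks)
  if (length(licks) == 0L) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      n_licks = integer()))
  }
  if (is.unsorted(licks)) stop("`licks` must be sorted ascending")
  run_id <- cumsum(c(0, diff(licks) >= max_ili_s))
  runs <- split(licks, run_id)
  runs <- runs[lengths(runs) >= 2L]
  data.frame(start_s = vapply(runs, min, numeric(1), USE.NAMES = FALSE),
             end_s = vapply(runs, max, numeric(1), USE.NAMES = FALSE),
             n_licks = vapply(runs, length, integer(1), USE.NAMES = FALSE))
}

smoothed_speed <- function(traj, smooth_n) {
  dt <- assert_uniform_sampling(traj$t_s, "trajectory")
  v <- c(0, sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2) / dt)
  if (smooth_n > 1L) {
    v <- as.numeric(stats::filter(v, rep(1 / smooth_n, smooth_n),
                                  sides = 2))
    v[is.na(v)] <- 0
  }
  list(v = v, dt = dt)
}

#' Detect movement epochs by speed hysteresis
#'
#' Computes instantaneous speed from a uniformly sampled trajectory,
#' smooths it with a short moving average, and applies hysteresis
#' thresholding: an epoch opens when speed rises to `speed_on_cm_s` and
#' closes when it falls below `speed_off_cm_s`; epochs shorter than
#' `min_dur_s` are dropped.
#'
#' @param traj Data frame `t_s`, `x_cm`, `y_cm`, uniformly sampled.
#' @param speed_on_cm_s Onset threshold (cm/s), default 2.
#' @param speed_off_cm_s Offset threshold (cm/s), default 1.
#' @param min_dur_s Minimum epoch duration (s), default 0.5.
#' @param smooth_n Moving-average length in samples, default 5.
#' @return Data frame with `onset_s`, `offset_s`, `peak_speed_cm_s`,
#'   `t_peak_s` per epoch.
#' @export
detect_movement_epochs <- function(traj, speed_on_cm_s = 2,
                                   speed_off_cm_s = 1, min_dur_s = 0.5,
                                   smooth_n = 5L) {
  if (speed_off_cm_s >= speed_on_cm_s) {
    stop("`speed_off_cm_s` must be below `speed_on_cm_s`")
  }
  sp <- smoothed_speed(traj, smooth_n)
  v <- sp$v
  epochs <- list()
  moving <- FALSE
  onset <- NA_integer_
  for (i in seq_along(v)) {
    if (!moving && v[i] >= speed_on_cm_s) {
      moving <- TRUE
      onset <- i
    } else if (moving && v[i] < speed_off_cm_s) {
      epochs[[length(epochs) + 1L]] <- c(onset, i - 1L)
      moving <- FALSE
    }
  }
  if (moving) epochs[[length(epochs) + 1L]] <- c(onset, length(v))
  if (length(epochs) == 0L) {
    return(data.frame(onset_s = numeric(), offset_s = numeric(),
                      peak_speed_cm_s = numeric(), t_peak_s = numeric()))
  }
  out <- do.call(rbind, lapply(epochs, function(e) {
    idx <- e[1L]:e[2L]
    pk <- idx[which.max(v[idx])]
    data.frame(onset_s = traj$t_s[e[1L]], offset_s = traj$t_s[e[2L]],
               peak_speed_cm_s = v[pk], t_peak_s = traj$t_s[pk])
  }))
  out[out$offset_s - out$onset_s >= min_dur_s, , drop = FALSE]
}

#' Detect approach events toward targets
#'
#' Emits one event per outside-to-inside crossing of a circle of
#' `radius_cm` around each target; remaining inside produces no further
#' events, and a re-entry requires a prior exit.
#'
#' @param traj Data frame `t_s`, `x_cm`, `y_cm`.
#' @param targets Data frame or matrix of target coordinates (`x_cm`,
#'   `y_cm`), one row per target.
#' @param radius_cm Approach radius (cm), default 5.
#' @return Data frame with `t_entry_s` and `target_id`, ordered by time.
#' @export
detect_approaches <- function(traj, targets, radius_cm = 5) {
  targets <- as.matrix(targets)
  out <- list()
  for (k in seq_len(nrow(targets))) {
    d <- sqrt((traj$x_cm - targets[k, 1L])^2 +
              (traj$y_cm - targets[k, 2L])^2)
    inside <- d <= radius_cm
    entries <- which(!inside[-length(inside)] & inside[-1L]) + 1L
    if (length(entries)) {
      out[[length(out) + 1L]] <- data.frame(t_entry_s = traj$t_s[entries],
                                            target_id = k)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(t_entry_s = numeric(), target_id = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$t_entry_s), , drop = FALSE]
}

#' Premature head entries on completed trials
#'
#' Head entries occurring between lever extension and the final press of
#' trials that were ultimately completed (i.e. receptacle checks before the
#' press requirement was met); entries after pellet delivery are excluded.
#'
#' @param trials A `trial_table` from [parse_trials()].
#' @param log The originating `event_log`.
#' @return Sorted numeric vector of head-entry times (s).
#' @export
premature_head_entries <- function(trials, log) {
  he <- log$t_s[log$label == "head_entry"]
  comp <- trials[trials$outcome == "completed", , drop = FALSE]
  out <- numeric()
  for (i in seq_len(nrow(comp))) {
    seg <- log[log$t_s >= comp$t_extension_s[i] &
               log$t_s <= comp$t_retraction_s[i], , drop = FALSE]
    last_press <- max(seg$t_s[seg$label == "press"])
    out <- c(out, he[he > comp$t_extension_s[i] & he <= last_press])
  }
  sort(out)
}

#' Schedule-advancement criterion
#'
#' Flags, for a sequence of training sessions, the sessions after which the
#' advancement criterion is met: at least `min_completed` completed
#' fixed-ratio trials on that session and on the preceding one (two
#' consecutive sessions at or above criterion).
#'
#' @param completed_per_session Integer vector of completed-trial counts,
#'   one per session in order.
#' @param min_completed Criterion count, default 30.
#' @return Logical vector, `TRUE` where the two-consecutive-session
#'   criterion is satisfied.
#' @export
check_schedule_advancement <- function(completed_per_session,
                                       min_completed = 30L) {
  n <- length(completed_per_session)
  ok <- completed_per_session >= min_completed
  c(FALSE, ok[-1L] & ok[-n])[seq_len(n)]
}
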