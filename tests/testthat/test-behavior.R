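manual_log <- function(trials, schedule = "FR5-5s") {
  # trials: list of lists(ext, presses, delivery, head_entry, retract, light)
  rows <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    t <- c(tr$ext, tr$presses, tr$delivery, tr$head_entry, tr$retract)
    l <- c("lever_extension", rep("press", length(tr$presses)),
           rep("pellet_delivery", length(tr$delivery)),
           rep("head_entry", length(tr$head_entry)), "lever_retraction")
    ord <- order(t)
    rows[[i]] <- data.frame(t_s = t[ord], label = l[ord], trial_index = i,
                            light_flag = isTRUE(tr$light))
  }
  structure(do.call(rbind, rows), class = c("event_log", "data.frame"),
            schedule = schedule)
}

test_that("trials classify as completed, incomplete, or omission by press count and limit", {
  log <- manual_log(list(
    list(ext = 0, presses = 0 + c(1, 2, 3, 4, 4.9), delivery = 4.95,
         head_entry = 5.5, retract = 5.6),                    # completed
    list(ext = 20, presses = 20 + c(1, 2, 3), delivery = numeric(),
         head_entry = numeric(), retract = 25),               # incomplete
    list(ext = 40, presses = numeric(), delivery = numeric(),
         head_entry = numeric(), retract = 45)))              # omission
  tr <- parse_trials(log)
  expect_equal(tr$outcome, c("completed", "incomplete", "omission"))
  expect_equal(tr$n_presses, c(5L, 3L, 0L))
  expect_equal(tr$initiation_latency_s, c(1, 1, NA))
  expect_equal(tr$retrieval_latency_s, c(5.5 - 4.95, NA, NA))
  expect_true(tr$reinforced_flag[1] && !tr$reinforced_flag[2])
})

test_that("five presses with the fifth beyond the time limit do not complete the trial", {
  log <- manual_log(list(
    list(ext = 0, presses = c(1, 2, 3, 4, 5.5), delivery = numeric(),
         head_entry = numeric(), retract = 6)))
  tr <- parse_trials(log)
  expect_equal(tr$outcome, "incomplete")
  # no limit: same presses complete under FR5-NTL
  attr(log, "schedule") <- "FR5-NTL"
  expect_equal(parse_trials(log)$outcome, "completed")
})

test_that("a press outside any trial is an error naming its timestamp", {
  log <- manual_log(list(
    list(ext = 0, presses = c(1, 2), delivery = numeric(),
         head_entry = numeric(), retract = 5)))
  loose <- rbind(as.data.frame(log),
                 data.frame(t_s = 9.25, label = "press", trial_index = NA,
                            light_flag = FALSE))
  loose <- structure(loose[order(loose$t_s), ],
                     class = c("event_log", "data.frame"),
                     schedule = "FR5-5s")
  expect_error(parse_trials(loose), "9.250")
})

test_that("simulated sessions parse back to their ground-truth outcomes", {
  for (seed in 1:3) {
    cfg <- behavior_sim_config("FR5-5s", n_trials = 40, p_engage = 0.8,
                               seed = seed)
    log <- simulate_fr_session(cfg)
    tr <- parse_trials(log)
    truth <- attr(log, "truth")
    expect_equal(tr$outcome, truth$outcome)
    expect_equal(tr$n_presses, truth$n_presses)
    expect_equal(tr$light_flag, truth$light_flag)
  }
})

test_that("degenerate engagement settings force the expected outcomes", {
  all_in <- simulate_fr_session(behavior_sim_config(
    "FR5-5s", n_trials = 20, p_engage = 1, press_rate_hz = 50, seed = 1))
  tr <- parse_trials(all_in)
  expect_true(all(tr$outcome == "completed"))
  expect_true(all(tr$n_presses == 5))
  expect_equal(sum(all_in$label == "pellet_delivery"), 20)
  none <- simulate_fr_session(behavior_sim_config(
    "FR5-5s", n_trials = 10, p_engage = 0, seed = 1))
  expect_true(all(parse_trials(none)$outcome == "omission"))
})

test_that("light-trial assignment hits the exact shuffled proportion", {
  cfg <- behavior_sim_config("FR5-5s", n_trials = 300, light_fraction = 0.33,
                             seed = 9)
  log <- simulate_fr_session(cfg)
  truth <- attr(log, "truth")
  n_light <- sum(truth$light_flag)
  expect_equal(n_light, round(0.33 * 300))
  expect_true(n_light >= 90 && n_light <= 110)
})

test_that("performance rates partition trials and sum to 100 per stratum", {
  log <- simulate_fr_session(behavior_sim_config(
    "FR5-5s", n_trials = 60, p_engage = 0.7, light_fraction = 0.33,
    seed = 4))
  tr <- parse_trials(log)
  perf <- session_performance(tr)
  sums <- perf$pct_completed + perf$pct_incomplete + perf$pct_omission
  expect_equal(sums, rep(100, nrow(perf)))
  counts <- table(factor(tr$outcome,
                         c("completed", "incomplete", "omission")))
  expect_equal(sum(counts), nrow(tr))
  expect_equal(perf$pct_completed[perf$stratum == "all"],
               100 * counts[["completed"]] / nrow(tr))
})

test_that("bout detection follows the two-or-more-licks, ILI-under-2-s rule", {
  b <- detect_bouts(c(0, 0.5, 3.0, 3.4, 3.9, 10.5))
  expect_equal(b$start_s, c(0, 3.0))
  expect_equal(b$end_s, c(0.5, 3.9))
  expect_equal(b$n_licks, c(2L, 3L))
  # an interval of exactly 2 s splits the run (strict inequality)
  split2 <- detect_bouts(c(0, 1, 3, 4))
  expect_equal(nrow(split2), 2)
  merged <- detect_bouts(c(0, 1, 2.999, 4))
  expect_equal(nrow(merged), 1)
  expect_equal(nrow(detect_bouts(numeric())), 0)
  expect_equal(nrow(detect_bouts(5)), 0)
  expect_error(detect_bouts(c(3, 1)), "sorted")
})

test_that("bout detection agrees with the brute-force oracle on random trains", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(0:15, 1)
    licks <- sort(round(runif(n, 0, 30), 3))
    got <- detect_bouts(licks)
    want <- oracle_bouts(licks)
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$end_s, want$end_s)
    expect_equal(got$n_licks, as.integer(want$n_licks))
    # compression: bout licks plus singletons reproduce the input set
    in_bout <- rep(FALSE, length(licks))
    for (j in seq_len(nrow(got))) {
      in_bout <- in_bout | (licks >= got$start_s[j] & licks <= got$end_s[j])
    }
    expect_equal(sum(in_bout), sum(got$n_licks))
  }
})

test_that("simulated lick trains contain exactly the constructed bouts", {
  licks <- simulate_lick_train(n_bouts = 2, licks_per_bout = 3,
                               intra_ili_s = 0.2, inter_bout_gap_s = 5)
  expect_equal(nrow(detect_bouts(licks)), 2)
  expect_equal(nrow(detect_bouts(
    simulate_lick_train(4, licks_per_bout = 1))), 0)
  expect_equal(simulate_lick_train(0, 3), numeric())
  expect_error(simulate_lick_train(2, 3, intra_ili_s = 2.5), "valid bout")
})

test_that("movement epochs recover a constructed square-wave speed profile", {
  segs <- data.frame(duration_s = c(3, 2, 3, 1.5, 3),
                     speed_cm_s = c(0, 10, 0, 8, 0))
  traj <- simulate_trajectory(segs, dt_s = 1 / 30)
  ep <- detect_movement_epochs(traj)
  expect_equal(nrow(ep), 2)
  dt <- 1 / 30
  expect_lt(abs(ep$onset_s[1] - 3), 5 * dt)   # smoothing blurs one edge
  expect_lt(abs(ep$offset_s[1] - 5), 5 * dt)
  expect_true(all(ep$onset_s <= ep$t_peak_s & ep$t_peak_s <= ep$offset_s))
  expect_equal(ep$peak_speed_cm_s, c(10, 8), tolerance = 0.05)
  # stationary trajectory yields no epochs
  still <- simulate_trajectory(data.frame(duration_s = 5, speed_cm_s = 0))
  expect_equal(nrow(detect_movement_epochs(still)), 0)
  # sub-threshold movement drops out; nonuniform sampling errors
  slow <- simulate_trajectory(data.frame(duration_s = c(2, 0.2, 2),
                                         speed_cm_s = c(0, 10, 0)))
  expect_equal(nrow(detect_movement_epochs(slow, min_dur_s = 0.5)), 0)
  bad <- traj
  bad$t_s[10] <- bad$t_s[10] + 0.01
  expect_error(detect_movement_epochs(bad), "uniform")
})

test_that("approach events fire once per outside-to-inside crossing of 5 cm", {
  # straight path through a target
  traj <- data.frame(t_s = seq(0, 10, by = 1 / 30))
  traj$x_cm <- -20 + 4 * traj$t_s
  traj$y_cm <- 0
  target <- data.frame(x_cm = 0, y_cm = 0)
  ap <- detect_approaches(traj, target)
  expect_equal(nrow(ap), 1)
  expect_equal(ap$t_entry_s, traj$t_s[min(which(abs(traj$x_cm) <= 5))])
  # never within radius
  far <- traj; far$y_cm <- 20
  expect_equal(nrow(detect_approaches(far, target)), 0)
  # dwelling inside produces a single event; re-entry needs a prior exit
  dwell <- data.frame(t_s = seq(0, 9, by = 0.1),
                      x_cm = c(seq(-10, 0, length.out = 31), rep(0, 30),
                               seq(0, -10, length.out = 30)),
                      y_cm = 0)
  expect_equal(nrow(detect_approaches(dwell, target)), 1)
  two_targets <- rbind(target, data.frame(x_cm = -40, y_cm = 0))
  expect_equal(detect_approaches(traj, two_targets)$target_id, 1)
})

test_that("premature head entries are those between extension and final press of completed trials", {
  log <- manual_log(list(
    list(ext = 0, presses = c(1, 2, 3, 4, 4.5), delivery = 4.55,
         head_entry = c(2.5, 3.7, 5.2), retract = 5.3),
    list(ext = 20, presses = 20 + c(1, 2), delivery = numeric(),
         head_entry = 23.5, retract = 25)))
  tr <- parse_trials(log)
  pre <- premature_head_entries(tr, log)
  expect_equal(pre, c(2.5, 3.7))  # 5.2 after delivery; 23.5 on incomplete
  no_he <- manual_log(list(list(ext = 0, presses = 1:5, delivery = 5.05,
                                head_entry = numeric(), retract = 6)))
  expect_equal(premature_head_entries(parse_trials(no_he), no_he),
               numeric())
})

test_that("the schedule-advancement criterion needs two consecutive sessions at 30", {
  counts <- c(10, 31, 35, 20, 30, 30, 29)
  expect_equal(check_schedule_advancement(counts),
               c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(check_schedule_advancement(40), FALSE)
})
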