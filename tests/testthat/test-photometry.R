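make_session <- function(channels, signals, controls = NULL, rate_hz = 15,
                         with_background = TRUE) {
  if (is.null(controls)) controls <- rep(5, length(channels))
  if (with_background) {
    channels <- c("off", channels)
    signals <- c(2, signals)
    controls <- c(2, controls)
  }
  n <- length(channels)
  photometry_session(
    data.frame(frame_index = seq_len(n) - 1L,
               t_s = (seq_len(n) - 1L) / (2 * rate_hz),
               channel = channels, roi_signal = signals,
               roi_control = controls),
    rate_hz = rate_hz)
}

test_that("demultiplex pairs each 473 frame with the preceding 405 frame", {
  s <- make_session(rep(c("405", "473"), 3), rep(c(1, 10), 3),
                    with_background = FALSE)
  pair <- demultiplex(s)
  expect_equal(pair$s405, c(1, 1, 1))
  expect_equal(pair$s473, c(10, 10, 10))
  # paired timestamps are the 473 frame times
  expect_equal(pair$t_s, s$t_s[s$channel == "473"])
})

test_that("a 30 Hz pulse train demultiplexes into two 15 Hz channels", {
  s <- make_session(rep(c("405", "473"), 150), rnorm(300),
                    with_background = FALSE)
  pair <- demultiplex(s)
  expect_length(pair$s473, 150)
  expect_length(pair$s405, 150)
  expect_equal(1 / median(diff(pair$t_s)), 15, tolerance = 1e-9)
})

test_that("unpaired edge frames are dropped with a warning; broken alternation errors", {
  s <- make_session(c("473", rep(c("405", "473"), 3)), c(9, rep(c(1, 10), 3)),
                    with_background = FALSE)
  expect_warning(pair <- demultiplex(s), "dropped 1")
  expect_length(pair$s473, 3)
  s2 <- make_session(c("405", "405", "473"), c(1, 1, 10),
                     with_background = FALSE)
  expect_error(demultiplex(s2), "alternation.*frame index 1")
})

test_that("background subtraction uses the mean of laser-off frames", {
  n <- 4
  s <- photometry_session(
    data.frame(frame_index = 0:(n + 1), t_s = 0:(n + 1) / 30,
               channel = c("off", "off", "405", "473", "405", "473"),
               roi_signal = c(1, 3, 10, 12, 10, 12),
               roi_control = c(0.5, 1.5, 7, 7, 7, 7)),
    rate_hz = 15)
  pair <- subtract_background(demultiplex(s), s)
  expect_equal(pair$s473, c(10, 10))  # 12 - mean(1, 3)
  expect_equal(pair$s405, c(8, 8))
  expect_equal(pair$c473, c(6, 6))    # 7 - mean(0.5, 1.5)
  expect_equal(unname(pair$background["signal"]), 2)
})

test_that("missing background frames error; excess background warns and permits negatives", {
  s <- make_session(rep(c("405", "473"), 2), rep(c(1, 10), 2),
                    with_background = FALSE)
  expect_error(subtract_background(demultiplex(s), s), "background")
  s2 <- photometry_session(
    data.frame(frame_index = 0:2, t_s = 0:2 / 30,
               channel = c("off", "405", "473"),
               roi_signal = c(50, 1, 10), roi_control = c(0, 5, 5)),
    rate_hz = 15)
  expect_warning(pair <- subtract_background(demultiplex(s2), s2),
                 "negative")
  expect_equal(pair$s473, -40)
})

test_that("stage-1 residuals vanish under exact linear dependence on the control", {
  set.seed(11)
  ctl <- rnorm(200, 10)
  s <- make_session(rep(c("405", "473"), each = 1, times = 200),
                    signals = as.vector(rbind(2 * ctl + 1, 3 * ctl - 2)),
                    controls = as.vector(rbind(ctl, ctl)),
                    with_background = FALSE)
  pair <- regress_out_control(demultiplex(s))
  expect_lt(max(abs(pair$s405)), 1e-9)
  expect_lt(max(abs(pair$s473)), 1e-9)
})

test_that("each regression stage leaves residuals orthogonal to the regressor", {
  set.seed(12)
  for (i in 1:5) {
    n <- 300
    pair <- structure(list(t_s = (1:n) / 15,
                           s473 = rnorm(n), s405 = rnorm(n),
                           c473 = rnorm(n, 10), c405 = rnorm(n, 10),
                           rate_hz = 15, n_dropped = 0L, r2 = list()),
                      class = "channel_pair")
    out <- regress_out_control(pair)
    expect_lt(abs(cor(out$s473, pair$c473)), 1e-10)
    expect_lt(abs(cor(out$s405, pair$c405)), 1e-10)
    res <- regress_out_isosbestic(out)
    expect_lt(abs(cor(as.numeric(res), out$s405)), 1e-10)
  }
})

test_that("zero-variance controls error unless the mean-subtraction fallback is requested", {
  s <- make_session(rep(c("405", "473"), 50),
                    signals = rnorm(100), controls = rep(4, 100),
                    with_background = FALSE)
  pair <- demultiplex(s)
  expect_error(regress_out_control(pair), "fallback")
  out <- regress_out_control(pair, fallback = TRUE)
  expect_equal(mean(out$s473), 0, tolerance = 1e-12)
})

test_that("identical 473 and 405 residual series regress to zero", {
  x <- rnorm(100)
  pair <- structure(list(s473 = x, s405 = x, rate_hz = 15, r2 = list()),
                    class = "channel_pair")
  expect_lt(max(abs(regress_out_isosbestic(pair))), 1e-12)
  pair$s405 <- rep(1, 100)
  expect_error(regress_out_isosbestic(pair), "zero variance")
})

test_that("session z-scoring standardizes and rejects degenerate input", {
  z <- zscore_session(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  w <- rnorm(50)
  w <- (w - mean(w)) / sd(w)
  expect_equal(zscore_session(w), w, tolerance = 1e-12)
  expect_error(zscore_session(rep(2, 10)), "zero variance")
  expect_error(zscore_session(1), "at least 2")
})

test_that("the full chain yields a mean-0, sd-1 trace and is scale invariant", {
  sim <- simulate_standard_session(seed = 3, duration_s = 60)
  tr <- process_session(sim$session)
  expect_lt(abs(mean(tr$z)), 1e-9)
  expect_lt(abs(sd(tr$z) - 1), 1e-9)
  scaled <- sim$session
  scaled$roi_signal <- scaled$roi_signal * 37.5
  scaled$roi_control <- scaled$roi_control * 37.5
  tr2 <- process_session(scaled)
  expect_equal(tr2$z, tr$z, tolerance = 1e-9)
})

test_that("the chain rejects the shared artifact and recovers the transient", {
  cors_art <- cors_sig <- numeric(5)
  for (i in 1:5) {
    sim <- simulate_standard_session(seed = 100 + i)
    tr <- suppressWarnings(process_session(sim$session))
    cors_art[i] <- abs(cor(tr$z, sim$truth$artifact_trace))
    cors_sig[i] <- cor(tr$z, sim$truth$clean_transient_trace)
  }
  expect_lt(median(cors_art), 0.05)
  expect_gt(median(cors_sig), 0.8)
})

test_that("laser drift injected into both fibers is removed by the control regression", {
  n <- session_frame_counts(120, 15)$n_channel
  drift <- 1 + 0.1 * sin(2 * pi * 0.05 * (seq_len(n) - 1) / 15)
  cfg <- photometry_sim_config(duration_s = 120, laser_drift = drift,
                               noise_sd = 0.1, seed = 21)
  sim <- simulate_photometry_session(cfg, events = seq(10, 110, by = 7))
  pair <- subtract_background(demultiplex(sim$session), sim$session)
  pair <- regress_out_control(pair)
  expect_lt(abs(cor(pair$s473, drift)), 0.05)
})

test_that("sessions without a control column fail at construction", {
  frames <- data.frame(frame_index = 0:3, t_s = 0:3 / 30,
                       channel = c("off", "405", "473", "405"),
                       roi_signal = c(1, 2, 3, 2))
  expect_error(photometry_session(frames, 15), "roi_control")
})

test_that("pipeline diagnostics report stage R-squared and background", {
  sim <- simulate_standard_session(seed = 5, duration_s = 60)
  tr <- process_session(sim$session)
  d <- tr$diagnostics
  expect_true(all(c("r2_control_473", "r2_control_405", "r2_isosbestic",
                    "n_dropped_frames", "background_signal") %in% names(d)))
  expect_gte(d$r2_isosbestic, 0)
  expect_lte(d$r2_isosbestic, 1)
})
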