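test_that("conditioning: sinusoid gives its analytic linear envelope", {
  rate <- 2000
  s <- sin(2 * pi * 100 * (0:(8 * rate - 1)) / rate)
  e <- condition_emg(s, rate)
  mid <- e$values[(2 * rate):(6 * rate)]
  expect_lt(abs(mean(mid) - 2 / pi) / (2 / pi), 0.02)
})

test_that("conditioning: DC input conditions to (near) zero", {
  rate <- 1000
  e <- condition_emg(rep(2.5, 4 * rate), rate)
  expect_lt(max(e$values), 1e-3)
})

test_that("conditioning rejects sub-Nyquist rates and short signals", {
  expect_error(condition_emg(rnorm(5000), rate = 500), "Nyquist")
  expect_error(condition_emg(rnorm(10), rate = 1000), "shorter")
})

test_that("conditioned envelope is non-negative", {
  set.seed(1)
  e <- condition_emg(rnorm(5000), rate = 1000)
  expect_gte(min(e$values), 0)
})

test_that("heel-strike detection is scale invariant and handles silence", {
  d <- small_gait_data()
  x <- rec_channel(d$fsr, "FSR_L_heel")
  a <- detect_heel_strikes(x, d$cfg$rate)
  b <- detect_heel_strikes(137.5 * x, d$cfg$rate)
  expect_identical(a, b)
  expect_identical(detect_heel_strikes(numeric(1000), 1000), numeric(0))
})

test_that("debounce suppresses events closer than the window", {
  rate <- 1000
  x <- numeric(2000)
  x[c(500:520, 560:580, 1500:1520)] <- 1
  hs <- detect_heel_strikes(x, rate, debounce = 0.2)
  expect_length(hs, 2L)
})

test_that("gait_events validates ordering; segment_strides needs 2 strikes", {
  expect_error(gait_events(left = c(1, 0.5)), "strictly increasing")
  expect_error(segment_strides(gait_events(left = 1, right = c(0.5, 1.5))),
               "at least 2")
  ev <- segment_strides(gait_events(left = c(0, 1.1, 2.3)))
  expect_equal(ev$n, 2L)
  expect_equal(ev$mean_stride, 1.15)
  expect_equal(ev$strides$duration, c(1.1, 1.2))
})

test_that("ERA of a stride-periodic signal reproduces one period", {
  rate <- 1000
  period <- 1
  t <- (0:(20 * rate - 1)) / rate
  sig <- list(values = 1 + cos(2 * pi * t / period), rate = rate)
  ev <- segment_strides(gait_events(left = seq(2, 17)))
  era <- event_related_average(sig, ev)
  expect_equal(era$n_events, 16L)
  expect_equal(era$value,
               1 + cos(2 * pi * era$lag / period), tolerance = 1e-9)
})

test_that("ERA drops and counts events whose window leaves the record", {
  sig <- list(values = rnorm(3000), rate = 1000)
  ev <- segment_strides(gait_events(left = c(0.2, 1.2, 2.2)))
  era <- event_related_average(sig, ev, window_s = 0.5)
  expect_equal(era$n_dropped, 1L)
  expect_equal(era$n_events, 2L)
  expect_error(event_related_average(sig, ev, window_s = 10), "no event")
})

test_that("ERA of the synthetic envelope matches kernel * mean heel pulse", {
  d <- small_gait_data()
  cfg <- d$cfg
  env <- condition_emg(rec_channel(d$emg, "EMG_L_BF"), cfg$rate, "BF")
  ev <- segment_strides(gait_events(left = d$ev$left, right = d$ev$right))
  era <- event_related_average(env, ev)
  # oracle on the post-event half-window: BF envelope from both kernels,
  # scaled by the belt-speed modulation and smoothed by the same 6 Hz
  # zero-lag low-pass as the conditioning chain
  o <- lms_predict(d$kern$BF_IH$coefficients,
                   rec_channel(d$fsr, "FSR_L_heel"))$estimate +
       lms_predict(d$kern$BF_CH$coefficients,
                   rec_channel(d$fsr, "FSR_R_heel"))$estimate
  tv <- (seq_along(o) - 1) / cfg$rate
  o <- o * pmax(1 + cfg$speed_gain * (speed_at(d$ev, tv) - 1.25), 0.1)
  bw <- signal::butter(4, 6 / (cfg$rate / 2), type = "low")
  osig <- list(values = as.numeric(signal::filtfilt(bw, o)), rate = cfg$rate)
  era0 <- event_related_average(osig, ev)
  post <- era$lag >= 0.05
  expect_lt(nrmse(era$value[post], era0$value[post]), 0.12)
})

test_that("mean heel template has mean-stride length and pulse shape", {
  d <- small_gait_data()
  ev <- segment_strides(gait_events(left = d$ev$left, right = d$ev$right))
  u <- mean_heel_template(rec_channel(d$fsr, "FSR_L_heel"), d$cfg$rate, ev)
  expect_length(u, round(ev$mean_stride * d$cfg$rate))
  expect_gte(min(u), 0)
  # loading occupies ~60% of the stride, swing tail near zero
  expect_lt(max(u[round(0.8 * length(u)):length(u)]), 0.05 * max(u))
  expect_gt(u[round(0.3 * length(u))], 0.5 * max(u))
})
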