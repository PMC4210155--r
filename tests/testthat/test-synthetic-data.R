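test_that("synth_config validates physical constraints", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(rate = 800), "twice the carrier band")
  expect_error(synth_config(snr = 0), "snr")
  expect_error(synth_config(stride_jitter = 0.5), "stride_jitter")
})

test_that("cadence model clips to [0.8, 1.6] s", {
  cfg <- synth_config()
  expect_equal(stride_duration(1.25, cfg), 1.4 / 1.25)
  expect_equal(stride_duration(0.5, cfg), 1.6)
  expect_equal(stride_duration(2.5, cfg), 0.8)
  expect_error(stride_duration(0, cfg), "positive")
})

test_that("speed sequence obeys the increment bound including the repeat seam", {
  prof <- generate_speed_sequence(n_settings = 20, speed_range = c(1.0, 1.5),
                                  repeats = 2,
                                  config = synth_config(seed = 3))
  v <- prof$settings$speed
  expect_length(v, 40L)
  steps <- abs(diff(v))
  expect_true(all(steps >= 0.05 - 1e-9 & steps <= 0.1 + 1e-9))
  expect_true(all(v >= 1.0 - 1e-9 & v <= 1.5 + 1e-9))
})

test_that("single-setting profile is constant with zero increments", {
  prof <- generate_speed_sequence(n_settings = 1, speed_range = c(1.2, 1.3),
                                  repeats = 1)
  expect_equal(prof$settings$speed, 1.2)
  expect_equal(prof$total_range, 0)
})

test_that("realized range is near the requested width across 100 seeds", {
  for (s in 1:100) {
    prof <- generate_speed_sequence(n_settings = 20,
                                    speed_range = c(1.0, 1.5), repeats = 1,
                                    config = synth_config(seed = s))
    rng <- prof$total_range
    expect_lte(rng, 0.5 + 1e-9)
    expect_gte(rng, 0.5 - 0.1 - 1e-9)
  }
})

test_that("speed sequence rejects bad ranges", {
  expect_error(generate_speed_sequence(speed_range = c(0.3, 1)), "0.5")
  expect_error(generate_speed_sequence(speed_range = c(1.0, 1.02)),
               "narrower")
})

test_that("constant-speed, zero-jitter profile gives constant intervals", {
  cfg <- synth_config(seed = 2, stride_jitter = 0)
  prof <- generate_speed_sequence(n_settings = 1, speed_range = c(1.25, 1.3),
                                  repeats = 1, steps_per_setting = 12,
                                  config = cfg)
  ev <- generate_gait_events(prof, cfg)
  expect_lt(diff(range(diff(ev$left))), 1e-9)
})

test_that("stride count per setting matches hold duration times cadence", {
  cfg <- synth_config(seed = 2)
  prof <- generate_speed_sequence(n_settings = 4, steps_per_setting = 25,
                                  repeats = 1, config = cfg)
  ev <- generate_gait_events(prof, cfg)
  expect_equal(length(ev$left), 4 * 25, tolerance = 0.08)
})

test_that("contralateral strikes fall near mid-stride", {
  d <- small_gait_data()
  ev <- d$ev
  phase <- (ev$right[seq_len(ev$n)] - ev$strides$start) /
    ev$strides$duration
  expect_true(all(phase > 0.35 & phase < 0.65))
  expect_lt(abs(mean(phase) - 0.5), 0.03)
})

test_that("FSR channels: zero in swing, unimodal stance pulse, onset at event", {
  cfg <- synth_config(seed = 9)
  ev <- segment_strides(gait_events(left = c(0.5, 1.7), right = c(1.1, 2.3)))
  fsr <- generate_fsr_signals(ev, cfg, duration = 3)
  x <- rec_channel(fsr, "FSR_L_heel")
  expect_equal(max(abs(x[1:499])), 0)       # before the first stance
  i0 <- round(0.5 * cfg$rate) + 1L
  expect_equal(x[i0], 0)
  expect_gt(x[i0 + 5L], 0)
  stance <- x[i0:(i0 + round(0.6 * 1.2 * cfg$rate))]
  d <- sign(diff(stance[stance > 0 | seq_along(stance) < 10]))
  expect_lte(sum(diff(d[d != 0]) != 0), 1)   # one rise-fall turn
})

test_that("empty event list yields an all-zero FSR recording", {
  fsr <- generate_fsr_signals(gait_events(), synth_config(), duration = 0.5)
  expect_equal(max(abs(fsr$samples)), 0)
})

test_that("heel strikes round-trip through the FSR channel within 1 sample", {
  d <- small_gait_data()
  for (side in c("left", "right")) {
    ch <- if (side == "left") "FSR_L_heel" else "FSR_R_heel"
    hs <- detect_heel_strikes(rec_channel(d$fsr, ch), d$cfg$rate)
    ref <- d$ev[[side]]
    expect_equal(length(hs), length(ref))
    expect_lt(max(abs(hs - ref)), 1 / d$cfg$rate + 1e-12)
  }
})

test_that("all-zero kernels leave the envelope at the noise floor", {
  cfg <- synth_config(seed = 4, snr = 10)
  ev <- segment_strides(gait_events(left = c(0.5, 1.6, 2.7),
                                    right = c(1.05, 2.15, 3.25)))
  kern <- list(RF_CH = gt_kernel("RF", "CH", numeric(100), cfg$rate))
  emg <- generate_emg(ev, kern, cfg)
  env <- condition_emg(rec_channel(emg, "EMG_L_RF"), cfg$rate)
  mid <- env$values[2000:3000]
  expect_lt(diff(range(mid)) / mean(mid), 0.8)  # flat floor, no gait bursts
})

test_that("conditioned envelope matches the convolution oracle at high SNR", {
  d <- small_gait_data()
  cfg <- d$cfg
  env <- condition_emg(rec_channel(d$emg, "EMG_L_RF"), cfg$rate, "RF")
  x <- rec_channel(d$fsr, "FSR_R_heel")
  o <- lms_predict(d$kern$RF_CH$coefficients, x)$estimate
  tv <- (seq_along(o) - 1) / cfg$rate
  o <- o * pmax(1 + cfg$speed_gain * (speed_at(d$ev, tv) - 1.25), 0.1)
  sk <- 3000:(length(o) - 3000)
  expect_lt(nrmse(env$values[sk], o[sk]), 0.10)
})

test_that("envelope amplitude increases with belt speed", {
  # shared kernels: cadence changes shift both pulse duration and pulse
  # rate (whose product is roughly constant), so with the kernel held
  # fixed the remaining trend is the speed-gain modulation
  cfg0 <- synth_config(seed = 6)
  kern <- default_kernels(cfg0, stride_s = 1.4 / 1.25)
  lv <- vapply(c(1.0, 1.5), function(v) {
    cfg <- synth_config(seed = 6)
    prof <- generate_speed_sequence(n_settings = 1,
                                    speed_range = c(v, v + 0.05),
                                    repeats = 1, steps_per_setting = 8,
                                    config = cfg)
    ev <- generate_gait_events(prof, cfg)
    emg <- generate_emg(ev, kern, cfg)
    env <- condition_emg(rec_channel(emg, "EMG_L_RF"), cfg$rate)
    mean(env$values[2000:(length(env$values) - 2000)])
  }, numeric(1))
  expect_gt(lv[2], lv[1])
})

test_that("generation is deterministic given the config", {
  a <- small_gait_data()
  cfg <- synth_config(seed = 5, snr = 1e6)
  prof <- generate_speed_sequence(n_settings = 3, steps_per_setting = 8,
                                  repeats = 1, config = cfg)
  ev <- generate_gait_events(prof, cfg)
  kern <- default_kernels(cfg, stride_s = ev$mean_stride)
  fsr <- generate_fsr_signals(ev, cfg)
  emg <- generate_emg(ev, kern, cfg, fsr = fsr)
  expect_identical(ev$left, a$ev$left)
  expect_identical(fsr$samples, a$fsr$samples)
  expect_identical(emg$samples, a$emg$samples)
})

test_that("kernels longer than two strides are rejected", {
  cfg <- synth_config(seed = 4)
  ev <- segment_strides(gait_events(left = c(0.5, 1.5, 2.5),
                                    right = c(1.0, 2.0, 3.0)))
  kern <- list(RF_CH = gt_kernel("RF", "CH", numeric(2500), cfg$rate))
  expect_error(generate_emg(ev, kern, cfg), "two strides")
})

test_that("write_fixture round-trips and is byte-identical for a fixed seed", {
  d <- small_gait_data()
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p1 <- write_fixture(d$emg, d$fsr, d$ev, d$kern, dir1)
  p2 <- write_fixture(d$emg, d$fsr, d$ev, d$kern, dir2)
  h <- function(p) readBin(p, "raw", file.size(p))
  for (nm in names(p1)) expect_identical(h(p1[[nm]]), h(p2[[nm]]))
  back <- read_recording(p1[["recording"]])
  expect_identical(back$channels, c(d$emg$channels, d$fsr$channels))
  full <- cbind(d$emg$samples, d$fsr$samples)
  expect_lt(max(abs(back$samples - full) / pmax(abs(full), 1e-12)), 1e-9)
  ev <- read.csv(p1[["events"]])
  # 12 significant digits in the ASCII fixture: lossless to 1e-9 relative
  expect_equal(sort(ev$time_s[ev$foot == "left"]), d$ev$left,
               tolerance = 1e-9)
})
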