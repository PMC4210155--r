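# A unit-impulse heel template turns fsr_convolve into an identity wrapper,
# which doubles as a convenient transfer_curve constructor for these tests.
.as_curve <- function(v, rate = 250, trigger = "CH")
  fsr_convolve(v, 1, rate, trigger = trigger)

.bump_curve <- function(centers, widths, amps, rate = 250, dur = 1) {
  t <- (0:(round(dur * rate) - 1)) / rate
  v <- numeric(length(t))
  for (i in seq_along(centers))
    v <- v + amps[i] * exp(-((t - centers[i])^2) / (2 * widths[i]^2))
  .as_curve(v, rate)
}

test_that("fsr_convolve with a unit-impulse template returns h unchanged", {
  h <- c(0, 1, 3, 2, 0.5)
  cv <- fsr_convolve(h, 1, rate = 250)
  expect_s3_class(cv, "transfer_curve")
  expect_equal(cv$H, h)
  expect_identical(cv$trigger, "CH")
  expect_error(fsr_convolve(h, numeric(0), 250), "empty")
})

test_that("fsr_convolve matches the brute-force convolution sum", {
  set.seed(1)
  h <- rnorm(40)
  u <- abs(rnorm(60))
  cv <- fsr_convolve(h, u, rate = 250, trigger = "IH")
  brute <- vapply(seq_along(h), function(n) {
    k <- 0:(n - 1)
    sum(h[k + 1] * c(u, numeric(40))[n - k])
  }, numeric(1))
  expect_equal(cv$H, brute, tolerance = 1e-12)
  expect_length(cv$H, length(h))
  expect_identical(cv$trigger, "IH")
})

test_that("locate_landmarks rejects a constant curve", {
  expect_error(locate_landmarks(.as_curve(rep(1, 200))), "constant")
})

test_that("locate_landmarks finds a single bump and flags boundary troughs", {
  cv <- locate_landmarks(.bump_curve(0.3, 0.05, 1))
  lm <- cv$landmarks
  expect_identical(lm$type, c("trough", "peak", "trough"))
  pk <- lm[lm$type == "peak", ]
  expect_lt(abs(pk$time - 0.3), 0.02)
  expect_false(pk$boundary)
})

test_that("locate_landmarks separates two bumps with an interior trough", {
  cv <- locate_landmarks(.bump_curve(c(0.2, 0.7), c(0.05, 0.05), c(1, 0.8)))
  lm <- cv$landmarks
  expect_identical(lm$type, c("trough", "peak", "trough", "peak", "trough"))
  pk <- lm[lm$type == "peak", ]
  expect_lt(abs(pk$time[1] - 0.2), 0.02)
  expect_lt(abs(pk$time[2] - 0.7), 0.02)
  mid <- lm[lm$type == "trough", ][2, ]
  expect_gt(mid$time, 0.3); expect_lt(mid$time, 0.6)
  expect_false(mid$boundary)
})

test_that("small ripples below the prominence threshold are ignored", {
  rate <- 250
  t <- (0:249) / rate
  v <- exp(-((t - 0.4)^2) / (2 * 0.08^2)) + 0.01 * sin(2 * pi * 30 * t)
  cv <- locate_landmarks(.as_curve(v, rate))
  expect_equal(sum(cv$landmarks$type == "peak"), 1L)
})

test_that("extract_action_segment spans trough to trough with the right delay", {
  cv <- locate_landmarks(.bump_curve(c(0.2, 0.7), c(0.05, 0.05), c(1, 0.8)))
  lm <- cv$landmarks
  seg <- extract_action_segment(cv, 2L, "knee", "extension", trigger = "AEA")
  expect_s3_class(seg, "action_segment")
  expect_identical(seg$trigger, "AEA")
  t0 <- lm$index[3]; t1 <- lm$index[5]
  expect_equal(seg$values, cv$H[t0:t1])
  expect_equal(seg$onset_delay, (t0 - 1) / cv$rate)
  expect_error(extract_action_segment(cv, 3L), "not present")
})

test_that("combine_knee_flexors sums on the union support and commutes", {
  mk <- function(center) {
    cv <- locate_landmarks(.bump_curve(center, 0.05, 1))
    extract_action_segment(cv, 1L, "knee", "flexion")
  }
  a <- mk(0.25); b <- mk(0.55)
  ab <- combine_knee_flexors(a, b)
  ba <- combine_knee_flexors(b, a)
  expect_equal(ab$values, ba$values)
  expect_equal(ab$onset_delay, min(a$onset_delay, b$onset_delay))
  # sum preserved: total area equals the sum of the parts
  expect_equal(sum(ab$values), sum(a$values) + sum(b$values),
               tolerance = 1e-12)
  # oracle: place each part at its own offset and add
  rate <- a$rate
  n <- length(ab$values)
  o <- numeric(n)
  for (s in list(a, b)) {
    i <- round((s$onset_delay - ab$onset_delay) * rate)
    o[i + seq_along(s$values)] <- o[i + seq_along(s$values)] + s$values
  }
  expect_equal(ab$values, o)
})

test_that("combine_knee_flexors rejects mismatched segments", {
  cv <- locate_landmarks(.bump_curve(0.3, 0.05, 1))
  kf <- extract_action_segment(cv, 1L, "knee", "flexion")
  hf <- extract_action_segment(cv, 1L, "hip", "flexion")
  ih <- extract_action_segment(cv, 1L, "knee", "flexion", trigger = "IH")
  expect_error(combine_knee_flexors(kf, hf), "knee flexion")
  expect_error(combine_knee_flexors(kf, ih), "trigger")
})

test_that("align_knee_onset zeroes the delay and rejects flat segments", {
  # second peak of a two-bump curve: its preceding trough is interior, so
  # the segment carries a nonzero trigger-to-onset delay to remove
  cv <- locate_landmarks(.bump_curve(c(0.2, 0.6), c(0.05, 0.05), c(1, 0.9)))
  seg <- extract_action_segment(cv, 2L, "knee", "flexion")
  expect_gt(seg$onset_delay, 0)
  aligned <- align_knee_onset(seg)
  expect_equal(aligned$onset_delay, 0)
  expect_equal(aligned$values, seg$values)
  seg$values <- rep(2, length(seg$values))
  expect_error(align_knee_onset(seg), "flat")
})

test_that("derive_joint_segments maps the four pairings to joint actions", {
  curves <- small_transfer_curves()
  segs <- derive_joint_segments(curves)
  expect_named(segs, c("hip_flexion", "hip_extension", "knee_flexion",
                       "knee_extension"))
  expect_identical(segs$hip_flexion$trigger, "CH")
  expect_identical(segs$hip_extension$trigger, "IH")
  expect_identical(segs$knee_flexion$trigger, "CH")
  expect_identical(segs$knee_extension$trigger, "AEA")
  expect_equal(segs$knee_flexion$onset_delay, 0)
  expect_equal(segs$knee_extension$onset_delay, 0)
  # hip flexion comes from the early RF bump, knee extension from the late one
  stride_s <- length(curves$RF_CH$H) / curves$RF_CH$rate
  hf_peak <- segs$hip_flexion$onset_delay +
    (which.max(segs$hip_flexion$values) - 1) / segs$hip_flexion$rate
  expect_lt(hf_peak, 0.5 * stride_s)
  for (s in segs) expect_gt(max(s$values), 0)
})

test_that("derive_joint_segments requires all four curves and scales linearly", {
  curves <- small_transfer_curves()
  expect_error(derive_joint_segments(curves[c("RF_CH", "BF_IH")]), "BF_CH")
  scaled <- lapply(curves, function(cv) { cv$H <- 2 * cv$H; cv })
  a <- derive_joint_segments(curves)
  b <- derive_joint_segments(scaled)
  for (nm in names(a)) {
    expect_equal(b[[nm]]$values, 2 * a[[nm]]$values, tolerance = 1e-9)
    expect_equal(b[[nm]]$onset_delay, a[[nm]]$onset_delay)
  }
})
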