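test_that("controller_config validates the AEA threshold", {
  expect_s3_class(controller_config(), "controller_config")
  expect_error(controller_config(theta_aea = 30), "inside the hip flexion")
})

test_that("extreme-angle guard ramps linearly to zero at the threshold", {
  expect_equal(extreme_angle_guard(0, 28, "flexion"), 1)
  expect_equal(extreme_angle_guard(25.5, 28, "flexion"), 0.5)
  expect_equal(extreme_angle_guard(28, 28, "flexion"), 0)
  expect_equal(extreme_angle_guard(30, 28, "flexion"), 0)
  expect_equal(extreme_angle_guard(-28, -28, "extension"), 0)
  expect_equal(extreme_angle_guard(-25.5, -28, "extension"), 0.5)
  expect_equal(extreme_angle_guard(0, -28, "extension"), 1)
})

test_that("derive_triggers fires only on rising edges and AEA up-crossings", {
  n <- 10
  contact <- cbind(c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                     FALSE, TRUE),
                   rep(TRUE, n))
  hip <- cbind(seq(0, 27, length.out = n), rep(20, n))
  tr <- derive_triggers(contact, hip)
  expect_equal(which(tr$contact_impulse[, 1] == 1), c(2L, 7L, 10L))
  expect_equal(sum(tr$contact_impulse[, 2]), 0)  # held high, no edge
  expect_equal(sum(tr$aea_impulse[, 1]), 1L)     # one up-crossing of 15 deg
  expect_equal(sum(tr$aea_impulse[, 2]), 0)      # starts above, never crosses
})

test_that("motor_drive wires triggers to the correct motors and signs", {
  tfs <- reference_motor_tfs("6A")
  n <- 300
  z <- matrix(0, n, 2)
  ci <- z; ci[5, 1] <- 1   # left foot touches down
  tr <- list(contact_impulse = ci, aea_impulse = z)
  U <- motor_drive(tr, tfs)
  # contralateral (right) hip and knee flex; ipsilateral (left) hip extends
  expect_equal(U[5:204, "hip_R"], tfs$hip_flexion$samples)
  expect_equal(U[5:104, "knee_R"], tfs$knee_flexion$samples)
  expect_equal(U[5:204, "hip_L"], -tfs$hip_extension$samples)
  expect_equal(max(abs(U[, "knee_L"])), 0)
  ai <- z; ai[10, 2] <- 1  # right hip reaches the AEA
  U2 <- motor_drive(list(contact_impulse = z, aea_impulse = ai), tfs)
  expect_equal(U2[10:109, "knee_R"], -tfs$knee_extension$samples)
  expect_equal(max(abs(U2[, c("hip_L", "hip_R", "knee_L")])), 0)
})

test_that("motor_drive is linear: superposed triggers sum", {
  tfs <- reference_motor_tfs("1B")
  n <- 400
  set.seed(2)
  mk <- function() {
    m <- matrix(0, n, 2)
    m[sample(n, 6), 1] <- 1; m[sample(n, 6), 2] <- 1
    m
  }
  t1 <- list(contact_impulse = mk(), aea_impulse = mk())
  t2 <- list(contact_impulse = mk(), aea_impulse = mk())
  both <- list(contact_impulse = t1$contact_impulse + t2$contact_impulse,
               aea_impulse = t1$aea_impulse + t2$aea_impulse)
  expect_equal(motor_drive(both, tfs),
               motor_drive(t1, tfs) + motor_drive(t2, tfs),
               tolerance = 1e-12)
})

test_that("apply_gain scales per motor and saturates at the rail", {
  cfg <- controller_config(gains = c(hip_L = 2, hip_R = 1,
                                     knee_L = 0.5, knee_R = 1))
  U <- matrix(1, 1, 4, dimnames = list(NULL, c("hip_L", "hip_R",
                                               "knee_L", "knee_R")))
  V <- apply_gain(U, cfg)
  expect_equal(as.numeric(V), c(4.6, 2.3, 1.15, 2.3))
  expect_equal(as.numeric(apply_gain(10 * U, cfg)), c(5, 5, 5, 5))
  expect_equal(as.numeric(apply_gain(-10 * U, cfg)), c(-5, -5, -5, -5))
  # guard factor scales before the rail
  expect_equal(as.numeric(apply_gain(U, cfg, gamma = 0)), c(0, 0, 0, 0))
})

test_that("online controller matches the offline LTI drive when unguarded", {
  tfs <- reference_motor_tfs("6A")
  cfg <- controller_config()
  n <- 500
  tick <- seq_len(n)
  # periodic alternating gait-like contacts, starting open
  contact <- cbind((tick %% 120) %in% 20:80,
                   ((tick + 60) %% 120) %in% 20:80)
  contact[1, ] <- FALSE
  hip <- cbind(20 * sin(2 * pi * tick / 120),
               20 * sin(2 * pi * (tick + 60) / 120))
  knee <- matrix(10, n, 2)  # safely inside both knee guards
  ctrl <- reflex_controller(tfs, cfg)
  U_on <- matrix(0, n, 4)
  for (i in tick) {
    cmd <- controller_step(ctrl, contact[i, ], hip[i, ], knee[i, ])
    U_on[i, ] <- cmd$U
  }
  U_off <- motor_drive(derive_triggers(contact, hip, cfg), tfs)
  expect_lt(max(abs(U_on - U_off)), 1e-12)
})

test_that("guard factors are reported and suppress drive at the extremes", {
  tfs <- reference_motor_tfs("6A")
  a <- reflex_controller(tfs)   # guarded leg at the hip-flexion extreme
  b <- reflex_controller(tfs)   # identical twin kept in the safe range
  # right-foot touchdown starts a left-hip-flexion playback on both
  controller_step(a, c(FALSE, TRUE), c(0, 0), c(10, 10))
  controller_step(b, c(FALSE, TRUE), c(0, 0), c(10, 10))
  # advance past the transfer-function delay so the playback is active
  for (i in 1:40) {
    controller_step(a, c(FALSE, TRUE), c(0, 0), c(10, 10))
    controller_step(b, c(FALSE, TRUE), c(0, 0), c(10, 10))
  }
  ca <- controller_step(a, c(FALSE, TRUE), c(25.5, 0), c(10, 10))
  cb <- controller_step(b, c(FALSE, TRUE), c(0, 0), c(10, 10))
  expect_gt(unname(cb$U["hip_L"]), 0)
  expect_equal(unname(ca$gamma["HF_L"]), 0.5)
  expect_equal(unname(ca$U["hip_L"]), 0.5 * unname(cb$U["hip_L"]))
  ca2 <- controller_step(a, c(FALSE, TRUE), c(28, 0), c(10, 10))
  expect_equal(unname(ca2$gamma["HF_L"]), 0)
  expect_equal(unname(ca2$U["hip_L"]), 0)
})

test_that("non-finite sensors hold the previous command", {
  tfs <- reference_motor_tfs("6A")
  ctrl <- reflex_controller(tfs)
  controller_step(ctrl, c(FALSE, TRUE), c(0, 0), c(10, 10))
  prev <- controller_step(ctrl, c(FALSE, TRUE), c(5, -5), c(10, 10))
  held <- controller_step(ctrl, c(FALSE, TRUE), c(NaN, -5), c(10, 10))
  expect_true(held$held)
  expect_equal(held$U, prev$U)
  expect_equal(held$V, prev$V)
})

test_that("all-zero sensors produce identically zero output (no CPG)", {
  tfs <- reference_motor_tfs("3B")
  ctrl <- reflex_controller(tfs)
  for (i in 1:300) {
    cmd <- controller_step(ctrl, c(FALSE, FALSE), c(0, 0), c(0, 0))
    expect_equal(max(abs(cmd$U)), 0)
    expect_equal(max(abs(cmd$V)), 0)
  }
})

test_that("controller rejects missing or wrong-rate transfer functions", {
  tfs <- reference_motor_tfs("6A")
  expect_error(reflex_controller(tfs[1:3]), "missing transfer function")
  slow <- reference_motor_tfs("6A", rate = 100)
  expect_error(reflex_controller(slow), "control rate")
})
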