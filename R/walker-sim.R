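#' Surrogate planar biped configuration
#'
#' A deliberately simple kinematic/first-order stand-in for a physical
#' planar biped: it exists to exercise the reflexive controller in closed
#' loop, not to reproduce a specific robot's dynamics. Hips are direct
#' drive (first-order lag toward an equilibrium set by the motor voltage);
#' knees are driven through an additional first-order spring lag and carry
#' a hard stop ("kneecap") at full extension. Ground contact is kinematic:
#' the swing foot lands when, with the knee extended and the leg
#' protracted, its geometric height reaches the ground.
#'
#' @param leg_length leg length (hip axis to foot) in m.
#' @param tau_hip hip motor first-order time constant, s.
#' @param tau_knee_motor knee motor time constant, s.
#' @param tau_knee_spring knee spring lag time constant, s.
#' @param k_hip,k_knee motor map, deg of joint-equilibrium per volt.
#' @param knee_contact_tol max knee flexion (deg) counting as "extended"
#'   for touchdown.
#' @param min_step_s shortest allowed interval between contacts, s.
#' @param double_support_s duration both feet report contact after a
#'   touchdown, s.
#' @param fall_timeout_s a fall is declared when no touchdown occurs for
#'   this long.
#' @param sensor_noise_sd additive angle sensor noise, deg (0 = none).
#' @return An object of class `plant_config`.
#' @export
plant_config <- function(leg_length = 0.3, tau_hip = 0.08,
                         tau_knee_motor = 0.05, tau_knee_spring = 0.05,
                         k_hip = 11, k_knee = 28, knee_contact_tol = 8,
                         min_step_s = 0.3, double_support_s = 0.05,
                         fall_timeout_s = 2.0, sensor_noise_sd = 0) {
  stopifnot(leg_length > 0, tau_hip > 0, tau_knee_motor > 0,
            tau_knee_spring > 0)
  structure(list(leg_length = leg_length, tau_hip = tau_hip,
                 tau_knee_motor = tau_knee_motor,
                 tau_knee_spring = tau_knee_spring, k_hip = k_hip,
                 k_knee = k_knee, knee_contact_tol = knee_contact_tol,
                 min_step_s = min_step_s,
                 double_support_s = double_support_s,
                 fall_timeout_s = fall_timeout_s,
                 sensor_noise_sd = sensor_noise_sd),
            class = "plant_config")
}

# vertical extent of a leg (units of leg length), thigh = shank = L/2
.leg_extent <- function(hip_deg, knee_deg) {
  h <- hip_deg * pi / 180; k <- knee_deg * pi / 180
  0.5 * cos(h) + 0.5 * cos(h - k)
}

#' Closed-loop walking simulation
#'
#' Runs the reflexive controller against the surrogate planar biped for
#' `duration` seconds at the control rate. Touchdown of the swing foot
#' (knee extended, leg protracted, geometric foot height at the ground,
#' and at least `min_step_s` since the previous contact) swaps the stance
#' leg, advances the walker by the step length
#' `L (sin(hip_swing) - sin(hip_stance))`, and feeds the new contact state
#' back to the controller. The run halts early and reports the strides
#' achieved when no touchdown occurs within the fall timeout or a hip
#' leaves its mechanical range. Deterministic for a fixed seed.
#'
#' @param tfs named list of the four `motor_tf`s
#'   (e.g. [reference_motor_tfs()]).
#' @param config a [controller_config()].
#' @param plant a [plant_config()].
#' @param duration simulated time, s.
#' @param seed integer seed (sensor noise; the default plant is
#'   noise-free and fully deterministic).
#' @return An object of class `walker_sim`: `trajectory` data frame (time,
#'   joint angles, contact flags, motor volts), `contacts` data frame
#'   (`time`, `foot`), `progress` (m), `fell`, `strides` and the configs.
#' @export
simulate_walker <- function(tfs, config = controller_config(),
                            plant = plant_config(), duration = 30,
                            seed = 1L) {
  set.seed(seed)
  ctrl <- reflex_controller(tfs, config)
  dt <- 1 / config$rate
  nt <- round(duration / dt)
  hip <- c(L = 12, R = -5)     # deg; right leg is the initial stance leg
  knee <- c(L = 0, R = 0)
  knee_motor <- c(L = 0, R = 0)
  stance <- 2L                  # 1 = left, 2 = right
  # no initial double support: only the stance foot reports contact on the
  # first tick, so the first reflex arc (stance extension + contralateral
  # swing flexion) starts cleanly instead of cancelling
  ds_until <- 0
  last_contact_t <- 0
  progress <- 0
  contacts <- list(data.frame(time = 0, foot = "right"))
  traj <- matrix(NA_real_, nt, 11)
  colnames(traj) <- c("time", "hip_L", "hip_R", "knee_L", "knee_R",
                      "contact_L", "contact_R", "V_hip_L", "V_hip_R",
                      "V_knee_L", "V_knee_R")
  fell <- FALSE
  hmin <- config$theta_ext[["hip_ext"]] - 10
  hmax <- config$theta_ext[["hip_flex"]] + 10
  for (i in seq_len(nt)) {
    t <- (i - 1) * dt
    swing <- 3L - stance
    contact <- c(FALSE, FALSE)
    contact[stance] <- TRUE
    if (t < ds_until) contact[swing] <- TRUE
    noise <- if (plant$sensor_noise_sd > 0)
      rnorm(4, sd = plant$sensor_noise_sd) else numeric(4)
    cmd <- controller_step(ctrl, contact,
                           hip + noise[1:2], knee + noise[3:4])
    V <- cmd$V
    # hip: first-order toward the voltage-set equilibrium
    hip_eq <- plant$k_hip * V[c("hip_L", "hip_R")]
    hip <- hip + (hip_eq - hip) / plant$tau_hip * dt
    hip <- pmin(pmax(hip, hmin), hmax)
    # knee: motor lag then spring lag, kneecap at full extension
    knee_eq <- plant$k_knee * V[c("knee_L", "knee_R")]
    knee_motor <- knee_motor + (knee_eq - knee_motor) /
      plant$tau_knee_motor * dt
    knee <- knee + (knee_motor - knee) / plant$tau_knee_spring * dt
    knee <- pmin(pmax(knee, 0), config$theta_ext[["knee_flex"]] + 10)
    names(hip) <- names(knee) <- c("L", "R")
    # touchdown?
    if (t - last_contact_t >= plant$min_step_s &&
        knee[swing] <= plant$knee_contact_tol && hip[swing] > 1 &&
        .leg_extent(hip[swing], knee[swing]) >=
          .leg_extent(hip[stance], 0) - 1e-6) {
      step_len <- plant$leg_length *
        (sin(hip[swing] * pi / 180) - sin(hip[stance] * pi / 180))
      progress <- progress + max(step_len, 0)
      stance <- swing
      last_contact_t <- t
      ds_until <- t + plant$double_support_s
      contacts[[length(contacts) + 1L]] <-
        data.frame(time = t, foot = c("left", "right")[stance])
    }
    traj[i, ] <- c(t, hip, knee, contact, V[c("hip_L", "hip_R")],
                   V[c("knee_L", "knee_R")])
    if (t - last_contact_t > plant$fall_timeout_s ||
        any(hip <= hmin + 0.01 & c(1, 2) == stance)) {
      fell <- TRUE
      traj <- traj[seq_len(i), , drop = FALSE]
      break
    }
  }
  contacts <- do.call(rbind, contacts)
  n_steps <- nrow(contacts) - 1L
  structure(list(trajectory = as.data.frame(traj), contacts = contacts,
                 progress = progress, fell = fell,
                 strides = floor(n_steps / 2),
                 duration = unname(traj[nrow(traj), "time"]),
                 config = config, plant = plant),
            class = "walker_sim")
}

#' @export
print.walker_sim <- function(x, ...) {
  cat(sprintf("<walker_sim> %.1f s simulated, %d strides, %.2f m progress%s\n",
              x$duration, x$strides, x$progress,
              if (x$fell) " (FELL)" else ""))
  invisible(x)
}

#' Gait metrics of a simulated run
#'
#' Stride duration is the mean interval between successive contacts of the
#' same foot; stride length is forward progress per stride; walking speed
#' is progress over elapsed time; relative speed is speed scaled to leg
#' lengths per second.
#'
#' @param sim a [simulate_walker()] result.
#' @return A list: `stride_duration_s`, `stride_length_m`, `speed_m_s`,
#'   `relative_speed` (leg lengths / s), `n_strides`.
#' @export
gait_metrics <- function(sim) {
  stopifnot(inherits(sim, "walker_sim"))
  if (sim$strides < 2L) stop("need at least 2 strides for gait metrics")
  durs <- unlist(lapply(c("left", "right"), function(f) {
    tt <- sim$contacts$time[sim$contacts$foot == f]
    diff(tt)
  }))
  speed <- sim$progress / sim$duration
  list(stride_duration_s = mean(durs),
       stride_length_m = sim$progress / sim$strides,
       speed_m_s = speed,
       relative_speed = speed / sim$plant$leg_length,
       n_strides = sim$strides)
}

#' Knee phase portrait and limit-cycle dispersion
#'
#' Builds the (angle, angular velocity) phase plane of a knee angle series
#' with central-difference velocities, and quantifies limit-cycle
#' regularity as the mean distance between successive points of the
#' Poincare section taken at heel strikes. A perfectly periodic gait gives
#' zero dispersion; perturbations show up as scatter that shrinks again as
#' the gait converges back to the cycle.
#'
#' @param x a [simulate_walker()] result, or a numeric knee-angle series.
#' @param rate sampling rate in Hz (numeric input).
#' @param events strike times in s (numeric input).
#' @param knee which knee column when `x` is a simulation (`"knee_L"` or
#'   `"knee_R"`).
#' @return A list of class `phase_portrait`: `angle`, `velocity`,
#'   `section` (matrix of Poincare points) and `dispersion`.
#' @export
phase_portrait <- function(x, rate = NULL, events = NULL, knee = "knee_R") {
  if (inherits(x, "walker_sim")) {
    v <- x$trajectory[[knee]]
    rate <- x$config$rate
    foot <- if (knee == "knee_R") "right" else "left"
    events <- x$contacts$time[x$contacts$foot == foot]
  } else {
    v <- as.numeric(x)
    if (is.null(rate)) stop("'rate' required for numeric input")
  }
  n <- length(v)
  if (n < 3L) stop("series too short")
  vel <- c(NA, (v[3:n] - v[1:(n - 2)]) * rate / 2, NA)
  section <- NULL
  dispersion <- NA_real_
  if (!is.null(events) && length(events) >= 3L) {
    idx <- round(events * rate) + 1L
    idx <- idx[idx >= 2L & idx <= n - 1L]
    section <- cbind(angle = v[idx], velocity = vel[idx])
    if (nrow(section) >= 2L) {
      d <- sqrt(rowSums((section[-1, , drop = FALSE] -
                         section[-nrow(section), , drop = FALSE])^2))
      dispersion <- mean(d)
    }
  }
  structure(list(angle = v, velocity = vel, section = section,
                 dispersion = dispersion),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("<phase_portrait> %d samples, dispersion %.4g\n",
              length(x$angle), x$dispersion))
  invisible(x)
}
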