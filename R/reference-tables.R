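# Shipped reference transfer-function parameter sets (sets 1A-6B).
#
# Twelve sets of fitted twitch parameters for the hip and knee motor
# transfer functions, obtained from treadmill walking of ten adults under
# two speed-sequence protocols (A: ~25 steps per speed setting, B: ~100):
# 1 = mean of all subjects, 2 = male mean, 3 = female mean, 4 = per-function
# minimum-final-MSE subject, 5/6 = two individual subjects. These are the
# sets deployed on the physical biped; they double as realistic inputs for
# tests and examples.

#' Reference hip transfer-function parameters
#'
#' Fitted twitch parameters (`tau1`, `tau2`, `T0`, ms) of the hip flexor
#' and extensor transfer functions for the twelve shipped sets.
#'
#' @return Data frame with columns `set`, `action` (flexion/extension),
#'   `tau1`, `tau2`, `T0`.
#' @export
reference_hip_params <- function() {
  sets <- c("1A", "1B", "2A", "2B", "3A", "3B",
            "4A", "4B", "5A", "5B", "6A", "6B")
  flex <- matrix(c(
    76.97, 76.96, 75,
    86.91, 86.91, 80,
    88.31, 88.31, 30,
    83.80, 83.80, 60,
    78.53, 78.52, 90,
    93.71, 93.71, 80,
    91.96, 91.96, 125,
    77.52, 77.52, 70,
    113.28, 113.28, 5,
    76.18, 76.18, 75,
    93.08, 93.08, 110,
    78.41, 78.41, 120), ncol = 3, byrow = TRUE)
  ext <- matrix(c(
    73.22, 73.22, 75,
    128.24, 81.73, 85,
    72.47, 72.47, 80,
    71.82, 71.82, 80,
    72.31, 72.31, 100,
    133.76, 133.76, 80,
    95.88, 34.27, 80,
    100.46, 100.46, 50,
    91.43, 91.43, 15,
    74.65, 74.65, 100,
    112.16, 112.16, 100,
    110.89, 110.89, 100), ncol = 3, byrow = TRUE)
  rbind(
    data.frame(set = sets, action = "flexion",
               tau1 = flex[, 1], tau2 = flex[, 2], T0 = flex[, 3]),
    data.frame(set = sets, action = "extension",
               tau1 = ext[, 1], tau2 = ext[, 2], T0 = ext[, 3]))
}

#' Reference knee transfer-function parameters
#'
#' Fitted twitch parameters (`tau1`, `tau2`, `T0`, ms) of the knee flexor
#' and extensor transfer functions for the twelve shipped sets. When
#' deployed, the knee `T0` values are set to zero because the sprung knee
#' joint supplies its own latency between motor drive and joint motion.
#'
#' @return Data frame with columns `set`, `action`, `tau1`, `tau2`, `T0`.
#' @export
reference_knee_params <- function() {
  sets <- c("1A", "1B", "2A", "2B", "3A", "3B",
            "4A", "4B", "5A", "5B", "6A", "6B")
  flex <- matrix(c(
    83.11, 83.11, 115,
    105.02, 105.02, 115,
    94.47, 94.47, 110,
    76.58, 76.58, 120,
    69.09, 69.09, 140,
    113.76, 113.76, 125,
    108.96, 108.96, 90,
    82.99, 82.85, 105,
    95.95, 95.95, 110,
    82.99, 82.85, 105,
    78.37, 78.37, 150,
    97.24, 97.22, 130), ncol = 3, byrow = TRUE)
  ext <- matrix(c(
    103.84, 103.84, 425,
    134.63, 134.59, 440,
    107.71, 107.71, 430,
    139.47, 139.47, 435,
    77.13, 77.12, 460,
    94.56, 94.56, 495,
    136.61, 136.54, 450,
    150.33, 150.33, 415,
    131.17, 131.17, 410,
    148.99, 148.99, 420,
    151.75, 151.75, 425,
    123.34, 123.34, 495), ncol = 3, byrow = TRUE)
  rbind(
    data.frame(set = sets, action = "flexion",
               tau1 = flex[, 1], tau2 = flex[, 2], T0 = flex[, 3]),
    data.frame(set = sets, action = "extension",
               tau1 = ext[, 1], tau2 = ext[, 2], T0 = ext[, 3]))
}

#' Reference hip transfer-function characteristics
#'
#' Measured duration (`dT50`, ms between the 50%-of-peak crossings) and
#' peak time (`Tpeak`, ms from trigger) of the hip flexor and extensor
#' transfer functions for the twelve shipped sets, together with the gait
#' outcome observed when each set drove the physical walker.
#'
#' @return Data frame with columns `set`, `gait` (stable/unstable),
#'   `dT50_flex`, `Tpeak_flex`, `dT50_ext`, `Tpeak_ext`.
#' @export
reference_hip_characteristics <- function() {
  data.frame(
    set = c("1B", "3B", "4B", "5A", "6A", "6B",
            "1A", "2A", "2B", "3A", "4A", "5B"),
    gait = rep(c("stable", "unstable"), each = 6),
    dT50_flex = c(175, 190, 155, 140, 220, 215,
                  160, 135, 155, 280, 225, 155),
    Tpeak_flex = c(215, 230, 190, 275, 230, 195,
                   190, 215, 205, 195, 225, 185),
    dT50_ext = c(190, 220, 165, 125, 230, 225,
                 160, 130, 165, 185, 130, 185),
    Tpeak_ext = c(255, 330, 245, 225, 275, 270,
                  180, 175, 175, 180, 145, 185))
}

#' Build the four motor transfer functions of a reference set
#'
#' Convenience constructor: finalizes hip flexion/extension and knee
#' flexion/extension [finalize_motor_tf()] waveforms from the shipped
#' reference parameters of one set.
#'
#' @param set set label, e.g. `"6A"`.
#' @param rate control rate in Hz.
#' @return Named list of `motor_tf`: `hip_flexion`, `hip_extension`,
#'   `knee_flexion`, `knee_extension`.
#' @export
reference_motor_tfs <- function(set = "6A", rate = 200) {
  hp <- reference_hip_params()
  kp <- reference_knee_params()
  pick <- function(df, act) {
    r <- df[df$set == set & df$action == act, ]
    if (nrow(r) != 1L) stop("unknown set '", set, "'")
    curve_params(1, r$tau1, r$tau2, r$T0)
  }
  list(hip_flexion = finalize_motor_tf(pick(hp, "flexion"), "hip", rate),
       hip_extension = finalize_motor_tf(pick(hp, "extension"), "hip", rate),
       knee_flexion = finalize_motor_tf(pick(kp, "flexion"), "knee", rate),
       knee_extension = finalize_motor_tf(pick(kp, "extension"), "knee", rate))
}
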