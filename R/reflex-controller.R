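#' Reflexive controller configuration
#'
#' Gains, extreme-angle guard thresholds and the anterior-extreme-angle
#' (AEA) trigger threshold of the reflexive walking controller. All angles
#' are in degrees with hip flexion positive (leg forward of vertical) and
#' knee flexion positive (0 = straight leg). The shipped thresholds and
#' gains are defaults tuned for the surrogate plant, not measured values.
#'
#' @param gains named numeric motor gains (`hip_L`, `hip_R`, `knee_L`,
#'   `knee_R`).
#' @param theta_ext named extreme-angle thresholds:
#'   `hip_flex` (max hip flexion), `hip_ext` (max extension, negative),
#'   `knee_flex` (max knee flexion), `knee_ext` (full extension, 0).
#' @param theta_aea hip flexion angle (deg) whose up-crossing triggers knee
#'   extension at terminal swing.
#' @param rate control rate in Hz (5 ms ticks at the default 200).
#' @param amp_gain motor amplifier gain applied after the motor gains.
#' @param rail output saturation in volts.
#' @param guard_band width (deg) of the soft guard ramp before each
#'   extreme angle.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(gains = c(hip_L = 1, hip_R = 1,
                                        knee_L = 1, knee_R = 1),
                              theta_ext = c(hip_flex = 28, hip_ext = -28,
                                            knee_flex = 75, knee_ext = 0),
                              theta_aea = 15, rate = 200, amp_gain = 2.3,
                              rail = 5, guard_band = 5) {
  stopifnot(rate > 0, all(is.finite(gains)), guard_band > 0, rail > 0)
  if (theta_aea >= theta_ext[["hip_flex"]])
    stop("AEA threshold must lie inside the hip flexion range")
  structure(list(gains = gains, theta_ext = theta_ext,
                 theta_aea = theta_aea, rate = rate, amp_gain = amp_gain,
                 rail = rail, guard_band = guard_band),
            class = "controller_config")
}

#' Extreme-angle guard factor
#'
#' Soft limiter preventing a joint from being driven beyond its extreme
#' angle: the factor is 1 inside the safe range, ramps linearly to 0 over
#' the final `band` degrees before the threshold, and is 0 at and beyond
#' it. It multiplies the drive of the motor pushing toward that extreme.
#'
#' @param angle joint angle(s), deg.
#' @param theta_ext extreme-angle threshold, deg.
#' @param direction `"flexion"` if the guarded motion increases the angle,
#'   `"extension"` if it decreases it.
#' @param band ramp width in deg.
#' @return Guard factor(s) in [0, 1].
#' @export
extreme_angle_guard <- function(angle, theta_ext,
                                direction = c("flexion", "extension"),
                                band = 5) {
  direction <- match.arg(direction)
  dist <- if (direction == "flexion") theta_ext - angle else angle - theta_ext
  pmin(pmax(dist / band, 0), 1)
}

#' Derive trigger impulse trains from sensor logs
#'
#' Converts boolean ground-contact states and hip angles, sampled at the
#' control rate, into unit impulse trains: a contact impulse on every
#' 0-to-1 contact transition (the derivative of the contact state) and an
#' AEA impulse whenever a hip angle up-crosses the AEA threshold.
#'
#' @param contact n x 2 logical matrix (columns left, right foot).
#' @param hip n x 2 numeric matrix of hip angles (deg).
#' @param config a [controller_config()].
#' @return A list of n x 2 0/1 matrices `contact_impulse` and
#'   `aea_impulse`.
#' @export
derive_triggers <- function(contact, hip, config = controller_config()) {
  contact <- as.matrix(contact); hip <- as.matrix(hip)
  stopifnot(ncol(contact) == 2L, ncol(hip) == 2L,
            nrow(contact) == nrow(hip))
  n <- nrow(contact)
  rising <- function(b) { b <- b > 0; rbind(c(FALSE, FALSE),
                                            b[-1, , drop = FALSE] &
                                            !b[-n, , drop = FALSE]) }
  up <- function(a) rbind(c(FALSE, FALSE),
                          a[-1, , drop = FALSE] >= config$theta_aea &
                          a[-n, , drop = FALSE] < config$theta_aea)
  list(contact_impulse = 1 * rising(contact), aea_impulse = 1 * up(hip))
}

#' Offline motor drive from trigger trains
#'
#' Convolves the trigger impulse trains with the four motor transfer
#' functions following the reflexive wiring -- hip flexion and knee flexion
#' from the contralateral contact, hip extension from the ipsilateral
#' contact, knee extension from the ipsilateral AEA impulse -- and combines
#' flexor (positive) and extensor (negative) drive per motor. The path is
#' linear and time invariant: overlapping playbacks from repeated triggers
#' sum.
#'
#' @param triggers a [derive_triggers()] result.
#' @param tfs named list of `motor_tf`s (`hip_flexion`, `hip_extension`,
#'   `knee_flexion`, `knee_extension`), e.g. [reference_motor_tfs()].
#' @return n x 4 numeric matrix `U` with columns `hip_L`, `hip_R`,
#'   `knee_L`, `knee_R`.
#' @export
motor_drive <- function(triggers, tfs) {
  need <- c("hip_flexion", "hip_extension", "knee_flexion", "knee_extension")
  if (!all(need %in% names(tfs)))
    stop("tfs must contain ", paste(need, collapse = ", "))
  ci <- triggers$contact_impulse
  ai <- triggers$aea_impulse
  n <- nrow(ci)
  cv <- function(train, tf) fir_predict(tf$samples, train)[seq_len(n)]
  other <- c(2L, 1L)
  U <- matrix(0, n, 4, dimnames = list(NULL, c("hip_L", "hip_R",
                                               "knee_L", "knee_R")))
  for (leg in 1:2) {
    U[, leg] <- cv(ci[, other[leg]], tfs$hip_flexion) -
                cv(ci[, leg], tfs$hip_extension)
    U[, 2L + leg] <- cv(ci[, other[leg]], tfs$knee_flexion) -
                     cv(ai[, leg], tfs$knee_extension)
  }
  U
}

#' Apply gains and saturation
#'
#' Final output stage: `V = gain x amplifier gain x Gamma x U`, saturated
#' at the output rail.
#'
#' @param U drive matrix or vector (columns/names `hip_L`, `hip_R`,
#'   `knee_L`, `knee_R`).
#' @param config a [controller_config()].
#' @param gamma guard factor(s) in [0, 1], same shape as `U` or scalar.
#' @return Saturated output voltages, same shape as `U`.
#' @export
apply_gain <- function(U, config = controller_config(), gamma = 1) {
  g <- config$gains[c("hip_L", "hip_R", "knee_L", "knee_R")]
  V <- if (is.matrix(U)) sweep(U * gamma, 2, g * config$amp_gain, `*`)
       else U * gamma * g * config$amp_gain
  pmin(pmax(V, -config$rail), config$rail)
}

#' Create a reflexive controller
#'
#' Stateful closed-loop form of the reflexive control law, advanced one
#' 5 ms tick at a time with [controller_step()]. The only state is the
#' previous contact/hip-angle sample (for edge detection), the pending
#' transfer-function playbacks, and the previous command (held on sensor
#' dropout). With all-zero sensor streams the output is identically zero:
#' there is no internal oscillator.
#'
#' @param tfs named list of the four `motor_tf`s.
#' @param config a [controller_config()].
#' @return An object of class `reflex_controller` (an environment).
#' @export
reflex_controller <- function(tfs, config = controller_config()) {
  need <- c("hip_flexion", "hip_extension", "knee_flexion", "knee_extension")
  miss <- setdiff(need, names(tfs))
  if (length(miss)) stop("missing transfer function(s): ",
                         paste(miss, collapse = ", "))
  for (nm in need)
    if (tfs[[nm]]$rate != config$rate)
      stop("transfer function '", nm, "' is not sampled at the control rate")
  e <- new.env(parent = emptyenv())
  e$tfs <- tfs
  e$config <- config
  e$maxlen <- max(vapply(tfs, function(tf) length(tf$samples), integer(1)))
  # ring buffers of pending playback: channels HF,HE,KF,KE x legs L,R
  e$buf <- matrix(0, e$maxlen, 8)
  colnames(e$buf) <- c(t(outer(c("HF", "HE", "KF", "KE"), c("L", "R"),
                               paste, sep = "_")))
  e$ptr <- 1L
  e$prev_contact <- c(FALSE, FALSE)
  e$prev_hip <- c(0, 0)
  e$prev_cmd <- setNames(numeric(4), c("hip_L", "hip_R", "knee_L", "knee_R"))
  class(e) <- "reflex_controller"
  e
}

#' @export
print.reflex_controller <- function(x, ...) {
  cat(sprintf("<reflex_controller> %g Hz, AEA %g deg, rail %g V\n",
              x$config$rate, x$config$theta_aea, x$config$rail))
  invisible(x)
}

.ring_add <- function(ctrl, channel, samples) {
  idx <- ((ctrl$ptr - 1L + seq_along(samples) - 1L) %% ctrl$maxlen) + 1L
  ctrl$buf[idx, channel] <- ctrl$buf[idx, channel] + samples
}

#' Advance the controller one tick
#'
#' One 5 ms control tick: detect contact rising edges and AEA up-crossings,
#' start the wired transfer-function playbacks (contralateral contact
#' drives hip and knee flexion, ipsilateral contact drives hip extension,
#' ipsilateral AEA drives knee extension; overlapping playbacks sum), read
#' the current drive, apply the extreme-angle guards per direction,
#' combine flexor minus extensor per motor, and apply gains and
#' saturation. A non-finite sensor sample holds the previous command.
#'
#' @param ctrl a [reflex_controller()].
#' @param contact logical length-2 (left, right foot on ground).
#' @param hip,knee numeric length-2 joint angles in deg.
#' @return A list of class `motor_command`: `U` (pre-gain drive), `V`
#'   (post-gain volts), `gamma` (guard factors, 8 channels) and `triggers`.
#' @export
controller_step <- function(ctrl, contact, hip, knee) {
  cfg <- ctrl$config
  if (any(!is.finite(c(hip, knee))) || any(is.na(contact))) {
    return(structure(list(U = ctrl$prev_cmd, V = apply_gain(ctrl$prev_cmd, cfg),
                          gamma = NULL, triggers = NULL, held = TRUE),
                     class = "motor_command"))
  }
  contact <- as.logical(contact)
  edge <- contact & !ctrl$prev_contact
  aea <- hip >= cfg$theta_aea & ctrl$prev_hip < cfg$theta_aea
  other <- c(2L, 1L)
  for (leg in 1:2) {
    side <- c("L", "R")[leg]
    if (edge[other[leg]]) {  # contralateral foot touched down
      .ring_add(ctrl, paste0("HF_", side), ctrl$tfs$hip_flexion$samples)
      .ring_add(ctrl, paste0("KF_", side), ctrl$tfs$knee_flexion$samples)
    }
    if (edge[leg])           # own foot touched down
      .ring_add(ctrl, paste0("HE_", side), ctrl$tfs$hip_extension$samples)
    if (aea[leg])            # own hip reached the AEA
      .ring_add(ctrl, paste0("KE_", side), ctrl$tfs$knee_extension$samples)
  }
  drive <- ctrl$buf[ctrl$ptr, ]
  ctrl$buf[ctrl$ptr, ] <- 0
  ctrl$ptr <- (ctrl$ptr %% ctrl$maxlen) + 1L
  band <- cfg$guard_band
  gamma <- setNames(numeric(8), colnames(ctrl$buf))
  U <- setNames(numeric(4), c("hip_L", "hip_R", "knee_L", "knee_R"))
  for (leg in 1:2) {
    side <- c("L", "R")[leg]
    g_hf <- extreme_angle_guard(hip[leg], cfg$theta_ext[["hip_flex"]],
                                "flexion", band)
    g_he <- extreme_angle_guard(hip[leg], cfg$theta_ext[["hip_ext"]],
                                "extension", band)
    g_kf <- extreme_angle_guard(knee[leg], cfg$theta_ext[["knee_flex"]],
                                "flexion", band)
    g_ke <- extreme_angle_guard(knee[leg], cfg$theta_ext[["knee_ext"]],
                                "extension", band)
    gamma[paste0(c("HF_", "HE_", "KF_", "KE_"), side)] <-
      c(g_hf, g_he, g_kf, g_ke)
    U[leg] <- g_hf * drive[paste0("HF_", side)] -
              g_he * drive[paste0("HE_", side)]
    U[2L + leg] <- g_kf * drive[paste0("KF_", side)] -
                   g_ke * drive[paste0("KE_", side)]
  }
  ctrl$prev_contact <- contact
  ctrl$prev_hip <- hip
  ctrl$prev_cmd <- U
  structure(list(U = U, V = apply_gain(U, cfg),
                 gamma = gamma,
                 triggers = list(contact = edge, aea = aea), held = FALSE),
            class = "motor_command")
}
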