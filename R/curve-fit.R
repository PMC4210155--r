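#' Critically damped muscle-twitch parameters
#'
#' Parameters of the second-order twitch surrogate fitted to each
#' joint-action segment: amplitude `A` (peak value, arbitrary units), rise
#' and fall time constants `tau1`, `tau2` (ms), and the delay `T0` (ms)
#' from the trigger signal to contraction onset.
#'
#' @param A peak amplitude (> 0).
#' @param tau1,tau2 rise and fall time constants in ms (> 0).
#' @param T0 trigger-to-onset delay in ms (>= 0).
#' @return An object of class `curve_params`.
#' @export
curve_params <- function(A, tau1, tau2, T0) {
  if (!(A > 0)) stop("A must be positive")
  if (!(tau1 > 0 && tau2 > 0)) stop("time constants must be positive")
  if (T0 < 0) stop("T0 must be non-negative")
  structure(list(A = A, tau1 = tau1, tau2 = tau2, T0 = T0),
            class = "curve_params")
}

#' @export
print.curve_params <- function(x, ...) {
  cat(sprintf("<curve_params> A=%.4g, tau1=%.2f ms, tau2=%.2f ms, T0=%.1f ms\n",
              x$A, x$tau1, x$tau2, x$T0))
  invisible(x)
}

#' Muscle-twitch model curve
#'
#' Impulse response of a (near-)critically damped second-order system,
#' normalized so that the peak value equals `A`: zero for `t < T0` and, for
#' `s = t - T0 >= 0`,
#' \deqn{h(s) = A (e^{-s/\tau_1} - e^{-s/\tau_2}) /
#'              (e^{-s^*/\tau_1} - e^{-s^*/\tau_2})}
#' where \eqn{s^* = \tau_1 \tau_2 \log(\tau_1/\tau_2) / (\tau_1 - \tau_2)}
#' is the peak time. In the critical limit \eqn{\tau_2 \to \tau_1 = \tau}
#' this is the analytic \eqn{A (s/\tau) e^{1 - s/\tau}}, peaking at
#' \eqn{s = \tau} with value `A`; both branches agree continuously.
#'
#' @param params a [curve_params()] (or list with `A`, `tau1`, `tau2`,
#'   `T0`).
#' @param t time axis in ms.
#' @return Numeric curve values.
#' @export
model_curve <- function(params, t) {
  A <- params$A; tau1 <- params$tau1; tau2 <- params$tau2; T0 <- params$T0
  s <- t - T0
  y <- numeric(length(t))
  pos <- s > 0
  sp <- s[pos]
  if (abs(tau1 - tau2) < 1e-9 * max(tau1, tau2)) {
    tau <- (tau1 + tau2) / 2
    y[pos] <- A * (sp / tau) * exp(1 - sp / tau)
  } else {
    speak <- log(tau1 / tau2) * tau1 * tau2 / (tau1 - tau2)
    denom <- exp(-speak / tau1) - exp(-speak / tau2)
    y[pos] <- A * (exp(-sp / tau1) - exp(-sp / tau2)) / denom
  }
  y
}

#' Fit the twitch model to an action segment
#'
#' Bounded Levenberg-Marquardt least-squares fit of [model_curve()] to a
#' segment. The fit starts from the supplied initialization (default:
#' `tau1 = tau2 = 50` ms, `T0 = 0`, `A` = segment peak) and, because the
#' residual surface has local minima in `(tau, T0)`, also from a small
#' deterministic set of data-derived starting points (onset, peak time and
#' width heuristics); the lowest-residual solution is returned. Bounds:
#' `tau` in [5, 500] ms, `T0` in [0, 500] ms.
#'
#' @param segment an `action_segment`, or a numeric vector with `rate`.
#' @param init a [curve_params()] initialization.
#' @param rate sampling rate in Hz when `segment` is numeric.
#' @param lower,upper named bounds for `A`, `tau1`, `tau2`, `T0`.
#' @return A list with `params` ([curve_params()]), `residual_rms`,
#'   `converged` and the raw optimizer object.
#' @export
fit_curve <- function(segment, init = NULL, rate = NULL,
                      lower = c(A = 1e-9, tau1 = 5, tau2 = 5, T0 = 0),
                      upper = c(A = Inf, tau1 = 500, tau2 = 500, T0 = 500)) {
  if (inherits(segment, "action_segment")) {
    y <- segment$values
    rate <- segment$rate
  } else {
    y <- as.numeric(segment)
    if (is.null(rate)) stop("'rate' required for numeric input")
  }
  if (length(y) < 4L) stop("segment too short to fit (need >= 4 samples)")
  t <- (seq_along(y) - 1) / rate * 1000  # ms
  pk <- max(y)
  if (pk <= 0) stop("segment has no positive excursion")
  if (is.null(init)) init <- curve_params(pk, 50, 50, 0)
  p_init <- c(A = init$A, tau1 = init$tau1, tau2 = init$tau2, T0 = init$T0)
  tp <- t[which.max(y)]
  on <- t[which(y > 0.01 * pk)[1]]
  tau0 <- max(tp - on, 6)
  starts <- list(p_init,
                 c(A = pk, tau1 = tau0, tau2 = tau0, T0 = max(on, 0)),
                 c(A = pk, tau1 = tau0 / 2, tau2 = 2 * tau0, T0 = max(on, 0)),
                 c(A = pk, tau1 = 2 * tau0, tau2 = tau0 / 2, T0 = max(on, 0)))
  resid_fn <- function(p)
    model_curve(list(A = p[["A"]], tau1 = p[["tau1"]], tau2 = p[["tau2"]],
                     T0 = p[["T0"]]), t) - y
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), pmin(upper, c(A = pk * 100, tau1 = 500,
                                              tau2 = 500, T0 = 500)))
    f <- try(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2)) best <- f
  }
  if (is.null(best)) stop("curve fit failed from every starting point")
  p <- best$par
  list(params = curve_params(p[["A"]], p[["tau1"]], p[["tau2"]], p[["T0"]]),
       residual_rms = sqrt(mean(best$fvec^2)),
       converged = best$info %in% 1:4,
       fit = best)
}

#' Finalize a motor transfer function
#'
#' Evaluates the fitted twitch model at the 200 Hz control rate, keeps only
#' positive values, and normalizes the amplitude to the 0-1 V output
#' range. Hip functions last one stride (1000 ms, 200 samples); knee
#' functions are halved to one step (500 ms, 100 samples) and their delay
#' constant is forced to zero (the sprung knee supplies its own latency).
#'
#' @param params a [curve_params()].
#' @param joint `"hip"` or `"knee"`.
#' @param rate control rate in Hz.
#' @return An object of class `motor_tf`: `samples` in [0, 1] with max 1,
#'   `rate`, `duration_ms`, `joint`.
#' @export
finalize_motor_tf <- function(params, joint = c("hip", "knee"), rate = 200) {
  joint <- match.arg(joint)
  duration_ms <- if (joint == "hip") 1000 else 500
  p <- params
  if (joint == "knee") p <- curve_params(p$A, p$tau1, p$tau2, 0)
  n <- round(duration_ms / 1000 * rate)
  t <- (seq_len(n) - 1) / rate * 1000
  v <- model_curve(p, t)
  v[v < 0] <- 0
  if (max(v) <= 0) stop("transfer function is identically zero")
  v <- v / max(v)
  structure(list(samples = v, rate = rate, duration_ms = duration_ms,
                 joint = joint, params = p),
            class = "motor_tf")
}

#' @export
print.motor_tf <- function(x, ...) {
  cat(sprintf("<motor_tf> %s: %d samples @ %g Hz (%d ms), peak 1\n",
              x$joint, length(x$samples), x$rate, x$duration_ms))
  invisible(x)
}

#' Transfer-function characteristics
#'
#' Computes the duration `dT50` (ms between the first up-crossing and the
#' last down-crossing of 50% of the peak, with linear interpolation between
#' samples) and the peak time `Tpeak` (ms from the trigger to the peak).
#'
#' @param tf a [finalize_motor_tf()] result, or numeric samples with
#'   `rate`.
#' @param rate sampling rate in Hz for numeric input.
#' @return A list of class `tf_characteristics`: `dT50`, `Tpeak` (ms) and
#'   `peak_at_boundary` flag.
#' @export
characterize <- function(tf, rate = NULL) {
  if (inherits(tf, "motor_tf")) {
    v <- tf$samples; rate <- tf$rate
  } else {
    v <- as.numeric(tf)
    if (is.null(rate)) stop("'rate' required for numeric input")
  }
  n <- length(v)
  pk_i <- which.max(v)
  pk <- v[pk_i]
  half <- pk / 2
  t_ms <- (seq_len(n) - 1) / rate * 1000
  cross_up <- NA_real_
  for (i in seq_len(pk_i - 1L)) {
    if (v[i] < half && v[i + 1L] >= half) {
      cross_up <- t_ms[i] + (half - v[i]) / (v[i + 1L] - v[i]) * 1000 / rate
      break
    }
  }
  cross_dn <- NA_real_
  if (pk_i < n) {
    for (i in (n - 1L):pk_i) {
      if (v[i] >= half && v[i + 1L] < half) {
        cross_dn <- t_ms[i] + (v[i] - half) / (v[i] - v[i + 1L]) * 1000 / rate
        break
      }
    }
  }
  boundary <- pk_i %in% c(1L, n) || is.na(cross_up) || is.na(cross_dn)
  if (is.na(cross_up)) cross_up <- t_ms[1]
  if (is.na(cross_dn)) cross_dn <- t_ms[n]
  dT50 <- cross_dn - cross_up
  if (n >= 2L && dT50 <= 0) dT50 <- 1000 / rate  # single-sample spike
  structure(list(dT50 = dT50, Tpeak = t_ms[pk_i],
                 peak_at_boundary = boundary),
            class = "tf_characteristics")
}

#' @export
print.tf_characteristics <- function(x, ...) {
  cat(sprintf("<tf_characteristics> dT50=%.1f ms, Tpeak=%.1f ms%s\n",
              x$dT50, x$Tpeak,
              if (x$peak_at_boundary) " (peak at boundary)" else ""))
  invisible(x)
}

#' Hip-duration stability heuristic
#'
#' The hip extensor activation should stay above half its peak for longer
#' than the hip flexor's (`ext dT50 > flex dT50`) for the stance leg to
#' extend far enough backward while the swing leg protracts; otherwise the
#' swing foot tends to scuff and the walker stumbles. A tendency observed
#' across transfer-function sets, not a guarantee: known exceptions exist
#' in both directions.
#'
#' @param flex,ext [characterize()] results for the hip flexor and
#'   extensor.
#' @return A list with logical `verdict` (`TRUE` predicts a stable gait)
#'   and `margin` (ms, `ext$dT50 - flex$dT50`).
#' @export
stability_heuristic <- function(flex, ext) {
  list(verdict = ext$dT50 > flex$dT50, margin = ext$dT50 - flex$dT50)
}
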