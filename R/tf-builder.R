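#' Convolve an impulse response with the mean heel template
#'
#' Converts a truncated impulse response `h` into the transfer curve
#' `H = h * u` (discrete convolution with the mean FSR heel-contact
#' template `u`, truncated to one stride). Triggering `H` with a unit
#' impulse is then equivalent to driving `h` with a typical heel-contact
#' loading curve, so a contact switch impulse can replace the FSR input.
#'
#' @param h truncated impulse response (numeric, one stride; see
#'   [apply_half_hanning()]).
#' @param u mean heel template from [mean_heel_template()].
#' @param rate sampling rate in Hz.
#' @param trigger trigger label carried along (`"CH"`, `"IH"` or `"AEA"`).
#' @return An object of class `transfer_curve`: `H`, `rate`, `trigger`,
#'   and `landmarks` (NULL until located).
#' @export
fsr_convolve <- function(h, u, rate, trigger = c("CH", "IH", "AEA")) {
  trigger <- match.arg(trigger)
  h <- as.numeric(h); u <- as.numeric(u)
  if (length(u) == 0L) stop("empty heel template")
  H <- fir_predict(h, c(u, numeric(max(0L, length(h) - length(u)))))
  H <- H[seq_len(length(h))]
  structure(list(H = H, rate = rate, trigger = trigger, landmarks = NULL),
            class = "transfer_curve")
}

#' @export
print.transfer_curve <- function(x, ...) {
  cat(sprintf("<transfer_curve> %d samples @ %g Hz, trigger %s, %s\n",
              length(x$H), x$rate, x$trigger,
              if (is.null(x$landmarks)) "landmarks not located"
              else sprintf("%d landmarks", nrow(x$landmarks))))
  invisible(x)
}

# moving-average smoothing over a given window (ms)
.smooth_ma <- function(v, rate, window_ms = 25) {
  w <- max(1L, round(window_ms / 1000 * rate))
  if (w %% 2L == 0L) w <- w + 1L
  k <- rep(1 / w, w)
  n <- length(v)
  padded <- c(rep(v[1], w %/% 2), v, rep(v[n], w %/% 2))
  as.numeric(stats::filter(padded, k, sides = 2))[(w %/% 2 + 1):(w %/% 2 + n)]
}

#' Locate peaks and troughs of a transfer curve
#'
#' Lightly smooths the curve (25 ms moving average) and scans for local
#' extrema, keeping peaks whose prominence exceeds a fraction of the curve
#' range and placing one trough (the minimum) between consecutive peaks and
#' before the first / after the last peak (curve ends stand in for missing
#' flanking troughs and are flagged). Plateau ties break to the earliest
#' sample.
#'
#' @param curve a [fsr_convolve()] transfer curve.
#' @param min_prominence minimal peak height above its flanking minima, as
#'   a fraction of the curve range.
#' @param smooth_ms smoothing window in ms.
#' @return The curve with a `landmarks` data frame (`type` = trough/peak,
#'   `index`, `time` s, `value`, `boundary` flag), alternating
#'   trough/peak/trough.
#' @export
locate_landmarks <- function(curve, min_prominence = 0.05, smooth_ms = 25) {
  stopifnot(inherits(curve, "transfer_curve"))
  v <- .smooth_ma(curve$H, curve$rate, smooth_ms)
  n <- length(v)
  if (diff(range(v)) == 0) stop("transfer curve is constant")
  # candidate local maxima (earliest sample of a plateau)
  d <- diff(v)
  cand <- which(d[-1] <= 0 & d[-length(d)] > 0) + 1L
  rng <- diff(range(v))
  peaks <- integer(0)
  for (i in cand) {
    lmin <- min(v[seq_len(i)]); rmin <- min(v[i:n])
    if (v[i] - max(lmin, rmin) >= min_prominence * rng) peaks <- c(peaks, i)
  }
  if (length(peaks) == 0L) stop("no interior peak found")
  # drop the lesser of two peaks not separated by a real dip
  keep <- rep(TRUE, length(peaks))
  if (length(peaks) > 1L) {
    for (j in seq_len(length(peaks) - 1L)) {
      seg <- v[peaks[j]:peaks[j + 1L]]
      if (min(seg) > min(v[peaks[j]], v[peaks[j + 1L]]) - min_prominence * rng)
        keep[if (v[peaks[j]] < v[peaks[j + 1L]]) j else j + 1L] <- FALSE
    }
    peaks <- peaks[keep]
  }
  rows <- list()
  add <- function(type, idx, boundary = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, index = idx, time = (idx - 1) / curve$rate,
      value = v[idx], boundary = boundary)
  pre <- v[seq_len(peaks[1])]
  ti <- which.min(pre)
  add("trough", ti, boundary = ti == 1L)
  for (j in seq_along(peaks)) {
    add("peak", peaks[j])
    to <- if (j < length(peaks)) peaks[j + 1L] else n
    seg <- v[peaks[j]:to]
    ti <- peaks[j] + which.min(seg) - 1L
    add("trough", ti, boundary = ti == n)
  }
  curve$landmarks <- do.call(rbind, rows)
  curve
}

#' Extract a joint-action segment from a transfer curve
#'
#' Selects the activity between the minimum of the trough preceding the
#' requested peak and the subsequent trough minimum, and records the delay
#' from the trigger to the segment start.
#'
#' @param curve a transfer curve with located landmarks (see
#'   [locate_landmarks()]).
#' @param peak which peak (1-based, in time order).
#' @param joint `"hip"` or `"knee"`.
#' @param action `"flexion"` or `"extension"`.
#' @param trigger optional trigger override (e.g. `"AEA"` for knee
#'   extension retriggered at the anterior extreme angle).
#' @return An object of class `action_segment`: `values`, `rate`, `joint`,
#'   `action`, `trigger`, `onset_delay` (s) and `boundary` flags.
#' @export
extract_action_segment <- function(curve, peak = 1L,
                                   joint = c("hip", "knee"),
                                   action = c("flexion", "extension"),
                                   trigger = NULL) {
  joint <- match.arg(joint); action <- match.arg(action)
  if (is.null(curve$landmarks)) curve <- locate_landmarks(curve)
  lm <- curve$landmarks
  pk <- which(lm$type == "peak")
  if (peak > length(pk)) stop("requested peak ", peak, " not present (",
                              length(pk), " found)")
  row <- pk[peak]
  t0 <- lm$index[row - 1L]; t1 <- lm$index[row + 1L]
  structure(list(values = curve$H[t0:t1], rate = curve$rate, joint = joint,
                 action = action,
                 trigger = trigger %||% curve$trigger,
                 onset_delay = (t0 - 1) / curve$rate,
                 boundary = c(start = lm$boundary[row - 1L],
                              end = lm$boundary[row + 1L])),
            class = "action_segment")
}

#' @export
print.action_segment <- function(x, ...) {
  cat(sprintf("<action_segment> %s %s (%s-triggered): %d samples @ %g Hz, onset delay %.3f s\n",
              x$joint, x$action, x$trigger, length(x$values), x$rate,
              x$onset_delay))
  invisible(x)
}

#' Combine two knee-flexor segments
#'
#' When two muscles drive the same action (knee flexion from the biceps
#' femoris and lateral gastrocnemius, both after contralateral heel
#' contact) the two transfer-function segments are summed on the union of
#' their absolute-time supports. Commutative.
#'
#' @param a,b `action_segment`s, both knee flexion with the same trigger.
#' @return A combined `action_segment`.
#' @export
combine_knee_flexors <- function(a, b) {
  stopifnot(inherits(a, "action_segment"), inherits(b, "action_segment"))
  if (a$trigger != b$trigger) stop("mismatched triggers")
  if (a$joint != "knee" || b$joint != "knee" ||
      a$action != "flexion" || b$action != "flexion")
    stop("both segments must be knee flexion")
  if (a$rate != b$rate) stop("mismatched rates")
  rate <- a$rate
  s0 <- min(a$onset_delay, b$onset_delay)
  end_a <- a$onset_delay + (length(a$values) - 1) / rate
  end_b <- b$onset_delay + (length(b$values) - 1) / rate
  n <- round((max(end_a, end_b) - s0) * rate) + 1L
  out <- numeric(n)
  ia <- round((a$onset_delay - s0) * rate)
  ib <- round((b$onset_delay - s0) * rate)
  out[ia + seq_along(a$values)] <- out[ia + seq_along(a$values)] + a$values
  out[ib + seq_along(b$values)] <- out[ib + seq_along(b$values)] + b$values
  structure(list(values = out, rate = rate, joint = "knee",
                 action = "flexion", trigger = a$trigger, onset_delay = s0,
                 boundary = c(start = FALSE, end = FALSE)),
            class = "action_segment")
}

#' Remove the trigger-to-onset delay of a knee segment
#'
#' The sprung knee has its own mechanical latency between motor drive and
#' joint motion, playing the role of the double-support delay between heel
#' strike and contralateral toe off in human walking; the recorded
#' trigger-to-onset delay is therefore subtracted from knee transfer
#' functions so the playback starts at the trigger. Hip segments keep their
#' delay (the hip motor is direct drive).
#'
#' @param seg an `action_segment`.
#' @return The segment with `onset_delay` set to zero.
#' @export
align_knee_onset <- function(seg) {
  stopifnot(inherits(seg, "action_segment"))
  if (max(seg$values) == min(seg$values))
    stop("onset undetectable on a flat segment")
  seg$onset_delay <- 0
  seg
}

#' Derive the four joint-action segments
#'
#' Applies the muscle-to-joint mapping to a named list of transfer curves:
#' hip flexion is the first rectus femoris peak after contralateral
#' contact; knee extension is the second rectus femoris peak, retriggered
#' at the anterior extreme angle and started at its preceding trough
#' minimum; hip extension is the biceps femoris peak after ipsilateral
#' contact; knee flexion is the sum of the biceps femoris and lateral
#' gastrocnemius segments after contralateral contact, with the
#' trigger-to-onset delay removed. The tibialis anterior acts only on the
#' ankle and is excluded.
#'
#' Peak roles on the rectus femoris curve are disambiguated by position:
#' the hip-flexion peak lies in the first half of the stride (swing), the
#' knee-extension peak near or after mid-stride.
#'
#' @param curves named list of transfer curves with elements `RF_CH`,
#'   `BF_IH`, `BF_CH`, `LG_CH`.
#' @return Named list of `action_segment`s: `hip_flexion`,
#'   `hip_extension`, `knee_flexion`, `knee_extension`.
#' @export
derive_joint_segments <- function(curves) {
  need <- c("RF_CH", "BF_IH", "BF_CH", "LG_CH")
  if (!all(need %in% names(curves)))
    stop("curves must contain ", paste(need, collapse = ", "))
  rf <- locate_landmarks(curves$RF_CH)
  lm <- rf$landmarks
  pk <- which(lm$type == "peak")
  stride_s <- length(rf$H) / rf$rate
  hip_pk <- which(lm$time[pk] < 0.5 * stride_s)
  knee_pk <- which(lm$time[pk] >= 0.35 * stride_s)
  if (length(hip_pk) == 0L || length(knee_pk) == 0L)
    stop("could not disambiguate the two rectus femoris peaks")
  hip_pk <- hip_pk[1]
  knee_pk <- setdiff(knee_pk, hip_pk)
  if (length(knee_pk) == 0L)
    stop("could not disambiguate the two rectus femoris peaks")
  knee_pk <- knee_pk[1]
  hf <- extract_action_segment(rf, hip_pk, "hip", "flexion")
  ke <- extract_action_segment(rf, knee_pk, "knee", "extension",
                               trigger = "AEA")
  ke <- align_knee_onset(ke)
  he <- extract_action_segment(locate_landmarks(curves$BF_IH), 1L,
                               "hip", "extension")
  kf_bf <- extract_action_segment(locate_landmarks(curves$BF_CH), 1L,
                                  "knee", "flexion")
  kf_lg <- extract_action_segment(locate_landmarks(curves$LG_CH), 1L,
                                  "knee", "flexion")
  kf <- align_knee_onset(combine_knee_flexors(kf_bf, kf_lg))
  list(hip_flexion = hf, hip_extension = he, knee_flexion = kf,
       knee_extension = ke)
}
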