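#' Gait events
#'
#' Per-foot heel-strike times. [segment_strides()] completes the object with
#' stride intervals of the reference foot, their mean duration and count.
#'
#' @param left,right strictly increasing heel-strike times (s) per foot.
#' @param ref reference foot for stride segmentation.
#' @param speed_steps optional data frame (`time`, `speed`) of belt-speed
#'   setting onsets (attached by the synthetic generator).
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(left = numeric(0), right = numeric(0),
                        ref = "left", speed_steps = NULL) {
  for (v in list(left, right))
    if (length(v) > 1L && any(diff(v) <= 0))
      stop("heel-strike times must be strictly increasing per foot")
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 ref = match.arg(ref, c("left", "right")),
                 speed_steps = speed_steps,
                 strides = NULL, mean_stride = NULL, n = NULL),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d left / %d right heel strikes",
              length(x$left), length(x$right)))
  if (!is.null(x$n))
    cat(sprintf("; %d strides (%s foot), mean %.3f s", x$n, x$ref,
                x$mean_stride))
  cat("\n")
  invisible(x)
}

#' EMG linear envelope
#'
#' Conditions a raw EMG channel to its linear envelope: DC-offset removal,
#' linear-phase FIR
#' band-pass 20-500 Hz (windowed-sinc, Hamming, order ~ 4 x rate / 20 Hz,
#' group delay compensated), full-wave rectification, then a zero-lag
#' fourth-order Butterworth low-pass at 6 Hz applied forward and backward.
#' Small negative excursions left by the low-pass are clipped to zero.
#' At a 1 kHz rate the 500 Hz edge coincides with Nyquist, so the upper
#' edge is capped at 0.98 x Nyquist.
#'
#' @param x raw EMG samples.
#' @param rate sampling rate in Hz; at least 1000 (Nyquist for the 500 Hz
#'   band edge).
#' @param muscle optional muscle label carried along.
#' @return An object of class `envelope_signal` with non-negative `values`,
#'   `rate` and `muscle`.
#' @export
condition_emg <- function(x, rate, muscle = NA_character_) {
  x <- as.numeric(x)
  if (rate < 1000)
    stop("sampling rate below Nyquist for the 500 Hz band edge")
  ord <- 2L * round(2 * rate / 20)  # even order, ~4 x (rate / lower edge)
  if (length(x) <= ord)
    stop("signal shorter than the band-pass filter warm-up")
  ny <- rate / 2
  band <- c(20, min(500, 0.98 * ny)) / ny
  b <- signal::fir1(ord, band, type = "pass")
  x <- x - mean(x)  # remove DC offset ahead of the band-pass
  # causal FIR then shift by the (ord/2)-sample group delay
  xf <- as.numeric(stats::filter(c(x, numeric(ord / 2)), b, sides = 1))
  xf <- xf[(ord / 2 + 1):(ord / 2 + length(x))]
  xf[is.na(xf)] <- 0
  bw <- signal::butter(4, 6 / ny, type = "low")
  env <- as.numeric(signal::filtfilt(bw, abs(xf)))
  env[env < 0] <- 0
  structure(list(values = env, rate = rate, muscle = muscle),
            class = "envelope_signal")
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("<envelope_signal> %s: %d samples @ %g Hz, peak %.3g\n",
              ifelse(is.na(x$muscle), "?", x$muscle), length(x$values),
              x$rate, max(x$values)))
  invisible(x)
}

#' Detect heel strikes on an FSR channel
#'
#' Finds rising crossings of `threshold_frac` times the channel maximum,
#' merges crossings closer than the debounce window, and then backtracks
#' from each crossing to the loading-curve onset (the last sample at or
#' below 1e-6 of the channel maximum, walking back at most one debounce
#' window), so that the reported event time is
#' the start of loading rather than the threshold crossing. Detection is
#' invariant to positive rescaling of the channel. An all-zero channel
#' yields no events.
#'
#' @param x FSR channel samples.
#' @param rate sampling rate in Hz.
#' @param threshold_frac crossing threshold as a fraction of the channel
#'   maximum.
#' @param debounce minimum event separation in seconds.
#' @return Numeric vector of event times in seconds (0-based: sample 1 is
#'   time 0).
#' @export
detect_heel_strikes <- function(x, rate, threshold_frac = 0.1,
                                debounce = 0.2) {
  x <- as.numeric(x)
  mx <- max(x)
  if (mx <= 0) return(numeric(0))
  thr <- threshold_frac * mx
  up <- which(x[-1] >= thr & x[-length(x)] < thr) + 1L
  if (length(up) == 0L) return(numeric(0))
  # debounce relative to the last *kept* event
  last <- up[1]; sel <- up[1]
  for (i in up[-1]) {
    if ((i - last) / rate >= debounce) {
      sel <- c(sel, i)
      last <- i
    }
  }
  eps <- 1e-6 * mx
  cap <- max(1L, round(debounce * rate))  # never walk back past one debounce
  onsets <- vapply(sel, function(i) {
    j <- i
    while (j > 1L && x[j - 1L] > eps && i - j < cap) j <- j - 1L
    max(j - 2L, 0L)  # 0-based index of the last at-or-below-eps sample
  }, numeric(1))
  onsets / rate
}

#' Segment strides
#'
#' A stride runs from one heel strike of the reference foot to the next
#' strike of the same foot. Requires at least two strikes on the reference
#' foot; reports per-stride intervals and their mean.
#'
#' @param events a [gait_events()] object.
#' @return The same object completed with `strides` (data frame `start`,
#'   `end`, `duration`), `mean_stride` (s) and `n`.
#' @export
segment_strides <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  ref <- if (events$ref == "left") events$left else events$right
  if (length(ref) < 2L)
    stop("need at least 2 heel strikes on the reference foot")
  events$strides <- data.frame(start = head(ref, -1), end = ref[-1],
                               duration = diff(ref))
  if (any(events$strides$duration <= 0)) stop("non-positive stride duration")
  events$mean_stride <- mean(events$strides$duration)
  events$n <- nrow(events$strides)
  events
}

#' Event-related average
#'
#' Averages a signal in lag windows of one stride duration before and after
#' each reference-foot heel strike. Events whose window extends beyond the
#' recording are dropped and counted.
#'
#' @param signal an [condition_emg()] envelope (or any list with `values`
#'   and `rate`).
#' @param events a completed [gait_events()] object (see
#'   [segment_strides()]).
#' @param window_s half-window length in s; defaults to the mean stride.
#' @return An object of class `era_curve`: `lag` (s, symmetric about 0),
#'   `value` (mean over events), `n_events` used and `n_dropped`.
#' @export
event_related_average <- function(signal, events, window_s = NULL) {
  ev <- segment_if_needed(events)
  if (is.null(window_s)) window_s <- ev$mean_stride
  rate <- signal$rate
  v <- signal$values
  half <- round(window_s * rate)
  ref <- if (ev$ref == "left") ev$left else ev$right
  centers <- round(ref * rate) + 1L
  ok <- centers - half >= 1L & centers + half <= length(v)
  if (!any(ok)) stop("no event window fits inside the recording")
  stack <- vapply(centers[ok],
                  function(c0) v[(c0 - half):(c0 + half)],
                  numeric(2L * half + 1L))
  structure(list(lag = (-half:half) / rate,
                 value = rowMeans(stack),
                 n_events = sum(ok), n_dropped = sum(!ok)),
            class = "era_curve")
}

segment_if_needed <- function(events) {
  if (is.null(events$mean_stride)) segment_strides(events) else events
}

#' @export
print.era_curve <- function(x, ...) {
  cat(sprintf("<era_curve> lag %.2f..%.2f s, %d events (%d dropped)\n",
              min(x$lag), max(x$lag), x$n_events, x$n_dropped))
  invisible(x)
}

#' Mean heel-contact template
#'
#' Cuts the heel FSR channel into per-stride segments (reference-foot
#' strike to next strike), resamples each to the mean stride length by
#' linear interpolation and averages across the N strides. The result is
#' the typical one-stride heel loading curve used to convert identified
#' impulse responses into contact-triggered transfer curves.
#'
#' @param x heel FSR channel samples.
#' @param rate sampling rate in Hz.
#' @param events a completed [gait_events()] object.
#' @return Numeric template of length `round(mean_stride * rate)`.
#' @export
mean_heel_template <- function(x, rate, events) {
  ev <- segment_if_needed(events)
  if (ev$n < 1L) stop("need at least one complete stride")
  len <- round(ev$mean_stride * rate)
  grid <- seq(0, 1, length.out = len)
  segs <- vapply(seq_len(ev$n), function(i) {
    i0 <- round(ev$strides$start[i] * rate) + 1L
    i1 <- round(ev$strides$end[i] * rate)
    i1 <- min(i1, length(x))
    if (i1 - i0 < 2L) return(rep(NA_real_, len))
    seg <- x[i0:i1]
    approx(seq(0, 1, length.out = length(seg)), seg, xout = grid)$y
  }, numeric(len))
  segs <- segs[, colSums(is.na(segs)) == 0L, drop = FALSE]
  if (ncol(segs) == 0L) stop("no usable strides inside the recording")
  rowMeans(segs)
}
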