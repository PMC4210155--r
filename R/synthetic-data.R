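#' Synthetic treadmill configuration
#'
#' Bundles the parameters of the synthetic gait-recording generator: sampling
#' rate, the cadence model mapping belt speed to stride duration, the EMG
#' carrier band, envelope signal-to-noise ratio, the speed-related amplitude
#' gain, stride-timing jitter and the random seed. A fixed seed yields
#' byte-identical output.
#'
#' The cadence model is `stride_s(v) = cadence_c0 / v`, clipped to
#' `[0.8, 1.6]` s. The EMG carrier is Gaussian noise band-passed to
#' `carrier_band` and scaled so that its linear envelope (rectified and
#' smoothed) is unity, which makes the conditioned envelope of the generated
#' EMG approximate the modulating envelope directly. The speed gain scales
#' envelope amplitude linearly with belt speed around 1.25 m/s.
#'
#' @param rate sampling rate in Hz; must exceed twice the carrier band's
#'   upper edge.
#' @param carrier_band two-element numeric, EMG carrier band in Hz.
#' @param snr envelope signal-to-noise ratio; the additive envelope noise
#'   floor is `max(envelope) / snr`.
#' @param speed_gain linear speed-gain coefficient (relative amplitude per
#'   m/s around the 1.25 m/s reference).
#' @param cadence_c0 cadence constant (m): stride duration is
#'   `cadence_c0 / speed`, clipped to `[0.8, 1.6]` s.
#' @param stride_jitter coefficient of variation of stride duration.
#' @param seed integer seed controlling all stochastic draws.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(rate = 1000, carrier_band = c(20, 450), snr = 20,
                         speed_gain = 0.8, cadence_c0 = 1.4,
                         stride_jitter = 0.03, seed = 1L) {
  stopifnot(length(carrier_band) == 2L, carrier_band[1] > 0,
            carrier_band[2] > carrier_band[1])
  if (rate <= 2 * carrier_band[2])
    stop("sampling rate must exceed twice the carrier band upper edge")
  if (snr <= 0) stop("'snr' must be positive")
  if (stride_jitter < 0 || stride_jitter > 0.2)
    stop("'stride_jitter' must be in [0, 0.2]")
  structure(list(rate = rate, carrier_band = carrier_band, snr = snr,
                 speed_gain = speed_gain, cadence_c0 = cadence_c0,
                 stride_jitter = stride_jitter, seed = as.integer(seed)),
            class = "synth_config")
}

#' Stride duration from belt speed
#'
#' Cadence model of the synthetic generator: `cadence_c0 / speed`, clipped
#' to `[0.8, 1.6]` s.
#'
#' @param speed belt speed(s) in m/s.
#' @param config a [synth_config()].
#' @return Stride duration(s) in seconds.
#' @export
stride_duration <- function(speed, config = synth_config()) {
  if (any(speed <= 0)) stop("belt speed must be positive")
  pmin(pmax(config$cadence_c0 / speed, 0.8), 1.6)
}

#' Pseudo-random treadmill speed sequence
#'
#' Generates a pseudo-random walk over belt speeds in which every change
#' between consecutive settings has magnitude between 0.05 and 0.1 m/s
#' (small increments that do not make the walker stumble), the requested
#' speed range is swept, and the whole sequence is tiled `repeats` times.
#' The walk ascends and descends between the range bounds with random step
#' sizes, and its tail is adjusted so that the wrap from the last setting of
#' one repeat to the first setting of the next is itself a legal increment.
#'
#' @param n_settings number of distinct speed settings per repeat (>= 1).
#' @param speed_range two-element numeric, min and max belt speed in m/s;
#'   must lie within `[0.5, 2.5]` and span at least one increment
#'   (0.05 m/s) unless `n_settings == 1`.
#' @param repeats number of times the sequence is repeated.
#' @param steps_per_setting gait steps held at each setting; together with
#'   the cadence model this fixes each setting's hold duration.
#' @param config a [synth_config()] (cadence model and seed).
#' @return An object of class `speed_profile` with a `settings` data frame
#'   (`speed` m/s, `hold_s` s), the realized `total_range`, and
#'   `steps_per_setting`.
#' @export
generate_speed_sequence <- function(n_settings = 20,
                                    speed_range = c(1.0, 1.5),
                                    repeats = 2, steps_per_setting = 25,
                                    config = synth_config()) {
  stopifnot(n_settings >= 1, repeats >= 1, length(speed_range) == 2L)
  vmin <- speed_range[1]; vmax <- speed_range[2]
  if (vmin < 0.5 || vmax > 2.5 || vmin >= vmax && n_settings > 1)
    stop("speed range must be within [0.5, 2.5] m/s with min < max")
  width <- vmax - vmin
  if (n_settings > 1 && width < 0.05)
    stop("speed range narrower than one increment (0.05 m/s)")
  set.seed(config$seed)
  if (n_settings == 1L) {
    speeds <- vmin
  } else {
    speeds <- numeric(n_settings)
    speeds[1] <- vmin
    dir <- 1
    for (i in 2:n_settings) {
      step <- runif(1, 0.05, 0.1)
      nxt <- speeds[i - 1] + dir * step
      if (nxt > vmax || nxt < vmin) {
        dir <- -dir
        nxt <- speeds[i - 1] + dir * step
        nxt <- min(max(nxt, vmin), vmax)
      }
      speeds[i] <- nxt
    }
    if (n_settings >= 4L)
      speeds <- .repair_cycle(speeds, vmin, vmax)
  }
  speeds <- rep(speeds, repeats)
  hold <- steps_per_setting * stride_duration(speeds, config)
  structure(list(settings = data.frame(speed = speeds, hold_s = hold),
                 total_range = max(speeds) - min(speeds),
                 steps_per_setting = steps_per_setting),
            class = "speed_profile")
}

# Rewrite the last three settings so that the jump from the final setting
# back to the first (when the sequence repeats) is a legal 0.05-0.1 m/s
# increment. Three mixed-sign steps of magnitude 0.05-0.1 can realize any
# net displacement up to 0.3 m/s.
.repair_cycle <- function(speeds, vmin, vmax) {
  n <- length(speeds)
  target <- min(speeds[1] + 0.075, vmax)  # final setting: one step from start
  anchor <- speeds[n - 3]
  gap <- target - anchor                  # net displacement over 3 steps
  g <- abs(gap); s <- if (gap >= 0) 1 else -1
  g <- min(g, 0.3)  # three steps can bridge at most 0.3 m/s
  steps <- if (g >= 0.15) {
    rep(s * g / 3, 3)
  } else if (g >= 0.1) {
    c(0.1 * s, -(0.2 - g) * s, 0.1 * s)
  } else {
    x <- (g + 0.1) / 2
    c(x * s, -0.1 * s, x * s)
  }
  # order the steps to stay inside [vmin, vmax]
  path <- anchor + cumsum(steps)
  if (any(path < vmin - 1e-9 | path > vmax + 1e-9)) {
    for (p in list(steps[c(2, 1, 3)], steps[c(1, 3, 2)], steps[c(3, 2, 1)],
                   steps[c(2, 3, 1)], steps[c(3, 1, 2)])) {
      path2 <- anchor + cumsum(p)
      if (all(path2 >= vmin - 1e-9 & path2 <= vmax + 1e-9)) {
        path <- path2
        break
      }
    }
  }
  speeds[(n - 2):n] <- pmin(pmax(path, vmin), vmax)
  speeds
}

#' @export
print.speed_profile <- function(x, ...) {
  cat(sprintf("<speed_profile> %d settings, %.2f-%.2f m/s (range %.2f), %g steps/setting\n",
              nrow(x$settings), min(x$settings$speed), max(x$settings$speed),
              x$total_range, x$steps_per_setting))
  invisible(x)
}

#' Heel-strike event schedule from a speed profile
#'
#' Walks through the speed profile and lays down alternating left/right
#' heel strikes. The reference (left) foot strikes at intervals given by the
#' cadence model with multiplicative stride-time jitter; the contralateral
#' (right) foot strikes near mid-stride (phase 0.5). The per-setting stride
#' count is the setting's hold duration times the cadence.
#'
#' @param profile a [generate_speed_sequence()] result.
#' @param config a [synth_config()].
#' @return An object of class `gait_events`: per-foot strike times (s), the
#'   belt-speed step function (`speed_steps`), and, via
#'   [segment_strides()], stride intervals.
#' @export
generate_gait_events <- function(profile, config = synth_config()) {
  stopifnot(inherits(profile, "speed_profile"))
  dur <- stride_duration(profile$settings$speed, config)
  if (any(!is.finite(dur)) || any(dur <= 0))
    stop("cadence model produced non-positive stride duration")
  set.seed(config$seed + 1L)
  left <- numeric(0); right <- numeric(0)
  onset <- cumsum(c(0, head(profile$settings$hold_s, -1)))
  t <- 0.5  # lead-in before the first strike
  for (i in seq_len(nrow(profile$settings))) {
    t_end <- onset[i] + profile$settings$hold_s[i]
    while (t < t_end) {
      s <- dur[i] * (1 + config$stride_jitter * max(min(rnorm(1), 3), -3))
      left <- c(left, t)
      right <- c(right, t + s * (0.5 + 0.02 * max(min(rnorm(1), 3), -3)))
      t <- t + s
    }
  }
  events <- gait_events(left = left, right = right,
                        speed_steps = data.frame(time = onset,
                                                 speed = profile$settings$speed))
  segment_strides(events)
}

#' Belt speed at given times
#'
#' Piecewise-constant belt speed from the setting onsets stored in a
#' `gait_events` object.
#'
#' @param events a `gait_events` object carrying `speed_steps`.
#' @param times numeric vector of times (s).
#' @return Speeds in m/s (constant 1.25 when no profile is attached).
#' @export
speed_at <- function(events, times) {
  st <- events$speed_steps
  if (is.null(st)) return(rep(1.25, length(times)))
  idx <- findInterval(times, st$time)
  idx[idx < 1L] <- 1L
  st$speed[idx]
}

# Raised-cosine stance loading pulse: zero at the strike sample, unimodal,
# back to zero at 60% of the local stride.
.stance_pulse <- function(n) {
  u <- seq(0, 1, length.out = n)
  sin(pi * u)^2
}

#' Synthetic FSR foot-contact channels
#'
#' Emits the eight FSR channels. Heel channels carry a smooth, unimodal,
#' normalized (0-1) raised-cosine loading pulse per stance, with onset at
#' the heel-strike sample and release at 60% of the local stride; the
#' remaining sites (first/fifth metatarsal, toe) are plausible filler pulses
#' shifted later into stance. Channels are zero throughout swing.
#'
#' @param events a `gait_events` object.
#' @param config a [synth_config()].
#' @param duration total record duration in s; default covers all events
#'   plus one mean stride.
#' @return A [gait_recording()] with channels `FSR_{L,R}_{heel,mt1,mt5,toe}`.
#' @export
generate_fsr_signals <- function(events, config = synth_config(),
                                 duration = NULL) {
  stopifnot(inherits(events, "gait_events"))
  rate <- config$rate
  all_t <- c(events$left, events$right)
  if (length(all_t) == 0L) {
    if (is.null(duration)) duration <- 1
    n <- round(duration * rate)
    return(gait_recording(matrix(0, n, 8), rate = rate,
                          channels = .fsr_labels()))
  }
  mean_stride <- if (!is.null(events$mean_stride)) events$mean_stride
                 else mean(diff(sort(events$left)))
  if (is.null(duration)) duration <- max(all_t) + mean_stride
  n <- round(duration * rate)
  sig <- matrix(0, n, 8)
  colnames(sig) <- .fsr_labels()
  for (side in c("L", "R")) {
    times <- if (side == "L") events$left else events$right
    if (length(times) == 0L) next
    strides <- c(diff(times), mean_stride)
    if (any(strides <= 0)) stop("overlapping stances on one foot")
    for (j in seq_along(times)) {
      i0 <- round(times[j] * rate) + 1L
      len <- round(0.6 * strides[j] * rate)
      idx <- i0:min(i0 + len - 1L, n)
      if (length(idx) < 2L || idx[1] > n) next
      pulse <- .stance_pulse(len)[seq_along(idx)]
      sig[idx, paste0("FSR_", side, "_heel")] <-
        sig[idx, paste0("FSR_", side, "_heel")] + pulse
      # filler sites: forefoot loads later in stance
      for (site in c("mt1", "mt5", "toe")) {
        lag <- switch(site, mt1 = 0.15, mt5 = 0.18, toe = 0.25)
        i1 <- i0 + round(lag * strides[j] * rate)
        idx2 <- i1:min(i1 + len - 1L, n)
        if (length(idx2) < 2L || idx2[1] > n) next
        sig[idx2, paste0("FSR_", side, "_", site)] <-
          sig[idx2, paste0("FSR_", side, "_", site)] +
          0.8 * .stance_pulse(len)[seq_along(idx2)]
      }
    }
  }
  gait_recording(sig, rate = rate, channels = colnames(sig))
}

.fsr_labels <- function()
  paste0("FSR_", rep(c("L", "R"), each = 4), "_",
         rep(c("heel", "mt1", "mt5", "toe"), 2))

#' Ground-truth muscle kernel
#'
#' The true impulse response from a heel-contact channel to a muscle's EMG
#' envelope, used by the generator and recovered by the identification
#' stage. Coefficients are sampled at the recording rate and span at most
#' one nominal stride.
#'
#' @param muscle one of `"TA"`, `"LG"`, `"RF"`, `"BF"`.
#' @param foot triggering heel: `"CH"` (contralateral) or `"IH"`
#'   (ipsilateral).
#' @param coefficients numeric kernel at the recording rate.
#' @param rate sampling rate in Hz.
#' @return An object of class `gt_kernel`.
#' @export
gt_kernel <- function(muscle, foot, coefficients, rate) {
  muscle <- match.arg(muscle, c("TA", "LG", "RF", "BF"))
  foot <- match.arg(foot, c("CH", "IH"))
  coefficients <- as.numeric(coefficients)
  if (!all(is.finite(coefficients))) stop("kernel coefficients must be finite")
  structure(list(muscle = muscle, foot = foot,
                 coefficients = coefficients, rate = rate),
            class = "gt_kernel")
}

#' @export
print.gt_kernel <- function(x, ...) {
  cat(sprintf("<gt_kernel> %s/%s, %d taps @ %g Hz (%.2f s)\n", x$muscle,
              x$foot, length(x$coefficients), x$rate,
              length(x$coefficients) / x$rate))
  invisible(x)
}

# smooth positive bump used to compose ground-truth kernels
.bump <- function(t, center, width, amp) {
  amp * exp(-0.5 * ((t - center) / width)^2)
}

#' Default ground-truth kernels
#'
#' Smooth single- or double-bump kernels, one stride long, emulating the
#' characteristic structure of the thigh and shank muscles used downstream:
#' RF after contralateral contact shows an early bump (hip flexion) and a
#' second bump near mid-stride (knee extension at terminal swing); BF after
#' ipsilateral contact shows an early stance bump (hip extension); BF and
#' LG after contralateral contact show swing-phase bumps (knee flexion).
#' The two RF bumps are half a stride apart so that, after convolution
#' with the 60%-stride heel loading pulse, the transfer curve still shows
#' the two separate peaks on which the joint-action mapping relies; closer
#' spacing is smeared into a single peak by that convolution.
#'
#' @param config a [synth_config()].
#' @param stride_s nominal stride duration in s.
#' @return Named list of [gt_kernel()] objects
#'   (`RF_CH`, `BF_IH`, `BF_CH`, `LG_CH`).
#' @export
default_kernels <- function(config = synth_config(), stride_s = 1.12) {
  rate <- config$rate
  t <- seq(0, stride_s, by = 1 / rate)
  list(
    RF_CH = gt_kernel("RF", "CH",
                      .bump(t, 0.05 * stride_s, 0.04 * stride_s, 1.0) +
                      .bump(t, 0.55 * stride_s, 0.05 * stride_s, 0.8), rate),
    BF_IH = gt_kernel("BF", "IH",
                      .bump(t, 0.12 * stride_s, 0.06 * stride_s, 1.0), rate),
    BF_CH = gt_kernel("BF", "CH",
                      .bump(t, 0.40 * stride_s, 0.06 * stride_s, 0.7), rate),
    LG_CH = gt_kernel("LG", "CH",
                      .bump(t, 0.25 * stride_s, 0.07 * stride_s, 0.9), rate)
  )
}

# band-limited Gaussian carrier normalized to unit linear envelope
.emg_carrier <- function(n, config) {
  w <- rnorm(n)
  ny <- config$rate / 2
  b <- signal::fir1(200, config$carrier_band / ny, type = "pass")
  x <- as.numeric(stats::filter(c(w, numeric(100)), b, sides = 1))[101:(100 + n)]
  x[is.na(x)] <- 0
  # E|X| = sigma * sqrt(2/pi) for Gaussian X; rescale so the rectified
  # mean (the linear envelope of the carrier) is 1
  x / (sd(x) * sqrt(2 / pi))
}

#' Synthetic surface EMG channels
#'
#' EMG for each kernel's muscle is band-limited carrier noise amplitude
#' modulated by the convolution of the triggering heel channel with the
#' ground-truth kernel, scaled by a linear speed gain, plus an additive
#' envelope noise floor of `max(envelope)/snr`. Both legs receive the same
#' kernels (left/right symmetric); unmodelled muscles get carrier at the
#' noise floor. The conditioned linear envelope of the output approximates
#' the modulating envelope.
#'
#' @param events a `gait_events` object.
#' @param kernels list of [gt_kernel()] objects (one per muscle/foot
#'   pairing), e.g. [default_kernels()].
#' @param config a [synth_config()].
#' @param fsr optional precomputed FSR recording from
#'   [generate_fsr_signals()]; generated if omitted.
#' @return A [gait_recording()] with the eight EMG channels.
#' @export
generate_emg <- function(events, kernels = default_kernels(config),
                         config = synth_config(), fsr = NULL) {
  stopifnot(inherits(events, "gait_events"))
  rate <- config$rate
  if (is.null(fsr)) fsr <- generate_fsr_signals(events, config)
  n <- nrow(fsr$samples)
  mean_stride <- events$mean_stride %||% 1.12
  labels <- paste0("EMG_", rep(c("L", "R"), each = 4), "_",
                   rep(c("TA", "LG", "RF", "BF"), 2))
  env <- matrix(0, n, 8, dimnames = list(NULL, labels))
  for (k in kernels) {
    if (length(k$coefficients) / k$rate > 2 * mean_stride)
      stop("kernel longer than two strides")
    for (leg in c("L", "R")) {
      heel_side <- if (k$foot == "IH") leg else setdiff(c("L", "R"), leg)
      x <- rec_channel(fsr, paste0("FSR_", heel_side, "_heel"))
      m <- fir_predict(k$coefficients, x)
      env[, paste0("EMG_", leg, "_", k$muscle)] <-
        env[, paste0("EMG_", leg, "_", k$muscle)] + m
    }
  }
  tvec <- (seq_len(n) - 1) / rate
  gain <- pmax(1 + config$speed_gain * (speed_at(events, tvec) - 1.25), 0.1)
  env <- env * gain
  floor_amp <- if (max(env) > 0) max(env) / config$snr else 1 / config$snr
  set.seed(config$seed + 2L)
  emg <- matrix(0, n, 8, dimnames = list(NULL, labels))
  for (j in seq_len(8L))
    emg[, j] <- .emg_carrier(n, config) * (env[, j] + floor_amp)
  gait_recording(emg, rate = rate, channels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic dataset to disk
#'
#' Writes the 16-channel recording (EMG then FSR columns, in the documented
#' order), a heel-strike event table, and a ground-truth sidecar (key/value
#' header plus a kernel coefficient table) as plain ASCII. Re-reading
#' reproduces the data to at least 1e-9 relative precision, and a fixed seed
#' yields byte-identical files.
#'
#' @param emg EMG [gait_recording()] (8 channels).
#' @param fsr FSR [gait_recording()] (8 channels).
#' @param events a `gait_events` object.
#' @param kernels list of [gt_kernel()] used to generate the data.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_fixture <- function(emg, fsr, events, kernels, dir) {
  stopifnot(inherits(emg, "gait_recording"), inherits(fsr, "gait_recording"))
  if (emg$rate != fsr$rate || nrow(emg$samples) != nrow(fsr$samples))
    stop("EMG and FSR recordings must share rate and length")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- gait_recording(cbind(emg$samples, fsr$samples), rate = emg$rate,
                        channels = c(emg$channels, fsr$channels))
  paths <- c(recording = file.path(dir, "recording.csv"),
             events = file.path(dir, "events.csv"),
             truth = file.path(dir, "truth.txt"))
  write_recording(rec, paths["recording"])
  ev <- rbind(data.frame(foot = "left", time_s = events$left),
              data.frame(foot = "right", time_s = events$right))
  ev <- ev[order(ev$time_s), ]
  con <- file(paths["events"], "wb")
  writeLines(c("foot,time_s",
               sprintf("%s,%s", ev$foot, .format_num(ev$time_s))), con)
  close(con)
  con <- file(paths["truth"], "wb")
  writeLines(sprintf("rate_hz=%s", .format_num(emg$rate)), con)
  for (nm in names(kernels)) {
    k <- kernels[[nm]]
    writeLines(sprintf("kernel %s muscle=%s foot=%s taps=%d", nm, k$muscle,
                       k$foot, length(k$coefficients)), con)
    writeLines(paste(.format_num(k$coefficients), collapse = ","), con)
  }
  close(con)
  invisible(paths)
}
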