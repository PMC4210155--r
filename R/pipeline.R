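#' Decimate a low-bandwidth signal
#'
#' Plain subsampling by an integer factor. Intended for the identification
#' stage inputs -- linear envelopes (6 Hz bandwidth) and FSR loading curves
#' (a few Hz) -- whose content sits far below the decimated Nyquist, so no
#' anti-alias filter is needed; refuse factors that would put the target
#' rate below 100 Hz where that assumption starts to bite.
#'
#' @param x numeric signal or `envelope_signal`.
#' @param rate sampling rate in Hz (taken from an `envelope_signal`).
#' @param factor integer decimation factor.
#' @return A list with `values` and the new `rate`.
#' @export
decimate_signal <- function(x, rate = NULL, factor = 4L) {
  if (inherits(x, "envelope_signal")) {
    rate <- x$rate
    x <- x$values
  }
  if (is.null(rate)) stop("'rate' required for numeric input")
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (rate / factor < 100)
    stop("decimated rate below 100 Hz; use a smaller factor")
  list(values = as.numeric(x)[seq(1L, length(x), by = factor)],
       rate = rate / factor)
}

# the four muscle/trigger pairings identified per subject; for the left
# leg, CH (contralateral heel) is the right foot and IH the left
.pipeline_pairings <- function() {
  data.frame(name = c("RF_CH", "BF_IH", "BF_CH", "LG_CH"),
             muscle = c("RF", "BF", "BF", "LG"),
             trigger = c("CH", "IH", "CH", "CH"),
             heel = c("FSR_R_heel", "FSR_L_heel",
                      "FSR_R_heel", "FSR_R_heel"),
             emg = c("EMG_L_RF", "EMG_L_BF", "EMG_L_BF", "EMG_L_LG"))
}

#' Analyze one subject recording
#'
#' The per-subject leg of the pipeline: detects heel strikes on both heel
#' FSR channels, segments strides, conditions the thigh/shank EMG channels
#' to linear envelopes, decimates envelopes and heel channels to the
#' identification rate, identifies the four muscle impulse responses with
#' the LMS filter, truncates them to one stride with the half-Hanning
#' taper, convolves with the mean heel template, derives the four
#' joint-action segments and fits the twitch model to each.
#'
#' @param recording a 16-channel [gait_recording()] (EMG + FSR).
#' @param decimate integer decimation factor before identification.
#' @param iterations LMS iterations (see [lms_identify()]).
#' @param mu LMS step size.
#' @return A list with `events`, `responses` (per pairing: `impulse`,
#'   truncated `h`, `final_mse`), `segments`, `fits` and a `params` data
#'   frame (`fn`, `A`, `tau1`, `tau2`, `T0`, `residual_rms`, `id_mse`).
#' @export
analyze_subject <- function(recording, decimate = 4L, iterations = 100,
                            mu = 0.01) {
  stopifnot(inherits(recording, "gait_recording"))
  rate <- recording$rate
  left <- detect_heel_strikes(rec_channel(recording, "FSR_L_heel"), rate)
  right <- detect_heel_strikes(rec_channel(recording, "FSR_R_heel"), rate)
  events <- segment_strides(gait_events(left = left, right = right))
  pair <- .pipeline_pairings()
  id <- list()
  curves <- list()
  templ <- list()
  for (heel in unique(pair$heel)) {
    dch <- decimate_signal(rec_channel(recording, heel), rate, decimate)
    foot_events <- if (heel == "FSR_L_heel")
      segment_strides(gait_events(left = left, right = right, ref = "left"))
    else
      segment_strides(gait_events(left = left, right = right, ref = "right"))
    templ[[heel]] <- list(
      x = dch$values, rate = dch$rate,
      template = mean_heel_template(dch$values, dch$rate, foot_events))
  }
  for (i in seq_len(nrow(pair))) {
    env <- condition_emg(rec_channel(recording, pair$emg[i]), rate,
                         muscle = pair$muscle[i])
    denv <- decimate_signal(env, factor = decimate)
    ht <- templ[[pair$heel[i]]]
    imp <- lms_identify(ht$x, denv$values, stride_s = events$mean_stride,
                        rate = ht$rate, mu = mu, iterations = iterations)
    h1 <- apply_half_hanning(imp)
    id[[pair$name[i]]] <- list(impulse = imp, h = h1,
                               final_mse = imp$final_mse)
    curves[[pair$name[i]]] <- fsr_convolve(h1, ht$template, ht$rate,
                                           trigger = pair$trigger[i])
  }
  segments <- derive_joint_segments(curves)
  fits <- lapply(segments, fit_curve)
  params <- do.call(rbind, lapply(names(fits), function(fn) {
    p <- fits[[fn]]$params
    src <- switch(fn, hip_flexion = "RF_CH", knee_extension = "RF_CH",
                  hip_extension = "BF_IH", knee_flexion = "BF_CH")
    data.frame(fn = fn, A = p$A, tau1 = p$tau1, tau2 = p$tau2, T0 = p$T0,
               residual_rms = fits[[fn]]$residual_rms,
               id_mse = id[[src]]$final_mse)
  }))
  list(events = events, responses = id, curves = curves,
       segments = segments, fits = fits, params = params)
}

#' Aggregate fitted parameters across subjects
#'
#' Pools the per-subject twitch parameters of each joint-action function
#' under one of four policies: the mean over all subjects (`"mean-all"`),
#' means within each level of a subject tag such as sex (`"by-tag"`), the
#' untouched per-subject values (`"per-subject"`), or, per function, the
#' subject whose identification reached the lowest final mean squared
#' error (`"min-mse"`).
#'
#' @param subjects list of [analyze_subject()] results.
#' @param policy aggregation policy.
#' @param tags character vector of subject tags (required for `"by-tag"`).
#' @return Data frame with columns `group`, `fn`, `A`, `tau1`, `tau2`,
#'   `T0`.
#' @export
aggregate_params <- function(subjects,
                             policy = c("mean-all", "by-tag",
                                        "per-subject", "min-mse"),
                             tags = NULL) {
  policy <- match.arg(policy)
  all <- do.call(rbind, lapply(seq_along(subjects), function(s) {
    df <- subjects[[s]]$params
    df$subject <- s
    df
  }))
  mean_of <- function(df, label) {
    out <- do.call(rbind, lapply(split(df, df$fn), function(g)
      data.frame(group = label, fn = g$fn[1], A = mean(g$A),
                 tau1 = mean(g$tau1), tau2 = mean(g$tau2),
                 T0 = mean(g$T0))))
    rownames(out) <- NULL
    out
  }
  if (policy == "mean-all") return(mean_of(all, "all"))
  if (policy == "by-tag") {
    if (is.null(tags) || length(tags) != length(subjects))
      stop("'by-tag' needs one tag per subject")
    all$tag <- tags[all$subject]
    out <- do.call(rbind, lapply(split(all, all$tag),
                                 function(g) mean_of(g, g$tag[1])))
    rownames(out) <- NULL
    return(out)
  }
  if (policy == "per-subject") {
    out <- all[, c("subject", "fn", "A", "tau1", "tau2", "T0")]
    out$group <- sprintf("subject%d", out$subject)
    rownames(out) <- NULL
    return(out[, c("group", "fn", "A", "tau1", "tau2", "T0")])
  }
  # min-mse: per function, take the subject with the lowest final MSE
  out <- do.call(rbind, lapply(split(all, all$fn), function(g) {
    b <- g[which.min(g$id_mse), ]
    data.frame(group = "min-mse", fn = b$fn, A = b$A, tau1 = b$tau1,
               tau2 = b$tau2, T0 = b$T0)
  }))
  rownames(out) <- NULL
  out
}

#' Build the four motor transfer functions from an aggregate table
#'
#' @param params an [aggregate_params()] table.
#' @param group which `group` row set to use.
#' @param rate control rate in Hz.
#' @return Named list of `motor_tf` (`hip_flexion`, `hip_extension`,
#'   `knee_flexion`, `knee_extension`).
#' @export
params_to_tfs <- function(params, group = params$group[1], rate = 200) {
  p <- params[params$group == group, ]
  pick <- function(fn, joint) {
    r <- p[p$fn == fn, ]
    if (nrow(r) != 1L) stop("no unique row for '", fn, "' in group '",
                            group, "'")
    finalize_motor_tf(curve_params(r$A, r$tau1, r$tau2, r$T0), joint, rate)
  }
  list(hip_flexion = pick("hip_flexion", "hip"),
       hip_extension = pick("hip_extension", "hip"),
       knee_flexion = pick("knee_flexion", "knee"),
       knee_extension = pick("knee_extension", "knee"))
}

#' End-to-end pipeline on a synthetic cohort
#'
#' Generates a cohort of synthetic treadmill recordings with known
#' ground-truth kernels, runs every subject through conditioning,
#' LMS identification, transfer-curve building and twitch fitting
#' ([analyze_subject()]), aggregates the fitted parameters
#' ([aggregate_params()]), deploys the aggregate transfer functions on the
#' surrogate walker ([simulate_walker()]) and reports gait metrics and the
#' hip-duration stability verdict. Deterministic for a fixed seed.
#'
#' @param n_subjects cohort size.
#' @param seed master seed; subject `s` uses `seed + 100 * s`.
#' @param n_settings,steps_per_setting,repeats speed-profile size per
#'   subject (see [generate_speed_sequence()]).
#' @param policy aggregation policy (see [aggregate_params()]).
#' @param decimate,iterations identification settings (see
#'   [analyze_subject()]).
#' @param sim_duration walker simulation length in s.
#' @param rate generator sampling rate in Hz.
#' @return An object of class `pipeline_report`: `subjects`, `tags`
#'   (alternating male/female), `aggregate`, `tfs`, `sim`, `metrics`,
#'   `stability`, and `provenance` (seed, cohort size, package version).
#' @export
run_pipeline <- function(n_subjects = 2, seed = 1L, n_settings = 8,
                         steps_per_setting = 15, repeats = 1,
                         policy = "mean-all", decimate = 4L,
                         iterations = 100, sim_duration = 30,
                         rate = 1000) {
  stopifnot(n_subjects >= 1)
  tags <- rep(c("male", "female"), length.out = n_subjects)
  subjects <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg <- synth_config(rate = rate, seed = seed + 100L * s)
    prof <- generate_speed_sequence(n_settings = n_settings,
                                    steps_per_setting = steps_per_setting,
                                    repeats = repeats, config = cfg)
    ev <- generate_gait_events(prof, cfg)
    kern <- default_kernels(cfg, stride_s = ev$mean_stride)
    fsr <- generate_fsr_signals(ev, cfg)
    emg <- generate_emg(ev, kern, cfg, fsr = fsr)
    rec <- gait_recording(cbind(emg$samples, fsr$samples), rate = rate,
                          channels = c(emg$channels, fsr$channels))
    subjects[[s]] <- analyze_subject(rec, decimate = decimate,
                                     iterations = iterations)
    truth[[s]] <- kern
  }
  agg <- aggregate_params(subjects, policy = policy,
                          tags = if (policy == "by-tag") tags else NULL)
  tfs <- params_to_tfs(agg, group = agg$group[1])
  sim <- simulate_walker(tfs, duration = sim_duration, seed = seed)
  metrics <- if (sim$strides >= 2L) gait_metrics(sim) else NULL
  stab <- stability_heuristic(characterize(tfs$hip_flexion),
                              characterize(tfs$hip_extension))
  structure(list(subjects = subjects, tags = tags, truth = truth,
                 aggregate = agg, tfs = tfs, sim = sim, metrics = metrics,
                 stability = stab,
                 provenance = list(
                   seed = as.integer(seed), n_subjects = n_subjects,
                   policy = policy, rate = rate, decimate = decimate,
                   iterations = iterations,
                   package = as.character(utils::packageVersion("reflexgait")))),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subject(s), policy %s, seed %d\n",
              x$provenance$n_subjects, x$provenance$policy,
              x$provenance$seed))
  print(x$aggregate, row.names = FALSE)
  cat(sprintf("walker: %d strides%s; stability heuristic: %s (margin %.1f ms)\n",
              x$sim$strides, if (x$sim$fell) " (fell)" else "",
              if (x$stability$verdict) "stable" else "unstable",
              x$stability$margin))
  invisible(x)
}
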