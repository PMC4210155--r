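# Shared synthetic datasets, generated once per test run and memoized.

.synth_cache <- new.env(parent = emptyenv())

# A small varied-speed recording: ~24 strides, all 16 channels.
small_gait_data <- function(seed = 5, snr = 1e6) {
  key <- sprintf("small_%d_%g", seed, snr)
  if (!is.null(.synth_cache[[key]])) return(.synth_cache[[key]])
  cfg <- synth_config(seed = seed, snr = snr)
  prof <- generate_speed_sequence(n_settings = 3, steps_per_setting = 8,
                                  repeats = 1, config = cfg)
  ev <- generate_gait_events(prof, cfg)
  kern <- default_kernels(cfg, stride_s = ev$mean_stride)
  fsr <- generate_fsr_signals(ev, cfg)
  emg <- generate_emg(ev, kern, cfg, fsr = fsr)
  out <- list(cfg = cfg, prof = prof, ev = ev, kern = kern,
              fsr = fsr, emg = emg)
  .synth_cache[[key]] <- out
  out
}

# Transfer curves for the four pairings derived from a small recording,
# skipping LMS: uses the ground-truth kernels directly (decimated), so
# tf_builder tests are independent of identification quality.
small_transfer_curves <- function() {
  if (!is.null(.synth_cache$curves)) return(.synth_cache$curves)
  d <- small_gait_data()
  rate <- d$cfg$rate
  dec <- 4L
  heel <- decimate_signal(rec_channel(d$fsr, "FSR_L_heel"), rate, dec)
  ev <- segment_strides(gait_events(left = d$ev$left, right = d$ev$right))
  templ <- mean_heel_template(heel$values, heel$rate, ev)
  curves <- lapply(names(d$kern), function(nm) {
    k <- d$kern[[nm]]
    kd <- dec * k$coefficients[seq(1, length(k$coefficients), by = dec)]
    kd <- kd[seq_len(min(length(kd), round(ev$mean_stride * heel$rate)))]
    fsr_convolve(kd, templ, heel$rate, trigger = k$foot)
  })
  names(curves) <- names(d$kern)
  .synth_cache$curves <- curves
  curves
}
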