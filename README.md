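# reflexgait

Identification of heel-contact → muscle-activation transfer functions from
gait recordings, and their deployment in a purely reflexive (sensor-triggered,
CPG-free) walking controller.

The package covers the full chain:

1. **Synthetic gait recordings** with known ground-truth kernels
   (`generate_speed_sequence()`, `generate_gait_events()`,
   `generate_fsr_signals()`, `generate_emg()`): treadmill-style walking at
   stepped belt speeds, 8 EMG + 8 FSR channels, plus delimited-ASCII I/O
   (`write_recording()` / `read_recording()` / `write_fixture()`).
2. **Conditioning and segmentation**: EMG linear envelopes
   (`condition_emg()`: band-pass, rectify, 6 Hz zero-lag low-pass),
   heel-strike detection on FSR channels (`detect_heel_strikes()`), stride
   segmentation (`segment_strides()`) and event-related averaging
   (`event_related_average()`, `mean_heel_template()`).
3. **System identification**: sample-sequential (N)LMS estimation of the FIR
   impulse response from heel FSR to EMG envelope (`lms_identify()`, compiled
   inner loop), a batch Wiener least-squares oracle (`wiener_solution()`),
   and half-Hanning truncation to one stride (`apply_half_hanning()`).
4. **Transfer curves and twitch fits**: convolution with the mean heel
   template (`fsr_convolve()`), landmark location and joint-action segment
   extraction (`locate_landmarks()`, `derive_joint_segments()`), and a
   bounded Levenberg–Marquardt fit of a critically damped second-order
   muscle-twitch model (`fit_curve()`, `model_curve()`), finalized to 200 Hz
   motor transfer functions (`finalize_motor_tf()`) with ΔT50/Tpeak
   characteristics (`characterize()`) and a hip-duration stability heuristic
   (`stability_heuristic()`).
5. **Reflexive control and simulation**: an LTI, trigger-driven walking
   controller with no internal oscillator (`reflex_controller()`,
   `controller_step()`, offline equivalent `motor_drive()`), twelve shipped
   reference parameter sets (`reference_motor_tfs()`), a surrogate planar
   biped (`simulate_walker()`) with gait metrics (`gait_metrics()`) and
   limit-cycle diagnostics (`phase_portrait()`).
6. **End-to-end pipeline**: multi-subject synthesis → identification →
   aggregation (4 policies) → deployment (`run_pipeline()`,
   `analyze_subject()`, `aggregate_params()`).

## Worked example

Synthesize one subject, identify its four muscle transfer functions, and
walk the surrogate biped with the fitted parameters:

```r
library(reflexgait)

## 1. synthesize a treadmill recording (4 belt-speed settings)
cfg  <- synth_config(seed = 7)
prof <- generate_speed_sequence(n_settings = 4, steps_per_setting = 12,
                                config = cfg)
ev   <- generate_gait_events(prof, cfg)
kern <- default_kernels(cfg, stride_s = ev$mean_stride)
fsr  <- generate_fsr_signals(ev, cfg)
emg  <- generate_emg(ev, kern, cfg, fsr = fsr)
rec  <- gait_recording(cbind(emg$samples, fsr$samples), rate = cfg$rate,
                       channels = c(emg$channels, fsr$channels))
rec
#> <gait_recording> 125450 samples x 16 channels @ 1000 Hz (125.45 s)
#>   channels: EMG_L_TA, EMG_L_LG, EMG_L_RF, EMG_L_BF, EMG_R_TA, EMG_R_LG, ...

## 2. identify + fit the four joint-action transfer functions
res <- analyze_subject(rec, iterations = 60)
print(res$params, row.names = FALSE, digits = 3)
#>              fn     A tau1  tau2  T0 residual_rms id_mse
#>     hip_flexion  91.6  202 202.5 207        10.28     41
#>   hip_extension 114.3  500  81.7 234        28.22    119
#>    knee_flexion 168.9  500 500.0 379        20.77    195
#>  knee_extension  86.7  292 301.3   0         9.73     41

## 3. deploy on the surrogate walker
agg <- aggregate_params(list(res), policy = "mean-all")
tfs <- params_to_tfs(agg)
sim <- simulate_walker(tfs, duration = 30)
sim
#> <walker_sim> 30.0 s simulated, 25 strides, 11.08 m progress
gait_metrics(sim)$stride_duration_s
#> [1] 1.17
stability_heuristic(characterize(tfs$hip_flexion),
                    characterize(tfs$hip_extension))$verdict
#> [1] TRUE
```

Or run the whole cohort pipeline in one call:

```r
report <- run_pipeline(n_subjects = 2, seed = 1)
report
```

The twelve shipped reference parameter sets walk directly:

```r
sim <- simulate_walker(reference_motor_tfs("6A"))
phase_portrait(sim, knee = "knee_R")$dispersion
```

## Command line

A thin CLI wraps the same functions (installed at
`system.file("reflexgait", package = "reflexgait")`):

```sh
reflexgait generate --out fixtures/ --seed 5 --settings 3 --steps 8
reflexgait analyze  --in fixtures/recording.csv --out params.csv
reflexgait pipeline --out report.json --seed 1 --subjects 2
```

## Acceptance targets

`scripts/acceptance.R` recomputes the three deterministic curve-fit
round-trip targets against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
# t1 = 88.3068 ms, t2 = 103.8439 ms, t3 = 100.0000 ms -> acceptance.json
```

## Testing

```r
devtools::test()           # full suite incl. tests/testthat/test-acceptance.R
```

See `vignettes/reflexgait-methods.Rmd` for the modeling choices
(twitch-model normalization, identification regime, conditioning chain).
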