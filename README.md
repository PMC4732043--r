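# spama

Motion-robust heart-rate tracking from photoplethysmography (PPG) by
time-varying spectral filtering against simultaneous accelerometer
channels, with pulse-waveform reconstruction, heart-rate-variability (HRV)
analysis, an ECG-derived reference, and a seeded synthetic generator with
exact ground truth.

## The science in brief

A wearable PPG sensor sees a strong spectral peak at the cardiac
fundamental (0.5–3 Hz, i.e. 30–180 bpm). During exercise, periodic limb
motion injects artifact peaks that are often stronger than the cardiac one
and can sweep straight through the heart-rate band, so "largest peak"
estimators fail exactly when heart rate matters most. Motion is
mechanical, though: the same frequencies appear in a co-located tri-axial
accelerometer, where the cardiac component does not. The algorithm
therefore:

1. slides an 8-s window (2-s or per-sample shift) over every channel and
   computes finely gridded, ENBW-normalized periodograms;
2. takes the top-3 PPG peaks and the dominant peak per accelerometer axis
   in the heart-rate band, and **flags** PPG peaks within 0.03 Hz of an
   accelerometer frequency as motion (accelerometer peaks must clear a
   crest-factor floor — peak PSD ≥ 12× the in-band mean — so noise maxima
   never count);
3. tracks the heart rate window to window by choosing the strongest
   unflagged peak within a 10 bpm continuity clamp, holding the previous
   value when nothing is admissible and spline-filling interior held runs
   offline;
4. reconstructs a surrogate pulse waveform from the amplitude and phase of
   the PPG spectrum at the tracked frequency (one sample per window in
   per-sample mode), and derives an NN-interval series for time-domain
   (SDNN, RMSSD, pNN50) and frequency-domain (LF/HF band) HRV analysis;
5. evaluates against an ECG reference (Pan–Tompkins style QRS detection)
   with the mean absolute error E1 (bpm) and mean relative error E2 (%).

The methods vignette (`vignettes/spectral-hr-tracking.Rmd`) documents the
spectral conventions, design decisions, and known limitations (mainlobe
merging for slowly co-moving artifact tones; window averaging of fast HRV
oscillations).

## Worked example

Simulate a 3-minute recording whose heart rate ramps 80 → 140 → 110 bpm
while a motion chirp sweeps down through the whole band (2.8 → 0.6 Hz),
mirrored on the z accelerometer axis; track it; score it against ground
truth:

```r
library(spama)

tones <- list(list(start = 20, end = 160, f_start = 2.8, f_end = 0.6,
                   amp_ppg = 1.2, amp_acc = 1, axes = "z"))
cfg <- synth_config(180, 20, cbind(c(0, 60, 120, 180), c(80, 80, 140, 110)),
                    hrv_mod = list(), ma_tones = tones, seed = 22)
syn <- synth_recording(cfg)

res <- spama_hr(syn$recording, S = 2, freq_step = 0.005)
res
#> spama_result: 87 windows; sources:
#>
#>   INIT     P1     P2 SPLINE
#>      1     20     64      2

head(res$track, 4)
#>    time   hr source  freq peak_power
#> 1  7.95 80.1   INIT 1.335   2.150152
#> 2  9.95 80.1     P1 1.335   2.176098
#> 3 11.95 80.1     P1 1.335   2.148379
#> 4 13.95 79.8     P1 1.330   2.156996

truth <- true_hr_track(syn$hr_true, res$track$time, T = 8)
hr_error_report(res$track, truth)
#> E1 = 0.355 bpm, E2 = 0.344% over 87 windows (0 unmatched)

# ablation: ignore the motion flags and the tracker follows the artifact
res0 <- spama_hr(syn$recording, S = 2, freq_step = 0.005,
                 use_ma_flags = FALSE)
error_e1(res0$track, truth)
#> [1] 31.80048
```

The `source` column shows the mechanism at work: where the chirp owns the
largest peak the rate is carried by the second-ranked unflagged peak
(`P2`); flagging ON yields E1 = 0.36 bpm where flagging OFF yields
31.8 bpm.

A command-line front end is installed under
`system.file("cli", "spama-cli.R", package = "spama")` with `simulate`,
`track` and `evaluate` subcommands operating on CSV recordings and tracks.

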