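test_that("a constant 72 bpm config puts the PPG peak at 1.2 Hz", {
  cfg <- synth_config(60, 20, 72, hrv_mod = list(), seed = 1)
  syn <- synth_recording(cfg)
  fr <- band_limit(periodogram_frame(syn$recording$ppg[1:160], 20,
                                     freq_step = 0.001), 0.5, 3)
  expect_equal(fr$freqs[which.max(fr$psd)], 1.2, tolerance = 0.01)
  expect_equal(length(syn$recording$ppg), 1200)
  # instantaneous truth is exactly constant
  expect_equal(unique(syn$hr_true$hr), 72)
  # NN truth: 60/72 s beats
  expect_equal(unique(round(syn$nn_true$nn, 6)), round(60000 / 72, 6))
})

test_that("identical seeds give bit-identical recordings", {
  cfg <- synth_config(30, 20, 80, ma_tones = list(
    list(start = 5, end = 25, f_start = 2, f_end = 2.5,
         amp_ppg = 1, amp_acc = 1, axes = "x")), seed = 42)
  a <- synth_recording(cfg)
  b <- synth_recording(cfg)
  expect_identical(a$recording$ppg, b$recording$ppg)
  expect_identical(a$recording$acc_y, b$recording$acc_y)
  expect_identical(a$nn_true, b$nn_true)
  # different seed differs
  cfg2 <- synth_config(30, 20, 80, seed = 43)
  expect_false(identical(synth_recording(cfg2)$recording$ppg,
                         a$recording$ppg))
})

test_that("motion tones appear on their assigned accelerometer axes only", {
  cfg <- synth_config(60, 20, 75, hrv_mod = list(), ma_tones = list(
    list(start = 0, end = 60, f_start = 2.2, f_end = 2.2,
         amp_ppg = 1, amp_acc = 1, axes = c("x", "z"))), seed = 3)
  syn <- synth_recording(cfg)
  peak_at <- function(ch) {
    fr <- band_limit(periodogram_frame(syn$recording[[ch]][1:160], 20,
                                       freq_step = 0.005), 0.5, 3)
    fr$freqs[which.max(fr$psd)]
  }
  expect_equal(peak_at("acc_x"), 2.2, tolerance = 0.01)
  expect_equal(peak_at("acc_z"), 2.2, tolerance = 0.01)
  # y carries only noise: its in-band maximum clears no crest-factor floor
  fry <- band_limit(periodogram_frame(syn$recording$acc_y[1:160], 20,
                                      freq_step = 0.005), 0.5, 3)
  expect_lt(max(fry$psd), 12 * mean(fry$psd))
})

test_that("accelerometers carry no cardiac component", {
  cfg <- synth_config(60, 20, 72, hrv_mod = list(), noise_sd = 0.05, seed = 6)
  syn <- synth_recording(cfg)
  # energy near 1.2 Hz in acc is at the noise floor while PPG towers above it
  fr_p <- band_limit(periodogram_frame(syn$recording$ppg[1:160], 20, 0.005),
                     1.1, 1.3)
  fr_a <- band_limit(periodogram_frame(syn$recording$acc_x[1:160], 20, 0.005),
                     1.1, 1.3)
  expect_gt(max(fr_p$psd) / max(fr_a$psd), 100)
})

test_that("protocol trajectories have the documented segment boundaries", {
  tr1 <- protocol_trajectory("type1")
  expect_equal(min(tr1[, "time"]), 0)
  expect_equal(max(tr1[, "time"]), 5 * 60)
  expect_true(all(diff(tr1[, "time"]) > 0))
  expect_true(all(tr1[, "hr"] >= 30 & tr1[, "hr"] <= 180))
  # first segment is the walk level, last returns to it
  expect_equal(unname(tr1[1, "hr"]), 95)
  expect_equal(unname(tr1[nrow(tr1), "hr"]), 95)

  tr4 <- protocol_trajectory("type4")
  expect_equal(max(tr4[, "time"]), 10 * 60)
  expect_equal(unname(tr4[1, "hr"]), 70)              # starts at rest
  expect_true(160 %in% tr4[, "hr"])           # reaches the run level
  # level changes occur at the 1/2/3/5/6/8/9 minute marks
  expect_true(all(c(60, 120, 180, 300, 360, 480, 540) %in% tr4[, "time"]))

  expect_error(protocol_trajectory("type9"), "unknown protocol")

  # custom levels propagate
  tr <- protocol_trajectory("type2", levels = c(rest = 60, walk = 90,
                                                jog = 120, run = 150))
  expect_equal(unname(tr[1, "hr"]), 60)
})

test_that("out-of-band trajectories and bad gaps are rejected", {
  expect_error(synth_config(60, 20, 200), "30-180")
  expect_error(synth_config(60, 20, cbind(c(0, 60), c(70, 20))), "30-180")
  expect_error(synth_config(60, 20, 72, gaps = list(c(50, 70))),
               "outside the recording")
  expect_error(synth_config(60, 20, 72, gaps = list(c(30, 20))),
               "outside the recording")
})

test_that("a dropout gap produces HOLD windows in real-time tracking", {
  cfg <- synth_config(120, 20, cbind(c(0, 120), c(80, 110)),
                      hrv_mod = list(), gaps = list(c(60, 70)),
                      noise_sd = 0.05, seed = 5)
  syn <- synth_recording(cfg)
  res <- spama_hr(syn$recording, S = 2, freq_step = 0.005, fill_gaps = FALSE)
  inside <- res$track$time >= 68 & res$track$time <= 70  # windows fully in gap
  expect_true(all(res$track$source[inside] == "HOLD"))
  # outside the gap region tracking is accurate
  outside <- res$track$time < 60 | res$track$time > 78
  truth <- true_hr_track(syn$hr_true, res$track$time, T = 8)
  expect_lt(mean(abs(res$track$hr[outside] - truth$hr[outside])), 2)
})

test_that("ramped trajectories integrate to the correct beat count", {
  cfg <- synth_config(100, 20, cbind(c(0, 100), c(60, 120)),
                      hrv_mod = list(), noise_sd = 0, seed = 9)
  syn <- synth_recording(cfg)
  # mean HR 90 bpm over 100 s => 150 cardiac cycles; beats = floor crossings
  expect_equal(nrow(syn$nn_true) + 1, 149, tolerance = 2)
  # NN truth reciprocates instantaneous HR at beat times within 1 ms
  hr_at <- stats::approx(syn$hr_true$time, syn$hr_true$hr,
                         xout = syn$nn_true$time)$y
  expect_equal(syn$nn_true$nn, 60000 / hr_at, tolerance = 1)
})

test_that("requested ECG channel carries detectable beats", {
  cfg <- synth_config(60, 20, 72, hrv_mod = list(), fs_ecg = 250, seed = 15)
  syn <- synth_recording(cfg)
  expect_equal(length(syn$recording$ecg), 15000)
  r <- detect_r_peaks(syn$recording$ecg, 250)
  expect_equal(60 / mean(diff(r)), 72, tolerance = 0.1)
})
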