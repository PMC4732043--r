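# hand-built peak sets (freq, power, rank in power order, flag)
mk_ps <- function(freq, power, flag, w = 2L, time = 0) {
  structure(list(window_index = w, time = time,
                 peaks = data.frame(freq = freq, power = power,
                                    phase = rep(0, length(freq)),
                                    rank = seq_along(freq), ma_flag = flag)),
            class = "peak_set")
}
empty_ps <- function(w = 1L) mk_ps(numeric(0), numeric(0), logical(0), w = w)

test_that("initialization uses the top peak or an explicit override", {
  ps <- mk_ps(c(1.5, 1.0), c(4, 1), c(FALSE, FALSE), w = 1L)
  expect_equal(init_hr(ps)$hr, 90)
  expect_equal(init_hr(ps)$source, "INIT")
  expect_equal(init_hr(ps, hr0 = 72)$hr, 72)
  expect_error(init_hr(empty_ps()), "no clean initial segment")
})

test_that("stepping selects the strongest admissible unflagged peak", {
  # clean window: top peak wins
  st <- hr_step(89, mk_ps(1.5, 4, FALSE))
  expect_equal(st$hr, 90)
  expect_equal(st$source, "P1")

  # top peak is motion: second peak carries the heart rate
  st <- hr_step(90, mk_ps(c(2.0, 1.5, 1.0), c(5, 3, 1),
                          c(TRUE, FALSE, FALSE)))
  expect_equal(st$hr, 90)
  expect_equal(st$source, "P2")

  # two top peaks are motion: third peak carries it
  st <- hr_step(90, mk_ps(c(2.0, 2.3, 1.52), c(5, 3, 1),
                          c(TRUE, TRUE, FALSE)))
  expect_equal(st$hr, 91.2)
  expect_equal(st$source, "P3")

  # sole unflagged peak violates the 10 bpm clamp: hold the previous value
  st <- hr_step(90, mk_ps(2.5, 4, FALSE))
  expect_equal(st$hr, 90)
  expect_equal(st$source, "HOLD")

  # everything flagged, or no peaks at all: hold, never an error
  expect_equal(hr_step(90, mk_ps(1.5, 4, TRUE))$source, "HOLD")
  expect_equal(hr_step(90, empty_ps(2L))$source, "HOLD")
})

test_that("power rank wins among admissible peaks, closeness breaks ties", {
  st <- hr_step(91, mk_ps(c(1.55, 1.50), c(4, 3), c(FALSE, FALSE)))
  expect_equal(st$hr, 93)  # stronger peak although 1.50 is closer
  st <- hr_step(91, mk_ps(c(1.55, 1.50), c(4, 4), c(FALSE, FALSE)))
  expect_equal(st$hr, 90)  # equal power: closest to previous wins
})

test_that("a clean constant recording tracks at the true rate, all P1", {
  cfg <- synth_config(120, 20, 72, hrv_mod = list(), noise_sd = 0.05,
                      seed = 7)
  syn <- synth_recording(cfg)
  res <- spama_hr(syn$recording, S = 2, freq_step = 0.005)
  expect_true(all(res$track$source[-1] == "P1"))
  expect_equal(res$track$hr, rep(72, nrow(res$track)), tolerance = 0.01)
})

test_that("a PPG identical to its accelerometers holds throughout", {
  x <- tone(1.4, 20, 60)
  rec <- recording(x, x, x, x, 20, 20)
  tf <- sliding_tfm(x, 20, T = 8, S = 2, freq_step = 0.005, band = c(0, 10))
  trk <- track_hr(tf, list(tf, tf, tf))
  expect_equal(trk$source[1], "INIT")
  expect_true(all(trk$source[-1] == "HOLD"))
})

test_that("a sweeping motion tone shared with the accelerometers is rejected", {
  # the tone sweeps quickly through the heart-rate trajectory; a tone that
  # co-moves with the cardiac peak for tens of seconds merges with it inside
  # one spectral mainlobe and is unresolvable by design (continuity holds)
  traj <- cbind(c(0, 60, 120, 180), c(80, 80, 140, 110))
  cfg <- synth_config(180, 20, traj, hrv_mod = list(),
                      ma_tones = list(list(start = 20, end = 160,
                                           f_start = 2.8, f_end = 0.6,
                                           amp_ppg = 1.2, amp_acc = 1,
                                           axes = "z")),
                      noise_sd = 0.05, seed = 22)
  syn <- synth_recording(cfg)
  res <- spama_hr(syn$recording, S = 2, freq_step = 0.005)
  truth <- true_hr_track(syn$hr_true, res$track$time, T = 8)
  expect_lt(error_e1(res$track, truth), 3)

  # ablation: ignoring the flags at least doubles the error
  res0 <- spama_hr(syn$recording, S = 2, freq_step = 0.005,
                   use_ma_flags = FALSE)
  expect_gt(error_e1(res0$track, truth), 2 * error_e1(res$track, truth))
})

test_that("tracking is deterministic and respects the clamp", {
  cfg <- synth_config(60, 20, cbind(c(0, 60), c(80, 100)), seed = 33)
  syn <- synth_recording(cfg)
  r1 <- spama_hr(syn$recording, S = 2, freq_step = 0.01, fill_gaps = FALSE)
  r2 <- spama_hr(syn$recording, S = 2, freq_step = 0.01, fill_gaps = FALSE)
  expect_identical(r1$track, r2$track)
  expect_true(all(abs(diff(r1$track$hr)) <= 10 + 1e-9))
})

test_that("spline filling restores interior gaps and leaves edges", {
  mk_trk <- function(hr, src) {
    structure(data.frame(time = seq_along(hr) * 2, hr = hr, source = src,
                         freq = hr / 60, peak_power = NA_real_),
              class = c("hr_track", "data.frame"))
  }
  # no holds: identity
  t0 <- mk_trk(c(80, 82, 84, 86), rep("P1", 4))
  expect_equal(fill_gaps_spline(t0), t0)

  # one interior sample removed from a linear ramp: spline restores it
  hr <- seq(80, 100, by = 2)
  src <- rep("P1", length(hr))
  hr[6] <- hr[5]; src[6] <- "HOLD"
  tf <- fill_gaps_spline(mk_trk(hr, src))
  expect_equal(tf$hr[6], 90, tolerance = 1e-6)
  expect_equal(tf$source[6], "SPLINE")

  # leading hold run is left untouched
  hr2 <- c(85, 85, 86, 88, 90, 92)
  src2 <- c("HOLD", "HOLD", "P1", "P1", "P1", "P1")
  tl <- fill_gaps_spline(mk_trk(hr2, src2))
  expect_equal(tl$source[1:2], c("HOLD", "HOLD"))
  expect_equal(tl$hr[1:2], c(85, 85))

  # too few anchors: unchanged with a warning
  expect_warning(out <- fill_gaps_spline(
    mk_trk(c(80, 80, 80, 82), c("P1", "HOLD", "HOLD", "P1"))),
    "anchor")
  expect_equal(out$hr, c(80, 80, 80, 82))
})

test_that("track CSV round-trips", {
  cfg <- synth_config(60, 20, 72, hrv_mod = list(), seed = 2)
  res <- spama_hr(synth_recording(cfg)$recording, S = 2, freq_step = 0.01)
  p <- file.path(tempdir(), "trk.csv")
  write_hr_track(res$track, p)
  trk2 <- read_hr_track(p)
  expect_equal(trk2$hr, res$track$hr, tolerance = 1e-9)
  expect_equal(trk2$source, res$track$source)
})
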