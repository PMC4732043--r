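#' Synthetic recording configuration
#'
#' Bundles the parameters of the synthetic generator, which emulates the
#' activity-protocol recordings the algorithm targets: an instantaneous
#' heart-rate trajectory (piecewise linear between breakpoints, optionally
#' modulated by LF/HF heart-rate-variability sinusoids), a PPG carrying the
#' cardiac fundamental plus an optional second harmonic, motion-artifact
#' tones shared between the PPG and chosen accelerometer axes (constant or
#' linearly chirping, so they can sweep across the heart-rate frequency),
#' white Gaussian sensor noise, and sensor-gap dropouts in which the PPG
#' signal collapses to the noise floor.
#'
#' @param duration Recording length (s).
#' @param fs Sampling rate for PPG/ACC channels (Hz), default 20 (the
#'   analysis rate); use 80 or 125 to exercise down-sampling.
#' @param hr_trajectory Two-column matrix or data frame of breakpoints
#'   `(time s, hr bpm)`, a single number (constant HR), or a protocol name
#'   accepted by [protocol_trajectory()]. HR must stay within 30-180 bpm.
#' @param hrv_mod List of `c(freq_hz, amplitude_bpm)` pairs added to the
#'   instantaneous HR. Defaults to a 3 bpm LF component at 0.1 Hz and a
#'   2 bpm HF component at 0.25 Hz, typical of light activity.
#' @param ma_tones List of motion-artifact tones, each a list/vector with
#'   named elements `start`, `end` (s), `f_start`, `f_end` (Hz), `amp_ppg`,
#'   `amp_acc`, `axes` (subset of `c("x","y","z")`).
#' @param harmonic_amp Relative amplitude of the PPG second harmonic
#'   (default 0.3).
#' @param noise_sd Gaussian noise SD per channel (default 0.05).
#' @param gaps List of `c(start, end)` dropout intervals (s).
#' @param fs_ecg Sampling rate of the synthetic reference ECG (Hz); `NULL`
#'   (default) omits the ECG channel.
#' @param ecg_peak_width SD of the Gaussian R-wave bump (s), default 0.01.
#' @param seed Integer seed fixing all randomness.
#' @return A `"synth_config"` list.
#' @export
synth_config <- function(duration = 300, fs = 20, hr_trajectory = 72,
                         hrv_mod = list(c(0.10, 3), c(0.25, 2)),
                         ma_tones = list(), harmonic_amp = 0.3,
                         noise_sd = 0.05, gaps = list(), fs_ecg = NULL,
                         ecg_peak_width = 0.01, seed = 1L) {
  if (is.character(hr_trajectory))
    hr_trajectory <- protocol_trajectory(hr_trajectory, duration = duration)
  if (is.numeric(hr_trajectory) && is.null(dim(hr_trajectory)) &&
      length(hr_trajectory) == 1L)
    hr_trajectory <- cbind(c(0, duration), c(hr_trajectory, hr_trajectory))
  traj <- as.matrix(hr_trajectory)
  if (ncol(traj) != 2L) stop("hr_trajectory needs columns (time, hr)")
  if (any(traj[, 2] < 30 | traj[, 2] > 180))
    stop("hr_trajectory leaves the 30-180 bpm band")
  for (g in gaps)
    if (g[1] < 0 || g[2] > duration || g[1] >= g[2])
      stop("gap interval outside the recording")
  structure(list(duration = duration, fs = fs, hr_trajectory = traj,
                 hrv_mod = hrv_mod, ma_tones = ma_tones,
                 harmonic_amp = harmonic_amp, noise_sd = noise_sd,
                 gaps = gaps, fs_ecg = fs_ecg,
                 ecg_peak_width = ecg_peak_width,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Piecewise-linear HR trajectories for the activity protocols
#'
#' Returns breakpoints `(time, hr)` matching the segment structure of the
#' four activity protocols: `type1` -- treadmill intervals of
#' 0.5/1/1/1/1/0.5 min alternating slow walk, moderate and fast running;
#' `type2`/`type3` -- 5 min of varied (resp. intensive) arm exercise,
#' rendered as alternating moderate segments; `type4` -- 1 min rest, 1 min
#' walking, 1 min rest, 2 min jogging, 1 min rest, 2 min running, 1 min
#' rest, 1 min arbitrary movement. HR levels are fixture constants
#' (defaults: rest 70, walk 95, jog 130, run 160 bpm) since the protocols
#' prescribe speeds, not heart rates; transitions ramp at `slope` bpm/s.
#'
#' @param name One of `"type1"`, `"type2"`, `"type3"`, `"type4"`.
#' @param levels Named numeric vector with entries `rest`, `walk`, `jog`,
#'   `run` (bpm).
#' @param slope Ramp rate between levels (bpm/s), default 1.
#' @param duration Ignored except for validation; protocols define their own
#'   length.
#' @return Two-column matrix of breakpoints `(time s, hr bpm)`.
#' @export
protocol_trajectory <- function(name,
                                levels = c(rest = 70, walk = 95,
                                           jog = 130, run = 160),
                                slope = 1, duration = NULL) {
  segs <- switch(name,
    type1 = list(mins = c(0.5, 1, 1, 1, 1, 0.5),
                 lev = c("walk", "jog", "run", "jog", "run", "walk")),
    type2 = list(mins = c(1, 1, 1, 1, 1),
                 lev = c("rest", "jog", "walk", "jog", "walk")),
    type3 = list(mins = c(1, 1, 1, 1, 1),
                 lev = c("walk", "run", "jog", "run", "jog")),
    type4 = list(mins = c(1, 1, 1, 2, 1, 2, 1, 1),
                 lev = c("rest", "walk", "rest", "jog", "rest", "run",
                         "rest", "walk")),
    stop("unknown protocol: ", name)
  )
  bounds <- c(0, cumsum(segs$mins * 60))
  lv <- unname(levels[segs$lev])
  t <- bounds[1]
  h <- lv[1]
  for (i in seq_along(lv)) {
    if (i > 1L && lv[i] != lv[i - 1]) {
      tau <- abs(lv[i] - lv[i - 1]) / slope
      # keep breakpoints strictly increasing even for short segments
      tau <- min(tau, 0.9 * segs$mins[i] * 60)
      t <- c(t, bounds[i], bounds[i] + tau)
      h <- c(h, lv[i - 1], lv[i])
    }
  }
  t <- c(t, bounds[length(bounds)])
  h <- c(h, lv[length(lv)])
  cbind(time = t, hr = h)
}

# instantaneous HR (bpm) at times t for a config
instantaneous_hr <- function(cfg, t) {
  hr <- stats::approx(cfg$hr_trajectory[, 1], cfg$hr_trajectory[, 2],
                      xout = t, rule = 2)$y
  for (m in cfg$hrv_mod) hr <- hr + m[2] * sin(2 * pi * m[1] * t)
  hr
}

# cumulative phase (rad) of a linear chirp from f0 to f1 over [s, e]
chirp_phase <- function(t, s, e, f0, f1) {
  u <- pmin(pmax(t - s, 0), e - s)
  2 * pi * (f0 * u + (f1 - f0) * u^2 / (2 * (e - s)))
}

#' Generate a synthetic recording with known ground truth
#'
#' Synthesizes the channels described in [synth_config()]. The cardiac
#' component uses continuous-phase synthesis (the phase is the cumulative
#' integral of the instantaneous frequency), so ground-truth beat times are
#' well defined as successive 2*pi phase crossings and the returned NN series
#' is exact. Accelerometer axes carry their assigned motion tones plus noise
#' but no cardiac component. Identical seeds give bit-identical output.
#'
#' @param cfg A [synth_config()].
#' @return List with `recording` (a [recording()]), `hr_true` (data frame
#'   `time`, `hr`: instantaneous ground truth at the channel rate), and
#'   `nn_true` (data frame `time`, `nn` in ms at ground-truth beat times).
#' @export
synth_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- as.integer(round(cfg$duration * cfg$fs))
  t <- (seq_len(n) - 1) / cfg$fs
  hr <- instantaneous_hr(cfg, t)
  f_inst <- hr / 60
  # cumulative trapezoid integral of f_inst
  phase <- 2 * pi * c(0, cumsum((f_inst[-1] + f_inst[-n]) / 2)) / cfg$fs

  ppg <- sin(phase) + cfg$harmonic_amp * sin(2 * phase)
  acc <- list(x = numeric(n), y = numeric(n), z = numeric(n))
  for (tone in cfg$ma_tones) {
    tone <- as.list(tone)
    ph <- chirp_phase(t, tone$start, tone$end, tone$f_start, tone$f_end)
    on <- t >= tone$start & t <= tone$end
    ppg[on] <- ppg[on] + tone$amp_ppg * sin(ph[on])
    for (ax in tone$axes)
      acc[[ax]][on] <- acc[[ax]][on] + tone$amp_acc * sin(ph[on])
  }
  for (g in cfg$gaps) ppg[t >= g[1] & t <= g[2]] <- 0
  ppg <- ppg + stats::rnorm(n, sd = cfg$noise_sd)
  for (ax in c("x", "y", "z"))
    acc[[ax]] <- acc[[ax]] + stats::rnorm(n, sd = cfg$noise_sd)

  # ground-truth beats: phase crossings of multiples of 2*pi
  n_beats <- floor(phase[n] / (2 * pi))
  t_beats <- if (n_beats >= 1)
    stats::approx(phase, t, xout = 2 * pi * seq_len(n_beats))$y
  else numeric(0)
  nn_true <- if (length(t_beats) >= 2L)
    data.frame(time = t_beats[-1], nn = diff(t_beats) * 1000)
  else data.frame(time = numeric(0), nn = numeric(0))

  ecg <- NULL
  if (!is.null(cfg$fs_ecg)) {
    ne <- as.integer(round(cfg$duration * cfg$fs_ecg))
    te <- (seq_len(ne) - 1) / cfg$fs_ecg
    ecg <- stats::rnorm(ne, sd = 0.01)
    for (tb in t_beats)
      ecg <- ecg + exp(-(te - tb)^2 / (2 * cfg$ecg_peak_width^2))
  }

  list(
    recording = recording(ppg = ppg, acc_x = acc$x, acc_y = acc$y,
                          acc_z = acc$z, fs_ppg = cfg$fs, fs_acc = cfg$fs,
                          ecg = ecg, fs_ecg = cfg$fs_ecg),
    hr_true = data.frame(time = t, hr = hr),
    nn_true = nn_true
  )
}

#' Window-averaged ground-truth HR on a track's grid
#'
#' The sliding-window spectral estimate measures (approximately) the mean
#' instantaneous heart rate over each window, so ground truth must be
#' compared on the same footing: for each window-end time `t(k)` this returns
#' the mean of the instantaneous HR over `[t(k) - T, t(k)]`.
#'
#' @param hr_true Data frame `time`, `hr` (from [synth_recording()]).
#' @param times Window-end times (s), e.g. an `"hr_track"`'s `time` column.
#' @param T Window length (s).
#' @return An `"hr_track"` with source `"TRUTH"`.
#' @export
true_hr_track <- function(hr_true, times, T = 8) {
  hr <- vapply(times, function(tk) {
    keep <- hr_true$time >= tk - T - 1e-9 & hr_true$time <= tk + 1e-9
    mean(hr_true$hr[keep])
  }, numeric(1))
  structure(data.frame(time = times, hr = hr, source = "TRUTH",
                       freq = hr / 60, peak_power = NA_real_),
            class = c("hr_track", "data.frame"))
}
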