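#' Initial heart-rate estimate from the first window
#'
#' The tracker requires a clean first segment: the heart rate is read off the
#' highest in-band spectral peak. When the start of the recording is known to
#' be corrupted, a starting heart rate can be supplied instead and overrides
#' the spectrum.
#'
#' @param first_peaks A `"peak_set"` for the first window.
#' @param hr0 Optional known starting heart rate (bpm); overrides the peaks.
#' @return A one-row data frame with columns `time`, `hr`, `source`
#'   (`"INIT"`), `freq`, `peak_power`.
#' @export
init_hr <- function(first_peaks, hr0 = NULL) {
  stopifnot(inherits(first_peaks, "peak_set"))
  if (!is.null(hr0)) {
    return(data.frame(time = first_peaks$time, hr = hr0, source = "INIT",
                      freq = hr0 / 60, peak_power = NA_real_))
  }
  if (nrow(first_peaks$peaks) == 0L)
    stop("no clean initial segment: first window has no spectral peaks ",
         "and no starting heart rate was supplied")
  p <- first_peaks$peaks[1, ]
  data.frame(time = first_peaks$time, hr = 60 * p$freq, source = "INIT",
             freq = p$freq, peak_power = p$power)
}

#' One tracking step: pick the heart-rate peak for the current window
#'
#' Among peaks not flagged as motion artifact, selects the highest-power peak
#' whose implied heart rate lies within `max_jump` bpm of the previous
#' estimate (ties broken toward the frequency closest to the previous HR).
#' The source label records the peak's original power rank (`"P1"`, `"P2"`,
#' `"P3"`): when the largest peak is motion, the second is taken; when the
#' two largest are motion, the third. If no admissible peak remains --
#' everything flagged, an undetectable window, or all candidates beyond the
#' continuity clamp -- the previous value is held (`"HOLD"`); holding is the
#' fallback, never an error.
#'
#' @param prev_hr Previous heart-rate estimate (bpm).
#' @param peaks A `"peak_set"` with `ma_flag` set (see [flag_ma_peaks()]).
#' @param max_jump Maximum allowed change from the previous window (bpm),
#'   default 10.
#' @param use_ma_flags If `FALSE`, ignore motion-artifact flags (ablation
#'   mode). Default `TRUE`.
#' @return A list with `hr`, `source`, `freq`, `peak_power`.
#' @export
hr_step <- function(prev_hr, peaks, max_jump = 10, use_ma_flags = TRUE) {
  stopifnot(inherits(peaks, "peak_set"))
  p <- peaks$peaks
  if (nrow(p) > 0L) {
    ok <- if (use_ma_flags) !p$ma_flag else rep(TRUE, nrow(p))
    ok <- ok & abs(60 * p$freq - prev_hr) <= max_jump + 1e-9
    if (any(ok)) {
      cand <- p[ok, , drop = FALSE]
      best <- order(-cand$power, abs(60 * cand$freq - prev_hr))[1]
      return(list(hr = 60 * cand$freq[best],
                  source = paste0("P", cand$rank[best]),
                  freq = cand$freq[best],
                  peak_power = cand$power[best]))
    }
  }
  list(hr = prev_hr, source = "HOLD", freq = prev_hr / 60,
       peak_power = NA_real_)
}

#' Track heart rate across a recording's time-frequency matrices
#'
#' Implements the per-window tracking loop: band-limit the PPG and
#' accelerometer spectra to the heart-rate band, take the top three PPG peaks
#' and the dominant peak per accelerometer axis, flag PPG peaks coincident
#' with accelerometer frequencies as motion artifacts, and step the tracker
#' under the continuity clamp. Windows whose in-band PPG power falls below a
#' small fraction of the recording's median window power are treated as
#' sensor-gap windows (no usable peaks, held in real time; see
#' [fill_gaps_spline()] for offline filling).
#'
#' @param ppg_tfm `"tfm"` of the PPG channel.
#' @param acc_tfms List of three `"tfm"`s (accelerometer x, y, z), same
#'   window length, shift and frame count as `ppg_tfm`.
#' @param band Heart-rate band `c(f_lo, f_hi)` in Hz, default `c(0.5, 3)`
#'   (30-180 bpm).
#' @param k Number of PPG peaks retained per window (default 3).
#' @param tol Motion-artifact frequency coincidence tolerance (Hz),
#'   default 0.03.
#' @param max_jump Continuity clamp (bpm per window step), default 10.
#' @param hr0 Optional known starting heart rate (bpm).
#' @param use_ma_flags Ablation switch; see [hr_step()].
#' @param power_floor,harmonics Passed to [ma_frequencies()].
#' @param min_separation Minimum peak separation (Hz), see [top_peaks()].
#' @param gap_rel_floor Window is a gap when its in-band power is below this
#'   fraction of the median window in-band power (default 0.01).
#' @return An `"hr_track"`: data frame with columns `time` (s), `hr` (bpm),
#'   `source` (`INIT`/`P1`/`P2`/`P3`/`HOLD`), `freq` (Hz), `peak_power`;
#'   tracking parameters are attached as the `"params"` attribute.
#' @export
track_hr <- function(ppg_tfm, acc_tfms, band = c(0.5, 3), k = 3, tol = 0.03,
                     max_jump = 10, hr0 = NULL, use_ma_flags = TRUE,
                     power_floor = 12, harmonics = FALSE,
                     min_separation = 0.05, gap_rel_floor = 0.01) {
  stopifnot(inherits(ppg_tfm, "tfm"), length(acc_tfms) == 3L)
  nw <- n_frames(ppg_tfm)
  for (a in acc_tfms) {
    if (!inherits(a, "tfm") || n_frames(a) != nw ||
        a$win_len != ppg_tfm$win_len ||
        abs(a$S - ppg_tfm$S) > 1e-12)
      stop("PPG and accelerometer time-frequency matrices do not share ",
           "window length, shift and frame count")
  }

  # band-limited in-band power per window for gap detection
  inband <- ppg_tfm$freqs >= band[1] & ppg_tfm$freqs <= band[2]
  df_grid <- ppg_tfm$freqs[2] - ppg_tfm$freqs[1]
  win_power <- colSums(ppg_tfm$psd[inband, , drop = FALSE]) * df_grid
  gap <- win_power < gap_rel_floor * stats::median(win_power)

  get_peaks <- function(w) {
    if (gap[w]) {
      fr <- tfm_frame(ppg_tfm, w)
      return(structure(list(window_index = w, time = fr$time,
                            peaks = data.frame(freq = numeric(0),
                                               power = numeric(0),
                                               phase = numeric(0),
                                               rank = integer(0),
                                               ma_flag = logical(0))),
                       class = "peak_set"))
    }
    pp <- top_peaks(band_limit(tfm_frame(ppg_tfm, w), band[1], band[2]),
                    k = k, min_separation = min_separation)
    acc_frames <- lapply(acc_tfms, function(a)
      band_limit(tfm_frame(a, w), band[1], band[2]))
    ma <- ma_frequencies(acc_frames, power_floor = power_floor,
                         harmonics = harmonics,
                         min_separation = min_separation)
    flag_ma_peaks(pp, ma, tol = tol)
  }

  first <- init_hr(get_peaks(1L), hr0 = hr0)
  out <- data.frame(time = ppg_tfm$times, hr = NA_real_,
                    source = NA_character_, freq = NA_real_,
                    peak_power = NA_real_)
  out[1, c("hr", "source", "freq", "peak_power")] <-
    first[, c("hr", "source", "freq", "peak_power")]
  if (nw > 1L) {
    for (w in 2:nw) {
      st <- hr_step(out$hr[w - 1L], get_peaks(w), max_jump = max_jump,
                    use_ma_flags = use_ma_flags)
      out$hr[w] <- st$hr
      out$source[w] <- st$source
      out$freq[w] <- st$freq
      out$peak_power[w] <- st$peak_power
    }
  }
  structure(out,
            params = list(band = band, k = k, tol = tol, max_jump = max_jump,
                          use_ma_flags = use_ma_flags,
                          power_floor = power_floor,
                          gap_rel_floor = gap_rel_floor,
                          T = ppg_tfm$T, S = ppg_tfm$S),
            gap = gap,
            class = c("hr_track", "data.frame"))
}

#' Fill interior held runs of an HR track by cubic-spline interpolation
#'
#' Offline post-processing of sensor-gap segments: runs of `HOLD` samples
#' bounded by valid samples on both sides are replaced with values of a
#' natural cubic spline fitted through all non-`HOLD` samples, with source
#' relabelled `SPLINE`. Leading and trailing held runs have no right/left
#' anchor and are left unchanged. With fewer than 4 anchor samples the track
#' is returned unchanged with a warning.
#'
#' @param trk An `"hr_track"`.
#' @return An `"hr_track"` of the same shape.
#' @export
fill_gaps_spline <- function(trk) {
  stopifnot(inherits(trk, "hr_track"))
  hold <- trk$source == "HOLD"
  if (!any(hold)) return(trk)
  anchor <- !hold
  if (sum(anchor) < 4L) {
    warning("fewer than 4 anchor samples; returning track unchanged")
    return(trk)
  }
  # interior holds: those with an anchor somewhere before AND after
  first_a <- min(which(anchor))
  last_a <- max(which(anchor))
  interior <- hold & seq_along(hold) > first_a & seq_along(hold) < last_a
  if (!any(interior)) return(trk)
  sf <- stats::splinefun(trk$time[anchor], trk$hr[anchor], method = "natural")
  trk$hr[interior] <- sf(trk$time[interior])
  trk$freq[interior] <- trk$hr[interior] / 60
  trk$source[interior] <- "SPLINE"
  trk$peak_power[interior] <- NA_real_
  trk
}

#' Write / read an HR track as CSV
#'
#' @param trk An `"hr_track"`.
#' @param path CSV path.
#' @return `path` (write) or an `"hr_track"` (read).
#' @export
write_hr_track <- function(trk, path) {
  utils::write.csv(data.frame(time_s = trk$time, hr_bpm = trk$hr,
                              source = trk$source),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hr_track
#' @export
read_hr_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(data.frame(time = df$time_s, hr = df$hr_bpm, source = df$source,
                       freq = df$hr_bpm / 60, peak_power = NA_real_),
            class = c("hr_track", "data.frame"))
}
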