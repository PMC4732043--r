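#' Run the full spectral-filter HR pipeline on a recording
#'
#' Convenience wrapper chaining the stages: down-sample PPG and accelerometer
#' channels to the analysis rate, compute sliding-window time-frequency
#' matrices of all four channels, track the heart rate with
#' motion-artifact flagging, and (optionally, offline) spline-fill interior
#' gap runs. Use `S = 2` for coarse HR monitoring and `S = "sample"` for
#' beat-to-beat analysis feeding HRV and waveform reconstruction.
#'
#' @param rec A [recording()].
#' @param analysis_fs Analysis rate (Hz), default 20.
#' @param T Window length (s), default 8.
#' @param S Window shift (s) or `"sample"`, default 2.
#' @param freq_step Frequency grid step (Hz), default 0.001. Coarser steps
#'   (e.g. 0.005) trade HR quantization (0.3 bpm at 0.005 Hz) for speed and
#'   memory in sample-by-sample runs.
#' @param taper Taper name, default `"hamming"`.
#' @param band Heart-rate band (Hz), default `c(0.5, 3)`.
#' @param fill_gaps Apply [fill_gaps_spline()] (offline mode), default
#'   `TRUE`.
#' @param tfm_band Frequency band retained in the stored matrices; defaults
#'   to `c(0, analysis_fs / 2)`. Must contain `band`.
#' @param ... Further tracking arguments passed to [track_hr()] (`tol`,
#'   `max_jump`, `hr0`, `use_ma_flags`, `power_floor`, `harmonics`,
#'   `min_separation`, `gap_rel_floor`).
#' @return A `"spama_result"`: list with `track` (an `"hr_track"`),
#'   `ppg_tfm`, `acc_tfms`, and the call parameters.
#' @export
spama_hr <- function(rec, analysis_fs = 20, T = 8, S = 2, freq_step = 0.001,
                     taper = "hamming", band = c(0.5, 3), fill_gaps = TRUE,
                     tfm_band = NULL, ...) {
  stopifnot(inherits(rec, "ppg_recording"))
  if (rec$fs_ppg != analysis_fs || rec$fs_acc != analysis_fs)
    rec <- downsample(rec, analysis_fs)
  if (is.null(tfm_band)) tfm_band <- c(0, analysis_fs / 2)
  mk <- function(x) sliding_tfm(x, fs = analysis_fs, T = T, S = S,
                                freq_step = freq_step, taper = taper,
                                band = tfm_band, t0 = rec$t0)
  ppg_tfm <- mk(rec$ppg)
  acc_tfms <- list(mk(rec$acc_x), mk(rec$acc_y), mk(rec$acc_z))
  trk <- track_hr(ppg_tfm, acc_tfms, band = band, ...)
  if (fill_gaps) trk <- fill_gaps_spline(trk)
  structure(list(track = trk, ppg_tfm = ppg_tfm, acc_tfms = acc_tfms,
                 params = list(analysis_fs = analysis_fs, T = T, S = S,
                               freq_step = freq_step, taper = taper,
                               band = band)),
            class = "spama_result")
}

#' @export
print.spama_result <- function(x, ...) {
  cat("spama_result:", nrow(x$track), "windows; sources:\n")
  print(table(x$track$source))
  invisible(x)
}
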