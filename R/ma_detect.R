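#' Motion-artifact candidate frequencies from accelerometer spectra
#'
#' For each accelerometer axis, takes the dominant (largest) in-band spectral
#' peak as a motion-artifact candidate frequency. An axis contributes a
#' candidate only when its dominant peak stands well above the axis's in-band
#' spectral floor, preventing flags from noise-floor maxima during rest: the
#' peak PSD must exceed `power_floor` times the mean in-band PSD (a spectral
#' crest factor). The maxima of a pure white-noise spectrum stay below about
#' 8x the mean, while a genuine motion tone exceeds the floor by orders of
#' magnitude, so the default of 12 separates the two regimes robustly.
#'
#' @param acc_frames List of band-limited `"spectral_frame"`s, one per axis,
#'   all from the same window.
#' @param power_floor Minimum crest factor (dominant-peak PSD over mean
#'   in-band PSD) for an axis to contribute (default 12).
#' @param harmonics If `TRUE`, also include 2x each retained fundamental
#'   (within the band). Default `FALSE`: only the largest peak per axis is
#'   used.
#' @param min_separation Passed to [top_peaks()].
#' @return An `"ma_freqs"` object: list with `window_index`, `time`, and
#'   `freqs` (possibly empty numeric vector of candidate MA frequencies, Hz).
#' @export
ma_frequencies <- function(acc_frames, power_floor = 12, harmonics = FALSE,
                           min_separation = 0.05) {
  stopifnot(length(acc_frames) >= 1)
  wi <- acc_frames[[1]]$window_index
  freqs <- numeric(0)
  f_hi <- max(acc_frames[[1]]$freqs)
  for (fr in acc_frames) {
    if (!identical(fr$window_index, wi))
      stop("accelerometer frames come from different windows")
    ps <- top_peaks(fr, k = 1, min_separation = min_separation)
    if (nrow(ps$peaks) == 0L) next
    floor_psd <- mean(fr$psd)
    if (floor_psd <= 0 || ps$peaks$power[1] < power_floor * floor_psd) next
    freqs <- c(freqs, ps$peaks$freq[1])
    if (harmonics && 2 * ps$peaks$freq[1] <= f_hi)
      freqs <- c(freqs, 2 * ps$peaks$freq[1])
  }
  structure(list(window_index = wi, time = acc_frames[[1]]$time,
                 freqs = unique(freqs)),
            class = "ma_freqs")
}

#' Flag PPG peaks that coincide with accelerometer frequencies
#'
#' Any PPG spectral peak within `tol` Hz of a motion-artifact candidate
#' frequency is flagged as motion artifact. Peaks are only flagged, never
#' removed, so the tracker can reason over the full ranked set.
#'
#' @param ppg_peaks A `"peak_set"` from the PPG spectrum.
#' @param ma An `"ma_freqs"` object from the same window.
#' @param tol Frequency coincidence tolerance in Hz (default 0.03 Hz,
#'   about 1.8 bpm).
#' @return The `"peak_set"` with `ma_flag` set.
#' @export
flag_ma_peaks <- function(ppg_peaks, ma, tol = 0.03) {
  stopifnot(inherits(ppg_peaks, "peak_set"), inherits(ma, "ma_freqs"))
  if (!identical(ppg_peaks$window_index, ma$window_index))
    stop("peak set (window ", ppg_peaks$window_index,
         ") and MA frequencies (window ", ma$window_index,
         ") come from different windows")
  if (nrow(ppg_peaks$peaks) == 0L || length(ma$freqs) == 0L) {
    ppg_peaks$peaks$ma_flag <- rep(FALSE, nrow(ppg_peaks$peaks))
    return(ppg_peaks)
  }
  ppg_peaks$peaks$ma_flag <- vapply(
    ppg_peaks$peaks$freq,
    function(f) any(abs(f - ma$freqs) <= tol),
    logical(1)
  )
  ppg_peaks
}
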