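#' Evaluate the reconstruction sinusoid
#'
#' The elementary reconstruction formula: `A * sin(2*pi*t*f + phi)`,
#' evaluated elementwise over equal-length (or recyclable) vectors.
#'
#' @param A Amplitude(s).
#' @param f Frequency(ies), Hz.
#' @param phi Phase(s), radians.
#' @param t Time(s), seconds.
#' @return Numeric vector.
#' @export
rec_signal <- function(A, f, phi, t) A * sin(2 * pi * t * f + phi)

#' Reconstruct a PPG surrogate from the tracked heart rate
#'
#' For each window `k` the reconstruction takes the heart-rate frequency
#' `f_HR(k)` from the track, and the amplitude and phase of the PPG spectrum
#' at the bin nearest `f_HR(k)`:
#' `RecSignal(k) = A_HR(k) * sin(2*pi*t(k)*f_HR(k) + phi_HR(k))`.
#'
#' The amplitude convention maps the ENBW-normalized PSD back to a sinusoid
#' amplitude, `A_HR = sqrt(2 * psd * df_eff)` with
#' `df_eff = fs * enbw^2 / win_len`, which is exact for an on-grid pure tone
#' (covered by the round-trip test). The stored spectral phase is referenced
#' to the window start; it is re-referenced here to absolute time zero
#' (`phi_HR = phase + pi/2 - 2*pi*f_HR*t_start`, wrapped to `(-pi, pi]`) so
#' that evaluating the sinusoid at the window-end timestamp `t(k)` reproduces
#' the underlying waveform sample. Intended for sample-by-sample windowing,
#' where one window end falls on every signal sample.
#'
#' @param trk An `"hr_track"` produced from `tfm` (same shift).
#' @param tfm The PPG `"tfm"` the track was computed from. Its frequency grid
#'   must cover the track's frequencies (do not band-limit more tightly than
#'   the tracking band).
#' @param unwrap_phase If `TRUE`, replace the per-window phase by its
#'   unwrapped cumulative version for a smoother waveform. Default `FALSE`:
#'   each window is evaluated independently.
#' @return A `"reconstructed_ppg"`: list with `time`, `samples`, and aux
#'   per-sample vectors `amplitude`, `freq` (Hz), `phase` (radians), plus
#'   `fs`.
#' @export
reconstruct_ppg <- function(trk, tfm, unwrap_phase = FALSE) {
  stopifnot(inherits(trk, "hr_track"), inherits(tfm, "tfm"))
  if (nrow(trk) != n_frames(tfm) || max(abs(trk$time - tfm$times)) > tfm$S / 2)
    stop("track and time-frequency matrix are not on the same window grid")
  df_eff <- tfm$fs * tfm$enbw^2 / tfm$win_len
  t_start <- tfm$times - (tfm$win_len - 1) / tfm$fs

  bins <- vapply(trk$freq, function(f) which.min(abs(tfm$freqs - f)),
                 integer(1))
  idx <- cbind(bins, seq_len(nrow(trk)))
  A <- sqrt(pmax(2 * tfm$psd[idx] * df_eff, 0))
  phi <- tfm$phase[idx] + pi / 2 - 2 * pi * trk$freq * t_start
  phi <- atan2(sin(phi), cos(phi))  # wrap to (-pi, pi]
  if (unwrap_phase) {
    total <- 2 * pi * trk$time * trk$freq + phi
    phi <- signal::unwrap(total) - 2 * pi * trk$time * trk$freq
  }
  structure(list(
    time = trk$time,
    samples = rec_signal(A, trk$freq, phi, trk$time),
    amplitude = A, freq = trk$freq, phase = phi,
    fs = 1 / tfm$S
  ), class = "reconstructed_ppg")
}

#' Export a reconstructed PPG as a two-column CSV
#' @param rp A `"reconstructed_ppg"`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_reconstruction <- function(rp, path) {
  utils::write.csv(data.frame(time_s = rp$time, value = rp$samples),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
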