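#' Taper window with equivalent noise bandwidth
#'
#' Returns the taper samples together with its equivalent noise bandwidth
#' (ENBW, in bins), `n * sum(w^2) / sum(w)^2`. The ENBW is used to normalize
#' periodogram power estimates so that tone peak heights are comparable
#' across tapers (rectangular taper has ENBW exactly 1).
#'
#' @param n Window length in samples.
#' @param taper One of `"hamming"`, `"hann"`, `"rect"`.
#' @return List with `w` (numeric vector) and `enbw` (bins).
#' @export
taper_window <- function(n, taper = c("hamming", "hann", "rect")) {
  taper <- match.arg(taper)
  w <- switch(taper,
              hamming = signal::hamming(n),
              hann = signal::hanning(n),
              rect = rep(1, n))
  list(w = as.numeric(w), enbw = n * sum(w^2) / sum(w)^2, taper = taper)
}

#' Single-segment periodogram frame (power + phase)
#'
#' Computes a one-sided, ENBW-normalized periodogram of one window segment on
#' a fixed frequency grid `[0, fs/2]` with step `freq_step`, achieved by
#' zero-padding the tapered transform. The segment mean is removed before
#' tapering so the DC lobe does not leak into the low edge of the heart-rate
#' band. The phase of the complex spectrum is retained for waveform
#' reconstruction.
#'
#' The PSD convention is
#' `psd(f) = g * |X(f)|^2 / (fs * sum(w^2) * enbw)`
#' with `g = 2` except at DC and Nyquist, so that for a rectangular taper
#' without zero-padding `sum(psd) * df` equals the mean square of the
#' (demeaned) segment.
#'
#' @param segment Numeric vector (length >= 2).
#' @param fs Sampling rate (Hz).
#' @param freq_step Frequency grid step (Hz); default 0.001.
#' @param taper Taper name; see [taper_window()].
#' @param detrend Remove the segment mean first (default `TRUE`).
#' @param window_index,time Optional bookkeeping carried on the frame.
#' @return A `"spectral_frame"`: list with `freqs`, `psd`, `phase`,
#'   `fs`, `enbw`, `win_len`, `taper`, `window_index`, `time`.
#' @export
periodogram_frame <- function(segment, fs, freq_step = 0.001,
                              taper = "hamming", detrend = TRUE,
                              window_index = 1L, time = NA_real_) {
  n <- length(segment)
  if (n < 2L) stop("segment must have at least 2 samples")
  if (freq_step <= 0) stop("freq_step must be > 0")
  if (freq_step > fs / n)
    warning("freq_step ", freq_step,
            " Hz is coarser than the natural resolution ", signif(fs / n, 4),
            " Hz")
  tw <- taper_window(n, taper)
  x <- if (detrend) segment - mean(segment) else segment
  nfft <- max(n, as.integer(round(fs / freq_step)))
  X <- stats::fft(c(x * tw$w, rep(0, nfft - n)))
  nkeep <- floor(nfft / 2) + 1L
  X <- X[seq_len(nkeep)]
  g <- rep(2, nkeep)
  g[1] <- 1
  if (nfft %% 2 == 0) g[nkeep] <- 1
  psd <- g * (Mod(X)^2) / (fs * sum(tw$w^2) * tw$enbw)
  structure(list(
    freqs = (seq_len(nkeep) - 1) * fs / nfft,
    psd = psd,
    phase = Arg(X),
    fs = fs, enbw = tw$enbw, win_len = n, taper = tw$taper,
    window_index = as.integer(window_index), time = time
  ), class = "spectral_frame")
}

#' Sliding-window time-frequency matrix
#'
#' Slides a `T`-second window through the signal in steps of `S` seconds
#' (or one sample when `S = "sample"`), computing a [periodogram_frame()]
#' at each position. Frame timestamps use the window-END convention: the
#' time of the last sample in the window (causal, real-time compatible).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate (Hz).
#' @param T Window length in seconds (default 8).
#' @param S Shift in seconds (default 2), or `"sample"` for one-sample
#'   shifts (`1/fs` s) as used for beat-to-beat HR / HRV analysis.
#' @param freq_step,taper,detrend Passed to [periodogram_frame()].
#' @param band Optional `c(f_lo, f_hi)`: store only this frequency band of
#'   each frame (memory control for sample-by-sample runs). `NULL` keeps the
#'   full `[0, fs/2]` grid.
#' @param t0 Start time of the first sample (s).
#' @return A `"tfm"` object: list with matrices `psd` and `phase`
#'   (frequencies x windows), `freqs`, `times`, and parameters `T`, `S`
#'   (seconds), `fs`, `enbw`, `win_len`, `taper`.
#' @export
sliding_tfm <- function(x, fs, T = 8, S = 2, freq_step = 0.001,
                        taper = "hamming", detrend = TRUE, band = NULL,
                        t0 = 0) {
  n <- length(x)
  wn <- as.integer(round(T * fs))
  if (n < wn) stop("signal shorter than window")
  sn <- if (identical(S, "sample")) 1L else as.integer(round(S * fs))
  if (sn < 1L) stop("shift S must be at least one sample")
  n_frames <- floor((n - wn) / sn) + 1L

  f0 <- periodogram_frame(x[seq_len(wn)], fs, freq_step, taper, detrend)
  keep <- if (is.null(band)) seq_along(f0$freqs) else
    which(f0$freqs >= band[1] & f0$freqs <= band[2])
  if (length(keep) == 0L) stop("band does not intersect the frequency grid")

  psd <- matrix(0, nrow = length(keep), ncol = n_frames)
  phase <- matrix(0, nrow = length(keep), ncol = n_frames)
  times <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    i0 <- (k - 1L) * sn
    fr <- if (k == 1L) f0 else
      periodogram_frame(x[(i0 + 1L):(i0 + wn)], fs, freq_step, taper, detrend)
    psd[, k] <- fr$psd[keep]
    phase[, k] <- fr$phase[keep]
    times[k] <- t0 + (i0 + wn - 1L) / fs
  }
  structure(list(
    psd = psd, phase = phase, freqs = f0$freqs[keep], times = times,
    T = T, S = if (identical(S, "sample")) 1 / fs else S,
    fs = fs, enbw = f0$enbw, win_len = wn, taper = f0$taper
  ), class = "tfm")
}

#' Number of windows in a time-frequency matrix
#' @param tfm A `"tfm"` object.
#' @return Integer frame count.
#' @export
n_frames <- function(tfm) ncol(tfm$psd)

#' Extract one window of a time-frequency matrix as a spectral frame
#' @param tfm A `"tfm"` object.
#' @param k Window index (1-based).
#' @return A `"spectral_frame"`.
#' @export
tfm_frame <- function(tfm, k) {
  stopifnot(k >= 1, k <= n_frames(tfm))
  structure(list(
    freqs = tfm$freqs, psd = tfm$psd[, k], phase = tfm$phase[, k],
    fs = tfm$fs, enbw = tfm$enbw, win_len = tfm$win_len, taper = tfm$taper,
    window_index = as.integer(k), time = tfm$times[k]
  ), class = "spectral_frame")
}

#' @export
print.tfm <- function(x, ...) {
  cat("tfm:", n_frames(x), "windows x", length(x$freqs), "frequencies\n")
  cat("  T =", x$T, "s, S =", x$S, "s, fs =", x$fs, "Hz, taper =", x$taper,
      "(ENBW", round(x$enbw, 4), "bins)\n")
  invisible(x)
}

#' Export a time-frequency matrix as delimited text
#'
#' Writes the PSD matrix with a frequency column and one column per window
#' (named by window-end time), suitable for plotting spectrograms.
#'
#' @param tfm A `"tfm"` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_tfm <- function(tfm, path) {
  df <- data.frame(freq_hz = tfm$freqs, tfm$psd)
  names(df)[-1] <- sprintf("t%.3f", tfm$times)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
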