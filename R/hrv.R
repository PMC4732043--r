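#' Convert a heart-rate track to an NN-interval series
#'
#' `NN(k) = 60000 / hr(k)` milliseconds, timestamps preserved. The series is
#' derived from the sample-by-sample heart-rate track rather than from
#' detected beats, matching the windowed spectral estimation that produced
#' it.
#'
#' @param trk An `"hr_track"` (or data frame with `time` and `hr`).
#' @return Data frame with columns `time` (s) and `nn` (ms).
#' @export
hr_to_nn <- function(trk) {
  if (nrow(trk) == 0L) stop("empty heart-rate track")
  if (any(trk$hr <= 0)) stop("nonpositive heart rate at index ",
                             which(trk$hr <= 0)[1])
  data.frame(time = trk$time, nn = 60000 / trk$hr)
}

#' Time-domain HRV measures
#'
#' Computes from an NN series: `mean_nn` (ms), `sdnn` (sample standard
#' deviation, n-1 denominator, ms), `rmssd` (root mean square of successive
#' differences, ms) and `pnn50` (fraction of successive differences exceeding
#' 50 ms in magnitude; denominator is the number of successive differences).
#'
#' @param nn Numeric vector of NN intervals (ms), or a data frame with an
#'   `nn` column; length >= 2.
#' @return Named list `mean_nn`, `sdnn`, `rmssd`, `pnn50`.
#' @export
time_domain_metrics <- function(nn) {
  if (is.data.frame(nn)) nn <- nn$nn
  if (length(nn) < 2L) stop("need at least 2 NN intervals")
  d <- diff(nn)
  list(mean_nn = mean(nn),
       sdnn = stats::sd(nn),
       rmssd = sqrt(mean(d^2)),
       pnn50 = mean(abs(d) > 50))
}

#' Power spectral density of an NN-interval series
#'
#' Linearly detrends the NN series, resamples it onto a uniform grid at
#' `fs_resample` by cubic spline, and computes a single full-span
#' ENBW-normalized periodogram (see [periodogram_frame()]).
#'
#' @param nn Data frame with `time` (s) and `nn` (ms), spanning >= 60 s.
#' @param fs_resample Uniform resampling rate (Hz), default 4.
#' @param freq_step Frequency grid step (Hz), default 0.001.
#' @param taper Taper name, default `"hamming"`.
#' @return A `"spectral_frame"` over `[0, fs_resample/2]`.
#' @export
hrv_psd <- function(nn, fs_resample = 4, freq_step = 0.001,
                    taper = "hamming") {
  stopifnot(is.data.frame(nn), all(c("time", "nn") %in% names(nn)))
  span <- diff(range(nn$time))
  if (span < 60) stop("NN series spans ", signif(span, 4),
                      " s; at least 60 s needed for LF/HF analysis")
  # linear detrend
  fit <- stats::lm.fit(cbind(1, nn$time), nn$nn)
  resid <- nn$nn - cbind(1, nn$time) %*% fit$coefficients
  t_out <- seq(min(nn$time), max(nn$time), by = 1 / fs_resample)
  y <- stats::spline(nn$time, resid, xout = t_out, method = "fmm")$y
  periodogram_frame(y, fs = fs_resample, freq_step = freq_step,
                    taper = taper, detrend = TRUE, time = max(t_out))
}

#' Pearson correlation between two PSDs over a frequency band
#'
#' The standard LF band is 0.04-0.15 Hz and the HF band 0.15-0.4 Hz.
#'
#' @param psd_a,psd_b `"spectral_frame"`s on the same frequency grid.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @return Pearson correlation coefficient over the in-band bins.
#' @export
band_correlation <- function(psd_a, psd_b, band) {
  stopifnot(inherits(psd_a, "spectral_frame"),
            inherits(psd_b, "spectral_frame"))
  if (length(psd_a$freqs) != length(psd_b$freqs) ||
      max(abs(psd_a$freqs - psd_b$freqs)) > 1e-9)
    stop("PSDs are not on a shared frequency grid")
  keep <- psd_a$freqs >= band[1] & psd_a$freqs <= band[2]
  if (!any(keep)) stop("band does not intersect the frequency grid")
  a <- psd_a$psd[keep]
  b <- psd_b$psd[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance PSD in band; correlation undefined")
  stats::cor(a, b)
}

#' Full HRV report for an HR track against a reference
#'
#' Computes the time-domain measures of the track's NN series and, when a
#' reference track is given, the LF- and HF-band Pearson correlations between
#' the two NN power spectra.
#'
#' @param trk An `"hr_track"`.
#' @param ref Optional reference `"hr_track"` (e.g. ECG-derived).
#' @param lf,hf Band definitions (Hz).
#' @param fs_resample,freq_step Passed to [hrv_psd()].
#' @return An `"hrv_report"`: list with `mean_nn`, `sdnn`, `rmssd`, `pnn50`,
#'   and (with a reference) `lf_corr`, `hf_corr`.
#' @export
hrv_report <- function(trk, ref = NULL, lf = c(0.04, 0.15),
                       hf = c(0.15, 0.4), fs_resample = 4,
                       freq_step = 0.001) {
  nn <- hr_to_nn(trk)
  out <- time_domain_metrics(nn)
  if (!is.null(ref)) {
    pa <- hrv_psd(nn, fs_resample, freq_step)
    pb <- hrv_psd(hr_to_nn(ref), fs_resample, freq_step)
    # grids share a step; truncate to the common length
    m <- min(length(pa$freqs), length(pb$freqs))
    trim <- function(p) {
      p$freqs <- p$freqs[seq_len(m)]; p$psd <- p$psd[seq_len(m)]
      p$phase <- p$phase[seq_len(m)]; p
    }
    out$lf_corr <- band_correlation(trim(pa), trim(pb), lf)
    out$hf_corr <- band_correlation(trim(pa), trim(pb), hf)
  }
  structure(out, class = "hrv_report")
}

#' @export
print.hrv_report <- function(x, ...) {
  cat("HRV report\n")
  cat(sprintf("  mean NN %.1f ms | SDNN %.2f ms | RMSSD %.2f ms | pNN50 %.3f\n",
              x$mean_nn, x$sdnn, x$rmssd, x$pnn50))
  if (!is.null(x$lf_corr))
    cat(sprintf("  vs reference: LF r = %.3f, HF r = %.3f\n",
                x$lf_corr, x$hf_corr))
  invisible(x)
}
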