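#' Restrict a spectral frame to a frequency band
#'
#' Truncates the frequency grid, PSD and phase of a frame to
#' `[f_lo, f_hi]`. The defaults bound the heart-rate search band,
#' 0.5-3 Hz (30-180 bpm), covering resting bradycardia through intense
#' exercise.
#'
#' @param frame A `"spectral_frame"`.
#' @param f_lo,f_hi Band edges in Hz; `0 <= f_lo < f_hi <= fs/2`.
#' @return A band-limited `"spectral_frame"`.
#' @export
band_limit <- function(frame, f_lo = 0.5, f_hi = 3.0) {
  stopifnot(inherits(frame, "spectral_frame"))
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= frame$fs / 2 + 1e-12))
    stop("invalid band: need 0 <= f_lo < f_hi <= fs/2")
  keep <- which(frame$freqs >= f_lo & frame$freqs <= f_hi)
  if (length(keep) == 0L) stop("band does not intersect the frequency grid")
  out <- frame
  out$freqs <- frame$freqs[keep]
  out$psd <- frame$psd[keep]
  out$phase <- frame$phase[keep]
  out
}

# indices of strict local maxima of y; plateaus credited to their lowest index
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Extract the top-k spectral peaks of a band-limited frame
#'
#' Finds strict local maxima of the PSD over the band-limited grid, imposes a
#' minimum peak separation (greedy, strongest first), and returns up to `k`
#' peaks ranked by descending power. The heart-rate pipeline uses `k = 3` for
#' the PPG spectrum and `k = 1` per accelerometer axis. Fewer than `k` local
#' maxima yield a smaller set; a flat or all-zero spectrum yields an empty
#' set.
#'
#' @param frame A band-limited `"spectral_frame"`.
#' @param k Maximum number of peaks (>= 1).
#' @param min_separation Minimum frequency distance between returned peaks
#'   (Hz); default 0.05 Hz (3 bpm) so one leakage lobe cannot supply several
#'   "peaks".
#' @return A `"peak_set"`: list with `window_index`, `time` and a data frame
#'   `peaks` with columns `freq`, `power`, `phase`, `rank`, `ma_flag`
#'   (initialized `FALSE`), sorted by descending power.
#' @export
top_peaks <- function(frame, k = 3, min_separation = 0.05) {
  stopifnot(inherits(frame, "spectral_frame"), k >= 1)
  idx <- local_maxima(frame$psd)
  sel <- integer(0)
  if (length(idx) > 0L) {
    idx <- idx[order(frame$psd[idx], decreasing = TRUE)]
    for (i in idx) {
      if (length(sel) == as.integer(k)) break
      if (all(abs(frame$freqs[i] - frame$freqs[sel]) >= min_separation))
        sel <- c(sel, i)
    }
  }
  peaks <- data.frame(
    freq = frame$freqs[sel],
    power = frame$psd[sel],
    phase = frame$phase[sel],
    rank = seq_along(sel),
    ma_flag = rep(FALSE, length(sel))
  )
  structure(list(window_index = frame$window_index, time = frame$time,
                 peaks = peaks),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set (window", x$window_index, "@", round(x$time, 3), "s):\n")
  print(x$peaks)
  invisible(x)
}
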