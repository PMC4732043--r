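#' Detect R peaks in an ECG channel (Pan-Tompkins stage chain)
#'
#' A faithful but compact implementation of the classic QRS detector:
#' band-pass 5-15 Hz (zero-phase Butterworth), five-point derivative,
#' squaring, 150 ms moving-window integration, then adaptive thresholding
#' with running signal/noise peak estimates
#' (`SPKI = 0.125*peak + 0.875*SPKI`, `NPKI` likewise,
#' `THR = NPKI + 0.25*(SPKI - NPKI)`) and a 200 ms refractory period.
#' Each accepted detection is refined to the local maximum of the squared
#' band-passed signal within +/-100 ms. Detections inside the `edge_guard`
#' zone at either end of the record are discarded: the zero-phase filter
#' output is unreliable within its transient there and yields misplaced
#' peaks.
#'
#' @param ecg Numeric ECG samples.
#' @param fs Sampling rate (Hz); >= 100 Hz recommended.
#' @param edge_guard Seconds ignored at each end of the record (default 0.3).
#' @return Numeric vector of R-peak times (s, relative to the first sample).
#' @export
detect_r_peaks <- function(ecg, fs, edge_guard = 0.3) {
  n <- length(ecg)
  if (n < fs) stop("ECG shorter than one second")
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, ecg - mean(ecg))
  d <- signal::filter(signal::Ma(c(1, 2, 0, -2, -1) * fs / 8), xf)
  sq <- as.numeric(d)^2
  mw <- as.integer(round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / mw, mw), sides = 1))
  integ[is.na(integ)] <- 0

  # candidate peaks of the integrated signal
  cand <- local_maxima(integ)
  if (length(cand) == 0L) stop("no detectable QRS peaks")
  # initialize thresholds from the first 2 s
  init <- integ[seq_len(min(n, 2L * as.integer(fs)))]
  spki <- max(init)
  npki <- mean(init) / 2
  refr <- as.integer(round(0.2 * fs))
  half <- as.integer(round(0.1 * fs))
  xf2 <- xf^2

  picks <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[i] > thr && (i - last) > refr) {
      # refine to the R peak in the band-passed signal
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      r <- lo + which.max(xf2[lo:hi]) - 1L
      if (length(picks) == 0L || (r - picks[length(picks)]) > refr) {
        picks <- c(picks, r)
        last <- i
        spki <- 0.125 * integ[i] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
  }
  tm <- (picks - 1L) / fs
  tm <- tm[tm >= edge_guard & tm <= (n - 1L) / fs - edge_guard]
  if (length(tm) == 0L) stop("no detectable QRS peaks")
  tm
}

#' Windowed reference heart rate from an ECG channel
#'
#' Detects R peaks with [detect_r_peaks()] and converts them to a per-window
#' reference heart rate on the same sliding-window grid as the PPG estimate:
#' for each window ending at `t(k)`, `HR_ref(k) = 60 / mean(RR)` over the
#' beat intervals falling entirely inside `[t(k) - T, t(k)]`. Windows without
#' a complete interval get `NA` and are dropped during track alignment.
#'
#' @param ecg Numeric ECG samples.
#' @param fs ECG sampling rate (Hz).
#' @param T Window length (s), default 8.
#' @param S Window shift (s), default 2.
#' @param t0 Time of the first ECG sample (s), default 0.
#' @param times Optional explicit window-end times (s); overrides `T`/`S`
#'   spacing (e.g. pass an estimate track's `time` column for exact
#'   alignment).
#' @return An `"hr_track"` with source `"REF"`.
#' @export
reference_hr_from_ecg <- function(ecg, fs, T = 8, S = 2, t0 = 0,
                                  times = NULL) {
  beats <- t0 + detect_r_peaks(ecg, fs)
  if (is.null(times)) {
    t_end <- t0 + (length(ecg) - 1) / fs
    times <- seq(t0 + T, t_end, by = S)
  }
  hr <- vapply(times, function(tk) {
    b <- beats[beats >= tk - T - 1e-9 & beats <= tk + 1e-9]
    if (length(b) < 2L) return(NA_real_)
    60 / mean(diff(b))
  }, numeric(1))
  ok <- !is.na(hr)
  structure(data.frame(time = times[ok], hr = hr[ok], source = "REF",
                       freq = hr[ok] / 60, peak_power = NA_real_),
            class = c("hr_track", "data.frame"))
}

# nearest-time inner join of two tracks; tol defaults to half the estimate's
# median time step
align_tracks <- function(est, ref, tol = NULL) {
  if (is.null(tol)) {
    step <- if (nrow(est) > 1L) stats::median(diff(est$time)) else 1
    tol <- step / 2
  }
  j <- vapply(est$time, function(t) {
    i <- which.min(abs(ref$time - t))
    if (abs(ref$time[i] - t) <= tol) i else NA_integer_
  }, integer(1))
  ok <- !is.na(j)
  if (!any(ok)) stop("tracks share no windows within the alignment tolerance")
  list(est = est$hr[ok], ref = ref$hr[j[ok]], n_dropped = sum(!ok))
}

#' Mean absolute heart-rate error (bpm)
#'
#' `E1 = mean_k |HR_est(k) - HR_ref(k)|` over windows shared by the two
#' tracks (nearest-time join within half a window shift).
#'
#' @param est,ref `"hr_track"`s on a common window grid.
#' @param tol Optional alignment tolerance (s).
#' @return E1 in bpm.
#' @export
error_e1 <- function(est, ref, tol = NULL) {
  al <- align_tracks(est, ref, tol)
  mean(abs(al$est - al$ref))
}

#' Mean relative absolute heart-rate error (percent)
#'
#' `E2 = mean_k |HR_est(k) - HR_ref(k)| / HR_ref(k) * 100`. The denominator
#' is always the reference.
#'
#' @inheritParams error_e1
#' @return E2 in percent.
#' @export
error_e2 <- function(est, ref, tol = NULL) {
  al <- align_tracks(est, ref, tol)
  if (any(al$ref == 0)) stop("reference heart rate contains zero")
  mean(abs(al$est - al$ref) / al$ref) * 100
}

#' Per-window error report against a reference track
#'
#' @inheritParams error_e1
#' @param exclude_spline Drop `SPLINE`-source windows from the comparison
#'   (default `FALSE`; offline results usually include interpolated regions).
#' @return An `"error_report"`: list with `e1` (bpm), `e2` (percent),
#'   `per_window` (absolute differences, bpm), `W` (window count),
#'   `n_dropped` (estimate windows without a reference partner).
#' @export
hr_error_report <- function(est, ref, tol = NULL, exclude_spline = FALSE) {
  if (exclude_spline) est <- est[est$source != "SPLINE", , drop = FALSE]
  al <- align_tracks(est, ref, tol)
  per <- abs(al$est - al$ref)
  structure(list(e1 = mean(per), e2 = mean(per / al$ref) * 100,
                 per_window = per, W = length(per),
                 n_dropped = al$n_dropped),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("E1 = %.3f bpm, E2 = %.3f%% over %d windows (%d unmatched)\n",
              x$e1, x$e2, x$W, x$n_dropped))
  invisible(x)
}
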