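# Brute-force single-frequency DFT: X(f) = sum_n x[n] w[n] exp(-2*pi*i*f*n/fs)
dft_at <- function(x, fs, f) {
  n <- seq_along(x) - 1
  sum(x * exp(-2i * pi * f * n / fs))
}

# Independent periodogram oracle: explicit DFT sums on the same grid and with
# the same one-sided ENBW-normalized scaling contract as the fast path.
dft_oracle <- function(segment, fs, freq_step, taper = "hamming",
                       detrend = TRUE) {
  n <- length(segment)
  tw <- taper_window(n, taper)
  x <- if (detrend) segment - mean(segment) else segment
  xw <- x * tw$w
  nfft <- max(n, as.integer(round(fs / freq_step)))
  nkeep <- floor(nfft / 2) + 1L
  freqs <- (seq_len(nkeep) - 1) * fs / nfft
  X <- vapply(freqs, function(f) dft_at(xw, fs, f), complex(1))
  g <- rep(2, nkeep)
  g[1] <- 1
  if (nfft %% 2 == 0) g[nkeep] <- 1
  list(freqs = freqs,
       psd = g * Mod(X)^2 / (fs * sum(tw$w^2) * tw$enbw),
       phase = Arg(X))
}

# exhaustive local-maxima scan (interior strict maxima, plateaus credited to
# their first sample), used as the peak-counting oracle
scan_local_maxima <- function(y) {
  out <- integer(0)
  for (i in 2:(length(y) - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) out <- c(out, i)
  }
  out
}

# sampled sinusoid helper
tone <- function(f, fs, dur, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * (0:(round(dur * fs) - 1)) / fs + phase)
}
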