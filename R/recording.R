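#' Multichannel wearable recording
#'
#' Container for a synchronized wearable recording: one PPG channel, three
#' accelerometer axes, and (optionally) a reference ECG channel, each with its
#' own sampling rate. PPG and accelerometer channels must cover the same time
#' span to within one sample period; a longer mismatch is an error.
#'
#' @param ppg Numeric vector, photoplethysmogram samples (arbitrary units).
#' @param acc_x,acc_y,acc_z Numeric vectors, accelerometer axes (arbitrary
#'   acceleration units).
#' @param fs_ppg,fs_acc Sampling rates (Hz) of the PPG and accelerometer
#'   channels.
#' @param ecg Optional numeric vector of ECG samples; `NULL` if absent.
#' @param fs_ecg Sampling rate (Hz) of the ECG channel; required when `ecg`
#'   is given.
#' @param t0 Start time in seconds (default 0); all channels share it.
#' @return An object of class `"ppg_recording"`: a list with the channel
#'   vectors, per-channel sampling rates and `t0`.
#' @export
recording <- function(ppg, acc_x, acc_y, acc_z, fs_ppg, fs_acc,
                      ecg = NULL, fs_ecg = NULL, t0 = 0) {
  chans <- list(ppg = ppg, acc_x = acc_x, acc_y = acc_y, acc_z = acc_z)
  for (nm in names(chans)) {
    x <- chans[[nm]]
    if (length(x) == 0L) stop("channel ", nm, " is empty")
    if (!is.numeric(x)) stop("channel ", nm, " is not numeric")
  }
  if (!is.numeric(fs_ppg) || fs_ppg <= 0) stop("fs_ppg must be > 0")
  if (!is.numeric(fs_acc) || fs_acc <= 0) stop("fs_acc must be > 0")
  if (!is.null(ecg)) {
    if (length(ecg) == 0L) stop("channel ecg is empty")
    if (is.null(fs_ecg) || fs_ecg <= 0) stop("fs_ecg must be > 0 when ecg is present")
  }

  # spans must agree within one sample period; tolerate by truncating to the
  # common span
  span_ppg <- length(ppg) / fs_ppg
  span_acc <- length(acc_x) / fs_acc
  tol <- max(1 / fs_ppg, 1 / fs_acc)
  if (abs(span_ppg - span_acc) > tol + 1e-12)
    stop("PPG and accelerometer spans differ by more than one sample period (",
         signif(span_ppg, 6), " s vs ", signif(span_acc, 6), " s)")
  span <- min(span_ppg, span_acc)
  n_ppg <- min(length(ppg), floor(span * fs_ppg + 1e-9))
  n_acc <- min(length(acc_x), floor(span * fs_acc + 1e-9))
  na <- vapply(chans[c("acc_x", "acc_y", "acc_z")], length, integer(1))
  if (any(na != na[1])) stop("accelerometer axes have unequal lengths")

  structure(list(
    ppg = as.numeric(ppg[seq_len(n_ppg)]),
    acc_x = as.numeric(acc_x[seq_len(n_acc)]),
    acc_y = as.numeric(acc_y[seq_len(n_acc)]),
    acc_z = as.numeric(acc_z[seq_len(n_acc)]),
    ecg = if (is.null(ecg)) NULL else as.numeric(ecg),
    fs_ppg = as.numeric(fs_ppg),
    fs_acc = as.numeric(fs_acc),
    fs_ecg = if (is.null(ecg)) NULL else as.numeric(fs_ecg),
    t0 = as.numeric(t0)
  ), class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat("ppg_recording:", round(length(x$ppg) / x$fs_ppg, 2), "s\n")
  cat("  ppg:", length(x$ppg), "samples @", x$fs_ppg, "Hz\n")
  cat("  acc:", length(x$acc_x), "samples @", x$fs_acc, "Hz (x,y,z)\n")
  if (!is.null(x$ecg))
    cat("  ecg:", length(x$ecg), "samples @", x$fs_ecg, "Hz\n")
  invisible(x)
}

#' Read a recording from a delimited text file
#'
#' Reads a CSV/TSV file with a header row and maps its columns onto the
#' recording channels. The channel map gives, for each channel, the column
#' name that holds it; sampling rates come from the layout. ECG may live in
#' the same file or in a separate file (at its own rate) named by
#' `layout$ecg_path`. A JSON sidecar (same path with extension `.json`) is
#' read automatically when `layout` is `NULL`.
#'
#' @param path Path to the delimited file.
#' @param layout A list with elements `ppg`, `acc_x`, `acc_y`, `acc_z`
#'   (column names), optional `ecg` (column name) or `ecg_path`
#'   (separate file with a single `ecg` column), `fs_ppg`, `fs_acc`,
#'   optional `fs_ecg`, optional `sep` (default ","), optional `t0`.
#'   When `NULL`, read from `<path>.json`.
#' @return A [recording()].
#' @export
load_recording <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(layout)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no layout given and no sidecar found at ", sidecar)
    layout <- jsonlite::fromJSON(sidecar)
  }
  sep <- if (is.null(layout$sep)) "," else layout$sep
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)

  pick <- function(field) {
    col <- layout[[field]]
    if (is.null(col)) col <- field
    if (!col %in% names(df)) stop("channel ", field, " not found (column '",
                                  col, "')")
    x <- df[[col]]
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(x))))[1]
      stop("non-numeric samples in channel ", field, " at row ", bad)
    }
    x
  }

  ecg <- NULL
  fs_ecg <- NULL
  if (!is.null(layout$ecg_path)) {
    edf <- utils::read.table(layout$ecg_path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    if (!"ecg" %in% names(edf)) stop("channel ecg not found in ", layout$ecg_path)
    ecg <- edf$ecg
    fs_ecg <- layout$fs_ecg
  } else if (!is.null(layout$ecg) && layout$ecg %in% names(df)) {
    ecg <- pick("ecg")
    fs_ecg <- layout$fs_ecg
  }

  recording(ppg = pick("ppg"),
            acc_x = pick("acc_x"), acc_y = pick("acc_y"), acc_z = pick("acc_z"),
            fs_ppg = layout$fs_ppg, fs_acc = layout$fs_acc,
            ecg = ecg, fs_ecg = fs_ecg,
            t0 = if (is.null(layout$t0)) 0 else layout$t0)
}

#' Write a recording to a delimited text file with a JSON sidecar
#'
#' PPG and accelerometer channels go into `path` (columns `ppg, acc_x, acc_y,
#' acc_z`); ECG, when present, into `<path stem>_ecg.csv`. The layout needed
#' by [load_recording()] is written to `<path>.json`. Samples are written
#' with 12 significant digits so a round trip is exact at double-text
#' precision.
#'
#' @param rec A [recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ppg_recording"))
  if (rec$fs_ppg != rec$fs_acc)
    stop("write_recording requires a common PPG/ACC rate; downsample first")
  df <- data.frame(ppg = rec$ppg, acc_x = rec$acc_x, acc_y = rec$acc_y,
                   acc_z = rec$acc_z)
  fmt <- function(d) {
    d[] <- lapply(d, function(col) sprintf("%.12g", col))
    d
  }
  utils::write.csv(fmt(df), path, row.names = FALSE, quote = FALSE)
  layout <- list(ppg = "ppg", acc_x = "acc_x", acc_y = "acc_y", acc_z = "acc_z",
                 fs_ppg = rec$fs_ppg, fs_acc = rec$fs_acc, t0 = rec$t0)
  if (!is.null(rec$ecg)) {
    epath <- paste0(sub("\\.[^.]*$", "", path), "_ecg.csv")
    utils::write.csv(fmt(data.frame(ecg = rec$ecg)), epath,
                     row.names = FALSE, quote = FALSE)
    layout$ecg_path <- epath
    layout$fs_ecg <- rec$fs_ecg
  }
  jsonlite::write_json(layout, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Anti-alias FIR low-pass: Hamming-windowed linear-phase design with passband
# edge at 0.4*target_fs and stopband edge at 0.5*target_fs (the new Nyquist),
# applied forward-backward for zero phase.
antialias_fir <- function(fs, target_fs) {
  # transition bandwidth 0.1*target_fs Hz; Hamming window needs ~3.3/N of
  # normalized (cycles/sample) width
  n <- 2L * ceiling(3.3 * fs / (0.1 * target_fs) / 2)
  wc <- 0.45 * target_fs / (fs / 2)
  b <- signal::fir1(n, wc, type = "low")
  b / sum(b)  # unit DC gain so constants pass through exactly
}

#' Down-sample PPG and accelerometer channels to the analysis rate
#'
#' Applies a zero-phase anti-alias FIR low-pass (passband edge at
#' `0.4 * target_fs`, stopband at the new Nyquist) to each PPG/ACC channel,
#' then resamples onto the target time grid (direct decimation for integer
#' rate ratios, cubic-spline sampling otherwise). The ECG channel, used only
#' for reference beat detection, is left at its native rate.
#'
#' @param rec A [recording()].
#' @param target_fs Target analysis rate in Hz (default 20, which covers
#'   heart rates up to 240 bpm). Must not exceed any PPG/ACC channel rate.
#' @return A [recording()] with `fs_ppg == fs_acc == target_fs`.
#' @export
downsample <- function(rec, target_fs = 20) {
  stopifnot(inherits(rec, "ppg_recording"))
  if (target_fs > rec$fs_ppg || target_fs > rec$fs_acc)
    stop("target_fs (", target_fs, " Hz) exceeds a channel sampling rate")

  ds1 <- function(x, fs) {
    if (fs == target_fs) return(x)
    b <- antialias_fir(fs, target_fs)
    # reflect ends before zero-phase filtering to suppress edge transients
    np <- min(length(b), length(x) - 1L)
    xp <- c(2 * x[1] - x[(np + 1):2], x,
            2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)])
    xf <- signal::filtfilt(signal::Ma(b), xp)
    xf <- xf[(np + 1):(np + length(x))]
    ratio <- fs / target_fs
    if (abs(ratio - round(ratio)) < 1e-9) {
      xf[seq(1L, length(xf), by = as.integer(round(ratio)))]
    } else {
      t_in <- (seq_along(xf) - 1) / fs
      n_out <- floor((length(xf) - 1) * target_fs / fs) + 1
      t_out <- (seq_len(n_out) - 1) / target_fs
      stats::spline(t_in, xf, xout = t_out, method = "fmm")$y
    }
  }

  recording(ppg = ds1(rec$ppg, rec$fs_ppg),
            acc_x = ds1(rec$acc_x, rec$fs_acc),
            acc_y = ds1(rec$acc_y, rec$fs_acc),
            acc_z = ds1(rec$acc_z, rec$fs_acc),
            fs_ppg = target_fs, fs_acc = target_fs,
            ecg = rec$ecg, fs_ecg = rec$fs_ecg, t0 = rec$t0)
}
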