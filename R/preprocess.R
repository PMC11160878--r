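#' Preprocess a recording into clean fixed-length windows
#'
#' Runs the standard cleaning chain ahead of feature extraction, in this
#' fixed order: zero-phase high-pass (2nd-order Butterworth) to remove
#' baseline drift; antialiased downsampling to `target_rate` (zero-phase
#' low-pass at 0.4 x `target_rate` followed by decimation, or polyphase
#' resampling for non-integer ratios); segmentation into contiguous
#' non-overlapping windows of `window_s` seconds (trailing partial window
#' dropped); and outlier repair, where any sample deviating from the
#' channel's recording-wide mean by more than `outlier_sd` recording-wide
#' standard deviations is replaced by the median of its 5-second window.
#' (The detection reference must be recording-wide: a lone spike inflates
#' a short window's own SD so much that its within-window `|z|` can never
#' exceed `sqrt(n_samples)`, and a 25-SD rule would be inert.)
#'
#' @param rec a [recording()].
#' @param target_rate output rate in Hz; must not exceed the input rate and
#'   `window_s * target_rate` must be an integer.
#' @param highpass_hz high-pass cutoff in Hz; 0 disables.
#' @param window_s window length in seconds.
#' @param outlier_sd repair threshold in window standard deviations;
#'   `Inf` disables repair.
#' @return A `segmented_recording`: list with `windows` (array
#'   n_windows x n_channels x samples), `rate`, `window_s`, `channels`,
#'   `source_id`, `start_s` (window start times), `outlier_sd`, and
#'   `signal` (the filtered, downsampled continuous matrix, kept so extra
#'   windows can later be cut at sub-window offsets).
#' @export
preprocess <- function(rec, target_rate = 100, highpass_hz = 2,
                       window_s = 5, outlier_sd = 25) {
  stopifnot(inherits(rec, "recording"))
  if (target_rate > rec$rate)
    stop("target_rate exceeds the recording rate")
  wlen <- window_s * target_rate
  if (abs(wlen - round(wlen)) > 1e-9)
    stop("window_s * target_rate must be an integer sample count")
  wlen <- as.integer(round(wlen))

  sig <- rec$signal
  if (highpass_hz > 0) {
    hp <- signal::butter(2, highpass_hz / (rec$rate / 2), type = "high")
    pad <- ceiling(3 * rec$rate / highpass_hz)
    sig <- apply(sig, 2, function(x) pad_filtfilt(hp, x, pad))
  }
  if (target_rate < rec$rate) {
    ratio <- rec$rate / target_rate
    # zero-phase FIR antialias at 0.4 x target rate, then decimate
    ord <- min(2 * floor(5 * ratio), 512)
    aa <- signal::fir1(ord, 0.4 * target_rate / (rec$rate / 2))
    sig <- apply(sig, 2, function(x) pad_filtfilt(aa, x, 3 * (ord + 1)))
    if (abs(ratio - round(ratio)) < 1e-9) {
      sig <- sig[seq(1, nrow(sig), by = round(ratio)), , drop = FALSE]
    } else {
      frac <- .ratio_pq(target_rate, rec$rate)
      sig <- apply(sig, 2, function(x)
        signal::resample(x, frac[1], frac[2]))
    }
  }

  n_win <- floor(nrow(sig) / wlen)
  if (n_win < 1)
    warning("recording shorter than one window; empty segmentation")
  # outlier detection is referenced to recording-wide per-channel
  # statistics (a lone spike inflates a 5-s window SD so much that a
  # per-window threshold of 25 SD could never fire); the replacement
  # value is the local window median
  rc <- colMeans(sig)
  rs <- apply(sig, 2, sd)
  windows <- array(
    0, dim = c(n_win, ncol(sig), wlen),
    dimnames = list(NULL, rec$channels, NULL)
  )
  for (w in seq_len(n_win)) {
    seg <- t(sig[((w - 1) * wlen + 1):(w * wlen), , drop = FALSE])
    windows[w, , ] <- repair_outliers(seg, outlier_sd, rc, rs)
  }
  structure(
    list(windows = windows, rate = target_rate, window_s = window_s,
         channels = rec$channels, source_id = rec$source_id,
         start_s = (seq_len(n_win) - 1) * window_s,
         outlier_sd = outlier_sd, repair_center = rc, repair_scale = rs,
         signal = sig),
    class = "segmented_recording"
  )
}

# Zero-phase filtering with odd end-reflection padding, so filter
# transients fall in the (discarded) pad rather than the signal.
pad_filtfilt <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(filt, c(front, x, back))
  y[(pad + 1):(pad + n)]
}

# seg: channels x samples matrix for one window; repair each channel.
# center/scale: recording-wide per-channel reference statistics.
repair_outliers <- function(seg, outlier_sd, center, scale) {
  if (!is.finite(outlier_sd)) return(seg)
  for (ch in seq_len(nrow(seg))) {
    if (is.na(scale[ch]) || scale[ch] == 0) next
    x <- seg[ch, ]
    bad <- abs(x - center[ch]) > outlier_sd * scale[ch]
    if (any(bad)) seg[ch, bad] <- median(x)
  }
  seg
}

.ratio_pq <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  # scale to integers first (rates may be non-integer)
  k <- 1
  while (abs(p * k - round(p * k)) > 1e-9 || abs(q * k - round(q * k)) > 1e-9)
    k <- k * 10
  p <- round(p * k); q <- round(q * k)
  d <- g(p, q)
  c(p / d, q / d)
}

#' @export
print.segmented_recording <- function(x, ...) {
  cat(sprintf(
    "<segmented_recording '%s'> %d windows x %d channel(s) x %d samples (%g s @ %g Hz)\n",
    x$source_id, dim(x$windows)[1], dim(x$windows)[2], dim(x$windows)[3],
    x$window_s, x$rate))
  invisible(x)
}

#' Number of windows in a segmentation
#' @param seg a `segmented_recording`.
#' @return window count.
#' @export
n_windows <- function(seg) dim(seg$windows)[1]

#' Write / read a segmented-recording HDF5 store
#'
#' Layout: `/windows` (n_windows x channels x samples), `/start_s`, and
#' root attributes `rate`, `window_s`, `channels`, `source_id`,
#' `outlier_sd`. The continuous signal is stored under `/signal`
#' (samples x channels) so sliding-window upsampling remains possible
#' after a round trip.
#'
#' @param seg a `segmented_recording`.
#' @param path output path (overwritten).
#' @return `write_segments` returns `path` invisibly; `read_segments`
#'   returns the `segmented_recording`.
#' @export
write_segments <- function(seg, path) {
  stopifnot(inherits(seg, "segmented_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(seg$windows, path, "windows")
  rhdf5::h5write(seg$start_s, path, "start_s")
  rhdf5::h5write(seg$signal, path, "signal")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::h5writeAttribute(seg$rate, fid, "rate")
  rhdf5::h5writeAttribute(seg$window_s, fid, "window_s")
  rhdf5::h5writeAttribute(seg$channels, fid, "channels")
  rhdf5::h5writeAttribute(as.character(seg$source_id), fid, "source_id")
  rhdf5::h5writeAttribute(seg$outlier_sd, fid, "outlier_sd")
  rhdf5::h5writeAttribute(seg$repair_center, fid, "repair_center")
  rhdf5::h5writeAttribute(seg$repair_scale, fid, "repair_scale")
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  at <- rhdf5::h5readAttributes(path, "/")
  w <- rhdf5::h5read(path, "windows")
  dimnames(w) <- list(NULL, as.character(at$channels), NULL)
  structure(
    list(windows = w, rate = as.numeric(at$rate),
         window_s = as.numeric(at$window_s),
         channels = as.character(at$channels),
         source_id = as.character(at$source_id),
         start_s = as.numeric(rhdf5::h5read(path, "start_s")),
         outlier_sd = as.numeric(at$outlier_sd),
         repair_center = as.numeric(at$repair_center),
         repair_scale = as.numeric(at$repair_scale),
         signal = rhdf5::h5read(path, "signal")),
    class = "segmented_recording"
  )
}
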