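#' Multichannel recording container
#'
#' A `recording` holds a continuous multichannel signal as a numeric matrix
#' with one column per channel, together with its sampling rate and channel
#' names. Amplitudes are in whatever unit the acquisition system produced
#' (typically microvolts); nothing downstream depends on the unit because
#' feature matrices are z-scored before modelling.
#'
#' @param signal numeric matrix, samples x channels (a vector is treated as
#'   one channel).
#' @param rate sampling rate in Hz (> 0).
#' @param channels character vector of channel names; defaults to the
#'   matrix column names or `ch1, ch2, ...`.
#' @param source_id identifier of the recording (file stem, animal id, ...).
#' @return An object of class `recording` with fields `signal`, `rate`,
#'   `channels`, `source_id`.
#' @export
recording <- function(signal, rate, channels = NULL, source_id = "recording") {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  stopifnot(is.matrix(signal), is.numeric(signal))
  if (ncol(signal) < 1) stop("recording needs at least one channel")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a single positive number")
  if (is.null(channels)) {
    channels <- colnames(signal)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(signal)))
  }
  if (length(channels) != ncol(signal))
    stop("channel name count does not match signal columns")
  colnames(signal) <- channels
  structure(
    list(signal = signal, rate = as.numeric(rate),
         channels = as.character(channels), source_id = source_id),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s'> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$source_id, ncol(x$signal), nrow(x$signal), x$rate,
              nrow(x$signal) / x$rate))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [recording()].
#' @return duration in seconds.
#' @export
duration_s <- function(rec) nrow(rec$signal) / rec$rate

#' Load a recording from disk
#'
#' Reads either an HDF5 store (dataset `/signal` laid out channels x
#' samples, with root attributes `rate`, `channels`, `source_id`) or a
#' standard 16-bit EDF file. For EDF, an explicit channel subset can be
#' requested by name; a missing requested channel is an error, which is how
#' recordings with an incompatible montage are rejected.
#'
#' @param path path to the file.
#' @param format `"hdf5"` or `"edf"`; guessed from the extension when
#'   missing.
#' @param channels optional character vector of channel names to select
#'   (order preserved as given).
#' @return A [recording()].
#' @export
load_recording <- function(path, format = NULL, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", h5 = "hdf5", hdf5 = "hdf5",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  format <- match.arg(format, c("hdf5", "edf"))
  rec <- switch(format, hdf5 = read_store(path), edf = read_edf(path))
  if (!is.null(channels)) {
    missing <- setdiff(channels, rec$channels)
    if (length(missing))
      stop("channel(s) not present in recording: ",
           paste(missing, collapse = ", "))
    rec <- recording(rec$signal[, channels, drop = FALSE], rec$rate,
                     channels, rec$source_id)
  }
  rec
}

#' Write / read a recording HDF5 store
#'
#' The store layout is a single dataset `/signal` (channels x samples,
#' doubles) with root attributes `rate` (Hz), `channels` and `source_id`.
#'
#' @param rec a [recording()].
#' @param path output path (overwritten).
#' @return `write_store` returns `path` invisibly; `read_store` returns a
#'   [recording()].
#' @export
write_store <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(t(rec$signal), path, "signal")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::h5writeAttribute(rec$rate, fid, "rate")
  rhdf5::h5writeAttribute(rec$channels, fid, "channels")
  rhdf5::h5writeAttribute(as.character(rec$source_id), fid, "source_id")
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  sig <- rhdf5::h5read(path, "signal")
  at <- rhdf5::h5readAttributes(path, "/")
  recording(t(sig), as.numeric(at$rate), as.character(at$channels),
            if (!is.null(at$source_id)) as.character(at$source_id) else "recording")
}

#' Read per-window seizure labels from an annotation CSV
#'
#' Two schemas are accepted: event rows with columns `start_s`, `stop_s`
#' (seconds, optionally `source_id`), or a per-window binary column named
#' `label`. Event times are rounded to the nearest window boundary and
#' rasterized to a 0/1 vector aligned with the base segmentation; an event
#' whose rounded start equals its rounded stop labels no window.
#'
#' @param path CSV path.
#' @param n_windows number of windows in the segmentation the labels must
#'   align to.
#' @param window_s window length in seconds.
#' @return Integer vector of 0/1 labels, length `n_windows`.
#' @export
read_labels <- function(path, n_windows, window_s = 5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("label" %in% names(df)) {
    lab <- as.integer(df$label)
    if (length(lab) != n_windows)
      stop("per-window label column has length ", length(lab),
           ", expected ", n_windows)
    if (!all(lab %in% c(0L, 1L))) stop("labels must be 0/1")
    return(lab)
  }
  if (!all(c("start_s", "stop_s") %in% names(df)))
    stop("annotation CSV needs either a 'label' column or 'start_s'/'stop_s'")
  events_to_labels_s(df$start_s, df$stop_s, n_windows, window_s)
}

# Rasterize event times (seconds) to per-window labels, rounding each
# endpoint independently to the nearest window boundary.
events_to_labels_s <- function(start_s, stop_s, n_windows, window_s) {
  lab <- integer(n_windows)
  if (length(start_s) == 0) return(lab)
  if (any(stop_s < start_s)) stop("event stop before start")
  if (any(start_s > n_windows * window_s))
    stop("event starts beyond recording end")
  sw <- round(start_s / window_s)
  ew <- pmin(round(stop_s / window_s), n_windows)
  for (i in seq_along(sw)) {
    if (ew[i] > sw[i]) lab[(sw[i] + 1):ew[i]] <- 1L
  }
  lab
}
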