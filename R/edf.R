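# Minimal standard EDF (16-bit) reader/writer. Covers the plain continuous
# case used by scalp-EEG archives: one fixed record duration, all requested
# channels sampled at the same rate, digital values scaled linearly to
# physical units. No EDF+ annotations.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to a standard EDF file
#'
#' Signals are scaled per channel to the full 16-bit digital range. The
#' record duration is 1 second, so the sampling rate must be an integer;
#' a trailing partial record is dropped.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  rate <- rec$rate
  if (rate != round(rate)) stop("EDF writer requires an integer sampling rate")
  ns <- ncol(rec$signal)
  n_rec <- floor(nrow(rec$signal) / rate)
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  pmin_ <- apply(rec$signal, 2, min)
  pmax_ <- apply(rec$signal, 2, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad(rec$source_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  fld(rec$channels, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(pmin_, digits = 7, width = 8), 8)
  fld(formatC(pmax_, digits = 7, width = 8), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(rate, ns), 8)
  fld(rep("", ns), 32)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    for (ch in seq_len(ns)) {
      dig <- round((rec$signal[idx, ch] - pmin_[ch]) / gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a standard EDF file
#'
#' @param path EDF path.
#' @param channels optional channel subset, selected by (trimmed) label in
#'   the order given; an absent channel is an error.
#' @return A [recording()]. All selected channels must share one sampling
#'   rate.
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                   # version
  rd(80)                                  # patient
  source_id <- rd(80)
  rd(8); rd(8)                            # date, time
  rd(8)                                   # header bytes
  rd(44)                                  # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)           # reserved
  sel <- seq_len(ns)
  if (!is.null(channels)) {
    sel <- match(channels, labels)
    if (anyNA(sel))
      stop("channel(s) not present in EDF: ",
           paste(channels[is.na(sel)], collapse = ", "))
  }
  if (length(unique(spr[sel])) != 1)
    stop("selected EDF channels have differing sampling rates")
  rate <- spr[sel][1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- matrix(0, nrow = n_rec * spr[sel][1], ncol = length(sel))
  for (r in seq_len(n_rec)) {
    rec_dat <- vector("list", ns)
    for (ch in seq_len(ns))
      rec_dat[[ch]] <- readBin(con, "integer", n = spr[ch], size = 2,
                               signed = TRUE, endian = "little")
    for (j in seq_along(sel)) {
      ch <- sel[j]
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      out[idx, j] <- (rec_dat[[ch]] - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  recording(out, rate, labels[sel], source_id)
}

#' Standard 18-channel bipolar scalp-EEG montage
#'
#' The longitudinal-bipolar channel set common across subjects in widely
#' used paediatric scalp-EEG archives.
#'
#' @return Character vector of 18 channel names.
#' @export
scalp_montage_18 <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1", "FP1-F3", "F3-C3", "C3-P3",
    "P3-O1", "FZ-CZ", "CZ-PZ", "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2")
}
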