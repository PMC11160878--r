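#' Feature specification
#'
#' Names the per-window features to compute. `single` features are computed
#' on each channel, `cross` features on each channel pair. The `"power"`
#' entry expands to one column per frequency band in `bands`.
#'
#' Single-channel features and their definitions (window `x`, n samples):
#' \describe{
#'   \item{autocorrelation}{unnormalized lag-1 product sum
#'     \eqn{\sum_i x_i x_{i+1}}}
#'   \item{line_length}{\eqn{\sum_i |x_i - x_{i-1}|}}
#'   \item{rms}{\eqn{\sqrt{\mathrm{mean}(x^2)}}}
#'   \item{mad}{mean absolute deviation \eqn{\mathrm{mean}|x - \bar x|}}
#'   \item{variance, std}{population variance and its square root}
#'   \item{power}{integrated single-window periodogram over each band,
#'     scaled so the total over all positive frequencies matches the
#'     window variance (Parseval)}
#'   \item{energy}{\eqn{\sum_i x_i^2}}
#'   \item{envelope}{mean magnitude of the analytic (Hilbert) signal}
#' }
#' Cross-channel features: `cross_correlation` (zero-lag Pearson r),
#' `covariance` (population), `abs_covariance`.
#'
#' @param single character vector of single-channel feature names.
#' @param cross character vector of cross-channel feature names.
#' @param bands list of `c(lo, hi)` Hz pairs for band power; names, when
#'   given, label the columns (`power_<name>`), otherwise
#'   `power_<lo>_<hi>` is used.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(single, cross = character(0), bands = list()) {
  single <- match.arg(single, .single_features, several.ok = TRUE)
  if (length(cross))
    cross <- match.arg(cross, .cross_features, several.ok = TRUE)
  for (b in bands) {
    if (length(b) != 2 || b[1] >= b[2])
      stop("each band must be c(lo, hi) with lo < hi")
  }
  if ("power" %in% single && !length(bands))
    stop("'power' requested but no bands given")
  structure(list(single = single, cross = cross, bands = bands),
            class = "feature_spec")
}

.single_features <- c("autocorrelation", "line_length", "rms", "mad",
                      "variance", "std", "power", "energy", "envelope")
.cross_features <- c("cross_correlation", "covariance", "abs_covariance")

#' Built-in feature specifications
#'
#' `mouse_feature_spec()` is the 2-channel LFP configuration: 9
#' single-channel features (including one broad 2-40 Hz power band) plus
#' the 3 cross-channel features on the single channel pair, i.e. 21
#' columns for 2 channels. `human_feature_spec()` is the 18-channel scalp
#' EEG configuration: no autocorrelation, no cross-channel features, and
#' power split into five bands (delta 1-4, theta 4.2-8, alpha 8.2-12,
#' beta 12.2-30, gamma 30.2-55 Hz), i.e. 12 features per channel and 216
#' columns for 18 channels.
#'
#' @return A [feature_spec()].
#' @export
mouse_feature_spec <- function() {
  feature_spec(
    single = c("autocorrelation", "line_length", "rms", "mad", "variance",
               "std", "power", "energy", "envelope"),
    cross = c("cross_correlation", "covariance", "abs_covariance"),
    bands = list(c(2, 40))
  )
}

#' @rdname mouse_feature_spec
#' @export
human_feature_spec <- function() {
  feature_spec(
    single = c("line_length", "rms", "variance", "std", "mad", "energy",
               "envelope", "power"),
    cross = character(0),
    bands = list(delta = c(1, 4), theta = c(4.2, 8), alpha = c(8.2, 12),
                 beta = c(12.2, 30), gamma = c(30.2, 55))
  )
}

band_labels <- function(bands) {
  nm <- names(bands)
  vapply(seq_along(bands), function(i) {
    if (!is.null(nm) && nzchar(nm[i])) paste0("power_", nm[i])
    else paste0("power_", format(bands[[i]][1]), "_", format(bands[[i]][2]))
  }, "")
}

# Expanded single-channel feature names for a spec (power -> bands).
single_feature_names <- function(spec) {
  unlist(lapply(spec$single, function(f)
    if (f == "power") band_labels(spec$bands) else f), use.names = FALSE)
}

# Analytic signal via FFT: zero negative frequencies, double positives.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# One-sided integrated periodogram over [lo, hi] Hz. Scaled so that the
# sum over all positive-frequency bins equals mean(x^2) minus the DC term,
# i.e. band powers partition the window variance.
band_power <- function(X2, n, rate, lo, hi) {
  k <- 1:floor(n / 2)                    # positive-frequency bins
  freq <- k * rate / n
  scale <- ifelse(n %% 2 == 0 & k == n / 2, 1, 2)   # Nyquist bin not doubled
  sel <- freq >= lo & freq <= hi
  sum(scale[sel] * X2[k[sel] + 1]) / n^2
}

#' Compute single-channel features for one window
#'
#' See [feature_spec()] for the definitions.
#'
#' @param window numeric sample vector (>= 2 samples).
#' @param rate sampling rate in Hz.
#' @param spec a [feature_spec()].
#' @return Named numeric vector, one value per (expanded) feature.
#' @export
single_channel_features <- function(window, rate, spec) {
  n <- length(window)
  if (n < 2) stop("window must have at least 2 samples")
  if (length(spec$bands) &&
      max(vapply(spec$bands, `[`, 0, 2)) > rate / 2)
    stop("band edge above Nyquist frequency")
  m <- mean(window)
  need_fft <- any(c("power", "envelope") %in% spec$single)
  if (need_fft) {
    X <- fft(window)
    X2 <- Mod(X)^2
  }
  out <- numeric(0)
  for (f in spec$single) {
    v <- switch(
      f,
      autocorrelation = sum(window[-n] * window[-1]),
      line_length = sum(abs(diff(window))),
      rms = sqrt(mean(window^2)),
      mad = mean(abs(window - m)),
      variance = mean((window - m)^2),
      std = sqrt(mean((window - m)^2)),
      energy = sum(window^2),
      envelope = {
        h <- numeric(n)
        if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
        else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
        mean(Mod(fft(X * h, inverse = TRUE) / n))
      },
      power = vapply(spec$bands, function(b)
        band_power(X2, n, rate, b[1], b[2]), 0)
    )
    out <- c(out, v)
  }
  names(out) <- single_feature_names(spec)
  out
}

#' Compute cross-channel features for one window pair
#'
#' `cross_correlation` is the zero-lag Pearson correlation (0 with a
#' warning when either channel has zero variance), `covariance` the
#' population covariance, `abs_covariance` its absolute value.
#'
#' @param w1,w2 numeric sample vectors of equal length (>= 2).
#' @param spec a [feature_spec()]; only its `cross` entry is used.
#' @return Named numeric vector.
#' @export
cross_channel_features <- function(w1, w2, spec = NULL) {
  if (length(w1) != length(w2)) stop("windows must have equal length")
  if (length(w1) < 2) stop("windows must have at least 2 samples")
  feats <- if (is.null(spec)) .cross_features else spec$cross
  m1 <- mean(w1); m2 <- mean(w2)
  cv <- mean((w1 - m1) * (w2 - m2))
  out <- vapply(feats, function(f) switch(
    f,
    cross_correlation = {
      s1 <- sd(w1); s2 <- sd(w2)
      if (s1 == 0 || s2 == 0) {
        warning("zero-variance channel; cross-correlation reported as 0")
        0
      } else cor(w1, w2)
    },
    covariance = cv,
    abs_covariance = abs(cv)
  ), 0)
  names(out) <- feats
  out
}

#' Build the window x feature matrix for a segmented recording
#'
#' Columns are ordered deterministically: for each channel in recording
#' order, the single-channel features in spec order (band powers expanded
#' in band order); then for each channel pair in `combn` order, the
#' cross-channel features in spec order. Column names are
#' `<feature>_<channel>` and `<feature>_<ch1>-<ch2>`.
#'
#' @param seg a `segmented_recording`.
#' @param spec a [feature_spec()].
#' @return A `feature_matrix`: numeric matrix (windows x features) with
#'   attribute `norm_state = "raw"`.
#' @export
build_feature_matrix <- function(seg, spec) {
  stopifnot(inherits(seg, "segmented_recording"))
  nw <- n_windows(seg)
  if (nw < 1) stop("segmentation has no complete window")
  nch <- dim(seg$windows)[2]
  sf <- single_feature_names(spec)
  pairs <- if (length(spec$cross) && nch >= 2)
    combn(nch, 2) else matrix(integer(0), nrow = 2)
  cols <- c(
    as.vector(outer(sf, seg$channels, function(f, ch) paste0(f, "_", ch))),
    if (ncol(pairs)) as.vector(apply(pairs, 2, function(p)
      paste0(spec$cross, "_", seg$channels[p[1]], "-", seg$channels[p[2]])))
  )
  out <- matrix(0, nrow = nw, ncol = length(cols),
                dimnames = list(NULL, cols))
  nsf <- length(sf)
  for (w in seq_len(nw)) {
    for (ch in seq_len(nch)) {
      out[w, ((ch - 1) * nsf + 1):(ch * nsf)] <-
        single_channel_features(seg$windows[w, ch, ], seg$rate, spec)
    }
    if (ncol(pairs)) {
      base <- nch * nsf
      ncf <- length(spec$cross)
      for (p in seq_len(ncol(pairs))) {
        out[w, (base + (p - 1) * ncf + 1):(base + p * ncf)] <-
          cross_channel_features(seg$windows[w, pairs[1, p], ],
                                 seg$windows[w, pairs[2, p], ], spec)
      }
    }
  }
  feature_matrix(out, norm_state = "raw")
}

#' Feature matrix constructor
#'
#' A thin class over a numeric windows x features matrix carrying its
#' normalization state (and, once z-scored, the training mean/SD used).
#'
#' @param values numeric matrix with unique column names.
#' @param norm_state `"raw"` or `"zscored"`.
#' @param center,scale per-feature constants (z-scored matrices only).
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, norm_state = "raw",
                           center = NULL, scale = NULL) {
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            !anyDuplicated(colnames(values)))
  structure(values, norm_state = norm_state, center = center,
            scale = scale, class = c("feature_matrix", class(values)))
}

#' @export
`[.feature_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    at <- attributes(x)
    cn <- colnames(out)
    feature_matrix(out, norm_state = at$norm_state,
                   center = at$center[cn], scale = at$scale[cn])
  } else out
}

#' Fit z-score constants on a training matrix and apply them
#'
#' Per-feature mean and (sample) SD are estimated on `train` only and then
#' applied to `train` and every matrix in `others`, so held-out data never
#' leak into the normalization. A zero-SD feature is mapped to an all-zero
#' column with a warning.
#'
#' @param train raw `feature_matrix` with >= 2 windows.
#' @param others list of raw `feature_matrix` objects with identical
#'   feature names.
#' @return List with `train`, `others` (both z-scored), and the fitted
#'   `center` and `scale` vectors.
#' @export
zscore_fit_apply <- function(train, others = list()) {
  stopifnot(inherits(train, "feature_matrix"))
  if (attr(train, "norm_state") != "raw")
    stop("train matrix is already normalized")
  if (nrow(train) < 2) stop("need >= 2 training windows to fit z-scores")
  center <- colMeans(train)
  scale <- apply(train, 2, sd)
  degen <- scale == 0
  if (any(degen)) {
    warning("zero-SD feature(s) mapped to zero: ",
            paste(colnames(train)[degen], collapse = ", "))
    scale[degen] <- 1
    center[degen] <- 0   # column was constant; (x - mean) = 0 anyway
  }
  app <- function(fm) {
    if (!identical(colnames(fm), colnames(train)))
      stop("feature names do not match the training matrix")
    z <- sweep(sweep(unclass(fm), 2, center), 2, scale, "/")
    if (any(degen)) z[, degen] <- 0
    feature_matrix(z, norm_state = "zscored", center = center, scale = scale)
  }
  ztr <- app(train)
  list(train = ztr, others = lapply(others, app),
       center = center, scale = scale)
}

#' Write / read a feature-matrix HDF5 store
#'
#' Layout: `/values` (windows x features), `/names`, attributes
#' `norm_state` plus `center`/`scale` when z-scored.
#'
#' @param fm a `feature_matrix`.
#' @param path output path (overwritten).
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the `feature_matrix`.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(unclass(fm)[, , drop = FALSE], path, "values")
  rhdf5::h5write(colnames(fm), path, "names")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::h5writeAttribute(attr(fm, "norm_state"), fid, "norm_state")
  if (!is.null(attr(fm, "center"))) {
    rhdf5::h5writeAttribute(attr(fm, "center"), fid, "center")
    rhdf5::h5writeAttribute(attr(fm, "scale"), fid, "scale")
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  v <- rhdf5::h5read(path, "values")
  colnames(v) <- as.character(rhdf5::h5read(path, "names"))
  at <- rhdf5::h5readAttributes(path, "/")
  center <- if (!is.null(at$center)) stats::setNames(as.numeric(at$center), colnames(v))
  scale <- if (!is.null(at$scale)) stats::setNames(as.numeric(at$scale), colnames(v))
  feature_matrix(v, norm_state = as.character(at$norm_state),
                 center = center, scale = scale)
}
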