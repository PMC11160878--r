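#' Synthetic recording configuration
#'
#' Describes a multichannel recording of stationary 1/f background noise
#' with planted seizure events: during each event an amplitude-modulated
#' oscillation inside `ictal_band` is added, with a trapezoidal envelope
#' (ramp-up, plateau, ramp-down) so event-boundary windows are genuinely
#' harder than event centers. The injected amplitude is
#' `(ictal_gain - 1) * background_sd`, so `ictal_gain = 1` is an exact
#' null configuration (nothing added). Ictal activity is correlated
#' across channels: a common oscillation enters every channel with weight
#' `sqrt(spread)` and a channel-specific one with weight
#' `sqrt(1 - spread)`.
#'
#' @param n_channels number of channels.
#' @param rate sampling rate in Hz.
#' @param duration_s recording length in seconds.
#' @param background_sd background noise SD (arbitrary units).
#' @param pink_exponent 1/f spectral exponent of the background (1 gives
#'   pink noise, 0 white).
#' @param seizures explicit list of `c(start_s, dur_s)` events, or `NULL`
#'   to place `n_seizures` events at jittered regular slots.
#' @param n_seizures number of events to plant when `seizures` is `NULL`.
#' @param dur_range `c(min, max)` event duration in seconds.
#' @param ictal_gain amplitude multiplier (>= 1) of ictal activity
#'   relative to background.
#' @param ictal_band `c(lo, hi)` Hz of the injected oscillation.
#' @param spread cross-channel correlation of ictal activity in \[0, 1\].
#' @param channels channel names.
#' @param seed integer seed.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_channels = 2, rate = 400, duration_s = 9000,
                         background_sd = 1, pink_exponent = 1,
                         seizures = NULL, n_seizures = 24,
                         dur_range = c(20, 40), ictal_gain = 5,
                         ictal_band = c(5, 15), spread = 0.8,
                         channels = NULL, seed = 1) {
  stopifnot(ictal_gain >= 1, spread >= 0, spread <= 1,
            ictal_band[1] < ictal_band[2], ictal_band[2] < rate / 2)
  if (is.null(channels)) {
    channels <- if (n_channels == 2) c("vHPC", "FC")
                else paste0("ch", seq_len(n_channels))
  }
  stopifnot(length(channels) == n_channels)
  if (!is.null(seizures)) {
    sz <- do.call(rbind, seizures)
    o <- order(sz[, 1])
    sz <- sz[o, , drop = FALSE]
    if (any(sz[, 1] < 0) || any(sz[, 1] + sz[, 2] > duration_s))
      stop("seizure events must lie within the recording")
    if (nrow(sz) > 1 &&
        any(sz[-1, 1] < (sz[, 1] + sz[, 2])[-nrow(sz)]))
      stop("seizure events overlap")
  }
  structure(
    list(n_channels = n_channels, rate = rate, duration_s = duration_s,
         background_sd = background_sd, pink_exponent = pink_exponent,
         seizures = seizures, n_seizures = n_seizures,
         dur_range = dur_range, ictal_gain = ictal_gain,
         ictal_band = ictal_band, spread = spread, channels = channels,
         seed = seed),
    class = "synth_config")
}

# 1/f^exponent noise of length n, unit SD, generated spectrally.
pink_noise <- function(n, exponent) {
  white <- rnorm(n)
  if (exponent == 0) return(white)
  X <- fft(white)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)                 # symmetric frequency index
  shape <- ifelse(f == 0, 0, f^(-exponent / 2))
  x <- Re(fft(X * shape, inverse = TRUE) / n)
  x / sd(x)
}

# Trapezoidal amplitude envelope over n samples (ramp fraction each side).
trapezoid <- function(n, ramp_frac = 0.15) {
  r <- max(1, round(n * ramp_frac))
  env <- rep(1, n)
  env[1:r] <- seq(0, 1, length.out = r)
  env[(n - r + 1):n] <- seq(1, 0, length.out = r)
  env
}

# Draw non-overlapping event times: one per equal slot, jittered.
draw_events <- function(cfg) {
  n <- cfg$n_seizures
  dur <- runif(n, cfg$dur_range[1], cfg$dur_range[2])
  slot <- cfg$duration_s / n
  margin <- 15
  if (slot < max(dur) + 2 * margin)
    stop("recording too short for the requested number of seizures")
  start <- (seq_len(n) - 1) * slot + margin +
    runif(n, 0, slot - dur - 2 * margin)
  cbind(start_s = start, dur_s = dur)
}

#' Generate a synthetic recording with planted seizures
#'
#' @param cfg a [synth_config()].
#' @param window_s window length used to rasterize the ground truth.
#' @return List with `recording` (a [recording()]), `events` (ground-truth
#'   [event_list()] in window indices), `labels` (per-window 0/1 vector
#'   over the full base segmentation at the native rate) and `schedule`
#'   (matrix of planted `start_s`/`dur_s`).
#' @export
generate_recording <- function(cfg, window_s = 5) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- round(cfg$duration_s * cfg$rate)
  out <- local_seed(cfg$seed, {
    sig <- matrix(0, nrow = n, ncol = cfg$n_channels)
    for (ch in seq_len(cfg$n_channels))
      sig[, ch] <- cfg$background_sd * pink_noise(n, cfg$pink_exponent)
    sched <- if (is.null(cfg$seizures)) draw_events(cfg)
             else do.call(rbind, lapply(cfg$seizures, function(e)
               c(start_s = e[1], dur_s = e[2])))
    amp <- (cfg$ictal_gain - 1) * cfg$background_sd
    if (amp > 0) {
      for (i in seq_len(nrow(sched))) {
        i0 <- round(sched[i, 1] * cfg$rate) + 1
        ne <- round(sched[i, 2] * cfg$rate)
        tt <- (seq_len(ne) - 1) / cfg$rate
        env <- trapezoid(ne) *
          (1 + 0.3 * sin(2 * pi * 0.4 * tt + runif(1, 0, 2 * pi)))
        fc <- runif(1, cfg$ictal_band[1], cfg$ictal_band[2])
        common <- sin(2 * pi * fc * tt + runif(1, 0, 2 * pi))
        for (ch in seq_len(cfg$n_channels)) {
          fo <- runif(1, cfg$ictal_band[1], cfg$ictal_band[2])
          own <- sin(2 * pi * fo * tt + runif(1, 0, 2 * pi))
          osc <- sqrt(cfg$spread) * common + sqrt(1 - cfg$spread) * own
          idx <- i0:(i0 + ne - 1)
          sig[idx, ch] <- sig[idx, ch] + amp * env * osc
        }
      }
    }
    list(sig = sig, sched = sched)
  })
  rec <- recording(out$sig, cfg$rate, cfg$channels,
                   sprintf("synth_seed%d", cfg$seed))
  n_win <- floor(cfg$duration_s / window_s)
  labels <- events_to_labels_s(out$sched[, 1],
                               out$sched[, 1] + out$sched[, 2],
                               n_win, window_s)
  events <- merge_events(labels, 1, window_s, source = "ground_truth")
  list(recording = rec, events = events, labels = labels,
       schedule = out$sched)
}

#' Generate a multi-subject synthetic dataset
#'
#' Per-subject configurations are drawn by jittering the template: the
#' ictal gain and background SD are multiplied by
#' `exp(rnorm(1, 0, heterogeneity))`, and each subject gets its own
#' derived seed. `heterogeneity = 0` makes all subjects statistically
#' identical (up to their seeds).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param template a [synth_config()] template.
#' @param heterogeneity SD of the log-normal per-subject jitter.
#' @param seed integer root seed.
#' @param window_s window length for truth rasterization.
#' @return Named list of subjects, each as returned by
#'   [generate_recording()] plus its `config`.
#' @export
generate_dataset <- function(n_subjects, template = synth_config(),
                             heterogeneity = 0, seed = 1, window_s = 5) {
  stopifnot(n_subjects >= 1)
  jit <- local_seed(child_seed(seed, 11),
                    exp(rnorm(2 * n_subjects, 0, heterogeneity)))
  out <- lapply(seq_len(n_subjects), function(s) {
    cfg <- template
    cfg$ictal_gain <- 1 + (template$ictal_gain - 1) * jit[2 * s - 1]
    cfg$background_sd <- template$background_sd * jit[2 * s]
    cfg$seed <- child_seed(seed, 500 + s)
    r <- generate_recording(cfg, window_s)
    r$recording$source_id <- sprintf("subject%02d", s)
    r$config <- cfg
    r
  })
  names(out) <- sprintf("subject%02d", seq_len(n_subjects))
  out
}
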