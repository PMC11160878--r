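#' Seizure event list
#'
#' Events are half-open, 0-based window-index intervals `[start, stop)`,
#' sorted and non-overlapping.
#'
#' @param start,stop integer vectors of interval bounds (0-based,
#'   half-open).
#' @param window_s window length in seconds.
#' @param source `"prediction"` or `"ground_truth"`.
#' @return An `event_list` (data.frame with columns `start`, `stop` and
#'   attributes `window_s`, `source`).
#' @export
event_list <- function(start, stop, window_s = 5, source = "prediction") {
  stopifnot(length(start) == length(stop), all(stop > start))
  if (length(start) > 1) {
    o <- order(start)
    start <- start[o]; stop <- stop[o]
    if (any(start[-1] < stop[-length(stop)])) stop("events overlap")
  }
  structure(data.frame(start = as.integer(start), stop = as.integer(stop)),
            window_s = window_s, source = source,
            class = c("event_list", "data.frame"))
}

#' Merge per-window predictions into seizure events
#'
#' Maximal runs of predicted-seizure windows become events; runs shorter
#' than `min_consecutive` windows are discarded. The standard event rule
#' requires at least two consecutive 5-second segments
#' (`min_consecutive = 2`); ground-truth labels are merged with
#' `min_consecutive = 1` so every annotated seizure counts regardless of
#' length.
#'
#' @param pred 0/1 per-window vector.
#' @param min_consecutive minimum run length, >= 1.
#' @param window_s window length in seconds.
#' @param source stored on the result.
#' @return An [event_list()].
#' @export
merge_events <- function(pred, min_consecutive = 2, window_s = 5,
                         source = "prediction") {
  stopifnot(min_consecutive >= 1)
  pred <- as.integer(pred)
  r <- rle(pred)
  ends <- cumsum(r$lengths)
  keep <- r$values == 1L & r$lengths >= min_consecutive
  event_list(start = (ends - r$lengths)[keep], stop = ends[keep],
             window_s = window_s, source = source)
}

#' Rasterize an event list to per-window labels
#'
#' @param ev an [event_list()].
#' @param n_windows output length.
#' @return Integer 0/1 vector.
#' @export
events_to_labels <- function(ev, n_windows) {
  lab <- integer(n_windows)
  for (i in seq_len(nrow(ev)))
    lab[(ev$start[i] + 1):min(ev$stop[i], n_windows)] <- 1L
  lab
}

#' Match predicted events against ground-truth events
#'
#' A true event counts as detected when at least one predicted event
#' shares at least one window with it; a predicted event is correct when
#' it overlaps at least one true event.
#'
#' @param pred_events,true_events [event_list()] objects with the same
#'   `window_s`.
#' @return List: `n_detected` (true events with an overlapping
#'   prediction), `n_correct_pred` (predicted events overlapping truth),
#'   `n_pred`, `n_true`, plus logical vectors `detected` and `correct`.
#' @export
match_events <- function(pred_events, true_events) {
  if (!isTRUE(all.equal(attr(pred_events, "window_s"),
                        attr(true_events, "window_s"))))
    stop("event lists use different window lengths")
  overlaps <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1
  np <- nrow(pred_events); nt <- nrow(true_events)
  detected <- vapply(seq_len(nt), function(i)
    any(overlaps(pred_events$start, pred_events$stop,
                 true_events$start[i], true_events$stop[i])), TRUE)
  correct <- vapply(seq_len(np), function(i)
    any(overlaps(true_events$start, true_events$stop,
                 pred_events$start[i], pred_events$stop[i])), TRUE)
  list(n_detected = sum(detected), n_correct_pred = sum(correct),
       n_pred = np, n_true = nt, detected = detected, correct = correct)
}

#' Window-level confusion counts and derived rates
#'
#' Counts true/false positives/negatives over windows and derives recall
#' (TP/(TP+FN)), precision (TP/(TP+FP)), specificity (TN/(TN+FP)),
#' F1 (harmonic mean of precision and recall) and balanced accuracy
#' ((recall+specificity)/2). A rate whose denominator is zero is reported
#' as 0 and its name recorded in `flags`, so aggregate tables stay
#' numeric.
#'
#' @param pred,truth 0/1 vectors of equal length.
#' @return List with `tp`, `tn`, `fp`, `fn`, the five rates, `flags`
#'   (character vector of zero-denominator rates) and `n`.
#' @export
segment_metrics <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) stop("length mismatch")
  tp <- sum(pred == 1L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  flags <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); 0 } else num / den
  }
  recall <- rate(tp, tp + fn, "recall")
  precision <- rate(tp, tp + fp, "precision")
  specificity <- rate(tn, tn + fp, "specificity")
  f1 <- rate(2 * precision * recall, precision + recall, "f1")
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       recall = recall, precision = precision, specificity = specificity,
       f1 = f1, balanced_accuracy = (recall + specificity) / 2,
       flags = flags, n = length(pred))
}

#' Event-level detection metrics
#'
#' Percent of true seizures detected (100 by convention when there are no
#' true events) and the false detection rate: incorrectly predicted
#' seizure events per hour of recording.
#'
#' @param pred_events,true_events [event_list()] objects.
#' @param duration_h total recording duration in hours (> 0).
#' @return List with `pct_detected`, `fdr` (events/hour), `n_detected`,
#'   `n_pred`, `n_true`, `duration_h`.
#' @export
event_metrics <- function(pred_events, true_events, duration_h) {
  if (duration_h <= 0) stop("duration_h must be positive")
  m <- match_events(pred_events, true_events)
  pct <- if (m$n_true == 0) 100 else 100 * m$n_detected / m$n_true
  fdr <- (m$n_pred - m$n_correct_pred) / duration_h
  list(pct_detected = pct, fdr = fdr, n_detected = m$n_detected,
       n_pred = m$n_pred, n_true = m$n_true, duration_h = duration_h)
}
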