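#' Stratified fold assignment
#'
#' Assigns each window to one of `k` folds so that class proportions are
#' preserved per fold (each class is shuffled and dealt round-robin).
#'
#' @param labels 0/1 vector.
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return Integer vector of fold ids in `1:k`, one per window.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Balanced accuracy of a prediction
#'
#' Mean of recall (sensitivity) and specificity; the tuning metric, robust
#' to the heavy class imbalance of seizure data.
#'
#' @param pred,truth 0/1 vectors of equal length.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(pred, truth) {
  segment_metrics(pred, truth)$balanced_accuracy
}

#' Grid-search hyperparameter tuning on balanced accuracy
#'
#' Exhaustively evaluates every grid point under stratified k-fold
#' cross-validation and returns the point maximizing the mean validation
#' balanced accuracy (ties broken by grid order). Folds are fixed across
#' grid points.
#'
#' @param kind model kind (see [fit_model()]).
#' @param fm feature matrix (training split, already normalized).
#' @param labels 0/1 window labels; both classes must be present in every
#'   fold, otherwise an error signals too few positive windows.
#' @param grid named list of hyperparameter vectors; defaults to
#'   [default_grid()].
#' @param folds number of CV folds (4 gives the 75/25 train/validation
#'   split used for tuning).
#' @param seed integer seed (fold assignment and stochastic fits).
#' @return List with `hyperparams` (best point), `score` (its mean
#'   balanced accuracy) and `table` (a data.frame of all points).
#' @export
tune_model <- function(kind, fm, labels, grid = default_grid(kind),
                       folds = 4, seed = 1) {
  stopifnot(length(grid) >= 1)
  labels <- as.integer(labels)
  fold <- stratified_folds(labels, folds, seed = child_seed(seed, 1))
  for (f in seq_len(folds)) {
    if (length(unique(labels[fold != f])) < 2 ||
        length(unique(labels[fold == f])) < 2)
      stop("a fold lost the minority class; too few positive windows")
  }
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  scores <- numeric(nrow(pts))
  x <- unclass(fm)
  for (g in seq_len(nrow(pts))) {
    hp <- as.list(pts[g, , drop = FALSE])
    names(hp) <- names(pts)
    ba <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_model(kind, x[tr, , drop = FALSE], labels[tr],
                     hyperparams = hp, seed = child_seed(seed, 100 + f))
      balanced_accuracy(predict(m, x[!tr, , drop = FALSE]), labels[!tr])
    }, 0)
    scores[g] <- mean(ba)
  }
  best <- which.max(scores)
  hp <- as.list(pts[best, , drop = FALSE])
  names(hp) <- names(pts)
  list(hyperparams = hp, score = scores[best],
       table = cbind(pts, balanced_accuracy = scores))
}

#' Train replicate models on stratified subsets
#'
#' Fits `repeats` models, each on a distinct stratified `(repeats-1)/repeats`
#' subset (the complement of one fold), so with `repeats = 5` each model
#' sees 80% of the training windows. Deterministic under `seed`.
#'
#' @param kind model kind.
#' @param hyperparams named list of hyperparameters.
#' @param fm feature matrix.
#' @param labels 0/1 labels.
#' @param repeats number of replicate models (= folds).
#' @param seed integer seed.
#' @return List of `repeats` fitted `seiz_model` objects; each carries a
#'   `train_idx` attribute with the window indices it was fitted on.
#' @export
train_model <- function(kind, hyperparams, fm, labels, repeats = 5,
                        seed = 1) {
  labels <- as.integer(labels)
  fold <- stratified_folds(labels, repeats, seed = child_seed(seed, 2))
  x <- unclass(fm)
  lapply(seq_len(repeats), function(f) {
    tr <- which(fold != f)
    if (length(unique(labels[tr])) < 2)
      stop("a training subset lost the minority class")
    m <- fit_model(kind, x[tr, , drop = FALSE], labels[tr],
                   hyperparams = hyperparams,
                   seed = child_seed(seed, 200 + f))
    attr(m, "train_idx") <- tr
    m
  })
}

#' Sliding-window upsampling of seizure segments
#'
#' Class imbalance control for training folds: for every ground-truth
#' seizure span, additional full-length windows are cut from the
#' continuous (filtered, downsampled) signal at `step_s` offsets across
#' the span and appended with label 1. Offsets that coincide with the base
#' segmentation grid are skipped (those windows already exist), so
#' `step_s = window_s` adds nothing. Windows extending past the end of the
#' signal are skipped. Outlier repair is applied to the new windows with
#' the segmentation's threshold. Apply to training folds only.
#'
#' @param seg a `segmented_recording` (must retain its continuous signal).
#' @param labels 0/1 base-window labels aligned to `seg`.
#' @param step_s sliding step in seconds (> 0; `step_s * rate` must be an
#'   integer).
#' @return List with `windows` (augmented array), `labels` (augmented
#'   vector), `start_s` (start time of every window) and `n_base` (count
#'   of original windows, which come first).
#' @export
upsample_seizures <- function(seg, labels, step_s = 0.5) {
  stopifnot(inherits(seg, "segmented_recording"))
  if (step_s <= 0) stop("step_s must be positive")
  step <- step_s * seg$rate
  if (abs(step - round(step)) > 1e-9)
    stop("step_s must be an integer number of samples at the working rate")
  labels <- as.integer(labels)
  stopifnot(length(labels) == n_windows(seg))
  wlen <- seg$window_s * seg$rate
  nsig <- nrow(seg$signal)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  extra_start <- numeric(0)
  for (i in seq_along(r$values)) {
    if (r$values[i] != 1L) next
    span_a <- seg$start_s[starts[i]]
    span_b <- span_a + r$lengths[i] * seg$window_s
    offs <- seq(0, (span_b - span_a) - seg$window_s, by = step_s)
    for (o in offs) {
      t0 <- span_a + o
      if (abs(t0 %% seg$window_s) < 1e-9) next          # base-grid window
      if (round(t0 * seg$rate) + wlen > nsig) next       # past signal end
      extra_start <- c(extra_start, t0)
    }
  }
  nb <- n_windows(seg)
  if (!length(extra_start)) {
    return(list(windows = seg$windows, labels = labels,
                start_s = seg$start_s, n_base = nb))
  }
  aug <- array(0, dim = c(nb + length(extra_start), dim(seg$windows)[2], wlen),
               dimnames = dimnames(seg$windows))
  aug[seq_len(nb), , ] <- seg$windows
  for (j in seq_along(extra_start)) {
    i0 <- round(extra_start[j] * seg$rate)
    w <- t(seg$signal[(i0 + 1):(i0 + wlen), , drop = FALSE])
    aug[nb + j, , ] <- repair_outliers(w, seg$outlier_sd,
                                       seg$repair_center, seg$repair_scale)
  }
  list(windows = aug, labels = c(labels, rep(1L, length(extra_start))),
       start_s = c(seg$start_s, extra_start), n_base = nb)
}

# Fit-and-evaluate one train/test split with leakage-safe plumbing:
# z-score constants, feature pruning/ranking and tuning all see the
# training windows only. Returns metrics plus provenance for auditing.
eval_split <- function(train_x, train_y, test_x, test_y, config) {
  zs <- zscore_fit_apply(train_x, list(test_x))
  tr <- zs$train; te <- zs$others[[1]]
  selected <- colnames(tr)
  if (isTRUE(config$select)) {
    pruned <- prune_correlated(tr, config$r_thresh)
    sel_fm <- tr[, pruned$selected, drop = FALSE]
    if (!is.null(config$k)) {
      k <- min(config$k, ncol(sel_fm))
      fs <- rank_univariate(sel_fm, train_y, config$rank_method, k)
      selected <- fs$selected
    } else selected <- pruned$selected
    tr <- tr[, selected, drop = FALSE]
    te <- te[, selected, drop = FALSE]
  }
  hp <- config$hyperparams
  if (!is.null(config$grid)) {
    tuned <- tune_model(config$model_kind, tr, train_y, config$grid,
                        folds = config$tune_folds, seed = config$seed)
    hp <- tuned$hyperparams
  }
  m <- fit_model(config$model_kind, unclass(tr), train_y,
                 hyperparams = if (is.null(hp)) list() else hp,
                 seed = child_seed(config$seed, 7))
  pred <- predict(m, te)
  sm <- segment_metrics(pred, test_y)
  pe <- merge_events(pred, config$min_consecutive, config$window_s)
  te_ev <- merge_events(test_y, 1, config$window_s, source = "ground_truth")
  em <- event_metrics(pe, te_ev, length(test_y) * config$window_s / 3600)
  list(metrics = sm, event_metrics = em, model = m,
       provenance = list(center = zs$center, scale = zs$scale,
                         selected = selected, hyperparams = m$hyperparams))
}

scheme_defaults <- function(config) {
  utils::modifyList(
    list(model_kind = "gnb", hyperparams = NULL, grid = NULL,
         select = TRUE, r_thresh = 0.99, k = NULL, rank_method = "anova",
         tune_folds = 4, intra_folds = 8, inter_groups = 4,
         min_consecutive = 2, window_s = 5, seed = 1),
    config)
}

#' Cross-validation schemes over a multi-subject dataset
#'
#' Three evaluation designs for multi-subject recordings:
#' \describe{
#'   \item{intra_subject}{per subject, nested stratified k-fold: an outer
#'     `intra_folds`-fold split provides the test fold, and tuning (when a
#'     grid is given) runs inside the outer-training windows.}
#'   \item{leave_one_out}{train on all subjects but one, test on the
#'     held-out subject, rotating over subjects.}
#'   \item{inter_subject}{subjects are split into `inter_groups` groups
#'     (remainder spread over the first groups); train on all-but-one
#'     group, test on the held-out group, rotating.}
#' }
#' In every scheme, z-scoring, feature selection and tuning are fitted on
#' the training windows only; each fold's report carries the constants
#' used so this can be audited.
#'
#' @param scheme `"intra_subject"`, `"leave_one_out"` or
#'   `"inter_subject"`.
#' @param dataset list of subjects, each a list with `features` (raw
#'   `feature_matrix`) and `labels` (0/1 vector).
#' @param config named list; recognised keys: `model_kind`, `hyperparams`,
#'   `grid`, `select`, `r_thresh`, `k`, `rank_method`, `tune_folds`,
#'   `intra_folds`, `inter_groups`, `min_consecutive`, `window_s`, `seed`.
#' @return List of per-fold reports (`fold`, `test_subjects`,
#'   `train_subjects`, `metrics`, `event_metrics`, `provenance`, and for
#'   intra-subject `test_idx`/`train_idx`).
#' @export
run_scheme <- function(scheme = c("intra_subject", "leave_one_out",
                                  "inter_subject"),
                       dataset, config = list()) {
  scheme <- match.arg(scheme)
  config <- scheme_defaults(config)
  ns <- length(dataset)
  if (scheme != "intra_subject" && ns < 2)
    stop("cross-subject schemes need at least 2 subjects")
  subj_names <- names(dataset)
  if (is.null(subj_names)) subj_names <- paste0("subject", seq_len(ns))
  bind <- function(idx) {
    list(x = feature_matrix(
           do.call(rbind, lapply(dataset[idx], function(s) unclass(s$features))),
           norm_state = "raw"),
         y = unlist(lapply(dataset[idx], function(s) as.integer(s$labels))))
  }
  reports <- list()
  if (scheme == "intra_subject") {
    for (s in seq_len(ns)) {
      y <- as.integer(dataset[[s]]$labels)
      fold <- stratified_folds(y, config$intra_folds,
                               seed = child_seed(config$seed, 300 + s))
      for (f in seq_len(config$intra_folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        r <- eval_split(dataset[[s]]$features[tr, , drop = FALSE], y[tr],
                        dataset[[s]]$features[te, , drop = FALSE], y[te],
                        config)
        r$fold <- sprintf("%s:%d", subj_names[s], f)
        r$test_subjects <- subj_names[s]
        r$train_subjects <- subj_names[s]
        r$train_idx <- tr; r$test_idx <- te
        reports <- c(reports, list(r))
      }
    }
  } else if (scheme == "leave_one_out") {
    for (s in seq_len(ns)) {
      trs <- setdiff(seq_len(ns), s)
      tr <- bind(trs); te <- bind(s)
      r <- eval_split(tr$x, tr$y, te$x, te$y, config)
      r$fold <- subj_names[s]
      r$test_subjects <- subj_names[s]
      r$train_subjects <- subj_names[trs]
      reports <- c(reports, list(r))
    }
  } else {
    g <- config$inter_groups
    if (ns %% g != 0)
      message("subject count not divisible by ", g,
              "; remainder distributed over the first groups")
    grp <- sort(rep_len(seq_len(g), ns))
    for (f in seq_len(g)) {
      trs <- which(grp != f); tes <- which(grp == f)
      tr <- bind(trs); te <- bind(tes)
      r <- eval_split(tr$x, tr$y, te$x, te$y, config)
      r$fold <- sprintf("group%d", f)
      r$test_subjects <- subj_names[tes]
      r$train_subjects <- subj_names[trs]
      reports <- c(reports, list(r))
    }
  }
  reports
}
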