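# Pipeline stage runner: each stage consumes the previous stage's on-disk
# artifact and writes its own, so runs are resumable and auditable.

.config_schema <- list(
  seed = NULL,
  paths = c("out", "recording", "labels"),
  preprocess = c("target_rate", "highpass_hz", "window_s", "outlier_sd",
                 "channels"),
  features = c("config", "single", "cross", "bands"),
  select = c("threshold", "method", "k", "ks", "include_pruned"),
  train = c("model", "grid", "tune", "tune_folds", "repeats"),
  events = c("min_consecutive"),
  simulate = c("n_channels", "rate", "duration_s", "background_sd",
               "pink_exponent", "n_seizures", "dur_range", "ictal_gain",
               "ictal_band", "spread"),
  review = c("mode", "decisions")
)

#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML (or an equivalent named list) with top-level
#' sections `seed`, `paths`, `preprocess`, `features`, `select`, `train`,
#' `events`, `simulate`, `review`. Unknown keys are errors, not warnings.
#'
#' @param config path to a YAML file, or a named list.
#' @return The validated config list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  bad <- setdiff(names(config), names(.config_schema))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in names(.config_schema)) {
    if (is.null(.config_schema[[sec]]) || is.null(config[[sec]])) next
    bad <- setdiff(names(config[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
  }
  defaults <- list(
    seed = 1,
    paths = list(out = "."),
    preprocess = list(target_rate = 100, highpass_hz = 2, window_s = 5,
                      outlier_sd = 25, channels = NULL),
    features = list(config = "mouse"),
    select = list(threshold = 0.99, method = "anova", k = NULL,
                  ks = c(4, 8), include_pruned = TRUE),
    train = list(model = "gnb", grid = NULL, tune = FALSE, tune_folds = 4,
                 repeats = 5),
    events = list(min_consecutive = 2),
    simulate = list(),
    review = list(mode = "accept_all", decisions = NULL)
  )
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

pipeline_spec <- function(cfg) {
  f <- cfg$features
  if (!is.null(f$config)) {
    switch(f$config, mouse = mouse_feature_spec(),
           human = human_feature_spec(),
           stop("unknown features.config: ", f$config))
  } else {
    feature_spec(f$single, if (is.null(f$cross)) character(0) else f$cross,
                 if (is.null(f$bands)) list() else f$bands)
  }
}

art <- function(cfg, name) file.path(cfg$paths$out, name)

log_stage <- function(cfg, stage, params, artifacts) {
  hashes <- vapply(artifacts, function(a)
    unname(tools::md5sum(art(cfg, a))), "")
  line <- sprintf("%s\t%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                  jsonlite::toJSON(params, auto_unbox = TRUE),
                  paste(artifacts, hashes, sep = ":", collapse = " "))
  cat(line, "\n", sep = "", file = art(cfg, "pipeline.log"), append = TRUE)
}

need <- function(cfg, name, stage) {
  p <- art(cfg, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "'; run the '", stage,
         "' stage first")
  p
}

#' Run the seizure-detection pipeline
#'
#' Chains the processing stages over on-disk artifacts inside
#' `paths$out`: `simulate` (synthetic recording + ground truth),
#' `preprocess` (filtered, downsampled 5-s windows), `extract` (feature
#' matrix), `select` (feature sets), `train` (tuned/replicated model),
#' `predict` (per-window predictions + merged events), `review`
#' (accept/reject each predicted event; text-mode) and `metrics`
#' (window- and event-level scores against the ground truth). Each stage
#' appends a log line with its parameters and artifact content hashes, so
#' a run can be replayed and verified from the config and seed alone.
#'
#' @param config YAML path or config list (see [read_run_config()]).
#' @param stages character vector of stages to run, in pipeline order.
#' @return Invisibly, a named list of artifact paths written.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "extract",
                                    "select", "train", "predict", "review",
                                    "metrics")) {
  cfg <- read_run_config(config)
  stages <- match.arg(stages, c("simulate", "preprocess", "extract",
                                "select", "train", "predict", "review",
                                "metrics"), several.ok = TRUE)
  dir.create(cfg$paths$out, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  pp <- cfg$preprocess

  if ("simulate" %in% stages) {
    sc <- do.call(synth_config, c(cfg$simulate, list(seed = cfg$seed)))
    g <- generate_recording(sc, window_s = pp$window_s)
    write_store(g$recording, art(cfg, "recording.h5"))
    truth <- data.frame(source_id = g$recording$source_id,
                        start_s = g$schedule[, 1],
                        stop_s = g$schedule[, 1] + g$schedule[, 2])
    write.csv(truth, art(cfg, "truth.csv"), row.names = FALSE)
    log_stage(cfg, "simulate", cfg$simulate, c("recording.h5", "truth.csv"))
    out$recording <- art(cfg, "recording.h5")
    out$truth <- art(cfg, "truth.csv")
  }
  if ("preprocess" %in% stages) {
    rec_path <- if (!is.null(cfg$paths$recording)) cfg$paths$recording
                else need(cfg, "recording.h5", "simulate")
    rec <- load_recording(rec_path, channels = pp$channels)
    seg <- preprocess(rec, pp$target_rate, pp$highpass_hz, pp$window_s,
                      pp$outlier_sd)
    write_segments(seg, art(cfg, "segments.h5"))
    log_stage(cfg, "preprocess", pp, "segments.h5")
    out$segments <- art(cfg, "segments.h5")
  }
  if ("extract" %in% stages) {
    seg <- read_segments(need(cfg, "segments.h5", "preprocess"))
    fm <- build_feature_matrix(seg, pipeline_spec(cfg))
    write_features(fm, art(cfg, "features.h5"))
    log_stage(cfg, "extract", cfg$features, "features.h5")
    out$features <- art(cfg, "features.h5")
  }
  labels_for <- function(n_win) {
    lp <- if (!is.null(cfg$paths$labels)) cfg$paths$labels
          else need(cfg, "truth.csv", "simulate")
    read_labels(lp, n_win, pp$window_s)
  }
  if ("select" %in% stages) {
    fm <- read_features(need(cfg, "features.h5", "extract"))
    labels <- labels_for(nrow(fm))
    zs <- zscore_fit_apply(fm)
    sets <- build_feature_sets(zs$train, labels,
                               r_thresh = cfg$select$threshold,
                               ks = unlist(cfg$select$ks),
                               methods = cfg$select$method,
                               include_pruned = cfg$select$include_pruned)
    jsonlite::write_json(
      lapply(sets, function(s) list(id = s$id, method = s$method,
                                    k = s$k, selected = s$selected)),
      art(cfg, "feature_sets.json"), auto_unbox = TRUE, null = "null")
    log_stage(cfg, "select", cfg$select, "feature_sets.json")
    out$feature_sets <- art(cfg, "feature_sets.json")
  }
  if ("train" %in% stages) {
    fm <- read_features(need(cfg, "features.h5", "extract"))
    labels <- labels_for(nrow(fm))
    zs <- zscore_fit_apply(fm)
    selected <- colnames(fm)
    if (file.exists(art(cfg, "feature_sets.json"))) {
      sets <- jsonlite::read_json(art(cfg, "feature_sets.json"),
                                  simplifyVector = TRUE)
      wanted <- if (!is.null(cfg$select$k))
        which(sets$k == cfg$select$k &
                startsWith(sets$method, cfg$select$method))[1] else 1L
      selected <- sets$selected[[wanted]]
    }
    tr <- zs$train[, selected, drop = FALSE]
    hp <- list()
    if (isTRUE(cfg$train$tune)) {
      grid <- if (is.null(cfg$train$grid)) default_grid(cfg$train$model)
              else cfg$train$grid
      hp <- tune_model(cfg$train$model, tr, labels, grid,
                       folds = cfg$train$tune_folds,
                       seed = cfg$seed)$hyperparams
    }
    models <- train_model(cfg$train$model, hp, tr, labels,
                          repeats = cfg$train$repeats, seed = cfg$seed)
    bundle <- list(models = models, kind = cfg$train$model,
                   hyperparams = models[[1]]$hyperparams,
                   selected = selected, center = zs$center,
                   scale = zs$scale)
    saveRDS(bundle, art(cfg, "model.rds"))
    jsonlite::write_json(
      list(kind = bundle$kind, hyperparams = bundle$hyperparams,
           repeats = cfg$train$repeats, selected = selected,
           center = as.list(zs$center[selected]),
           scale = as.list(zs$scale[selected])),
      art(cfg, "model.json"), auto_unbox = TRUE, digits = NA)
    log_stage(cfg, "train", cfg$train, c("model.rds", "model.json"))
    out$model <- art(cfg, "model.rds")
  }
  if ("predict" %in% stages) {
    fm <- read_features(need(cfg, "features.h5", "extract"))
    bundle <- readRDS(need(cfg, "model.rds", "train"))
    z <- sweep(sweep(unclass(fm), 2, bundle$center), 2, bundle$scale, "/")
    z <- z[, bundle$selected, drop = FALSE]
    votes <- vapply(bundle$models, function(m)
      predict(m, feature_matrix(z, "zscored")), integer(nrow(z)))
    pred <- as.integer(rowMeans(votes) >= 0.5)   # majority, ties positive
    ev <- merge_events(pred, cfg$events$min_consecutive, pp$window_s)
    write.csv(data.frame(window = seq_along(pred) - 1,
                         start_s = (seq_along(pred) - 1) * pp$window_s,
                         pred = pred),
              art(cfg, "predictions.csv"), row.names = FALSE)
    write.csv(data.frame(start = ev$start, stop = ev$stop,
                         start_s = ev$start * pp$window_s,
                         stop_s = ev$stop * pp$window_s),
              art(cfg, "events.csv"), row.names = FALSE)
    log_stage(cfg, "predict", cfg$events, c("predictions.csv", "events.csv"))
    out$predictions <- art(cfg, "predictions.csv")
    out$events <- art(cfg, "events.csv")
  }
  if ("review" %in% stages) {
    ev <- read.csv(need(cfg, "events.csv", "predict"))
    fm <- read_features(need(cfg, "features.h5", "extract"))
    accept <- review_events(ev, fm, cfg$review, pp$window_s)
    write.csv(ev[accept, , drop = FALSE], art(cfg, "curated_events.csv"),
              row.names = FALSE)
    log_stage(cfg, "review", cfg$review["mode"], "curated_events.csv")
    out$curated <- art(cfg, "curated_events.csv")
  }
  if ("metrics" %in% stages) {
    pred <- read.csv(need(cfg, "predictions.csv", "predict"))$pred
    labels <- labels_for(length(pred))
    sm <- segment_metrics(pred, labels)
    pe <- merge_events(pred, cfg$events$min_consecutive, pp$window_s)
    te <- merge_events(labels, 1, pp$window_s, source = "ground_truth")
    em <- event_metrics(pe, te, length(pred) * pp$window_s / 3600)
    jsonlite::write_json(c(sm[setdiff(names(sm), "flags")],
                           em[c("pct_detected", "fdr", "n_pred", "n_true",
                                "n_detected")]),
                         art(cfg, "metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    log_stage(cfg, "metrics", cfg$events, "metrics.json")
    out$metrics <- art(cfg, "metrics.json")
  }
  invisible(out)
}

# Accept/reject each predicted event. Modes: accept_all; decisions (CSV
# with an 'accept' column, one row per event); interactive terminal
# prompt showing times and peak feature values.
review_events <- function(ev, fm, review_cfg, window_s) {
  n <- nrow(ev)
  if (n == 0) return(logical(0))
  mode <- review_cfg$mode
  if (mode == "accept_all") return(rep(TRUE, n))
  if (mode == "decisions") {
    d <- read.csv(review_cfg$decisions)
    if (nrow(d) != n) stop("decision file has ", nrow(d),
                           " rows for ", n, " events")
    return(as.logical(d$accept))
  }
  if (mode != "interactive") stop("unknown review mode: ", mode)
  if (!interactive()) stop("interactive review requires a terminal; use ",
                           "mode 'accept_all' or 'decisions'")
  accept <- logical(n)
  for (i in seq_len(n)) {
    rows <- (ev$start[i] + 1):ev$stop[i]
    peak <- sort(apply(unclass(fm)[rows, , drop = FALSE], 2, max),
                 decreasing = TRUE)[1:3]
    cat(sprintf("event %d/%d: %.0f-%.0f s; peak features: %s\n", i, n,
                ev$start_s[i], ev$stop_s[i],
                paste(names(peak), signif(peak, 3), sep = "=",
                      collapse = ", ")))
    ans <- readline("accept? [y/n] ")
    accept[i] <- tolower(substr(ans, 1, 1)) == "y"
  }
  accept
}
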