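# Shared fixtures, all generated in code. Expensive objects are memoised in
# a session-level cache so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small two-channel synthetic recording for module-level tests.
small_world <- function() {
  memo("small_world", {
    cfg <- synth_config(duration_s = 900, n_seizures = 4, rate = 200,
                        seed = 42)
    g <- generate_recording(cfg)
    seg <- preprocess(g$recording)
    fm <- build_feature_matrix(seg, mouse_feature_spec())
    list(cfg = cfg, gen = g, seg = seg, fm = fm, labels = g$labels)
  })
}

# Full-scale train/test pair at the generator's default study conditions
# (24 planted seizures, ictal_gain 5), used by the end-to-end checks.
accept_world <- function() {
  memo("accept_world", {
    build <- function(seed) {
      g <- generate_recording(synth_config(seed = seed))
      seg <- preprocess(g$recording)
      list(gen = g, fm = build_feature_matrix(seg, mouse_feature_spec()),
           labels = g$labels)
    }
    list(train = build(101L), test = build(102L))
  })
}

# A subject with Gaussian class-conditional features (no signal stage),
# for scheme-harness and leakage tests.
gauss_subject <- function(n = 200, p = 6, sep = 3, pos_frac = 0.2,
                          seed = 1) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, pos_frac)
    if (sum(y) < 2) y[1:2] <- 1L
    if (sum(1 - y) < 2) y[(n - 1):n] <- 0L
    x <- matrix(rnorm(n * p), n, p) + sep * y
    colnames(x) <- paste0("feat", seq_len(p))
    list(features = feature_matrix(x, "raw"), labels = as.integer(y))
  })
}

gauss_dataset <- function(n_subjects, n = 200, sep = 3, seed = 1) {
  ds <- lapply(seq_len(n_subjects), function(s)
    gauss_subject(n = n, sep = sep, seed = seed + s))
  names(ds) <- paste0("subject", seq_len(n_subjects))
  ds
}

# Independent brute-force confusion-table rates, written from the metric
# formulas directly (not via segment_metrics).
brute_rates <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  safe <- function(a, b) if (b == 0) 0 else a / b
  recall <- safe(tp, tp + fn); precision <- safe(tp, tp + fp)
  specificity <- safe(tn, tn + fp)
  f1 <- safe(2 * precision * recall, precision + recall)
  list(tp = tp, tn = tn, fp = fp, fn = fn, recall = recall,
       precision = precision, specificity = specificity, f1 = f1,
       balanced_accuracy = (recall + specificity) / 2)
}

# Independent run-length scan: events as (start, stop) 0-based half-open.
brute_runs <- function(v, min_len) {
  out <- NULL
  i <- 1; n <- length(v)
  while (i <= n) {
    if (v[i] == 1) {
      j <- i
      while (j < n && v[j + 1] == 1) j <- j + 1
      if (j - i + 1 >= min_len) out <- rbind(out, c(i - 1, j))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out)) matrix(integer(0), ncol = 2)
  else cbind(out[, 1], out[, 2])
}
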