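#' Feature set
#'
#' An ordered subset of feature names plus the method that produced it.
#'
#' @param id identifier.
#' @param selected ordered character vector of feature names (no
#'   duplicates).
#' @param method one of `"correlation_prune"`, `"anova_topk"`,
#'   `"mutual_info_topk"`.
#' @param k target count for ranked sets, `NA` for pruning.
#' @return A `feature_set`.
#' @export
feature_set <- function(id, selected, method, k = NA_integer_) {
  stopifnot(!anyDuplicated(selected))
  structure(list(id = id, selected = as.character(selected),
                 method = method, k = k),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set '%s'> method=%s k=%s, %d features\n", x$id,
              x$method, ifelse(is.na(x$k), "-", x$k), length(x$selected)))
  invisible(x)
}

#' Drop highly correlated features
#'
#' Greedy keep-first scan in column order: a feature is dropped when its
#' absolute Pearson correlation with any retained earlier feature exceeds
#' `r_thresh`. Deterministic and idempotent; retained features keep their
#' original order. Zero-variance columns (undefined correlation) are
#' retained and left for the ranking stage to handle.
#'
#' @param fm `feature_matrix` with >= 2 windows.
#' @param r_thresh correlation threshold (0.99 for the 2-channel LFP
#'   configuration, 0.90 for the 18-channel scalp configuration).
#' @return A `feature_set` with `method = "correlation_prune"`.
#' @export
prune_correlated <- function(fm, r_thresh = 0.99) {
  stopifnot(nrow(fm) >= 2)
  cm <- suppressWarnings(abs(cor(unclass(fm))))
  cm[!is.finite(cm)] <- 0
  p <- ncol(fm)
  keep <- logical(p)
  for (j in seq_len(p)) {
    keep[j] <- !any(cm[j, keep] > r_thresh)
  }
  feature_set(sprintf("pruned_r%g", r_thresh), colnames(fm)[keep],
              "correlation_prune")
}

# Vectorized one-way (two-group) ANOVA F statistic per column.
# Degenerate columns (zero within- and between-group variance) get -Inf so
# they rank last; zero within- with non-zero between-group variance gets Inf.
anova_f <- function(x, y) {
  x <- unclass(x)
  i1 <- y == 1L
  n0 <- sum(!i1); n1 <- sum(i1); n <- n0 + n1
  m0 <- colMeans(x[!i1, , drop = FALSE])
  m1 <- colMeans(x[i1, , drop = FALSE])
  m <- colMeans(x)
  ssb <- n0 * (m0 - m)^2 + n1 * (m1 - m)^2
  ssw <- colSums(sweep(x[!i1, , drop = FALSE], 2, m0)^2) +
    colSums(sweep(x[i1, , drop = FALSE], 2, m1)^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- -Inf
  f[is.nan(f)] <- -Inf
  f
}

# Mutual information between a continuous feature and a binary label,
# nearest-neighbour estimator for the discrete/continuous case
# (digamma form, k neighbours within the feature's own class).
mi_knn <- function(x, y, k = 3) {
  n <- length(x)
  classes <- unique(y)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  psi <- digamma
  m <- numeric(n)
  nc <- numeric(n)
  kk <- numeric(n)
  for (cl in classes) {
    idx <- which(ys == cl)
    ncl <- length(idx)
    kc <- min(k, ncl - 1)
    if (kc < 1) return(0)
    xv <- xs[idx]
    for (jj in seq_along(idx)) {
      # distance to the kc-th nearest same-class neighbour (sorted scan)
      lo <- jj; hi <- jj
      for (s in seq_len(kc)) {
        dl <- if (lo > 1) xv[jj] - xv[lo - 1] else Inf
        dr <- if (hi < ncl) xv[hi + 1] - xv[jj] else Inf
        if (dl <= dr) lo <- lo - 1 else hi <- hi + 1
      }
      d <- max(xv[jj] - xv[lo], xv[hi] - xv[jj])
      i <- idx[jj]
      if (d == 0) {
        # ties: count all points at zero distance in the full sample
        m[i] <- sum(xs == xs[i])
        kk[i] <- sum(xv == xv[jj]) - 1
      } else {
        m[i] <- sum(xs >= xs[i] - d & xs <= xs[i] + d)
        kk[i] <- kc
      }
      nc[i] <- ncl
    }
  }
  mi <- psi(n) - mean(psi(nc)) + mean(psi(pmax(kk, 1))) - mean(psi(m))
  max(mi, 0)
}

#' Rank features against the class label
#'
#' `method = "anova"` scores each feature by the one-way F statistic
#' between its class-conditional values; `method = "mutual_info"` by a
#' nearest-neighbour mutual-information estimate. The top `k` features are
#' returned in descending score order, ties broken by original column
#' order; a feature with zero variance in both classes is ranked last.
#'
#' @param fm `feature_matrix`.
#' @param labels 0/1 vector, one per window; both classes must be present.
#' @param method `"anova"` or `"mutual_info"`.
#' @param k number of features to keep (<= ncol(fm)).
#' @return A `feature_set`.
#' @export
rank_univariate <- function(fm, labels, method = c("anova", "mutual_info"),
                            k) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(fm))
  if (length(unique(labels)) < 2)
    stop("both classes must be present to rank features")
  if (k > ncol(fm)) stop("k exceeds the number of features")
  score <- switch(method,
    anova = anova_f(fm, labels),
    mutual_info = apply(unclass(fm), 2, mi_knn, y = labels)
  )
  ord <- order(-score, seq_along(score))
  sel <- colnames(fm)[ord[seq_len(k)]]
  feature_set(sprintf("%s_top%d", method, k), sel,
              paste0(method, "_topk"), k = as.integer(k))
}

#' Construct the standard family of feature sets
#'
#' First prunes features correlated above `r_thresh`; then, for each `k`
#' in `ks` and each ranking method, ranks the pruned features against the
#' label and keeps the top `k`. With `include_pruned = TRUE` (the
#' 2-channel LFP construction) the pruned set itself is feature-set 1,
#' giving `1 + |methods| * |ks|` sets (e.g. 5 sets for both methods with
#' ks = c(4, 8)); the scalp-EEG construction uses `include_pruned = FALSE`
#' with `methods = "anova"`, ks = c(10, 20, 40).
#'
#' @param fm raw or z-scored `feature_matrix` (training windows only).
#' @param labels 0/1 window labels.
#' @param r_thresh pruning threshold.
#' @param ks integer vector of ranked-set sizes (possibly empty).
#' @param methods ranking methods to apply.
#' @param include_pruned include the pruned set as the first feature set.
#' @return List of `feature_set` objects.
#' @export
build_feature_sets <- function(fm, labels, r_thresh = 0.99, ks = c(4, 8),
                               methods = c("anova", "mutual_info"),
                               include_pruned = TRUE) {
  pruned <- prune_correlated(fm, r_thresh)
  fmp <- fm[, pruned$selected, drop = FALSE]
  sets <- if (include_pruned) list(pruned) else list()
  for (method in methods) {
    for (k in ks) {
      k <- min(k, ncol(fmp))
      sets <- c(sets, list(rank_univariate(fmp, labels, method, k)))
    }
  }
  sets
}
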