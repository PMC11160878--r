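#' Interpretable classifier families
#'
#' Four model kinds are supported, chosen for interpretability and their
#' ability to train on very large window collections:
#' \describe{
#'   \item{gnb}{Gaussian naive Bayes with variance smoothing
#'     (`var_smoothing` times the largest feature variance is added to all
#'     class-conditional variances).}
#'   \item{dtree}{CART decision tree (via \pkg{rpart}); hyperparameters
#'     `maxdepth`, `criterion` (`"gini"` or `"information"`), `minbucket`,
#'     `cp`.}
#'   \item{sgd_linear}{linear model fitted by stochastic gradient descent;
#'     `loss = "log"` gives logistic regression, `loss = "hinge"` a linear
#'     SVM; penalties `l2`, `l1`, `elasticnet` with strength `alpha`.}
#'   \item{pac}{passive-aggressive classifier (PA-I, hinge loss) with
#'     aggressiveness `C`.}
#' }
#'
#' @param kind one of `"gnb"`, `"dtree"`, `"sgd_linear"`, `"pac"`.
#' @param x numeric feature matrix (windows x features) with column names.
#' @param y 0/1 labels, one per row of `x`.
#' @param hyperparams named list; unset entries take the defaults from
#'   [default_hyperparams()].
#' @param seed integer seed for the stochastic kinds (sample shuffling);
#'   ignored by gnb and dtree.
#' @return A `seiz_model` with fields `kind`, `hyperparams`, `fit`,
#'   `feature_names`.
#' @export
fit_model <- function(kind = c("gnb", "dtree", "sgd_linear", "pac"),
                      x, y, hyperparams = list(), seed = NULL) {
  kind <- match.arg(kind)
  x <- unclass(x)
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)))
  hp <- utils::modifyList(default_hyperparams(kind), hyperparams)
  fit <- switch(kind,
    gnb = fit_gnb(x, y, hp),
    dtree = fit_dtree(x, y, hp),
    sgd_linear = fit_sgd(x, y, hp, seed),
    pac = fit_pac(x, y, hp, seed)
  )
  structure(list(kind = kind, hyperparams = hp, fit = fit,
                 feature_names = colnames(x)),
            class = "seiz_model")
}

#' Default hyperparameters per model kind
#' @param kind model kind.
#' @return Named list of defaults.
#' @export
default_hyperparams <- function(kind) {
  switch(kind,
    gnb = list(var_smoothing = 1e-9),
    dtree = list(maxdepth = 30, criterion = "gini", minbucket = 1,
                 cp = 0.001),
    sgd_linear = list(loss = "log", penalty = "l2", alpha = 1e-4,
                      l1_ratio = 0.15, epochs = 5),
    pac = list(C = 1, epochs = 5),
    stop("unknown model kind: ", kind)
  )
}

#' Default tuning grids per model kind
#'
#' The grids searched during balanced-accuracy tuning. Small by design;
#' override any entry through the `grid` argument of [tune_model()].
#'
#' @param kind model kind.
#' @return Named list of vectors (the grid axes).
#' @export
default_grid <- function(kind) {
  switch(kind,
    gnb = list(var_smoothing = 10^seq(-12, -3)),
    dtree = list(maxdepth = c(3, 5, 10, 30),
                 criterion = c("gini", "information"),
                 minbucket = c(1, 5, 20)),
    sgd_linear = list(loss = c("log", "hinge"),
                      alpha = 10^seq(-6, -1),
                      penalty = c("l2", "l1", "elasticnet")),
    pac = list(C = 10^seq(-3, 2)),
    stop("unknown model kind: ", kind)
  )
}

fit_gnb <- function(x, y, hp) {
  stats_c <- function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    list(mean = colMeans(xi),
         var = colMeans(sweep(xi, 2, colMeans(xi))^2),
         prior = nrow(xi) / nrow(x))
  }
  s0 <- stats_c(0L); s1 <- stats_c(1L)
  glob <- colMeans(sweep(x, 2, colMeans(x))^2)
  eps <- hp$var_smoothing * max(glob)
  if (eps <= 0) eps <- hp$var_smoothing   # all-constant degenerate input
  list(theta = rbind(`0` = s0$mean, `1` = s1$mean),
       sigma2 = rbind(`0` = s0$var + eps, `1` = s1$var + eps),
       prior = c(`0` = s0$prior, `1` = s1$prior), eps = eps)
}

fit_dtree <- function(x, y, hp) {
  df <- as.data.frame(x)
  safe <- paste0("f", seq_len(ncol(x)))
  names(df) <- safe
  df$.y <- factor(y, levels = c(0, 1))
  split <- if (hp$criterion == "gini") "gini" else "information"
  fit <- rpart::rpart(
    .y ~ ., data = df, method = "class",
    parms = list(split = split),
    control = rpart::rpart.control(
      maxdepth = min(hp$maxdepth, 30), minbucket = hp$minbucket,
      minsplit = max(2L, 2L * hp$minbucket), cp = hp$cp,
      maxcompete = 0, maxsurrogate = 0, usesurrogate = 0, xval = 0)
  )
  list(rpart = fit, safe_names = safe)
}

# sklearn-style 'optimal' learning-rate schedule for SGD.
sgd_schedule <- function(alpha) {
  typw <- sqrt(1 / sqrt(alpha))
  eta0 <- typw / max(1, 1)     # |dloss| at the typical margin is ~1 for both losses
  t0 <- 1 / (eta0 * alpha)
  function(t) 1 / (alpha * (t0 + t))
}

# Both stochastic fits return the average of the iterates over the final
# epoch (Polyak averaging), which stabilizes the learned direction.
fit_sgd <- function(x, y, hp, seed) {
  ys <- ifelse(y == 1L, 1, -1)
  n <- nrow(x); p <- ncol(x)
  w <- numeric(p); b <- 0
  wsum <- numeric(p); bsum <- 0
  eta <- sgd_schedule(hp$alpha)
  t <- 0
  local_seed(if (is.null(seed)) 0L else seed, {
    for (ep in seq_len(hp$epochs)) {
      last <- ep == hp$epochs
      for (i in sample.int(n)) {
        t <- t + 1
        e <- eta(t)
        z <- sum(w * x[i, ]) + b
        g <- switch(hp$loss,
          log = -ys[i] / (1 + exp(ys[i] * z)),
          hinge = if (ys[i] * z < 1) -ys[i] else 0,
          stop("unknown loss: ", hp$loss))
        pen <- switch(hp$penalty,
          l2 = w,
          l1 = sign(w),
          elasticnet = hp$l1_ratio * sign(w) + (1 - hp$l1_ratio) * w,
          stop("unknown penalty: ", hp$penalty))
        w <- w - e * (g * x[i, ] + hp$alpha * pen)
        b <- b - e * g
        if (last) { wsum <- wsum + w; bsum <- bsum + b }
      }
    }
  })
  list(w = stats::setNames(wsum / n, colnames(x)), b = bsum / n)
}

fit_pac <- function(x, y, hp, seed) {
  ys <- ifelse(y == 1L, 1, -1)
  n <- nrow(x); p <- ncol(x)
  w <- numeric(p); b <- 0
  wsum <- numeric(p); bsum <- 0
  local_seed(if (is.null(seed)) 0L else seed, {
    for (ep in seq_len(hp$epochs)) {
      last <- ep == hp$epochs
      for (i in sample.int(n)) {
        z <- sum(w * x[i, ]) + b
        l <- max(0, 1 - ys[i] * z)
        if (l > 0) {
          tau <- min(hp$C, l / (sum(x[i, ]^2) + 1))
          w <- w + tau * ys[i] * x[i, ]
          b <- b + tau * ys[i]
        }
        if (last) { wsum <- wsum + w; bsum <- bsum + b }
      }
    }
  })
  list(w = stats::setNames(wsum / n, colnames(x)), b = bsum / n)
}

#' Predict per-window classes
#'
#' @param object a `seiz_model`.
#' @param fm feature matrix whose column names match the model's
#'   `feature_names`.
#' @param ... unused.
#' @return Integer 0/1 vector, one prediction per window.
#' @export
predict.seiz_model <- function(object, fm, ...) {
  x <- unclass(fm)
  if (!identical(colnames(x), object$feature_names))
    stop("feature names do not match the trained model")
  switch(object$kind,
    gnb = {
      f <- object$fit
      ll <- function(cl) {
        th <- f$theta[cl, ]; s2 <- f$sigma2[cl, ]
        rowSums(sweep(sweep(x, 2, th)^2, 2, -2 * s2, "/") +
                  matrix(-0.5 * log(2 * pi * s2), nrow(x), ncol(x),
                         byrow = TRUE)) + log(f$prior[cl])
      }
      as.integer(ll("1") > ll("0"))
    },
    dtree = {
      df <- as.data.frame(x)
      names(df) <- object$fit$safe_names
      as.integer(as.character(predict(object$fit$rpart, df, type = "class")))
    },
    as.integer(x %*% object$fit$w + object$fit$b > 0)
  )
}

#' @export
print.seiz_model <- function(x, ...) {
  cat(sprintf("<seiz_model %s> %d features; hyperparams: %s\n", x$kind,
              length(x$feature_names),
              paste(names(x$hyperparams), unlist(x$hyperparams),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Per-feature contributions of a fitted model
#'
#' The interpretability metric depends on the model kind: Gini importance
#' for trees (summed split improvement per feature), absolute weights for
#' the linear kinds, and for Gaussian naive Bayes the feature separation
#' score \eqn{|\mu_1 - \mu_0| / (\sigma_1 + \sigma_0)} computed from the
#' fitted class-conditional parameters. Scores are normalized to sum to 1.
#'
#' @param model a fitted `seiz_model`.
#' @return Named numeric vector (one entry per feature, in training
#'   column order) with attribute `metric` naming the score used.
#' @export
feature_contributions <- function(model) {
  stopifnot(inherits(model, "seiz_model"))
  fn <- model$feature_names
  raw <- switch(model$kind,
    gnb = {
      f <- model$fit
      s <- sqrt(f$sigma2)
      if (any(s["0", ] + s["1", ] == 0))
        stop("zero class SDs; increase var_smoothing")
      abs(f$theta["1", ] - f$theta["0", ]) / (s["0", ] + s["1", ])
    },
    dtree = gini_importance(model$fit, fn),
    abs(model$fit$w)
  )
  metric <- switch(model$kind, gnb = "separation_score",
                   dtree = "gini_importance", "abs_weight")
  tot <- sum(raw)
  if (tot == 0) {
    warning("all contributions zero; returning uniform scores")
    raw <- rep(1, length(raw))
    tot <- length(raw)
  }
  structure(stats::setNames(raw / tot, fn), metric = metric)
}

# Gini importance from rpart primary splits (trees are grown with
# maxcompete = maxsurrogate = 0, so the splits matrix has exactly one row
# per internal node, in frame order).
gini_importance <- function(fit, feature_names) {
  rp <- fit$rpart
  imp <- stats::setNames(numeric(length(feature_names)), feature_names)
  fr <- rp$frame
  internal <- fr$var != "<leaf>"
  if (!any(internal)) return(imp)
  vars <- as.character(fr$var[internal])
  improve <- rp$splits[, "improve"]
  idx <- match(vars, fit$safe_names)
  for (i in seq_along(vars))
    imp[idx[i]] <- imp[idx[i]] + improve[i]
  imp
}
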