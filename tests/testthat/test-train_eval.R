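# Two well-separated Gaussian classes with known parameters.
two_gauss <- function(n = 400, p = 4, sep = 3, pos_frac = 0.25, seed = 1) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, pos_frac)
    x <- matrix(rnorm(n * p), n, p)
    x[, 1:2] <- x[, 1:2] + sep * y
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, y = as.integer(y))
  })
}

test_that("gnb recovers class parameters and matches naiveBayes", {
  d <- two_gauss(n = 600, seed = 2)
  m <- fit_model("gnb", d$x, d$y)
  n1 <- sum(d$y)
  # class means within 3 standard errors of the generator truth
  expect_lt(max(abs(m$fit$theta["1", 1:2] - 3)), 3 / sqrt(n1))
  expect_lt(max(abs(m$fit$theta["0", ])), 3 / sqrt(600 - n1))

  skip_if_not_installed("e1071")
  nb <- e1071::naiveBayes(data.frame(d$x), factor(d$y))
  agree <- mean(predict(m, d$x) ==
                  as.integer(as.character(predict(nb, data.frame(d$x)))))
  expect_gte(agree, 0.99)
})

test_that("gnb predicts the class whose mean a window sits on", {
  m <- fit_model("gnb", rbind(matrix(0, 10, 2), matrix(4, 10, 2)) |>
                   (\(x) { colnames(x) <- c("a", "b"); x })(),
                 rep(c(0L, 1L), each = 10))
  at0 <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "b")))
  at1 <- matrix(4, 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(m, at0), 0L)
  expect_equal(predict(m, at1), 1L)
})

test_that("linear kinds follow the sign of the decision function", {
  m <- structure(list(kind = "sgd_linear",
                      hyperparams = list(),
                      fit = list(w = c(a = 2, b = -1), b = -1),
                      feature_names = c("a", "b")),
                 class = "seiz_model")
  x <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(m, x), c(1L, 0L))   # 2-1>0 ; -1-1<0
  expect_error(predict(m, x[, 2:1]), "feature names")
})

test_that("every kind separates high-margin classes", {
  d <- two_gauss(n = 500, sep = 4, seed = 3)
  for (kind in c("gnb", "dtree", "sgd_linear", "pac")) {
    m <- fit_model(kind, d$x, d$y, seed = 5)
    sm <- segment_metrics(predict(m, d$x), d$y)
    expect_gte(sm$recall, 0.95)
    expect_gte(sm$specificity, 0.9)
  }
  # linear kinds recover the separating direction up to scale
  for (kind in c("sgd_linear", "pac")) {
    w <- fit_model(kind, d$x, d$y, seed = 5)$fit$w
    cosine <- sum(w * c(1, 1, 0, 0)) / sqrt(sum(w^2) * 2)
    expect_gt(cosine, 0.95)
  }
})

test_that("stochastic fits are deterministic under a fixed seed", {
  d <- two_gauss(seed = 4)
  for (kind in c("sgd_linear", "pac")) {
    m1 <- fit_model(kind, d$x, d$y, seed = 11)
    m2 <- fit_model(kind, d$x, d$y, seed = 11)
    expect_identical(m1$fit, m2$fit)
  }
})

test_that("feature contributions are normalized and kind-appropriate", {
  # closed-form separation scores from a hand-built gnb fit
  m <- structure(list(
    kind = "gnb", hyperparams = list(var_smoothing = 0),
    fit = list(theta = rbind(`0` = c(f1 = 0, f2 = 1),
                             `1` = c(f1 = 2, f2 = 1)),
               sigma2 = rbind(`0` = c(1, 4), `1` = c(1, 4)), eps = 0),
    feature_names = c("f1", "f2")), class = "seiz_model")
  fc <- feature_contributions(m)
  expect_equal(attr(fc, "metric"), "separation_score")
  # raw scores: |2-0|/(1+1) = 1 and |1-1|/(2+2) = 0
  expect_equal(as.numeric(fc), c(1, 0))

  mlin <- structure(list(kind = "sgd_linear", hyperparams = list(),
                         fit = list(w = c(3, 1, 0, 0), b = 0),
                         feature_names = paste0("f", 1:4)),
                    class = "seiz_model")
  expect_equal(as.numeric(feature_contributions(mlin)),
               c(0.75, 0.25, 0, 0))

  d <- two_gauss(seed = 6)
  for (kind in c("gnb", "dtree", "sgd_linear", "pac")) {
    fc <- feature_contributions(fit_model(kind, d$x, d$y, seed = 2))
    expect_true(all(fc >= 0))
    expect_equal(sum(fc), 1, tolerance = 1e-9)
    expect_equal(names(fc), paste0("f", 1:4))
  }
  # the tree should concentrate importance on the informative features
  fcd <- feature_contributions(fit_model("dtree", d$x, d$y))
  expect_gt(sum(fcd[c("f1", "f2")]), 0.9)
})

test_that("stratified folds preserve class proportions", {
  y <- c(rep(1, 37), rep(0, 363))
  fold <- stratified_folds(y, 4, seed = 9)
  global <- mean(y)
  for (f in 1:4) {
    nf <- sum(fold == f)
    # positive count within one window of the proportional share
    expect_lte(abs(sum(y[fold == f]) - global * nf), 1)
  }
})

test_that("grid search maximizes balanced accuracy and honours edge cases", {
  d <- two_gauss(n = 300, sep = 4, seed = 7)
  fm <- feature_matrix(d$x)

  one <- tune_model("gnb", fm, d$y, grid = list(var_smoothing = 1e-9))
  expect_equal(one$hyperparams$var_smoothing, 1e-9)

  # crushing regularization drives the linear model to chance
  tn <- tune_model("sgd_linear", fm, d$y,
                   grid = list(alpha = c(1e-4, 1e4)), seed = 3)
  expect_equal(tn$hyperparams$alpha, 1e-4)
  expect_gt(tn$score, 0.9)
  expect_lte(tn$table$balanced_accuracy[tn$table$alpha == 1e4], tn$score)

  few <- d; few$y <- c(rep(1L, 2), rep(0L, 298))
  expect_error(tune_model("gnb", fm, few$y, folds = 4), "minority")
})

test_that("replicate training uses distinct stratified 80% subsets", {
  d <- two_gauss(seed = 8)
  ms <- train_model("gnb", list(), feature_matrix(d$x), d$y,
                    repeats = 5, seed = 13)
  expect_length(ms, 5)
  idx <- lapply(ms, attr, "train_idx")
  for (i in seq_along(idx))
    expect_equal(length(idx[[i]]) / length(d$y), 0.8, tolerance = 0.02)
  # the held-out fifths partition the data
  held <- lapply(idx, function(i) setdiff(seq_along(d$y), i))
  expect_setequal(unlist(held), seq_along(d$y))
  expect_equal(sum(lengths(held)), length(d$y))

  again <- train_model("gnb", list(), feature_matrix(d$x), d$y,
                       repeats = 5, seed = 13)
  expect_identical(lapply(ms, `[[`, "fit"), lapply(again, `[[`, "fit"))
})

test_that("sliding-window upsampling enumerates sub-window placements", {
  w <- small_world()
  seg <- w$seg
  lab <- integer(n_windows(seg))
  lab[11:12] <- 1L                       # one 10-s seizure at 50-60 s
  up <- upsample_seizures(seg, lab, step_s = 0.5)
  # 5-s placements in a 10-s span at 0.5-s stride: offsets 0, 0.5, ..., 5.0
  expect_equal(sum(up$labels), 11)
  expect_equal(up$n_base, n_windows(seg))
  expect_equal(dim(up$windows)[1], n_windows(seg) + 9)  # 2 base + 9 new
  # new windows are cut from the continuous signal, not duplicated
  news <- up$start_s[(up$n_base + 1):length(up$start_s)]
  expect_equal(sort(news), 50 + setdiff(seq(0, 5, 0.5), c(0, 5)))

  same <- upsample_seizures(seg, lab, step_s = seg$window_s)
  expect_equal(dim(same$windows)[1], n_windows(seg))
  none <- upsample_seizures(seg, integer(n_windows(seg)), 0.5)
  expect_equal(dim(none$windows)[1], n_windows(seg))
  expect_error(upsample_seizures(seg, lab, 0), "positive")
})

test_that("cross-validation schemes produce the documented fold layouts", {
  ds24 <- gauss_dataset(24, n = 60, seed = 20)
  rep24 <- run_scheme("inter_subject", ds24,
                      config = list(select = FALSE, window_s = 5))
  expect_length(rep24, 4)
  for (r in rep24) {
    expect_length(r$train_subjects, 18)
    expect_length(r$test_subjects, 6)
    expect_length(intersect(r$train_subjects, r$test_subjects), 0)
  }

  ds16 <- gauss_dataset(16, n = 60, seed = 40)
  rep16 <- run_scheme("inter_subject", ds16,
                      config = list(select = FALSE))
  expect_equal(vapply(rep16, function(r) length(r$train_subjects), 0L),
               rep(12L, 4))

  ds3 <- gauss_dataset(3, n = 80, seed = 60)
  loo <- run_scheme("leave_one_out", ds3, config = list(select = FALSE))
  expect_length(loo, 3)
  expect_setequal(vapply(loo, `[[`, "", "test_subjects"), names(ds3))
  for (r in loo) expect_false(r$test_subjects %in% r$train_subjects)

  intra <- run_scheme("intra_subject", gauss_dataset(1, n = 160, seed = 80),
                      config = list(select = FALSE, intra_folds = 4))
  expect_length(intra, 4)
  tests <- unlist(lapply(intra, `[[`, "test_idx"))
  expect_setequal(tests, seq_len(160))   # outer folds partition the windows
})
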