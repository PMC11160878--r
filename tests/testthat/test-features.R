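mouse_spec <- mouse_feature_spec()

test_that("single-channel features match their defining formulas", {
  sp <- feature_spec(c("autocorrelation", "line_length", "rms", "mad",
                       "variance", "std", "energy"))
  x <- c(0, 1, 0, 1)
  f <- single_channel_features(x, 100, sp)
  expect_equal(unname(f["line_length"]), 3)   # |1|+|−1|+|1|
  expect_equal(unname(f["autocorrelation"]), sum(x[-4] * x[-1]))
  expect_equal(unname(f["energy"]), 2)

  # degenerate constant window
  g <- single_channel_features(rep(-3, 100), 100, sp)
  expect_equal(unname(g[c("line_length", "variance", "std", "mad")]),
               rep(0, 4))
  expect_equal(unname(g["rms"]), 3)

  # brute-force oracle on a random window
  y <- withr::with_seed(1, rnorm(250))
  h <- single_channel_features(y, 100, sp)
  expect_equal(unname(h["rms"]), sqrt(mean(y^2)))
  expect_equal(unname(h["mad"]), mean(abs(y - mean(y))))
  expect_equal(unname(h["variance"]), mean((y - mean(y))^2))
  expect_equal(unname(h["std"]), sqrt(mean((y - mean(y))^2)))
  expect_error(single_channel_features(1, 100, sp), "2 samples")
})

test_that("envelope and band power recover a pure sinusoid", {
  rate <- 100; n <- 500; A <- 2
  t <- (seq_len(n) - 1) / rate
  x <- A * sin(2 * pi * 10 * t)     # 10 Hz: integer cycles in the window
  sp <- feature_spec(c("envelope", "power"),
                     bands = list(in_band = c(8, 12), out_band = c(20, 40)))
  f <- single_channel_features(x, rate, sp)
  expect_equal(unname(f["envelope"]), A, tolerance = 1e-8)
  expect_equal(unname(f["power_in_band"]), A^2 / 2, tolerance = 1e-8)
  expect_lt(unname(f["power_out_band"]), 1e-10)
})

test_that("band powers partition the window variance (Parseval)", {
  rate <- 100; n <- 500
  bands <- list(c(0.01, 10), c(10.01, 25), c(25.01, 50))
  sp <- feature_spec("power", bands = bands)
  for (s in 1:5) {
    x <- withr::with_seed(s, rnorm(n))
    f <- single_channel_features(x, rate, sp)
    expect_equal(unname(sum(f)), mean((x - mean(x))^2), tolerance = 1e-10)
  }
})

test_that("cross-channel features behave under self- and anti-pairing", {
  w <- withr::with_seed(2, rnorm(300))
  f <- cross_channel_features(w, w)
  expect_equal(unname(f["cross_correlation"]), 1)
  expect_equal(unname(f["covariance"]), mean((w - mean(w))^2))
  g <- cross_channel_features(w, -w)
  expect_equal(unname(g["cross_correlation"]), -1)
  expect_equal(unname(g["abs_covariance"]), mean((w - mean(w))^2))

  for (s in 1:5) {
    u <- withr::with_seed(100 + s, rnorm(500))
    v <- withr::with_seed(200 + s, rnorm(500))
    expect_lt(abs(cross_channel_features(u, v)["cross_correlation"]), 0.15)
  }
  expect_warning(z <- cross_channel_features(rep(1, 10), rnorm(10)),
                 "zero-variance")
  expect_equal(unname(z["cross_correlation"]), 0)
  expect_error(cross_channel_features(1:3, 1:4), "equal length")
})

make_seg <- function(arr, rate = 100, window_s = 5,
                     channels = paste0("ch", seq_len(dim(arr)[2]))) {
  dimnames(arr) <- list(NULL, channels, NULL)
  structure(list(windows = arr, rate = rate, window_s = window_s,
                 channels = channels, source_id = "fix",
                 start_s = (seq_len(dim(arr)[1]) - 1) * window_s,
                 outlier_sd = Inf,
                 signal = matrix(0, dim(arr)[1] * dim(arr)[3], dim(arr)[2])),
            class = "segmented_recording")
}

test_that("feature matrix dimensionality matches the channel configuration", {
  arr2 <- withr::with_seed(3, array(rnorm(4 * 2 * 500), c(4, 2, 500)))
  fm2 <- build_feature_matrix(make_seg(arr2, channels = c("vHPC", "FC")),
                              mouse_spec)
  expect_equal(ncol(fm2), 21)    # 9 per channel + 3 cross
  expect_equal(sum(grepl("_vHPC-FC$", colnames(fm2))), 3)

  arr18 <- withr::with_seed(4, array(rnorm(3 * 18 * 500), c(3, 18, 500)))
  fm18 <- build_feature_matrix(
    make_seg(arr18, rate = 256, channels = scalp_montage_18()),
    human_feature_spec())
  expect_equal(ncol(fm18), 216)  # 12 features x 18 channels, no cross

  arr1 <- withr::with_seed(5, array(rnorm(4 * 1 * 500), c(4, 1, 500)))
  fm1 <- build_feature_matrix(make_seg(arr1), mouse_spec)
  expect_equal(ncol(fm1), 9)     # no pairs exist for one channel
})

test_that("channel permutation permutes feature blocks identically", {
  arr <- withr::with_seed(6, array(rnorm(3 * 2 * 200), c(3, 2, 200)))
  sega <- make_seg(arr, channels = c("A", "B"))
  segb <- make_seg(arr[, 2:1, , drop = FALSE], channels = c("B", "A"))
  fa <- build_feature_matrix(sega, mouse_spec)
  fb <- build_feature_matrix(segb, mouse_spec)
  for (nm in grep("_A$|_B$", colnames(fa), value = TRUE))
    expect_equal(fb[, nm], fa[, nm])
})

test_that("features scale correctly with signal amplitude", {
  x <- withr::with_seed(7, rnorm(500))
  y <- withr::with_seed(8, rnorm(500))
  k <- 3.7
  sp <- feature_spec(c("line_length", "rms", "mad", "variance", "std",
                       "energy", "envelope", "power"),
                     bands = list(c(2, 40)))
  f1 <- single_channel_features(x, 100, sp)
  fk <- single_channel_features(k * x, 100, sp)
  lin <- c("line_length", "rms", "mad", "std", "envelope")
  quad <- c("variance", "energy", "power_2_40")
  expect_equal(unname(fk[lin]), unname(k * f1[lin]))
  expect_equal(unname(fk[quad]), unname(k^2 * f1[quad]))
  c1 <- cross_channel_features(x, y)
  ck <- cross_channel_features(k * x, k * y)
  expect_equal(unname(ck["cross_correlation"]),
               unname(c1["cross_correlation"]))
  expect_equal(unname(ck["covariance"]), unname(k^2 * c1["covariance"]))
})

test_that("ictal windows dominate background on the standard features", {
  w <- small_world()
  fm <- w$fm
  ictal <- w$labels == 1
  for (feat in c("line_length_vHPC", "variance_vHPC", "envelope_vHPC")) {
    expect_gt(median(fm[ictal, feat]), median(fm[!ictal, feat]))
  }
})

test_that("z-scoring is fitted on training data and applied frozen", {
  x <- withr::with_seed(9, matrix(rnorm(200 * 5), 200, 5))
  colnames(x) <- paste0("f", 1:5)
  ho <- withr::with_seed(10, matrix(rnorm(400 * 5), 400, 5))
  colnames(ho) <- colnames(x)
  zs <- zscore_fit_apply(feature_matrix(x), list(feature_matrix(ho)))
  expect_lt(max(abs(colMeans(zs$train))), 1e-10)
  expect_lt(max(abs(apply(zs$train, 2, sd) - 1)), 1e-10)
  # held-out matrix from the same distribution: means within 3/sqrt(n)
  expect_lt(max(abs(colMeans(zs$others[[1]]))), 3 / sqrt(400))

  xc <- cbind(x, const = 1)
  expect_warning(z2 <- zscore_fit_apply(feature_matrix(xc)), "zero-SD")
  expect_equal(as.numeric(z2$train[, "const"]), rep(0, 200))

  bad <- feature_matrix(matrix(rnorm(20), 10, 2,
                               dimnames = list(NULL, c("a", "b"))))
  expect_error(zscore_fit_apply(feature_matrix(x), list(bad)),
               "do not match")
})

test_that("feature matrices round-trip through the HDF5 store", {
  w <- small_world()
  zs <- zscore_fit_apply(w$fm)
  path <- withr::local_tempfile(fileext = ".h5")
  write_features(zs$train, path)
  back <- read_features(path)
  expect_equal(unclass(back), unclass(zs$train), ignore_attr = TRUE)
  expect_equal(colnames(back), colnames(zs$train))
  expect_equal(attr(back, "norm_state"), "zscored")
  expect_equal(attr(back, "center"), attr(zs$train, "center"))
})
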