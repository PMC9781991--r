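test_that("hand-computable predictor values are exact", {
  expect_equal(compute_predictor(c(1, -1, 1, -1), "MAV"), 1)
  expect_equal(compute_predictor(c(1, -1, 1, -1), "ZC"), 3)
  expect_equal(compute_predictor(c(1, 2, 0), "SSI"), 5)
  expect_equal(compute_predictor(c(1, 2, 0), "IEMG"), 3)
  expect_equal(compute_predictor(c(1, 2, 0), "RMS"), sqrt(5 / 3))
  expect_equal(compute_predictor(c(1, 2, 0), "WL"), 3)  # |2-1| + |0-2|
  expect_error(compute_predictor(c(1, 2, 0), "XYZ"), "unknown predictor")
  expect_error(compute_predictor(c(1, 2), "MAV"), "at least 3")
})

test_that("ZC matches a brute-force sign-change count", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(100)
    brute <- sum(vapply(seq_len(99), function(j) {
      x[j] * x[j + 1] < 0
    }, logical(1)))
    expect_equal(compute_predictor(x, "ZC"), brute)
  }
})

test_that("kurtosis and skewness agree with the independent moment estimators", {
  set.seed(12)
  x <- rnorm(500)
  expect_equal(compute_predictor(x, "K"), e1071::kurtosis(x, type = 1) + 3,
               tolerance = 1e-12)
  expect_equal(compute_predictor(x, "SK"), e1071::skewness(x, type = 1),
               tolerance = 1e-12)
  expect_equal(compute_predictor(x, "MAD"), stats::mad(x, constant = 1))
})

test_that("amplitude scaling acts linearly or not at all, as each definition dictates", {
  set.seed(13)
  x <- rnorm(300)
  g <- 3.7
  linear <- c("MAV", "RMS", "STD", "IEMG", "WL", "AAC", "DASDV", "MAD")
  for (p in linear) {
    expect_equal(compute_predictor(g * x, p), g * compute_predictor(x, p),
                 tolerance = 1e-10, label = p)
  }
  invariant <- c("ZC", "SSC", "K", "SK", "FC", "SE")
  for (p in invariant) {
    expect_equal(compute_predictor(g * x, p), compute_predictor(x, p),
                 tolerance = 1e-8, label = p)
  }
})

test_that("regular signals score low sample entropy and near-unit fractal dimension", {
  t <- seq(0, 1, length.out = 500)
  sine <- sin(2 * pi * 5 * t)
  set.seed(14)
  noise <- rnorm(500)
  expect_lt(compute_predictor(sine, "SE"), compute_predictor(noise, "SE"))
  expect_lt(compute_predictor(sine, "FC"), 1.2)
  expect_gt(compute_predictor(noise, "FC"), 1.8)
})

test_that("extraction produces the channel-major layout with one row per unit", {
  db <- tiny_db()
  preds <- c("MAV", "RMS", "ZC", "WL")
  fm <- extract_features(db, preds, trim_start = 0.2)
  expect_equal(dim(fm$values), c(18, 2 * 4))
  expect_equal(colnames(fm$values)[1:4], paste0("ch1_", preds))
  expect_equal(colnames(fm$values)[5:8], paste0("ch2_", preds))

  wspec <- window_spec(100, 40)
  fm_w <- extract_features(db, preds, wspec = wspec, trim_start = 0.2)
  nw <- n_windows(400, 50, 30)
  expect_equal(nrow(fm_w$values), 18 * nw)
  expect_equal(max(fm_w$meta$window), nw)

  # single recording, single predictor, 1 channel reduces to compute_predictor
  rec <- db[[1]]
  rec$samples <- rec$samples[, 1, drop = FALSE]
  fm1 <- extract_features(list(rec), "RMS")
  expect_equal(unname(fm1$values[1, 1]),
               compute_predictor(rec$samples[, 1], "RMS"))
})

test_that("segmented and unsegmented extraction agree for a one-window recording", {
  rec <- emgselect:::new_recording(matrix(rnorm(500), ncol = 2), fs = 1000,
                                   subject = 1, movement = "M",
                                   repetition = 1)
  un <- extract_features(list(rec), c("MAV", "ZC", "SSI"))
  seg <- extract_features(list(rec), c("MAV", "ZC", "SSI"),
                          wspec = window_spec(250, 190))
  expect_equal(nrow(seg$values), 1)
  expect_equal(seg$values[1, ], un$values[1, ])
})

test_that("column selection preserves order and refuses empty masks", {
  db <- tiny_db()
  fm <- extract_features(db, c("MAV", "RMS", "ZC"), trim_start = 0.2)
  all_on <- select_columns(fm, rep(1, 6))
  expect_identical(all_on$values, fm$values)
  sub <- select_columns(fm, c(1, 0, 1, 0, 0, 1))
  expect_equal(colnames(sub$values), c("ch1_MAV", "ch1_ZC", "ch2_ZC"))
  expect_error(select_columns(fm, rep(0, 6)), "no columns")
  expect_error(select_columns(fm, c(1, 0)), "length")
})

test_that("dropping p predictors removes channels * p columns", {
  db <- tiny_db()
  fm <- extract_features(db, c("MAV", "RMS", "ZC", "WL"), trim_start = 0.2)
  red <- drop_predictors(fm, c("RMS", "WL"))
  expect_equal(ncol(red$values), ncol(fm$values) - 2 * 2)
  expect_equal(red$predictors, c("MAV", "ZC"))
  expect_error(drop_predictors(fm, "nope"), "not present")
  expect_error(drop_predictors(fm, c("MAV", "RMS", "ZC", "WL")), "all")
})

test_that("feature-matrix CSV round trip preserves values, layout and labels", {
  db <- tiny_db()
  fm <- extract_features(db, c("MAV", "ZC"), wspec = window_spec(200, 100),
                         trim_start = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$predictors, fm$predictors)
  expect_equal(back$channels, fm$channels)
  expect_lt(max(abs(back$values - fm$values)), 1e-9)
  expect_equal(back$meta$movement, fm$meta$movement)
  expect_equal(back$meta$window, fm$meta$window)
})
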