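test_that("class metrics evaluate the confusion-count formulas exactly", {
  m <- class_metrics(TP = 5, TN = 5, FP = 0, FN = 0)
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity",
                          "efficiency")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 efficiency = 1))
  m2 <- class_metrics(TP = 30, TN = 50, FP = 10, FN = 10)
  expect_equal(m2$accuracy, 0.8)
  expect_equal(m2$sensitivity, 0.75)
  expect_equal(m2$specificity, 5 / 6)
  expect_equal(m2$efficiency,
               efficiency(m2$accuracy, m2$sensitivity, m2$specificity))
  expect_error(class_metrics(-1, 0, 0, 2), "non-negative")
})

test_that("undefined metrics are explicit NA markers, not silent zeros", {
  m <- class_metrics(TP = 0, TN = 10, FP = 0, FN = 0)  # no positives
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$efficiency))
  per <- rbind(cbind(class = "a", m),
               cbind(class = "b", class_metrics(5, 5, 0, 0)))
  expect_warning(mac <- macro_average(per), "excluded")
  expect_equal(unname(mac["sensitivity"]), 1)  # only the defined class
})

test_that("published per-class efficiencies reproduce from their own accuracy/sensitivity/specificity", {
  arm_ga <- reference_performance("arm_ga_train")
  fb <- arm_ga[arm_ga$class == "FB", ]
  expect_equal(round(efficiency(fb$accuracy, fb$sensitivity,
                                fb$specificity), 2), 95.59)
  arm_pso <- reference_performance("arm_pso_train")
  fb2 <- arm_pso[arm_pso$class == "FB", ]
  expect_equal(round(efficiency(fb2$accuracy, fb2$sensitivity,
                                fb2$specificity), 2), 87.48)
})

test_that("one-vs-rest counts always tile the sample", {
  set.seed(1)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    truth <- sample(letters[1:4], n, replace = TRUE)
    pred <- sample(letters[1:4], n, replace = TRUE)
    rep <- performance_report(truth, pred)
    per <- rep$per_class
    expect_true(all(per$TP + per$FN == as.vector(table(truth))))
    expect_true(all(per$TP + per$TN + per$FP + per$FN == n))
    expect_equal(unname(rep$macro),
                 unname(colMeans(per[c("accuracy", "sensitivity",
                                       "specificity", "efficiency")])))
  }
})

test_that("report writers produce readable CSV and JSON", {
  rep <- performance_report(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_performance_report(rep, csv)
  write_performance_report(rep, js)
  expect_equal(read.csv(csv)$TP, rep$per_class$TP)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$n, 4)
})

test_that("sensitivity analysis reports Eq-style percentage changes consistently", {
  d <- toy_classes(n_per_class = 30, k = 3, informative = 1, noise = 3,
                   sep = 6, seed = 2)
  test <- toy_classes(n_per_class = 15, k = 3, informative = 1, noise = 3,
                      sep = 6, seed = 3)
  rep <- sensitivity_analysis(d$x, d$y, test$x, test$y,
                              spec = svm_spec("linear"))
  expect_equal(rep$feature[1], "(none)")
  expect_equal(rep$delta[1], 0)
  expect_equal(rep$pct_change[1], 0)
  # the printed identity: pct_change = (Y2 - Y1)/Y1 * 100 on every row
  expect_equal(rep$pct_change, (rep$Y2 - rep$Y1) / rep$Y1 * 100)
  # removing the informative feature hurts more than removing any noise one
  drop <- abs(rep$pct_change[-1])
  names(drop) <- rep$feature[-1]
  expect_gt(drop["inf1"], max(drop[c("nse1", "nse2", "nse3")]))

  expect_error(sensitivity_analysis(d$x, d$y, test$x, test$y,
                                    mask = c(1, 0, 0, 0)), ">= 2 features")
})
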