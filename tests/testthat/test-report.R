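test_that("metrics from a hand-built confusion matrix are exact", {
  conf <- matrix(c(18, 1, 0, 1, 0,
                   2, 15, 2, 1, 0,
                   0, 3, 16, 1, 0,
                   1, 0, 2, 17, 0,
                   0, 0, 0, 0, 20), 5, byrow = TRUE)
  rpt <- report_from_confusion(conf, fall_labels())
  ref <- metrics_by_hand(conf)
  expect_equal(rpt$accuracy, ref$accuracy)
  expect_equal(unname(rpt$tpr), unname(ref$tpr))
  expect_equal(unname(rpt$precision), unname(ref$precision))
  expect_equal(rpt$n_samples, 100)
  expect_equal(unname(rowSums(rpt$confusion)), rep(20, 5))
})

test_that("perfect and constant predictors give the expected extremes", {
  truth <- rep(fall_labels(), each = 20)
  perfect <- classification_report(truth, truth)
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(unname(perfect$tpr), rep(1, 5))
  expect_equal(unname(diag(perfect$confusion)), rep(20, 5))
  constant <- classification_report(truth, rep("forward_fall", 100))
  expect_equal(constant$accuracy, 0.2)
  expect_true(all(is.na(constant$precision[-1])))
})

test_that("classes absent from the truth yield NA recall", {
  truth <- rep("forward_fall", 5)
  pred <- c("forward_fall", "forward_fall", "left_fall", "forward_fall",
            "forward_fall")
  rpt <- classification_report(truth, pred)
  expect_true(is.na(rpt$tpr[["backward_fall"]]))
  expect_equal(rpt$tpr[["forward_fall"]], 0.8)
})

test_that("reports serialise to CSV and JSON and read back", {
  truth <- rep(fall_labels(), each = 4)
  set.seed(2)
  pred <- sample(truth)
  rpt <- classification_report(truth, pred)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_report(rpt, csv, js)
  tab <- read.csv(csv)
  expect_equal(tab$class, fall_labels())
  expect_equal(tab$tpr, unname(rpt$tpr))
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$accuracy, rpt$accuracy)
  expect_equal(unname(unlist(parsed$tpr)), unname(rpt$tpr))
})
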