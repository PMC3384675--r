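test_that("confusion scoring matches hand-computed counts", {
  det <- data.frame(query_id = "q1", scene_index = 0:3,
                    present = c(TRUE, FALSE, FALSE, FALSE))
  tru <- data.frame(query_id = "q1", scene_index = 0:3,
                    present = c(TRUE, FALSE, FALSE, FALSE))
  cc <- score_detections(det, tru)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 1, tn = 3, fp = 0, fn = 0))
  det$present <- !det$present
  cc2 <- score_detections(det, tru)
  expect_equal(unlist(cc2[c("tp", "tn", "fp", "fn")]),
               c(tp = 0, tn = 0, fp = 3, fn = 1))
  expect_error(score_detections(
    data.frame(query_id = "qX", scene_index = 9, present = TRUE), tru),
    "no ground truth")
  ## 20-decision fixture scored by hand: 5 queries x 4 scenes
  set.seed(40)
  d20 <- expand.grid(query_id = paste0("q", 1:5), scene_index = 0:3)
  t20 <- d20
  t20$present <- t20$scene_index == 0          # truly present once per query
  d20$present <- t20$present
  d20$present[c(1, 7, 12)] <- !d20$present[c(1, 7, 12)]  # 1 FN + 2 FP by hand
  cc3 <- score_detections(d20, t20)
  expect_equal(unlist(cc3[c("tp", "tn", "fp", "fn")]),
               c(tp = 4, tn = 13, fp = 2, fn = 1))
})

test_that("index formulas reproduce the 303-query / 100-scene arithmetic", {
  rep <- correlation_indexes(confusion_counts(tp = 300, fn = 3,
                                              tn = 29997, fp = 3))
  expect_equal(round(rep$se, 2), 99.01)
  expect_equal(round(rep$sp, 2), 99.99)
  perfect <- correlation_indexes(confusion_counts(10, 90, 0, 0))
  expect_equal(c(perfect$se, perfect$sp, perfect$ex, perfect$er),
               c(100, 100, 100, 0))
  expect_error(correlation_indexes(confusion_counts(0, 0, 0, 0)), "no decisions")
  ## undefined sensitivity when no positives were scored
  nopos <- correlation_indexes(confusion_counts(tp = 0, tn = 5, fp = 1, fn = 0))
  expect_true(is.na(nopos$se))
})

test_that("exactitude and error always sum to 100", {
  set.seed(41)
  for (trial in 1:50) {
    cc <- confusion_counts(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(1:50, 1))
    rep <- correlation_indexes(cc)
    expect_equal(rep$ex + rep$er, 100)
    expect_true(all(unlist(rep[c("ex", "er")]) >= 0 &
                    unlist(rep[c("ex", "er")]) <= 100))
  }
})

test_that("calibration lands strictly inside the gap of separable classes", {
  neg <- c(1, 2, 3, 4)
  pos <- c(8, 9, 10)
  thr <- calibrate_threshold(c(neg, pos), c(rep(FALSE, 4), rep(TRUE, 3)))
  expect_gt(as.numeric(thr), max(neg))
  expect_lt(as.numeric(thr), min(pos))
  expect_equal(attr(thr, "exactitude"), 100)
  expect_error(calibrate_threshold(1:3, c(TRUE, TRUE, TRUE)), "one positive")
})

test_that("calibration equals the exhaustive-search optimum on random inputs", {
  set.seed(42)
  for (trial in 1:20) {
    n <- 100
    truth <- runif(n) < 0.3
    intensity <- rnorm(n, mean = ifelse(truth, 1, 0))
    got <- as.numeric(calibrate_threshold(intensity, truth))
    want <- brute_calibrate(intensity, truth)
    expect_equal(got, want)
  }
  ## tied intensities across classes are handled
  intensity <- rep(c(1, 2, 2, 3), 5)
  truth <- rep(c(FALSE, FALSE, TRUE, TRUE), 5)
  expect_equal(as.numeric(calibrate_threshold(intensity, truth)),
               brute_calibrate(intensity, truth))
})

test_that("localization categories partition the scored detections", {
  det <- data.frame(query_id = paste0("q", 1:6), scene_index = 0,
                    present = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                    est_start_base = c(500, 600, 810, 450, 903, 100))
  tru <- data.frame(query_id = paste0("q", 1:6), scene_index = 0,
                    present = TRUE,
                    true_start = c(500, 700, 810, 450, 999, 100))
  rep <- locate_report(det, tru, width = 100)
  expect_equal(rep["exact", "n_objects"], 3)
  expect_equal(rep["one_row_shift", "n_objects"], 1)
  expect_equal(rep["wrong", "n_objects"], 1)
  expect_equal(rep["total", "n_objects"], 5)   # the absent one is not scored
  expect_equal(sum(rep[c("exact", "one_row_shift", "wrong"), "n_objects"]),
               rep["total", "n_objects"])
  expect_equal(rep["total", "percentage"], 100)
})

test_that("percent formatting supports comma and point decimal marks", {
  expect_equal(format_percent(99.013), "99.01")
  expect_equal(format_percent(99.013, ","), "99,01")
})

test_that("index reports are invariant under query relabeling", {
  set.seed(43)
  det <- expand.grid(query_id = paste0("q", 1:8), scene_index = 0:9)
  det$present <- runif(80) < 0.2
  tru <- expand.grid(query_id = paste0("q", 1:8), scene_index = 0:9)
  tru$present <- tru$scene_index == 3
  r1 <- correlation_indexes(score_detections(det, tru))
  relabel <- function(df) {
    df$query_id <- sub("q", "query-", df$query_id); df
  }
  r2 <- correlation_indexes(score_detections(relabel(det), relabel(tru)))
  expect_equal(r1, r2)
})
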