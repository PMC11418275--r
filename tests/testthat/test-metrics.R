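# Precision/recall conventions, average precision against a brute-force
# PR integration, and the positioning-error statistics.

test_that("precision and recall follow their definitions and conventions", {
  expect_equal(precision_pct(5, 5), 50)
  expect_equal(recall_pct(9, 1), 90)
  expect_equal(recall_pct(0, 0), 0)      # zero-denominator convention
  expect_equal(precision_pct(0, 0), 0)
  expect_error(precision_pct(-1, 2), "non-negative")
  expect_error(recall_pct(1, -2), "non-negative")
})

test_that("average precision handles the boundary cases", {
  gt <- data.frame(image = 1, xmin = c(0, 40), ymin = c(0, 40),
                   xmax = c(20, 60), ymax = c(20, 60))
  perfect <- gt
  perfect$score <- c(0.3, 0.9)           # any scores: all hits
  expect_equal(average_precision(perfect, gt), 100)
  none <- perfect[0, ]
  expect_equal(average_precision(none, gt), 0)
  expect_error(average_precision(perfect, gt[0, ]), "no ground-truth")
})

test_that("a stated hit pattern reproduces the hand-evaluated staircase", {
  # 3 GT; 4 ranked predictions hitting (hit, miss, hit, hit):
  # precision at the hits = 1/1, 2/3, 3/4; recall steps of 1/3 each
  # raw staircase: (1 + 2/3 + 3/4) / 3; interpolated: (1 + 3/4 + 3/4) / 3
  gt <- data.frame(image = 1, xmin = c(0, 100, 200), ymin = 0,
                   xmax = c(20, 120, 220), ymax = 20)
  pred <- data.frame(image = 1,
                     xmin = c(0, 300, 100, 200), ymin = c(0, 300, 0, 0),
                     xmax = c(20, 320, 120, 220), ymax = c(20, 320, 20, 20),
                     score = c(0.9, 0.8, 0.7, 0.6))
  expect_equal(average_precision(pred, gt, method = "staircase"),
               100 * (1 + 2 / 3 + 3 / 4) / 3)
  expect_equal(average_precision(pred, gt, method = "interp"),
               100 * (1 + 3 / 4 + 3 / 4) / 3)
  expect_equal(brute_force_ap(pred, gt), 100 * (1 + 2 / 3 + 3 / 4) / 3)
})

test_that("AP agrees with an independent brute-force PR integration", {
  set.seed(31)
  for (rep in 1:25) {
    case <- random_detection_case(n_gt = sample(2:6, 1),
                                  n_pred = sample(1:10, 1),
                                  n_img = sample(1:2, 1))
    expect_equal(average_precision(case$pred, case$gt, method = "staircase"),
                 brute_force_ap(case$pred, case$gt), tolerance = 1e-9)
  }
})

test_that("AP is invariant to monotone score rescaling and FP monotonicity", {
  set.seed(7)
  case <- random_detection_case(6, 8)
  ap0 <- average_precision(case$pred, case$gt)
  resc <- case$pred
  resc$score <- 0.1 + 0.5 * resc$score^3   # strictly monotone map
  expect_equal(average_precision(resc, case$gt), ap0)
  # appending a false positive at the lowest score never increases AP
  fp <- case$pred[1, ]
  fp$xmin <- 900; fp$xmax <- 920; fp$ymin <- 900; fp$ymax <- 920
  fp$score <- min(case$pred$score) / 2
  expect_lte(average_precision(rbind(case$pred, fp), case$gt), ap0)
})

test_that("single class means mAP equals AP, and multi-threshold mAP averages", {
  set.seed(13)
  case <- random_detection_case(5, 7)
  expect_equal(mean_average_precision(case$pred, case$gt),
               average_precision(case$pred, case$gt))
  thrs <- seq(0.5, 0.95, 0.05)
  expect_equal(mean_average_precision(case$pred, case$gt, thrs),
               mean(sapply(thrs, function(t)
                 average_precision(case$pred, case$gt, t))))
})

test_that("positioning-error statistics match their closed forms", {
  r <- localization_errors(c(3, -5, 4), c(1, 2, 3), c(0, 0, 0))
  expect_equal(unname(r$delta["X"]), 4)
  expect_equal(unname(r$se["Y"]), 1 / sqrt(3))  # sd = 1, n = 3
  expect_equal(unname(r$delta["Z"]), 0)
  expect_equal(unname(r$se["Z"]), 0)
  expect_equal(r$n, 3L)
  expect_error(localization_errors(1, 2, 3), "at least 2")
  r1 <- localization_errors(1, 2, 3, se = FALSE)
  expect_true(is.na(r1$se["X"]))
  expect_error(localization_errors(c(1, 2), c(1, 2, 3), c(1, 2)),
               "equal length")
})
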