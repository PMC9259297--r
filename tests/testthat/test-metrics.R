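# Printed confusion rows from the reference evaluation campaign: each row is
# TP, FP, TN, FN and the precision/sensitivity/F1 values they must yield.
reference_rows <- list(
  list(c(20, 1, 225, 21),  c(0.952381, 0.487805, 0.645161)),
  list(c(51, 3, 1348, 0),  c(0.944444, 1.000000, 0.971429)),
  list(c(46, 0, 961, 3),   c(1.000000, 0.938776, 0.968421)),
  list(c(53, 0, 483, 0),   c(1.000000, 1.000000, 1.000000)),
  list(c(10, 0, 305, 9),   c(1.000000, 0.526316, 0.689655)),
  list(c(18, 0, 1885, 1),  c(1.000000, 0.947368, 0.972973)),
  list(c(19, 1, 1508, 0),  c(0.950000, 1.000000, 0.974359)),
  list(c(4, 0, 157, 4),    c(1.000000, 0.500000, 0.666667)),
  list(c(7, 0, 1107, 1),   c(1.000000, 0.875000, 0.933333)),
  list(c(7, 0, 157, 1),    c(1.000000, 0.875000, 0.933333)),
  list(c(95, 40, 605, 1),  c(0.703704, 0.989583, 0.822511)),
  list(c(48, 0, 1482, 9),  c(1.000000, 0.842105, 0.914286)),
  list(c(11, 2, 1621, 1),  c(0.846154, 0.916667, 0.880000)),
  list(c(3, 1, 260, 18),   c(0.750000, 0.142857, 0.240000))
)

test_that("every reference confusion row reproduces its printed metrics", {
  for (row in reference_rows) {
    ev <- eval_result(TP = row[[1]][1], FP = row[[1]][2],
                      TN = row[[1]][3], FN = row[[1]][4])
    expect_equal(round(c(ev$PPV, ev$TPR, ev$F1), 6), row[[2]])
  }
})

test_that("score counts a labelled vector pair correctly", {
  pred <- c(1, 1, 0, 0, 1, 0)
  truth <- c(1, 0, 0, 1, 1, 0)
  ev <- score(pred, truth)
  expect_equal(c(ev$TP, ev$FP, ev$TN, ev$FN), c(2L, 1L, 2L, 1L))
  # permutation invariance
  set.seed(1); perm <- sample(6)
  ev2 <- score(pred[perm], truth[perm])
  expect_equal(ev[c("TP", "FP", "TN", "FN")], ev2[c("TP", "FP", "TN", "FN")])
  expect_error(score(c(1, 0), c(1)), "length")
  # zero denominators flag and zero out
  ev0 <- score(c(0, 0), c(0, 0))
  expect_equal(c(ev0$PPV, ev0$TPR, ev0$F1), c(0, 0, 0))
  expect_setequal(ev0$undefined, c("PPV", "TPR", "F1"))
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  set.seed(3)
  for (i in 1:50) {
    ev <- eval_result(TP = sample(1:50, 1), FP = sample(0:50, 1),
                      TN = sample(0:500, 1), FN = sample(0:50, 1))
    expect_equal(ev$F1, 2 / (1 / ev$PPV + 1 / ev$TPR))
    expect_true(all(c(ev$PPV, ev$TPR, ev$F1) >= 0 &
                      c(ev$PPV, ev$TPR, ev$F1) <= 1))
  }
})

test_that("exclusion percentage matches the reference selection statistics", {
  expect_equal(reduction_phi(605.00, 2000), 69.750)
  expect_equal(reduction_phi(586.68, 2000), 70.666)
  expect_equal(reduction_phi(437.90, 2000), 78.105)
  expect_equal(reduction_phi(251.48, 2000), 87.426)
  expect_equal(reduction_phi(0, 2000), 100)
  expect_error(reduction_phi(10, 0), "positive")
})

test_that("events-vs-exclusion correlation is strongly negative", {
  rho <- events_exclusion_correlation(c(183, 218, 66, 27),
                                      c(69.750, 70.666, 78.105, 87.426))
  expect_equal(round(rho, 2), -0.93)
  x <- c(1, 4, 2, 8)
  expect_equal(events_exclusion_correlation(x, x), 1)
  expect_equal(events_exclusion_correlation(x, -x), -1)
  expect_error(events_exclusion_correlation(c(1, 1, 1), c(1, 2, 3)),
               "variance")
  expect_error(events_exclusion_correlation(1:2, 1:2), "at least 3")
})

test_that("run summaries agree with an independent statistics oracle", {
  expect_equal(unclass(summarize_runs(rep(100, 31)))[1:5],
               list(min = 100, median = 100, max = 100, mean = 100, sigma = 0))
  s <- summarize_runs(c(1, 2, 3))
  expect_equal(s$median, 2); expect_equal(s$mean, 2)

  set.seed(8)
  totals <- sample(100:900, 31, replace = TRUE)
  s31 <- summarize_runs(totals)
  # brute-force recomputation
  expect_equal(s31$mean, sum(totals) / 31)
  expect_equal(s31$sigma, sqrt(sum((totals - mean(totals))^2) / 30))
  expect_equal(s31$median, sort(totals)[16])
  expect_equal(s31$phi, (1 - mean(totals) / 2000) * 100)
  expect_error(summarize_runs(numeric()), "non-empty")
})

test_that("event-mode scoring collapses marker-sharing windows into one instance", {
  # hand-built sliding dataset: 5 windows, windows 2-3 share marker 1,
  # window 5 holds marker 2, windows 1 and 4 are event-free
  ds <- structure(list(
    X = matrix(0, 5, 4), label = c(0L, 1L, 1L, 0L, 1L),
    start = c(1L, 11L, 21L, 31L, 41L),
    marker_ids = list(integer(), 1L, 1L, integer(), 2L),
    size = 10L, overlap = 0.5, role = "validation",
    channel_labels = "A"), class = "window_dataset")

  # detector fires on window 3 only: marker 1 caught once, marker 2 missed
  ev <- score_windows(ds, c(0, 0, 1, 0, 0))
  expect_equal(c(ev$TP, ev$FP, ev$TN, ev$FN), c(1L, 0L, 2L, 1L))
  # firing on both windows of the same event still counts one TP
  ev2 <- score_windows(ds, c(0, 1, 1, 0, 0))
  expect_equal(c(ev2$TP, ev2$FN), c(1L, 1L))
  # a false alarm on an event-free window is one FP
  ev3 <- score_windows(ds, c(1, 0, 0, 0, 1))
  expect_equal(c(ev3$TP, ev3$FP, ev3$TN, ev3$FN), c(1L, 1L, 1L, 1L))
  # window mode scores all five windows independently
  evw <- score_windows(ds, c(0, 1, 1, 0, 1), mode = "window")
  expect_equal(c(evw$TP, evw$FP, evw$TN, evw$FN), c(3L, 0L, 2L, 0L))
})
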