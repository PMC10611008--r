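test_that("rounding is half-up at 2 decimals", {
  expect_equal(round_half_up(98.745), 98.75)
  expect_equal(round_half_up(90.905), 90.91)
  expect_equal(round_half_up(-2.675), -2.68)
  expect_equal(round_half_up(1.004999), 1.00)
})

test_that("counting accuracy reproduces hand-computed worked examples", {
  # |43 - 53| / 53 -> 81.13
  expect_equal(counting_accuracy(43, 53), 81.13)
  expect_equal(counting_accuracy(81, 80), 98.75)
  expect_equal(counting_accuracy(10, 11), 90.91)
  expect_equal(counting_accuracy(103, 110), 93.64)
  expect_equal(counting_accuracy(25, 25), 100)
  # symmetric in the error direction: over- and under-count by the same
  # amount give the same Pc
  expect_equal(counting_accuracy(48, 53), counting_accuracy(58, 53))
  expect_error(counting_accuracy(5, 0), "zero")
})

test_that("APc and mAPc are plain rounded means", {
  pcs <- c(96.97, 100, 100, 93.75)
  expect_equal(apc(pcs), 97.68)
  expect_equal(mapc(c(97.68, 92.12, 93.74)), 94.51)
  expect_error(apc(numeric(0)), "at least one")
  expect_error(mapc(numeric(0)), "at least one")
})

test_that("eval_counts assembles per-video, per-class and overall views", {
  counts <- tibble::tibble(
    video = rep(paste0("v", 1:4), each = 3),
    class = rep(c("flower", "green_fruit", "red_fruit"), times = 4),
    truth = c(33, 20, 10, 28, 22, 12, 30, 18, 9, 32, 21, 11),
    automated = c(32, 19, 10, 28, 20, 12, 30, 18, 8, 30, 21, 10))
  ev <- eval_counts(counts)
  expect_s3_class(ev, "count_eval")
  expect_equal(nrow(ev$per_video), 12)
  expect_equal(ev$per_video$pc[1], counting_accuracy(32, 33))
  flower <- ev$per_class$apc[ev$per_class$class == "flower"]
  expect_equal(flower, apc(counting_accuracy(c(32, 28, 30, 30),
                                             c(33, 28, 30, 32))))
  expect_equal(ev$mapc, mapc(ev$per_class$apc))
  expect_error(eval_counts(counts[, -1]), "missing column")
})

test_that("greedy matching resolves the three-detection staircase correctly", {
  # t1 and t2 in one frame; d1 best-overlaps t1, d2 overlaps both,
  # d3 overlaps t2 only but below threshold once t2 is taken by d2.
  truths <- dplyr::bind_rows(det_at(0, 100, 100), det_at(0, 190, 100))
  truths$score <- NULL
  d1 <- det_at(0, 104, 100, score = 0.9)    # IoU with t1 ~ 0.9
  d2 <- det_at(0, 160, 100, score = 0.8)    # overlaps t1 (~0.27) and t2 (~0.45)
  d3 <- det_at(0, 230, 100, score = 0.7)    # overlaps t2 only, IoU ~ 0.33
  m <- match_detections_to_truth(dplyr::bind_rows(d1, d2, d3), truths,
                                 iou_threshold = 0.25)
  expect_equal(m$summary$tp, 2)
  expect_equal(m$summary$fp, 1)
  expect_equal(m$summary$fn, 0)
  # d1 and d2 are the true positives (score order 0.9, 0.8, 0.7)
  expect_equal(m$dets$tp, c(TRUE, TRUE, FALSE))
})

test_that("each truth box is consumed at most once", {
  truths <- det_at(0, 100, 100)
  truths$score <- NULL
  dets <- dplyr::bind_rows(det_at(0, 100, 100, score = 0.9),
                           det_at(0, 102, 100, score = 0.8))
  m <- match_detections_to_truth(dets, truths)
  expect_equal(m$summary$tp, 1)
  expect_equal(m$summary$fp, 1)
  expect_equal(m$summary$fn, 0)
})

test_that("AP is exact on degenerate rankings", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7), rep(TRUE, 3), 3), 1)
  expect_equal(average_precision(c(0.9, 0.8), rep(FALSE, 2), 4), 0)
  expect_equal(average_precision(numeric(0), logical(0), 5), 0)
  # one TP ranked after one FP over 1 truth: envelope precision 1/2
  expect_equal(average_precision(c(0.9, 0.8), c(FALSE, TRUE), 1), 0.5)
  expect_error(average_precision(0.9, TRUE, 0), "undefined")
})

test_that("all-point AP agrees with the definition-style oracle", {
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(3:40, 1)
    scores <- stats::runif(n)
    tp <- stats::runif(n) < 0.6
    n_truth <- sum(tp) + sample(0:5, 1)
    if (n_truth == 0) n_truth <- 1
    expect_equal(average_precision(scores, tp, n_truth),
                 ap_oracle(scores, tp, n_truth), tolerance = 1e-10)
  }
})

test_that("11-point AP stays within [0, 1] and below-or-near all-point", {
  set.seed(52)
  scores <- stats::runif(20)
  tp <- stats::runif(20) < 0.7
  a11 <- average_precision(scores, tp, sum(tp), "11point")
  expect_gte(a11, 0); expect_lte(a11, 1)
})

test_that("mean AP reproduces the cross-class summary", {
  expect_equal(mean_ap(c(94.9, 94.6, 95.4)), 94.97)
  expect_equal(mean_ap(c(95, 95, 95)), 95)
})

test_that("detection evaluation is invariant to class interleaving", {
  set.seed(53)
  mk <- function(cls, n, x0) {
    d <- dplyr::bind_rows(lapply(1:n, function(i) {
      det_at(i %% 5, x0 + 90 * i, 200, score = stats::runif(1), class = cls)
    }))
    d
  }
  dets <- dplyr::bind_rows(mk("flower", 8, 0), mk("red_fruit", 8, 40))
  truths <- dets[stats::runif(16) < 0.7, c("frame", "x1", "y1", "x2", "y2",
                                           "class")]
  if (!all(c("flower", "red_fruit") %in% truths$class)) {
    truths <- dets[1:16, c("frame", "x1", "y1", "x2", "y2", "class")]
  }
  e1 <- eval_detections(dets, truths)
  e2 <- eval_detections(dets[sample(16), ], truths[sample(nrow(truths)), ])
  expect_equal(dplyr::arrange(e1$per_class, class),
               dplyr::arrange(e2$per_class, class))
  expect_equal(e1$map, e2$map)
})
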