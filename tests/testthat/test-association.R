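test_that("score partition is exhaustive, disjoint, and boundary-correct", {
  d <- dplyr::bind_rows(det_at(0, 100, 100, score = 0.9),
                        det_at(0, 200, 100, score = 0.3),
                        det_at(0, 300, 100, score = 0.05),
                        det_at(0, 400, 100, score = 0.6),   # exactly tau_high
                        det_at(0, 500, 100, score = 0.1))   # exactly tau_low
  p <- partition_by_score(d, tau_high = 0.6, tau_low = 0.1)
  expect_equal(p$high$score, c(0.9, 0.6))
  expect_equal(p$low$score, c(0.3, 0.1))
  expect_equal(p$discarded$score, 0.05)
  expect_equal(sort(c(p$high$.det_index, p$low$.det_index,
                      p$discarded$.det_index)), 1:5)

  e <- partition_by_score(d[0, ], 0.6, 0.1)
  expect_equal(vapply(e, nrow, integer(1)), c(high = 0L, low = 0L,
                                              discarded = 0L))
  expect_error(partition_by_score(d, tau_high = 0.1, tau_low = 0.6),
               "thresholds")
})

test_that("matching respects the IoU floor and the class gate", {
  trk <- tibble::tibble(track_id = 1L, class = "flower",
                        x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  near <- det_at(0, 5.5, 5, w = 10, h = 10)          # high IoU
  m <- match_tracks(trk, near, min_iou = 0.2)
  expect_equal(m$matches$track_id, 1L)
  expect_equal(m$matches$det_index, 1L)

  m2 <- match_tracks(trk, dplyr::mutate(near, class = "red_fruit"),
                     min_iou = 0.2, class_gated = TRUE)
  expect_equal(nrow(m2$matches), 0)
  expect_equal(m2$unmatched_tracks, 1L)
  expect_equal(m2$unmatched_dets, 1L)

  far <- det_at(0, 9.5, 9.5, w = 10, h = 10)          # IoU below floor
  m3 <- match_tracks(trk, far, min_iou = 0.5)
  expect_equal(nrow(m3$matches), 0)
})

test_that("assignment equals the exhaustive-permutation optimum", {
  set.seed(31)
  classes <- c("flower", "green_fruit", "red_fruit")
  for (rep in 1:60) {
    nt <- sample(1:6, 1); nd <- sample(1:6, 1)
    trk <- random_boxes(nt)
    trk$track_id <- seq_len(nt)
    trk$class <- sample(classes, nt, replace = TRUE)
    det <- random_boxes(nd)
    det$frame <- 0L; det$score <- stats::runif(nd)
    det$class <- sample(classes, nd, replace = TRUE)
    m <- match_tracks(trk, det, min_iou = 0, class_gated = TRUE)
    got <- sum(m$matches$iou)
    want <- oracle_matched_iou(box_iou_matrix(trk, det),
                               gate = outer(trk$class, det$class, `!=`),
                               min_iou = 0)
    expect_equal(got, want, tolerance = 1e-10)
    # accounting: everything in exactly one bucket
    expect_equal(sort(c(m$matches$track_id, m$unmatched_tracks)),
                 trk$track_id)
    expect_equal(sort(c(m$matches$det_index, m$unmatched_dets)),
                 seq_len(nd))
  }
})

test_that("matches pair identical classes whenever gating is on", {
  set.seed(32)
  classes <- c("flower", "green_fruit", "red_fruit")
  for (rep in 1:20) {
    trk <- random_boxes(8); det <- random_boxes(8)
    trk$track_id <- 1:8
    trk$class <- sample(classes, 8, replace = TRUE)
    det$class <- sample(classes, 8, replace = TRUE)
    m <- match_tracks(trk, det, min_iou = 0, class_gated = TRUE)
    if (nrow(m$matches) > 0) {
      expect_equal(trk$class[match(m$matches$track_id, trk$track_id)],
                   det$class[m$matches$det_index])
    }
  }
})

test_that("two-stage association follows the BYTE workflow", {
  cfg <- tracker_config()
  # cold start: no tracks, two high-score detections become candidates
  no_tracks <- tibble::tibble(track_id = integer(), class = character(),
                              status = character(), age = integer(),
                              x1 = numeric(), y1 = numeric(),
                              x2 = numeric(), y2 = numeric())
  d <- dplyr::bind_rows(det_at(0, 100, 100, score = 0.9),
                        det_at(0, 400, 100, score = 0.8))
  a <- byte_associate(no_tracks, d, cfg)
  expect_equal(a$new_track_candidates, c(1L, 2L))

  # a lone low-score detection with no nearby track is simply discarded
  a2 <- byte_associate(no_tracks, det_at(0, 100, 100, score = 0.3), cfg)
  expect_equal(length(a2$new_track_candidates), 0)
  expect_equal(nrow(a2$stage1$matches) + nrow(a2$stage2$matches), 0)

  # an occluded (low-score) detection is recovered in stage 2
  trk <- tibble::tibble(track_id = 1L, class = "flower",
                        status = "tracked", age = 5L,
                        x1 = 60, y1 = 50, x2 = 140, y2 = 150)
  low <- det_at(0, 100, 100, score = 0.3)
  a3 <- byte_associate(trk, low, cfg)
  expect_equal(nrow(a3$stage1$matches), 0)
  expect_equal(a3$stage2$matches$track_id, 1L)
  expect_length(a3$unmatched_track_ids, 0)

  # but a lost track does not get the stage-2 chance
  trk_lost <- dplyr::mutate(trk, status = "lost")
  a4 <- byte_associate(trk_lost, low, cfg)
  expect_equal(a4$unmatched_track_ids, 1L)
})
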