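W <- 1280

test_that("band membership uses closed intervals at both edges", {
  bands <- roi_bands("double", band_frac = 0.15)
  left <- bands[bands$band == "left", ]
  right <- bands[bands$band == "right", ]
  at <- function(cx) det_at(0, cx, 300, w = 10, h = 10)
  edge <- 0.15 * W
  expect_true(center_in_band(at(edge), left, W))       # boundary is inside
  expect_false(center_in_band(at(edge + 1e-6), left, W))
  expect_true(center_in_band(at(0), left, W))
  expect_true(center_in_band(at(W - edge), right, W))
  expect_false(center_in_band(at(W - edge - 1e-6), right, W))
  expect_true(center_in_band(at(W), right, W))
})

test_that("single-band mode keeps only the requested side", {
  b <- roi_bands("single", side = "right", band_frac = 0.2)
  expect_equal(b$band, "right")
  expect_equal(b$x_min_frac, 0.8)
  expect_error(roi_bands(band_frac = 0), "band_frac")
})

step_frames <- function(ctr, th) {
  for (f in sort(unique(th$frame))) roi_update(ctr, th[th$frame == f, ])
  ctr
}

test_that("a track sitting inside a band is counted exactly once", {
  th <- linear_stream(0:39, x0 = 60, y0 = 300, vx = 1)   # 40 frames in band
  th$track_id <- 1L
  th$status <- "tracked"
  ctr <- new_roi_counter(frame_width = W)
  step_frames(ctr, th)
  tot <- roi_totals(ctr)
  expect_equal(unname(tot["flower"]), 1L)
  expect_equal(sum(tot), 1L)
})

test_that("leaving and re-entering the same band does not double count", {
  xs <- c(seq(100, 400, by = 20), seq(400, 100, by = -20))  # out and back
  th <- dplyr::bind_rows(lapply(seq_along(xs), function(i) {
    d <- det_at(i - 1L, xs[i], 300)
    d$track_id <- 1L; d$status <- "tracked"; d
  }))
  ctr <- new_roi_counter(frame_width = W)
  step_frames(ctr, th)
  expect_equal(sum(roi_totals(ctr)), 1L)
})

test_that("only tracked-status rows are counted", {
  d <- det_at(0, 60, 300)
  d$track_id <- 1L; d$status <- "lost"
  ctr <- new_roi_counter(frame_width = W)
  roi_update(ctr, d)
  expect_equal(sum(roi_totals(ctr)), 0L)
})

test_that("per-band lists count a full crossing in both bands; shared lists once", {
  th <- linear_stream(0:63, x0 = 40, y0 = 300, vx = 19.5)  # left edge to right
  th$track_id <- 1L; th$status <- "tracked"
  ctr <- new_roi_counter(frame_width = W, shared_lists = FALSE)
  rep <- roi_finalize(step_frames(ctr, th))
  expect_equal(rep$count[rep$band == "left" & rep$class == "flower"], 1L)
  expect_equal(rep$count[rep$band == "right" & rep$class == "flower"], 1L)
  expect_equal(unique(rep$total[rep$class == "flower"]), 2L)

  ctr2 <- new_roi_counter(frame_width = W, shared_lists = TRUE)
  expect_equal(sum(roi_totals(step_frames(ctr2, th))), 1L)
})

test_that("the frame log is monotone non-decreasing per class", {
  scene <- generate_scene(sim_config(n_frames = 150, targets_per_class = 3,
                                     seed = 5))
  th <- track_detections(scene$detections)
  rep <- count_track_history(th, frame_width = scene$config$frame_width)
  log <- attr(rep, "frame_log")
  for (cls in c("flower", "green_fruit", "red_fruit")) {
    expect_true(all(diff(log[[cls]]) >= 0))
    expect_equal(max(log[[cls]]),
                 rep$total[rep$class == cls][1])
  }
})

test_that("finalize reports every band/class cell and clears state", {
  ctr <- new_roi_counter(frame_width = W)
  d <- det_at(0, 60, 300, class = "red_fruit")
  d$track_id <- 9L; d$status <- "tracked"
  roi_update(ctr, d)
  rep <- roi_finalize(ctr)
  expect_s3_class(rep, "count_report")
  expect_equal(nrow(rep), 6)  # 3 classes x 2 bands
  expect_equal(sum(rep$count), 1L)
  expect_equal(rep$total[rep$class == "red_fruit"][1], 1L)
  expect_equal(rep$total[rep$class == "flower"][1], 0L)
  # state cleared: the same ID counts again after finalize
  roi_update(ctr, d)
  expect_equal(sum(roi_totals(ctr)), 1L)
})
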