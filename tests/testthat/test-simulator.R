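test_that("scene generation is a pure function of its config", {
  cfg <- sim_config(n_frames = 80, targets_per_class = 3, seed = 101)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$detections, b$detections)
  expect_identical(a$true_counts, b$true_counts)
  # and does not disturb the session RNG stream
  set.seed(3); before <- stats::runif(1)
  set.seed(3); invisible(generate_scene(cfg)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("the noiseless limit emits the truth with unit confidence", {
  scene <- generate_scene(quiet_sim(n_frames = 100, targets_per_class = 3,
                                    seed = 11))
  d <- scene$detections
  expect_true(all(d$score == 1))
  expect_true(all(d$origin == "true"))
  truth_key <- paste(scene$truth$frame, scene$truth$target_id)
  expect_setequal(paste(d$frame, d$target_id), truth_key)
  merged <- dplyr::inner_join(
    d, scene$truth, by = c("frame", "target_id"), suffix = c("", ".t"))
  expect_equal(merged$x1, merged$x1.t)
  expect_equal(merged$y2, merged$y2.t)
})

test_that("true counts equal unique band transits of the truth", {
  scene <- generate_scene(sim_config(n_frames = 200, targets_per_class = 4,
                                     seed = 13))
  bands <- roi_bands("double")
  W <- scene$config$frame_width
  for (i in seq_len(nrow(scene$true_counts))) {
    row <- scene$true_counts[i, ]
    band <- bands[bands$band == row$band, ]
    tr <- scene$truth[scene$truth$class == row$class, ]
    manual <- length(unique(tr$target_id[center_in_band(tr, band, W)]))
    expect_equal(row$n, manual)
  }
})

test_that("every target eventually transits its side's band", {
  scene <- generate_scene(sim_config(n_frames = 400, targets_per_class = 5,
                                     seed = 17))
  per_class <- dplyr::count(scene$targets, class)
  tot <- dplyr::summarise(dplyr::group_by(scene$true_counts, class),
                          n = sum(n), .groups = "drop")
  expect_equal(dplyr::arrange(tot, class)$n,
               dplyr::arrange(per_class, class)$n)
})

test_that("degrading at level 0 is the identity", {
  scene <- generate_scene(sim_config(n_frames = 80, targets_per_class = 3,
                                     seed = 19))
  expect_identical(degrade_scene(scene, 0)$detections, scene$detections)
})

test_that("degradation monotonically removes true detections", {
  scene <- generate_scene(sim_config(n_frames = 120, targets_per_class = 4,
                                     dropout = 0.08, occlusion_prob = 0.02,
                                     seed = 23))
  n_true <- function(d) sum(d$origin == "true")
  kept <- vapply(0:3, function(l) n_true(degrade_scene(scene, l)$detections),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
  expect_lt(kept[4], kept[1])
  # and monotonically adds false positives
  n_fp <- vapply(0:3, function(l) {
    sum(degrade_scene(scene, l)$detections$origin == "false")
  }, numeric(1))
  expect_true(all(diff(n_fp) >= 0))
})

test_that("detections never leave the score domain or the label set", {
  scene <- generate_scene(sim_config(n_frames = 150, targets_per_class = 5,
                                     seed = 29))
  for (l in c(0, 2)) {
    d <- degrade_scene(scene, l)$detections
    expect_true(all(d$score > 0 & d$score <= 1))
    expect_true(all(d$class %in% scene$config$classes))
    expect_true(all(d$x2 > d$x1 & d$y2 > d$y1))
    expect_silent(validate_detections(d[, c("frame", "x1", "y1", "x2", "y2",
                                            "score", "class")]))
  }
})

test_that("simulated targets never overlap in the noiseless geometry", {
  scene <- generate_scene(quiet_sim(n_frames = 200, targets_per_class = 8,
                                    seed = 31))
  by_frame <- split(scene$truth, scene$truth$frame)
  worst <- max(vapply(by_frame, function(fr) {
    if (nrow(fr) < 2) return(0)
    m <- box_iou_matrix(fr, fr)
    diag(m) <- 0
    max(m)
  }, numeric(1)))
  expect_equal(worst, 0)
})

test_that("config validation rejects out-of-range noise settings", {
  expect_error(sim_config(dropout = 1.2), "probabilit")
  expect_error(sim_config(occlusion_prob = -0.1), "probabilit")
  expect_error(sim_config(speed_range = c(20, 12)), "speed")
  expect_error(sim_config(n_frames = 0), "n_frames")
})
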