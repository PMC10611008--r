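# In-code fixtures shared across test files.

# One detection row from center/size.
det_at <- function(frame, cx, cy, w = 80, h = 100, score = 0.9,
                   class = "flower") {
  tibble::tibble(frame = as.integer(frame),
                 x1 = cx - w / 2, y1 = cy - h / 2,
                 x2 = cx + w / 2, y2 = cy + h / 2,
                 score = score, class = class)
}

# Detection stream for one target on a constant-velocity path.
linear_stream <- function(frames, x0 = 200, y0 = 400, vx = 5, vy = 0,
                          w = 80, h = 100, score = 0.9, class = "flower") {
  dplyr::bind_rows(lapply(frames, function(f) {
    det_at(f, x0 + vx * f, y0 + vy * f, w, h, score, class)
  }))
}

# Random valid boxes (corner form).
random_boxes <- function(n, max_xy = 500, max_wh = 120) {
  x1 <- stats::runif(n, 0, max_xy)
  y1 <- stats::runif(n, 0, max_xy)
  tibble::tibble(x1 = x1, y1 = y1,
                 x2 = x1 + stats::runif(n, 1, max_wh),
                 y2 = y1 + stats::runif(n, 1, max_wh))
}

# Fast-to-run scene configs.
quiet_sim <- function(..., seed) {
  sim_config(dropout = 0, occlusion_prob = 0, jitter_sd = 0, fp_rate = 0,
             score_spread = 0, seed = seed, ...)
}
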