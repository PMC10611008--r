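#' Simulation configuration
#'
#' Describes a synthetic inspection pass: the camera advances along the
#' aisle at roughly walking speed, so plants on the two rows slide
#' horizontally outward through the edge counting bands. Targets of the
#' three classes enter mid-frame as they come into view, translate at a
#' constant per-lane pixel velocity, cross their side's band and exit.
#' Detector imperfections are modelled as confidence spread, frame-wise
#' dropout, occlusion episodes that suppress the score into the
#' low-confidence band (the events that exercise the second association
#' stage), localization jitter and short-lived false positives.
#'
#' Targets are laid out in horizontal lanes with vertical spacing larger
#' than any box height, and targets sharing a lane share its speed, so
#' ground-truth boxes never overlap: identity is unambiguous and the
#' noiseless pipeline must recover counts exactly.
#'
#' @param frame_width,frame_height Frame size in pixels (default
#'   1920x1080).
#' @param n_frames Number of frames (default 600, twenty seconds at 30
#'   fps).
#' @param frame_rate Frames per second (default 30; metadata only, the
#'   dynamics are per-frame).
#' @param targets_per_class Targets generated per class, split across the
#'   two sides (default 30).
#' @param classes Class labels.
#' @param speed_range Per-lane horizontal speed range, px/frame (default
#'   12–20, the apparent motion of near plants at ~1 m/s and 30 fps).
#' @param size_ranges Named list of box-height ranges (px) per class.
#' @param dropout Per-frame probability a true detection is missing.
#' @param occlusion_prob Probability a target suffers one occlusion
#'   episode during its transit.
#' @param occlusion_frames Episode duration range in frames.
#' @param occlusion_score_range Confidence range during an episode;
#'   defaults inside the low band `[tau_low, tau_high)`.
#' @param occlusion_shrink Box scale factor during an episode.
#' @param jitter_sd Localization jitter (px) on the box center.
#' @param fp_rate Expected false positives per frame.
#' @param fp_score_range Confidence range of false positives.
#' @param score_spread True-detection confidence is `1 - score_spread * U`;
#'   0 gives exact unit confidence.
#' @param seed Integer seed fixing the whole stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(frame_width = 1920, frame_height = 1080,
                       n_frames = 600, frame_rate = 30,
                       targets_per_class = 30,
                       classes = c("flower", "green_fruit", "red_fruit"),
                       speed_range = c(12, 20),
                       size_ranges = list(flower = c(40, 70),
                                          green_fruit = c(50, 90),
                                          red_fruit = c(60, 100)),
                       dropout = 0.05,
                       occlusion_prob = 0.2,
                       occlusion_frames = c(3, 8),
                       occlusion_score_range = c(0.15, 0.5),
                       occlusion_shrink = 0.9,
                       jitter_sd = 2,
                       fp_rate = 0.5,
                       fp_score_range = c(0.1, 0.5),
                       score_spread = 0.25,
                       seed = 1L) {
  probs <- c(dropout, occlusion_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_frames < 1) stop("n_frames must be at least 1", call. = FALSE)
  if (length(speed_range) != 2 || speed_range[1] <= 0 ||
      speed_range[2] < speed_range[1]) {
    stop("speed_range must be an increasing pair of positive speeds",
         call. = FALSE)
  }
  if (fp_rate < 0 || jitter_sd < 0 || score_spread < 0 || score_spread > 1) {
    stop("noise magnitudes must be non-negative (score_spread <= 1)",
         call. = FALSE)
  }
  miss <- setdiff(classes, names(size_ranges))
  if (length(miss) > 0) {
    stop("size_ranges missing class(es): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

# Maximum number of false-positive slots pre-drawn per frame; the active
# count is binomial with mean fp_rate.
.MAX_FP_SLOTS <- 8L

#' Generate a synthetic inspection scene
#'
#' Builds ground-truth trajectories, the true per-class band-transit
#' counts, and a per-frame detection stream. All randomness — including
#' the latent variables behind dropout, occlusion, jitter and false
#' positives — is drawn once under the config seed and stored in the
#' scene, so [degrade_scene()] can re-apply noise at scaled rates
#' without re-rolling the dice.
#'
#' @param config A [sim_config()].
#' @return A `sim_scene`: list with `config`, `targets` (one row per
#'   target: class, side, lane, speed, entry frame), `truth` (per-frame
#'   true boxes plus latent noise columns), `fp_latents`,
#'   `detections` (the observed stream) and `true_counts`
#'   (tibble `band, class, n`).
#' @examples
#' scene <- generate_scene(sim_config(n_frames = 100, targets_per_class = 3,
#'                                    seed = 42))
#' scene$true_counts
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  W <- config$frame_width; H <- config$frame_height
  n_total <- config$targets_per_class * length(config$classes)
  empty_truth <- tibble::tibble(
    target_id = integer(), class = character(), side = character(),
    frame = integer(), x1 = numeric(), y1 = numeric(), x2 = numeric(),
    y2 = numeric(), u_drop = numeric(), u_score = numeric(),
    in_episode = logical(), u_occ_score = numeric(),
    jit_x = numeric(), jit_y = numeric())

  # ---- target layout ------------------------------------------------------
  targets <- tibble::tibble(
    target_id = seq_len(n_total),
    class = rep(config$classes, each = config$targets_per_class))
  if (n_total > 0 && config$n_frames > 0) {
    # alternate sides within each class so both rows carry every class
    targets$side <- unlist(lapply(seq_along(config$classes), function(i) {
      rep_len(c("left", "right"), config$targets_per_class)
    }))
    h_max <- max(vapply(config$size_ranges[config$classes], max, numeric(1)))
    lane_spacing <- h_max * 1.25
    n_lanes <- max(1L, floor(0.85 * H / lane_spacing))

    box_h <- vapply(seq_len(n_total), function(i) {
      stats::runif(1, config$size_ranges[[targets$class[i]]][1],
                   config$size_ranges[[targets$class[i]]][2])
    }, numeric(1))
    box_w <- box_h * stats::runif(n_total, 0.75, 1.25)
    targets$box_w <- box_w
    targets$box_h <- box_h

    targets$entry_frame <- NA_integer_
    targets$speed <- NA_real_
    targets$lane <- NA_integer_
    rows <- vector("list", n_total)
    for (side in c("left", "right")) {
      side_idx <- which(targets$side == side)
      idx <- side_idx[sample.int(length(side_idx))]  # mix classes across lanes
      if (length(idx) == 0) next
      lane_of <- rep_len(seq_len(n_lanes), length(idx))
      # right-side lane grid offset half a spacing to avoid cross-side
      # contact near the frame center
      y0 <- 0.08 * H + if (side == "right") lane_spacing / 2 else 0
      for (l in unique(lane_of)) {
        members <- idx[lane_of == l]
        v <- stats::runif(1, config$speed_range[1], config$speed_range[2])
        spawn <- stats::runif(1, 0.32, 0.45) * W
        x0 <- if (side == "left") spawn else W - spawn
        vx <- if (side == "left") -v else v
        dur <- ceiling((spawn + max(targets$box_w[members]) / 2) / v)
        gap_min <- ceiling(1.6 * max(targets$box_w[members]) / v)
        slack <- max(0, config$n_frames - dur - 1)
        gap <- max(gap_min,
                   floor(slack / max(1, length(members))))
        e0 <- floor(stats::runif(1, 0, max(1, min(gap, slack) )))
        for (k in seq_along(members)) {
          i <- members[k]
          entry <- min(e0 + (k - 1L) * gap, max(0, config$n_frames - 2L))
          cy <- y0 + (l - 0.5) * lane_spacing +
            stats::runif(1, -0.05, 0.05) * lane_spacing
          frames <- entry:(config$n_frames - 1L)
          cx <- x0 + vx * (frames - entry)
          keep <- cx > -targets$box_w[i] & cx < W + targets$box_w[i]
          frames <- frames[keep]; cx <- cx[keep]
          nf <- length(frames)
          if (nf == 0) next
          # one potential occlusion episode per target
          ep_len <- round(stats::runif(1, config$occlusion_frames[1],
                                       config$occlusion_frames[2]))
          ep_start <- if (nf > ep_len) sample.int(nf - ep_len, 1) else 1L
          in_ep <- seq_len(nf) >= ep_start & seq_len(nf) < ep_start + ep_len
          rows[[i]] <- tibble::tibble(
            target_id = i, class = targets$class[i], side = side,
            frame = as.integer(frames),
            x1 = cx - targets$box_w[i] / 2, y1 = cy - targets$box_h[i] / 2,
            x2 = cx + targets$box_w[i] / 2, y2 = cy + targets$box_h[i] / 2,
            u_drop = stats::runif(nf), u_score = stats::runif(nf),
            in_episode = in_ep, u_occ_score = stats::runif(nf),
            jit_x = stats::rnorm(nf), jit_y = stats::rnorm(nf))
          targets$entry_frame[i] <- frames[1]
          targets$speed[i] <- vx
          targets$lane[i] <- l
        }
      }
    }
    targets$u_occ <- stats::runif(n_total)
    truth <- dplyr::bind_rows(rows)
    truth <- if (nrow(truth) == 0) empty_truth else
      dplyr::arrange(truth, .data$frame, .data$target_id)
  } else {
    truth <- empty_truth
    targets$side <- rep(NA_character_, n_total)
    targets$u_occ <- rep(NA_real_, n_total)
  }

  # ---- false-positive latents --------------------------------------------
  nf_slots <- config$n_frames * .MAX_FP_SLOTS
  fp_latents <- if (nf_slots > 0) {
    fh <- stats::runif(nf_slots, 30, 90)
    fw <- fh * stats::runif(nf_slots, 0.7, 1.3)
    fx <- stats::runif(nf_slots, 0, W - fw)
    fy <- stats::runif(nf_slots, 0, H - fh)
    tibble::tibble(
      frame = rep(seq_len(config$n_frames) - 1L, each = .MAX_FP_SLOTS),
      u = stats::runif(nf_slots),
      x1 = fx, y1 = fy, x2 = fx + fw, y2 = fy + fh,
      score = stats::runif(nf_slots, config$fp_score_range[1],
                           config$fp_score_range[2]),
      class = sample(config$classes, nf_slots, replace = TRUE))
  } else {
    tibble::tibble(frame = integer(), u = numeric(), x1 = numeric(),
                   y1 = numeric(), x2 = numeric(), y2 = numeric(),
                   score = numeric(), class = character())
  }

  # ---- true band-transit counts ------------------------------------------
  bands <- roi_bands("double")
  true_counts <- tidyr::expand_grid(band = bands$band,
                                    class = config$classes)
  true_counts$n <- vapply(seq_len(nrow(true_counts)), function(i) {
    band <- bands[bands$band == true_counts$band[i], ]
    tr <- truth[truth$class == true_counts$class[i], ]
    if (nrow(tr) == 0) return(0L)
    inside <- center_in_band(tr, band, W)
    length(unique(tr$target_id[inside]))
  }, integer(1))

  scene <- structure(
    list(config = config, targets = targets, truth = truth,
         fp_latents = fp_latents, true_counts = true_counts,
         detections = NULL),
    class = "sim_scene")
  scene$detections <- .apply_noise(scene, level = 0)
  scene
}

# Re-derive the detection stream from stored latents at a given noise
# level; multiplier (1 + level) scales dropout, occlusion and FP rates.
.apply_noise <- function(scene, level = 0) {
  cfg <- scene$config
  truth <- scene$truth
  mult <- 1 + level
  p_drop <- min(1, cfg$dropout * mult)
  p_occ <- min(1, cfg$occlusion_prob * mult)
  p_fp <- min(1, cfg$fp_rate * mult / .MAX_FP_SLOTS)

  det <- NULL
  if (nrow(truth) > 0) {
    occ_on <- scene$targets$u_occ[truth$target_id] < p_occ & truth$in_episode
    kept <- truth$u_drop >= p_drop
    t <- truth[kept, ]
    occ_on <- occ_on[kept]
    cx <- (t$x1 + t$x2) / 2 + t$jit_x * cfg$jitter_sd
    cy <- (t$y1 + t$y2) / 2 + t$jit_y * cfg$jitter_sd
    w <- pmax(t$x2 - t$x1, 4) * ifelse(occ_on, cfg$occlusion_shrink, 1)
    h <- pmax(t$y2 - t$y1, 4) * ifelse(occ_on, cfg$occlusion_shrink, 1)
    score <- 1 - cfg$score_spread * t$u_score
    score[occ_on] <- cfg$occlusion_score_range[1] +
      t$u_occ_score[occ_on] * diff(cfg$occlusion_score_range)
    det <- tibble::tibble(
      frame = t$frame, x1 = cx - w / 2, y1 = cy - h / 2,
      x2 = cx + w / 2, y2 = cy + h / 2,
      score = score, class = t$class, origin = "true",
      target_id = t$target_id)
  }
  fps <- scene$fp_latents[scene$fp_latents$u < p_fp, ]
  if (nrow(fps) > 0) {
    fp_det <- tibble::tibble(frame = fps$frame, x1 = fps$x1, y1 = fps$y1,
                             x2 = fps$x2, y2 = fps$y2, score = fps$score,
                             class = fps$class, origin = "false",
                             target_id = NA_integer_)
    det <- dplyr::bind_rows(det, fp_det)
  }
  if (is.null(det)) {
    det <- tibble::tibble(frame = integer(), x1 = numeric(), y1 = numeric(),
                          x2 = numeric(), y2 = numeric(), score = numeric(),
                          class = character(), origin = character(),
                          target_id = integer())
  }
  dplyr::arrange(det, .data$frame, .data$x1, .data$y1)
}

#' Stress a scene with more detector noise
#'
#' Re-applies the scene's stored noise latents with dropout, occlusion
#' and false-positive rates scaled by `1 + level`. Level 0 returns the
#' scene unchanged; because the latent draws are fixed, every detection
#' missing at one level is also missing at any higher level (the knob is
#' monotone).
#'
#' @param scene A `sim_scene`.
#' @param level Non-negative noise level.
#' @return The scene with a recomputed `detections` table and the level
#'   recorded in `$noise_level`.
#' @export
degrade_scene <- function(scene, level) {
  stopifnot(inherits(scene, "sim_scene"), level >= 0)
  scene$detections <- .apply_noise(scene, level)
  scene$noise_level <- level
  scene
}

#' Ground-truth boxes of a scene as a detection-style table
#'
#' @param scene A `sim_scene`.
#' @return Tibble `frame, x1, y1, x2, y2, class` (one row per target per
#'   frame), usable as the truth side of [eval_detections()].
#' @export
scene_truth_boxes <- function(scene) {
  dplyr::select(scene$truth, "frame", "x1", "y1", "x2", "y2", "class",
                "target_id")
}
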