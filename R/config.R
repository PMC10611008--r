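#' Tracker configuration
#'
#' Bundles every tunable of the tracking pipeline. Detections are split by
#' confidence into a high band (`score >= tau_high`), a low band
#' (`tau_low <= score < tau_high`) and a discard set; high detections are
#' associated first, unmatched previously-tracked tracks get a second
#' chance against the low band. A track unmatched for more than `max_lost`
#' consecutive frames is discarded, so a target may vanish for up to
#' `max_lost` frames (default 30, one second at 30 fps) and keep its ID.
#'
#' Score thresholds and IoU floors are not dictated by the counting method
#' itself; the defaults are the reference BYTE settings.
#'
#' @param tau_high High-confidence threshold (default 0.6).
#' @param tau_low Low-confidence floor (default 0.1); detections below it
#'   are discarded outright.
#' @param first_stage_min_iou Minimum IoU for a stage-1 (high-confidence)
#'   match (default 0.2).
#' @param second_stage_min_iou Minimum IoU for a stage-2 (low-confidence)
#'   match (default 0.5).
#' @param new_track_thresh Minimum score for an unmatched detection to
#'   start a new track (default `tau_high`).
#' @param max_lost Frames a lost track is retained before removal
#'   (default 30); removal triggers strictly after `max_lost` frames
#'   without a match.
#' @param min_hits Matches required before a track is emitted (default 1:
#'   new tracks are output on their first frame, no probation period).
#' @param class_gated Gate association on class labels (default `TRUE`);
#'   disable only for ablation.
#' @param state_convention `"paper"` (state slot `s` = aspect ratio with a
#'   velocity term, `r` = height held constant) or `"sort"` (`s` = area
#'   with a velocity term, `r` = aspect ratio held constant).
#' @param std_weight_position,std_weight_velocity Kalman noise scale
#'   factors; standard deviations are these weights times the box height.
#' @param classes Character vector of class labels.
#' @return A list of class `tracker_config`.
#' @examples
#' cfg <- tracker_config(max_lost = 30)
#' cfg$tau_high
#' @export
tracker_config <- function(tau_high = 0.6,
                           tau_low = 0.1,
                           first_stage_min_iou = 0.2,
                           second_stage_min_iou = 0.5,
                           new_track_thresh = tau_high,
                           max_lost = 30L,
                           min_hits = 1L,
                           class_gated = TRUE,
                           state_convention = c("paper", "sort"),
                           std_weight_position = 1 / 20,
                           std_weight_velocity = 1 / 160,
                           classes = c("flower", "green_fruit", "red_fruit")) {
  state_convention <- match.arg(state_convention)
  if (!(tau_low >= 0 && tau_low < tau_high && tau_high <= 1)) {
    stop("score thresholds must satisfy 0 <= tau_low < tau_high <= 1",
         call. = FALSE)
  }
  for (v in c(first_stage_min_iou, second_stage_min_iou)) {
    if (v < 0 || v > 1) stop("IoU floors must lie in [0, 1]", call. = FALSE)
  }
  if (max_lost < 1) stop("max_lost must be >= 1", call. = FALSE)
  if (min_hits < 1) stop("min_hits must be >= 1", call. = FALSE)
  structure(
    list(tau_high = tau_high, tau_low = tau_low,
         first_stage_min_iou = first_stage_min_iou,
         second_stage_min_iou = second_stage_min_iou,
         new_track_thresh = new_track_thresh,
         max_lost = as.integer(max_lost), min_hits = as.integer(min_hits),
         class_gated = isTRUE(class_gated),
         state_convention = state_convention,
         std_weight_position = std_weight_position,
         std_weight_velocity = std_weight_velocity,
         classes = classes),
    class = "tracker_config")
}

#' Region-of-interest counting bands
#'
#' Vertical full-height strips at the frame edges ("counting belts"). In
#' double-side mode one band sits at each edge, filming the two plant rows
#' on either side of the inspection aisle; single-side mode keeps one.
#' Band extent is expressed as fractions of the frame width.
#'
#' @param mode `"double"` (default) or `"single"`.
#' @param side For single mode, `"left"` or `"right"`.
#' @param band_frac Band width as a fraction of frame width (default 0.15,
#'   wide enough that a target crossing at inspection speed stays in the
#'   band for many frames).
#' @return Tibble with columns `band`, `x_min_frac`, `x_max_frac`.
#' @examples
#' roi_bands()                      # both edges, 15% each
#' roi_bands("single", side = "right")
#' @export
roi_bands <- function(mode = c("double", "single"),
                      side = c("left", "right"),
                      band_frac = 0.15) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  if (band_frac <= 0 || band_frac > 1) {
    stop("band_frac must lie in (0, 1]", call. = FALSE)
  }
  left <- tibble::tibble(band = "left", x_min_frac = 0, x_max_frac = band_frac)
  right <- tibble::tibble(band = "right", x_min_frac = 1 - band_frac,
                          x_max_frac = 1)
  if (mode == "double") {
    dplyr::bind_rows(left, right)
  } else if (side == "left") left else right
}

#' Hash a configuration object
#'
#' Stable content hash recorded in count-report metadata so outputs can be
#' traced to the exact configuration that produced them.
#'
#' @param config Any R object (typically a `tracker_config` or
#'   `sim_config`).
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  rlang::hash(config)
}

#' Read a YAML run configuration
#'
#' Maps a YAML file onto [tracker_config()], [roi_bands()] and
#' [sim_config()] arguments. Unknown keys are rejected, so typos fail
#' loudly before any computation.
#'
#' @param path Path to a YAML file with optional top-level sections
#'   `tracker`, `roi` and `simulator`.
#' @return A list with elements `tracker` (a `tracker_config`), `roi`
#'   (a band tibble) and `simulator` (a `sim_config`).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("tracker", "roi", "simulator", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  check_args <- function(given, fn, what) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad) > 0) {
      stop("unknown ", what, " option(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    given
  }
  trk <- do.call(tracker_config,
                 check_args(raw$tracker %||% list(), tracker_config, "tracker"))
  roi <- do.call(roi_bands,
                 check_args(raw$roi %||% list(), roi_bands, "roi"))
  sim <- do.call(sim_config,
                 check_args(raw$simulator %||% list(), sim_config, "simulator"))
  list(tracker = trk, roi = roi, simulator = sim, seed = raw$seed %||% NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
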