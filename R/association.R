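#' Partition detections by confidence score
#'
#' First step of BYTE association: split a frame's detections into a
#' high-scoring set (`score >= tau_high`), a low-scoring set
#' (`tau_low <= score < tau_high`) and a discarded set (`score < tau_low`).
#' The partition is exhaustive and disjoint; input order is preserved
#' within each part.
#'
#' @param dets Detection tibble (rows of one frame).
#' @param tau_high,tau_low Score thresholds, `0 <= tau_low < tau_high <= 1`.
#' @return List of tibbles `high`, `low`, `discarded`, each with a
#'   `.det_index` column giving the row index in `dets`.
#' @export
partition_by_score <- function(dets, tau_high = 0.6, tau_low = 0.1) {
  if (!(tau_low >= 0 && tau_low < tau_high && tau_high <= 1)) {
    stop("score thresholds must satisfy 0 <= tau_low < tau_high <= 1",
         call. = FALSE)
  }
  dets$.det_index <- seq_len(nrow(dets))
  list(high = vctrs::vec_slice(dets, dets$score >= tau_high),
       low = vctrs::vec_slice(dets, dets$score >= tau_low &
                                dets$score < tau_high),
       discarded = vctrs::vec_slice(dets, dets$score < tau_low))
}

# Large finite stand-in for an infinite (forbidden) assignment cost.
.FORBIDDEN_COST <- 1e6

#' Match predicted tracks to detections by optimal assignment
#'
#' Solves the rectangular linear assignment problem on cost
#' `1 - IoU(predicted box, detection box)` via the Hungarian algorithm.
#' With class gating on, cross-class pairs carry a prohibitively large
#' cost, which makes the solution identical to solving one assignment
#' problem per class. Assignments whose IoU falls below `min_iou` (or that
#' pair different classes) are demoted to unmatched. Row order of `tracks`
#' is the deterministic tie-break: callers pass tracks sorted by age
#' (descending) then track ID (ascending).
#'
#' @param tracks Tibble with columns `track_id`, `class` and predicted
#'   box corners `x1, y1, x2, y2`.
#' @param dets Detection tibble; a `.det_index` column (original row
#'   indices) is honoured if present, otherwise row numbers are used.
#' @param min_iou Minimum IoU for a match to stand.
#' @param class_gated Forbid cross-class pairs (default `TRUE`).
#' @return List with `matches` (tibble `track_id`, `det_index`, `iou`),
#'   `unmatched_tracks` (track IDs) and `unmatched_dets` (detection
#'   indices). Every input track and detection appears in exactly one
#'   component.
#' @export
match_tracks <- function(tracks, dets, min_iou = 0.2, class_gated = TRUE) {
  det_index <- if (".det_index" %in% names(dets)) dets$.det_index
               else seq_len(nrow(dets))
  empty <- list(
    matches = tibble::tibble(track_id = integer(), det_index = integer(),
                             iou = numeric()),
    unmatched_tracks = tracks$track_id %||% integer(),
    unmatched_dets = det_index)
  if (nrow(tracks) == 0L || nrow(dets) == 0L) return(empty)

  iou <- box_iou_matrix(tracks, dets)
  cost <- 1 - iou
  if (class_gated) {
    gate <- outer(tracks$class, dets$class, `!=`)
    cost[gate] <- .FORBIDDEN_COST
  }

  # solve_LSAP needs nrow <= ncol; transpose when tracks outnumber dets
  if (nrow(cost) <= ncol(cost)) {
    sol <- as.integer(clue::solve_LSAP(cost))
    pairs <- cbind(track = seq_len(nrow(cost)), det = sol)
  } else {
    sol <- as.integer(clue::solve_LSAP(t(cost)))
    pairs <- cbind(track = sol, det = seq_len(ncol(cost)))
  }

  keep <- cost[pairs] < .FORBIDDEN_COST / 2 &
    iou[pairs] >= pmax(min_iou, .Machine$double.eps)
  pairs <- pairs[keep, , drop = FALSE]

  list(
    matches = tibble::new_tibble(list(
      track_id = tracks$track_id[pairs[, "track"]],
      det_index = det_index[pairs[, "det"]],
      iou = as.numeric(iou[pairs])), nrow = nrow(pairs)),
    unmatched_tracks = setdiff(tracks$track_id,
                               tracks$track_id[pairs[, "track"]]),
    unmatched_dets = setdiff(det_index, det_index[pairs[, "det"]]))
}

#' Two-stage BYTE association for one frame
#'
#' Stage 1 matches high-confidence detections against all live (tracked
#' and lost) tracks. Stage 2 gives the remaining unmatched
#' previously-tracked tracks a second chance against the low-confidence
#' detections — the mechanism that holds on to occluded targets whose
#' scores dip. Lost tracks sit out stage 2: their predicted boxes are too
#' stale for a low-confidence IoU to be trustworthy. Unmatched
#' high-confidence detections with score at or above the new-track
#' threshold become candidates for fresh trajectories; unmatched
#' low-confidence detections are discarded.
#'
#' @param tracks Tibble of live tracks: `track_id`, `class`, `status`
#'   (`"tracked"` or `"lost"`), `age` (frames since creation) and
#'   predicted box corners. Sorted internally by age descending then ID
#'   ascending for deterministic tie-breaks.
#' @param dets Detection tibble for the frame.
#' @param config A [tracker_config()].
#' @return List with `stage1` and `stage2` (each a [match_tracks()]
#'   result), `new_track_candidates` (row indices into `dets`) and
#'   `unmatched_track_ids` (IDs unmatched after both stages).
#' @export
byte_associate <- function(tracks, dets, config = tracker_config()) {
  if (nrow(tracks) > 0) {
    tracks <- vctrs::vec_slice(tracks, order(-tracks$age, tracks$track_id))
  }
  parts <- partition_by_score(dets, config$tau_high, config$tau_low)

  stage1 <- match_tracks(tracks, parts$high,
                         min_iou = config$first_stage_min_iou,
                         class_gated = config$class_gated)

  leftovers <- vctrs::vec_slice(
    tracks, tracks$track_id %in% stage1$unmatched_tracks &
      tracks$status == "tracked")
  stage2 <- match_tracks(leftovers, parts$low,
                         min_iou = config$second_stage_min_iou,
                         class_gated = config$class_gated)

  unmatched <- setdiff(stage1$unmatched_tracks, stage2$matches$track_id)
  cand <- parts$high$.det_index[
    parts$high$.det_index %in% stage1$unmatched_dets &
      parts$high$score >= config$new_track_thresh]

  list(stage1 = stage1, stage2 = stage2,
       new_track_candidates = cand,
       unmatched_track_ids = unmatched)
}
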