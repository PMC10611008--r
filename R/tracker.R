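#' Create a tracker
#'
#' A tracker is a stateful object (an environment) advanced one frame at a
#' time with [tracker_step()]. Each live track carries a Kalman state, a
#' class label fixed at creation, and a lifecycle status: `tracked`
#' (matched this frame), `lost` (unmatched, retained for re-association)
#' or `removed` (unmatched for more than `max_lost` frames; dropped, its
#' ID is never reused). Track IDs start at 1 and are globally unique
#' across classes.
#'
#' @param config A [tracker_config()].
#' @return A `fruit_tracker` object.
#' @seealso [track_detections()] for the one-shot interface.
#' @export
new_tracker <- function(config = tracker_config()) {
  trk <- new.env(parent = emptyenv())
  trk$config <- config
  trk$tracks <- list()
  trk$next_id <- 1L
  trk$last_frame <- -1L
  trk$n_created <- 0L
  trk$transitions <- character()
  class(trk) <- "fruit_tracker"
  trk
}

.track_tbl <- function(tracker, frame) {
  tracks <- tracker$tracks
  if (length(tracks) == 0L) {
    return(tibble::tibble(track_id = integer(), class = character(),
                          status = character(), age = integer(),
                          x1 = numeric(), y1 = numeric(),
                          x2 = numeric(), y2 = numeric()))
  }
  means <- vapply(tracks, function(t) t$kf$mean[1:4], numeric(4))
  obs <- tibble::tibble(u = means[1, ], v = means[2, ],
                        s = pmax(means[3, ], 1e-6),
                        r = pmax(means[4, ], 1e-6))
  boxes <- box_from_observation(obs, tracker$config$state_convention)
  n <- length(tracks)
  tibble::new_tibble(list(
    track_id = vapply(tracks, `[[`, integer(1), "id"),
    class = vapply(tracks, `[[`, character(1), "class"),
    status = vapply(tracks, `[[`, character(1), "status"),
    age = frame - vapply(tracks, `[[`, integer(1), "start_frame"),
    x1 = boxes$x1, y1 = boxes$y1, x2 = boxes$x2, y2 = boxes$y2),
    nrow = n)
}

#' Advance the tracker by one frame
#'
#' Runs the per-frame cycle: predict all live tracks forward, associate
#' them with the frame's detections in two confidence stages
#' ([byte_associate()]), correct matched tracks, demote unmatched tracked
#' tracks to lost, remove tracks unmatched for more than `max_lost`
#' frames, and start new tracks from unmatched high-confidence
#' detections. Frames must arrive in strictly increasing order; frames
#' with no detections still advance prediction and the lost-frame
#' counters.
#'
#' @param tracker A [new_tracker()] object (modified in place).
#' @param dets Detection tibble for one frame (may have zero rows).
#' @param frame Frame index; inferred from `dets` when omitted.
#' @param validate Validate the frame's detections (default `TRUE`;
#'   [track_detections()] disables it after validating the whole stream
#'   once).
#' @return Tibble of the tracks emitted for this frame (status
#'   `tracked`), with columns `frame, track_id, class, x1, y1, x2, y2,
#'   score, status`.
#' @export
tracker_step <- function(tracker, dets, frame = NULL, validate = TRUE) {
  cfg <- tracker$config
  if (is.null(frame)) {
    if (nrow(dets) == 0L) stop("frame index required for an empty frame",
                               call. = FALSE)
    frame <- dets$frame[1]
  }
  frame <- as.integer(frame)
  if (nrow(dets) > 0) {
    if (validate) validate_detections(dets, classes = cfg$classes)
    if (any(dets$frame != frame)) {
      stop("all detections passed to tracker_step() must share one frame",
           call. = FALSE)
    }
  }
  if (frame <= tracker$last_frame) {
    stop("out-of-order frame ", frame, ": tracker already at frame ",
         tracker$last_frame, call. = FALSE)
  }

  # predict every live track up to the current frame
  dt <- if (tracker$last_frame < 0L) 1L else frame - tracker$last_frame
  for (k in seq_along(tracker$tracks)) {
    for (i in seq_len(dt)) {
      tracker$tracks[[k]]$kf <- kf_predict(tracker$tracks[[k]]$kf, cfg)
    }
  }

  assoc <- byte_associate(.track_tbl(tracker, frame), dets, cfg)
  obs <- if (nrow(dets) > 0) {
    as.matrix(box_to_observation(dets, cfg$state_convention))
  } else NULL
  matches <- rbind(
    as.matrix(assoc$stage1$matches[c("track_id", "det_index")]),
    as.matrix(assoc$stage2$matches[c("track_id", "det_index")]))

  id_of <- vapply(tracker$tracks, `[[`, integer(1), "id")
  emit_det <- integer()   # row of dets backing each emitted track
  emit_id <- integer()

  if (nrow(matches) > 0) {
    for (r in seq_len(nrow(matches))) {
      k <- match(matches[r, "track_id"], id_of)
      j <- matches[r, "det_index"]
      t <- tracker$tracks[[k]]
      if (t$status == "lost") {
        tracker$transitions <- c(tracker$transitions, "lost->tracked")
      }
      t$kf <- .kf_correct_z(t$kf, obs[j, ], dets$class[j], cfg)
      t$status <- "tracked"
      t$last_frame <- frame
      t$hit_count <- t$hit_count + 1L
      t$last_score <- dets$score[j]
      tracker$tracks[[k]] <- t
      if (t$hit_count >= cfg$min_hits) {
        emit_det <- c(emit_det, j)
        emit_id <- c(emit_id, t$id)
      }
    }
  }

  # unmatched tracked tracks become lost; stale lost tracks are removed
  drop <- integer()
  for (k in seq_along(tracker$tracks)) {
    t <- tracker$tracks[[k]]
    if (t$id %in% assoc$unmatched_track_ids || t$last_frame < frame) {
      if (t$status == "tracked" && t$last_frame < frame) {
        tracker$tracks[[k]]$status <- "lost"
        tracker$transitions <- c(tracker$transitions, "tracked->lost")
      }
      if (frame - t$last_frame > cfg$max_lost) {
        drop <- c(drop, k)
        tracker$transitions <- c(tracker$transitions, "lost->removed")
      }
    }
    tracker$tracks[[k]]$frames_since_update <- frame - t$last_frame
  }
  if (length(drop) > 0) tracker$tracks <- tracker$tracks[-drop]

  # fresh trajectories from unmatched high-confidence detections
  for (j in assoc$new_track_candidates) {
    t <- list(id = tracker$next_id, class = dets$class[j],
              kf = .kf_init_z(obs[j, ], dets$class[j], cfg),
              status = "tracked",
              frames_since_update = 0L, start_frame = frame,
              last_frame = frame, hit_count = 1L,
              last_score = dets$score[j])
    tracker$next_id <- tracker$next_id + 1L
    tracker$n_created <- tracker$n_created + 1L
    tracker$transitions <- c(tracker$transitions, "new->tracked")
    tracker$tracks[[length(tracker$tracks) + 1L]] <- t
    if (cfg$min_hits <= 1L) {
      emit_det <- c(emit_det, j)
      emit_id <- c(emit_id, t$id)
    }
  }

  tracker$last_frame <- frame
  ord <- order(emit_id)
  j <- emit_det[ord]
  tibble::new_tibble(list(
    frame = rep(frame, length(j)), track_id = emit_id[ord],
    class = dets$class[j],
    x1 = dets$x1[j], y1 = dets$y1[j], x2 = dets$x2[j], y2 = dets$y2[j],
    score = dets$score[j], status = rep("tracked", length(j))),
    nrow = length(j))
}

#' Track a detection stream
#'
#' One-shot interface: feeds every frame of a detection stream through a
#' fresh tracker and collects the per-frame record of emitted tracks.
#' Every integer frame between the first and last observed frame is
#' stepped, so lost-track counters advance through detection gaps.
#'
#' @param dets Detection tibble for the whole stream (sorted by frame).
#' @param config A [tracker_config()].
#' @param n_frames Total number of frames; defaults to `max(frame) + 1`.
#'   Frames beyond the last detection still age lost tracks.
#' @return A `track_history` tibble: `frame, track_id, class, x1, y1, x2,
#'   y2, score, status`, sorted by frame then track ID, with tracker
#'   bookkeeping (IDs created, transition log, config hash) in the
#'   `tracker_info` attribute.
#' @examples
#' scene <- generate_scene(sim_config(n_frames = 80, targets_per_class = 2,
#'                                    seed = 1))
#' hist <- track_detections(scene$detections)
#' dplyr::n_distinct(hist$track_id)
#' @export
track_detections <- function(dets, config = tracker_config(),
                             n_frames = NULL) {
  validate_detections(dets, classes = config$classes)
  empty <- tibble::tibble(frame = integer(), track_id = integer(),
                          class = character(), x1 = numeric(),
                          y1 = numeric(), x2 = numeric(), y2 = numeric(),
                          score = numeric(), status = character())
  tracker <- new_tracker(config)
  if (nrow(dets) == 0L && is.null(n_frames)) {
    return(structure(empty, class = c("track_history", class(empty)),
                     tracker_info = list(n_created = 0L,
                                         transitions = character(),
                                         config_hash = config_hash(config))))
  }
  first <- if (nrow(dets) > 0) min(dets$frame) else 0L
  last <- if (is.null(n_frames)) max(dets$frame) else n_frames - 1L
  by_frame <- split(seq_len(nrow(dets)), dets$frame)
  out <- vector("list", last - first + 1L)
  for (f in seq.int(first, last)) {
    rows <- by_frame[[as.character(f)]]
    fd <- if (is.null(rows)) empty else vctrs::vec_slice(dets, rows)
    out[[f - first + 1L]] <- tracker_step(tracker, fd, frame = f,
                                          validate = FALSE)
  }
  hist <- dplyr::arrange(dplyr::bind_rows(out), .data$frame, .data$track_id)
  structure(hist, class = c("track_history", class(hist)),
            tracker_info = list(n_created = tracker$n_created,
                                transitions = tracker$transitions,
                                config_hash = config_hash(config)))
}
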