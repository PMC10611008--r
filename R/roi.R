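#' Is a box center inside a counting band?
#'
#' The band test ignores the vertical coordinate: bands span the full
#' frame height. The interval is closed, so a center exactly on a band
#' edge is inside.
#'
#' @param box Data frame of boxes in corner form (vectorised over rows).
#' @param band One row of a [roi_bands()] tibble.
#' @param frame_width Frame width in pixels.
#' @return Logical vector.
#' @export
center_in_band <- function(box, band, frame_width) {
  if (frame_width <= 0) stop("frame_width must be positive", call. = FALSE)
  cx <- (box$x1 + box$x2) / 2
  cx >= band$x_min_frac * frame_width & cx <= band$x_max_frac * frame_width
}

#' Create an ROI counting state
#'
#' Holds, per (band, class), the list of track IDs already counted and
#' the running per-class totals. A track ID contributes at most once per
#' band and class; the lists persist until [roi_finalize()] clears them.
#'
#' @param bands A [roi_bands()] tibble.
#' @param classes Character vector of class labels.
#' @param frame_width Frame width in pixels.
#' @param shared_lists If `TRUE`, the counted-ID list is shared across
#'   bands, so an ID seen in both bands counts once overall. Default
#'   `FALSE`: the two bands film different plant rows, and an ID cannot
#'   legitimately appear in both.
#' @return A `roi_counter` object.
#' @export
new_roi_counter <- function(bands = roi_bands(),
                            classes = c("flower", "green_fruit", "red_fruit"),
                            frame_width = 1920,
                            shared_lists = FALSE) {
  ctr <- new.env(parent = emptyenv())
  ctr$bands <- bands
  ctr$classes <- classes
  ctr$frame_width <- frame_width
  ctr$shared_lists <- isTRUE(shared_lists)
  ctr$counted <- new.env(parent = emptyenv())  # key "band|class" -> id vector
  ctr$log <- list()                            # per-frame running counts
  class(ctr) <- "roi_counter"
  ctr
}

.roi_key <- function(ctr, band, class) {
  if (ctr$shared_lists) paste0("all|", class) else paste0(band, "|", class)
}

#' Update ROI counts with one frame of tracked targets
#'
#' For every track with status `tracked` whose box center lies inside a
#' band: if its ID is not yet in that band's list for its class, the ID
#' is added and the class counter increments by one; IDs already in the
#' list are skipped. Lost tracks are ignored — a predicted box is not a
#' confirmed observation.
#'
#' @param counter A [new_roi_counter()] (modified in place).
#' @param frame_tracks Tibble of tracks for one frame (output of
#'   [tracker_step()] or one frame of a `track_history`).
#' @return The counter, invisibly.
#' @export
roi_update <- function(counter, frame_tracks) {
  tr <- frame_tracks[frame_tracks$status == "tracked", ]
  if (nrow(tr) > 0) {
    for (b in seq_len(nrow(counter$bands))) {
      band <- counter$bands[b, ]
      inside <- center_in_band(tr, band, counter$frame_width)
      hits <- tr[inside, ]
      if (nrow(hits) == 0) next
      for (cls in unique(hits$class)) {
        key <- .roi_key(counter, band$band, cls)
        ids <- counter$counted[[key]]
        new_ids <- setdiff(hits$track_id[hits$class == cls], ids)
        if (length(new_ids) > 0) {
          counter$counted[[key]] <- c(ids, new_ids)
        }
      }
    }
  }
  if (nrow(frame_tracks) > 0) {
    counter$log[[length(counter$log) + 1L]] <-
      c(frame = frame_tracks$frame[1], roi_totals(counter))
  }
  invisible(counter)
}

# Named per-class totals from the counted-ID lists.
roi_totals <- function(counter) {
  out <- stats::setNames(integer(length(counter$classes)), counter$classes)
  for (key in ls(counter$counted)) {
    cls <- sub("^[^|]*\\|", "", key)
    out[cls] <- out[cls] + length(counter$counted[[key]])
  }
  out
}

#' Finalize ROI counts
#'
#' Returns the per-class totals with a per-band breakdown, then clears
#' the counted-ID lists: a rerun on a new stream starts from zero.
#'
#' @param counter A [new_roi_counter()].
#' @return A `count_report` tibble with columns `class, band, count,
#'   total` (`total` repeats the class total on every band row); the
#'   per-frame running-count log is kept in the `frame_log` attribute.
#' @export
roi_finalize <- function(counter) {
  bands <- if (counter$shared_lists) "all" else counter$bands$band
  grid <- tidyr::expand_grid(class = counter$classes, band = bands)
  grid$count <- vapply(seq_len(nrow(grid)), function(i) {
    length(counter$counted[[paste0(grid$band[i], "|", grid$class[i])]])
  }, integer(1))
  report <- grid |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(total = sum(.data$count)) |>
    dplyr::ungroup()
  frame_log <- if (length(counter$log) > 0) {
    tibble::as_tibble(do.call(rbind, counter$log))
  } else NULL
  rm(list = ls(counter$counted), envir = counter$counted)
  counter$log <- list()
  structure(report, class = c("count_report", class(report)),
            frame_log = frame_log)
}

#' Count band transits in a track history
#'
#' One-shot interface: replays a `track_history` frame by frame through
#' the ROI counter and finalizes. Equivalent to interleaving
#' [roi_update()] with tracking.
#'
#' @param history A `track_history` tibble from [track_detections()].
#' @param bands A [roi_bands()] tibble.
#' @param frame_width Frame width in pixels.
#' @param classes Class labels to report (zero counts included).
#' @param shared_lists See [new_roi_counter()].
#' @return A `count_report` tibble; see [roi_finalize()].
#' @examples
#' scene <- generate_scene(sim_config(n_frames = 120, targets_per_class = 3,
#'                                    seed = 7))
#' hist <- track_detections(scene$detections)
#' count_track_history(hist, frame_width = 1920)
#' @export
count_track_history <- function(history, bands = roi_bands(),
                                frame_width = 1920,
                                classes = c("flower", "green_fruit",
                                            "red_fruit"),
                                shared_lists = FALSE) {
  ctr <- new_roi_counter(bands, classes, frame_width, shared_lists)
  if (nrow(history) > 0) {
    for (rows in split(seq_len(nrow(history)), history$frame)) {
      roi_update(ctr, history[rows, ])
    }
  }
  roi_finalize(ctr)
}
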