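#' Default class-label mapping
#'
#' Bijective map between integer class IDs used in files and label
#' strings used in memory.
#'
#' @param classes Character vector of labels; IDs are assigned 0, 1, ...
#'   in order.
#' @return Named integer vector (names = labels, values = IDs).
#' @export
class_map <- function(classes = c("flower", "green_fruit", "red_fruit")) {
  if (anyDuplicated(classes)) stop("class labels must be unique",
                                   call. = FALSE)
  stats::setNames(seq_along(classes) - 1L, classes)
}

.label_of <- function(ids, map, file = "<input>") {
  idx <- match(ids, unname(map))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(file, ": unknown class id ", ids[bad], " at data row ", bad,
         call. = FALSE)
  }
  names(map)[idx]
}

#' Read a detection stream
#'
#' Two dialects are supported.
#' `mot_csv`: one headerless CSV with the ten MOT-Challenge columns
#' `frame,id,x,y,w,h,score,class_id,-1,-1` — `x, y` the box top-left in
#' pixels, `id` is `-1` for raw detections, and column 8 carries the
#' class ID (as MOT ground-truth files do; raw MOT detections normally
#' leave it `-1`).
#' `yolo_txt`: a directory of one text file per frame (frame index from
#' the file name), rows `class_id cx cy w h score` with coordinates
#' normalized to `[0, 1]`; `frame_size` is required to restore absolute
#' pixels.
#'
#' @param path File (mot_csv) or directory (yolo_txt).
#' @param dialect `"mot_csv"` or `"yolo_txt"`.
#' @param classes Class labels defining the integer mapping (see
#'   [class_map()]).
#' @param frame_size `c(width, height)` in pixels; required for
#'   `yolo_txt`.
#' @return A detection tibble (`frame, x1, y1, x2, y2, score, class`)
#'   sorted by frame.
#' @export
read_detections <- function(path, dialect = c("mot_csv", "yolo_txt"),
                            classes = c("flower", "green_fruit",
                                        "red_fruit"),
                            frame_size = NULL) {
  dialect <- match.arg(dialect)
  map <- class_map(classes)
  if (dialect == "mot_csv") {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    raw <- suppressWarnings(
      readr::read_csv(path, col_names = FALSE, col_types = "dddddddddd",
                      progress = FALSE))
    if (nrow(raw) == 0 || ncol(raw) == 0) {
      return(tibble::tibble(frame = integer(), x1 = numeric(),
                            y1 = numeric(), x2 = numeric(), y2 = numeric(),
                            score = numeric(), class = character()))
    }
    if (ncol(raw) != 10) {
      stop(path, ": expected 10 MOT columns, found ", ncol(raw),
           call. = FALSE)
    }
    bad <- which(raw$X5 <= 0 | raw$X6 <= 0)
    if (length(bad) > 0) {
      stop(path, ": non-positive box size at data row ", bad[1],
           call. = FALSE)
    }
    det <- tibble::tibble(
      frame = as.integer(raw$X1), x1 = raw$X3, y1 = raw$X4,
      x2 = raw$X3 + raw$X5, y2 = raw$X4 + raw$X6, score = raw$X7,
      class = .label_of(as.integer(raw$X8), map, path))
  } else {
    if (is.null(frame_size)) {
      stop("frame_size = c(width, height) is required for yolo_txt input",
           call. = FALSE)
    }
    if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    det <- dplyr::bind_rows(lapply(files, function(f) {
      frame <- as.integer(gsub("\\D", "", basename(f)))
      if (is.na(frame)) {
        stop(f, ": cannot derive a frame index from the file name",
             call. = FALSE)
      }
      if (file.size(f) == 0) return(NULL)
      raw <- utils::read.table(f, col.names = c("class_id", "cx", "cy",
                                                "w", "h", "score"))
      if (any(raw$w <= 0 | raw$h <= 0)) {
        stop(f, ": non-positive box size at line ",
             which(raw$w <= 0 | raw$h <= 0)[1], call. = FALSE)
      }
      tibble::tibble(
        frame = frame,
        x1 = (raw$cx - raw$w / 2) * frame_size[1],
        y1 = (raw$cy - raw$h / 2) * frame_size[2],
        x2 = (raw$cx + raw$w / 2) * frame_size[1],
        y2 = (raw$cy + raw$h / 2) * frame_size[2],
        score = raw$score,
        class = .label_of(as.integer(raw$class_id), map, f))
    }))
    if (nrow(det) == 0) {
      det <- tibble::tibble(frame = integer(), x1 = numeric(),
                            y1 = numeric(), x2 = numeric(), y2 = numeric(),
                            score = numeric(), class = character())
    }
  }
  det <- dplyr::arrange(det, .data$frame)
  validate_detections(det, classes = classes)
  det
}

#' Write a detection stream
#'
#' Inverse of [read_detections()]; round-trips canonical streams.
#'
#' @param dets Detection tibble.
#' @param path Output file (mot_csv) or directory (yolo_txt).
#' @param dialect,classes,frame_size See [read_detections()]. For
#'   `yolo_txt`, a file is written for every frame `0 .. n_frames - 1`
#'   (empty frames give empty files).
#' @param ids Optional track IDs for MOT column 2 (default `-1`, raw
#'   detections).
#' @param n_frames Number of frame files for yolo_txt; defaults to
#'   `max(frame) + 1`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path,
                             dialect = c("mot_csv", "yolo_txt"),
                             classes = c("flower", "green_fruit",
                                         "red_fruit"),
                             frame_size = NULL, ids = NULL,
                             n_frames = NULL) {
  dialect <- match.arg(dialect)
  map <- class_map(classes)
  validate_detections(dets, classes = classes)
  if (dialect == "mot_csv") {
    out <- data.frame(
      X1 = dets$frame,
      X2 = if (is.null(ids)) rep(-1L, nrow(dets)) else ids,
      X3 = dets$x1, X4 = dets$y1,
      X5 = dets$x2 - dets$x1, X6 = dets$y2 - dets$y1,
      X7 = dets$score, X8 = unname(map[dets$class]),
      X9 = rep(-1L, nrow(dets)), X10 = rep(-1L, nrow(dets)))
    readr::write_csv(out, path, col_names = FALSE, progress = FALSE)
  } else {
    if (is.null(frame_size)) {
      stop("frame_size = c(width, height) is required for yolo_txt output",
           call. = FALSE)
    }
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    if (is.null(n_frames)) {
      n_frames <- if (nrow(dets) > 0) max(dets$frame) + 1L else 0L
    }
    for (f in seq_len(n_frames) - 1L) {
      d <- dets[dets$frame == f, ]
      file <- file.path(path, sprintf("%06d.txt", f))
      if (nrow(d) == 0) { file.create(file); next }
      lines <- sprintf(
        "%d %.10g %.10g %.10g %.10g %.10g",
        unname(map[d$class]),
        (d$x1 + d$x2) / 2 / frame_size[1],
        (d$y1 + d$y2) / 2 / frame_size[2],
        (d$x2 - d$x1) / frame_size[1],
        (d$y2 - d$y1) / frame_size[2],
        d$score)
      writeLines(lines, file)
    }
  }
  invisible(path)
}

#' Write and read a track history
#'
#' The mot_csv dialect with real track IDs in column 2 and the class ID
#' in column 8; rows sorted by frame then ID.
#'
#' @param history A `track_history` tibble.
#' @param path Output CSV path.
#' @param classes Class labels defining the integer mapping.
#' @return `path` (writer) / a `track_history` tibble (reader).
#' @export
write_track_history <- function(history, path,
                                classes = c("flower", "green_fruit",
                                            "red_fruit")) {
  history <- dplyr::arrange(history, .data$frame, .data$track_id)
  write_detections(dplyr::select(history, -dplyr::any_of("status")),
                   path, "mot_csv", classes = classes,
                   ids = history$track_id)
}

#' @rdname write_track_history
#' @export
read_track_history <- function(path, classes = c("flower", "green_fruit",
                                                 "red_fruit")) {
  raw <- suppressWarnings(
    readr::read_csv(path, col_names = FALSE, col_types = "dddddddddd",
                    progress = FALSE))
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    hist <- tibble::tibble(frame = integer(), track_id = integer(),
                           class = character(), x1 = numeric(),
                           y1 = numeric(), x2 = numeric(), y2 = numeric(),
                           score = numeric(), status = character())
    return(structure(hist, class = c("track_history", class(hist))))
  }
  hist <- tibble::tibble(
    frame = as.integer(raw$X1), track_id = as.integer(raw$X2),
    class = .label_of(as.integer(raw$X8), class_map(classes), path),
    x1 = raw$X3, y1 = raw$X4, x2 = raw$X3 + raw$X5, y2 = raw$X4 + raw$X6,
    score = raw$X7, status = "tracked")
  hist <- dplyr::arrange(hist, .data$frame, .data$track_id)
  structure(hist, class = c("track_history", class(hist)))
}

#' Write a count report
#'
#' CSV columns `class, band, count, total`; optionally a JSON sidecar
#' with run metadata (config hash, seed) for provenance.
#'
#' @param report A `count_report` from [roi_finalize()].
#' @param path Output CSV path.
#' @param json_path Optional JSON output path.
#' @param config,seed Optional run metadata recorded in the JSON.
#' @return `path`, invisibly.
#' @export
write_count_report <- function(report, path, json_path = NULL,
                               config = NULL, seed = NULL) {
  readr::write_csv(report[c("class", "band", "count", "total")], path,
                   progress = FALSE)
  if (!is.null(json_path)) {
    meta <- list(
      counts = stats::setNames(
        as.list(dplyr::distinct(report,
                                .data$class, .data$total)$total),
        dplyr::distinct(report, .data$class, .data$total)$class),
      per_band = report[c("class", "band", "count")],
      config_hash = if (is.null(config)) NULL else config_hash(config),
      seed = seed)
    jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_count_report
#' @export
read_count_report <- function(path) {
  rep <- readr::read_csv(path, col_types = readr::cols(
    class = "c", band = "c", count = "i", total = "i"), progress = FALSE)
  structure(rep, class = c("count_report", class(rep)))
}

#' Read a ground-truth count table
#'
#' @param path CSV with columns `video_id, class, true_count`.
#' @return Tibble with those columns.
#' @export
read_truth_counts <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    video_id = "c", class = "c", true_count = "i"), progress = FALSE)
}
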