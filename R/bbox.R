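#' Bounding-box geometry
#'
#' Boxes are axis-aligned, stored in corner form `(x1, y1, x2, y2)` in
#' continuous pixel units, origin top-left, y increasing downward. A box is
#' valid when `x2 > x1` and `y2 > y1` (strictly positive area). Center form
#' `(cx, cy, w, h)` and the Kalman observation form `(u, v, s, r)` — center
#' point, aspect ratio `w/h`, height — are derived views of the corner form.
#'
#' @param x1,y1,x2,y2 Numeric vectors of corner coordinates.
#' @return `bbox()` returns a tibble with columns `x1, y1, x2, y2`.
#' @examples
#' bbox(0, 0, 10, 20)
#' @export
bbox <- function(x1, y1, x2, y2) {
  b <- tibble::tibble(x1 = as.numeric(x1), y1 = as.numeric(y1),
                      x2 = as.numeric(x2), y2 = as.numeric(y2))
  validate_bbox(b)
  b
}

#' @rdname bbox
#' @param box A data frame with columns `x1, y1, x2, y2`.
#' @export
validate_bbox <- function(box) {
  need <- c("x1", "y1", "x2", "y2")
  miss <- setdiff(need, names(box))
  if (length(miss) > 0) {
    stop("box is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !(box$x2 > box$x1 & box$y2 > box$y1)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    stop("degenerate bounding box (zero or negative width/height) at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  invisible(box)
}

#' Intersection over union of axis-aligned boxes
#'
#' The overlap ratio used both as the association cost basis (cost = 1 - IoU)
#' and as the detection-correctness criterion (a detection is correct when
#' IoU with a ground-truth box is at least 0.5). Vectorised over rows;
#' the two inputs are recycled to a common length.
#'
#' @param a,b Data frames of boxes in corner form (`x1, y1, x2, y2`).
#' @return Numeric vector of IoU values in `[0, 1]`; 0 for disjoint boxes,
#'   1 iff the boxes coincide.
#' @examples
#' box_iou(bbox(0, 0, 2, 2), bbox(1, 0, 3, 2))  # 1/3
#' @export
box_iou <- function(a, b) {
  validate_bbox(a)
  validate_bbox(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), ]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), ]
  iw <- pmax(0, pmin(a$x2, b$x2) - pmax(a$x1, b$x1))
  ih <- pmax(0, pmin(a$y2, b$y2) - pmax(a$y1, b$y1))
  inter <- iw * ih
  union <- (a$x2 - a$x1) * (a$y2 - a$y1) + (b$x2 - b$x1) * (b$y2 - b$y1) - inter
  inter / union
}

#' Pairwise IoU matrix
#'
#' @param a Data frame of `n` boxes; `b` data frame of `m` boxes.
#' @param b See `a`.
#' @return An `n x m` matrix with `[i, j] = IoU(a[i], b[j])`.
#' @export
box_iou_matrix <- function(a, b) {
  validate_bbox(a)
  validate_bbox(b)
  n <- nrow(a)
  m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(numeric(0), nrow = n, ncol = m))
  iw <- pmax(0, outer(a$x2, b$x2, pmin) - outer(a$x1, b$x1, pmax))
  ih <- pmax(0, outer(a$y2, b$y2, pmin) - outer(a$y1, b$y1, pmax))
  inter <- iw * ih
  area_a <- (a$x2 - a$x1) * (a$y2 - a$y1)
  area_b <- (b$x2 - b$x1) * (b$y2 - b$y1)
  inter / (outer(area_a, area_b, `+`) - inter)
}

#' Convert between corner form and the Kalman observation form
#'
#' The motion model observes `(u, v, s, r)`: box center `(u, v)`, aspect
#' ratio `s = w/h`, and height `r`. An alternative convention swaps the
#' roles so that `s` is the scale (area `w*h`) and `r` the aspect ratio,
#' matching the SORT tracker's state layout.
#'
#' @param box Data frame of boxes in corner form.
#' @param convention `"paper"` (`s` = aspect ratio, `r` = height, the
#'   default) or `"sort"` (`s` = area, `r` = aspect ratio).
#' @return `box_to_observation()`: tibble with columns `u, v, s, r`;
#'   `box_from_observation()`: tibble of boxes in corner form.
#' @examples
#' box_to_observation(bbox(0, 0, 10, 20))  # u = 5, v = 10, s = 0.5, r = 20
#' @export
box_to_observation <- function(box, convention = c("paper", "sort")) {
  convention <- match.arg(convention)
  validate_bbox(box)
  w <- box$x2 - box$x1
  h <- box$y2 - box$y1
  u <- (box$x1 + box$x2) / 2
  v <- (box$y1 + box$y2) / 2
  if (convention == "paper") {
    tibble::new_tibble(list(u = u, v = v, s = w / h, r = h),
                       nrow = length(u))
  } else {
    tibble::new_tibble(list(u = u, v = v, s = w * h, r = w / h),
                       nrow = length(u))
  }
}

#' @rdname box_to_observation
#' @param obs Data frame with columns `u, v, s, r`.
#' @export
box_from_observation <- function(obs, convention = c("paper", "sort")) {
  convention <- match.arg(convention)
  if (convention == "paper") {
    h <- obs$r
    w <- obs$s * obs$r
  } else {
    w <- sqrt(obs$s * obs$r)
    h <- sqrt(obs$s / obs$r)
  }
  tibble::new_tibble(list(x1 = obs$u - w / 2, y1 = obs$v - h / 2,
                          x2 = obs$u + w / 2, y2 = obs$v + h / 2),
                     nrow = length(w))
}

#' Validate a detection table
#'
#' A detection stream is a tibble with one row per detection: `frame`
#' (integer, >= 0, non-decreasing), corner-form box columns, `score` in
#' `[0, 1]` and `class` drawn from a configured label set.
#'
#' @param det Data frame of detections.
#' @param classes Character vector of allowed class labels, or `NULL` to
#'   skip the label check.
#' @return The input, invisibly, after validation.
#' @export
validate_detections <- function(det, classes = NULL) {
  need <- c("frame", "x1", "y1", "x2", "y2", "score", "class")
  miss <- setdiff(need, names(det))
  if (length(miss) > 0) {
    stop("detections missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(det) == 0L) return(invisible(det))
  validate_bbox(det)
  if (any(det$frame < 0) || any(det$frame != floor(det$frame))) {
    stop("frame indices must be non-negative integers", call. = FALSE)
  }
  if (is.unsorted(det$frame)) {
    stop("detection stream must be sorted by frame (non-decreasing)",
         call. = FALSE)
  }
  if (any(det$score < 0 | det$score > 1)) {
    stop("detection scores must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(classes) && !all(det$class %in% classes)) {
    stop("detection class labels outside the configured label set: ",
         paste(unique(setdiff(det$class, classes)), collapse = ", "),
         call. = FALSE)
  }
  invisible(det)
}
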