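#' Round half-up
#'
#' Tables report percentages rounded half-up to two decimals; base
#' `round()` rounds half-even, so worked examples would drift on exact
#' halves.
#'
#' @param x Numeric vector (non-negative in all uses here).
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Counting accuracy Pc
#'
#' Per-video, per-class agreement between the automated count and the
#' ground-truth count: `Pc = (1 - |Na - Nt| / Nt) * 100`, as a
#' percentage rounded to two decimals. Over- and under-counting are
#' penalised symmetrically; `Pc = 100` iff the counts agree exactly.
#'
#' @param na Automated count(s), non-negative integers.
#' @param nt True count(s), positive integers.
#' @return Numeric vector of percentages (at most 100; can drop below 0
#'   when the automated count is more than double the truth).
#' @examples
#' counting_accuracy(43, 53)   # 81.13
#' counting_accuracy(103, 110) # 93.64
#' @export
counting_accuracy <- function(na, nt) {
  if (any(nt <= 0)) {
    stop("counting accuracy is undefined for a true count of zero",
         call. = FALSE)
  }
  if (any(na < 0)) stop("automated counts must be non-negative", call. = FALSE)
  round_half_up((1 - abs(na - nt) / nt) * 100, 2)
}

#' Per-class counting precision APc and its cross-class mean mAPc
#'
#' `apc()` averages one class's per-video Pc values over the test
#' videos; `mapc()` averages the per-class APc values across classes.
#' Both are unweighted means reported to two decimals.
#'
#' @param pcs Numeric vector of Pc percentages (one per video).
#' @return Percentage rounded to two decimals.
#' @examples
#' apc(counting_accuracy(c(64, 95, 13, 15), c(66, 95, 13, 16)))  # 97.68
#' mapc(c(97.68, 93.97, 91.89))                                  # 94.51
#' @export
apc <- function(pcs) {
  if (length(pcs) == 0) stop("apc() needs at least one Pc value",
                             call. = FALSE)
  round_half_up(mean(pcs), 2)
}

#' @rdname apc
#' @param apcs Numeric vector of per-class APc percentages, one per class.
#' @export
mapc <- function(apcs) {
  if (length(apcs) == 0) stop("mapc() needs at least one APc value",
                              call. = FALSE)
  round_half_up(mean(apcs), 2)
}

#' Evaluate automated counts against ground truth
#'
#' Computes the full counting-evaluation table: Pc per (video, class),
#' APc per class over videos, and the cross-class mAPc.
#'
#' @param counts Data frame with columns `video`, `class`, `automated`,
#'   `truth` — one row per video and class.
#' @return A `count_eval` object: list with `per_video` (the input plus
#'   `pc`), `per_class` (tibble `class`, `apc`) and `mapc`.
#' @examples
#' tbl <- tibble::tibble(video = c(1, 2), class = "flower",
#'                       automated = c(64, 95), truth = c(66, 95))
#' eval_counts(tbl)$per_class
#' @export
eval_counts <- function(counts) {
  need <- c("video", "class", "automated", "truth")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    stop("counts missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  per_video <- counts |>
    dplyr::mutate(pc = counting_accuracy(.data$automated, .data$truth))
  per_class <- per_video |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(apc = apc(.data$pc), .groups = "drop")
  structure(list(per_video = per_video, per_class = per_class,
                 mapc = mapc(per_class$apc)),
            class = "count_eval")
}

#' @export
print.count_eval <- function(x, ...) {
  cat("Counting evaluation over", dplyr::n_distinct(x$per_video$video),
      "video(s)\n")
  print(x$per_class)
  cat("mAPc:", x$mapc, "%\n")
  invisible(x)
}

#' Match detections to ground-truth boxes
#'
#' Greedy matching in score-descending order, within frame and class: a
#' detection is a true positive when its best-overlapping unmatched
#' ground-truth box has IoU at or above the threshold; each truth box is
#' consumed at most once. Unmatched detections are false positives,
#' unmatched truths false negatives.
#'
#' @param dets Detection tibble (`frame`, box corners, `score`, `class`).
#' @param truths Ground-truth tibble (`frame`, box corners, `class`).
#' @param iou_threshold Correctness threshold (default 0.5).
#' @return List with `dets` (input sorted by class and descending score,
#'   plus logical `tp`) and `summary` (per-class `tp`, `fp`, `fn`,
#'   `precision`, `recall`).
#' @export
match_detections_to_truth <- function(dets, truths, iou_threshold = 0.5) {
  classes <- union(unique(dets$class), unique(truths$class))
  out <- purrr::map(classes, function(cls) {
    d <- dets[dets$class == cls, ]
    d <- d[order(-d$score), ]
    g <- truths[truths$class == cls, ]
    tp <- logical(nrow(d))
    used <- logical(nrow(g))
    for (i in seq_len(nrow(d))) {
      cand <- which(!used & g$frame == d$frame[i])
      if (length(cand) == 0) next
      ious <- box_iou(d[i, ], g[cand, ])
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        tp[i] <- TRUE
        used[cand[j]] <- TRUE
      }
    }
    d$tp <- tp
    n_tp <- sum(tp)
    list(dets = d,
         summary = tibble::tibble(class = cls, tp = n_tp,
                                  fp = nrow(d) - n_tp, fn = sum(!used)))
  })
  dets_out <- purrr::list_rbind(purrr::map(out, "dets"))
  summary <- purrr::list_rbind(purrr::map(out, "summary")) |>
    dplyr::mutate(
      precision = ifelse(.data$tp + .data$fp > 0,
                         .data$tp / (.data$tp + .data$fp), NA_real_),
      recall = ifelse(.data$tp + .data$fn > 0,
                      .data$tp / (.data$tp + .data$fn), NA_real_))
  list(dets = dets_out, summary = summary)
}

#' Average precision from a scored detection list
#'
#' Area under the precision–recall curve for one class: detections are
#' swept in score-descending order, precision is replaced by its
#' right-to-left running maximum (the precision envelope), and the area
#' is accumulated over every recall increment (all-point interpolation).
#' The PASCAL-style 11-point scheme is available as an alternative.
#'
#' @param scores Detection confidence scores.
#' @param tp Logical vector, `TRUE` where the detection matched a truth
#'   box.
#' @param n_truth Number of ground-truth positives for the class.
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, tp, n_truth,
                              interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  if (n_truth <= 0) stop("AP undefined without ground-truth positives",
                         call. = FALSE)
  if (length(scores) == 0) return(0)
  ord <- order(-scores)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_truth
  precision <- cum_tp / (cum_tp + cum_fp)
  env <- rev(cummax(rev(precision)))
  if (interpolation == "all") {
    dr <- diff(c(0, recall))
    sum(dr * env)
  } else {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      ok <- recall >= r - 1e-12
      if (any(ok)) max(precision[ok]) else 0
    }, numeric(1)))
  }
}

#' Unweighted cross-class mean of average precisions
#'
#' @param aps Numeric vector of per-class AP values (fractions or
#'   percentages).
#' @param digits Decimals for reporting (default 2).
#' @return The mean, rounded half-up.
#' @examples
#' mean_ap(c(94.1, 94.8, 96.1))  # 95
#' @export
mean_ap <- function(aps, digits = 2) {
  if (length(aps) == 0) stop("mean_ap() needs at least one AP", call. = FALSE)
  round_half_up(mean(aps), digits)
}

#' Evaluate a detection set against ground truth
#'
#' Per-class precision, recall and average precision at the configured
#' IoU threshold, plus the unweighted mAP. Classes with no ground-truth
#' positives cannot support an AP and are excluded with a warning.
#'
#' @param dets Detection tibble.
#' @param truths Ground-truth tibble.
#' @param iou_threshold IoU correctness threshold (default 0.5).
#' @param interpolation AP interpolation scheme, see
#'   [average_precision()].
#' @return A `detection_eval` object: list with `per_class` (tibble
#'   `class`, `tp`, `fp`, `fn`, `precision`, `recall`, `ap`) and `map`.
#' @export
eval_detections <- function(dets, truths, iou_threshold = 0.5,
                            interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  m <- match_detections_to_truth(dets, truths, iou_threshold)
  per_class <- m$summary
  per_class$ap <- purrr::map_dbl(per_class$class, function(cls) {
    n_truth <- sum(truths$class == cls)
    if (n_truth == 0) return(NA_real_)
    d <- m$dets[m$dets$class == cls, ]
    average_precision(d$score, d$tp, n_truth, interpolation)
  })
  if (anyNA(per_class$ap)) {
    warning("class(es) without ground-truth positives excluded from mAP: ",
            paste(per_class$class[is.na(per_class$ap)], collapse = ", "),
            call. = FALSE)
  }
  structure(list(per_class = per_class,
                 map = mean(per_class$ap, na.rm = TRUE)),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  print(x$per_class)
  cat("mAP:", x$map, "\n")
  invisible(x)
}
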