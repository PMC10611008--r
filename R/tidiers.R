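#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for tracking and counting results
#'
#' `tidy()` returns the per-unit table of a result object; `glance()`
#' a one-row summary.
#'
#' @param x A `track_history`, `count_report`, `count_eval` or
#'   `detection_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @name fruittrack-tidiers
NULL

#' @rdname fruittrack-tidiers
#' @method glance track_history
#' @export
glance.track_history <- function(x, ...) {
  info <- attr(x, "tracker_info")
  tibble::tibble(
    n_frames = dplyr::n_distinct(x$frame),
    n_tracks = dplyr::n_distinct(x$track_id),
    n_ids_created = info$n_created %||% NA_integer_,
    n_rows = nrow(x))
}

#' @rdname fruittrack-tidiers
#' @method tidy count_report
#' @export
tidy.count_report <- function(x, ...) {
  tibble::as_tibble(x)[c("class", "band", "count", "total")]
}

#' @rdname fruittrack-tidiers
#' @method glance count_report
#' @export
glance.count_report <- function(x, ...) {
  tot <- dplyr::distinct(tibble::as_tibble(x), .data$class, .data$total)
  out <- tibble::as_tibble(as.list(stats::setNames(tot$total, tot$class)))
  out$total <- sum(tot$total)
  out
}

#' @rdname fruittrack-tidiers
#' @method tidy count_eval
#' @export
tidy.count_eval <- function(x, ...) {
  x$per_video
}

#' @rdname fruittrack-tidiers
#' @method glance count_eval
#' @export
glance.count_eval <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$per_class, names_from = "class",
                             values_from = "apc",
                             names_glue = "apc_{class}")
  wide$mapc <- x$mapc
  wide$n_videos <- dplyr::n_distinct(x$per_video$video)
  wide
}

#' @rdname fruittrack-tidiers
#' @method tidy detection_eval
#' @export
tidy.detection_eval <- function(x, ...) {
  x$per_class
}

#' @rdname fruittrack-tidiers
#' @method glance detection_eval
#' @export
glance.detection_eval <- function(x, ...) {
  tibble::tibble(map = x$map, n_classes = sum(!is.na(x$per_class$ap)))
}

#' Plot a track history
#'
#' Horizontal position of each track's box center against frame index,
#' one line per track ID, coloured by class — fragmentation and ID
#' switches show up as broken or crossing lines.
#'
#' @param object A `track_history`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot track_history
#' @export
autoplot.track_history <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      cx = (.data$x1 + .data$x2) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$cx,
                                   group = .data$track_id,
                                   colour = .data$class)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "frame", y = "box center x (px)", colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a count report
#'
#' @param object A `count_report`.
#' @param ... Unused.
#' @return A ggplot object (per-class counts, stacked by band).
#' @method autoplot count_report
#' @export
autoplot.count_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$class, y = .data$count,
                               fill = .data$band)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "count", fill = "band") +
    ggplot2::theme_minimal()
}

#' Plot a counting evaluation
#'
#' @param object A `count_eval`.
#' @param ... Unused.
#' @return A ggplot object (per-video Pc by class, with per-class APc
#'   overlaid).
#' @method autoplot count_eval
#' @export
autoplot.count_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_video,
                  ggplot2::aes(x = factor(.data$video), y = .data$pc,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(data = object$per_class,
                        ggplot2::aes(yintercept = .data$apc,
                                     colour = .data$class),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = "video", y = "counting accuracy Pc (%)",
                  fill = "class") +
    ggplot2::theme_minimal()
}
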