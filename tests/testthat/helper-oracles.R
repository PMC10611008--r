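# Independent oracles: deliberately naive implementations used to freeze
# expected values, kept free of the package's own algorithms.

# IoU by counting unit pixel cells; integer-coordinate boxes only.
raster_iou_oracle <- function(a, b) {
  cells <- function(box) {
    if (box$x2 <= box$x1 || box$y2 <= box$y1) return(character(0))
    g <- expand.grid(x = seq(box$x1, box$x2 - 1), y = seq(box$y1, box$y2 - 1))
    paste(g$x, g$y)
  }
  ca <- cells(a); cb <- cells(b)
  inter <- length(intersect(ca, cb))
  inter / (length(ca) + length(cb) - inter)
}

# Minimum-cost one-to-one assignment by exhaustive enumeration (<= 6x6).
# Returns the pair matrix (rows: track, det) of one optimal solution and
# the optimal cost.
brute_force_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- list(cost = Inf, pairs = NULL)
  recurse <- function(row, used, acc, pairs) {
    if (row > nr) {
      if (acc < best$cost - 1e-12) {
        best$cost <<- acc
        best$pairs <<- pairs
      }
      return(invisible())
    }
    if (nr <= nc) {
      for (j in seq_len(nc)) {
        if (!used[j]) {
          recurse(row + 1L, replace(used, j, TRUE), acc + cost[row, j],
                  rbind(pairs, c(row, j)))
        }
      }
    }
  }
  if (nr <= nc) {
    recurse(1L, logical(nc), 0, NULL)
  } else {
    sub <- brute_force_assignment(t(cost))
    best$cost <- sub$cost
    best$pairs <- sub$pairs[, 2:1, drop = FALSE]
  }
  best
}

# Total IoU actually matched by an optimal assignment, after applying the
# same demotion rules as the tracker (forbidden cost, minimum IoU).
oracle_matched_iou <- function(iou, gate = NULL, min_iou = 0) {
  cost <- 1 - iou
  if (!is.null(gate)) cost[gate] <- 1e6
  sol <- brute_force_assignment(cost)
  keep <- cost[sol$pairs] < 5e5 & iou[sol$pairs] > max(min_iou, 0)
  sum(iou[sol$pairs][keep])
}

# Average precision straight from the definition: the precision envelope
# q(r) = max{p_i : r_i >= r}, integrated stepwise over recall.
ap_oracle <- function(scores, tp, n_truth) {
  ord <- order(-scores)
  tp <- tp[ord]
  recall <- cumsum(tp) / n_truth
  precision <- cumsum(tp) / seq_along(tp)
  q <- function(r) {
    ok <- recall >= r - 1e-12
    if (any(ok)) max(precision[ok]) else 0
  }
  bps <- sort(unique(recall[recall > 0]))
  prev <- 0
  total <- 0
  for (r in bps) {
    total <- total + (r - prev) * q(r)
    prev <- r
  }
  total
}
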