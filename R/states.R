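#' State definition in a two-dimensional CV space
#'
#' Axis-aligned regions for the closed state, the S1 state and the reactive
#' rectangle between them.  Regions are half-open boxes `[lo, hi)` on each
#' axis so every point receives exactly one label.
#'
#' @param closed,s1,reactive Length-four numerics `c(x_lo, x_hi, y_lo, y_hi)`.
#' @return Object of class `state_definition`.
#' @export
state_definition <- function(closed, s1, reactive) {
  boxes <- list(closed = closed, s1 = s1, reactive = reactive)
  for (b in boxes) stopifnot(length(b) == 4, b[1] < b[2], b[3] < b[4])
  if (boxes_overlap(closed, s1) || boxes_overlap(closed, reactive) ||
      boxes_overlap(s1, reactive))
    stop("state regions must be pairwise disjoint")
  structure(boxes, class = "state_definition")
}

boxes_overlap <- function(a, b) {
  a[1] < b[2] && b[1] < a[2] && a[3] < b[4] && b[3] < a[4]
}

#' @export
print.state_definition <- function(x, ...) {
  f <- function(b) sprintf("[%.3g, %.3g) x [%.3g, %.3g)", b[1], b[2], b[3], b[4])
  cat("<state_definition>\n  closed  ", f(x$closed), "\n  S1      ",
      f(x$s1), "\n  reactive", f(x$reactive), "\n")
  invisible(x)
}

in_box <- function(pts, b) {
  pts[, 1] >= b[1] & pts[, 1] < b[2] & pts[, 2] >= b[3] & pts[, 2] < b[4]
}

#' Assign CV-space points to states
#'
#' @param points Numeric matrix (n x 2) or a length-two vector.
#' @param def A `state_definition`.
#' @return Character vector in `{"closed", "S1", "reactive", "outside"}`.
#' @export
assign_state <- function(points, def) {
  stopifnot(inherits(def, "state_definition"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  out <- rep("outside", nrow(points))
  out[in_box(points, def$reactive)] <- "reactive"
  out[in_box(points, def$closed)] <- "closed"
  out[in_box(points, def$s1)] <- "S1"
  out
}

# connected components of a logical bin matrix under 4-connectivity
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      a <- p[1]; b <- p[2]
      if (a < 1 || b < 1 || a > nrow(mask) || b > ncol(mask)) next
      if (!mask[a, b] || lab[a, b] != 0L) next
      lab[a, b] <- cur
      stack <- c(stack, list(c(a - 1, b), c(a + 1, b), c(a, b - 1),
                             c(a, b + 1)))
    }
  }
  lab
}

#' Derive state regions from the path density in CV space
#'
#' Histograms the pooled path points on a 2D grid, keeps bins above the
#' `high_density_quantile` of occupied-bin counts, and extracts the two
#' largest connected components as the closed and S1 seeds (the component
#' with the smaller mean first-CV value is `closed`, matching the S1-positive
#' sign convention).  The reactive rectangle may be supplied explicitly; by
#' default a rectangle spanning the gap between the two state boxes along
#' their separation axis is suggested.
#'
#' @param points Pooled n x 2 matrix of CV projections from at least 2 paths.
#' @param bins Bins per axis (default 100).
#' @param high_density_quantile Quantile of occupied-bin counts defining
#'   "high density" (default 0.90).
#' @param rectangle Optional explicit reactive rectangle
#'   `c(x_lo, x_hi, y_lo, y_hi)`.
#' @param pad Fractional padding added around the component bounding boxes.
#' @return A `state_definition`.
#' @export
density_regions <- function(points, bins = 100, high_density_quantile = 0.90,
                            rectangle = NULL, pad = 0.02) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 10)
  bx <- seq(min(points[, 1]), max(points[, 1]), length.out = bins + 1)
  by <- seq(min(points[, 2]), max(points[, 2]), length.out = bins + 1)
  ix <- pmin(findInterval(points[, 1], bx, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(points[, 2], by, rightmost.closed = TRUE), bins)
  h <- matrix(0L, bins, bins)
  for (k in seq_len(nrow(points))) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1L
  occ <- h[h > 0]
  thr <- stats::quantile(occ, high_density_quantile)
  lab <- label_components(h >= thr)
  sizes <- tabulate(lab[lab > 0])
  # ignore speck components (isolated rim bins of one density blob)
  min_size <- max(3, ceiling(0.05 * sum(sizes)))
  if (sum(sizes >= min_size) < 2)
    stop("fewer than two high-density components found; supply the state ",
         "regions or the reactive rectangle explicitly")
  top2 <- order(sizes, decreasing = TRUE)[1:2]
  box_of <- function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    x_lo <- bx[min(w[, 1])]; x_hi <- bx[max(w[, 1]) + 1]
    y_lo <- by[min(w[, 2])]; y_hi <- by[max(w[, 2]) + 1]
    px <- pad * (x_hi - x_lo + 1e-12); py <- pad * (y_hi - y_lo + 1e-12)
    c(x_lo - px, x_hi + px, y_lo - py, y_hi + py)
  }
  b1 <- box_of(top2[1]); b2 <- box_of(top2[2])
  if (mean(b1[1:2]) <= mean(b2[1:2])) { closed <- b1; s1 <- b2 }
  else { closed <- b2; s1 <- b1 }
  if (boxes_overlap(closed, s1)) {
    # bounding boxes of diagonal components can overlap; trim both along
    # the axis of larger centre separation to restore a gap
    dx <- abs(mean(s1[1:2]) - mean(closed[1:2]))
    dy <- abs(mean(s1[3:4]) - mean(closed[3:4]))
    ax <- if (dx >= dy) 1:2 else 3:4
    lo_first <- mean(closed[ax]) <= mean(s1[ax])
    mid <- (mean(closed[ax]) + mean(s1[ax])) / 2
    gap <- 0.02 * abs(mean(s1[ax]) - mean(closed[ax])) + 1e-9
    if (lo_first) {
      closed[ax[2]] <- min(closed[ax[2]], mid - gap)
      s1[ax[1]] <- max(s1[ax[1]], mid + gap)
    } else {
      s1[ax[2]] <- min(s1[ax[2]], mid - gap)
      closed[ax[1]] <- max(closed[ax[1]], mid + gap)
    }
  }
  if (is.null(rectangle)) {
    # span of the path points crossing the gap, on the non-separating axis
    cross_span <- function(sel, other_col) {
      if (sum(sel) < 3) return(NULL)
      q <- stats::quantile(points[sel, other_col], c(0.005, 0.995))
      m <- 0.05 * (q[2] - q[1] + 1e-12)
      c(q[1] - m, q[2] + m)
    }
    gap_x <- s1[1] - closed[2]
    gap_y <- max(s1[3] - closed[4], closed[3] - s1[4])
    if (gap_x >= gap_y && gap_x > 0) {
      span <- cross_span(points[, 1] > closed[2] & points[, 1] < s1[1], 2)
      if (is.null(span)) span <- c(min(closed[3], s1[3]),
                                   max(closed[4], s1[4]))
      rectangle <- c(closed[2], s1[1], span[1], span[2])
    } else if (gap_y > 0) {
      lo_box <- if (s1[3] - closed[4] > 0) closed else s1
      hi_box <- if (s1[3] - closed[4] > 0) s1 else closed
      span <- cross_span(points[, 2] > lo_box[4] & points[, 2] < hi_box[3],
                         1)
      if (is.null(span)) span <- c(min(closed[1], s1[1]),
                                   max(closed[2], s1[2]))
      rectangle <- c(span[1], span[2], lo_box[4], hi_box[3])
    } else {
      stop("state components are not separated along either axis; supply ",
           "the reactive rectangle explicitly")
    }
  }
  state_definition(closed, s1, rectangle)
}
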