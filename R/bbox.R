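#' Centre-form bounding boxes
#'
#' Boxes are represented in centre form `(cx, cy, w, h)`: centre coordinates,
#' width and height. Units are the caller's (pixels or normalised
#' coordinates); all geometry here is units-agnostic. Most functions accept a
#' length-4 numeric vector, an `n x 4` matrix, or a data frame with columns
#' `cx, cy, w, h`, and are vectorised over rows with recycling between the two
#' box arguments.
#'
#' @param cx,cy Box centre coordinates.
#' @param w,h Box width and height; must be strictly positive.
#' @return `bbox()` returns a data frame with columns `cx, cy, w, h`.
#' @examples
#' b <- bbox(0.5, 0.5, 1, 1)
#' bbox_corners(b)
#' @export
bbox <- function(cx, cy, w, h) {
  b <- data.frame(cx = cx, cy = cy, w = w, h = h)
  as.data.frame(as_bbox(b))
}

#' Coerce to a bounding-box matrix
#'
#' @param x Numeric vector of length 4 (`cx, cy, w, h`), an `n x 4` matrix, or
#'   a data frame with those columns.
#' @return An `n x 4` numeric matrix with columns `cx, cy, w, h`.
#' @export
as_bbox <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("cx", "cy", "w", "h") %in% names(x)))
    m <- as.matrix(x[, c("cx", "cy", "w", "h")])
  } else if (is.matrix(x)) {
    stopifnot(ncol(x) == 4)
    m <- x
  } else {
    stopifnot(is.numeric(x), length(x) == 4)
    m <- matrix(x, nrow = 1)
  }
  colnames(m) <- c("cx", "cy", "w", "h")
  if (!all(is.finite(m))) stop("invalid box: non-finite coordinates")
  if (any(m[, "w"] <= 0) || any(m[, "h"] <= 0)) {
    stop("invalid box: width and height must be positive")
  }
  m
}

#' Corner form of a box
#'
#' @param b Boxes in any form accepted by [as_bbox()].
#' @return An `n x 4` matrix with columns `x1, y1, x2, y2` (`x1 < x2`,
#'   `y1 < y2`).
#' @export
bbox_corners <- function(b) {
  m <- as_bbox(b)
  out <- cbind(
    x1 = m[, "cx"] - m[, "w"] / 2, y1 = m[, "cy"] - m[, "h"] / 2,
    x2 = m[, "cx"] + m[, "w"] / 2, y2 = m[, "cy"] + m[, "h"] / 2
  )
  out
}

#' Centre-form box from corner coordinates
#'
#' @param x1,y1,x2,y2 Corner coordinates with `x1 < x2`, `y1 < y2`.
#' @return A data frame of boxes (see [bbox()]).
#' @export
bbox_from_corners <- function(x1, y1, x2, y2) {
  bbox((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1)
}

# recycle two box matrices to a common number of rows
recycle_boxes <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  list(a = a, b = b, n = n)
}
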