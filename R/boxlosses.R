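#' Shape-IoU and CIoU bounding-box regression losses
#'
#' The Shape-IoU loss augments plain IoU with (i) width/height weights derived
#' from the ground-truth box shape through a dataset-level `scale` factor,
#' (ii) a centre-distance penalty normalised by the diagonal of the minimum
#' enclosing axis-aligned rectangle of the two boxes, and (iii) an
#' exponentially saturating width/height-difference term:
#'
#' \deqn{L = 1 - IoU + distance^{shape} + \omega \cdot \Omega^{shape}}
#'
#' with `ww = 2 w_g^s / (w_g^s + h_g^s)`, `hh = 2 h_g^s / (w_g^s + h_g^s)`,
#' `distance = hh (\Delta x)^2/c^2 + ww (\Delta y)^2/c^2`, and
#' `\Omega = (1 - e^{-\omega_w})^\theta + (1 - e^{-\omega_h})^\theta` where
#' `\omega_w = hh |w - w_g| / max(w, w_g)` and symmetrically for heights.
#' The cross-weighting (height weight `hh` on the x/width terms and `ww` on
#' the y/height terms) is deliberate and kept exactly as defined.
#'
#' @name boxlosses
NULL

EPS_BOX <- 1e-9

#' Intersection over union of two boxes
#'
#' @param a,b Boxes in any form accepted by [as_bbox()]; vectorised with
#'   recycling over rows.
#' @return Numeric vector of IoU values in `[0, 1]`; symmetric in `a`, `b`.
#' @examples
#' box_iou(bbox(0.5, 0.5, 1, 1), bbox(1.0, 0.5, 1, 1)) # 1/3
#' @export
box_iou <- function(a, b) {
  r <- recycle_boxes(a, b)
  ca <- bbox_corners(r$a); cb <- bbox_corners(r$b)
  iw <- pmin(ca[, "x2"], cb[, "x2"]) - pmax(ca[, "x1"], cb[, "x1"])
  ih <- pmin(ca[, "y2"], cb[, "y2"]) - pmax(ca[, "y1"], cb[, "y1"])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- r$a[, "w"] * r$a[, "h"] + r$b[, "w"] * r$b[, "h"] - inter
  unname(inter / pmax(union, EPS_BOX))
}

#' Shape-IoU parameter set
#'
#' @param scale Dataset-level size factor applied to the ground-truth width
#'   and height when forming the shape weights; `scale = 0` makes the weights
#'   neutral (`ww = hh = 1`). Must be `>= 0`.
#' @param theta Exponent of the shape-difference term (default 4).
#' @param omega_weight Coefficient on the shape-difference term (default 0.5).
#' @return A list with class `shape_iou_params`.
#' @export
shape_iou_params <- function(scale = 0, theta = 4, omega_weight = 0.5) {
  if (!is.numeric(scale) || scale < 0) stop("parameter error: scale must be >= 0")
  if (!is.numeric(theta) || theta <= 0) stop("parameter error: theta must be > 0")
  if (!is.numeric(omega_weight) || omega_weight < 0) {
    stop("parameter error: omega_weight must be >= 0")
  }
  structure(list(scale = scale, theta = theta, omega_weight = omega_weight),
            class = "shape_iou_params")
}

#' Ground-truth shape weights
#'
#' @param gt Ground-truth boxes.
#' @param scale Size factor, `>= 0`.
#' @return A two-column matrix `(ww, hh)`; rows always satisfy `ww + hh == 2`.
#' @export
shape_weights <- function(gt, scale = 0) {
  if (!is.numeric(scale) || length(scale) != 1 || scale < 0) {
    stop("parameter error: scale must be a single value >= 0")
  }
  g <- as_bbox(gt)
  ws <- g[, "w"]^scale
  hs <- g[, "h"]^scale
  ww <- 2 * ws / (ws + hs)
  cbind(ww = ww, hh = 2 - ww)
}

# enclosing-rectangle squared diagonal of box pair (floored)
enclosing_c2 <- function(ca, cb) {
  cw <- pmax(ca[, "x2"], cb[, "x2"]) - pmin(ca[, "x1"], cb[, "x1"])
  ch <- pmax(ca[, "y2"], cb[, "y2"]) - pmin(ca[, "y1"], cb[, "y1"])
  pmax(cw^2 + ch^2, EPS_BOX)
}

#' Weighted, normalised centre-distance penalty
#'
#' `hh` weights the x-offset and `ww` the y-offset (cross-weighting); the
#' squared offsets are normalised by the squared diagonal of the minimum
#' enclosing axis-aligned rectangle of the two boxes.
#'
#' @param b Predicted boxes.
#' @param gt Ground-truth boxes.
#' @param ww,hh Shape weights from [shape_weights()].
#' @return Numeric vector; `0` iff the centres coincide, bounded by `ww + hh`.
#' @export
shape_distance <- function(b, gt, ww = 1, hh = 1) {
  r <- recycle_boxes(b, gt)
  c2 <- enclosing_c2(bbox_corners(r$a), bbox_corners(r$b))
  dx2 <- (r$a[, "cx"] - r$b[, "cx"])^2
  dy2 <- (r$a[, "cy"] - r$b[, "cy"])^2
  unname(hh * dx2 / c2 + ww * dy2 / c2)
}

#' Exponential width/height-difference term
#'
#' @inheritParams shape_distance
#' @param theta Shape exponent (default 4).
#' @return Numeric vector in `[0, 2)`.
#' @export
shape_omega <- function(b, gt, ww = 1, hh = 1, theta = 4) {
  r <- recycle_boxes(b, gt)
  om_w <- hh * abs(r$a[, "w"] - r$b[, "w"]) / pmax(pmax(r$a[, "w"], r$b[, "w"]), EPS_BOX)
  om_h <- ww * abs(r$a[, "h"] - r$b[, "h"]) / pmax(pmax(r$a[, "h"], r$b[, "h"]), EPS_BOX)
  unname((1 - exp(-om_w))^theta + (1 - exp(-om_h))^theta)
}

#' Shape-IoU loss with per-term breakdown
#'
#' @param b Predicted boxes.
#' @param gt Ground-truth boxes (recycled against `b`).
#' @param params A [shape_iou_params()] object.
#' @return A data frame with one row per box pair and columns `iou`, `ww`,
#'   `hh`, `distance_shape`, `omega_shape`, `total`. `total` is `0` iff the
#'   boxes are identical, and lies in `[0, 4]` for `omega_weight = 0.5`.
#' @examples
#' shape_iou_loss(bbox(0.5, 0.5, 1, 1), bbox(0.5, 0.5, 2, 1))
#' @export
shape_iou_loss <- function(b, gt, params = shape_iou_params()) {
  stopifnot(inherits(params, "shape_iou_params"))
  r <- recycle_boxes(b, gt)
  w <- shape_weights(r$b, params$scale)
  iou <- box_iou(r$a, r$b)
  dist <- shape_distance(r$a, r$b, ww = w[, "ww"], hh = w[, "hh"])
  om <- shape_omega(r$a, r$b, ww = w[, "ww"], hh = w[, "hh"], theta = params$theta)
  data.frame(
    iou = iou, ww = unname(w[, "ww"]), hh = unname(w[, "hh"]),
    distance_shape = dist, omega_shape = om,
    total = 1 - iou + dist + params$omega_weight * om
  )
}

#' Analytic gradient of the Shape-IoU loss
#'
#' Gradient of `shape_iou_loss(...)$total` with respect to the predicted box
#' parameters `(cx, cy, w, h)`. Piecewise-smooth: at measure-zero ties
#' (equal widths, aligned corners) a subgradient is returned.
#'
#' @inheritParams shape_iou_loss
#' @return An `n x 4` matrix with columns `cx, cy, w, h`.
#' @export
shape_iou_grad <- function(b, gt, params = shape_iou_params()) {
  stopifnot(inherits(params, "shape_iou_params"))
  r <- recycle_boxes(b, gt)
  p <- r$a; g <- r$b
  cp <- bbox_corners(p); cg <- bbox_corners(g)
  wgt <- shape_weights(g, params$scale)
  ww <- wgt[, "ww"]; hh <- wgt[, "hh"]

  # ---- IoU term ----
  iw <- pmin(cp[, "x2"], cg[, "x2"]) - pmax(cp[, "x1"], cg[, "x1"])
  ih <- pmin(cp[, "y2"], cg[, "y2"]) - pmax(cp[, "y1"], cg[, "y1"])
  ovl <- iw > 0 & ih > 0
  I <- ifelse(ovl, iw * ih, 0)
  A <- p[, "w"] * p[, "h"]
  U <- pmax(A + g[, "w"] * g[, "h"] - I, EPS_BOX)
  # dI w.r.t. prediction corners (zero when boxes disjoint)
  dI_px1 <- ifelse(ovl & cp[, "x1"] > cg[, "x1"], -ih, 0)
  dI_px2 <- ifelse(ovl & cp[, "x2"] < cg[, "x2"], ih, 0)
  dI_py1 <- ifelse(ovl & cp[, "y1"] > cg[, "y1"], -iw, 0)
  dI_py2 <- ifelse(ovl & cp[, "y2"] < cg[, "y2"], iw, 0)
  dI <- cbind(
    cx = dI_px1 + dI_px2,
    cy = dI_py1 + dI_py2,
    w = (dI_px2 - dI_px1) / 2,
    h = (dI_py2 - dI_py1) / 2
  )
  dA <- cbind(cx = 0, cy = 0, w = p[, "h"], h = p[, "w"])
  dIoU <- (dI * (U + I) - I * dA) / U^2

  # ---- distance term ----
  cw <- pmax(cp[, "x2"], cg[, "x2"]) - pmin(cp[, "x1"], cg[, "x1"])
  ch <- pmax(cp[, "y2"], cg[, "y2"]) - pmin(cp[, "y1"], cg[, "y1"])
  c2 <- pmax(cw^2 + ch^2, EPS_BOX)
  dx <- p[, "cx"] - g[, "cx"]; dy <- p[, "cy"] - g[, "cy"]
  ex_lo <- cp[, "x1"] < cg[, "x1"]  # prediction provides left edge
  ex_hi <- cp[, "x2"] > cg[, "x2"]
  ey_lo <- cp[, "y1"] < cg[, "y1"]
  ey_hi <- cp[, "y2"] > cg[, "y2"]
  dcw <- cbind(cx = as.numeric(ex_hi) - as.numeric(ex_lo), cy = 0,
               w = (as.numeric(ex_hi) + as.numeric(ex_lo)) / 2, h = 0)
  dch <- cbind(cx = 0, cy = as.numeric(ey_hi) - as.numeric(ey_lo),
               w = 0, h = (as.numeric(ey_hi) + as.numeric(ey_lo)) / 2)
  dc2 <- 2 * cw * dcw + 2 * ch * dch
  num <- hh * dx^2 + ww * dy^2
  ddist <- cbind(cx = 2 * hh * dx, cy = 2 * ww * dy, w = 0, h = 0) / c2 -
    (num / c2^2) * dc2

  # ---- omega term ----
  mw <- pmax(pmax(p[, "w"], g[, "w"]), EPS_BOX)
  mh <- pmax(pmax(p[, "h"], g[, "h"]), EPS_BOX)
  om_w <- hh * abs(p[, "w"] - g[, "w"]) / mw
  om_h <- ww * abs(p[, "h"] - g[, "h"]) / mh
  dom_w_dw <- ifelse(p[, "w"] > g[, "w"], hh * g[, "w"] / p[, "w"]^2,
                     ifelse(p[, "w"] < g[, "w"], -hh / g[, "w"], 0))
  dom_h_dh <- ifelse(p[, "h"] > g[, "h"], ww * g[, "h"] / p[, "h"]^2,
                     ifelse(p[, "h"] < g[, "h"], -ww / g[, "h"], 0))
  th <- params$theta
  dOm_w <- th * (1 - exp(-om_w))^(th - 1) * exp(-om_w)
  dOm_h <- th * (1 - exp(-om_h))^(th - 1) * exp(-om_h)
  dOmega <- cbind(cx = 0, cy = 0, w = dOm_w * dom_w_dw, h = dOm_h * dom_h_dh)

  out <- -dIoU + ddist + params$omega_weight * dOmega
  colnames(out) <- c("cx", "cy", "w", "h")
  out
}

#' Complete-IoU (CIoU) loss
#'
#' Baseline loss for comparison experiments:
#' `1 - IoU + rho^2/c^2 + alpha * v`, with `rho` the centre distance, `c` the
#' enclosing-rectangle diagonal, `v` the squared arctan aspect-ratio gap, and
#' `alpha = v / (1 - IoU + v)`.
#'
#' @inheritParams shape_distance
#' @param breakdown If `TRUE`, return a data frame with the individual terms.
#' @return Numeric vector of losses (or a data frame when `breakdown = TRUE`).
#' @export
ciou_loss <- function(b, gt, breakdown = FALSE) {
  r <- recycle_boxes(b, gt)
  iou <- box_iou(r$a, r$b)
  c2 <- enclosing_c2(bbox_corners(r$a), bbox_corners(r$b))
  rho2 <- (r$a[, "cx"] - r$b[, "cx"])^2 + (r$a[, "cy"] - r$b[, "cy"])^2
  v <- (4 / pi^2) *
    (atan(r$b[, "w"] / r$b[, "h"]) - atan(r$a[, "w"] / r$a[, "h"]))^2
  alpha <- v / pmax(1 - iou + v, EPS_BOX)
  total <- unname(1 - iou + rho2 / c2 + alpha * v)
  if (breakdown) {
    return(data.frame(iou = iou, center = unname(rho2 / c2),
                      aspect = unname(alpha * v), total = total))
  }
  total
}

#' Gradient of the CIoU loss
#'
#' `alpha` is treated as a constant during differentiation, the usual
#' convention for this loss.
#'
#' @inheritParams ciou_loss
#' @return An `n x 4` matrix with columns `cx, cy, w, h`.
#' @export
ciou_grad <- function(b, gt) {
  r <- recycle_boxes(b, gt)
  p <- r$a; g <- r$b
  cp <- bbox_corners(p); cg <- bbox_corners(g)

  iw <- pmin(cp[, "x2"], cg[, "x2"]) - pmax(cp[, "x1"], cg[, "x1"])
  ih <- pmin(cp[, "y2"], cg[, "y2"]) - pmax(cp[, "y1"], cg[, "y1"])
  ovl <- iw > 0 & ih > 0
  I <- ifelse(ovl, iw * ih, 0)
  U <- pmax(p[, "w"] * p[, "h"] + g[, "w"] * g[, "h"] - I, EPS_BOX)
  iou <- I / U
  dI <- cbind(
    cx = ifelse(ovl & cp[, "x1"] > cg[, "x1"], -ih, 0) +
      ifelse(ovl & cp[, "x2"] < cg[, "x2"], ih, 0),
    cy = ifelse(ovl & cp[, "y1"] > cg[, "y1"], -iw, 0) +
      ifelse(ovl & cp[, "y2"] < cg[, "y2"], iw, 0),
    w = (ifelse(ovl & cp[, "x2"] < cg[, "x2"], ih, 0) -
           ifelse(ovl & cp[, "x1"] > cg[, "x1"], -ih, 0)) / 2,
    h = (ifelse(ovl & cp[, "y2"] < cg[, "y2"], iw, 0) -
           ifelse(ovl & cp[, "y1"] > cg[, "y1"], -iw, 0)) / 2
  )
  dA <- cbind(cx = 0, cy = 0, w = p[, "h"], h = p[, "w"])
  dIoU <- (dI * (U + I) - I * dA) / U^2

  cw <- pmax(cp[, "x2"], cg[, "x2"]) - pmin(cp[, "x1"], cg[, "x1"])
  ch <- pmax(cp[, "y2"], cg[, "y2"]) - pmin(cp[, "y1"], cg[, "y1"])
  c2 <- pmax(cw^2 + ch^2, EPS_BOX)
  dx <- p[, "cx"] - g[, "cx"]; dy <- p[, "cy"] - g[, "cy"]
  ex_lo <- cp[, "x1"] < cg[, "x1"]; ex_hi <- cp[, "x2"] > cg[, "x2"]
  ey_lo <- cp[, "y1"] < cg[, "y1"]; ey_hi <- cp[, "y2"] > cg[, "y2"]
  dcw <- cbind(cx = as.numeric(ex_hi) - as.numeric(ex_lo), cy = 0,
               w = (as.numeric(ex_hi) + as.numeric(ex_lo)) / 2, h = 0)
  dch <- cbind(cx = 0, cy = as.numeric(ey_hi) - as.numeric(ey_lo),
               w = 0, h = (as.numeric(ey_hi) + as.numeric(ey_lo)) / 2)
  dc2 <- 2 * cw * dcw + 2 * ch * dch
  rho2 <- dx^2 + dy^2
  dcenter <- cbind(cx = 2 * dx, cy = 2 * dy, w = 0, h = 0) / c2 -
    (rho2 / c2^2) * dc2

  gap <- atan(g[, "w"] / g[, "h"]) - atan(p[, "w"] / p[, "h"])
  v <- (4 / pi^2) * gap^2
  alpha <- v / pmax(1 - iou + v, EPS_BOX)
  denom <- p[, "w"]^2 + p[, "h"]^2
  dv <- cbind(cx = 0, cy = 0,
              w = (4 / pi^2) * 2 * gap * (-p[, "h"] / denom),
              h = (4 / pi^2) * 2 * gap * (p[, "w"] / denom))

  out <- -dIoU + dcenter + alpha * dv
  colnames(out) <- c("cx", "cy", "w", "h")
  out
}
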