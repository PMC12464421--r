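# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the loss oracle is a direct one-expression
# transliteration of the defining formulas, the AP oracle integrates the
# interpolated precision envelope on a dense recall grid, and the Koch
# fixture has a known fractal dimension.

random_box <- function(span = 2) {
  bbox(stats::runif(1, -span, span), stats::runif(1, -span, span),
       stats::runif(1, 0.2, span), stats::runif(1, 0.2, span))
}

# single-expression evaluation of the Shape-IoU loss
oracle_shape_iou <- function(b, gt, scale = 0, theta = 4, ow = 0.5) {
  bx <- as.numeric(as_bbox(b)); gx <- as.numeric(as_bbox(gt))
  cx <- bx[1]; cy <- bx[2]; w <- bx[3]; h <- bx[4]
  gcx <- gx[1]; gcy <- gx[2]; gw <- gx[3]; gh <- gx[4]
  inter <- max(0, min(cx + w / 2, gcx + gw / 2) - max(cx - w / 2, gcx - gw / 2)) *
    max(0, min(cy + h / 2, gcy + gh / 2) - max(cy - h / 2, gcy - gh / 2))
  iou <- inter / (w * h + gw * gh - inter)
  ww <- 2 * gw^scale / (gw^scale + gh^scale)
  hh <- 2 * gh^scale / (gw^scale + gh^scale)
  c2 <- (max(cx + w / 2, gcx + gw / 2) - min(cx - w / 2, gcx - gw / 2))^2 +
    (max(cy + h / 2, gcy + gh / 2) - min(cy - h / 2, gcy - gh / 2))^2
  dist <- hh * (cx - gcx)^2 / c2 + ww * (cy - gcy)^2 / c2
  om_w <- hh * abs(w - gw) / max(w, gw)
  om_h <- ww * abs(h - gh) / max(h, gh)
  omega <- (1 - exp(-om_w))^theta + (1 - exp(-om_h))^theta
  1 - iou + dist + ow * omega
}

# AP oracle: greedy-matched flags -> integrate max-precision envelope on a
# dense recall grid
oracle_ap <- function(tp_sorted, n_gt, grid = 4000) {
  cum_tp <- cumsum(tp_sorted); cum_fp <- cumsum(!tp_sorted)
  rec <- cum_tp / n_gt
  pre <- cum_tp / (cum_tp + cum_fp)
  rs <- seq(0, 1, length.out = grid + 1)[-1]
  penv <- vapply(rs, function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(pre[ok]) else 0
  }, numeric(1))
  sum(penv) / grid
}

# pooled matching flags (package matcher; the AP oracle integrates them)
match_all_images_oracle <- function(dets, gts) {
  nevuscreen:::match_all_images(dets, gts, 0.5)
}

# triadic Koch curve points on a segment (recursive), dimension log 4 / log 3
koch_segment <- function(p1, p2, depth) {
  if (depth == 0) return(rbind(p1))
  d <- (p2 - p1) / 3
  a <- p1 + d; b <- p1 + 2 * d
  rot <- matrix(c(cos(-pi / 3), -sin(-pi / 3), sin(-pi / 3), cos(-pi / 3)), 2)
  peak <- a + as.vector(rot %*% d)
  rbind(koch_segment(p1, a, depth - 1), koch_segment(a, peak, depth - 1),
        koch_segment(peak, b, depth - 1), koch_segment(b, p2, depth - 1))
}

# closed Koch snowflake polygon (counter-clockwise), centred
koch_snowflake <- function(radius = 100, depth = 4, center = c(128, 128)) {
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  v <- cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
  pts <- rbind(koch_segment(v[1, ], v[2, ], depth),
               koch_segment(v[2, ], v[3, ], depth),
               koch_segment(v[3, ], v[1, ], depth))
  colnames(pts) <- c("x", "y")
  pts
}

# even-odd point-in-polygon rasterisation onto a canvas x canvas mask
rasterize_polygon <- function(pts, canvas) {
  xs <- matrix(rep(seq_len(canvas), each = canvas), canvas)
  ys <- matrix(rep(seq_len(canvas), times = canvas), canvas)
  n <- nrow(pts)
  inside <- matrix(FALSE, canvas, canvas)
  j <- n
  for (i in seq_len(n)) {
    xi <- pts[i, 1]; yi <- pts[i, 2]; xj <- pts[j, 1]; yj <- pts[j, 2]
    crosses <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# circle mask + analytic contour
circle_fixture <- function(canvas = 128, radius = 40) {
  spec <- lesion_spec("benign", radius, position = c(canvas / 2, canvas / 2))
  gen_mask(spec, canvas)
}

# contour of r(phi) = 1 + a * cos(k phi), unit radius scaled to px
harmonic_contour <- function(a, k, radius = 40, n = 1440,
                             center = c(64, 64), phase = 0) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- radius * (1 + a * cos(k * phi + phase))
  cbind(x = center[1] + r * cos(phi), y = center[2] + r * sin(phi))
}
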