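#' Lesion boundary morphometrics
#'
#' Quantitative descriptors of lesion shape used to characterise malignant
#' boundary behaviour: Zhang-Suen skeleton topology (lobulation / satellite
#' outgrowth), a scale-resolved box-counting fractal dimension of the boundary
#' (multiscale serration), elliptic Fourier descriptor magnitudes (boundary
#' frequency content), and a polar radial-distance profile (asymmetry).
#'
#' Masks are binary matrices indexed `[row = y, col = x]` with foreground
#' `TRUE`/`1`; before any analysis the largest connected component is
#' selected. Contours are ordered closed point lists in `(x, y)` pixel
#' coordinates (sub-pixel values allowed for synthetic contours).
#'
#' @name morphology
NULL

# coerce to logical matrix, keep largest 8-connected component
mask_clean <- function(mask, fill_holes = FALSE) {
  m <- matrix(as.numeric(mask) > 0.5, nrow = nrow(mask))
  if (!any(m)) stop("empty mask")
  lab <- EBImage::bwlabel(EBImage::Image(t(m)))
  tab <- tabulate(as.integer(lab))
  keep <- which.max(tab)
  m <- t(as.matrix(lab) == keep)
  if (fill_holes) {
    m <- t(as.matrix(EBImage::fillHull(EBImage::Image(t(m)))) > 0)
  }
  m
}

#' Outer contour of a mask
#'
#' @param mask Binary matrix (`[y, x]` indexing).
#' @return An ordered closed contour: a matrix with columns `x`, `y`
#'   (1-based pixel coordinates, not repeating the first point).
#' @export
mask_contour <- function(mask) {
  m <- mask_clean(mask, fill_holes = TRUE)
  oc <- EBImage::ocontour(EBImage::Image(t(m) * 1))
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1  # 0-based -> 1-based
  colnames(pts) <- c("x", "y")
  pts
}

# centroid from mask moments (row/col means of foreground)
mask_centroid <- function(mask) {
  m <- mask_clean(mask, fill_holes = TRUE)
  idx <- which(m, arr.ind = TRUE)
  c(x = mean(idx[, 2]), y = mean(idx[, 1]))
}

#' Zhang-Suen skeletonisation with node census
#'
#' Iterative two-subcycle thinning to a 1-px-wide, connectivity-preserving
#' skeleton, followed by an 8-neighbour census: terminal points have exactly
#' one skeleton neighbour; branch points are skeleton pixels whose crossing
#' number (0-to-1 transitions around the 8-neighbour cycle) is three or
#' more, so that a simple crossing counts as one branch point rather than a
#' cluster of high-degree pixels.
#'
#' @param mask Binary lesion mask.
#' @return A list with `skeleton` (logical matrix), `branch_points`,
#'   `terminal_points`, `skeleton_px`, and `branch_density` (branch points
#'   per 100 skeleton pixels).
#' @export
zhang_suen <- function(mask) {
  m <- mask_clean(mask, fill_holes = TRUE)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  sh <- function(M, dy, dx) {
    # neighbour field: value of M at offset (dy, dx) for each interior pixel
    M[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- pad[2:(H + 1), 2:(W + 1)]
      p2 <- sh(pad, -1, 0); p3 <- sh(pad, -1, 1); p4 <- sh(pad, 0, 1)
      p5 <- sh(pad, 1, 1);  p6 <- sh(pad, 1, 0);  p7 <- sh(pad, 1, -1)
      p8 <- sh(pad, 0, -1); p9 <- sh(pad, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      del <- P & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        changed <- TRUE
        inner <- pad[2:(H + 1), 2:(W + 1)]
        inner[del] <- FALSE
        pad[2:(H + 1), 2:(W + 1)] <- inner
      }
    }
    if (!changed) break
  }
  skel <- pad[2:(H + 1), 2:(W + 1)]
  # neighbour + crossing-number census
  padk <- matrix(FALSE, H + 2, W + 2)
  padk[2:(H + 1), 2:(W + 1)] <- skel
  q2 <- sh(padk, -1, 0); q3 <- sh(padk, -1, 1); q4 <- sh(padk, 0, 1)
  q5 <- sh(padk, 1, 1);  q6 <- sh(padk, 1, 0);  q7 <- sh(padk, 1, -1)
  q8 <- sh(padk, 0, -1); q9 <- sh(padk, -1, -1)
  nb <- q2 + q3 + q4 + q5 + q6 + q7 + q8 + q9
  crossings <- (!q2 & q3) + (!q3 & q4) + (!q4 & q5) + (!q5 & q6) +
    (!q6 & q7) + (!q7 & q8) + (!q8 & q9) + (!q9 & q2)
  n_px <- sum(skel)
  terminals <- sum(skel & nb == 1)
  branches <- sum(skel & crossings >= 3)
  list(skeleton = skel, branch_points = branches, terminal_points = terminals,
       skeleton_px = n_px,
       branch_density = if (n_px > 0) 100 * branches / n_px else 0)
}

#' Scale-resolved local fractal dimension of the boundary
#'
#' Windows of side `s` slide along the boundary; within each window the
#' boundary pixels are box-counted over the dyadic sub-box sizes `s/16`,
#' `s/8`, `s/4` (floored at 2 px, a range that stays above the pixel floor
#' and below window saturation) and the local dimension is the regression
#' slope of `log N` against `log(1/eps)`. The spectrum reports the mean
#' local dimension per window size, clipped to `[1, 2]`.
#'
#' @param mask Binary lesion mask.
#' @param windows Window sizes in pixels (default `c(16, 32, 64, 128, 256)`).
#' @return A data frame with columns `window` and `fd`. Windows larger than
#'   the image are skipped with a warning.
#' @export
local_fd_spectrum <- function(mask, windows = c(16, 32, 64, 128, 256)) {
  contour <- mask_contour(mask)
  H <- nrow(mask); W <- ncol(mask)
  res <- lapply(windows, function(s) {
    if (s > max(H, W)) {
      warning(sprintf("window %d px larger than image, skipped", s))
      return(NULL)
    }
    step <- max(1L, as.integer(s / 2))
    centers <- contour[seq(1, nrow(contour), by = step), , drop = FALSE]
    fds <- apply(centers, 1, function(ct) {
      inw <- abs(contour[, "x"] - ct["x"]) <= s / 2 &
        abs(contour[, "y"] - ct["y"]) <= s / 2
      pts <- contour[inw, , drop = FALSE]
      if (nrow(pts) < 4) return(NA_real_)
      eps <- unique(pmax(2, s / c(16, 8, 4)))
      if (length(eps) < 2) return(NA_real_)
      n_boxes <- vapply(eps, function(e) {
        bx <- floor((pts[, "x"] - (ct["x"] - s / 2)) / e)
        by <- floor((pts[, "y"] - (ct["y"] - s / 2)) / e)
        length(unique(bx + 1e6 * by))
      }, numeric(1))
      fit <- stats::lm.fit(cbind(1, log(1 / eps)), log(n_boxes))
      fit$coefficients[2]
    })
    data.frame(window = s, fd = min(2, max(1, mean(fds, na.rm = TRUE))))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no usable window sizes")
  out
}

# closed-contour check: endpoint gap must be small relative to segments
check_closed <- function(pts) {
  if (nrow(pts) >= 2 && all(pts[1, ] == pts[nrow(pts), ])) {
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  gap <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  if (gap > 4 * max(stats::median(seg), 1)) stop("open contour")
  pts
}

#' Elliptic Fourier descriptor magnitudes
#'
#' Kuhl-Giardina elliptic Fourier coefficients `(a, b, c, d)` per harmonic
#' under arc-length parameterisation of the closed contour; the reported
#' magnitude per harmonic is `sqrt(a^2 + b^2 + c^2 + d^2)` normalised by the
#' first harmonic, so a pure ellipse concentrates all energy at harmonic 1.
#'
#' @param contour Closed contour matrix with columns `x`, `y`, or a binary
#'   mask (the contour is then extracted).
#' @param n_harmonics Number of harmonics (default 20).
#' @return A data frame with columns `harmonic` and `magnitude`
#'   (`magnitude[1] == 1`).
#' @export
efd_magnitudes <- function(contour, n_harmonics = 20) {
  if (is.matrix(contour) && ncol(contour) == 2) {
    pts <- contour
  } else {
    pts <- mask_contour(contour)
  }
  pts <- check_closed(pts)
  if (nrow(pts) < 4 * n_harmonics) {
    stop(sprintf("contour too short: need >= %d points", 4 * n_harmonics))
  }
  x <- pts[, 1]; y <- pts[, 2]
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  t1 <- cumsum(dt); t0 <- c(0, t1[-length(t1)])
  T <- t1[length(t1)]
  mags <- vapply(seq_len(n_harmonics), function(n) {
    w <- 2 * n * pi / T
    cn <- T / (2 * n^2 * pi^2)
    a <- cn * sum(dx / dt * (cos(w * t1) - cos(w * t0)))
    b <- cn * sum(dx / dt * (sin(w * t1) - sin(w * t0)))
    cc <- cn * sum(dy / dt * (cos(w * t1) - cos(w * t0)))
    d <- cn * sum(dy / dt * (sin(w * t1) - sin(w * t0)))
    sqrt(a^2 + b^2 + cc^2 + d^2)
  }, numeric(1))
  data.frame(harmonic = seq_len(n_harmonics), magnitude = mags / mags[1])
}

#' Polar radial-distance profile
#'
#' Radius from the centroid per angular bin using a star-shaped (maximum
#' crossing) reduction; empty bins are filled by circular linear
#' interpolation. Summaries: mean radius, oscillation
#' `(max - min) / mean`, per-contour-point normalised deviations
#' `(r - mean) / mean`, and the deviation-exceedance fraction.
#'
#' @param contour Closed contour (`x`, `y` matrix) or a binary mask.
#' @param n_bins Number of angular bins (default 360).
#' @param centroid Optional `c(x, y)` centroid; defaults to the polygon
#'   centroid of the contour (or mask moments when a mask is given).
#' @return A list with `angle` (bin centres, degrees), `radius`,
#'   `mean_radius`, `oscillation`, `deviations`, and `frac_over(t)` values
#'   accessible through [frac_over()]. If more than 5% of bins have multiple
#'   boundary crossings this is noted in `multi_crossing_frac`.
#' @export
radial_profile <- function(contour, n_bins = 360, centroid = NULL) {
  if (is.matrix(contour) && ncol(contour) == 2) {
    pts <- check_closed(contour)
    if (is.null(centroid)) centroid <- c(mean(pts[, 1]), mean(pts[, 2]))
  } else {
    pts <- mask_contour(contour)
    if (is.null(centroid)) centroid <- mask_centroid(contour)
  }
  if (nrow(pts) < 3) stop("degenerate contour: need >= 3 points")
  dxv <- pts[, 1] - centroid[1]; dyv <- pts[, 2] - centroid[2]
  r <- sqrt(dxv^2 + dyv^2)
  if (any(r <= 0)) stop("degenerate contour: centroid on boundary")
  phi <- (atan2(dyv, dxv) %% (2 * pi))
  bin <- pmin(floor(phi / (2 * pi) * n_bins) + 1, n_bins)
  rad <- rep(NA_real_, n_bins)
  agg <- tapply(r, bin, max)
  rad[as.integer(names(agg))] <- agg
  counts <- tabulate(bin, nbins = n_bins)
  multi <- mean(counts > ceiling(length(r) / n_bins) * 3)
  # circular linear interpolation of empty bins
  if (anyNA(rad)) {
    filled <- which(!is.na(rad))
    if (length(filled) < 2) stop("degenerate contour: too few angular bins")
    idx3 <- c(filled - n_bins, filled, filled + n_bins)
    val3 <- rep(rad[filled], 3)
    rad <- stats::approx(idx3, val3, xout = seq_len(n_bins))$y
  }
  rbar <- mean(rad)
  dev <- (r - rbar) / rbar
  structure(list(
    angle = (seq_len(n_bins) - 0.5) * 360 / n_bins,
    radius = rad, mean_radius = rbar,
    oscillation = (max(rad) - min(rad)) / rbar,
    deviations = dev,
    multi_crossing_frac = multi
  ), class = "radial_profile")
}

#' Fraction of boundary points deviating beyond a threshold
#'
#' @param profile A [radial_profile()] result.
#' @param t Threshold on `|r - mean| / mean` (default 0.10).
#' @return Fraction of contour points with normalised deviation above `t`;
#'   monotone non-increasing in `t`.
#' @export
frac_over <- function(profile, t = 0.10) {
  mean(abs(profile$deviations) > t)
}

#' Benign-criteria morphology report
#'
#' Bundles the morphometric descriptors with two pigment criteria measured on
#' the RGB image: within-lesion colour dispersion (mean per-channel standard
#' deviation) and border sharpness (mean normalised intensity step across the
#' boundary over a short normal span). Benign nevi are expected to be
#' symmetric (low radial deviation), uniformly pigmented (low colour
#' dispersion) and sharply demarcated (high border gradient).
#'
#' @param mask Binary lesion mask.
#' @param image Optional aligned RGB array `H x W x 3` in `[0, 1]`.
#' @param fd_windows Window sizes for [local_fd_spectrum()].
#' @return A nested list (JSON-serialisable) with `skeleton`, `fd_spectrum`,
#'   `efd`, `radial` (including `frac_over_10`), and when `image` is given,
#'   `colour_sd` and `border_gradient`.
#' @export
benign_criteria_report <- function(mask, image = NULL,
                                   fd_windows = c(16, 32, 64)) {
  sk <- zhang_suen(mask)
  contour <- mask_contour(mask)
  fd <- local_fd_spectrum(mask, fd_windows)
  n_h <- min(20, max(1, floor(nrow(contour) / 4)))
  efd <- efd_magnitudes(contour, n_harmonics = n_h)
  rp <- radial_profile(contour, centroid = mask_centroid(mask))
  rep <- list(
    skeleton = sk[c("branch_points", "terminal_points", "skeleton_px",
                    "branch_density")],
    fd_spectrum = fd,
    efd = efd,
    radial = list(mean_radius = rp$mean_radius,
                  oscillation = rp$oscillation,
                  frac_over_10 = frac_over(rp, 0.10))
  )
  if (!is.null(image)) {
    m <- mask_clean(mask, fill_holes = TRUE)
    px <- apply(image, 3, function(ch) ch[m])
    rep$colour_sd <- mean(apply(px, 2, stats::sd))
    rep$border_gradient <- border_gradient(mask, image, contour)
  }
  rep
}

# mean normalised intensity step across the border over a +-2 px normal span
border_gradient <- function(mask, image, contour = NULL) {
  if (is.null(contour)) contour <- mask_contour(mask)
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  m <- mask_clean(mask, fill_holes = TRUE)
  ctr <- mask_centroid(mask)
  H <- nrow(gray); W <- ncol(gray)
  inside <- mean(gray[m]); outside <- mean(gray[!m])
  contrast <- abs(inside - outside)
  if (contrast < 1e-6) return(0)
  idx <- seq(1, nrow(contour), length.out = min(200, nrow(contour)))
  steps <- vapply(idx, function(i) {
    p <- contour[round(i), ]
    nv <- c(p["x"] - ctr["x"], p["y"] - ctr["y"])
    nv <- nv / max(sqrt(sum(nv^2)), 1e-9)
    pi_ <- round(p - 2 * nv); po <- round(p + 2 * nv)
    if (any(c(pi_, po) < 1) || pi_["x"] > W || po["x"] > W ||
        pi_["y"] > H || po["y"] > H) return(NA_real_)
    abs(gray[pi_["y"], pi_["x"]] - gray[po["y"], po["x"]])
  }, numeric(1))
  mean(steps, na.rm = TRUE) / contrast
}
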