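#' Synthetic dermoscopic lesion generator
#'
#' Generates procedural dermoscopic-style images for which the benign /
#' malignant distinction is constructed from the three clinical benign-nevus
#' criteria: symmetry, uniform pigmentation, and a sharply demarcated border.
#' Benign specs satisfy all three (radial oscillation under 10%, no pigment
#' patches, border blend at most 2 px); malignant specs always violate the
#' symmetry/border-shape criterion (lobulation and/or serration of the
#' outline) and may additionally violate pigment homogeneity or border
#' sharpness. Lesion outlines are radial harmonic curves
#' `r(phi) = R (1 + sum_k a_k cos(k phi + phase_k))` rasterised onto a
#' procedural skin background, with optional dark curvilinear hair strokes
#' (occlusion grades 0 none / 1 sparse / 2 dense).
#'
#' @name synthgen
NULL

#' Lesion specification
#'
#' @param class `"benign"` or `"malignant"`.
#' @param radius Base radius in pixels.
#' @param harmonics Integer vector of radial harmonic orders.
#' @param amplitudes Amplitudes `a_k` aligned with `harmonics`.
#' @param phases Phases aligned with `harmonics`.
#' @param colour Base pigment RGB (length 3, in `[0, 1]`).
#' @param het_patches Number of pigment-heterogeneity patches (benign: 0).
#' @param het_contrast Patch contrast (added/subtracted intensity).
#' @param border_softness Border blend width in px (benign: <= 2).
#' @param position Lesion centre `c(x, y)` in px.
#' @param patient_id Patient identifier (string).
#' @return A list with class `lesion_spec`.
#' @export
lesion_spec <- function(class, radius, harmonics = integer(0),
                        amplitudes = numeric(0), phases = numeric(0),
                        colour = c(0.42, 0.28, 0.20), het_patches = 0,
                        het_contrast = 0, border_softness = 1,
                        position = NULL, patient_id = "p1") {
  stopifnot(class %in% c("benign", "malignant"),
            length(amplitudes) == length(harmonics),
            length(phases) == length(harmonics), radius > 0)
  structure(list(class = class, radius = radius, harmonics = harmonics,
                 amplitudes = amplitudes, phases = phases, colour = colour,
                 het_patches = het_patches, het_contrast = het_contrast,
                 border_softness = border_softness, position = position,
                 patient_id = patient_id),
            class = "lesion_spec")
}

#' Draw a random lesion specification
#'
#' Benign amplitudes keep the total radial modulation under 4% of the base
#' radius (oscillation well below 10%, `frac_over(0.10) = 0`); malignant
#' specs draw lobulation (low harmonics, amplitudes 0.12-0.22) and/or
#' serration (harmonics 9-15), and with probability 0.5 each also pigment
#' patches or a blurred border.
#'
#' @param class `"benign"` or `"malignant"`.
#' @param canvas Canvas side in px.
#' @param patient_id Patient identifier.
#' @return A [lesion_spec()].
#' @export
random_lesion_spec <- function(class, canvas = 64, patient_id = "p1") {
  radius <- stats::runif(1, 0.16, 0.28) * canvas
  margin <- radius * 1.45 + 2
  pos <- stats::runif(2, margin, canvas - margin)
  if (class == "benign") {
    ks <- 2:4
    a <- stats::runif(3)
    a <- a / sum(a) * stats::runif(1, 0.01, 0.04)
    spec <- lesion_spec("benign", radius, ks, a, stats::runif(3, 0, 2 * pi),
                        colour = pmax(0, c(0.42, 0.28, 0.20) +
                                        stats::rnorm(3, 0, 0.03)),
                        het_patches = 0, het_contrast = 0,
                        border_softness = stats::runif(1, 0.5, 2),
                        position = pos, patient_id = patient_id)
  } else {
    ks <- integer(0); a <- numeric(0)
    lobe <- stats::runif(1) < 0.8
    serr <- stats::runif(1) < 0.6
    if (!lobe && !serr) lobe <- TRUE
    if (lobe) {
      kl <- sample(2:5, 2)
      ks <- c(ks, kl)
      a <- c(a, stats::runif(2, 0.12, 0.22))
    }
    if (serr) {
      kh <- sample(9:15, 2)
      ks <- c(ks, kh)
      a <- c(a, stats::runif(2, 0.04, 0.08))
    }
    het <- stats::runif(1) < 0.5
    blur <- stats::runif(1) < 0.5
    spec <- lesion_spec("malignant", radius, ks, a,
                        stats::runif(length(ks), 0, 2 * pi),
                        colour = pmax(0, c(0.38, 0.25, 0.18) +
                                        stats::rnorm(3, 0, 0.04)),
                        het_patches = if (het) sample(3:6, 1) else 0,
                        het_contrast = if (het) stats::runif(1, 0.15, 0.30) else 0,
                        border_softness = if (blur) stats::runif(1, 6, 12) else
                          stats::runif(1, 0.5, 2),
                        position = pos, patient_id = patient_id)
  }
  spec
}

#' Rasterise a lesion outline into a mask and analytic contour
#'
#' Deterministic given the spec: the boundary is
#' `r(phi) = R (1 + sum a_k cos(k phi + phase_k))`, rasterised as the
#' star-shaped region `r_pixel <= r(phi)`.
#'
#' @param spec A [lesion_spec()].
#' @param canvas Canvas side in px.
#' @return A list with `mask` (logical matrix `[y, x]`) and `contour`
#'   (sub-pixel closed contour, columns `x, y`, 720 samples).
#' @export
gen_mask <- function(spec, canvas = 64) {
  pos <- spec$position
  if (is.null(pos)) pos <- c(canvas / 2, canvas / 2)
  phi_dense <- seq(0, 2 * pi, length.out = 1441)[-1441]
  rfun <- function(phi) {
    mod <- rep(1, length(phi))
    for (i in seq_along(spec$harmonics)) {
      mod <- mod + spec$amplitudes[i] *
        cos(spec$harmonics[i] * phi + spec$phases[i])
    }
    spec$radius * mod
  }
  if (min(rfun(phi_dense)) <= 0) {
    stop("spec error: amplitudes drive the radius to zero or below")
  }
  xs <- matrix(rep(seq_len(canvas), each = canvas), canvas)   # [y, x] -> x
  ys <- matrix(rep(seq_len(canvas), times = canvas), canvas)  # [y, x] -> y
  dx <- xs - pos[1]; dy <- ys - pos[2]
  rp <- sqrt(dx^2 + dy^2)
  phip <- atan2(dy, dx)
  mask <- rp <= rfun(phip)
  if (!any(mask)) stop("spec error: lesion smaller than one pixel")
  phi_c <- seq(0, 2 * pi, length.out = 721)[-721]
  rc <- rfun(phi_c)
  contour <- cbind(x = pos[1] + rc * cos(phi_c), y = pos[2] + rc * sin(phi_c))
  list(mask = mask, contour = contour)
}

# tight centre-form bbox of a mask, in pixel units
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  y1 <- min(idx[, 1]) - 0.5; y2 <- max(idx[, 1]) + 0.5
  x1 <- min(idx[, 2]) - 0.5; x2 <- max(idx[, 2]) + 0.5
  bbox_from_corners(x1, y1, x2, y2)
}

# smooth low-frequency field in [-1, 1], canvas x canvas (bilinear upsample)
lowfreq_field <- function(canvas, cells = 4) {
  g <- matrix(stats::runif((cells + 1)^2, -1, 1), cells + 1)
  xi <- seq(1, cells + 1, length.out = canvas)
  i0 <- pmin(floor(xi), cells); f <- xi - i0
  rows <- g[i0, , drop = FALSE] * (1 - f) + g[i0 + 1, , drop = FALSE] * f
  t(apply(rows, 1, function(r) r[i0] * (1 - f) + r[i0 + 1] * f))
}

#' Render a lesion onto a procedural skin background
#'
#' @param spec A [lesion_spec()].
#' @param canvas Canvas side in px.
#' @param hair_grade Hair occlusion grade: 0 none, 1 sparse vellus strokes,
#'   2 dense terminal strokes.
#' @param phototype Fitzpatrick phototype `"II"` (lighter) or `"III"`
#'   (darker background tone).
#' @return A `synthetic_sample`: list with `image` (`H x W x 3` in `[0,1]`),
#'   `mask`, `contour`, `box` (tight centre-form bbox, px), `class`,
#'   `patient_id`, `hair_grade`, `phototype`.
#' @export
render_lesion <- function(spec, canvas = 64, hair_grade = 0, phototype = "II") {
  gm <- gen_mask(spec, canvas)
  mask <- gm$mask
  base <- if (phototype == "II") c(0.88, 0.74, 0.66) else c(0.80, 0.64, 0.54)
  lf <- lowfreq_field(canvas)
  img <- array(0, dim = c(canvas, canvas, 3))
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + 0.03 * lf +
      matrix(stats::rnorm(canvas^2, 0, 0.012), canvas)
  }
  # lesion layer with optional pigment-heterogeneity patches
  les <- array(rep(spec$colour, each = canvas^2), dim = c(canvas, canvas, 3))
  if (spec$het_patches > 0) {
    idx <- which(mask, arr.ind = TRUE)
    for (p in seq_len(spec$het_patches)) {
      ctr <- idx[sample(nrow(idx), 1), ]
      rad <- stats::runif(1, 0.15, 0.4) * spec$radius
      sgn <- sample(c(-1, 1), 1)
      ys <- matrix(rep(seq_len(canvas), times = canvas), canvas)
      xs <- matrix(rep(seq_len(canvas), each = canvas), canvas)
      d2 <- (ys - ctr[1])^2 + (xs - ctr[2])^2
      blob <- exp(-d2 / (2 * rad^2))
      for (ch in 1:3) {
        les[, , ch] <- les[, , ch] + sgn * spec$het_contrast * blob
      }
    }
  }
  for (ch in 1:3) {
    les[, , ch] <- les[, , ch] + matrix(stats::rnorm(canvas^2, 0, 0.015), canvas)
  }
  # border blend: alpha ramps over border_softness px of inside distance
  dm <- t(as.matrix(EBImage::distmap(EBImage::Image(t(mask) * 1))))
  alpha <- pmin(dm / max(spec$border_softness, 0.5), 1)
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - alpha) + les[, , ch] * alpha
  }
  n_hair <- switch(as.character(hair_grade), "0" = 0,
                   "1" = sample(3:6, 1), "2" = sample(10:18, 1))
  if (n_hair > 0) img <- draw_hairs(img, n_hair, dark = hair_grade == 2)
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, mask = mask, contour = gm$contour,
                 box = mask_bbox(mask), class = spec$class,
                 patient_id = spec$patient_id, hair_grade = hair_grade,
                 phototype = phototype),
            class = "synthetic_sample")
}

# quadratic-bezier dark strokes, thickness 1 px
draw_hairs <- function(img, n, dark = FALSE) {
  canvas <- dim(img)[1]
  shade <- if (dark) c(0.10, 0.08, 0.06) else c(0.35, 0.30, 0.26)
  for (s in seq_len(n)) {
    p <- matrix(stats::runif(6, 1, canvas), 3, 2)
    t <- seq(0, 1, length.out = 4 * canvas)
    bx <- (1 - t)^2 * p[1, 1] + 2 * (1 - t) * t * p[2, 1] + t^2 * p[3, 1]
    by <- (1 - t)^2 * p[1, 2] + 2 * (1 - t) * t * p[2, 2] + t^2 * p[3, 2]
    xi <- round(bx); yi <- round(by)
    ok <- xi >= 1 & xi <= canvas & yi >= 1 & yi <= canvas
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[cbind(yi[ok], xi[ok])] <- shade[ch]
      img[, , ch] <- pl
    }
  }
  img
}

#' Augmentation configuration
#'
#' Defaults follow the training augmentation battery: horizontal flip
#' `p = 0.5`, vertical flip `p = 0.3`, random scaling 0.5-1.2x, HSV jitter
#' H +-20% / S +-30% / V +-30%, Gaussian noise `sigma = 0.1`, and random
#' rectangular occlusion (area <= 20%, aspect ratio 0.5-2; applied with
#' probability 0.3, a package choice since no rate is prescribed).
#'
#' @param p_hflip,p_vflip Flip probabilities.
#' @param scale_range Scaling range (about the canvas centre).
#' @param hsv HSV jitter half-ranges `c(h, s, v)` as fractions.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param p_occlusion Probability of rectangular occlusion.
#' @param occl_area Maximum occluded area fraction.
#' @param occl_ar Occluder aspect-ratio range.
#' @return A list with class `augment_config`.
#' @export
augment_config <- function(p_hflip = 0.5, p_vflip = 0.3,
                           scale_range = c(0.5, 1.2),
                           hsv = c(0.2, 0.3, 0.3), noise_sigma = 0.1,
                           p_occlusion = 0.3, occl_area = 0.2,
                           occl_ar = c(0.5, 2)) {
  stopifnot(p_hflip >= 0, p_hflip <= 1, p_vflip >= 0, p_vflip <= 1,
            p_occlusion >= 0, p_occlusion <= 1, occl_area <= 1)
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip,
                 scale_range = scale_range, hsv = hsv,
                 noise_sigma = noise_sigma, p_occlusion = p_occlusion,
                 occl_area = occl_area, occl_ar = occl_ar),
            class = "augment_config")
}

# nearest-neighbour scale about the canvas centre, same canvas size
scale_about_center <- function(plane, s, fill) {
  n <- nrow(plane)
  ctr <- (n + 1) / 2
  src <- round(ctr + (seq_len(n) - ctr) / s)
  ok <- src >= 1 & src <= n
  out <- matrix(fill, n, n)
  out[ok, ok] <- plane[src[ok], src[ok]]
  out
}

#' Apply the augmentation battery to a sample
#'
#' Geometric operators transform the ground-truth box analytically along
#' with the raster; occlusion never covers more than the configured area.
#'
#' @param sample A `synthetic_sample` from [render_lesion()].
#' @param cfg An [augment_config()].
#' @return The augmented sample (same structure; `contour` is dropped since
#'   photometric operators do not preserve its meaning).
#' @export
augment_sample <- function(sample, cfg = augment_config()) {
  img <- sample$image; mask <- sample$mask
  box <- as_bbox(sample$box)
  canvas <- dim(img)[1]
  ctr <- (canvas + 1) / 2
  if (stats::runif(1) < cfg$p_hflip) {
    img <- img[, rev(seq_len(canvas)), , drop = FALSE]
    mask <- mask[, rev(seq_len(canvas))]
    box[, "cx"] <- canvas + 1 - box[, "cx"]
  }
  if (stats::runif(1) < cfg$p_vflip) {
    img <- img[rev(seq_len(canvas)), , , drop = FALSE]
    mask <- mask[rev(seq_len(canvas)), ]
    box[, "cy"] <- canvas + 1 - box[, "cy"]
  }
  s <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
  if (abs(s - 1) > 1e-9) {
    fill_cols <- apply(img, 3, stats::median)
    for (ch in 1:3) img[, , ch] <- scale_about_center(img[, , ch], s, fill_cols[ch])
    mask <- scale_about_center(mask, s, FALSE)
    box[, "cx"] <- ctr + (box[, "cx"] - ctr) * s
    box[, "cy"] <- ctr + (box[, "cy"] - ctr) * s
    box[, "w"] <- box[, "w"] * s
    box[, "h"] <- box[, "h"] * s
  }
  if (any(cfg$hsv > 0)) {
    rgbm <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                  as.vector(img[, , 3]))
    hsvm <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
    jit <- stats::runif(3, -cfg$hsv, cfg$hsv)
    hsvm[1, ] <- (hsvm[1, ] + jit[1]) %% 1
    hsvm[2, ] <- pmin(pmax(hsvm[2, ] * (1 + jit[2]), 0), 1)
    hsvm[3, ] <- pmin(pmax(hsvm[3, ] * (1 + jit[3]), 0), 1)
    cols <- grDevices::hsv(hsvm[1, ], hsvm[2, ], hsvm[3, ])
    rgb2 <- grDevices::col2rgb(cols) / 255
    for (ch in 1:3) img[, , ch] <- matrix(rgb2[ch, ], canvas)
  }
  if (cfg$noise_sigma > 0) {
    img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sigma), dim(img))
  }
  if (stats::runif(1) < cfg$p_occlusion) {
    area <- stats::runif(1, 0.02, cfg$occl_area) * canvas^2
    ar <- stats::runif(1, cfg$occl_ar[1], cfg$occl_ar[2])
    ow <- min(canvas, round(sqrt(area * ar)))
    oh <- min(canvas, round(sqrt(area / ar)))
    ox <- sample(canvas - ow + 1, 1); oy <- sample(canvas - oh + 1, 1)
    shade <- stats::runif(1, 0.05, 0.3)
    for (ch in 1:3) img[oy:(oy + oh - 1), ox:(ox + ow - 1), ch] <- shade
  }
  img <- pmin(pmax(img, 0), 1)
  out <- sample
  out$image <- img; out$mask <- mask
  out$box <- as.data.frame(box)
  out$contour <- NULL
  out
}

#' ImageNet channel standardisation
#'
#' Scales to `[0, 1]` if needed, then applies per-channel
#' `(x - mean) / sd` with means `(0.485, 0.456, 0.406)` and standard
#' deviations `(0.229, 0.224, 0.225)`.
#'
#' @param image `H x W x 3` array in `[0, 1]` or `[0, 255]`.
#' @return Standardised array of the same shape.
#' @export
normalize_image <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("expected an H x W x 3 RGB array")
  }
  if (max(image) > 1.5) image <- image / 255
  mu <- c(0.485, 0.456, 0.406); sd <- c(0.229, 0.224, 0.225)
  for (ch in 1:3) image[, , ch] <- (image[, , ch] - mu[ch]) / sd[ch]
  image
}

#' Invert [normalize_image()]
#'
#' @param image Standardised array.
#' @return Array back on the `[0, 1]` scale.
#' @export
denormalize_image <- function(image) {
  mu <- c(0.485, 0.456, 0.406); sd <- c(0.229, 0.224, 0.225)
  for (ch in 1:3) image[, , ch] <- image[, , ch] * sd[ch] + mu[ch]
  image
}

#' Patient-level train/validation split
#'
#' Patients (never individual images) are partitioned so that the training
#' image count is as close as patient granularity allows to the requested
#' ratio; with one image per patient a 9:1 split of 2,040 images yields
#' exactly 1,836 / 204.
#'
#' @param manifest Data frame with a `patient_id` column.
#' @param ratio Training fraction (default 0.9).
#' @return A list with `train` and `val` data frames.
#' @export
split_by_patient <- function(manifest, ratio = 0.9) {
  stopifnot(!is.null(manifest$patient_id))
  pats <- unique(manifest$patient_id)
  if (length(pats) < 2) stop("need at least 2 patients to split")
  pats <- sample(pats)
  sizes <- vapply(pats, function(p) sum(manifest$patient_id == p), numeric(1))
  cum <- cumsum(sizes)
  target <- ratio * nrow(manifest)
  k <- which.min(abs(cum - target))
  train_p <- pats[seq_len(k)]
  list(train = manifest[manifest$patient_id %in% train_p, , drop = FALSE],
       val = manifest[!manifest$patient_id %in% train_p, , drop = FALSE])
}

#' Write YOLO-format label files
#'
#' One text file per image with lines `"0 cx cy w h"` normalised to `[0, 1]`.
#'
#' @param boxes Named list: per image, a box table (centre form, pixels).
#' @param canvas Image side in px used for normalisation.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_yolo <- function(boxes, canvas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(boxes), function(id) {
    b <- as_bbox(boxes[[id]]) / canvas
    corners <- bbox_corners(b)
    if (any(corners < -1e-6) || any(corners > 1 + 1e-6)) {
      stop("box out of image bounds: ", id)
    }
    lines <- sprintf("0 %.6f %.6f %.6f %.6f",
                     b[, "cx"], b[, "cy"], b[, "w"], b[, "h"])
    path <- file.path(dir, paste0(id, ".txt"))
    writeLines(lines, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read YOLO-format label files
#'
#' @param paths Label file paths.
#' @param canvas Image side in px; boxes are returned in pixel units.
#' @return Named list of box data frames with a `class_id` column.
#' @export
read_yolo <- function(paths, canvas = 1) {
  out <- lapply(paths, function(p) {
    lines <- readLines(p)
    rows <- lapply(seq_along(lines), function(i) {
      f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(f) != 5 || anyNA(f)) {
        stop(sprintf("parse error in %s line %d", p, i))
      }
      data.frame(class_id = as.integer(f[1]), cx = f[2] * canvas,
                 cy = f[3] * canvas, w = f[4] * canvas, h = f[5] * canvas)
    })
    do.call(rbind, rows)
  })
  names(out) <- sub("\\.txt$", "", basename(paths))
  out
}

# printed cohort composition: phototype II/III and hair grades 0/1/2
COHORT_PHOTOTYPE <- c(II = 1115, III = 1290) / 2405
COHORT_HAIR <- c(`0` = 2258, `1` = 104, `2` = 43) / 2405

# largest-remainder integer allocation of n into proportions p
allocate_counts <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Build a cohort manifest
#'
#' Benign images form the training pool; melanomas form an external test
#' cohort used only for screening. Phototype and hair-grade tags are
#' allocated deterministically by largest remainder from the study cohort
#' composition (phototypes II/III 46.36%/53.64%; hair grades
#' 93.89%/4.32%/1.79%), then shuffled across images.
#'
#' @param n_benign,n_melanoma Cohort sizes (full scale: 2040 / 365).
#' @param images_per_patient Images per patient (default 1).
#' @return A data frame manifest with columns `id`, `class`, `patient_id`,
#'   `phototype`, `hair_grade`, `split_role`.
#' @export
make_cohort <- function(n_benign = 2040, n_melanoma = 365,
                        images_per_patient = 1) {
  n <- n_benign + n_melanoma
  if (n == 0) return(data.frame())
  cls <- c(rep("benign", n_benign), rep("malignant", n_melanoma))
  pt_counts <- allocate_counts(n, COHORT_PHOTOTYPE)
  hair_counts <- allocate_counts(n, COHORT_HAIR)
  phototype <- sample(rep(names(COHORT_PHOTOTYPE), pt_counts))
  hair <- sample(rep(as.integer(names(COHORT_HAIR)), hair_counts))
  n_pat <- ceiling(n / images_per_patient)
  patient <- paste0("pat", rep(seq_len(n_pat), each = images_per_patient)[seq_len(n)])
  data.frame(
    id = sprintf("img%05d", seq_len(n)), class = cls, patient_id = patient,
    phototype = phototype, hair_grade = hair,
    split_role = ifelse(cls == "benign", "train_pool", "external_test")
  )
}

#' Generate samples for a manifest
#'
#' @param manifest Rows from [make_cohort()].
#' @param canvas Canvas side in px.
#' @return Named list of `synthetic_sample`s (names = manifest `id`).
#' @export
gen_samples <- function(manifest, canvas = 64) {
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    spec <- random_lesion_spec(row$class, canvas, row$patient_id)
    render_lesion(spec, canvas, hair_grade = row$hair_grade,
                  phototype = row$phototype)
  })
  names(out) <- manifest$id
  out
}

#' Write a synthetic dataset to disk
#'
#' Layout: `images/*.png`, `masks/*.png`, `labels/*.txt` (YOLO),
#' `manifest.csv`.
#'
#' @param dir Output directory.
#' @param manifest A cohort manifest.
#' @param canvas Canvas side in px.
#' @return Invisibly, the manifest with file paths attached.
#' @export
gen_dataset <- function(dir, manifest, canvas = 64) {
  for (d in c("images", "masks", "labels")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  samples <- gen_samples(manifest, canvas)
  boxes <- lapply(samples, `[[`, "box")
  write_yolo(boxes, canvas, file.path(dir, "labels"))
  for (id in names(samples)) {
    png::writePNG(samples[[id]]$image, file.path(dir, "images", paste0(id, ".png")))
    png::writePNG(samples[[id]]$mask * 1, file.path(dir, "masks", paste0(id, ".png")))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
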