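test_that("Zhang-Suen thinning reduces simple shapes to expected skeletons", {
  # 1-px horizontal line: unchanged, two terminals, no branches
  line <- matrix(FALSE, 9, 20); line[5, 3:18] <- TRUE
  sk <- zhang_suen(line)
  expect_equal(sk$skeleton, line)
  expect_equal(sk$terminal_points, 2)
  expect_equal(sk$branch_points, 0)
  # filled disk: skeleton collapses near the centroid, no branching
  disk <- circle_fixture(canvas = 41, radius = 15)$mask
  skd <- zhang_suen(disk)
  idx <- which(skd$skeleton, arr.ind = TRUE)
  ctr <- c(21, 21)
  expect_true(all(sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2) <= 3))
  expect_equal(skd$branch_points, 0)
  expect_error(zhang_suen(matrix(FALSE, 5, 5)), "empty")
})

test_that("plus-sign mask yields one branch point and four terminals", {
  plus <- matrix(FALSE, 21, 21)
  plus[11, 3:19] <- TRUE
  plus[3:19, 11] <- TRUE
  sk <- zhang_suen(plus)
  expect_equal(sk$branch_points, 1)
  expect_equal(sk$terminal_points, 4)
})

test_that("skeletons stay inside the mask on random blobs", {
  set.seed(12)
  for (i in 1:5) {
    spec <- random_lesion_spec(sample(c("benign", "malignant"), 1), 64)
    mask <- gen_mask(spec, 64)$mask
    sk <- zhang_suen(mask)
    expect_true(all(mask[sk$skeleton]))
    expect_gt(sk$skeleton_px, 0)
  }
})

test_that("fractal dimension separates smooth and fractal boundaries", {
  # large square: straight sides, FD near 1 at all usable scales
  sq <- matrix(FALSE, 200, 200); sq[40:160, 40:160] <- TRUE
  fd_sq <- local_fd_spectrum(sq, windows = c(16, 32, 64))
  expect_true(all(abs(fd_sq$fd - 1) < 0.05))
  # circle: smooth limit at windows much smaller than the radius
  circ <- circle_fixture(canvas = 240, radius = 90)$mask
  fd_c <- local_fd_spectrum(circ, windows = c(16, 32))
  expect_true(all(abs(fd_c$fd - 1) < 0.08))
  # Koch snowflake boundary: FD near log 4 / log 3 where the window spans
  # several self-similar generations
  koch <- rasterize_polygon(
    koch_snowflake(radius = 230, depth = 4, center = c(256, 256)), 512)
  fd_k <- local_fd_spectrum(koch, windows = 128)
  expect_true(all(abs(fd_k$fd - log(4) / log(3)) < 0.1))
  expect_gt(fd_k$fd[1], max(fd_sq$fd) + 0.1)
  expect_warning(local_fd_spectrum(sq, windows = c(16, 1024)), "skipped")
})

test_that("elliptic Fourier spectra concentrate energy correctly", {
  circ <- harmonic_contour(0, 1, radius = 40)
  efd_c <- efd_magnitudes(circ, 20)
  expect_equal(efd_c$magnitude[1], 1)
  expect_true(all(efd_c$magnitude[-1] < 1e-3))
  # an ellipse is first-harmonic dominated; under arc-length
  # parameterisation eccentricity leaks small odd side harmonics only
  phi <- seq(0, 2 * pi, length.out = 1441)[-1441]
  ell <- cbind(x = 60 + 50 * cos(phi), y = 60 + 20 * sin(phi))
  efd_e <- efd_magnitudes(ell, 20)
  expect_true(all(efd_e$magnitude[-1] < 0.1))
  expect_true(all(efd_e$magnitude[c(2, 4, 6)] < 1e-6))
  # 5-lobed rose: the lobe energy sits in the 5-fold symmetry side bands
  # (harmonics 4 and 6); everything else above DC is far smaller
  rose <- harmonic_contour(0.2, 5, radius = 40)
  efd_r <- efd_magnitudes(rose, 20)
  side <- efd_r$magnitude[c(4, 6)]
  others <- efd_r$magnitude[-c(1, 4, 6)]
  expect_true(all(others < min(side) / 2))
  expect_error(efd_magnitudes(circ[1:300, ], 20), "open contour")
})

test_that("EFD spectrum is invariant to start point and rotation", {
  rose <- harmonic_contour(0.15, 4, radius = 40)
  base <- efd_magnitudes(rose, 12)$magnitude
  shifted <- rbind(rose[501:nrow(rose), ], rose[1:500, ])
  expect_equal(efd_magnitudes(shifted, 12)$magnitude, base, tolerance = 1e-6)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- rose %*% R
  colnames(rot) <- c("x", "y")
  expect_equal(efd_magnitudes(rot, 12)$magnitude, base, tolerance = 1e-6)
})

test_that("radial profile quantifies oscillation and deviation fractions", {
  circ <- harmonic_contour(0, 1, radius = 40)
  rp <- radial_profile(circ)
  expect_lt(rp$oscillation, 0.01)
  expect_equal(frac_over(rp, 0.10), 0)
  expect_equal(rp$mean_radius, 40, tolerance = 0.1)
  # r = 1 + 0.16 cos(2 phi): oscillation (1.16 - 0.84) / 1 = 32%
  two <- harmonic_contour(0.16, 2, radius = 50)
  rp2 <- radial_profile(two)
  expect_equal(rp2$oscillation, 0.32, tolerance = 0.01)
  # r = 1 + 0.2 cos(2 phi): |dev| > 0.1 on 2/3 of the angle measure
  dev <- harmonic_contour(0.2, 2, radius = 50)
  rp3 <- radial_profile(dev)
  expect_equal(frac_over(rp3, 0.10), 2 / 3, tolerance = 0.02)
  expect_error(radial_profile(circ[1:2, , drop = FALSE]), "contour")
})

test_that("radial profile rotates with the shape and frac_over is monotone", {
  base <- harmonic_contour(0.16, 2, radius = 50)
  rot <- harmonic_contour(0.16, 2, radius = 50, phase = pi / 3)
  rp1 <- radial_profile(base); rp2 <- radial_profile(rot)
  expect_equal(rp1$oscillation, rp2$oscillation, tolerance = 0.01)
  expect_equal(sort(rp1$radius), sort(rp2$radius), tolerance = 0.5)
  ts <- seq(0, 0.3, by = 0.05)
  fr <- vapply(ts, function(t) frac_over(rp1, t), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("benign criteria report separates generator classes", {
  set.seed(13)
  ben <- render_lesion(random_lesion_spec("benign", 96), 96)
  mal <- render_lesion(random_lesion_spec("malignant", 96), 96)
  rb <- benign_criteria_report(ben$mask, ben$image, fd_windows = c(16, 32))
  rm <- benign_criteria_report(mal$mask, mal$image, fd_windows = c(16, 32))
  expect_lt(rb$radial$frac_over_10, 0.15)
  expect_gt(rm$radial$frac_over_10, 0.15)
  # all fields present and finite
  for (rep in list(rb, rm)) {
    expect_true(is.finite(rep$skeleton$branch_points))
    expect_true(all(is.finite(rep$fd_spectrum$fd)))
    expect_true(all(is.finite(rep$efd$magnitude)))
    expect_true(is.finite(rep$radial$oscillation))
    expect_true(is.finite(rep$colour_sd))
    expect_true(is.finite(rep$border_gradient))
  }
})
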