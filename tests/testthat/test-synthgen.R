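test_that("mask generation is deterministic and honours the harmonics", {
  disk <- lesion_spec("benign", 20, position = c(32, 32))
  gm <- gen_mask(disk, 64)
  rp <- radial_profile(gm$contour)
  expect_lt(rp$oscillation, 1e-6)
  # a2 = 0.16 lobed outline: 32% oscillation, tied to the morphology module
  lobed <- lesion_spec("malignant", 20, harmonics = 2, amplitudes = 0.16,
                       phases = 0, position = c(32, 32))
  rp2 <- radial_profile(gen_mask(lobed, 64)$contour)
  expect_equal(rp2$oscillation, 0.32, tolerance = 0.01)
  expect_equal(gen_mask(lobed, 64)$mask, gen_mask(lobed, 64)$mask)
  bad <- lesion_spec("malignant", 20, harmonics = 2, amplitudes = 1.5,
                     phases = 0, position = c(32, 32))
  expect_error(gen_mask(bad, 64), "spec error")
})

test_that("rendering satisfies the benign construction criteria", {
  set.seed(20)
  spec <- random_lesion_spec("benign", 64)
  s <- render_lesion(spec, 64)
  m <- s$mask
  px <- apply(s$image, 3, function(ch) ch[m])
  expect_lt(mean(apply(px, 2, stats::sd)), 0.10)
  # stored gt box equals the recomputed tight bbox of the mask
  expect_equal(as_bbox(s$box), nevuscreen:::mask_bbox(m) |> as_bbox())
  expect_true(all(s$image >= 0 & s$image <= 1))
})

test_that("hair strokes appear only at occlusion grades above zero", {
  spec <- lesion_spec("benign", 12, position = c(32, 32), border_softness = 1)
  set.seed(21); g0 <- render_lesion(spec, 64, hair_grade = 0)
  set.seed(21); g2 <- render_lesion(spec, 64, hair_grade = 2)
  set.seed(21); g0b <- render_lesion(spec, 64, hair_grade = 0)
  expect_identical(g0$image, g0b$image)
  dark0 <- sum(g0$image[, , 1] < 0.15)
  dark2 <- sum(g2$image[, , 1] < 0.15)
  expect_gt(dark2, dark0 + 50)
})

test_that("an all-off augmentation config is the identity", {
  set.seed(22)
  s <- render_lesion(random_lesion_spec("benign", 64), 64)
  cfg <- augment_config(p_hflip = 0, p_vflip = 0, scale_range = c(1, 1),
                        hsv = c(0, 0, 0), noise_sigma = 0, p_occlusion = 0)
  a <- augment_sample(s, cfg)
  expect_equal(a$image, s$image)
  expect_equal(as_bbox(a$box), as_bbox(s$box))
})

test_that("horizontal flip mirrors the box and geometric ops track the mask", {
  set.seed(23)
  s <- render_lesion(random_lesion_spec("benign", 64), 64)
  cfg <- augment_config(p_hflip = 1, p_vflip = 0, scale_range = c(1, 1),
                        hsv = c(0, 0, 0), noise_sigma = 0, p_occlusion = 0)
  a <- augment_sample(s, cfg)
  expect_equal(a$box$cx, 65 - s$box$cx)
  expect_equal(a$box$cy, s$box$cy)
  # flip + rescale: recomputed mask bbox within 1 px of the transformed box
  cfg2 <- augment_config(p_hflip = 1, p_vflip = 1, scale_range = c(0.6, 1.2),
                         hsv = c(0, 0, 0), noise_sigma = 0, p_occlusion = 0)
  for (i in 1:5) {
    a2 <- augment_sample(s, cfg2)
    recomputed <- as_bbox(nevuscreen:::mask_bbox(a2$mask))
    expect_true(all(abs(recomputed - as_bbox(a2$box)) <= 1))
  }
})

test_that("flip frequency matches its configured probability", {
  set.seed(24)
  s <- render_lesion(lesion_spec("benign", 8, position = c(20, 20)), 48)
  cfg <- augment_config(p_hflip = 0.5, p_vflip = 0, scale_range = c(1, 1),
                        hsv = c(0, 0, 0), noise_sigma = 0, p_occlusion = 0)
  flips <- vapply(1:600, function(i) {
    augment_sample(s, cfg)$box$cx != s$box$cx
  }, logical(1))
  # 99.9% binomial band around p = 0.5 at n = 600
  expect_lt(abs(mean(flips) - 0.5), 3.3 * sqrt(0.25 / 600))
})

test_that("ImageNet standardisation and its inverse round-trip", {
  px <- array(0, dim = c(1, 1, 3))
  px[1, 1, ] <- c(0.485, 0.456, 0.406)
  expect_equal(as.vector(normalize_image(px)), c(0, 0, 0), tolerance = 1e-12)
  ones <- array(1, dim = c(2, 2, 3))
  nz <- normalize_image(ones)
  expect_equal(nz[1, 1, ], (1 - c(0.485, 0.456, 0.406)) /
                 c(0.229, 0.224, 0.225))
  set.seed(25)
  img <- array(stats::runif(48), dim = c(4, 4, 3))
  expect_equal(denormalize_image(normalize_image(img)), img,
               tolerance = 1e-6)
  expect_error(normalize_image(matrix(0, 3, 3)), "RGB")
})

test_that("patient-level split is exact for single-image patients", {
  man <- make_cohort(2040, 0)
  set.seed(26)
  sp <- split_by_patient(man, 0.9)
  expect_equal(nrow(sp$train), 1836)
  expect_equal(nrow(sp$val), 204)
  expect_length(intersect(sp$train$patient_id, sp$val$patient_id), 0)
  # multi-image patients never straddle the split
  man2 <- make_cohort(100, 0, images_per_patient = 10)
  sp2 <- split_by_patient(man2, 0.9)
  expect_equal(nrow(sp2$train), 90)
  expect_length(intersect(sp2$train$patient_id, sp2$val$patient_id), 0)
  expect_error(split_by_patient(data.frame(patient_id = "p1")), "2 patients")
})

test_that("YOLO label files round-trip and reject bad input", {
  dir <- withr::local_tempdir()
  boxes <- list(a = bbox(320, 320, 320, 320))
  write_yolo(boxes, 640, dir)
  expect_equal(readLines(file.path(dir, "a.txt")),
               "0 0.500000 0.500000 0.500000 0.500000")
  set.seed(27)
  rb <- list(r1 = bbox(stats::runif(3, 20, 40), stats::runif(3, 20, 40),
                       stats::runif(3, 5, 20), stats::runif(3, 5, 20)))
  write_yolo(rb, 64, dir)
  back <- read_yolo(file.path(dir, "r1.txt"), 64)
  expect_equal(as_bbox(back$r1[, c("cx", "cy", "w", "h")]), as_bbox(rb$r1),
               tolerance = 1e-4)
  expect_error(write_yolo(list(bad = bbox(60, 60, 20, 20)), 64, dir),
               "out of image bounds")
  writeLines("0 0.5 0.5", file.path(dir, "broken.txt"))
  expect_error(read_yolo(file.path(dir, "broken.txt")), "parse error")
})

test_that("full-scale cohort manifest reproduces the printed composition", {
  set.seed(28)
  man <- make_cohort(2040, 365)
  expect_equal(nrow(man), 2405)
  expect_equal(sum(man$class == "benign"), 2040)
  expect_equal(sum(man$class == "malignant"), 365)
  expect_equal(sum(man$phototype == "II"), 1115)
  expect_equal(sum(man$phototype == "III"), 1290)
  expect_equal(as.integer(table(man$hair_grade)), c(2258L, 104L, 43L))
  expect_equal(round(100 * mean(man$phototype == "II"), 2), 46.36)
  expect_equal(round(100 * mean(man$hair_grade > 0), 2), 6.11)
})

test_that("generator and morphology agree on the benign shape rule", {
  set.seed(29)
  n <- 15
  agree <- 0
  for (cl in c("benign", "malignant")) {
    for (i in seq_len(n)) {
      gm <- gen_mask(random_lesion_spec(cl, 96), 96)
      fo <- frac_over(radial_profile(gm$contour), 0.10)
      pass <- fo <= 0.15
      if ((cl == "benign") == pass) agree <- agree + 1
    }
  }
  expect_gte(agree / (2 * n), 0.95)
})
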