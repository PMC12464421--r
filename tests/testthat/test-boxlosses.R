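test_that("IoU handles identity, disjoint and partial overlap", {
  u <- bbox(0.5, 0.5, 1, 1)
  expect_equal(box_iou(u, u), 1)
  expect_equal(box_iou(u, bbox(5, 5, 1, 1)), 0)
  expect_equal(box_iou(u, bbox(1.0, 0.5, 1, 1)), 1 / 3)
  # symmetry
  set.seed(1)
  for (i in 1:20) {
    a <- random_box(); b <- random_box()
    expect_equal(box_iou(a, b), box_iou(b, a))
  }
  expect_error(bbox(0, 0, -1, 1), "invalid box")
})

test_that("shape weights follow the ground-truth aspect and sum to 2", {
  expect_equal(unname(shape_weights(bbox(0, 0, 3, 0.7), scale = 0)[1, ]),
               c(1, 1))
  expect_equal(unname(shape_weights(bbox(0, 0, 2, 2), scale = 1.7)[1, ]),
               c(1, 1))
  expect_equal(unname(shape_weights(bbox(0, 0, 2, 1), scale = 1)[1, ]),
               c(4 / 3, 2 / 3))
  set.seed(2)
  for (i in 1:50) {
    w <- shape_weights(random_box(), scale = stats::runif(1, 0, 3))
    expect_equal(unname(w[1, "ww"] + w[1, "hh"]), 2)
  }
  expect_error(shape_weights(bbox(0, 0, 1, 1), scale = -1), "parameter error")
})

test_that("centre-distance penalty is normalised by the enclosing diagonal", {
  expect_equal(shape_distance(bbox(1, 2, 3, 4), bbox(1, 2, 1, 1)), 0)
  # enclosing box x in [-1, 2], y in [-1, 1]: c^2 = 13
  expect_equal(shape_distance(bbox(0, 0, 2, 2), bbox(1, 0, 2, 2)), 1 / 13)
  set.seed(3)
  for (i in 1:20) {
    a <- random_box(); b <- random_box()
    expect_equal(shape_distance(a, b, ww = 1, hh = 1),
                 shape_distance(b, a, ww = 1, hh = 1))
  }
})

test_that("shape-difference term matches its closed form and is monotone", {
  expect_equal(shape_omega(bbox(3, 1, 2, 5), bbox(0, 0, 2, 5)), 0)
  expect_equal(shape_omega(bbox(0, 0, 1, 1), bbox(0, 0, 2, 1)),
               (1 - exp(-0.5))^4)
  widths <- seq(1, 1.9, by = 0.1)
  oms <- shape_omega(bbox(0, 0, widths, 1), bbox(0, 0, 2, 1))
  expect_true(all(diff(oms) < 0))  # shrinking |w - w_gt| shrinks omega
})

test_that("Shape-IoU loss breakdown matches the worked example", {
  zero <- shape_iou_loss(bbox(1, 1, 2, 3), bbox(1, 1, 2, 3))
  expect_equal(zero$total, 0)
  l <- shape_iou_loss(bbox(0.5, 0.5, 1, 1), bbox(0.5, 0.5, 2, 1))
  expect_equal(l$iou, 0.5)
  expect_equal(l$distance_shape, 0)
  expect_equal(l$omega_shape, (1 - exp(-0.5))^4)
  expect_equal(l$total, 0.5 + 0.5 * (1 - exp(-0.5))^4, tolerance = 1e-12)
})

test_that("batch evaluation equals elementwise evaluation", {
  set.seed(4)
  B <- do.call(rbind, replicate(10, random_box(), simplify = FALSE))
  G <- do.call(rbind, replicate(10, random_box(), simplify = FALSE))
  batch <- shape_iou_loss(B, G)
  for (i in 1:10) {
    single <- shape_iou_loss(B[i, ], G[i, ])
    expect_equal(batch$total[i], single$total)
  }
})

test_that("loss agrees with an independent single-expression oracle", {
  set.seed(5)
  for (i in 1:1000) {
    b <- random_box(); g <- random_box()
    sc <- stats::runif(1, 0, 2)
    expect_equal(shape_iou_loss(b, g, shape_iou_params(scale = sc))$total,
                 oracle_shape_iou(b, g, scale = sc), tolerance = 1e-9)
  }
})

test_that("loss stays in [0, 4] and vanishes only at identity", {
  set.seed(6)
  for (i in 1:200) {
    b <- random_box(); g <- random_box()
    tot <- shape_iou_loss(b, g)$total
    expect_gte(tot, 0); expect_lte(tot, 4)
    if (!isTRUE(all.equal(as_bbox(b), as_bbox(g)))) expect_gt(tot, 0)
  }
})

test_that("analytic gradients agree with central differences", {
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    b <- random_box(); g <- random_box()
    pr <- shape_iou_params(scale = stats::runif(1, 0, 2))
    gr <- shape_iou_grad(b, g, pr)
    h <- 1e-6
    for (k in 1:4) {
      bp <- as_bbox(b); bm <- as_bbox(b)
      bp[1, k] <- bp[1, k] + h; bm[1, k] <- bm[1, k] - h
      fd <- (shape_iou_loss(bp, g, pr)$total -
               shape_iou_loss(bm, g, pr)$total) / (2 * h)
      worst <- max(worst, abs(fd - gr[1, k]))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("CIoU baseline degenerates correctly and decomposes consistently", {
  expect_equal(ciou_loss(bbox(1, 1, 2, 3), bbox(1, 1, 2, 3)), 0)
  # concentric, same aspect ratio: centre and aspect terms vanish
  b <- bbox(0, 0, 1, 2); g <- bbox(0, 0, 2, 4)
  expect_equal(ciou_loss(b, g), 1 - box_iou(b, g), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:100) {
    a <- random_box(); g <- random_box()
    br <- ciou_loss(a, g, breakdown = TRUE)
    expect_equal(1 - br$iou + br$center + br$aspect, br$total,
                 tolerance = 1e-10)
    expect_equal(br$total, ciou_loss(a, g), tolerance = 1e-10)
  }
})

test_that("gradient descent under Shape-IoU recovers the target box", {
  descend <- function(grad_fn, b0, gt, lr = 0.05, steps = 400) {
    b <- as_bbox(b0)
    iou_hit <- Inf
    for (s in seq_len(steps)) {
      g <- grad_fn(b, gt)
      b[1, ] <- b[1, ] - lr * g[1, ]
      b[1, "w"] <- max(b[1, "w"], 1e-3); b[1, "h"] <- max(b[1, "h"], 1e-3)
      if (is.infinite(iou_hit) && box_iou(b, gt) >= 0.99) iou_hit <- s
      if (s == 50) err50 <- sqrt(b[1, "cx"]^2 + b[1, "cy"]^2)
    }
    list(iou_hit = iou_hit, centre_err_50 = err50, final = b)
  }
  shape_grad <- function(b, gt) shape_iou_grad(b, gt)
  # numerical gradient of the plain 1 - IoU objective
  plain_grad <- function(b, gt) {
    g <- matrix(0, 1, 4, dimnames = list(NULL, c("cx", "cy", "w", "h")))
    h <- 1e-5
    for (k in 1:4) {
      bp <- b; bm <- b
      bp[1, k] <- bp[1, k] + h; bm[1, k] <- bm[1, k] - h
      g[1, k] <- ((1 - box_iou(bp, gt)) - (1 - box_iou(bm, gt))) / (2 * h)
    }
    g
  }
  set.seed(9)
  gt <- bbox(0, 0, 1, 1)
  for (i in 1:5) {
    # centre-offset initialisation: same size as the target, shifted centre
    b0 <- bbox(stats::runif(1, 0.2, 0.6), stats::runif(1, 0.2, 0.6), 1, 1)
    rs <- descend(shape_grad, b0, gt)
    rp <- descend(plain_grad, b0, gt)
    # Shape-IoU always reaches IoU >= 0.99, and its weighted normalised
    # centre penalty drives the centre offset down at least as fast
    expect_lt(rs$iou_hit, Inf)
    expect_lte(rs$centre_err_50, rp$centre_err_50 + 1e-9)
  }
  # disjoint initialisation: the distance term still provides a pull while
  # plain 1 - IoU has a vanishing gradient and never moves
  b0 <- bbox(3, 3, 1, 1)
  rs <- descend(shape_grad, b0, gt, lr = 0.2, steps = 3000)
  rp <- descend(plain_grad, b0, gt, lr = 0.2, steps = 3000)
  expect_lt(rs$iou_hit, Inf)
  expect_equal(as_bbox(rp$final), as_bbox(b0))
})
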