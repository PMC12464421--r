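tiny_cfg <- function(...) detector_config(img_size = 64, ...)

test_that("H-Swish matches its closed form", {
  expect_equal(hswish(0), 0)
  expect_equal(hswish(3), 3)
  expect_equal(hswish(-3), 0)
  expect_equal(hswish(-5), 0)
  expect_equal(hswish(1), 2 / 3)
  x <- seq(-6, 6, by = 0.25)
  expect_equal(hswish(x), x * pmin(pmax(x + 3, 0), 6) / 6)
})

test_that("backbone and neck keep exact stride arithmetic", {
  set.seed(30)
  model <- build_detector(tiny_cfg())
  img <- array(stats::runif(64 * 64 * 3), c(64, 64, 3, 1))
  fw <- detector_forward(model, img)
  expect_equal(dim(fw$features$P3)[1:2], c(8, 8))
  expect_equal(dim(fw$features$P4)[1:2], c(4, 4))
  expect_equal(dim(fw$features$P5)[1:2], c(2, 2))
  expect_equal(dim(fw$neck$P3)[1:2], c(8, 8))
  expect_equal(dim(fw$neck$P5)[1:2], c(2, 2))
  expect_true(all(vapply(fw$neck, function(f) all(is.finite(f)), logical(1))))
  # inputs not divisible by 32 are padded (and reported)
  odd <- array(stats::runif(50 * 70 * 3), c(50, 70, 3, 1))
  expect_message(fw2 <- detector_forward(model, odd), "padded")
  expect_equal(dim(fw2$features$P3)[1:2], c(64, 96) / 8)
})

test_that("depthwise-separable backbone is lighter than the plain baseline", {
  set.seed(31)
  n_params <- function(m) {
    backbone <- grep("^(stem|b[1-7])\\.", names(m$params), value = TRUE)
    sum(vapply(m$params[backbone], function(p) length(p$val), numeric(1)))
  }
  lc <- build_detector(tiny_cfg(pp_lcnet = TRUE))
  base <- build_detector(tiny_cfg(pp_lcnet = FALSE))
  expect_lt(n_params(lc), n_params(base))
})

test_that("ablation toggles change exactly their own component", {
  set.seed(32)
  variants <- list(
    baseline = tiny_cfg(pp_lcnet = FALSE, mca = FALSE, shape_iou = FALSE),
    pp_lcnet = tiny_cfg(pp_lcnet = TRUE, mca = FALSE, shape_iou = FALSE),
    mca = tiny_cfg(pp_lcnet = FALSE, mca = TRUE, shape_iou = FALSE),
    shape_iou = tiny_cfg(pp_lcnet = FALSE, mca = FALSE, shape_iou = TRUE),
    full = tiny_cfg(pp_lcnet = TRUE, mca = TRUE, shape_iou = TRUE)
  )
  models <- lapply(variants, build_detector)
  pn <- lapply(models, function(m) names(m$params))
  # MCA toggle adds the attention parameters, nothing else
  expect_setequal(setdiff(pn$mca, pn$baseline),
                  grep("^mca", pn$mca, value = TRUE))
  # Shape-IoU is a pure loss swap: identical architecture
  expect_identical(pn$shape_iou, pn$baseline)
  # the loss toggle changes only the box component of the reported losses
  set.seed(33)
  man <- make_cohort(4, 0)
  samples <- gen_samples(man, 64)
  bt <- nevuscreen:::batch_from_samples(samples)
  m <- build_detector(tiny_cfg(shape_iou = TRUE))
  fw <- detector_forward(m, bt$x, training = TRUE)
  l_shape <- nevuscreen:::branch_losses(fw$heads$o2m, bt$gts, m$cfg, 10)
  cfg_ciou <- m$cfg; cfg_ciou$shape_iou <- FALSE
  l_ciou <- nevuscreen:::branch_losses(fw$heads$o2m, bt$gts, cfg_ciou, 10)
  nevuscreen:::tape_stop()
  expect_equal(l_shape$loss_cls, l_ciou$loss_cls)
  expect_equal(l_shape$loss_dfl, l_ciou$loss_dfl)
  expect_false(isTRUE(all.equal(l_shape$loss_box, l_ciou$loss_box)))
})

test_that("task-aligned assignment ranks candidates deterministically", {
  # single anchor sitting exactly on the single gt
  anchors <- data.frame(ax = 5, ay = 5, stride = 8)
  pred <- bbox(5, 5, 4, 4)
  gt <- bbox(5, 5, 4, 4)
  asg <- assign_targets(anchors, pred, gt)
  expect_equal(asg$one2many$anchor, 1)
  expect_equal(asg$one2one$anchor, 1)
  # empty ground truth: no positives
  asg0 <- assign_targets(anchors, pred, NULL)
  expect_equal(nrow(asg0$one2many), 0)
  # 3 anchors, IoUs 0.9 / 0.6 / 0.3, equal scores, k = 2
  anchors3 <- data.frame(ax = c(5, 5.5, 6), ay = c(5, 5, 5), stride = 8)
  preds <- rbind(bbox(5, 5, 4, 4.21), bbox(5.8, 5, 4, 4), bbox(7, 5, 4, 4))
  ious <- box_iou(preds, bbox(5, 5, 4, 4))
  expect_true(all(diff(ious) < 0))
  asg3 <- assign_targets(anchors3, preds, bbox(5, 5, 4, 4), k = 2)
  expect_equal(sort(asg3$one2many$anchor), c(1, 2))
  expect_equal(asg3$one2one$anchor, 1)
  # one-to-one positives are a subset of one-to-many positives
  set.seed(34)
  for (i in 1:10) {
    anchors_r <- data.frame(ax = stats::runif(20, 0, 64),
                            ay = stats::runif(20, 0, 64), stride = 8)
    preds_r <- bbox(anchors_r$ax, anchors_r$ay,
                    stats::runif(20, 5, 30), stats::runif(20, 5, 30))
    gts_r <- rbind(bbox(20, 20, 18, 18), bbox(48, 44, 16, 20))
    a <- assign_targets(anchors_r, preds_r, gts_r,
                        scores = stats::runif(20))
    expect_true(all(a$one2one$anchor %in% a$one2many$anchor))
    expect_lte(nrow(a$one2one), nrow(gts_r))
  }
})

test_that("training reduces the loss on a small synthetic batch", {
  set.seed(35)
  man <- make_cohort(8, 0)
  samples <- gen_samples(man, 64)
  model <- build_detector(tiny_cfg())
  bt <- nevuscreen:::batch_from_samples(samples)
  first <- detector_train_step(model, bt$x, bt$gts, lr = 0.01)
  for (s in 1:19) last <- detector_train_step(model, bt$x, bt$gts, lr = 0.01)
  expect_lt(last["cls"], first["cls"])
  expect_lt(last["box"] + last["dfl"], first["box"] + first["dfl"])
  expect_true(all(is.finite(last)))
})

test_that("inference is deterministic, sorted, threshold-monotone, NMS-free", {
  set.seed(36)
  model <- build_detector(tiny_cfg())
  img <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  d1 <- detector_infer(model, img, conf_thresh = 0)
  d2 <- detector_infer(model, img, conf_thresh = 0)
  expect_identical(d1, d2)
  expect_true(!is.unsorted(rev(d1$score)))
  d_half <- detector_infer(model, img, conf_thresh = 0.5)
  expect_gte(nrow(d1), nrow(d_half))
  expect_true(all(d1$class_id == 0L))
})
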