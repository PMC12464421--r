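#' One-stage nevus detector
#'
#' A three-stage single-class detector assembled from: a lightweight
#' depthwise-separable backbone (H-Swish activations, squeeze-and-excitation,
#' 5x5 tail kernels, SPPF plus SE-based global recalibration at 1/32), a
#' path-aggregation neck with split-merge (C2f) fusion, separable stride-2
#' (SCDown) reduction and an MCA attention block before each output node, and
#' a decoupled head with distribution-focal-loss (DFL) box regression trained
#' under dual (one-to-many / one-to-one) label assignment. Inference keeps
#' only the one-to-one branch and applies no NMS. Ablation switches toggle
#' the backbone style, the MCA blocks and the Shape-IoU box loss
#' independently.
#'
#' The default `tiny` profile is sized for CPU-scale experiments on 64-160 px
#' synthetic images; the full-resolution profile mirrors the published
#' training setup (640 px input, batch 64, 100 epochs, SGD momentum 0.9,
#' weight decay 5e-4, cosine learning rate 0.01 to 1e-5, validation every 5
#' epochs, early stop after 15 stagnant checks).
#'
#' @name detector
NULL

#' H-Swish activation
#'
#' `x * clamp(x + 3, 0, 6) / 6`.
#'
#' @param x Numeric vector or array.
#' @return Same shape as `x`.
#' @examples
#' hswish(c(-3, 0, 1, 3)) # 0, 0, 2/3, 3
#' @export
hswish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6

#' Detector configuration
#'
#' @param img_size Training input side in px (multiple of 32).
#' @param pp_lcnet Use the depthwise-separable backbone (`FALSE`: plain-conv
#'   baseline backbone of identical tap channels).
#' @param mca Insert MCA blocks before the neck output nodes.
#' @param shape_iou Use the Shape-IoU box loss (`FALSE`: CIoU baseline).
#' @param widths Channel widths `c(stem, c2, p3, p4, p5)`.
#' @param head_hidden Hidden width of the head branches.
#' @param nbins DFL bins per box side.
#' @param conf_thresh Inference confidence threshold.
#' @param shape_scale Shape-IoU `scale` factor (dataset-level constant).
#' @return A list with class `detector_config`.
#' @export
detector_config <- function(img_size = 64, pp_lcnet = TRUE, mca = TRUE,
                            shape_iou = TRUE,
                            widths = c(8, 16, 32, 64, 96),
                            head_hidden = 32, nbins = 16,
                            conf_thresh = 0.5, shape_scale = 0) {
  stopifnot(img_size %% 32 == 0)
  structure(list(img_size = img_size, pp_lcnet = pp_lcnet, mca = mca,
                 shape_iou = shape_iou, widths = widths,
                 head_hidden = head_hidden, nbins = nbins,
                 conf_thresh = conf_thresh, shape_scale = shape_scale),
            class = "detector_config")
}

#' Published full-scale training defaults
#'
#' @return A list: input 640 px, batch 64, 100 epochs, SGD momentum 0.9,
#'   weight decay 5e-4, cosine learning rate 0.01 to 1e-5, validation every
#'   5 epochs, early-stop patience 15.
#' @export
detector_train_defaults <- function() {
  list(img_size = 640, batch_size = 64, epochs = 100, momentum = 0.9,
       weight_decay = 5e-4, lr0 = 0.01, lrf = 1e-5, val_every = 5,
       patience = 15)
}

collect_params <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    lp <- layers[[nm]]$params
    if (length(lp)) {
      names(lp) <- paste0(nm, ".", names(lp))
      out <- c(out, lp)
    }
  }
  out
}

#' Build a detector
#'
#' @param cfg A [detector_config()].
#' @return A `detector` object (layers, parameter nodes, config).
#' @export
build_detector <- function(cfg = detector_config()) {
  w <- cfg$widths
  L <- list()
  if (cfg$pp_lcnet) {
    L$stem <- make_conv_bn(3, w[1], 3, 2)
    L$b1 <- make_dwsep(w[1], w[2], 3, 2)
    L$b2 <- make_dwsep(w[2], w[2], 3, 1)
    L$b3 <- make_dwsep(w[2], w[3], 3, 2)
    L$b4 <- make_dwsep(w[3], w[3], 3, 1)
    L$b5 <- make_dwsep(w[3], w[4], 5, 2, use_se = TRUE)
    L$b6 <- make_dwsep(w[4], w[4], 5, 1, use_se = TRUE)
    L$b7 <- make_dwsep(w[4], w[5], 5, 2, use_se = TRUE)
  } else {
    L$stem <- make_conv_bn(3, w[1], 3, 2)
    L$b1 <- make_conv_bn(w[1], w[2], 3, 2)
    L$b2 <- make_conv_bn(w[2], w[2], 3, 1)
    L$b3 <- make_conv_bn(w[2], w[3], 3, 2)
    L$b4 <- make_conv_bn(w[3], w[3], 3, 1)
    L$b5 <- make_conv_bn(w[3], w[4], 3, 2)
    L$b6 <- make_conv_bn(w[4], w[4], 3, 1)
    L$b7 <- make_conv_bn(w[4], w[5], 3, 2)
  }
  L$sppf <- make_sppf(w[5], w[5])
  L$psa <- make_se(w[5])
  # classification-pretrain path (unused by detection training)
  L$cls_proj <- make_conv(w[5], 128, 1)

  L$n_c2f_p4 <- make_c2f(w[5] + w[4], w[4])
  L$n_c2f_p3 <- make_c2f(w[4] + w[3], w[3])
  L$n_down3 <- make_scdown(w[3], w[3])
  L$n_c2f_p4b <- make_c2f(w[3] + w[4], w[4])
  L$n_down4 <- make_scdown(w[4], w[4])
  L$n_c2f_p5b <- make_c2f(w[4] + w[5], w[5])
  hw <- cfg$img_size
  if (cfg$mca) {
    L$mca3 <- make_mca(w[3], hw / 8, hw / 8)
    L$mca4 <- make_mca(w[4], hw / 16, hw / 16)
    L$mca5 <- make_mca(w[5], hw / 32, hw / 32)
  } else {
    L$mca3 <- identity_layer(); L$mca4 <- identity_layer()
    L$mca5 <- identity_layer()
  }
  hh <- cfg$head_hidden
  for (br in c("o2m", "o2o")) {
    for (i in 1:3) {
      cin <- w[2 + i]
      L[[paste0(br, "_cls", i, "a")]] <- make_conv_bn(cin, hh, 3)
      L[[paste0(br, "_cls", i, "b")]] <- make_conv(hh, 1, 1, bias_init = -4)
      L[[paste0(br, "_reg", i, "a")]] <- make_conv_bn(cin, hh, 3)
      L[[paste0(br, "_reg", i, "b")]] <- make_conv(hh, 4 * cfg$nbins, 1)
    }
  }
  states <- list()
  for (nm in names(L)) {
    if (!is.null(L[[nm]]$state)) states[[nm]] <- L[[nm]]$state
  }
  structure(list(cfg = cfg, layers = L, params = collect_params(L),
                 states = states, opt = new.env(parent = emptyenv())),
            class = "detector")
}

# pad an (H, W, 3, N) batch to multiples of 32 (bottom/right)
pad_to_32 <- function(x) {
  d <- dim(x)
  H2 <- ceiling(d[1] / 32) * 32; W2 <- ceiling(d[2] / 32) * 32
  if (H2 == d[1] && W2 == d[2]) return(x)
  message(sprintf("input %dx%d padded to %dx%d", d[1], d[2], H2, W2))
  out <- array(0, dim = c(H2, W2, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  out
}

#' Forward pass
#'
#' @param model A built [build_detector()] object.
#' @param images `H x W x 3 x N` array (or a single `H x W x 3` image) of
#'   ImageNet-standardised pixels; sides are padded to multiples of 32 when
#'   needed.
#' @param training Batch-statistics mode for batch norm; also records the
#'   tape for backpropagation.
#' @return A list with `heads` (per branch `o2m` / `o2o`, per scale: `cls`
#'   and `reg` nodes plus `stride`) and `features` (P3/P4/P5 arrays at
#'   exactly 1/8, 1/16, 1/32 resolution).
#' @export
detector_forward <- function(model, images, training = FALSE) {
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1)
  images <- pad_to_32(images)
  if (training) tape_start() else tape_stop()
  L <- model$layers
  x <- nn_const(images)
  t <- training
  s <- L$stem$fwd(x, t)
  s <- L$b2$fwd(L$b1$fwd(s, t), t)
  p3 <- L$b4$fwd(L$b3$fwd(s, t), t)
  p4 <- L$b5$fwd(p3, t)
  p4 <- L$b6$fwd(p4, t)
  p5 <- L$b7$fwd(p4, t)
  p5 <- L$psa$fwd(L$sppf$fwd(p5, t), t)

  p4p <- L$n_c2f_p4$fwd(op_concat_c(list(op_upsample2(p5), p4)), t)
  p3p <- L$n_c2f_p3$fwd(op_concat_c(list(op_upsample2(p4p), p3)), t)
  p4b <- L$n_c2f_p4b$fwd(op_concat_c(list(L$n_down3$fwd(p3p, t), p4p)), t)
  p5b <- L$n_c2f_p5b$fwd(op_concat_c(list(L$n_down4$fwd(p4b, t), p5)), t)
  m3 <- L$mca3$fwd(p3p, t)
  m4 <- L$mca4$fwd(p4b, t)
  m5 <- L$mca5$fwd(p5b, t)

  feats <- list(m3, m4, m5)
  strides <- c(8, 16, 32)
  heads <- list()
  for (br in c("o2m", "o2o")) {
    heads[[br]] <- lapply(1:3, function(i) {
      f <- feats[[i]]
      list(
        cls = L[[paste0(br, "_cls", i, "b")]]$fwd(
          L[[paste0(br, "_cls", i, "a")]]$fwd(f, t), t),
        reg = L[[paste0(br, "_reg", i, "b")]]$fwd(
          L[[paste0(br, "_reg", i, "a")]]$fwd(f, t), t),
        stride = strides[i]
      )
    })
  }
  list(heads = heads,
       features = list(P3 = p3$val, P4 = p4$val, P5 = p5$val),
       neck = list(P3 = m3$val, P4 = m4$val, P5 = m5$val))
}

# anchor centres for a (Ho, Wo) grid; flat order matches array flattening
anchor_grid <- function(Ho, Wo, stride) {
  data.frame(
    ax = rep((seq_len(Wo) - 0.5) * stride, each = Ho),
    ay = rep((seq_len(Ho) - 0.5) * stride, times = Wo),
    stride = stride
  )
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# decode DFL regression channels into centre-form boxes for one image
decode_boxes <- function(reg_mat, anchors, nbins) {
  bins <- 0:(nbins - 1)
  d <- matrix(0, nrow(reg_mat), 4)
  for (s in 1:4) {
    P <- softmax_rows(reg_mat[, (s - 1) * nbins + seq_len(nbins), drop = FALSE])
    d[, s] <- as.vector(P %*% bins)
  }
  l <- d[, 1] * anchors$stride; tt <- d[, 2] * anchors$stride
  r <- d[, 3] * anchors$stride; b <- d[, 4] * anchors$stride
  data.frame(cx = anchors$ax + (r - l) / 2, cy = anchors$ay + (b - tt) / 2,
             w = pmax(l + r, 1e-6), h = pmax(tt + b, 1e-6))
}

#' Task-aligned dual label assignment
#'
#' Candidates are anchors whose centre lies inside the ground-truth box
#' (falling back to the highest-IoU anchor when none does); they are ranked
#' by the task-aligned metric `score^alpha * IoU^beta`, deterministically
#' breaking ties by lowest anchor index. The one-to-many branch keeps the
#' top-`k` anchors per ground truth, the one-to-one branch the top-1, so
#' one-to-one positives are always a subset of one-to-many positives.
#'
#' @param anchors Data frame with anchor centres `ax, ay`.
#' @param pred_boxes Predicted boxes aligned with `anchors` (centre form).
#' @param gts Ground-truth boxes (0 or more rows).
#' @param scores Predicted class scores per anchor (default 1).
#' @param alpha,beta Task-aligned exponents (defaults 1 and 6).
#' @param k One-to-many candidates per ground truth (default 10).
#' @return A list with `one2many` (data frame `anchor`, `gt`) and `one2one`
#'   (one row per gt).
#' @export
assign_targets <- function(anchors, pred_boxes, gts, scores = NULL,
                           alpha = 1, beta = 6, k = 10) {
  n_gt <- NROW(gts)
  empty <- data.frame(anchor = integer(), gt = integer())
  if (n_gt == 0) return(list(one2many = empty, one2one = empty))
  if (is.null(scores)) scores <- rep(1, nrow(anchors))
  pb <- as_bbox(pred_boxes)
  g <- as_bbox(as.data.frame(gts)[, c("cx", "cy", "w", "h")])
  o2m <- list(); o2o <- list()
  for (j in seq_len(n_gt)) {
    gc <- bbox_corners(g[j, , drop = FALSE])
    inside <- anchors$ax > gc[1, "x1"] & anchors$ax < gc[1, "x2"] &
      anchors$ay > gc[1, "y1"] & anchors$ay < gc[1, "y2"]
    ious <- box_iou(pb, g[j, , drop = FALSE])
    cand <- which(inside)
    if (!length(cand)) cand <- which.max(ious)
    metric <- pmax(scores[cand], 1e-9)^alpha * pmax(ious[cand], 1e-9)^beta
    ord <- cand[order(-metric, cand)]
    o2m[[j]] <- data.frame(anchor = ord[seq_len(min(k, length(ord)))], gt = j)
    o2o[[j]] <- data.frame(anchor = ord[1], gt = j)
  }
  o2m <- do.call(rbind, o2m); o2o <- do.call(rbind, o2o)
  # resolve anchors claimed by several ground truths: keep the higher metric
  dedup <- function(df) {
    if (!anyDuplicated(df$anchor)) return(df)
    keep <- !logical(nrow(df))
    for (a in unique(df$anchor[duplicated(df$anchor)])) {
      rows <- which(df$anchor == a)
      met <- vapply(rows, function(r) {
        j <- df$gt[r]
        box_iou(pb[a, , drop = FALSE], g[j, , drop = FALSE])
      }, numeric(1))
      keep[rows[-which.max(met)]] <- FALSE
    }
    df[keep, , drop = FALSE]
  }
  list(one2many = dedup(o2m), one2one = dedup(o2o))
}

# ---- loss assembly -------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# per-branch losses and seed gradients; head_k = 10 (o2m) or 1 (o2o)
branch_losses <- function(branch, gt_list, cfg, head_k,
                          box_w = 5, cls_w = 1, dfl_w = 0.5) {
  nb <- cfg$nbins
  N <- dim(branch[[1]]$cls$val)[4]
  scale_meta <- lapply(branch, function(sc) {
    d <- dim(sc$cls$val)
    list(Ho = d[1], Wo = d[2], anchors = anchor_grid(d[1], d[2], sc$stride))
  })
  anchors <- do.call(rbind, lapply(scale_meta, `[[`, "anchors"))
  n_per <- vapply(scale_meta, function(m) m$Ho * m$Wo, numeric(1))
  offs <- cumsum(c(0, n_per))
  seeds_cls <- lapply(branch, function(sc) array(0, dim = dim(sc$cls$val)))
  seeds_reg <- lapply(branch, function(sc) array(0, dim = dim(sc$reg$val)))
  loss_box <- 0; loss_cls <- 0; loss_dfl <- 0; n_pos_tot <- 0
  per_img <- vector("list", N)
  for (n in seq_len(N)) {
    z <- unlist(lapply(branch, function(sc) as.vector(sc$cls$val[, , 1, n])))
    regm <- do.call(rbind, lapply(seq_along(branch), function(i) {
      matrix(branch[[i]]$reg$val[, , , n], nrow = n_per[i], ncol = 4 * nb)
    }))
    pred <- decode_boxes(regm, anchors, nb)
    sig <- sigmoid(z)
    asg <- assign_targets(anchors, pred, gt_list[[n]], scores = sig, k = head_k)
    pos <- asg$one2many
    if (head_k == 1) pos <- asg$one2one
    per_img[[n]] <- list(z = z, sig = sig, regm = regm, pred = pred, pos = pos)
    n_pos_tot <- n_pos_tot + nrow(pos)
  }
  norm <- max(1, n_pos_tot)
  for (n in seq_len(N)) {
    st <- per_img[[n]]
    tvec <- numeric(length(st$z))
    tvec[st$pos$anchor] <- 1
    # classification BCE with logits
    loss_cls <- loss_cls + cls_w *
      sum(log(1 + exp(-abs(st$z))) + pmax(st$z, 0) - st$z * tvec) / norm
    gz <- cls_w * (st$sig - tvec) / norm
    for (i in seq_along(branch)) {
      idx <- (offs[i] + 1):offs[i + 1]
      seeds_cls[[i]][, , 1, n] <- gz[idx]
    }
  }
  # box + DFL terms, vectorised over all positives of the batch
  pos_all <- do.call(rbind, lapply(seq_len(N), function(n) {
    p <- per_img[[n]]$pos
    if (nrow(p)) cbind(n = n, p) else NULL
  }))
  if (!is.null(pos_all) && nrow(pos_all)) {
    np <- nrow(pos_all)
    a <- pos_all$anchor
    stride_v <- anchors$stride[a]
    pb <- do.call(rbind, lapply(seq_len(np), function(r) {
      as.matrix(per_img[[pos_all$n[r]]]$pred[a[r], c("cx", "cy", "w", "h")])
    }))
    gb <- do.call(rbind, lapply(seq_len(np), function(r) {
      as_bbox(as.data.frame(gt_list[[pos_all$n[r]]])[, c("cx", "cy", "w", "h")])[
        pos_all$gt[r], , drop = FALSE]
    }))
    if (cfg$shape_iou) {
      params <- shape_iou_params(scale = cfg$shape_scale)
      loss_box <- box_w * sum(shape_iou_loss(pb, gb, params)$total) / norm
      G <- shape_iou_grad(pb, gb, params) * box_w / norm
    } else {
      loss_box <- box_w * sum(ciou_loss(pb, gb)) / norm
      G <- ciou_grad(pb, gb) * box_w / norm
    }
    # chain through decode: box -> expected bin value e per side (l,t,r,b)
    ge <- cbind(
      -G[, "cx"] * stride_v / 2 + G[, "w"] * stride_v,
      -G[, "cy"] * stride_v / 2 + G[, "h"] * stride_v,
      G[, "cx"] * stride_v / 2 + G[, "w"] * stride_v,
      G[, "cy"] * stride_v / 2 + G[, "h"] * stride_v
    )
    gc <- bbox_corners(gb)
    tdist <- cbind(anchors$ax[a] - gc[, "x1"], anchors$ay[a] - gc[, "y1"],
                   gc[, "x2"] - anchors$ax[a], gc[, "y2"] - anchors$ay[a]) /
      stride_v
    tdist <- pmin(pmax(tdist, 0), nb - 1 - 1e-3)
    zmat <- do.call(rbind, lapply(seq_len(np), function(r) {
      per_img[[pos_all$n[r]]]$regm[a[r], ]
    }))
    sc_i <- findInterval(a - 0.5, offs)
    ai <- a - offs[sc_i]
    Ho_v <- vapply(scale_meta, `[[`, numeric(1), "Ho")[sc_i]
    ho <- (ai - 1) %% Ho_v + 1
    wo <- (ai - 1) %/% Ho_v + 1
    bins <- 0:(nb - 1)
    rows <- seq_len(np)
    for (s in 1:4) {
      P <- softmax_rows(zmat[, (s - 1) * nb + seq_len(nb), drop = FALSE])
      e <- as.vector(P %*% bins)
      gz_side <- P * (matrix(bins, np, nb, byrow = TRUE) - e) * ge[, s]
      lo <- floor(tdist[, s]); whi <- tdist[, s] - lo; wlo <- 1 - whi
      Y <- matrix(0, np, nb)
      Y[cbind(rows, lo + 1)] <- wlo
      Y[cbind(rows, lo + 2)] <- whi
      loss_dfl <- loss_dfl - dfl_w *
        sum(wlo * log(pmax(P[cbind(rows, lo + 1)], 1e-12)) +
              whi * log(pmax(P[cbind(rows, lo + 2)], 1e-12))) / (4 * norm)
      gz_side <- gz_side + dfl_w * (P - Y) / (4 * norm)
      for (i in seq_along(branch)) {
        sel <- which(sc_i == i)
        if (!length(sel)) next
        idx <- cbind(rep(ho[sel], each = nb), rep(wo[sel], each = nb),
                     rep((s - 1) * nb + seq_len(nb), times = length(sel)),
                     rep(pos_all$n[sel], each = nb))
        seeds_reg[[i]][idx] <- seeds_reg[[i]][idx] + as.vector(t(gz_side[sel, , drop = FALSE]))
      }
    }
  }
  list(loss_box = loss_box, loss_cls = loss_cls, loss_dfl = loss_dfl,
       seeds_cls = seeds_cls, seeds_reg = seeds_reg, n_pos = n_pos_tot)
}

#' One optimisation step
#'
#' Runs the forward pass in training mode, computes the one-to-many and
#' one-to-one branch losses (box via Shape-IoU or CIoU per configuration,
#' classification BCE, and distribution focal loss), backpropagates and
#' applies an SGD-with-momentum update.
#'
#' @param model A `detector`.
#' @param images `H x W x 3 x N` standardised batch.
#' @param gt_list List (length N) of ground-truth box tables, pixel units.
#' @param lr Learning rate.
#' @param momentum,weight_decay SGD parameters (weight decay applies to
#'   convolution kernels only).
#' @return Named numeric vector `c(box, cls, dfl)` (sum over both branches).
#' @export
detector_train_step <- function(model, images, gt_list, lr = 0.01,
                                momentum = 0.9, weight_decay = 5e-4) {
  fw <- detector_forward(model, images, training = TRUE)
  cfg <- model$cfg
  lo_m <- branch_losses(fw$heads$o2m, gt_list, cfg, head_k = 10)
  lo_o <- branch_losses(fw$heads$o2o, gt_list, cfg, head_k = 1)
  outs <- list(); seeds <- list()
  for (i in 1:3) {
    outs <- c(outs, list(fw$heads$o2m[[i]]$cls, fw$heads$o2m[[i]]$reg,
                         fw$heads$o2o[[i]]$cls, fw$heads$o2o[[i]]$reg))
    seeds <- c(seeds, list(lo_m$seeds_cls[[i]], lo_m$seeds_reg[[i]],
                           lo_o$seeds_cls[[i]], lo_o$seeds_reg[[i]]))
  }
  losses <- c(box = lo_m$loss_box + lo_o$loss_box,
              cls = lo_m$loss_cls + lo_o$loss_cls,
              dfl = lo_m$loss_dfl + lo_o$loss_dfl)
  if (any(!is.finite(losses))) {
    stop("NaN/Inf loss encountered: ", paste(round(losses, 4), collapse = ", "))
  }
  nn_backward(outs, seeds)
  tape_stop()
  sgd_step(model, lr, momentum, weight_decay)
  losses
}

sgd_step <- function(model, lr, momentum = 0.9, weight_decay = 5e-4) {
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    if (weight_decay > 0 && !is.null(dim(p$val)) && length(dim(p$val)) == 4) {
      g <- g + weight_decay * p$val
    }
    v <- model$opt[[nm]]
    if (is.null(v)) v <- 0
    v <- momentum * v - lr * g
    model$opt[[nm]] <- v
    p$val <- p$val + v
    p$grad <- NULL
  }
  invisible(NULL)
}

# samples (synthetic_sample list) -> standardised batch + gt list
batch_from_samples <- function(samples, augment = NULL) {
  imgs <- lapply(samples, function(s) {
    if (!is.null(augment)) s <- augment_sample(s, augment)
    list(img = normalize_image(s$image), box = s$box)
  })
  d <- dim(imgs[[1]]$img)
  x <- array(0, dim = c(d[1], d[2], 3, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]$img
  list(x = x, gts = lapply(imgs, `[[`, "box"))
}

#' Train a detector on synthetic samples
#'
#' SGD with momentum and a cosine learning-rate schedule; validation mAP@0.5
#' is evaluated every `val_every` epochs and the best-scoring parameters are
#' restored at the end (early stop after `patience` stagnant epochs).
#'
#' @param model A `detector` (modified in place).
#' @param train_samples List of `synthetic_sample`s.
#' @param val_samples Optional validation samples.
#' @param epochs,batch_size Training schedule.
#' @param lr0,lrf Initial and final cosine learning rates.
#' @param warmup_epochs Linear learning-rate ramp over the first epochs
#'   (stabilises the random-initialisation phase).
#' @param momentum,weight_decay SGD parameters.
#' @param val_every Validation interval in epochs.
#' @param patience Early-stop patience in epochs.
#' @param augment Optional [augment_config()] applied online.
#' @param verbose Print per-epoch losses.
#' @return Data frame log with per-epoch `box`, `cls`, `dfl` (and `map50`
#'   at validation epochs).
#' @export
detector_train <- function(model, train_samples, val_samples = NULL,
                           epochs = 30, batch_size = 16, lr0 = 0.01,
                           lrf = 1e-5, momentum = 0.9, weight_decay = 5e-4,
                           warmup_epochs = 3, val_every = 5, patience = 15,
                           augment = NULL, verbose = FALSE) {
  n <- length(train_samples)
  log <- data.frame()
  best_map <- -Inf; best_vals <- NULL; best_states <- NULL; last_improve <- 0
  for (e in seq_len(epochs)) {
    lr <- lrf + 0.5 * (lr0 - lrf) * (1 + cos(pi * (e - 1) / max(1, epochs - 1)))
    if (warmup_epochs > 0 && e <= warmup_epochs) lr <- lr * e / warmup_epochs
    ord <- sample(n)
    tot <- c(box = 0, cls = 0, dfl = 0); nb <- 0
    for (b0 in seq(1, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1, n)]
      bt <- batch_from_samples(train_samples[idx], augment)
      tot <- tot + detector_train_step(model, bt$x, bt$gts, lr,
                                       momentum, weight_decay)
      nb <- nb + 1
    }
    row <- data.frame(epoch = e, box = tot[1] / nb, cls = tot[2] / nb,
                      dfl = tot[3] / nb, map50 = NA_real_)
    if (!is.null(val_samples) && (e %% val_every == 0 || e == epochs)) {
      row$map50 <- detector_evaluate(model, val_samples)$map50
      if (row$map50 > best_map + 1e-9) {
        best_map <- row$map50
        # snapshot parameters AND batch-norm running statistics
        best_vals <- lapply(model$params, function(p) p$val)
        best_states <- lapply(model$states, function(st) {
          list(mean = st$mean, var = st$var)
        })
        last_improve <- e
      } else if (e - last_improve >= patience) {
        log <- rbind(log, row)
        if (verbose) message(sprintf("early stop at epoch %d", e))
        break
      }
    }
    log <- rbind(log, row)
    if (verbose) {
      message(sprintf("epoch %3d lr %.4f box %.3f cls %.3f dfl %.3f map %s",
                      e, lr, row$box, row$cls, row$dfl,
                      ifelse(is.na(row$map50), "-", sprintf("%.3f", row$map50))))
    }
  }
  if (!is.null(best_vals)) {
    for (nm in names(best_vals)) model$params[[nm]]$val <- best_vals[[nm]]
    for (nm in names(best_states)) {
      model$states[[nm]]$mean <- best_states[[nm]]$mean
      model$states[[nm]]$var <- best_states[[nm]]$var
    }
  }
  rownames(log) <- NULL
  log
}

#' NMS-free inference
#'
#' Decodes the one-to-one head directly into image-space boxes; detections
#' below the confidence threshold are dropped and results are sorted by
#' descending score. No NMS is applied.
#'
#' @param model A `detector`.
#' @param image `H x W x 3` image in `[0, 1]` (standardised internally) or a
#'   `synthetic_sample`.
#' @param conf_thresh Confidence threshold (inclusive); default from config.
#' @param max_det Maximum detections returned.
#' @return Data frame with columns `cx, cy, w, h, score, class_id` (class 0,
#'   "nevus"), sorted by descending score.
#' @export
detector_infer <- function(model, image, conf_thresh = NULL, max_det = 30) {
  if (inherits(image, "synthetic_sample")) image <- image$image
  if (is.null(conf_thresh)) conf_thresh <- model$cfg$conf_thresh
  x <- normalize_image(image)
  fw <- detector_forward(model, x, training = FALSE)
  nb <- model$cfg$nbins
  branch <- fw$heads$o2o
  out <- lapply(branch, function(sc) {
    d <- dim(sc$cls$val)
    anchors <- anchor_grid(d[1], d[2], sc$stride)
    regm <- matrix(sc$reg$val[, , , 1], nrow = d[1] * d[2], ncol = 4 * nb)
    boxes <- decode_boxes(regm, anchors, nb)
    boxes$score <- sigmoid(as.vector(sc$cls$val[, , 1, 1]))
    boxes
  })
  dets <- do.call(rbind, out)
  dets <- dets[dets$score >= conf_thresh, , drop = FALSE]
  dets <- dets[order(-dets$score), , drop = FALSE]
  if (nrow(dets) > max_det) dets <- dets[seq_len(max_det), , drop = FALSE]
  dets$class_id <- rep(0L, nrow(dets))
  rownames(dets) <- NULL
  dets
}

#' Evaluate a detector on samples
#'
#' @param model A `detector`.
#' @param samples List of `synthetic_sample`s with ground-truth boxes.
#' @param conf_thresh Confidence threshold for precision/recall.
#' @return An [evaluation_report()] list.
#' @export
detector_evaluate <- function(model, samples, conf_thresh = 0.5) {
  dets <- list(); gts <- list()
  for (i in seq_along(samples)) {
    id <- sprintf("img%04d", i)
    d <- detector_infer(model, samples[[i]], conf_thresh = 0.001)
    if (nrow(d)) d$image_id <- id
    dets[[i]] <- d
    g <- as.data.frame(samples[[i]]$box)
    g$image_id <- id
    gts[[i]] <- g
  }
  dets <- do.call(rbind, dets[vapply(dets, nrow, integer(1)) > 0])
  gts <- do.call(rbind, gts)
  evaluation_report(dets, gts, conf_thresh)
}
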