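#' Layer constructors for the tiny detector
#'
#' Each constructor returns a list with `params` (parameter nodes) and
#' `fwd(x, training)`. Convolutions use "same" padding unless noted;
#' batch-normalised convolutions carry no conv bias.
#'
#' @name nn-layers
#' @keywords internal
NULL

he_init <- function(k, cpg, cout) {
  array(stats::rnorm(k * k * cpg * cout, 0, sqrt(2 / (k * k * cpg))),
        dim = c(k, k, cpg, cout))
}

# conv + BN + activation ("hswish", "sigmoid" or "none")
make_conv_bn <- function(cin, cout, k = 3, stride = 1, groups = 1,
                         act = "hswish") {
  cpg <- cin / groups
  stopifnot(cpg == round(cpg))
  w <- nn_param(he_init(k, cpg, cout))
  zero_b <- nn_const(numeric(cout))
  gamma <- nn_param(rep(1, cout)); beta <- nn_param(numeric(cout))
  state <- new.env(parent = emptyenv())
  state$mean <- numeric(cout); state$var <- rep(1, cout)
  pad <- (k - 1) %/% 2
  list(
    params = list(w = w, gamma = gamma, beta = beta),
    state = state,
    fwd = function(x, training = TRUE) {
      y <- op_conv2d(x, w, zero_b, stride, pad, groups)
      y <- op_bn(y, gamma, beta, state, training)
      switch(act, hswish = op_hswish(y), sigmoid = op_sigmoid(y), y)
    }
  )
}

# plain conv with bias, no BN, no activation (head output projections)
make_conv <- function(cin, cout, k = 1, bias_init = 0) {
  w <- nn_param(he_init(k, cin, cout) * 0.1)
  b <- nn_param(rep(bias_init, length.out = cout))
  pad <- (k - 1) %/% 2
  list(params = list(w = w, b = b),
       fwd = function(x, training = TRUE) op_conv2d(x, w, b, 1L, pad, 1L))
}

# squeeze-and-excitation channel recalibration
make_se <- function(c, r = 4) {
  hid <- max(2, c %/% r)
  fc1 <- make_conv(c, hid, 1)
  fc2 <- make_conv(hid, c, 1)
  list(
    params = c(fc1$params, fc2$params),
    fwd = function(x, training = TRUE) {
      s <- op_gap(x)
      s <- op_hswish(fc1$fwd(s, training))
      s <- op_sigmoid(fc2$fwd(s, training))
      op_mul(x, s)
    }
  )
}

# depthwise-separable block: k x k depthwise + optional SE + 1 x 1 pointwise
make_dwsep <- function(cin, cout, k = 3, stride = 1, use_se = FALSE) {
  dw <- make_conv_bn(cin, cin, k, stride, groups = cin)
  se <- if (use_se) make_se(cin) else NULL
  pw <- make_conv_bn(cin, cout, 1)
  list(
    params = c(dw$params, if (!is.null(se)) se$params, pw$params),
    fwd = function(x, training = TRUE) {
      y <- dw$fwd(x, training)
      if (!is.null(se)) y <- se$fwd(y, training)
      pw$fwd(y, training)
    }
  )
}

# SPPF: 1x1 reduce, three serial 5x5 max-pools, concat, 1x1 project
make_sppf <- function(cin, cout) {
  half <- max(4, cin %/% 2)
  cv1 <- make_conv_bn(cin, half, 1)
  cv2 <- make_conv_bn(half * 4, cout, 1)
  list(
    params = c(cv1$params, cv2$params),
    fwd = function(x, training = TRUE) {
      a <- cv1$fwd(x, training)
      p1 <- op_maxpool(a, 5L, 1L, 2L)
      p2 <- op_maxpool(p1, 5L, 1L, 2L)
      p3 <- op_maxpool(p2, 5L, 1L, 2L)
      cv2$fwd(op_concat_c(list(a, p1, p2, p3)), training)
    }
  )
}

# split-merge fusion block (C2f-style): 1x1 in, bottleneck on one half,
# concat all, 1x1 out
make_c2f <- function(cin, cout) {
  half <- max(4, cout %/% 2)
  cv1 <- make_conv_bn(cin, 2 * half, 1)
  b1 <- make_conv_bn(half, half, 3)
  b2 <- make_conv_bn(half, half, 3)
  cv2 <- make_conv_bn(3 * half, cout, 1)
  list(
    params = c(cv1$params, b1$params, b2$params, cv2$params),
    fwd = function(x, training = TRUE) {
      y <- cv1$fwd(x, training)
      a <- op_slice_c(y, seq_len(half))
      b <- op_slice_c(y, half + seq_len(half))
      bb <- op_add(b, b2$fwd(b1$fwd(b, training), training))
      cv2$fwd(op_concat_c(list(a, b, bb)), training)
    }
  )
}

# separable stride-2 reduction (SCDown)
make_scdown <- function(cin, cout) {
  dw <- make_conv_bn(cin, cin, 3, stride = 2, groups = cin, act = "none")
  pw <- make_conv_bn(cin, cout, 1)
  list(
    params = c(dw$params, pw$params),
    fwd = function(x, training = TRUE) pw$fwd(dw$fwd(x, training), training)
  )
}

# MCA block on the tape (channel / height / width branches, avg+std fusion)
make_mca <- function(C, H, W) {
  mk_branch <- function(len) {
    k <- min(mca_kernel_size(len), if (len %% 2 == 1) len else len + 1)
    list(kern = nn_param(numeric(k)), logits = nn_param(numeric(2)))
  }
  br <- list(channel = mk_branch(C), height = mk_branch(H),
             width = mk_branch(W))
  branch_fwd <- function(xb, p) {
    avg <- op_gap(xb)
    std <- op_std_hw(xb)
    lam <- op_softmax_vec(p$logits)
    d <- op_lincomb2(op_get(lam, 1), avg, op_get(lam, 2), std)
    op_sigmoid(op_conv1d_c(d, p$kern))
  }
  list(
    params = list(ck = br$channel$kern, cl = br$channel$logits,
                  hk = br$height$kern, hl = br$height$logits,
                  wk = br$width$kern, wl = br$width$logits),
    fwd = function(x, training = TRUE) {
      dims <- dim(x$val)
      wc <- branch_fwd(x, br$channel)
      wh <- branch_fwd(op_permute3(x, c(2, 3, 1)), br$height)
      ww <- branch_fwd(op_permute3(x, c(1, 3, 2)), br$width)
      op_mul(x, op_bcast_avg3(wc, wh, ww, dims))
    }
  )
}

identity_layer <- function() {
  list(params = list(), fwd = function(x, training = TRUE) x)
}
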