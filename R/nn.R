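#' Minimal reverse-mode training engine
#'
#' A small tape-based reverse-mode automatic-differentiation engine used to
#' train the tiny detector profile on CPU. Tensors are column-major R arrays
#' with layout `(H, W, C, N)`; convolution and max-pooling run through
#' compiled kernels. The engine supports exactly the operations the detector
#' needs (convolution, batch normalisation, H-Swish/sigmoid activations,
#' concatenation/slicing, nearest upsampling, pooled statistics for the
#' attention block) and is not a general-purpose framework.
#'
#' @name nn-engine
#' @keywords internal
NULL

.nn <- new.env(parent = emptyenv())

tape_start <- function() .nn$tape <- list()
tape_stop <- function() .nn$tape <- NULL

new_node <- function(val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val; nd$grad <- NULL
  nd$parents <- parents; nd$backfn <- backfn
  if (!is.null(.nn$tape)) .nn$tape[[length(.nn$tape) + 1L]] <- nd
  nd
}

# leaf (parameter) node: persists across tapes, accumulates grad
nn_param <- function(val) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val; nd$grad <- NULL; nd$parents <- list(); nd$backfn <- NULL
  nd
}

nn_const <- function(val) nn_param(val)

# reverse pass: seed `outs` with `seeds`, walk the tape backwards
nn_backward <- function(outs, seeds) {
  for (i in seq_along(outs)) {
    nd <- outs[[i]]
    nd$grad <- if (is.null(nd$grad)) seeds[[i]] else nd$grad + seeds[[i]]
  }
  tape <- .nn$tape
  for (j in rev(seq_along(tape))) {
    nd <- tape[[j]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
    nd$grad <- NULL  # free interim grads
  }
  invisible(NULL)
}

# ---- broadcasting helpers (dims of length 4; singleton axes expand) ----
expand_to <- function(a, dims) {
  d <- dim(a)
  ix <- lapply(1:4, function(i) {
    if (d[i] == dims[i]) seq_len(dims[i]) else rep(1L, dims[i])
  })
  a[ix[[1]], ix[[2]], ix[[3]], ix[[4]], drop = FALSE]
}

reduce_to <- function(g, dims) {
  gd <- dim(g)
  for (i in 1:4) {
    if (dims[i] == 1L && gd[i] > 1L) {
      g <- apply(g, setdiff(1:4, i), sum)
      gd[i] <- 1L
      dim(g) <- gd
    }
  }
  g
}

# ---- primitive ops ----

op_conv2d <- function(x, w, b, stride = 1L, pad = 0L, groups = 1L) {
  y <- cpp_conv2d_fw(x$val, dim(x$val), w$val, dim(w$val), b$val,
                     stride, pad, groups)
  new_node(y, list(x, w, b), function(g) {
    r <- cpp_conv2d_bw(x$val, dim(x$val), w$val, dim(w$val), g,
                       stride, pad, groups)
    list(r$gx, r$gw, r$gb)
  })
}

op_maxpool <- function(x, k, stride = 1L, pad = 0L) {
  r <- cpp_maxpool_fw(x$val, dim(x$val), k, stride, pad)
  xd <- dim(x$val)
  new_node(r$y, list(x), function(g) {
    list(cpp_maxpool_bw(g, r$argmax, xd))
  })
}

# batch norm over (H, W, N) per channel; `state` holds running stats
op_bn <- function(x, gamma, beta, state, training = TRUE, momentum = 0.1,
                  eps = 1e-5) {
  d <- dim(x$val); C <- d[3]
  xm <- matrix(x$val, ncol = C * d[4])  # columns: (c, n) pairs, c fastest
  if (training) {
    cm <- colMeans(xm)
    cm2 <- colMeans(xm^2)
    mu <- rowMeans(matrix(cm, C, d[4]))
    ex2 <- rowMeans(matrix(cm2, C, d[4]))
    v <- pmax(ex2 - mu^2, 0)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean; v <- state$var
  }
  istd <- 1 / sqrt(v + eps)
  bc <- function(vec) array(rep(vec, each = d[1] * d[2]), dim = d)
  xhat <- (x$val - bc(mu)) * bc(istd)
  y <- bc(gamma$val) * xhat + bc(beta$val)
  m <- d[1] * d[2] * d[4]
  new_node(y, list(x, gamma, beta), function(g) {
    gm <- matrix(g, ncol = C * d[4])
    xh <- matrix(xhat, ncol = C * d[4])
    sum_c <- function(M) rowSums(matrix(colSums(M), C, d[4]))
    gbeta <- sum_c(gm)
    ggamma <- sum_c(gm * xh)
    if (training) {
      gx <- bc(gamma$val * istd) *
        (g - bc(gbeta / m) - xhat * bc(ggamma / m))
    } else {
      gx <- bc(gamma$val * istd) * g
    }
    list(gx, ggamma, gbeta)
  })
}

op_hswish <- function(x) {
  v <- x$val
  inner <- pmin(pmax(v + 3, 0), 6)
  y <- v * inner / 6
  deriv <- ifelse(v <= -3, 0, ifelse(v >= 3, 1, (2 * v + 3) / 6))
  new_node(y, list(x), function(g) list(g * deriv))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  new_node(s, list(x), function(g) list(g * s * (1 - s)))
}

op_add <- function(x, y) {
  new_node(x$val + y$val, list(x, y), function(g) list(g, g))
}

op_mul <- function(x, y) {
  dims <- pmax(dim(x$val), dim(y$val))
  xv <- expand_to(x$val, dims); yv <- expand_to(y$val, dims)
  new_node(xv * yv, list(x, y), function(g) {
    list(reduce_to(g * yv, dim(x$val)), reduce_to(g * xv, dim(y$val)))
  })
}

op_concat_c <- function(nodes) {
  ds <- lapply(nodes, function(n) dim(n$val))
  cs <- vapply(ds, `[`, integer(1), 3)
  d0 <- ds[[1]]
  out <- array(0, dim = c(d0[1], d0[2], sum(cs), d0[4]))
  off <- 0L
  for (n in nodes) {
    cc <- dim(n$val)[3]
    out[, , (off + 1):(off + cc), ] <- n$val
    off <- off + cc
  }
  new_node(out, nodes, function(g) {
    off <- 0L
    lapply(cs, function(cc) {
      gg <- g[, , (off + 1):(off + cc), , drop = FALSE]
      off <<- off + cc
      gg
    })
  })
}

op_slice_c <- function(x, idx) {
  d <- dim(x$val)
  new_node(x$val[, , idx, , drop = FALSE], list(x), function(g) {
    gx <- array(0, dim = d)
    gx[, , idx, ] <- g
    list(gx)
  })
}

op_upsample2 <- function(x) {
  d <- dim(x$val)
  ri <- rep(seq_len(d[1]), each = 2); ci <- rep(seq_len(d[2]), each = 2)
  new_node(x$val[ri, ci, , , drop = FALSE], list(x), function(g) {
    H2 <- 2 * d[1]; W2 <- 2 * d[2]
    gx <- g[seq(1, H2, 2), , , , drop = FALSE] +
      g[seq(2, H2, 2), , , , drop = FALSE]
    gx <- gx[, seq(1, W2, 2), , , drop = FALSE] +
      gx[, seq(2, W2, 2), , , drop = FALSE]
    list(gx)
  })
}

# global average pool over (H, W) -> (1, 1, C, N)
op_gap <- function(x) {
  d <- dim(x$val)
  hw <- d[1] * d[2]
  cm <- colMeans(matrix(x$val, ncol = d[3] * d[4]))
  y <- array(cm, dim = c(1, 1, d[3], d[4]))
  new_node(y, list(x), function(g) {
    list(expand_to(g, d) / hw)
  })
}

# population std over (H, W) per (C, N) -> (1, 1, C, N)
op_std_hw <- function(x, eps = 1e-10) {
  d <- dim(x$val)
  hw <- d[1] * d[2]
  xm <- matrix(x$val, ncol = d[3] * d[4])
  mu <- colMeans(xm)
  v <- pmax(colMeans(xm^2) - mu^2, 0)
  s <- sqrt(v + eps)
  y <- array(s, dim = c(1, 1, d[3], d[4]))
  mu_a <- array(rep(mu, each = hw), dim = d)
  s_a <- array(rep(s, each = hw), dim = d)
  new_node(y, list(x), function(g) {
    ge <- expand_to(g, d)
    list(ge * (x$val - mu_a) / (hw * s_a))
  })
}

op_permute3 <- function(x, perm) {
  inv <- order(perm)
  new_node(aperm(x$val, c(perm, 4)), list(x), function(g) {
    list(aperm(g, c(inv, 4)))
  })
}

# 1-D convolution along the C axis of a (1, 1, L, N) node, same padding
op_conv1d_c <- function(x, kern) {
  d <- dim(x$val)
  L <- d[3]; N <- d[4]
  k <- length(kern$val); half <- (k - 1) / 2
  D <- matrix(x$val, L, N)
  P <- rbind(matrix(0, half, N), D, matrix(0, half, N))
  y <- matrix(0, L, N)
  for (j in seq_len(k)) y <- y + kern$val[j] * P[j:(j + L - 1), , drop = FALSE]
  new_node(array(y, dim = d), list(x, kern), function(g) {
    G <- matrix(g, L, N)
    GP <- rbind(matrix(0, half, N), G, matrix(0, half, N))
    gD <- matrix(0, L, N)
    gk <- numeric(k)
    for (j in seq_len(k)) {
      # y[l] += k[j] * P[l + j - 1]  =>  gD[m] += k[j] * G[m - j + 1 + half]
      gD <- gD + kern$val[j] * GP[(k - j + 1):(k - j + L), , drop = FALSE]
      gk[j] <- sum(kern$val[j] * 0 + G * P[j:(j + L - 1), , drop = FALSE])
    }
    list(array(gD, dim = d), gk)
  })
}

# scalar-weighted combination a*x + b*y with scalar parameter nodes a, b
op_lincomb2 <- function(a, x, b, y) {
  new_node(a$val[1] * x$val + b$val[1] * y$val, list(a, x, b, y), function(g) {
    list(sum(g * x$val), a$val[1] * g, sum(g * y$val), b$val[1] * g)
  })
}

op_softmax_vec <- function(x) {
  z <- x$val - max(x$val)
  p <- exp(z) / sum(exp(z))
  new_node(p, list(x), function(g) {
    list(p * (g - sum(g * p)))
  })
}

op_get <- function(x, i) {
  n <- length(x$val)
  new_node(x$val[i], list(x), function(g) {
    gv <- numeric(n); gv[i] <- g
    list(gv)
  })
}

# attention broadcast average: weights along C, H, W -> (H, W, C, N) map / 3
op_bcast_avg3 <- function(wc, wh, ww, dims) {
  a1 <- expand_to(wc$val, dims)
  a2 <- expand_to(aperm(wh$val, c(3, 1, 2, 4)), dims)
  a3 <- expand_to(aperm(ww$val, c(1, 3, 2, 4)), dims)
  new_node((a1 + a2 + a3) / 3, list(wc, wh, ww), function(g) {
    g3 <- g / 3
    gc <- reduce_to(g3, dim(wc$val))
    gh <- aperm(reduce_to(g3, c(dims[1], 1, 1, dims[4])), c(2, 3, 1, 4))
    gw <- aperm(reduce_to(g3, c(1, dims[2], 1, dims[4])), c(1, 3, 2, 4))
    list(gc, gh, gw)
  })
}
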