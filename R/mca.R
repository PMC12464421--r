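#' Multidimensional collaborative attention (MCA)
#'
#' A light attention block that models attention independently along the
#' channel, width and height axes of a `C x H x W` feature map. Each branch
#' squeezes the map to a descriptor by a learned convex fusion of average and
#' standard-deviation pooling (max pooling is computed as context and can be
#' added as an optional third fusion term), excites the descriptor with a
#' 1-D local convolution of odd width `k` followed by a sigmoid, and the
#' three sigmoid-normalised attention maps are averaged before multiplying
#' the input. Output shape always equals input shape and attention values lie
#' strictly in `(0, 1)`.
#'
#' @name mca
NULL

#' Adaptive 1-D excitation kernel size
#'
#' Nearest odd integer to `log2(len) / 2 + 1/2`, floored at 3.
#'
#' @param len Descriptor length.
#' @return An odd integer `>= 3`.
#' @export
mca_kernel_size <- function(len) {
  t <- abs(log2(max(len, 1))) / 2 + 0.5
  k <- max(3, round(t))
  if (k %% 2 == 0) k <- k + 1
  as.integer(k)
}

# pooled statistics over all but one axis of a (C, H, W) array
branch_stats <- function(x, axis = c("channel", "width", "height")) {
  axis <- match.arg(axis)
  keep <- switch(axis, channel = 1, height = 2, width = 3)
  n_pool <- prod(dim(x)[-keep])
  if (n_pool < 1) stop("empty axis")
  avg <- apply(x, keep, mean)
  # population standard deviation (0 for singleton pools)
  sq <- apply(x, keep, function(v) mean(v^2))
  std <- sqrt(pmax(sq - avg^2, 0))
  mx <- apply(x, keep, max)
  list(avg = avg, std = std, max = mx)
}

#' Squeeze phase: fused pooled descriptor along one axis
#'
#' @param x A `C x H x W` numeric array.
#' @param axis `"channel"`, `"width"` or `"height"`.
#' @param fusion Non-negative fusion weights: length 2 `(avg, std)` or
#'   length 3 `(avg, std, max)`; normalised internally to a convex
#'   combination.
#' @return Descriptor vector of length `C`, `W` or `H` respectively.
#' @export
squeeze_stats <- function(x, axis = "channel", fusion = c(0.5, 0.5)) {
  stopifnot(length(dim(x)) == 3, length(fusion) %in% c(2, 3),
            all(fusion >= 0), sum(fusion) > 0)
  fusion <- fusion / sum(fusion)
  st <- branch_stats(x, axis)
  d <- fusion[1] * st$avg + fusion[2] * st$std
  if (length(fusion) == 3) d <- d + fusion[3] * st$max
  d
}

#' Excitation phase: 1-D local convolution plus sigmoid
#'
#' Zero-padded same-length convolution with a single shared kernel of odd
#' width `k`, followed by a sigmoid; outputs are strictly in `(0, 1)`.
#'
#' @param descriptor Numeric descriptor vector.
#' @param kernel Numeric kernel of odd length.
#' @return Weight vector the same length as `descriptor`.
#' @export
excitation <- function(descriptor, kernel) {
  k <- length(kernel)
  if (k %% 2 == 0) stop("config error: kernel size must be odd")
  n <- length(descriptor)
  stopifnot(n >= 1)
  half <- (k - 1) / 2
  padded <- c(rep(0, half), descriptor, rep(0, half))
  conv <- vapply(seq_len(n), function(i) {
    sum(kernel * padded[i:(i + k - 1)])
  }, numeric(1))
  1 / (1 + exp(-conv))
}

#' MCA parameter set
#'
#' Kernels default to zero (neutral: every attention weight starts at 0.5)
#' and fusion weights to an equal convex pair; both are the learnable state
#' of the block. Branch weights are not shared.
#'
#' @param C,H,W Feature-map dimensions.
#' @param kernel_size `"adaptive"` (see [mca_kernel_size()]) or an odd
#'   integer used for all branches.
#' @param use_max_pool Include max pooling as a third fusion term.
#' @return A list with class `mca_params` holding per-branch `kernel` and
#'   `fusion` entries plus the configuration.
#' @export
mca_params <- function(C, H, W, kernel_size = "adaptive",
                       use_max_pool = FALSE) {
  lens <- c(channel = C, height = H, width = W)
  branches <- lapply(names(lens), function(br) {
    k <- if (identical(kernel_size, "adaptive")) {
      mca_kernel_size(lens[[br]])
    } else {
      if (kernel_size %% 2 == 0) stop("config error: kernel size must be odd")
      as.integer(kernel_size)
    }
    k <- min(k, if (lens[[br]] %% 2 == 1) lens[[br]] else lens[[br]] + 1)
    nf <- if (use_max_pool) 3 else 2
    list(kernel = rep(0, k), fusion = rep(1 / nf, nf))
  })
  names(branches) <- names(lens)
  structure(list(C = C, H = H, W = W, branches = branches,
                 use_max_pool = use_max_pool),
            class = "mca_params")
}

#' MCA forward pass
#'
#' @param x A `C x H x W` numeric array.
#' @param params An [mca_params()] object matching the input dimensions.
#' @return Array of the same shape: `x` multiplied elementwise by the
#'   averaged attention map.
#' @export
mca_forward <- function(x, params) {
  stopifnot(inherits(params, "mca_params"), length(dim(x)) == 3)
  d <- dim(x)
  stopifnot(d[1] == params$C, d[2] == params$H, d[3] == params$W)
  w_ch <- excitation(squeeze_stats(x, "channel", params$branches$channel$fusion),
                     params$branches$channel$kernel)
  w_h <- excitation(squeeze_stats(x, "height", params$branches$height$fusion),
                    params$branches$height$kernel)
  w_w <- excitation(squeeze_stats(x, "width", params$branches$width$fusion),
                    params$branches$width$kernel)
  att <- (array(w_ch, dim = d) +
            array(rep(w_h, each = d[1]), dim = d) +
            array(rep(w_w, each = d[1] * d[2]), dim = d)) / 3
  x * att
}
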