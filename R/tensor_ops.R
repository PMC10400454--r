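# Low-level tensor primitives. Activation tensors are numeric arrays with
# dim (H, W, C, N); the exported block-level operations also accept single
# feature maps (H, W, C) and return the same rank they were given.

lift4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array feature map")
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    attr(x, "was3d") <- TRUE
  } else if (length(d) == 4L) {
    attr(x, "was3d") <- NULL
  } else {
    stop("feature maps must have 3 or 4 dimensions, got ", length(d))
  }
  x
}

drop4d <- function(y, like) {
  if (isTRUE(attr(like, "was3d"))) dim(y) <- dim(y)[1:3]
  attr(y, "was3d") <- NULL
  y
}

# Multiply/add a per-channel vector across an (H, W, C, N) array. With this
# memory layout rep(v, each = H*W) recycles exactly over the batch dim.
chan_mul <- function(x, v) {
  d <- dim(x)
  x * rep(v, each = d[1] * d[2])
}

chan_add <- function(x, v) {
  d <- dim(x)
  x + rep(v, each = d[1] * d[2])
}

chan_stats <- function(x) chan_stats_cpp(x)

# Sum of gradient over everything but the channel axis.
chan_sum <- function(x) chan_sum_cpp(x)

conv_out_dim <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L

# Fast path for pointwise (1x1, stride 1) convolutions: one matmul per
# image, no im2col and no output permutation.
conv1x1_fwd <- function(x, w, bias) {
  d <- dim(x)
  HW <- d[1] * d[2]
  cout <- dim(w)[4]
  wm <- w
  dim(wm) <- c(d[3], cout)
  y <- array(0, c(d[1], d[2], cout, d[4]))
  for (n in seq_len(d[4])) {
    xm <- x[, , , n]
    dim(xm) <- c(HW, d[3])
    ym <- xm %*% wm
    if (!is.null(bias)) ym <- ym + rep(bias, each = HW)
    y[, , , n] <- ym
  }
  y
}

conv1x1_bwd <- function(x, w, dy, need_dx = TRUE) {
  d <- dim(x)
  HW <- d[1] * d[2]
  cout <- dim(w)[4]
  wm <- w
  dim(wm) <- c(d[3], cout)
  dwm <- matrix(0, d[3], cout)
  db <- numeric(cout)
  dx <- if (need_dx) array(0, d) else NULL
  for (n in seq_len(d[4])) {
    xm <- x[, , , n]
    dim(xm) <- c(HW, d[3])
    dym <- dy[, , , n]
    dim(dym) <- c(HW, cout)
    dwm <- dwm + crossprod(xm, dym)
    db <- db + colSums(dym)
    if (need_dx) dx[, , , n] <- tcrossprod(dym, wm)
  }
  dim(dwm) <- dim(w)
  list(dx = dx, dw = dwm, db = db)
}

#' 2-D convolution (NHWC single-tensor layout)
#'
#' Plain zero-padded cross-correlation used by every convolutional layer in
#' the toolkit. Kernels are arrays `(k, k, C_in, C_out)`.
#'
#' @param x array `(H, W, C_in)` or `(H, W, C_in, N)`.
#' @param w kernel array `(k, k, C_in, C_out)`.
#' @param bias optional length-`C_out` bias.
#' @param stride integer stride.
#' @param pad integer zero padding; default `(k - 1) / 2` ("same" for odd k).
#' @return array of rank matching `x` with `C_out` channels.
#' @export
conv2d <- function(x, w, bias = NULL, stride = 1L, pad = NULL) {
  x <- lift4d(x)
  kd <- dim(w)
  k <- kd[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  d <- dim(x)
  if (d[3] != kd[3]) stop("conv2d: input has ", d[3], " channels, kernel expects ", kd[3])
  if (k == 1L && stride == 1L && pad == 0L) {
    y <- conv1x1_fwd(x, w, bias)
    attr(y, "was3d") <- attr(x, "was3d")
    return(drop4d(y, x))
  }
  cols <- im2col_cpp(x, as.integer(k), as.integer(stride), as.integer(pad))
  wf <- w
  dim(wf) <- c(k * k * kd[3], kd[4])
  ymat <- crossprod(cols, wf) # (Ho*Wo*N) x Cout
  Ho <- conv_out_dim(d[1], k, stride, pad)
  Wo <- conv_out_dim(d[2], k, stride, pad)
  y <- aperm(array(ymat, c(Ho, Wo, d[4], kd[4])), c(1, 2, 4, 3))
  if (!is.null(bias)) y <- chan_add(y, bias)
  attr(y, "was3d") <- attr(x, "was3d")
  drop4d(y, x)
}

conv2d_train <- function(x, w, bias = NULL, stride = 1L, pad = NULL) {
  kd <- dim(w)
  k <- kd[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  d <- dim(x)
  if (k == 1L && stride == 1L && pad == 0L) {
    return(list(y = conv1x1_fwd(x, w, bias), x = x, xdim = d,
                k = k, stride = stride, pad = pad, fast = TRUE))
  }
  cols <- im2col_cpp(x, as.integer(k), as.integer(stride), as.integer(pad))
  wf <- w
  dim(wf) <- c(k * k * kd[3], kd[4])
  ymat <- crossprod(cols, wf)
  Ho <- conv_out_dim(d[1], k, stride, pad)
  Wo <- conv_out_dim(d[2], k, stride, pad)
  y <- aperm(array(ymat, c(Ho, Wo, d[4], kd[4])), c(1, 2, 4, 3))
  if (!is.null(bias)) y <- chan_add(y, bias)
  list(y = y, cols = cols, xdim = d, k = k, stride = stride, pad = pad)
}

conv2d_bwd <- function(cache, w, dy, need_dx = TRUE) {
  if (isTRUE(cache$fast)) return(conv1x1_bwd(cache$x, w, dy, need_dx))
  kd <- dim(w)
  d <- dim(dy)
  dyt <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = kd[4])
  dw <- cache$cols %*% dyt
  dim(dw) <- kd
  db <- colSums(dyt)
  dx <- NULL
  if (need_dx) {
    wf <- w
    dim(wf) <- c(kd[1] * kd[1] * kd[3], kd[4])
    dcols <- tcrossprod(wf, dyt)
    dx <- col2im_cpp(dcols, cache$xdim[1], cache$xdim[2], cache$xdim[3],
                     cache$xdim[4], as.integer(cache$k),
                     as.integer(cache$stride), as.integer(cache$pad))
  }
  list(dx = dx, dw = dw, db = db)
}

#' Depthwise 2-D convolution
#'
#' One `k x k` kernel per channel; this is the "cheap linear transformation"
#' that synthesizes ghost channels in a Ghost module.
#'
#' @param x array `(H, W, C)` or `(H, W, C, N)`.
#' @param w kernel array `(k, k, C)`.
#' @param stride integer stride.
#' @param pad zero padding; default `(k - 1) / 2`.
#' @return array of the same rank as `x`.
#' @export
dwconv2d <- function(x, w, stride = 1L, pad = NULL) {
  x <- lift4d(x)
  k <- dim(w)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  if (dim(x)[3] != dim(w)[3]) stop("dwconv2d: channel mismatch")
  y <- dwconv_fwd_cpp(x, w, as.integer(stride), as.integer(pad))
  attr(y, "was3d") <- attr(x, "was3d")
  drop4d(y, x)
}

#' Batch-normalization transform
#'
#' Applies `gamma * (z - mean) / sqrt(sd^2 + eps) + beta` per channel. `gamma`
#' is the learnable scaling factor whose magnitude is used as the channel
#' importance score by the pruning workflow; with `gamma = 0` the output is
#' the constant `beta` regardless of the input.
#'
#' @param z array `(H, W, C)` / `(H, W, C, N)`, or a length-`C` vector of
#'   per-channel values.
#' @param gamma,beta per-channel scale and shift.
#' @param mean,sd per-channel batch mean and standard deviation (`sd >= 0`).
#' @param eps positive stabilizer added to the variance.
#' @return same shape as `z`.
#' @export
bn_forward <- function(z, gamma, beta, mean, sd, eps = 1e-5) {
  if (eps <= 0) stop("bn_forward: eps must be > 0")
  ns <- vapply(list(gamma, beta, mean, sd), length, 1L)
  if (length(unique(ns)) != 1L) stop("bn_forward: parameter arrays must share channel length")
  invstd <- 1 / sqrt(sd^2 + eps)
  if (is.null(dim(z))) {
    if (length(z) != length(gamma)) stop("bn_forward: z length must equal channel count")
    return(gamma * (z - mean) * invstd + beta)
  }
  z <- lift4d(z)
  y <- chan_affine_cpp(z, gamma * invstd, beta - gamma * mean * invstd)
  attr(y, "was3d") <- attr(z, "was3d")
  drop4d(y, z)
}

bn_train_fwd <- function(x, gamma, beta, eps) {
  st <- chan_stats(x)
  invstd <- 1 / sqrt(st$var + eps)
  xhat <- chan_affine_cpp(x, invstd, -st$mean * invstd)
  y <- chan_affine_cpp(xhat, gamma, beta)
  list(y = y, xhat = xhat, invstd = invstd, mean = st$mean, var = st$var, m = st$m)
}

bn_bwd <- function(cache, gamma, dy) {
  m <- cache$m
  dgamma <- chan_sum(dy * cache$xhat)
  dbeta <- chan_sum(dy)
  coef <- gamma * cache$invstd / m
  dx <- chan_affine_cpp(dy, m * coef, -coef * dbeta) -
    chan_affine_cpp(cache$xhat, coef * dgamma, numeric(length(coef)))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

maxpool2d <- function(x, k, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  maxpool_fwd_cpp(x, as.integer(k), as.integer(stride), as.integer(pad))
}

upsample_nearest <- function(x, f = 2L) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , , drop = FALSE]
}

upsample_nearest_bwd <- function(dy, f = 2L) {
  d <- dim(dy)
  H <- d[1] %/% f
  W <- d[2] %/% f
  CN <- d[3] * d[4]
  s1 <- colSums(array(dy, c(f, H * f * W * CN)))
  dim(s1) <- c(H, f, W, CN)
  s2 <- colSums(aperm(s1, c(2, 1, 3, 4)))
  array(s2, c(H, W, d[3], d[4]))
}

#' Focus (space-to-depth) slicing
#'
#' Samples the four interleaved pixel sub-grids of an even-sized map and
#' stacks them on the channel axis: `(H, W, C) -> (H/2, W/2, 4C)`. The
#' operation is a pure permutation of values; [focus_inverse()] undoes it
#' exactly.
#'
#' @param x array `(H, W, C)` or `(H, W, C, N)` with even height and width.
#' @return the sliced array.
#' @export
focus_forward <- function(x) {
  x <- lift4d(x)
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop("focus_forward: height and width must be even")
  }
  ro <- seq(1L, d[1], 2L)
  re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L)
  ce <- seq(2L, d[2], 2L)
  y <- array(0, c(d[1] %/% 2L, d[2] %/% 2L, 4L * d[3], d[4]))
  cs <- d[3]
  y[, , seq_len(cs), ] <- x[ro, co, , , drop = FALSE]
  y[, , cs + seq_len(cs), ] <- x[re, co, , , drop = FALSE]
  y[, , 2L * cs + seq_len(cs), ] <- x[ro, ce, , , drop = FALSE]
  y[, , 3L * cs + seq_len(cs), ] <- x[re, ce, , , drop = FALSE]
  attr(y, "was3d") <- attr(x, "was3d")
  drop4d(y, x)
}

#' @rdname focus_forward
#' @export
focus_inverse <- function(x) {
  x <- lift4d(x)
  d <- dim(x)
  cs <- d[3] %/% 4L
  if (d[3] %% 4L != 0L) stop("focus_inverse: channels must be divisible by 4")
  y <- array(0, c(2L * d[1], 2L * d[2], cs, d[4]))
  ro <- seq(1L, 2L * d[1], 2L)
  re <- seq(2L, 2L * d[1], 2L)
  co <- seq(1L, 2L * d[2], 2L)
  ce <- seq(2L, 2L * d[2], 2L)
  y[ro, co, , ] <- x[, , seq_len(cs), , drop = FALSE]
  y[re, co, , ] <- x[, , cs + seq_len(cs), , drop = FALSE]
  y[ro, ce, , ] <- x[, , 2L * cs + seq_len(cs), , drop = FALSE]
  y[re, ce, , ] <- x[, , 3L * cs + seq_len(cs), , drop = FALSE]
  attr(y, "was3d") <- attr(x, "was3d")
  drop4d(y, x)
}

#' Spatial pyramid pooling
#'
#' Concatenates the input with same-padding max pools of several receptive
#' fields, leaving the spatial size unchanged and multiplying channels by
#' `length(pool_sizes) + 1`.
#'
#' @param x array `(H, W, C)` or `(H, W, C, N)`.
#' @param pool_sizes odd pooling windows.
#' @return pooled concatenation.
#' @export
spp_forward <- function(x, pool_sizes = c(5L, 9L, 13L)) {
  x <- lift4d(x)
  parts <- c(list(x), lapply(pool_sizes, function(k) maxpool2d(x, k)$y))
  y <- cat_channels(parts)
  attr(y, "was3d") <- attr(x, "was3d")
  drop4d(y, x)
}

cat_channels <- function(xs) {
  d1 <- dim(xs[[1]])
  cc <- vapply(xs, function(x) dim(x)[3], 1L)
  y <- array(0, c(d1[1], d1[2], sum(cc), d1[4]))
  at <- 0L
  for (x in xs) {
    y[, , at + seq_len(dim(x)[3]), ] <- x
    at <- at + dim(x)[3]
  }
  y
}

split_channels <- function(dy, sizes) {
  at <- 0L
  out <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    out[[i]] <- dy[, , at + seq_len(sizes[i]), , drop = FALSE]
    at <- at + sizes[i]
  }
  out
}
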