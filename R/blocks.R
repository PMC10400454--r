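# Ghost / ECA / GE building blocks in functional form. The layer graph in
# network.R composes the same primitives; these entry points exist so each
# block can be exercised and reasoned about in isolation.

#' Ghost module specification
#'
#' Describes a Ghost module: a primary convolution produces `n/s` "real"
#' channels and `s - 1` cheap depthwise transforms synthesize the remaining
#' ghost channels, so the full output has `n` channels at roughly `1/s` of
#' the cost of a standard convolution.
#'
#' @param c input channels.
#' @param n output channels; must be divisible by `s`.
#' @param k primary kernel size (odd).
#' @param s split factor (`>= 1`); `s = 1` degenerates to a standard
#'   convolution.
#' @param stride primary convolution stride.
#' @param out_h,out_w output spatial size, used by the cost model.
#' @return a `ghost_spec` list.
#' @export
ghost_spec <- function(c, n, k = 1L, s = 2L, stride = 1L,
                       out_h = 1L, out_w = 1L) {
  if (s < 1L) stop("ghost_spec: s must be >= 1")
  if (n %% s != 0L) stop("ghost_spec: n (", n, ") must be divisible by s (", s, ")")
  if (k %% 2L != 1L) stop("ghost_spec: kernel size must be odd")
  structure(list(c = c, n = n, k = k, s = s, stride = stride,
                 out_h = out_h, out_w = out_w),
            class = "ghost_spec")
}

#' Cost model for standard vs Ghost convolution
#'
#' `conv_cost` counts the multiplications of a standard convolution,
#' `h' * w' * n * k^2 * c`; `ghost_cost` counts the primary convolution on
#' `n/s` channels plus the `s - 1` cheap depthwise transforms. Their ratio
#' is exactly `s * c / (c + s - 1)`, which approaches the split factor `s`
#' as the channel count grows.
#'
#' @param spec a [ghost_spec()].
#' @return operation count.
#' @export
conv_cost <- function(spec) {
  with(spec, out_h * out_w * n * k^2 * c)
}

#' @rdname conv_cost
#' @export
ghost_cost <- function(spec) {
  with(spec, out_h * out_w * (n / s) * k^2 * c +
         (s - 1) * out_h * out_w * (n / s) * k^2)
}

#' @rdname conv_cost
#' @param c input channels.
#' @param s split factor.
#' @export
ghost_compression_ratio <- function(c, s) s * c / (c + s - 1)

#' Adaptive ECA kernel size
#'
#' Efficient channel attention picks the 1-D convolution kernel from the
#' channel count: `k = |log2(C)/gamma + b/gamma|` rounded to the nearest odd
#' integer (ties rounded up), floored at 1.
#'
#' @param C channel count (`>= 1`).
#' @param gamma,b rule coefficients.
#' @return odd positive integer kernel size.
#' @examples
#' eca_kernel_size(256) # 5
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (length(C) != 1L || !is.finite(C) || C < 1) {
    stop("eca_kernel_size: C must be a single value >= 1")
  }
  k <- log2(C) / gamma + b / gamma
  lo <- 2 * floor((k - 1) / 2) + 1 # largest odd <= k (or k itself if odd)
  hi <- lo + 2
  kk <- if ((hi - k) <= (k - lo)) hi else lo
  max(1L, as.integer(kk))
}

eca1d_fwd <- function(v, w) {
  # v: C x N channel descriptor; w: odd-length kernel, zero padded.
  k <- length(w)
  h <- (k - 1L) %/% 2L
  C <- nrow(v)
  y <- matrix(0, C, ncol(v))
  for (j in seq_len(k)) {
    off <- j - 1L - h
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    if (any(ok)) y[ok, ] <- y[ok, ] + w[j] * v[src[ok], , drop = FALSE]
  }
  y
}

eca1d_bwd <- function(v, w, dy) {
  k <- length(w)
  h <- (k - 1L) %/% 2L
  C <- nrow(v)
  dv <- matrix(0, C, ncol(v))
  dw <- numeric(k)
  for (j in seq_len(k)) {
    off <- j - 1L - h
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    if (any(ok)) {
      dv[src[ok], ] <- dv[src[ok], , drop = FALSE] + w[j] * dy[ok, , drop = FALSE]
      dw[j] <- sum(dy[ok, , drop = FALSE] * v[src[ok], , drop = FALSE])
    }
  }
  list(dv = dv, dw = dw)
}

# Per-image channel means: returns C x N matrix.
gap_channels <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, nrow = d[1] * d[2]))
  matrix(m, d[3], d[4])
}

#' Efficient channel attention forward pass
#'
#' Global average pooling reduces the map to a per-channel descriptor, a
#' zero-padded 1-D convolution of kernel `k` mixes neighbouring channels,
#' and a sigmoid gate rescales each input channel. Output shape equals the
#' input shape.
#'
#' @param x array `(H, W, C)` or `(H, W, C, N)`.
#' @param w length-`k` 1-D convolution weights (`k` odd, typically from
#'   [eca_kernel_size()]).
#' @return gated array, same shape as `x`.
#' @export
eca_forward <- function(x, w) {
  x <- lift4d(x)
  if (length(w) %% 2L != 1L) stop("eca_forward: kernel length must be odd")
  d <- dim(x)
  v <- gap_channels(x)
  g <- sigmoid(eca1d_fwd(v, w))
  y <- x * rep(as.vector(g), each = d[1] * d[2])
  attr(y, "was3d") <- attr(x, "was3d")
  drop4d(y, x)
}

#' Ghost module forward pass
#'
#' The primary convolution produces the `n/s` real channels; each of the
#' `s - 1` cheap depthwise transforms maps the real channels to a ghost
#' copy; the concatenation gives the `n` output channels. Raw convolutions
#' only — in a network the builder interleaves batch norm and activations.
#'
#' @param x input map `(H, W, c)` or `(H, W, c, N)`.
#' @param spec a [ghost_spec()].
#' @param weights list with `primary` (`(k, k, c, n/s)` kernel) and, for
#'   `s > 1`, `cheap` (`(3, 3, n/s, s - 1)`: one depthwise kernel set per
#'   ghost copy).
#' @return array with `n` channels.
#' @export
ghost_module_forward <- function(x, spec, weights) {
  x <- lift4d(x)
  if (dim(x)[3] != spec$c) stop("ghost_module_forward: input channel mismatch")
  m <- spec$n %/% spec$s
  p <- conv2d(x, weights$primary, stride = spec$stride)
  parts <- list(p)
  if (spec$s > 1L) {
    for (j in seq_len(spec$s - 1L)) {
      parts[[j + 1L]] <- dwconv2d(p, weights$cheap[, , , j])
    }
  }
  y <- cat_channels(lapply(parts, lift4d))
  stopifnot(dim(y)[3] == spec$n)
  attr(y, "was3d") <- attr(x, "was3d")
  drop4d(y, x)
}

#' Ghost-ECA (GE) bottleneck forward pass
#'
#' The residual unit used by the lightweight backbone: ghost module (with
#' activation), optional stride-2 depthwise downsampling, efficient channel
#' attention, second ghost module (linear), plus a shortcut (identity at
#' stride 1 with matching channels, depthwise + pointwise projection
#' otherwise).
#'
#' @param x input map.
#' @param config list with `cin`, `cout`, `stride` (1 or 2), `s` (ghost
#'   split, default 2) and `act` (activation name, default `"silu"`).
#' @param weights list with `gm1`, `gm2` (each a [ghost_module_forward()]
#'   weight list), `eca` (1-D kernel or `NULL` to skip attention), `dw`
#'   (stride-2 depthwise kernel, stride-2 blocks only) and `short`
#'   (`list(dw, pw)` projection weights when the shortcut is not identity).
#' @return array with `cout` channels.
#' @export
ge_block_forward <- function(x, config, weights) {
  x <- lift4d(x)
  stride <- config[["stride"]] %||% 1L
  if (!stride %in% c(1L, 2L)) stop("ge_block_forward: stride must be 1 or 2")
  s <- config[["s"]] %||% 2L # exact indexing: $s would partial-match $stride
  act <- config[["act"]] %||% "silu"
  mid <- config[["mid"]] %||% config[["cout"]]
  sp1 <- ghost_spec(config[["cin"]], mid, s = s)
  sp2 <- ghost_spec(mid, config[["cout"]], s = s)
  t <- act_fwd(act, ghost_module_forward(x, sp1, weights$gm1))
  t <- lift4d(t)
  if (stride == 2L) t <- lift4d(dwconv2d(t, weights$dw, stride = 2L))
  if (!is.null(weights$eca)) t <- lift4d(eca_forward(t, weights$eca))
  t <- lift4d(ghost_module_forward(t, sp2, weights$gm2))
  if (stride == 1L && config[["cin"]] == config[["cout"]]) {
    sc <- x
  } else {
    sc <- lift4d(dwconv2d(x, weights$short$dw, stride = stride))
    sc <- lift4d(conv2d(sc, weights$short$pw))
  }
  y <- t + sc
  attr(y, "was3d") <- attr(x, "was3d")
  drop4d(y, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adaptive spatial feature fusion of three pyramid levels
#'
#' Resizes the two non-target levels to the target level's shape
#' (1x1-convolution channel compression, then nearest-neighbour upsampling
#' toward finer targets or stacked stride-2 3x3 convolutions toward coarser
#' ones), derives per-position weight logits, normalizes them with a
#' softmax so the three weights form a simplex at every position, and
#' returns the weighted blend. For already-aligned inputs the `logits` map
#' can be supplied directly, which exposes the bare fusion rule.
#'
#' @param levels list of three maps `(H_l, W_l, C_l)`, finest (stride 8)
#'   first.
#' @param target_level 1, 2 or 3.
#' @param weights list with `compress` (per-level 1x1 kernels, `NULL` for
#'   the target), `down` (per-level list of stride-2 3x3 kernels where
#'   downsampling is needed) and `logit` (`list(w, b)`: 1x1 kernel over the
#'   three stacked resized maps producing 3 logit channels). Ignored when
#'   `logits` is given and levels are aligned.
#' @param logits optional `(H_t, W_t, 3)` array of raw fusion logits.
#' @return fused map with the target level's shape.
#' @export
asff_fuse <- function(levels, target_level, weights = NULL, logits = NULL) {
  stopifnot(length(levels) == 3, target_level %in% 1:3)
  tgt <- lift4d(levels[[target_level]])
  td <- dim(tgt)
  xs <- vector("list", 3)
  for (s in 1:3) {
    x <- lift4d(levels[[s]])
    if (s != target_level) {
      if (!is.null(weights$compress[[s]])) {
        x <- lift4d(conv2d(x, weights$compress[[s]]))
      }
      if (dim(x)[1] < td[1]) {
        x <- upsample_nearest(x, td[1] %/% dim(x)[1])
      } else if (dim(x)[1] > td[1] && !is.null(weights$down[[s]])) {
        for (j in seq_along(weights$down[[s]])) {
          x <- lift4d(conv2d(x, weights$down[[s]][[j]], stride = 2L))
        }
      }
    }
    if (!all(dim(x)[1:3] == td[1:3])) {
      stop("asff_fuse: level ", s, " does not match the target shape ",
           "after compression and resizing")
    }
    xs[[s]] <- x
  }
  if (is.null(logits)) {
    cat3 <- cat_channels(xs)
    logits <- conv2d(cat3, weights$logit$w, weights$logit$b)
  } else {
    logits <- lift4d(logits)
  }
  mx <- pmax(logits[, , 1, , drop = FALSE], logits[, , 2, , drop = FALSE],
             logits[, , 3, , drop = FALSE])
  e1 <- exp(logits[, , 1, , drop = FALSE] - mx)
  e2 <- exp(logits[, , 2, , drop = FALSE] - mx)
  e3 <- exp(logits[, , 3, , drop = FALSE] - mx)
  tot <- e1 + e2 + e3
  bc <- function(w) w[, , rep(1L, td[3]), , drop = FALSE]
  y <- bc(e1 / tot) * xs[[1]] + bc(e2 / tot) * xs[[2]] + bc(e3 / tot) * xs[[3]]
  attr(y, "was3d") <- attr(lift4d(levels[[target_level]]), "was3d")
  drop4d(y, lift4d(levels[[target_level]]))
}
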