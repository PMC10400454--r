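# Layer-graph representation of a detector. A network is a topologically
# ordered named list of layer records plus bookkeeping; forward and backward
# passes walk the list. This stays deliberately close to how the field's
# detector codebases are organized (explicit modules, no autodiff DSL): every
# layer type has a hand-written gradient.

new_netbuilder <- function() {
  nb <- new.env(parent = emptyenv())
  nb$layers <- list()
  nb
}

add_layer <- function(nb, name, type, inputs = character(), ...) {
  if (!is.null(nb$layers[[name]])) stop("duplicate layer name: ", name)
  nb$layers[[name]] <- c(list(name = name, type = type, inputs = inputs), list(...))
  name
}

finish_net <- function(nb, outputs, config, strides = c(8L, 16L, 32L)) {
  structure(list(
    layers = nb$layers,
    outputs = outputs,
    strides = strides,
    config = config,
    initialized = isTRUE(nb$initialized),
    pruned_removed = 0L
  ), class = "pest_net")
}

#' @export
print.pest_net <- function(x, ...) {
  cfg <- x$config
  cat("<pest_net> ", cfg$variant %||% "custom",
      " | backbone=", cfg$backbone, " neck=", cfg$neck,
      " head_act=", cfg$head_activation,
      " classes=", cfg$num_classes, "\n", sep = "")
  cat("  layers: ", length(x$layers),
      " | learnable parameters: ", format(count_params(x), big.mark = ","),
      if (!x$initialized) " (weights not allocated)", "\n", sep = "")
  invisible(x)
}

layer_param_sizes <- function(l) {
  switch(l$type,
    conv = c(w = l$k * l$k * l$cin * l$cout, b = if (isTRUE(l$bias)) l$cout else 0),
    dwconv = c(w = l$k * l$k * l$c),
    bn = c(gamma = l$c, beta = l$c),
    eca = c(w = l$k),
    numeric(0)
  )
}

#' Count learnable parameters
#'
#' Enumerates every learnable tensor in the network (convolution kernels,
#' biases, batch-norm scale and shift, ECA kernels) and sums their sizes.
#' The count is independent of input size and of whether weight arrays have
#' been allocated.
#'
#' @param net a `pest_net` from [build_model()].
#' @return total learnable parameter count.
#' @export
count_params <- function(net) {
  sum(vapply(net$layers, function(l) sum(layer_param_sizes(l)), 0))
}

# Shape inference: list name -> c(H, W, C) for a given square input size.
net_shapes <- function(net, input_size = NULL) {
  input_size <- input_size %||% net$config$input_size
  sh <- list()
  for (l in net$layers) {
    sh[[l$name]] <- switch(l$type,
      input = c(input_size, input_size, l$channels),
      conv = {
        s <- sh[[l$inputs]]
        pad <- l$pad %||% ((l$k - 1L) %/% 2L)
        c(conv_out_dim(s[1], l$k, l$stride, pad),
          conv_out_dim(s[2], l$k, l$stride, pad), l$cout)
      },
      dwconv = {
        s <- sh[[l$inputs]]
        pad <- (l$k - 1L) %/% 2L
        c(conv_out_dim(s[1], l$k, l$stride, pad),
          conv_out_dim(s[2], l$k, l$stride, pad), l$c)
      },
      bn = sh[[l$inputs]],
      act = sh[[l$inputs]],
      eca = sh[[l$inputs]],
      maxpool = sh[[l$inputs]],
      upsample = {
        s <- sh[[l$inputs]]
        c(s[1] * l$f, s[2] * l$f, s[3])
      },
      focus = {
        s <- sh[[l$inputs]]
        c(s[1] %/% 2L, s[2] %/% 2L, s[3] * 4L)
      },
      concat = {
        ss <- lapply(l$inputs, function(nm) sh[[nm]])
        c(ss[[1]][1], ss[[1]][2], sum(vapply(ss, function(s) s[3], 1)))
      },
      add = sh[[l$inputs[1]]],
      asff = sh[[l$inputs[1]]],
      stop("shape inference: unknown layer type ", l$type)
    )
  }
  sh
}

#' Per-layer summary table
#'
#' Emits one row per layer with output spatial size, kernel size, channel
#' fan-in/out, learnable parameters and convolution FLOPs under the
#' `2 * H * W * (C_in * K^2 + 1) * C_out` convention (applied to 2-D
#' convolutions; other layer types are counted as zero-FLOP plumbing, the
#' usual convention for conv-dominated detectors).
#'
#' @param net a `pest_net`.
#' @param input_size square input size in pixels (default: the model
#'   config's).
#' @return a `data.frame`.
#' @export
summarize_layers <- function(net, input_size = NULL) {
  sh <- net_shapes(net, input_size)
  rows <- lapply(net$layers, function(l) {
    s <- sh[[l$name]]
    k <- l$k %||% NA_integer_
    cin <- switch(l$type,
      conv = l$cin, dwconv = l$c,
      if (length(l$inputs)) sh[[l$inputs[1]]][3] else NA_integer_)
    fl <- switch(l$type,
      conv = 2 * s[1] * s[2] * (l$cin * l$k^2 + 1) * l$cout,
      dwconv = 2 * s[1] * s[2] * (l$k^2 + 1) * l$c,
      0)
    data.frame(layer = l$name, type = l$type, H = s[1], W = s[2],
               K = if (is.null(k)) NA_integer_ else k,
               C_in = cin, C_out = s[3],
               params = sum(layer_param_sizes(l)), flops = fl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count forward-pass FLOPs
#'
#' Sums `2 * H * W * (C_in * K^2 + 1) * C_out` over all convolutions and
#' also reports the multiply-accumulate count (half of it), since published
#' tables mix the two conventions.
#'
#' @inheritParams summarize_layers
#' @return `list(flops =, macs =)`.
#' @export
count_flops <- function(net, input_size = NULL) {
  tab <- summarize_layers(net, input_size)
  fl <- sum(tab$flops)
  list(flops = fl, macs = fl / 2)
}

# ---- weight initialization ---------------------------------------------

net_init_params <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    l <- switch(l$type,
      conv = {
        sd <- sqrt(2 / (l$k * l$k * l$cin))
        l$w <- array(rnorm(l$k * l$k * l$cin * l$cout, sd = sd),
                     c(l$k, l$k, l$cin, l$cout))
        if (isTRUE(l$bias)) {
          l$b <- rep(l$bias_init %||% 0, l$cout)
        }
        l
      },
      dwconv = {
        sd <- sqrt(2 / (l$k * l$k))
        l$w <- array(rnorm(l$k * l$k * l$c, sd = sd), c(l$k, l$k, l$c))
        l
      },
      bn = {
        l$gamma <- rep(1, l$c)
        l$beta <- rep(0, l$c)
        l$rmean <- rep(0, l$c)
        l$rvar <- rep(1, l$c)
        l
      },
      eca = {
        l$w <- rnorm(l$k, sd = sqrt(1 / l$k))
        l
      },
      l
    )
    net$layers[[nm]] <- l
  }
  net$initialized <- TRUE
  net
}

# ---- forward -----------------------------------------------------------

# Add the constant contribution of pruned-away input channels back onto a
# convolution output. Static folds convolve the removed channels' constant
# values with the retained kernel slices (cached per input size, exact under
# zero padding); dynamic folds cover constants that pass through an ECA gate
# upstream (1x1 consumers), whose scale is a per-image scalar.
apply_fold <- function(y, l, xdim, acts) {
  f <- l$fold
  if (is.null(f)) return(y)
  d <- dim(y)
  if (!is.null(f$static) && any(f$static$v != 0)) {
    key <- paste0("..fold.", l$name, ".", xdim[1], "x", xdim[2])
    corr <- acts$foldcache[[key]]
    if (is.null(corr)) {
      nd <- length(f$static$v)
      cm <- array(rep(f$static$v, each = xdim[1] * xdim[2]),
                  c(xdim[1], xdim[2], nd, 1L))
      corr <- conv2d(cm, f$static$w, stride = l$stride,
                     pad = l$pad %||% ((l$k - 1L) %/% 2L))
      acts$foldcache[[key]] <- corr
    }
    y <- y + array(corr, d) # recycles the single-image map over the batch
  }
  if (!is.null(f$dynamic)) {
    g <- acts[[paste0(f$dynamic$eca, "..removed_gates")]] # ndrop x N
    g <- g[f$dynamic$pos, , drop = FALSE]
    add <- t(f$dynamic$S) %*% (f$dynamic$v * g) # cout x N
    y <- y + rep(as.vector(add), each = d[1] * d[2])
  }
  y
}

net_forward <- function(net, x, train = FALSE, frozen_modules = character()) {
  if (!net$initialized) {
    stop("network weights are not allocated; build with init = TRUE or call net_init_params()")
  }
  acts <- new.env(parent = emptyenv())
  acts$foldcache <- new.env(parent = emptyenv())
  caches <- if (train) new.env(parent = emptyenv()) else NULL
  bn_updates <- if (train) list() else NULL
  x <- lift4d(x)
  attr(x, "was3d") <- NULL
  for (l in net$layers) {
    y <- switch(l$type,
      input = x,
      conv = {
        xin <- acts[[l$inputs]]
        if (train) {
          cc <- conv2d_train(xin, l$w, l$b, l$stride, l$pad)
          cc$y <- apply_fold(cc$y, l, dim(xin), acts)
          caches[[l$name]] <- cc[intersect(names(cc),
            c("cols", "x", "fast", "xdim", "k", "stride", "pad"))]
          cc$y
        } else {
          y0 <- conv2d(xin, l$w, l$b, l$stride, l$pad)
          apply_fold(y0, l, dim(xin), acts)
        }
      },
      dwconv = {
        xin <- acts[[l$inputs]]
        if (train) caches[[l$name]] <- list(xdim = dim(xin))
        dwconv2d(xin, l$w, l$stride)
      },
      bn = {
        xin <- acts[[l$inputs]]
        if (train && !(l$module %in% frozen_modules)) {
          bf <- bn_train_fwd(xin, l$gamma, l$beta, l$eps)
          caches[[l$name]] <- bf[c("xhat", "invstd", "mean", "var", "m")]
          mom <- l$momentum
          n <- bf$m
          bn_updates[[l$name]] <- list(
            rmean = (1 - mom) * l$rmean + mom * bf$mean,
            rvar = (1 - mom) * l$rvar + mom * bf$var * n / max(n - 1, 1)
          )
          bf$y
        } else {
          bn_forward(xin, l$gamma, l$beta, l$rmean, sqrt(l$rvar), l$eps)
        }
      },
      act = {
        xin <- acts[[l$inputs]]
        act_fwd(l$fun, xin)
      },
      eca = {
        xin <- acts[[l$inputs]]
        d <- dim(xin)
        v <- gap_channels(xin)
        if (!is.null(l$removed)) {
          vf <- matrix(0, l$c_orig, d[4])
          vf[l$kept_pos, ] <- v
          vf[l$removed$pos, ] <- l$removed$const
          pre <- eca1d_fwd(vf, l$w)
          g_full <- sigmoid(pre)
          acts[[paste0(l$name, "..removed_gates")]] <- g_full[l$removed$pos, , drop = FALSE]
          g <- g_full[l$kept_pos, , drop = FALSE]
        } else {
          vf <- v
          pre <- eca1d_fwd(v, l$w)
          g <- sigmoid(pre)
        }
        if (train) caches[[l$name]] <- list(x = xin, v = v, vf = vf, g = g)
        xin * rep(as.vector(g), each = d[1] * d[2])
      },
      maxpool = {
        xin <- acts[[l$inputs]]
        mp <- maxpool2d(xin, l$k, l$stride, l$pad)
        if (train) caches[[l$name]] <- list(idx = mp$idx, xdim = dim(xin))
        mp$y
      },
      upsample = upsample_nearest(acts[[l$inputs]], l$f),
      focus = focus_forward(acts[[l$inputs]]),
      concat = {
        xs <- lapply(l$inputs, function(nm) acts[[nm]])
        if (train) caches[[l$name]] <- list(sizes = vapply(xs, function(z) dim(z)[3], 1L))
        cat_channels(xs)
      },
      add = acts[[l$inputs[1]]] + acts[[l$inputs[2]]],
      asff = {
        xs <- lapply(l$inputs[1:3], function(nm) acts[[nm]])
        lg <- acts[[l$inputs[4]]]
        d <- dim(xs[[1]])
        # stable softmax over the 3 logit channels
        mx <- pmax(lg[, , 1, , drop = FALSE], lg[, , 2, , drop = FALSE],
                   lg[, , 3, , drop = FALSE])
        e1 <- exp(lg[, , 1, , drop = FALSE] - mx)
        e2 <- exp(lg[, , 2, , drop = FALSE] - mx)
        e3 <- exp(lg[, , 3, , drop = FALSE] - mx)
        tot <- e1 + e2 + e3
        w1 <- e1 / tot; w2 <- e2 / tot; w3 <- e3 / tot
        bc <- function(w) w[, , rep(1L, d[3]), , drop = FALSE]
        if (train) caches[[l$name]] <- list(w = list(w1, w2, w3), xs = xs)
        bc(w1) * xs[[1]] + bc(w2) * xs[[2]] + bc(w3) * xs[[3]]
      },
      stop("forward: unknown layer type ", l$type)
    )
    acts[[l$name]] <- y
  }
  list(outs = lapply(stats::setNames(net$outputs, net$outputs),
                     function(nm) acts[[nm]]),
       acts = acts, caches = caches, bn_updates = bn_updates)
}

# ---- backward ----------------------------------------------------------

# douts: named list (output layer name -> gradient array). Returns an env of
# parameter gradients keyed layer name, each a list(dw=, db=, dgamma=, ...).
# Gradient flow stops wherever no unfrozen parameter remains upstream.
net_backward <- function(net, fw, douts, frozen_modules = character()) {
  acts <- fw$acts
  caches <- fw$caches
  grads <- new.env(parent = emptyenv())
  dacc <- new.env(parent = emptyenv())
  for (nm in names(douts)) dacc[[nm]] <- douts[[nm]]
  layers <- net$layers
  has_params <- c(conv = TRUE, dwconv = TRUE, bn = TRUE, eca = TRUE)
  need <- logical(length(layers))
  names(need) <- names(layers)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    own <- isTRUE(has_params[l$type]) && !(l$module %in% frozen_modules)
    need[i] <- own || (length(l$inputs) && any(need[l$inputs]))
  }
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    dy <- dacc[[l$name]]
    if (is.null(dy)) next
    rm(list = l$name, envir = dacc)
    addg <- function(nm, g) {
      if (!need[nm]) return(invisible(NULL))
      cur <- dacc[[nm]]
      dacc[[nm]] <- if (is.null(cur)) g else cur + g
    }
    fro <- l$module %in% frozen_modules
    switch(l$type,
      input = NULL,
      conv = {
        need_dx <- need[l$inputs]
        bw <- conv2d_bwd(caches[[l$name]], l$w, dy, need_dx = need_dx)
        if (!fro) grads[[l$name]] <- list(
          dw = bw$dw, db = if (isTRUE(l$bias)) bw$db else NULL)
        if (need_dx) addg(l$inputs, bw$dx)
      },
      dwconv = {
        xin <- acts[[l$inputs]]
        bw <- dwconv_bwd_cpp(xin, l$w, dy, as.integer(l$stride),
                             as.integer((l$k - 1L) %/% 2L))
        if (!fro) grads[[l$name]] <- list(dw = bw$dw)
        addg(l$inputs, bw$dx)
      },
      bn = {
        bw <- bn_bwd(caches[[l$name]], l$gamma, dy)
        if (!fro) grads[[l$name]] <- list(dgamma = bw$dgamma, dbeta = bw$dbeta)
        addg(l$inputs, bw$dx)
      },
      act = {
        xin <- acts[[l$inputs]]
        addg(l$inputs, dy * act_bwd(l$fun, xin))
      },
      eca = {
        cc <- caches[[l$name]]
        d <- dim(cc$x)
        gb <- rep(as.vector(cc$g), each = d[1] * d[2])
        dx <- dy * gb
        dgchan <- chan_sum_per_image(dy * cc$x) # C x N
        dpre_kept <- dgchan * cc$g * (1 - cc$g)
        if (!is.null(l$removed)) {
          dpre <- matrix(0, l$c_orig, d[4])
          dpre[l$kept_pos, ] <- dpre_kept
        } else {
          dpre <- dpre_kept
        }
        bw <- eca1d_bwd(cc$vf, l$w, dpre)
        dv <- if (!is.null(l$removed)) bw$dv[l$kept_pos, , drop = FALSE] else bw$dv
        dx <- dx + rep(as.vector(dv), each = d[1] * d[2]) / (d[1] * d[2])
        if (!fro) grads[[l$name]] <- list(dw = bw$dw)
        addg(l$inputs, dx)
      },
      maxpool = {
        cc <- caches[[l$name]]
        addg(l$inputs, maxpool_bwd_cpp(dy, cc$idx, cc$xdim[1], cc$xdim[2],
                                       cc$xdim[3], cc$xdim[4]))
      },
      upsample = addg(l$inputs, upsample_nearest_bwd(dy, l$f)),
      focus = addg(l$inputs, focus_inverse(dy)),
      concat = {
        cc <- caches[[l$name]]
        parts <- split_channels(dy, cc$sizes)
        for (j in seq_along(l$inputs)) addg(l$inputs[j], parts[[j]])
      },
      add = {
        addg(l$inputs[1], dy)
        addg(l$inputs[2], dy)
      },
      asff = {
        cc <- caches[[l$name]]
        d <- dim(cc$xs[[1]])
        bc <- function(w) w[, , rep(1L, d[3]), , drop = FALSE]
        dws <- vector("list", 3)
        for (j in 1:3) {
          addg(l$inputs[j], dy * bc(cc$w[[j]]))
          dws[[j]] <- apply(dy * cc$xs[[j]], c(1, 2, 4), sum) # H x W x N
        }
        wsum <- cc$w[[1]] * 0
        for (j in 1:3) wsum <- wsum + array(dws[[j]], dim(cc$w[[j]])) * cc$w[[j]]
        dlg <- array(0, c(d[1], d[2], 3, d[4]))
        for (j in 1:3) {
          dlg[, , j, ] <- cc$w[[j]] * (array(dws[[j]], dim(cc$w[[j]])) - wsum)
        }
        addg(l$inputs[4], dlg)
      },
      stop("backward: unknown layer type ", l$type)
    )
  }
  grads
}

# Sum over spatial dims only: returns C x N.
chan_sum_per_image <- function(x) {
  d <- dim(x)
  matrix(colSums(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
}

#' Run a forward pass
#'
#' Evaluates the detector on one image or a batch and returns the three raw
#' head output maps (strides 8/16/32), each with `4 + 1 + num_classes`
#' channels per location.
#'
#' @param net an initialized `pest_net`.
#' @param x image array `(H, W, 3)` or `(H, W, 3, N)`, values in `[0, 1]`.
#' @return named list of head output arrays.
#' @export
predict_raw <- function(net, x) {
  net_forward(net, x, train = FALSE)$outs
}
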