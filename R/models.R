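# Model configuration and network assembly.

#' Model configuration
#'
#' Describes a detector variant by its depth/width multipliers, backbone and
#' neck kinds, head activation and class count. Named presets cover the
#' standard reference variants (`"yolox-s"`, `"yolox-m"`, `"yolox-l"`,
#' `"yolox-x"`: CSPDarknet + PAFPN + SiLU, 80-class heads) and the
#' lightweight pest detector (`"pest"`: GhostNet-GE backbone, ASFF-augmented
#' neck, TS-activated heads, 2 classes; `"pest-nano"` is the same design at
#' desk scale: width 0.125, depth 0.11, 256 px input).
#'
#' @param variant preset name, or `NULL` to specify fields directly.
#' @param depth_multiplier,width_multiplier positive scaling of stage depth
#'   and channel width.
#' @param backbone `"cspdarknet"` or `"ghostnet_ge"`.
#' @param neck `"pafpn"` or `"pafpn_asff"`.
#' @param head_activation `"silu"` or `"ts"`.
#' @param num_classes number of object classes (`>= 1`).
#' @param input_size square input size, divisible by 32.
#' @return a `model_config` list.
#' @export
model_config <- function(variant = NULL, depth_multiplier = NULL,
                         width_multiplier = NULL,
                         backbone = c("cspdarknet", "ghostnet_ge"),
                         neck = c("pafpn", "pafpn_asff"),
                         head_activation = c("silu", "ts"),
                         num_classes = NULL, input_size = NULL) {
  presets <- list(
    "yolox-s" = list(0.33, 0.50, "cspdarknet", "pafpn", "silu", 80L, 640L),
    "yolox-m" = list(0.67, 0.75, "cspdarknet", "pafpn", "silu", 80L, 640L),
    "yolox-l" = list(1.00, 1.00, "cspdarknet", "pafpn", "silu", 80L, 640L),
    "yolox-x" = list(1.33, 1.25, "cspdarknet", "pafpn", "silu", 80L, 640L),
    "pest" = list(0.33, 0.50, "ghostnet_ge", "pafpn_asff", "ts", 2L, 640L),
    "pest-nano" = list(0.11, 0.125, "ghostnet_ge", "pafpn_asff", "ts", 2L, 256L)
  )
  if (!is.null(variant)) {
    p <- presets[[variant]]
    if (is.null(p)) {
      stop("unknown variant '", variant, "'; available: ",
           paste(names(presets), collapse = ", "))
    }
    depth_multiplier <- depth_multiplier %||% p[[1]]
    width_multiplier <- width_multiplier %||% p[[2]]
    backbone <- if (missing(backbone)) p[[3]] else match.arg(backbone)
    neck <- if (missing(neck)) p[[4]] else match.arg(neck)
    head_activation <- if (missing(head_activation)) p[[5]] else match.arg(head_activation)
    num_classes <- num_classes %||% p[[6]]
    input_size <- input_size %||% p[[7]]
  } else {
    backbone <- match.arg(backbone)
    neck <- match.arg(neck)
    head_activation <- match.arg(head_activation)
    num_classes <- num_classes %||% 2L
    input_size <- input_size %||% 640L
  }
  if (is.null(depth_multiplier) || is.null(width_multiplier) ||
      depth_multiplier <= 0 || width_multiplier <= 0) {
    stop("model_config: multipliers must be positive")
  }
  if (num_classes < 1L) stop("model_config: num_classes must be >= 1")
  if (input_size %% 32L != 0L) stop("model_config: input_size must be divisible by 32")
  structure(list(variant = variant %||% "custom",
                 depth_multiplier = depth_multiplier,
                 width_multiplier = width_multiplier,
                 backbone = backbone, neck = neck,
                 head_activation = head_activation,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size)),
            class = "model_config")
}

# ---- shared building blocks --------------------------------------------

conv_unit <- function(nb, prefix, from, cin, cout, k, stride = 1L,
                      act = "silu", module = "backbone", prunable = TRUE) {
  cv <- add_layer(nb, paste0(prefix, ".conv"), "conv", from,
                  k = as.integer(k), stride = as.integer(stride),
                  pad = (as.integer(k) - 1L) %/% 2L,
                  cin = as.integer(cin), cout = as.integer(cout),
                  bias = FALSE, module = module)
  bn <- add_layer(nb, paste0(prefix, ".bn"), "bn", cv,
                  c = as.integer(cout), eps = 1e-5, momentum = 0.1,
                  prunable = prunable, module = module)
  add_layer(nb, paste0(prefix, ".act"), "act", bn, fun = act, module = module)
}

csp_layer <- function(nb, prefix, from, cin, cout, n, shortcut = TRUE,
                      act = "silu", module = "backbone") {
  h <- cout %/% 2L
  c1 <- conv_unit(nb, paste0(prefix, ".conv1"), from, cin, h, 1L, 1L, act, module)
  c2 <- conv_unit(nb, paste0(prefix, ".conv2"), from, cin, h, 1L, 1L, act, module)
  cur <- c1
  for (i in seq_len(n)) {
    b1 <- conv_unit(nb, paste0(prefix, ".b", i, ".conv1"), cur, h, h, 1L, 1L, act, module)
    b2 <- conv_unit(nb, paste0(prefix, ".b", i, ".conv2"), b1, h, h, 3L, 1L, act, module)
    if (shortcut) {
      cur <- add_layer(nb, paste0(prefix, ".b", i, ".add"), "add", c(cur, b2),
                       module = module)
    } else {
      cur <- b2
    }
  }
  cat <- add_layer(nb, paste0(prefix, ".cat"), "concat", c(cur, c2), module = module)
  conv_unit(nb, paste0(prefix, ".conv3"), cat, 2L * h, cout, 1L, 1L, act, module)
}

spp_block <- function(nb, prefix, from, cin, cout, act = "silu",
                      module = "backbone") {
  h <- cin %/% 2L
  c1 <- conv_unit(nb, paste0(prefix, ".conv1"), from, cin, h, 1L, 1L, act, module)
  pools <- vapply(c(5L, 9L, 13L), function(k) {
    add_layer(nb, paste0(prefix, ".pool", k), "maxpool", c1,
              k = k, stride = 1L, pad = (k - 1L) %/% 2L, module = module)
  }, "")
  cat <- add_layer(nb, paste0(prefix, ".cat"), "concat", c(c1, pools),
                   module = module)
  conv_unit(nb, paste0(prefix, ".conv2"), cat, 4L * h, cout, 1L, 1L, act, module)
}

# Ghost module as layers: primary 1x1 conv-bn-act on m = cout/2 channels,
# cheap depthwise 3x3 (bn + same activation) ghost copy, concatenated.
ghost_module_layers <- function(nb, prefix, from, cin, cout, act, module,
                                stride = 1L) {
  m <- cout %/% 2L
  p <- conv_unit(nb, paste0(prefix, ".primary"), from, cin, m, 1L, stride, act, module)
  dw <- add_layer(nb, paste0(prefix, ".cheap.dw"), "dwconv", p,
                  k = 3L, stride = 1L, c = m, module = module)
  dbn <- add_layer(nb, paste0(prefix, ".cheap.bn"), "bn", dw,
                   c = m, eps = 1e-5, momentum = 0.1, prunable = TRUE,
                   module = module)
  g <- add_layer(nb, paste0(prefix, ".cheap.act"), "act", dbn, fun = act,
                 module = module)
  add_layer(nb, paste0(prefix, ".cat"), "concat", c(p, g), module = module)
}

# Ghost-ECA bottleneck: gm1 -> (stride-2 depthwise) -> ECA -> gm2 (linear)
# with residual shortcut.
ge_block_layers <- function(nb, prefix, from, cin, cout, stride, act, module) {
  mid <- cout
  t <- ghost_module_layers(nb, paste0(prefix, ".gm1"), from, cin, mid, act, module)
  if (stride == 2L) {
    dw <- add_layer(nb, paste0(prefix, ".down.dw"), "dwconv", t,
                    k = 3L, stride = 2L, c = mid, module = module)
    t <- add_layer(nb, paste0(prefix, ".down.bn"), "bn", dw,
                   c = mid, eps = 1e-5, momentum = 0.1, prunable = TRUE,
                   module = module)
  }
  t <- add_layer(nb, paste0(prefix, ".eca"), "eca", t,
                 k = eca_kernel_size(mid), module = module)
  t <- ghost_module_layers(nb, paste0(prefix, ".gm2"), t, mid, cout,
                           "identity", module)
  if (stride == 1L && cin == cout) {
    sc <- from
  } else {
    sdw <- add_layer(nb, paste0(prefix, ".short.dw"), "dwconv", from,
                     k = 3L, stride = stride, c = cin, module = module)
    sbn <- add_layer(nb, paste0(prefix, ".short.dwbn"), "bn", sdw,
                     c = cin, eps = 1e-5, momentum = 0.1, prunable = FALSE,
                     module = module)
    spw <- add_layer(nb, paste0(prefix, ".short.pw"), "conv", sbn,
                     k = 1L, stride = 1L, pad = 0L, cin = cin, cout = cout,
                     bias = FALSE, module = module)
    sc <- add_layer(nb, paste0(prefix, ".short.bn"), "bn", spw,
                    c = cout, eps = 1e-5, momentum = 0.1, prunable = TRUE,
                    module = module)
  }
  add_layer(nb, paste0(prefix, ".add"), "add", c(t, sc), module = module)
}

# ---- backbones ---------------------------------------------------------

backbone_cspdarknet <- function(nb, W, D, act = "silu") {
  add_layer(nb, "input", "input", character(), channels = 3L, module = "backbone")
  fc <- add_layer(nb, "stem.focus", "focus", "input", module = "backbone")
  stem <- conv_unit(nb, "stem", fc, 12L, W(64), 3L, 1L, act, "backbone",
                    prunable = FALSE)
  d2 <- conv_unit(nb, "dark2.down", stem, W(64), W(128), 3L, 2L, act)
  d2 <- csp_layer(nb, "dark2.csp", d2, W(128), W(128), D(3), TRUE, act)
  d3 <- conv_unit(nb, "dark3.down", d2, W(128), W(256), 3L, 2L, act)
  c3 <- csp_layer(nb, "dark3.csp", d3, W(256), W(256), D(9), TRUE, act)
  d4 <- conv_unit(nb, "dark4.down", c3, W(256), W(512), 3L, 2L, act)
  c4 <- csp_layer(nb, "dark4.csp", d4, W(512), W(512), D(9), TRUE, act)
  d5 <- conv_unit(nb, "dark5.down", c4, W(512), W(1024), 3L, 2L, act)
  d5 <- spp_block(nb, "dark5.spp", d5, W(1024), W(1024), act)
  c5 <- csp_layer(nb, "dark5.csp", d5, W(1024), W(1024), D(3), FALSE, act)
  list(c3 = c3, c4 = c4, c5 = c5)
}

backbone_ghostnet_ge <- function(nb, W, D, act = "silu") {
  add_layer(nb, "input", "input", character(), channels = 3L, module = "backbone")
  fc <- add_layer(nb, "stem.focus", "focus", "input", module = "backbone")
  stem <- conv_unit(nb, "stem", fc, 12L, W(64), 3L, 1L, act, "backbone",
                    prunable = FALSE)
  stage <- function(prefix, from, cin, cout, n) {
    cur <- ge_block_layers(nb, paste0(prefix, ".ge1"), from, cin, cout, 2L,
                           act, "backbone")
    for (i in seq_len(max(n - 1L, 0L))) {
      cur <- ge_block_layers(nb, paste0(prefix, ".ge", i + 1L), cur, cout,
                             cout, 1L, act, "backbone")
    }
    cur
  }
  s2 <- stage("gstage2", stem, W(64), W(128), D(3))
  c3 <- stage("gstage3", s2, W(128), W(256), D(9))
  c4 <- stage("gstage4", c3, W(256), W(512), D(9))
  s5 <- ge_block_layers(nb, "gstage5.ge1", c4, W(512), W(1024), 2L, act, "backbone")
  s5 <- spp_block(nb, "gstage5.spp", s5, W(1024), W(1024), act)
  c5 <- s5
  for (i in seq_len(max(D(3) - 1L, 0L))) {
    c5 <- ge_block_layers(nb, paste0("gstage5.ge", i + 1L), c5, W(1024),
                          W(1024), 1L, act, "backbone")
  }
  list(c3 = c3, c4 = c4, c5 = c5)
}

# ---- neck and heads ----------------------------------------------------

neck_pafpn <- function(nb, W, D, act, bb) {
  lat0 <- conv_unit(nb, "neck.lateral0", bb$c5, W(1024), W(512), 1L, 1L, act, "neck")
  up0 <- add_layer(nb, "neck.up0", "upsample", lat0, f = 2L, module = "neck")
  cat0 <- add_layer(nb, "neck.cat0", "concat", c(up0, bb$c4), module = "neck")
  p4t <- csp_layer(nb, "neck.c3p4", cat0, 2L * W(512), W(512), D(3), FALSE, act, "neck")
  red1 <- conv_unit(nb, "neck.reduce1", p4t, W(512), W(256), 1L, 1L, act, "neck")
  up1 <- add_layer(nb, "neck.up1", "upsample", red1, f = 2L, module = "neck")
  cat1 <- add_layer(nb, "neck.cat1", "concat", c(up1, bb$c3), module = "neck")
  p3 <- csp_layer(nb, "neck.c3p3", cat1, 2L * W(256), W(256), D(3), FALSE, act, "neck")
  bu2 <- conv_unit(nb, "neck.bu2", p3, W(256), W(256), 3L, 2L, act, "neck")
  cat2 <- add_layer(nb, "neck.cat2", "concat", c(bu2, red1), module = "neck")
  p4 <- csp_layer(nb, "neck.c3n3", cat2, 2L * W(256), W(512), D(3), FALSE, act, "neck")
  bu1 <- conv_unit(nb, "neck.bu1", p4, W(512), W(512), 3L, 2L, act, "neck")
  cat3 <- add_layer(nb, "neck.cat3", "concat", c(bu1, lat0), module = "neck")
  p5 <- csp_layer(nb, "neck.c3n4", cat3, 2L * W(512), W(1024), D(3), FALSE, act, "neck")
  list(p3 = p3, p4 = p4, p5 = p5, chans = c(W(256), W(512), W(1024)))
}

# Adaptive spatial feature fusion over the three pyramid levels, applied to
# each output level. Non-target levels are compressed by 1x1 convolution to
# the target's channel count, then resized (nearest-neighbour upsampling to
# finer levels; stacked stride-2 3x3 convolutions to coarser levels). Weight
# logits come from 1x1 convolutions on the resized maps and are softmax
# normalized per position.
asff_attach <- function(nb, W, act, levels, chans) {
  wc <- max(4L, W(16))
  out <- character(3)
  for (t in 1:3) {
    xs <- character(3)
    for (s in 1:3) {
      if (s == t) {
        xs[s] <- levels[[s]]
        next
      }
      cur <- conv_unit(nb, sprintf("asff%d.compress%d", t, s), levels[[s]],
                       chans[s], chans[t], 1L, 1L, act, "neck")
      if (s > t) {
        cur <- add_layer(nb, sprintf("asff%d.up%d", t, s), "upsample", cur,
                         f = 2L^(s - t), module = "neck")
      } else {
        for (j in seq_len(t - s)) {
          cur <- conv_unit(nb, sprintf("asff%d.down%d.%d", t, s, j), cur,
                           chans[t], chans[t], 3L, 2L, act, "neck")
        }
      }
      xs[s] <- cur
    }
    ws <- vapply(1:3, function(s) {
      conv_unit(nb, sprintf("asff%d.wcompress%d", t, s), xs[s],
                chans[t], wc, 1L, 1L, act, "neck")
    }, "")
    wcat <- add_layer(nb, sprintf("asff%d.wcat", t), "concat", ws, module = "neck")
    logits <- add_layer(nb, sprintf("asff%d.wlogits", t), "conv", wcat,
                        k = 1L, stride = 1L, pad = 0L, cin = 3L * wc,
                        cout = 3L, bias = TRUE, module = "neck")
    out[t] <- add_layer(nb, sprintf("asff%d.fuse", t), "asff",
                        c(xs, logits), module = "neck")
  }
  list(p3 = out[1], p4 = out[2], p5 = out[3], chans = chans)
}

heads_decoupled <- function(nb, W, act, num_classes, nk) {
  outs <- character(3)
  ins <- c(nk$p3, nk$p4, nk$p5)
  for (i in 1:3) {
    pre <- sprintf("head%d", i)
    stem <- conv_unit(nb, paste0(pre, ".stem"), ins[i], nk$chans[i], W(256),
                      1L, 1L, act, "head")
    cls <- stem
    for (j in 1:2) {
      cls <- conv_unit(nb, paste0(pre, ".cls", j), cls, W(256), W(256), 3L,
                       1L, act, "head")
    }
    reg <- stem
    for (j in 1:2) {
      reg <- conv_unit(nb, paste0(pre, ".reg", j), reg, W(256), W(256), 3L,
                       1L, act, "head")
    }
    clsp <- add_layer(nb, paste0(pre, ".cls_pred"), "conv", cls,
                      k = 1L, stride = 1L, pad = 0L, cin = W(256),
                      cout = num_classes, bias = TRUE, bias_init = -4.595,
                      module = "head")
    regp <- add_layer(nb, paste0(pre, ".reg_pred"), "conv", reg,
                      k = 1L, stride = 1L, pad = 0L, cin = W(256), cout = 4L,
                      bias = TRUE, module = "head")
    objp <- add_layer(nb, paste0(pre, ".obj_pred"), "conv", reg,
                      k = 1L, stride = 1L, pad = 0L, cin = W(256), cout = 1L,
                      bias = TRUE, bias_init = -4.595, module = "head")
    outs[i] <- add_layer(nb, paste0(pre, ".out"), "concat",
                         c(regp, objp, clsp), module = "head")
  }
  outs
}

#' Build a detector network
#'
#' Assembles the full layer graph for a [model_config()]: backbone
#' (CSPDarknet with Focus stem, CSP stages and SPP, or the lightweight
#' GhostNet of Ghost-ECA bottlenecks), PAFPN neck (optionally followed by
#' adaptive spatial feature fusion of the three levels), and decoupled
#' heads emitting maps at strides 8/16/32 with `4 + 1 + num_classes`
#' channels per location.
#'
#' @param config a [model_config()] (or a preset name).
#' @param init allocate and initialize weight arrays (needed for forward
#'   passes; counting parameters or FLOPs does not require it).
#' @param seed optional RNG seed for weight initialization.
#' @return a `pest_net`.
#' @examples
#' net <- build_model(model_config("yolox-s"), init = FALSE)
#' count_params(net)
#' @export
build_model <- function(config, init = TRUE, seed = NULL) {
  if (is.character(config)) config <- model_config(config)
  stopifnot(inherits(config, "model_config"))
  wm <- config$width_multiplier
  dm <- config$depth_multiplier
  W <- function(c) max(1L, as.integer(c * wm))
  D <- function(n) max(1L, as.integer(round(n * dm)))
  nb <- new_netbuilder()
  bb <- switch(config$backbone,
    cspdarknet = backbone_cspdarknet(nb, W, D, "silu"),
    ghostnet_ge = backbone_ghostnet_ge(nb, W, D, "silu"),
    stop("unknown backbone: ", config$backbone)
  )
  nk <- neck_pafpn(nb, W, D, "silu", bb)
  if (config$neck == "pafpn_asff") nk <- asff_attach(nb, W, "silu", nk, nk$chans)
  outs <- heads_decoupled(nb, W, config$head_activation, config$num_classes, nk)
  net <- finish_net(nb, outs, config)
  if (init) net <- net_init_params(net, seed)
  net
}
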