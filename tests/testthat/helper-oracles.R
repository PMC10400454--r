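# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations: rasterized geometry, a literal transcription
# of the soft suppression recursion, and exhaustive rectangle integration.

# Monte-Carlo-free rasterization: overlap measured by counting subpixel
# centers on a fine grid covering both boxes. Discretization error scales
# with perimeter/n; n = 1600 keeps it safely below 1e-3 on unit-scale boxes.
raster_iou <- function(a, b, n = 1600) {
  x0 <- min(a[1], b[1]); x1 <- max(a[3], b[3])
  y0 <- min(a[2], b[2]); y1 <- max(a[4], b[4])
  xs <- seq(x0, x1, length.out = n + 1)[-1] - (x1 - x0) / (2 * n)
  ys <- seq(y0, y1, length.out = n + 1)[-1] - (y1 - y0) / (2 * n)
  gx <- rep(xs, times = n); gy <- rep(ys, each = n)
  ina <- gx > a[1] & gx < a[3] & gy > a[2] & gy < a[4]
  inb <- gx > b[1] & gx < b[3] & gy > b[2] & gy < b[4]
  sum(ina & inb) / sum(ina | inb)
}

raster_diou <- function(a, b, n = 1600) {
  rho2 <- ((a[1] + a[3]) / 2 - (b[1] + b[3]) / 2)^2 +
    ((a[2] + a[4]) / 2 - (b[2] + b[4]) / 2)^2
  c2 <- (max(a[3], b[3]) - min(a[1], b[1]))^2 +
    (max(a[4], b[4]) - min(a[2], b[2]))^2
  raster_iou(a, b, n) - rho2 / c2
}

# Literal sequential transcription of the soft suppression rule for one
# class: pick the max-score box, decay every other box whose DIoU reaches
# the threshold by exp(-DIoU^2 / sigma), repeat; drop below the floor.
oracle_soft_diou <- function(boxes, scores, Nt = 0.5, sigma = 0.5,
                             floor = 1e-3) {
  idx <- seq_along(scores)
  kept_i <- integer(0); kept_s <- numeric(0)
  while (length(idx)) {
    o <- order(-scores[idx], idx)
    m <- idx[o[1]]
    kept_i <- c(kept_i, m); kept_s <- c(kept_s, scores[m])
    idx <- setdiff(idx, m)
    for (i in idx) {
      d <- diou(boxes[m, ], boxes[i, ])
      if (d >= Nt) scores[i] <- scores[i] * exp(-d^2 / sigma)
    }
  }
  keep <- kept_s >= floor
  ord <- order(-kept_s[keep], seq_along(kept_i[keep]))
  list(idx = kept_i[keep][ord], scores = kept_s[keep][ord])
}

random_detections <- function(n, seed, classes = 1L, span = 60) {
  set.seed(seed)
  x1 <- runif(n, 0, span); y1 <- runif(n, 0, span)
  data.frame(x1 = x1, y1 = y1,
             x2 = x1 + runif(n, 4, 30), y2 = y1 + runif(n, 4, 30),
             score = round(runif(n), 4),
             class_id = sample.int(classes, n, replace = TRUE))
}

# Exhaustive rectangle integration of the precision-envelope area.
oracle_ap <- function(flags, n_truths) {
  if (n_truths == 0) return(NA_real_)
  if (!length(flags)) return(0)
  tp <- cumsum(flags); fp <- cumsum(!flags)
  rec <- tp / n_truths; prec <- tp / (tp + fp)
  area <- 0; prev_r <- 0
  for (i in seq_along(flags)) {
    if (rec[i] > prev_r) {
      area <- area + (rec[i] - prev_r) * max(prec[i:length(prec)])
      prev_r <- rec[i]
    }
  }
  area
}

tiny_csp_config <- function(input_size = 64L) {
  model_config(NULL, depth_multiplier = 0.11, width_multiplier = 0.125,
               backbone = "cspdarknet", neck = "pafpn",
               head_activation = "silu", num_classes = 2L,
               input_size = input_size)
}

randomize_bn <- function(net, seed = 1L, gamma_range = c(0.4, 1.4)) {
  set.seed(seed)
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    if (l$type == "bn") {
      net$layers[[nm]]$gamma <- runif(l$c, gamma_range[1], gamma_range[2])
      net$layers[[nm]]$beta <- rnorm(l$c, 0, 0.3)
      net$layers[[nm]]$rmean <- rnorm(l$c, 0, 0.2)
      net$layers[[nm]]$rvar <- runif(l$c, 0.5, 2)
    }
  }
  net
}

# Zero the gamma of a fraction of (whole, untainted) coupled channel groups.
zero_some_groups <- function(net, frac = 0.3, seed = 2L) {
  cg <- pestlite:::channel_groups(net)
  tab <- pestlite:::bn_gamma_table(net, cg)
  roots <- unique(tab$root[!tab$taint])
  set.seed(seed)
  zro <- sample(roots, max(1L, floor(length(roots) * frac)))
  for (nm in unique(tab$layer)) {
    g <- cg$groups[[nm]]
    sel <- g %in% zro
    if (any(sel)) net$layers[[nm]]$gamma[sel] <- 0
  }
  net
}
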