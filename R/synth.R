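# Seeded synthetic orchard scenes: textured foliage background plus curved
# larva capsules ("young": brown, mottled; "old": green, smooth with small
# protrusions), optional leaf occluders up to a target covered fraction, and
# front/side/back lighting. Every scene emits exact VOC ground truth, so the
# whole detection pipeline is testable without any downloaded data.

#' Scene specification
#'
#' @param canvas square canvas size in pixels.
#' @param n_larvae number of larvae to draw.
#' @param young_fraction probability that a larva is of class "young".
#' @param occlusion target covered fraction per larva, in `[0, 1)`; the
#'   generator adds leaf occluders until the measured fraction is within
#'   0.05 of the target.
#' @param lighting `"front"`, `"side"` or `"back"`.
#' @param seed RNG seed; identical specs render identical scenes.
#' @export
scene_spec <- function(canvas = 256L, n_larvae = 2L, young_fraction = 0.5,
                       occlusion = 0, lighting = c("front", "side", "back"),
                       seed = 1L) {
  lighting <- match.arg(lighting)
  if (occlusion < 0 || occlusion >= 1) stop("scene_spec: occlusion target must be in [0, 1)")
  if (n_larvae < 0) stop("scene_spec: n_larvae must be >= 0")
  structure(list(canvas = as.integer(canvas), n_larvae = as.integer(n_larvae),
                 young_fraction = young_fraction, occlusion = occlusion,
                 lighting = lighting, seed = as.integer(seed)),
            class = "scene_spec")
}

# coarse-noise field upscaled to (h, w) by bilinear interpolation
noise_field <- function(h, w, coarse, lo, hi) {
  g <- matrix(runif(coarse^2, lo, hi), coarse, coarse)
  ii <- seq(1, coarse, length.out = h)
  jj <- seq(1, coarse, length.out = w)
  i0 <- pmin(floor(ii), coarse - 1)
  j0 <- pmin(floor(jj), coarse - 1)
  fi <- matrix(ii - i0, h, w)
  fj <- matrix(jj - j0, h, w, byrow = TRUE)
  a <- g[i0, j0, drop = FALSE]
  b <- g[i0 + 1, j0, drop = FALSE]
  cc <- g[i0, j0 + 1, drop = FALSE]
  d <- g[i0 + 1, j0 + 1, drop = FALSE]
  a * (1 - fi) * (1 - fj) + b * fi * (1 - fj) + cc * (1 - fi) * fj + d * fi * fj
}

ellipse_mask <- function(H, W, cx, cy, a, b, theta) {
  X <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  Y <- matrix(seq_len(H) - 0.5, H, W)
  dx <- X - cx
  dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

paint <- function(img, mask, col) {
  for (c in 1:3) {
    plane <- img[, , c]
    plane[mask] <- col[c]
    img[, , c] <- plane
  }
  img
}

# capsule along a quadratic Bezier; returns mask and spine samples
larva_mask <- function(H, W, p0, p1, p2, r0) {
  ts <- seq(0, 1, length.out = 25)
  bx <- (1 - ts)^2 * p0[1] + 2 * (1 - ts) * ts * p1[1] + ts^2 * p2[1]
  by <- (1 - ts)^2 * p0[2] + 2 * (1 - ts) * ts * p1[2] + ts^2 * p2[2]
  rr <- r0 * (0.35 + 0.65 * sin(pi * ts)^0.7)
  X <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  Y <- matrix(seq_len(H) - 0.5, H, W)
  m <- matrix(FALSE, H, W)
  for (i in seq_along(ts)) {
    m <- m | ((X - bx[i])^2 + (Y - by[i])^2 <= rr[i]^2)
  }
  list(mask = m, bx = bx, by = by, r = rr)
}

draw_larva <- function(img, lm, class) {
  H <- dim(img)[1]; W <- dim(img)[2]
  m <- lm$mask
  if (class == "young") {
    base <- c(115, 72, 38)
    tex <- noise_field(H, W, 10, 0.65, 1.35)
    for (c in 1:3) {
      plane <- img[, , c]
      plane[m] <- base[c] * tex[m]
      img[, , c] <- plane
    }
    # bird-dropping style pale saddle patch mid-body
    mid <- length(lm$bx) %/% 2L
    sm <- ellipse_mask(H, W, lm$bx[mid], lm$by[mid], lm$r[mid] * 0.9,
                       lm$r[mid] * 0.6, 0)
    img <- paint(img, sm & m, c(205, 195, 175))
    # dark mottling spots
    for (k in 1:4) {
      i <- sample(seq_along(lm$bx), 1)
      sp <- ellipse_mask(H, W, lm$bx[i] + runif(1, -3, 3),
                         lm$by[i] + runif(1, -3, 3),
                         lm$r[i] * 0.35, lm$r[i] * 0.25, runif(1, 0, pi))
      img <- paint(img, sp & m, base * 0.45)
    }
  } else {
    base <- c(96, 178, 66)
    shade <- noise_field(H, W, 6, 0.92, 1.08)
    for (c in 1:3) {
      plane <- img[, , c]
      plane[m] <- base[c] * shade[m]
      img[, , c] <- plane
    }
    # sheen stripe along the spine
    X <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
    Y <- matrix(seq_len(H) - 0.5, H, W)
    sheen <- matrix(FALSE, H, W)
    for (i in seq_along(lm$bx)) {
      sheen <- sheen | ((X - lm$bx[i])^2 + (Y - (lm$by[i] - lm$r[i] * 0.4))^2 <=
                          (lm$r[i] * 0.3)^2)
    }
    for (c in 1:3) {
      plane <- img[, , c]
      sel <- sheen & m
      plane[sel] <- pmin(plane[sel] + 45, 255)
      img[, , c] <- plane
    }
    # glandular horn protrusions at the head end
    hm <- ellipse_mask(H, W, lm$bx[2], lm$by[2] - lm$r[2],
                       lm$r[2] * 0.35, lm$r[2] * 0.6, 0.4)
    img <- paint(img, hm, c(205, 120, 40))
    m <- m | hm
  }
  list(img = img, mask = m)
}

apply_lighting <- function(img, lighting) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (lighting == "side") {
    g <- seq(1.15, 0.78, length.out = W)
    out <- img * rep(rep(g, each = H), times = 3)
    out <- floor(out + 0.5)
    out[out > 255] <- 255
    out
  } else if (lighting == "back") {
    out <- brightness_contrast(img, 0.55, -10)
    gray <- (out[, , 1] + out[, , 2] + out[, , 3]) / 3
    for (c in 1:3) out[, , c] <- 0.62 * out[, , c] + 0.38 * gray
    floor(out + 0.5)
  } else {
    img
  }
}

#' Render one synthetic scene
#'
#' Draws a textured foliage background, the requested larvae, leaf
#' occluders until each larva's measured covered fraction is within 0.05 of
#' the target, and the lighting transform; then records bounding boxes and
#' per-object occlusion fractions measured from the final pixel-owner map.
#'
#' @param spec a [scene_spec()].
#' @param id image id for the annotation.
#' @return list with `image` (array `(H, W, 3)`, 0..255), `ann`
#'   ([annotation()]), `owner` (integer pixel-owner matrix: 0 background or
#'   occluder, i for larva i) and `totals` (per-larva mask pixel counts).
#' @export
generate_scene <- function(spec, id = sprintf("scene_%06d", spec$seed)) {
  set.seed(spec$seed)
  n <- spec$canvas
  H <- n; W <- n
  img <- array(0, c(H, W, 3))
  base <- c(68, 112, 52)
  for (c in 1:3) {
    img[, , c] <- base[c] * noise_field(H, W, 8, 0.72, 1.28) +
      matrix(rnorm(H * W, 0, 5), H, W)
  }
  # background leaf texture
  for (k in seq_len(6)) {
    em <- ellipse_mask(H, W, runif(1, 0, W), runif(1, 0, H),
                       runif(1, 0.1, 0.25) * W, runif(1, 0.05, 0.12) * W,
                       runif(1, 0, pi))
    tone <- runif(1, 0.75, 1.2)
    for (c in 1:3) {
      plane <- img[, , c]
      plane[em] <- base[c] * tone + rnorm(sum(em), 0, 4)
      img[, , c] <- plane
    }
  }
  owner <- matrix(0L, H, W)
  classes <- character(0)
  totals <- integer(0)
  boxes <- NULL
  masks <- list()
  for (i in seq_len(spec$n_larvae)) {
    cls <- if (runif(1) < spec$young_fraction) "young" else "old"
    scale <- if (cls == "young") 0.75 else 1
    len <- runif(1, 0.32, 0.5) * n * scale
    r0 <- runif(1, 0.05, 0.075) * n * scale
    ctr <- runif(2, 0.25, 0.75) * n
    th <- runif(1, 0, 2 * pi)
    dir <- c(cos(th), sin(th))
    nrm <- c(-dir[2], dir[1])
    bow <- runif(1, -0.25, 0.25) * len
    p0 <- ctr - dir * len / 2
    p2 <- ctr + dir * len / 2
    p1 <- ctr + nrm * bow
    lm <- larva_mask(H, W, p0, p1, p2, r0)
    dl <- draw_larva(img, lm, cls)
    img <- dl$img
    owner[dl$mask] <- i
    masks[[i]] <- dl$mask
    classes <- c(classes, cls)
    totals <- c(totals, sum(dl$mask))
  }
  # leaf occluders per larva until the covered fraction reaches the target
  if (spec$occlusion > 0) {
    for (i in seq_len(spec$n_larvae)) {
      tries <- 0L
      repeat {
        occ <- 1 - sum(owner == i) / totals[i]
        if (occ >= spec$occlusion - 0.04 || tries >= 80L) break
        tries <- tries + 1L
        idx <- which(masks[[i]], arr.ind = TRUE)
        at <- idx[sample.int(nrow(idx), 1), ]
        a <- sqrt(0.07 * totals[i] / pi) * runif(1, 0.9, 1.3)
        em <- ellipse_mask(H, W, at[2], at[1], a * 1.6, a * 0.8,
                           runif(1, 0, pi))
        tone <- runif(1, 0.8, 1.15)
        leaf <- base * tone
        img <- paint(img, em, leaf)
        for (c in 1:3) {
          plane <- img[, , c]
          plane[em] <- leaf[c] + rnorm(sum(em), 0, 4)
          img[, , c] <- plane
        }
        owner[em] <- 0L
      }
    }
  }
  img[img < 0] <- 0
  img[img > 255] <- 255
  img <- apply_lighting(floor(img + 0.5), spec$lighting)
  if (spec$n_larvae > 0) {
    rows <- lapply(seq_len(spec$n_larvae), function(i) {
      idx <- which(masks[[i]], arr.ind = TRUE)
      data.frame(class = classes[i],
                 x1 = min(idx[, 2]) - 1, y1 = min(idx[, 1]) - 1,
                 x2 = max(idx[, 2]), y2 = max(idx[, 1]),
                 occlusion = 1 - sum(owner == i) / totals[i])
    })
    boxes <- do.call(rbind, rows)
  }
  list(image = img, ann = annotation(id, W, H, boxes), owner = owner,
       totals = totals)
}

#' Generate a set of synthetic scenes in memory
#'
#' Per-image parameters are drawn from the given ranges under one master
#' seed; each scene then renders from its own derived seed, so the set is
#' reproducible as a whole.
#'
#' @param n_images number of scenes.
#' @param canvas canvas size.
#' @param n_range inclusive range for the larva count.
#' @param young_fraction class-mix probability.
#' @param occlusion_range range of per-image occlusion targets.
#' @param lighting lighting modes to sample uniformly.
#' @param seed master seed.
#' @return list of samples `list(id, image, ann)` (with generator extras).
#' @export
generate_samples <- function(n_images, canvas = 256L, n_range = c(1L, 3L),
                             young_fraction = 0.5, occlusion_range = c(0, 0.6),
                             lighting = c("front", "side", "back"),
                             seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  nls <- sample(seq(n_range[1], n_range[2]), n_images, replace = TRUE)
  occs <- runif(n_images, occlusion_range[1], occlusion_range[2])
  lits <- sample(lighting, n_images, replace = TRUE)
  lapply(seq_len(n_images), function(i) {
    sp <- scene_spec(canvas, nls[i], young_fraction, occs[i], lits[i],
                     seed = seeds[i])
    id <- sprintf("synth_%04d", i)
    sc <- generate_scene(sp, id = id)
    list(id = id, image = sc$image, ann = sc$ann, spec = sp,
         owner = sc$owner, totals = sc$totals)
  })
}

#' Generate a synthetic VOC dataset on disk
#'
#' Renders `n_images` scenes, splits them 7:2:1 with occlusion-stratified
#' test subsets, and writes the VOC tree plus a `manifest.json` recording
#' every scene spec (replaying the manifest regenerates the identical
#' dataset).
#'
#' @inheritParams generate_samples
#' @param dir output directory (must be empty unless `force`).
#' @param force overwrite a non-empty directory.
#' @return the directory, invisibly.
#' @export
generate_dataset <- function(n_images, dir, canvas = 256L,
                             n_range = c(1L, 3L), young_fraction = 0.5,
                             occlusion_range = c(0, 0.6),
                             lighting = c("front", "side", "back"),
                             seed = 1L, force = FALSE) {
  if (n_images < 1) stop("generate_dataset: n_images must be >= 1")
  samples <- generate_samples(n_images, canvas, n_range, young_fraction,
                              occlusion_range, lighting, seed)
  anns <- stats::setNames(lapply(samples, `[[`, "ann"),
                          vapply(samples, `[[`, "", "id"))
  splits <- split_dataset(anns, split_spec(seed = seed))
  write_voc_dataset(samples, dir, splits = splits, force = force)
  manifest <- list(
    n_images = n_images, canvas = canvas, n_range = n_range,
    young_fraction = young_fraction, occlusion_range = occlusion_range,
    lighting = lighting, seed = seed,
    scenes = lapply(samples, function(s) unclass(s$spec))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
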