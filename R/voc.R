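# PASCAL VOC annotation I/O, photometric and geometric augmentation, and
# dataset splitting with occlusion stratification.
#
# Images are numeric arrays (H, W, 3) with 8-bit values 0..255. Boxes use
# continuous corner coordinates with origin at the top-left: VOC's 1-based
# inclusive pixel coordinates map to internal corners as x1 = xmin - 1,
# x2 = xmax (so VOC xmin = 1 is the left image edge 0.0).

VOC_CLASSES <- c("young", "old")

#' Construct an image annotation
#'
#' @param id image identifier (file stem).
#' @param width,height image size in pixels.
#' @param objects `data.frame` with columns `class` (in the vocabulary),
#'   `x1, y1, x2, y2` (continuous corners within the image) and optionally
#'   `occlusion` (fraction of the object covered, in `[0, 1]`; defaults 0).
#' @return an `annotation` list.
#' @export
annotation <- function(id, width, height, objects = NULL) {
  if (is.null(objects) || !nrow(objects)) {
    objects <- data.frame(class = character(0), x1 = numeric(0),
                          y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
                          occlusion = numeric(0))
  }
  if (is.null(objects$occlusion)) objects$occlusion <- 0
  bad <- setdiff(unique(objects$class), VOC_CLASSES)
  if (length(bad)) stop("annotation: unknown class '", bad[1], "'")
  if (nrow(objects)) {
    if (any(objects$x1 < 0 | objects$y1 < 0 |
            objects$x2 > width | objects$y2 > height)) {
      stop("annotation: box outside image bounds (field bndbox)")
    }
    if (any(objects$x2 <= objects$x1 | objects$y2 <= objects$y1)) {
      stop("annotation: degenerate box (field bndbox)")
    }
  }
  structure(list(id = id, width = width, height = height,
                 objects = objects), class = "annotation")
}

#' Read / write PASCAL VOC XML annotations
#'
#' The occlusion fraction is carried in a non-standard `<occlusion>` element
#' per object (absent means 0). Round trips preserve class and box content
#' exactly.
#'
#' @param path XML file path.
#' @return an [annotation()].
#' @export
read_voc_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed VOC XML '", path, "': ",
                                           conditionMessage(e)))
  id <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  id <- tools::file_path_sans_ext(id)
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
  if (is.na(w) || is.na(h)) stop("VOC XML '", path, "': missing or invalid size element")
  objs <- xml2::xml_find_all(doc, "./object")
  rows <- lapply(objs, function(o) {
    cls <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    if (!cls %in% VOC_CLASSES) {
      stop("VOC XML '", path, "': unknown class '", cls, "' (field name)")
    }
    num <- function(fld) {
      v <- as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0("./bndbox/", fld))))
      if (is.na(v)) stop("VOC XML '", path, "': invalid bndbox field ", fld)
      v
    }
    occ <- xml2::xml_find_first(o, "./occlusion")
    data.frame(class = cls,
               x1 = num("xmin") - 1, y1 = num("ymin") - 1,
               x2 = num("xmax"), y2 = num("ymax"),
               occlusion = if (length(occ) && !is.na(xml2::xml_text(occ))) {
                 as.numeric(xml2::xml_text(occ))
               } else 0)
  })
  objects <- if (length(rows)) do.call(rbind, rows) else NULL
  annotation(id, w, h, objects)
}

#' @rdname read_voc_xml
#' @param ann an [annotation()].
#' @export
write_voc_xml <- function(ann, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", paste0(ann$id, ".png"))
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(ann$width))
  xml2::xml_add_child(sz, "height", as.character(ann$height))
  xml2::xml_add_child(sz, "depth", "3")
  for (i in seq_len(nrow(ann$objects))) {
    o <- ann$objects[i, ]
    on <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(on, "name", o$class)
    bb <- xml2::xml_add_child(on, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(o$x1 + 1, digits = 10))
    xml2::xml_add_child(bb, "ymin", format(o$y1 + 1, digits = 10))
    xml2::xml_add_child(bb, "xmax", format(o$x2, digits = 10))
    xml2::xml_add_child(bb, "ymax", format(o$y2, digits = 10))
    xml2::xml_add_child(on, "occlusion", format(o$occlusion, digits = 10))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Photometric brightness/contrast transform
#'
#' Per-pixel `x * omega + psi`, clipped to `[0, 255]` and rounded half-up.
#' `omega` scales contrast, `psi` shifts brightness.
#'
#' @param image numeric array with 8-bit values.
#' @param omega contrast factor (`> 0`).
#' @param psi brightness offset in intensity units.
#' @return transformed image, same shape.
#' @export
brightness_contrast <- function(image, omega, psi) {
  if (omega <= 0) stop("brightness_contrast: omega must be > 0")
  out <- floor(image * omega + psi + 0.5)
  out[out < 0] <- 0
  out[out > 255] <- 255
  dim(out) <- dim(image)
  out
}

# ---- geometric transforms with exact box bookkeeping -------------------

# Warp by the affine map (x', y')^T = A %*% (x, y, 1)^T acting on continuous
# image coordinates; nearest-neighbour inverse sampling, constant fill.
warp_affine <- function(image, A, fill = c(0, 0, 0)) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  Ai <- solve(rbind(A, c(0, 0, 1)))[1:2, ]
  xs <- rep(seq_len(W) - 0.5, each = H)
  ys <- rep(seq_len(H) - 0.5, times = W)
  src <- Ai %*% rbind(xs, ys, 1)
  j <- floor(src[1, ]) + 1
  i <- floor(src[2, ]) + 1
  ok <- i >= 1 & i <= H & j >= 1 & j <= W
  out <- array(rep(fill, each = H * W), d)
  lin_ok <- (j[ok] - 1) * H + i[ok]
  pix <- (seq_len(H * W))[ok]
  for (c in 1:3) {
    plane <- image[, , c]
    oplane <- out[, , c]
    oplane[pix] <- plane[lin_ok]
    out[, , c] <- oplane
  }
  out
}

transform_boxes <- function(objects, A, width, height) {
  if (!nrow(objects)) return(objects)
  keep <- logical(nrow(objects))
  for (i in seq_len(nrow(objects))) {
    cx <- c(objects$x1[i], objects$x2[i], objects$x1[i], objects$x2[i])
    cy <- c(objects$y1[i], objects$y1[i], objects$y2[i], objects$y2[i])
    pts <- A %*% rbind(cx, cy, 1)
    x1 <- max(0, min(pts[1, ])); x2 <- min(width, max(pts[1, ]))
    y1 <- max(0, min(pts[2, ])); y2 <- min(height, max(pts[2, ]))
    if (x2 - x1 >= 2 && y2 - y1 >= 2) {
      keep[i] <- TRUE
      objects$x1[i] <- x1; objects$x2[i] <- x2
      objects$y1[i] <- y1; objects$y2[i] <- y2
    }
  }
  dropped <- sum(!keep)
  if (dropped) {
    message("augmentation: dropped ", dropped, " object(s) left outside the canvas")
  }
  objects[keep, , drop = FALSE]
}

bg_fill <- function(image) apply(image, 3, stats::median)

aug_one <- function(sample, op, pool) {
  img <- sample$image
  ann <- sample$ann
  H <- dim(img)[1]; W <- dim(img)[2]
  A <- NULL
  if (op == "flip") {
    A <- cbind(c(-1, 0), c(0, 1), c(W, 0))
  } else if (op == "translate") {
    tx <- runif(1, -0.15, 0.15) * W
    ty <- runif(1, -0.15, 0.15) * H
    A <- cbind(c(1, 0), c(0, 1), c(tx, ty))
  } else if (op == "rotate") {
    th <- runif(1, -12, 12) * pi / 180
    R <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    ctr <- c(W / 2, H / 2)
    A <- cbind(R, ctr - R %*% ctr)
  } else if (op == "affine") {
    sh <- runif(2, -0.12, 0.12)
    S <- cbind(c(1, sh[2]), c(sh[1], 1))
    ctr <- c(W / 2, H / 2)
    A <- cbind(S, ctr - S %*% ctr)
  }
  if (!is.null(A)) {
    img <- warp_affine(img, A, fill = bg_fill(img))
    objects <- transform_boxes(ann$objects, A, W, H)
  } else if (op == "blur") {
    ebi <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
    img <- aperm(as.array(EBImage::gblur(ebi, sigma = 1.2)), c(2, 1, 3)) * 255
    img[img < 0] <- 0; img[img > 255] <- 255
    objects <- ann$objects
  } else if (op == "splice") {
    others <- pool[sample.int(length(pool), 3, replace = length(pool) < 3)]
    tiles <- c(list(sample), others)
    img <- array(0, c(H, W, 3))
    objects <- NULL
    h2 <- H %/% 2L; w2 <- W %/% 2L
    offs <- list(c(0, 0), c(0, w2), c(h2, 0), c(h2, w2))
    for (ti in 1:4) {
      t <- tiles[[ti]]
      ebi <- EBImage::Image(aperm(t$image / 255, c(2, 1, 3)), colormode = "Color")
      small <- aperm(as.array(EBImage::resize(ebi, w = w2, h = h2)), c(2, 1, 3)) * 255
      oy <- offs[[ti]][1]; ox <- offs[[ti]][2]
      img[oy + seq_len(h2), ox + seq_len(w2), ] <- small
      ob <- t$ann$objects
      if (nrow(ob)) {
        sx <- w2 / dim(t$image)[2]; sy <- h2 / dim(t$image)[1]
        ob$x1 <- ob$x1 * sx + ox; ob$x2 <- ob$x2 * sx + ox
        ob$y1 <- ob$y1 * sy + oy; ob$y2 <- ob$y2 * sy + oy
        objects <- rbind(objects, ob)
      }
    }
    if (is.null(objects)) objects <- ann$objects[0, ]
  } else {
    stop("unknown augmentation op: ", op)
  }
  # photometric jitter always applied on top of the geometric op
  img <- brightness_contrast(img, runif(1, 0.6, 1.4), runif(1, -30, 30))
  list(id = paste0(ann$id, "_", op), image = img,
       ann = annotation(paste0(ann$id, "_", op), W, H, objects))
}

#' Expand a dataset fivefold by augmentation
#'
#' Each image yields four augmented variants; the operation for each
#' variant is drawn among translation, Gaussian blur, affine shear, small
#' rotation, horizontal flip and 2x2 mosaic splicing, always combined with
#' a random brightness/contrast jitter (`omega` in `[0.6, 1.4]`, `psi` in
#' `[-30, 30]`). Boxes are transformed with the same geometry, clipped to
#' the canvas, and objects left without positive area are dropped (with a
#' message). Seeded runs are reproducible.
#'
#' @param samples list of samples, each `list(id, image, ann)`.
#' @param seed RNG seed.
#' @return list of `5 * length(samples)` samples (originals first).
#' @export
expand_dataset <- function(samples, seed = 1L) {
  if (!length(samples)) stop("expand_dataset: empty input set")
  set.seed(seed)
  ops <- c("translate", "blur", "affine", "rotate", "flip", "splice")
  out <- samples
  for (s in samples) {
    pick <- sample(ops, 4, replace = FALSE)
    for (vi in seq_along(pick)) {
      v <- aug_one(s, pick[vi], pool = samples)
      v$id <- paste0(s$id, "_aug", vi)
      v$ann$id <- v$id
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

#' Split specification
#'
#' @param ratios train/test/val fractions summing to 1.
#' @param occlusion_cut mean per-image occlusion separating the lightly
#'   occluded test subset A from the heavily occluded subset B.
#' @param seed RNG seed for the random partition.
#' @export
split_spec <- function(ratios = c(train = 0.7, test = 0.2, val = 0.1),
                       occlusion_cut = 0.3, seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("split_spec: ratios must sum to 1")
  structure(list(ratios = ratios, occlusion_cut = occlusion_cut, seed = seed),
            class = "split_spec")
}

#' Random 7:2:1 dataset split with occlusion-stratified test subsets
#'
#' Partitions image ids into train/test/val at the configured ratios
#' (rounded within one image), then splits the test set by mean per-image
#' object occlusion: below the cut goes to subset A (light occlusion), the
#' rest to subset B (heavy occlusion). Images without objects count as
#' occlusion 0.
#'
#' @param anns named list of [annotation()]s (names are image ids).
#' @param spec a [split_spec()].
#' @param ab also compute the A/B test subsets (requires occlusion
#'   metadata).
#' @return list with `train`, `test`, `val`, and (if `ab`) `test_A`,
#'   `test_B` character vectors of ids.
#' @export
split_dataset <- function(anns, spec = split_spec(), ab = TRUE) {
  ids <- names(anns)
  n <- length(ids)
  set.seed(spec$seed)
  perm <- sample(ids)
  n_tr <- round(spec$ratios[["train"]] * n)
  n_te <- round(spec$ratios[["test"]] * n)
  n_te <- min(n_te, n - n_tr)
  out <- list(train = sort(perm[seq_len(n_tr)]),
              test = sort(perm[n_tr + seq_len(n_te)]),
              val = sort(perm[seq(n_tr + n_te + 1, length.out = n - n_tr - n_te)]))
  if (ab) {
    occ <- vapply(out$test, function(id) {
      o <- anns[[id]]$objects$occlusion
      if (is.null(o)) return(NA_real_)
      if (!length(o)) return(0)
      mean(o)
    }, 0)
    if (any(is.na(occ))) {
      stop("split_dataset: occlusion metadata missing for test image(s); ",
           "cannot form A/B subsets")
    }
    out$test_A <- out$test[occ < spec$occlusion_cut]
    out$test_B <- out$test[occ >= spec$occlusion_cut]
  }
  out
}

# ---- VOC directory layout ----------------------------------------------

#' Write / read a VOC directory tree
#'
#' Layout: `JPEGImages/` (lossless PNG files), `Annotations/` (VOC XML with
#' the `<occlusion>` extension), `ImageSets/Main/` (split lists).
#'
#' @param samples list of samples `list(id, image, ann)`.
#' @param dir target directory.
#' @param splits optional result of [split_dataset()] to write as
#'   `ImageSets/Main/*.txt`.
#' @param force overwrite a non-empty directory.
#' @export
write_voc_dataset <- function(samples, dir, splits = NULL, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop("write_voc_dataset: target directory is not empty (use force = TRUE)")
  }
  for (d in c("JPEGImages", "Annotations", "ImageSets/Main")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  for (s in samples) {
    png::writePNG(s$image / 255,
                  file.path(dir, "JPEGImages", paste0(s$id, ".png")))
    write_voc_xml(s$ann, file.path(dir, "Annotations", paste0(s$id, ".xml")))
  }
  if (!is.null(splits)) {
    for (nm in names(splits)) {
      writeLines(splits[[nm]],
                 file.path(dir, "ImageSets", "Main", paste0(nm, ".txt")))
    }
  }
  invisible(dir)
}

#' @rdname write_voc_dataset
#' @param ids optional subset of image ids to read.
#' @export
read_voc_dataset <- function(dir, ids = NULL) {
  xmls <- list.files(file.path(dir, "Annotations"), pattern = "\\.xml$",
                     full.names = TRUE)
  if (!is.null(ids)) {
    xmls <- xmls[tools::file_path_sans_ext(basename(xmls)) %in% ids]
  }
  lapply(xmls, function(p) {
    ann <- read_voc_xml(p)
    ipath <- file.path(dir, "JPEGImages", paste0(ann$id, ".png"))
    img <- NULL
    if (file.exists(ipath)) {
      img <- png::readPNG(ipath) * 255
    } else {
      jp <- file.path(dir, "JPEGImages", paste0(ann$id, ".jpg"))
      if (file.exists(jp)) img <- jpeg::readJPEG(jp) * 255
    }
    list(id = ann$id, image = img, ann = ann)
  })
}
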