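# Box geometry, head decoding, and non-maximum suppression.

check_boxes <- function(b) {
  b <- matrix(as.numeric(b), ncol = 4)
  if (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2])) {
    stop("degenerate box: x2 must exceed x1 and y2 must exceed y1")
  }
  b
}

#' Intersection over union of axis-aligned boxes
#'
#' Boxes are continuous corner coordinates `(x1, y1, x2, y2)`, origin
#' top-left; areas are exact products, so there is no pixel-inclusivity
#' ambiguity.
#'
#' @param a,b length-4 vectors or n x 4 matrices (recycled row-wise).
#' @return IoU in `[0, 1]`, vectorized over rows.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
  a <- check_boxes(a)
  b <- check_boxes(b)
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  ua <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
    (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  inter / ua
}

#' Distance-IoU
#'
#' `DIoU = IoU - rho^2 / c^2` where `rho` is the distance between box
#' centers and `c` the diagonal of the minimum enclosing box. Values lie in
#' `(-1, 1]`; well-separated boxes approach -1, so it penalizes
#' center offset even when the overlap is unchanged.
#'
#' @inheritParams iou
#' @return DIoU, vectorized over rows.
#' @examples
#' diou(c(0, 0, 2, 2), c(1, 1, 3, 3)) # 1/7 - 1/9
#' @export
diou <- function(a, b) {
  a <- check_boxes(a)
  b <- check_boxes(b)
  rho2 <- ((a[, 1] + a[, 3]) / 2 - (b[, 1] + b[, 3]) / 2)^2 +
    ((a[, 2] + a[, 4]) / 2 - (b[, 2] + b[, 4]) / 2)^2
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  iou(a, b) - rho2 / (cw^2 + ch^2)
}

#' NMS configuration
#'
#' @param method `"soft_diou"` (score decay by `exp(-DIoU^2 / sigma)` for
#'   overlaps at or above the threshold), `"hard_diou"` or `"hard_iou"`
#'   (classical removal).
#' @param threshold overlap threshold `N_t` in `(0, 1)`.
#' @param sigma positive decay coefficient for the soft method.
#' @param score_floor detections whose decayed score falls below this are
#'   dropped from the final output.
#' @return an `nms_config` list.
#' @export
nms_config <- function(method = c("soft_diou", "hard_diou", "hard_iou"),
                       threshold = 0.5, sigma = 0.5, score_floor = 1e-3) {
  method <- match.arg(method)
  if (threshold <= 0 || threshold >= 1) stop("nms_config: threshold must be in (0, 1)")
  if (sigma <= 0) stop("nms_config: sigma must be > 0")
  structure(list(method = method, threshold = threshold, sigma = sigma,
                 score_floor = score_floor), class = "nms_config")
}

empty_detections <- function() {
  data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
             y2 = numeric(0), score = numeric(0), class_id = integer(0))
}

# Deterministic ordering: score descending, then original index ascending.
det_order <- function(scores, idx) order(-scores, idx)

nms_one_class <- function(d, cfg) {
  overlap <- function(a, b) {
    if (cfg$method == "hard_iou") iou(a, b) else diou(a, b)
  }
  n <- nrow(d)
  scores <- d$score
  alive <- rep(TRUE, n)
  kept <- integer(0)
  kept_scores <- numeric(0)
  while (any(alive)) {
    cand <- which(alive)
    m <- cand[det_order(scores[cand], cand)][1]
    kept <- c(kept, m)
    kept_scores <- c(kept_scores, scores[m])
    alive[m] <- FALSE
    rest <- which(alive)
    if (!length(rest)) break
    ov <- overlap(as.matrix(d[rep(m, length(rest)), 1:4]),
                  as.matrix(d[rest, 1:4]))
    if (cfg$method == "soft_diou") {
      decay <- ov >= cfg$threshold
      scores[rest[decay]] <- scores[rest[decay]] *
        exp(-ov[decay]^2 / cfg$sigma)
    } else {
      drop <- ov >= cfg$threshold
      alive[rest[drop]] <- FALSE
    }
  }
  out <- d[kept, , drop = FALSE]
  out$score <- kept_scores
  out <- out[out$score >= cfg$score_floor, , drop = FALSE]
  out[det_order(out$score, seq_len(nrow(out))), , drop = FALSE]
}

nms_by_class <- function(dets, cfg) {
  if (!nrow(dets)) return(empty_detections())
  if (any(dets$score < 0 | dets$score > 1)) stop("detection scores must lie in [0, 1]")
  parts <- lapply(split(dets, dets$class_id), nms_one_class, cfg = cfg)
  out <- do.call(rbind, parts)
  out <- out[det_order(out$score, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Soft distance-IoU non-maximum suppression
#'
#' Per class, repeatedly keeps the highest-scoring box `M`; every remaining
#' box whose DIoU with `M` reaches the threshold `N_t` has its confidence
#' multiplied by `exp(-DIoU^2 / sigma)` instead of being deleted, so heavily
#' occluded, overlapping larvae are not suppressed outright. Decay compounds
#' across iterations; after the queue is exhausted, detections whose score
#' fell below `score_floor` are dropped and the rest are returned sorted by
#' final score (ties broken by original index).
#'
#' @param dets detections `data.frame` with columns
#'   `x1, y1, x2, y2, score, class_id`.
#' @param cfg an [nms_config()].
#' @return filtered detections with decayed scores.
#' @export
soft_diou_nms <- function(dets, cfg = nms_config()) {
  cfg$method <- "soft_diou"
  nms_by_class(dets, cfg)
}

#' Hard non-maximum suppression
#'
#' Classical greedy suppression: boxes whose overlap with the kept box
#' reaches the threshold are removed. The overlap measure is DIoU
#' (`method = "hard_diou"`) or plain IoU (`"hard_iou"`).
#'
#' @inheritParams soft_diou_nms
#' @export
hard_nms <- function(dets, cfg = nms_config(method = "hard_diou")) {
  if (cfg$method == "soft_diou") stop("hard_nms: use soft_diou_nms() for the soft method")
  nms_by_class(dets, cfg)
}

#' Decode raw head outputs into detections
#'
#' Anchor-free decode: per cell, the predicted `(dx, dy)` offsets are added
#' to the 0-based grid coordinates and scaled by the stride; width and
#' height are `exp` of the predictions times the stride; the confidence is
#' `sigmoid(objectness) * sigmoid(class score)` for the best class.
#' Detections under `score_threshold` are dropped.
#'
#' @param head_outputs list of arrays `(H, W, 5 + num_classes)` (or with a
#'   trailing singleton batch dim), finest level first.
#' @param strides integer strides matching `head_outputs`.
#' @param score_threshold minimum confidence.
#' @return detections `data.frame` (`x1, y1, x2, y2, score, class_id`).
#' @export
decode_predictions <- function(head_outputs, strides = c(8L, 16L, 32L),
                               score_threshold = 0.05) {
  if (length(head_outputs) != length(strides)) {
    stop("decode_predictions: need one output map per stride")
  }
  res <- list()
  for (li in seq_along(head_outputs)) {
    hm <- head_outputs[[li]]
    d <- dim(hm)
    if (length(d) == 4L) {
      if (d[4] != 1L) stop("decode_predictions: expected a single image")
      dim(hm) <- d[1:3]
      d <- d[1:3]
    }
    if (d[3] < 6L) stop("decode_predictions: head map must have 4+1+classes channels")
    s <- strides[li]
    nc <- d[3] - 5L
    obj <- sigmoid(hm[, , 5])
    cls <- sigmoid(hm[, , 5 + seq_len(nc), drop = FALSE])
    best <- apply(cls, c(1, 2), which.max)
    bestp <- apply(cls, c(1, 2), max)
    score <- obj * bestp
    sel <- which(score >= score_threshold, arr.ind = TRUE)
    if (!nrow(sel)) next
    r <- sel[, 1]
    cc <- sel[, 2]
    lin <- cbind(r, cc)
    cx <- (cc - 1 + hm[, , 1][lin]) * s
    cy <- (r - 1 + hm[, , 2][lin]) * s
    w <- exp(hm[, , 3][lin]) * s
    h <- exp(hm[, , 4][lin]) * s
    res[[length(res) + 1L]] <- data.frame(
      x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2,
      score = score[lin], class_id = as.integer(best[lin]))
  }
  if (!length(res)) return(empty_detections())
  out <- do.call(rbind, res)
  out <- out[det_order(out$score, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read detections as TSV
#'
#' Columns: `image_id, class, score, x1, y1, x2, y2`.
#'
#' @param dets named list of detection data.frames (names are image ids), or
#'   a single data.frame with an `image_id` column.
#' @param path output file.
#' @param class_names class vocabulary used to translate `class_id`.
#' @export
write_detections_tsv <- function(dets, path, class_names = c("young", "old")) {
  if (is.data.frame(dets)) dets <- split(dets, dets$image_id)
  rows <- lapply(names(dets), function(id) {
    d <- dets[[id]]
    if (!nrow(d)) return(NULL)
    data.frame(image_id = id, class = class_names[d$class_id],
               score = d$score, x1 = d$x1, y1 = d$y1, x2 = d$x2, y2 = d$y2)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(image_id = character(0), class = character(0),
                      score = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0))
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections_tsv
#' @export
read_detections_tsv <- function(path, class_names = c("young", "old")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$class_id <- match(tab$class, class_names)
  split(tab[, c("x1", "y1", "x2", "y2", "score", "class_id")], tab$image_id)
}
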