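# Detection evaluation: greedy matching, precision/recall/F1, average
# precision as the area under the precision-recall curve, mAP, FPS.

#' Matching configuration
#'
#' @param iou_threshold minimum IoU for a detection to match a ground-truth
#'   box, in `(0, 1)`.
#' @return a `match_config` list.
#' @export
match_config <- function(iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    stop("match_config: iou_threshold must be in (0, 1)")
  }
  structure(list(iou_threshold = iou_threshold), class = "match_config")
}

#' Greedy detection-to-truth matching
#'
#' Detections are processed in descending score order; each is matched to
#' the unmatched same-class ground truth with the highest IoU at or above
#' the threshold (TP), otherwise it is a false positive. Ground truths left
#' unmatched are false negatives.
#'
#' @param dets detections `data.frame` (`x1, y1, x2, y2, score, class_id`).
#' @param truths ground truth `data.frame` (`x1, y1, x2, y2, class_id`).
#' @param cfg a [match_config()].
#' @return list with `tp` (logical per detection, in descending score
#'   order), `scores` (the corresponding scores), `fn` (unmatched truths)
#'   and `order` (row indices of `dets` in evaluation order).
#' @export
match_detections <- function(dets, truths, cfg = match_config()) {
  ord <- det_order(dets$score, seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  matched <- rep(FALSE, nrow(truths))
  tp <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    cand <- which(!matched & truths$class_id == d$class_id[i])
    if (!length(cand)) next
    ious <- iou(as.matrix(d[rep(i, length(cand)), c("x1", "y1", "x2", "y2")]),
                as.matrix(truths[cand, c("x1", "y1", "x2", "y2")]))
    j <- which.max(ious)
    if (ious[j] >= cfg$iou_threshold) {
      tp[i] <- TRUE
      matched[cand[j]] <- TRUE
    }
  }
  list(tp = tp, scores = d$score, fn = sum(!matched), order = ord)
}

#' Precision, recall and F1
#'
#' Standard count ratios; the degenerate `0/0` cases are defined as 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return a scalar in `[0, 1]`.
#' @export
precision <- function(tp, fp) if (tp + fp == 0) 0 else tp / (tp + fp)

#' @rdname precision
#' @export
recall <- function(tp, fn) if (tp + fn == 0) 0 else tp / (tp + fn)

#' @rdname precision
#' @param p,r precision and recall.
#' @export
f1_score <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Average precision from an ordered TP/FP sequence
#'
#' Area under the precision-recall curve for one class. With
#' `interpolation = "all"` (default) the full precision envelope is
#' integrated (the curve is a true integral over recall); `"11point"` is
#' the legacy 11-point average.
#'
#' @param tp_flags logical vector, detections in descending score order
#'   (`TRUE` = matched a truth).
#' @param n_truths number of ground-truth boxes for the class.
#' @param interpolation `"all"` or `"11point"`.
#' @return AP in `[0, 1]`, or `NA` when `n_truths` is 0.
#' @export
average_precision <- function(tp_flags, n_truths,
                              interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  if (n_truths == 0) return(NA_real_)
  if (!length(tp_flags)) return(0)
  tp_cum <- cumsum(tp_flags)
  fp_cum <- cumsum(!tp_flags)
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- tp_cum / n_truths
  if (interpolation == "11point") {
    return(mean(vapply(seq(0, 1, 0.1), function(r) {
      p <- prec[rec >= r]
      if (length(p)) max(p) else 0
    }, 0)))
  }
  # precision envelope from the right, then rectangle sum over recall steps
  r <- c(0, rec)
  p <- c(0, prec)
  env <- rev(cummax(rev(p)))
  sum((r[-1] - r[-length(r)]) * env[-1])
}

#' Mean average precision
#'
#' Unweighted mean over classes that have ground truth (classes with
#' undefined AP are skipped).
#'
#' @param aps numeric vector of per-class APs (may contain `NA`).
#' @return mAP in `[0, 1]`.
#' @export
mean_ap <- function(aps) {
  ok <- !is.na(aps)
  if (!any(ok)) stop("mean_ap: no class has a defined AP")
  mean(aps[ok])
}

#' Frames per second
#'
#' @param n number of images processed.
#' @param t total wall time in seconds (`> 0`).
#' @return `n / t`.
#' @export
fps <- function(n, t) {
  if (t <= 0) stop("fps: total time must be > 0")
  n / t
}

#' Evaluate detections against ground truth
#'
#' Pools detections over a set of images, matches per image and class,
#' and reports counts, precision/recall/F1 (over all supplied detections),
#' per-class AP and mAP.
#'
#' @param dets named list (by image id) of detection data.frames.
#' @param truths named list (by image id) of ground-truth data.frames
#'   (`x1, y1, x2, y2, class_id`).
#' @param cfg a [match_config()].
#' @param class_names class vocabulary.
#' @param interpolation AP interpolation, see [average_precision()].
#' @return an `eval_result` list with `counts`, `precision`, `recall`,
#'   `f1`, `ap` (per class), `map` and per-class PR curves.
#' @export
evaluate_detections <- function(dets, truths, cfg = match_config(),
                                class_names = c("young", "old"),
                                interpolation = "all") {
  ids <- names(truths)
  nclass <- length(class_names)
  per_class <- vector("list", nclass)
  for (k in seq_len(nclass)) {
    flags <- list()
    scores <- list()
    n_truth <- 0L
    fn_at_thresh <- 0L
    for (id in ids) {
      tr <- truths[[id]]
      tr <- tr[tr$class_id == k, , drop = FALSE]
      de <- dets[[id]]
      if (is.null(de)) de <- empty_detections()
      de <- de[de$class_id == k, , drop = FALSE]
      n_truth <- n_truth + nrow(tr)
      if (nrow(de)) {
        m <- match_detections(de, tr, cfg)
        flags[[length(flags) + 1L]] <- m$tp
        scores[[length(scores) + 1L]] <- m$scores
        fn_at_thresh <- fn_at_thresh + m$fn
      } else {
        fn_at_thresh <- fn_at_thresh + nrow(tr)
      }
    }
    fl <- unlist(flags)
    sc <- unlist(scores)
    if (length(sc)) {
      o <- det_order(sc, seq_along(sc))
      fl <- fl[o]
      sc <- sc[o]
    } else {
      fl <- logical(0)
      sc <- numeric(0)
    }
    per_class[[k]] <- list(flags = fl, scores = sc, n_truth = n_truth,
                           fn = fn_at_thresh)
  }
  tp <- sum(vapply(per_class, function(x) sum(x$flags), 0))
  fp <- sum(vapply(per_class, function(x) sum(!x$flags), 0))
  fn <- sum(vapply(per_class, function(x) x$fn, 0))
  p <- precision(tp, fp)
  r <- recall(tp, fn)
  aps <- vapply(per_class, function(x) {
    average_precision(x$flags, x$n_truth, interpolation)
  }, 0)
  names(aps) <- class_names
  curves <- lapply(per_class, function(x) {
    if (!length(x$flags) || x$n_truth == 0) {
      return(data.frame(recall = numeric(0), precision = numeric(0)))
    }
    tpc <- cumsum(x$flags)
    data.frame(recall = tpc / x$n_truth,
               precision = tpc / seq_along(x$flags))
  })
  names(curves) <- class_names
  structure(list(
    counts = c(TP = tp, FP = fp, FN = fn),
    precision = p, recall = r, f1 = f1_score(p, r),
    ap = aps, map = mean_ap(aps), pr_curves = curves
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> TP=", x$counts["TP"], " FP=", x$counts["FP"],
      " FN=", x$counts["FN"], "\n", sep = "")
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f\n",
              x$precision, x$recall, x$f1))
  for (nm in names(x$ap)) cat(sprintf("  AP[%s] %.4f\n", nm, x$ap[nm]))
  cat(sprintf("  mAP %.4f\n", x$map))
  invisible(x)
}
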