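# Training: cosine-annealed SGD with momentum, two-phase transfer schedule
# (frozen backbone, then full fine-tuning), label smoothing, and a standard
# anchor-free detection loss with center-prior assignment.

#' Cosine annealing learning rate
#'
#' `eta_t = 0.5 * (1 + cos(t * pi / T)) * eta`: starts at `eta`, decays
#' monotonically to 0 at `t = T`. `t` is the current optimizer step and `T`
#' the total number of steps.
#'
#' @param t current step, `0 <= t <= T`.
#' @param T total steps, `> 0`.
#' @param eta base learning rate.
#' @return the annealed rate.
#' @export
cosine_lr <- function(t, T, eta) {
  if (T <= 0) stop("cosine_lr: T must be > 0")
  if (any(t < 0) || any(t > T)) stop("cosine_lr: t must lie in [0, T]")
  0.5 * (1 + cos(t * pi / T)) * eta
}

#' Training phase configuration
#'
#' Defaults mirror the two-phase transfer schedule: phase 1 freezes the
#' backbone (100 epochs, batch 32, lr 1e-3), phase 2 trains everything
#' (100 epochs, batch 16, lr 1e-4); momentum 0.93 and weight decay 5e-4
#' throughout.
#'
#' @param epochs number of epochs (`>= 0`).
#' @param batch_size minibatch size.
#' @param initial_lr peak learning rate fed to the cosine schedule.
#' @param momentum SGD momentum in `(0, 1)`.
#' @param weight_decay L2 penalty on convolution weights.
#' @param freeze_backbone hold all backbone parameters fixed.
#' @export
phase_config <- function(epochs, batch_size, initial_lr, momentum = 0.93,
                         weight_decay = 5e-4, freeze_backbone = FALSE) {
  if (epochs < 0) stop("phase_config: epochs must be >= 0")
  if (momentum <= 0 || momentum >= 1) stop("phase_config: momentum must be in (0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, momentum = momentum,
                 weight_decay = weight_decay,
                 freeze_backbone = isTRUE(freeze_backbone)),
            class = "phase_config")
}

#' Label smoothing targets
#'
#' Epsilon-smoothed one-hot target: the positive class gets
#' `1 - eps + eps/K`, every other class `eps/K`.
#'
#' @param class_id positive class index (1-based).
#' @param K number of classes.
#' @param eps smoothing mass.
#' @return length-`K` target vector.
#' @export
label_smooth <- function(class_id, K, eps = 0.01) {
  t <- rep(eps / K, K)
  t[class_id] <- 1 - eps + eps / K
  t
}

# ---- target assignment -------------------------------------------------

# Center-prior assignment: each ground-truth box is routed to one pyramid
# level by its size (max dimension <= 8*stride), and every cell of that
# level whose center falls inside the box is a positive. Ties on a cell go
# to the smaller box. Boxes too small to contain any cell center fall back
# to the single nearest cell.
assign_targets <- function(ann, input_size, strides = c(8L, 16L, 32L)) {
  out <- lapply(strides, function(s) {
    g <- input_size %/% s
    list(grid = g, pos = matrix(0L, 0, 2), box = matrix(0, 0, 4),
         class_id = integer(0), area = numeric(0))
  })
  obj <- ann$objects
  if (!nrow(obj)) return(out)
  cls_ids <- match(obj$class, VOC_CLASSES)
  for (i in seq_len(nrow(obj))) {
    w <- obj$x2[i] - obj$x1[i]
    h <- obj$y2[i] - obj$y1[i]
    size <- max(w, h)
    li <- which(size <= 8 * strides)[1]
    if (is.na(li)) li <- length(strides)
    s <- strides[li]
    g <- out[[li]]$grid
    cmin <- max(1L, floor(obj$x1[i] / s) + 1L)
    cmax <- min(g, ceiling(obj$x2[i] / s))
    rmin <- max(1L, floor(obj$y1[i] / s) + 1L)
    rmax <- min(g, ceiling(obj$y2[i] / s))
    cells <- NULL
    for (r in seq(rmin, rmax)) {
      for (cc in seq(cmin, cmax)) {
        cx <- (cc - 0.5) * s
        cy <- (r - 0.5) * s
        if (cx >= obj$x1[i] && cx <= obj$x2[i] &&
            cy >= obj$y1[i] && cy <= obj$y2[i]) {
          cells <- rbind(cells, c(r, cc))
        }
      }
    }
    if (is.null(cells)) {
      r <- min(max(1L, ceiling((obj$y1[i] + h / 2) / s)), g)
      cc <- min(max(1L, ceiling((obj$x1[i] + w / 2) / s)), g)
      cells <- matrix(c(r, cc), 1)
    }
    area <- w * h
    lv <- out[[li]]
    for (ci in seq_len(nrow(cells))) {
      dup <- which(lv$pos[, 1] == cells[ci, 1] & lv$pos[, 2] == cells[ci, 2])
      if (length(dup)) {
        if (lv$area[dup[1]] <= area) next
        lv$pos <- lv$pos[-dup, , drop = FALSE]
        lv$box <- lv$box[-dup, , drop = FALSE]
        lv$class_id <- lv$class_id[-dup]
        lv$area <- lv$area[-dup]
      }
      lv$pos <- rbind(lv$pos, cells[ci, ])
      lv$box <- rbind(lv$box, c(obj$x1[i], obj$y1[i], obj$x2[i], obj$y2[i]))
      lv$class_id <- c(lv$class_id, cls_ids[i])
      lv$area <- c(lv$area, area)
    }
    out[[li]] <- lv
  }
  out
}

# gradient of (1 - IoU) w.r.t. the predicted corners; subgradient 0 at ties
iou_and_grad <- function(p, g) {
  iw <- min(p[3], g[3]) - max(p[1], g[1])
  ih <- min(p[4], g[4]) - max(p[2], g[2])
  Ap <- (p[3] - p[1]) * (p[4] - p[2])
  Ag <- (g[3] - g[1]) * (g[4] - g[2])
  if (iw <= 0 || ih <= 0) {
    return(list(iou = 0, grad = NULL))
  }
  I <- iw * ih
  U <- Ap + Ag - I
  dI <- c(if (p[1] > g[1]) -ih else 0,
          if (p[2] > g[2]) -iw else 0,
          if (p[3] < g[3]) ih else 0,
          if (p[4] < g[4]) iw else 0)
  dAp <- c(-(p[4] - p[2]), -(p[3] - p[1]), p[4] - p[2], p[3] - p[1])
  diou_dcorner <- dI * (U + I) / U^2 + dAp * (-I / U^2)
  list(iou = I / U, grad = -diou_dcorner) # gradient of the loss 1 - IoU
}

#' Detection loss (and head gradients)
#'
#' IoU box-regression loss on positives (weight 5), binary cross-entropy
#' objectness over all cells, and binary cross-entropy classification with
#' label smoothing on positives, all normalized by the number of positives.
#' Assignment is the center prior of [assign_targets()]. When a positive
#' prediction does not overlap its target at all (IoU gradient vanishes) an
#' L1 pull on the raw box parameters takes over.
#'
#' @param preds list of head output arrays `(H, W, 5 + K, N)`.
#' @param targets list (length N) of [assign_targets()] results.
#' @param num_classes number of classes `K`.
#' @param smoothing label smoothing mass.
#' @param reg_weight box-loss weight.
#' @param l1_weight weight of the auxiliary L1 loss on the raw (encoded)
#'   box parameters of positives; gives direct, well-conditioned size and
#'   offset supervision alongside the IoU term.
#' @param grad also compute gradients w.r.t. the raw head outputs.
#' @param strides head strides.
#' @return list with `total`, `box`, `obj`, `cls`, `n_pos` and (if `grad`)
#'   `grads` (list of arrays matching `preds`).
#' @export
detection_loss <- function(preds, targets, num_classes, smoothing = 0.01,
                           reg_weight = 5, l1_weight = 1, grad = FALSE,
                           strides = c(8L, 16L, 32L)) {
  N <- dim(preds[[1]])[4]
  n_pos <- 0L
  for (n in seq_len(N)) {
    for (li in seq_along(preds)) n_pos <- n_pos + nrow(targets[[n]][[li]]$pos)
  }
  norm <- max(n_pos, 1L)
  loss_box <- 0; loss_obj <- 0; loss_cls <- 0
  grads <- if (grad) lapply(preds, function(p) array(0, dim(p))) else NULL
  for (li in seq_along(preds)) {
    hm <- preds[[li]]
    s <- strides[li]
    obj_logit <- hm[, , 5, , drop = FALSE]
    so <- sigmoid(obj_logit)
    tgt_obj <- array(0, dim(obj_logit))
    for (n in seq_len(N)) {
      lv <- targets[[n]][[li]]
      np <- nrow(lv$pos)
      if (!np) next
      for (j in seq_len(np)) {
        r <- lv$pos[j, 1]; cc <- lv$pos[j, 2]
        tgt_obj[r, cc, 1, n] <- 1
        gt <- lv$box[j, ]
        # decode this cell's box
        dx <- hm[r, cc, 1, n]; dy <- hm[r, cc, 2, n]
        lw <- hm[r, cc, 3, n]; lh <- hm[r, cc, 4, n]
        cx <- (cc - 1 + dx) * s; cy <- (r - 1 + dy) * s
        w <- exp(lw) * s; h <- exp(lh) * s
        p <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
        ig <- iou_and_grad(p, gt)
        # encoded targets for the auxiliary L1 term
        tw <- log((gt[3] - gt[1]) / s); th <- log((gt[4] - gt[2]) / s)
        tdx <- (gt[1] + gt[3]) / 2 / s - (cc - 1)
        tdy <- (gt[2] + gt[4]) / 2 / s - (r - 1)
        dpar <- c(dx - tdx, dy - tdy, lw - tw, lh - th)
        loss_box <- loss_box + (l1_weight / reg_weight) * sum(abs(dpar))
        if (grad) {
          grads[[li]][r, cc, 1:4, n] <- grads[[li]][r, cc, 1:4, n] +
            sign(dpar) * l1_weight / norm
        }
        if (is.null(ig$grad)) {
          loss_box <- loss_box + 1 # disjoint boxes: IoU term at its maximum
        } else {
          loss_box <- loss_box + (1 - ig$iou)
          if (grad) {
            gc <- ig$grad
            gdx <- (gc[1] + gc[3]) * s
            gdy <- (gc[2] + gc[4]) * s
            glw <- (gc[3] - gc[1]) * 0.5 * w
            glh <- (gc[4] - gc[2]) * 0.5 * h
            grads[[li]][r, cc, 1:4, n] <- grads[[li]][r, cc, 1:4, n] +
              c(gdx, gdy, glw, glh) * reg_weight / norm
          }
        }
        # classification on positives
        tcl <- label_smooth(lv$class_id[j], num_classes, smoothing)
        cl <- hm[r, cc, 5 + seq_len(num_classes), n]
        scl <- sigmoid(cl)
        loss_cls <- loss_cls + sum(-tcl * log(pmax(scl, 1e-12)) -
                                     (1 - tcl) * log(pmax(1 - scl, 1e-12)))
        if (grad) {
          grads[[li]][r, cc, 5 + seq_len(num_classes), n] <-
            grads[[li]][r, cc, 5 + seq_len(num_classes), n] + (scl - tcl) / norm
        }
      }
    }
    loss_obj <- loss_obj + sum(-tgt_obj * log(pmax(so, 1e-12)) -
                                 (1 - tgt_obj) * log(pmax(1 - so, 1e-12)))
    if (grad) grads[[li]][, , 5, ] <- grads[[li]][, , 5, , drop = FALSE] +
        (so - tgt_obj) / norm
  }
  loss_obj <- loss_obj / norm
  loss_box <- loss_box / norm
  loss_cls <- loss_cls / norm
  list(total = reg_weight * loss_box + loss_obj + loss_cls,
       box = loss_box, obj = loss_obj, cls = loss_cls,
       n_pos = n_pos, grads = grads)
}

# ---- SGD ---------------------------------------------------------------

decayable <- function(type, slot) {
  (type %in% c("conv", "eca") && slot == "w") || (type == "dwconv" && slot == "w")
}

sgd_step <- function(net, grads, state, lr, momentum, weight_decay,
                     frozen_modules = character(), sparsity_lambda = 0) {
  for (nm in ls(grads)) {
    l <- net$layers[[nm]]
    if (l$module %in% frozen_modules) next
    g <- grads[[nm]]
    slots <- list(conv = c(dw = "w", db = "b"), dwconv = c(dw = "w"),
                  bn = c(dgamma = "gamma", dbeta = "beta"), eca = c(dw = "w"))
    sm <- slots[[l$type]]
    for (gslot in names(sm)) {
      gr <- g[[gslot]]
      if (is.null(gr)) next
      slot <- sm[[gslot]]
      if (l$type == "bn" && slot == "gamma" && sparsity_lambda > 0 &&
          isTRUE(l$prunable)) {
        gr <- gr + sparsity_lambda * sign(l[[slot]])
      }
      if (weight_decay > 0 && decayable(l$type, slot)) {
        gr <- gr + weight_decay * l[[slot]]
      }
      key <- paste0(nm, "|", slot)
      v <- state[[key]]
      if (is.null(v)) v <- 0 * gr
      v <- momentum * v - lr * gr
      state[[key]] <- v
      net$layers[[nm]][[slot]] <- l[[slot]] + v
    }
  }
  net
}

apply_bn_updates <- function(net, updates) {
  for (nm in names(updates)) {
    net$layers[[nm]]$rmean <- updates[[nm]]$rmean
    net$layers[[nm]]$rvar <- updates[[nm]]$rvar
  }
  net
}

#' Train a detector
#'
#' SGD with momentum and cosine-annealed (optionally warm-up) learning
#' rate. Supports backbone freezing, L1 sparsity on prunable batch-norm
#' scaling factors, and per-epoch checkpoints.
#'
#' @param net an initialized `pest_net`.
#' @param samples list of samples `list(id, image, ann)`; all images must
#'   share the network input size.
#' @param epochs,batch_size,initial_lr,momentum,weight_decay,freeze_backbone
#'   see [phase_config()].
#' @param smoothing label smoothing mass.
#' @param sparsity_lambda L1 penalty on BN gamma (0 disables).
#' @param warmup_frac fraction of total steps with a linear learning-rate
#'   ramp before cosine decay (used by [finetune()]).
#' @param seed RNG seed controlling shuffling.
#' @param checkpoint_dir if set, writes one checkpoint file per epoch.
#' @param phase label recorded in the history.
#' @param verbose print per-epoch loss.
#' @return list with `net`, `history` (data.frame: epoch, phase, lr, loss
#'   components) and `state` (optimizer state env).
#' @export
train_detector <- function(net, samples, epochs, batch_size = 8L,
                           initial_lr = 1e-3, momentum = 0.93,
                           weight_decay = 5e-4, freeze_backbone = FALSE,
                           smoothing = 0.01, sparsity_lambda = 0,
                           warmup_frac = 0, seed = 1L,
                           checkpoint_dir = NULL, phase = "train",
                           verbose = FALSE) {
  if (!length(samples)) stop("train_detector: empty training set")
  nimg <- length(samples)
  K <- net$config$num_classes
  input_size <- dim(samples[[1]]$image)[1]
  targets <- lapply(samples, function(s) {
    assign_targets(s$ann, input_size, net$strides)
  })
  steps_per_epoch <- ceiling(nimg / batch_size)
  total_steps <- max(epochs * steps_per_epoch, 1L)
  warm <- floor(warmup_frac * total_steps)
  state <- new.env(parent = emptyenv())
  history <- NULL
  frozen <- if (freeze_backbone) "backbone" else character()
  set.seed(seed)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nimg)
    ep_loss <- c(total = 0, box = 0, obj = 0, cls = 0)
    nb <- 0L
    for (bi in seq_len(steps_per_epoch)) {
      idx <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, nimg)]
      x <- array(0, c(input_size, input_size, 3L, length(idx)))
      for (j in seq_along(idx)) x[, , , j] <- samples[[idx[j]]]$image / 255
      lr <- if (step < warm && warm > 0) {
        initial_lr * (step + 1) / warm
      } else {
        cosine_lr(min(step, total_steps), total_steps, initial_lr)
      }
      fw <- net_forward(net, x, train = TRUE, frozen_modules = frozen)
      net <- apply_bn_updates(net, fw$bn_updates)
      ls <- detection_loss(fw$outs, targets[idx], K, smoothing,
                           grad = TRUE, strides = net$strides)
      douts <- stats::setNames(ls$grads, net$outputs)
      grads <- net_backward(net, fw, douts, frozen_modules = frozen)
      net <- sgd_step(net, grads, state, lr, momentum, weight_decay,
                      frozen_modules = frozen,
                      sparsity_lambda = sparsity_lambda)
      ep_loss <- ep_loss + c(ls$total, ls$box, ls$obj, ls$cls)
      nb <- nb + 1L
      step <- step + 1L
    }
    ep_loss <- ep_loss / nb
    history <- rbind(history, data.frame(
      epoch = ep, phase = phase, lr = lr, loss = ep_loss[1],
      box = ep_loss[2], obj = ep_loss[3], cls = ep_loss[4]))
    if (verbose) {
      message(sprintf("[%s] epoch %d/%d lr %.2e loss %.4f", phase, ep,
                      epochs, lr, ep_loss[1]))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(net, file.path(checkpoint_dir,
                             sprintf("%s_epoch%03d.rds", phase, ep)))
    }
  }
  rownames(history) <- NULL
  list(net = net, history = history, state = state)
}

#' Two-phase transfer training
#'
#' Phase 1 freezes every backbone parameter and trains neck and heads;
#' phase 2 unfreezes and fine-tunes the whole network at a lower rate. Both
#' phases use cosine annealing, momentum 0.93, weight decay 5e-4 and label
#' smoothing 0.01 by default.
#'
#' @param net an initialized `pest_net`.
#' @param samples training samples.
#' @param phase1,phase2 [phase_config()]s.
#' @param seed RNG seed.
#' @param checkpoint_dir optional per-epoch checkpoint directory.
#' @param verbose print progress.
#' @return list with `net` and combined `history`.
#' @export
two_phase_train <- function(net, samples,
                            phase1 = phase_config(100, 32, 1e-3,
                                                  freeze_backbone = TRUE),
                            phase2 = phase_config(100, 16, 1e-4),
                            seed = 1L, checkpoint_dir = NULL,
                            verbose = FALSE) {
  r1 <- train_detector(net, samples, phase1$epochs, phase1$batch_size,
                       phase1$initial_lr, phase1$momentum,
                       phase1$weight_decay, phase1$freeze_backbone,
                       seed = seed, checkpoint_dir = checkpoint_dir,
                       phase = "phase1", verbose = verbose)
  r2 <- train_detector(r1$net, samples, phase2$epochs, phase2$batch_size,
                       phase2$initial_lr, phase2$momentum,
                       phase2$weight_decay, phase2$freeze_backbone,
                       seed = seed + 1L, checkpoint_dir = checkpoint_dir,
                       phase = "phase2", verbose = verbose)
  list(net = r2$net, history = rbind(r1$history, r2$history))
}

#' Warm-up fine-tuning
#'
#' Training restart used after pruning: the learning rate ramps linearly
#' over the first 10% of steps (so step 0 trains well below the peak rate),
#' then follows cosine decay.
#'
#' @param net a (typically pruned) `pest_net`.
#' @param samples training samples.
#' @param epochs,batch_size,initial_lr,seed,verbose as in
#'   [train_detector()].
#' @return list with `net` and `history`.
#' @export
finetune <- function(net, samples, epochs = 10L, batch_size = 8L,
                     initial_lr = 1e-4, seed = 1L, verbose = FALSE) {
  if (epochs == 0L) return(list(net = net, history = NULL))
  r <- train_detector(net, samples, epochs, batch_size, initial_lr,
                      warmup_frac = 0.1, seed = seed, phase = "finetune",
                      verbose = verbose)
  list(net = r$net, history = r$history)
}

#' Run detection on one image
#'
#' Forward pass, anchor-free decode, then NMS.
#'
#' @param net an initialized `pest_net`.
#' @param image array `(H, W, 3)` with 0..255 values.
#' @param score_threshold decode confidence floor.
#' @param nms an [nms_config()].
#' @return detections `data.frame`.
#' @export
detect_image <- function(net, image, score_threshold = 0.3,
                         nms = nms_config()) {
  outs <- predict_raw(net, image / 255)
  dets <- decode_predictions(outs, net$strides, score_threshold)
  nms_by_class(dets, nms)
}

#' Evaluate a detector on a sample set
#'
#' @param net an initialized `pest_net`.
#' @param samples evaluation samples.
#' @param score_threshold decode confidence floor.
#' @param nms an [nms_config()].
#' @param cfg a [match_config()].
#' @return an `eval_result`.
#' @export
evaluate_model <- function(net, samples, score_threshold = 0.3,
                           nms = nms_config(), cfg = match_config()) {
  dets <- list()
  truths <- list()
  for (s in samples) {
    dets[[s$id]] <- detect_image(net, s$image, score_threshold, nms)
    ob <- s$ann$objects
    truths[[s$id]] <- data.frame(x1 = ob$x1, y1 = ob$y1, x2 = ob$x2,
                                 y2 = ob$y2,
                                 class_id = match(ob$class, VOC_CLASSES))
  }
  evaluate_detections(dets, truths, cfg)
}
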