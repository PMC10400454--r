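test_that("cosine annealing hits its endpoints and is scale invariant", {
  expect_equal(cosine_lr(0, 100, 0.01), 0.01)
  expect_equal(cosine_lr(100, 100, 0.01), 0)
  expect_equal(cosine_lr(50, 100, 0.01), 0.005)
  expect_error(cosine_lr(101, 100, 0.01), "t must lie")
  expect_error(cosine_lr(1, 0, 0.01), "T must be")
  # eta_t / eta depends only on t / T
  for (frac in c(0.1, 0.33, 0.77)) {
    expect_equal(cosine_lr(frac * 40, 40, 1), cosine_lr(frac * 4000, 4000, 1))
  }
  # monotonically non-increasing
  lr <- cosine_lr(0:200, 200, 0.01)
  expect_true(all(diff(lr) <= 0))
})

test_that("label smoothing matches the epsilon formula", {
  expect_equal(label_smooth(1, 2, 0.01), c(0.995, 0.005))
  expect_equal(label_smooth(2, 2, 0.01), c(0.005, 0.995))
  expect_equal(sum(label_smooth(3, 5, 0.1)), 1)
  expect_equal(label_smooth(1, 2, 0), c(1, 0))
})

test_that("center-prior assignment routes boxes by size and position", {
  ann <- annotation("t", 256, 256, data.frame(
    class = c("young", "old"), x1 = c(16, 100), y1 = c(16, 100),
    x2 = c(48, 228), y2 = c(48, 228), occlusion = 0))
  tg <- pestlite:::assign_targets(ann, 256)
  # 32-px box -> stride 8; 128-px box -> stride 16
  expect_gt(nrow(tg[[1]]$pos), 0)
  expect_gt(nrow(tg[[2]]$pos), 0)
  expect_identical(nrow(tg[[3]]$pos), 0L)
  # every positive cell center lies inside its assigned box
  for (li in 1:2) {
    lv <- tg[[li]]
    s <- c(8, 16, 32)[li]
    for (j in seq_len(nrow(lv$pos))) {
      cx <- (lv$pos[j, 2] - 0.5) * s
      cy <- (lv$pos[j, 1] - 0.5) * s
      expect_true(cx >= lv$box[j, 1] && cx <= lv$box[j, 3])
      expect_true(cy >= lv$box[j, 2] && cy <= lv$box[j, 4])
    }
  }
  # empty image assigns nothing
  tg0 <- pestlite:::assign_targets(annotation("e", 256, 256), 256)
  expect_true(all(vapply(tg0, function(l) nrow(l$pos), 1L) == 0L))
})

test_that("detection loss is zero-box at the optimum and decomposes", {
  ann <- annotation("t", 64, 64, data.frame(class = "old", x1 = 8, y1 = 8,
                                            x2 = 40, y2 = 40, occlusion = 0))
  tg <- list(pestlite:::assign_targets(ann, 64))
  mk <- function() lapply(c(8, 16, 32), function(s) {
    array(-30, c(64 %/% s, 64 %/% s, 7, 1))
  })
  # perfect predictions: encoded targets at positives, saturated logits
  preds <- mk()
  for (li in 1:3) {
    lv <- tg[[1]][[li]]
    s <- c(8, 16, 32)[li]
    for (j in seq_len(nrow(lv$pos))) {
      r <- lv$pos[j, 1]; cc <- lv$pos[j, 2]
      gt <- lv$box[j, ]
      preds[[li]][r, cc, 1, 1] <- (gt[1] + gt[3]) / 2 / s - (cc - 1)
      preds[[li]][r, cc, 2, 1] <- (gt[2] + gt[4]) / 2 / s - (r - 1)
      preds[[li]][r, cc, 3, 1] <- log((gt[3] - gt[1]) / s)
      preds[[li]][r, cc, 4, 1] <- log((gt[4] - gt[2]) / s)
      preds[[li]][r, cc, 5, 1] <- 30
      preds[[li]][r, cc, 5 + lv$class_id[j], 1] <- 30
    }
  }
  ls <- detection_loss(preds, tg, 2)
  expect_equal(ls$box, 0, tolerance = 1e-9)
  expect_lt(ls$obj, 1e-9)
  # the classification floor is the smoothing cross-entropy, not zero
  expect_gt(ls$cls, 0)
  # empty image: objectness-only loss
  tg0 <- list(pestlite:::assign_targets(annotation("e", 64, 64), 64))
  ls0 <- detection_loss(mk(), tg0, 2)
  expect_equal(ls0$box, 0)
  expect_equal(ls0$cls, 0)
  expect_gt(ls0$obj, 0)
  expect_equal(ls0$total, ls0$obj)
})

test_that("loss components match hand-computed BCE on a toy cell", {
  # 2x2 stride-32 toy: one positive cell with known logits
  ann <- annotation("t", 64, 64, data.frame(class = "young", x1 = 2, y1 = 2,
                                            x2 = 62, y2 = 62, occlusion = 0))
  tg <- pestlite:::assign_targets(ann, 64, strides = 32L)
  preds <- list(array(0, c(2, 2, 7, 1)))
  preds[[1]][, , 5, 1] <- c(2, -1, 0.5, -3)
  ls <- detection_loss(preds, list(list(tg[[1]])), 2, smoothing = 0,
                       l1_weight = 0, strides = 32L)
  np <- nrow(tg[[1]]$pos)
  sig <- function(x) 1 / (1 + exp(-x))
  tmat <- matrix(0, 2, 2)
  for (j in seq_len(np)) tmat[tg[[1]]$pos[j, 1], tg[[1]]$pos[j, 2]] <- 1
  lmat <- matrix(c(2, -1, 0.5, -3), 2, 2)
  bce <- -tmat * log(sig(lmat)) - (1 - tmat) * log(1 - sig(lmat))
  expect_equal(ls$obj, sum(bce) / np, tolerance = 1e-12)
})

test_that("two-phase training freezes the backbone then unfreezes", {
  set.seed(1)
  samples <- generate_samples(4, canvas = 64, seed = 61,
                              occlusion_range = c(0, 0))
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 3)
  r1 <- train_detector(net, samples, epochs = 1, batch_size = 2,
                       initial_lr = 1e-3, freeze_backbone = TRUE, seed = 9)
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    if (!is.null(l$module) && l$module == "backbone" && l$type == "conv") {
      expect_identical(r1$net$layers[[nm]]$w, l$w)
    }
  }
  # a head conv did move
  moved <- any(vapply(names(net$layers), function(nm) {
    l <- net$layers[[nm]]
    l$type == "conv" && l$module == "head" &&
      !identical(r1$net$layers[[nm]]$w, l$w)
  }, TRUE))
  expect_true(moved)
})

test_that("a short training run reduces the loss deterministically", {
  samples <- generate_samples(6, canvas = 64, seed = 71,
                              occlusion_range = c(0, 0.2))
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 4)
  r <- two_phase_train(net, samples,
                       phase1 = phase_config(2, 2, 2e-3, freeze_backbone = TRUE),
                       phase2 = phase_config(2, 2, 5e-4), seed = 13)
  expect_lt(tail(r$history$loss, 1), r$history$loss[1])
  expect_identical(nrow(r$history), 4L)
  expect_identical(unique(r$history$phase), c("phase1", "phase2"))
  # same seed, same result (bitwise on a weight tensor)
  net_b <- build_model(tiny_csp_config(), init = TRUE, seed = 4)
  r_b <- two_phase_train(net_b, samples,
                         phase1 = phase_config(2, 2, 2e-3, freeze_backbone = TRUE),
                         phase2 = phase_config(2, 2, 5e-4), seed = 13)
  expect_identical(r$net$layers$head1.cls_pred$w, r_b$net$layers$head1.cls_pred$w)
  expect_equal(r$history$loss, r_b$history$loss)
})

test_that("finetune warms up below the peak rate and zero epochs is identity", {
  samples <- generate_samples(4, canvas = 64, seed = 81,
                              occlusion_range = c(0, 0))
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 5)
  expect_identical(finetune(net, samples, epochs = 0)$net, net)
  r <- finetune(net, samples, epochs = 2, batch_size = 1, initial_lr = 1e-3,
                seed = 3)
  expect_lt(r$history$lr[1], 1e-3) # still warming up at the first epoch end
})

test_that("per-epoch checkpoints are written", {
  samples <- generate_samples(2, canvas = 64, seed = 91,
                              occlusion_range = c(0, 0))
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 6)
  ckdir <- file.path(tempdir(), "ckpt_test")
  unlink(ckdir, recursive = TRUE)
  train_detector(net, samples, epochs = 2, batch_size = 2,
                 initial_lr = 1e-4, seed = 2, checkpoint_dir = ckdir)
  expect_length(list.files(ckdir, pattern = "epoch"), 2)
  unlink(ckdir, recursive = TRUE)
})
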