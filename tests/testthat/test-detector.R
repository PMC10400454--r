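test_that("model configs validate and presets resolve", {
  cfg <- model_config("yolox-s")
  expect_equal(cfg$depth_multiplier, 0.33)
  expect_equal(cfg$width_multiplier, 0.5)
  expect_identical(cfg$num_classes, 80L)
  expect_error(model_config("yolox-q"), "unknown variant")
  expect_error(model_config(NULL, 0.5, 0.5, input_size = 100), "divisible by 32")
  expect_error(model_config(NULL, -1, 0.5), "positive")
  expect_error(model_config(NULL, 0.5, 0.5, num_classes = 0), "num_classes")
})

test_that("head outputs obey the stride-8/16/32 contract for every axis", {
  combos <- list(
    list(backbone = "cspdarknet", neck = "pafpn", act = "silu"),
    list(backbone = "ghostnet_ge", neck = "pafpn", act = "silu"),
    list(backbone = "cspdarknet", neck = "pafpn_asff", act = "ts"),
    list(backbone = "ghostnet_ge", neck = "pafpn_asff", act = "ts"))
  for (cb in combos) {
    cfg <- model_config(NULL, 0.11, 0.125, backbone = cb$backbone,
                        neck = cb$neck, head_activation = cb$act,
                        num_classes = 2L, input_size = 96L)
    net <- build_model(cfg, init = TRUE, seed = 1)
    outs <- predict_raw(net, array(runif(96 * 96 * 3), c(96, 96, 3)))
    expect_length(outs, 3)
    for (li in 1:3) {
      g <- 96L %/% c(8L, 16L, 32L)[li]
      expect_identical(dim(outs[[li]])[1:3], c(g, g, 7L),
                       info = paste(cb$backbone, cb$neck, li))
    }
  }
})

test_that("parameter counting is an exact enumeration of learnable tensors", {
  cfg <- tiny_csp_config()
  net <- build_model(cfg, init = TRUE, seed = 2)
  # oracle: walk the allocated arrays directly
  brute <- 0
  for (l in net$layers) {
    for (slot in c("w", "b", "gamma", "beta")) {
      if (!is.null(l[[slot]])) brute <- brute + length(l[[slot]])
    }
  }
  expect_identical(count_params(net), brute)
  # shape-only build agrees with the allocated build
  net0 <- build_model(cfg, init = FALSE)
  expect_identical(count_params(net0), count_params(net))
})

test_that("ghost backbone is strictly lighter; TS costs no parameters", {
  base <- list(0.33, 0.25)
  csp <- build_model(model_config(NULL, base[[1]], base[[2]],
                                  backbone = "cspdarknet", num_classes = 2),
                     init = FALSE)
  gho <- build_model(model_config(NULL, base[[1]], base[[2]],
                                  backbone = "ghostnet_ge", num_classes = 2),
                     init = FALSE)
  expect_lt(count_params(gho), count_params(csp))
  ts <- build_model(model_config(NULL, base[[1]], base[[2]],
                                 backbone = "cspdarknet",
                                 head_activation = "ts", num_classes = 2),
                    init = FALSE)
  expect_identical(count_params(ts), count_params(csp))
})

test_that("layer summaries and FLOPs follow the printed conventions", {
  cfg <- tiny_csp_config()
  net <- build_model(cfg, init = FALSE)
  tab <- summarize_layers(net)
  stem <- tab[tab$layer == "stem.conv", ]
  # Focus stem at 64 px: 32x32 output, 12 -> W(64)=8 channels, k=3
  expect_equal(stem$H, 32)
  expect_equal(stem$C_in, 12)
  expect_equal(stem$C_out, 8)
  expect_equal(stem$params, 3 * 3 * 12 * 8)
  expect_equal(stem$flops, 2 * 32 * 32 * (12 * 9 + 1) * 8)
  fl <- count_flops(net)
  expect_equal(fl$macs, fl$flops / 2)
  # single-conv check of the formula: H=W=2, Cin=1, K=1, Cout=1 -> 16
  expect_equal(2 * 2 * 2 * (1 * 1 + 1) * 1, 16)
  # parameters are input-size invariant; FLOPs scale with H*W
  expect_identical(count_params(net), count_params(net))
  f64 <- count_flops(net, 64)$flops
  f128 <- count_flops(net, 128)$flops
  expect_equal(f128 / f64, 4, tolerance = 0.01)
})

test_that("ASFF weights form a simplex and blend as specified", {
  set.seed(6)
  H <- 8
  lv <- lapply(1:3, function(i) array(rnorm(H * H * 4), c(H, H, 4)))
  # equal logits: the fused map is the plain mean
  z <- array(0, c(H, H, 3))
  y <- asff_fuse(lv, 1, logits = z)
  expect_equal(y, (lv[[1]] + lv[[2]] + lv[[3]]) / 3)
  # softmax limit: a dominant logit selects its level
  z2 <- z; z2[, , 1] <- 20
  expect_equal(asff_fuse(lv, 1, logits = z2), lv[[1]], tolerance = 1e-4)
  # random logits: weights sum to one at every position, so fusing
  # identical inputs returns the input
  z3 <- array(rnorm(H * H * 3), c(H, H, 3))
  same <- list(lv[[1]], lv[[1]], lv[[1]])
  expect_equal(asff_fuse(same, 2, logits = z3), lv[[1]], tolerance = 1e-12)
})

test_that("ASFF resizes non-target levels with compression and striding", {
  set.seed(7)
  lv <- list(array(rnorm(16 * 16 * 2), c(16, 16, 2)),
             array(rnorm(8 * 8 * 4), c(8, 8, 4)),
             array(rnorm(4 * 4 * 8), c(4, 4, 8)))
  w <- list(
    compress = list(NULL, array(rnorm(4 * 2, sd = 0.5), c(1, 1, 4, 2)),
                    array(rnorm(8 * 2, sd = 0.5), c(1, 1, 8, 2))),
    logit = list(w = array(rnorm(6 * 3, sd = 0.3), c(1, 1, 6, 3)),
                 b = rep(0, 3)))
  y <- asff_fuse(lv, 1, weights = w)
  expect_identical(dim(y), c(16L, 16L, 2L))
  # coarser target: finer levels enter through stride-2 convolutions
  w3 <- list(
    compress = list(array(rnorm(2 * 8, sd = 0.5), c(1, 1, 2, 8)),
                    array(rnorm(4 * 8, sd = 0.5), c(1, 1, 4, 8)), NULL),
    down = list(list(array(rnorm(9 * 8 * 8, sd = 0.2), c(3, 3, 8, 8)),
                     array(rnorm(9 * 8 * 8, sd = 0.2), c(3, 3, 8, 8))),
                list(array(rnorm(9 * 8 * 8, sd = 0.2), c(3, 3, 8, 8)))),
    logit = list(w = array(rnorm(24 * 3, sd = 0.3), c(1, 1, 24, 3)),
                 b = rep(0, 3)))
  y3 <- asff_fuse(lv, 3, weights = w3)
  expect_identical(dim(y3), c(4L, 4L, 8L))
  expect_error(asff_fuse(lv, 2, logits = array(0, c(8, 8, 3))), "match")
})

test_that("decode + detect integrate with a built model", {
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 5)
  img <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  dets <- detect_image(net, img, score_threshold = 1e-4)
  expect_true(is.data.frame(dets))
  if (nrow(dets)) {
    expect_true(all(dets$score >= 1e-4 & dets$score <= 1))
    expect_true(all(dets$class_id %in% 1:2))
  }
})
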