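test_that("sparsity penalty is the scaled L1 norm of the scaling factors", {
  expect_equal(sparsity_penalty(c(1, -2, 3), 0.001), 0.006)
  expect_equal(sparsity_penalty(rnorm(10), 0), 0)
  expect_equal(sparsity_penalty(rep(0, 5), 0.5), 0)
  expect_error(sparsity_penalty(1, -1), "lambda")
})

test_that("channel ranking sorts |gamma| globally with stable ties", {
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 1)
  net <- randomize_bn(net, seed = 2)
  rk <- rank_channels(net)
  expect_true(all(diff(rk$abs_gamma) >= 0))
  # matches an independent full sort
  gathered <- unlist(lapply(net$layers, function(l) {
    if (l$type == "bn" && isTRUE(l$prunable)) abs(l$gamma) else NULL
  }))
  expect_equal(rk$abs_gamma, unname(sort(gathered)))
  # all-equal gammas: provenance (layer order, then channel) breaks ties
  for (nm in names(net$layers)) {
    if (net$layers[[nm]]$type == "bn") {
      net$layers[[nm]]$gamma <- rep(0.5, net$layers[[nm]]$c)
    }
  }
  rk2 <- rank_channels(net)
  first_bn <- rk2$layer[1]
  expect_equal(rk2$channel[rk2$layer == first_bn],
               sort(rk2$channel[rk2$layer == first_bn]))
})

test_that("plans honor the ratio, the quantile rule and the layer floor", {
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 3)
  net <- randomize_bn(net, seed = 4)
  # ratio 0: keep everything
  p0 <- build_pruning_plan(net, 0)
  expect_identical(p0$removed, 0L)
  expect_true(all(unlist(p0$keep)))
  expect_error(build_pruning_plan(net, 1), "ratio")
  p65 <- build_pruning_plan(net, 0.65)
  target <- floor(0.65 * p65$prunable_total)
  expect_lte(abs(p65$removed - target), max(2, 0.02 * p65$prunable_total))
  # no layer was emptied
  for (nm in names(p65$keep)) expect_gte(sum(p65$keep[[nm]]), 1)
})

test_that("ten uncoupled channels at ratio 0.65 lose exactly six", {
  # one prunable 10-channel BN between a conv and a biased output conv
  nb <- pestlite:::new_netbuilder()
  pestlite:::add_layer(nb, "input", "input", character(), channels = 3L,
                       module = "backbone")
  pestlite:::conv_unit(nb, "body", "input", 3L, 10L, 3L, 1L, "silu", "backbone")
  pestlite:::add_layer(nb, "out", "conv", "body.act", k = 1L, stride = 1L,
                       pad = 0L, cin = 10L, cout = 2L, bias = TRUE,
                       module = "head")
  net <- pestlite:::finish_net(nb, "out", model_config(NULL, 1, 1,
                                                       num_classes = 2))
  net <- pestlite:::net_init_params(net, seed = 1)
  net$layers$body.bn$gamma <- seq(0.1, 1, by = 0.1)
  plan <- build_pruning_plan(net, 0.65)
  expect_identical(plan$removed, 6L)
  expect_equal(plan$gamma_star, 0.6)
  expect_equal(which(!plan$keep$body.bn), 1:6)
})

test_that("a layer whose channels all rank lowest keeps exactly one channel", {
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 5)
  net <- randomize_bn(net, seed = 6, gamma_range = c(0.5, 1.5))
  # push one uncoupled layer's gammas to the global bottom
  victim <- "neck.lateral0.bn"
  net$layers[[victim]]$gamma <- seq(1e-6, 1e-5,
                                    length.out = net$layers[[victim]]$c)
  plan <- build_pruning_plan(net, 0.6, layer_floor = 0)
  expect_identical(sum(plan$keep[[victim]]), 1L)
  # the survivor is the largest |gamma|
  expect_identical(which(plan$keep[[victim]]), net$layers[[victim]]$c)
  # the default proportional floor keeps a working reserve instead
  plan2 <- build_pruning_plan(net, 0.6)
  expect_gte(sum(plan2$keep[[victim]]),
             ceiling(0.2 * net$layers[[victim]]$c))
})

test_that("achieved prune fraction lands within 2 points on a >=100-channel net", {
  cfg <- model_config(NULL, 0.33, 0.25, backbone = "cspdarknet",
                      neck = "pafpn", num_classes = 2, input_size = 64)
  net <- build_model(cfg, init = TRUE, seed = 7)
  net <- randomize_bn(net, seed = 8, gamma_range = c(0, 1))
  tab <- pestlite:::bn_gamma_table(net)
  expect_gte(nrow(tab), 100)
  for (ratio in c(0.3, 0.5, 0.65)) {
    plan <- build_pruning_plan(net, ratio)
    expect_lt(abs(plan$achieved - ratio), 0.02, label = paste("ratio", ratio))
  }
})

test_that("ratio-0 pruning leaves behavior bit-identical", {
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 9)
  net <- randomize_bn(net, seed = 10)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  y0 <- predict_raw(net, x)
  pruned <- apply_pruning(net, build_pruning_plan(net, 0))
  expect_identical(predict_raw(pruned, x), y0)
})

test_that("removing zero-gamma channels preserves the function", {
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 11)
  net <- randomize_bn(net, seed = 12)
  net <- zero_some_groups(net, frac = 0.3, seed = 13)
  plan <- build_pruning_plan(net, 0.25)
  expect_equal(plan$gamma_star, 0) # only exact-zero groups were removed
  pruned <- apply_pruning(net, plan)
  expect_lt(count_params(pruned), count_params(net))
  set.seed(14)
  for (rep in 1:20) {
    x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
    y0 <- predict_raw(net, x)
    y1 <- predict_raw(pruned, x)
    for (nm in names(y0)) expect_lt(max(abs(y0[[nm]] - y1[[nm]])), 1e-5)
  }
})

test_that("pruning at a ratio is idempotent at the same ratio", {
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 15)
  net <- randomize_bn(net, seed = 16, gamma_range = c(0, 1))
  plan <- build_pruning_plan(net, 0.4)
  pruned <- apply_pruning(net, plan)
  plan2 <- build_pruning_plan(pruned, 0.4)
  expect_identical(plan2$removed, 0L)
  expect_identical(count_params(apply_pruning(pruned, plan2)),
                   count_params(pruned))
  # and the achieved fraction is anchored to the original network
  expect_equal(plan2$achieved, plan$achieved)
})

test_that("pruned GE/ASFF networks stay runnable end to end", {
  cfg <- model_config("pest-nano", input_size = 64)
  net <- build_model(cfg, init = TRUE, seed = 17)
  net <- randomize_bn(net, seed = 18, gamma_range = c(0, 1))
  plan <- build_pruning_plan(net, 0.5)
  pruned <- apply_pruning(net, plan)
  expect_lt(count_params(pruned), count_params(net))
  outs <- predict_raw(pruned, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_length(outs, 3)
  expect_identical(dim(outs[[1]])[1:3], c(8L, 8L, 7L))
  # a pruned network can still train (one step does not error)
  samples <- generate_samples(2, canvas = 64, seed = 19,
                              occlusion_range = c(0, 0))
  r <- train_detector(pruned, samples, epochs = 1, batch_size = 2,
                      initial_lr = 1e-4, seed = 20)
  expect_s3_class(r$history, "data.frame")
})

test_that("plan serialization writes valid JSON", {
  net <- build_model(tiny_csp_config(), init = TRUE, seed = 21)
  net <- randomize_bn(net, seed = 22, gamma_range = c(0, 1))
  plan <- build_pruning_plan(net, 0.3)
  f <- tempfile(fileext = ".json")
  write_pruning_plan(plan, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$ratio, 0.3)
  expect_equal(length(back$keep), length(plan$keep))
})
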