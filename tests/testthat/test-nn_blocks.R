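test_that("TS activation matches its definition and a high-precision oracle", {
  expect_identical(ts_activation(0), 0)
  # reference values computed with a 30-digit arbitrary-precision evaluation
  # of tanh(x) * log(1 + exp(x))
  expect_equal(ts_activation(10), 10.000045357675957, tolerance = 1e-12)
  expect_equal(ts_activation(-10), -4.5398899029716436e-05, tolerance = 1e-12)
  expect_equal(ts_activation(1.5), 1.540031257294276, tolerance = 1e-12)
  expect_equal(ts_activation(-0.5), -0.21907910825170952, tolerance = 1e-12)
  # numerically stable in both tails
  expect_equal(ts_activation(800), 800)
  expect_equal(ts_activation(-800), 0)
})

test_that("TS activation has the right asymptotics and keeps shapes", {
  x <- seq(5, 60, by = 5)
  expect_true(all(abs(ts_activation(x) / x - 1) < 1e-2))
  expect_true(all(diff(abs(ts_activation(-x))) < 0)) # decays to 0 on the left
  a <- array(rnorm(24), c(2, 3, 4))
  expect_identical(dim(ts_activation(a)), dim(a))
})

test_that("ECA kernel size follows the adaptive odd rule", {
  expect_identical(eca_kernel_size(256), 5L) # 4.5 -> ties round up
  expect_identical(eca_kernel_size(2), 1L)
  expect_identical(eca_kernel_size(512), 5L)
  expect_identical(eca_kernel_size(1), 1L)
  ks <- vapply(1:4096, eca_kernel_size, 1L)
  expect_true(all(ks %% 2 == 1))
  expect_true(all(ks >= 1))
  expect_true(all(diff(ks) >= 0)) # non-decreasing in C
  expect_error(eca_kernel_size(0), "C must be")
})

test_that("Ghost cost model reproduces the closed-form compression ratio", {
  sp <- ghost_spec(1, 1, k = 1, s = 1, out_h = 1, out_w = 1)
  expect_equal(conv_cost(sp), 1)
  expect_equal(ghost_cost(sp), 1)
  expect_equal(ghost_compression_ratio(64, 2), 128 / 65)
  for (s in c(1, 2, 4)) {
    for (c in c(8, 64, 256)) {
      n <- 4 * s
      sp <- ghost_spec(c, n, k = 3, s = s, out_h = 5, out_w = 7)
      expect_lte(ghost_cost(sp), conv_cost(sp))
      expect_equal(conv_cost(sp) / ghost_cost(sp),
                   ghost_compression_ratio(c, s))
    }
  }
  expect_error(ghost_spec(4, 5, s = 2), "divisible")
})

test_that("ghost module concatenates real and ghost channels", {
  set.seed(1)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  # s = 1: plain convolution
  sp1 <- ghost_spec(3, 4, k = 1, s = 1)
  w1 <- list(primary = array(rnorm(3 * 4), c(1, 1, 3, 4)))
  expect_equal(ghost_module_forward(x, sp1, w1), conv2d(x, w1$primary))
  # s = 2 with identity depthwise kernels: ghosts duplicate the real half
  sp2 <- ghost_spec(3, 4, k = 1, s = 2)
  idk <- array(0, c(3, 3, 2, 1))
  idk[2, 2, , 1] <- 1
  w2 <- list(primary = array(rnorm(3 * 2), c(1, 1, 3, 2)), cheap = idk)
  y <- ghost_module_forward(x, sp2, w2)
  expect_identical(dim(y), c(8L, 8L, 4L))
  expect_equal(y[, , 3:4], y[, , 1:2])
})

test_that("ECA gates per channel and preserves shape", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 4, mean = 2), c(6, 6, 4))
  expect_identical(dim(eca_forward(x, rnorm(3))), dim(x))
  # saturated gate: huge kernel weight and positive means -> identity
  y <- eca_forward(x, 50)
  expect_equal(y, x, tolerance = 1e-6)
  # k = 1: channel i scaled by sigmoid(w * mean_i)
  w <- 0.7
  y1 <- eca_forward(x, w)
  m <- apply(x, 3, mean)
  for (ch in 1:4) {
    expect_equal(y1[, , ch], x[, , ch] * pestlite:::sigmoid(w * m[ch]))
  }
})

test_that("GE block reduces to its shortcut with zero trunk weights", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  zero_gm <- function(cin, cout) {
    list(primary = array(0, c(1, 1, cin, cout %/% 2)),
         cheap = array(0, c(3, 3, cout %/% 2, 1)))
  }
  cfg <- list(cin = 4, cout = 4, stride = 1)
  w <- list(gm1 = zero_gm(4, 4), gm2 = zero_gm(4, 4), eca = rnorm(3))
  expect_equal(ge_block_forward(x, cfg, w), x)
  # stride 2 halves the spatial dims
  cfg2 <- list(cin = 4, cout = 8, stride = 2)
  w2 <- list(gm1 = zero_gm(4, 8), gm2 = zero_gm(8, 8), eca = rnorm(3),
             dw = array(rnorm(9 * 8), c(3, 3, 8)),
             short = list(dw = array(rnorm(9 * 4), c(3, 3, 4)),
                          pw = array(rnorm(4 * 8), c(1, 1, 4, 8))))
  expect_identical(dim(ge_block_forward(x, cfg2, w2)), c(4L, 4L, 8L))
  # with a saturated ECA gate the block equals the ECA-free composition;
  # positive weights on positive inputs keep every channel mean positive,
  # so a large single-tap kernel drives each gate to 1
  gm <- function(cin, cout) {
    list(primary = array(abs(rnorm(cin * cout / 2, sd = 0.5)),
                         c(1, 1, cin, cout %/% 2)),
         cheap = array(abs(rnorm(9 * cout / 2, sd = 0.5)),
                       c(3, 3, cout %/% 2, 1)))
  }
  w3 <- list(gm1 = gm(4, 4), gm2 = gm(4, 4), eca = 60)
  w3_free <- w3
  w3_free$eca <- NULL
  y_gated <- ge_block_forward(abs(x), cfg, w3)
  y_free <- ge_block_forward(abs(x), cfg, w3_free)
  expect_equal(y_gated, y_free, tolerance = 1e-4)
})

test_that("focus slicing is a lossless permutation", {
  set.seed(4)
  x <- array(rnorm(640 * 2 * 2 * 3 / 4 / 160), c(4, 4, 3))
  y <- focus_forward(x)
  expect_identical(dim(y), c(2L, 2L, 12L))
  expect_equal(focus_inverse(y), x)
  expect_equal(sort(as.vector(y)), sort(as.vector(x)))
  # the published input contract: (640, 640, 3) -> (320, 320, 12)
  big <- array(0, c(640, 640, 3))
  expect_identical(dim(focus_forward(big)), c(320L, 320L, 12L))
  expect_error(focus_forward(array(0, c(5, 4, 3))), "even")
  const <- array(7, c(6, 6, 2))
  expect_true(all(focus_forward(const) == 7))
})

test_that("spatial pyramid pooling concatenates same-size pools", {
  x <- array(3.5, c(20, 20, 2))
  y <- spp_forward(x)
  expect_identical(dim(y), c(20L, 20L, 8L))
  expect_true(all(y == 3.5))
  # a single bright pixel dilates to k x k blocks in the pooled channels
  z <- array(0, c(15, 15, 1))
  z[8, 8, 1] <- 1
  yz <- spp_forward(z, pool_sizes = c(5, 9, 13))
  for (pi in seq_along(c(5, 9, 13))) {
    k <- c(5, 9, 13)[pi]
    plane <- yz[, , 1 + pi]
    expect_equal(sum(plane), k^2)
    expect_true(all(plane[8 + seq(-(k - 1) / 2, (k - 1) / 2), 8] == 1))
  }
})

test_that("batch-norm transform matches its closed form", {
  g <- c(2, 0.5); b <- c(1, -1); mu <- c(0.3, -0.2); sd <- c(1.1, 0.9)
  # centered input maps to beta
  expect_equal(bn_forward(mu, g, b, mu, sd), b)
  # gamma = 0 pins the output at beta regardless of input
  z <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  y <- bn_forward(z, c(0, 0), b, mu, sd)
  expect_true(all(y[, , 1] == b[1]) && all(y[, , 2] == b[2]))
  # standardization with unit gamma/zero beta over the defining batch
  set.seed(5)
  zz <- array(rnorm(8 * 8 * 2 * 6, mean = 3, sd = 2), c(8, 8, 2, 6))
  st <- pestlite:::chan_stats(zz)
  yy <- bn_forward(zz, c(1, 1), c(0, 0), st$mean, sqrt(st$var), eps = 1e-12)
  m <- pestlite:::chan_stats(yy)
  expect_equal(m$mean, c(0, 0), tolerance = 1e-8)
  expect_equal(m$var, c(1, 1), tolerance = 1e-6)
  expect_error(bn_forward(z, g, b, mu, sd, eps = 0), "eps")
  expect_error(bn_forward(z, g, b, mu, c(1, 2, 3)), "channel length")
})
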