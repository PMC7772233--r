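# Brute-force index oracle for the sub-pixel rearrangement (0-based):
# out[i, j, c] = in[i %/% r, j %/% r, c*r^2 + (i %% r)*r + (j %% r)].
subpixel_oracle <- function(x, r) {
  d <- dim(x)
  C <- d[3] %/% (r * r)
  out <- array(NA_real_, c(d[1] * r, d[2] * r, C))
  for (cc in 0:(C - 1))
    for (i in 0:(d[1] * r - 1))
      for (j in 0:(d[2] * r - 1))
        out[i + 1, j + 1, cc + 1] <-
          x[i %/% r + 1, j %/% r + 1,
            cc * r * r + (i %% r) * r + (j %% r) + 1]
  out
}

test_that("subpixel_rearrange matches the index oracle on exhaustive small tensors", {
  set.seed(42)
  for (H in 1:3) for (W in 1:3) for (r in 1:3) for (C in 1:2) {
    x <- array(stats::rnorm(H * W * C * r * r), c(H, W, C * r * r))
    expect_identical(subpixel_rearrange(x, r), subpixel_oracle(x, r))
  }
})

test_that("subpixel_rearrange is a pure permutation with an exact inverse", {
  set.seed(1)
  x <- array(stats::rnorm(4 * 5 * 8), c(4, 5, 8))
  y <- subpixel_rearrange(x, 2)
  expect_identical(dim(y), c(8L, 10L, 2L))
  expect_identical(sort(as.vector(y)), sort(as.vector(x)))
  expect_identical(thinseg:::subpixel_inverse(y, 2), x)
  expect_identical(subpixel_rearrange(x, 1), x)
  expect_error(subpixel_rearrange(x, 3), "divisible")
})

test_that("subpixel_stage reduces to rearrangement under an identity kernel", {
  set.seed(2)
  x <- array(stats::rnorm(3 * 3 * 4), c(3, 3, 4))
  # 1x1 identity convolution: w[1,1,i,j] = 1 iff i == j
  w <- array(0, c(1, 1, 4, 4))
  for (i in 1:4) w[1, 1, i, i] <- 1
  expect_equal(subpixel_stage(x, w, numeric(4), 2), subpixel_rearrange(x, 2),
               tolerance = 1e-12)
  # zero weights and constant bias give a constant map
  w0 <- array(0, c(3, 3, 4, 4))
  out <- subpixel_stage(x, w0, rep(2.5, 4), 2)
  expect_true(all(out == 2.5))
})

test_that("subpixel_stage upscales spatial dims by exactly r", {
  set.seed(3)
  for (r in c(1L, 2L, 4L)) {
    cin <- 3L
    cout <- 2L * r * r
    x <- array(stats::rnorm(8 * 8 * cin), c(8, 8, cin))
    w <- array(stats::rnorm(3 * 3 * cin * cout, 0, 0.1), c(3, 3, cin, cout))
    y <- subpixel_stage(x, w, numeric(cout), r)
    expect_identical(dim(y), c(8L * r, 8L * r, 2L))
  }
})

test_that("model config validates the decoder/encoder downsampling contract", {
  expect_error(model_config(decoder_channels = c(16L, 8L)), "downsampling")
  expect_error(model_config(num_classes = 1L), "num_classes")
  cfg <- model_config()
  expect_equal(cfg$upscale_factor^length(cfg$decoder_channels),
               thinseg:::encoder_downsample(cfg), ignore_attr = TRUE)
})

test_that("build_model is seed-deterministic and pretrained errors offline", {
  m1 <- build_model(tiny_model(seed = 5L))
  m2 <- build_model(tiny_model(seed = 5L))
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_model(seed = 6L))
  expect_false(identical(m1$params, m3$params))
  expect_error(build_model(model_config("resnet34", pretrained = TRUE)),
               "pretrained = FALSE")
})

test_that("forward pass yields normalized probabilities quickly at 64x64", {
  m <- build_model(model_config(seed = 8L))
  x <- array(stats::rnorm(64 * 64 * 3), c(64, 64, 3))
  elapsed <- system.time(p <- model_forward(m, x))[["elapsed"]]
  expect_lt(elapsed, 1)
  expect_identical(dim(p), c(64L, 64L, 2L))
  sums <- apply(p, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(p >= 0))
  # model is not degenerate: different inputs give different outputs
  p0 <- model_forward(m, array(0, c(64, 64, 3)))
  p1 <- model_forward(m, array(1, c(64, 64, 3)))
  expect_false(isTRUE(all.equal(p0, p1)))
})

test_that("non-multiple spatial sizes are padded and cropped transparently", {
  m <- build_model(tiny_model(seed = 9L))
  x <- array(stats::rnorm(37 * 42 * 3), c(37, 42, 3))
  p <- model_forward(m, x)
  expect_identical(dim(p), c(37L, 42L, 2L))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-5)
})

test_that("the ResNet-34 topology builds and runs forward", {
  m <- build_model(model_config("resnet34", seed = 1L))
  p <- model_forward(m, array(stats::rnorm(64 * 64 * 3), c(64, 64, 3)))
  expect_identical(dim(p), c(64L, 64L, 2L))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-5)
})

test_that("tape gradients match numerical differentiation", {
  m <- build_model(tiny_model(seed = 7L))
  set.seed(2)
  x <- array(stats::rnorm(16 * 16 * 3), c(16, 16, 3))
  y <- matrix(sample(0:1, 256, TRUE), 16, 16)
  lossfun <- function(params) {
    fw <- thinseg:::forward_net(thinseg:::model_with(m, params), x)
    supervised_loss(thinseg:::softmax_hw(fw$logits), y)
  }
  fw <- thinseg:::forward_net(m, x)
  p <- thinseg:::softmax_hw(fw$logits)
  g <- thinseg:::net_backward(fw$tape, fw$logits_id,
                              thinseg:::grad_supervised_logits(p, y))
  eps <- 1e-5
  for (nm in c("stem_w", "down2_w", "res3_w", "stem_n_g", "dec1_pn_g",
               "head_w", "head_b")) {
    i <- which.max(abs(g[[nm]]))
    pp <- m$params
    pp[[nm]][i] <- pp[[nm]][i] + eps
    up <- lossfun(pp)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
    dn <- lossfun(pp)
    expect_equal(g[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-4,
                 label = sprintf("analytic gradient of %s", nm))
  }
})
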