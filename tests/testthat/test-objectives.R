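# Helpers building constant probability maps.
const_prob <- function(p_fg, H = 4L, W = 4L) {
  out <- array(0, c(H, W, 2L))
  out[, , 1] <- 1 - p_fg
  out[, , 2] <- p_fg
  out
}

test_that("divergence generators satisfy f(1) = 0 and the f(0) conventions", {
  kl <- divergence_kind("kl")
  chi <- divergence_kind("pearson_chi2")
  expect_identical(kl$f(1), 0)
  expect_identical(chi$f(1), 0)
  expect_identical(kl$f(0), 0)    # limit convention for x log x
  expect_identical(chi$f(0), -1)  # direct evaluation of x^2 - 1
})

test_that("supervised loss matches closed forms", {
  y <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
  perfect <- array(0, c(2, 2, 2))
  perfect[, , 1] <- (y == 0) * 1
  perfect[, , 2] <- (y == 1) * 1
  expect_equal(supervised_loss(perfect, y), 0, tolerance = 1e-9)
  expect_equal(supervised_loss(const_prob(0.5, 2, 2), y), log(2),
               tolerance = 1e-9)
  # invariance to joint pixel permutation
  set.seed(4)
  p <- array(stats::runif(32), c(4, 4, 2))
  p <- p / array(p[, , 1] + p[, , 2], dim(p))
  yy <- matrix(sample(0:1, 16, TRUE), 4, 4)
  perm <- sample(16)
  p2 <- array(c(p[, , 1][perm], p[, , 2][perm]), dim(p))
  y2 <- matrix(yy[perm], 4, 4)
  expect_equal(supervised_loss(p, yy), supervised_loss(p2, y2),
               tolerance = 1e-12)
  # exact zeros at the true class are clamped, not an error
  expect_true(is.finite(supervised_loss(const_prob(0), matrix(1L, 4, 4))))
})

test_that("target loss hits its closed-form values at uniform and one-hot", {
  uni <- const_prob(0.5)
  hot <- const_prob(1)
  expect_equal(target_loss(uni, "kl"), 0, tolerance = 1e-9)
  expect_equal(target_loss(uni, "pearson_chi2"), 0, tolerance = 1e-9)
  expect_equal(target_loss(hot, "pearson_chi2"), -1, tolerance = 1e-9)
  expect_equal(target_loss(hot, "kl"), -log(2), tolerance = 1e-9)
})

test_that("target loss is nonpositive, maximized at uniform, minimized one-hot", {
  grid <- seq(0, 1, by = 0.01)
  for (kind in c("kl", "pearson_chi2")) {
    vals <- vapply(grid, function(q) target_loss(const_prob(q), kind), 1)
    expect_true(all(vals <= 1e-12))
    expect_identical(grid[which.max(vals)], 0.5)
    expect_true(which.min(vals) %in% c(1L, length(grid)))
    if (kind == "pearson_chi2") expect_true(all(vals >= -1 - 1e-12))
  }
})

test_that("total loss composes the two terms and reduces correctly", {
  y <- matrix(0L, 4, 4)
  perfect <- const_prob(0)           # all background, matching y
  hot <- const_prob(1)
  uni <- const_prob(0.5)
  cfg0 <- loss_config(lambda = 0)
  cfg1 <- loss_config(lambda = 1, divergence = "pearson_chi2")
  expect_equal(total_loss(perfect, y, hot, cfg0), supervised_loss(perfect, y),
               tolerance = 1e-12)
  expect_equal(total_loss(perfect, y, uni, cfg1), 0, tolerance = 1e-9)
  expect_equal(total_loss(perfect, y, hot, cfg1), -1, tolerance = 1e-9)
  lam <- 0.37
  expect_equal(total_loss(perfect, y, hot, loss_config(lambda = lam)),
               lam * -1, tolerance = 1e-9)
})

test_that("binary gradient references match the printed closed forms", {
  expect_equal(binary_gradient_reference(0.5, "kl"), 0, tolerance = 1e-12)
  expect_equal(binary_gradient_reference(0.5, "pearson_chi2"), 0,
               tolerance = 1e-12)
  expect_equal(binary_gradient_reference(0, "pearson_chi2"), 2)
  expect_equal(binary_gradient_reference(1, "pearson_chi2"), -2)
  expect_equal(binary_gradient_reference(0.25, "kl"), log(0.75) - log(0.25))
  expect_warning(g <- binary_gradient_reference(c(0, 1), "kl"), "unbounded")
  expect_identical(g, c(Inf, -Inf))
})

test_that("chi-square gradients stay bounded while KL explodes near the endpoints", {
  p <- c(1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.1, 0.5, 0.9, 0.99, 1 - 1e-3,
         1 - 1e-6)
  chi <- binary_gradient_reference(p, "pearson_chi2")
  kl <- binary_gradient_reference(p, "kl")
  expect_true(all(abs(chi) <= 2))
  expect_gt(abs(kl[p == 1e-6][1]), abs(kl[p == 1e-3][1]))
  expect_gt(abs(kl[p == 1e-3][1]), 2)
  # on a shrinking grid the KL gradient exceeds any fixed bound
  expect_gt(max(abs(binary_gradient_reference(10^-(6:12), "kl"))), 20)
})

test_that("numeric derivative of the chi-square loss along the binary simplex is proportional to the printed form", {
  # d/dp target_loss((1-p, p)) computed numerically, compared with 2 - 4p up
  # to one shared constant: proportionality and the 0.5 zero-crossing, not
  # equality (the printed form absorbs a constant factor).
  qs <- seq(0.1, 0.9, by = 0.1)
  h <- 1e-6
  num <- vapply(qs, function(q)
    (target_loss(const_prob(q + h), "pearson_chi2") -
       target_loss(const_prob(q - h), "pearson_chi2")) / (2 * h), 1)
  ref <- 2 - 4 * qs
  ratio <- num[ref != 0] / ref[ref != 0]
  expect_lt(max(abs(ratio - ratio[1])), 1e-3)
  expect_lt(abs(num[qs == 0.5]), 1e-6)
})

test_that("softmax-chain gradients of both losses match numerical differentiation", {
  set.seed(11)
  z <- array(stats::rnorm(4 * 4 * 3), c(4, 4, 3))
  y <- matrix(sample(0:2, 16, TRUE), 4, 4)
  for (kind in c("pearson_chi2", "kl")) {
    gt <- thinseg:::grad_target_logits(thinseg:::softmax_hw(z), kind)
    gs <- thinseg:::grad_supervised_logits(thinseg:::softmax_hw(z), y)
    h <- 1e-6
    for (idx in sample(length(z), 5)) {
      zp <- z; zp[idx] <- zp[idx] + h
      zm <- z; zm[idx] <- zm[idx] - h
      numt <- (target_loss(thinseg:::softmax_hw(zp), kind) -
                 target_loss(thinseg:::softmax_hw(zm), kind)) / (2 * h)
      nums <- (supervised_loss(thinseg:::softmax_hw(zp), y) -
                 supervised_loss(thinseg:::softmax_hw(zm), y)) / (2 * h)
      expect_equal(gt[idx], numt, tolerance = 1e-4)
      expect_equal(gs[idx], nums, tolerance = 1e-4)
    }
  }
})
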