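# Composite loss: hand-evaluated examples, algebraic identities, analytic
# gradients against finite differences, and the weight grid search.

test_that("pixel BCE matches hand evaluation and clamps safely", {
  g <- c(1, 0, 1, 0)
  expect_equal(bce_pixel_loss(rep(0.5, 4), g), log(2), tolerance = 1e-12)
  expect_equal(bce_pixel_loss(c(0.9, 0.1), c(1, 0)),
               -0.5 * (log(0.9) + log(0.9)), tolerance = 1e-12)
  expect_equal(bce_pixel_loss(c(0.9, 0.1), c(1, 0)), 0.105361, tolerance = 1e-5)
  # p == g at the clamp: loss is finite and tiny
  expect_lt(bce_pixel_loss(c(1, 0), c(1, 0)), 1e-5)
  expect_true(is.finite(bce_pixel_loss(c(0, 1), c(1, 0))))
})

test_that("soft Dice matches hand evaluation, including the empty-empty case", {
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 0, 0, 0), epsilon = 1e-12),
               1 - 2 / 3, tolerance = 1e-9)
  # identical binary masks: epsilon-exact zero
  g <- c(1, 1, 0, 1)
  expect_equal(dice_loss(g, g), 0, tolerance = 1e-6)
  # both empty: the smoothing constant makes the ratio exactly 1
  expect_equal(dice_loss(rep(0, 8), rep(0, 8)), 0)
  # binary symmetry
  p <- c(1, 0, 1, 0); q <- c(1, 1, 0, 0)
  expect_equal(dice_loss(p, q), dice_loss(q, p), tolerance = 1e-12)
  expect_all_in(vapply(1:10, function(s) {
    pr <- cytomtl:::with_seed(s, runif(20))
    gt <- cytomtl:::with_seed(s + 100, rbinom(20, 1, 0.4))
    dice_loss(pr, gt)
  }, numeric(1)), 0, 1)
})

test_that("segmentation loss is the stated affine combination", {
  p <- c(0.7, 0.2, 0.9, 0.4); g <- c(1, 0, 1, 0)
  expect_equal(seg_loss(p, g, loss_weights(1, 0)), bce_pixel_loss(p, g))
  expect_equal(seg_loss(p, g, loss_weights(0, 1)), dice_loss(p, g))
  # hand evaluation at N = 4, p == 0.5, half-ones truth
  w <- loss_weights(0.6, 0.4)
  ph <- rep(0.5, 4); gh <- c(1, 1, 0, 0)
  d <- 1 - (2 * 1 + w$epsilon) / (2 + 2 + w$epsilon)
  expect_equal(seg_loss(ph, gh, w), 0.6 * log(2) + 0.4 * d, tolerance = 1e-12)
  expect_gte(seg_loss(p, g, loss_weights()), 0)
})

test_that("classification loss matches hand evaluation", {
  expect_equal(cls_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(cls_loss(0.1, 0), -log(0.9), tolerance = 1e-12)
  expect_lt(cls_loss(1 - 1e-9, 1), 1e-6)
})

test_that("total loss composes seg and cls terms with alpha", {
  p <- matrix(c(0.8, 0.3, 0.6, 0.1), 2, 2)
  g <- matrix(c(1, 0, 1, 0), 2, 2)
  w0 <- loss_weights(alpha = 0)
  expect_equal(total_loss(p, g, 0.7, 1, w0), seg_loss(p, g, w0))
  w1 <- loss_weights(alpha = 1)
  expect_equal(total_loss(p, g, 0.5, 1, w1),
               seg_loss(p, g, w1) + log(2), tolerance = 1e-12)
  # distillation probability averaged inside the classification term
  expect_equal(total_loss(p, g, 0.5, 1, w1, dist_prob = 0.5),
               seg_loss(p, g, w1) + log(2), tolerance = 1e-12)
  # monotone in alpha
  w2 <- loss_weights(alpha = 2)
  expect_gte(total_loss(p, g, 0.4, 1, w2), total_loss(p, g, 0.4, 1, w1))
})

test_that("loss gradients match finite differences and point the right way", {
  pr <- cytomtl:::with_seed(21, array(runif(6 * 6 * 2, 0.05, 0.95), c(6, 6, 2)))
  gt <- cytomtl:::with_seed(22, array(rbinom(6 * 6 * 2, 1, 0.3), c(6, 6, 2)))
  w <- loss_weights()
  an <- seg_loss(pr, gt, w, grad = TRUE)
  eps <- 1e-6
  for (i in c(1, 10, 40, 72)) {
    pp <- pr; pp[i] <- pp[i] + eps
    pm <- pr; pm[i] <- pm[i] - eps
    num <- (seg_loss(pp, gt, w) - seg_loss(pm, gt, w)) / (2 * eps)
    expect_equal(an$grad[i], num, tolerance = 1e-5)
  }
  # increasing predicted overlap always reduces Dice loss where truth is 1
  dd <- dice_loss(pr, gt, grad = TRUE)
  expect_true(all(dd$grad[gt == 1] < 0))
})

test_that("grid search returns the argmax with documented tie-breaks", {
  single <- data.frame(lambda1 = 0.5, lambda2 = 0.5, alpha = 1)
  got <- grid_search_weights(function(w) 1, single)
  expect_equal(got$lambda1, 0.5)
  # indicator of the study optimum recovers (0.6, 0.4, 1.0)
  ind <- function(w) as.numeric(w$lambda1 == 0.6 && w$alpha == 1)
  best <- grid_search_weights(ind)
  expect_equal(c(best$lambda1, best$lambda2, best$alpha), c(0.6, 0.4, 1))
  # the returned configuration scores at least as high as every grid point
  scorer <- function(w) sin(3 * w$lambda1) + cos(w$alpha)
  top <- grid_search_weights(scorer)
  grid <- attr(top, "grid")
  expect_equal(scorer(top), max(grid$score))
  # ties break to smaller alpha then larger lambda1
  tie <- grid_search_weights(function(w) 0)
  expect_equal(tie$alpha, 0.5)
  expect_equal(tie$lambda1, 0.8)
  expect_error(grid_search_weights(function(w) 1,
                                   data.frame(lambda1 = 0.7, lambda2 = 0.2,
                                              alpha = 1)), "lambda1")
  expect_error(grid_search_weights(function(w) 1, data.frame()), "empty")
})
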