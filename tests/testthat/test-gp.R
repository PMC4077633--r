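test_that("evidence reduces to closed-form Gaussian densities", {
  # single observation, negligible signal: standard-normal log density at 0
  h <- gp_hyper(1e-12, 1, 1)
  v <- log_marginal_likelihood(h, matrix(0), 0, jitter = 0)$value
  expect_equal(v, -0.5 * log(2 * pi), tolerance = 1e-9)

  # two far-apart points: K ~ I, targets iid N(0, 2)
  h2 <- gp_hyper(1, 1, 1)
  v2 <- log_marginal_likelihood(h2, matrix(c(0, 1e6)), c(0, 0),
                                jitter = 0)$value
  expect_equal(v2, -log(4 * pi), tolerance = 1e-9)
})

test_that("evidence and gradients match dense oracle and finite differences", {
  for (s in 1:6) {
    inst <- random_gp_instance(n = sample(2:8, 1), m = sample(1:3, 1),
                               seed = 100 + s)
    got <- log_marginal_likelihood(inst$hyper, inst$X, inst$y, jitter = 0)
    expect_equal(got$value, dense_lml(inst$hyper, inst$X, inst$y),
                 tolerance = 1e-8)
    fd <- fd_lml_gradient(inst$hyper, inst$X, inst$y)
    expect_equal(unname(got$gradient), fd, tolerance = 1e-4)
  }
})

test_that("hyperparameter optimization recovers a known generative GP", {
  true <- gp_hyper(1, 0.5, 0.01)
  errs <- sapply(1:20, function(s) {
    set.seed(2000 + s)
    X <- matrix(runif(200, -3, 3))
    y <- draw_gp_observations(X, true, seed = 3000 + s)
    gp <- fit_gp(X, y, config = gp_fit_config(restarts = 1), seed = s)
    # the model fits in standardized-covariate units: convert the true
    # length scale with the training column scale before comparing
    l_true_std <- true$length_scales / gp$covariates$scale
    abs(c(log(gp$hyper$amplitude) - log(true$amplitude),
          log(gp$hyper$length_scales) - log(l_true_std),
          log(gp$hyper$noise_variance) - log(true$noise_variance)))
  })
  expect_true(all(apply(errs, 1, median) < 0.5))
})

test_that("fit evidence is never below any restart's initialization", {
  set.seed(11)
  X <- matrix(runif(60, -2, 2))
  y <- sin(X[, 1]) + rnorm(60, 0, 0.2)
  gp <- fit_gp(X, y, config = gp_fit_config(restarts = 3), seed = 5)
  vy <- var(y - mean(y))
  init <- gp_hyper(vy, 1, vy / 2)
  v0 <- log_marginal_likelihood(init, gp$covariates, gp$targets)$value
  expect_gte(gp$log_evidence, v0)
})

test_that("constant targets yield a degenerate but finite fit", {
  X <- matrix(rnorm(20), 20, 1)
  gp <- suppressWarnings(fit_gp(X, rep(2.5, 20), seed = 1))
  expect_true(is.finite(gp$log_evidence))
  expect_lt(gp$hyper$amplitude + gp$hyper$noise_variance, 1e-4)
})

test_that("ARD assigns longer length scales to irrelevant covariates", {
  ratio <- sapply(1:20, function(s) {
    set.seed(4000 + s)
    n <- 100
    x_inf <- runif(n, -3, 3)
    x_irr <- rnorm(n)
    y <- sin(x_inf) + rnorm(n, 0, 0.1)
    gp <- fit_gp(cbind(x_inf, x_irr), y,
                 config = gp_fit_config(restarts = 2), seed = s)
    gp$hyper$length_scales[2] / gp$hyper$length_scales[1]
  })
  expect_gt(median(ratio), 1)
})

test_that("predictions interpolate noise-free data and revert to the prior far away", {
  set.seed(3)
  X <- matrix(seq(-2, 2, length.out = 10))
  y <- cos(X[, 1])
  h <- gp_hyper(1, 1, 1e-10)
  gp <- gp_exact(X, y, h)
  at_train <- gp_predict(gp, X)
  expect_equal(at_train$mean, y, tolerance = 1e-4)
  expect_true(all(at_train$latent_variance < 1e-4))

  far <- gp_predict(gp, matrix(50))
  expect_equal(far$mean, gp$y_center, tolerance = 1e-6)
  expect_equal(far$observation_variance,
               h$amplitude + h$noise_variance, tolerance = 1e-6)
})

test_that("single-training-point prediction matches the hand-computed posterior", {
  # a = 1, l = 1, s2 = 1, x = 0, y = 2 (uncentered), x* = 0:
  # mean = 1*(1+1)^-1*2 = 1; u2 = 1 - 1/2 + 1 = 1.5; z(y*=2) = 1/sqrt(1.5)
  gp <- gp_exact(matrix(0), 2, gp_hyper(1, 1, 1), center_targets = FALSE,
                 jitter = 0)
  pr <- gp_predict(gp, matrix(0), ystar = 2)
  expect_equal(pr$mean, 1, tolerance = 1e-12)
  expect_equal(pr$observation_variance, 1.5, tolerance = 1e-12)
  expect_equal(pr$z, 1 / sqrt(1.5), tolerance = 1e-12)
})

test_that("observation variance dominates latent variance and the noise floor", {
  inst <- random_gp_instance(10, 2, seed = 9)
  y <- draw_gp_observations(inst$X, inst$hyper, seed = 10)
  gp <- gp_exact(inst$X, y, inst$hyper)
  pr <- gp_predict(gp, matrix(rnorm(12), 6, 2))
  expect_true(all(pr$observation_variance >=
                    inst$hyper$noise_variance - 1e-12))
  expect_true(all(pr$observation_variance >= pr$latent_variance))
})

test_that("adding a training point never increases latent variance", {
  set.seed(21)
  h <- gp_hyper(1, 1, 0.1)
  X <- matrix(runif(15, -2, 2))
  y <- draw_gp_observations(X, h, seed = 22)
  Xstar <- matrix(seq(-2, 2, length.out = 9))
  v_small <- gp_predict(gp_exact(exact_cov(X[1:10, , drop = FALSE]),
                                 y[1:10], h, center_targets = FALSE,
                                 jitter = 0),
                        exact_cov(Xstar))$latent_variance
  v_large <- gp_predict(gp_exact(exact_cov(X), y, h,
                                 center_targets = FALSE, jitter = 0),
                        exact_cov(Xstar))$latent_variance
  expect_true(all(v_large <= v_small + 1e-8))
})

test_that("held-out z-scores are calibrated under the generative model", {
  # moderate-size version of the calibration property; the full 10,000-
  # score run lives in the acceptance suite
  h <- gp_hyper(1, 1, 0.25)
  zs <- unlist(lapply(1:20, function(s) {
    set.seed(5000 + s)
    X <- matrix(runif(80, -3, 3))
    y <- draw_gp_observations(X, h, seed = 6000 + s)
    gp <- gp_exact(exact_cov(X[1:40, , drop = FALSE]), y[1:40], h,
                   center_targets = FALSE)
    gp_predict(gp, exact_cov(X[41:80, , drop = FALSE]),
               ystar = y[41:80])$z
  }))
  expect_lt(abs(mean(zs)), 3 / sqrt(length(zs)))
  expect_gt(var(zs), 0.85)
  expect_lt(var(zs), 1.15)
})
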