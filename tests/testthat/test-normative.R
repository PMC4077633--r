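cfg_fast <- normative_config(fit = gp_fit_config(restarts = 1, maxit = 100))

test_that("duplicated voxels train to identical models", {
  ph <- make_phantom_matrix(30, 1, 0, seed = 1)
  Y <- cbind(ph$Y[, 1], ph$Y[, 1], ph$Y[, 1])
  ms <- train_voxelwise(Y, ph$X, mask = rep(TRUE, 3), config = cfg_fast,
                        seed = 7)
  expect_equal(ms$models[[1]]$hyper, ms$models[[2]]$hyper)
  expect_equal(ms$models[[2]]$hyper, ms$models[[3]]$hyper)
  expect_equal(ms$evidence_map[1], ms$evidence_map[3])
})

test_that("evidence tracks the noise map across structured and noise voxels", {
  ph <- make_phantom_matrix(40, 10, 10, seed = 2)
  ms <- train_voxelwise(ph$Y, ph$X, config = cfg_fast, seed = 1)
  expect_equal(length(ms$models), 20)
  # structured voxels: higher evidence, lower noise
  expect_gt(median(ms$evidence_map[1:10]), median(ms$evidence_map[11:20]))
  expect_lt(cor(ms$noise_map, ms$evidence_map, method = "spearman"), -0.8)
})

test_that("mask auto-derivation follows the mean-intensity threshold exactly", {
  set.seed(3)
  n <- 25
  Y <- cbind(matrix(rnorm(n * 2, 0.9, 0.05), n),    # above threshold
             matrix(rnorm(n * 2, 0.01, 0.005), n))  # background
  ms <- train_voxelwise(Y, cbind(age = runif(n, 20, 90)),
                        config = cfg_fast, seed = 1)
  expect_identical(ms$voxel_index, which(colMeans(Y) > 0.05))
})

test_that("voxelwise training is invariant to chunking", {
  ph <- make_phantom_matrix(25, 2, 2, seed = 4)
  full <- train_voxelwise(ph$Y, ph$X, mask = rep(TRUE, 4),
                          config = cfg_fast, seed = 9)
  part1 <- train_voxelwise(ph$Y, ph$X, mask = c(TRUE, TRUE, FALSE, FALSE),
                           config = cfg_fast, seed = 9)
  part2 <- train_voxelwise(ph$Y, ph$X, mask = c(FALSE, FALSE, TRUE, TRUE),
                           config = cfg_fast, seed = 9)
  expect_equal(full$models[[1]]$hyper, part1$models[[1]]$hyper)
  expect_equal(full$models[[3]]$hyper, part2$models[[1]]$hyper)
  expect_equal(full$models[[4]]$log_evidence, part2$models[[2]]$log_evidence)
})

test_that("NPMs satisfy the z = error / sqrt(uncertainty) identity with NaN outside the mask", {
  ph <- make_phantom_matrix(30, 3, 1, seed = 5)
  mask <- array(c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 4)), c(2, 2, 2))
  ms <- train_voxelwise(ph$Y, ph$X, mask = mask, config = cfg_fast,
                        seed = 2)
  te <- make_phantom_matrix(8, 3, 1, seed = 6)
  npm <- compute_npm(ms, te$X, te$Y)
  expect_equal(npm$z_matrix,
               npm$error_matrix / npm$uncertainty_matrix)
  vol <- npm$subjects[[1]]$z
  expect_equal(dim(vol), c(2, 2, 2))
  expect_true(all(is.nan(vol[!mask])))
  expect_true(all(is.finite(vol[mask])))
})

test_that("inflating one observation shifts its z-score by the expected amount", {
  ph <- make_phantom_matrix(60, 1, 0, seed = 7)
  ms <- train_voxelwise(ph$Y, ph$X, mask = TRUE, config = cfg_fast,
                        seed = 3)
  gp <- ms$models[[1]]
  xstar <- ph$X[1, , drop = FALSE]
  base <- compute_npm(ms, xstar, ph$Y[1, , drop = FALSE])
  sig <- sqrt(gp$hyper$noise_variance)
  # +3 noise-sd on the transformed scale maps back through the Box-Cox
  y_obs <- ph$Y[1, 1]
  y_trans <- apply_rescaled(gp$boxcox, y_obs)
  y_infl <- invert_rescaled(gp$boxcox, y_trans + 3 * sig)
  infl <- compute_npm(ms, xstar, matrix(y_infl, 1, 1))
  u <- base$uncertainty_matrix[1, 1]
  expect_equal(infl$z_matrix[1, 1] - base$z_matrix[1, 1], 3 * sig / u,
               tolerance = 1e-6)
})

test_that("held-out healthy subjects produce calibrated voxel z-scores", {
  ph <- make_phantom_matrix(120, 2, 0, seed = 8)
  ms <- train_voxelwise(ph$Y[1:80, ], ph$X[1:80, ], mask = c(TRUE, TRUE),
                        config = cfg_fast, seed = 4)
  npm <- compute_npm(ms, ph$X[81:120, ], ph$Y[81:120, ])
  z <- as.vector(npm$z_matrix)
  expect_lt(abs(mean(z)), 0.35)
  expect_gt(var(z), 0.5); expect_lt(var(z), 1.6)
})

test_that("global z-scores respond to atrophy at fixed intracranial volume", {
  set.seed(11)
  n <- 120
  age <- runif(n, 20, 90)
  sex <- rep_len(c(0, 1), n)
  fstr <- rep_len(c(0, 0, 1), n)
  ticv <- rnorm(n, 1500, 80)
  tgmv <- 0.45 * ticv - 1.2 * (age - 50) + rnorm(n, 0, 15)
  twmv <- 0.35 * ticv + rnorm(n, 0, 15)
  tcsf <- ticv - tgmv - twmv
  covar <- data.frame(age, sex, fstr)
  vols <- data.frame(tgmv, twmv, tcsf)
  gm <- train_global(covar, vols,
                     config = normative_config(boxcox = FALSE,
                                               fit = gp_fit_config(restarts = 1)),
                     seed = 5)

  # subject observed exactly at the model prediction scores zero
  xstar <- data.frame(age = 55, sex = 1, fstr = 0,
                      ticv = 1500)
  pred <- gp_predict(gm$models$tgmv,
                     as.matrix(cbind(xstar[c("age", "sex")],
                                     ticv = 1500, fstr = 0))[,
                       gm$covariate_schema, drop = FALSE])
  z0 <- compute_global_z(gm, cbind(xstar, tgmv = 0),
                         data.frame(tgmv = pred$mean, twmv = 600,
                                    tcsf = 1500 - pred$mean - 600))
  expect_equal(z0$z_tgmv, 0, tolerance = 1e-8)

  # atrophy: shrink tgmv, grow tcsf, ticv fixed
  i <- 1:20
  atro <- data.frame(tgmv = tgmv[i] - 100, twmv = twmv[i],
                     tcsf = tcsf[i] + 100)
  za <- compute_global_z(gm, data.frame(age = age[i], sex = sex[i],
                                        fstr = fstr[i], ticv = ticv[i]),
                         atro)
  expect_lt(median(za$z_tgmv), 0)
  expect_gt(median(za$z_tcsf), 0)
})

test_that("naive-Bayes posterior follows the likelihood arithmetic", {
  ll <- rnorm(50)
  post <- naive_bayes_posterior(list(healthy = ll, ad = ll),
                                priors = c(healthy = 0.3, ad = 0.7))
  expect_equal(unname(post$posterior), c(0.3, 0.7), tolerance = 1e-12)

  ll2 <- ll; ll2[1] <- ll2[1] + log(9)
  p2 <- naive_bayes_posterior(list(a = ll2, b = ll),
                              priors = c(a = 0.5, b = 0.5))
  expect_equal(unname(p2$posterior), c(0.9, 0.1), tolerance = 1e-12)

  perm <- sample(50)
  p3 <- naive_bayes_posterior(list(a = ll2[perm], b = ll[perm]),
                              priors = c(a = 0.5, b = 0.5))
  expect_equal(p3$posterior, p2$posterior, tolerance = 1e-12)

  expect_error(naive_bayes_posterior(list(a = ll, b = ll[-1]),
                                     priors = c(a = 0.5, b = 0.5)),
               "same voxel set")
  expect_error(naive_bayes_posterior(list(a = ll, b = c(ll[-1], NA)),
                                     priors = c(a = 0.5, b = 0.5)),
               "non-finite")
  expect_error(naive_bayes_posterior(list(a = ll, b = ll),
                                     priors = c(a = 0.5, b = 0.6)),
               "sum to 1")
})

test_that("healthy-state log-likelihoods feed the posterior sensibly", {
  ph <- make_phantom_matrix(50, 2, 0, seed = 12)
  ms <- train_voxelwise(ph$Y[1:40, ], ph$X[1:40, ], mask = c(TRUE, TRUE),
                        config = cfg_fast, seed = 6)
  ll_typical <- healthy_log_likelihood(ms, ph$X[41, , drop = FALSE],
                                       ph$Y[41, ])
  ll_atrophic <- healthy_log_likelihood(ms, ph$X[41, , drop = FALSE],
                                        ph$Y[41, ] * 0.6)
  expect_gt(sum(ll_typical), sum(ll_atrophic))
  post <- naive_bayes_posterior(
    list(healthy = ll_typical, other = ll_atrophic),
    priors = c(healthy = 0.5, other = 0.5))
  expect_gt(post$posterior[["healthy"]], 0.5)
})

test_that("full-sample uncertainty profile collapses to one deterministic value", {
  ph <- make_phantom_matrix(40, 1, 0, seed = 13)
  prof1 <- uncertainty_profile(list(X = ph$X, y = ph$Y[, 1]),
                               Xstar = ph$X[1:10, ], sizes = 40,
                               repeats = 4, seed = 1,
                               config = gp_fit_config(restarts = 1))
  prof2 <- uncertainty_profile(list(X = ph$X, y = ph$Y[, 1]),
                               Xstar = ph$X[1:10, ], sizes = 40,
                               repeats = 9, seed = 2,
                               config = gp_fit_config(restarts = 1))
  expect_equal(prof1$mean_u, prof2$mean_u, tolerance = 1e-12)
  expect_equal(prof1$sd_u, prof2$sd_u, tolerance = 1e-12)
})
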