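# Dense brute-force evidence: explicit inverse and log-determinant.
dense_lml <- function(hyper, X, y) {
  n <- length(y)
  K <- se_ard_kernel(X, X, hyper) + diag(hyper$noise_variance, n)
  as.numeric(-0.5 * t(y) %*% solve(K) %*% y -
               0.5 * determinant(K, logarithm = TRUE)$modulus -
               0.5 * n * log(2 * pi))
}

# Central finite differences of the evidence over log-hyperparameters.
fd_lml_gradient <- function(hyper, X, y, h = 1e-5) {
  lh <- c(log(hyper$amplitude), log(hyper$length_scales),
          log(hyper$noise_variance))
  m <- length(hyper$length_scales)
  f <- function(v) {
    hh <- gp_hyper(exp(v[1]), exp(v[1 + seq_len(m)]), exp(v[m + 2]))
    log_marginal_likelihood(hh, X, y, jitter = 0)$value
  }
  vapply(seq_along(lh), function(i) {
    p <- lh; p[i] <- p[i] + h
    q <- lh; q[i] <- q[i] - h
    (f(p) - f(q)) / (2 * h)
  }, 1)
}

random_gp_instance <- function(n, m, seed) {
  set.seed(seed)
  list(X = matrix(rnorm(n * m), n, m),
       y = rnorm(n),
       hyper = gp_hyper(exp(runif(1, -1, 1)),
                        exp(runif(m, -0.5, 0.5)),
                        exp(runif(1, -2, 0))))
}

# Identity standardization: keeps covariates on their raw scale so that
# fixed "true" hyperparameters mean the same thing to the generator and
# to the model (fit_gp/gp_exact otherwise z-standardize internally).
exact_cov <- function(X) {
  X <- as.matrix(X)
  covariate_matrix(X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
}

# Draw a joint sample from N(0, K + s2 I) over the rows of X.
draw_gp_observations <- function(X, hyper, seed) {
  n <- nrow(X)
  K <- se_ard_kernel(X, X, hyper) + diag(hyper$noise_variance + 1e-10, n)
  set.seed(seed)
  drop(t(chol(K)) %*% rnorm(n))
}

# Tiny structured phantom: subjects x voxels, first `n_signal` voxels
# follow an age trajectory with low noise, the rest are pure noise.
make_phantom_matrix <- function(n_sub, n_signal, n_noise, seed) {
  set.seed(seed)
  age <- runif(n_sub, 20, 90)
  v <- n_signal + n_noise
  Y <- matrix(0, n_sub, v)
  for (j in seq_len(n_signal))
    Y[, j] <- 0.9 + 0.004 * age + rnorm(n_sub, 0, 0.02)
  for (j in n_signal + seq_len(n_noise))
    Y[, j] <- 0.5 + rnorm(n_sub, 0, 0.2)
  list(Y = Y, age = age,
       X = cbind(age = age, sex = rep_len(c(0, 1), n_sub)))
}
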