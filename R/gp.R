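#' Fit settings for GP hyperparameter optimization
#'
#' @param restarts number of optimizer starts; the first uses the default
#'   initialization, later ones jitter each log-hyperparameter by
#'   N(0, `restart_sd`^2).
#' @param maxit maximum L-BFGS iterations per start.
#' @param restart_sd standard deviation of the restart jitter on the
#'   log-hyperparameters.
#' @param jitter initial diagonal jitter, as a fraction of the amplitude,
#'   added before Cholesky factorization.
#' @param jitter_max largest jitter fraction tried (escalated by factors of
#'   10 on Cholesky failure) before declaring the kernel ill-conditioned.
#' @return a list of class `gp_fit_config`.
#' @export
gp_fit_config <- function(restarts = 3L, maxit = 200L, restart_sd = 0.5,
                          jitter = 1e-8, jitter_max = 1e-2) {
  structure(list(restarts = as.integer(restarts), maxit = as.integer(maxit),
                 restart_sd = restart_sd, jitter = jitter,
                 jitter_max = jitter_max),
            class = "gp_fit_config")
}

# Cholesky of K + noise*I + jitter*amplitude*I with jitter escalation.
# Returns list(L = lower factor, jitter = fraction used).
chol_with_jitter <- function(K, noise_variance, amplitude,
                             jitter = 1e-8, jitter_max = 1e-2) {
  n <- nrow(K)
  j <- jitter
  repeat {
    Ky <- K + diag(noise_variance + j * amplitude, n)
    L <- tryCatch(t(chol(Ky)), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
    if (j >= jitter_max)
      stop("ill-conditioned kernel: Cholesky failed after jitter escalation")
    j <- j * 10
  }
}

# Core evidence evaluation on precomputed per-dimension scaled distances.
# sqd0: list of raw squared-distance matrices (unit length scales).
# Returns value and gradient w.r.t. (log a, log l_1..m, log s2).
lml_core <- function(loghyper, sqd0, y, jitter = 1e-8, jitter_max = 1e-2,
                     want_grad = TRUE) {
  m <- length(sqd0)
  a <- exp(loghyper[1])
  ell2 <- exp(2 * loghyper[1 + seq_len(m)])
  s2 <- exp(loghyper[m + 2])
  n <- length(y)
  D2 <- 0
  for (d in seq_len(m)) D2 <- D2 + sqd0[[d]] / ell2[d]
  K <- a * exp(-0.5 * D2)
  ch <- chol_with_jitter(K, s2, a, jitter, jitter_max)
  L <- ch$L
  alpha <- backsolve(t(L), forwardsolve(L, y))
  value <- -0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
  if (!want_grad)
    return(list(value = value, L = L, alpha = alpha, jitter = ch$jitter))
  Kinv <- chol2inv(t(L))
  W <- tcrossprod(alpha) - Kinv           # d lml / dK = 0.5 * W
  grad <- numeric(m + 2)
  grad[1] <- 0.5 * sum(W * K)             # d K / d log a = K
  for (d in seq_len(m))
    grad[1 + d] <- 0.5 * sum(W * (K * (sqd0[[d]] / ell2[d])))
  grad[m + 2] <- 0.5 * s2 * sum(diag(W))  # d K / d log s2 = s2 * I
  list(value = value, grad = grad, L = L, alpha = alpha, jitter = ch$jitter)
}

#' Log marginal likelihood (evidence) of a GP regression model
#'
#' Evaluates the exact log marginal likelihood
#' -1/2 y' (K + s2 I)^-1 y - 1/2 log|K + s2 I| - n/2 log(2 pi)
#' of centered targets `y` under the squared-exponential ARD kernel, with
#' analytic gradients with respect to the log-hyperparameters
#' (log amplitude, log length scales, log noise variance).
#'
#' @param hyper a [gp_hyper()] object.
#' @param X standardized covariates (matrix or `gp_covariates`).
#' @param y numeric target vector (assumed centered; no centering is done
#'   here).
#' @param jitter,jitter_max diagonal jitter policy (fractions of the
#'   amplitude) used to keep the Cholesky factorization stable.
#' @return a list with `value` (scalar evidence) and `gradient` (named
#'   vector over log-hyperparameters).
#' @export
log_marginal_likelihood <- function(hyper, X, y, jitter = 1e-8,
                                    jitter_max = 1e-2) {
  stopifnot(inherits(hyper, "gp_hyper"))
  if (inherits(X, "gp_covariates")) X <- X$std
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  m <- length(hyper$length_scales)
  if (ncol(X) != m) stop("covariate dimension does not match length scales")
  sqd0 <- scaled_sqdist(X, X, rep(1, m))
  lh <- c(log(hyper$amplitude), log(hyper$length_scales),
          log(hyper$noise_variance))
  res <- lml_core(lh, sqd0, y, jitter, jitter_max)
  names(res$grad) <- c("log_amplitude",
                       paste0("log_length_scale_", seq_len(m)),
                       "log_noise_variance")
  list(value = res$value, gradient = res$grad)
}

#' Fit a GP regression model by evidence optimization
#'
#' Optimizes the log marginal likelihood over log amplitude, log length
#' scales and log noise variance with multi-restart L-BFGS using analytic
#' gradients. Covariates are z-standardized per column with training
#' statistics; targets are centered by their training mean (the GP prior
#' mean is zero) and the mean is added back at prediction time.
#'
#' Initialization: log a = log var(y), log s2 = log(var(y)/2), log l = 0
#' per dimension; further restarts jitter each log-parameter by
#' N(0, `restart_sd`^2). Deterministic given `seed`.
#'
#' @param X raw covariate matrix (n x m) or a `gp_covariates` object
#'   (whose standardization is reused).
#' @param y numeric target vector of length n (n >= 2), finite.
#' @param config a [gp_fit_config()].
#' @param seed integer seed controlling restart jitter.
#' @return an object of class `trained_gp` with elements `hyper`,
#'   `covariates`, `y_center`, `targets` (centered), `L` (lower Cholesky
#'   factor of K + s2 I + jitter), `alpha`, `log_evidence`, `converged`.
#' @export
fit_gp <- function(X, y, config = gp_fit_config(), seed = 1L) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("targets must be finite")
  if (length(y) < 2) stop("at least 2 training subjects required")
  cov <- if (inherits(X, "gp_covariates")) X else covariate_matrix(X)
  if (nrow(cov$std) != length(y)) stop("X rows and y length differ")
  m <- ncol(cov$std)
  y_center <- mean(y)
  yc <- y - y_center
  vy <- stats::var(yc)
  if (!is.finite(vy) || vy <= 0) vy <- 1e-12
  sqd0 <- scaled_sqdist(cov$std, cov$std, rep(1, m))
  init <- c(log(vy), rep(0, m), log(vy / 2))

  fn <- function(p) -lml_core(p, sqd0, yc, config$jitter, config$jitter_max,
                              want_grad = FALSE)$value
  gr <- function(p) -lml_core(p, sqd0, yc, config$jitter,
                              config$jitter_max)$grad

  best <- NULL
  any_conv <- FALSE
  for (r in seq_len(config$restarts)) {
    p0 <- init
    if (r > 1) {
      set.seed(as.integer(seed) + r - 1L)
      p0 <- init + stats::rnorm(m + 2, 0, config$restart_sd)
    }
    fit <- tryCatch(
      stats::optim(p0, fn, gr, method = "L-BFGS-B",
                   lower = rep(-15, m + 2), upper = rep(15, m + 2),
                   control = list(maxit = config$maxit)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    best <- list(par = init, value = fn(init))
    warning("all optimizer restarts failed; returning initialization")
  }
  if (!any_conv)
    warning("GP hyperparameter optimization did not report convergence")

  p <- best$par
  hyper <- gp_hyper(exp(p[1]), exp(p[1 + seq_len(m)]), exp(p[m + 2]))
  final <- lml_core(p, sqd0, yc, config$jitter, config$jitter_max,
                    want_grad = FALSE)
  structure(
    list(hyper = hyper, covariates = cov, y_center = y_center,
         targets = yc, L = final$L, alpha = final$alpha,
         log_evidence = final$value, jitter_used = final$jitter,
         converged = any_conv, boxcox = NULL),
    class = "trained_gp"
  )
}

#' Condition a GP on data at fixed hyperparameters
#'
#' Builds a `trained_gp` without any optimization: the supplied
#' hyperparameters are taken as known and the training data are
#' factorized once. Useful for calibration studies where data are drawn
#' from a known generative GP, and for rebuilding models from stored
#' hyperparameters.
#'
#' @param X raw covariate matrix or `gp_covariates`.
#' @param y numeric target vector.
#' @param hyper a [gp_hyper()] object.
#' @param center_targets subtract the training mean from `y` (added back
#'   at prediction); set FALSE when `y` is already centered under the
#'   zero-mean prior.
#' @param jitter,jitter_max diagonal jitter policy.
#' @return a `trained_gp`.
#' @export
gp_exact <- function(X, y, hyper, center_targets = TRUE,
                     jitter = 1e-8, jitter_max = 1e-2) {
  stopifnot(inherits(hyper, "gp_hyper"))
  cov <- if (inherits(X, "gp_covariates")) X else covariate_matrix(X)
  y <- as.numeric(y)
  y_center <- if (center_targets) mean(y) else 0
  yc <- y - y_center
  K <- se_ard_kernel(cov, cov, hyper)
  ch <- chol_with_jitter(K, hyper$noise_variance, hyper$amplitude,
                         jitter, jitter_max)
  alpha <- backsolve(t(ch$L), forwardsolve(ch$L, yc))
  n <- length(yc)
  lml <- -0.5 * sum(yc * alpha) - sum(log(diag(ch$L))) -
    0.5 * n * log(2 * pi)
  structure(
    list(hyper = hyper, covariates = cov, y_center = y_center,
         targets = yc, L = ch$L, alpha = alpha, log_evidence = lml,
         jitter_used = ch$jitter, converged = TRUE, boxcox = NULL),
    class = "trained_gp"
  )
}

#' @export
print.trained_gp <- function(x, ...) {
  cat(sprintf("<trained_gp> n = %d, m = %d, log evidence = %.4f%s\n",
              length(x$targets), ncol(x$covariates$std), x$log_evidence,
              if (x$converged) "" else " (not converged)"))
  print(x$hyper)
  invisible(x)
}

#' Predictive distribution and z-scores at new covariates
#'
#' Computes the closed-form GP predictive mean and variance at test
#' covariates, and, when observed values are supplied, the z-scores of
#' the predictive distribution, delta = (y* - mean) / sqrt(u2) with
#' u2 = latent variance + noise variance. Negative delta means less
#' volume than predicted (atrophy); positive means hypertrophy.
#'
#' @param model a `trained_gp` from [fit_gp()].
#' @param Xstar raw test covariate matrix (standardized internally with
#'   the training shift/scale) or a pre-standardized `gp_covariates`.
#' @param ystar optional observed values at the test covariates, on the
#'   same (possibly transformed) scale as the training targets.
#' @return an object of class `gp_predictive` with vectors `mean`,
#'   `latent_variance`, `observation_variance` and (if `ystar` given) `z`.
#' @export
gp_predict <- function(model, Xstar, ystar = NULL) {
  stopifnot(inherits(model, "trained_gp"))
  Xs <- if (inherits(Xstar, "gp_covariates")) Xstar
        else standardize_covariates(Xstar, model$covariates)
  Ks <- se_ard_kernel(Xs, model$covariates, model$hyper)   # p x n
  mean <- drop(Ks %*% model$alpha) + model$y_center
  v <- forwardsolve(model$L, t(Ks))                        # n x p
  latent <- pmax(model$hyper$amplitude - colSums(v^2), 0)
  obsvar <- latent + model$hyper$noise_variance
  out <- list(mean = mean, latent_variance = latent,
              observation_variance = obsvar)
  if (!is.null(ystar)) {
    ystar <- as.numeric(ystar)
    if (length(ystar) != length(mean))
      stop("ystar length does not match number of test rows")
    out$z <- (ystar - mean) / sqrt(obsvar)
  }
  structure(out, class = "gp_predictive")
}
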