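#' Box-Cox power transformation
#'
#' f_lambda(y) = (y^lambda - 1)/lambda for lambda != 0 and log(y) for
#' lambda = 0; continuous in lambda at 0.
#'
#' @param y strictly positive numeric vector.
#' @param lambda_ scalar power parameter.
#' @return transformed vector.
#' @export
boxcox_forward <- function(y, lambda_) {
  y <- as.numeric(y)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("Box-Cox requires strictly positive data; apply a positive shift first")
  if (abs(lambda_) < .Machine$double.eps) log(y)
  else (y^lambda_ - 1) / lambda_
}

#' Inverse Box-Cox transformation
#'
#' @param z transformed values.
#' @param lambda_ scalar power parameter used in the forward transform.
#' @return original-scale values.
#' @export
boxcox_inverse <- function(z, lambda_) {
  if (abs(lambda_) < .Machine$double.eps) exp(z)
  else (lambda_ * z + 1)^(1 / lambda_)
}

#' Profile log-likelihood of the Box-Cox parameter
#'
#' L(lambda) = -(n/2) log sigma2_hat(lambda) + (lambda - 1) sum(log y),
#' where sigma2_hat is the maximum-likelihood (1/n) residual variance of
#' the transformed data about its mean (intercept-only model; the
#' transform is a separate step before any regression modeling) and the
#' second term is the log Jacobian of the transformation.
#'
#' @param lambda_ scalar power parameter.
#' @param y strictly positive vector, length >= 3.
#' @return scalar log-likelihood; `-Inf` (with a warning) when the
#'   transformed data are degenerate (zero residual variance).
#' @export
boxcox_loglik <- function(lambda_, y) {
  y <- as.numeric(y)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("Box-Cox requires strictly positive data; apply a positive shift first")
  n <- length(y)
  if (n < 3) stop("need at least 3 observations")
  z <- boxcox_forward(y, lambda_)
  s2 <- sum((z - mean(z))^2) / n
  if (!is.finite(s2) || s2 <= 0) {
    warning("zero residual variance in Box-Cox likelihood")
    return(-Inf)
  }
  -0.5 * n * log(s2) + (lambda_ - 1) * sum(log(y))
}

#' Fit the Box-Cox parameter by maximum likelihood
#'
#' Maximizes [boxcox_loglik()] over lambda in `bounds` by bounded scalar
#' optimization and records the training mean mu and the Taylor-rescale
#' derivative f'_lambda(mu) = mu^(lambda - 1). When the data contain
#' non-positive values a configurable positive shift is added first and
#' stored in the model, so the same shift is reapplied to test data.
#'
#' @param y numeric training vector.
#' @param bounds search interval for lambda.
#' @param shift positive shift added when `any(y <= 0)`; recorded in the
#'   model (0 when no shift was needed).
#' @return an object of class `boxcox_model` with `lambda`, `mean`
#'   (mu, of the shifted data), `scale` (f'_lambda(mu)) and `shift`.
#' @export
fit_lambda <- function(y, bounds = c(-3, 3), shift = 1e-4) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("y must be finite")
  applied_shift <- 0
  if (any(y <= 0)) {
    applied_shift <- shift - min(y)
    y <- y + applied_shift
  }
  opt <- stats::optimize(function(l) boxcox_loglik(l, y),
                         interval = bounds, maximum = TRUE)
  lambda_ <- opt$maximum
  tol <- 1e-3 * diff(bounds)
  if (min(abs(lambda_ - bounds)) < tol)
    warning(sprintf("Box-Cox lambda hit search boundary (lambda = %.3f)",
                    lambda_))
  mu <- mean(y)
  structure(
    list(lambda = lambda_, mean = mu, scale = mu^(lambda_ - 1),
         shift = applied_shift),
    class = "boxcox_model"
  )
}

#' @export
print.boxcox_model <- function(x, ...) {
  cat(sprintf("<boxcox_model> lambda = %.4f, mu = %.4g, scale = %.4g, shift = %.4g\n",
              x$lambda, x$mean, x$scale, x$shift))
  invisible(x)
}

#' Apply a fitted Box-Cox transform with variance rescaling
#'
#' Returns f_lambda(y) / f'_lambda(mu), using the training lambda, mu and
#' shift unchanged (never re-estimated on test data). By the first-order
#' Taylor expansion of f_lambda around mu, the variance of the output
#' approximately matches the variance of y; with lambda = 1 the output is
#' exactly y - 1.
#'
#' @param model a `boxcox_model` from [fit_lambda()].
#' @param y numeric vector (training or test data on the original scale).
#' @return rescaled transformed vector.
#' @export
apply_rescaled <- function(model, y) {
  stopifnot(inherits(model, "boxcox_model"))
  boxcox_forward(as.numeric(y) + model$shift, model$lambda) / model$scale
}

#' Invert the rescaled Box-Cox transform
#'
#' @param model a `boxcox_model`.
#' @param z rescaled transformed values.
#' @return original-scale values.
#' @export
invert_rescaled <- function(model, z) {
  stopifnot(inherits(model, "boxcox_model"))
  boxcox_inverse(as.numeric(z) * model$scale, model$lambda) - model$shift
}

#' Residual-normality diagnostics
#'
#' Computes the correlation of the residuals' Q-Q plot against standard
#' normal plotting positions, plus the standardized third and fourth
#' sample moments. Kurtosis is reported raw (not excess): a normal sample
#' gives values near 3.
#'
#' @param residuals numeric vector.
#' @return a list of class `normality_report` with `qq_correlation`,
#'   `skewness`, `kurtosis`.
#' @export
normality_report <- function(residuals) {
  r <- as.numeric(residuals)
  r <- r[is.finite(r)]
  n <- length(r)
  if (n < 4) stop("need at least 4 residuals")
  q_theor <- stats::qnorm(stats::ppoints(n))
  qq <- stats::cor(sort(r), q_theor)
  m <- mean(r)
  m2 <- mean((r - m)^2)
  structure(
    list(qq_correlation = qq,
         skewness = mean((r - m)^3) / m2^1.5,
         kurtosis = mean((r - m)^4) / m2^2),
    class = "normality_report"
  )
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf("<normality_report> QQ cor = %.4f, skewness = %.3f, kurtosis = %.3f\n",
              x$qq_correlation, x$skewness, x$kurtosis))
  invisible(x)
}
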