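#' GP hyperparameters for the squared-exponential ARD kernel
#'
#' @param amplitude positive scalar signal variance `a` of the kernel.
#' @param length_scales vector of positive characteristic length scales,
#'   one per covariate dimension (in standardized-covariate units). Small
#'   length scales mark covariates the latent function varies quickly
#'   along; very large fitted length scales mark irrelevant covariates
#'   (automatic relevance determination).
#' @param noise_variance positive scalar observation-noise variance
#'   (in transformed-data units when a Box-Cox step precedes the GP).
#' @return an object of class `gp_hyper`.
#' @export
gp_hyper <- function(amplitude, length_scales, noise_variance) {
  amplitude <- as.numeric(amplitude)
  length_scales <- as.numeric(length_scales)
  noise_variance <- as.numeric(noise_variance)
  if (length(amplitude) != 1 || !is.finite(amplitude) || amplitude <= 0)
    stop("amplitude must be a positive finite scalar")
  if (length(length_scales) < 1 ||
      any(!is.finite(length_scales) | length_scales <= 0))
    stop("length_scales must be positive and finite")
  if (length(noise_variance) != 1 || !is.finite(noise_variance) ||
      noise_variance <= 0)
    stop("noise_variance must be a positive finite scalar")
  structure(
    list(amplitude = amplitude, length_scales = length_scales,
         noise_variance = noise_variance),
    class = "gp_hyper"
  )
}

#' @export
print.gp_hyper <- function(x, ...) {
  cat(sprintf("<gp_hyper> a = %.4g, noise var = %.4g, length scales = %s\n",
              x$amplitude, x$noise_variance,
              paste(signif(x$length_scales, 4), collapse = ", ")))
  invisible(x)
}

# Per-dimension scaled squared distances, returned as a list of p x q
# matrices (x_p[d] - x_q[d])^2 / l_d^2. Shared by kernel and gradient code.
scaled_sqdist <- function(Xp, Xq, length_scales) {
  lapply(seq_along(length_scales), function(d) {
    outer(Xp[, d], Xq[, d], "-")^2 / length_scales[d]^2
  })
}

#' Squared-exponential ARD covariance between two covariate sets
#'
#' Evaluates k(x_p, x_q) = a * exp(-1/2 * sum_d (x_pd - x_qd)^2 / l_d^2)
#' for all pairs of rows. Both inputs must already be standardized with
#' the same (training) shift and scale.
#'
#' @param Xp,Xq numeric matrices (or `gp_covariates`, whose standardized
#'   values are used) with m columns each.
#' @param hyper a [gp_hyper()] object whose `length_scales` has length m.
#' @return a p x q covariance matrix with entries in (0, a].
#' @export
se_ard_kernel <- function(Xp, Xq, hyper) {
  stopifnot(inherits(hyper, "gp_hyper"))
  if (inherits(Xp, "gp_covariates")) Xp <- Xp$std
  if (inherits(Xq, "gp_covariates")) Xq <- Xq$std
  Xp <- as.matrix(Xp); Xq <- as.matrix(Xq)
  m <- length(hyper$length_scales)
  if (ncol(Xp) != m || ncol(Xq) != m)
    stop(sprintf("kernel input dimension mismatch: %d and %d columns, %d length scales",
                 ncol(Xp), ncol(Xq), m))
  D2 <- Reduce(`+`, scaled_sqdist(Xp, Xq, hyper$length_scales))
  hyper$amplitude * exp(-0.5 * D2)
}
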