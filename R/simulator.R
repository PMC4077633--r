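#' Two-level mixed-effects trajectory ensemble specification
#'
#' Parameterizes an ensemble of individual lifespan trajectories of a
#' volumetric measure. Each subject follows a quadratic function of age,
#' y(t) = theta0 + theta1 t + theta2 t^2 (+ theta3 * max(0, t - theta4)
#' when `disease` is on), with subject-level parameters drawn from a
#' Gaussian second-level model and i.i.d. Gaussian observation noise.
#' A cross-sectional cohort samples one observation per subject at an age
#' drawn uniformly over `age_range`.
#'
#' Presets fill in the simulation conditions used throughout the package
#' validation:
#' \describe{
#'   \item{`fig2_large`}{healthy ensemble with large individual
#'     differences, Var(theta) = diag(6e-3, 1e-6, 2e-10), observation
#'     noise variance 0.01.}
#'   \item{`fig2_small`}{healthy ensemble with small individual
#'     differences, Var(theta) = diag(6e-4, 1e-7, 2e-11), observation
#'     noise variance 6e-6.}
#'   \item{`fig3_disease`}{diseased ensemble: the large-differences
#'     healthy law plus a linear decline with mean slope -0.02 after a
#'     Gaussian onset age with mean 65 and variance 20, observation noise
#'     variance 2e-5.}
#' }
#' All presets use E(theta) = (0.92, 4e-3, 1e-4), ages uniform on
#' [20, 90] years, and n = 640 subjects.
#'
#' @param preset optional preset name (`"fig2_large"`, `"fig2_small"`,
#'   `"fig3_disease"`); explicit arguments override preset entries.
#' @param n_subjects number of subjects (one observation each).
#' @param theta2_mean second-level means of the trajectory parameters
#'   (intercept, linear, quadratic, and for diseased ensembles disease
#'   slope and onset age).
#' @param theta1_var diagonal of the between-subject parameter covariance,
#'   same order as `theta2_mean`. The onset entry is a variance (its
#'   square root is the onset-age standard deviation in years).
#' @param noise_var first-level observation-noise variance.
#' @param age_range sampling interval (years) for the single observation
#'   per subject.
#' @param covariate_corr target correlations corr(x_k, theta_k) between
#'   the generated covariate columns and the true intercept/linear/
#'   quadratic parameters; each in [0, 1].
#' @param disease logical; include the post-onset linear decline term.
#' @param seed integer seed; the cohort is bit-reproducible given
#'   (spec, seed).
#' @return a list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(preset = NULL, n_subjects = 640L,
                          theta2_mean = NULL, theta1_var = NULL,
                          noise_var = NULL, age_range = c(20, 90),
                          covariate_corr = c(1, 1, 1), disease = NULL,
                          seed = 1L) {
  presets <- list(
    fig2_large = list(theta2_mean = c(0.92, 4e-3, 1e-4),
                      theta1_var = c(6e-3, 1e-6, 2e-10),
                      noise_var = 0.01, disease = FALSE),
    fig2_small = list(theta2_mean = c(0.92, 4e-3, 1e-4),
                      theta1_var = c(6e-4, 1e-7, 2e-11),
                      noise_var = 6e-6, disease = FALSE),
    fig3_disease = list(theta2_mean = c(0.92, 4e-3, 1e-4, -0.02, 65),
                        theta1_var = c(6e-3, 1e-6, 2e-10, 1e-4, 20),
                        noise_var = 2e-5, disease = TRUE)
  )
  if (!is.null(preset)) {
    if (!preset %in% names(presets))
      stop(sprintf("unknown preset '%s'; available: %s", preset,
                   paste(names(presets), collapse = ", ")))
    p <- presets[[preset]]
    if (is.null(theta2_mean)) theta2_mean <- p$theta2_mean
    if (is.null(theta1_var)) theta1_var <- p$theta1_var
    if (is.null(noise_var)) noise_var <- p$noise_var
    if (is.null(disease)) disease <- p$disease
  }
  if (is.null(disease)) disease <- FALSE
  if (is.null(theta2_mean) || is.null(theta1_var) || is.null(noise_var))
    stop("theta2_mean, theta1_var and noise_var are required without a preset")
  if (length(theta2_mean) != length(theta1_var))
    stop("theta2_mean and theta1_var lengths differ")
  if (disease && length(theta2_mean) != 5)
    stop("disease ensembles need 5 parameters (intercept, linear, quadratic, slope, onset)")
  if (!disease && length(theta2_mean) != 3)
    stop("healthy ensembles need 3 parameters (intercept, linear, quadratic)")
  if (any(theta1_var < 0) || noise_var < 0) stop("variances must be >= 0")
  if (any(covariate_corr < 0 | covariate_corr > 1))
    stop("covariate_corr entries must lie in [0, 1]")
  if (diff(age_range) <= 0) stop("age_range lower bound must be below upper")
  structure(
    list(preset = preset, n_subjects = as.integer(n_subjects),
         theta2_mean = theta2_mean, theta1_var = theta1_var,
         noise_var = noise_var, age_range = age_range,
         covariate_corr = covariate_corr, disease = disease,
         seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec>%s n = %d, %s, noise var = %.3g, ages [%g, %g]\n",
              if (is.null(x$preset)) "" else paste0(" [", x$preset, "]"),
              x$n_subjects, if (x$disease) "diseased" else "healthy",
              x$noise_var, x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Generate covariates correlated with true change parameters
#'
#' For each trajectory parameter theta_k, builds a covariate column
#' x_k = r * standardize(theta_k) + sqrt(1 - r^2) * e with independent
#' standard-normal e, so that corr(x_k, theta_k) converges to the target
#' r. At r = 1 the covariate is exactly the standardized parameter (no
#' noise path); at r = 0 it is independent noise.
#'
#' Standardization uses the ensemble's population mean and standard
#' deviation when supplied (the default from the simulator), so
#' independently simulated cohorts map parameters to covariates
#' identically; otherwise the sample moments are used.
#'
#' @param true_theta n x k matrix of per-subject trajectory parameters.
#' @param target_r vector of k target correlations in [0, 1].
#' @param seed integer seed for the independent noise.
#' @param center,scale optional population mean and standard deviation of
#'   each parameter column, used for the standardization.
#' @return an n x k matrix of covariate columns.
#' @export
correlated_covariates <- function(true_theta, target_r, seed = 1L,
                                  center = NULL, scale = NULL) {
  true_theta <- as.matrix(true_theta)
  k <- ncol(true_theta)
  if (length(target_r) != k)
    stop("target_r length must match the number of parameter columns")
  if (any(target_r < 0 | target_r > 1)) stop("target_r must lie in [0, 1]")
  n <- nrow(true_theta)
  if (is.null(center)) center <- colMeans(true_theta)
  if (is.null(scale)) scale <- apply(true_theta, 2, stats::sd)
  set.seed(as.integer(seed))
  X <- matrix(0, n, k)
  for (d in seq_len(k)) {
    s <- scale[d]
    z <- if (is.finite(s) && s > 0) (true_theta[, d] - center[d]) / s
         else rep(0, n)
    r <- target_r[d]
    X[, d] <- if (r == 1) z
              else if (r == 0) stats::rnorm(n)
              else r * z + sqrt(1 - r^2) * stats::rnorm(n)
  }
  colnames(X) <- paste0("x", seq_len(k) - 1L)
  X
}

simulate_cohort <- function(spec) {
  n <- spec$n_subjects
  k <- length(spec$theta2_mean)
  set.seed(spec$seed)
  theta <- sapply(seq_len(k), function(d)
    stats::rnorm(n, spec$theta2_mean[d], sqrt(spec$theta1_var[d])))
  theta <- matrix(theta, nrow = n)
  ages <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  f <- theta[, 1] + theta[, 2] * ages + theta[, 3] * ages^2
  onset <- NULL
  if (spec$disease) {
    onset <- theta[, 5]
    f <- f + theta[, 4] * pmax(0, ages - onset)
  }
  y <- f + stats::rnorm(n, 0, sqrt(spec$noise_var))
  # covariates relate to the intercept/linear/quadratic parameters only;
  # drawn from an independent stream so healthy/diseased share the
  # pre-onset law regardless of the extra disease-parameter draws
  xc <- correlated_covariates(theta[, 1:3, drop = FALSE],
                              spec$covariate_corr,
                              seed = spec$seed + 500000L,
                              center = spec$theta2_mean[1:3],
                              scale = sqrt(spec$theta1_var[1:3]))
  covariates <- cbind(age = ages, xc)
  out <- list(observations = y, ages = ages, covariates = covariates,
              true_theta = theta, spec = spec)
  if (spec$disease) {
    out$onset_age <- onset
    out$years_since_onset <- ages - onset
  }
  structure(out, class = "simulated_cohort")
}

#' Simulate a healthy cross-sectional cohort
#'
#' Draws subject-level trajectory parameters from the second-level
#' Gaussian model, samples one observation per subject at a uniform age,
#' adds Gaussian observation noise, and attaches covariates correlated
#' with the true change parameters at the specified levels.
#'
#' @param spec an [ensemble_spec()] with `disease = FALSE`.
#' @return a `simulated_cohort` with `observations`, `ages`,
#'   `covariates` (matrix with columns age, x0, x1, x2) and `true_theta`.
#' @export
simulate_healthy <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (spec$disease) stop("spec has disease = TRUE; use simulate_diseased()")
  simulate_cohort(spec)
}

#' Simulate a diseased cross-sectional cohort
#'
#' As [simulate_healthy()], plus a per-subject linear decline
#' theta3 * max(0, t - theta4) after a Gaussian random onset age theta4.
#' Before onset the trajectory law is identical to the healthy ensemble
#' with matched first three parameters.
#'
#' @param spec an [ensemble_spec()] with `disease = TRUE` (e.g. the
#'   `fig3_disease` preset).
#' @return a `simulated_cohort` with additional `onset_age` and
#'   `years_since_onset` fields.
#' @export
simulate_diseased <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (!spec$disease) stop("spec has disease = FALSE; use simulate_healthy()")
  simulate_cohort(spec)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> n = %d, %s, mean y = %.4f\n",
              length(x$observations),
              if (x$spec$disease) "diseased" else "healthy",
              mean(x$observations)))
  invisible(x)
}

#' Write a cohort as a small NIfTI phantom stack plus covariate table
#'
#' Replicates each subject's scalar observation into the voxels of a
#' small 3-D phantom: voxels inside `effect_mask` carry the cohort signal
#' plus independent Gaussian noise, background voxels carry low-level
#' pure noise (below the 0.05 mean-intensity mask threshold), so the
#' written stack exercises the full image pipeline without any download.
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if missing).
#' @param grid_dim integer vector of 3 phantom dimensions.
#' @param effect_mask logical 3-D array of signal-carrying voxels;
#'   default: a central block of roughly half the voxels.
#' @param voxel_noise_sd standard deviation of the independent per-voxel
#'   noise added on top of the subject signal.
#' @param seed integer seed.
#' @return invisibly, a list with `image_paths`, `mask_path`,
#'   `covariates_path` and the `effect_mask` used.
#' @export
export_cohort_as_images <- function(cohort, dir, grid_dim = c(5, 5, 5),
                                    effect_mask = NULL,
                                    voxel_noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(effect_mask)) {
    effect_mask <- array(FALSE, grid_dim)
    idx <- lapply(grid_dim, function(d) seq_len(max(1, floor(d / 2))) +
                    floor(d / 4))
    effect_mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  }
  stopifnot(all(dim(effect_mask) == grid_dim))
  n <- length(cohort$observations)
  nv <- prod(grid_dim)
  set.seed(as.integer(seed))
  image_paths <- character(n)
  ids <- sprintf("sub%03d", seq_len(n))
  for (i in seq_len(n)) {
    vol <- array(abs(stats::rnorm(nv, 0.01, 0.005)), grid_dim)
    ne <- sum(effect_mask)
    vol[effect_mask] <- cohort$observations[i] +
      stats::rnorm(ne, 0, voxel_noise_sd)
    image_paths[i] <- file.path(dir, paste0(ids[i], ".nii"))
    RNifti::writeNifti(RNifti::asNifti(vol), image_paths[i])
  }
  mask_path <- file.path(dir, "mask.nii")
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(effect_mask),
                                           grid_dim)), mask_path)
  covar <- data.frame(subject_id = ids, cohort$covariates,
                      check.names = FALSE)
  covariates_path <- file.path(dir, "covariates.csv")
  utils::write.csv(covar, covariates_path, row.names = FALSE)
  invisible(list(image_paths = image_paths, mask_path = mask_path,
                 covariates_path = covariates_path,
                 effect_mask = effect_mask))
}
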