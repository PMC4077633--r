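#' Settings for voxelwise normative model training
#'
#' @param boxcox logical; fit a per-voxel Box-Cox transform before the GP.
#' @param boxcox_shift positive shift applied to voxels containing
#'   non-positive values before the Box-Cox transform.
#' @param mask_threshold mean-intensity threshold used to derive a mask
#'   when none is supplied: a voxel is modeled when its training sample
#'   mean exceeds this value.
#' @param fit a [gp_fit_config()] passed to every per-voxel GP fit.
#' @return a list of class `normative_config`.
#' @export
normative_config <- function(boxcox = TRUE, boxcox_shift = 1e-4,
                             mask_threshold = 0.05,
                             fit = gp_fit_config()) {
  structure(list(boxcox = boxcox, boxcox_shift = boxcox_shift,
                 mask_threshold = mask_threshold, fit = fit),
            class = "normative_config")
}

# Derive the per-voxel seed from the master seed; kept below 2^31.
voxel_seed <- function(seed, j) bitwXor(as.integer(seed), as.integer(j))

#' Train one GP per masked voxel
#'
#' Mass-univariate training: for every in-mask voxel, optionally fit a
#' Box-Cox transform on the training data, then fit a GP by evidence
#' optimization on the (transformed, centered) data. Voxels are
#' statistically independent; per-voxel seeds are derived as
#' `xor(seed, voxel_index)` so results do not depend on processing order
#' or chunking. Failed per-voxel fits are flagged and produce NaN in all
#' derived maps.
#'
#' @param Y n x v matrix of per-voxel observations (rows = subjects). If
#'   a mask volume is supplied with more voxels than columns of `Y` and
#'   `ncol(Y)` equals the full grid size, `Y` is subset to the in-mask
#'   columns.
#' @param X covariate matrix or data frame (n rows, schema columns such
#'   as age, sex, tgmv, twmv, tcsf, fstr).
#' @param mask optional logical/numeric 3-D array (or vector) marking
#'   modeled voxels. When absent, the mask is derived as
#'   `colMeans(Y) > mask_threshold`.
#' @param config a [normative_config()].
#' @param seed master integer seed.
#' @return an object of class `voxel_model_set` holding the per-voxel
#'   models, the mask (row-major linear voxel order), the covariate
#'   schema, `evidence_map`, `noise_map` (log sigma-hat) and the training
#'   data needed for refits.
#' @export
train_voxelwise <- function(Y, X, mask = NULL,
                            config = normative_config(), seed = 1L) {
  Y <- as.matrix(Y)
  Xm <- as.matrix(X)
  if (nrow(Y) != nrow(Xm)) stop("rows of Y and X must align")
  grid_dim <- NULL
  if (is.null(mask)) {
    mask <- colMeans(Y) > config$mask_threshold
  } else {
    if (!is.null(dim(mask))) grid_dim <- dim(mask)
    mask <- as.logical(as.vector(mask) != 0)
    if (length(mask) != ncol(Y) && sum(mask) != ncol(Y))
      stop(sprintf("mask voxel count (%d) does not match Y columns (%d)",
                   length(mask), ncol(Y)))
  }
  voxel_index <- which(mask)
  # Y may cover the full grid or already be restricted to in-mask columns
  Yin <- if (ncol(Y) == length(mask)) Y[, voxel_index, drop = FALSE]
         else Y
  cov <- covariate_matrix(Xm)
  l <- length(voxel_index)
  models <- vector("list", l)
  evidence_map <- noise_map <- lambda_map <- rep(NA_real_, l)
  failed <- logical(l)
  for (k in seq_len(l)) {
    j <- voxel_index[k]
    res <- tryCatch({
      yj <- Yin[, k]
      bc <- NULL
      if (config$boxcox) {
        bc <- fit_lambda(yj, shift = config$boxcox_shift)
        yj <- apply_rescaled(bc, Yin[, k])
      }
      gp <- fit_gp(cov, yj, config = config$fit, seed = voxel_seed(seed, j))
      gp$boxcox <- bc
      gp
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[k] <- TRUE
    } else {
      models[[k]] <- res
      evidence_map[k] <- res$log_evidence
      noise_map[k] <- 0.5 * log(res$hyper$noise_variance)
      if (!is.null(res$boxcox)) lambda_map[k] <- res$boxcox$lambda
    }
  }
  if (any(failed))
    warning(sprintf("%d of %d voxel fits failed (%.1f%%)", sum(failed), l,
                    100 * mean(failed)))
  structure(
    list(models = models, mask = mask, grid_dim = grid_dim,
         voxel_index = voxel_index, covariate_schema = colnames(Xm),
         covariates = cov, train_Y = Yin,
         evidence_map = evidence_map, noise_map = noise_map,
         lambda_map = lambda_map, failed = failed,
         config = config, seed = as.integer(seed)),
    class = "voxel_model_set"
  )
}

#' @export
print.voxel_model_set <- function(x, ...) {
  cat(sprintf("<voxel_model_set> %d voxels, %d subjects, covariates: %s\n",
              length(x$models), nrow(x$covariates$values),
              paste(x$covariate_schema, collapse = ", ")))
  if (any(x$failed))
    cat(sprintf("  %d voxel fits failed\n", sum(x$failed)))
  invisible(x)
}

# Place an in-mask vector into a grid volume (NaN outside the mask) when
# grid dimensions are known; otherwise return a full-length vector.
unmask_volume <- function(models, values) {
  full <- rep(NaN, length(models$mask))
  full[models$voxel_index] <- values
  if (!is.null(models$grid_dim)) array(full, models$grid_dim) else full
}

#' Normative Probability Maps for test subjects
#'
#' For every test subject, computes the voxelwise z-scores delta of the
#' GP predictive distribution (the NPM) together with the companion maps:
#' predicted mean, prediction error (observed - predicted) and square
#' root of the predictive uncertainty. Observed test values are
#' transformed with each voxel's \emph{training} Box-Cox model (never
#' re-estimated), so all maps live on the transformed scale. Outside the
#' mask all maps are NaN.
#'
#' @param models a `voxel_model_set` from [train_voxelwise()].
#' @param Xstar test covariate matrix/data frame with the training schema
#'   columns.
#' @param Ystar n* x v matrix of observed test values on the original
#'   scale (full grid or in-mask columns).
#' @return a list of class `npm_result`: per-subject lists with elements
#'   `z`, `predicted`, `error`, `sqrt_uncertainty` (volumes when grid
#'   dimensions are known, in-mask vectors otherwise), plus matrices
#'   `z_matrix`, `mean_matrix`, `uncertainty_matrix` (subjects x voxels).
#' @export
compute_npm <- function(models, Xstar, Ystar) {
  stopifnot(inherits(models, "voxel_model_set"))
  Xs <- as.matrix(Xstar)
  if (!is.null(colnames(Xs)) &&
      !identical(colnames(Xs), models$covariate_schema)) {
    if (!all(models$covariate_schema %in% colnames(Xs)))
      stop("test covariates are missing schema columns: ",
           paste(setdiff(models$covariate_schema, colnames(Xs)),
                 collapse = ", "))
    Xs <- Xs[, models$covariate_schema, drop = FALSE]
  }
  Ystar <- as.matrix(Ystar)
  if (ncol(Ystar) == length(models$mask)) {
    Ystar <- Ystar[, models$voxel_index, drop = FALSE]
  } else if (ncol(Ystar) != length(models$voxel_index)) {
    stop("Ystar columns match neither the grid nor the in-mask voxel count")
  }
  p <- nrow(Xs)
  l <- length(models$models)
  zs <- mu <- err <- uu <- matrix(NaN, p, l)
  Xstd <- standardize_covariates(Xs, models$covariates)
  for (k in seq_len(l)) {
    gp <- models$models[[k]]
    if (is.null(gp)) next
    yk <- Ystar[, k]
    if (!is.null(gp$boxcox)) yk <- apply_rescaled(gp$boxcox, yk)
    pred <- gp_predict(gp, Xstd, ystar = yk)
    zs[, k] <- pred$z
    mu[, k] <- pred$mean
    err[, k] <- yk - pred$mean
    uu[, k] <- sqrt(pred$observation_variance)
  }
  subjects <- lapply(seq_len(p), function(i) {
    list(z = unmask_volume(models, zs[i, ]),
         predicted = unmask_volume(models, mu[i, ]),
         error = unmask_volume(models, err[i, ]),
         sqrt_uncertainty = unmask_volume(models, uu[i, ]))
  })
  structure(list(subjects = subjects, z_matrix = zs, mean_matrix = mu,
                 error_matrix = err, uncertainty_matrix = uu),
            class = "npm_result")
}

#' Train global tissue-volume models
#'
#' Fits one GP per global measure (tgmv, twmv, tcsf) on covariates
#' age, sex, ticv, fstr, with ticv = tgmv + twmv + tcsf derived when
#' absent. Globals are modeled untransformed by default.
#'
#' @param covariates data frame with columns age, sex, fstr and either
#'   ticv or the three tissue volumes.
#' @param volumes data frame (or matrix) with columns tgmv, twmv, tcsf.
#' @param config a [normative_config()]; `boxcox = FALSE` by default for
#'   globals unless the supplied config enables it.
#' @param seed integer seed.
#' @return an object of class `global_model_set` with one `trained_gp`
#'   per measure.
#' @export
train_global <- function(covariates, volumes,
                         config = normative_config(boxcox = FALSE),
                         seed = 1L) {
  volumes <- as.data.frame(volumes)
  need <- c("tgmv", "twmv", "tcsf")
  if (!all(need %in% names(volumes)))
    stop("volumes must contain columns tgmv, twmv, tcsf")
  covariates <- as.data.frame(covariates)
  if (!"ticv" %in% names(covariates))
    covariates$ticv <- volumes$tgmv + volumes$twmv + volumes$tcsf
  schema <- c("age", "sex", "ticv", "fstr")
  if (!all(schema %in% names(covariates)))
    stop("global covariates must contain: ", paste(schema, collapse = ", "))
  Xm <- as.matrix(covariates[, schema])
  cov <- covariate_matrix(Xm)
  models <- lapply(seq_along(need), function(k) {
    y <- volumes[[need[k]]]
    bc <- NULL
    if (config$boxcox) {
      bc <- fit_lambda(y, shift = config$boxcox_shift)
      y <- apply_rescaled(bc, volumes[[need[k]]])
    }
    gp <- fit_gp(cov, y, config = config$fit,
                 seed = voxel_seed(seed, k))
    gp$boxcox <- bc
    gp
  })
  names(models) <- need
  structure(list(models = models, covariate_schema = schema,
                 covariates = cov, config = config,
                 seed = as.integer(seed)),
            class = "global_model_set")
}

#' Global tissue-volume z-scores for test subjects
#'
#' @param models a `global_model_set` from [train_global()].
#' @param covariates test covariate data frame (age, sex, fstr, and ticv
#'   or the three volumes to derive it).
#' @param volumes test data frame with observed tgmv, twmv, tcsf.
#' @return a data frame with columns z_tgmv, z_twmv, z_tcsf, one row per
#'   test subject.
#' @export
compute_global_z <- function(models, covariates, volumes) {
  stopifnot(inherits(models, "global_model_set"))
  volumes <- as.data.frame(volumes)
  covariates <- as.data.frame(covariates)
  if (!"ticv" %in% names(covariates))
    covariates$ticv <- volumes$tgmv + volumes$twmv + volumes$tcsf
  Xs <- as.matrix(covariates[, models$covariate_schema])
  Xstd <- standardize_covariates(Xs, models$covariates)
  out <- lapply(names(models$models), function(nm) {
    gp <- models$models[[nm]]
    y <- volumes[[nm]]
    if (!is.null(gp$boxcox)) y <- apply_rescaled(gp$boxcox, y)
    gp_predict(gp, Xstd, ystar = y)$z
  })
  names(out) <- paste0("z_", names(models$models))
  as.data.frame(out)
}

#' Naive-Bayes posterior over disease states
#'
#' Combines per-voxel log-likelihoods of the observed scan under each
#' candidate disease state's generative model, assuming conditional
#' independence across voxels, into a posterior over states:
#' P(D_i | scan) proportional to P(D_i) * prod_j P(y_j | D_i).
#' Computed in log space with max-subtraction for numerical stability.
#'
#' @param log_likelihood_maps named list, one numeric vector of per-voxel
#'   log-densities per state; all states must cover the same voxels with
#'   finite values (no silent marginalization).
#' @param priors named numeric vector of prior state probabilities,
#'   summing to 1; names must match `log_likelihood_maps`.
#' @return a list of class `disease_posterior` with `priors`,
#'   `log_likelihoods` (per-state totals) and `posterior`.
#' @export
naive_bayes_posterior <- function(log_likelihood_maps, priors) {
  states <- names(log_likelihood_maps)
  if (is.null(states) || any(states == ""))
    stop("log_likelihood_maps must be a named list of states")
  if (!setequal(states, names(priors)))
    stop("prior names do not match the likelihood states")
  priors <- priors[states]
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1")
  lens <- vapply(log_likelihood_maps, length, 1L)
  if (length(unique(lens)) != 1)
    stop("all states must supply a likelihood for the same voxel set")
  if (any(vapply(log_likelihood_maps, function(v) any(!is.finite(v)), TRUE)))
    stop("non-finite log-likelihood entries; every state must cover every voxel")
  total <- vapply(log_likelihood_maps, sum, 1)
  lp <- log(priors) + total
  lp <- lp - max(lp)
  post <- exp(lp) / sum(exp(lp))
  structure(list(priors = priors, log_likelihoods = total,
                 posterior = post),
            class = "disease_posterior")
}

#' Per-voxel log-likelihood of a scan under the healthy model
#'
#' Evaluates the GP predictive density (mean and observation variance) of
#' the observed in-mask values for one test subject; the canonical input
#' to [naive_bayes_posterior()] for the healthy state.
#'
#' @param models a `voxel_model_set`.
#' @param xstar single-row test covariates.
#' @param ystar observed values for that subject (full grid or in-mask).
#' @return numeric vector of per-voxel log-densities.
#' @export
healthy_log_likelihood <- function(models, xstar, ystar) {
  npm <- compute_npm(models, xstar, matrix(ystar, nrow = 1))
  z <- npm$z_matrix[1, ]
  u <- npm$uncertainty_matrix[1, ]
  stats::dnorm(z, log = TRUE) - log(u)
}

#' Predictive-uncertainty profile over training sample size
#'
#' Refits the GP of one voxel on random training subsamples of several
#' sizes and records the mean and the across-subject standard deviation
#' of the predictive uncertainty u (square root of the predictive
#' variance) in a fixed test set, averaged over repeats. Growing the
#' training sample mainly stabilizes u across test subjects; its average
#' changes comparatively little.
#'
#' @param models a `voxel_model_set` (its stored training data are
#'   resampled) or a list with elements `X` (raw covariates) and `y`.
#' @param Xstar test covariates (raw).
#' @param sizes integer vector of training subsample sizes.
#' @param repeats random subsamples per size (sizes equal to the full
#'   sample collapse to one deterministic fit).
#' @param seed integer seed.
#' @param voxel in-mask voxel index used when `models` is a
#'   `voxel_model_set`.
#' @param config a [gp_fit_config()] for the refits.
#' @return a data frame with columns `size`, `mean_u`, `sd_u`.
#' @export
uncertainty_profile <- function(models, Xstar, sizes, repeats = 5L,
                                seed = 1L, voxel = 1L,
                                config = gp_fit_config()) {
  if (inherits(models, "voxel_model_set")) {
    X <- models$covariates$values
    y <- models$train_Y[, voxel]
    bc <- models$models[[voxel]]$boxcox
    if (!is.null(bc)) y <- apply_rescaled(bc, y)
  } else {
    X <- as.matrix(models$X)
    y <- as.numeric(models$y)
  }
  Xstar <- as.matrix(Xstar)
  n <- length(y)
  rows <- lapply(sizes, function(s) {
    reps <- if (s >= n) 1L else as.integer(repeats)
    us <- matrix(NA_real_, reps, nrow(Xstar))
    for (r in seq_len(reps)) {
      if (s >= n) {
        idx <- seq_len(n)
      } else {
        set.seed(as.integer(seed) + 1000L * match(s, sizes) + r)
        idx <- sample.int(n, s)
      }
      gp <- fit_gp(X[idx, , drop = FALSE], y[idx], config = config,
                   seed = as.integer(seed) + r)
      us[r, ] <- sqrt(gp_predict(gp, Xstar)$observation_variance)
    }
    data.frame(size = s, mean_u = mean(rowMeans(us)),
               sd_u = mean(apply(us, 1, stats::sd)))
  })
  do.call(rbind, rows)
}
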