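#' Read a stack of coregistered NIfTI volumes into a subject-by-voxel matrix
#'
#' All volumes must share grid dimensions; affines must agree within
#' 1e-4. Subjects are ordered by `ids` when given (e.g. to match a
#' covariate table); otherwise file order is kept.
#'
#' @param paths character vector of per-subject 3-D NIfTI paths, or a
#'   single 4-D NIfTI path.
#' @param ids optional subject IDs, one per path, used for reordering and
#'   error messages.
#' @return a list of class `image_stack` with `data` (n x v matrix over
#'   the full grid, row-major voxel order), `dim`, `ids`, and the first
#'   volume's NIfTI header as `template`.
#' @export
read_image_stack <- function(paths, ids = NULL) {
  stopifnot(length(paths) >= 1)
  vols <- lapply(paths, RNifti::readNifti)
  if (length(paths) == 1 && length(dim(vols[[1]])) == 4) {
    v4 <- vols[[1]]
    d <- dim(v4)
    data <- matrix(aperm(as.array(v4), c(4, 1, 2, 3)), nrow = d[4])
    grid <- d[1:3]
    ids <- ids %||% sprintf("sub%03d", seq_len(d[4]))
    template <- vols[[1]]
  } else {
    dims <- lapply(vols, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
      stop(sprintf("grid dimension mismatch across volumes: %s vs %s",
                   paste(dims[[1]], collapse = "x"),
                   paste(dims[[which(vapply(dims, paste, "", collapse = "x") !=
                                       paste(dims[[1]], collapse = "x"))[1]]],
                         collapse = "x")))
    affines <- lapply(vols, function(v) RNifti::xform(v))
    for (i in seq_along(affines))
      if (max(abs(affines[[i]] - affines[[1]])) > 1e-4)
        stop("affine mismatch across volumes beyond 1e-4")
    grid <- dims[[1]]
    data <- do.call(rbind, lapply(vols, as.vector))
    ids <- ids %||% sub("\\.nii(\\.gz)?$", "", basename(paths))
    template <- vols[[1]]
  }
  rownames(data) <- ids
  structure(list(data = data, dim = grid, ids = ids, template = template),
            class = "image_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align an image stack to a covariate table by subject ID
#'
#' @param stack an `image_stack`.
#' @param covariates data frame with a `subject_id` column.
#' @return the covariate data frame reordered to the stack's subject
#'   order; errors list any mismatched IDs.
#' @export
align_by_id <- function(stack, covariates) {
  if (!"subject_id" %in% names(covariates))
    stop("covariate table needs a subject_id column to join on")
  missing_img <- setdiff(stack$ids, covariates$subject_id)
  missing_cov <- setdiff(covariates$subject_id, stack$ids)
  if (length(missing_img) || length(missing_cov))
    stop(sprintf("ID mismatch between images and covariates; no covariates for [%s]; no images for [%s]",
                 paste(missing_img, collapse = ", "),
                 paste(missing_cov, collapse = ", ")))
  covariates[match(stack$ids, covariates$subject_id), , drop = FALSE]
}

#' Read and validate a covariate table
#'
#' @param path CSV path with one header row and one row per subject.
#' @param schema `"local"` (age, sex, tgmv, twmv, tcsf, fstr),
#'   `"global"` (age, sex, ticv, fstr; ticv derived from the tissue
#'   volumes when absent), `"simulated"` (age, x0, x1, x2), or an
#'   explicit character vector of required columns.
#' @param binary_labels optional named list mapping string labels of
#'   binary columns to 0/1, e.g. `list(sex = c(F = 0, M = 1))`.
#' @return a data frame containing `subject_id` (if present) and the
#'   schema columns, validated finite, with an attribute `schema`.
#' @export
read_covariates <- function(path, schema = "local", binary_labels = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- if (length(schema) > 1) schema
          else switch(schema,
                      local = c("age", "sex", "tgmv", "twmv", "tcsf", "fstr"),
                      global = c("age", "sex", "ticv", "fstr"),
                      simulated = c("age", "x0", "x1", "x2"),
                      stop(sprintf("unknown schema '%s'", schema)))
  if (identical(schema, "global") && !"ticv" %in% names(df) &&
      all(c("tgmv", "twmv", "tcsf") %in% names(df)))
    df$ticv <- df$tgmv + df$twmv + df$tcsf
  for (nm in names(binary_labels)) {
    if (nm %in% names(df) && is.character(df[[nm]])) {
      map <- binary_labels[[nm]]
      bad <- setdiff(unique(df[[nm]]), names(map))
      if (length(bad))
        stop(sprintf("unmapped labels in column %s: %s", nm,
                     paste(bad, collapse = ", ")))
      df[[nm]] <- as.numeric(map[df[[nm]]])
    }
  }
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("covariate file is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  for (nm in cols) {
    if (!is.numeric(df[[nm]]))
      stop(sprintf("covariate column %s is not numeric", nm))
    if (any(!is.finite(df[[nm]])))
      stop(sprintf("non-finite values in covariate column %s", nm))
  }
  if ("subject_id" %in% names(df) && anyDuplicated(df$subject_id))
    stop("duplicate subject_id entries in covariate file")
  keep <- intersect(c("subject_id", cols), names(df))
  out <- df[, keep, drop = FALSE]
  attr(out, "schema") <- cols
  out
}

#' Write NPM result volumes as NIfTI files
#'
#' Writes, per test subject, the z map, predicted mean, prediction error
#' and square-root uncertainty volumes (NaN outside the mask).
#'
#' @param npm an `npm_result` from [compute_npm()] whose model set knew
#'   its grid dimensions.
#' @param models the `voxel_model_set` used (for grid/mask geometry).
#' @param dir output directory.
#' @param ids optional subject IDs for file naming.
#' @param template optional NIfTI template for header/affine.
#' @return invisibly, a character matrix of written paths
#'   (subjects x map types).
#' @export
write_npm <- function(npm, models, dir, ids = NULL, template = NULL) {
  stopifnot(inherits(npm, "npm_result"))
  if (is.null(models$grid_dim))
    stop("model set has no grid dimensions; cannot write volumes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- length(npm$subjects)
  ids <- ids %||% sprintf("sub%03d", seq_len(p))
  kinds <- c("z", "predicted", "error", "sqrt_uncertainty")
  paths <- matrix("", p, length(kinds), dimnames = list(ids, kinds))
  for (i in seq_len(p)) {
    for (k in kinds) {
      vol <- npm$subjects[[i]][[k]]
      img <- if (is.null(template)) RNifti::asNifti(vol)
             else RNifti::asNifti(vol, reference = template)
      paths[i, k] <- file.path(dir, sprintf("%s_%s.nii", ids[i], k))
      RNifti::writeNifti(img, paths[i, k])
    }
  }
  invisible(paths)
}

#' Export the per-voxel Box-Cox lambda map as a NIfTI volume
#'
#' @param models a `voxel_model_set` with grid dimensions.
#' @param path output NIfTI path.
#' @export
write_lambda_map <- function(models, path) {
  if (is.null(models$grid_dim))
    stop("model set has no grid dimensions; cannot write a volume")
  RNifti::writeNifti(RNifti::asNifti(unmask_volume(models,
                                                   models$lambda_map)),
                     path)
  invisible(path)
}

serialize_gp <- function(gp) {
  list(hyper = list(amplitude = gp$hyper$amplitude,
                    length_scales = gp$hyper$length_scales,
                    noise_variance = gp$hyper$noise_variance),
       y_center = gp$y_center,
       targets = gp$targets,
       log_evidence = gp$log_evidence,
       jitter_used = gp$jitter_used,
       converged = gp$converged,
       boxcox = if (is.null(gp$boxcox)) NULL else
         list(lambda = gp$boxcox$lambda, mean = gp$boxcox$mean,
              scale = gp$boxcox$scale, shift = gp$boxcox$shift))
}

deserialize_gp <- function(rec, cov, jitter = 1e-8, jitter_max = 1e-2) {
  hyper <- gp_hyper(rec$hyper$amplitude, unlist(rec$hyper$length_scales),
                    rec$hyper$noise_variance)
  K <- se_ard_kernel(cov, cov, hyper)
  ch <- chol_with_jitter(K, hyper$noise_variance, hyper$amplitude,
                         jitter, jitter_max)
  y <- unlist(rec$targets)
  alpha <- backsolve(t(ch$L), forwardsolve(ch$L, y))
  bc <- NULL
  if (!is.null(rec$boxcox))
    bc <- structure(list(lambda = rec$boxcox$lambda, mean = rec$boxcox$mean,
                         scale = rec$boxcox$scale, shift = rec$boxcox$shift),
                    class = "boxcox_model")
  structure(
    list(hyper = hyper, covariates = cov, y_center = rec$y_center,
         targets = y, L = ch$L, alpha = alpha,
         log_evidence = rec$log_evidence, jitter_used = rec$jitter_used,
         converged = isTRUE(rec$converged), boxcox = bc),
    class = "trained_gp"
  )
}

#' Save a voxel model set to a versioned JSON container
#'
#' Self-describing text container holding the covariate schema and
#' standardization constants, the mask (grid dimensions + row-major
#' in-mask indices), per-voxel hyperparameters, Box-Cox parameters and
#' training targets, and the raw training covariates. Cholesky
#' factorizations are rebuilt on load. Metadata round-trips bit-stably;
#' floats to full double precision.
#'
#' @param models a `voxel_model_set` or `global_model_set`.
#' @param path output file path (JSON).
#' @export
save_model_set <- function(models, path) {
  if (inherits(models, "voxel_model_set")) {
    payload <- list(
      format = "gpnorm_model_set", version = 1L, kind = "voxel",
      covariate_schema = models$covariate_schema,
      center = models$covariates$center, scale = models$covariates$scale,
      train_covariates = models$covariates$values,
      grid_dim = models$grid_dim, mask_index = models$voxel_index,
      mask_length = length(models$mask), seed = models$seed,
      models = lapply(models$models, function(m)
        if (is.null(m)) NULL else serialize_gp(m)),
      train_Y = models$train_Y
    )
  } else if (inherits(models, "global_model_set")) {
    payload <- list(
      format = "gpnorm_model_set", version = 1L, kind = "global",
      covariate_schema = models$covariate_schema,
      center = models$covariates$center, scale = models$covariates$scale,
      train_covariates = models$covariates$values, seed = models$seed,
      models = lapply(models$models, serialize_gp)
    )
  } else stop("unsupported model object")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model set saved with [save_model_set()]
#'
#' @param path JSON container path.
#' @return a `voxel_model_set` or `global_model_set`.
#' @export
load_model_set <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "gpnorm_model_set"))
    stop("not a gpnorm model container")
  cov <- covariate_matrix(as.matrix(p$train_covariates),
                          column_names = p$covariate_schema,
                          center = unlist(p$center),
                          scale = unlist(p$scale))
  if (identical(p$kind, "voxel")) {
    recs <- if (is.data.frame(p$models)) split(p$models, seq_len(nrow(p$models)))
            else p$models
    models <- lapply(recs, function(r) {
      if (is.null(r) || (is.list(r) && length(r) == 0)) NULL
      else deserialize_gp(r, cov)
    })
    mask <- rep(FALSE, p$mask_length)
    mask[unlist(p$mask_index)] <- TRUE
    evidence_map <- vapply(models, function(m)
      if (is.null(m)) NA_real_ else m$log_evidence, 1)
    noise_map <- vapply(models, function(m)
      if (is.null(m)) NA_real_ else 0.5 * log(m$hyper$noise_variance), 1)
    lambda_map <- vapply(models, function(m)
      if (is.null(m) || is.null(m$boxcox)) NA_real_ else m$boxcox$lambda, 1)
    structure(
      list(models = models, mask = mask,
           grid_dim = if (is.null(p$grid_dim)) NULL else unlist(p$grid_dim),
           voxel_index = unlist(p$mask_index),
           covariate_schema = p$covariate_schema, covariates = cov,
           train_Y = as.matrix(p$train_Y), evidence_map = evidence_map,
           noise_map = noise_map, lambda_map = lambda_map,
           failed = vapply(models, is.null, TRUE),
           config = NULL, seed = p$seed),
      class = "voxel_model_set"
    )
  } else {
    models <- lapply(p$models, function(r) deserialize_gp(r, cov))
    names(models) <- names(p$models)
    structure(list(models = models, covariate_schema = p$covariate_schema,
                   covariates = cov, config = NULL, seed = p$seed),
              class = "global_model_set")
  }
}
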