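#' Construct a covariate matrix with training standardization
#'
#' Wraps an n x m numeric matrix of subject covariates (rows = subjects,
#' columns = covariates such as age, sex, global volumes, field strength)
#' together with per-column standardization constants. Columns are
#' z-standardized (shift by the column mean, divide by the column standard
#' deviation); binary columns coded 0/1 are standardized like any other so
#' that ARD length scales are comparable across covariates. Constant columns
#' get unit scale to avoid division by zero.
#'
#' Test-set covariates must be standardized with the \emph{training}
#' constants; use [standardize_covariates()] with the training object.
#'
#' @param values numeric matrix or data frame, one row per subject, no
#'   missing entries.
#' @param column_names optional character vector of column labels; defaults
#'   to the matrix column names.
#' @param center,scale optional externally supplied standardization
#'   constants (length m); when omitted they are computed from `values`.
#' @return an object of class `gp_covariates` holding the standardized
#'   matrix (`$std`), the raw values (`$values`), `$center`, `$scale` and
#'   `$column_names`.
#' @export
covariate_matrix <- function(values, column_names = NULL,
                             center = NULL, scale = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("covariate matrix contains missing or non-finite entries")
  if (is.null(column_names))
    column_names <- colnames(values)
  if (is.null(column_names))
    column_names <- paste0("x", seq_len(ncol(values)))
  if (length(column_names) != ncol(values))
    stop("column_names length does not match covariate count")
  if (is.null(center)) center <- colMeans(values)
  if (is.null(scale)) {
    scale <- apply(values, 2, stats::sd)
    scale[!is.finite(scale) | scale <= 0] <- 1
  }
  std <- sweep(sweep(values, 2, center, "-"), 2, scale, "/")
  structure(
    list(values = values, std = std, center = center, scale = scale,
         column_names = column_names),
    class = "gp_covariates"
  )
}

#' Standardize new covariates with training constants
#'
#' @param values numeric matrix of test covariates, columns in the same
#'   order as the training matrix.
#' @param train a `gp_covariates` object fitted on the training sample.
#' @return a `gp_covariates` object standardized with the training shift
#'   and scale.
#' @export
standardize_covariates <- function(values, train) {
  stopifnot(inherits(train, "gp_covariates"))
  values <- as.matrix(values)
  if (ncol(values) != length(train$center))
    stop(sprintf("covariate dimension mismatch: got %d columns, expected %d",
                 ncol(values), length(train$center)))
  covariate_matrix(values, column_names = train$column_names,
                   center = train$center, scale = train$scale)
}

#' @export
print.gp_covariates <- function(x, ...) {
  cat(sprintf("<gp_covariates> %d subjects x %d covariates: %s\n",
              nrow(x$values), ncol(x$values),
              paste(x$column_names, collapse = ", ")))
  invisible(x)
}
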