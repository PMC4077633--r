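#' GLM training-sample fit and test-sample prediction
#'
#' Ordinary least squares with an intercept: B = (X'X)^-1 X'Y estimated
#' in the training sample, predictions Xtest B in the test sample. The
#' reference prediction method the GP model is compared against.
#'
#' @param Xtrain,Xtest numeric covariate matrices (no intercept column;
#'   one is added internally).
#' @param Ytrain numeric vector or matrix of training targets.
#' @return predicted values for the test rows (vector when `Ytrain` is a
#'   vector).
#' @export
glm_fit_predict <- function(Xtrain, Ytrain, Xtest) {
  Xtrain <- cbind(1, as.matrix(Xtrain))
  Xtest <- cbind(1, as.matrix(Xtest))
  yv <- is.null(dim(Ytrain))
  Ytrain <- as.matrix(Ytrain)
  XtX <- crossprod(Xtrain)
  B <- tryCatch(solve(XtX, crossprod(Xtrain, Ytrain)),
                error = function(e) NULL)
  if (is.null(B)) {
    warning("rank-deficient design; using pseudoinverse")
    s <- svd(Xtrain)
    pos <- s$d > max(dim(Xtrain)) * .Machine$double.eps * s$d[1]
    B <- s$v[, pos, drop = FALSE] %*%
      ((t(s$u[, pos, drop = FALSE]) %*% Ytrain) / s$d[pos])
  }
  pred <- Xtest %*% B
  if (yv) drop(pred) else pred
}

#' Single-case t statistic against a control sample
#'
#' t = (mean(controls) - patient) / (sd(controls) * sqrt(1/n + 1)),
#' the two-sample t with group sizes (n, 1). Positive t means the patient
#' lies below the control mean (atrophy under the volume convention).
#'
#' @param controls numeric vector of control values (n >= 2).
#' @param patient scalar patient value.
#' @param method_tag label recorded in the result.
#' @return a list of class `single_case_result` with `statistic`,
#'   `method_tag`, `n_controls`.
#' @export
single_case_t <- function(controls, patient, method_tag = "t_raw") {
  controls <- as.numeric(controls)
  patient <- as.numeric(patient)[1]
  n <- length(controls)
  if (n < 2) stop("need at least 2 controls")
  s <- stats::sd(controls)
  stat <- if (s == 0) {
    warning("zero control variance; t undefined")
    NaN
  } else (mean(controls) - patient) / (s * sqrt(1 / n + 1))
  structure(list(statistic = stat, method_tag = method_tag, n_controls = n),
            class = "single_case_result")
}

#' Covariate-corrected single-case t statistic
#'
#' Residualizes the control values and the patient value against selected
#' covariate columns using coefficients estimated in the controls only,
#' then applies the single-case t to the residuals. With `columns`
#' restricted to age this is the age-corrected variant; with all columns
#' it corrects for every covariate effect.
#'
#' @param controls_y numeric control values.
#' @param controls_X control covariate matrix.
#' @param patient_y scalar patient value.
#' @param patient_x patient covariate row.
#' @param columns indices or names of the covariate columns to correct
#'   for (default: all).
#' @return a `single_case_result`.
#' @export
corrected_single_case_t <- function(controls_y, controls_X, patient_y,
                                    patient_x, columns = NULL) {
  controls_X <- as.matrix(controls_X)
  patient_x <- matrix(as.numeric(patient_x), nrow = 1)
  if (!is.null(columns)) {
    controls_X <- controls_X[, columns, drop = FALSE]
    patient_x <- patient_x[, columns, drop = FALSE]
  }
  Xc <- cbind(1, controls_X)
  beta <- tryCatch(solve(crossprod(Xc), crossprod(Xc, controls_y)),
                   error = function(e) {
                     warning("rank-deficient correction design; using pseudoinverse")
                     MASS_ginv(crossprod(Xc)) %*% crossprod(Xc, controls_y)
                   })
  res_c <- controls_y - drop(Xc %*% beta)
  res_p <- patient_y - drop(cbind(1, patient_x) %*% beta)
  out <- single_case_t(res_c, res_p, method_tag = "t_corrected")
  out
}

# Minimal Moore-Penrose inverse (avoids a hard MASS dependency for the
# rank-deficient fallback path only).
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' ROC curve and AUC from scores and labels
#'
#' AUC computed via the rank (Mann-Whitney) statistic with midranks for
#' ties; orientation fixed so that a larger score indicates disease.
#' Signed statistics where more-negative means more diseased (GP delta)
#' or more-positive means more diseased already (single-case t of
#' volumes) must be oriented by the caller; see `flip`.
#'
#' @param scores numeric vector.
#' @param labels logical or 0/1 vector, TRUE/1 = diseased.
#' @param flip if TRUE, scores are negated first (use for statistics
#'   where more negative = more diseased, e.g. delta).
#' @return a list of class `roc_result` with `thresholds`, `tpr`, `fpr`
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels, flip = FALSE) {
  scores <- as.numeric(scores)
  if (flip) scores <- -scores
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both diseased and healthy labels")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  thresholds <- c(Inf, scores[ord])
  tp <- c(0, cumsum(labels[ord]))
  fp <- c(0, cumsum(!labels[ord]))
  structure(list(thresholds = thresholds, tpr = tp / n1, fpr = fp / n0,
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Mean detection statistic profiled by years since disease onset
#'
#' Bins each subject's statistic by years relative to the individual
#' onset age and averages within bins, one profile per method. Used to
#' compare how steeply different single-case statistics decline after
#' onset.
#'
#' @param years_since_onset numeric vector, one entry per subject.
#' @param statistics data frame or named list of per-subject statistics
#'   (one column per method).
#' @param breaks bin boundaries in years relative to onset (default
#'   2-year bins over [-20, 20]).
#' @return a data frame with `bin_mid`, `n` and one mean-statistic column
#'   per method.
#' @export
onset_profile <- function(years_since_onset, statistics,
                          breaks = seq(-20, 20, by = 2)) {
  statistics <- as.data.frame(statistics)
  bin <- cut(years_since_onset, breaks = breaks, include.lowest = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- data.frame(bin_mid = mids,
                    n = as.integer(table(bin)))
  for (nm in names(statistics))
    out[[nm]] <- as.numeric(tapply(statistics[[nm]], bin, mean))
  out
}
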