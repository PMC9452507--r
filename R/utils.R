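#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residualize the columns of a matrix on a covariate matrix
#'
#' Projects each column of `m` onto the orthogonal complement of the column
#' space of `cbind(1, covariates)`. Used by the association scans, which work
#' on covariate-residualized expression and dosage.
#'
#' @param m numeric matrix (rows = samples).
#' @param covariates numeric matrix of covariates (rows = samples) or NULL
#'   for intercept-only adjustment.
#' @return matrix of residuals, same dimensions as `m`.
#' @keywords internal
residualize <- function(m, covariates = NULL) {
  m <- as.matrix(m)
  x <- cbind(rep(1, nrow(m)), covariates)
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("covariate matrix is rank-deficient (collinear columns)")
  qr.resid(qx, m)
}

# number of model covariates (excluding intercept); 0 for NULL
n_covariates <- function(covariates) if (is.null(covariates)) 0L else ncol(as.matrix(covariates))

# column-standardize, dropping zero-variance columns
standardize_cols <- function(m, drop_constant = TRUE) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  keep <- if (drop_constant) sdv > 0 else rep(TRUE, ncol(m))
  if (!any(keep)) stop("all columns are constant")
  sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
}

# p-value floor: never emit exactly 0 (underflow marker handled by callers)
p_floor <- function(p) pmax(p, 5e-324)

# deterministic sub-seed derivation; keeps results < 2^31
sub_seed <- function(seed, offset) {
  s <- (as.numeric(seed) * 97L + offset) %% 2147483647
  as.integer(s)
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0,1]", name))
}
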