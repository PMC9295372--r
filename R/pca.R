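# Correlation-matrix PCA with contribution-rate component selection.

#' Standardize a table column-wise
#'
#' z-scores each column (mean 0, SD 1) and keeps the constants so new data
#' can be projected later. Errors on constant columns, naming them.
#'
#' @param x numeric matrix or data.frame.
#' @return list with `z` (matrix), `center`, `scale`.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ctr <- colMeans(x)
  list(z = scale(x, center = ctr, scale = sds), center = ctr, scale = sds)
}

#' Contribution rates from eigenvalues
#'
#' rate_i = 100 lambda_i / sum(lambda); accumulated_i is the running sum.
#'
#' @param eigenvalues non-negative eigenvalues in descending order.
#' @return list with `rate` and `accumulated` (both percent).
#' @examples
#' contribution_rates(omeprazole_reference()$eigenvalues)
#' @export
contribution_rates <- function(eigenvalues) {
  if (any(eigenvalues < 0)) stop("eigenvalues must be >= 0", call. = FALSE)
  if (is.unsorted(rev(eigenvalues))) {
    stop("eigenvalues must be in descending order", call. = FALSE)
  }
  total <- sum(eigenvalues)
  if (total == 0) stop("all eigenvalues are zero", call. = FALSE)
  rate <- 100 * eigenvalues / total
  list(rate = rate, accumulated = cumsum(rate))
}

#' Smallest component count reaching an accumulated contribution threshold
#'
#' @param accumulated accumulated contribution (percent, non-decreasing).
#' @param threshold percent in (0, 100]; default 90.
#' @return integer k.
#' @export
select_components <- function(accumulated, threshold = 90) {
  if (threshold <= 0 || threshold > 100) {
    stop("`threshold` must lie in (0, 100]", call. = FALSE)
  }
  which(accumulated >= threshold - 1e-8)[1L]
}

#' Fit a correlation-matrix PCA transform
#'
#' Standardizes the input, eigendecomposes the sample correlation matrix,
#' fixes eigenvector signs (the largest-magnitude element of each loading is
#' made positive, for reproducibility), computes contribution rates and
#' selects the smallest k whose accumulated contribution reaches the
#' threshold.
#'
#' @param x numeric matrix or data.frame (rows = observations).
#' @param threshold accumulated-contribution threshold in percent.
#' @return object of class `pca_transform`: `center`, `scale`,
#'   `eigenvalues`, `loadings`, `rate`, `accumulated`, `k`, `variables`.
#' @export
pca_fit <- function(x, threshold = 90) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (nrow(x) < p + 1) {
    warning("fewer than p + 1 rows: correlation matrix is rank deficient")
  }
  std <- standardize(x)
  e <- eigen(cor(x), symmetric = TRUE)
  vals <- pmax(e$values, 0) # clip numerically tiny negatives
  vecs <- e$vectors
  for (j in seq_len(p)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  cr <- contribution_rates(vals)
  structure(list(center = std$center, scale = std$scale,
                 eigenvalues = vals, loadings = vecs,
                 rate = cr$rate, accumulated = cr$accumulated,
                 k = select_components(cr$accumulated, threshold),
                 threshold = threshold,
                 variables = colnames(x)),
            class = "pca_transform")
}

#' Project data onto the leading principal components
#'
#' z-scores `newdata` with the stored constants and multiplies by the first
#' `k` loading vectors.
#'
#' @param object a fitted `pca_transform`.
#' @param newdata matrix or data.frame with the training schema.
#' @param k number of components (defaults to the selected count).
#' @param ... unused.
#' @return score matrix (n x k).
#' @export
predict.pca_transform <- function(object, newdata, k = object$k, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$variables)) {
    if (!is.null(colnames(newdata))) {
      if (!all(object$variables %in% colnames(newdata))) {
        stop("newdata is missing variable(s): ",
             paste(setdiff(object$variables, colnames(newdata)), collapse = ", "),
             call. = FALSE)
      }
      newdata <- newdata[, object$variables, drop = FALSE]
    } else if (ncol(newdata) != length(object$variables)) {
      stop("newdata has ", ncol(newdata), " columns; expected ",
           length(object$variables), call. = FALSE)
    }
  }
  z <- scale(newdata, center = object$center, scale = object$scale)
  unname(z %*% object$loadings[, seq_len(k), drop = FALSE])
}

#' Eigenvalue / contribution-rate table of a fitted PCA
#'
#' @param object a `pca_transform`.
#' @return data.frame: `component`, `eigenvalue`, `contribution_pct`,
#'   `accumulated_pct`.
#' @export
pca_table <- function(object) {
  data.frame(component = seq_along(object$eigenvalues),
             eigenvalue = object$eigenvalues,
             contribution_pct = object$rate,
             accumulated_pct = object$accumulated)
}
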