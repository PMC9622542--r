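# Principal-component prioritization: eigendecomposition of the covariance
# matrix of standardized criteria (i.e. the correlation matrix) and
# first-component Z1 scores used to select nutrient-favorable alternatives.

#' First principal component of the standardized criteria
#'
#' Standardizes each criterion column (mean 0, sample sd 1; a constant
#' criterion raises an error and must be dropped by the caller), forms the
#' covariance matrix of the standardized data, and eigendecomposes it. The
#' Z1 score of alternative `i` is the projection of its standardized row on
#' the eigenvector of the dominant eigenvalue. The eigenvector sign is
#' oriented so its loading on `sign_criterion` (default TN) is negative,
#' making low Z1 correspond to nutrient-favorable alternatives; the applied
#' sign is recorded.
#'
#' @param table Alternatives data.frame.
#' @param criteria Criterion names to include (default all seven).
#' @param sign_criterion Criterion whose first-component loading is forced
#'   negative (ignored with a note if absent from `criteria`).
#' @return An object of class `pca_result`: `cov` (matrix A), `values`
#'   (eigenvalues, descending), `vectors` (unit-length columns), `z1`
#'   (named scores), `var_frac` (lambda1 / sum lambda), `sign` (+1/-1
#'   applied to the first eigenvector), `criteria`.
#' @export
pca_first_component <- function(table, criteria = names(criterion_columns()),
                                sign_criterion = "TN") {
  if (nrow(table) < 2L) stop("PCA needs at least two alternatives")
  measures <- criteria_matrix(table, criteria)
  x <- apply(measures, 2, standardize)
  a <- stats::cov(x)
  eig <- eigen(a, symmetric = TRUE)
  sgn <- 1
  if (sign_criterion %in% criteria &&
      eig$vectors[match(sign_criterion, criteria), 1] > 0)
    sgn <- -1
  eig$vectors[, 1] <- sgn * eig$vectors[, 1]
  z1 <- drop(x %*% eig$vectors[, 1])
  names(z1) <- as.character(table$id)
  rownames(eig$vectors) <- criteria
  structure(list(cov = a, values = eig$values, vectors = eig$vectors,
                 z1 = z1, var_frac = eig$values[1] / sum(eig$values),
                 sign = sgn, criteria = criteria),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA over %d criteria: lambda1 = %.4f (%.1f%% of variance)\n",
              length(x$criteria), x$values[1], 100 * x$var_frac))
  cat("first-component loadings:\n")
  print(round(x$vectors[, 1], 4))
  invisible(x)
}

#' Alternatives with the lowest Z1 scores
#'
#' @param result A `pca_result`.
#' @param k Set size (default 100); ties at the boundary break by ascending
#'   id, and all ids are returned when fewer than `k` exist.
#' @return Character vector of ids.
#' @export
lowest_k_z1 <- function(result, k = 100) {
  stopifnot(inherits(result, "pca_result"))
  if (k < 1) stop("k must be >= 1")
  ids <- names(result$z1)
  num <- suppressWarnings(as.numeric(ids))
  tie_key <- if (anyNA(num)) rank(ids) else num
  ord <- order(result$z1, tie_key)
  ids[utils::head(ord, min(k, length(ids)))]
}
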