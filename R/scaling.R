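# Strength-of-preference scaling of raw criteria measures: linear value and
# distance transforms anchored at the per-criterion worst/best, a
# risk-averse empirical-CDF transform for the heavy-tailed criteria, binary
# presence scaling, and z-standardization for the PCA route.

#' Criterion specifications
#'
#' The seven criteria, their preferred direction, objective grouping and
#' default scaling mode. TN, TP and CF use the empirical-CDF (risk-averse)
#' scale because their measures are heavy-tailed; AG, EHA and WS are linear;
#' FP is a binary presence flag. TN, TP, AG, EHA and FP serve the water
#' quality objective; WS and CF serve climate resilience.
#'
#' @return A data.frame with columns `name`, `direction`, `group`,
#'   `scaling`.
#' @export
default_criterion_specs <- function() {
  data.frame(
    name = c("TN", "TP", "AG", "EHA", "FP", "WS", "CF"),
    direction = c(rep("increase", 4), "binary-yes", "increase", "increase"),
    group = c(rep("water_quality", 5), rep("climate_resilience", 2)),
    scaling = c("ecdf", "ecdf", "linear", "linear", "binary", "linear",
                "ecdf"),
    stringsAsFactors = FALSE)
}

#' Linear value and distance scaling
#'
#' `scale_linear_value` maps a criterion's measures onto `[0, 1]` with the
#' worst value at 0 and the best at 1: `x = (z - z*) / (z** - z*)`.
#' `scale_linear_distance` is its complement `x = (z** - z) / (z** - z*)`,
#' the distance from the ideal, so the two sum to 1 elementwise. A constant
#' criterion carries no preference information: every alternative receives
#' 0.5 and a warning is issued.
#'
#' @param z Numeric vector of measures for one criterion.
#' @return Numeric vector in `[0, 1]`.
#' @export
scale_linear_value <- function(z) {
  if (!length(z) || all(is.na(z))) stop("no finite measures to scale")
  lo <- min(z, na.rm = TRUE); hi <- max(z, na.rm = TRUE)
  if (hi == lo) {
    warning("constant criterion: all alternatives scaled to 0.5")
    return(rep(0.5, length(z)))
  }
  (z - lo) / (hi - lo)
}

#' @rdname scale_linear_value
#' @export
scale_linear_distance <- function(z) {
  if (!length(z) || all(is.na(z))) stop("no finite measures to scale")
  lo <- min(z, na.rm = TRUE); hi <- max(z, na.rm = TRUE)
  if (hi == lo) {
    warning("constant criterion: all alternatives scaled to 0.5")
    return(rep(0.5, length(z)))
  }
  (hi - z) / (hi - lo)
}

#' Empirical-CDF (risk-averse) scaling
#'
#' Scales each measure to the probability that an observed value is less
#' than or equal to it: `x_i = #\{k : z_k <= z_i\} / n`. For heavy-tailed
#' criteria this curve is largely concave, encoding marginally decreasing
#' preference for the rare very large measures. Ties share the
#' less-than-or-equal count. Under distance orientation the complement
#' `1 - ECDF` is returned so the best measure is nearest the ideal.
#'
#' @param z Numeric vector of measures.
#' @param orientation `"value"` (higher better) or `"distance"` (lower
#'   better).
#' @return Numeric vector in `[0, 1]`.
#' @export
scale_ecdf <- function(z, orientation = c("value", "distance")) {
  orientation <- match.arg(orientation)
  if (!length(z) || all(is.na(z))) stop("no finite measures to scale")
  n <- sum(!is.na(z))
  x <- vapply(z, function(v) sum(z <= v, na.rm = TRUE) / n, numeric(1))
  if (orientation == "distance") 1 - x else x
}

#' Binary presence scaling
#'
#' @param flags 0/1 (or logical) vector.
#' @param orientation `"value"` (presence scores 1) or `"distance"`
#'   (presence scores 0).
#' @return Numeric 0/1 vector.
#' @export
scale_binary <- function(flags, orientation = c("value", "distance")) {
  orientation <- match.arg(orientation)
  f <- as.numeric(flags)
  if (!all(f %in% c(0, 1), na.rm = TRUE))
    stop("binary criterion contains non-binary values")
  if (orientation == "distance") 1 - f else f
}

#' Z-standardization
#'
#' Centers and scales a criterion to mean 0, sample standard deviation 1
#' (n - 1 denominator). A constant criterion cannot be standardized and
#' must be dropped before PCA.
#'
#' @param z Numeric vector, length >= 2, non-constant.
#' @return Numeric vector of z-scores.
#' @export
standardize <- function(z) {
  if (length(z) < 2L) stop("standardization needs at least two measures")
  s <- stats::sd(z)
  if (is.na(s) || s == 0) stop("degenerate (constant) criterion")
  (z - mean(z)) / s
}

#' Scale a full criteria matrix
#'
#' Applies each criterion's configured scaler (linear, ecdf or binary) in
#' the requested orientation, recording the per-criterion worst and best
#' raw measures.
#'
#' @param measures Numeric matrix from [criteria_matrix()] (columns named
#'   by criterion).
#' @param specs Criterion specification data.frame
#'   (default [default_criterion_specs()]).
#' @param orientation `"value"` or `"distance"`.
#' @return An object of class `scaled_matrix`: list with `values` (matrix in
#'   `[0, 1]`), `orientation`, `worst`, `best`.
#' @export
scale_matrix <- function(measures, specs = default_criterion_specs(),
                         orientation = c("value", "distance")) {
  orientation <- match.arg(orientation)
  crits <- colnames(measures)
  missing <- setdiff(crits, specs$name)
  if (length(missing))
    stop("no specification for criteria: ", paste(missing, collapse = ", "))
  vals <- measures
  for (j in crits) {
    mode <- specs$scaling[specs$name == j]
    z <- measures[, j]
    vals[, j] <- switch(mode,
      linear = if (orientation == "value") scale_linear_value(z)
               else scale_linear_distance(z),
      ecdf = scale_ecdf(z, orientation),
      binary = scale_binary(z, orientation),
      stop("unknown scaling mode: ", mode))
  }
  structure(list(values = vals, orientation = orientation,
                 worst = apply(measures, 2, min),
                 best = apply(measures, 2, max)),
            class = "scaled_matrix")
}

#' ECDF concavity index
#'
#' Fraction of non-positive second differences of the interpolated
#' empirical CDF, evaluated on an even probability grid (equivalently, the
#' fraction of non-negative second differences of the empirical quantile
#' function). Values near 1 indicate a largely concave CDF, the shape that
#' justifies the risk-averse ECDF scale for heavy-tailed criteria.
#'
#' @param z Numeric sample.
#' @param probs Probability grid (default deciles 0.1 to 0.9; a coarse grid
#'   averages sampling noise in the quantile spacings).
#' @return Fraction in `[0, 1]`.
#' @export
ecdf_concavity <- function(z, probs = seq(0.1, 0.9, by = 0.1)) {
  q <- stats::quantile(z, probs, names = FALSE, type = 7)
  d2 <- diff(q, differences = 2)
  mean(d2 >= 0)
}
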