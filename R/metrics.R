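#' @include AllClasses.R
NULL

#' Pearson correlation between predictions and observations
#'
#' Standard product-moment coefficient. A constant input vector makes the
#' correlation undefined and raises an error rather than silently returning
#' 0 or NA.
#'
#' @param pred,obs equal-length numeric vectors (length >= 2).
#' @return scalar in [-1, 1].
#' @export
pearsonR <- function(pred, obs) {
    if (length(pred) != length(obs)) stop("pred and obs must have equal length")
    if (length(pred) < 2L) stop("need at least two observations")
    if (anyNA(pred) || anyNA(obs)) stop("NA values in pred or obs")
    if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
        stop("undefined correlation: constant input vector")
    stats::cor(pred, obs)
}

#' Mean squared error on the original affinity scale
#'
#' @param pred,obs equal-length numeric vectors, un-standardized.
#' @return mean of squared differences.
#' @export
mseValues <- function(pred, obs) {
    if (length(pred) != length(obs)) stop("pred and obs must have equal length")
    if (length(pred) < 1L) stop("need at least one observation")
    mean((pred - obs)^2)
}
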