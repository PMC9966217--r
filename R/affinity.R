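#' @include AllClasses.R
NULL

#' pKd from a dissociation constant
#'
#' \code{pKd = -log10(Kd)}, with \code{Kd = [P][L]/[C]} in molar units.
#' @param kd dissociation constant(s), molar, > 0.
#' @return numeric pKd value(s).
#' @export
pKdFromKd <- function(kd) {
    if (any(!is.finite(kd)) || any(kd <= 0))
        stop("Kd must be finite and positive")
    -log10(kd)
}

#' Negate a docking score
#'
#' Docking engines emit scores where lower is better; the regression target
#' is the negated score so that higher values mean putatively higher
#' affinity.
#' @param score docking score(s), finite.
#' @return \code{-score}.
#' @export
negateDockingScore <- function(score) {
    if (any(!is.finite(score))) stop("docking score must be finite")
    -score
}

#' Fit affinity standardization parameters
#'
#' mu is the arithmetic mean and sigma the population standard deviation
#' (divisor n) of the supplied affinity labels. The n vs n-1 choice is
#' immaterial at database scale but fixed here for reproducibility.
#'
#' @param values numeric affinities, length >= 2, non-constant.
#' @return \linkS4class{StandardizationParams}.
#' @export
fitStandardizer <- function(values) {
    values <- as.numeric(values)
    if (length(values) < 2L || anyNA(values))
        stop("need at least two finite affinity values")
    mu <- mean(values)
    sigma <- sqrt(mean((values - mu)^2))
    if (sigma == 0)
        stop("zero-variance affinities: standardization undefined for constant targets")
    StandardizationParams(mu = mu, sigma = sigma)
}

#' Standardize / de-standardize affinity values
#'
#' The standardization map (d - mu)/sigma and its inverse. Being a positive affine
#' map, standardization leaves the Pearson correlation of predictions with
#' targets unchanged; reported MSE is always computed on de-standardized
#' values.
#'
#' @param d,dPrime numeric values on the original / standardized scale.
#' @param params a \linkS4class{StandardizationParams}.
#' @return numeric vector.
#' @export
standardizeValues <- function(d, params) {
    stopifnot(is(params, "StandardizationParams"))
    (d - params@mu) / params@sigma
}

#' @rdname standardizeValues
#' @export
destandardizeValues <- function(dPrime, params) {
    stopifnot(is(params, "StandardizationParams"))
    dPrime * params@sigma + params@mu
}
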