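#' @include AllClasses.R AllGenerics.R metrics.R
NULL

#' Standard atomic masses (g/mol) for the supported species
#' @export
ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06, F = 18.998, CL = 35.45,
                   BR = 79.904, I = 126.904)

#' @describeIn ComplexStructure-class ligand molecular weight: the sum of
#'   standard atomic masses over ligand-role atoms (g/mol). Errors if a
#'   ligand element has no tabulated mass.
#' @export
setMethod("molecularWeight", "ComplexStructure", function(x) {
    lig <- x@atoms$element[x@atoms$role == "ligand"]
    if (!length(lig)) stop("complex has no ligand atoms")
    unknown <- setdiff(lig, names(ATOMIC_MASSES))
    if (length(unknown))
        stop("no tabulated atomic mass for element(s): ",
             paste(unknown, collapse = ", "))
    sum(ATOMIC_MASSES[lig])
})

#' Fit the molecular-weight linear baseline
#'
#' The null model for per-target scoring: affinity = A + B * MW, with A and
#' B fitted by ordinary least squares on the whole supplied database (no
#' held-out set, so its Rp is in-sample by construction).
#'
#' @param complexes list of \linkS4class{ComplexStructure}.
#' @param affinities numeric affinities in the same order, or an affinity
#'   data.frame as in [featurizeDatabase()].
#' @return A \linkS4class{LinearMWModel}.
#' @export
fitMwBaseline <- function(complexes, affinities) {
    mw <- vapply(complexes, molecularWeight, 0)
    if (is.data.frame(affinities)) {
        idx <- match(vapply(complexes, complexId, ""), affinities$complexId)
        if (anyNA(idx)) stop("missing affinity for some complexes")
        affinities <- affinities$value[idx]
    }
    stopifnot(length(affinities) == length(complexes))
    if (length(unique(mw)) < 2L)
        stop("rank-deficient fit: all ligands have the same molecular weight")
    fit <- stats::lm(affinities ~ mw)
    co <- stats::coef(fit)
    rp <- if (stats::sd(stats::fitted(fit)) > 0)
        stats::cor(stats::fitted(fit), affinities) else NA_real_
    m <- new("LinearMWModel", intercept = unname(co[1]), slope = unname(co[2]),
             inSampleRp = rp)
    attr(m, "fit") <- fit
    m
}

#' Predict affinities from the molecular-weight baseline
#'
#' @param model a \linkS4class{LinearMWModel}.
#' @param complexes list of \linkS4class{ComplexStructure} (or a numeric
#'   vector of molecular weights).
#' @return numeric predictions A + B * MW.
#' @export
predictMwBaseline <- function(model, complexes) {
    stopifnot(is(model, "LinearMWModel"))
    mw <- if (is.numeric(complexes)) complexes
          else vapply(complexes, molecularWeight, 0)
    model@intercept + model@slope * mw
}

setMethod("show", "LinearMWModel", function(object) {
    cat(sprintf("LinearMWModel: affinity = %.4g + %.4g * MW (in-sample Rp %.3f)\n",
                object@intercept, object@slope, object@inSampleRp))
})
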