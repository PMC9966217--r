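#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn FeaturizationScheme-class total number of descriptor channels.
#' @param x a \code{FeaturizationScheme}.
#' @export
setMethod("descriptorDim", "FeaturizationScheme", function(x) {
    length(x@targetSpecies) * length(x@ligandSpecies) * as.integer(x@nIntervals)
})

#' @describeIn DescriptorSet-class descriptor dimension (number of rows).
#' @param x a \code{DescriptorSet}.
#' @export
setMethod("descriptorDim", "DescriptorSet", function(x) nrow(x))

#' @describeIn FeaturizationScheme-class channel labels
#'   "A-A'-k", in storage order: interval-major, then target species,
#'   then ligand species, each in its listed order.
#' @export
setMethod("channelNames", "FeaturizationScheme", function(x) {
    grid <- expand.grid(lig = x@ligandSpecies, tgt = x@targetSpecies,
                        k = seq_len(x@nIntervals), stringsAsFactors = FALSE)
    paste(grid$tgt, grid$lig, grid$k, sep = "-")
})

#' @describeIn DescriptorSet-class channel labels (row names).
#' @export
setMethod("channelNames", "DescriptorSet", function(x) rownames(x))

#' @describeIn DescriptorSet-class the generating featurization scheme.
#' @export
setMethod("scheme", "DescriptorSet", function(x) x@scheme)

#' @describeIn DescriptorSet-class whether counts were normalized.
#' @export
setMethod("isNormalized", "DescriptorSet", function(x) x@normalized)

setMethod("show", "FeaturizationScheme", function(object) {
    cat("FeaturizationScheme:",
        length(object@targetSpecies), "target x",
        length(object@ligandSpecies), "ligand species,",
        object@nIntervals, "interval(s) of width", object@intervalWidth, "A\n")
    cat("  descriptor dimension:", descriptorDim(object),
        " (pair cutoff", object@nIntervals * object@intervalWidth, "A)\n")
})

#' Fingerprint of a featurization scheme
#'
#' Canonical string identifying a scheme; used to refuse mixing descriptors,
#' normalizers and models built under different schemes.
#' @param scheme a \linkS4class{FeaturizationScheme}.
#' @return single string.
#' @export
schemeFingerprint <- function(scheme) {
    paste0("t:", paste(scheme@targetSpecies, collapse = ","),
           "|l:", paste(scheme@ligandSpecies, collapse = ","),
           "|w:", format(scheme@intervalWidth, digits = 15),
           "|k:", scheme@nIntervals)
}

#' Distance-interval bounds
#'
#' The k-th interval of width \code{width} spans \code{[(k-1)*width,
#' k*width)}; membership is half-open so every pair distance falls in
#' exactly one interval and a coincident pair (d = 0) belongs to k = 1.
#'
#' @param k interval index, 1-based.
#' @param width interval width in Angstrom (> 0).
#' @param nIntervals optional upper bound on \code{k} for range checking.
#' @return numeric c(rmin, rmax) in Angstrom.
#' @examples
#' intervalBounds(1, 2)  # 0 2
#' intervalBounds(4, 2)  # 6 8
#' @export
intervalBounds <- function(k, width, nIntervals = NULL) {
    if (length(k) != 1L || is.na(k) || k < 1L || k != floor(k))
        stop("interval index k must be a positive integer")
    if (!is.null(nIntervals) && k > nIntervals)
        stop(sprintf("interval index %d out of range (nIntervals = %d)", k, nIntervals))
    if (width <= 0) stop("interval width must be positive")
    c(rmin = (k - 1) * width, rmax = k * width)
}

# channel index for (target-species index ti, ligand-species index li, interval k):
# interval-major, then target, then ligand — matches channelNames().
.channelIndex <- function(ti, li, k, nTarget, nLigand) {
    (k - 1L) * nTarget * nLigand + (ti - 1L) * nLigand + li
}

#' @describeIn ComplexStructure-class count target-ligand atom pairs per
#'   (species pair, distance interval) channel. Atoms whose element is not
#'   in the respective species list are ignored, as are pairs at or beyond
#'   the scheme's distance cutoff. Returns a named non-negative integer
#'   vector of length \code{descriptorDim(scheme)}.
#' @param scheme a \linkS4class{FeaturizationScheme}.
#' @export
setMethod("countPairs", signature(x = "ComplexStructure", scheme = "FeaturizationScheme"),
    function(x, scheme) {
        a <- x@atoms
        nT <- length(scheme@targetSpecies)
        nL <- length(scheme@ligandSpecies)
        kmax <- scheme@nIntervals
        ell <- scheme@intervalWidth
        counts <- integer(descriptorDim(scheme))

        tgt <- a[a$role == "target" & a$element %in% scheme@targetSpecies, ]
        lig <- a[a$role == "ligand" & a$element %in% scheme@ligandSpecies, ]
        if (nrow(tgt) && nrow(lig)) {
            ti <- match(tgt$element, scheme@targetSpecies)
            li <- match(lig$element, scheme@ligandSpecies)
            # all pairwise distances, targets x ligands
            d2 <- outer(tgt$x, lig$x, "-")^2 +
                  outer(tgt$y, lig$y, "-")^2 +
                  outer(tgt$z, lig$z, "-")^2
            k <- floor(sqrt(d2) / ell) + 1  # half-open bins
            keep <- k <= kmax
            if (any(keep)) {
                ch <- .channelIndex(ti[row(k)[keep]], li[col(k)[keep]],
                                    as.integer(k[keep]), nT, nL)
                tab <- tabulate(ch, nbins = length(counts))
                counts <- counts + tab
            }
        }
        names(counts) <- channelNames(scheme)
        counts
    })

#' Featurize a database of complexes
#'
#' Computes the pair-count descriptor vector of every complex and assembles
#' them into a \linkS4class{DescriptorSet} (rows = channels, columns =
#' complexes, in input order).
#'
#' @param complexes list of \linkS4class{ComplexStructure}.
#' @param scheme a \linkS4class{FeaturizationScheme}.
#' @param affinities optional affinity table: data.frame with columns
#'   \code{complexId}, \code{value}, \code{kind} (one kind per database), or
#'   a numeric vector named by complex id.
#' @return A \linkS4class{DescriptorSet} with raw (unnormalized) counts.
#' @export
featurizeDatabase <- function(complexes, scheme = FeaturizationScheme(),
                              affinities = NULL) {
    ids <- vapply(complexes, complexId, character(1))
    if (anyDuplicated(ids))
        stop("duplicate complexId in database: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    mat <- matrix(0, nrow = descriptorDim(scheme), ncol = length(complexes),
                  dimnames = list(channelNames(scheme), ids))
    for (i in seq_along(complexes)) {
        v <- tryCatch(countPairs(complexes[[i]], scheme), error = function(e)
            stop(sprintf("featurization failed for complex '%s': %s",
                         ids[i], conditionMessage(e)), call. = FALSE))
        mat[, i] <- v
    }
    cd <- S4Vectors::DataFrame(
        proteinId = vapply(complexes, proteinId, character(1)),
        row.names = ids)
    if (!is.null(affinities)) {
        if (is.numeric(affinities)) {
            affinities <- data.frame(complexId = names(affinities),
                                     value = unname(affinities),
                                     kind = NA_character_)
        }
        idx <- match(ids, affinities$complexId)
        if (anyNA(idx) && length(complexes))
            stop("missing affinity for complex(es): ",
                 paste(ids[is.na(idx)], collapse = ", "))
        cd$affinity <- affinities$value[idx]
        cd$affinityKind <- as.character(affinities$kind[idx])
    }
    grid <- expand.grid(lig = scheme@ligandSpecies, tgt = scheme@targetSpecies,
                        k = seq_len(scheme@nIntervals), stringsAsFactors = FALSE)
    rd <- S4Vectors::DataFrame(targetSpecies = grid$tgt, ligandSpecies = grid$lig,
                               interval = grid$k, row.names = channelNames(scheme))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = mat), rowData = rd, colData = cd)
    new("DescriptorSet", se, scheme = scheme, normalized = FALSE)
}

#' Fit the global-maximum descriptor normalizer
#'
#' The normalization constant is the maximum over all channels of all
#' complexes in the fitted set. Descriptors scaled by it lie in [0, 1] for
#' the fitted set; held-out complexes may exceed 1.
#'
#' @param x a raw-count \linkS4class{DescriptorSet}, or a numeric matrix.
#' @return \linkS4class{NormalizationConstants}.
#' @export
fitNormalizer <- function(x) {
    fp <- NA_character_
    if (is(x, "DescriptorSet")) {
        if (isNormalized(x)) stop("normalizer must be fitted on raw counts")
        fp <- schemeFingerprint(scheme(x))
        x <- SummarizedExperiment::assay(x, "counts")
    }
    if (length(x) == 0L) stop("cannot fit a normalizer on an empty matrix")
    gm <- max(x)
    if (gm <= 0)
        stop("degenerate normalizer: all descriptors are zero")
    NormalizationConstants(globalMax = gm, schemeFingerprint = fp)
}

#' Apply a fitted normalizer
#'
#' Divides every descriptor entry by the fitted global maximum.
#'
#' @param x a raw-count \linkS4class{DescriptorSet} or numeric matrix.
#' @param constants a \linkS4class{NormalizationConstants}.
#' @return object of the same class as \code{x}, scaled.
#' @export
applyNormalizer <- function(x, constants) {
    stopifnot(is(constants, "NormalizationConstants"))
    if (is(x, "DescriptorSet")) {
        if (isNormalized(x)) stop("DescriptorSet is already normalized")
        fp <- constants@schemeFingerprint
        if (!is.na(fp) && fp != schemeFingerprint(scheme(x)))
            stop("normalizer was fitted under a different featurization scheme")
        SummarizedExperiment::assay(x, "counts") <-
            SummarizedExperiment::assay(x, "counts") / constants@globalMax
        x@normalized <- TRUE
        return(x)
    }
    x / constants@globalMax
}

setMethod("show", "DescriptorSet", function(object) {
    cat("DescriptorSet:", nrow(object), "channels x", ncol(object), "complexes",
        if (object@normalized) "(normalized)" else "(raw counts)", "\n")
    cat("  scheme:", length(object@scheme@targetSpecies), "x",
        length(object@scheme@ligandSpecies), "species,",
        object@scheme@nIntervals, "intervals of",
        object@scheme@intervalWidth, "A\n")
    pids <- unique(SummarizedExperiment::colData(object)$proteinId)
    cat("  proteins:", length(pids), "\n")
    if ("affinity" %in% names(SummarizedExperiment::colData(object)))
        cat("  affinity kind:",
            unique(stats::na.omit(SummarizedExperiment::colData(object)$affinityKind)), "\n")
})
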