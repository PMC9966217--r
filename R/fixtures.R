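#' @include AllClasses.R featurizer.R mw-baseline.R
NULL

# deterministic sub-seed derivation (kept below 2^31 - 1)
.deriveSeed <- function(seed, ...) {
    x <- (as.numeric(seed) %% 2147483647) + 1
    for (k in c(...)) x <- (x * 69069 + as.numeric(k) + 1) %% 2147483647
    as.integer(x)
}

#' Create a synthetic-database specification
#'
#' Defaults emulate a mid-sized computer-generated benchmark at desk scale:
#' ten distinct proteins with one hundred docked ligands each, drug-like
#' element composition concentrated on H/C/N/O with traces of P and S,
#' pocket-shell geometry (target atoms at 2-12 Angstrom from the ligand
#' region, ligand atoms in a 4 Angstrom ball) and Gaussian affinity noise
#' of 0.5 pKi units. The geometry is deliberately crude -- no sterics, no
#' bonds -- because the featurizer only sees distances and species; these
#' are fixtures, not physical poses.
#'
#' @param nProteins,ligandsPerProtein database layout.
#' @param targetAtomRange,ligandAtomRange inclusive atom-count ranges.
#' @param targetSpeciesFreq,ligandSpeciesFreq named sampling weights.
#' @param pocketShell,ligandRadius geometry (Angstrom).
#' @param affinityModel planted structure-affinity relationship; see
#'   \linkS4class{FixtureSpec}.
#' @param params planted parameters; missing entries are filled with
#'   deterministic defaults drawn under \code{seed}.
#' @param scheme featurization scheme used by descriptor-based models.
#' @param noiseSd Gaussian noise SD on the affinity scale.
#' @param seed master seed; the whole database is a deterministic function
#'   of it.
#' @return A \linkS4class{FixtureSpec}.
#' @export
FixtureSpec <- function(nProteins = 10L, ligandsPerProtein = 100L,
                        targetAtomRange = c(60L, 120L),
                        ligandAtomRange = c(15L, 40L),
                        targetSpeciesFreq = c(H = 0.35, C = 0.35, N = 0.15,
                                              O = 0.10, P = 0.025, S = 0.025),
                        ligandSpeciesFreq = c(H = 0.35, C = 0.35, N = 0.15,
                                              O = 0.10, P = 0.025, S = 0.025),
                        pocketShell = c(2, 12), ligandRadius = 4,
                        affinityModel = c("pair_linear", "mw_linear",
                                          "protein_id_only", "nonlinear"),
                        params = list(), scheme = FeaturizationScheme(),
                        noiseSd = 0.5, seed = 1L) {
    affinityModel <- match.arg(affinityModel)
    if (affinityModel == "pair_linear" && is.null(params$w)) {
        set.seed(.deriveSeed(seed, 101))
        params$w <- stats::rnorm(descriptorDim(scheme), sd = 0.02)
    }
    if (affinityModel == "mw_linear") {
        if (is.null(params$A)) params$A <- 2
        if (is.null(params$B)) params$B <- 0.01
    }
    if (affinityModel == "protein_id_only" && is.null(params$proteinEffects)) {
        set.seed(.deriveSeed(seed, 102))
        params$proteinEffects <- stats::rnorm(nProteins, mean = 7, sd = 2)
    }
    if (affinityModel == "nonlinear") {
        if (is.null(params$scale1)) params$scale1 <- 50
        if (is.null(params$scale2)) params$scale2 <- 50
    }
    new("FixtureSpec", nProteins = as.integer(nProteins),
        ligandsPerProtein = as.integer(ligandsPerProtein),
        targetAtomRange = as.integer(targetAtomRange),
        ligandAtomRange = as.integer(ligandAtomRange),
        targetSpeciesFreq = targetSpeciesFreq,
        ligandSpeciesFreq = ligandSpeciesFreq,
        pocketShell = as.numeric(pocketShell),
        ligandRadius = as.numeric(ligandRadius),
        affinityModel = affinityModel, params = params, scheme = scheme,
        noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# uniform direction vectors
.randDirs <- function(n) {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v / sqrt(rowSums(v^2))
}

.sampleSpecies <- function(n, freq) {
    sample(toupper(names(freq)), n, replace = TRUE, prob = freq / sum(freq))
}

#' Generate one synthetic complex
#'
#' The target atom cloud is a deterministic function of (seed,
#' proteinIndex): the same protein cloud recurs across all of its ligands,
#' so protein identity is geometrically real and vertical splits are
#' meaningful. The ligand cloud is fresh per (proteinIndex, ligandIndex).
#' Ids follow \code{"P<p>_L<l>"} / \code{"P<p>"}.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param proteinIndex,ligandIndex 1-based indices within the spec's layout.
#' @return A \linkS4class{ComplexStructure}.
#' @export
generateComplex <- function(spec, proteinIndex, ligandIndex) {
    stopifnot(proteinIndex >= 1L, proteinIndex <= spec@nProteins,
              ligandIndex >= 1L, ligandIndex <= spec@ligandsPerProtein)
    # protein cloud: depends on (seed, proteinIndex) only
    set.seed(.deriveSeed(spec@seed, 1, proteinIndex))
    nT <- sample(spec@targetAtomRange[1]:spec@targetAtomRange[2], 1L)
    rT <- stats::runif(nT, spec@pocketShell[1], spec@pocketShell[2])
    posT <- .randDirs(nT) * rT
    elT <- .sampleSpecies(nT, spec@targetSpeciesFreq)
    # ligand cloud: fresh per (proteinIndex, ligandIndex)
    set.seed(.deriveSeed(spec@seed, 2, proteinIndex, ligandIndex))
    nL <- sample(spec@ligandAtomRange[1]:spec@ligandAtomRange[2], 1L)
    rL <- spec@ligandRadius * stats::runif(nL)^(1 / 3)  # uniform in the ball
    posL <- .randDirs(nL) * rL
    elL <- .sampleSpecies(nL, spec@ligandSpeciesFreq)
    ComplexStructure(
        sprintf("P%02d_L%04d", proteinIndex, ligandIndex),
        sprintf("P%02d", proteinIndex),
        data.frame(element = c(elT, elL),
                   x = round(c(posT[, 1], posL[, 1]), 3),
                   y = round(c(posT[, 2], posL[, 2]), 3),
                   z = round(c(posT[, 3], posL[, 3]), 3),
                   role = rep(c("target", "ligand"), c(nT, nL)),
                   stringsAsFactors = FALSE))
}

.fixtureIndices <- function(x) {
    m <- regmatches(complexId(x),
                    regexec("^P([0-9]+)_L([0-9]+)$", complexId(x)))[[1]]
    if (length(m) != 3L)
        stop("complexId does not follow the fixture naming scheme: ", complexId(x))
    as.integer(m[2:3])
}

#' Planted affinity of a synthetic complex
#'
#' Evaluates the spec's structure-affinity relationship on one complex:
#' \describe{
#'   \item{pair_linear}{\code{sum(w * countPairs(x, scheme))}}
#'   \item{mw_linear}{\code{A + B * molecularWeight(x)}}
#'   \item{protein_id_only}{the per-protein constant}
#'   \item{nonlinear}{\code{4 * tanh(s1/scale1) + (s2/scale2)^2} where s1,
#'     s2 are the total counts in the first and second distance interval}
#' }
#' plus Gaussian noise of SD \code{noiseSd}, seeded deterministically per
#' complex so databases are reproducible.
#'
#' @param x a fixture \linkS4class{ComplexStructure}.
#' @param spec the generating \linkS4class{FixtureSpec}.
#' @return scalar affinity.
#' @export
plantedAffinity <- function(x, spec) {
    idx <- .fixtureIndices(x)
    base <- switch(spec@affinityModel,
        pair_linear = {
            v <- countPairs(x, spec@scheme)
            if (length(spec@params$w) != length(v))
                stop(sprintf("planted weight vector length %d does not match descriptor dimension %d",
                             length(spec@params$w), length(v)))
            sum(spec@params$w * v)
        },
        mw_linear = spec@params$A + spec@params$B * molecularWeight(x),
        protein_id_only = spec@params$proteinEffects[idx[1]],
        nonlinear = {
            v <- countPairs(x, spec@scheme)
            perInterval <- length(spec@scheme@targetSpecies) *
                length(spec@scheme@ligandSpecies)
            s1 <- sum(v[seq_len(perInterval)])
            s2 <- if (spec@scheme@nIntervals >= 2L)
                sum(v[perInterval + seq_len(perInterval)]) else 0
            4 * tanh(s1 / spec@params$scale1) + (s2 / spec@params$scale2)^2
        })
    if (spec@noiseSd > 0) {
        set.seed(.deriveSeed(spec@seed, 3, idx[1], idx[2]))
        base <- base + stats::rnorm(1, sd = spec@noiseSd)
    }
    base
}

#' Generate a complete synthetic database
#'
#' Produces every complex of the spec's layout with its planted affinity.
#' With \code{dir} set, also writes an on-disk database in the package's
#' interchange format -- one protein and one ligand PDB file per complex
#' plus a \code{manifest.csv} -- consumable by [readManifest()] and the
#' command-line interface. Regeneration under the same seed is
#' bit-identical.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param dir optional output directory.
#' @return list with \code{complexes} (list of
#'   \linkS4class{ComplexStructure}) and \code{affinities} (data.frame
#'   \code{complexId}, \code{value}, \code{kind}).
#' @export
generateDatabase <- function(spec, dir = NULL) {
    validObject(spec)
    grid <- expand.grid(l = seq_len(spec@ligandsPerProtein),
                        p = seq_len(spec@nProteins))
    complexes <- mapply(function(p, l) generateComplex(spec, p, l),
                        grid$p, grid$l, SIMPLIFY = FALSE)
    affinities <- data.frame(
        complexId = vapply(complexes, complexId, ""),
        value = vapply(complexes, plantedAffinity, 0, spec = spec),
        kind = "pKi", stringsAsFactors = FALSE)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        pf <- paste0(vapply(complexes, complexId, ""), "_protein.pdb")
        lf <- paste0(vapply(complexes, complexId, ""), "_ligand.pdb")
        for (i in seq_along(complexes))
            writeComplex(complexes[[i]], file.path(dir, pf[i]), file.path(dir, lf[i]))
        utils::write.csv(data.frame(
            complex_id = affinities$complexId,
            protein_id = vapply(complexes, proteinId, ""),
            protein_file = pf, ligand_file = lf,
            affinity_value = affinities$value,
            affinity_kind = affinities$kind), row.names = FALSE,
            file = file.path(dir, "manifest.csv"))
    }
    list(complexes = complexes, affinities = affinities)
}
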