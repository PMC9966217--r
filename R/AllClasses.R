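#' Default atomic species considered on the target (protein) side
#'
#' Ten species: H, C, N, O, F, P, S, Cl, Br, I. Hydrogens are part of the
#' representation, so input structures are expected to be protonated.
#' @export
TARGET_SPECIES <- c("H", "C", "N", "O", "F", "P", "S", "CL", "BR", "I")

#' Default atomic species considered on the ligand side
#'
#' Six species: H, C, N, O, P, S. Ligands containing halogens or metals fall
#' outside this set; their out-of-set atoms are silently ignored by the
#' featurizer and can be surveyed with [speciesFilterReport()].
#' @export
LIGAND_SPECIES <- c("H", "C", "N", "O", "P", "S")

# ---- FeaturizationScheme ----------------------------------------------------

#' Featurization scheme for distance-binned atomic pair counts
#'
#' A scheme fixes the atomic species considered on each side of the
#' protein-ligand interface, the distance-interval width (Angstrom) and the
#' number of consecutive intervals. Each combination (target species A,
#' ligand species A', interval k) is one descriptor channel, so the
#' descriptor dimension is \code{length(targetSpecies) * length(ligandSpecies)
#' * nIntervals}. With the default 10 target and 6 ligand species each
#' interval contributes 60 channels; the default width 2 Angstrom with 4
#' intervals yields 240 channels and an 8 Angstrom pair cutoff.
#'
#' @slot targetSpecies uppercase element symbols counted on the target side.
#' @slot ligandSpecies uppercase element symbols counted on the ligand side.
#' @slot intervalWidth interval width in Angstrom (> 0).
#' @slot nIntervals number of consecutive distance intervals (>= 1).
#' @export
setClass("FeaturizationScheme",
    representation(
        targetSpecies = "character",
        ligandSpecies = "character",
        intervalWidth = "numeric",
        nIntervals    = "integer"
    )
)

setValidity("FeaturizationScheme", function(object) {
    msg <- character()
    if (length(object@targetSpecies) == 0L || anyDuplicated(object@targetSpecies))
        msg <- c(msg, "targetSpecies must be non-empty without duplicates")
    if (length(object@ligandSpecies) == 0L || anyDuplicated(object@ligandSpecies))
        msg <- c(msg, "ligandSpecies must be non-empty without duplicates")
    if (any(!nzchar(object@targetSpecies)) || any(!nzchar(object@ligandSpecies)))
        msg <- c(msg, "species symbols must be non-empty strings")
    if (length(object@intervalWidth) != 1L || !is.finite(object@intervalWidth) ||
        object@intervalWidth <= 0)
        msg <- c(msg, "intervalWidth must be a single positive number")
    if (length(object@nIntervals) != 1L || is.na(object@nIntervals) ||
        object@nIntervals < 1L)
        msg <- c(msg, "nIntervals must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' Create a featurization scheme
#'
#' @param targetSpecies,ligandSpecies element symbols (case-insensitive,
#'   stored uppercase). Defaults are the 10-species target list and
#'   6-species ligand list.
#' @param intervalWidth distance interval width in Angstrom. The widths
#'   explored in the descriptor scan are 1.5, 2 and 3; any positive value is
#'   accepted. Default 2.
#' @param nIntervals number of intervals; pairs farther apart than
#'   \code{nIntervals * intervalWidth} are not counted. Default 4.
#' @return A \linkS4class{FeaturizationScheme}.
#' @examples
#' sch <- FeaturizationScheme()
#' descriptorDim(sch)  # 240
#' @export
FeaturizationScheme <- function(targetSpecies = TARGET_SPECIES,
                                ligandSpecies = LIGAND_SPECIES,
                                intervalWidth = 2,
                                nIntervals = 4L) {
    new("FeaturizationScheme",
        targetSpecies = toupper(as.character(targetSpecies)),
        ligandSpecies = toupper(as.character(ligandSpecies)),
        intervalWidth = as.numeric(intervalWidth),
        nIntervals = as.integer(nIntervals))
}

# ---- ComplexStructure -------------------------------------------------------

#' A protein-ligand complex as two typed atom sets
#'
#' Holds the atoms of one complex with their element symbols, Cartesian
#' coordinates (Angstrom) and role (\code{"target"} or \code{"ligand"}).
#' \code{proteinId} names the target protein and drives vertical /
#' per-target split logic; \code{complexId} identifies the complex within a
#' database.
#'
#' @slot complexId single non-empty string.
#' @slot proteinId single non-empty string.
#' @slot atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{role}; at least one target and one ligand atom.
#' @export
setClass("ComplexStructure",
    representation(
        complexId = "character",
        proteinId = "character",
        atoms     = "data.frame"
    )
)

setValidity("ComplexStructure", function(object) {
    msg <- character()
    a <- object@atoms
    need <- c("element", "x", "y", "z", "role")
    if (!all(need %in% names(a)))
        return(sprintf("atoms must have columns %s", paste(need, collapse = ", ")))
    if (length(object@complexId) != 1L || !nzchar(object@complexId))
        msg <- c(msg, "complexId must be a single non-empty string")
    if (length(object@proteinId) != 1L || !nzchar(object@proteinId))
        msg <- c(msg, "proteinId must be a single non-empty string")
    if (!all(a$role %in% c("target", "ligand")))
        msg <- c(msg, "atom role must be 'target' or 'ligand'")
    if (!any(a$role == "target") || !any(a$role == "ligand"))
        msg <- c(msg, "complex needs at least one target and one ligand atom")
    if (any(!nzchar(a$element)) || anyNA(a$element))
        msg <- c(msg, "every atom needs a non-empty element symbol")
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
        msg <- c(msg, "atom coordinates must all be finite")
    if (length(msg)) msg else TRUE
})

#' Construct a complex structure from an atom table
#'
#' @param complexId,proteinId identifiers (see class docs).
#' @param atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{role}. Elements are uppercased.
#' @return A \linkS4class{ComplexStructure}.
#' @export
ComplexStructure <- function(complexId, proteinId, atoms) {
    atoms <- as.data.frame(atoms)
    atoms$element <- toupper(as.character(atoms$element))
    atoms$role <- as.character(atoms$role)
    rownames(atoms) <- NULL
    new("ComplexStructure", complexId = as.character(complexId),
        proteinId = as.character(proteinId), atoms = atoms)
}

# ---- Normalization / standardization ---------------------------------------

#' Database-level descriptor normalization constant
#'
#' The single scaling constant used to map raw pair counts into [0, 1]:
#' the maximum entry over all channels of all complexes the normalizer was
#' fitted on. Held-out complexes may exceed 1 after scaling; that is
#' expected and allowed.
#'
#' @slot globalMax positive scalar.
#' @slot schemeFingerprint fingerprint of the scheme the constant belongs to.
#' @export
setClass("NormalizationConstants",
    representation(globalMax = "numeric", schemeFingerprint = "character"))

setValidity("NormalizationConstants", function(object) {
    if (length(object@globalMax) != 1L || !is.finite(object@globalMax) ||
        object@globalMax <= 0)
        return("globalMax must be a single positive finite number")
    TRUE
})

#' @rdname NormalizationConstants-class
#' @param globalMax positive scalar maximum.
#' @param schemeFingerprint scheme fingerprint string.
#' @export
NormalizationConstants <- function(globalMax, schemeFingerprint = NA_character_) {
    new("NormalizationConstants", globalMax = as.numeric(globalMax),
        schemeFingerprint = as.character(schemeFingerprint))
}

#' Affinity standardization parameters
#'
#' Mean and population standard deviation of the affinity labels used to
#' standardize regression targets, d' = (d - mu) / sigma. Predictions are
#' always reported back on the original scale via the inverse map.
#'
#' @slot mu database mean.
#' @slot sigma population standard deviation (> 0, divisor n).
#' @export
setClass("StandardizationParams",
    representation(mu = "numeric", sigma = "numeric"))

setValidity("StandardizationParams", function(object) {
    if (length(object@mu) != 1L || !is.finite(object@mu))
        return("mu must be a single finite number")
    if (length(object@sigma) != 1L || !is.finite(object@sigma) || object@sigma <= 0)
        return("sigma must be a single positive number")
    TRUE
})

#' @rdname StandardizationParams-class
#' @param mu,sigma mean and positive standard deviation.
#' @export
StandardizationParams <- function(mu, sigma) {
    new("StandardizationParams", mu = as.numeric(mu), sigma = as.numeric(sigma))
}

# ---- DescriptorSet ----------------------------------------------------------

#' Descriptor database: channels x complexes
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"counts"} assay
#' holds one descriptor vector per complex (rows = channels, columns =
#' complexes). \code{rowData} carries the channel decomposition
#' (\code{targetSpecies}, \code{ligandSpecies}, \code{interval});
#' \code{colData} carries \code{proteinId} and, when supplied,
#' \code{affinity} and \code{affinityKind}. The generating
#' \linkS4class{FeaturizationScheme} travels in the \code{scheme} slot.
#'
#' @slot scheme the featurization scheme that produced the rows.
#' @slot normalized whether the counts were divided by a global maximum.
#' @export
setClass("DescriptorSet",
    contains = "SummarizedExperiment",
    representation(scheme = "FeaturizationScheme", normalized = "logical"))

setValidity("DescriptorSet", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("DescriptorSet needs a 'counts' assay")
    if (nrow(object) != descriptorDim(object@scheme))
        msg <- c(msg, "number of rows must equal the scheme's descriptor dimension")
    if (!"proteinId" %in% names(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain proteinId")
    m <- SummarizedExperiment::assay(object, "counts")
    if (length(m) && min(m) < 0)
        msg <- c(msg, "descriptor counts must be non-negative")
    if (length(object@normalized) != 1L || is.na(object@normalized))
        msg <- c(msg, "normalized flag must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

# ---- Network / training -----------------------------------------------------

#' Fully connected network architecture
#'
#' All hidden layers share the same width and use the hyperbolic tangent
#' activation; the output layer is a single linear neuron. The number of
#' hidden layers does not count the descriptor (input) layer nor the output
#' neuron.
#'
#' @slot nHiddenLayers number of hidden layers (>= 1).
#' @slot nHiddenUnits neurons per hidden layer (>= 1).
#' @slot inputDim descriptor dimension the network expects.
#' @slot l2Lambda L2 weight-decay coefficient (>= 0); default 0 because the
#'   accompanying regularization study found no benefit from larger values.
#' @slot seed integer seed controlling weight initialization.
#' @export
setClass("NetworkSpec",
    representation(
        nHiddenLayers = "integer",
        nHiddenUnits  = "integer",
        inputDim      = "integer",
        l2Lambda      = "numeric",
        seed          = "integer"
    )
)

setValidity("NetworkSpec", function(object) {
    msg <- character()
    if (object@nHiddenLayers < 1L) msg <- c(msg, "nHiddenLayers must be >= 1")
    if (object@nHiddenUnits < 1L) msg <- c(msg, "nHiddenUnits must be >= 1")
    if (object@inputDim < 1L) msg <- c(msg, "inputDim must be >= 1")
    if (object@l2Lambda < 0) msg <- c(msg, "l2Lambda must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname NetworkSpec-class
#' @param nHiddenLayers,nHiddenUnits,inputDim,l2Lambda,seed see slots.
#' @export
NetworkSpec <- function(nHiddenLayers = 2L, nHiddenUnits = 20L,
                        inputDim = 240L, l2Lambda = 0, seed = 1L) {
    new("NetworkSpec", nHiddenLayers = as.integer(nHiddenLayers),
        nHiddenUnits = as.integer(nHiddenUnits), inputDim = as.integer(inputDim),
        l2Lambda = as.numeric(l2Lambda), seed = as.integer(seed))
}

#' Training configuration for the pair-count network
#'
#' @slot batchSize mini-batch size; around 50 suits databases of a few
#'   thousand complexes and around 200 suits tens of thousands.
#' @slot maxEpochs hard cap on training epochs.
#' @slot patience early-stopping patience: training stops once the monitored
#'   mean squared error has not improved for this many epochs, and the
#'   best-monitor weights are restored.
#' @slot monitor \code{"validation"} (default) holds out a fraction of the
#'   training data to drive early stopping; \code{"test"} monitors the test
#'   set itself, replicating the historical protocol in which no validation
#'   set was practical (information leaks into the stopping decision).
#' @slot validationFraction fraction of training data held out when
#'   \code{monitor = "validation"}.
#' @slot learningRate,beta1,beta2,epsilon ADAM hyperparameters.
#' @export
setClass("TrainConfig",
    representation(
        batchSize = "integer", maxEpochs = "integer", patience = "integer",
        monitor = "character", validationFraction = "numeric",
        learningRate = "numeric", beta1 = "numeric", beta2 = "numeric",
        epsilon = "numeric"
    )
)

setValidity("TrainConfig", function(object) {
    msg <- character()
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@patience < 1L) msg <- c(msg, "patience must be >= 1")
    if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
    if (!object@monitor %in% c("validation", "test"))
        msg <- c(msg, "monitor must be 'validation' or 'test'")
    if (object@validationFraction <= 0 || object@validationFraction >= 1)
        msg <- c(msg, "validationFraction must be in (0, 1)")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param batchSize,maxEpochs,patience,monitor,validationFraction see slots.
#' @param learningRate,beta1,beta2,epsilon ADAM hyperparameters.
#' @export
TrainConfig <- function(batchSize = 50L, maxEpochs = 300L, patience = 20L,
                        monitor = c("validation", "test"),
                        validationFraction = 0.1,
                        learningRate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8) {
    new("TrainConfig", batchSize = as.integer(batchSize),
        maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
        monitor = match.arg(monitor),
        validationFraction = as.numeric(validationFraction),
        learningRate = as.numeric(learningRate), beta1 = as.numeric(beta1),
        beta2 = as.numeric(beta2), epsilon = as.numeric(epsilon))
}

#' A trained scoring function
#'
#' Bundles the fitted network weights with everything needed to score new
#' complexes end to end: the featurization scheme, the descriptor
#' normalization constant and the affinity standardizer. Predictions from
#' [predictAffinity()] are always on the original affinity scale.
#'
#' @slot spec the network architecture.
#' @slot weights list of layer weight matrices and bias vectors.
#' @slot scheme featurization scheme the model was trained under.
#' @slot normalizer descriptor normalization constants.
#' @slot standardizer affinity standardization parameters.
#' @slot history per-epoch data.frame: train loss, monitored MSE and Rp.
#' @export
setClass("TrainedModel",
    representation(
        spec = "NetworkSpec", weights = "list",
        scheme = "FeaturizationScheme",
        normalizer = "NormalizationConstants",
        standardizer = "StandardizationParams",
        history = "data.frame"
    )
)

# ---- Splits / evaluation ----------------------------------------------------

#' Train/test split plan
#'
#' @slot kind \code{"horizontal"} (random complexes; a protein may appear on
#'   both sides), \code{"vertical"} (test proteins wholly absent from
#'   training) or \code{"per_target"} (both sides restricted to one protein).
#' @slot trainIds,testIds disjoint complex-id sets.
#' @slot heldOutProteins proteins defining a vertical test set.
#' @slot targetProtein the single protein of a per-target plan.
#' @slot seed RNG seed the plan was drawn with (NA if deterministic).
#' @export
setClass("SplitPlan",
    representation(
        kind = "character", trainIds = "character", testIds = "character",
        heldOutProteins = "character", targetProtein = "character",
        seed = "integer"
    )
)

setValidity("SplitPlan", function(object) {
    msg <- character()
    if (!object@kind %in% c("horizontal", "vertical", "per_target"))
        msg <- c(msg, "kind must be horizontal, vertical or per_target")
    if (length(intersect(object@trainIds, object@testIds)))
        msg <- c(msg, "train and test ids must be disjoint")
    if (anyDuplicated(object@trainIds) || anyDuplicated(object@testIds))
        msg <- c(msg, "duplicate ids within a side")
    if (object@kind == "vertical" && length(object@heldOutProteins) == 0L)
        msg <- c(msg, "vertical plan needs heldOutProteins")
    if (object@kind == "per_target" &&
        (length(object@targetProtein) != 1L || is.na(object@targetProtein)))
        msg <- c(msg, "per_target plan needs a single targetProtein")
    if (length(msg)) msg else TRUE
})

SplitPlan <- function(kind, trainIds, testIds, heldOutProteins = character(),
                      targetProtein = NA_character_, seed = NA_integer_) {
    new("SplitPlan", kind = kind, trainIds = as.character(trainIds),
        testIds = as.character(testIds),
        heldOutProteins = as.character(heldOutProteins),
        targetProtein = as.character(targetProtein), seed = as.integer(seed))
}

#' Repeat-averaged evaluation result
#'
#' Scores from repeated train/test runs: per-repeat Pearson correlation and
#' MSE (original affinity scale), their means and the standard error of the
#' mean (sample SD of the repeats / sqrt(number of repeats); NA for a single
#' repeat).
#'
#' @slot kind split kind evaluated.
#' @slot scores data.frame with one row per repeat: \code{repeat_}, \code{seed},
#'   \code{rp}, \code{mse}, \code{nTrain}, \code{nTest}.
#' @slot meanRp,semRp,meanMse,semMse aggregate statistics.
#' @slot nTrain training-set size (last repeat; repeats share it by design).
#' @export
setClass("EvalResult",
    representation(
        kind = "character", scores = "data.frame",
        meanRp = "numeric", semRp = "numeric",
        meanMse = "numeric", semMse = "numeric", nTrain = "integer"
    )
)

EvalResult <- function(kind, scores) {
    n <- nrow(scores)
    semOf <- function(v) if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_
    new("EvalResult", kind = kind, scores = scores,
        meanRp = mean(scores$rp), semRp = semOf(scores$rp),
        meanMse = mean(scores$mse), semMse = semOf(scores$mse),
        nTrain = as.integer(scores$nTrain[n]))
}

#' Ligand molecular-weight linear baseline
#'
#' The null model for per-target scoring: affinity = A + B * MW with A, B
#' fitted by ordinary least squares on a per-target database.
#'
#' @slot intercept A (affinity units).
#' @slot slope B (affinity units per g/mol).
#' @slot inSampleRp Pearson correlation of fitted values with the training
#'   affinities (the fit is in-sample by construction).
#' @export
setClass("LinearMWModel",
    representation(intercept = "numeric", slope = "numeric", inSampleRp = "numeric"))

# ---- Synthetic fixtures -----------------------------------------------------

#' Specification of a synthetic complex database
#'
#' Generates crude but geometrically meaningful complexes: each protein is a
#' fixed atom cloud in a spherical shell (2-12 Angstrom radii) around the
#' origin, reused across all of its ligands so protein identity is real and
#' vertical splits are meaningful; each ligand is a fresh atom cloud in a
#' ball (radius 4 Angstrom) at the origin. Affinities are planted through a
#' known function of the descriptors, of the ligand molecular weight, or of
#' protein identity alone, plus Gaussian noise.
#'
#' @slot nProteins,ligandsPerProtein database layout.
#' @slot targetAtomRange,ligandAtomRange inclusive atom-count ranges.
#' @slot targetSpeciesFreq,ligandSpeciesFreq named sampling probabilities.
#' @slot pocketShell c(rmin, rmax) for target atoms, Angstrom.
#' @slot ligandRadius ball radius for ligand atoms, Angstrom.
#' @slot affinityModel one of \code{"pair_linear"}, \code{"mw_linear"},
#'   \code{"protein_id_only"}, \code{"nonlinear"}.
#' @slot params planted parameters: \code{w} (length descriptorDim) for
#'   pair_linear; \code{A}, \code{B} for mw_linear; \code{proteinEffects}
#'   (length nProteins) for protein_id_only; \code{scale1}, \code{scale2}
#'   for nonlinear.
#' @slot scheme featurization scheme used by descriptor-based affinity models.
#' @slot noiseSd Gaussian noise SD on the affinity scale (default 0.5).
#' @slot seed master seed; all generation is deterministic given it.
#' @export
setClass("FixtureSpec",
    representation(
        nProteins = "integer", ligandsPerProtein = "integer",
        targetAtomRange = "integer", ligandAtomRange = "integer",
        targetSpeciesFreq = "numeric", ligandSpeciesFreq = "numeric",
        pocketShell = "numeric", ligandRadius = "numeric",
        affinityModel = "character", params = "list",
        scheme = "FeaturizationScheme", noiseSd = "numeric", seed = "integer"
    )
)

setValidity("FixtureSpec", function(object) {
    msg <- character()
    if (object@nProteins < 1L || object@ligandsPerProtein < 1L)
        msg <- c(msg, "protein and ligand counts must be positive")
    if (length(object@targetAtomRange) != 2L || any(object@targetAtomRange < 1L) ||
        diff(object@targetAtomRange) < 0)
        msg <- c(msg, "targetAtomRange must be an increasing positive pair")
    if (length(object@ligandAtomRange) != 2L || any(object@ligandAtomRange < 1L) ||
        diff(object@ligandAtomRange) < 0)
        msg <- c(msg, "ligandAtomRange must be an increasing positive pair")
    if (is.null(names(object@targetSpeciesFreq)) ||
        any(object@targetSpeciesFreq < 0) || sum(object@targetSpeciesFreq) <= 0)
        msg <- c(msg, "targetSpeciesFreq must be named non-negative weights")
    if (is.null(names(object@ligandSpeciesFreq)) ||
        any(object@ligandSpeciesFreq < 0) || sum(object@ligandSpeciesFreq) <= 0)
        msg <- c(msg, "ligandSpeciesFreq must be named non-negative weights")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (!object@affinityModel %in%
        c("pair_linear", "mw_linear", "protein_id_only", "nonlinear"))
        msg <- c(msg, "unknown affinityModel")
    if (object@affinityModel == "pair_linear" &&
        length(object@params$w) != descriptorDim(object@scheme))
        msg <- c(msg, sprintf("params$w must have length %d (scheme descriptorDim)",
                              descriptorDim(object@scheme)))
    if (object@affinityModel == "mw_linear" &&
        (is.null(object@params$A) || is.null(object@params$B)))
        msg <- c(msg, "mw_linear needs params$A and params$B")
    if (object@affinityModel == "protein_id_only" &&
        length(object@params$proteinEffects) != object@nProteins)
        msg <- c(msg, "params$proteinEffects must have length nProteins")
    if (length(msg)) msg else TRUE
})
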