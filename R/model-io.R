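#' @include fcnn.R
NULL

.modelChecksum <- function(wts) {
    sum(vapply(wts$W, sum, 0)) + sum(vapply(wts$b, sum, 0))
}

# doubles as %.17g strings: JSON number formatting is not guaranteed to
# round-trip the last ulp, 17 significant digits are
.numOut <- function(x) sprintf("%.17g", x)
.numIn <- function(x) as.numeric(x)

#' Save / load a trained scoring function
#'
#' The model bundle is a directory with two JSON files: \code{metadata.json}
#' (architecture, featurization scheme, normalizer, standardizer, a weight
#' checksum and the training history) and \code{weights.json} (full-precision
#' weight matrices). \code{loadModel} verifies the checksum and the scheme
#' fingerprint and errors on mismatch, so a corrupted or mixed-up bundle is
#' refused rather than silently mis-scoring. Load-then-predict reproduces
#' the saved model's predictions exactly.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param path bundle directory (created if absent).
#' @return \code{saveModel}: invisibly, \code{path}; \code{loadModel}: a
#'   \linkS4class{TrainedModel}.
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "TrainedModel"))
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sch <- model@scheme
    meta <- list(
        format = "pairscore-model-1",
        spec = list(nHiddenLayers = model@spec@nHiddenLayers,
                    nHiddenUnits = model@spec@nHiddenUnits,
                    inputDim = model@spec@inputDim,
                    l2Lambda = model@spec@l2Lambda,
                    seed = model@spec@seed),
        scheme = list(targetSpecies = sch@targetSpecies,
                      ligandSpecies = sch@ligandSpecies,
                      intervalWidth = sch@intervalWidth,
                      nIntervals = sch@nIntervals),
        schemeFingerprint = schemeFingerprint(sch),
        normalizer = list(globalMax = .numOut(model@normalizer@globalMax)),
        standardizer = list(mu = .numOut(model@standardizer@mu),
                            sigma = .numOut(model@standardizer@sigma)),
        checksum = .numOut(.modelChecksum(model@weights)),
        history = model@history)
    jsonlite::write_json(meta, file.path(path, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    wts <- list(
        W = lapply(model@weights$W, function(w)
            list(dim = dim(w), data = .numOut(as.numeric(w)))),
        b = lapply(model@weights$b, function(v) .numOut(as.numeric(v))))
    jsonlite::write_json(wts, file.path(path, "weights.json"))
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    metaFile <- file.path(path, "metadata.json")
    wtsFile <- file.path(path, "weights.json")
    if (!file.exists(metaFile) || !file.exists(wtsFile))
        stop("not a model bundle: expected metadata.json and weights.json under ", path)
    meta <- tryCatch(jsonlite::read_json(metaFile, simplifyVector = TRUE),
                     error = function(e) stop("corrupted model metadata: ",
                                              conditionMessage(e), call. = FALSE))
    if (!identical(meta$format, "pairscore-model-1"))
        stop("unrecognized model bundle format")
    raw <- tryCatch(jsonlite::read_json(wtsFile, simplifyVector = TRUE),
                    error = function(e) stop("corrupted model weights: ",
                                             conditionMessage(e), call. = FALSE))
    W <- lapply(seq_along(raw$W$dim), function(l)
        matrix(.numIn(raw$W$data[[l]]), raw$W$dim[[l]][1], raw$W$dim[[l]][2]))
    b <- lapply(raw$b, .numIn)
    wts <- list(W = W, b = b)
    if (!isTRUE(abs(.modelChecksum(wts) - .numIn(meta$checksum)) < 1e-10))
        stop("integrity error: weight checksum mismatch (corrupted bundle?)")
    sch <- FeaturizationScheme(meta$scheme$targetSpecies, meta$scheme$ligandSpecies,
                               meta$scheme$intervalWidth, meta$scheme$nIntervals)
    if (!identical(schemeFingerprint(sch), meta$schemeFingerprint))
        stop("integrity error: scheme fingerprint mismatch")
    new("TrainedModel",
        spec = NetworkSpec(meta$spec$nHiddenLayers, meta$spec$nHiddenUnits,
                           meta$spec$inputDim, meta$spec$l2Lambda, meta$spec$seed),
        weights = wts, scheme = sch,
        normalizer = NormalizationConstants(.numIn(meta$normalizer$globalMax),
                                            meta$schemeFingerprint),
        standardizer = StandardizationParams(.numIn(meta$standardizer$mu),
                                             .numIn(meta$standardizer$sigma)),
        history = as.data.frame(meta$history))
}
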