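#' @include AllClasses.R AllGenerics.R featurizer.R affinity.R metrics.R
NULL

# ---- network primitives -----------------------------------------------------
# Weights are a list(W = list of inputDim x h, h x h, ..., h x 1 matrices,
#                    b = list of bias vectors, one per layer).
# Hidden activation tanh, linear single-unit output.

.layerDims <- function(spec) {
    c(spec@inputDim, rep(spec@nHiddenUnits, spec@nHiddenLayers), 1L)
}

#' Closed-form parameter count of a network spec
#'
#' \code{inputDim*Nh + Nh} for the first layer, \code{(Nl-1)*(Nh^2 + Nh)}
#' for the remaining hidden layers and \code{Nh + 1} for the single output
#' neuron.
#' @param spec a \linkS4class{NetworkSpec}.
#' @return integer parameter count.
#' @export
nParameters <- function(spec) {
    d <- spec@inputDim; h <- spec@nHiddenUnits; L <- spec@nHiddenLayers
    as.integer(d * h + h + (L - 1) * (h * h + h) + h + 1)
}

#' Build an untrained network
#'
#' Initializes weights with a symmetric uniform fan-based (Glorot-style)
#' scheme suited to tanh units, deterministically under the spec's seed:
#' the same seed yields bit-identical weights. Biases start at zero.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return list with elements \code{W} (weight matrices) and \code{b}
#'   (bias vectors), one per layer.
#' @export
buildNetwork <- function(spec) {
    validObject(spec)
    dims <- .layerDims(spec)
    set.seed(spec@seed)
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
        fanIn <- dims[l]; fanOut <- dims[l + 1L]
        lim <- sqrt(6 / (fanIn + fanOut))
        W[[l]] <- matrix(stats::runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
        b[[l]] <- numeric(fanOut)
    }
    list(W = W, b = b)
}

# forward pass; returns prediction vector and per-layer activations
.forward <- function(wts, X) {
    L <- length(wts$W)
    A <- vector("list", L + 1L)
    A[[1L]] <- X
    for (l in seq_len(L - 1L))
        A[[l + 1L]] <- tanh(sweep(A[[l]] %*% wts$W[[l]], 2, wts$b[[l]], "+"))
    out <- sweep(A[[L]] %*% wts$W[[L]], 2, wts$b[[L]], "+")
    list(pred = drop(out), A = A)
}

# loss = MSE + lambda * sum of squared weights (biases excluded)
.loss <- function(wts, X, y, lambda) {
    pred <- .forward(wts, X)$pred
    mean((pred - y)^2) + lambda * sum(vapply(wts$W, function(w) sum(w^2), 0))
}

# analytic gradient of .loss via backpropagation
.gradient <- function(wts, X, y, lambda) {
    L <- length(wts$W)
    fw <- .forward(wts, X)
    n <- nrow(X)
    gW <- vector("list", L); gb <- vector("list", L)
    delta <- matrix(2 * (fw$pred - y) / n, ncol = 1L)  # d loss / d output
    for (l in rev(seq_len(L))) {
        gW[[l]] <- crossprod(fw$A[[l]], delta) + 2 * lambda * wts$W[[l]]
        gb[[l]] <- colSums(delta)
        if (l > 1L)  # through tanh: A = tanh(Z) so dZ = dA * (1 - A^2)
            delta <- (delta %*% t(wts$W[[l]])) * (1 - fw$A[[l]]^2)
    }
    list(W = gW, b = gb)
}

.adamInit <- function(wts) {
    zero <- function(x) lapply(x, function(m) m * 0)
    list(mW = zero(wts$W), vW = zero(wts$W),
         mb = zero(wts$b), vb = zero(wts$b), t = 0L)
}

.adamStep <- function(wts, grad, st, cfg) {
    st$t <- st$t + 1L
    lr <- cfg@learningRate * sqrt(1 - cfg@beta2^st$t) / (1 - cfg@beta1^st$t)
    for (l in seq_along(wts$W)) {
        st$mW[[l]] <- cfg@beta1 * st$mW[[l]] + (1 - cfg@beta1) * grad$W[[l]]
        st$vW[[l]] <- cfg@beta2 * st$vW[[l]] + (1 - cfg@beta2) * grad$W[[l]]^2
        wts$W[[l]] <- wts$W[[l]] - lr * st$mW[[l]] / (sqrt(st$vW[[l]]) + cfg@epsilon)
        st$mb[[l]] <- cfg@beta1 * st$mb[[l]] + (1 - cfg@beta1) * grad$b[[l]]
        st$vb[[l]] <- cfg@beta2 * st$vb[[l]] + (1 - cfg@beta2) * grad$b[[l]]^2
        wts$b[[l]] <- wts$b[[l]] - lr * st$mb[[l]] / (sqrt(st$vb[[l]]) + cfg@epsilon)
    }
    list(wts = wts, st = st)
}

# mini-batch ADAM with early stopping on the monitored MSE; restores the
# best-monitor weights. X, y on the normalized/standardized scales.
.trainCore <- function(wts, X, y, cfg, lambda, monX, monY) {
    n <- nrow(X)
    st <- .adamInit(wts)
    best <- list(mse = Inf, wts = wts, epoch = 0L)
    hist <- vector("list", cfg@maxEpochs)
    for (epoch in seq_len(cfg@maxEpochs)) {
        perm <- sample.int(n)
        starts <- seq(1L, n, by = cfg@batchSize)
        for (s in starts) {
            idx <- perm[s:min(s + cfg@batchSize - 1L, n)]
            grad <- .gradient(wts, X[idx, , drop = FALSE], y[idx], lambda)
            upd <- .adamStep(wts, grad, st, cfg)
            wts <- upd$wts; st <- upd$st
        }
        trainLoss <- .loss(wts, X, y, lambda)
        if (!is.finite(trainLoss))
            stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch))
        monPred <- .forward(wts, monX)$pred
        monMse <- mean((monPred - monY)^2)
        monRp <- if (stats::sd(monPred) > 0 && stats::sd(monY) > 0)
            stats::cor(monPred, monY) else NA_real_
        hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                    monitorMse = monMse, monitorRp = monRp)
        if (monMse < best$mse)
            best <- list(mse = monMse, wts = wts, epoch = epoch)
        if (epoch - best$epoch >= cfg@patience) break
    }
    list(weights = best$wts, finalWeights = wts,
         history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
         bestEpoch = best$epoch)
}

# ---- high-level training ----------------------------------------------------

.assayT <- function(ds, ids) {
    m <- SummarizedExperiment::assay(ds, "counts")
    t(m[, ids, drop = FALSE])
}

.affinityOf <- function(ds, ids) {
    cd <- SummarizedExperiment::colData(ds)
    if (!"affinity" %in% names(cd))
        stop("DescriptorSet carries no affinity labels")
    v <- cd[ids, "affinity"]
    if (anyNA(v)) stop("missing affinity for some requested complexes")
    as.numeric(v)
}

#' Train a scoring function on a descriptor database
#'
#' End-to-end supervised training: descriptors are scaled by the
#' global-maximum normalizer, affinities standardized, and the tanh network
#' fitted by mini-batch ADAM with early stopping on a monitored MSE. In
#' \code{mode = "clean"} (default) the normalizer and standardizer are
#' fitted on the training complexes only and a fraction of the training set
#' is held out as the early-stopping monitor, so nothing leaks from the
#' test set. \code{mode = "legacy"} reproduces the historical protocol:
#' normalizer and standardizer are fitted on the whole database and the
#' test set itself drives early stopping (requires \code{testIds}).
#'
#' @param ds raw-count \linkS4class{DescriptorSet} with affinity labels.
#' @param trainIds complex ids to train on (default: all columns).
#' @param networkSpec a \linkS4class{NetworkSpec}; its \code{inputDim} must
#'   match the descriptor dimension (defaults to a 2x20 network on the
#'   set's dimension).
#' @param config a \linkS4class{TrainConfig}.
#' @param mode \code{"clean"} or \code{"legacy"}; see Details.
#' @param testIds complex ids monitored in legacy mode.
#' @param seed seed for mini-batch shuffling and the validation split.
#' @return A \linkS4class{TrainedModel}.
#' @export
trainScoringFunction <- function(ds, trainIds = colnames(ds),
                                 networkSpec = NULL,
                                 config = TrainConfig(),
                                 mode = c("clean", "legacy"),
                                 testIds = NULL, seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(is(ds, "DescriptorSet"))
    if (isNormalized(ds))
        stop("train on raw counts; normalization is fitted internally")
    validObject(config)
    trainIds <- as.character(trainIds)
    if (!all(trainIds %in% colnames(ds)))
        stop("unknown complex ids in trainIds")
    if (is.null(networkSpec))
        networkSpec <- NetworkSpec(inputDim = nrow(ds), seed = seed)
    if (networkSpec@inputDim != nrow(ds))
        stop(sprintf("network inputDim (%d) does not match descriptor dimension (%d)",
                     networkSpec@inputDim, nrow(ds)))

    fitIds <- if (mode == "legacy") colnames(ds) else trainIds
    normalizer <- fitNormalizer(
        SummarizedExperiment::assay(ds, "counts")[, fitIds, drop = FALSE])
    normalizer@schemeFingerprint <- schemeFingerprint(scheme(ds))
    standardizer <- fitStandardizer(.affinityOf(ds, fitIds))

    set.seed(seed)
    if (mode == "legacy") {
        if (is.null(testIds) || !length(testIds))
            stop("legacy mode monitors the test set: supply testIds")
        fitRows <- trainIds
        monIds <- as.character(testIds)
    } else {
        nVal <- max(2L, round(length(trainIds) * config@validationFraction))
        if (nVal >= length(trainIds))
            stop("training set too small for a validation split")
        monIds <- sample(trainIds, nVal)
        fitRows <- setdiff(trainIds, monIds)
    }
    if (length(fitRows) < config@batchSize)
        stop(sprintf("training set (%d) smaller than the batch size (%d)",
                     length(fitRows), config@batchSize))

    X <- applyNormalizer(.assayT(ds, fitRows), normalizer)
    y <- standardizeValues(.affinityOf(ds, fitRows), standardizer)
    monX <- applyNormalizer(.assayT(ds, monIds), normalizer)
    monY <- standardizeValues(.affinityOf(ds, monIds), standardizer)

    wts <- buildNetwork(networkSpec)
    fit <- .trainCore(wts, X, y, config, networkSpec@l2Lambda, monX, monY)

    new("TrainedModel", spec = networkSpec, weights = fit$weights,
        scheme = scheme(ds), normalizer = normalizer,
        standardizer = standardizer, history = fit$history)
}

#' @describeIn TrainedModel-class per-epoch training history.
#' @param x a \code{TrainedModel}.
#' @export
setMethod("trainingHistory", "TrainedModel", function(x) x@history)

setMethod("show", "TrainedModel", function(object) {
    cat(sprintf("TrainedModel: %dx%d tanh network on %d descriptors (%d parameters)\n",
                object@spec@nHiddenLayers, object@spec@nHiddenUnits,
                object@spec@inputDim, nParameters(object@spec)))
    cat(sprintf("  standardizer mu=%.4g sigma=%.4g; normalizer max=%.4g; %d epochs\n",
                object@standardizer@mu, object@standardizer@sigma,
                object@normalizer@globalMax, nrow(object@history)))
})

.predictMatrix <- function(model, X) {
    if (ncol(X) != model@spec@inputDim)
        stop(sprintf("descriptor dimension mismatch: model expects %d, got %d",
                     model@spec@inputDim, ncol(X)))
    Xn <- applyNormalizer(X, model@normalizer)
    destandardizeValues(.forward(model@weights, Xn)$pred, model@standardizer)
}

#' @describeIn TrainedModel-class predict affinities on the original scale.
#'   \code{newdata} may be a raw-count \linkS4class{DescriptorSet} built
#'   under the model's scheme, a numeric matrix of raw counts (complexes in
#'   rows), or a list of \linkS4class{ComplexStructure} (featurized with the
#'   model's scheme). Deterministic: identical inputs give identical outputs.
#' @param object a \code{TrainedModel}.
#' @param newdata complexes or descriptors to score.
#' @param ... unused.
#' @export
setMethod("predictAffinity", "TrainedModel", function(object, newdata, ...) {
    if (is(newdata, "DescriptorSet")) {
        if (isNormalized(newdata))
            stop("supply raw counts; the model applies its own normalizer")
        fp <- object@normalizer@schemeFingerprint
        if (!is.na(fp) && fp != schemeFingerprint(scheme(newdata)))
            stop("DescriptorSet was built under a different featurization scheme")
        return(.predictMatrix(object, .assayT(newdata, colnames(newdata))))
    }
    if (is.list(newdata) && all(vapply(newdata, is, TRUE, "ComplexStructure"))) {
        X <- do.call(rbind, lapply(newdata, function(cx)
            countPairs(cx, object@scheme)))
        return(.predictMatrix(object, X))
    }
    if (is.numeric(newdata)) {
        if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
        return(.predictMatrix(object, newdata))
    }
    stop("newdata must be a DescriptorSet, a numeric matrix, or a list of ComplexStructure")
})
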