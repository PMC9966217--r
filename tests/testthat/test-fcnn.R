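test_that("parameter counts match the closed form", {
    countWeights <- function(w) sum(lengths(w$W)) + sum(lengths(w$b))
    s1 <- NetworkSpec(2, 20, inputDim = 240)
    expect_equal(nParameters(s1), 5261L)
    expect_equal(countWeights(buildNetwork(s1)), nParameters(s1))
    s2 <- NetworkSpec(4, 40, inputDim = 240)
    expect_equal(nParameters(s2), 240L * 40L + 40L + 3L * (40L * 40L + 40L) + 40L + 1L)
    expect_equal(countWeights(buildNetwork(s2)), nParameters(s2))
    s3 <- NetworkSpec(1, 3, inputDim = 5)
    expect_equal(countWeights(buildNetwork(s3)), nParameters(s3))
    expect_error(NetworkSpec(0, 5, 10), "nHiddenLayers")
})

test_that("initialization is deterministic under the spec seed", {
    s <- NetworkSpec(2, 8, inputDim = 12, seed = 99)
    expect_identical(buildNetwork(s), buildNetwork(s))
    s2 <- NetworkSpec(2, 8, inputDim = 12, seed = 100)
    expect_false(identical(buildNetwork(s), buildNetwork(s2)))
})

test_that("analytic gradients match finite differences on a tiny network", {
    set.seed(5)
    spec <- NetworkSpec(1, 3, inputDim = 5, l2Lambda = 0.01, seed = 3)
    wts <- buildNetwork(spec)
    X <- matrix(rnorm(4 * 5), 4, 5)
    y <- rnorm(4)
    lam <- spec@l2Lambda
    g <- pairscore:::.gradient(wts, X, y, lam)
    eps <- 1e-6
    for (l in seq_along(wts$W)) {
        for (idx in seq_len(length(wts$W[[l]]))) {
            wp <- wts; wp$W[[l]][idx] <- wp$W[[l]][idx] + eps
            wm <- wts; wm$W[[l]][idx] <- wm$W[[l]][idx] - eps
            num <- (pairscore:::.loss(wp, X, y, lam) -
                    pairscore:::.loss(wm, X, y, lam)) / (2 * eps)
            expect_equal(g$W[[l]][idx], num, tolerance = 1e-4)
        }
        for (idx in seq_along(wts$b[[l]])) {
            wp <- wts; wp$b[[l]][idx] <- wp$b[[l]][idx] + eps
            wm <- wts; wm$b[[l]][idx] <- wm$b[[l]][idx] - eps
            num <- (pairscore:::.loss(wp, X, y, lam) -
                    pairscore:::.loss(wm, X, y, lam)) / (2 * eps)
            expect_equal(g$b[[l]][idx], num, tolerance = 1e-4)
        }
    }
})

test_that("training recovers a planted linear map and is seed-deterministic", {
    ds <- smallLinearDb()
    plan <- horizontalSplit(ds, nTest = 70, seed = 3)
    fit <- function(seed) trainScoringFunction(
        ds, trainIds(plan), NetworkSpec(2, 20, inputDim = 240, seed = seed),
        fastConfig(), seed = seed)
    m <- fit(1)
    pred <- predictAffinity(m, ds[, testIds(plan)])
    obs <- SummarizedExperiment::colData(ds)[testIds(plan), "affinity"]
    expect_gt(pearsonR(pred, obs), 0.9)
    expect_true(all(is.finite(pred)))
    # determinism: same seed reproduces weights, history and predictions
    m2 <- fit(1)
    expect_identical(m@weights, m2@weights)
    expect_identical(trainingHistory(m), trainingHistory(m2))
    expect_identical(pred, predictAffinity(m2, ds[, testIds(plan)]))
    expect_identical(pred, predictAffinity(m, ds[, testIds(plan)]))
})

test_that("strong L2 regularization shrinks weights and hurts fit", {
    ds <- smallLinearDb()
    plan <- horizontalSplit(ds, nTest = 70, seed = 3)
    # shrinkage of the optimized weights, on the raw training core (the
    # public API restores best-monitor weights, which hides late shrinkage)
    norm2 <- function(w) sum(vapply(w$W, function(m) sum(m^2), 0))
    nc <- fitNormalizer(ds)
    X <- pairscore:::.assayT(ds, trainIds(plan)) / nc@globalMax
    y <- scale(SummarizedExperiment::colData(ds)[trainIds(plan), "affinity"])[, 1]
    cfg <- fastConfig(maxEpochs = 40L, patience = 40L)
    spec <- NetworkSpec(2, 20, inputDim = 240, seed = 1)
    run <- function(lam) {
        set.seed(1)
        pairscore:::.trainCore(buildNetwork(spec), X[-(1:30), ], y[-(1:30)],
                               cfg, lam, X[1:30, ], y[1:30])
    }
    expect_lt(norm2(run(1e3)$finalWeights), norm2(run(0)$finalWeights) / 10)
    # end to end, heavy regularization costs test correlation
    fitLam <- function(lam) trainScoringFunction(
        ds, trainIds(plan), NetworkSpec(2, 20, inputDim = 240, l2Lambda = lam, seed = 1),
        fastConfig(maxEpochs = 40L), seed = 1)
    obs <- SummarizedExperiment::colData(ds)[testIds(plan), "affinity"]
    rp0 <- pearsonR(predictAffinity(fitLam(0), ds[, testIds(plan)]), obs)
    predBig <- predictAffinity(fitLam(1e3), ds[, testIds(plan)])
    rpBig <- if (sd(predBig) > 0) pearsonR(predBig, obs) else 0
    expect_lt(rpBig, rp0)
})

test_that("training validates shapes, batch sizes and affinity presence", {
    ds <- smallLinearDb()
    expect_error(trainScoringFunction(ds, networkSpec = NetworkSpec(1, 4, inputDim = 60)),
                 "inputDim")
    expect_error(trainScoringFunction(ds, trainIds = colnames(ds)[1:20],
                                      config = TrainConfig(batchSize = 50)),
                 "batch size|validation")
    expect_error(trainScoringFunction(ds, trainIds = c("nope")), "unknown complex ids")
    m <- trainScoringFunction(ds, networkSpec = NetworkSpec(1, 4, inputDim = 240),
                              config = fastConfig(maxEpochs = 3L), seed = 1)
    expect_error(predictAffinity(m, matrix(0, 2, 60)), "dimension mismatch")
    nds <- applyNormalizer(ds, fitNormalizer(ds))
    expect_error(trainScoringFunction(nds), "raw counts")
})

test_that("legacy mode monitors the test set and fits scalers on the whole database", {
    ds <- smallLinearDb()
    plan <- horizontalSplit(ds, nTest = 70, seed = 9)
    m <- trainScoringFunction(ds, trainIds(plan),
                              NetworkSpec(1, 8, inputDim = 240, seed = 2),
                              fastConfig(maxEpochs = 20L, monitor = "test"),
                              mode = "legacy", testIds = testIds(plan), seed = 2)
    aff <- SummarizedExperiment::colData(ds)$affinity
    expect_equal(m@standardizer@mu, mean(aff))
    expect_equal(m@normalizer@globalMax, max(SummarizedExperiment::assay(ds)))
    expect_error(trainScoringFunction(ds, trainIds(plan), mode = "legacy",
                                      config = fastConfig(monitor = "test")),
                 "testIds")
})

test_that("model bundles round-trip exactly and detect corruption", {
    ds <- smallLinearDb()
    m <- trainScoringFunction(ds, networkSpec = NetworkSpec(1, 6, inputDim = 240, seed = 4),
                              config = fastConfig(maxEpochs = 5L), seed = 4)
    sub <- ds[, 1:10]
    pred <- predictAffinity(m, sub)
    td <- withr::local_tempdir()
    bundle <- file.path(td, "model")
    saveModel(m, bundle)
    m2 <- loadModel(bundle)
    expect_identical(predictAffinity(m2, sub), pred)
    expect_equal(m2@spec@nHiddenUnits, 6L)
    # corrupt one weight: checksum must catch it
    wf <- file.path(bundle, "weights.json")
    txt <- readLines(wf, warn = FALSE)
    txt <- sub("(\"data\":\\[\")[^\"]+", "\\19.9e9", txt)
    writeLines(txt, wf)
    expect_error(loadModel(bundle), "integrity|corrupted")
    expect_error(loadModel(td), "not a model bundle")
})
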