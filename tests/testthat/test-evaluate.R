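tinySpec <- function(seed = 1) NetworkSpec(1, 6, inputDim = 240, seed = seed)

test_that("evaluate aggregates per-repeat scores with a recomputable SEM", {
    ds <- smallLinearDb()
    res <- evaluateProtocol(ds, "horizontal", nRepeats = 3, nTest = 60,
                            networkSpec = tinySpec(),
                            config = fastConfig(maxEpochs = 25L), seed = 7)
    sc <- repeatScores(res)
    expect_equal(nrow(sc), 3)
    expect_equal(res@meanRp, mean(sc$rp))
    expect_equal(res@semRp, sd(sc$rp) / sqrt(3))
    expect_equal(res@meanMse, mean(sc$mse))
    expect_true(all(sc$rp >= -1 & sc$rp <= 1))
    expect_true(all(sc$nTest == 60))
    # a single repeat has no SEM
    res1 <- evaluateProtocol(ds, "horizontal", nRepeats = 1, nTest = 60,
                             networkSpec = tinySpec(),
                             config = fastConfig(maxEpochs = 10L), seed = 7)
    expect_true(is.na(res1@semRp))
    # master seed reproducibility
    res2 <- evaluateProtocol(ds, "horizontal", nRepeats = 3, nTest = 60,
                             networkSpec = tinySpec(),
                             config = fastConfig(maxEpochs = 25L), seed = 7)
    expect_identical(repeatScores(res2), sc)
})

test_that("learning curves track training-set size and report percentages", {
    ds <- smallLinearDb()
    lc <- learningCurve(ds, ntGrid = c(100, 250), protocol = "horizontal",
                        nRepeats = 2, nTest = 60, networkSpec = tinySpec(),
                        config = fastConfig(maxEpochs = 30L), seed = 5)
    expect_equal(lc$nTrain, c(100L, 250L))
    expect_equal(lc$pctTrain, 100 * c(100, 250) / ncol(ds))
    expect_true(all(is.finite(lc$meanRp)))
    results <- attr(lc, "results")
    expect_equal(unique(repeatScores(results[[1]])$nTrain), 100)
    # more noiseless linear data never hurts (one-SEM tolerance)
    expect_gte(lc$meanRp[2], lc$meanRp[1] - lc$semRp[1] - lc$semRp[2])
    expect_error(learningCurve(ds, ntGrid = 10000, protocol = "horizontal",
                               nRepeats = 2, nTest = 60,
                               networkSpec = tinySpec(),
                               config = fastConfig()), "exceeds|larger")
})

test_that("descriptor scan enumerates the width/interval grid and finds the planted range", {
    # planted affinity uses only pairs within 4 A (intervals 1-2 at width 2)
    sch <- FeaturizationScheme()
    set.seed(3)
    w <- numeric(240); w[1:120] <- rnorm(120, sd = 0.05)
    fs <- FixtureSpec(nProteins = 4, ligandsPerProtein = 50,
                      affinityModel = "pair_linear", params = list(w = w),
                      noiseSd = 0, seed = 13)
    db <- generateDatabase(fs)
    tab <- scanDescriptors(db$complexes, db$affinities,
                           widths = 2, maxIntervals = 3L,
                           nTest = 40, nRepeats = 2,
                           networkTemplate = NetworkSpec(1, 8, inputDim = 1),
                           config = fastConfig(maxEpochs = 30L), seed = 2)
    expect_equal(nrow(tab), 3)
    expect_equal(tab$nDescriptors, 60 * (1:3))
    expect_equal(sum(tab$best), 1)
    # the best combination must cover the planted 4 A range
    best <- tab[tab$best, ]
    expect_gte(best$width * best$nIntervals, 4)
    # default grid shape: 6 + 7 + 5 = 18 combinations
    grid <- do.call(rbind, lapply(seq_along(c(1.5, 2, 3)), function(i)
        data.frame(w = c(1.5, 2, 3)[i], k = seq_len(c(6L, 7L, 5L)[i]))))
    expect_equal(nrow(grid), 18)
})

test_that("architecture scan orders capacity sensibly on a nonlinear fixture", {
    fs <- FixtureSpec(nProteins = 4, ligandsPerProtein = 60,
                      affinityModel = "nonlinear",
                      params = list(scale1 = 120, scale2 = 150),
                      noiseSd = 0, seed = 19)
    db <- generateDatabase(fs)
    ds <- featurizeDatabase(db$complexes, FeaturizationScheme(), db$affinities)
    tab <- scanArchitecture(ds, architectures = list(c(1L, 5L), c(4L, 40L)),
                            nTest = 48, nRepeats = 2,
                            config = fastConfig(maxEpochs = 40L), seed = 3)
    expect_equal(nrow(tab), 2)
    expect_equal(tab$label, c("1x5", "4x40"))
    sem <- max(tab$semRp, na.rm = TRUE)
    expect_gte(tab$meanRp[2], tab$meanRp[1] - sem)
    # reproducible under the same master seed
    tab2 <- scanArchitecture(ds, architectures = list(c(1L, 5L), c(4L, 40L)),
                             nTest = 48, nRepeats = 2,
                             config = fastConfig(maxEpochs = 40L), seed = 3)
    expect_equal(tab$meanRp, tab2$meanRp)
})

test_that("MW baseline recovers exact linear laws and degenerates loudly", {
    set.seed(9)
    mkLig <- function(nC, nH, id) ComplexStructure(id, "P", data.frame(
        element = c("C", rep("C", nC), rep("H", nH)),
        x = c(10, rnorm(nC + nH)), y = 0, z = 0,
        role = c("target", rep("ligand", nC + nH))))
    cxs <- lapply(1:8, function(i) mkLig(i + 2, 2 * i, paste0("c", i)))
    mw <- vapply(cxs, molecularWeight, 0)
    aff <- 2 + 0.01 * mw
    model <- fitMwBaseline(cxs, aff)
    expect_equal(model@intercept, 2, tolerance = 1e-9)
    expect_equal(model@slope, 0.01, tolerance = 1e-9)
    expect_equal(predictMwBaseline(model, cxs), aff, tolerance = 1e-9)
    # B = 0: constant predictions at the mean affinity
    flat <- fitMwBaseline(cxs, rep(5, 8) + 0 * mw)
    expect_equal(predictMwBaseline(flat, cxs), rep(5, 8), tolerance = 1e-9)
    # constant MW is rank-deficient
    same <- lapply(1:4, function(i) mkLig(3, 4, paste0("s", i)))
    expect_error(fitMwBaseline(same, 1:4), "rank-deficient")
})

test_that("MW baseline recovers planted coefficients within 3 SE under noise", {
    ok <- 0L
    for (seed in 1:5) {
        fs <- FixtureSpec(nProteins = 1, ligandsPerProtein = 120,
                          affinityModel = "mw_linear",
                          params = list(A = 2, B = 0.01),
                          noiseSd = 0.5, seed = seed)
        db <- generateDatabase(fs)
        model <- fitMwBaseline(db$complexes, db$affinities)
        se <- summary(attr(model, "fit"))$coefficients[, "Std. Error"]
        if (abs(model@intercept - 2) <= 3 * se[1] &&
            abs(model@slope - 0.01) <= 3 * se[2]) ok <- ok + 1L
    }
    expect_gte(ok, 4L)  # 3-SE coverage should hold for nearly all seeds
})
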