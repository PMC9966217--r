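test_that("scheme dimensions follow species-list and interval arithmetic", {
    expect_equal(descriptorDim(FeaturizationScheme(nIntervals = 1)), 60L)
    expect_equal(descriptorDim(FeaturizationScheme()), 240L)
    expect_equal(descriptorDim(FeaturizationScheme(nIntervals = 7)), 420L)
    sch <- FeaturizationScheme(targetSpecies = c("C", "N"),
                               ligandSpecies = c("H", "C", "O"),
                               nIntervals = 5)
    expect_equal(descriptorDim(sch), 2L * 3L * 5L)
    expect_length(channelNames(sch), 30)
    expect_equal(channelNames(sch)[1], "C-H-1")
    expect_error(FeaturizationScheme(targetSpecies = c("C", "C")), "duplicates")
    expect_error(FeaturizationScheme(intervalWidth = 0), "positive")
})

test_that("interval bounds are ((k-1)l, kl) with half-open membership", {
    expect_equal(unname(intervalBounds(1, 2)), c(0, 2))
    expect_equal(unname(intervalBounds(4, 2)), c(6, 8))
    expect_equal(unname(intervalBounds(5, 3)), c(12, 15))
    expect_equal(unname(intervalBounds(2, 1.5)), c(1.5, 3))
    expect_error(intervalBounds(0, 2), "positive integer")
    expect_error(intervalBounds(5, 2, nIntervals = 4), "out of range")
})

test_that("single-pair complexes land in the right channel", {
    sch <- FeaturizationScheme()
    v <- countPairs(twoAtomComplex("C", "O", d = 1), sch)
    expect_equal(sum(v), 1)
    expect_equal(unname(v["C-O-1"]), 1)
    # exactly on an interval edge: belongs to the upper interval
    v2 <- countPairs(twoAtomComplex("C", "O", d = 2), sch)
    expect_equal(unname(v2["C-O-2"]), 1)
    expect_equal(unname(v2["C-O-1"]), 0)
    # beyond the cutoff: not counted
    expect_equal(sum(countPairs(twoAtomComplex("C", "O", d = 8), sch)), 0)
    # out-of-scheme ligand species gives an all-zero vector
    expect_equal(sum(countPairs(twoAtomComplex("C", "CL", d = 1), sch)), 0)
})

test_that("count_pairs matches the brute-force oracle on random complexes", {
    set.seed(11)
    schemes <- list(FeaturizationScheme(),
                    FeaturizationScheme(intervalWidth = 1.5, nIntervals = 6),
                    FeaturizationScheme(intervalWidth = 3, nIntervals = 5))
    for (i in 1:20) {
        cx <- randomComplex(nTarget = sample(5:30, 1), nLigand = sample(3:10, 1),
                            spread = 6, extraElements = c("FE", "ZN"))
        sch <- schemes[[1 + i %% 3]]
        expect_equal(unname(countPairs(cx, sch)),
                     unname(oracleCountPairs(cx, sch)))
    }
    # dense 30x10 case from a fixed geometry
    cx <- randomComplex(30, 10, spread = 4)
    expect_equal(countPairs(cx, FeaturizationScheme()),
                 oracleCountPairs(cx, FeaturizationScheme()),
                 ignore_attr = FALSE)
})

test_that("descriptors are invariant to rigid motion and atom permutation", {
    set.seed(21)
    sch <- FeaturizationScheme()
    for (i in 1:5) {
        cx <- randomComplex(15, 8, spread = 5)
        v <- countPairs(cx, sch)
        moved <- applyRigidMotion(cx, randomRotation(), rnorm(3, sd = 20))
        expect_equal(countPairs(moved, sch), v, tolerance = 1e-12)
        a <- atoms(cx)
        perm <- c(sample(which(a$role == "target")), sample(which(a$role == "ligand")))
        shuffled <- ComplexStructure(complexId(cx), proteinId(cx), a[perm, ])
        expect_equal(countPairs(shuffled, sch), v)
    }
})

test_that("halving the interval width refines bins consistently", {
    set.seed(31)
    fine <- FeaturizationScheme(intervalWidth = 1.5, nIntervals = 2)
    coarse <- FeaturizationScheme(intervalWidth = 3, nIntervals = 1)
    for (i in 1:5) {
        cx <- randomComplex(12, 6, spread = 3)
        vf <- countPairs(cx, fine)
        vc <- countPairs(cx, coarse)
        # summing the two 1.5 A intervals recovers the single 3 A interval
        expect_equal(unname(vf[1:60] + vf[61:120]), unname(vc))
    }
})

test_that("total counts and interval monotonicity behave as conservation laws", {
    set.seed(41)
    for (i in 1:5) {
        cx <- randomComplex(12, 6, spread = 6)
        a <- atoms(cx)
        sch4 <- FeaturizationScheme()
        v4 <- countPairs(cx, sch4)
        # channel total equals the number of in-species pairs closer than the cutoff
        tgt <- a[a$role == "target" & a$element %in% TARGET_SPECIES, ]
        lig <- a[a$role == "ligand" & a$element %in% LIGAND_SPECIES, ]
        d <- sqrt(outer(tgt$x, lig$x, "-")^2 + outer(tgt$y, lig$y, "-")^2 +
                  outer(tgt$z, lig$z, "-")^2)
        expect_equal(sum(v4), sum(d < 8))
        # a larger interval count never changes or decreases retained channels
        v6 <- countPairs(cx, FeaturizationScheme(nIntervals = 6))
        expect_equal(unname(v6[1:240]), unname(v4))
        expect_true(all(v6 >= 0))
    }
})

test_that("featurizeDatabase preserves order and propagates per-complex identity", {
    set.seed(51)
    cxs <- lapply(1:3, function(i) randomComplex(8, 4, id = paste0("c", i),
                                                 pid = paste0("p", i %% 2)))
    ds <- featurizeDatabase(cxs, FeaturizationScheme())
    expect_s4_class(ds, "DescriptorSet")
    expect_equal(dim(ds), c(240L, 3L))
    expect_equal(colnames(ds), c("c1", "c2", "c3"))
    for (i in 1:3)
        expect_equal(unname(SummarizedExperiment::assay(ds)[, i]),
                     unname(countPairs(cxs[[i]], scheme(ds))))
    # identical complexes give identical rows
    same <- lapply(1:3, function(i) {
        cx <- cxs[[1]]
        ComplexStructure(paste0("dup", i), proteinId(cx), atoms(cx))
    })
    ds2 <- featurizeDatabase(same, FeaturizationScheme())
    m <- SummarizedExperiment::assay(ds2)
    expect_equal(m[, 1], m[, 2], ignore_attr = TRUE)
    expect_equal(m[, 1], m[, 3], ignore_attr = TRUE)
    # empty database keeps the channel dimension
    ds0 <- featurizeDatabase(list(), FeaturizationScheme())
    expect_equal(dim(ds0), c(240L, 0L))
    expect_error(featurizeDatabase(c(cxs, cxs[1]), FeaturizationScheme()),
                 "duplicate complexId")
})

test_that("normalization divides by the global maximum and is invertible", {
    m <- matrix(c(0, 2, 4, 1), 2, byrow = TRUE)
    nc <- fitNormalizer(m)
    expect_equal(nc@globalMax, 4)
    expect_equal(applyNormalizer(m, nc), matrix(c(0, 0.5, 1, 0.25), 2, byrow = TRUE))
    expect_equal(fitNormalizer(matrix(7))@globalMax, 7)
    expect_error(fitNormalizer(matrix(0, 2, 2)), "degenerate")
    # round trip: normalize then multiply back
    set.seed(61)
    big <- matrix(rpois(200, 5), 20)
    nc2 <- fitNormalizer(big)
    expect_equal(applyNormalizer(big, nc2) * nc2@globalMax, big)
    # all entries of the fitted matrix land in [0, 1]
    scaled <- applyNormalizer(big, nc2)
    expect_true(all(scaled >= 0 & scaled <= 1))
    # DescriptorSet path refuses scheme mixing and double normalization
    cxs <- lapply(1:2, function(i) randomComplex(8, 4, id = paste0("c", i)))
    ds <- featurizeDatabase(cxs, FeaturizationScheme())
    nds <- applyNormalizer(ds, fitNormalizer(ds))
    expect_true(isNormalized(nds))
    expect_error(applyNormalizer(nds, fitNormalizer(ds)), "already normalized")
    other <- featurizeDatabase(cxs, FeaturizationScheme(nIntervals = 2))
    expect_error(applyNormalizer(other, fitNormalizer(ds)), "different featurization")
})
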