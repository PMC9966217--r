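# Brute-force O(N^2) pair-count oracle: explicit double loop over atom pairs
# and explicit interval-membership checks, independent of the vectorized
# production path.
oracleCountPairs <- function(cx, scheme) {
    a <- atoms(cx)
    counts <- setNames(numeric(descriptorDim(scheme)), channelNames(scheme))
    tgt <- a[a$role == "target", ]
    lig <- a[a$role == "ligand", ]
    for (i in seq_len(nrow(tgt))) {
        if (!tgt$element[i] %in% scheme@targetSpecies) next
        for (j in seq_len(nrow(lig))) {
            if (!lig$element[j] %in% scheme@ligandSpecies) next
            d <- sqrt((tgt$x[i] - lig$x[j])^2 + (tgt$y[i] - lig$y[j])^2 +
                      (tgt$z[i] - lig$z[j])^2)
            for (k in seq_len(scheme@nIntervals)) {
                b <- intervalBounds(k, scheme@intervalWidth)
                if (d >= b[1] && d < b[2]) {
                    nm <- paste(tgt$element[i], lig$element[j], k, sep = "-")
                    counts[nm] <- counts[nm] + 1
                    break
                }
            }
        }
    }
    counts
}

# quick random complex, optionally with out-of-scheme elements mixed in
randomComplex <- function(nTarget = 10, nLigand = 5, id = "c1", pid = "p1",
                          spread = 5, extraElements = character()) {
    tEl <- sample(c(TARGET_SPECIES, extraElements), nTarget, replace = TRUE)
    lEl <- sample(c(LIGAND_SPECIES, extraElements), nLigand, replace = TRUE)
    n <- nTarget + nLigand
    ComplexStructure(id, pid, data.frame(
        element = c(tEl, lEl),
        x = round(runif(n, -spread, spread), 3),
        y = round(runif(n, -spread, spread), 3),
        z = round(runif(n, -spread, spread), 3),
        role = rep(c("target", "ligand"), c(nTarget, nLigand))))
}

# one target atom + one ligand atom at a chosen separation
twoAtomComplex <- function(tEl = "C", lEl = "O", d = 1, id = "c1", pid = "p1") {
    ComplexStructure(id, pid, data.frame(
        element = c(tEl, lEl), x = c(0, d), y = 0, z = 0,
        role = c("target", "ligand")))
}

# uniform random rotation matrix (det +1)
randomRotation <- function() {
    qr.out <- qr(matrix(rnorm(9), 3))
    Q <- qr.Q(qr.out)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
}

applyRigidMotion <- function(cx, R, shift) {
    a <- atoms(cx)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    a$x <- xyz[, 1] + shift[1]
    a$y <- xyz[, 2] + shift[2]
    a$z <- xyz[, 3] + shift[3]
    ComplexStructure(complexId(cx), proteinId(cx), a)
}

# small pre-featurized planted-linear database shared by slower tests
smallLinearDb <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            fs <- FixtureSpec(nProteins = 5, ligandsPerProtein = 70,
                              affinityModel = "pair_linear", noiseSd = 0,
                              seed = 42)
            db <- generateDatabase(fs)
            cache <<- featurizeDatabase(db$complexes, FeaturizationScheme(),
                                        db$affinities)
        }
        cache
    }
})

fastConfig <- function(maxEpochs = 60L, patience = 10L, ...)
    TrainConfig(batchSize = 50L, maxEpochs = maxEpochs, patience = patience, ...)
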