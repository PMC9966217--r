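#' @include fcnn.R splits.R
NULL

#' @describeIn EvalResult-class per-repeat score table.
#' @param x an \code{EvalResult}.
#' @export
setMethod("repeatScores", "EvalResult", function(x) x@scores)

setMethod("show", "EvalResult", function(object) {
    cat(sprintf("EvalResult (%s), %d repeat(s), N_t = %d:\n",
                object@kind, nrow(object@scores), object@nTrain))
    cat(sprintf("  Rp  = %.4f +/- %s\n", object@meanRp,
                if (is.na(object@semRp)) "NA" else sprintf("%.4f", object@semRp)))
    cat(sprintf("  MSE = %.4f +/- %s\n", object@meanMse,
                if (is.na(object@semMse)) "NA" else sprintf("%.4f", object@semMse)))
})

.respec <- function(spec, inputDim = spec@inputDim, seed = spec@seed) {
    NetworkSpec(spec@nHiddenLayers, spec@nHiddenUnits, inputDim,
                spec@l2Lambda, seed)
}

# master-seed scheme: one run seed deterministically spawns per-repeat seeds,
# so any single repeat can be re-run in isolation
.spawnSeeds <- function(seed, n) {
    set.seed(seed)
    sample.int(2^30, n)
}

#' Evaluate a scoring function over a list of split plans
#'
#' Trains one fresh model per plan and scores its test set: Pearson Rp and
#' MSE on the original affinity scale. Aggregates mean and SEM (sample SD
#' of the repeats / sqrt(number of repeats); NA for a single repeat).
#'
#' @param ds raw-count \linkS4class{DescriptorSet} with affinities.
#' @param plans list of \linkS4class{SplitPlan}.
#' @param networkSpec \linkS4class{NetworkSpec} template (seed is replaced
#'   per repeat); default 2x20 on the set's dimension.
#' @param config a \linkS4class{TrainConfig}.
#' @param mode \code{"clean"} or \code{"legacy"}; see [trainScoringFunction()].
#' @param seeds integer per-repeat seeds (default derived from \code{seed}).
#' @param seed master seed used when \code{seeds} is NULL.
#' @return An \linkS4class{EvalResult}.
#' @export
evaluateSplits <- function(ds, plans, networkSpec = NULL,
                           config = TrainConfig(), mode = c("clean", "legacy"),
                           seeds = NULL, seed = 1L) {
    mode <- match.arg(mode)
    if (is.null(networkSpec)) networkSpec <- NetworkSpec(inputDim = nrow(ds))
    if (is.null(seeds)) seeds <- .spawnSeeds(seed, length(plans))
    stopifnot(length(seeds) == length(plans))
    rows <- vector("list", length(plans))
    failures <- character()
    for (r in seq_along(plans)) {
        plan <- plans[[r]]
        res <- tryCatch({
            model <- trainScoringFunction(
                ds, trainIds = trainIds(plan),
                networkSpec = .respec(networkSpec, nrow(ds), seeds[r]),
                config = config, mode = mode, testIds = testIds(plan),
                seed = seeds[r])
            pred <- predictAffinity(model, ds[, testIds(plan)])
            obs <- .affinityOf(ds, testIds(plan))
            data.frame(repeat_ = r, seed = seeds[r],
                       rp = pearsonR(pred, obs), mse = mseValues(pred, obs),
                       nTrain = length(trainIds(plan)),
                       nTest = length(testIds(plan)))
        }, error = function(e) e)
        if (inherits(res, "error"))
            failures <- c(failures, sprintf("repeat %d: %s", r, conditionMessage(res)))
        else rows[[r]] <- res
    }
    if (length(failures))
        stop("evaluation failed for ", length(failures), " repeat(s):\n  ",
             paste(failures, collapse = "\n  "))
    EvalResult(splitKind(plans[[1L]]), do.call(rbind, rows))
}

#' Repeat-averaged evaluation under a benchmark protocol
#'
#' Builds a fresh split per repeat under the requested protocol, trains a
#' fresh network on each, and aggregates test Rp and MSE. Horizontal
#' repeats use pairwise-disjoint test sets whenever
#' \code{nRepeats * nTest} fits in the database.
#'
#' @inheritParams evaluateSplits
#' @param protocol \code{"horizontal"}, \code{"vertical"} or
#'   \code{"per_target"}.
#' @param nRepeats number of train/test repetitions (default 10).
#' @param nTest,testFraction test-set size (horizontal / per-target).
#' @param heldOutProteins vertical protocol: proteins whose complexes form
#'   the test set.
#' @param targetProtein per-target protocol: the single protein used.
#' @param nTrain optional training-set size (subsampled fresh per repeat).
#' @param seed master seed spawning per-repeat seeds.
#' @return An \linkS4class{EvalResult}.
#' @export
evaluateProtocol <- function(ds,
                             protocol = c("horizontal", "vertical", "per_target"),
                             nRepeats = 10L, nTest = NULL, testFraction = NULL,
                             heldOutProteins = NULL, targetProtein = NULL,
                             nTrain = NULL, networkSpec = NULL,
                             config = TrainConfig(), mode = c("clean", "legacy"),
                             seed = 1L) {
    protocol <- match.arg(protocol)
    mode <- match.arg(mode)
    seeds <- .spawnSeeds(seed, nRepeats)
    n <- ncol(ds)
    plans <- switch(protocol,
        horizontal = {
            nt <- .resolveNTest(n, nTest, testFraction)
            base <- if (nRepeats * nt <= n)
                horizontalSplits(ds, nt, nRepeats, seed = seeds[1L])
            else
                lapply(seeds, function(s) horizontalSplit(ds, nTest = nt, seed = s))
            if (!is.null(nTrain)) {
                base <- lapply(seq_along(base), function(r) {
                    set.seed(seeds[r])
                    SplitPlan("horizontal",
                              sample(trainIds(base[[r]]), nTrain),
                              testIds(base[[r]]), seed = seeds[r])
                })
            }
            base
        },
        vertical = {
            if (is.null(heldOutProteins)) stop("vertical protocol needs heldOutProteins")
            lapply(seeds, function(s)
                verticalSplit(ds, heldOutProteins, nTrain = nTrain, seed = s))
        },
        per_target = {
            if (is.null(targetProtein)) stop("per_target protocol needs targetProtein")
            if (is.null(nTest)) stop("per_target protocol needs nTest")
            lapply(seeds, function(s) {
                plan <- perTargetSplit(ds, targetProtein, nTest, seed = s)
                if (!is.null(nTrain)) {
                    set.seed(s)
                    plan <- SplitPlan("per_target",
                                      sample(trainIds(plan), nTrain),
                                      testIds(plan),
                                      targetProtein = targetProtein, seed = s)
                }
                plan
            })
        })
    evaluateSplits(ds, plans, networkSpec, config, mode, seeds = seeds)
}

#' Leave-one-target-out evaluation
#'
#' Trains one scoring function per protein on everything except that
#' protein's complexes and tests on them. Returns the per-protein scores
#' and their average.
#'
#' @inheritParams evaluateSplits
#' @return list with \code{perTarget} (data.frame: proteinId, rp, mse,
#'   nTrain, nTest) and \code{meanRp}, \code{meanMse} (unweighted averages
#'   over proteins).
#' @export
evaluateLeaveOneTargetOut <- function(ds, networkSpec = NULL,
                                      config = TrainConfig(),
                                      mode = c("clean", "legacy"), seed = 1L) {
    mode <- match.arg(mode)
    plans <- leaveOneTargetOut(ds)
    seeds <- .spawnSeeds(seed, length(plans))
    rows <- lapply(seq_along(plans), function(i) {
        res <- evaluateSplits(ds, plans[i], networkSpec, config, mode,
                              seeds = seeds[i])
        sc <- repeatScores(res)
        data.frame(proteinId = names(plans)[i], rp = sc$rp, mse = sc$mse,
                   nTrain = sc$nTrain, nTest = sc$nTest)
    })
    perTarget <- do.call(rbind, rows)
    list(perTarget = perTarget,
         meanRp = mean(perTarget$rp), meanMse = mean(perTarget$mse))
}

#' Learning curve: performance as a function of training-set size
#'
#' For each requested size the training side is subsampled fresh per repeat
#' and the protocol evaluated; reports the mean and SEM of Rp and MSE per
#' size, plus the percentage of the database used for training.
#'
#' @inheritParams evaluateProtocol
#' @param ntGrid increasing vector of training-set sizes.
#' @return data.frame with one row per size: \code{nTrain}, \code{pctTrain},
#'   \code{meanRp}, \code{semRp}, \code{meanMse}, \code{semMse}; the
#'   underlying \linkS4class{EvalResult}s in attribute \code{"results"}.
#' @export
learningCurve <- function(ds, ntGrid,
                          protocol = c("horizontal", "vertical", "per_target"),
                          nRepeats = 10L, nTest = NULL, testFraction = NULL,
                          heldOutProteins = NULL, targetProtein = NULL,
                          networkSpec = NULL, config = TrainConfig(),
                          mode = c("clean", "legacy"), seed = 1L) {
    protocol <- match.arg(protocol)
    mode <- match.arg(mode)
    results <- lapply(seq_along(ntGrid), function(i)
        evaluateProtocol(ds, protocol, nRepeats = nRepeats, nTest = nTest,
                         testFraction = testFraction,
                         heldOutProteins = heldOutProteins,
                         targetProtein = targetProtein, nTrain = ntGrid[i],
                         networkSpec = networkSpec, config = config,
                         mode = mode, seed = seed + i - 1L))
    out <- data.frame(
        nTrain = as.integer(ntGrid),
        pctTrain = 100 * ntGrid / ncol(ds),
        meanRp = vapply(results, function(r) r@meanRp, 0),
        semRp = vapply(results, function(r) r@semRp, 0),
        meanMse = vapply(results, function(r) r@meanMse, 0),
        semMse = vapply(results, function(r) r@semMse, 0))
    attr(out, "results") <- results
    out
}

#' Scan featurization schemes (interval width x interval count)
#'
#' Re-featurizes the database for every (width, nIntervals) combination,
#' evaluates each horizontally and tabulates the mean Rp against the
#' descriptor count, flagging the best-scoring combination. The default
#' grid spans interval counts up to 6, 7 and 5 for widths 1.5, 2 and 3
#' Angstrom (18 combinations).
#'
#' @param complexes list of \linkS4class{ComplexStructure}.
#' @param affinities affinity table as in [featurizeDatabase()].
#' @param widths interval widths (Angstrom) to scan.
#' @param maxIntervals same length as \code{widths}: largest interval count
#'   per width (each scanned from 1).
#' @inheritParams evaluateProtocol
#' @param nTest horizontal test-set size per evaluation.
#' @param networkTemplate \linkS4class{NetworkSpec} template; inputDim is
#'   replaced per combination.
#' @return data.frame: width, nIntervals, nDescriptors, meanRp, semRp, best.
#' @export
scanDescriptors <- function(complexes, affinities,
                            widths = c(1.5, 2, 3),
                            maxIntervals = c(6L, 7L, 5L),
                            nTest, nRepeats = 10L,
                            networkTemplate = NetworkSpec(),
                            config = TrainConfig(),
                            mode = c("clean", "legacy"), seed = 1L) {
    stopifnot(length(widths) == length(maxIntervals))
    mode <- match.arg(mode)
    grid <- do.call(rbind, lapply(seq_along(widths), function(i)
        data.frame(width = widths[i], nIntervals = seq_len(maxIntervals[i]))))
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        sch <- FeaturizationScheme(intervalWidth = grid$width[i],
                                   nIntervals = grid$nIntervals[i])
        ds <- featurizeDatabase(complexes, sch, affinities)
        res <- evaluateProtocol(ds, "horizontal", nRepeats = nRepeats,
                                nTest = nTest,
                                networkSpec = .respec(networkTemplate, nrow(ds)),
                                config = config, mode = mode, seed = seed)
        data.frame(width = grid$width[i], nIntervals = grid$nIntervals[i],
                   nDescriptors = descriptorDim(sch),
                   meanRp = res@meanRp, semRp = res@semRp)
    })
    out <- do.call(rbind, rows)
    out$best <- seq_len(nrow(out)) == which.max(out$meanRp)
    out
}

#' Scan network architectures
#'
#' Evaluates a grid of (hidden layers x hidden units) architectures under
#' the horizontal protocol on a fixed descriptor set.
#'
#' @inheritParams evaluateProtocol
#' @param nTest horizontal test-set size per evaluation.
#' @param architectures list of \code{c(nHiddenLayers, nHiddenUnits)} pairs,
#'   e.g. \code{list(c(2, 20), c(3, 20), c(4, 40))}.
#' @return data.frame: label, nHiddenLayers, nHiddenUnits, meanRp, semRp, best.
#' @export
scanArchitecture <- function(ds, architectures = list(c(2L, 20L), c(3L, 20L), c(4L, 40L)),
                             nTest, nRepeats = 10L, nTrain = NULL,
                             config = TrainConfig(),
                             mode = c("clean", "legacy"), seed = 1L) {
    mode <- match.arg(mode)
    rows <- lapply(architectures, function(a) {
        spec <- NetworkSpec(a[1], a[2], inputDim = nrow(ds))
        res <- evaluateProtocol(ds, "horizontal", nRepeats = nRepeats,
                                nTest = nTest, nTrain = nTrain,
                                networkSpec = spec, config = config,
                                mode = mode, seed = seed)
        data.frame(label = sprintf("%dx%d", a[1], a[2]),
                   nHiddenLayers = a[1], nHiddenUnits = a[2],
                   meanRp = res@meanRp, semRp = res@semRp)
    })
    out <- do.call(rbind, rows)
    out$best <- seq_len(nrow(out)) == which.max(out$meanRp)
    out
}
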