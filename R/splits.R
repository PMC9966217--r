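#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn SplitPlan-class training-side complex ids.
#' @param x a \code{SplitPlan}.
#' @export
setMethod("trainIds", "SplitPlan", function(x) x@trainIds)

#' @describeIn SplitPlan-class test-side complex ids.
#' @export
setMethod("testIds", "SplitPlan", function(x) x@testIds)

#' @describeIn SplitPlan-class split kind.
#' @export
setMethod("splitKind", "SplitPlan", function(x) x@kind)

setMethod("show", "SplitPlan", function(object) {
    cat(sprintf("SplitPlan (%s): %d train / %d test complexes\n", object@kind,
                length(object@trainIds), length(object@testIds)))
    if (length(object@heldOutProteins))
        cat("  held-out proteins:", paste(object@heldOutProteins, collapse = ", "), "\n")
    if (!is.na(object@targetProtein))
        cat("  target protein:", object@targetProtein, "\n")
})

# A "database" for split purposes is anything that yields complex ids and
# their protein ids: a DescriptorSet, or a data.frame with columns
# complexId and proteinId (so split bookkeeping works from a bare manifest).
.splitTable <- function(db) {
    if (is(db, "DescriptorSet"))
        return(data.frame(
            complexId = colnames(db),
            proteinId = SummarizedExperiment::colData(db)$proteinId,
            stringsAsFactors = FALSE))
    if (is.data.frame(db)) {
        names(db)[names(db) == "complex_id"] <- "complexId"
        names(db)[names(db) == "protein_id"] <- "proteinId"
        if (!all(c("complexId", "proteinId") %in% names(db)))
            stop("database data.frame needs complexId and proteinId columns")
        return(db[, c("complexId", "proteinId")])
    }
    stop("unsupported database representation")
}

.resolveNTest <- function(n, nTest, testFraction) {
    if (!is.null(nTest)) return(as.integer(nTest))  # nTest wins when both given
    if (is.null(testFraction)) stop("supply nTest or testFraction")
    as.integer(round(n * testFraction))
}

#' Horizontal (random) train/test split
#'
#' Uniform random test selection without replacement. A protein may occur
#' on both sides, bound to different ligands -- that is what makes the split
#' horizontal and, for universal scoring functions, optimistic.
#'
#' @param db a \linkS4class{DescriptorSet} or a data.frame with
#'   \code{complexId} and \code{proteinId} columns.
#' @param nTest test-set size; takes precedence over \code{testFraction}.
#' @param testFraction fraction of the database used for testing (rounded
#'   to the nearest integer count).
#' @param seed RNG seed; a fixed seed gives a reproducible plan.
#' @return A \linkS4class{SplitPlan}.
#' @export
horizontalSplit <- function(db, nTest = NULL, testFraction = NULL, seed = 1L) {
    tab <- .splitTable(db)
    n <- nrow(tab)
    nTest <- .resolveNTest(n, nTest, testFraction)
    if (nTest < 1L || nTest >= n)
        stop(sprintf("nTest (%d) must be in [1, %d)", nTest, n))
    set.seed(seed)
    test <- sample(tab$complexId, nTest)
    SplitPlan("horizontal", setdiff(tab$complexId, test), test, seed = seed)
}

#' Repeated horizontal splits with pairwise-disjoint test sets
#'
#' When \code{nRepeats * nTest} fits in the database, the repeat test sets
#' are drawn as a partition of one big sample, so they are pairwise
#' disjoint ("non-overlapping splittings"). Otherwise independent random
#' splits are drawn, with a warning.
#'
#' @inheritParams horizontalSplit
#' @param nRepeats number of repeats (default 10).
#' @return list of \linkS4class{SplitPlan}.
#' @export
horizontalSplits <- function(db, nTest, nRepeats = 10L, seed = 1L) {
    tab <- .splitTable(db)
    n <- nrow(tab)
    if (nTest >= n) stop("nTest must be smaller than the database")
    if (nRepeats * nTest <= n) {
        set.seed(seed)
        pool <- sample(tab$complexId, nRepeats * nTest)
        lapply(seq_len(nRepeats), function(r) {
            test <- pool[((r - 1L) * nTest + 1L):(r * nTest)]
            SplitPlan("horizontal", setdiff(tab$complexId, test), test,
                      seed = seed)
        })
    } else {
        warning("database too small for disjoint test sets; drawing independent splits")
        lapply(seq_len(nRepeats), function(r)
            horizontalSplit(db, nTest = nTest, seed = seed + r - 1L))
    }
}

#' Vertical split: hold out whole proteins
#'
#' The test set is every complex of the held-out proteins; no complex of a
#' test protein appears in training. This is the stringent generalization
#' benchmark for a universal scoring function.
#'
#' @inheritParams horizontalSplit
#' @param heldOutProteins protein ids defining the test set.
#' @param nTrain optionally subsample the training side to this size
#'   (for learning curves); NULL keeps all remaining complexes.
#' @return A \linkS4class{SplitPlan}.
#' @export
verticalSplit <- function(db, heldOutProteins, nTrain = NULL, seed = 1L) {
    tab <- .splitTable(db)
    heldOutProteins <- as.character(heldOutProteins)
    if (!length(heldOutProteins)) stop("heldOutProteins must be non-empty")
    unknown <- setdiff(heldOutProteins, tab$proteinId)
    if (length(unknown))
        stop("unknown protein id(s): ", paste(unknown, collapse = ", "))
    isTest <- tab$proteinId %in% heldOutProteins
    train <- tab$complexId[!isTest]
    if (!length(train))
        stop("no proteins left for training after the hold-out")
    if (!is.null(nTrain)) {
        if (nTrain > length(train))
            stop(sprintf("nTrain (%d) exceeds the available train pool (%d)",
                         nTrain, length(train)))
        set.seed(seed)
        train <- sample(train, nTrain)
    }
    SplitPlan("vertical", train, tab$complexId[isTest],
              heldOutProteins = heldOutProteins, seed = seed)
}

#' Leave-one-target-out plans
#'
#' One vertical plan per protein: its complexes form the whole test set and
#' everything else trains. Across plans the test sets partition the
#' database.
#'
#' @inheritParams horizontalSplit
#' @return named list of \linkS4class{SplitPlan}, one per protein.
#' @export
leaveOneTargetOut <- function(db) {
    tab <- .splitTable(db)
    prots <- unique(tab$proteinId)
    if (length(prots) < 2L)
        stop("leave-one-target-out needs at least two proteins")
    plans <- lapply(prots, function(p) verticalSplit(db, p))
    names(plans) <- prots
    plans
}

#' Per-target split
#'
#' Restricts the database to one protein's complexes and splits those
#' horizontally; both sides contain only the target protein.
#'
#' @inheritParams horizontalSplit
#' @param targetProtein the single protein id.
#' @return A \linkS4class{SplitPlan}.
#' @export
perTargetSplit <- function(db, targetProtein, nTest, seed = 1L) {
    tab <- .splitTable(db)
    own <- tab$complexId[tab$proteinId == targetProtein]
    if (!length(own)) stop("unknown protein id: ", targetProtein)
    if (length(own) <= nTest)
        stop(sprintf("target '%s' has only %d complexes, not enough for nTest = %d",
                     targetProtein, length(own), nTest))
    set.seed(seed)
    test <- sample(own, nTest)
    SplitPlan("per_target", setdiff(own, test), test,
              targetProtein = targetProtein, seed = seed)
}
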