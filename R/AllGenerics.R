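#' @include AllClasses.R
NULL

#' S4 generics used across the package
#'
#' Accessor and computation generics whose methods are documented on the
#' corresponding class pages: \linkS4class{FeaturizationScheme},
#' \linkS4class{ComplexStructure}, \linkS4class{DescriptorSet},
#' \linkS4class{SplitPlan}, \linkS4class{EvalResult} and
#' \linkS4class{TrainedModel}.
#'
#' @param x,object the object to query or act on.
#' @param scheme a \linkS4class{FeaturizationScheme}.
#' @param newdata complexes or descriptors to score.
#' @param ... passed on to methods.
#' @name pairscore-generics
#' @rdname pairscore-generics
NULL

#' @rdname pairscore-generics
#' @export
setGeneric("descriptorDim", function(x) standardGeneric("descriptorDim"))

#' @rdname pairscore-generics
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname pairscore-generics
#' @export
setGeneric("countPairs", function(x, scheme) standardGeneric("countPairs"))

#' @rdname pairscore-generics
#' @export
setGeneric("complexId", function(x) standardGeneric("complexId"))

#' @rdname pairscore-generics
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname pairscore-generics
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname pairscore-generics
#' @export
setGeneric("speciesFilterReport", function(x, scheme) standardGeneric("speciesFilterReport"))

#' @rdname pairscore-generics
#' @export
setGeneric("molecularWeight", function(x) standardGeneric("molecularWeight"))

#' @rdname pairscore-generics
#' @export
setGeneric("predictAffinity", function(object, newdata, ...) standardGeneric("predictAffinity"))

#' @rdname pairscore-generics
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))

#' @rdname pairscore-generics
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))

#' @rdname pairscore-generics
#' @export
setGeneric("splitKind", function(x) standardGeneric("splitKind"))

#' @rdname pairscore-generics
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname pairscore-generics
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @rdname pairscore-generics
#' @export
setGeneric("repeatScores", function(x) standardGeneric("repeatScores"))

#' @rdname pairscore-generics
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
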