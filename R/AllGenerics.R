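#' @include AllClasses.R
NULL

#' Accessors for the package's S4 containers
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param object One of the package's S4 objects.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackCoverage", function(object) standardGeneric("trackCoverage"))
#' @rdname accessors
#' @export
setMethod("trackCoverage", "CoverageTrack", function(object) object@coverage)

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(object) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setMethod("chromLengths", "CoverageTrack",
          function(object) vapply(object@coverage, length, 0L))

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setMethod("signalMatrix", "PromoterSignalMatrix", function(object) object@signal)

#' @rdname accessors
#' @export
setGeneric("signalRepresentation", function(object) standardGeneric("signalRepresentation"))
#' @rdname accessors
#' @export
setMethod("signalRepresentation", "PromoterSignalMatrix",
          function(object) object@representation)

#' @rdname accessors
#' @export
setGeneric("conditionOf", function(object) standardGeneric("conditionOf"))
#' @rdname accessors
#' @export
setMethod("conditionOf", "PromoterSignalMatrix", function(object) object@condition)

#' @rdname accessors
#' @export
setGeneric("countsMatrix", function(object) standardGeneric("countsMatrix"))
#' @rdname accessors
#' @export
setMethod("countsMatrix", "ExpressionTable", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("geneLengths", function(object) standardGeneric("geneLengths"))
#' @rdname accessors
#' @export
setMethod("geneLengths", "ExpressionTable", function(object) object@geneLengths)

#' @rdname accessors
#' @export
setGeneric("fpkm", function(object) standardGeneric("fpkm"))
#' @rdname accessors
#' @export
setMethod("fpkm", "ExpressionTable", function(object) {
  if (nrow(object@fpkm) == 0)
    stop("FPKM not computed yet; run computeFpkm() first")
  object@fpkm
})

#' @rdname accessors
#' @export
setGeneric("modelTerms", function(object) standardGeneric("modelTerms"))
#' @rdname accessors
#' @export
setMethod("modelTerms", "MarsModel", function(object) object@terms)

#' @rdname accessors
#' @export
setGeneric("selectedTfs", function(object) standardGeneric("selectedTfs"))
#' @rdname accessors
#' @export
setMethod("selectedTfs", "MarsModel", function(object) object@selectedTfs)

#' @rdname accessors
#' @export
setGeneric("modelGcv", function(object) standardGeneric("modelGcv"))
#' @rdname accessors
#' @export
setMethod("modelGcv", "MarsModel", function(object) object@gcv)

#' @rdname accessors
#' @export
setGeneric("modelR2", function(object) standardGeneric("modelR2"))
#' @rdname accessors
#' @export
setMethod("modelR2", "MarsModel", function(object) object@r2)

#' @rdname accessors
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setMethod("assignments", "ClusterModel", function(object) object@assignments)

#' @rdname accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setMethod("centroids", "ClusterModel", function(object) object@centroids)

#' @rdname accessors
#' @export
setGeneric("bicCurve", function(object) standardGeneric("bicCurve"))
#' @rdname accessors
#' @export
setMethod("bicCurve", "ClusterModel", function(object) object@bicCurve)

#' @rdname accessors
#' @export
setGeneric("bundleTruth", function(object) standardGeneric("bundleTruth"))
#' @rdname accessors
#' @export
setMethod("bundleTruth", "SyntheticBundle", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("bundleBinding", function(object) standardGeneric("bundleBinding"))
#' @rdname accessors
#' @export
setMethod("bundleBinding", "SyntheticBundle", function(object) object@binding)

#' @rdname accessors
#' @export
setGeneric("bundleExpression", function(object) standardGeneric("bundleExpression"))
#' @rdname accessors
#' @export
setMethod("bundleExpression", "SyntheticBundle", function(object) object@expression)

#' @rdname accessors
#' @export
setGeneric("bundleTracks", function(object) standardGeneric("bundleTracks"))
#' @rdname accessors
#' @export
setMethod("bundleTracks", "SyntheticBundle", function(object) object@tracks)

#' @rdname accessors
#' @export
setGeneric("bundleTss", function(object) standardGeneric("bundleTss"))
#' @rdname accessors
#' @export
setMethod("bundleTss", "SyntheticBundle", function(object) object@tss)
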