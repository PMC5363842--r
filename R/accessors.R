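# Accessor generics and methods; slots are never reached into directly by
# user code.

#' @rdname KzfpClusters-class
#' @param x A `KzfpClusters` object.
#' @export
setGeneric("clusterSpans", function(x) standardGeneric("clusterSpans"))

#' @rdname KzfpClusters-class
#' @export
setMethod("clusterSpans", "KzfpClusters", function(x) x@clusters)

#' @rdname KzfpClusters-class
#' @export
setGeneric("clusterElements", function(x) standardGeneric("clusterElements"))

#' @rdname KzfpClusters-class
#' @export
setMethod("clusterElements", "KzfpClusters", function(x) x@elements)

#' @rdname KzfpClusters-class
#' @export
setGeneric("isolatedElements", function(x) standardGeneric("isolatedElements"))

#' @rdname KzfpClusters-class
#' @export
setMethod("isolatedElements", "KzfpClusters", function(x) {
  x@elements[is.na(x@elements$cluster_id)]
})

#' @rdname ShuffleResult-class
#' @param x A `ShuffleResult` object.
#' @export
setGeneric("observedCount", function(x) standardGeneric("observedCount"))

#' @rdname ShuffleResult-class
#' @export
setMethod("observedCount", "ShuffleResult", function(x) x@observed)

#' @rdname ShuffleResult-class
#' @export
setGeneric("nullCounts", function(x) standardGeneric("nullCounts"))

#' @rdname ShuffleResult-class
#' @export
setMethod("nullCounts", "ShuffleResult", function(x) x@nullCounts)

#' @rdname ShuffleResult-class
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))

#' @rdname ShuffleResult-class
#' @export
setMethod("empiricalP", "ShuffleResult", function(x) x@empiricalP)

#' @rdname ShuffleResult-class
#' @export
setGeneric("expectedCount", function(x) standardGeneric("expectedCount"))

#' @rdname ShuffleResult-class
#' @export
setMethod("expectedCount", "ShuffleResult", function(x) x@expected)

#' Coerce a MetaProfile to a data.frame
#'
#' @param x A `MetaProfile` object.
#' @param ... Unused.
#' @return A data.frame with columns `grid`, `mean`, `ci_low`, `ci_high`.
#' @export
setMethod("as.data.frame", "MetaProfile", function(x, ...) {
  data.frame(grid = x@grid, mean = x@mean,
             ci_low = x@ciLow, ci_high = x@ciHigh)
})

#' Coerce a CorrelationProfile to a data.frame
#'
#' @param x A `CorrelationProfile` object.
#' @param ... Unused.
#' @return A data.frame with columns `offset` (bin center) and `count`.
#' @export
setMethod("as.data.frame", "CorrelationProfile", function(x, ...) {
  data.frame(offset = x@offsets, count = x@counts)
})

#' @rdname MetaProfile-class
#' @param x A `MetaProfile` object.
#' @export
setGeneric("profileMean", function(x) standardGeneric("profileMean"))

#' @rdname MetaProfile-class
#' @export
setMethod("profileMean", "MetaProfile", function(x) x@mean)

#' @rdname MetaProfile-class
#' @export
setGeneric("profileCi", function(x) standardGeneric("profileCi"))

#' @rdname MetaProfile-class
#' @export
setMethod("profileCi", "MetaProfile", function(x) {
  cbind(low = x@ciLow, high = x@ciHigh)
})

#' @rdname SegmentMatrix-class
#' @param x A `SegmentMatrix` object.
#' @export
setGeneric("segmentPresence", function(x) standardGeneric("segmentPresence"))

#' @rdname SegmentMatrix-class
#' @export
setMethod("segmentPresence", "SegmentMatrix", function(x) x@present)

#' @rdname SegmentMatrix-class
#' @export
setGeneric("segmentMismatches", function(x) standardGeneric("segmentMismatches"))

#' @rdname SegmentMatrix-class
#' @export
setMethod("segmentMismatches", "SegmentMatrix", function(x) x@mismatches)

#' @rdname CoverageTrack-class
#' @param x A `CoverageTrack` object.
#' @export
setGeneric("coverageRle", function(x) standardGeneric("coverageRle"))

#' @rdname CoverageTrack-class
#' @export
setMethod("coverageRle", "CoverageTrack", function(x) x@track)

#' @rdname CoverageTrack-class
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname CoverageTrack-class
#' @export
setMethod("librarySize", "CoverageTrack", function(x) x@librarySize)
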