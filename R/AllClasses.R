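#' @import methods
#' @import stats
#' @import utils
#' @importClassesFrom IRanges SimpleRleList
#' @importClassesFrom GenomicRanges GRanges
NULL

#' KzfpClusters: single-linkage clusters of repeat-anchored units
#'
#' Container returned by [buildClusters()]. Holds the input elements with
#' their cluster assignment (`cluster_id` metadata column, `NA` for isolated
#' elements) and one span per cluster running from the first member's start
#' to the last member's end.
#'
#' @slot elements A [GenomicRanges::GRanges] of the clustered elements with
#'   metadata column `cluster_id` (integer, `NA` = isolated).
#' @slot clusters A [GenomicRanges::GRanges] of cluster spans with metadata
#'   columns `cluster_id`, `n_members` and `members` (comma-separated names).
#' @slot maxGap Maximum permitted inter-element gap in bp.
#' @slot minSize Minimum number of chained elements forming a cluster.
#'
#' @seealso [buildClusters()], [clusterSpans()], [isolatedElements()]
#' @export
setClass("KzfpClusters",
  representation(
    elements = "GRanges",
    clusters = "GRanges",
    maxGap = "numeric",
    minSize = "integer"
  )
)

setValidity("KzfpClusters", function(object) {
  cl <- object@clusters
  el <- object@elements
  msgs <- character()
  if (length(cl)) {
    if (is.null(cl$cluster_id) || is.null(cl$n_members)) {
      msgs <- c(msgs, "cluster spans need 'cluster_id' and 'n_members' columns")
    } else if (any(cl$n_members < object@minSize)) {
      msgs <- c(msgs, "every cluster must have at least 'minSize' members")
    }
  }
  if (length(el) && is.null(el$cluster_id)) {
    msgs <- c(msgs, "elements need a 'cluster_id' column (NA for isolated)")
  }
  if (length(msgs)) msgs else TRUE
})

#' CorrelationProfile: positional-correlation histogram
#'
#' Histogram of signed offsets between anchor points and feature points,
#' accumulated over all anchors within a symmetric window; produced by
#' [positionalCorrelation()].
#'
#' @slot offsets Numeric bin centers (bp), symmetric around zero.
#' @slot counts Integer feature counts per bin.
#' @slot nAnchors Number of anchors contributing.
#' @slot halfWindow Half-window size in bp.
#' @slot binWidth Bin width in bp.
#' @export
setClass("CorrelationProfile",
  representation(
    offsets = "numeric",
    counts = "integer",
    nAnchors = "integer",
    halfWindow = "numeric",
    binWidth = "numeric"
  )
)

setValidity("CorrelationProfile", function(object) {
  if (length(object@offsets) != length(object@counts)) {
    return("offsets and counts must have equal length")
  }
  if (any(object@counts < 0L)) return("counts must be non-negative")
  TRUE
})

#' ShuffleResult: observed-vs-permutation-null enrichment summary
#'
#' Result of [shuffleEnrichment()]: an observed overlap count, the null
#' counts from within-chromosome shuffles, and the add-one empirical p-value
#' \eqn{(1 + \#\{null \ge obs\}) / (n_{shuffles} + 1)}.
#'
#' @slot observed Observed overlap count.
#' @slot nullCounts Integer vector of null counts, one per shuffle.
#' @slot expected Mean of the null counts.
#' @slot empiricalP Add-one empirical p-value in (0, 1].
#' @slot nShuffles Number of shuffles performed.
#' @slot seed Seed used (NA if none supplied).
#' @export
setClass("ShuffleResult",
  representation(
    observed = "integer",
    nullCounts = "integer",
    expected = "numeric",
    empiricalP = "numeric",
    nShuffles = "integer",
    seed = "integer"
  )
)

setValidity("ShuffleResult", function(object) {
  msgs <- character()
  if (length(object@nullCounts) != object@nShuffles) {
    msgs <- c(msgs, "nullCounts length must equal nShuffles")
  }
  p <- object@empiricalP
  if (p <= 0 || p > 1) msgs <- c(msgs, "empiricalP must lie in (0, 1]")
  expect <- (1 + sum(object@nullCounts >= object@observed)) /
    (object@nShuffles + 1)
  if (abs(p - expect) > 1e-12) {
    msgs <- c(msgs, "empiricalP must equal (1 + #{null >= obs}) / (n + 1)")
  }
  if (length(msgs)) msgs else TRUE
})

#' MetaProfile: aggregate strand-oriented signal profile
#'
#' Average coverage over anchored, strand-oriented windows spanning a fixed
#' upstream flank, a length-normalised element body, and a fixed downstream
#' flank; produced by [metaprofile()].
#'
#' @slot grid Monotone grid coordinates: negative bp upstream of the 5' end,
#'   body bin centers mapped onto a nominal 1 kb body, and positive bp
#'   downstream of the 3' end offset by the nominal body length.
#' @slot mean Per-position mean signal across elements.
#' @slot ciLow,ciHigh 95\% confidence band (normal approximation).
#' @slot nElements Number of elements aggregated.
#' @slot flankUp,flankDown Flank sizes in bp.
#' @slot bodyBins Number of body bins.
#' @export
setClass("MetaProfile",
  representation(
    grid = "numeric",
    mean = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    nElements = "integer",
    flankUp = "numeric",
    flankDown = "numeric",
    bodyBins = "integer"
  )
)

setValidity("MetaProfile", function(object) {
  msgs <- character()
  n <- length(object@grid)
  if (length(object@mean) != n || length(object@ciLow) != n ||
      length(object@ciHigh) != n) {
    msgs <- c(msgs, "grid, mean, ciLow, ciHigh must have equal length")
  }
  if (is.unsorted(object@grid, strictly = TRUE)) {
    msgs <- c(msgs, "grid must be strictly increasing")
  }
  ok <- !is.na(object@mean)
  if (any(object@ciLow[ok] > object@mean[ok] + 1e-9) ||
      any(object@ciHigh[ok] < object@mean[ok] - 1e-9)) {
    msgs <- c(msgs, "confidence band must bracket the mean pointwise")
  }
  if (length(msgs)) msgs else TRUE
})

#' SegmentMatrix: segment presence/absence across homologous regions
#'
#' Presence calls and mismatch counts of reference DNA segments across a set
#' of gene regions, produced by [buildSegmentMatrix()] and consumed by
#' [emergenceOrder()].
#'
#' @slot present Logical matrix, genes (rows) by segments (columns).
#' @slot mismatches Numeric matrix of mismatch counts against the segment's
#'   reference copy; `NA` where the segment is absent.
#' @export
setClass("SegmentMatrix",
  representation(
    present = "matrix",
    mismatches = "matrix"
  )
)

setValidity("SegmentMatrix", function(object) {
  msgs <- character()
  if (!is.logical(object@present)) msgs <- c(msgs, "present must be logical")
  if (!identical(dim(object@present), dim(object@mismatches))) {
    msgs <- c(msgs, "present and mismatches must have identical dimensions")
  }
  if (ncol(object@present) > 0 && any(colSums(object@present) < 1L)) {
    msgs <- c(msgs, "every segment must be present in at least one gene")
  }
  if (any(object@mismatches[object@present] < 0, na.rm = TRUE)) {
    msgs <- c(msgs, "mismatch counts must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' CoverageTrack: per-base coverage with a library size
#'
#' Piecewise-constant, non-negative coverage over chromosomes (bedGraph
#' semantics) stored as a run-length encoded list, plus the total signal
#' used for counts-per-million normalisation.
#'
#' @slot track A [IRanges::RleList], one run-length vector per chromosome.
#' @slot librarySize Total signal (sum over all bases).
#' @export
setClass("CoverageTrack",
  representation(
    track = "SimpleRleList",
    librarySize = "numeric"
  )
)

setValidity("CoverageTrack", function(object) {
  msgs <- character()
  mins <- vapply(object@track, function(r) min(as.numeric(S4Vectors::runValue(r)), Inf),
                 numeric(1))
  if (any(mins < 0)) msgs <- c(msgs, "coverage values must be non-negative")
  if (object@librarySize < 0) msgs <- c(msgs, "librarySize must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn KzfpClusters Compact display.
#' @param object A `KzfpClusters` object.
#' @export
setMethod("show", "KzfpClusters", function(object) {
  cat(sprintf(
    "KzfpClusters: %d cluster(s) from %d element(s) (%d isolated)\n",
    length(object@clusters), length(object@elements),
    sum(is.na(object@elements$cluster_id))
  ))
  cat(sprintf("  rule: >= %d members, adjacent gap < %g bp\n",
              object@minSize, object@maxGap))
})

#' @describeIn CorrelationProfile Compact display.
#' @param object A `CorrelationProfile` object.
#' @export
setMethod("show", "CorrelationProfile", function(object) {
  cat(sprintf(
    "CorrelationProfile: %d bins of %g bp over +/-%g bp, %d anchors, %d pairs\n",
    length(object@offsets), object@binWidth, object@halfWindow,
    object@nAnchors, sum(object@counts)
  ))
})

#' @describeIn ShuffleResult Compact display.
#' @param object A `ShuffleResult` object.
#' @export
setMethod("show", "ShuffleResult", function(object) {
  cat(sprintf(
    "ShuffleResult: observed %d vs expected %.2f (%d shuffles), empirical p = %.4g\n",
    object@observed, object@expected, object@nShuffles, object@empiricalP
  ))
})

#' @describeIn MetaProfile Compact display.
#' @param object A `MetaProfile` object.
#' @export
setMethod("show", "MetaProfile", function(object) {
  cat(sprintf(
    "MetaProfile over %d elements: -%g bp | %d body bins | +%g bp (%d grid points)\n",
    object@nElements, object@flankUp, object@bodyBins, object@flankDown,
    length(object@grid)
  ))
})

#' @describeIn SegmentMatrix Compact display.
#' @param object A `SegmentMatrix` object.
#' @export
setMethod("show", "SegmentMatrix", function(object) {
  cat(sprintf("SegmentMatrix: %d gene(s) x %d segment(s)\n",
              nrow(object@present), ncol(object@present)))
  print(object@present)
})

#' @describeIn CoverageTrack Compact display.
#' @param object A `CoverageTrack` object.
#' @export
setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack: %d chromosome(s), library size %g\n",
              length(object@track), object@librarySize))
})
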