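# Chaining of repeat-anchored units into clusters, upstream-KRAB
# association, positional correlation, and peak-overlap Fisher tests.

#' Chain genomic elements into clusters by single linkage
#'
#' Elements on one chromosome are sorted by start and adjacent elements are
#' linked when the gap between them (end-to-start distance, possibly
#' negative for overlapping elements) is strictly less than `maxGap`.
#' Chains with at least `minSize` members become clusters, numbered
#' sequentially in (chromosome, start) order; all other elements are
#' flagged isolated. The defaults encode the rule of at least 8 elements
#' less than 500 kb apart; `minSize = 10` gives the comparator rule used
#' for olfactory/vomeronasal receptor gene clusters.
#'
#' @param elements A `GRanges` of elements (any strand; may overlap).
#' @param maxGap Maximum adjacent gap in bp (exclusive bound).
#' @param minSize Minimum chain size to be called a cluster.
#' @return A [KzfpClusters-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(start = seq(1, by = 401000, length.out = 8), width = 1000))
#' buildClusters(gr)  # one cluster of 8: every gap is 400 kb < 500 kb
#' @export
buildClusters <- function(elements, maxGap = 500000, minSize = 8L) {
  checkGRanges(elements)
  stopifnot(isNumber(maxGap), maxGap > 0, isCount(minSize, min = 1))
  if (any(BiocGenerics::width(elements) < 1L)) {
    stop("invalid intervals: zero or negative width", call. = FALSE)
  }
  minSize <- as.integer(minSize)
  el <- elements
  el$cluster_id <- NA_integer_
  el$.idx <- seq_along(el)
  chroms <- sort(unique(as.character(GenomeInfoDb::seqnames(el))))
  chainId <- rep(NA_integer_, length(el))
  chainKey <- list()
  for (chrom in chroms) {
    on_chrom <- which(as.character(GenomeInfoDb::seqnames(el)) == chrom)
    ord <- on_chrom[order(BiocGenerics::start(el)[on_chrom],
                          BiocGenerics::end(el)[on_chrom])]
    if (length(ord) == 0L) next
    starts <- BiocGenerics::start(el)[ord]
    ends <- BiocGenerics::end(el)[ord]
    # running maximum end handles contained intervals: the chain extends as
    # far right as any member seen so far
    maxEnd <- cummax(ends)
    gap <- starts[-1] - maxEnd[-length(maxEnd)] - 1L  # 0-based half-open gap
    newChain <- c(TRUE, gap >= maxGap)
    local <- cumsum(newChain)
    for (k in unique(local)) {
      members <- ord[local == k]
      if (length(members) >= minSize) {
        chainKey[[length(chainKey) + 1L]] <- list(chrom = chrom,
                                                  members = members)
      }
    }
  }
  if (length(chainKey)) {
    firstStart <- vapply(chainKey, function(ck) {
      min(BiocGenerics::start(el)[ck$members])
    }, numeric(1))
    chromOf <- vapply(chainKey, `[[`, "", "chrom")
    ordc <- order(chromOf, firstStart)
    chainKey <- chainKey[ordc]
    for (cid in seq_along(chainKey)) {
      chainId[chainKey[[cid]]$members] <- cid
    }
  }
  el$cluster_id <- chainId
  spans <- if (length(chainKey)) {
    GenomicRanges::GRanges(
      seqnames = vapply(chainKey, `[[`, "", "chrom"),
      ranges = IRanges::IRanges(
        start = vapply(chainKey, function(ck)
          min(BiocGenerics::start(el)[ck$members]), numeric(1)),
        end = vapply(chainKey, function(ck)
          max(BiocGenerics::end(el)[ck$members]), numeric(1))
      ),
      cluster_id = seq_along(chainKey),
      n_members = vapply(chainKey, function(ck) length(ck$members), integer(1)),
      members = vapply(chainKey, function(ck) {
        nm <- if (!is.null(el$name)) el$name[ck$members] else
          as.character(ck$members)
        paste(nm[order(BiocGenerics::start(el)[ck$members])], collapse = ",")
      }, "")
    )
  } else {
    GenomicRanges::GRanges(cluster_id = integer(), n_members = integer(),
                           members = character())
  }
  el$.idx <- NULL
  methods::new("KzfpClusters", elements = el, clusters = spans,
               maxGap = maxGap, minSize = minSize)
}

#' Cluster table in the shape of a supplementary cluster listing
#'
#' @param x A [KzfpClusters-class] object.
#' @return A data.frame with columns `cluster_id`, `chrom`, `start`, `end`,
#'   `n_members`, `members`.
#' @export
clusterTable <- function(x) {
  stopifnot(methods::is(x, "KzfpClusters"))
  cl <- clusterSpans(x)
  data.frame(
    cluster_id = cl$cluster_id,
    chrom = as.character(GenomeInfoDb::seqnames(cl)),
    start = BiocGenerics::start(cl),
    end = BiocGenerics::end(cl),
    n_members = cl$n_members,
    members = cl$members,
    stringsAsFactors = FALSE
  )
}

#' Associate each element with its nearest qualifying upstream feature
#'
#' "Upstream" is strand-aware relative to the element: a feature qualifies
#' when its 3'-most coordinate (in the element's orientation) lies within
#' `maxDistance` of the element's 5' end, on the upstream side (distance 0,
#' i.e. a feature ending exactly at the element's 5' end, qualifies). Ties
#' are broken by smaller distance, then by leftmost genomic coordinate.
#' Unstranded elements are treated as "+" with a warning.
#'
#' @param elements,features `GRanges` on shared chromosomes.
#' @param maxDistance Maximum upstream distance in bp (inclusive).
#' @return A data.frame with one row per element: `feature` (index into
#'   `features`, `NA` when none qualifies) and `distance` (bp).
#' @export
associateUpstreamFeature <- function(elements, features, maxDistance = 30000) {
  checkGRanges(elements)
  checkGRanges(features)
  stopifnot(isNumber(maxDistance), maxDistance >= 0)
  estrand <- effectiveStrand(elements)
  echrom <- as.character(GenomeInfoDb::seqnames(elements))
  fchrom <- as.character(GenomeInfoDb::seqnames(features))
  fstart <- BiocGenerics::start(features)
  fend <- BiocGenerics::end(features)
  out <- data.frame(feature = rep(NA_integer_, length(elements)),
                    distance = rep(NA_real_, length(elements)))
  for (i in seq_along(elements)) {
    same <- which(fchrom == echrom[i])
    if (!length(same)) next
    if (estrand[i] == "+") {
      e5 <- BiocGenerics::start(elements)[i]
      anchor <- fend[same]
      dist <- e5 - anchor
    } else {
      e5 <- BiocGenerics::end(elements)[i]
      anchor <- fstart[same]
      dist <- anchor - e5
    }
    ok <- which(dist >= 0 & dist <= maxDistance)
    if (!length(ok)) next
    cand <- same[ok]
    d <- dist[ok]
    pick <- order(d, fstart[cand])[1]
    out$feature[i] <- cand[pick]
    out$distance[i] <- d[pick]
  }
  out
}

#' Extend intervals at their 3' end
#'
#' Strand-aware 3' extension used as a preprocessing step before positional
#' correlation (e.g. gene coordinates extended by 1 kb at the 3' end).
#'
#' @param gr A `GRanges`.
#' @param bp Extension in bp.
#' @return The extended `GRanges`.
#' @export
extend3prime <- function(gr, bp) {
  checkGRanges(gr)
  stopifnot(isNumber(bp), bp >= 0)
  s <- effectiveStrand(gr)
  plus <- s == "+"
  BiocGenerics::end(gr)[plus] <- BiocGenerics::end(gr)[plus] + bp
  BiocGenerics::start(gr)[!plus] <-
    pmax(1L, BiocGenerics::start(gr)[!plus] - bp)
  gr
}

#' @noRd
anchorPoints <- function(gr, point, strand) {
  start <- BiocGenerics::start(gr)
  end <- BiocGenerics::end(gr)
  switch(point,
    midpoint = floor((start + end) / 2),
    "start-5" = ifelse(strand == "+", start, end),
    "end-3" = ifelse(strand == "+", end, start)
  )
}

#' Positional correlation between two feature tracks
#'
#' For every anchor, signed offsets from the anchor point to every feature
#' point within a symmetric window are accumulated into a histogram. Offsets
#' are flipped for minus-strand anchors, so positive offsets always mean
#' "downstream of the anchor". Bins are half-open `[edge, edge + binWidth)`;
#' an offset exactly on a bin boundary falls in the right-hand bin, and an
#' offset of exactly `+halfWindow` is outside the window.
#'
#' @param anchors,features `GRanges`; at least one anchor is required.
#' @param halfWindow Half-window size in bp (e.g. 15000 or 10000).
#' @param binWidth Bin width in bp; must divide `2 * halfWindow`.
#' @param anchorPoint Which point of each anchor to use: `"midpoint"`,
#'   `"start-5"` (strand-aware 5' end) or `"end-3"`.
#' @param featurePoint Same choice for features.
#' @return A [CorrelationProfile-class] object.
#' @export
positionalCorrelation <- function(anchors, features, halfWindow = 15000,
                                  binWidth = 500,
                                  anchorPoint = c("midpoint", "start-5", "end-3"),
                                  featurePoint = c("midpoint", "start-5", "end-3")) {
  checkGRanges(anchors, allowEmpty = FALSE)
  checkGRanges(features)
  anchorPoint <- match.arg(anchorPoint)
  featurePoint <- match.arg(featurePoint)
  stopifnot(isNumber(halfWindow), halfWindow > 0, isNumber(binWidth),
            binWidth > 0)
  if ((2 * halfWindow) %% binWidth != 0) {
    stop("'binWidth' must divide 2 * halfWindow", call. = FALSE)
  }
  astrand <- effectiveStrand(anchors)
  fstrand <- effectiveStrand(features)
  apt <- anchorPoints(anchors, anchorPoint, astrand)
  fpt <- anchorPoints(features, featurePoint, fstrand)
  achrom <- as.character(GenomeInfoDb::seqnames(anchors))
  fchrom <- as.character(GenomeInfoDb::seqnames(features))
  edges <- seq(-halfWindow, halfWindow, by = binWidth)
  counts <- integer(length(edges) - 1L)
  for (chrom in unique(achrom)) {
    ai <- which(achrom == chrom)
    fi <- which(fchrom == chrom)
    if (!length(fi)) next
    off <- rep(fpt[fi], times = length(ai)) -
      rep(apt[ai], each = length(fi))
    flip <- rep(astrand[ai] == "-", each = length(fi))
    off[flip] <- -off[flip]
    inwin <- off >= -halfWindow & off < halfWindow
    if (!any(inwin)) next
    bin <- floor((off[inwin] + halfWindow) / binWidth) + 1L
    tab <- tabulate(bin, nbins = length(counts))
    counts <- counts + tab
  }
  methods::new("CorrelationProfile",
               offsets = edges[-length(edges)] + binWidth / 2,
               counts = counts,
               nAnchors = length(anchors),
               halfWindow = halfWindow, binWidth = binWidth)
}

#' Fisher's exact test of peak association against a shuffled control
#'
#' Builds the 2x2 table (real vs within-chromosome shuffled control
#' elements) x (has at least one peak within `window` bp vs none) and
#' applies a two-sided exact test. The control preserves element counts,
#' lengths and chromosomes. The odds ratio is the sample odds ratio with a
#' Haldane correction (0.5 added to every cell) when any cell is zero.
#'
#' @param elements,peaks `GRanges`.
#' @param window Maximum distance in bp for a peak to count (0 = overlap
#'   only).
#' @param seqlengths Named vector of chromosome lengths for shuffling.
#' @param seed Integer seed for the shuffle (optional).
#' @return A list with `table` (2x2 matrix), `odds_ratio`, `p_value` and
#'   `control` (the shuffled `GRanges`).
#' @export
overlapFisher <- function(elements, peaks, window = 10000, seqlengths,
                          seed = NULL) {
  checkGRanges(elements, allowEmpty = FALSE)
  checkGRanges(peaks)
  stopifnot(isNumber(window), window >= 0)
  control <- withSeed(seed, shuffleIntervals(elements, seqlengths))
  hasPeak <- function(el) {
    IRanges::overlapsAny(el + window, peaks)
  }
  realHit <- sum(hasPeak(elements))
  ctrlHit <- sum(hasPeak(control))
  tab <- matrix(c(realHit, length(elements) - realHit,
                  ctrlHit, length(control) - ctrlHit),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("real", "control"), c("peak", "none")))
  p <- stats::fisher.test(tab)$p.value
  or_tab <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
  list(table = tab, odds_ratio = or, p_value = p, control = control)
}
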