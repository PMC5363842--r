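# Permutation nulls and composition summaries: within-chromosome shuffles,
# TE subfamily enrichment, peak composition, differential-acetylation
# summaries.

#' Shuffle intervals uniformly within their chromosomes
#'
#' Each interval keeps its chromosome and length; its start is redrawn
#' uniformly so the interval stays within the chromosome. Overlaps among
#' shuffled intervals are permitted (independent repositioning).
#'
#' @param gr A `GRanges`.
#' @param seqlengths Named numeric vector of chromosome lengths (bp).
#' @return A `GRanges` of the same length, widths and chromosomes.
#' @export
shuffleIntervals <- function(gr, seqlengths) {
  checkGRanges(gr)
  lens <- chromLengthsFor(gr, seqlengths)
  widths <- BiocGenerics::width(gr)
  if (any(widths > lens)) {
    stop("interval longer than its chromosome", call. = FALSE)
  }
  maxStart <- lens - widths + 1
  newStart <- floor(stats::runif(length(gr), min = 1, max = maxStart + 1))
  newStart <- pmin(newStart, maxStart)  # guard the measure-zero upper edge
  out <- gr
  IRanges::ranges(out) <- IRanges::IRanges(start = newStart, width = widths)
  out
}

#' Permutation-null enrichment of features in regions
#'
#' The observed statistic is the number of features overlapping (by at
#' least 1 bp) any region. The null redraws positions by within-chromosome
#' shuffling — of the regions (e.g. cluster spans shuffled 100 times) or of
#' the features (e.g. peaks shuffled 10,000 times) — and recounts. The
#' empirical p-value uses the add-one estimator
#' \eqn{(1 + \#\{null \ge obs\}) / (n + 1)}, which can never be zero.
#'
#' @param regions,features `GRanges`.
#' @param seqlengths Named chromosome lengths.
#' @param nShuffles Number of shuffles.
#' @param mode Shuffle `"features"` or `"regions"`.
#' @param seed Integer seed (optional).
#' @return A [ShuffleResult-class] object.
#' @export
shuffleEnrichment <- function(regions, features, seqlengths,
                              nShuffles = 100L,
                              mode = c("shuffle_features", "shuffle_regions"),
                              seed = NULL) {
  checkGRanges(regions)
  checkGRanges(features)
  mode <- match.arg(mode)
  stopifnot(isCount(nShuffles, min = 1))
  nShuffles <- as.integer(nShuffles)
  # plain per-chromosome vectors: the shuffle loop stays cheap even at
  # 10,000 permutations
  fchrom <- as.character(GenomeInfoDb::seqnames(features))
  fstart <- BiocGenerics::start(features)
  fwidth <- BiocGenerics::width(features)
  rchrom <- as.character(GenomeInfoDb::seqnames(regions))
  rstart <- BiocGenerics::start(regions)
  rend <- BiocGenerics::end(regions)
  rwidth <- rend - rstart + 1L
  flens <- chromLengthsFor(features, seqlengths)
  rlens <- chromLengthsFor(regions, seqlengths)
  if (any(fwidth > flens) || any(rwidth > rlens)) {
    stop("interval longer than its chromosome", call. = FALSE)
  }
  # features overlapping >= 1 region (>= 1 bp, strand-ignored), given
  # per-feature start positions
  countHits <- function(fs, rs, re) {
    fe <- fs + fwidth - 1L
    hit <- logical(length(fs))
    for (chrom in unique(fchrom)) {
      fi <- fchrom == chrom
      ri <- which(rchrom == chrom)
      if (!length(ri)) next
      # reduce to sorted disjoint regions so one findInterval decides
      o <- ri[order(rs[ri])]
      cs <- rs[o]
      ce <- cummax(re[o])
      keep <- c(TRUE, cs[-1] > ce[-length(ce)] + 0L)
      grp <- cumsum(keep)
      ms <- tapply(cs, grp, min)
      me <- tapply(ce, grp, max)
      idx <- findInterval(fe[fi], ms)
      hit[fi] <- idx >= 1L & me[pmax(idx, 1L)] >= fs[fi]
    }
    sum(hit)
  }
  observed <- countHits(fstart, rstart, rend)
  fmax <- flens - fwidth + 1
  rmax <- rlens - rwidth + 1
  nullCounts <- withSeed(seed, {
    vapply(seq_len(nShuffles), function(i) {
      if (mode == "shuffle_features") {
        fs <- pmin(floor(stats::runif(length(fstart), 1, fmax + 1)), fmax)
        countHits(fs, rstart, rend)
      } else {
        rs <- pmin(floor(stats::runif(length(rstart), 1, rmax + 1)), rmax)
        countHits(fstart, rs, rs + rwidth - 1L)
      }
    }, integer(1))
  })
  methods::new("ShuffleResult",
               observed = as.integer(observed),
               nullCounts = as.integer(nullCounts),
               expected = mean(nullCounts),
               empiricalP = (1 + sum(nullCounts >= observed)) / (nShuffles + 1),
               nShuffles = nShuffles,
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Transposable-element subfamily over-representation in clusters
#'
#' For each repeat subfamily, tests over-representation among repeats
#' falling inside cluster spans against the genome-wide repeat background
#' with a one-sided exact hypergeometric test on the 2x2 table
#' (in clusters vs outside) x (this subfamily vs all other repeats).
#' Raw p-values are reported and compared to `alpha` (no multiple-testing
#' correction by default; `adjust = TRUE` applies Benjamini-Hochberg, a
#' documented deviation from the raw-threshold convention).
#'
#' @param clusters A [KzfpClusters-class] object or `GRanges` of region
#'   spans.
#' @param repeats A `GRanges` of genome-wide repeats with a `subfamily`
#'   metadata column (as from `readGenomicIntervals(..., "RepeatMasker")`).
#' @param alpha Significance threshold on the (adjusted) p-value.
#' @param adjust Apply Benjamini-Hochberg correction across subfamilies.
#' @return A data.frame with one row per subfamily: counts and proportions
#'   in the region and genome, `p`, and `significant`.
#' @export
subfamilyEnrichment <- function(clusters, repeats, alpha = 0.01,
                                adjust = FALSE) {
  spans <- if (methods::is(clusters, "KzfpClusters")) clusterSpans(clusters)
           else clusters
  checkGRanges(spans)
  checkGRanges(repeats, allowEmpty = FALSE)
  if (is.null(repeats$subfamily)) {
    stop("'repeats' needs a 'subfamily' metadata column", call. = FALSE)
  }
  stopifnot(isNumber(alpha), alpha > 0, alpha < 1)
  inRegion <- IRanges::overlapsAny(repeats, spans)
  subfam <- as.character(repeats$subfamily)
  total <- length(repeats)
  nIn <- sum(inRegion)
  res <- lapply(sort(unique(subfam)), function(sf) {
    isSf <- subfam == sf
    a <- sum(isSf & inRegion)          # subfamily in region
    sfTotal <- sum(isSf)
    # P(X >= a) drawing nIn repeats from sfTotal subfamily / rest
    p <- stats::phyper(a - 1, sfTotal, total - sfTotal, nIn,
                       lower.tail = FALSE)
    data.frame(
      subfamily = sf,
      count_region = a,
      count_genome = sfTotal,
      prop_region = if (nIn > 0) a / nIn else 0,
      prop_genome = sfTotal / total,
      p = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- (if (adjust) out$p_adj else out$p) < alpha
  out
}

#' Composition of peaks across units, selected TEs and other sequence
#'
#' Assigns every peak to exactly one category by priority: KZFP/rGU (any
#' overlap with a unit), then the selected TE subfamily with the largest
#' overlap (ties to the leftmost TE), then "other". Selected TEs exclude
#' the Satellite, Simple_repeat, Low_complexity and Unknown classes and any
#' subfamily with fewer than `minSubfamilyHits` members among the supplied
#' repeats (restrict `repeats` to cluster spans before calling to reproduce
#' the in-cluster convention).
#'
#' @param peaks,units `GRanges`.
#' @param repeats `GRanges` with `rep_class` and `subfamily` columns.
#' @param minSubfamilyHits Minimum subfamily size to count as selected.
#' @param excludeClasses Repeat classes never selected.
#' @return A data.frame with columns `category`, `count`, `fraction`
#'   (fractions over all peaks; zero rows sum to 0 when there are no
#'   peaks), plus an `assignment` attribute giving each peak's category.
#' @export
peakComposition <- function(peaks, units, repeats, minSubfamilyHits = 100L,
                            excludeClasses = c("Satellite", "Simple_repeat",
                                               "Low_complexity", "Unknown")) {
  checkGRanges(peaks)
  checkGRanges(units)
  checkGRanges(repeats)
  stopifnot(isCount(minSubfamilyHits, min = 0))
  subfam <- as.character(repeats$subfamily)
  cls <- as.character(repeats$rep_class)
  sfCounts <- table(subfam)
  selected <- !(cls %in% excludeClasses) &
    as.vector(sfCounts[subfam]) >= minSubfamilyHits
  selRepeats <- repeats[selected]
  assignment <- rep("other", length(peaks))
  if (length(units)) {
    assignment[IRanges::overlapsAny(peaks, units)] <- "KZFP/rGU"
  }
  open <- which(assignment == "other")
  if (length(open) && length(selRepeats)) {
    hits <- GenomicRanges::findOverlaps(peaks[open], selRepeats)
    if (length(hits)) {
      ov <- BiocGenerics::width(IRanges::pintersect(
        IRanges::ranges(peaks[open])[S4Vectors::queryHits(hits)],
        IRanges::ranges(selRepeats)[S4Vectors::subjectHits(hits)]
      ))
      df <- data.frame(q = S4Vectors::queryHits(hits),
                       s = S4Vectors::subjectHits(hits), ov = ov)
      df <- df[order(df$q, -df$ov,
                     BiocGenerics::start(selRepeats)[df$s]), ]
      best <- df[!duplicated(df$q), ]
      assignment[open[best$q]] <-
        as.character(selRepeats$subfamily)[best$s]
    }
  }
  cats <- c("KZFP/rGU",
            sort(unique(as.character(selRepeats$subfamily))), "other")
  counts <- vapply(cats, function(ct) sum(assignment == ct), integer(1))
  out <- data.frame(category = cats, count = counts,
                    fraction = if (length(peaks)) counts / length(peaks)
                               else rep(0, length(cats)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "assignment") <- assignment
  out
}

#' @noRd
mergedOverlapBases <- function(a, b) {
  sum(BiocGenerics::width(GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
}

#' Differential-acetylation summaries between two peak sets
#'
#' Computes (a) the fraction of cluster-span bases covered by KO peaks but
#' not WT peaks (interval subtraction on merged sets), with a variant that
#' first discards peaks overlapping supplied promoters; (b) for every
#' repeat subfamily with at least `minTe` members inside clusters, the
#' ratio of members overlapping a KO peak to members overlapping a WT peak
#' (`NA` when the denominator is zero); and (c) the per-cluster peak count
#' normalised by cluster span length, per condition.
#'
#' @param peaksWt,peaksKo `GRanges` peak sets (overlapping input intervals
#'   are merged before arithmetic).
#' @param clusters A [KzfpClusters-class] object or `GRanges` of spans.
#' @param promoters Optional `GRanges` of promoters for the exclusion
#'   variant.
#' @param repeats Optional `GRanges` with a `subfamily` column for the
#'   per-subfamily ratios.
#' @param minTe Minimum subfamily size inside clusters for a ratio.
#' @return A list with `ko_only_fraction`, `ko_only_fraction_no_promoter`
#'   (`NA` when no promoters are given), `subfamily_ratios` (data.frame)
#'   and `cluster_density` (data.frame).
#' @export
differentialAcetylationSummary <- function(peaksWt, peaksKo, clusters,
                                           promoters = NULL, repeats = NULL,
                                           minTe = 3L) {
  spans <- if (methods::is(clusters, "KzfpClusters")) clusterSpans(clusters)
           else clusters
  checkGRanges(spans, allowEmpty = FALSE)
  checkGRanges(peaksWt)
  checkGRanges(peaksKo)
  stopifnot(isCount(minTe, min = 1))
  wt <- GenomicRanges::reduce(peaksWt, ignore.strand = TRUE)
  ko <- GenomicRanges::reduce(peaksKo, ignore.strand = TRUE)
  spanBases <- sum(BiocGenerics::width(GenomicRanges::reduce(spans, ignore.strand = TRUE)))
  koOnlyIn <- function(wtSet, koSet) {
    koOnly <- GenomicRanges::setdiff(koSet, wtSet, ignore.strand = TRUE)
    mergedOverlapBases(koOnly, spans) / spanBases
  }
  frac <- koOnlyIn(wt, ko)
  fracNoProm <- NA_real_
  if (!is.null(promoters) && length(promoters)) {
    keepWt <- !IRanges::overlapsAny(peaksWt, promoters)
    keepKo <- !IRanges::overlapsAny(peaksKo, promoters)
    fracNoProm <- koOnlyIn(
      GenomicRanges::reduce(peaksWt[keepWt], ignore.strand = TRUE),
      GenomicRanges::reduce(peaksKo[keepKo], ignore.strand = TRUE))
  }
  subRatios <- data.frame(subfamily = character(), n = integer(),
                          n_ko = integer(), n_wt = integer(),
                          ratio = numeric(), stringsAsFactors = FALSE)
  if (!is.null(repeats) && length(repeats)) {
    inCl <- repeats[IRanges::overlapsAny(repeats, spans)]
    subfam <- as.character(inCl$subfamily)
    for (sf in sort(unique(subfam))) {
      members <- inCl[subfam == sf]
      if (length(members) < minTe) next
      nKo <- sum(IRanges::overlapsAny(members, ko))
      nWt <- sum(IRanges::overlapsAny(members, wt))
      subRatios <- rbind(subRatios, data.frame(
        subfamily = sf, n = length(members), n_ko = nKo, n_wt = nWt,
        ratio = if (nWt > 0) nKo / nWt else NA_real_,
        stringsAsFactors = FALSE
      ))
    }
  }
  dens <- data.frame(
    cluster_id = if (!is.null(spans$cluster_id)) spans$cluster_id
                 else seq_along(spans),
    span = BiocGenerics::width(spans),
    n_wt = GenomicRanges::countOverlaps(spans, wt),
    n_ko = GenomicRanges::countOverlaps(spans, ko)
  )
  dens$density_wt <- dens$n_wt / dens$span
  dens$density_ko <- dens$n_ko / dens$span
  list(ko_only_fraction = frac,
       ko_only_fraction_no_promoter = fracNoProm,
       subfamily_ratios = subRatios,
       cluster_density = dens)
}
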