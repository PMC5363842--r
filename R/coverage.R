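# Strand-aware coverage metaprofiles, fold-change response classification,
# per-cluster category summaries, and distance-to-peak stratification.

#' Build a CoverageTrack from a bedGraph-style GRanges
#'
#' @param gr A `GRanges` with a numeric `score` column (non-overlapping per
#'   chromosome), or a path to a bedGraph file.
#' @param seqlengths Named chromosome lengths; chromosomes absent from `gr`
#'   get zero coverage.
#' @param librarySize Total signal used for counts-per-million
#'   normalisation; defaults to the track's own total.
#' @return A [CoverageTrack-class] object.
#' @export
coverageTrack <- function(gr, seqlengths, librarySize = NULL) {
  if (is.character(gr)) gr <- readBedGraph(gr)
  checkGRanges(gr)
  if (is.null(gr$score)) stop("'gr' needs a 'score' column", call. = FALSE)
  if (any(gr$score < 0)) stop("coverage values must be >= 0", call. = FALSE)
  gr <- GenomeInfoDb::keepSeqlevels(
    gr, intersect(GenomeInfoDb::seqlevels(gr), names(seqlengths)),
    pruning.mode = "coarse"
  )
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr) <- seqlengths
  rle <- GenomicRanges::coverage(gr, weight = gr$score)
  total <- sum(vapply(rle, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                             S4Vectors::runLength(r)),
                      numeric(1)))
  if (is.null(librarySize)) librarySize <- total
  methods::new("CoverageTrack", track = rle, librarySize = librarySize)
}

# Extract the per-base signal over [from, to] on one chromosome, NA outside
# chromosome bounds.
#' @noRd
trackWindow <- function(rle, chrom, from, to) {
  out <- rep(NA_real_, to - from + 1L)
  if (!chrom %in% names(rle)) return(out)
  r <- rle[[chrom]]
  n <- length(r)
  lo <- max(1L, from)
  hi <- min(n, to)
  if (lo > hi) return(out)
  out[(lo - from + 1L):(hi - from + 1L)] <-
    as.numeric(S4Vectors::window(r, lo, hi))
  out
}

# Mean of x over `bins` near-equal chunks; empty chunks (body shorter than
# the bin count) take the nearest position's value.
#' @noRd
rebinMeans <- function(x, bins) {
  w <- length(x)
  out <- numeric(bins)
  for (b in seq_len(bins)) {
    lo <- floor((b - 1L) * w / bins) + 1L
    hi <- floor(b * w / bins)
    if (hi < lo) {
      pos <- min(w, max(1L, ceiling(b * w / bins)))
      out[b] <- x[pos]
    } else {
      out[b] <- mean(x[lo:hi])
    }
  }
  out
}

#' Aggregate metaprofile of coverage around elements
#'
#' For each element the track (normalised to counts-per-million) is sampled
#' over a strand-oriented window: `flankUp` bp upstream of the 5' end at
#' 1 bp resolution, the element body rescaled to `bodyBins` bins, and
#' `flankDown` bp downstream of the 3' end. Minus-strand windows are
#' reversed so the grid always reads 5' to 3'. Windows extending beyond a
#' chromosome are masked, not errors. The confidence band is the normal
#' approximation `mean +/- 1.96 * sd / sqrt(n)` per grid position.
#'
#' @param elements A non-empty `GRanges`.
#' @param track A [CoverageTrack-class].
#' @param flankUp,flankDown Flank sizes in bp (defaults 1500 and 3500).
#' @param bodyBins Number of length-normalised body bins.
#' @param normalize Normalise to counts-per-million before aggregation.
#' @return A [MetaProfile-class] object.
#' @export
metaprofile <- function(elements, track, flankUp = 1500, flankDown = 3500,
                        bodyBins = 100L, normalize = TRUE) {
  checkGRanges(elements, allowEmpty = FALSE)
  stopifnot(methods::is(track, "CoverageTrack"), isCount(bodyBins, min = 1),
            isNumber(flankUp), flankUp >= 0, isNumber(flankDown),
            flankDown >= 0)
  rle <- coverageRle(track)
  scale <- if (normalize && librarySize(track) > 0) {
    1e6 / librarySize(track)
  } else 1
  strand <- effectiveStrand(elements)
  chrom <- as.character(GenomeInfoDb::seqnames(elements))
  total <- flankUp + bodyBins + flankDown
  mat <- matrix(NA_real_, length(elements), total)
  for (i in seq_along(elements)) {
    s <- BiocGenerics::start(elements)[i]
    e <- BiocGenerics::end(elements)[i]
    if (strand[i] == "+") {
      win <- trackWindow(rle, chrom[i], s - flankUp, e + flankDown)
    } else {
      win <- rev(trackWindow(rle, chrom[i], s - flankDown, e + flankUp))
    }
    body <- win[(flankUp + 1L):(length(win) - flankDown)]
    mat[i, ] <- c(if (flankUp > 0) win[seq_len(flankUp)],
                  rebinMeans(body, bodyBins),
                  if (flankDown > 0) win[(length(win) - flankDown + 1L):
                                           length(win)]) * scale
  }
  n <- colSums(!is.na(mat))
  mu <- colMeans(mat, na.rm = TRUE)
  sdev <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  sdev[n <= 1L] <- 0
  se <- ifelse(n > 0, sdev / sqrt(pmax(n, 1)), NA_real_)
  grid <- c(if (flankUp > 0) seq(-flankUp, -1),
            (seq_len(bodyBins) - 0.5) / bodyBins * 1000,
            if (flankDown > 0) 1000 + seq_len(flankDown))
  methods::new("MetaProfile", grid = grid, mean = mu,
               ciLow = mu - 1.96 * se, ciHigh = mu + 1.96 * se,
               nElements = length(elements), flankUp = flankUp,
               flankDown = flankDown, bodyBins = as.integer(bodyBins))
}

#' Mean signal of a track over each element
#'
#' @param track A [CoverageTrack-class].
#' @param elements A `GRanges`.
#' @param normalize Counts-per-million normalisation.
#' @return Numeric vector of per-element mean coverage.
#' @export
elementSignal <- function(track, elements, normalize = FALSE) {
  checkGRanges(elements)
  stopifnot(methods::is(track, "CoverageTrack"))
  rle <- coverageRle(track)
  scale <- if (normalize && librarySize(track) > 0) {
    1e6 / librarySize(track)
  } else 1
  chrom <- as.character(GenomeInfoDb::seqnames(elements))
  vapply(seq_along(elements), function(i) {
    w <- trackWindow(rle, chrom[i], BiocGenerics::start(elements)[i],
                     BiocGenerics::end(elements)[i])
    mean(w, na.rm = TRUE) * scale
  }, numeric(1))
}

#' Classify per-element response between two conditions by fold change
#'
#' A declared, threshold-based stand-in for differential-expression
#' testing: `log2fc = log2((b + pseudocount) / (a + pseudocount))`; an
#' element is `up` when `log2fc >= lfcThreshold` and its larger mean
#' reaches `minSignal`, `down` symmetrically, `unchanged` otherwise.
#'
#' @param countsA,countsB Numeric vectors of normalised per-element signal
#'   (same element order).
#' @param lfcThreshold Absolute log2 fold-change threshold.
#' @param minSignal Minimum of `max(a, b)` for a call.
#' @param pseudocount Added to both means.
#' @param labels Optional element labels.
#' @return A data.frame with `element`, `mean_a`, `mean_b`, `log2fc`,
#'   `class`.
#' @export
classifyResponse <- function(countsA, countsB, lfcThreshold = 1,
                             minSignal = 0, pseudocount = 1,
                             labels = NULL) {
  if (length(countsA) != length(countsB)) {
    stop("'countsA' and 'countsB' must have equal length", call. = FALSE)
  }
  stopifnot(isNumber(lfcThreshold), lfcThreshold >= 0, isNumber(pseudocount),
            pseudocount >= 0)
  if (is.null(labels)) labels <- as.character(seq_along(countsA))
  lfc <- log2((countsB + pseudocount) / (countsA + pseudocount))
  pass <- pmax(countsA, countsB) >= minSignal
  cls <- rep("unchanged", length(lfc))
  cls[pass & lfc >= lfcThreshold] <- "up"
  cls[pass & lfc <= -lfcThreshold] <- "down"
  data.frame(element = labels, mean_a = countsA, mean_b = countsB,
             log2fc = lfc, class = cls, stringsAsFactors = FALSE)
}

#' Per-cluster, per-category mean log2 fold change
#'
#' Categories with fewer than `minN` members in a cluster are omitted; the
#' overall cluster mean is computed across all retained elements.
#'
#' @param calls A data.frame from [classifyResponse()].
#' @param memberships A data.frame with columns `element`, `cluster`,
#'   `category` (e.g. KZFP/rGU, ERVK, ERV1, other TE).
#' @param minN Minimum category size per cluster.
#' @return A list with `per_category` (cluster, category, n, mean_log2fc)
#'   and `overall` (cluster, n, mean_log2fc over retained elements).
#' @export
perClusterCategoryFc <- function(calls, memberships, minN = 5L) {
  stopifnot(is.data.frame(calls), is.data.frame(memberships),
            isCount(minN, min = 1))
  need <- c("element", "cluster", "category")
  if (!all(need %in% names(memberships))) {
    stop("'memberships' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- merge(memberships, calls[, c("element", "log2fc")], by = "element")
  perCat <- do.call(rbind, lapply(split(df, df[, c("cluster", "category")],
                                        drop = TRUE), function(g) {
    data.frame(cluster = g$cluster[1], category = g$category[1],
               n = nrow(g), mean_log2fc = mean(g$log2fc),
               stringsAsFactors = FALSE)
  }))
  if (is.null(perCat)) {
    perCat <- data.frame(cluster = character(), category = character(),
                         n = integer(), mean_log2fc = numeric())
  }
  rownames(perCat) <- NULL
  perCat <- perCat[perCat$n >= minN, , drop = FALSE]
  retained <- merge(df, perCat[, c("cluster", "category")],
                    by = c("cluster", "category"))
  overall <- do.call(rbind, lapply(split(retained, retained$cluster),
                                   function(g) {
    data.frame(cluster = g$cluster[1], n = nrow(g),
               mean_log2fc = mean(g$log2fc), stringsAsFactors = FALSE)
  }))
  if (is.null(overall)) {
    overall <- data.frame(cluster = character(), n = integer(),
                          mean_log2fc = numeric())
  }
  rownames(overall) <- NULL
  list(per_category = perCat, overall = overall)
}

#' Stratify elements by their distance to the nearest peak
#'
#' Exclusive assignment in precedence order: overlapping a peak, then an
#' edge-to-edge gap under 5 kb, under 20 kb, and 20 kb or more. Bounds are
#' strict, so a gap of exactly 5000 bp falls in the "<20 kb" bin. Elements
#' on peak-free chromosomes land in the ">=20 kb" bin.
#'
#' @param elements,peaks `GRanges`.
#' @param values Optional numeric vector (one per element) summarised per
#'   bin.
#' @return A list with `assignment` (factor with levels `overlap`,
#'   `lt5kb`, `lt20kb`, `ge20kb`) and `summary` (per-bin n and, when
#'   `values` is given, mean value).
#' @export
stratifyByPeakDistance <- function(elements, peaks, values = NULL) {
  checkGRanges(elements)
  checkGRanges(peaks)
  lv <- c("overlap", "lt5kb", "lt20kb", "ge20kb")
  bin <- rep("ge20kb", length(elements))
  if (length(peaks)) {
    ov <- IRanges::overlapsAny(elements, peaks, ignore.strand = TRUE)
    d <- GenomicRanges::distanceToNearest(elements, peaks,
                                          ignore.strand = TRUE)
    dist <- rep(Inf, length(elements))
    dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    bin[dist < 20000] <- "lt20kb"
    bin[dist < 5000] <- "lt5kb"
    bin[ov] <- "overlap"
  }
  assignment <- factor(bin, levels = lv)
  summary <- data.frame(bin = lv, n = as.integer(table(assignment)[lv]))
  if (!is.null(values)) {
    stopifnot(length(values) == length(elements))
    summary$mean_value <- vapply(lv, function(b) {
      v <- values[assignment == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  list(assignment = assignment, summary = summary)
}

#' Compare responses of in-cluster vs isolated elements
#'
#' Two-sample rank-sum (Wilcoxon) comparison of log2 fold changes between
#' elements inside clusters and their isolated counterparts.
#'
#' @param calls A data.frame from [classifyResponse()].
#' @param inCluster Logical vector, one per call.
#' @return A list with per-group `n`, `median_log2fc`, `mean_log2fc` and
#'   the rank-sum `p_value`.
#' @export
compareClusterVsIsolated <- function(calls, inCluster) {
  stopifnot(is.data.frame(calls), is.logical(inCluster),
            length(inCluster) == nrow(calls))
  a <- calls$log2fc[inCluster]
  b <- calls$log2fc[!inCluster]
  if (!length(a) || !length(b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- stats::wilcox.test(a, b, exact = FALSE)
  list(
    n_cluster = length(a), n_isolated = length(b),
    median_log2fc_cluster = stats::median(a),
    median_log2fc_isolated = stats::median(b),
    mean_log2fc_cluster = mean(a), mean_log2fc_isolated = mean(b),
    p_value = wt$p.value
  )
}
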