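# Segment homology matrices, Dollo-style paralog emergence ordering, and
# retrocopy (processed pseudogene) detection.

#' Build a segment presence/absence matrix across homologous regions
#'
#' Each segment's reference subsequence is locally aligned (affine gaps,
#' same scheme as [progressiveAlign()]) against every region. The segment
#' is called present in a region when the best local alignment covers at
#' least `coverageMin` of the segment length at identity at least
#' `identityMin`; the mismatch count of that alignment is recorded. An
#' interrupted homology still counts as present while coverage holds.
#'
#' @param regions Named `DNAStringSet` or named character vector of region
#'   sequences (typically gene loci).
#' @param segmentation A data.frame with columns `segment` (label),
#'   `region` (reference region name), `start`, `end` (1-based inclusive
#'   coordinates within the reference region).
#' @param identityMin Minimum alignment identity (matches / alignment
#'   columns).
#' @param coverageMin Minimum fraction of segment residues aligned.
#' @inheritParams alignDna
#' @return A [SegmentMatrix-class] object (genes x segments).
#' @export
buildSegmentMatrix <- function(regions, segmentation, identityMin = 0.8,
                               coverageMin = 0.8, match = 1, mismatch = -1,
                               gapOpen = -4, gapExtend = -1) {
  if (methods::is(regions, "XStringSet")) regions <- as.character(regions)
  stopifnot(is.character(regions), !is.null(names(regions)))
  need <- c("segment", "region", "start", "end")
  if (!all(need %in% names(segmentation))) {
    stop("'segmentation' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  genes <- names(regions)
  segs <- as.character(segmentation$segment)
  present <- matrix(FALSE, length(genes), length(segs),
                    dimnames = list(genes, segs))
  mism <- matrix(NA_real_, length(genes), length(segs),
                 dimnames = list(genes, segs))
  for (s in seq_along(segs)) {
    refRegion <- as.character(segmentation$region[s])
    if (!refRegion %in% genes) {
      stop("unknown reference region: ", refRegion, call. = FALSE)
    }
    from <- segmentation$start[s]
    to <- segmentation$end[s]
    if (from < 1 || to > nchar(regions[[refRegion]]) || from > to) {
      stop("invalid coordinates for segment ", segs[s], call. = FALSE)
    }
    refSeq <- substr(regions[[refRegion]], from, to)
    segLen <- nchar(refSeq)
    for (g in seq_along(genes)) {
      al <- alignDna(refSeq, regions[[g]], match, mismatch, gapOpen,
                     gapExtend, type = "local")
      ac <- alignedChars(al)
      cols <- length(ac$a)
      if (cols == 0L) next
      matches <- sum(ac$a == ac$b & ac$a != "-")
      refAligned <- sum(ac$a != "-")
      identity <- matches / cols
      if (refAligned / segLen >= coverageMin && identity >= identityMin) {
        present[g, s] <- TRUE
        mism[g, s] <- sum(ac$a != ac$b & ac$a != "-" & ac$b != "-")
      }
    }
  }
  methods::new("SegmentMatrix", present = present, mismatches = mism)
}

#' Order paralog emergence from segment presence (Dollo parsimony)
#'
#' Segments are treated as characters gained exactly once and never
#' regained: the set of genes carrying a segment must form one subtree, so
#' the gene-sets of all segments must be pairwise nested or disjoint. The
#' resulting hierarchy is returned as a rooted tree whose leaves are the
#' genes; genes whose segment set equals the gains on an internal path
#' attach directly at that level (ancestral, earlier-emerging lineages).
#' The output is invariant to gene and segment input order.
#'
#' @param x A [SegmentMatrix-class] or a logical matrix (genes x segments).
#' @return A rooted `phylo` object.
#' @examples
#' m <- rbind(
#'   Zfp932  = c(rep(TRUE, 5), FALSE, FALSE, FALSE, FALSE),
#'   Gm15446 = c(rep(TRUE, 5), TRUE, TRUE, TRUE, FALSE),
#'   GmX     = c(rep(TRUE, 5), TRUE, TRUE, FALSE, TRUE)
#' )
#' colnames(m) <- paste0("s", 1:9)
#' ape::write.tree(emergenceOrder(m))  # (Zfp932,(Gm15446,GmX));
#' @export
emergenceOrder <- function(x) {
  mat <- if (methods::is(x, "SegmentMatrix")) segmentPresence(x) else x
  if (!is.logical(mat) || is.null(rownames(mat))) {
    stop("'x' must be a logical matrix with gene row names", call. = FALSE)
  }
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  if (ncol(mat) > 1L) mat <- mat[, order(colnames(mat)), drop = FALSE]
  genes <- rownames(mat)
  if (length(genes) == 1L) {
    return(ape::read.tree(text = sprintf("(%s);", genes)))
  }
  if (any(colSums(mat) == 0L)) {
    stop("segment absent from every gene: ",
         paste(colnames(mat)[colSums(mat) == 0L], collapse = ", "),
         call. = FALSE)
  }
  geneSets <- lapply(seq_len(ncol(mat)), function(s) genes[mat[, s]])
  segNames <- colnames(mat)
  # single-gain consistency: gene-sets pairwise nested or disjoint
  for (i in seq_along(geneSets)) {
    for (j in seq_along(geneSets)) {
      if (j <= i) next
      a <- geneSets[[i]]; b <- geneSets[[j]]
      inter <- intersect(a, b)
      if (length(inter) && !all(a %in% b) && !all(b %in% a)) {
        stop(sprintf(
          paste0("no single-gain solution: segments '%s' and '%s' conflict ",
                 "(genes %s carry both, %s only the first, %s only the second)"),
          segNames[i], segNames[j], paste(inter, collapse = "/"),
          paste(setdiff(a, b), collapse = "/"),
          paste(setdiff(b, a), collapse = "/")
        ), call. = FALSE)
      }
    }
  }
  sets <- unique(lapply(geneSets, sort))
  # segments carried by every gene are gains on the root branch: they do
  # not affect the topology, so the corresponding full set collapses into
  # the root
  sets <- sets[lengths(sets) < length(genes)]
  sets <- sets[order(-lengths(sets), vapply(sets, `[`, "", 1L))]
  isSubset <- function(a, b) all(a %in% b)
  parentOf <- function(k) {
    candidates <- which(vapply(seq_along(sets), function(m) {
      m != k && isSubset(sets[[k]], sets[[m]]) &&
        length(sets[[m]]) > length(sets[[k]])
    }, logical(1)))
    if (!length(candidates)) 0L  # root
    else candidates[which.min(lengths(sets)[candidates])]
  }
  parents <- if (length(sets)) vapply(seq_along(sets), parentOf, integer(1))
             else integer(0)
  # the smallest set containing each gene; 0 = root
  homeOf <- vapply(genes, function(g) {
    containing <- which(vapply(sets, function(s) g %in% s, logical(1)))
    if (!length(containing)) 0L
    else containing[which.min(lengths(sets)[containing])]
  }, integer(1))
  buildNode <- function(k) {
    childSets <- which(parents == k)
    ownGenes <- genes[homeOf == k]
    parts <- c(lapply(childSets, buildNode), as.list(ownGenes))
    keys <- vapply(parts, function(p) attr(p, "minLeaf") %||% p, "")
    parts <- parts[order(keys)]
    txt <- if (length(parts) == 1L) parts[[1]]
           else paste0("(", paste(unlist(parts), collapse = ","), ")")
    attr(txt, "minLeaf") <- min(keys)
    txt
  }
  txt <- buildNode(0L)
  if (!startsWith(txt, "(")) txt <- paste0("(", txt, ")")
  ape::read.tree(text = paste0(txt, ";"))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate a 3'-proximal poly-A run
#'
#' Finds the longest run of adenines (allowing one non-A per 10 positions,
#' i.e. >= 90\% purity) of length at least `minRun` ending within `maxDist`
#' of the sequence 3' end.
#'
#' @param seq Character scalar, 5' to 3'.
#' @param minRun Minimum run length.
#' @param maxDist Maximum distance of the run end from the 3' end.
#' @return A list with `length` (0 when none found) and `dist` from the 3'
#'   end.
#' @export
findPolyARun <- function(seq, minRun = 10L, maxDist = 200L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  windowStart <- max(1L, n - maxDist - 10L * minRun + 1L)
  chars <- strsplit(substr(seq, windowStart, n), "", fixed = TRUE)[[1]]
  m <- length(chars)
  isA <- chars == "A"
  best <- list(length = 0L, dist = NA_integer_)
  csum <- cumsum(!isA)
  for (e in seq_len(m)) {
    distEnd <- m - e
    if (distEnd > maxDist) next
    for (s in seq_len(e)) {
      len <- e - s + 1L
      if (len < minRun) next
      nonA <- csum[e] - (if (s > 1L) csum[s - 1L] else 0L)
      if (nonA <= len %/% 10L && len > best$length) {
        best <- list(length = len, dist = distEnd)
      }
    }
  }
  best
}

#' Detect processed pseudogenes (retrocopies) among candidate loci
#'
#' A candidate is called a retrocopy when it (i) has exactly one exon,
#' (ii) carries a genomically encoded poly-A run near its 3' end
#' ([findPolyARun()]), and (iii) shows at least `identityMin` global
#' identity with the concatenated exonic sequence of its best-matching
#' intron-containing donor. All three criteria are individually necessary.
#' Sequences must be supplied 5' to 3' (reverse-complemented by the caller
#' for minus-strand loci).
#'
#' @param candidateSeqs Named `DNAStringSet` or character vector of
#'   candidate locus sequences.
#' @param candidateExons Named integer vector: exon count per candidate.
#' @param donorSeqs Named `DNAStringSet` or character vector of donor
#'   exonic (spliced) sequences.
#' @param donorExons Named integer vector: exon count per donor (all must
#'   be >= 2).
#' @param polyAMinRun,polyAMaxDist Poly-A rule parameters.
#' @param identityMin Minimum global identity with the best donor.
#' @inheritParams alignDna
#' @return A data.frame with one row per candidate: `candidate`, `donor`,
#'   `exon_count`, `polyA_run`, `polyA_dist`, `identity`, `verdict`.
#' @export
detectRetrocopies <- function(candidateSeqs, candidateExons, donorSeqs,
                              donorExons, polyAMinRun = 10L,
                              polyAMaxDist = 200L, identityMin = 0.8,
                              match = 1, mismatch = -1, gapOpen = -4,
                              gapExtend = -1) {
  if (methods::is(candidateSeqs, "XStringSet")) {
    candidateSeqs <- as.character(candidateSeqs)
  }
  if (methods::is(donorSeqs, "XStringSet")) donorSeqs <- as.character(donorSeqs)
  if (!length(donorSeqs)) stop("empty donor list", call. = FALSE)
  if (any(donorExons < 2L)) {
    stop("donor transcripts must have >= 2 exons", call. = FALSE)
  }
  stopifnot(!is.null(names(candidateSeqs)), !is.null(names(donorSeqs)))
  rows <- lapply(names(candidateSeqs), function(id) {
    seq <- candidateSeqs[[id]]
    nEx <- candidateExons[[id]]
    polyA <- findPolyARun(seq, polyAMinRun, polyAMaxDist)
    ident <- vapply(names(donorSeqs), function(d) {
      ac <- alignedChars(alignDna(seq, donorSeqs[[d]], match, mismatch,
                                  gapOpen, gapExtend))
      sum(ac$a == ac$b & ac$a != "-") / length(ac$a)
    }, numeric(1))
    bestDonor <- names(donorSeqs)[which.max(ident)]
    data.frame(
      candidate = id,
      donor = bestDonor,
      exon_count = nEx,
      polyA_run = polyA$length,
      polyA_dist = polyA$dist,
      identity = max(ident),
      verdict = nEx == 1L && polyA$length >= polyAMinRun &&
        max(ident) >= identityMin,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
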