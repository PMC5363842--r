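# Per-cluster progressive alignment, consensus calling, p-distances and
# neighbor-joining similarity trees.

DNA_ALPHA <- c("A", "C", "G", "T")

# Substitution matrix over A/C/G/T/N: N is scored neutrally (0) against
# everything so ambiguity neither rewards nor punishes an alignment.
#' @noRd
dnaScoreMatrix <- function(match, mismatch) {
  letters <- c(DNA_ALPHA, "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Pairwise global or local DNA alignment with affine gaps
#'
#' Wrapper over [Biostrings::pairwiseAlignment()] using the gap convention
#' in which a gap of length L costs `gapOpen + (L - 1) * gapExtend` (both
#' supplied as negative scores). `N` is scored 0 against any base.
#'
#' @param a,b Character scalars or `XString`s.
#' @param match,mismatch,gapOpen,gapExtend Scoring parameters (penalties
#'   negative).
#' @param type `"global"` or `"local"`.
#' @return The `PairwiseAlignments` object.
#' @export
alignDna <- function(a, b, match = 1, mismatch = -1, gapOpen = -4,
                     gapExtend = -1, type = "global") {
  stopifnot(gapOpen <= 0, gapExtend <= 0, abs(gapOpen) >= abs(gapExtend))
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(a)),
    Biostrings::DNAString(as.character(b)),
    substitutionMatrix = dnaScoreMatrix(match, mismatch),
    gapOpening = abs(gapOpen) - abs(gapExtend),
    gapExtension = abs(gapExtend),
    type = type
  )
}

#' @noRd
alignedChars <- function(al) {
  list(
    a = strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]],
    b = strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  )
}

#' @noRd
msaMatrix <- function(msa) {
  do.call(rbind, strsplit(as.character(msa), "", fixed = TRUE))
}

#' @noRd
msaConsensusString <- function(mat) {
  apply(mat, 2L, function(col) {
    counts <- vapply(DNA_ALPHA, function(l) sum(col == l), integer(1))
    if (all(counts == 0L)) "N" else DNA_ALPHA[which.max(counts)]
  }) |> paste(collapse = "")
}

#' Progressive multiple sequence alignment
#'
#' Aligns sequences progressively: a guide order is derived from 6-mer
#' profile distances (closest pair first, then greedy joining of the
#' nearest remaining sequence), and each sequence is aligned globally
#' against the running alignment's majority consensus with affine gaps.
#' Deterministic given inputs and parameters.
#'
#' @param seqs A named `DNAStringSet` or named character vector (length
#'   >= 1; a single sequence is returned as a 1-row alignment).
#' @inheritParams alignDna
#' @return A `DNAStringSet` of equal-width gapped rows in the input order.
#' @export
progressiveAlign <- function(seqs, match = 1, mismatch = -1, gapOpen = -4,
                             gapExtend = -1) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) == 0L) stop("no sequences supplied", call. = FALSE)
  if (any(BiocGenerics::width(seqs) == 0L)) {
    stop("empty sequence in input", call. = FALSE)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (n == 1L) return(seqs)
  k <- min(6L, min(BiocGenerics::width(seqs)))
  prof <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  d <- as.matrix(stats::dist(prof))
  diag(d) <- Inf
  first <- which(d == min(d), arr.ind = TRUE)
  first <- first[order(first[, 1], first[, 2]), , drop = FALSE][1, ]
  ord <- sort(c(first[[1]], first[[2]]))
  remaining <- setdiff(seq_len(n), ord)
  while (length(remaining)) {
    dd <- d[remaining, ord, drop = FALSE]
    best <- remaining[order(apply(dd, 1L, min), remaining)[1]]
    ord <- c(ord, best)
    remaining <- setdiff(remaining, best)
  }
  mat <- matrix(strsplit(as.character(seqs[[ord[1]]]), "")[[1]], nrow = 1L)
  for (idx in ord[-1]) {
    cons <- msaConsensusString(mat)
    al <- alignDna(cons, as.character(seqs[[idx]]), match, mismatch,
                   gapOpen, gapExtend)
    ac <- alignedChars(al)
    newMat <- matrix("-", nrow = nrow(mat) + 1L, ncol = length(ac$a))
    oldCol <- 0L
    for (j in seq_along(ac$a)) {
      if (ac$a[j] != "-") {
        oldCol <- oldCol + 1L
        newMat[seq_len(nrow(mat)), j] <- mat[, oldCol]
      }
    }
    newMat[nrow(newMat), ] <- ac$b
    mat <- newMat
  }
  rows <- apply(mat, 1L, paste, collapse = "")
  out <- Biostrings::DNAStringSet(rows[order(ord)])
  names(out) <- names(seqs)
  out
}

#' Majority consensus of a multiple alignment
#'
#' Columns where gaps hold a strict majority are dropped. Otherwise the
#' most frequent residue is emitted when its frequency among non-gap
#' characters reaches `minFrac`, and `N` otherwise; ties break by fixed
#' alphabet order (A < C < G < T).
#'
#' @param msa A gapped, equal-width `DNAStringSet` (or character vector)
#'   from [progressiveAlign()].
#' @param minFrac Minimum non-gap frequency for a residue call.
#' @return A single consensus string (over ACGTN).
#' @export
consensusFromMsa <- function(msa, minFrac = 0.5) {
  stopifnot(isNumber(minFrac), minFrac > 0, minFrac <= 1)
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows must have equal width", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  n <- nrow(mat)
  out <- character(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    gaps <- sum(col == "-")
    nonGap <- n - gaps
    if (gaps > nonGap) next  # gap-majority column dropped
    counts <- vapply(DNA_ALPHA, function(l) sum(col == l), integer(1))
    top <- which.max(counts)  # ties resolve to earliest letter
    out <- c(out,
             if (nonGap > 0 && counts[top] / nonGap >= minFrac)
               DNA_ALPHA[top] else "N")
  }
  paste(out, collapse = "")
}

#' Pairwise p-distance matrix between consensus sequences
#'
#' Each pair is globally aligned with the same affine scheme as
#' [progressiveAlign()]; the distance is the fraction of mismatching
#' positions among aligned columns where both sequences have a non-gap,
#' non-N character.
#'
#' @param consensuses Named character vector or `DNAStringSet` (length
#'   >= 2).
#' @inheritParams alignDna
#' @return A symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
pdistanceMatrix <- function(consensuses, match = 1, mismatch = -1,
                            gapOpen = -4, gapExtend = -1) {
  if (methods::is(consensuses, "XStringSet")) {
    consensuses <- as.character(consensuses)
  }
  n <- length(consensuses)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  labs <- names(consensuses)
  if (is.null(labs)) labs <- paste0("c", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ac <- alignedChars(alignDna(consensuses[[i]], consensuses[[j]],
                                  match, mismatch, gapOpen, gapExtend))
      ok <- ac$a != "-" & ac$b != "-" & ac$a != "N" & ac$b != "N"
      if (!any(ok)) {
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     labs[i], labs[j]), call. = FALSE)
      }
      d[i, j] <- d[j, i] <- mean(ac$a[ok] != ac$b[ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining with the Saitou-Nei Q criterion. Ties in Q
#' are broken by the lexicographically smallest pair of node labels (an
#' internal node carries the smallest leaf label it contains). Negative
#' branch-length estimates are clamped to zero, with the total clamped
#' deficit attached as the `"negative_branch_deficit"` attribute.
#'
#' @param d Symmetric numeric matrix with labels as dimnames (>= 3 taxa).
#' @return An unrooted `phylo` object (trifurcating root node).
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("'d' must be a square matrix", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop("'d' must be symmetric", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  newick <- labs
  minLab <- labs
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) {
      deficit <<- deficit - x
      0
    } else x
  }
  fmt <- function(x) sprintf("%.10g", x)
  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    ties <- which(q - qmin < 1e-12, arr.ind = TRUE)
    ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
    keys <- apply(ties, 1L, function(ij) {
      paste(sort(c(minLab[ij[1]], minLab[ij[2]])), collapse = "\r")
    })
    pick <- ties[order(keys)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    node <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(li), newick[j], fmt(lj))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    newick <- c(newick[keep], node)
    minLab <- c(minLab[keep], min(minLab[c(i, j)]))
    rownames(d2) <- colnames(d2) <- NULL
    d <- pmax(d2, 0)
    n <- n - 1L
  }
  l1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 newick[1], fmt(l1), newick[2], fmt(l2), newick[3], fmt(l3))
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_branch_deficit") <- deficit
  tree
}

#' Per-cluster consensus sequences and similarity tree
#'
#' Convenience wrapper running align, consensus, p-distance and neighbor
#' joining over a list of per-cluster sequence sets.
#'
#' @param clusterSeqs Named list of `DNAStringSet`s (or character vectors),
#'   one per cluster.
#' @inheritParams alignDna
#' @param minFrac Consensus majority threshold.
#' @return A list with `consensus` (named character vector), `distance`
#'   (matrix) and `tree` (`phylo`).
#' @export
clusterConsensusTree <- function(clusterSeqs, match = 1, mismatch = -1,
                                 gapOpen = -4, gapExtend = -1,
                                 minFrac = 0.5) {
  stopifnot(is.list(clusterSeqs), length(clusterSeqs) >= 3L)
  if (is.null(names(clusterSeqs))) {
    names(clusterSeqs) <- paste0("cluster", seq_along(clusterSeqs))
  }
  cons <- vapply(clusterSeqs, function(s) {
    consensusFromMsa(progressiveAlign(s, match, mismatch, gapOpen,
                                      gapExtend), minFrac)
  }, "")
  d <- pdistanceMatrix(cons, match, mismatch, gapOpen, gapExtend)
  list(consensus = cons, distance = d, tree = njTree(d))
}
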