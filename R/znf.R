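# C2H2 zinc-finger motif detection, KRAB-domain scoring, in-frame
# KRAB-to-ZNF ORF scanning, and zinc-fingerprint extraction.

# Order in which C-X(2,4)-C-X(12)-H-X(3,4)-H gap combinations are tried at a
# candidate position: total motif length ascending (shortest match wins),
# then the C-C gap ascending. Total length = 16 + cgap + hgap, i.e. 21-24.
C2H2_GAP_ORDER <- list(c(2L, 3L), c(2L, 4L), c(3L, 3L),
                       c(3L, 4L), c(4L, 3L), c(4L, 4L))

#' Find C2H2 zinc-finger motifs in a protein sequence
#'
#' Scans left to right for the canonical C2H2 pattern
#' `C-X(2,4)-C-X(12)-H-X(3,4)-H` (21-24 residues). At each candidate
#' position the shortest match is taken and scanning resumes after the final
#' histidine, so reported motifs are non-overlapping. The ambiguity code `X`
#' never matches a zinc-coordinating anchor position.
#'
#' @param protein An [Biostrings::AAString], single-element `AAStringSet`, or
#'   character scalar over the 20-letter alphabet plus `X`.
#' @return A data.frame with one row per motif: `start`, `end` (1-based
#'   inclusive protein offsets), anchor positions `c1`, `c2`, `h1`, `h2`,
#'   the 12-residue `spacer` between the second cysteine and first
#'   histidine, and the `linker` (up to 7 residues following the motif).
#' @examples
#' findC2H2Motifs("CPVESCDRRFSRSDELTRHIRIH")
#' @seealso [extractFingerprint()]
#' @export
findC2H2Motifs <- function(protein) {
  s <- asProteinString(protein)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  rows <- vector("list", 8L)
  nrows <- 0L
  i <- 1L
  while (i + 20L <= n) {
    if (chars[i] == "C") {
      matched <- FALSE
      for (gaps in C2H2_GAP_ORDER) {
        c2 <- i + gaps[1] + 1L
        h1 <- c2 + 13L
        h2 <- h1 + gaps[2] + 1L
        if (h2 <= n && chars[c2] == "C" && chars[h1] == "H" && chars[h2] == "H") {
          nrows <- nrows + 1L
          rows[[nrows]] <- data.frame(
            start = i, end = h2, c1 = i, c2 = c2, h1 = h1, h2 = h2,
            spacer = substr(s, c2 + 1L, h1 - 1L),
            linker = substr(s, h2 + 1L, min(h2 + 7L, n)),
            stringsAsFactors = FALSE
          )
          i <- h2 + 1L
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  if (nrows == 0L) {
    return(data.frame(start = integer(), end = integer(), c1 = integer(),
                      c2 = integer(), h1 = integer(), h2 = integer(),
                      spacer = character(), linker = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows[seq_len(nrows)])
}

#' @noRd
asProteinString <- function(protein) {
  if (methods::is(protein, "XStringSet")) {
    if (length(protein) != 1L) stop("supply a single protein sequence", call. = FALSE)
    protein <- protein[[1]]
  }
  if (methods::is(protein, "XString")) protein <- as.character(protein)
  if (!is.character(protein) || length(protein) != 1L) {
    stop("'protein' must be a single sequence", call. = FALSE)
  }
  protein
}

#' Extract the zinc fingerprint of a ZNF array
#'
#' The fingerprint is the ordered list of specificity triplets, one per
#' finger: the residues at alpha-helix positions -1, +3 and +6, which are
#' the residues at positions 6, 9 and 12 of the 12-residue spacer between
#' the second cysteine and the first histidine (equivalently 7, 4 and 1
#' positions before the first histidine).
#'
#' @param motifs A data.frame from [findC2H2Motifs()].
#' @return Character vector of 3-letter triplets in N-to-C motif order.
#' @examples
#' m <- findC2H2Motifs("CPVESCDRRFSRSDELTRHIRIH")
#' extractFingerprint(m)  # "RER", the canonical Zif268 finger-1 triplet
#' @export
extractFingerprint <- function(motifs) {
  if (!is.data.frame(motifs) || is.null(motifs$spacer)) {
    stop("'motifs' must come from findC2H2Motifs()", call. = FALSE)
  }
  if (any(nchar(motifs$spacer) != 12L)) {
    stop("all spacers must be exactly 12 residues", call. = FALSE)
  }
  vapply(motifs$spacer, function(sp) {
    paste0(substr(sp, 6L, 6L), substr(sp, 9L, 9L), substr(sp, 12L, 12L))
  }, "", USE.NAMES = FALSE)
}

#' Dash-join / split zinc fingerprints
#'
#' Fingerprints are serialised as dash-joined triplets (e.g. `"RER-QSN"`).
#'
#' @param fp Character vector of triplets.
#' @return `fingerprintString()`: a single string; `parseFingerprint()`: a
#'   character vector of triplets.
#' @export
fingerprintString <- function(fp) paste(fp, collapse = "-")

#' @rdname fingerprintString
#' @param x A dash-joined fingerprint string.
#' @export
parseFingerprint <- function(x) {
  if (!nzchar(x)) return(character())
  strsplit(x, "-", fixed = TRUE)[[1]]
}

#' Canonical KRAB-A box consensus packaged for detection and simulation
#'
#' A 42-residue KRAB-A box consensus used both to build the default scoring
#' model ([krabPssm()]) and as the planting template of the synthetic-genome
#' generator, which keeps sensitivity analyses self-consistent.
#'
#' @return A 42-character amino-acid string.
#' @export
krabConsensus <- function() {
  "RTLVTFKDVFVDFTREEWKLLDTAQQIVYRNVMLENYKNLVS"
}

#' Position-specific scoring matrix for the KRAB-A box
#'
#' Builds a log2-odds PSSM over the 20 standard amino acids against a
#' uniform background: the consensus residue of each column receives
#' probability `pConsensus`, the remaining mass is spread over the other 19
#' residues. Stop codons and `X` never contribute positively.
#'
#' @param consensus Amino-acid consensus string (default [krabConsensus()]).
#' @param pConsensus Probability mass on the consensus residue per column.
#' @return A 20 x nchar(consensus) numeric matrix (bits), with attribute
#'   `max_score` giving the maximum attainable window score.
#' @export
krabPssm <- function(consensus = krabConsensus(), pConsensus = 0.9) {
  stopifnot(isNumber(pConsensus), pConsensus > 0, pConsensus < 1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  if (!all(cons %in% aa)) {
    stop("consensus contains letters outside the 20-letter alphabet",
         call. = FALSE)
  }
  w <- length(cons)
  pssm <- matrix(log2((1 - pConsensus) / 19 / (1 / 20)),
                 nrow = 20L, ncol = w, dimnames = list(aa, NULL))
  pssm[cbind(match(cons, aa), seq_len(w))] <- log2(pConsensus / (1 / 20))
  attr(pssm, "max_score") <- sum(apply(pssm, 2L, max))
  pssm
}

# Score every window of a translated frame against the PSSM. Residues
# outside the PSSM alphabet (stops, X) receive a prohibitive penalty so no
# window containing them can reach a sensible threshold.
#' @noRd
scoreProteinWindows <- function(protein, pssm) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  w <- ncol(pssm)
  n <- length(chars)
  if (n < w) return(numeric(0))
  code <- match(chars, rownames(pssm))
  nwin <- n - w + 1L
  scores <- numeric(nwin)
  for (col in seq_len(w)) {
    contrib <- pssm[, col][code[col:(col + nwin - 1L)]]
    contrib[is.na(contrib)] <- -1000
    scores <- scores + contrib
  }
  scores
}

# Greedy merge of overlapping above-threshold windows within one frame,
# keeping the maximum-scoring window of each overlap group.
#' @noRd
pickWindowMaxima <- function(scores, threshold, width) {
  cand <- which(scores >= threshold)
  picked <- integer(0)
  while (length(cand)) {
    best <- cand[which.max(scores[cand])]
    picked <- c(picked, best)
    cand <- cand[abs(cand - best) >= width]
  }
  sort(picked)
}

# Translate the six frames of a DNA sequence. Returns a list of frames with
# strand, frame offset (0-2) and the protein string (stops as "*").
#' @noRd
sixFrames <- function(dna) {
  if (is.character(dna)) dna <- Biostrings::DNAString(dna)
  if (methods::is(dna, "DNAStringSet")) {
    if (length(dna) != 1L) stop("supply a single DNA sequence", call. = FALSE)
    dna <- dna[[1]]
  }
  L <- length(dna)
  rc <- Biostrings::reverseComplement(dna)
  frames <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") dna else rc
    for (f in 0:2) {
      len <- 3L * ((L - f) %/% 3L)
      if (len < 3L) next
      sub <- Biostrings::subseq(src, f + 1L, f + len)
      prot <- suppressWarnings(as.character(
        Biostrings::translate(sub, if.fuzzy.codon = "X")
      ))
      frames[[length(frames) + 1L]] <- list(strand = strand, frame = f,
                                            protein = prot, dnaLength = L)
    }
  }
  frames
}

# Map a protein-coordinate interval [aaStart, aaEnd] of a given frame back
# to 1-based genomic coordinates.
#' @noRd
frameToGenomic <- function(aaStart, aaEnd, frame, strand, dnaLength) {
  ntStart <- frame + 3L * (aaStart - 1L) + 1L
  ntEnd <- frame + 3L * aaEnd
  if (strand == "+") {
    c(ntStart, ntEnd)
  } else {
    c(dnaLength - ntEnd + 1L, dnaLength - ntStart + 1L)
  }
}

#' Detect KRAB domains in genomic DNA
#'
#' Translates all six frames and scores every window against a KRAB-A
#' position-specific scoring matrix. Hits are above-threshold local score
#' maxima; overlapping hits within one frame are merged keeping the
#' maximum. The default threshold is 60\% of the maximum attainable score.
#'
#' @param dna A [Biostrings::DNAString], single-element `DNAStringSet`, or
#'   character scalar over `ACGTN`.
#' @param pssm Scoring matrix from [krabPssm()] (or compatible: amino-acid
#'   row names, one column per consensus position).
#' @param threshold Minimum window score in bits.
#' @param seqname Chromosome name attached to the returned ranges.
#' @return A `GRanges` of KRAB hits with metadata columns `score` and
#'   `frame`.
#' @export
detectKrab <- function(dna, pssm = krabPssm(),
                       threshold = 0.6 * attr(pssm, "max_score"),
                       seqname = "seq") {
  if (is.null(rownames(pssm))) {
    stop("'pssm' must have amino-acid row names", call. = FALSE)
  }
  if (!all(rownames(pssm) %in% strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1]])) {
    stop("'pssm' row alphabet is not amino acids", call. = FALSE)
  }
  w <- ncol(pssm)
  hits <- list()
  for (fr in sixFrames(dna)) {
    scores <- scoreProteinWindows(fr$protein, pssm)
    for (p in pickWindowMaxima(scores, threshold, w)) {
      g <- frameToGenomic(p, p + w - 1L, fr$frame, fr$strand, fr$dnaLength)
      hits[[length(hits) + 1L]] <- data.frame(
        start = g[1], end = g[2], strand = fr$strand, frame = fr$frame,
        score = scores[p], aa_pos = p
      )
    }
  }
  if (!length(hits)) {
    return(GenomicRanges::GRanges(score = numeric(), frame = integer()))
  }
  df <- do.call(rbind, hits)
  GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    score = df$score,
    frame = df$frame
  )
}

#' Scan genomic DNA for in-frame KRAB-to-ZNF open reading frames
#'
#' For every KRAB hit in every frame and strand, the translation is extended
#' to the next stop codon and the KRAB-to-stop segment is scanned for C2H2
#' motifs. An ORF is reported when at least `minZnf` motifs follow the KRAB
#' domain with no intervening stop codon (guaranteed by construction, since
#' the scanned segment ends at the first stop).
#'
#' @inheritParams detectKrab
#' @param minZnf Minimum number of C2H2 motifs (default 3, matching the
#'   three consecutive finger motifs of the anchoring repeat consensus).
#' @return A `GRanges`, one range per ORF (KRAB start through stop codon, or
#'   segment end when no stop occurs), with metadata columns `krab_score`,
#'   `frame`, `n_znf`, `fingerprint` (dash-joined triplets) and `protein`
#'   (the KRAB-to-stop amino-acid sequence).
#' @export
scanKzfpOrfs <- function(dna, pssm = krabPssm(),
                         threshold = 0.6 * attr(pssm, "max_score"),
                         minZnf = 3L, seqname = "seq") {
  stopifnot(isCount(minZnf, min = 1))
  w <- ncol(pssm)
  orfs <- list()
  seen <- character(0)
  for (fr in sixFrames(dna)) {
    scores <- scoreProteinWindows(fr$protein, pssm)
    chars <- strsplit(fr$protein, "", fixed = TRUE)[[1]]
    stops <- which(chars == "*")
    for (p in pickWindowMaxima(scores, threshold, w)) {
      nextStop <- stops[stops >= p]
      segEnd <- if (length(nextStop)) nextStop[1] - 1L else length(chars)
      key <- paste(fr$strand, fr$frame, segEnd, sep = ":")
      if (key %in% seen) next
      segment <- substr(fr$protein, p, segEnd)
      motifs <- findC2H2Motifs(segment)
      if (nrow(motifs) < minZnf) next
      seen <- c(seen, key)
      genEnd <- min(segEnd + 1L, length(chars))  # include the stop codon
      g <- frameToGenomic(p, genEnd, fr$frame, fr$strand, fr$dnaLength)
      orfs[[length(orfs) + 1L]] <- data.frame(
        start = g[1], end = g[2], strand = fr$strand, frame = fr$frame,
        krab_score = scores[p], n_znf = nrow(motifs),
        fingerprint = fingerprintString(extractFingerprint(motifs)),
        protein = segment, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(orfs)) {
    return(GenomicRanges::GRanges(krab_score = numeric(), frame = integer(),
                                  n_znf = integer(), fingerprint = character(),
                                  protein = character()))
  }
  df <- do.call(rbind, orfs)
  df <- df[order(df$start, df$end), , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    krab_score = df$krab_score,
    frame = df$frame,
    n_znf = df$n_znf,
    fingerprint = df$fingerprint,
    protein = df$protein
  )
}
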