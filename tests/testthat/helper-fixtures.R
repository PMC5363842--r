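# Shared fixture builders (all data generated in code at test time).

gr <- function(chrom, start, end, strand = "*", name = NULL) {
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                strand = strand)
  if (!is.null(name)) out$name <- name
  out
}

# Deterministic amino-acid -> DNA encoding for constructing test sequences.
TEST_CODON <- c(
  A = "GCA", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGA",
  H = "CAC", I = "ATC", K = "AAG", L = "CTC", M = "ATG", N = "AAC",
  P = "CCA", Q = "CAG", R = "AGA", S = "AGC", T = "ACA", V = "GTC",
  W = "TGG", Y = "TAC"
)

encodeAA <- function(aa) {
  paste(TEST_CODON[strsplit(aa, "", fixed = TRUE)[[1]]], collapse = "")
}

# A canonical 21-residue C2H2 finger with a chosen specificity triplet at
# spacer positions 6/9/12, followed by the conserved linker.
makeFinger <- function(triplet = "RER", cg = 2, hg = 3) {
  sp <- rep("S", 12)
  tri <- strsplit(triplet, "", fixed = TRUE)[[1]]
  sp[c(6, 9, 12)] <- tri
  paste0("C", strrep("A", cg), "C", paste(sp, collapse = ""),
         "H", strrep("A", hg), "H", "TGEKPY")
}

# DNA of a minimal KRAB -> spacer -> n-finger gene in frame 0.
makeKzfpGeneDna <- function(nFingers = 3, triplets = NULL, spacerAa = 20,
                            withStop = FALSE) {
  if (is.null(triplets)) triplets <- rep("RER", nFingers)
  fingers <- paste(vapply(triplets, makeFinger, ""), collapse = "")
  spacer <- strrep("Q", spacerAa)
  aa <- paste0(krabConsensus(), spacer, fingers)
  dna <- encodeAA(aa)
  if (withStop) {
    # replace the middle spacer codon with a stop
    pos <- (nchar(krabConsensus()) + spacerAa %/% 2) * 3 + 1
    substr(dna, pos, pos + 2) <- "TAA"
  }
  paste0(dna, "TGA")
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randomFingerprint <- function(n, nSymbols = 5) {
  symbols <- vapply(seq_len(nSymbols), function(i) {
    paste(sample(LETTERS[1:12], 3, replace = TRUE), collapse = "")
  }, "")
  sample(symbols, n, replace = TRUE)
}

# Small GenomeConfig variants used across tests.
smallConfig <- function(...) {
  args <- list(
    chromLengths = c(chr1 = 200000, chr2 = 250000),
    clusterSpecs = data.frame(chrom = "chr1", n_units = 8L,
                              gap_min = 2000, gap_max = 5000),
    nIsolated = 0L, isolatedChrom = "chr2", nRetrocopies = 2L,
    tePerCluster = 30L, teBackground = 60L
  )
  do.call(genomeConfig, utils::modifyList(args, list(...)))
}
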