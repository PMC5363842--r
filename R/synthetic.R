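# Seeded synthetic-genome generator: chromosome layouts with planted unit
# clusters, isolated units and retrocopies; TE annotations with an
# ERVK/ERV1 bias inside clusters; in-frame KRAB-to-ZNF coding sequences;
# WT/KO peak sets and negative-binomial coverage; ground-truth tables.

SAFE_AA <- strsplit("ADEFGIKLNPQRSTVWY", "")[[1]]  # no C/H/M ambiguity, no stop

CODON_OF <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

#' Synthetic genome configuration
#'
#' Captures the study conditions the generator emulates: chromosomes
#' carrying clusters of repeat-anchored KZFP units (adjacent gaps far below
#' the 500 kb chaining rule), isolated units separated by gaps above it,
#' in-frame KRAB-to-ZNF coding sequences with the KRAB segment a short
#' in-frame distance upstream (well within 30 kb), an ERVK/ERV1-biased TE
#' mix inside clusters versus a LINE/SINE-dominated background, intronless
#' poly-A-tailed retrocopies of cluster genes on another chromosome, and a
#' WT/KO regulatory-signal model in which repressive peaks over unit 3'
#' ends disappear upon KO while a fraction of cluster TEs gains
#' activation-style peaks.
#'
#' @param chromLengths Named chromosome lengths (bp).
#' @param clusterSpecs data.frame with columns `chrom`, `n_units`,
#'   `gap_min`, `gap_max` (inter-gene gaps in bp), one row per planted
#'   cluster.
#' @param nIsolated Number of isolated units (placed on `isolatedChrom` in
#'   runs of at most `maxIsolatedRun`, separated by `isolationGap`).
#' @param isolatedChrom Chromosome hosting isolated units and retrocopies.
#' @param isolationGap Gap separating isolated runs (bp; must exceed the
#'   cluster chaining gap so no spurious cluster forms).
#' @param maxIsolatedRun Largest isolated run (must stay below the cluster
#'   minimum size).
#' @param nZnfRange Range of zinc-finger counts per unit.
#' @param krabOffsetRange Range of the in-frame KRAB-to-array spacer (bp;
#'   rounded to codons).
#' @param mutationRate Per-base substitution probability applied to planted
#'   coding blocks.
#' @param nRetrocopies Number of intronless poly-A-tailed retrocopies.
#' @param polyALength Genomically encoded adenine run at retrocopy 3' ends.
#' @param teMixInCluster,teMixBackground data.frames with columns
#'   `subfamily`, `family`, `class`, `prob` (probabilities summing to 1).
#' @param tePerCluster,teBackground TE counts inside each cluster span and
#'   genome-wide background.
#' @param teLenRange TE length range (bp).
#' @param peakWidth Peak width (bp).
#' @param kap1TeFraction Fraction of cluster ERVK/ERV1 TEs carrying a WT
#'   repressive peak.
#' @param enhancerGainFraction Fraction of cluster TEs gaining a KO
#'   activation peak.
#' @param coverageMeans Named list of `c(wt=, ko=)` means per expression
#'   class: `unit_cluster`, `unit_isolated`, `retrocopy`, `te_gain`,
#'   `te_other`.
#' @param dispersion Negative-binomial dispersion (0 = noise-free means).
#' @param seed Default seed used when the simulate functions get none.
#' @return A validated list of class `"GenomeConfig"`.
#' @export
genomeConfig <- function(
  chromLengths = c(chr1 = 400000, chr2 = 400000, chr3 = 400000,
                   chr4 = 1800000),
  clusterSpecs = data.frame(chrom = c("chr1", "chr2", "chr3"),
                            n_units = 10L, gap_min = 3000, gap_max = 8000),
  nIsolated = 20L,
  isolatedChrom = "chr4",
  isolationGap = 600000,
  maxIsolatedRun = 7L,
  nZnfRange = c(4L, 8L),
  krabOffsetRange = c(300, 1500),
  mutationRate = 0,
  nRetrocopies = 5L,
  polyALength = 16L,
  teMixInCluster = data.frame(
    subfamily = c("IAPEz", "RLTR10", "RLTR4", "MuRRS", "L1Md", "B1_Mus"),
    family = c("ERVK", "ERVK", "ERV1", "ERV1", "L1", "Alu"),
    class = c("LTR", "LTR", "LTR", "LTR", "LINE", "SINE"),
    prob = c(0.25, 0.15, 0.15, 0.10, 0.20, 0.15)
  ),
  teMixBackground = data.frame(
    subfamily = c("IAPEz", "RLTR10", "RLTR4", "MuRRS", "L1Md", "B1_Mus"),
    family = c("ERVK", "ERVK", "ERV1", "ERV1", "L1", "Alu"),
    class = c("LTR", "LTR", "LTR", "LTR", "LINE", "SINE"),
    prob = c(0.04, 0.03, 0.03, 0.02, 0.48, 0.40)
  ),
  tePerCluster = 40L,
  teBackground = 300L,
  teLenRange = c(300, 900),
  peakWidth = 400L,
  kap1TeFraction = 0.3,
  enhancerGainFraction = 0.4,
  coverageMeans = list(unit_cluster = c(wt = 30, ko = 120),
                       unit_isolated = c(wt = 30, ko = 30),
                       retrocopy = c(wt = 20, ko = 20),
                       te_gain = c(wt = 5, ko = 20),
                       te_other = c(wt = 5, ko = 5)),
  dispersion = 0.1,
  seed = 1L
) {
  cfg <- list(
    chromLengths = chromLengths, clusterSpecs = clusterSpecs,
    nIsolated = as.integer(nIsolated), isolatedChrom = isolatedChrom,
    isolationGap = isolationGap, maxIsolatedRun = as.integer(maxIsolatedRun),
    nZnfRange = as.integer(nZnfRange), krabOffsetRange = krabOffsetRange,
    mutationRate = mutationRate, nRetrocopies = as.integer(nRetrocopies),
    polyALength = as.integer(polyALength),
    teMixInCluster = teMixInCluster, teMixBackground = teMixBackground,
    tePerCluster = as.integer(tePerCluster),
    teBackground = as.integer(teBackground), teLenRange = teLenRange,
    peakWidth = as.integer(peakWidth), kap1TeFraction = kap1TeFraction,
    enhancerGainFraction = enhancerGainFraction,
    coverageMeans = coverageMeans, dispersion = dispersion,
    seed = as.integer(seed)
  )
  class(cfg) <- "GenomeConfig"
  validateGenomeConfig(cfg)
  cfg
}

#' @noRd
validateGenomeConfig <- function(cfg) {
  stopifnot(is.numeric(cfg$chromLengths), !is.null(names(cfg$chromLengths)),
            all(cfg$chromLengths > 0))
  for (mix in list(cfg$teMixInCluster, cfg$teMixBackground)) {
    stopifnot(is.data.frame(mix),
              all(c("subfamily", "family", "class", "prob") %in% names(mix)),
              all(nzchar(mix$subfamily)), all(nzchar(mix$class)))
    if (abs(sum(mix$prob) - 1) > 1e-6) {
      stop("TE mix probabilities must sum to 1", call. = FALSE)
    }
  }
  stopifnot(cfg$nIsolated >= 0, cfg$nRetrocopies >= 0,
            cfg$tePerCluster >= 0, cfg$teBackground >= 0,
            cfg$mutationRate >= 0, cfg$mutationRate < 1,
            cfg$dispersion >= 0,
            cfg$kap1TeFraction >= 0, cfg$kap1TeFraction <= 1,
            cfg$enhancerGainFraction >= 0, cfg$enhancerGainFraction <= 1,
            length(cfg$nZnfRange) == 2L, cfg$nZnfRange[1] >= 1,
            cfg$nZnfRange[1] <= cfg$nZnfRange[2],
            cfg$krabOffsetRange[1] >= 3,
            cfg$krabOffsetRange[1] <= cfg$krabOffsetRange[2],
            cfg$isolatedChrom %in% names(cfg$chromLengths),
            cfg$maxIsolatedRun >= 1)
  if (nrow(cfg$clusterSpecs)) {
    stopifnot(all(cfg$clusterSpecs$chrom %in% names(cfg$chromLengths)),
              all(cfg$clusterSpecs$n_units >= 1),
              all(cfg$clusterSpecs$gap_min > 0),
              all(cfg$clusterSpecs$gap_min <= cfg$clusterSpecs$gap_max))
  }
  invisible(cfg)
}

# One unit's structural design: ZNF count, per-finger gap decomposition,
# fingerprint, spacer length. The gap string "cg:hg,..." fixes the motif
# lengths, and thereby the unit width: 3 * sum(16 + cg + hg + 6).
#' @noRd
designUnit <- function(nZnf, spacerNt) {
  cg <- sample(2:4, nZnf, replace = TRUE)
  hg <- sample(3:4, nZnf, replace = TRUE)
  triplets <- vapply(seq_len(nZnf), function(i) {
    paste(sample(SAFE_AA, 3L, replace = TRUE), collapse = "")
  }, "")
  list(
    n_znf = nZnf,
    gaps = paste(paste(cg, hg, sep = ":"), collapse = ","),
    fingerprint = paste(triplets, collapse = "-"),
    spacer_nt = spacerNt,
    unit_width = 3L * sum(16L + cg + hg + 6L)
  )
}

#' @noRd
unitBlockWidth <- function(design) {
  126L + design$spacer_nt + design$unit_width
}

#' Simulate genome annotations and ground truth
#'
#' Lays out clusters of KRAB-anchored units, isolated units, retrocopies
#' and transposable elements on the configured chromosomes, and returns
#' interval annotations together with a truth table describing every
#' planted object. Sequence content is materialised separately by
#' [simulateSequences()]; regulatory signal by [simulateSignal()].
#'
#' @param config A [genomeConfig()] object.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with `units`, `krab`, `repeats`, `clusters`,
#'   `retrocopies` (`GRanges`), `truth` (master data.frame, one row per
#'   planted object) and `seqlengths`.
#' @export
simulateAnnotations <- function(config, seed = config$seed) {
  validateGenomeConfig(config)
  withSeed(seed, {
    truth <- list()
    addTruth <- function(kind, id, chrom, start, end, strand,
                         cluster_id = NA_integer_, n_znf = NA_integer_,
                         gaps = NA_character_, fingerprint = NA_character_,
                         spacer_nt = NA_integer_, donor = NA_character_,
                         subfamily = NA_character_, family = NA_character_,
                         rep_class = NA_character_, n_exons = NA_integer_) {
      truth[[length(truth) + 1L]] <<- list(
        kind = kind, id = id, chrom = chrom, start = start, end = end,
        strand = strand, cluster_id = as.integer(cluster_id),
        n_znf = as.integer(n_znf), gaps = gaps, fingerprint = fingerprint,
        spacer_nt = as.integer(spacer_nt), donor = donor,
        subfamily = subfamily, family = family, rep_class = rep_class,
        n_exons = as.integer(n_exons)
      )
    }
    materializeTruth <- function(rows) {
      fields <- names(rows[[1]])
      out <- lapply(fields, function(f) {
        unlist(lapply(rows, `[[`, f), use.names = FALSE)
      })
      names(out) <- fields
      as.data.frame(out, stringsAsFactors = FALSE)
    }
    unitCounter <- 0L
    donorPool <- list()
    placeUnit <- function(chrom, blockStart, clusterId, design, strand,
                          nExons) {
      unitCounter <<- unitCounter + 1L
      id <- sprintf("unit%03d", unitCounter)
      bw <- unitBlockWidth(design)
      if (strand == "+") {
        krabStart <- blockStart
        krabEnd <- blockStart + 125L
        unitStart <- krabEnd + design$spacer_nt + 1L
        unitEnd <- unitStart + design$unit_width - 1L
      } else {
        unitStart <- blockStart
        unitEnd <- blockStart + design$unit_width - 1L
        krabStart <- unitEnd + design$spacer_nt + 1L
        krabEnd <- krabStart + 125L
      }
      addTruth("unit", id, chrom, unitStart, unitEnd, strand,
               cluster_id = clusterId, n_znf = design$n_znf,
               gaps = design$gaps, fingerprint = design$fingerprint,
               spacer_nt = design$spacer_nt, n_exons = nExons)
      addTruth("krab", paste0(id, "_krab"), chrom, krabStart, krabEnd,
               strand, cluster_id = clusterId)
      list(id = id, blockEnd = blockStart + bw - 1L, design = design,
           chrom = chrom, strand = strand)
    }
    # ---- clusters -------------------------------------------------------
    clusterId <- 0L
    specs <- config$clusterSpecs
    for (k in seq_len(nrow(specs))) {
      clusterId <- clusterId + 1L
      chrom <- as.character(specs$chrom[k])
      cursor <- 30000L
      spacerNt <- 3L * round(stats::runif(1, config$krabOffsetRange[1],
                                          config$krabOffsetRange[2]) / 3)
      first <- TRUE
      for (u in seq_len(specs$n_units[k])) {
        gap <- round(stats::runif(1, specs$gap_min[k], specs$gap_max[k]))
        blockStart <- cursor + (if (first) 0L else gap)
        first <- FALSE
        nZnf <- sample(config$nZnfRange[1]:config$nZnfRange[2], 1L)
        design <- designUnit(nZnf, spacerNt)
        strand <- sample(c("+", "-"), 1L)
        placed <- placeUnit(chrom, blockStart, clusterId, design, strand,
                            nExons = if (u == 1L) 2L else 1L)
        if (u == 1L) donorPool[[length(donorPool) + 1L]] <- placed
        cursor <- placed$blockEnd
      }
      if (cursor > config$chromLengths[[chrom]] - 10000L) {
        stop("chromosome ", chrom, " too short for requested content",
             call. = FALSE)
      }
    }
    # ---- isolated units -------------------------------------------------
    isoChrom <- config$isolatedChrom
    cursor <- 30000L
    for (u in seq_len(config$nIsolated)) {
      if (u > 1L && (u - 1L) %% config$maxIsolatedRun == 0L) {
        cursor <- cursor + config$isolationGap
      } else if (u > 1L) {
        cursor <- cursor + round(stats::runif(1, 3000, 8000))
      }
      nZnf <- sample(config$nZnfRange[1]:config$nZnfRange[2], 1L)
      spacerNt <- 3L * round(stats::runif(1, config$krabOffsetRange[1],
                                          config$krabOffsetRange[2]) / 3)
      design <- designUnit(nZnf, spacerNt)
      strand <- sample(c("+", "-"), 1L)
      placed <- placeUnit(isoChrom, cursor, NA_integer_, design, strand,
                          nExons = 1L)
      cursor <- placed$blockEnd
    }
    # ---- retrocopies ----------------------------------------------------
    cursor <- cursor + 50000L
    if (config$nRetrocopies > 0L && !length(donorPool)) {
      stop("retrocopies requested but no cluster donors available",
           call. = FALSE)
    }
    for (r in seq_len(config$nRetrocopies)) {
      donor <- donorPool[[(r - 1L) %% length(donorPool) + 1L]]
      width <- 126L + donor$design$unit_width + config$polyALength
      start <- cursor + 20000L
      strand <- sample(c("+", "-"), 1L)
      addTruth("retrocopy", sprintf("retro%02d", r), isoChrom, start,
               start + width - 1L, strand, n_znf = donor$design$n_znf,
               gaps = donor$design$gaps,
               fingerprint = donor$design$fingerprint,
               donor = donor$id, n_exons = 1L)
      cursor <- start + width - 1L
    }
    if ((config$nIsolated > 0L || config$nRetrocopies > 0L) &&
        cursor > config$chromLengths[[isoChrom]] - 10000L) {
      stop("chromosome ", isoChrom, " too short for requested content",
           call. = FALSE)
    }
    truthDf <- materializeTruth(truth)
    # ---- cluster spans --------------------------------------------------
    units <- truthDf[truthDf$kind == "unit", ]
    for (cid in sort(unique(units$cluster_id[!is.na(units$cluster_id)]))) {
      m <- units[!is.na(units$cluster_id) & units$cluster_id == cid, ]
      addTruth("cluster", sprintf("cluster%02d", cid), m$chrom[1],
               min(m$start), max(m$end), "*", cluster_id = cid)
    }
    # ---- transposable elements -----------------------------------------
    clusters <- materializeTruth(truth)
    clusters <- clusters[clusters$kind == "cluster", ]
    teCounter <- 0L
    placeTe <- function(chrom, start, len, mixRow, clusterId) {
      teCounter <<- teCounter + 1L
      addTruth("te", sprintf("te%04d", teCounter), chrom, start,
               start + len - 1L, sample(c("+", "-"), 1L),
               cluster_id = clusterId,
               subfamily = mixRow$subfamily, family = mixRow$family,
               rep_class = mixRow$class)
    }
    for (k in seq_len(nrow(clusters))) {
      span <- clusters[k, ]
      for (t in seq_len(config$tePerCluster)) {
        len <- round(stats::runif(1, config$teLenRange[1],
                                  config$teLenRange[2]))
        start <- round(stats::runif(1, span$start,
                                    max(span$start, span$end - len)))
        row <- config$teMixInCluster[
          sample(nrow(config$teMixInCluster), 1L,
                 prob = config$teMixInCluster$prob), ]
        placeTe(span$chrom, start, len, row, span$cluster_id)
      }
    }
    lens <- config$chromLengths
    for (t in seq_len(config$teBackground)) {
      repeat {
        chrom <- sample(names(lens), 1L, prob = lens / sum(lens))
        len <- round(stats::runif(1, config$teLenRange[1],
                                  config$teLenRange[2]))
        start <- round(stats::runif(1, 1, lens[[chrom]] - len))
        inside <- any(clusters$chrom == chrom & start <= clusters$end &
                        start + len - 1L >= clusters$start)
        if (!inside) break
      }
      row <- config$teMixBackground[
        sample(nrow(config$teMixBackground), 1L,
               prob = config$teMixBackground$prob), ]
      placeTe(chrom, start, len, row, NA_integer_)
    }
    truthDf <- materializeTruth(truth)
    asGRanges <- function(df, extraCols = character()) {
      if (!nrow(df)) return(GenomicRanges::GRanges())
      gr <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$start, df$end),
                                   strand = df$strand, name = df$id)
      for (cc in extraCols) S4Vectors::mcols(gr)[[cc]] <- df[[cc]]
      gr
    }
    list(
      units = asGRanges(truthDf[truthDf$kind == "unit", ],
                        c("cluster_id", "n_znf", "fingerprint", "n_exons")),
      krab = asGRanges(truthDf[truthDf$kind == "krab", ], "cluster_id"),
      repeats = asGRanges(truthDf[truthDf$kind == "te", ],
                          c("cluster_id", "subfamily", "family", "rep_class")),
      clusters = asGRanges(truthDf[truthDf$kind == "cluster", ],
                           "cluster_id"),
      retrocopies = asGRanges(truthDf[truthDf$kind == "retrocopy", ],
                              c("n_znf", "fingerprint", "donor", "n_exons")),
      truth = truthDf,
      seqlengths = config$chromLengths
    )
  })
}

#' @noRd
aaToDna <- function(aa) {
  paste(CODON_OF[strsplit(aa, "", fixed = TRUE)[[1]]], collapse = "")
}

# Amino-acid sequence of one unit's coding block (KRAB, spacer, ZNF array)
# from its truth-row design. Spacer and X-region residues are drawn from a
# cysteine/histidine-free alphabet so the planted motif count and
# fingerprint are exact.
#' @noRd
unitProtein <- function(truthRow, spacerTemplate = NULL) {
  gaps <- strsplit(strsplit(truthRow$gaps, ",", fixed = TRUE)[[1]], ":")
  triplets <- strsplit(truthRow$fingerprint, "-", fixed = TRUE)[[1]]
  spacerLen <- truthRow$spacer_nt / 3L
  spacer <- if (!is.null(spacerTemplate)) spacerTemplate else
    paste(sample(SAFE_AA, spacerLen, replace = TRUE), collapse = "")
  fingers <- vapply(seq_along(gaps), function(i) {
    cg <- as.integer(gaps[[i]][1])
    hg <- as.integer(gaps[[i]][2])
    tri <- strsplit(triplets[i], "", fixed = TRUE)[[1]]
    sp12 <- sample(SAFE_AA, 12L, replace = TRUE)
    sp12[c(6L, 9L, 12L)] <- tri
    paste0("C", paste(sample(SAFE_AA, cg, replace = TRUE), collapse = ""),
           "C", paste(sp12, collapse = ""),
           "H", paste(sample(SAFE_AA, hg, replace = TRUE), collapse = ""),
           "H", "TGEKPY")
  }, "")
  list(krab = krabConsensus(), spacer = spacer,
       array = paste(fingers, collapse = ""))
}

#' @noRd
mutateDna <- function(dna, rate) {
  if (rate <= 0) return(dna)
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' @noRd
revcompChar <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Simulate genome sequence for planted annotations
#'
#' Builds a random background genome and writes every planted unit and
#' retrocopy coding block into it: a KRAB-A segment (the packaged
#' consensus), an in-frame stop-free spacer, and the designed C2H2 finger
#' array joined by TGEKPY linkers, with per-base substitutions at the
#' configured mutation rate. Units sharing a cluster share a spacer
#' template (their common ancestry); donor units carry the spacer as an
#' annotated intron while retrocopies carry the spliced KRAB+array copy
#' followed by a genomically encoded adenine run. Minus-strand blocks are
#' written as reverse complements.
#'
#' @param config A [genomeConfig()] object.
#' @param ann Result of [simulateAnnotations()] on the same config.
#' @param seed Integer seed.
#' @return A named `DNAStringSet`, one sequence per chromosome.
#' @export
simulateSequences <- function(config, ann, seed = config$seed) {
  validateGenomeConfig(config)
  if (!identical(names(config$chromLengths), names(ann$seqlengths))) {
    stop("annotations do not match this config", call. = FALSE)
  }
  withSeed(seed + 1L, {
    genome <- lapply(config$chromLengths, function(L) {
      sample(c("A", "C", "G", "T"), L, replace = TRUE)
    })
    truth <- ann$truth
    units <- truth[truth$kind == "unit", ]
    # per-cluster shared spacer templates
    spacerTemplates <- list()
    for (cid in sort(unique(units$cluster_id[!is.na(units$cluster_id)]))) {
      len <- units$spacer_nt[!is.na(units$cluster_id) &
                               units$cluster_id == cid][1] / 3L
      spacerTemplates[[as.character(cid)]] <-
        paste(sample(SAFE_AA, len, replace = TRUE), collapse = "")
    }
    writeBlock <- function(chrom, start, end, dna) {
      stopifnot(nchar(dna) == end - start + 1L)
      genome[[chrom]][start:end] <<- strsplit(dna, "", fixed = TRUE)[[1]]
    }
    proteins <- list()
    for (i in seq_len(nrow(units))) {
      row <- units[i, ]
      tmpl <- if (!is.na(row$cluster_id)) {
        spacerTemplates[[as.character(row$cluster_id)]]
      } else NULL
      prot <- unitProtein(row, tmpl)
      proteins[[row$id]] <- prot
      dna <- paste0(aaToDna(prot$krab), aaToDna(prot$spacer),
                    aaToDna(prot$array))
      dna <- mutateDna(dna, config$mutationRate)
      blockStart <- if (row$strand == "+") row$start - 126L - row$spacer_nt
                    else row$start
      blockEnd <- blockStart + nchar(dna) - 1L
      if (row$strand == "-") dna <- revcompChar(dna)
      writeBlock(row$chrom, blockStart, blockEnd, dna)
    }
    retros <- truth[truth$kind == "retrocopy", ]
    for (i in seq_len(nrow(retros))) {
      row <- retros[i, ]
      donorProt <- proteins[[row$donor]]
      dna <- paste0(aaToDna(donorProt$krab), aaToDna(donorProt$array),
                    strrep("A", config$polyALength))
      dna <- mutateDna(dna, config$mutationRate)
      if (row$strand == "-") dna <- revcompChar(dna)
      writeBlock(row$chrom, row$start, row$end, dna)
    }
    Biostrings::DNAStringSet(
      setNames(vapply(genome, paste, "", collapse = ""),
               names(config$chromLengths))
    )
  })
}

#' Simulate WT/KO peak sets and coverage
#'
#' WT places repressor-style peaks over unit 3' ends and over a configured
#' fraction of cluster ERVK/ERV1 elements; KO removes them and adds
#' activation-style peaks over a configured fraction of cluster TEs.
#' Per-element coverage is drawn from a negative-binomial model whose mean
#' depends on the element's truth expression class (cluster units are
#' upregulated in KO; isolated units, retrocopies and untouched TEs are
#' unchanged; enhancer-gaining TEs are upregulated).
#'
#' @param config A [genomeConfig()] object.
#' @param ann Result of [simulateAnnotations()].
#' @param seed Integer seed.
#' @return A list with `peaks_wt`, `peaks_ko` (`GRanges`), `elements` (a
#'   `GRanges` over units, retrocopies and TEs with `kind`, `expr_class`,
#'   `count_wt`, `count_ko`), and `track_wt`, `track_ko`
#'   ([CoverageTrack-class]).
#' @export
simulateSignal <- function(config, ann, seed = config$seed) {
  validateGenomeConfig(config)
  withSeed(seed + 2L, {
    units <- ann$units
    tes <- ann$repeats
    retros <- ann$retrocopies
    w <- config$peakWidth
    lens <- ann$seqlengths
    peaksAt <- function(chroms, centers) {
      if (!length(centers)) {
        return(GenomicRanges::GRanges())
      }
      start <- pmax(1, round(centers - w / 2))
      end <- pmin(unname(lens[chroms]), start + w - 1L)
      GenomicRanges::GRanges(chroms, IRanges::IRanges(start, end))
    }
    # WT repressive peaks: unit 3' ends + selected cluster ERVK/ERV1 TEs
    ustrand <- effectiveStrand(units)
    end3 <- ifelse(ustrand == "+", BiocGenerics::end(units),
                   BiocGenerics::start(units))
    inClTe <- which(!is.na(tes$cluster_id))
    ervTe <- inClTe[as.character(tes$family)[inClTe] %in% c("ERVK", "ERV1")]
    nKap1 <- round(config$kap1TeFraction * length(ervTe))
    kap1Te <- if (nKap1 > 0) sort(ervTe[sample.int(length(ervTe), nKap1)])
              else integer(0)
    teMid <- (BiocGenerics::start(tes) + BiocGenerics::end(tes)) / 2
    teChrom <- as.character(GenomeInfoDb::seqnames(tes))
    peaksWt <- suppressWarnings(c(
      peaksAt(as.character(GenomeInfoDb::seqnames(units)), end3),
      peaksAt(teChrom[kap1Te], teMid[kap1Te])
    ))
    # KO activation peaks over a fraction of cluster TEs
    nGain <- round(config$enhancerGainFraction * length(inClTe))
    gainTe <- if (nGain > 0) sort(inClTe[sample.int(length(inClTe), nGain)])
              else integer(0)
    peaksKo <- peaksAt(teChrom[gainTe], teMid[gainTe])
    # expression classes and counts
    elements <- suppressWarnings(c(
      GenomicRanges::granges(units),
      GenomicRanges::granges(retros),
      GenomicRanges::granges(tes)
    ))  # seqlevel merging across chromosomes is intended here
    elements$name <- c(units$name, retros$name, tes$name)
    elements$kind <- c(rep("unit", length(units)),
                       rep("retrocopy", length(retros)),
                       rep("te", length(tes)))
    teClass <- rep("te_other", length(tes))
    teClass[gainTe] <- "te_gain"
    elements$model_class <- c(
      ifelse(is.na(units$cluster_id), "unit_isolated", "unit_cluster"),
      rep("retrocopy", length(retros)),
      teClass
    )
    elements$expr_class <- ifelse(
      elements$model_class %in% c("unit_cluster", "te_gain"), "up",
      "unchanged"
    )
    drawCount <- function(mu) {
      if (config$dispersion <= 0) return(mu)
      stats::rnbinom(1L, size = 1 / config$dispersion, mu = mu)
    }
    elements$count_wt <- vapply(elements$model_class, function(cl) {
      drawCount(config$coverageMeans[[cl]][["wt"]])
    }, numeric(1))
    elements$count_ko <- vapply(elements$model_class, function(cl) {
      drawCount(config$coverageMeans[[cl]][["ko"]])
    }, numeric(1))
    trackFor <- function(counts) {
      gr <- GenomicRanges::granges(elements)
      gr$score <- counts
      coverageTrack(gr, lens)
    }
    list(peaks_wt = peaksWt, peaks_ko = peaksKo, elements = elements,
         track_wt = trackFor(elements$count_wt),
         track_ko = trackFor(elements$count_ko))
  })
}

#' Write a simulated dataset as plain-text files
#'
#' Emits the standard formats the pipeline consumes: genome FASTA, BED
#' files for units, KRAB hits, clusters and per-condition peaks, a
#' RepeatMasker-style TSV for TEs, per-condition bedGraph coverage, and the
#' truth table as TSV.
#'
#' @param dir Output directory (created if needed).
#' @param ann Result of [simulateAnnotations()].
#' @param genome Optional `DNAStringSet` from [simulateSequences()].
#' @param signal Optional result of [simulateSignal()].
#' @return Invisibly, the named vector of written paths.
#' @export
writeSyntheticDataset <- function(dir, ann, genome = NULL, signal = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(name, fn) {
    p <- file.path(dir, name)
    fn(p)
    paths[name] <<- p
  }
  wr("units.bed", function(p) writeBed(ann$units, p))
  wr("krab.bed", function(p) writeBed(ann$krab, p))
  wr("clusters.bed", function(p) writeBed(ann$clusters, p))
  wr("repeats.tsv", function(p) {
    df <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(ann$repeats)),
      start = BiocGenerics::start(ann$repeats),
      end = BiocGenerics::end(ann$repeats),
      strand = as.character(BiocGenerics::strand(ann$repeats)),
      subfamily = ann$repeats$subfamily,
      family = ann$repeats$family,
      rep_class = ann$repeats$rep_class
    )
    writeTsv(df, p)
  })
  wr("truth.tsv", function(p) writeTsv(ann$truth, p))
  if (!is.null(genome)) {
    wr("genome.fa", function(p) writeFasta(genome, p))
  }
  if (!is.null(signal)) {
    wr("peaks_wt.bed", function(p) writeBed(signal$peaks_wt, p))
    wr("peaks_ko.bed", function(p) writeBed(signal$peaks_ko, p))
    wr("coverage_wt.bedgraph", function(p) {
      writeBedGraph(trackToBedGraph(signal$track_wt), p)
    })
    wr("coverage_ko.bedgraph", function(p) {
      writeBedGraph(trackToBedGraph(signal$track_ko), p)
    })
    wr("elements.tsv", function(p) {
      writeTsv(as.data.frame(signal$elements), p)
    })
  }
  invisible(paths)
}

#' @noRd
trackToBedGraph <- function(track) {
  gr <- methods::as(coverageRle(track), "GRanges")
  names(S4Vectors::mcols(gr)) <- "score"
  gr[gr$score != 0]
}
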