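# End-to-end demo pipeline over the synthetic-genome generator: every
# analysis stage run on one seeded dataset, with plain-text outputs and a
# truth-table comparison summary.

#' @noRd
extractSeq <- function(genome, chrom, start, end, strand) {
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Recovery of truth loci by ORF calls
#'
#' @param orfs `GRanges` from [scanKzfpOrfs()] (any chromosome mix).
#' @param truthLoci `GRanges` of planted coding loci (units, retrocopies).
#' @return A list with `sensitivity`, `precision`, `n_calls`, `n_truth`.
#' @export
orfRecovery <- function(orfs, truthLoci) {
  checkGRanges(orfs)
  checkGRanges(truthLoci)
  if (!length(truthLoci)) stop("empty truth set", call. = FALSE)
  hitTruth <- IRanges::overlapsAny(truthLoci, orfs)
  hitCall <- IRanges::overlapsAny(orfs, truthLoci)
  list(sensitivity = mean(hitTruth),
       precision = if (length(orfs)) mean(hitCall) else NA_real_,
       n_calls = length(orfs), n_truth = length(truthLoci))
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Generates a seeded synthetic genome (annotations, sequence, WT/KO
#' signal), runs every analysis stage — ORF scanning, cluster building, TE
#' subfamily enrichment, peak-shuffle enrichment, per-cluster consensus
#' and neighbor-joining tree, retrocopy detection, response
#' classification, per-cluster fold-change summaries, metaprofiles and
#' differential-acetylation summaries — and writes all inputs and outputs
#' as plain-text files. Given the same config and seed the output files
#' are byte-identical across runs.
#'
#' @param outDir Output directory.
#' @param seed Integer seed driving all randomness.
#' @param config A [genomeConfig()]; defaults to the packaged demo
#'   conditions (3 clusters of 10 units, 20 isolated units, 5
#'   retrocopies).
#' @param nShuffles Shuffles for the peak-enrichment null.
#' @return Invisibly, a list with the main result objects and a `summary`
#'   list of headline numbers (also written to `summary.tsv`).
#' @export
runDemoPipeline <- function(outDir, seed = 1L,
                            config = genomeConfig(seed = seed),
                            nShuffles = 100L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulateAnnotations(config, seed)
  genome <- simulateSequences(config, ann, seed)
  signal <- simulateSignal(config, ann, seed)
  writeSyntheticDataset(outDir, ann, genome, signal)

  # ORF scanning over every chromosome
  orfs <- GenomicRanges::GRangesList(lapply(names(genome), function(chrom) {
    scanKzfpOrfs(genome[[chrom]], seqname = chrom)
  }))
  orfs <- unlist(orfs)
  truthLoci <- c(GenomicRanges::granges(ann$units),
                 GenomicRanges::granges(ann$retrocopies))
  rec <- orfRecovery(orfs, truthLoci)
  writeTsv(as.data.frame(orfs), file.path(outDir, "orfs.tsv"))

  # clusters
  cl <- buildClusters(ann$units)
  writeTsv(clusterTable(cl), file.path(outDir, "cluster_table.tsv"))
  truthSets <- lapply(split(ann$units$name, ann$units$cluster_id), sort)
  foundSets <- lapply(split(
    clusterElements(cl)$name, clusterElements(cl)$cluster_id
  ), sort)
  clusterRecovery <- length(truthSets) == length(foundSets) &&
    all(vapply(seq_along(truthSets), function(i) {
      identical(truthSets[[i]], foundSets[[i]])
    }, logical(1)))

  # TE subfamily enrichment inside clusters
  subfam <- subfamilyEnrichment(cl, ann$repeats)
  writeTsv(subfam, file.path(outDir, "subfamily_enrichment.tsv"))

  # peak enrichment against the within-chromosome shuffle null
  shuf <- shuffleEnrichment(clusterSpans(cl), signal$peaks_wt,
                            ann$seqlengths, nShuffles = nShuffles,
                            mode = "shuffle_features", seed = seed)
  writeTsv(data.frame(observed = observedCount(shuf),
                      expected = expectedCount(shuf),
                      empirical_p = empiricalP(shuf),
                      n_shuffles = nShuffles),
           file.path(outDir, "peak_shuffle.tsv"))

  # per-cluster consensus and similarity tree
  clSeqs <- lapply(split(seq_along(ann$units),
                         ann$units$cluster_id), function(idx) {
    vapply(idx, function(i) {
      extractSeq(genome,
                 as.character(GenomeInfoDb::seqnames(ann$units))[i],
                 BiocGenerics::start(ann$units)[i],
                 BiocGenerics::end(ann$units)[i],
                 as.character(BiocGenerics::strand(ann$units))[i])
    }, "")
  })
  names(clSeqs) <- paste0("cluster", names(clSeqs))
  phylo <- clusterConsensusTree(clSeqs)
  writeFasta(setNames(phylo$consensus, names(clSeqs)),
             file.path(outDir, "cluster_consensus.fa"))
  writeTsv(cbind(data.frame(cluster = rownames(phylo$distance)),
                 as.data.frame(phylo$distance)),
           file.path(outDir, "cluster_distance.tsv"))
  writeNewick(phylo$tree, file.path(outDir, "cluster_tree.nwk"))

  # retrocopy detection: retrocopies and all units as candidates, cluster
  # donor genes (2 exons) as donors
  truth <- ann$truth
  units <- truth[truth$kind == "unit", ]
  krabs <- truth[truth$kind == "krab", ]
  retros <- truth[truth$kind == "retrocopy", ]
  geneBlock <- function(row) {
    kr <- krabs[krabs$id == paste0(row$id, "_krab"), ]
    extractSeq(genome, row$chrom, min(row$start, kr$start),
               max(row$end, kr$end), row$strand)
  }
  donors <- units[units$n_exons >= 2L, ]
  donorSeqs <- setNames(vapply(seq_len(nrow(donors)), function(i) {
    row <- donors[i, ]
    kr <- krabs[krabs$id == paste0(row$id, "_krab"), ]
    paste0(extractSeq(genome, row$chrom, kr$start, kr$end, row$strand),
           extractSeq(genome, row$chrom, row$start, row$end, row$strand))
  }, ""), donors$id)
  candRows <- rbind(retros[, c("id", "chrom", "start", "end", "strand",
                               "n_exons")],
                    units[, c("id", "chrom", "start", "end", "strand",
                              "n_exons")])
  candSeqs <- setNames(vapply(seq_len(nrow(candRows)), function(i) {
    row <- candRows[i, ]
    if (row$id %in% units$id) geneBlock(units[units$id == row$id, ])
    else extractSeq(genome, row$chrom, row$start, row$end, row$strand)
  }, ""), candRows$id)
  retroCalls <- detectRetrocopies(candSeqs,
                                  setNames(candRows$n_exons, candRows$id),
                                  donorSeqs,
                                  setNames(donors$n_exons, donors$id))
  writeTsv(retroCalls, file.path(outDir, "retrocopy_calls.tsv"))
  retroSens <- mean(retroCalls$verdict[retroCalls$candidate %in% retros$id])
  retroFp <- sum(retroCalls$verdict[retroCalls$candidate %in% units$id])

  # response classification and per-cluster summaries
  el <- signal$elements
  calls <- classifyResponse(el$count_wt, el$count_ko, labels = el$name)
  writeTsv(calls, file.path(outDir, "response_calls.tsv"))
  inCl <- IRanges::overlapsAny(el, clusterSpans(cl)) & el$kind != "retrocopy"
  category <- ifelse(el$kind == "unit", "KZFP/rGU",
               ifelse(el$kind == "te" &
                        overlapFamily(el, ann$repeats) == "ERVK", "ERVK",
               ifelse(el$kind == "te" &
                        overlapFamily(el, ann$repeats) == "ERV1", "ERV1",
                      "other TE")))
  clustOf <- clusterOfElement(el, cl)
  memberships <- data.frame(element = el$name, cluster = clustOf,
                            category = category)[inCl & !is.na(clustOf), ]
  fc <- perClusterCategoryFc(calls, memberships)
  writeTsv(fc$per_category, file.path(outDir, "cluster_category_fc.tsv"))
  writeTsv(fc$overall, file.path(outDir, "cluster_overall_fc.tsv"))
  unitIdx <- which(el$kind == "unit")
  s3d <- compareClusterVsIsolated(calls[unitIdx, ],
                                  !is.na(ann$units$cluster_id))

  # metaprofiles over units, WT vs KO
  profWt <- metaprofile(ann$units, signal$track_wt)
  profKo <- metaprofile(ann$units, signal$track_ko)
  writeTsv(as.data.frame(profWt), file.path(outDir, "metaprofile_wt.tsv"))
  writeTsv(as.data.frame(profKo), file.path(outDir, "metaprofile_ko.tsv"))

  # differential acetylation style summaries + distance stratification
  da <- differentialAcetylationSummary(signal$peaks_wt, signal$peaks_ko,
                                       cl, repeats = ann$repeats)
  writeTsv(da$subfamily_ratios, file.path(outDir, "subfamily_ko_wt.tsv"))
  writeTsv(da$cluster_density, file.path(outDir, "cluster_peak_density.tsv"))
  strat <- stratifyByPeakDistance(ann$units, signal$peaks_wt,
                                  values = calls$log2fc[unitIdx])
  writeTsv(strat$summary, file.path(outDir, "peak_distance_bins.tsv"))

  meanClusterUnitFc <- mean(calls$log2fc[unitIdx][
    !is.na(ann$units$cluster_id)])
  summary <- list(
    n_units = nrow(units),
    n_orf_calls = rec$n_calls,
    orf_sensitivity = rec$sensitivity,
    orf_precision = rec$precision,
    n_clusters_found = length(clusterSpans(cl)),
    cluster_recovery = as.numeric(clusterRecovery),
    n_significant_subfamilies = sum(subfam$significant),
    top_enrichment_is_erv = as.numeric(
      subfam$subfamily[which.min(subfam$p)] %in%
        config$teMixInCluster$subfamily[
          config$teMixInCluster$family %in% c("ERVK", "ERV1")]
    ),
    peak_shuffle_p = empiricalP(shuf),
    retrocopy_sensitivity = retroSens,
    retrocopy_false_positives = retroFp,
    mean_log2fc_cluster_units = meanClusterUnitFc,
    cluster_vs_isolated_p = s3d$p_value,
    ko_only_fraction = da$ko_only_fraction
  )
  writeTsv(data.frame(metric = names(summary),
                      value = formatNum(unlist(summary))),
           file.path(outDir, "summary.tsv"))
  invisible(list(ann = ann, genome = genome, signal = signal, orfs = orfs,
                 clusters = cl, subfamilies = subfam, shuffle = shuf,
                 phylo = phylo, retrocopies = retroCalls, calls = calls,
                 cluster_fc = fc, s3d = s3d, profiles = list(wt = profWt,
                                                             ko = profKo),
                 acetylation = da, stratification = strat,
                 summary = summary))
}

#' @noRd
overlapFamily <- function(el, repeats) {
  fam <- rep(NA_character_, length(el))
  isTe <- el$kind == "te"
  idx <- match(el$name[isTe], repeats$name)
  fam[isTe] <- as.character(repeats$family)[idx]
  fam
}

#' @noRd
clusterOfElement <- function(el, cl) {
  spans <- clusterSpans(cl)
  hits <- GenomicRanges::findOverlaps(el, spans, ignore.strand = TRUE)
  out <- rep(NA_integer_, length(el))
  out[S4Vectors::queryHits(hits)] <- spans$cluster_id[
    S4Vectors::subjectHits(hits)]
  out
}
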