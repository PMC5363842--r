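test_that("a forced layout yields exactly one truth cluster of eight", {
  cfg <- smallConfig()
  ann <- simulateAnnotations(cfg, seed = 1)
  expect_equal(length(ann$clusters), 1L)
  expect_equal(sum(ann$truth$kind == "unit"), 8L)
  expect_equal(sum(!is.na(ann$units$cluster_id)), 8L)
  expect_equal(sum(ann$truth$kind == "retrocopy"), 2L)
  # every planted object has one truth row within chromosome bounds
  expect_true(all(ann$truth$start >= 1))
  expect_true(all(ann$truth$end <= cfg$chromLengths[ann$truth$chrom]))
})

test_that("fixed seeds freeze the generator; changed seeds move it", {
  cfg <- smallConfig()
  a1 <- simulateAnnotations(cfg, seed = 5)
  a2 <- simulateAnnotations(cfg, seed = 5)
  expect_identical(a1$truth, a2$truth)
  g1 <- simulateSequences(cfg, a1, seed = 5)
  g2 <- simulateSequences(cfg, a2, seed = 5)
  expect_identical(as.character(g1), as.character(g2))
  s1 <- simulateSignal(cfg, a1, seed = 5)
  s2 <- simulateSignal(cfg, a2, seed = 5)
  expect_identical(s1$elements$count_ko, s2$elements$count_ko)
  expect_identical(BiocGenerics::start(s1$peaks_ko),
                   BiocGenerics::start(s2$peaks_ko))
  a3 <- simulateAnnotations(cfg, seed = 6)
  expect_false(identical(a1$truth, a3$truth))
})

test_that("noise-free planted units are recovered exactly, fingerprints included", {
  cfg <- smallConfig()
  ann <- simulateAnnotations(cfg, seed = 2)
  genome <- simulateSequences(cfg, ann, seed = 2)
  orfs <- unlist(GenomicRanges::GRangesList(lapply(names(genome), function(ch) {
    scanKzfpOrfs(genome[[ch]], seqname = ch)
  })))
  truthLoci <- c(GenomicRanges::granges(ann$units),
                 GenomicRanges::granges(ann$retrocopies))
  rec <- orfRecovery(orfs, truthLoci)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$precision, 1)
  # the planted fingerprint is recovered verbatim for every unit
  for (i in seq_along(ann$units)) {
    o <- orfs[IRanges::overlapsAny(orfs, ann$units[i])]
    expect_equal(o$fingerprint, ann$units$fingerprint[i])
    expect_equal(o$n_znf, ann$units$n_znf[i])
  }
})

test_that("planted retrocopies are detected with their true donors", {
  cfg <- smallConfig()
  ann <- simulateAnnotations(cfg, seed = 3)
  genome <- simulateSequences(cfg, ann, seed = 3)
  truth <- ann$truth
  retros <- truth[truth$kind == "retrocopy", ]
  units <- truth[truth$kind == "unit", ]
  krabs <- truth[truth$kind == "krab", ]
  getSeq <- function(chrom, s, e, strand) {
    x <- Biostrings::subseq(genome[[chrom]], s, e)
    if (strand == "-") x <- Biostrings::reverseComplement(x)
    as.character(x)
  }
  donors <- units[units$n_exons >= 2, ]
  donorSeqs <- setNames(vapply(seq_len(nrow(donors)), function(i) {
    row <- donors[i, ]
    kr <- krabs[krabs$id == paste0(row$id, "_krab"), ]
    paste0(getSeq(row$chrom, kr$start, kr$end, row$strand),
           getSeq(row$chrom, row$start, row$end, row$strand))
  }, ""), donors$id)
  candSeqs <- setNames(vapply(seq_len(nrow(retros)), function(i) {
    row <- retros[i, ]
    getSeq(row$chrom, row$start, row$end, row$strand)
  }, ""), retros$id)
  calls <- detectRetrocopies(candSeqs, setNames(retros$n_exons, retros$id),
                             donorSeqs, setNames(donors$n_exons, donors$id))
  expect_true(all(calls$verdict))
  expect_equal(calls$donor, retros$donor)
})

test_that("planted expression effects are recovered at scale", {
  cfg <- genomeConfig(
    chromLengths = c(chr1 = 300000, chr2 = 50000),
    clusterSpecs = data.frame(chrom = "chr1", n_units = 8L,
                              gap_min = 2000, gap_max = 4000),
    nIsolated = 0L, isolatedChrom = "chr2", nRetrocopies = 0L,
    tePerCluster = 500L, teBackground = 0L, teLenRange = c(80, 120),
    enhancerGainFraction = 1,
    coverageMeans = list(unit_cluster = c(wt = 30, ko = 120),
                         unit_isolated = c(wt = 30, ko = 30),
                         retrocopy = c(wt = 20, ko = 20),
                         te_gain = c(wt = 100, ko = 400),
                         te_other = c(wt = 100, ko = 100)),
    dispersion = 0.1
  )
  ann <- simulateAnnotations(cfg, seed = 4)
  sig <- simulateSignal(cfg, ann, seed = 4)
  el <- sig$elements
  gain <- el$model_class == "te_gain"
  expect_gte(sum(gain), 500)
  calls <- classifyResponse(el$count_wt[gain], el$count_ko[gain])
  # mean recovered log2 fold change within +/- 0.1 of the planted 4x
  expect_equal(mean(calls$log2fc), 2, tolerance = 0.05)

  # dispersion 0 gives noise-free class means
  cfg0 <- smallConfig(dispersion = 0)
  ann0 <- simulateAnnotations(cfg0, seed = 4)
  sig0 <- simulateSignal(cfg0, ann0, seed = 4)
  un <- sig0$elements[sig0$elements$model_class == "unit_cluster"]
  expect_true(all(un$count_wt == 30))
  expect_true(all(un$count_ko == 120))
})

test_that("a matched TE mix produces no subfamily enrichment beyond chance", {
  mix <- data.frame(
    subfamily = c("IAPEz", "RLTR10", "RLTR4", "MuRRS", "L1Md", "B1_Mus"),
    family = c("ERVK", "ERVK", "ERV1", "ERV1", "L1", "Alu"),
    class = c("LTR", "LTR", "LTR", "LTR", "LINE", "SINE"),
    prob = rep(1 / 6, 6)
  )
  rejections <- 0L
  tests <- 0L
  for (r in 1:40) {
    cfg <- smallConfig(teMixInCluster = mix, teMixBackground = mix,
                       teBackground = 150L)
    ann <- simulateAnnotations(cfg, seed = 100 + r)
    res <- subfamilyEnrichment(ann$clusters, ann$repeats, alpha = 0.01)
    rejections <- rejections + sum(res$significant)
    tests <- tests + nrow(res)
  }
  # one-sided exact tests at alpha 0.01 are conservative under the null
  expect_lte(rejections / tests, 0.03)
})

test_that("impossible layouts fail before any output", {
  expect_error(
    simulateAnnotations(genomeConfig(
      chromLengths = c(chr1 = 50000, chr2 = 2000000),
      clusterSpecs = data.frame(chrom = "chr1", n_units = 10L,
                                gap_min = 3000, gap_max = 8000),
      isolatedChrom = "chr2"
    ), seed = 1),
    "too short"
  )
})
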