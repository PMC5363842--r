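test_that("shuffle enrichment: saturation, add-one floor, p bounds", {
  sl <- c(chr1 = 100000)
  whole <- gr("chr1", 1, 100000)
  feats <- gr("chr1", sample.int(90000, 20), sample.int(90000, 20) + 90200)
  feats <- gr("chr1", seq(1000, by = 4000, length.out = 20),
              seq(1000, by = 4000, length.out = 20) + 499)
  res <- shuffleEnrichment(whole, feats, sl, nShuffles = 50, seed = 1)
  # regions cover the chromosome: every shuffle reproduces the observed count
  expect_equal(observedCount(res), 20L)
  expect_true(all(nullCounts(res) == 20L))
  expect_equal(empiricalP(res), 1)

  # all features inside a 1% region: no null reaches the observed count
  sl2 <- c(chr1 = 1e7)
  region <- gr("chr1", 1, 1e5)
  f2 <- gr("chr1", seq(100, by = 800, length.out = 50),
           seq(100, by = 800, length.out = 50) + 99)
  res2 <- shuffleEnrichment(region, f2, sl2, nShuffles = 100, seed = 2)
  expect_equal(empiricalP(res2), 1 / 101)
  expect_gt(empiricalP(res2), 0)
  expect_lte(empiricalP(res2), 1)

  expect_error(
    shuffleEnrichment(region, gr("chr1", 1, 2e7), sl2, nShuffles = 5),
    "longer than its chromosome"
  )
})

test_that("shuffle enrichment agrees with GRanges overlap counting", {
  set.seed(41)
  sl <- c(a = 5e5, b = 3e5)
  for (rep in 1:10) {
    nr <- sample(1:6, 1); nf <- sample(1:40, 1)
    rst <- sample.int(2e5, nr)
    regs <- gr(sample(c("a", "b"), nr, replace = TRUE),
               rst, rst + sample.int(50000, nr))
    fst <- sample.int(25e4, nf)
    feats <- gr(sample(c("a", "b"), nf, replace = TRUE),
                fst, fst + sample.int(1000, nf))
    res <- shuffleEnrichment(regs, feats, sl, nShuffles = 3, seed = rep)
    expect_equal(observedCount(res),
                 sum(IRanges::overlapsAny(feats, regs,
                                          ignore.strand = TRUE)))
  }
})

test_that("subfamily enrichment matches the exact hypergeometric oracle", {
  # planted extreme: subfamily only inside clusters
  spans <- gr("chr1", 1, 100000)
  mk <- function(n, inRegion, subfam) {
    start <- if (inRegion) sample.int(9e4, n) else 2e5 + sample.int(9e5, n)
    out <- gr("chr1", start, start + 200)
    out$subfamily <- subfam
    out
  }
  set.seed(42)
  reps <- c(mk(20, TRUE, "SFX"), mk(100, TRUE, "BG"), mk(10000, FALSE, "BG"))
  res <- subfamilyEnrichment(spans, reps, alpha = 0.01)
  sfx <- res[res$subfamily == "SFX", ]
  expect_lt(sfx$p, 1e-6)
  expect_true(sfx$significant)

  # identical composition in and out: nothing significant
  reps2 <- c(mk(50, TRUE, "S1"), mk(50, TRUE, "S2"),
             mk(50, FALSE, "S1"), mk(50, FALSE, "S2"))
  res2 <- subfamilyEnrichment(spans, reps2, alpha = 0.01)
  expect_true(all(!res2$significant))
  expect_true(all(res2$p > 0.2))

  # p equals an explicit dhyper tail sum over enumerated tables
  for (case in list(c(20, 120, 10120), c(5, 60, 200), c(1, 10, 50))) {
    a <- case[1]; nIn <- case[2]; total <- case[3]
    sfTotal <- a + 3
    oracle <- sum(dhyper(a:min(sfTotal, nIn), sfTotal, total - sfTotal, nIn))
    got <- phyper(a - 1, sfTotal, total - sfTotal, nIn, lower.tail = FALSE)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("peak composition applies priority, subfamily floor and empty case", {
  units <- gr("chr1", 1000, 2000)
  mkte <- function(start, end, subfam, cls = "LTR") {
    x <- gr("chr1", start, end)
    x$subfamily <- subfam
    x$rep_class <- cls
    x
  }
  reps <- c(mkte(1500, 2500, "ERVKx"), mkte(5000, 6000, "ERVKx"),
            mkte(8000, 9000, "RareTE"))
  # peak overlapping both a unit and a TE counts as KZFP/rGU
  peaks <- c(gr("chr1", 1900, 2100), gr("chr1", 5100, 5200),
             gr("chr1", 8100, 8200), gr("chr1", 50000, 50100))
  comp <- peakComposition(peaks, units, reps, minSubfamilyHits = 2)
  expect_equal(comp$count[comp$category == "KZFP/rGU"], 1L)
  expect_equal(comp$count[comp$category == "ERVKx"], 1L)
  # RareTE has 1 < 2 hits: its peak falls to "other", with the distal peak
  expect_equal(comp$count[comp$category == "other"], 2L)
  expect_equal(sum(comp$fraction), 1)

  # a subfamily just below the floor is not selected
  reps99 <- do.call(c, lapply(seq(10000, by = 2000, length.out = 99),
                              function(s) mkte(s, s + 500, "Almost")))
  peaks99 <- gr("chr1", 10100, 10200)
  comp99 <- peakComposition(peaks99, units[0], reps99,
                            minSubfamilyHits = 100)
  expect_false("Almost" %in% comp99$category[comp99$count > 0])
  expect_equal(comp99$count[comp99$category == "other"], 1L)

  empty <- peakComposition(peaks[0], units, reps, minSubfamilyHits = 2)
  expect_true(all(empty$count == 0L))
  expect_true(all(empty$fraction == 0))
})

test_that("differential acetylation: identity, hand-built fraction, exclusions", {
  cluster <- gr("chr1", 1, 100000)
  cluster$cluster_id <- 1L
  wt <- gr("chr1", c(10000, 30000), c(10999, 30999))
  # identical peak sets: no KO-only bases
  same <- differentialAcetylationSummary(wt, wt, cluster)
  expect_equal(same$ko_only_fraction, 0)

  # KO adds one 1 kb peak inside the 100 kb span: fraction exactly 0.01
  ko <- c(wt, gr("chr1", 50001, 51000))
  res <- differentialAcetylationSummary(wt, ko, cluster)
  expect_equal(res$ko_only_fraction, 0.01)

  # subfamilies need >= 3 members in clusters for a ratio
  mkte <- function(start, subfam) {
    x <- gr("chr1", start, start + 400)
    x$subfamily <- subfam
    x
  }
  reps <- c(mkte(10100, "Big"), mkte(30100, "Big"), mkte(50100, "Big"),
            mkte(70000, "Tiny"), mkte(80000, "Tiny"))
  res2 <- differentialAcetylationSummary(wt, ko, cluster, repeats = reps,
                                         minTe = 3)
  expect_equal(res2$subfamily_ratios$subfamily, "Big")
  expect_equal(res2$subfamily_ratios$n_ko, 3L)  # all Big overlap KO peaks?
  expect_equal(res2$subfamily_ratios$n_wt, 2L)

  # promoter-exclusion variant drops the added peak
  prom <- gr("chr1", 50001, 50100)
  res3 <- differentialAcetylationSummary(wt, ko, cluster, promoters = prom)
  expect_equal(res3$ko_only_fraction_no_promoter, 0)
})

test_that("interval subtraction conserves bases on random peak sets", {
  set.seed(43)
  for (rep in 1:200) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    s1 <- sample.int(5e4, n1, replace = TRUE)
    s2 <- sample.int(5e4, n2, replace = TRUE)
    a <- GenomicRanges::reduce(gr("c", s1, s1 + sample.int(3000, n1,
                                                           replace = TRUE)))
    b <- GenomicRanges::reduce(gr("c", s2, s2 + sample.int(3000, n2,
                                                           replace = TRUE)))
    w <- function(x) sum(BiocGenerics::width(x))
    expect_equal(w(a),
                 w(GenomicRanges::intersect(a, b)) +
                   w(GenomicRanges::setdiff(a, b)))
  }
})
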