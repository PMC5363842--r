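makeTrack <- function(values, elements, seqlengths, librarySize = NULL) {
  grv <- elements
  grv$score <- values
  coverageTrack(grv, seqlengths, librarySize = librarySize)
}

test_that("metaprofile of a constant track has zero-width confidence band", {
  sl <- c(chr1 = 100000)
  el <- gr("chr1", seq(20000, by = 10000, length.out = 5),
           seq(20000, by = 10000, length.out = 5) + 999, strand = "+")
  # constant value c everywhere
  g <- gr("chr1", 1, 100000)
  g$score <- 7
  tr <- coverageTrack(g, sl)
  p <- metaprofile(el, tr, flankUp = 500, flankDown = 500, bodyBins = 20,
                   normalize = FALSE)
  expect_true(all(abs(profileMean(p) - 7) < 1e-9))
  ci <- profileCi(p)
  expect_true(all(abs(ci[, "high"] - ci[, "low"]) < 1e-9))
})

test_that("metaprofile is strand-mirror symmetric", {
  sl <- c(chr1 = 50000)
  # a step up at position 20000
  g <- c(gr("chr1", 1, 19999), gr("chr1", 20000, 50000))
  g$score <- c(1, 5)
  tr <- coverageTrack(g, sl)
  plus <- gr("chr1", 20000, 21999, strand = "+")
  # mirrored element: the step sits at its 5' end on the minus strand
  minus <- gr("chr1", 28001, 30000, strand = "-")
  gm <- c(gr("chr1", 1, 30000), gr("chr1", 30001, 50000))
  gm$score <- c(5, 1)
  trm <- coverageTrack(gm, sl, librarySize = librarySize(tr))
  pp <- metaprofile(plus, tr, normalize = FALSE)
  pm <- metaprofile(minus, trm, normalize = FALSE)
  expect_equal(profileMean(pp), profileMean(pm))
})

test_that("metaprofile is linear in the track", {
  sl <- c(chr1 = 30000)
  set.seed(81)
  g1 <- gr("chr1", seq(1, 29001, by = 1000), seq(1000, 30000, by = 1000))
  g1$score <- runif(length(g1), 0, 10)
  g2 <- g1
  g2$score <- runif(length(g2), 0, 3)
  gsum <- g1
  gsum$score <- g1$score + g2$score
  el <- gr("chr1", c(5000, 12000, 21000), c(5999, 13499, 21799),
           strand = c("+", "-", "+"))
  args <- list(elements = el, flankUp = 300, flankDown = 700,
               bodyBins = 10, normalize = FALSE)
  p1 <- do.call(metaprofile, c(args, list(track = coverageTrack(g1, sl))))
  p2 <- do.call(metaprofile, c(args, list(track = coverageTrack(g2, sl))))
  ps <- do.call(metaprofile, c(args, list(track = coverageTrack(gsum, sl))))
  expect_equal(profileMean(ps), profileMean(p1) + profileMean(p2),
               tolerance = 1e-9)
})

test_that("confidence width shrinks as 1 / sqrt(n)", {
  sl <- c(chr1 = 5200000)
  widths <- c()
  for (n in c(25, 100, 400)) {
    el <- gr("chr1", seq(2000, by = 10000, length.out = n),
             seq(2000, by = 10000, length.out = n) + 999, strand = "+")
    v <- qnorm(ppoints(n))
    v <- 10 + (v - mean(v)) / sd(v)  # unit sample sd exactly
    tr <- makeTrack(v, el, sl)
    p <- metaprofile(el, tr, flankUp = 0, flankDown = 0, bodyBins = 5,
                     normalize = FALSE)
    ci <- profileCi(p)
    widths <- c(widths, mean(ci[, "high"] - ci[, "low"]))
  }
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.1)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.1)
  expect_equal(widths[1] / widths[3], 4, tolerance = 0.1)
})

test_that("windows beyond chromosome ends are masked, not errors", {
  sl <- c(chr1 = 3000)
  g <- gr("chr1", 1, 3000)
  g$score <- 2
  tr <- coverageTrack(g, sl)
  el <- gr("chr1", 100, 600, strand = "+")
  p <- metaprofile(el, tr, flankUp = 500, flankDown = 500, bodyBins = 10,
                   normalize = FALSE)
  m <- profileMean(p)
  expect_true(all(is.na(m[1:99])))         # off-chromosome upstream
  expect_true(all(abs(m[!is.na(m)] - 2) < 1e-9))
})

test_that("response classification: arithmetic, pseudocount, antisymmetry", {
  calls <- classifyResponse(c(100, 0, 50), c(400, 0, 55),
                            lfcThreshold = 1, minSignal = 10)
  expect_equal(calls$log2fc[1], log2(401 / 101))
  expect_equal(calls$class[1], "up")
  expect_equal(calls$log2fc[2], 0)  # pseudocount floor
  expect_equal(calls$class[2], "unchanged")
  expect_equal(calls$class[3], "unchanged")

  # large means: log2 fold change approaches the planted value
  big <- classifyResponse(1e6, 4e6)
  expect_equal(big$log2fc, 2, tolerance = 1e-4)

  set.seed(82)
  a <- runif(50, 0, 100)
  b <- runif(50, 0, 100)
  fwd <- classifyResponse(a, b, minSignal = 5)
  rev_ <- classifyResponse(b, a, minSignal = 5)
  expect_equal(rev_$log2fc, -fwd$log2fc)
  expect_equal(rev_$class == "up", fwd$class == "down")
  expect_error(classifyResponse(1:3, 1:4), "equal length")
})

test_that("per-cluster category means drop small categories", {
  calls <- classifyResponse(rep(10, 12), c(rep(40, 11), 10),
                            labels = paste0("e", 1:12))
  memberships <- data.frame(
    element = paste0("e", 1:12),
    cluster = rep(c("cl1", "cl2"), c(9, 3)),
    category = c(rep("KZFP/rGU", 5), rep("ERVK", 4), rep("ERV1", 3))
  )
  fc <- perClusterCategoryFc(calls, memberships, minN = 5)
  expect_equal(sort(unique(fc$per_category$category)), "KZFP/rGU")
  # ERVK (4 members) and ERV1 (3) are dropped
  expect_equal(fc$per_category$n, 5L)
  expect_equal(fc$per_category$mean_log2fc, log2(41 / 11))
  expect_equal(fc$overall$cluster, "cl1")
  expect_equal(fc$overall$n, 5L)

  # identical values: category means equal the overall mean
  calls2 <- classifyResponse(rep(10, 12), rep(40, 12),
                             labels = paste0("e", 1:12))
  memberships2 <- data.frame(element = paste0("e", 1:12), cluster = "cl1",
                             category = rep(c("KZFP/rGU", "ERVK"), 6))
  fc2 <- perClusterCategoryFc(calls2, memberships2, minN = 5)
  expect_true(all(abs(fc2$per_category$mean_log2fc -
                        fc2$overall$mean_log2fc) < 1e-12))
})

test_that("distance stratification is exclusive with strict bounds", {
  peaks <- gr("chr1", 100000, 100999)
  el <- c(
    gr("chr1", 100500, 100600),   # overlap
    gr("chr1", 101001, 101100),   # adjacent: gap 1? distance 1
    gr("chr1", 106000, 106100),   # gap 5000 exactly -> <20 kb
    gr("chr1", 104000, 104100),   # gap 3000 -> <5 kb
    gr("chr1", 130000, 130100),   # gap 29000 -> >=20 kb
    gr("chr2", 500, 600)          # peak-free chromosome -> >=20 kb
  )
  res <- stratifyByPeakDistance(el, peaks)
  expect_equal(as.character(res$assignment),
               c("overlap", "lt5kb", "lt20kb", "lt5kb", "ge20kb", "ge20kb"))
  # overlap wins even when another peak is 1 bp away
  el2 <- gr("chr1", 100500, 100600)
  peaks2 <- c(peaks, gr("chr1", 100602, 100700))
  expect_equal(as.character(stratifyByPeakDistance(el2, peaks2)$assignment),
               "overlap")

  # quadratic brute-force oracle on random instances
  set.seed(83)
  for (rep in 1:25) {
    ne <- sample(1:30, 1); np <- sample(0:10, 1)
    est <- sample.int(2e5, ne)
    els <- gr(sample(c("a", "b"), ne, replace = TRUE), est, est + 500)
    pst <- sample.int(2e5, np)
    pks <- if (np > 0) gr(sample(c("a", "b"), np, replace = TRUE),
                          pst, pst + 300)
           else gr("a", 1, 2)[0]
    got <- as.character(stratifyByPeakDistance(els, pks)$assignment)
    for (i in seq_len(ne)) {
      same <- which(as.character(GenomeInfoDb::seqnames(pks)) ==
                      as.character(GenomeInfoDb::seqnames(els))[i])
      if (!length(same)) {
        expect_equal(got[i], "ge20kb")
        next
      }
      s <- BiocGenerics::start(els)[i]; e <- BiocGenerics::end(els)[i]
      ps <- BiocGenerics::start(pks)[same]; pe <- BiocGenerics::end(pks)[same]
      ov <- any(ps <= e & pe >= s)
      d <- min(pmax(ps - e - 1, s - pe - 1, 0))
      want <- if (ov) "overlap" else if (d < 5000) "lt5kb"
              else if (d < 20000) "lt20kb" else "ge20kb"
      expect_equal(got[i], want)
    }
  }
})

test_that("in-cluster vs isolated comparison flags planted upregulation", {
  set.seed(84)
  lfcUp <- rnorm(50, 2, 0.3)
  lfcNull <- rnorm(50, 0, 0.3)
  calls <- data.frame(element = paste0("e", 1:100),
                      log2fc = c(lfcUp, lfcNull))
  res <- compareClusterVsIsolated(calls, rep(c(TRUE, FALSE), each = 50))
  expect_lt(res$p_value, 1e-10)
  expect_gt(res$mean_log2fc_cluster, res$mean_log2fc_isolated)
  expect_error(compareClusterVsIsolated(calls, rep(TRUE, 100)), "non-empty")
})
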