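# Exhaustive oracle: union-find (connected components) over the pairwise
# gap relation, computed with igraph on the full adjacency matrix.
oracleClusters <- function(x, maxGap, minSize) {
  chroms <- as.character(GenomeInfoDb::seqnames(x))
  start0 <- BiocGenerics::start(x) - 1
  end0 <- BiocGenerics::end(x)
  memb <- rep(NA_integer_, length(x))
  comp_id <- 0L
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    s <- start0[idx]; e <- end0[idx]
    gap <- pmax(outer(s, e, `-`), t(outer(s, e, `-`)))
    adj <- gap < maxGap
    diag(adj) <- TRUE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    for (k in unique(comp)) {
      members <- idx[comp == k]
      if (length(members) >= minSize) {
        comp_id <- comp_id + 1L
        memb[members] <- comp_id
      }
    }
  }
  memb
}

sameGrouping <- function(a, b) {
  ok <- identical(is.na(a), is.na(b))
  au <- a[!is.na(a)]; bu <- b[!is.na(b)]
  ok && length(unique(paste(au, bu))) == length(unique(au)) &&
    length(unique(au)) == length(unique(bu))
}

test_that("eight elements with 400 kb gaps form one cluster; seven do not", {
  x <- gr("chr1", seq(1, by = 401000, length.out = 8),
          seq(1, by = 401000, length.out = 8) + 999)
  cl <- buildClusters(x)
  expect_equal(length(clusterSpans(cl)), 1L)
  expect_equal(clusterSpans(cl)$n_members, 8L)
  expect_equal(length(isolatedElements(cl)), 0L)

  y <- gr("chr1", seq(1, by = 2000, length.out = 7),
          seq(1, by = 2000, length.out = 7) + 999)
  cl7 <- buildClusters(y)
  expect_equal(length(clusterSpans(cl7)), 0L)
  expect_equal(length(isolatedElements(cl7)), 7L)
})

test_that("a gap of exactly 500 kb breaks the chain (strict bound)", {
  # 0-based half-open gap between end and next start is exactly 500000
  starts <- cumsum(c(1, rep(1000 + 500000, 7)))
  x <- gr("chr1", starts, starts + 999)
  expect_equal(length(clusterSpans(buildClusters(x))), 0L)
  starts2 <- cumsum(c(1, rep(1000 + 499999, 7)))
  x2 <- gr("chr1", starts2, starts2 + 999)
  expect_equal(length(clusterSpans(buildClusters(x2))), 1L)
})

test_that("clustering is input-order invariant and matches the union-find oracle", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(2:120, 1)
    maxGap <- sample(c(1000, 10000, 100000), 1)
    minSize <- sample(2:8, 1)
    start <- sample.int(5e5, n, replace = TRUE)
    x <- gr(sample(c("c1", "c2"), n, replace = TRUE),
            start, start + sample.int(2000, n, replace = TRUE))
    cl <- buildClusters(x, maxGap = maxGap, minSize = minSize)
    got <- clusterElements(cl)$cluster_id
    want <- oracleClusters(x, maxGap, minSize)
    expect_true(sameGrouping(got, want))
    # order invariance
    perm <- sample(n)
    cl2 <- buildClusters(x[perm], maxGap = maxGap, minSize = minSize)
    expect_true(sameGrouping(clusterElements(cl2)$cluster_id, got[perm]))
  }
})

test_that("the receptor-gene comparator rule is a parameterization (minSize 10)", {
  x <- gr("chr1", seq(1, by = 20000, length.out = 9),
          seq(1, by = 20000, length.out = 9) + 999)
  expect_equal(length(clusterSpans(buildClusters(x, minSize = 10))), 0L)
  x10 <- gr("chr1", seq(1, by = 20000, length.out = 10),
            seq(1, by = 20000, length.out = 10) + 999)
  cl <- buildClusters(x10, minSize = 10)
  expect_equal(clusterSpans(cl)$n_members, 10L)
})

test_that("upstream association is strand-aware with a strict distance cap", {
  el <- gr("chr1", 100000, 101000, strand = "+")
  # feature ending 10 kb 5' of the element start
  f <- gr("chr1", 89000, 90000)
  a <- associateUpstreamFeature(el, f)
  expect_equal(a$feature, 1L)
  expect_equal(a$distance, 10000)
  # mirrored geometry on the minus strand: feature on the right
  elm <- gr("chr1", 100000, 101000, strand = "-")
  fm <- gr("chr1", 111000, 112000)
  am <- associateUpstreamFeature(elm, fm)
  expect_equal(am$feature, 1L)
  expect_equal(am$distance, 10000)
  # 31 kb away: no association; exactly 30 kb: associated
  far <- gr("chr1", 68000, 69000)
  expect_true(is.na(associateUpstreamFeature(el, far)$feature))
  at30 <- gr("chr1", 60000, 70000)
  expect_equal(associateUpstreamFeature(el, at30)$feature, 1L)
  # tie-break: nearest feature wins
  both <- c(gr("chr1", 89000, 90000), gr("chr1", 94000, 95000))
  expect_equal(associateUpstreamFeature(el, both)$feature, 2L)
})

test_that("positional correlation: self-anchoring, strand flip, mass conservation", {
  a <- gr("chr1", c(1000, 5000, 9000), c(1400, 5400, 9400), strand = "+")
  p <- positionalCorrelation(a, a, halfWindow = 2000, binWidth = 200)
  df <- as.data.frame(p)
  expect_equal(sum(df$count), 3L)  # only the self pairs are in range
  expect_equal(df$offset[df$count > 0], 100)  # offset 0 in right-hand bin

  # features exactly +2 kb downstream of anchors on both strands
  plus <- gr("chr1", 10000, 10400, strand = "+")
  minus <- gr("chr1", 10000, 10400, strand = "-")
  fplus <- GenomicRanges::shift(gr("chr1", 10000, 10400), 2000)
  fminus <- GenomicRanges::shift(gr("chr1", 10000, 10400), -2000)
  pp <- as.data.frame(positionalCorrelation(plus, fplus, 5000, 500))
  pm <- as.data.frame(positionalCorrelation(minus, fminus, 5000, 500))
  expect_equal(pp$offset[pp$count > 0], 2250)
  expect_equal(pm$offset[pm$count > 0], 2250)

  # total mass equals the quadratic brute-force pair count
  set.seed(32)
  for (rep in 1:20) {
    na <- sample(1:15, 1); nf <- sample(1:30, 1)
    anc <- gr("c1", sample.int(50000, na), sample.int(50000, na) + 51000,
              strand = sample(c("+", "-"), na, replace = TRUE))
    fea <- gr("c1", sample.int(100000, nf), sample.int(100000, nf) + 100001)
    hw <- 4000; bw <- 500
    prof <- positionalCorrelation(anc, fea, hw, bw)
    am <- floor((BiocGenerics::start(anc) + BiocGenerics::end(anc)) / 2)
    fm <- floor((BiocGenerics::start(fea) + BiocGenerics::end(fea)) / 2)
    brute <- 0L
    for (i in seq_len(na)) {
      off <- fm - am[i]
      if (as.character(BiocGenerics::strand(anc))[i] == "-") off <- -off
      brute <- brute + sum(off >= -hw & off < hw)
    }
    expect_equal(sum(as.data.frame(prof)$count), brute)
  }
  expect_error(positionalCorrelation(anc[0], fea, 4000, 500))
  expect_error(positionalCorrelation(anc, fea, 4000, 300), "divide")
})

test_that("overlap Fisher test matches the closed-form extreme table", {
  # 10 elements all with peaks, far from where a shuffled control can land
  el <- gr("chr1", seq(1000, by = 3000, length.out = 10),
           seq(1000, by = 3000, length.out = 10) + 499)
  peaks <- el
  sl <- c(chr1 = 1e9)
  res <- overlapFisher(el, peaks, window = 100, seqlengths = sl, seed = 5)
  expect_equal(unname(res$table[1, ]), c(10L, 0L))
  expect_equal(unname(res$table[2, ]), c(0L, 10L))
  # Haldane-corrected odds ratio (10.5 * 10.5) / (0.5 * 0.5)
  expect_equal(res$odds_ratio, 441)
  # two-sided exact p for the 10/0 vs 0/10 table
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)  # already significant at n >= 8
})
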