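# Exhaustive affine-gap global alignment oracle (gap of length L costs
# open + (L-1) * extend), implemented as plain recursion over three states.
oracleAlignScore <- function(a, b, match, mismatch, open, extend) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- open + (j - 2) * extend
  for (i in 2:(n + 1)) X[i, 1] <- open + (i - 2) * extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + open, X[i - 1, j] + extend,
                     Y[i - 1, j] + open)
      Y[i, j] <- max(M[i, j - 1] + open, Y[i, j - 1] + extend,
                     X[i, j - 1] + open)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

test_that("pairwise alignment scores follow the declared gap convention", {
  al <- alignDna("ACGT", "ACT", match = 1, mismatch = -1,
                 gapOpen = -2, gapExtend = -1)
  expect_equal(Biostrings::score(al), 1)  # 3 matches, one length-1 gap at -2
  set.seed(51)
  for (rep in 1:40) {
    a <- randomDna(sample(2:8, 1))
    b <- randomDna(sample(2:8, 1))
    got <- Biostrings::score(alignDna(a, b, 1, -1, -4, -1))
    expect_equal(got, oracleAlignScore(a, b, 1, -1, -4, -1), info = paste(a, b))
  }
})

test_that("progressive alignment is structurally sound", {
  s <- c(a = "ACGTACGT", b = "ACGTACGT")
  msa <- progressiveAlign(s)
  expect_equal(as.character(msa), s)  # identical pair: gap-free

  set.seed(52)
  seqs <- setNames(vapply(1:5, function(i) randomDna(sample(40:80, 1)), ""),
                   paste0("s", 1:5))
  msa2 <- progressiveAlign(seqs)
  w <- unique(BiocGenerics::width(msa2))
  expect_length(w, 1L)
  expect_gte(w, max(nchar(seqs)))
  degap <- gsub("-", "", as.character(msa2), fixed = TRUE)
  expect_equal(degap, seqs)  # degapping recovers every input

  expect_equal(as.character(progressiveAlign(c(x = "ACGT"))), c(x = "ACGT"))
  expect_error(progressiveAlign(c(x = "")), "empty")
})

test_that("consensus calling: majority vote, tie-break, gap-majority drop", {
  expect_equal(consensusFromMsa(c("AC", "AC", "AT")), "AC")
  # 50/50 split resolves to the alphabetically first residue
  expect_equal(consensusFromMsa(c("A", "C"), minFrac = 0.5), "A")
  # gap-strict-majority column dropped; length shrinks
  expect_equal(consensusFromMsa(c("A-G", "A-G", "ACG")), "AG")
  # below the majority threshold the call is N
  expect_equal(consensusFromMsa(c("AA", "AC", "AG", "AT")), "AN")
})

test_that("p-distances: identity, arithmetic, N exclusion, symmetry", {
  d <- pdistanceMatrix(c(u = "AAAA", v = "AAAA", w = "AAAT"))
  expect_equal(d["u", "v"], 0)
  expect_equal(d["u", "w"], 0.25)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  dn <- pdistanceMatrix(c(x = "AANA", y = "AATA"))
  expect_equal(dn["x", "y"], 0)  # the N column is not comparable
  expect_error(pdistanceMatrix(c(x = "NNN", y = "AAA")), "no comparable")
})

test_that("neighbor joining recovers additive trees exactly", {
  # three taxa: closed-form branch lengths
  d3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- njTree(d3)
  el <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(sort(unname(el)), c(2, 3, 7))

  # random additive matrices from random binary trees: topology and branch
  # lengths recovered (RF = 0, cophenetic distances reproduced)
  skip_if_not_installed("phangorn")
  set.seed(53)
  for (rep in 1:15) {
    ntax <- sample(4:10, 1)
    tr <- ape::rtree(ntax, rooted = FALSE)
    tr$edge.length <- round(stats::runif(length(tr$edge.length), 0.1, 2), 3)
    D <- ape::cophenetic.phylo(tr)
    D <- D[order(rownames(D)), order(colnames(D))]
    got <- njTree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(got), ape::unroot(tr)), 0)
    expect_equal(ape::cophenetic.phylo(got)[rownames(D), colnames(D)], D,
                 tolerance = 1e-6)
    # independent cross-check against the reference NJ implementation
    expect_equal(phangorn::RF.dist(ape::unroot(got),
                                   ape::unroot(ape::nj(D))), 0)
  }
})

test_that("NJ joins the two nearest taxa first on an ultrametric matrix", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(8, 4, 4, dimnames = list(labs, labs))
  D[cbind(labs, labs)] <- 0
  D["A", "B"] <- D["B", "A"] <- 1
  D["C", "D"] <- D["D", "C"] <- 6
  tr <- njTree(D)
  # A and B must be siblings: the split {A,B} | {C,D} is present
  skip_if_not_installed("phangorn")
  want <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(want)), 0)
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
})

test_that("lineage simulation: align-consensus-distance-NJ recovers the tree", {
  skip_if_not_installed("phangorn")
  set.seed(54)
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  evolveTree <- function(tr, root, rate) {
    seqs <- character(max(tr$edge))
    ord <- ape::reorder.phylo(tr, "postorder")
    rootNode <- ord$edge[nrow(ord$edge), 1]
    seqs[rootNode] <- root
    for (k in rev(seq_len(nrow(ord$edge)))) {
      e <- ord$edge[k, ]
      seqs[e[2]] <- mutate(seqs[e[1]], rate)
    }
    setNames(seqs[seq_along(tr$tip.label)], tr$tip.label)
  }
  ok <- 0
  for (rep in 1:5) {
    tr <- ape::rtree(6, rooted = FALSE)
    tr$tip.label <- paste0("cl", 1:6)
    root <- randomDna(400)
    lineage <- evolveTree(tr, root, rate = 0.06)
    clusterSeqs <- lapply(lineage, function(s) {
      setNames(vapply(1:5, function(i) mutate(s, 0.01), ""),
               paste0("m", 1:5))
    })
    res <- clusterConsensusTree(clusterSeqs)
    if (phangorn::RF.dist(ape::unroot(res$tree), ape::unroot(tr)) == 0) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 4)
})
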