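# Independent O(n^2) oracles for the fingerprint operations.

oracleTandem <- function(fp) {
  n <- length(fp)
  out <- data.frame(triplet = character(), start = integer(),
                    copies = integer(), stringsAsFactors = FALSE)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && fp[j + 1] == fp[i]) j <- j + 1
    if (j > i) {
      out <- rbind(out, data.frame(triplet = fp[i], start = i,
                                   copies = j - i + 1,
                                   stringsAsFactors = FALSE))
    }
    i <- j + 1
  }
  out
}

# Same maximality rule as the implementation (longer blocks consume
# positions; within a length, first-occurrence order; greedy left-to-right
# occurrence selection), re-derived with a position-set bookkeeping scheme.
oracleBlocks <- function(fp, kmin = 2, kmax = 7) {
  n <- length(fp)
  used <- integer(0)
  res <- list()
  empty <- data.frame(block = character(), k = integer(),
                      occurrences = character(), stringsAsFactors = FALSE)
  if (n < 2 * kmin) return(empty)
  for (k in seq(min(kmax, floor(n / 2)), kmin, by = -1)) {
    if (k < kmin) break
    starts <- seq_len(n - k + 1)
    key <- vapply(starts, function(i) paste(fp[i:(i + k - 1)],
                                            collapse = "\r"), "")
    for (g in unique(key)) {
      pos <- starts[key == g]
      if (length(pos) < 2) next
      pos <- Filter(function(p) length(intersect(p:(p + k - 1), used)) == 0,
                    pos)
      taken <- integer(0)
      for (p in pos) {
        if (!length(taken) || p > max(taken) + k - 1) taken <- c(taken, p)
      }
      if (length(taken) >= 2) {
        used <- union(used, unlist(lapply(taken, function(p) p:(p + k - 1))))
        res[[length(res) + 1]] <- data.frame(
          block = gsub("\r", "-", g, fixed = TRUE), k = k,
          occurrences = paste(taken, collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(block = character(), k = integer(),
               occurrences = character(), stringsAsFactors = FALSE)
}

# Brute-force maximal common substrings: every (i, j, len) with equality,
# kept only when not extendable on either side.
oracleShared <- function(a, b, minLen) {
  n <- length(a); m <- length(b)
  res <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (a[i] != b[j]) next
      if (i > 1 && j > 1 && a[i - 1] == b[j - 1]) next  # not left-maximal
      len <- 0
      while (i + len <= n && j + len <= m && a[i + len] == b[j + len]) {
        len <- len + 1
      }
      if (len >= minLen) {
        res[[length(res) + 1]] <- data.frame(
          block = paste(a[i:(i + len - 1)], collapse = "-"),
          start_a = i, start_b = j, length = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(block = character(), start_a = integer(),
               start_b = integer(), length = integer(),
               stringsAsFactors = FALSE)
}

sortBlocks <- function(df) {
  df <- df[order(df$start_a, df$start_b, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

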