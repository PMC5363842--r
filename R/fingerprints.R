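# Diversification analysis of zinc fingerprints: tandem duplications,
# repeated triplet blocks, and blocks shared between paralogs (optionally
# on the reversed array, mirroring opposite-strand encoding).

#' Maximal tandem duplications of a triplet within a fingerprint
#'
#' @param fp Character vector of specificity triplets (a fingerprint).
#' @return A data.frame with one row per maximal run of >= 2 identical
#'   consecutive triplets: `triplet`, `start` (1-based index), `copies`.
#' @examples
#' findTandemDuplications(c("QSN", "QSN", "QSN", "QSN", "RER"))
#' @export
findTandemDuplications <- function(fp) {
  stopifnot(is.character(fp))
  if (length(fp) < 2L) {
    return(data.frame(triplet = character(), start = integer(),
                      copies = integer(), stringsAsFactors = FALSE))
  }
  r <- rle(fp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= 2L
  data.frame(triplet = r$values[keep], start = starts[keep],
             copies = r$lengths[keep], stringsAsFactors = FALSE)
}

#' Repeated blocks of 2-7 sequential triplets within one fingerprint
#'
#' For block length k descending from `kmax` to `kmin`, reports blocks that
#' occur at two or more non-overlapping positions. Positions consumed by a
#' longer reported block are not re-reported inside shorter blocks, so each
#' repetition is attributed to its maximal block. Within one length, blocks
#' are processed in order of first occurrence; occurrences are selected
#' greedily left to right.
#'
#' @param fp Character vector of triplets.
#' @param kmin,kmax Block length bounds.
#' @return A data.frame with `block` (dash-joined triplets), `k` and
#'   `occurrences` (comma-joined 1-based start indices).
#' @export
findRepeatedBlocks <- function(fp, kmin = 2L, kmax = 7L) {
  stopifnot(is.character(fp), isCount(kmin, min = 1), isCount(kmax, min = 1),
            kmin <= kmax)
  n <- length(fp)
  out <- data.frame(block = character(), k = integer(),
                    occurrences = character(), stringsAsFactors = FALSE)
  if (n < 2L * kmin) return(out)
  consumed <- rep(FALSE, n)
  for (k in rev(seq.int(kmin, min(kmax, n %/% 2L)))) {
    grams <- vapply(seq_len(n - k + 1L), function(i) {
      paste(fp[i:(i + k - 1L)], collapse = "-")
    }, "")
    for (g in unique(grams)) {
      pos <- which(grams == g)
      if (length(pos) < 2L) next
      free <- pos[vapply(pos, function(p) !any(consumed[p:(p + k - 1L)]),
                         logical(1))]
      chosen <- integer(0)
      lastEnd <- 0L
      for (p in free) {
        if (p > lastEnd) {
          chosen <- c(chosen, p)
          lastEnd <- p + k - 1L
        }
      }
      if (length(chosen) >= 2L) {
        for (p in chosen) consumed[p:(p + k - 1L)] <- TRUE
        out <- rbind(out, data.frame(
          block = g, k = k, occurrences = paste(chosen, collapse = ","),
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  out
}

#' @noRd
commonBlocksOneWay <- function(a, b, minLen) {
  n <- length(a)
  m <- length(b)
  L <- matrix(0L, n + 1L, m + 1L)
  res <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (a[i] == b[j]) L[i + 1L, j + 1L] <- L[i, j] + 1L
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      len <- L[i + 1L, j + 1L]
      if (len < minLen) next
      extendable <- i < n && j < m && a[i + 1L] == b[j + 1L]
      if (extendable) next
      res[[length(res) + 1L]] <- data.frame(
        block = paste(a[(i - len + 1L):i], collapse = "-"),
        start_a = i - len + 1L, start_b = j - len + 1L, length = len,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(block = character(), start_a = integer(),
               start_b = integer(), length = integer(),
               stringsAsFactors = FALSE)
}

#' Triplet blocks shared between two fingerprints
#'
#' Reports all maximal common contiguous triplet substrings of length at
#' least `minLen`, with start positions in both fingerprints. With
#' `allowReverse`, the second fingerprint is additionally matched in
#' reversed order (arrays encoded on the opposite strand read backwards);
#' such matches are flagged and their `start_b` refers to the original
#' orientation (start of the matched stretch, leftmost index).
#'
#' @param fpA,fpB Character vectors of triplets.
#' @param minLen Minimum shared block length.
#' @param allowReverse Also match against the reversed second fingerprint.
#' @return A data.frame with `block`, `start_a`, `start_b`, `length`,
#'   `reversed`.
#' @export
sharedFingerprintBlocks <- function(fpA, fpB, minLen = 2L,
                                    allowReverse = TRUE) {
  stopifnot(is.character(fpA), is.character(fpB), isCount(minLen, min = 1))
  fwd <- commonBlocksOneWay(fpA, fpB, minLen)
  fwd$reversed <- rep(FALSE, nrow(fwd))
  if (!allowReverse) return(fwd)
  rev_ <- commonBlocksOneWay(fpA, rev(fpB), minLen)
  if (nrow(rev_)) {
    # map the reversed-coordinate start back to the leftmost original index
    rev_$start_b <- length(fpB) - (rev_$start_b + rev_$length - 1L) + 1L
    rev_$reversed <- TRUE
  } else {
    rev_$reversed <- logical(0)
  }
  out <- rbind(fwd, rev_)
  rownames(out) <- NULL
  out
}
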