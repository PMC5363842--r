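# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global \code{.Random.seed} so that seeded package
#' functions do not disturb the caller's RNG stream. A \code{NULL} seed
#' evaluates the expression against the current stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' @noRd
isCount <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

#' @noRd
isNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

#' Strand of a GRanges as "+"/"-", treating "*" as "+" with a warning
#' @noRd
effectiveStrand <- function(gr) {
  s <- as.character(BiocGenerics::strand(gr))
  if (any(s == "*")) {
    warning("unstranded features treated as '+' where orientation matters")
    s[s == "*"] <- "+"
  }
  s
}

#' Validate a GRanges argument
#' @noRd
checkGRanges <- function(x, arg = deparse(substitute(x)), allowEmpty = TRUE) {
  if (!methods::is(x, "GRanges")) {
    stop(sprintf("'%s' must be a GRanges object", arg), call. = FALSE)
  }
  if (!allowEmpty && length(x) == 0L) {
    stop(sprintf("'%s' must not be empty", arg), call. = FALSE)
  }
  invisible(x)
}

#' Named seqlengths lookup with error on missing chromosome
#' @noRd
chromLengthsFor <- function(gr, seqlengths) {
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  missing <- setdiff(unique(chroms), names(seqlengths))
  if (length(missing)) {
    stop("no chromosome length supplied for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unname(seqlengths[chroms])
}
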