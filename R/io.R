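# Format I/O. Internal coordinates follow the Bioconductor convention
# (GRanges, 1-based closed); BED (0-based half-open) and RepeatMasker/GTF
# (1-based inclusive) conventions are converted only at these boundaries,
# preserving interval length.

#' Read genomic intervals from BED, GTF or RepeatMasker .out files
#'
#' All dialects are returned as a [GenomicRanges::GRanges]. BED input is
#' 0-based half-open and converted to 1-based closed; GTF and RepeatMasker
#' coordinates are 1-based inclusive and kept verbatim. RepeatMasker rows
#' additionally carry `rep_class`, `rep_family` (the class/family field
#' split on "/") and `subfamily` (the repeat name) metadata columns.
#' Chromosome names are matched verbatim downstream: no "chr" normalisation
#' is ever applied.
#'
#' @param file Path to the input file.
#' @param dialect One of `"BED"`, `"GTF"`, `"RepeatMasker"`.
#' @return A `GRanges`. BED: metadata columns `name`, `score` when present.
#'   GTF: `source`, `type`, `score`, `attributes`. RepeatMasker: `rep_class`,
#'   `rep_family`, `subfamily`, `score`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tu1\t0\t+", bed)
#' gr <- readGenomicIntervals(bed, "BED")
#' start(gr)  # 101: 1-based closed internally, length preserved
#' @export
readGenomicIntervals <- function(file, dialect = c("BED", "GTF", "RepeatMasker")) {
  dialect <- match.arg(dialect)
  lines <- readLines(file)
  switch(dialect,
    BED = parseBedLines(lines),
    GTF = parseGtfLines(lines),
    RepeatMasker = parseRepeatMaskerLines(lines)
  )
}

#' @noRd
parseFail <- function(dialect, lineno, msg) {
  stop(sprintf("%s parse error at line %d: %s", dialect, lineno, msg),
       call. = FALSE)
}

#' @noRd
parseBedLines <- function(lines) {
  keep <- !grepl("^(#|track|browser)|^\\s*$", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < 3L)
  if (length(bad)) parseFail("BED", idx[bad[1]], "fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) parseFail("BED", idx[bad[1]], "non-numeric coordinates")
  bad <- which(end0 <= start0)
  if (length(bad)) parseFail("BED", idx[bad[1]], "end <= start")
  bad <- which(!nzchar(chrom))
  if (length(bad)) parseFail("BED", idx[bad[1]], "empty chromosome name")
  name <- ifelse(n >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), ".")
  score <- ifelse(n >= 5L, vapply(fields, function(f) f[min(5L, length(f))], "0"), "0")
  strand <- ifelse(n >= 6L, vapply(fields, function(f) f[min(6L, length(f))], "*"), "*")
  bad <- which(!strand %in% c("+", "-", "*", "."))
  if (length(bad)) parseFail("BED", idx[bad[1]], "invalid strand field")
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand
  )
  if (any(n >= 4L)) gr$name <- name
  if (any(n >= 5L)) gr$score <- suppressWarnings(as.numeric(score))
  gr
}

#' @noRd
parseGtfLines <- function(lines) {
  keep <- !grepl("^#|^\\s*$", lines)
  idx <- which(keep)
  if (!length(idx)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < 9L)
  if (length(bad)) parseFail("GTF", idx[bad[1]], "fewer than 9 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad)) parseFail("GTF", idx[bad[1]], "non-numeric coordinates")
  bad <- which(end1 < start1)
  if (length(bad)) parseFail("GTF", idx[bad[1]], "end < start after conversion")
  strand <- vapply(fields, `[[`, "", 7L)
  strand[!strand %in% c("+", "-")] <- "*"
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6L)))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start1, end = end1),
    strand = strand
  )
  gr$source <- vapply(fields, `[[`, "", 2L)
  gr$type <- vapply(fields, `[[`, "", 3L)
  gr$score <- score
  gr$attributes <- vapply(fields, `[[`, "", 9L)
  gr
}

# Standard 15-column RepeatMasker .out layout: SW score, div, del, ins,
# query, begin, end, (left), strand (+ or C), repeat name, class/family,
# repeat begin, end, (left), ID. Three header lines are skipped when present.
#' @noRd
parseRepeatMaskerLines <- function(lines) {
  idx <- seq_along(lines)
  if (length(lines) >= 1 && grepl("^\\s*SW", lines[1])) {
    skip <- min(3L, length(lines))
    lines <- lines[-seq_len(skip)]
    idx <- idx[-seq_len(skip)]
  }
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  idx <- idx[keep]
  if (!length(lines)) return(GenomicRanges::GRanges())
  fields <- strsplit(trimws(lines), "\\s+")
  n <- lengths(fields)
  bad <- which(n < 15L)
  if (length(bad)) parseFail("RepeatMasker", idx[bad[1]], "fewer than 15 columns")
  chrom <- vapply(fields, `[[`, "", 5L)
  begin <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
  bad <- which(is.na(begin) | is.na(end))
  if (length(bad)) parseFail("RepeatMasker", idx[bad[1]], "non-numeric coordinates")
  bad <- which(end < begin)
  if (length(bad)) parseFail("RepeatMasker", idx[bad[1]], "end < begin")
  strand <- vapply(fields, `[[`, "", 9L)
  strand <- ifelse(strand == "C", "-", ifelse(strand == "+", "+", "*"))
  subfamily <- vapply(fields, `[[`, "", 10L)
  classfam <- vapply(fields, `[[`, "", 11L)
  split <- strsplit(classfam, "/", fixed = TRUE)
  rep_class <- vapply(split, `[[`, "", 1L)
  rep_family <- vapply(split, function(s) if (length(s) >= 2) s[[2]] else s[[1]], "")
  bad <- which(!nzchar(rep_class) | !nzchar(subfamily))
  if (length(bad)) parseFail("RepeatMasker", idx[bad[1]], "empty class or repeat name")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = begin, end = end),
    strand = strand
  )
  gr$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  gr$rep_class <- rep_class
  gr$rep_family <- rep_family
  gr$subfamily <- subfamily
  gr
}

#' Read a bedGraph coverage file
#'
#' Accepts the 4-column bedGraph dialect (chrom, start, end, value; 0-based
#' half-open) and returns a `GRanges` with a `score` metadata column in
#' 1-based closed coordinates.
#'
#' @param file Path to a bedGraph file.
#' @return A `GRanges` with numeric `score`.
#' @export
readBedGraph <- function(file) {
  lines <- readLines(file)
  keep <- !grepl("^(#|track|browser)|^\\s*$", lines)
  idx <- which(keep)
  if (!length(idx)) return(GenomicRanges::GRanges(score = numeric()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) parseFail("bedGraph", idx[bad[1]], "fewer than 4 fields")
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(start0) | is.na(end0) | is.na(value))
  if (length(bad)) parseFail("bedGraph", idx[bad[1]], "non-numeric field")
  bad <- which(end0 <= start0)
  if (length(bad)) parseFail("bedGraph", idx[bad[1]], "end <= start")
  GenomicRanges::GRanges(
    seqnames = vapply(fields, `[[`, "", 1L),
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    score = value
  )
}

#' Read sequence records from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()] adding the integrity checks the pipeline
#' relies on: duplicate identifiers and empty sequence bodies are errors.
#' Line folding is handled by the underlying reader; case is preserved.
#'
#' @param file Path to a FASTA file.
#' @param type `"DNA"`, `"AA"` or `"B"` (raw, any alphabet).
#' @return A [Biostrings::XStringSet].
#' @export
readFastaRecords <- function(file, type = c("DNA", "AA", "B")) {
  type <- match.arg(type)
  reader <- switch(type,
    DNA = Biostrings::readDNAStringSet,
    AA = Biostrings::readAAStringSet,
    B = Biostrings::readBStringSet
  )
  seqs <- reader(file)
  ids <- sub("\\s.*$", "", names(seqs))
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(BiocGenerics::width(seqs) == 0L)) {
    stop("empty sequence body for: ",
         paste(ids[BiocGenerics::width(seqs) == 0L], collapse = ", "),
         call. = FALSE)
  }
  seqs
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr A `GRanges`; `name` and `score` metadata columns are used when
#'   present, `"."` and 0 otherwise.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeBed <- function(gr, file) {
  checkGRanges(gr)
  name <- if (!is.null(gr$name)) gr$name else rep(".", length(gr))
  score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   as.character(GenomeInfoDb::seqnames(gr)),
                   BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                   name, formatNum(score), strand)
  writeLines(lines, file)
  invisible(file)
}

#' Write a coverage GRanges as bedGraph
#'
#' @param gr A `GRanges` with a numeric `score` column.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeBedGraph <- function(gr, file) {
  checkGRanges(gr)
  if (is.null(gr$score)) stop("'gr' needs a 'score' column", call. = FALSE)
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(GenomeInfoDb::seqnames(gr)),
                   BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                   formatNum(gr$score))
  writeLines(lines, file)
  invisible(file)
}

#' @noRd
formatNum <- function(x) {
  out <- trimws(formatC(x, format = "fg", digits = 15))
  has_dot <- grepl(".", out, fixed = TRUE)
  out[has_dot] <- sub("\\.$", "", sub("0+$", "", out[has_dot]))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs An [Biostrings::XStringSet] or named character vector.
#' @param file Output path.
#' @param width Line width for sequence folding.
#' @return Invisibly, `file`.
#' @export
writeFasta <- function(seqs, file, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(seqs, file, width = width)
  invisible(file)
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are rounded to a fixed decimal precision so output is
#' reproducible across platforms.
#'
#' @param tree An [ape::read.tree()]-style `phylo` object.
#' @param file Output path.
#' @param digits Decimal digits for branch lengths.
#' @return Invisibly, `file`.
#' @export
writeNewick <- function(tree, file, digits = 6L) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object", call. = FALSE)
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, digits)
  }
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Write a data.frame as TSV with a header row
#'
#' @param df A data.frame.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeTsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}
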