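#' @include AllClasses.R AllGenerics.R
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Read genomic peaks from a BED file
#'
#' BED3+ with 0-based half-open coordinates; the strand is taken from
#' column 6 when present, else \code{"."} (unstranded).  Coordinates are
#' converted to the 1-based closed convention of \code{GRanges}; peak
#' names from column 4 are kept when present.
#'
#' @param path BED file path.
#' @return a \code{GRanges}.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  n <- length(lines)
  chrom <- character(n); s <- integer(n); e <- integer(n)
  str <- rep(".", n); nm <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t|\\s+")[[1L]]
    if (length(f) < 3L)
      stop(sprintf("line %d of %s: BED needs at least 3 columns",
                   lineno[i], path), call. = FALSE)
    si <- suppressWarnings(as.integer(f[2L]))
    ei <- suppressWarnings(as.integer(f[3L]))
    if (is.na(si) || is.na(ei))
      stop(sprintf("line %d of %s: non-integer coordinates",
                   lineno[i], path), call. = FALSE)
    if (si >= ei)
      stop(sprintf("line %d of %s: start (%d) must be < end (%d)",
                   lineno[i], path, si, ei), call. = FALSE)
    chrom[i] <- f[1L]; s[i] <- si; e[i] <- ei
    if (length(f) >= 4L) nm[i] <- f[4L]
    if (length(f) >= 6L && f[6L] %in% c("+", "-")) str[i] <- f[6L]
  }
  gr <- GRanges(chrom, IRanges(s + 1L, e), strand = sub("\\.", "*", str))
  if (any(!is.na(nm))) names(gr) <- nm
  gr
}

#' Write genomic peaks as BED6
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
  nm <- if (is.null(names(gr))) sprintf("peak%d", seq_along(gr)) else
    names(gr)
  str <- as.character(strand(gr))
  str[str == "*"] <- "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     nm, str), path)
  invisible(path)
}

#' Strand-aware within-distance peak overlap
#'
#' Two peaks qualify as overlapping when they lie on the same chromosome,
#' their strands are compatible, and the gap between them is at most
#' \code{maxGap} base pairs (gap 0 for overlapping or bookended
#' intervals).  With \code{strict = FALSE} (default) an unstranded peak
#' (\code{"."}/\code{"*"}) is compatible with any strand -- ChIP-seq
#' peaks are typically unstranded; \code{strict = TRUE} demands identical
#' strand characters.  Set \code{sameStrand = FALSE} to ignore strand
#' entirely.
#'
#' @param a,b \code{GRanges} peak sets (non-empty).
#' @param maxGap maximum gap in bp (default 150).
#' @param sameStrand require strand compatibility (default TRUE).
#' @param strict require identical strands (default FALSE).
#' @return an [OverlapSummary-class].
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+")
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 400), "+")
#' overlapPeaks(a, b)          # gap 100 <= 150: qualifies
#' @export
overlapPeaks <- function(a, b, maxGap = 150L, sameStrand = TRUE,
                         strict = FALSE) {
  if (length(a) == 0 || length(b) == 0)
    stop("both peak sets must be non-empty", call. = FALSE)
  if (maxGap < 0) stop("maxGap must be >= 0", call. = FALSE)
  # differing chromosome sets between a and b are routine, not a problem
  hits <- suppressWarnings(
    findOverlaps(a, b, maxgap = maxGap,
                 ignore.strand = !sameStrand || strict))
  if (sameStrand && strict) {
    sa <- as.character(strand(a))[queryHits(hits)]
    sb <- as.character(strand(b))[subjectHits(hits)]
    hits <- hits[sa == sb]
  }
  new("OverlapSummary",
      nA = length(a), nB = length(b),
      aWithB = length(unique(queryHits(hits))),
      bWithA = length(unique(subjectHits(hits))),
      pairs = length(hits),
      maxGap = as.integer(maxGap), sameStrand = sameStrand)
}

#' Qualifying peak pairs as a BEDPE-like table
#'
#' @inheritParams overlapPeaks
#' @return a data.frame with one row per qualifying pair (coordinates
#'   back in BED convention) and the gap between the two peaks.
#' @export
overlapPairs <- function(a, b, maxGap = 150L, sameStrand = TRUE,
                         strict = FALSE) {
  if (length(a) == 0 || length(b) == 0)
    stop("both peak sets must be non-empty", call. = FALSE)
  hits <- suppressWarnings(
    findOverlaps(a, b, maxgap = maxGap,
                 ignore.strand = !sameStrand || strict))
  qa <- queryHits(hits); sb <- subjectHits(hits)
  if (sameStrand && strict) {
    ok <- as.character(strand(a))[qa] == as.character(strand(b))[sb]
    qa <- qa[ok]; sb <- sb[ok]
  }
  gap <- pmax(0L, pmax(start(a)[qa], start(b)[sb]) -
                  pmin(end(a)[qa], end(b)[sb]) - 1L)
  data.frame(
    chrom_a = as.character(seqnames(a))[qa], start_a = start(a)[qa] - 1L,
    end_a = end(a)[qa], strand_a = as.character(strand(a))[qa],
    chrom_b = as.character(seqnames(b))[sb], start_b = start(b)[sb] - 1L,
    end_b = end(b)[sb], strand_b = as.character(strand(b))[sb],
    gap = gap, stringsAsFactors = FALSE)
}

setMethod("show", "OverlapSummary", function(object) {
  cat(sprintf(
    "OverlapSummary (maxGap %d bp, %sstrand-aware):\n", object@maxGap,
    if (object@sameStrand) "" else "not "))
  cat(sprintf("  A: %d peaks, %d with a partner in B (%.1f%%)\n",
              object@nA, object@aWithB, 100 * object@aWithB / object@nA))
  cat(sprintf("  B: %d peaks, %d with a partner in A (%.1f%%)\n",
              object@nB, object@bWithA, 100 * object@bWithA / object@nB))
  cat(sprintf("  qualifying pairs: %d\n", object@pairs))
})
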