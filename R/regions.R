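#' @include AllClasses.R AllGenerics.R
NULL

#' Region annotation of a construct
#'
#' A region annotation is a data.frame with columns \code{name},
#' \code{start}, \code{end} (residue numbers, inclusive), non-overlapping.
#' [regionAnnotation()] validates; [readRegionAnnotation()] reads the
#' 3-column whitespace-separated text format.
#'
#' @param name,start,end vectors defining the regions.
#' @return a validated annotation data.frame.
#' @export
regionAnnotation <- function(name, start, end) {
  ann <- data.frame(name = as.character(name), start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (any(ann$start > ann$end))
    stop("region start must not exceed end", call. = FALSE)
  ord <- order(ann$start)
  a <- ann[ord, , drop = FALSE]
  if (nrow(a) > 1 && any(a$start[-1L] <= a$end[-nrow(a)]))
    stop("regions must not overlap", call. = FALSE)
  ann
}

#' @rdname regionAnnotation
#' @param path a 3-column text file (name, start, end; \code{#} comments).
#' @export
readRegionAnnotation <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("name", "start", "end"),
                          stringsAsFactors = FALSE)
  regionAnnotation(df$name, df$start, df$end)
}

#' Default SRM-SANT1 region annotation
#'
#' The construct spans residues 141-251.  Helix boundaries follow the
#' secondary-structure analysis of the domain (alpha1 168-178, alpha2
#' 221-230, alpha3 237-247); the SRM/linker split at 158/159 matches the
#' construct starts of the two studied fragments and is overridable, as is
#' everything else, via a custom annotation.
#'
#' @return an annotation data.frame.
#' @export
defaultRegionAnnotation <- function() {
  regionAnnotation(
    name = c("SRM", "linker", "alpha1", "alpha1-alpha2 loop", "alpha2",
             "alpha2-alpha3 loop", "alpha3", "C-term"),
    start = c(141L, 159L, 168L, 179L, 221L, 231L, 237L, 248L),
    end   = c(158L, 167L, 178L, 220L, 230L, 236L, 247L, 251L))
}

#' Count classified residues per region and significance tier
#'
#' Every classified residue is assigned to exactly one region (or to an
#' implicit \code{"unannotated"} bin for gaps inside the construct
#' bounds); residues outside the construct bounds are an error.
#'
#' @param result a [SignificanceResult-class].
#' @param annotation a region annotation data.frame
#'   (default [defaultRegionAnnotation()]).
#' @return a data.frame of counts with one row per region (annotation
#'   order, then \code{"unannotated"} if non-empty) and one column per
#'   tier, plus a \code{total} column.
#' @export
classifyRegions <- function(result, annotation = defaultRegionAnnotation()) {
  stopifnot(is(result, "SignificanceResult"))
  lo <- min(annotation$start)
  hi <- max(annotation$end)
  res <- result@residue
  out <- res[res < lo | res > hi]
  if (length(out) > 0)
    stop("residue(s) outside construct bounds [", lo, ", ", hi, "]: ",
         paste(out, collapse = ", "), call. = FALSE)
  region <- rep("unannotated", length(res))
  for (i in seq_len(nrow(annotation)))
    region[res >= annotation$start[i] & res <= annotation$end[i]] <-
      annotation$name[i]
  tierLv <- c("not_significant", "ge_1sd", "ge_1p5sd")
  regLv <- c(annotation$name, "unannotated")
  tab <- table(factor(region, levels = regLv),
               factor(result@tier, levels = tierLv))
  df <- as.data.frame.matrix(tab)
  df <- cbind(region = rownames(df), df, total = rowSums(df))
  rownames(df) <- NULL
  if (df$total[df$region == "unannotated"] == 0)
    df <- df[df$region != "unannotated", , drop = FALSE]
  df
}

#' Write the per-region summary table
#'
#' @param summary a data.frame from [classifyRegions()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeRegionSummary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
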