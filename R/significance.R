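#' @include AllClasses.R AllGenerics.R
NULL

#' Classify significantly perturbed residues (trimmed threshold)
#'
#' The classification population is the endpoint CSP of assigned,
#' non-broadened residues (prolines and broadened resonances are excluded
#' from the statistics but reported by the pipeline).  The
#' \code{ceiling(trimFraction * n)} residues with the largest CSP are
#' removed, the mean and sample standard deviation are computed on the
#' remainder, and every residue of the population -- including the trimmed
#' ones -- is classified against \code{mean + 1.0 SD} and
#' \code{mean + 1.5 SD} with strict \code{>}.  Ties at the trim boundary
#' are broken by residue number so the output is deterministic.
#'
#' @param x a [CSPExperiment-class].
#' @param trimFraction fraction of the largest CSPs removed before the
#'   statistics (default 0.10).
#' @param minPopulation smallest admissible population size (default 5).
#' @return a [SignificanceResult-class].
#' @export
classifySignificance <- function(x, trimFraction = 0.10, minPopulation = 5L) {
  stopifnot(is(x, "CSPExperiment"))
  keep <- x@status == "assigned" & !is.na(x@endpointCSP)
  res <- x@residue[keep]
  val <- x@endpointCSP[keep]
  n <- length(val)
  if (n < minPopulation)
    stop("significance classification needs at least ", minPopulation,
         " assigned, non-broadened residues (got ", n, ")", call. = FALSE)
  k <- as.integer(ceiling(trimFraction * n))
  ord <- order(-val, res)            # largest first; ties by residue number
  trimmedIdx <- ord[seq_len(k)]
  rest <- val[-trimmedIdx]
  m <- mean(rest)
  s <- stats::sd(rest)               # sample (n-1) SD
  t1 <- m + 1.0 * s
  t15 <- m + 1.5 * s
  tier <- ifelse(val > t15, "ge_1p5sd",
                 ifelse(val > t1, "ge_1sd", "not_significant"))
  trimmed <- logical(n)
  trimmed[trimmedIdx] <- TRUE
  new("SignificanceResult",
      residue = res, endpointCSP = val, tier = tier, trimmed = trimmed,
      threshold1sd = t1, threshold1p5sd = t15,
      populationMean = m, populationSD = s)
}

#' Write the significance table
#'
#' Thresholds and trimmed-population statistics go into \code{#}-prefixed
#' header lines; the body is residue, endpoint CSP, tier, trimmed flag.
#'
#' @param x a [SignificanceResult-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSignificanceTable <- function(x, path) {
  hdr <- c(sprintf("# population_mean\t%s", as.character(x@populationMean)),
           sprintf("# population_sd\t%s", as.character(x@populationSD)),
           sprintf("# threshold_1sd\t%s", as.character(x@threshold1sd)),
           sprintf("# threshold_1p5sd\t%s", as.character(x@threshold1p5sd)),
           "residue\tendpoint_csp\ttier\ttrimmed")
  body <- sprintf("%d\t%s\t%s\t%s", x@residue, as.character(x@endpointCSP),
                  x@tier, ifelse(x@trimmed, "yes", "no"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("tiers", "SignificanceResult",
          function(x) stats::setNames(x@tier, x@residue))

#' @rdname accessors
#' @export
setMethod("thresholds", "SignificanceResult", function(x)
  c(ge_1sd = x@threshold1sd, ge_1p5sd = x@threshold1p5sd))

#' @rdname significantResidues
#' @export
setMethod("significantResidues", "SignificanceResult",
          function(x, tier = "ge_1sd") {
  tier <- match.arg(tier, c("ge_1sd", "ge_1p5sd"))
  keep <- if (tier == "ge_1sd") x@tier %in% c("ge_1sd", "ge_1p5sd")
          else x@tier == "ge_1p5sd"
  x@residue[keep]
})

setMethod("show", "SignificanceResult", function(object) {
  tab <- table(factor(object@tier,
                      levels = c("not_significant", "ge_1sd", "ge_1p5sd")))
  cat(sprintf("SignificanceResult: %d residues classified\n",
              length(object@residue)))
  cat(sprintf("  trimmed %d | mean %.5f, SD %.5f ppm\n",
              sum(object@trimmed), object@populationMean,
              object@populationSD))
  cat(sprintf("  thresholds: >1.0 SD %.5f, >1.5 SD %.5f ppm\n",
              object@threshold1sd, object@threshold1p5sd))
  cat(sprintf("  tiers: not_significant %d, ge_1sd %d, ge_1p5sd %d\n",
              tab[[1L]], tab[[2L]], tab[[3L]]))
})
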