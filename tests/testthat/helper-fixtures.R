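# Shared fixture builders: everything is generated in code at test time.

# A minimal hand-built titration: `shifts` is a list of length n_points,
# each an (n_residues x 2) matrix of absolute (dH, dN); NA rows = absent.
makeSeries <- function(shifts, L, P = 0.1, residues = NULL, types = NULL) {
  n <- nrow(shifts[[1]])
  if (is.null(residues)) residues <- seq_len(n) + 100L
  if (is.null(types)) types <- rep("A", n)
  pls <- lapply(shifts, function(m)
    csptitr:::.newPeakList(residues, types, m[, 1], m[, 2]))
  TitrationSeries(pls, ligandConc = L, proteinConc = P)
}

# Noiseless forward trajectories for given per-residue (ddmax, theta),
# shared kd; returns the shift list for makeSeries().
forwardShifts <- function(L, P, kd, ddmax, theta,
                          apoH = 8.2, apoN = 118, w = 0.20) {
  n <- length(ddmax)
  apoH <- rep_len(apoH, n); apoN <- rep_len(apoN, n)
  lapply(L, function(l) {
    dd <- ddmax * isotherm(max(l, 0), P, kd, 1)
    if (l == 0) dd <- rep(0, n)
    cbind(apoH + dd * cos(theta), apoN + dd * sin(theta) / w)
  })
}

# Independent brute-force oracle for the trimmed significance rule.
bruteSignificance <- function(values, residues = seq_along(values),
                              trim = 0.10) {
  n <- length(values)
  k <- ceiling(trim * n)
  ord <- order(-values, residues)
  rest <- values[-ord[seq_len(k)]]
  m <- sum(rest) / length(rest)
  s <- sqrt(sum((rest - m)^2) / (length(rest) - 1))
  list(mean = m, sd = s, t1 = m + s, t15 = m + 1.5 * s,
       trimmed = sort(residues[ord[seq_len(k)]]),
       sig1 = sort(residues[values > m + s]),
       sig15 = sort(residues[values > m + 1.5 * s]))
}

# O(n^2) brute-force oracle for the within-distance same-strand overlap
# rule, on BED-convention (0-based half-open) coordinates.
bruteOverlap <- function(a, b, maxGap = 150, sameStrand = TRUE,
                         strict = FALSE) {
  compat <- function(x, y) {
    if (!sameStrand) return(TRUE)
    if (strict) return(x == y)
    x == "." || y == "." || x == y
  }
  pairs <- 0L
  aHit <- logical(nrow(a)); bHit <- logical(nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    if (!compat(a$strand[i], b$strand[j])) next
    gap <- max(0L, max(a$start[i], b$start[j]) - min(a$end[i], b$end[j]))
    if (gap <= maxGap) {
      pairs <- pairs + 1L
      aHit[i] <- TRUE; bHit[j] <- TRUE
    }
  }
  list(pairs = pairs, aWithB = sum(aHit), bWithA = sum(bHit))
}

bedToGRanges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = sub("\\.", "*", df$strand))
}

randomBedSet <- function(n, chroms = c("chr1", "chr2"), span = 50000) {
  start <- sample.int(span, n)
  width <- sample(50:500, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             strand = sample(c("+", "-", "."), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
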