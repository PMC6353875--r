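#' @include AllClasses.R AllGenerics.R binding.R
NULL

# Evaluate expr with a temporarily seeded RNG, restoring global state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate an HSQC titration series
#'
#' Forward model of a fast-exchange single-site titration.  A fraction of
#' residues are binders: each gets a residue-specific saturated shift
#' change (\code{ddmax}, drawn uniformly from \code{ddmaxRange}) and a
#' random fixed 2-D direction, and at every titration point its peak is
#' displaced from the apo position along that direction so that the
#' weighted CSP of the noiseless displacement equals the ligand-depletion
#' isotherm value ([isotherm()]) at the shared true Kd.  Non-binders stay
#' at their apo position.  Independent Gaussian noise of SD
#' \code{noiseSd} ppm is then added to each dimension at every point
#' (including apo).  Optionally, binder peaks whose noiseless fraction
#' bound falls inside the \code{broadening} window are marked absent,
#' mimicking intermediate-exchange broadening at partial saturation.
#'
#' Defaults mirror a weak histone-peptide interaction followed on a
#' 0.1 mM protein sample titrated to 32 molar equivalents.
#'
#' @param trueKd shared binder dissociation constant, mM (default 0.3).
#' @param proteinConc protein concentration, mM (default 0.1).
#' @param molarRatios ligand:protein ratios, apo (0) first
#'   (default 0, 1, 2, 4, 8, 16, 32).
#' @param nResidues number of assigned residues (default 84).
#' @param binderFraction fraction of residues that bind (default 0.2).
#' @param ddmaxRange range of saturated shift changes, ppm
#'   (default 0.05--0.25).
#' @param noiseSd Gaussian noise SD per dimension, ppm (default 0.005;
#'   0 gives a noiseless series).
#' @param broadening \code{NULL} (no broadening) or a fraction-bound
#'   window, e.g. \code{c(0.3, 0.7)}, inside which binder peaks vanish.
#' @param nitrogenWeight weight used to resolve the displacement
#'   direction (default 0.20, matching the analysis default).
#' @param resStart first residue number (default 141).
#' @param seed master seed; \code{directionSeed}/\code{noiseSeed}
#'   (defaults \code{seed} and \code{seed + 1}) separate the binder
#'   geometry draw from the noise draw so noise replicates can share one
#'   ground truth.
#' @param directionSeed,noiseSeed see \code{seed}.
#' @return a list with \code{series} (a [TitrationSeries-class]) and
#'   \code{truth} (a data.frame: residue, binder flag, kd, ddmax,
#'   direction angle).  Identical seeds give bit-identical output.
#' @export
simulateTitration <- function(trueKd = 0.3, proteinConc = 0.1,
                              molarRatios = c(0, 1, 2, 4, 8, 16, 32),
                              nResidues = 84L, binderFraction = 0.2,
                              ddmaxRange = c(0.05, 0.25), noiseSd = 0.005,
                              broadening = NULL, nitrogenWeight = 0.20,
                              resStart = 141L, seed = 1L,
                              directionSeed = seed, noiseSeed = seed + 1L) {
  if (molarRatios[1L] != 0 || any(diff(molarRatios) <= 0))
    stop("molarRatios must start at 0 and increase strictly", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  if (trueKd <= 0 || proteinConc <= 0)
    stop("trueKd and proteinConc must be > 0", call. = FALSE)
  if (binderFraction < 0 || binderFraction > 1)
    stop("binderFraction must be in [0, 1]", call. = FALSE)
  if (diff(ddmaxRange) < 0 || ddmaxRange[1L] <= 0)
    stop("ddmaxRange must be a positive interval", call. = FALSE)
  if (!is.null(broadening) &&
      (length(broadening) != 2L || broadening[1L] > broadening[2L]))
    stop("broadening must be NULL or c(lo, hi) with lo <= hi",
         call. = FALSE)
  n <- as.integer(nResidues)
  np <- length(molarRatios)
  L <- molarRatios * proteinConc
  residues <- resStart + seq_len(n) - 1L

  geom <- .withSeed(directionSeed, {
    nb <- round(binderFraction * n)
    binder <- logical(n)
    binder[sample.int(n, nb)] <- TRUE
    list(binder = binder,
         type = sample(setdiff(.AA1, "P"), n, replace = TRUE),
         apoH = stats::runif(n, 7.6, 9.4),
         apoN = stats::runif(n, 106, 130),
         ddmax = stats::runif(n, ddmaxRange[1L], ddmaxRange[2L]),
         theta = stats::runif(n, 0, 2 * pi))
  })
  noise <- if (noiseSd > 0)
    .withSeed(noiseSeed, array(stats::rnorm(n * np * 2L, 0, noiseSd),
                               dim = c(n, np, 2L)))
  else array(0, dim = c(n, np, 2L))

  fracBound <- isotherm(L, proteinConc, trueKd, 1)   # in [0, 1]
  pls <- vector("list", np)
  for (j in seq_len(np)) {
    dd <- ifelse(geom$binder, geom$ddmax * fracBound[j], 0)
    # resolve the CSP magnitude along the fixed direction so that the
    # weighted norm of the noiseless displacement equals dd
    dH <- geom$apoH + dd * cos(geom$theta) + noise[, j, 1L]
    dN <- geom$apoN + dd * sin(geom$theta) / nitrogenWeight +
      noise[, j, 2L]
    if (!is.null(broadening)) {
      gone <- geom$binder & fracBound[j] >= broadening[1L] &
        fracBound[j] <= broadening[2L]
      dH[gone] <- NA_real_
      dN[gone] <- NA_real_
    }
    pls[[j]] <- .newPeakList(residues, geom$type, dH, dN)
  }
  truth <- data.frame(
    residue = residues, binder = geom$binder,
    kd = ifelse(geom$binder, trueKd, NA_real_),
    ddmax = ifelse(geom$binder, geom$ddmax, NA_real_),
    theta = geom$theta)
  list(series = TitrationSeries(pls, ligandConc = L,
                                proteinConc = proteinConc,
                                ligandName = "simulated ligand",
                                proteinName = "simulated protein"),
       truth = truth)
}

#' Simulate a pair of genomic peak sets with planted overlaps
#'
#' Set A is placed uniformly on a single chromosome.  A fraction of the B
#' peaks is planted next to A peaks (cyclically over A, so
#' \code{sharedFraction = 1} with \code{nB >= nA} touches every A peak)
#' at a gap drawn uniformly from \code{0..jitterBp}, on the anchor's
#' strand; the rest are placed uniformly with random strand.
#'
#' @param nA,nB peak counts.
#' @param genomeSize chromosome length, bp (default 5e7).
#' @param sharedFraction fraction of B peaks planted near A (default 0.3).
#' @param jitterBp maximum planted gap, bp (default 50).
#' @param peakWidth width of every peak, bp (default 200).
#' @param seed RNG seed.
#' @return a list with \code{a}, \code{b} (\code{GRanges}) and
#'   \code{truth} (a data.frame: B index, planted flag, anchor A index,
#'   planted gap).
#' @export
simulatePeakSets <- function(nA = 100L, nB = 100L, genomeSize = 5e7,
                             sharedFraction = 0.3, jitterBp = 50L,
                             peakWidth = 200L, seed = 1L) {
  if (sharedFraction < 0 || sharedFraction > 1)
    stop("sharedFraction must be in [0, 1]", call. = FALSE)
  if (jitterBp < 0 || peakWidth <= 0 || genomeSize <= 4 * peakWidth)
    stop("invalid peak-set configuration", call. = FALSE)
  .withSeed(seed, {
    margin <- peakWidth + jitterBp + 1L
    aStart <- sort(sample.int(as.integer(genomeSize - 2L * margin),
                              nA)) + margin
    aStrand <- sample(c("+", "-"), nA, replace = TRUE)
    a <- GRanges("chr1", IRanges(aStart, width = peakWidth),
                 strand = aStrand)
    nShared <- round(sharedFraction * nB)
    planted <- seq_len(nB) <= nShared
    anchor <- rep(NA_integer_, nB)
    gap <- rep(NA_integer_, nB)
    bStart <- integer(nB); bStrand <- character(nB)
    for (i in seq_len(nB)) {
      if (planted[i]) {
        anchor[i] <- ((i - 1L) %% nA) + 1L
        gap[i] <- if (jitterBp > 0) sample.int(jitterBp + 1L, 1L) - 1L
                  else 0L
        # place downstream of the anchor at exactly `gap` bp separation
        bStart[i] <- aStart[anchor[i]] + peakWidth + gap[i]
        bStrand[i] <- aStrand[anchor[i]]
      } else {
        bStart[i] <- sample.int(as.integer(genomeSize - 2L * margin),
                                1L) + margin
        bStrand[i] <- sample(c("+", "-"), 1L)
      }
    }
    b <- GRanges("chr1", IRanges(bStart, width = peakWidth),
                 strand = bStrand)
    list(a = a, b = b,
         truth = data.frame(b_index = seq_len(nB), planted = planted,
                            anchor = anchor, gap = gap))
  })
}
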