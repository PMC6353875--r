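#' @include AllClasses.R AllGenerics.R
NULL

#' One-site binding isotherm with ligand depletion
#'
#' Observed shift change at total ligand \code{L} and total protein
#' \code{P} for a single site of dissociation constant \code{kd} and
#' saturated shift change \code{ddmax}:
#' \deqn{\Delta\delta = \Delta\delta_{max}\,
#'   \frac{(L+P+K_d) - \sqrt{(L+P+K_d)^2 - 4PL}}{2P}}
#' i.e. the exact quadratic solution for the bound fraction, valid when
#' bound ligand is a non-negligible part of the total (the regime of weak,
#' mM-scale interactions followed by NMR).  Vectorized over \code{L} (and
#' \code{P}).
#'
#' @param L total ligand concentration(s), mM (>= 0).
#' @param P total protein concentration(s), mM (> 0).
#' @param kd dissociation constant, mM (> 0).
#' @param ddmax shift change at saturation, ppm (> 0).
#' @return shift change(s) in \code{[0, ddmax]}, ppm.
#' @examples
#' isotherm(L = 0.1, P = 0.1, kd = 0.3, ddmax = 1)  # 0.2087122
#' @export
isotherm <- function(L, P, kd, ddmax) {
  if (any(P <= 0)) stop("P must be > 0", call. = FALSE)
  if (any(L < 0)) stop("L must be >= 0", call. = FALSE)
  if (kd <= 0 || ddmax <= 0) stop("kd and ddmax must be > 0", call. = FALSE)
  s <- L + P + kd
  disc <- s^2 - 4 * P * L
  # disc = (L-P)^2 + 2 kd (L+P) + kd^2 > 0 always; clamp roundoff
  disc[disc < 0] <- 0
  ddmax * (s - sqrt(disc)) / (2 * P)
}

#' Fit the ligand-depletion isotherm to one residue's CSP trajectory
#'
#' Nonlinear least squares (Levenberg-Marquardt with positivity bounds,
#' via \pkg{minpack.lm}) of \code{(kd, ddmax)} against the residue's
#' normalized CSP at each titration point.  Starting values are
#' scale-aware: \code{kd} at the median non-zero ligand concentration and
#' \code{ddmax} at 1.2 times the largest observed CSP.  At least three
#' non-apo points with a defined CSP are required.  The fraction of
#' protein bound at the final usable point, evaluated at the fitted
#' parameters, gives the saturation flag.
#'
#' @param x a [CSPExperiment-class].
#' @param residue residue number to fit.
#' @param saturationCutoff fraction bound at the final point above which
#'   the titration is considered saturated (default 0.8).
#' @param maxIter maximum optimizer iterations.
#' @return a [BindingFit-class].  On optimizer failure the fit is returned
#'   with \code{converged = FALSE} and a warning.
#' @export
fitResidue <- function(x, residue, saturationCutoff = 0.8, maxIter = 200L) {
  stopifnot(is(x, "CSPExperiment"))
  i <- match(residue, x@residue)
  if (is.na(i)) stop("residue ", residue, " not in experiment", call. = FALSE)
  csp <- x@csp[i, ]
  L <- x@design$ligandConc
  P <- x@design$proteinConc
  ok <- !is.na(csp)
  if (sum(ok & L > 0) < 3L)
    stop("residue ", residue, ": need >= 3 non-apo points with defined CSP",
         call. = FALSE)
  L <- L[ok]; P <- P[ok]; y <- csp[ok]
  kd0 <- stats::median(L[L > 0])
  dd0 <- 1.2 * max(y)
  if (dd0 <= 0) dd0 <- 1e-3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ isotherm(L, P, kd, ddmax),
                      start = list(kd = kd0, ddmax = dd0),
                      lower = c(kd = 1e-9, ddmax = 1e-9),
                      control = minpack.lm::nls.lm.control(
                        maxiter = maxIter, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("fit failed for residue ", residue, ": ",
            conditionMessage(fit), call. = FALSE)
    return(new("BindingFit", residueNumber = as.integer(residue),
               kd = NA_real_, ddmax = NA_real_, kdStderr = NA_real_,
               converged = FALSE, saturated = FALSE,
               fracBoundEnd = NA_real_))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  conv <- isTRUE(fit$convInfo$isConv)
  nEnd <- length(L)
  fb <- isotherm(L[nEnd], P[nEnd], est[["kd"]], est[["ddmax"]]) /
    est[["ddmax"]]
  fb <- min(max(fb, 0), 1)
  new("BindingFit",
      residueNumber = as.integer(residue),
      kd = unname(est[["kd"]]), ddmax = unname(est[["ddmax"]]),
      kdStderr = unname(se), converged = conv,
      saturated = fb >= saturationCutoff, fracBoundEnd = fb)
}

#' Fit all (or a subset of) residues of a CSP experiment
#'
#' @param x a [CSPExperiment-class].
#' @param residues residue numbers to fit; default all assigned,
#'   non-broadened residues.
#' @param saturationCutoff,maxIter passed to [fitResidue()].
#' @return a \code{DataFrame} with one row per fitted residue and columns
#'   \code{residue}, \code{kd}, \code{kdStderr}, \code{ddmax},
#'   \code{converged}, \code{saturated}, \code{fracBoundEnd}.
#' @export
fitResidues <- function(x, residues = NULL, saturationCutoff = 0.8,
                        maxIter = 200L) {
  if (is.null(residues))
    residues <- x@residue[x@status == "assigned"]
  fits <- lapply(residues, function(r)
    fitResidue(x, r, saturationCutoff = saturationCutoff,
               maxIter = maxIter))
  DataFrame(
    residue = vapply(fits, slot, integer(1), "residueNumber"),
    kd = vapply(fits, slot, numeric(1), "kd"),
    kdStderr = vapply(fits, slot, numeric(1), "kdStderr"),
    ddmax = vapply(fits, slot, numeric(1), "ddmax"),
    converged = vapply(fits, slot, logical(1), "converged"),
    saturated = vapply(fits, slot, logical(1), "saturated"),
    fracBoundEnd = vapply(fits, slot, numeric(1), "fracBoundEnd"))
}

#' Aggregate per-residue Kd values into a global affinity
#'
#' Candidates are the converged fits of significantly perturbed residues.
#' A single pass computes the mean and sample SD over all candidate Kd
#' values and removes residues whose Kd deviates from that mean by at
#' least two SD.  If half or more of the candidates are removed, or more
#' than half of them did not reach saturation, the affinity is reported as
#' a lower limit, "greater than" the smallest (highest-affinity)
#' per-residue Kd.  Otherwise the mean and SD are recomputed over the
#' retained residues.
#'
#' When all candidate Kd values are numerically identical (SD below 1e-8
#' relative to the mean) no residue is excluded: the literal 2-SD rule
#' would otherwise remove every member of a zero-variance population.
#'
#' @param fits a \code{DataFrame} from [fitResidues()].
#' @param significant residue numbers classified significant (see
#'   [significantResidues()]); \code{NULL} keeps all fitted residues.
#' @return a [GlobalKd-class].
#' @export
aggregateGlobalKd <- function(fits, significant = NULL) {
  cand <- fits[fits$converged, , drop = FALSE]
  if (!is.null(significant))
    cand <- cand[cand$residue %in% significant, , drop = FALSE]
  n <- nrow(cand)
  if (n < 2L)
    stop("global Kd needs at least 2 converged fits of significant ",
         "residues (got ", n, ")", call. = FALSE)
  kd <- cand$kd
  m <- mean(kd)
  s <- stats::sd(kd)
  degenerate <- is.na(s) || s <= 1e-8 * max(abs(m), .Machine$double.eps)
  excl <- if (degenerate) rep(FALSE, n) else abs(kd - m) >= 2 * s
  unsatFrac <- mean(!cand$saturated)
  if (mean(excl) >= 0.5 || unsatFrac > 0.5) {
    return(new("GlobalKd", meanKd = NA_real_, sdKd = NA_real_,
               residuesUsed = integer(0),
               residuesExcluded = as.integer(cand$residue[excl]),
               isLowerLimit = TRUE, limitValue = min(kd)))
  }
  keep <- kd[!excl]
  new("GlobalKd",
      meanKd = mean(keep), sdKd = stats::sd(keep),
      residuesUsed = as.integer(cand$residue[!excl]),
      residuesExcluded = as.integer(cand$residue[excl]),
      isLowerLimit = FALSE, limitValue = NA_real_)
}

#' Format a global-affinity result for reports
#'
#' \code{"0.30 +/- 0.10 mM"}, \code{"> 0.9 mM"} (lower limit), or
#' \code{"NB"} when passed \code{NULL} (no binding: no significant
#' residues to fit).
#'
#' @param x a [GlobalKd-class] or \code{NULL}.
#' @param digits significant digits.
#' @return a character scalar.
#' @export
formatGlobalKd <- function(x, digits = 2) {
  if (is.null(x)) return("NB")
  stopifnot(is(x, "GlobalKd"))
  if (x@isLowerLimit)
    sprintf("> %s mM", signif(x@limitValue, digits))
  else
    sprintf("%s +/- %s mM", signif(x@meanKd, digits), signif(x@sdKd, digits))
}

#' Write the per-residue fit table
#'
#' @param fits a \code{DataFrame} from [fitResidues()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeFitTable <- function(fits, path) {
  utils::write.table(as.data.frame(fits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("isLowerLimit", "GlobalKd", function(x) x@isLowerLimit)

setMethod("show", "BindingFit", function(object) {
  cat(sprintf(
    "BindingFit residue %d: Kd = %.4g mM (se %.2g), ddmax = %.4g ppm\n",
    object@residueNumber, object@kd, object@kdStderr, object@ddmax))
  cat(sprintf("  converged %s | %.0f%% bound at endpoint (%ssaturated)\n",
              object@converged, 100 * object@fracBoundEnd,
              if (object@saturated) "" else "not "))
})

setMethod("show", "GlobalKd", function(object) {
  cat("GlobalKd:", formatGlobalKd(object), "\n")
  if (object@isLowerLimit) {
    cat(sprintf("  underdetermined; limit from the highest-affinity residue\n"))
  } else {
    cat(sprintf("  %d residues used, %d excluded (2-SD rule)\n",
                length(object@residuesUsed),
                length(object@residuesExcluded)))
  }
})
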