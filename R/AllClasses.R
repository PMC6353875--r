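#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' TitrationSeries: an ordered NMR titration
#'
#' Holds an ordered series of titration points (apo first), each with a
#' ligand concentration, a protein concentration and an assigned amide peak
#' list.  Peak lists are data.frames with columns \code{residue} (integer),
#' \code{type} (one-letter amino-acid code), \code{dH} and \code{dN}
#' (chemical shifts, ppm; \code{NA} when the peak is broadened beyond
#' detection) and \code{present} (logical).
#'
#' Invariants enforced by the validity method: the first point is the apo
#' reference (ligand concentration 0), ligand concentrations are strictly
#' increasing, at least three points are present, molar ratios agree with
#' ligand/protein to 1e-6, and residue numbers are unique within each list.
#'
#' @slot design a \code{DataFrame} with one row per titration point and
#'   columns \code{ligandConc}, \code{proteinConc} (mM) and
#'   \code{molarRatio}.
#' @slot peakLists a list of peak-list data.frames, parallel to
#'   \code{design}.
#' @slot ligandName,proteinName free-text labels.
#'
#' @seealso [TitrationSeries()] for the constructor,
#'   [readTitration()] to build one from files.
#' @export
setClass("TitrationSeries",
  slots = c(
    design      = "DataFrame",
    peakLists   = "list",
    ligandName  = "character",
    proteinName = "character"
  )
)

.validPeakList <- function(pl, label) {
  req <- c("residue", "type", "dH", "dN", "present")
  missing <- setdiff(req, names(pl))
  if (length(missing) > 0)
    return(sprintf("%s: missing peak-list column(s): %s",
                   label, paste(missing, collapse = ", ")))
  if (anyDuplicated(pl$residue)) {
    dup <- pl$residue[duplicated(pl$residue)][1L]
    return(sprintf("%s: duplicate residue number %d", label, dup))
  }
  if (!is.numeric(pl$dH) || !is.numeric(pl$dN))
    return(sprintf("%s: dH/dN must be numeric", label))
  if (any(pl$present & (is.na(pl$dH) | is.na(pl$dN))))
    return(sprintf("%s: present peaks must have defined shifts", label))
  NULL
}

setValidity("TitrationSeries", function(object) {
  msgs <- character()
  d <- object@design
  n <- nrow(d)
  if (!all(c("ligandConc", "proteinConc", "molarRatio") %in% names(d)))
    return("design must have ligandConc, proteinConc, molarRatio columns")
  if (length(object@peakLists) != n)
    return("number of peak lists must match number of titration points")
  if (n < 3L)
    msgs <- c(msgs, "a titration requires at least 3 points")
  if (n >= 1L && d$ligandConc[1L] != 0)
    msgs <- c(msgs, "first point must be the apo reference (ligandConc = 0)")
  if (n >= 2L && any(diff(d$ligandConc) <= 0))
    msgs <- c(msgs, "ligand concentrations must be strictly increasing")
  if (any(d$ligandConc < 0)) msgs <- c(msgs, "ligandConc must be >= 0")
  if (any(d$proteinConc <= 0)) msgs <- c(msgs, "proteinConc must be > 0")
  ratio <- ifelse(d$proteinConc > 0, d$ligandConc / d$proteinConc, NA_real_)
  if (any(abs(ratio - d$molarRatio) > 1e-6, na.rm = TRUE))
    msgs <- c(msgs, "molarRatio must equal ligandConc/proteinConc (tol 1e-6)")
  for (i in seq_len(n)) {
    m <- .validPeakList(object@peakLists[[i]], sprintf("point %d", i))
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' CSPExperiment: per-residue chemical shift perturbation trajectories
#'
#' Result container of [computeCSPs()].  Rows follow the apo peak list;
#' columns of the trajectory matrices follow the titration points.
#'
#' @slot residue integer residue numbers (apo list order).
#' @slot type one-letter residue types.
#' @slot status one of \code{"assigned"}, \code{"proline"},
#'   \code{"broadened"}.  Broadened residues carry \code{NA} trajectories
#'   from the first titration point at which their peak is absent.
#' @slot dH,dN matrices (residues x points) of shift changes relative to
#'   apo, ppm.
#' @slot csp matrix of normalized perturbations
#'   \eqn{\sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_N)^2}}.
#' @slot endpointCSP last defined normalized perturbation per residue.
#' @slot firstAbsent index of the first point with a missing peak
#'   (\code{NA} if never absent).
#' @slot design copy of the titration design.
#' @slot nitrogenWeight the weight \eqn{w} applied to \eqn{\Delta\delta_N}.
#' @export
setClass("CSPExperiment",
  slots = c(
    residue        = "integer",
    type           = "character",
    status         = "character",
    dH             = "matrix",
    dN             = "matrix",
    csp            = "matrix",
    endpointCSP    = "numeric",
    firstAbsent    = "integer",
    design         = "DataFrame",
    nitrogenWeight = "numeric"
  )
)

setValidity("CSPExperiment", function(object) {
  n <- length(object@residue)
  if (length(object@status) != n || length(object@endpointCSP) != n)
    return("per-residue slots must have equal length")
  if (!all(object@status %in% c("assigned", "proline", "broadened")))
    return("unknown status value")
  if (any(object@csp < 0, na.rm = TRUE))
    return("normalized CSPs must be non-negative")
  if (ncol(object@csp) > 0 && any(object@csp[, 1L] != 0, na.rm = TRUE))
    return("apo-vs-apo CSP must be zero")
  TRUE
})

#' SignificanceResult: trimmed-threshold classification of perturbed residues
#'
#' Produced by [classifySignificance()].  The population is the endpoint
#' CSP of assigned, non-broadened residues; the top 10% (ceiling) are
#' trimmed before the mean and sample SD are computed, and every residue in
#' the population (including trimmed ones) is classified against
#' mean + 1.0 SD and mean + 1.5 SD with strict inequality.
#'
#' @slot residue,endpointCSP the classified population.
#' @slot tier one of \code{"not_significant"}, \code{"ge_1sd"},
#'   \code{"ge_1p5sd"} per residue.
#' @slot trimmed logical; was the residue removed before computing the
#'   threshold statistics.
#' @slot threshold1sd,threshold1p5sd classification thresholds, ppm.
#' @slot populationMean,populationSD trimmed-population statistics, ppm.
#' @export
setClass("SignificanceResult",
  slots = c(
    residue        = "integer",
    endpointCSP    = "numeric",
    tier           = "character",
    trimmed        = "logical",
    threshold1sd   = "numeric",
    threshold1p5sd = "numeric",
    populationMean = "numeric",
    populationSD   = "numeric"
  )
)

setValidity("SignificanceResult", function(object) {
  n <- length(object@residue)
  if (length(object@tier) != n || length(object@trimmed) != n ||
      length(object@endpointCSP) != n)
    return("per-residue slots must have equal length")
  if (!all(object@tier %in% c("not_significant", "ge_1sd", "ge_1p5sd")))
    return("unknown tier value")
  if (object@threshold1p5sd < object@threshold1sd)
    return("1.5-SD threshold cannot lie below the 1-SD threshold")
  TRUE
})

#' BindingFit: per-residue one-site ligand-depletion fit
#'
#' @slot residueNumber integer.
#' @slot kd fitted dissociation constant, mM.
#' @slot ddmax fitted saturated shift change, ppm.
#' @slot kdStderr standard error of \code{kd} from the fit covariance, mM.
#' @slot converged optimizer convergence flag.
#' @slot saturated whether the fraction bound at the final point reaches
#'   the saturation cutoff.
#' @slot fracBoundEnd fraction of protein bound at the final titration
#'   point, evaluated at the fitted parameters.
#' @export
setClass("BindingFit",
  slots = c(
    residueNumber = "integer",
    kd            = "numeric",
    ddmax         = "numeric",
    kdStderr      = "numeric",
    converged     = "logical",
    saturated     = "logical",
    fracBoundEnd  = "numeric"
  )
)

setValidity("BindingFit", function(object) {
  if (isTRUE(object@converged) &&
      (!is.na(object@kd) && object@kd <= 0 ||
       !is.na(object@ddmax) && object@ddmax <= 0))
    return("converged fits must have positive kd and ddmax")
  if (!is.na(object@fracBoundEnd) &&
      (object@fracBoundEnd < -1e-9 || object@fracBoundEnd > 1 + 1e-9))
    return("fracBoundEnd must lie in [0, 1]")
  TRUE
})

#' GlobalKd: aggregated affinity over per-residue fits
#'
#' Either a mean +/- SD over retained residues, or a lower-limit form
#' ("> x mM") when the exclusion or saturation rules indicate the affinity
#' is underdetermined.
#'
#' @slot meanKd,sdKd mean and SD over retained residues, mM (\code{NA} in
#'   the lower-limit form).
#' @slot residuesUsed,residuesExcluded residue numbers retained / removed
#'   by the 2-SD rule.
#' @slot isLowerLimit logical.
#' @slot limitValue the smallest per-residue Kd, mM (\code{NA} unless
#'   lower limit).
#' @export
setClass("GlobalKd",
  slots = c(
    meanKd           = "numeric",
    sdKd             = "numeric",
    residuesUsed     = "integer",
    residuesExcluded = "integer",
    isLowerLimit     = "logical",
    limitValue       = "numeric"
  )
)

setValidity("GlobalKd", function(object) {
  if (length(intersect(object@residuesUsed, object@residuesExcluded)) > 0)
    return("a residue cannot be both used and excluded")
  if (object@isLowerLimit) {
    if (!is.na(object@meanKd) || !is.na(object@sdKd))
      return("lower-limit results carry no mean/SD")
    if (is.na(object@limitValue))
      return("lower-limit results must carry a limit value")
  }
  TRUE
})

#' RestraintSpec: active-residue lists for data-driven docking
#'
#' @slot activeA protein (chain A) active residues.
#' @slot activeB peptide (chain B) active residues.
#' @slot distLower,distUpper effective distance bounds, Angstrom.
#' @export
setClass("RestraintSpec",
  slots = c(
    activeA   = "integer",
    activeB   = "integer",
    distLower = "numeric",
    distUpper = "numeric"
  )
)

setValidity("RestraintSpec", function(object) {
  if (length(object@activeA) == 0 || length(object@activeB) == 0)
    return("both active-residue sets must be non-empty")
  if (object@distLower > object@distUpper)
    return("distLower must not exceed distUpper")
  TRUE
})

#' OverlapSummary: strand-aware within-distance peak co-occurrence counts
#'
#' @slot nA,nB input peak counts.
#' @slot aWithB,bWithA peaks in one set with at least one qualifying
#'   partner in the other.
#' @slot pairs number of qualifying (a, b) pairs.
#' @slot maxGap the gap threshold used, bp.
#' @slot sameStrand whether strand compatibility was required.
#' @export
setClass("OverlapSummary",
  slots = c(
    nA         = "integer",
    nB         = "integer",
    aWithB     = "integer",
    bWithA     = "integer",
    pairs      = "integer",
    maxGap     = "integer",
    sameStrand = "logical"
  )
)

setValidity("OverlapSummary", function(object) {
  if (object@aWithB > object@nA || object@bWithA > object@nB)
    return("per-set overlap counts cannot exceed set sizes")
  if (object@pairs < max(object@aWithB, object@bWithA))
    return("pair count cannot be below the per-set counts")
  TRUE
})
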