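#' @include AllClasses.R
NULL

#' Accessors for titration and CSP objects
#'
#' Small accessor generics used across the package: number of titration
#' points, per-point concentrations, peak lists, trajectory matrices,
#' statuses and significance tiers.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return the corresponding slot content; see individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("ligandConc", function(x) standardGeneric("ligandConc"))

#' @rdname accessors
#' @export
setGeneric("proteinConc", function(x) standardGeneric("proteinConc"))

#' @rdname accessors
#' @export
setGeneric("molarRatio", function(x) standardGeneric("molarRatio"))

#' @rdname accessors
#' @export
setGeneric("peakLists", function(x) standardGeneric("peakLists"))

#' @rdname accessors
#' @export
setGeneric("titrationDesign", function(x) standardGeneric("titrationDesign"))

#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' @rdname accessors
#' @export
setGeneric("residueStatus", function(x) standardGeneric("residueStatus"))

#' @rdname accessors
#' @export
setGeneric("cspMatrix", function(x) standardGeneric("cspMatrix"))

#' @rdname accessors
#' @export
setGeneric("endpointCSP", function(x) standardGeneric("endpointCSP"))

#' @rdname accessors
#' @export
setGeneric("tiers", function(x) standardGeneric("tiers"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' Residues classified at or above a significance tier
#'
#' @param x a [SignificanceResult-class].
#' @param tier minimum tier, \code{"ge_1sd"} (default) or
#'   \code{"ge_1p5sd"}.
#' @return integer vector of residue numbers.
#' @export
setGeneric("significantResidues",
           function(x, tier = "ge_1sd") standardGeneric("significantResidues"))

#' @rdname accessors
#' @export
setGeneric("isLowerLimit", function(x) standardGeneric("isLowerLimit"))
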