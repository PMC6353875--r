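#' @include AllClasses.R AllGenerics.R
NULL

#' Build a docking-restraint specification from CSP significance
#'
#' Residues classified at or above the chosen tier become the active set
#' of the protein (chain A); the peptide's active set (chain B) is given
#' explicitly, since CSPs are observed on the protein side only.  An
#' explicit \code{activeOverride} replaces the tier-derived set, e.g. to
#' use a manually curated residue list.  Restraints are emitted in the
#' ambiguous one-to-many form (each active A residue paired with the
#' disjunction of all active B residues).
#'
#' @param result a [SignificanceResult-class].
#' @param partnerResidues active residues of the peptide partner.
#' @param tier minimum tier for the protein active set (default
#'   \code{"ge_1sd"}).
#' @param activeOverride optional explicit protein active set.
#' @param distLower,distUpper effective distance bounds, Angstrom
#'   (defaults 0 and 2.0, the common effective-distance convention for
#'   CSP-derived ambiguous restraints).
#' @return a [RestraintSpec-class].
#' @export
buildRestraints <- function(result, partnerResidues, tier = "ge_1sd",
                            activeOverride = NULL, distLower = 0,
                            distUpper = 2.0) {
  if (length(partnerResidues) == 0)
    stop("partnerResidues must be non-empty", call. = FALSE)
  activeA <- if (!is.null(activeOverride)) as.integer(activeOverride)
             else significantResidues(result, tier = tier)
  if (length(activeA) == 0)
    stop("no significant residues at tier ", tier,
         "; supply activeOverride to set the active residues manually",
         call. = FALSE)
  new("RestraintSpec", activeA = sort(unique(activeA)),
      activeB = sort(unique(as.integer(partnerResidues))),
      distLower = distLower, distUpper = distUpper)
}

#' Write an ambiguous-restraint table
#'
#' One CNS-style assign statement per active residue of chain A, pairing
#' it with the disjunction of every active residue of chain B, with the
#' target distance and lower/upper offsets derived from the spec bounds:
#' \code{assign (resid N and segid A) ((resid M1 and segid B) or ...)
#' upper upper-lower 0.0}.  A JSON sidecar (\code{<path>.json}) carries
#' the active lists.
#'
#' @param spec a [RestraintSpec-class].
#' @param path output path for the restraint table.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeAirTable <- function(spec, path, sidecar = TRUE) {
  stopifnot(is(spec, "RestraintSpec"))
  validObject(spec)
  sel <- paste(sprintf("(resid %d and segid B)", spec@activeB),
               collapse = " or ")
  lines <- sprintf("assign (resid %d and segid A) (%s) %.2f %.2f %.2f",
                   spec@activeA, sel, spec@distUpper,
                   spec@distUpper - spec@distLower, 0)
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write restraint table to ",
                                    path, ": ", conditionMessage(e),
                                    call. = FALSE))
  if (sidecar)
    jsonlite::write_json(
      list(active_a = spec@activeA, active_b = spec@activeB,
           dist_lower = spec@distLower, dist_upper = spec@distUpper),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Parse back an ambiguous-restraint table
#'
#' Inverse of [writeAirTable()]; used for round-trip checks.
#'
#' @param path restraint table path.
#' @return a [RestraintSpec-class].
#' @export
readAirTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  activeA <- integer(length(lines))
  activeB <- NULL
  upper <- lower <- NA_real_
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i],
      regexec(paste0("^assign \\(resid ([0-9]+) and segid A\\) \\((.*)\\)",
                     "\\s+([0-9.]+)\\s+([0-9.]+)\\s+([0-9.]+)\\s*$"),
              lines[i]))[[1L]]
    if (length(m) != 6L)
      stop("unparseable restraint line ", i, " in ", path, call. = FALSE)
    activeA[i] <- as.integer(m[2L])
    b <- as.integer(regmatches(m[3L],
           gregexpr("resid ([0-9]+)", m[3L]))[[1L]] |>
           sub(pattern = "resid ", replacement = ""))
    if (is.null(activeB)) activeB <- b
    upper <- as.numeric(m[4L])
    lower <- upper - as.numeric(m[5L])
  }
  new("RestraintSpec", activeA = sort(unique(activeA)),
      activeB = sort(unique(activeB)), distLower = lower,
      distUpper = upper)
}

setMethod("show", "RestraintSpec", function(object) {
  cat(sprintf("RestraintSpec: %d active residues (chain A) x %d (chain B)\n",
              length(object@activeA), length(object@activeB)))
  cat(sprintf("  effective distance bounds %.1f-%.1f A\n",
              object@distLower, object@distUpper))
  cat("  A:", paste(object@activeA, collapse = ", "), "\n")
  cat("  B:", paste(object@activeB, collapse = ", "), "\n")
})
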