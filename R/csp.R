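#' @include AllClasses.R AllGenerics.R
NULL

#' Normalized (weighted) chemical shift perturbation
#'
#' Combines amide 1H and 15N shift changes into a single perturbation
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 +
#'   (w\,\Delta\delta_N)^2}}{dd = sqrt(dH^2 + (w dN)^2)}
#' with the nitrogen weight \eqn{w} compensating for the larger 15N shift
#' dispersion.  The default weight is 0.20, the standard choice for
#' backbone amides.  The function is vectorized and even in both
#' arguments.
#'
#' @param dH,dN shift changes, ppm.
#' @param nitrogenWeight scale applied to \code{dN} (> 0).
#' @return non-negative perturbation(s), ppm.
#' @examples
#' normalizedCSP(0.10, 0.50)          # 0.1414214
#' @export
normalizedCSP <- function(dH, dN, nitrogenWeight = 0.20) {
  if (!is.numeric(nitrogenWeight) || length(nitrogenWeight) != 1L ||
      !is.finite(nitrogenWeight) || nitrogenWeight <= 0)
    stop("nitrogenWeight must be a single positive number", call. = FALSE)
  bad <- (!is.na(dH) & !is.finite(dH)) | (!is.na(dN) & !is.finite(dN))
  if (any(bad))
    stop("non-finite chemical shift difference", call. = FALSE)
  sqrt(dH^2 + (nitrogenWeight * dN)^2)
}

#' Compute per-residue CSP trajectories for a titration
#'
#' For every residue in the apo peak list, shift differences are taken
#' point-minus-apo and combined with [normalizedCSP()].  Prolines (type
#' \code{P}) carry no backbone amide and get status \code{"proline"} with
#' no trajectory.  A residue whose peak is absent at any non-apo point is
#' flagged \code{"broadened"}; its trajectory is defined only before the
#' first absent point (and stays undefined afterwards even if the peak
#' reappears).  A residue present at a later point but missing from the
#' apo list is an error, since no reference position exists.
#'
#' @param series a [TitrationSeries-class].
#' @param nitrogenWeight weight on the 15N dimension (default 0.20).
#' @return a [CSPExperiment-class].
#' @export
computeCSPs <- function(series, nitrogenWeight = 0.20) {
  stopifnot(is(series, "TitrationSeries"))
  validObject(series)
  apo <- series@peakLists[[1L]]
  n <- nrow(apo)
  np <- nPoints(series)
  apoResidues <- apo$residue
  for (j in 2:np) {
    extra <- setdiff(series@peakLists[[j]]$residue, apoResidues)
    if (length(extra) > 0)
      stop("residue(s) ", paste(extra, collapse = ", "), " present at point ",
           j, " but absent from the apo reference", call. = FALSE)
  }
  dH <- dN <- csp <- matrix(NA_real_, n, np)
  firstAbsent <- rep(NA_integer_, n)
  status <- rep("assigned", n)
  status[apo$type == "P"] <- "proline"
  status[!apo$present] <- "broadened"
  firstAbsent[!apo$present] <- 1L
  for (i in seq_len(n)) {
    if (status[i] == "proline" || !apo$present[i]) next
    dH[i, 1L] <- dN[i, 1L] <- csp[i, 1L] <- 0
    for (j in 2:np) {
      pl <- series@peakLists[[j]]
      k <- match(apoResidues[i], pl$residue)
      if (is.na(k) || !pl$present[k]) {
        if (is.na(firstAbsent[i])) {
          status[i] <- "broadened"
          firstAbsent[i] <- j
        }
        next
      }
      if (!is.na(firstAbsent[i])) next  # reappeared: stays undefined
      dH[i, j] <- pl$dH[k] - apo$dH[i]
      dN[i, j] <- pl$dN[k] - apo$dN[i]
      csp[i, j] <- normalizedCSP(dH[i, j], dN[i, j], nitrogenWeight)
    }
  }
  endpoint <- vapply(seq_len(n), function(i) {
    v <- csp[i, ][!is.na(csp[i, ])]
    if (length(v) == 0) NA_real_ else v[length(v)]
  }, numeric(1))
  new("CSPExperiment",
      residue = as.integer(apoResidues), type = apo$type, status = status,
      dH = dH, dN = dN, csp = csp, endpointCSP = endpoint,
      firstAbsent = firstAbsent, design = series@design,
      nitrogenWeight = nitrogenWeight)
}

#' Write the per-residue CSP table
#'
#' One row per residue: residue number, type, status, per-point shift
#' differences and normalized CSPs, and the endpoint CSP.
#'
#' @param x a [CSPExperiment-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCspTable <- function(x, path) {
  np <- ncol(x@csp)
  df <- data.frame(residue = x@residue, type = x@type, status = x@status)
  for (j in seq_len(np)) {
    df[[sprintf("dH_%d", j - 1L)]] <- x@dH[, j]
    df[[sprintf("dN_%d", j - 1L)]] <- x@dN[, j]
    df[[sprintf("csp_%d", j - 1L)]] <- x@csp[, j]
  }
  df$endpoint_csp <- x@endpointCSP
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("residueNumbers", "CSPExperiment", function(x) x@residue)

#' @rdname accessors
#' @export
setMethod("residueStatus", "CSPExperiment",
          function(x) stats::setNames(x@status, x@residue))

#' @rdname accessors
#' @export
setMethod("cspMatrix", "CSPExperiment", function(x) {
  m <- x@csp
  dimnames(m) <- list(x@residue, NULL)
  m
})

#' @rdname accessors
#' @export
setMethod("endpointCSP", "CSPExperiment",
          function(x) stats::setNames(x@endpointCSP, x@residue))

#' @rdname accessors
#' @export
setMethod("nPoints", "CSPExperiment", function(x) ncol(x@csp))

#' @rdname accessors
#' @export
setMethod("titrationDesign", "CSPExperiment", function(x) x@design)

setMethod("show", "CSPExperiment", function(object) {
  tab <- table(factor(object@status,
                      levels = c("assigned", "proline", "broadened")))
  cat(sprintf("CSPExperiment: %d residues x %d points (15N weight %.2f)\n",
              length(object@residue), ncol(object@csp),
              object@nitrogenWeight))
  cat(sprintf("  assigned %d, proline %d, broadened %d\n",
              tab[["assigned"]], tab[["proline"]], tab[["broadened"]]))
  ok <- object@status == "assigned"
  if (any(ok))
    cat(sprintf("  endpoint CSP range %.4f..%.4f ppm over assigned residues\n",
                min(object@endpointCSP[ok]), max(object@endpointCSP[ok])))
})
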