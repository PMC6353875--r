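#' @include AllClasses.R AllGenerics.R
NULL

.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.newPeakList <- function(residue, type, dH, dN) {
  present <- !(is.na(dH) | is.na(dN))
  data.frame(residue = as.integer(residue), type = as.character(type),
             dH = as.numeric(dH), dN = as.numeric(dN), present = present,
             stringsAsFactors = FALSE)
}

#' Read an assigned amide peak list
#'
#' Two dialects are supported.  \code{"tsv"} is a canonical four-column
#' table (\code{resnum}, \code{restype}, \code{H_ppm}, \code{N_ppm};
#' whitespace separated, optional header, \code{#} comments).  The sentinel
#' \code{NA} in both shift columns marks a peak broadened beyond detection
#' at this titration point.  \code{"sparky"} is a Sparky-style export with
#' an assignment label (e.g. \code{G172N-H}) followed by \code{w1} (15N,
#' ppm) and \code{w2} (1H, ppm).
#'
#' Amide shifts outside the usual windows (1H 5--12 ppm, 15N 100--135 ppm)
#' trigger a warning, not an error; non-numeric shifts other than the
#' sentinel are an error with the offending line number.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"sparky"}.
#' @return a peak-list data.frame with columns \code{residue}, \code{type},
#'   \code{dH}, \code{dN}, \code{present}, input order preserved.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("resnum\trestype\tH_ppm\tN_ppm",
#'              "172\tV\t8.20\t120.00",
#'              "173\tE\tNA\tNA"), tf)
#' readPeakList(tf)
#' @export
readPeakList <- function(path, dialect = c("tsv", "sparky")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("peak list file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (dialect == "tsv") {
    if (length(lines) > 0 && grepl("^\\s*resnum\\b", lines[1L])) {
      hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
      req <- c("resnum", "restype", "H_ppm", "N_ppm")
      miss <- setdiff(req, hdr)
      if (length(miss) > 0)
        stop("missing required column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      lines <- lines[-1L]; lineno <- lineno[-1L]
    }
    pl <- .parsePeakLines(lines, lineno, path)
  } else {
    pl <- .parseSparkyLines(lines, lineno, path)
  }
  if (anyDuplicated(pl$residue)) {
    dup <- pl$residue[duplicated(pl$residue)][1L]
    stop("duplicate residue number ", dup, " in ", path, call. = FALSE)
  }
  .warnShiftWindows(pl, path)
  pl
}

.parsePeakLines <- function(lines, lineno, path) {
  n <- length(lines)
  res <- integer(n); typ <- character(n); dH <- numeric(n); dN <- numeric(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 4L)
      stop(sprintf("unparseable row at line %d of %s (expected 4 columns)",
                   lineno[i], path), call. = FALSE)
    rn <- suppressWarnings(as.integer(f[1L]))
    if (is.na(rn))
      stop(sprintf("unparseable residue number at line %d of %s",
                   lineno[i], path), call. = FALSE)
    res[i] <- rn
    typ[i] <- f[2L]
    dH[i] <- .parseShift(f[3L], lineno[i], path)
    dN[i] <- .parseShift(f[4L], lineno[i], path)
  }
  .newPeakList(res, typ, dH, dN)
}

.parseSparkyLines <- function(lines, lineno, path) {
  # drop a Sparky header row ("Assignment  w1  w2")
  if (length(lines) > 0 && grepl("^\\s*Assignment\\b", lines[1L])) {
    lines <- lines[-1L]; lineno <- lineno[-1L]
  }
  n <- length(lines)
  res <- integer(n); typ <- character(n); dH <- numeric(n); dN <- numeric(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 3L)
      stop(sprintf("unparseable row at line %d of %s (expected label w1 w2)",
                   lineno[i], path), call. = FALSE)
    m <- regmatches(f[1L], regexec("^([A-Za-z])([0-9]+)N-H$", f[1L]))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("unparseable assignment label '%s' at line %d of %s",
                   f[1L], lineno[i], path), call. = FALSE)
    res[i] <- as.integer(m[3L])
    typ[i] <- toupper(m[2L])
    # Sparky convention for 1H-15N HSQC: w1 = 15N, w2 = 1H
    dN[i] <- .parseShift(f[2L], lineno[i], path)
    dH[i] <- .parseShift(f[3L], lineno[i], path)
  }
  .newPeakList(res, typ, dH, dN)
}

.parseShift <- function(token, lineno, path) {
  if (toupper(token) == "NA") return(NA_real_)
  v <- suppressWarnings(as.numeric(token))
  if (is.na(v))
    stop(sprintf("non-numeric chemical shift '%s' at line %d of %s",
                 token, lineno, path), call. = FALSE)
  v
}

.warnShiftWindows <- function(pl, path) {
  p <- pl$present
  if (any(p & (pl$dH < 5 | pl$dH > 12)))
    warning("1H shifts outside [5, 12] ppm in ", path, call. = FALSE)
  if (any(p & (pl$dN < 100 | pl$dN > 135)))
    warning("15N shifts outside [100, 135] ppm in ", path, call. = FALSE)
  invisible(pl)
}

#' Write a peak list in the canonical TSV dialect
#'
#' Inverse of [readPeakList()] for the \code{"tsv"} dialect; absent peaks
#' are written with the \code{NA} sentinel.  Numbers are written with
#' \code{as.character} so a read/write round trip preserves values exactly.
#'
#' @param pl a peak-list data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePeakList <- function(pl, path) {
  msg <- .validPeakList(pl, "peak list")
  if (!is.null(msg)) stop(msg, call. = FALSE)
  lines <- c("resnum\trestype\tH_ppm\tN_ppm",
             sprintf("%d\t%s\t%s\t%s", pl$residue, pl$type,
                     ifelse(pl$present, as.character(pl$dH), "NA"),
                     ifelse(pl$present, as.character(pl$dN), "NA")))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a TitrationSeries
#'
#' @param peakLists list of peak-list data.frames, apo first.
#' @param ligandConc ligand concentration per point, mM.  Derived from
#'   \code{molarRatio * proteinConc} when omitted.
#' @param proteinConc protein concentration, mM; scalar or per point.
#' @param molarRatio ligand:protein molar ratio per point; derived when
#'   omitted.
#' @param ligandName,proteinName labels.
#' @return a [TitrationSeries-class].
#' @export
TitrationSeries <- function(peakLists, ligandConc = NULL, proteinConc,
                            molarRatio = NULL, ligandName = "",
                            proteinName = "") {
  n <- length(peakLists)
  proteinConc <- rep_len(as.numeric(proteinConc), n)
  if (is.null(ligandConc)) {
    if (is.null(molarRatio))
      stop("one of ligandConc or molarRatio is required", call. = FALSE)
    ligandConc <- as.numeric(molarRatio) * proteinConc
  }
  if (is.null(molarRatio)) molarRatio <- ligandConc / proteinConc
  new("TitrationSeries",
      design = DataFrame(ligandConc = as.numeric(ligandConc),
                         proteinConc = proteinConc,
                         molarRatio = as.numeric(molarRatio)),
      peakLists = peakLists,
      ligandName = as.character(ligandName),
      proteinName = as.character(proteinName))
}

#' Read a titration design and its peak lists
#'
#' The design is a YAML file:
#' \preformatted{
#' protein_name: SRM-SANT1
#' ligand_name: H4(1-21)
#' protein_conc: 0.1          # mM, series default
#' dialect: tsv               # optional, tsv (default) or sparky
#' points:
#'   - peaklist: apo.tsv
#'     molar_ratio: 0         # or ligand_conc (mM); one is required
#'   - peaklist: p1.tsv
#'     molar_ratio: 1
#'     protein_conc: 0.095    # optional per-point override (dilution)
#'   ...
#' }
#' Peak-list paths are resolved relative to the config file.  The apo point
#' must come first and ligand concentrations must increase strictly; at
#' least three points are required.
#'
#' @param configPath path to the YAML design.
#' @return a validated [TitrationSeries-class].
#' @export
readTitration <- function(configPath) {
  if (!file.exists(configPath))
    stop("titration config not found: ", configPath, call. = FALSE)
  cfg <- yaml::read_yaml(configPath)
  if (is.null(cfg$points) || length(cfg$points) < 3L)
    stop("a titration requires at least 3 points (got ",
         length(cfg$points), ")", call. = FALSE)
  if (is.null(cfg$protein_conc))
    stop("config is missing protein_conc", call. = FALSE)
  dialect <- if (is.null(cfg$dialect)) "tsv" else cfg$dialect
  base <- dirname(normalizePath(configPath))
  n <- length(cfg$points)
  L <- numeric(n); P <- numeric(n); pls <- vector("list", n)
  for (i in seq_len(n)) {
    pt <- cfg$points[[i]]
    if (is.null(pt$peaklist))
      stop("point ", i, " is missing a peaklist path", call. = FALSE)
    path <- pt$peaklist
    if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(base, path)
    if (!file.exists(path))
      stop("peak list file not found: ", path, " (point ", i, ")",
           call. = FALSE)
    P[i] <- if (!is.null(pt$protein_conc)) pt$protein_conc else cfg$protein_conc
    if (!is.null(pt$ligand_conc)) {
      L[i] <- pt$ligand_conc
      if (!is.null(pt$molar_ratio) &&
          abs(pt$molar_ratio - L[i] / P[i]) > 1e-6)
        stop("point ", i, ": molar_ratio inconsistent with ligand_conc",
             call. = FALSE)
    } else if (!is.null(pt$molar_ratio)) {
      L[i] <- pt$molar_ratio * P[i]
    } else {
      stop("point ", i, " needs ligand_conc or molar_ratio", call. = FALSE)
    }
    pls[[i]] <- readPeakList(path, dialect = dialect)
  }
  if (L[1L] != 0)
    stop("no apo point: the first titration point must have ligand 0",
         call. = FALSE)
  if (any(diff(L) <= 0))
    stop("ligand concentrations must be strictly increasing across points",
         call. = FALSE)
  TitrationSeries(pls, ligandConc = L, proteinConc = P,
                  ligandName = if (is.null(cfg$ligand_name)) "" else
                    cfg$ligand_name,
                  proteinName = if (is.null(cfg$protein_name)) "" else
                    cfg$protein_name)
}

#' Write a titration series to a directory
#'
#' Writes one canonical TSV peak list per point plus a \code{design.yaml}
#' readable by [readTitration()].
#'
#' @param series a [TitrationSeries-class].
#' @param dir output directory (created if needed).
#' @return the path of the design file, invisibly.
#' @export
writeTitration <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nPoints(series)
  d <- titrationDesign(series)
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    fn <- sprintf("point%02d.tsv", i - 1L)
    writePeakList(series@peakLists[[i]], file.path(dir, fn))
    pts[[i]] <- list(peaklist = fn, ligand_conc = d$ligandConc[i],
                     protein_conc = d$proteinConc[i])
  }
  cfg <- list(protein_name = series@proteinName,
              ligand_name = series@ligandName,
              protein_conc = d$proteinConc[1L],
              dialect = "tsv", points = pts)
  path <- file.path(dir, "design.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

## ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("nPoints", "TitrationSeries", function(x) nrow(x@design))

#' @rdname accessors
#' @export
setMethod("ligandConc", "TitrationSeries", function(x) x@design$ligandConc)

#' @rdname accessors
#' @export
setMethod("proteinConc", "TitrationSeries", function(x) x@design$proteinConc)

#' @rdname accessors
#' @export
setMethod("molarRatio", "TitrationSeries", function(x) x@design$molarRatio)

#' @rdname accessors
#' @export
setMethod("peakLists", "TitrationSeries", function(x) x@peakLists)

#' @rdname accessors
#' @export
setMethod("titrationDesign", "TitrationSeries", function(x) x@design)

setMethod("show", "TitrationSeries", function(object) {
  d <- object@design
  cat(sprintf("TitrationSeries: %s + %s\n",
              if (nzchar(object@proteinName)) object@proteinName else
                "<protein>",
              if (nzchar(object@ligandName)) object@ligandName else
                "<ligand>"))
  cat(sprintf("  %d points, [P] = %s mM, molar ratios %s\n",
              nrow(d), paste(format(unique(d$proteinConc)), collapse = "/"),
              paste(format(d$molarRatio, trim = TRUE), collapse = ", ")))
  cat(sprintf("  %d residues in apo peak list\n",
              nrow(object@peakLists[[1L]])))
})
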