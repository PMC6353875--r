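#' @include AllClasses.R AllGenerics.R csp.R significance.R binding.R regions.R restraints.R
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full titration analysis pipeline
#'
#' Ingest (already-parsed series) -> per-residue CSPs -> trimmed-threshold
#' significance -> per-residue isotherm fits of the significant residues
#' -> global Kd aggregation -> region mapping -> optional restraint
#' export.  Residues enter the affinity fits when they are classified at
#' or above \code{fitTier} \emph{and} their endpoint CSP exceeds the
#' detectability floor \code{minCSP}: the relative threshold alone always
#' places a few residues in the upper tail of a pure-noise population, so
#' a floor a few times the shift-measurement precision is what turns "all
#' perturbations are within noise" into a no-binding call.  When no
#' residue passes both, or fewer than two fitted residues converge, the
#' run reports \code{"NB"} (no binding) and skips aggregation.
#'
#' The run is deterministic given its inputs; with \code{outDir} set, the
#' machine-readable outputs (TSV tables and \code{summary.json}) are
#' byte-identical across re-runs.
#'
#' @param series a [TitrationSeries-class] (e.g. from [readTitration()]
#'   or [simulateTitration()]).
#' @param outDir optional output directory for report files.
#' @param nitrogenWeight 15N weight of the CSP normalization
#'   (default 0.20).
#' @param trimFraction fraction trimmed before the significance
#'   statistics (default 0.10).
#' @param fitTier minimum significance tier for residues entering the Kd
#'   fits (default \code{"ge_1sd"}).
#' @param saturationCutoff fraction-bound cutoff for the saturation flag
#'   (default 0.8).
#' @param minCSP minimum endpoint perturbation, ppm, for a significant
#'   residue to enter fitting (default 0.03, several times the typical
#'   0.005 ppm amide shift measurement precision).
#' @param annotation region annotation
#'   (default [defaultRegionAnnotation()]); \code{NULL} skips region
#'   mapping.
#' @param partnerResidues optional peptide active residues; when given, a
#'   restraint table is built and (with \code{outDir}) written.
#' @param verbose log each rule application with \code{message()}.
#' @return a list with elements \code{csp}, \code{significance},
#'   \code{fits}, \code{globalKd} (a [GlobalKd-class] or \code{NULL}),
#'   \code{label} (the formatted affinity, \code{"NB"} for no binding),
#'   \code{regions} and \code{restraints}.
#' @export
runTitrationPipeline <- function(series, outDir = NULL,
                                 nitrogenWeight = 0.20,
                                 trimFraction = 0.10,
                                 fitTier = "ge_1sd",
                                 saturationCutoff = 0.8,
                                 minCSP = 0.03,
                                 annotation = defaultRegionAnnotation(),
                                 partnerResidues = NULL,
                                 verbose = TRUE) {
  say <- if (verbose) message else function(...) invisible(NULL)
  csp <- .stage("csp", computeCSPs(series, nitrogenWeight = nitrogenWeight))
  say(sprintf("csp: %d residues, %d broadened, %d proline",
              length(csp@residue), sum(csp@status == "broadened"),
              sum(csp@status == "proline")))
  sig <- .stage("significance",
                classifySignificance(csp, trimFraction = trimFraction))
  say(sprintf(paste0("significance: trimmed %d of %d; mean %.5f, ",
                     "SD %.5f; thresholds %.5f / %.5f ppm"),
              sum(sig@trimmed), length(sig@residue), sig@populationMean,
              sig@populationSD, sig@threshold1sd, sig@threshold1p5sd))
  sigRes <- significantResidues(sig, tier = fitTier)
  aboveFloor <- sig@residue[sig@endpointCSP > minCSP]
  nBelow <- length(setdiff(sigRes, aboveFloor))
  if (nBelow > 0)
    say(sprintf("%d significant residue(s) below the %.3f ppm floor", nBelow,
                minCSP))
  sigRes <- intersect(sigRes, aboveFloor)
  fits <- NULL; global <- NULL
  if (length(sigRes) == 0) {
    say("no significant residues: reporting NB (no binding)")
  } else {
    say(sprintf("fitting %d significant residues", length(sigRes)))
    fits <- .stage("fit",
                   fitResidues(csp, residues = sigRes,
                               saturationCutoff = saturationCutoff))
    nConv <- sum(fits$converged)
    if (nConv < 2L) {
      say("fewer than 2 converged fits: reporting NB")
    } else {
      global <- .stage("aggregate", aggregateGlobalKd(fits, sigRes))
      if (global@isLowerLimit)
        say(sprintf("global Kd underdetermined: lower limit %s",
                    formatGlobalKd(global)))
      else
        say(sprintf("global Kd %s (%d used, %d excluded by the 2-SD rule)",
                    formatGlobalKd(global), length(global@residuesUsed),
                    length(global@residuesExcluded)))
    }
  }
  regions <- if (!is.null(annotation))
    .stage("regions", classifyRegions(sig, annotation)) else NULL
  restraints <- NULL
  if (!is.null(partnerResidues) && length(sigRes) > 0)
    restraints <- .stage("restraints",
                         buildRestraints(sig, partnerResidues,
                                         tier = fitTier))
  label <- formatGlobalKd(global)
  out <- list(csp = csp, significance = sig, fits = fits,
              globalKd = global, label = label, regions = regions,
              restraints = restraints)
  if (!is.null(outDir)) .writeReportBundle(out, outDir)
  out
}

#' @rdname runTitrationPipeline
#' @param configPath a YAML run config with keys \code{titration} (path
#'   to a design readable by [readTitration()]), and optionally
#'   \code{nitrogen_weight}, \code{trim_fraction}, \code{fit_tier},
#'   \code{saturation_cutoff}, \code{annotation} (3-column file),
#'   \code{partner_residues}, \code{out_dir}.
#' @export
runTitrationPipelineConfig <- function(configPath, verbose = TRUE) {
  if (!file.exists(configPath))
    stop("run config not found: ", configPath, call. = FALSE)
  cfg <- yaml::read_yaml(configPath)
  if (is.null(cfg$titration))
    stop("run config is missing the titration design path", call. = FALSE)
  base <- dirname(normalizePath(configPath))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else
    file.path(base, p)
  series <- .stage("ingest", readTitration(resolve(cfg$titration)))
  ann <- if (!is.null(cfg$annotation))
    readRegionAnnotation(resolve(cfg$annotation)) else
      defaultRegionAnnotation()
  runTitrationPipeline(
    series,
    outDir = if (!is.null(cfg$out_dir)) resolve(cfg$out_dir) else NULL,
    nitrogenWeight = if (!is.null(cfg$nitrogen_weight))
      cfg$nitrogen_weight else 0.20,
    trimFraction = if (!is.null(cfg$trim_fraction)) cfg$trim_fraction
      else 0.10,
    fitTier = if (!is.null(cfg$fit_tier)) cfg$fit_tier else "ge_1sd",
    saturationCutoff = if (!is.null(cfg$saturation_cutoff))
      cfg$saturation_cutoff else 0.8,
    minCSP = if (!is.null(cfg$min_csp)) cfg$min_csp else 0.03,
    annotation = ann,
    partnerResidues = if (!is.null(cfg$partner_residues))
      as.integer(cfg$partner_residues) else NULL,
    verbose = verbose)
}

.writeReportBundle <- function(out, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeCspTable(out$csp, file.path(outDir, "csp_table.tsv"))
  writeSignificanceTable(out$significance,
                         file.path(outDir, "significance.tsv"))
  if (!is.null(out$fits))
    writeFitTable(out$fits, file.path(outDir, "fits.tsv"))
  if (!is.null(out$regions))
    writeRegionSummary(out$regions, file.path(outDir, "regions.tsv"))
  if (!is.null(out$restraints))
    writeAirTable(out$restraints, file.path(outDir, "restraints.tbl"))
  g <- out$globalKd
  summary <- list(
    label = out$label,
    n_residues = length(out$csp@residue),
    n_broadened = sum(out$csp@status == "broadened"),
    thresholds = list(ge_1sd = out$significance@threshold1sd,
                      ge_1p5sd = out$significance@threshold1p5sd),
    n_significant =
      length(significantResidues(out$significance, "ge_1sd")),
    global_kd = if (is.null(g)) NULL else list(
      is_lower_limit = g@isLowerLimit,
      mean_kd = if (g@isLowerLimit) NULL else g@meanKd,
      sd_kd = if (g@isLowerLimit) NULL else g@sdKd,
      limit_value = if (g@isLowerLimit) g@limitValue else NULL,
      residues_used = g@residuesUsed,
      residues_excluded = g@residuesExcluded))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  rpt <- c("Titration analysis report",
           "=========================",
           sprintf("Residues analysed : %d", summary$n_residues),
           sprintf("Broadened         : %d", summary$n_broadened),
           sprintf("Significant (>1SD): %d", summary$n_significant),
           sprintf("Global Kd         : %s", out$label))
  writeLines(rpt, file.path(outDir, "report.txt"))
  invisible(outDir)
}
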