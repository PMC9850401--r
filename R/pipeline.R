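#' Pipeline configuration
#'
#' Declarative configuration for the end-to-end commands. Values can
#' come from a YAML file ([readPipelineConfig()]); arguments passed
#' directly override file values, which override the defaults.
#'
#' @param tolerancePpm m/z tolerance, ppm.
#' @param rtToleranceMin retention-time tolerance, minutes.
#' @param adducts adduct search set.
#' @param bounds composition bounds ([annotationBounds()]).
#' @param minSnr,minPoints peak detection settings.
#' @param dryLoadingMgPerMl dry matter loading, mg/mL.
#' @param moistureFraction fresh-sample moisture fraction.
#' @param seed master seed; all randomness flows from it.
#' @param paths named list of file locations (`library`, `design`,
#'   `runs`, `out`).
#' @return a named list of validated settings.
#' @export
pipelineConfig <- function(tolerancePpm = 15, rtToleranceMin = 0.5,
                           adducts = c("sodium", "proton", "ammonium"),
                           bounds = annotationBounds(), minSnr = 3,
                           minPoints = 5, dryLoadingMgPerMl = 25,
                           moistureFraction = 0, seed = 1L,
                           paths = list()) {
  cfg <- list(tolerancePpm = tolerancePpm, rtToleranceMin = rtToleranceMin,
              adducts = adducts, bounds = bounds, minSnr = minSnr,
              minPoints = minPoints,
              dryLoadingMgPerMl = dryLoadingMgPerMl,
              moistureFraction = moistureFraction, seed = as.integer(seed),
              paths = paths)
  if (cfg$tolerancePpm <= 0 || cfg$rtToleranceMin <= 0) {
    stop("tolerances must be positive")
  }
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML key/value sections mapped onto [pipelineConfig()] arguments;
#' keys absent from the file keep their defaults. The configuration
#' round-trips through [writePipelineConfig()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  if (!is.null(raw$bounds)) raw$bounds <- do.call(annotationBounds, raw$bounds)
  do.call(pipelineConfig, raw)
}

#' @rdname readPipelineConfig
#' @param config configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

writeRunLog <- function(outDir, command, config, outputs) {
  log <- list(tool = "glycoquant",
              version = as.character(utils::packageVersion("glycoquant")),
              command = command, config_hash = configHash(config),
              outputs = outputs)
  jsonlite::write_json(log, file.path(outDir, paste0(command, "_log.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Pipeline commands
#'
#' End-to-end orchestration over the module functions; each command
#' writes its tabular outputs plus a machine-readable JSON log with the
#' tool version and a configuration hash, and returns its main result
#' invisibly. Re-running with identical inputs yields identical result
#' files.
#'
#' `cmdSimulate` writes synthetic standard runs (one polysaccharide
#' each), a calibration dilution series with its design CSV, and the
#' ground-truth tables. `cmdBuildLibrary` builds and writes the
#' fingerprint library. `cmdCalibrate` fits the top-3 averaged
#' zero-intercept curves from the calibration runs and writes the curve
#' report CSV (r2, slope, MDL in both units, S/N at MDL).
#' `cmdQuantify` annotates sample runs, assigns peaks, and writes the
#' absolute + relative results CSV.
#'
#' @param config [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param levels calibration concentrations, ug/mL.
#' @param polyNames polysaccharides to simulate.
#' @param standardRuns named list of runs/paths per polysaccharide.
#' @param libraryPath fingerprint library file.
#' @param calibrationRuns named list of runs/paths, names matching
#'   `design$run_id`.
#' @param design calibration design data.frame (or CSV path) with
#'   columns `polysaccharide`, `level`, `concentration_ugml`, `run_id`.
#' @param curves list of [CalibrationCurve-class] (from `cmdCalibrate`).
#' @param sampleRuns named list of sample runs/paths.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmdSimulate <- function(config, outDir, levels = 2000 / 2^(0:5),
                        polyNames = names(simPolysaccharides())) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfg <- simConfig(seed = config$seed)
  std <- list()
  for (i in seq_along(polyNames)) {
    scfg <- cfg
    scfg$seed <- cfg$seed + 1000L + i
    run <- simulateRun(stats::setNames(2000, polyNames[i]), config = scfg)
    p <- file.path(outDir, paste0("standard_", polyNames[i], ".mzML"))
    writeMzML(run, p)
    utils::write.table(groundTruth(run),
                       sub("\\.mzML$", "_truth.tsv", p),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    std[[polyNames[i]]] <- p
  }
  ser <- simulateCalibrationSeries(polyNames, levels = levels, config = cfg)
  calPaths <- character()
  for (nm in names(ser$runs)) {
    p <- file.path(outDir, paste0(nm, ".mzML"))
    writeMzML(ser$runs[[nm]], p)
    calPaths[nm] <- p
  }
  utils::write.csv(ser$design, file.path(outDir, "calibration_design.csv"),
                   row.names = FALSE)
  writeRunLog(outDir, "simulate", config,
              list(standards = std, calibration = as.list(calPaths)))
  invisible(list(standards = std, calibration = calPaths,
                 design = ser$design))
}

#' @rdname pipeline-commands
#' @export
cmdBuildLibrary <- function(config, standardRuns, libraryPath) {
  lib <- buildLibrary(standardRuns, tolerancePpm = config$tolerancePpm,
                      rtTolerance = config$rtToleranceMin,
                      bounds = config$bounds, adducts = config$adducts,
                      minSnr = config$minSnr, minPoints = config$minPoints)
  writeLibrary(lib, libraryPath)
  writeRunLog(dirname(libraryPath), "build-library", config,
              list(library = libraryPath))
  invisible(lib)
}

#' @rdname pipeline-commands
#' @export
cmdCalibrate <- function(config, libraryPath, calibrationRuns, design,
                         outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  lib <- if (is.character(libraryPath)) readLibrary(libraryPath) else
    libraryPath
  if (is.character(design)) {
    design <- utils::read.csv(design, stringsAsFactors = FALSE)
  }
  peaksByRun <- lapply(calibrationRuns, function(rn) {
    if (is.character(rn)) rn <- readRun(rn)
    annotateRun(rn, tolerancePpm = config$tolerancePpm,
                bounds = config$bounds, adducts = config$adducts,
                minSnr = config$minSnr, minPoints = config$minPoints)
  })
  polys <- unique(design$polysaccharide)
  curves <- lapply(polys, function(p) {
    top3 <- selectTop3(lib, p)
    d <- design[design$polysaccharide == p, , drop = FALSE]
    lv <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
      m <- measureTop3(peaksByRun[[d$run_id[i]]], lib, p, top3 = top3,
                       rtTolerance = config$rtToleranceMin)
      data.frame(conc = d$concentration_ugml[i], area = m$area,
                 snr = m$snr, n_top3 = m$n_top3)
    }))
    calibrationCurve(p, top3, lv)
  })
  names(curves) <- polys
  rep <- curveReport(curves, config$dryLoadingMgPerMl)
  utils::write.csv(rep, file.path(outDir, "calibration_report.csv"),
                   row.names = FALSE)
  writeCurves(curves, file.path(outDir, "curves.json"))
  writeRunLog(outDir, "calibrate", config,
              list(report = file.path(outDir, "calibration_report.csv"),
                   curves = file.path(outDir, "curves.json")))
  invisible(curves)
}

#' @rdname pipeline-commands
#' @export
cmdQuantify <- function(config, libraryPath, curves, sampleRuns, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  lib <- if (is.character(libraryPath)) readLibrary(libraryPath) else
    libraryPath
  if (is.character(curves)) curves <- readCurves(curves)
  if (is.null(curves) || !length(curves)) {
    stop("no calibration curves supplied; run cmdCalibrate first")
  }
  res <- list()
  for (nm in names(sampleRuns)) {
    rn <- sampleRuns[[nm]]
    if (is.character(rn)) rn <- readRun(rn)
    pk <- annotateRun(rn, tolerancePpm = config$tolerancePpm,
                      bounds = config$bounds, adducts = config$adducts,
                      minSnr = config$minSnr, minPoints = config$minPoints)
    asg <- matchPeaks(pk, lib, rtTolerance = config$rtToleranceMin)
    frac <- relativeQuant(asg)
    for (p in names(curves)) {
      m <- measureTop3(pk, lib, p,
                       top3 = selectTop3(lib, p),
                       rtTolerance = config$rtToleranceMin)
      q <- quantifySignal(m$area, curves[[p]],
                          dryLoadingMgPerMl = config$dryLoadingMgPerMl,
                          moistureFraction = config$moistureFraction)
      q$sample <- nm
      q$relative_fraction <- if (p %in% names(frac)) frac[[p]] else 0
      res[[length(res) + 1L]] <- q
    }
    if ("UNASSIGNED" %in% names(frac)) {
      res[[length(res) + 1L]] <- data.frame(
        polysaccharide = "UNASSIGNED", conc_ugml = NA_real_,
        conc_dry_pct = NA_real_, conc_fresh_g_per_100g = NA_real_,
        below_mdl = NA, sample = nm,
        relative_fraction = frac[["UNASSIGNED"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out <- out[, c("sample", "polysaccharide", "conc_ugml", "conc_dry_pct",
                 "conc_fresh_g_per_100g", "below_mdl",
                 "relative_fraction")]
  utils::write.csv(out, file.path(outDir, "results.csv"), row.names = FALSE)
  writeRunLog(outDir, "quantify", config,
              list(results = file.path(outDir, "results.csv")))
  invisible(out)
}

#' Persist fitted calibration curves as JSON
#'
#' @param curves named list of [CalibrationCurve-class].
#' @param path JSON file.
#' @return `writeCurves`: `path` invisibly; `readCurves`: the list.
#' @export
writeCurves <- function(curves, path) {
  obj <- lapply(curves, function(cv) {
    list(polysaccharide = cv@polysaccharide, top3 = cv@top3,
         levels = cv@levels, slope = cv@slope, r2 = cv@r2,
         mdl_ugml = cv@mdlUgml, snr_at_mdl = cv@snrAtMdl)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCurves
#' @export
readCurves <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  curves <- lapply(obj, function(o) {
    new("CalibrationCurve", polysaccharide = o$polysaccharide,
        top3 = o$top3, levels = as.data.frame(o$levels),
        slope = o$slope, r2 = o$r2, mdlUgml = o$mdl_ugml,
        snrAtMdl = o$snr_at_mdl)
  })
  names(curves) <- vapply(curves, function(cv) cv@polysaccharide,
                          character(1))
  curves
}
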