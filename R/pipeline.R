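#' Read a wide spectra CSV
#'
#' Expects a header with `sample_id` followed by exactly 1,060 point
#' columns (`pt_0001`..`pt_1060`), one row per milking sample, comma
#' separated, "." decimal. Any other column count or a non-numeric cell is
#' an error naming the offender.
#'
#' @param path CSV file path.
#' @return a [SpectraSet-class] (stage `"raw"`). An empty file with a
#'   valid header yields an empty set.
#' @export
readSpectraCsv <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  if (ncol(dt) != 1061L)
    stop(sprintf("expected sample_id + 1,060 point columns, found %d point column(s)",
                 ncol(dt) - 1L))
  ids <- as.character(dt[[1]])
  m <- dt[, -1, drop = FALSE]
  if (nrow(m)) for (j in seq_along(m)) {
    if (!is.numeric(m[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(m[[j]]))))[1]
      stop(sprintf("non-numeric absorbance at row %d, column %s",
                   bad, names(m)[j]))
    }
  }
  m <- as.matrix(m)
  if (nrow(m) == 0L) m <- matrix(numeric(0), nrow = 0L, ncol = 1060L)
  SpectraSet(m, sampleIds = ids, samplesInRows = TRUE)
}

#' Write a wide spectra CSV
#'
#' Inverse of [readSpectraCsv()]: one row per sample, columns `sample_id`,
#' `pt_0001`..`pt_1060`.
#'
#' @param spectra a raw [SpectraSet-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSpectraCsv <- function(spectra, path) {
  stopifnot(methods::is(spectra, "SpectraSet"))
  m <- spectraMatrix(spectra)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Desk-scale configuration for the population-level run
#'
#' A bundled configuration emulating the large-scale application at desk
#' scale: 3 farms, several summer heat waves per year (June, July and
#' August events of increasing intensity) so that the windowed-THI axis is
#' populated above the threshold, and the visit arm in the final year.
#'
#' @param seed master seed.
#' @param nFarms,nCowsPerFarm,nYears study dimensions.
#' @return a [SimulationConfig-class].
#' @export
populationConfig <- function(seed = 42L, nFarms = 3L, nCowsPerFarm = 80L,
                             nYears = 3L) {
  startYear <- 2020L
  waves <- do.call(rbind, lapply(seq_len(nYears), function(k) {
    yr <- startYear + k - 1L
    data.frame(
      start = as.Date(sprintf(c("%d-06-04", "%d-07-12", "%d-08-14"), yr)),
      length = c(9L, 8L, 9L), peakThi = c(70, 73, 75))
  }))
  simulationConfig(seed = seed, nFarms = nFarms, nCowsPerFarm = nCowsPerFarm,
                   nYears = nYears, startYear = startYear, heatWaves = waves)
}

# Merge standardized protein/Mg residuals onto surface-temperature records
# by (animal, test date).
.mergeResiduals <- function(surface, fits) {
  key <- function(a, d) paste(a, format(as.Date(d), "%Y%m%d"), sep = "_")
  out <- surface
  for (nm in c("protein", "mg")) {
    r <- standardizedResiduals(fits[[nm]])
    out[[paste0("r_", nm)]] <-
      r$std_residual[match(key(surface$animal, surface$date),
                           key(r$animal, r$date))]
  }
  if (anyNA(out$r_protein) || anyNA(out$r_mg))
    stop("surface-temperature records without matching test-day residuals")
  out
}

#' Run the full heat-stress phenotyping pipeline
#'
#' Executes the whole chain on a synthetic study: simulate -> windowed THI
#' -> test-day-model residuals -> reference classes -> spectral
#' preprocessing -> PLS temperature and RF class calibration -> combined
#' phenotype for every record -> record filters, Snell scores, population
#' mixed model and THI-binned means. When `outdir` is given, every stage
#' writes its CSV artifact plus a plain-text run manifest.
#'
#' @param config a [SimulationConfig-class] (default [populationConfig()]).
#' @param traits traits fitted with the test-day model (protein and Mg are
#'   required for the reference classes).
#' @param plsMaxComponents largest PLS component count tried.
#' @param plsNcomp optional pinned PLS component count.
#' @param rfTopVariables retained variables in the final forest.
#' @param thiMinBin minimum records per reported THI bin (desk-scale
#'   default 50).
#' @param foldSeed seed for fold assignment and training-set draws.
#' @param outdir optional output directory for CSV artifacts.
#' @return list with the simulation, fits, models, per-record predictions,
#'   Snell table, population-model solutions and THI summary.
#' @export
runHeatStressPipeline <- function(config = populationConfig(),
                                  traits = c("milk", "fat", "protein", "mg"),
                                  plsMaxComponents = 50L, plsNcomp = NULL,
                                  rfTopVariables = 50L, thiMinBin = 50L,
                                  foldSeed = NULL, outdir = NULL) {
  stopifnot(all(c("protein", "mg") %in% traits))
  if (is.null(foldSeed)) foldSeed <- childSeed(config@seed, 11L)
  sim <- simulateHerdData(config, includeVisits = TRUE)
  records <- testDayData(sim)

  fits <- lapply(stats::setNames(traits, traits), function(tr)
    fitTestDayModel(records, tr, pedigreeData(sim)))

  surface <- .mergeResiduals(surfaceTempData(sim), fits)
  stats <- thermoneutralStats(surface)
  heat <- surface[surface$period == "heatwave", , drop = FALSE]
  heat$sample_id <- paste(heat$animal, format(as.Date(heat$date), "%Y%m%d"),
                          sep = "_")
  classified <- classifyReference(heat, stats)

  hist <- records[!records$visit, , drop = FALSE]
  eligible <- hist[controlEligible(as.integer(format(hist$date, "%m")),
                                   hist$thi_td3d), , drop = FALSE]
  training <- assembleTrainingSet(classified, eligible, seed = foldSeed)

  features <- spectraMatrix(selectRegions(firstDerivative(spectraData(sim))))
  month <- as.integer(format(records$date, "%m"))
  names(month) <- records$sample_id

  ref <- surface
  ref$sample_id <- paste(ref$animal, format(as.Date(ref$date), "%Y%m%d"),
                         sep = "_")
  ref <- makeGroupFolds(ref, k = 5L, seed = foldSeed)
  plsModel <- fitPlsTemperature(features[ref$sample_id, , drop = FALSE],
                                ref$mean_temp, ref$fold,
                                maxComponents = plsMaxComponents,
                                ncomp = plsNcomp)

  trainInfo <- training
  trainInfo$animal <- sub("_[0-9]{8}$", "", trainInfo$sample_id)
  trainInfo$period <- ifelse(trainInfo$provenance == "augmented",
                             "control", "heatwave")
  trainInfo <- makeGroupFolds(trainInfo, k = 5L, seed = foldSeed)
  rfModel <- fitRfClassifier(features[trainInfo$sample_id, , drop = FALSE],
                             month[trainInfo$sample_id], trainInfo$class,
                             trainInfo$fold, nTopVariables = rfTopVariables,
                             seed = foldSeed)

  predictions <- data.frame(
    sample_id = records$sample_id, animal = records$animal,
    farm = records$farm, date = records$date, lactation = records$lactation,
    dim = records$dim, milk = records$milk, thi_td3d = records$thi_td3d,
    pred_temp = predictTemperature(plsModel, features),
    pred_class = predictClass(rfModel, features, month))
  predictions$combined <- combineHeatStress(predictions$pred_temp,
                                            predictions$pred_class)

  predictions$htd <- paste(predictions$farm, format(predictions$date, "%Y%m%d"),
                           sep = "_")
  filtered <- filterPopulationRecords(predictions)
  freq <- table(factor(filtered$combined, levels = c("0", "0.5", "1")))
  if (any(freq == 0)) {
    warning("a combined-phenotype class is absent; using raw values instead of Snell scores")
    snell <- NULL
    filtered$score <- filtered$combined
  } else {
    snell <- snellScores(as.numeric(freq))
    snell$category <- c("0", "0.5", "1")
    filtered$score <- snell$score[match(as.character(filtered$combined),
                                        snell$category)]
  }
  popFit <- fitPopulationModel(filtered, pedigreeData(sim))
  thiSummary <- thiBinnedMeans(predictions, minBin = thiMinBin)

  result <- list(sim = sim, fits = fits, thermoneutralStats = stats,
                 classified = classified, training = training,
                 plsModel = plsModel, rfModel = rfModel,
                 predictions = predictions, filtered = filtered,
                 snell = snell, populationFit = popFit,
                 thiSummary = thiSummary)
  if (!is.null(outdir)) writePipelineArtifacts(result, outdir)
  result
}

#' Write pipeline artifacts as CSV plus a run manifest
#'
#' @param result list returned by [runHeatStressPipeline()].
#' @param outdir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writePipelineArtifacts <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) data.table::fwrite(df, file.path(outdir, name))
  sim <- result$sim
  w(weatherData(sim), "weather.csv")
  w(sim@dailyThi, "daily_thi.csv")
  w(pedigreeData(sim), "pedigree.csv")
  w(testDayData(sim), "testday.csv")
  writeSpectraCsv(spectraData(sim), file.path(outdir, "spectra.csv"))
  if (nrow(surfaceTempData(sim))) w(surfaceTempData(sim), "surface_temperature.csv")
  resid <- do.call(rbind, lapply(names(result$fits), function(tr) {
    r <- standardizedResiduals(result$fits[[tr]])
    data.frame(sample_id = r$sample_id, trait = tr, residual = r$residual,
               standardized_residual = r$std_residual)
  }))
  w(resid, "residuals.csv")
  w(result$training, "training_set.csv")
  w(result$predictions, "predictions.csv")
  w(result$populationFit$solutions, "solutions.csv")
  w(result$thiSummary, "thi_summary.csv")
  cfg <- sim@config
  manifest <- c(
    sprintf("heatmir pipeline run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
    sprintf("master seed: %d", cfg@seed),
    sprintf("child seeds: weather=%d pedigree=%d testday=%d spectra=%d surface=%d",
            childSeed(cfg@seed, 1L), childSeed(cfg@seed, 2L),
            childSeed(cfg@seed, 3L), childSeed(cfg@seed, 4L),
            childSeed(cfg@seed, 5L)),
    sprintf("farms=%d cows/farm=%d years=%d start=%d", cfg@nFarms,
            cfg@nCowsPerFarm, cfg@nYears, cfg@startYear),
    sprintf("THI threshold=%g; PLS ncomp=%d on %d points; RF accuracy (oof)=%.3f",
            cfg@thiThreshold, result$plsModel@ncomp,
            length(result$plsModel@selectedPoints), result$rfModel@accuracy),
    sprintf("records: testday=%d, reference=%d, filtered=%d",
            nrow(testDayData(sim)), nrow(surfaceTempData(sim)),
            nrow(result$filtered)))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(outdir)
}
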