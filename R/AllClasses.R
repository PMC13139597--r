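#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

#' SpectraSet: FT-MIR spectra as a SummarizedExperiment
#'
#' Container for milk FT-MIR spectra. Spectral points are rows (features),
#' milking samples are columns, following the Bioconductor convention. The
#' single assay `"absorbance"` holds absorbance (or derivative-absorbance)
#' values; `rowData` carries the original 1-based point number (`point`) and
#' a derived wavenumber label (`wavenumber`, cm^-1); `metadata(x)$stage`
#' records the preprocessing stage (`"raw"`, `"derivative"` or
#' `"selected"`). Raw spectra must have exactly 1,060 points; a gap-5 first
#' derivative has 1,056 (points 3..1,058).
#'
#' @aliases SpectraSet-class
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"point" %in% names(rowData(object)))
    msg <- c(msg, "rowData must contain a 'point' column of original point numbers")
  stage <- metadata(object)$stage %||% "raw"
  pts <- rowData(object)$point
  if (!is.null(pts)) {
    if (is.unsorted(pts, strictly = TRUE))
      msg <- c(msg, "point numbers must be strictly increasing")
    if (identical(stage, "raw") && nrow(object) != 1060L)
      msg <- c(msg, sprintf("raw spectra must have exactly 1,060 points, got %d", nrow(object)))
    if (identical(stage, "derivative") && nrow(object) != 1056L)
      msg <- c(msg, sprintf("derivative spectra must have exactly 1,056 points, got %d", nrow(object)))
    if (!identical(stage, "raw") && (any(pts < 3L) || any(pts > 1058L)))
      msg <- c(msg, "derivative/selected point numbers must lie within 3..1,058")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet from an absorbance matrix
#'
#' @param absorbance numeric matrix, either points x samples or
#'   samples x points (auto-detected from a 1,060-sized dimension when
#'   `samplesInRows` is `NA`).
#' @param sampleIds sample identifiers (defaults to existing dimnames).
#' @param points original 1-based point numbers (default `1:1060`).
#' @param stage preprocessing stage label.
#' @param samplesInRows logical; set when the orientation is ambiguous.
#' @param colData optional per-sample annotation.
#' @return a [SpectraSet-class] object.
#' @export
SpectraSet <- function(absorbance, sampleIds = NULL, points = NULL,
                       stage = "raw", samplesInRows = NA, colData = NULL) {
  absorbance <- as.matrix(absorbance)
  if (is.na(samplesInRows)) {
    samplesInRows <- nrow(absorbance) != 1060L && ncol(absorbance) == 1060L
  }
  if (samplesInRows) absorbance <- t(absorbance)
  n <- nrow(absorbance)
  if (identical(stage, "raw") && n != 1060L)
    stop(sprintf("raw spectra must have exactly 1,060 points, got %d", n))
  points <- as.integer(points %||% seq_len(n))
  if (length(points) != n) stop("length of 'points' must match the number of spectral points")
  if (is.null(sampleIds)) sampleIds <- colnames(absorbance) %||% paste0("s", seq_len(ncol(absorbance)))
  dimnames(absorbance) <- list(sprintf("pt_%04d", points), as.character(sampleIds))
  rd <- DataFrame(point = points, wavenumber = wavenumberAxis()[points])
  cd <- if (is.null(colData)) DataFrame(row.names = as.character(sampleIds)) else DataFrame(colData)
  se <- SummarizedExperiment(assays = list(absorbance = absorbance),
                             rowData = rd, colData = cd,
                             metadata = list(stage = stage))
  methods::new("SpectraSet", se)
}

#' @describeIn SpectraSet-accessors original point numbers of the spectral rows
#' @export
pointNumbers <- function(x) rowData(x)$point

#' Accessors for SpectraSet
#'
#' `spectraMatrix()` returns the samples x points absorbance matrix (the
#' transposed assay, convenient for model fitting); `pointNumbers()` the
#' original point numbers; `spectraStage()` the preprocessing stage.
#'
#' @param x a [SpectraSet-class].
#' @return a matrix, integer vector or character scalar respectively.
#' @name SpectraSet-accessors
#' @export
spectraMatrix <- function(x) t(assay(x, "absorbance"))

#' @describeIn SpectraSet-accessors preprocessing stage label
#' @export
spectraStage <- function(x) metadata(x)$stage %||% "raw"

setMethod("show", "SpectraSet", function(object) {
  cat(sprintf("SpectraSet [%s]: %d spectral points x %d samples\n",
              spectraStage(object), nrow(object), ncol(object)))
  pts <- pointNumbers(object)
  cat(sprintf("  point numbers %d..%d; wavenumbers %.2f..%.2f cm^-1\n",
              min(pts), max(pts), min(rowData(object)$wavenumber),
              max(rowData(object)$wavenumber)))
})

#' Simulation configuration for the synthetic herd generator
#'
#' Holds every knob of the synthetic multi-farm study: herd sizes, the
#' heat-wave calendar, the planted trait depressions per THI unit of excess
#' heat load, the per-cow tolerance distribution, the spectral heat-stress
#' signature and noise levels. Identical configurations (including `seed`)
#' generate bit-identical datasets.
#'
#' Slots:
#' \describe{
#'   \item{seed}{master seed; per-component child seeds are derived from it.}
#'   \item{nFarms, nCowsPerFarm, nYears, startYear}{study dimensions.}
#'   \item{heatWaves}{data.frame with columns `start` (Date), `length`
#'     (days) and `peakThi` (target daily THI on the peak day); regional
#'     waves applied to every farm. Intervals must not overlap.}
#'   \item{baselineTempMean}{farm-level baseline udder surface temperature
#'     (degrees C), recycled across farms.}
#'   \item{tempHeatSlope}{surface-temperature rise per unit of effective
#'     heat load (degrees C).}
#'   \item{thiThreshold}{windowed THI above which heat load accrues.}
#'   \item{traitEffectSizes}{named depressions per unit heat load for
#'     `milk` (kg), `fat` (\%), `protein` (\%), `mg` (mg/L).}
#'   \item{traitNoiseSd}{residual SD of the four traits, same naming.}
#'   \item{toleranceSd}{SD of the per-cow heat-tolerance distribution
#'     (mean 0.3, clamped to \[0, 1\]; tolerance 1 means no response).}
#'   \item{parityHeatMult}{heat-load multipliers for lactation classes
#'     1, 2, 3+ (the planted parity susceptibility ordering).}
#'   \item{dimSusceptibility}{named vector `peak`, `width`, `floor`, `amp`
#'     of the Gaussian-bump DIM susceptibility curve
#'     `floor + amp * exp(-((DIM - peak)/width)^2)`.}
#'   \item{spectralNoiseSd}{i.i.d. absorbance noise SD.}
#'   \item{hsSignature}{1,060-vector of absorbance perturbation per unit
#'     effective heat load.}
#'   \item{surfaceNoiseSd}{noise SD of each PM/AM surface temperature.}
#'   \item{weatherParams}{named vector `seasonalMean`, `seasonalAmp`,
#'     `diurnalAmp`, `noiseSd` of the weather model (degrees C).}
#' }
#'
#' @aliases SimulationConfig-class
#' @export
setClass("SimulationConfig", representation(
  seed = "integer", nFarms = "integer", nCowsPerFarm = "integer",
  nYears = "integer", startYear = "integer", heatWaves = "data.frame",
  baselineTempMean = "numeric", tempHeatSlope = "numeric",
  thiThreshold = "numeric", traitEffectSizes = "numeric",
  traitNoiseSd = "numeric", toleranceSd = "numeric",
  parityHeatMult = "numeric", dimSusceptibility = "numeric",
  spectralNoiseSd = "numeric", hsSignature = "numeric",
  surfaceNoiseSd = "numeric", weatherParams = "numeric",
  toleranceMean = "numeric", structuralVariance = "numeric",
  nSires = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nFarms < 1L || object@nCowsPerFarm < 1L || object@nYears < 1L)
    msg <- c(msg, "all counts must be >= 1")
  if (object@toleranceSd < 0) msg <- c(msg, "toleranceSd must be >= 0")
  if (object@spectralNoiseSd < 0) msg <- c(msg, "spectralNoiseSd must be >= 0")
  if (length(object@hsSignature) != 1060L)
    msg <- c(msg, sprintf("hsSignature must have length 1,060, got %d", length(object@hsSignature)))
  tr <- c("milk", "fat", "protein", "mg")
  if (!all(tr %in% names(object@traitEffectSizes)))
    msg <- c(msg, "traitEffectSizes must be named milk, fat, protein, mg")
  if (!all(tr %in% names(object@traitNoiseSd)))
    msg <- c(msg, "traitNoiseSd must be named milk, fat, protein, mg")
  hw <- object@heatWaves
  if (nrow(hw)) {
    if (!all(c("start", "length", "peakThi") %in% names(hw)))
      msg <- c(msg, "heatWaves needs columns start, length, peakThi")
    else {
      s <- as.Date(hw$start); e <- s + hw$length - 1
      o <- order(s)
      if (nrow(hw) > 1 && any(s[o][-1] <= e[o][-nrow(hw)]))
        msg <- c(msg, "heat-wave intervals overlap; reject config")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d farm(s) x %d cow(s) x %d year(s) from %d, seed %d\n",
              object@nFarms, object@nCowsPerFarm, object@nYears,
              object@startYear, object@seed))
  cat(sprintf("  %d heat wave(s); THI threshold %.0f; protein depression %.3f %%/unit\n",
              nrow(object@heatWaves), object@thiThreshold,
              object@traitEffectSizes[["protein"]]))
})

#' Multi-farm synthetic study container
#'
#' Returned by [simulateHerdData()]. Bundles the generated weather, daily
#' THI, pedigree, cow profiles, test-day records, spectra and udder
#' surface-temperature records, together with the configuration and the
#' visit calendar, so every downstream stage of the pipeline can run from
#' this one object.
#'
#' @aliases HeatStressSim-class
#' @export
setClass("HeatStressSim", representation(
  config = "SimulationConfig", weather = "data.frame", dailyThi = "data.frame",
  pedigree = "data.frame", cows = "data.frame", testDays = "data.frame",
  spectra = "SpectraSet", surfaceTemps = "data.frame", visits = "data.frame"))

setMethod("show", "HeatStressSim", function(object) {
  cat(sprintf("HeatStressSim: %d farms, %d cows, %d test-day records, %d spectra, %d surface-temperature records\n",
              object@config@nFarms, nrow(object@cows), nrow(object@testDays),
              ncol(object@spectra), nrow(object@surfaceTemps)))
})

#' @describeIn HeatStressSim-class generated hourly weather table
#' @export
weatherData <- function(x) x@weather
#' @describeIn HeatStressSim-class test-day record table
#' @export
testDayData <- function(x) x@testDays
#' @describeIn HeatStressSim-class pedigree table (0 = unknown parent)
#' @export
pedigreeData <- function(x) x@pedigree
#' @describeIn HeatStressSim-class spectra as a [SpectraSet-class]
#' @export
spectraData <- function(x) x@spectra
#' @describeIn HeatStressSim-class udder surface-temperature records
#' @export
surfaceTempData <- function(x) x@surfaceTemps

#' Fitted random-regression test-day model
#'
#' Result of [fitTestDayModel()]: fixed/random solutions of the mixed-model
#' equations, raw and standardized residuals per record, the residual SD
#' used for standardization, and the variance components that were assumed.
#'
#' @aliases TestDayFit-class
#' @export
setClass("TestDayFit", representation(
  trait = "character", solutions = "list", residuals = "data.frame",
  residualSd = "numeric", vc = "list", nEquations = "integer"))

setMethod("show", "TestDayFit", function(object) {
  cat(sprintf("TestDayFit [%s]: %d records, %d equations, residual SD %.4g\n",
              object@trait, nrow(object@residuals), object@nEquations,
              object@residualSd))
})

#' @describeIn TestDayFit-class residual table with `residual` and
#'   `std_residual` columns per record
#' @export
standardizedResiduals <- function(x) x@residuals

#' Calibrated PLS surface-temperature model
#'
#' Result of [fitPlsTemperature()]: the retained spectral points after the
#' correlation pre-selection, the final mixOmics PLS fit, the selected
#' number of latent variables, and the grouped cross-validation report
#' (R2cv and RMSEcv per component count, plus pooled out-of-fold
#' predictions).
#'
#' @aliases PlsTemperatureModel-class
#' @export
setClass("PlsTemperatureModel", representation(
  selectedPoints = "integer", ncomp = "integer", fit = "ANY",
  cvReport = "data.frame", cvPredictions = "data.frame",
  threshold = "numeric"))

setMethod("show", "PlsTemperatureModel", function(object) {
  best <- object@cvReport[object@cvReport$ncomp == object@ncomp, ]
  cat(sprintf("PlsTemperatureModel: %d latent variables on %d pre-selected points (|r| >= %.2f)\n",
              object@ncomp, length(object@selectedPoints), object@threshold))
  if (nrow(best))
    cat(sprintf("  R2cv %.3f, RMSEcv %.3f degrees C\n", best$r2cv, best$rmsecv))
})

#' Two-stage random-forest heat-stress classifier
#'
#' Result of [fitRfClassifier()]: the stage-1 importance ranking, the
#' retained top variables, the final ranger forest, and the grouped
#' out-of-fold confusion report (accuracy, per-class sensitivity and
#' specificity).
#'
#' @aliases RfClassModel-class
#' @export
setClass("RfClassModel", representation(
  fit = "ANY", topVariables = "character", importance = "numeric",
  confusion = "table", accuracy = "numeric", classStats = "data.frame",
  config = "list", oofPredictions = "data.frame"))

setMethod("show", "RfClassModel", function(object) {
  cat(sprintf("RfClassModel: %d retained variables, out-of-fold accuracy %.3f\n",
              length(object@topVariables), object@accuracy))
})
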