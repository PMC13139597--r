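# Internal structural constants of the trait simulator. Lactation-curve
# shapes are Wilmink-type (a + b*exp(-0.05*DIM) + c*DIM); the fixed-effect
# layout of the test-day model can absorb them.
.traitNames <- c("milk", "fat", "protein", "mg")
.geneticSd <- c(milk = 1.8, fat = 0.18, protein = 0.09, mg = 2.5)
.permEnvSd <- .geneticSd * 0.7
.herdYearSd <- c(milk = 1.0, fat = 0.08, protein = 0.04, mg = 1.5)
.lactEffect <- list(milk = c(0, 2.5, 4.0), fat = c(0, 0.06, 0.10),
                    protein = c(0, -0.04, -0.07), mg = c(0, 0.8, 1.2))

.baseCurve <- function(trait, dim) {
  switch(trait,
    milk = 29 - 14 * exp(-0.05 * dim) - 0.035 * dim,
    fat = 4.0 + 0.6 * exp(-0.05 * dim) + 0.0015 * dim,
    protein = 3.10 + 0.50 * exp(-0.05 * dim) + 0.0022 * dim,
    mg = 98 + 6 * exp(-0.05 * dim) + 0.012 * dim)
}

# Fixed spectral constructors: a smooth baseline, one band profile per milk
# component, and the default heat-stress signature (both signs, confined to
# the informative regions of the default mask).
.spectralBaseline <- function() {
  0.15 + gaussBand(90, 120, 0.25) + gaussBand(350, 180, 0.15) +
    gaussBand(700, 250, 0.10)
}
.signatureFat <- function() gaussBand(512, 14, 0.040) + gaussBand(214, 6, 0.030)
.signatureProtein <- function() gaussBand(85, 30, 0.050) + gaussBand(140, 14, 0.030)
.signatureMg <- function() gaussBand(152, 10, 0.030) + gaussBand(505, 8, 0.020)

#' Default planted spectral heat-stress signature
#'
#' A smooth 1,060-point perturbation (absorbance per unit effective heat
#' load) with bands of both signs inside the informative regions, so the
#' calibration stage has a genuine heat signal to find.
#'
#' @return numeric vector of length 1,060.
#' @export
defaultHsSignature <- function() {
  0.003 * (gaussBand(60, 15) - 0.7 * gaussBand(130, 18) + 0.5 * gaussBand(510, 10))
}

#' Default heat-wave calendar
#'
#' One regional heat wave per summer, alternating between a mid-June event
#' (peak daily THI 73) in odd study years and a mid-August event (peak 75)
#' in even years, as Belgian heat waves shift across the summer from year
#' to year. Used when a [simulationConfig()] gives no explicit calendar.
#'
#' @param nYears number of study years.
#' @param startYear first calendar year.
#' @return data.frame with columns `start`, `length`, `peakThi`.
#' @export
defaultHeatWaves <- function(nYears, startYear) {
  waves <- lapply(seq_len(nYears), function(k) {
    yr <- startYear + k - 1L
    if (k %% 2L == 1L)
      data.frame(start = as.Date(sprintf("%d-06-04", yr)), length = 9L, peakThi = 73)
    else
      data.frame(start = as.Date(sprintf("%d-08-14", yr)), length = 9L, peakThi = 75)
  })
  do.call(rbind, waves)
}

#' Build a simulation configuration
#'
#' Constructs a validated [SimulationConfig-class]. All defaults together
#' define the reference synthetic study: a temperate (Belgian-like) climate
#' whose thermoneutral summer days stay just below the THI threshold of 60,
#' one calibrated heat wave per summer, protein and Mg carrying the largest
#' planted depressions per unit heat load (relative to their residual SD),
#' milk intermediate and scaled by yield level, fat near zero, and per-cow
#' heat tolerance drawn around 0.3 with SD 0.25.
#'
#' @param seed master seed (integer).
#' @param nFarms,nCowsPerFarm,nYears,startYear study dimensions.
#' @param heatWaves heat-wave calendar; `NULL` for [defaultHeatWaves()].
#' @param baselineTempMean,tempHeatSlope,thiThreshold surface-temperature
#'   model parameters (degrees C, degrees C per THI unit, THI units).
#' @param traitEffectSizes named planted depressions per unit heat load.
#' @param traitNoiseSd named residual SDs of the traits.
#' @param toleranceMean,toleranceSd per-cow tolerance distribution
#'   (clamped to \[0, 1\]).
#' @param parityHeatMult heat-load multipliers for lactation classes 1, 2, 3+.
#' @param dimSusceptibility named `peak`, `width`, `floor`, `amp` of the
#'   DIM susceptibility curve.
#' @param spectralNoiseSd,hsSignature spectral noise SD and 1,060-point
#'   heat signature.
#' @param surfaceNoiseSd PM/AM surface-temperature noise SD.
#' @param weatherParams named `seasonalMean`, `seasonalAmp`, `diurnalAmp`,
#'   `noiseSd` (degrees C).
#' @param structuralVariance scalar multiplier on the genetic, permanent-
#'   environment and herd-year SDs (0 gives a purely deterministic herd).
#' @param nSires founder sires shared across farms (0 makes every cow a
#'   founder).
#' @return a [SimulationConfig-class] object.
#' @export
simulationConfig <- function(seed = 1L, nFarms = 2L, nCowsPerFarm = 40L,
                             nYears = 2L, startYear = 2021L, heatWaves = NULL,
                             baselineTempMean = 35.1, tempHeatSlope = 0.3,
                             thiThreshold = 60,
                             traitEffectSizes = c(milk = 0.25, fat = 0.005,
                                                  protein = 0.03, mg = 1.2),
                             traitNoiseSd = c(milk = 2.0, fat = 0.25,
                                              protein = 0.12, mg = 4.0),
                             toleranceMean = 0.3, toleranceSd = 0.25,
                             parityHeatMult = c(0.75, 1, 1.25),
                             dimSusceptibility = c(peak = 35, width = 18,
                                                   floor = 0.3, amp = 1.0),
                             spectralNoiseSd = 0.0015,
                             hsSignature = defaultHsSignature(),
                             surfaceNoiseSd = 0.35,
                             weatherParams = c(seasonalMean = 8.5,
                                               seasonalAmp = 6.5,
                                               diurnalAmp = 4.0, noiseSd = 0.8),
                             structuralVariance = 1, nSires = NULL) {
  if (is.null(heatWaves)) heatWaves <- defaultHeatWaves(nYears, startYear)
  if (is.null(nSires)) nSires <- max(4L, 2L * nFarms)
  methods::new("SimulationConfig",
    seed = as.integer(seed), nFarms = as.integer(nFarms),
    nCowsPerFarm = as.integer(nCowsPerFarm), nYears = as.integer(nYears),
    startYear = as.integer(startYear), heatWaves = heatWaves,
    baselineTempMean = baselineTempMean, tempHeatSlope = tempHeatSlope,
    thiThreshold = thiThreshold, traitEffectSizes = traitEffectSizes,
    traitNoiseSd = traitNoiseSd,
    toleranceSd = toleranceSd, parityHeatMult = parityHeatMult,
    dimSusceptibility = dimSusceptibility,
    spectralNoiseSd = spectralNoiseSd, hsSignature = hsSignature,
    surfaceNoiseSd = surfaceNoiseSd, weatherParams = weatherParams,
    toleranceMean = toleranceMean, structuralVariance = structuralVariance,
    nSires = as.integer(nSires))
}

cfgToleranceMean <- function(config) config@toleranceMean
cfgStructVar <- function(config) config@structuralVariance
cfgNSires <- function(config) config@nSires

dimSusceptibilityMult <- function(config, dim) {
  p <- config@dimSusceptibility
  p[["floor"]] + p[["amp"]] * exp(-((dim - p[["peak"]]) / p[["width"]])^2)
}

# Effective heat load of a record: THI excess over the threshold, scaled by
# the cow's tolerance and the planted parity and lactation-stage
# susceptibility multipliers. Shared by traits, spectra and surface temps
# so the pipeline has one well-defined detection target.
effectiveHeatLoad <- function(config, thi, tolerance, lactation, dim) {
  pmax(0, thi - config@thiThreshold) * (1 - tolerance) *
    config@parityHeatMult[pmin(lactation, 3L)] *
    dimSusceptibilityMult(config, dim)
}

.rhFromTemp <- function(temp, noise = 0) {
  pmin(100, pmax(5, 80 - 1.8 * (temp - 10) + noise))
}

#' Generate hourly weather with calibrated heat waves
#'
#' Per-farm hourly temperature = seasonal sinusoid (peak mid-July) +
#' diurnal sinusoid (peak 15:00) + farm offset + noise + heat-wave bumps;
#' relative humidity is anticorrelated with temperature and clipped to
#' \[5, 100\]. Each configured wave's bump amplitude is calibrated by
#' root-finding so that the recomputed daily THI on the wave's peak day
#' equals the configured peak THI. The series starts 10 days before the
#' study's first January so the windowed THI is defined for every test day.
#'
#' @param config a [SimulationConfig-class].
#' @param nDays optional series length in days (overrides the study span;
#'   no lead-in is added then).
#' @return data.frame with columns `farm`, `timestamp` (POSIXct, UTC),
#'   `temp_c`, `rh_pct`.
#' @export
generateWeather <- function(config, nDays = NULL) {
  methods::validObject(config)
  set.seed(childSeed(config@seed, 1L))
  wp <- config@weatherParams
  if (is.null(nDays)) {
    start <- as.Date(sprintf("%d-01-01", config@startYear)) - 10L
    end <- as.Date(sprintf("%d-12-31", config@startYear + config@nYears - 1L))
  } else {
    start <- as.Date(sprintf("%d-01-01", config@startYear))
    end <- start + as.integer(nDays) - 1L
  }
  stamps <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
                as.POSIXct(paste(end, "23:00:00"), tz = "UTC"), by = "hour")
  doy <- as.numeric(format(stamps, "%j"))
  hr <- as.numeric(format(stamps, "%H"))
  dts <- as.Date(stamps, tz = "UTC")
  waves <- config@heatWaves
  out <- vector("list", config@nFarms)
  for (f in seq_len(config@nFarms)) {
    det <- wp[["seasonalMean"]] +
      wp[["seasonalAmp"]] * cos(2 * pi * (doy - 197) / 365.25) +
      wp[["diurnalAmp"]] * cos(2 * pi * (hr - 15) / 24) + 0.3 * (f - 1)
    tnoise <- stats::rnorm(length(det), 0, wp[["noiseSd"]])
    rhnoise <- stats::rnorm(length(det), 0, 3)
    temp <- det + tnoise
    if (nrow(waves)) {
      bump <- numeric(length(temp))
      for (w in seq_len(nrow(waves))) {
        ws <- as.Date(waves$start[w]); L <- waves$length[w]
        days <- ws + seq_len(L) - 1L
        env <- sin(pi * seq_len(L) / (L + 1))^2
        env <- env / max(env)
        peakDay <- days[which.max(env)]
        pk <- which(dts == peakDay)
        if (!length(pk)) next
        obj <- function(dT) {
          tt <- temp[pk] + dT
          mean(hourlyThi(tt, .rhFromTemp(tt, rhnoise[pk]))) - waves$peakThi[w]
        }
        if (obj(0) >= 0) next  # already at or above the target peak
        dT <- stats::uniroot(obj, c(0, 60))$root
        for (j in seq_len(L)) {
          idx <- which(dts == days[j])
          bump[idx] <- bump[idx] + dT * env[j]
        }
      }
      temp <- temp + bump
    }
    out[[f]] <- data.frame(
      farm = sprintf("F%02d", f), timestamp = stamps, temp_c = temp,
      rh_pct = .rhFromTemp(temp, rhnoise))
  }
  do.call(rbind, out)
}

#' Generate pedigree and cow profiles
#'
#' Founder sires (shared across farms, connecting the herds) and per-farm
#' founder dams precede their daughters in the pedigree, so Henderson's
#' rules apply by a single forward scan. Each cow receives a farm, a first
#' calving date (staggered so the herd milks year-round, one calving per
#' 365 days thereafter), an initial parity, per-trait genetic merit
#' (midparent plus Mendelian sampling), permanent-environment effects and a
#' heat tolerance in \[0, 1\].
#'
#' @param config a [SimulationConfig-class].
#' @return list with `pedigree` (animal, sire, dam; "0" = unknown) and
#'   `cows` (one row per cow with profile columns).
#' @export
generatePedigree <- function(config) {
  methods::validObject(config)
  set.seed(childSeed(config@seed, 2L))
  nS <- cfgNSires(config)
  nC <- config@nFarms * config@nCowsPerFarm
  sv <- cfgStructVar(config)
  gFound <- function(n) matrix(stats::rnorm(4L * n, 0, rep(.geneticSd * sv, each = n)),
                               n, 4L, dimnames = list(NULL, .traitNames))
  if (nS > 0L) {
    sires <- sprintf("S%03d", seq_len(nS))
    dams <- sprintf("D%04d", seq_len(nC))
    cowsId <- sprintf("C%04d", seq_len(nC))
    ped <- data.frame(
      animal = c(sires, dams, cowsId),
      sire = c(rep("0", nS + nC), sires[sample.int(nS, nC, replace = TRUE)]),
      dam = c(rep("0", nS + nC), dams),
      stringsAsFactors = FALSE)
    gS <- gFound(nS); gD <- gFound(nC)
    mend <- matrix(stats::rnorm(nC * 4, 0, rep(.geneticSd * sv * sqrt(0.5), each = nC)),
                   nC, 4, dimnames = list(NULL, .traitNames))
    gC <- 0.5 * gS[match(ped$sire[nS + nC + seq_len(nC)], sires), , drop = FALSE] +
      0.5 * gD + mend
  } else {
    cowsId <- sprintf("C%04d", seq_len(nC))
    ped <- data.frame(animal = cowsId, sire = "0", dam = "0",
                      stringsAsFactors = FALSE)
    gC <- gFound(nC)
  }
  firstJan <- as.Date(sprintf("%d-01-01", config@startYear))
  cows <- data.frame(
    animal = cowsId,
    farm = sprintf("F%02d", rep(seq_len(config@nFarms), each = config@nCowsPerFarm)),
    sire = if (nS > 0L) ped$sire[match(cowsId, ped$animal)] else "0",
    dam = if (nS > 0L) ped$dam[match(cowsId, ped$animal)] else "0",
    firstCalving = firstJan + sample.int(660, nC, replace = TRUE) - 361L,
    initialParity = sample(1:4, nC, replace = TRUE, prob = c(0.35, 0.3, 0.2, 0.15)),
    tolerance = pmin(1, pmax(0, stats::rnorm(nC, cfgToleranceMean(config),
                                             config@toleranceSd))),
    stringsAsFactors = FALSE)
  g <- as.data.frame(gC); names(g) <- paste0("g_", .traitNames)
  pe <- matrix(stats::rnorm(4L * nC, 0, rep(.permEnvSd * sv, each = nC)),
               nC, 4L, dimnames = list(NULL, .traitNames))
  pe <- as.data.frame(pe); names(pe) <- paste0("pe_", .traitNames)
  list(pedigree = ped, cows = cbind(cows, g, pe))
}

# Lactation state of each cow at a date: most recent calving with
# 5 <= DIM <= 305, or NA if dry. One calving per 365 days.
.lactationAt <- function(cows, date) {
  off <- as.numeric(as.Date(date) - cows$firstCalving)
  k <- floor(off / 365)
  dim <- off - 365 * k
  inMilk <- off >= 0 & dim >= 5 & dim <= 305
  list(dim = ifelse(inMilk, dim, NA_real_),
       lactation = ifelse(inMilk, cows$initialParity + k, NA_integer_))
}

# Two herd recording days per month per farm (frequent-recording scheme),
# staggered across farms so regional heat waves intersect only some herd
# test days.
routineTestDays <- function(farmIndex) {
  d1 <- 3L + 6L * ((farmIndex - 1L) %% 4L)
  d2 <- ((d1 + 23L) %% 28L) + 1L
  sort(c(d1, d2))
}

routineTestDates <- function(config) {
  out <- list()
  for (f in seq_len(config@nFarms)) {
    days <- routineTestDays(f)
    for (yr in config@startYear + seq_len(config@nYears) - 1L) {
      out[[length(out) + 1L]] <- data.frame(
        farm = sprintf("F%02d", f),
        date = as.Date(sprintf("%d-%02d-%02d", rep(yr, 24), rep(1:12, each = 2), days)))
    }
  }
  do.call(rbind, out)
}

#' Generate test-day milk records
#'
#' For every herd test date (monthly routine recording per farm, plus any
#' extra visit dates) and every cow in milk (5 <= DIM <= 305), simulates
#' milk yield, fat \%, protein \% and Mg concentration (mg/L) as
#' herd-year + lactation-class + Wilmink-type lactation curve + genetic +
#' permanent environment + heat term + noise. The heat term is
#' `-effectSize * effectiveHeatLoad` (milk additionally scaled by the
#' cow's yield level), with the effective load computed from the windowed
#' THI of the farm's weather. Ground-truth columns (`thi_td3d`,
#' `heat_load`, `th_*`) are carried for evaluation.
#'
#' @param cows cow profile table from [generatePedigree()].
#' @param weather hourly weather from [generateWeather()].
#' @param config a [SimulationConfig-class].
#' @param extraDates optional data.frame `farm`, `date` of additional herd
#'   test days (e.g. surface-temperature visit days); flagged `visit`.
#' @return data.frame of test-day records, one row per cow x test day.
#' @export
generateTestDayRecords <- function(cows, weather, config, extraDates = NULL) {
  set.seed(childSeed(config@seed, 3L))
  daily <- computeDailyThi(weather)
  sched <- routineTestDates(config)
  sched$visit <- FALSE
  if (!is.null(extraDates) && nrow(extraDates)) {
    extraDates <- data.frame(farm = extraDates$farm,
                             date = as.Date(extraDates$date), visit = TRUE)
    sched <- rbind(sched, extraDates)
  }
  # a visit may coincide with a routine recording day: one record, flagged
  sched <- stats::aggregate(visit ~ farm + date, sched, any)
  sched <- sched[order(sched$farm, sched$date), ]
  sv <- cfgStructVar(config)
  hyKeys <- unique(paste(sched$farm, format(sched$date, "%Y"), sep = "_"))
  nHy <- length(hyKeys)
  hy <- matrix(stats::rnorm(4L * nHy, 0, rep(.herdYearSd * sv, each = nHy)),
               nHy, 4L, dimnames = list(hyKeys, .traitNames))

  recs <- list()
  for (i in seq_len(nrow(sched))) {
    farm <- sched$farm[i]; dt <- sched$date[i]
    missingDates <- character(0)
    thiTd <- tryCatch(thiWindow(daily, dt, farm = farm), error = function(e)
      stop("missing weather for test day ", format(dt), " at ", farm, ": ",
           conditionMessage(e)))
    cf <- cows[cows$farm == farm, , drop = FALSE]
    st <- .lactationAt(cf, dt)
    ok <- !is.na(st$dim)
    if (!any(ok)) next
    cf <- cf[ok, , drop = FALSE]
    dim <- st$dim[ok]; lact <- st$lactation[ok]
    load <- effectiveHeatLoad(config, thiTd, cf$tolerance, lact, dim)
    hyRow <- hy[paste(farm, format(dt, "%Y"), sep = "_"), ]
    n <- nrow(cf)
    r <- data.frame(
      sample_id = paste(cf$animal, format(dt, "%Y%m%d"), sep = "_"),
      animal = cf$animal, farm = farm, date = dt, visit = sched$visit[i],
      lactation = as.integer(lact), dim = as.integer(dim),
      thi_td3d = thiTd, heat_load = load, stringsAsFactors = FALSE)
    for (tr in .traitNames) {
      e <- config@traitEffectSizes[[tr]]
      base <- .baseCurve(tr, dim) + .lactEffect[[tr]][pmin(lact, 3L)]
      th <- -e * load * if (tr == "milk") .baseCurve("milk", dim) / 30 else 1
      val <- base + hyRow[[tr]] + cf[[paste0("g_", tr)]] + cf[[paste0("pe_", tr)]] +
        th + stats::rnorm(n, 0, config@traitNoiseSd[[tr]])
      r[[tr]] <- val
      r[[paste0("th_", tr)]] <- th
    }
    recs[[length(recs) + 1L]] <- r
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Generate FT-MIR spectra for test-day records
#'
#' Each spectrum is a fixed smooth baseline plus component band profiles
#' scaled by the record's fat, protein and Mg values, plus the planted
#' heat-stress signature scaled by the record's effective heat load, plus
#' i.i.d. noise; exactly 1,060 points per sample.
#'
#' @param records test-day records from [generateTestDayRecords()].
#' @param config a [SimulationConfig-class].
#' @return a [SpectraSet-class] (stage `"raw"`) with per-sample metadata.
#' @export
generateSpectra <- function(records, config) {
  if (length(config@hsSignature) != 1060L)
    stop("hsSignature must have length 1,060")
  set.seed(childSeed(config@seed, 4L))
  n <- nrow(records)
  base <- .spectralBaseline()
  comp <- cbind(.signatureFat(), .signatureProtein(), .signatureMg(),
                config@hsSignature)
  conc <- rbind(records$fat, records$protein, records$mg / 100, records$heat_load)
  m <- base + comp %*% conc +
    matrix(stats::rnorm(1060L * n, 0, config@spectralNoiseSd), 1060L, n)
  SpectraSet(m, sampleIds = records$sample_id, samplesInRows = FALSE,
             colData = data.frame(
               sample_id = records$sample_id, animal = records$animal,
               farm = records$farm, date = records$date,
               month = as.integer(format(records$date, "%m")),
               row.names = records$sample_id))
}

#' Default visit calendar (heat-wave and thermoneutral recording days)
#'
#' Every farm is visited twice in the final study year: once on the peak
#' day of that year's summer heat wave and once during a thermoneutral
#' October day.
#'
#' @param config a [SimulationConfig-class].
#' @return data.frame with `farm`, `date`, `period`.
#' @export
defaultVisits <- function(config) {
  lastYear <- config@startYear + config@nYears - 1L
  hw <- config@heatWaves
  hw <- hw[format(as.Date(hw$start), "%Y") == as.character(lastYear) &
             as.integer(format(as.Date(hw$start), "%m")) %in% 6:8, , drop = FALSE]
  if (!nrow(hw)) stop("no summer heat wave in the final study year to schedule visits")
  hw <- hw[which.max(hw$peakThi), ]
  L <- hw$length
  env <- sin(pi * seq_len(L) / (L + 1))^2
  peak <- as.Date(hw$start) + which.max(env) - 1L
  farms <- sprintf("F%02d", seq_len(config@nFarms))
  rbind(
    data.frame(farm = farms, date = peak, period = "heatwave"),
    data.frame(farm = farms, date = as.Date(sprintf("%d-10-15", lastYear)),
               period = "thermoneutral"))
}

#' Generate udder surface-temperature records
#'
#' For each visit, every cow in milk gets a PM temperature (evening
#' milking, THI of hours 12-21 of the visit day) and an AM temperature
#' (next-morning milking, cooler overnight THI of hours 0-8 of the next
#' day): farm baseline + slope x effective heat load + noise. The stored
#' mean is the average of the two, one record per cow and visit.
#'
#' @param cows cow profiles from [generatePedigree()].
#' @param weather hourly weather from [generateWeather()].
#' @param config a [SimulationConfig-class].
#' @param visits visit calendar as from [defaultVisits()].
#' @return data.frame with `animal`, `farm`, `date`, `period`, `pm_temp`,
#'   `am_temp`, `mean_temp`.
#' @export
generateSurfaceTemperatures <- function(cows, weather, config,
                                        visits = defaultVisits(config)) {
  set.seed(childSeed(config@seed, 5L))
  thiAll <- hourlyThi(weather$temp_c, weather$rh_pct)
  wDate <- as.Date(weather$timestamp, tz = "UTC")
  wHour <- as.integer(format(weather$timestamp, "%H"))
  periodThi <- function(farm, date, hours, day) {
    sel <- weather$farm == farm & wDate == (as.Date(date) + day) & wHour %in% hours
    if (!any(sel)) stop("weather missing for visit at ", farm, " on ", format(date))
    mean(thiAll[sel])
  }
  bl <- rep_len(config@baselineTempMean, config@nFarms)
  names(bl) <- sprintf("F%02d", seq_len(config@nFarms))
  out <- list()
  for (i in seq_len(nrow(visits))) {
    farm <- visits$farm[i]; dt <- as.Date(visits$date[i])
    cf <- cows[cows$farm == farm, , drop = FALSE]
    st <- .lactationAt(cf, dt)
    ok <- !is.na(st$dim)
    if (!any(ok)) next
    cf <- cf[ok, , drop = FALSE]
    dim <- st$dim[ok]; lact <- st$lactation[ok]
    thiPm <- periodThi(farm, dt, 12:21, 0L)
    thiAm <- periodThi(farm, dt, 0:8, 1L)
    n <- nrow(cf)
    loadPm <- effectiveHeatLoad(config, thiPm, cf$tolerance, lact, dim)
    loadAm <- effectiveHeatLoad(config, thiAm, cf$tolerance, lact, dim)
    pm <- bl[[farm]] + config@tempHeatSlope * loadPm +
      stats::rnorm(n, 0, config@surfaceNoiseSd)
    am <- bl[[farm]] + config@tempHeatSlope * loadAm +
      stats::rnorm(n, 0, config@surfaceNoiseSd)
    out[[length(out) + 1L]] <- data.frame(
      animal = cf$animal, farm = farm, date = dt, period = visits$period[i],
      pm_temp = pm, am_temp = am, mean_temp = (pm + am) / 2,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete multi-farm study
#'
#' Orchestrates the generator: weather (with calibrated heat waves),
#' pedigree and cow profiles, the visit calendar, test-day records
#' (routine monthly recording plus visit days), FT-MIR spectra for every
#' record, and udder surface temperatures at the visits. Each component
#' draws from a deterministic child seed of the master seed, so an
#' identical configuration reproduces the dataset exactly.
#'
#' @param config a [SimulationConfig-class].
#' @param includeVisits include the surface-temperature visit arm
#'   (default `TRUE`); without it only routine recording is simulated.
#' @return a [HeatStressSim-class] object.
#' @export
simulateHerdData <- function(config = simulationConfig(), includeVisits = TRUE) {
  methods::validObject(config)
  weather <- generateWeather(config)
  gp <- generatePedigree(config)
  visits <- if (includeVisits) defaultVisits(config) else
    data.frame(farm = character(), date = as.Date(character()),
               period = character())
  extra <- if (nrow(visits)) visits[, c("farm", "date")] else NULL
  records <- generateTestDayRecords(gp$cows, weather, config, extraDates = extra)
  spectra <- generateSpectra(records, config)
  surface <- if (nrow(visits))
    generateSurfaceTemperatures(gp$cows, weather, config, visits) else
    data.frame()
  methods::new("HeatStressSim", config = config, weather = weather,
               dailyThi = computeDailyThi(weather), pedigree = gp$pedigree,
               cows = gp$cows, testDays = records, spectra = spectra,
               surfaceTemps = surface, visits = visits)
}
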