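test_that("degenerate weather configs give constant series and exact counts", {
  cfg <- simulationConfig(
    seed = 3, nFarms = 1, nCowsPerFarm = 2, nYears = 1,
    weatherParams = c(seasonalMean = 20, seasonalAmp = 0, diurnalAmp = 0,
                      noiseSd = 0),
    heatWaves = data.frame(start = as.Date(character()), length = integer(),
                           peakThi = numeric()))
  w <- generateWeather(cfg, nDays = 2)
  expect_identical(nrow(w), 48L)            # 1 farm x 2 days x 24 hours
  expect_identical(length(unique(w$temp_c)), 1L)
  expect_true(all(w$rh_pct >= 5 & w$rh_pct <= 100))
})

test_that("a planted heat wave reproduces its peak daily THI through the THI module", {
  cfg <- simulationConfig(seed = 4, nFarms = 2, nCowsPerFarm = 2, nYears = 1)
  w <- generateWeather(cfg)
  daily <- computeDailyThi(w)
  hw <- cfg@heatWaves[1, ]
  env <- sin(pi * seq_len(hw$length) / (hw$length + 1))^2
  peak <- as.Date(hw$start) + which.max(env) - 1
  for (f in unique(daily$farm)) {
    got <- daily$thi_daily[daily$farm == f & daily$date == peak]
    expect_lt(abs(got - hw$peakThi), 1)
  }
})

test_that("overlapping heat waves are rejected", {
  expect_error(simulationConfig(
    heatWaves = data.frame(start = as.Date(c("2021-06-01", "2021-06-05")),
                           length = c(9L, 9L), peakThi = c(70, 72))),
    "overlap")
})

test_that("pedigrees are topologically ordered and connect farms through sires", {
  cfg <- simulationConfig(seed = 8, nFarms = 2, nCowsPerFarm = 30, nYears = 1)
  gp <- generatePedigree(cfg)
  ped <- gp$pedigree
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$animal
  for (col in c("sire", "dam")) {
    known <- ped[[col]] != "0"
    expect_true(all(pos[ped[[col]][known]] < pos[ped$animal[known]]))
  }
  # at least one sire has daughters in both farms
  byFarm <- table(gp$cows$sire, gp$cows$farm)
  expect_gte(sum(rowSums(byFarm > 0) == 2), 1)
  expect_true(all(gp$cows$tolerance >= 0 & gp$cows$tolerance <= 1))
  # 1 cow, no sire generation: a single founder row with unknown parents
  solo <- generatePedigree(simulationConfig(seed = 1, nFarms = 1,
                                            nCowsPerFarm = 1, nSires = 0))
  expect_identical(nrow(solo$pedigree), 1L)
  expect_identical(solo$pedigree$sire, "0")
  expect_identical(solo$pedigree$dam, "0")
})

test_that("test-day records follow the planted heat-term formula exactly", {
  sim <- smallSim()
  td <- testDayData(sim)
  cfg <- sim@config
  expect_true(all(td$dim >= 5))
  e <- cfg@traitEffectSizes
  expect_equal(td$th_protein, -e[["protein"]] * td$heat_load)
  expect_equal(td$th_mg, -e[["mg"]] * td$heat_load)
  expect_equal(td$th_fat, -e[["fat"]] * td$heat_load)
  # milk term is additionally scaled by the yield level
  expect_equal(td$th_milk,
               -e[["milk"]] * td$heat_load * heatmir:::.baseCurve("milk", td$dim) / 30)
  # heat load recomputes from tolerance, parity and DIM multipliers
  tol <- sim@cows$tolerance[match(td$animal, sim@cows$animal)]
  expect_equal(td$heat_load,
               pmax(0, td$thi_td3d - cfg@thiThreshold) * (1 - tol) *
                 cfg@parityHeatMult[pmin(td$lactation, 3)] *
                 heatmir:::dimSusceptibilityMult(cfg, td$dim))
})

test_that("with zero effects and zero noise, traits depend only on DIM and parity", {
  cfg <- simulationConfig(
    seed = 2, nFarms = 1, nCowsPerFarm = 8, nYears = 2,
    traitEffectSizes = c(milk = 0, fat = 0, protein = 0, mg = 0),
    traitNoiseSd = c(milk = 0, fat = 0, protein = 0, mg = 0),
    structuralVariance = 0)
  sim <- simulateHerdData(cfg, includeVisits = FALSE)
  td <- testDayData(sim)
  key <- paste(td$dim, pmin(td$lactation, 3))
  spread <- tapply(td$protein, key, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
  expect_true(all(td$heat_load * c(0) == 0))
})

test_that("identical configurations generate byte-identical datasets", {
  cfg <- simulationConfig(seed = 77, nFarms = 1, nCowsPerFarm = 6, nYears = 1)
  s1 <- simulateHerdData(cfg)
  s2 <- simulateHerdData(cfg)
  expect_identical(weatherData(s1), weatherData(s2))
  expect_identical(testDayData(s1), testDayData(s2))
  expect_identical(SummarizedExperiment::assay(spectraData(s1)),
                   SummarizedExperiment::assay(spectraData(s2)))
  expect_identical(surfaceTempData(s1), surfaceTempData(s2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  data.table::fwrite(testDayData(s1), f1)
  data.table::fwrite(testDayData(s2), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("spectra are linear in composition and carry the heat signature", {
  sim <- smallSim()
  cfg <- sim@config
  td <- testDayData(sim)
  # zero noise, equal composition -> identical spectra
  base <- td[1:2, ]
  base$fat <- 4; base$protein <- 3.3; base$mg <- 100; base$heat_load <- 0
  cfg0 <- cfg; cfg0@spectralNoiseSd <- 0
  sp <- SummarizedExperiment::assay(generateSpectra(base, cfg0))
  expect_equal(sp[, 1], sp[, 2])
  # doubling the protein difference doubles the spectral difference
  p1 <- base; p1$protein <- c(3.3, 3.4)
  p2 <- base; p2$protein <- c(3.3, 3.5)
  d1 <- diff(t(SummarizedExperiment::assay(generateSpectra(p1, cfg0))))
  d2 <- diff(t(SummarizedExperiment::assay(generateSpectra(p2, cfg0))))
  expect_equal(2 * d1, d2, tolerance = 1e-12)
  # mean affected-minus-unaffected spectrum is proportional to the signature
  hot <- td$heat_load > 2; cool <- td$heat_load == 0
  m <- SummarizedExperiment::assay(spectraData(sim))
  diffSpec <- rowMeans(m[, hot, drop = FALSE]) - rowMeans(m[, cool, drop = FALSE])
  sig <- cfg@hsSignature
  slope <- coef(lm(diffSpec ~ sig))[2]
  expect_gt(slope, 0)
  expect_gt(cor(diffSpec[sig != 0], sig[sig != 0]), 0.5)
})

test_that("surface temperatures average PM and AM and respond to heat", {
  sim <- smallSim()
  st <- surfaceTempData(sim)
  expect_equal(st$mean_temp, (st$pm_temp + st$am_temp) / 2)
  agg <- tapply(st$mean_temp, list(st$farm, st$period), mean)
  expect_true(all(agg[, "heatwave"] > agg[, "thermoneutral"]))
  # zero slope, zero noise: every temperature equals the farm baseline
  cfg0 <- simulationConfig(seed = 9, nFarms = 1, nCowsPerFarm = 5, nYears = 2,
                           tempHeatSlope = 0, surfaceNoiseSd = 0)
  s0 <- simulateHerdData(cfg0)
  expect_true(all(abs(surfaceTempData(s0)$mean_temp - 35.1) < 1e-12))
})
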