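test_that("record filters apply the printed thresholds and are idempotent", {
  rec <- data.frame(
    htd = c(rep("h1", 9), rep("h2", 10), "h2", "h2"),
    dim = c(rep(100, 19), 4, 100),
    milk = c(rep(25, 19), 25, 2.9))
  f <- filterPopulationRecords(rec)
  # 9-record HTD entirely dropped, 10-record HTD kept
  expect_identical(sort(unique(f$htd)), "h2")
  expect_identical(nrow(f), 10L)
  rep <- attr(f, "filter_report")
  expect_identical(unname(rep["dropped_dim"]), 1L)
  expect_identical(unname(rep["dropped_milk"]), 1L)
  # milk exactly 3 kg is kept; DIM 5 and 365 are kept
  edge <- data.frame(htd = rep("h", 12), dim = c(5, 365, rep(100, 10)),
                     milk = c(3, 3, rep(20, 10)))
  expect_identical(nrow(filterPopulationRecords(edge)), 12L)
  # idempotence
  f2 <- filterPopulationRecords(f)
  expect_identical(f2$htd, f$htd)
  expect_identical(nrow(f2), nrow(f))
})

test_that("milk-yield classes follow the printed half-open bins", {
  expect_identical(milkYieldClass(14.99), 1L)
  expect_identical(milkYieldClass(15), 2L)     # lower bound inclusive
  expect_identical(milkYieldClass(40), 7L)
  expect_identical(milkYieldClass(c(3, 19.99, 20, 34.99, 35, 39.99, 55)),
                   c(1L, 2L, 3L, 5L, 6L, 6L, 7L))
})

test_that("5-day DIM classes bin from 5 with the 365 cap", {
  expect_identical(dimClass5d(5), 1L)
  expect_identical(dimClass5d(9), 1L)
  expect_identical(dimClass5d(10), 2L)
  expect_identical(dimClass5d(365), 73L)
  expect_error(dimClass5d(4), "\\[5, 365\\]")
  expect_error(dimClass5d(366), "\\[5, 365\\]")
})

test_that("Snell scores are symmetric, ordered and scale invariant", {
  s <- snellScores(c(a = 50, b = 50))
  expect_equal(s$score[1], -s$score[2])           # logistic symmetry
  expect_equal(s$score[2], 2 * log(2))            # closed form for 50/50
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:5, 1)
    f <- stats::setNames(runif(k, 1, 100), letters[1:k])
    sc <- snellScores(f)$score
    expect_true(all(diff(sc) > 0))                # strictly increasing
    expect_equal(snellScores(10 * f)$score, sc)   # scale invariance
  }
  expect_error(snellScores(c(a = 3, b = 0, c = 2)), "merge")
  expect_error(snellScores(c(a = 5)), "2 categories")
  # the printed frequency pattern (94/4/2 %) yields ordered scores
  s3 <- snellScores(c(`0` = 94, `0.5` = 4, `1` = 2))
  expect_true(all(diff(s3$score) > 0))
})

test_that("the population model matches the dense oracle and recovers planted contrasts", {
  set.seed(40)
  # small instance against the dense MME oracle
  n <- 40
  rec <- data.frame(
    htd = sample(c("h1", "h2", "h3"), n, replace = TRUE),
    lactation = sample(1:3, n, replace = TRUE),
    dim = sample(c(10, 60), n, replace = TRUE),
    milk = sample(c(12, 22), n, replace = TRUE),
    animal = c(sprintf("a%02d", 1:10),
               sample(sprintf("a%02d", 1:10), n - 10, replace = TRUE)),
    score = rnorm(n))
  ped <- data.frame(animal = sprintf("a%02d", 1:10), sire = "0", dam = "0")
  fit <- fitPopulationModel(rec, ped)
  X <- heatmir:::fixedDesign(list(
    htd = factor(rec$htd), lact = factor(rec$lactation),
    dimCl = factor(dimClass5d(rec$dim)), milkCl = factor(milkYieldClass(rec$milk))))
  Za <- outer(rec$animal, ped$animal, "==") * 1
  lamA <- (0.90 / 0.05) * diag(10)
  oracle <- denseMMEOracle(as.matrix(X), rec$score,
                           list(list(Z = Za, lambda = lamA),
                                list(Z = Za, lambda = lamA)))
  got <- c(fit$solutions$estimate, fit$random$animal, fit$random$permEnv)
  expect_equal(unname(got), as.vector(oracle), tolerance = 1e-8)
})

test_that("zero planted effects give null fixed-effect contrasts", {
  set.seed(41)
  n <- 600
  rec <- data.frame(
    htd = sample(sprintf("h%02d", 1:6), n, replace = TRUE),
    lactation = sample(1:3, n, replace = TRUE),
    dim = sample(5:365, n, replace = TRUE),
    milk = runif(n, 10, 45),
    animal = sample(sprintf("a%03d", 1:60), n, replace = TRUE),
    score = rnorm(n))
  ped <- data.frame(animal = sprintf("a%03d", 1:60), sire = "0", dam = "0")
  fit <- fitPopulationModel(rec, ped)
  lact <- solutionProfile(fit, "lactation")
  se <- 1 / sqrt(n / 3)
  expect_true(all(abs(lact$estimate) < 3 * se * 2))
})

test_that("THI-binned means group by integer THI and suppress small bins", {
  rec <- data.frame(thi_td3d = c(rep(50L, 999), rep(60L, 1000)),
                    combined = c(rep(0, 999), rep(0.5, 1000)),
                    pred_temp = 35)
  tb <- thiBinnedMeans(rec)               # default minimum of 1,000
  expect_identical(tb$thi, 60L)           # the 999-record bin is suppressed
  expect_equal(tb$mean_combined, 0.5)
  tb2 <- thiBinnedMeans(rec, minBin = 10)
  expect_identical(tb2$thi, c(50L, 60L))
  expect_equal(tb2$mean_combined, c(0, 0.5))
  allZero <- data.frame(thi_td3d = rep(55L, 2000), combined = 0)
  expect_equal(thiBinnedMeans(allZero)$mean_combined, 0)
})
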