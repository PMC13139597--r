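test_that("grouped folds never split a cow-period and deal groups evenly", {
  rec <- data.frame(animal = rep(sprintf("c%02d", 1:5), each = 4),
                    period = rep(c("heatwave", "thermoneutral"), 10))
  f <- makeGroupFolds(rec, k = 5, seed = 1)
  expect_equal(as.vector(table(unique(cbind(f$animal, f$period, f$fold))[, 3])),
               rep(2, 5))
  grp <- paste(f$animal, f$period)
  expect_true(all(tapply(f$fold, grp, function(v) length(unique(v))) == 1))
  # a cow's two periods may fall in different folds, but records within a
  # group never split
  f2 <- makeGroupFolds(rec, k = 5, seed = 1)
  expect_identical(f$fold, f2$fold)
  expect_error(makeGroupFolds(rec[rec$animal %in% c("c01", "c02"), ], k = 5),
               "groups")
})

test_that("the month-risk dummy flags April through September", {
  expect_identical(monthRiskDummy(7), 1L)
  expect_identical(monthRiskDummy(12), 0L)
  expect_identical(monthRiskDummy(c(4, 9)), c(1L, 1L))  # boundary months
  expect_identical(monthRiskDummy(c(3, 10)), c(0L, 0L))
  expect_identical(monthRiskDummy(as.Date("2021-08-15")), 1L)
  expect_error(monthRiskDummy(13))
})

test_that("PLS at full rank reproduces the least-squares oracle", {
  set.seed(20)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- sprintf("pt_%04d", 1:5)
  rownames(X) <- paste0("s", 1:n)
  y <- rnorm(n, 35, 1)
  folds <- rep(1:5, length.out = n)
  m <- fitPlsTemperature(X, y, folds, maxComponents = 5, threshold = 0,
                         ncomp = 5)
  ols <- unname(fitted(lm(y ~ X)))
  expect_equal(predictTemperature(m, X), ols, tolerance = 1e-8)
})

test_that("noise-free linear targets give R2cv of 1 and slope 1", {
  set.seed(21)
  n <- 150
  X <- matrix(rnorm(n * 20), n, 20)
  colnames(X) <- sprintf("pt_%04d", 1:20)
  rownames(X) <- paste0("s", 1:n)
  y <- 35 + X[, 1] + X[, 2] - X[, 3]
  folds <- makeGroupFolds(
    data.frame(animal = rep(sprintf("c%03d", 1:50), each = 3),
               period = rep(c("heatwave", "thermoneutral", "heatwave"), 50)),
    k = 5, seed = 3)$fold
  m <- fitPlsTemperature(X, y, folds, maxComponents = 12)
  best <- max(m@cvReport$r2cv)
  expect_lt(abs(best - 1), 1e-6)
  cv <- m@cvPredictions
  expect_equal(unname(coef(lm(cv$observed ~ cv$predicted))[2]), 1,
               tolerance = 1e-6)
})

test_that("the PLS CV curve and final model respect the pre-selection contract", {
  sim <- smallSim()
  surface <- surfaceTempData(sim)
  surface$sample_id <- paste(surface$animal,
                             format(as.Date(surface$date), "%Y%m%d"), sep = "_")
  feats <- spectraMatrix(selectRegions(firstDerivative(spectraData(sim))))
  ref <- makeGroupFolds(surface, k = 5, seed = 7)
  m <- fitPlsTemperature(feats[ref$sample_id, ], ref$mean_temp, ref$fold,
                         maxComponents = 15)
  expect_true(all(m@selectedPoints %in% defaultRegionMask()))
  expect_lte(m@ncomp, length(m@selectedPoints))
  expect_gt(max(m@cvReport$r2cv), 0.5)
  # prediction uses exactly the stored points
  expect_error(predictTemperature(m, feats[, 1:5]), "selected points")
})

test_that("RF separates planted classes and collapses to chance on permuted labels", {
  set.seed(30)
  n <- 300; p <- 12
  cls <- factor(rep(c("X0", "X0.5", "X1"), each = n / 3),
                levels = c("X0", "X0.5", "X1"), ordered = TRUE)
  shift <- (as.integer(cls) - 2) * 3        # well-separated class means
  X <- matrix(rnorm(n * p), n, p)
  X[, 1:4] <- X[, 1:4] + shift
  colnames(X) <- sprintf("pt_%04d", seq_len(p))
  rownames(X) <- paste0("s", seq_len(n))
  month <- sample(1:12, n, replace = TRUE)
  folds <- makeGroupFolds(data.frame(animal = rep(sprintf("g%03d", 1:100), 3),
                                     period = "x"), k = 5, seed = 5)$fold
  m <- fitRfClassifier(X, month, cls, folds, nTopVariables = 6, seed = 11)
  expect_gt(m@accuracy, 0.95)
  # confusion rows sum to per-class truth counts
  expect_equal(unname(rowSums(m@confusion)), as.vector(table(cls)))
  # permuted labels: accuracy within Monte-Carlo error of 1/3
  perm <- sample(cls)
  m0 <- fitRfClassifier(X, month, perm, folds, nTopVariables = 6, seed = 11)
  expect_lt(abs(m0@accuracy - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / n))
  # seeded reproducibility, bit for bit
  m2 <- fitRfClassifier(X, month, cls, folds, nTopVariables = 6, seed = 11)
  expect_identical(m@oofPredictions$predicted, m2@oofPredictions$predicted)
  expect_identical(predictClass(m, X, month), predictClass(m2, X, month))
})

test_that("the combination rule is exact at its printed boundaries and monotone", {
  expect_equal(combineHeatStress(36.0, "X1"), 1)     # 'at least 36' inclusive
  expect_equal(combineHeatStress(35.9, "X1"), 0)
  expect_equal(combineHeatStress(37.2, "X0"), 0)
  expect_equal(combineHeatStress(36.0, "X0.5"), 0.5)
  temps <- seq(34, 39, by = 0.25)
  for (cl in c("X0", "X0.5", "X1")) {
    v <- combineHeatStress(temps, rep(cl, length(temps)))
    expect_true(all(diff(v) >= 0))      # monotone in temperature
  }
  for (t in temps) {
    v <- combineHeatStress(rep(t, 3), c("X0", "X0.5", "X1"))
    expect_true(all(diff(v) >= 0))      # monotone in class upgrades
  }
})
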