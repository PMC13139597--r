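test_that("DIM standardization maps the printed anchors", {
  expect_equal(standardizeDim(5), -1)
  expect_equal(standardizeDim(185), 0)
  expect_equal(standardizeDim(365), 1)
  expect_equal(standardizeDim(500), 1)  # capped above 365
  expect_error(standardizeDim(4), ">= 5")
})

test_that("Legendre covariates evaluate the printed polynomials", {
  expect_equal(unname(legendreCovariates(0)), matrix(c(1, 0, -0.5), 1))
  expect_equal(unname(legendreCovariates(1)), matrix(c(1, 1, 1), 1))
  expect_equal(unname(legendreCovariates(-1)), matrix(c(1, -1, 1), 1))
  expect_error(legendreCovariates(1.2), "within")
})

test_that("A-inverse from Henderson's rules matches dense inversion", {
  # single founder
  expect_equal(as.matrix(aInverse(data.frame(animal = "x", sire = "0", dam = "0"))),
               matrix(1, dimnames = list("x", "x")))
  # sire-dam-offspring trio against the printed dense relationship
  trio <- data.frame(animal = c("s", "d", "o"), sire = c("0", "0", "s"),
                     dam = c("0", "0", "d"))
  A <- matrix(c(1, 0, .5, 0, 1, .5, .5, .5, 1), 3)
  expect_equal(unname(as.matrix(aInverse(trio))), solve(A), tolerance = 1e-12)
  # random 30-animal pedigrees: A^-1 A = I against the tabular-method oracle
  for (seed in 1:5) {
    ped <- randomPedigree(30, seed = seed)
    Ai <- as.matrix(aInverse(ped))
    A <- denseRelationship(ped)
    expect_lt(max(abs(Ai %*% A - diag(30))), 1e-10)
  }
  bad <- data.frame(animal = c("o", "s"), sire = c("s", "0"), dam = c("0", "0"))
  expect_error(aInverse(bad), "topologically")
})

test_that("the sparse MME solver reproduces the dense direct-inversion oracle", {
  for (seed in 1:25) {
    inst <- randomMMEInstance(seed)
    sol <- solveMME(inst$X, inst$y, inst$blocks)
    oracle <- denseMMEOracle(inst$X, inst$y, inst$blocks)
    got <- c(sol$beta, unlist(sol$u, use.names = FALSE))
    expect_lt(max(abs(got - as.vector(oracle))) / max(1, max(abs(oracle))), 1e-8)
  }
})

test_that("residual standardization uses the population SD", {
  expect_equal(standardizeResiduals(c(-1, 1)), c(-1, 1))
  set.seed(4)
  e <- rnorm(50)
  s <- standardizeResiduals(e)
  expect_equal(sqrt(mean(s^2) - mean(s)^2), 1)
  expect_equal(s[e == 0], numeric(0))
  expect_error(standardizeResiduals(rep(2, 5)), "zero")
})

test_that("test-day model residuals collapse to OLS in the no-shrinkage limit", {
  sim <- smallSim()
  td <- testDayData(sim)
  vy <- var(td$protein)
  tiny <- list(Ga = diag(3) * 1e-10 * vy, Gp = diag(3) * 1e-10 * vy,
               sigma2e = 0.5 * vy)
  fit <- fitTestDayModel(td, "protein", pedigreeData(sim), vc = tiny)
  herdYear <- factor(paste(td$farm, format(td$date, "%Y")))
  month <- factor(format(td$date, "%m"))
  lact <- factor(pmin(td$lactation, 3))
  dimc <- factor(heatmir:::dimClass19(td$dim))
  ols <- residuals(lm(td$protein ~ herdYear + month + lact + dimc))
  expect_equal(unname(fit@residuals$residual), unname(ols), tolerance = 1e-6)
  # OLS residuals are orthogonal to the fixed design
  X <- model.matrix(~ herdYear + month + lact + dimc)
  expect_lt(max(abs(crossprod(X, fit@residuals$residual))), 1e-4)
})

test_that("shifting the trait by a constant leaves residuals unchanged", {
  sim <- smallSim()
  td <- testDayData(sim)
  fit1 <- fitTestDayModel(td, "protein", pedigreeData(sim))
  td2 <- td
  td2$protein <- td2$protein + 10
  vc <- fit1@vc  # same components, not re-derived from the shifted variance
  fit2 <- fitTestDayModel(td2, "protein", pedigreeData(sim), vc = vc)
  expect_equal(fit1@residuals$residual, fit2@residuals$residual, tolerance = 1e-8)
})

test_that("raising the residual variance shrinks random-effect solutions", {
  sim <- smallSim()
  td <- testDayData(sim)
  vy <- var(td$protein)
  base <- list(Ga = diag(c(0.2, 0.02, 0.01)) * vy,
               Gp = diag(c(0.2, 0.02, 0.01)) * vy, sigma2e = 0.3 * vy)
  more <- base; more$sigma2e <- 3 * vy
  f1 <- fitTestDayModel(td, "protein", pedigreeData(sim), vc = base)
  f2 <- fitTestDayModel(td, "protein", pedigreeData(sim), vc = more)
  expect_lt(sqrt(sum(f2@solutions$genetic^2)), sqrt(sum(f1@solutions$genetic^2)))
  expect_lt(sqrt(sum(f2@solutions$permEnv^2)), sqrt(sum(f1@solutions$permEnv^2)))
})

test_that("a tiny instance matches the dense mixed-model oracle end to end", {
  # 6 records, 2 unrelated animals, identity relationship
  ped <- data.frame(animal = c("a1", "a2"), sire = "0", dam = "0")
  rec <- data.frame(
    animal = rep(c("a1", "a2"), each = 3),
    farm = "F01",
    date = rep(as.Date(c("2021-03-01", "2021-06-01", "2021-03-15")), 2),
    lactation = rep(c(1L, 2L), each = 3),
    dim = c(7, 40, 8, 6, 35, 38),
    protein = c(3.3, 3.2, 3.4, 3.5, 3.1, 3.6))
  vc <- list(Ga = diag(c(0.02, 0.002, 0.001)), Gp = diag(c(0.02, 0.002, 0.001)),
             sigma2e = 0.01)
  fit <- fitTestDayModel(rec, "protein", ped, vc = vc)
  # oracle: same parameterization (first factor full, later factors drop
  # their first level) built densely and inverted directly
  X <- cbind(hy = 1,
             jun = as.integer(format(rec$date, "%m") == "06"),
             lact2 = as.integer(rec$lactation == 2),
             dim6 = as.integer(heatmir:::dimClass19(rec$dim) == 6))
  Q <- legendreCovariates(standardizeDim(rec$dim))
  Z <- matrix(0, 6, 6)
  for (i in 1:6) {
    a <- match(rec$animal[i], ped$animal)
    Z[i, (a - 1) * 3 + 1:3] <- Q[i, ]
  }
  lamA <- vc$sigma2e * (diag(2) %x% solve(vc$Ga))
  lamP <- vc$sigma2e * (diag(2) %x% solve(vc$Gp))
  oracle <- denseMMEOracle(X, rec$protein,
                           list(list(Z = Z, lambda = lamA),
                                list(Z = Z, lambda = lamP)))
  got <- c(fit@solutions$fixed, fit@solutions$genetic, fit@solutions$permEnv)
  expect_equal(unname(got), as.vector(oracle), tolerance = 1e-8)
})
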