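#' Standardize days in milk to \[-1, 1\]
#'
#' Maps DIM to the Legendre support via x = 2 (DIM - 5) / 360 - 1, capped
#' at 1 for DIM above 365. DIM below 5 is invalid.
#'
#' @param dim days in milk, >= 5.
#' @return numeric vector in \[-1, 1\].
#' @export
#' @examples
#' standardizeDim(c(5, 185, 500))
standardizeDim <- function(dim) {
  if (any(dim < 5)) stop("DIM must be >= 5")
  pmin(2 * (dim - 5) / (365 - 5) - 1, 1)
}

#' Second-degree Legendre covariates
#'
#' Returns P0 = 1, P1 = x, P2 = (3 x^2 - 1) / 2 evaluated at standardized
#' DIM, the random-regression covariates of the test-day model.
#'
#' @param x standardized DIM in \[-1, 1\].
#' @return matrix with columns P0, P1, P2.
#' @export
legendreCovariates <- function(x) {
  if (any(abs(x) > 1)) stop("standardized DIM must lie within [-1, 1]")
  cbind(P0 = rep(1, length(x)), P1 = x, P2 = 0.5 * (3 * x^2 - 1))
}

# 19 DIM classes of the test-day model fixed-effect layout. The printed
# bins 251-305 / 305-365 overlap at 305; resolved as 251-304 / 305-365.
dimClass19 <- function(dim) {
  if (any(dim < 5)) stop("DIM must be >= 5")
  edges <- c(5, 11, 16, 21, 26, 31, 41, 51, 61, 71, 81, 91, 101, 121, 151,
             201, 251, 305, 366)
  findInterval(dim, edges)
}

#' Default variance components for the test-day model
#'
#' The study design supplies no estimated (co)variance components, so the
#' model is solved at user-supplied values. The default gives moderate
#' shrinkage: genetic and permanent-environment regression-coefficient
#' covariances `diag(0.2, 0.02, 0.01) * varY` and residual variance
#' `0.5 * varY`.
#'
#' @param varY phenotypic variance of the trait.
#' @return list with 3x3 matrices `Ga`, `Gp` and scalar `sigma2e`.
#' @export
defaultVarianceComponents <- function(varY) {
  list(Ga = diag(c(0.2, 0.02, 0.01)) * varY,
       Gp = diag(c(0.2, 0.02, 0.01)) * varY,
       sigma2e = 0.5 * varY)
}

#' Fit the single-trait random-regression test-day model
#'
#' Solves, by Henderson's mixed-model equations, the model
#' y = Xb + Q(Z1 a + Z2 p) + e with fixed effects herd x year, month of
#' recording (12 levels), lactation-number class (1, 2, 3+) and 19 DIM
#' classes; each animal carries three additive-genetic regression
#' coefficients on the second-degree Legendre covariates (covariance
#' `Ga` kron A across relatives) and three permanent-environment
#' coefficients (`Gp` kron I). Identifiability: the first factor keeps all
#' levels, every later factor drops its first level. Residuals are
#' standardized by their population SD over the fitted dataset.
#'
#' @param records data.frame with columns `animal`, `farm`, `date` (Date),
#'   `lactation`, `dim` and the trait column.
#' @param trait name of the trait column to fit.
#' @param pedigree pedigree data.frame (`animal`, `sire`, `dam`,
#'   topologically ordered); animals with records must appear in it.
#' @param vc variance components as from [defaultVarianceComponents()];
#'   default uses the trait's observed variance.
#' @return a [TestDayFit-class] object.
#' @export
fitTestDayModel <- function(records, trait, pedigree, vc = NULL) {
  stopifnot(is.data.frame(records),
            all(c("animal", "farm", "date", "lactation", "dim", trait) %in% names(records)))
  y <- records[[trait]]
  if (is.null(vc)) vc <- defaultVarianceComponents(stats::var(y))
  stopifnot(is.matrix(vc$Ga), is.matrix(vc$Gp), vc$sigma2e > 0)
  X <- fixedDesign(list(
    herdYear = paste(records$farm, format(as.Date(records$date), "%Y"), sep = "_"),
    month = factor(as.integer(format(as.Date(records$date), "%m")), levels = 1:12),
    lactClass = factor(pmin(records$lactation, 3L), levels = 1:3),
    dimCl = factor(dimClass19(records$dim), levels = 1:19)))
  Q <- legendreCovariates(standardizeDim(records$dim))

  pedIds <- as.character(pedigree$animal)
  recAnimal <- as.character(records$animal)
  if (!all(recAnimal %in% pedIds))
    stop("records contain animals absent from the pedigree")
  Ainv <- aInverse(pedigree)
  nA <- length(pedIds)
  rowI <- rep(seq_len(nrow(records)), each = 3L)
  colA <- rep((match(recAnimal, pedIds) - 1L) * 3L, each = 3L) +
    rep(1:3, times = nrow(records))
  Z1 <- Matrix::sparseMatrix(i = rowI, j = colA, x = as.vector(t(Q)),
                             dims = c(nrow(records), 3L * nA))
  colnames(Z1) <- paste(rep(pedIds, each = 3), c("P0", "P1", "P2"), sep = ".")
  recIds <- sort(unique(recAnimal))
  colP <- rep((match(recAnimal, recIds) - 1L) * 3L, each = 3L) +
    rep(1:3, times = nrow(records))
  Z2 <- Matrix::sparseMatrix(i = rowI, j = colP, x = as.vector(t(Q)),
                             dims = c(nrow(records), 3L * length(recIds)))
  colnames(Z2) <- paste(rep(recIds, each = 3), c("P0", "P1", "P2"), sep = ".")

  lambdaA <- vc$sigma2e * (Ainv %x% solve(vc$Ga))
  lambdaP <- vc$sigma2e * (Matrix::Diagonal(length(recIds)) %x% solve(vc$Gp))
  sol <- solveMME(X, y, list(
    list(Z = Z1, lambda = lambdaA, name = "genetic"),
    list(Z = Z2, lambda = lambdaP, name = "permEnv")))

  resid <- sol$residuals
  res <- standardizeResidualVector(resid)
  residDf <- data.frame(
    sample_id = if ("sample_id" %in% names(records)) records$sample_id else seq_along(y),
    animal = recAnimal, date = as.Date(records$date),
    residual = resid, std_residual = res$std,
    stringsAsFactors = FALSE)
  methods::new("TestDayFit", trait = trait,
               solutions = list(fixed = sol$beta, genetic = sol$u$genetic,
                                permEnv = sol$u$permEnv),
               residuals = residDf, residualSd = res$sd, vc = vc,
               nEquations = length(sol$beta) + 3L * (nA + length(recIds)))
}

# Population-SD standardization shared by the exported helper and the fit.
standardizeResidualVector <- function(e) {
  if (length(e) < 2L) stop("need at least 2 residuals to standardize")
  sd <- sqrt(mean(e^2) - mean(e)^2)  # population SD (divide by n)
  if (sd == 0) stop("residual standard deviation is zero; cannot standardize")
  list(std = e / sd, sd = sd)
}

#' Standardize residuals by their (population) SD
#'
#' Divides each residual by the population standard deviation of the whole
#' residual vector, so that different traits are comparable on one scale.
#'
#' @param e numeric residual vector (>= 2 values, nonzero SD).
#' @return numeric vector with population SD 1.
#' @export
standardizeResiduals <- function(e) {
  standardizeResidualVector(e)$std
}
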