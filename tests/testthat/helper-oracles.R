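# Independent oracles and shared fixtures, built in code.

# Dense numerator relationship matrix by the tabular method (recursion on an
# ordered pedigree), independent of the Henderson-rules inverse it checks.
denseRelationship <- function(pedigree) {
  ids <- as.character(pedigree$animal)
  n <- length(ids)
  idx <- function(p) {
    i <- match(as.character(p), ids)
    i[as.character(p) %in% c("0", "") | is.na(p)] <- NA_integer_
    i
  }
  si <- idx(pedigree$sire); di <- idx(pedigree$dam)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    for (j in seq_len(i - 1L)) {
      val <- 0
      if (!is.na(s)) val <- val + 0.5 * A[j, s]
      if (!is.na(d)) val <- val + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- val
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

# Random topologically-ordered pedigree without inbreeding: each later
# animal draws parents (possibly unknown) from earlier, mutually unrelated
# animals, so Henderson's simple rules are exact. The relationship matrix is
# grown alongside by the tabular recursion to screen candidate matings.
randomPedigree <- function(n, nFounders = max(3L, n %/% 4L), seed = 1L) {
  set.seed(seed)
  ids <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep("0", n)
  A <- diag(n)
  setRow <- function(A, i, s, d) {
    for (j in seq_len(i - 1L)) {
      val <- 0
      if (s > 0) val <- val + 0.5 * A[j, s]
      if (d > 0) val <- val + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- val
    }
    A
  }
  for (i in (nFounders + 1L):n) {
    s <- d <- 0L
    if (stats::runif(1) < 0.85) s <- sample.int(i - 1L, 1)
    if (stats::runif(1) < 0.85) {
      cand <- which(if (s > 0) A[seq_len(i - 1L), s] == 0 else
        rep(TRUE, i - 1L))
      cand <- setdiff(cand, s)
      if (length(cand)) d <- if (length(cand) == 1L) cand else sample(cand, 1)
    }
    if (s > 0) sire[i] <- ids[s]
    if (d > 0) dam[i] <- ids[d]
    A <- setRow(A, i, s, d)
  }
  data.frame(animal = ids, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# Dense mixed-model-equations oracle by direct inversion.
denseMMEOracle <- function(X, y, randomBlocks = list()) {
  X <- as.matrix(X)
  Zs <- lapply(randomBlocks, function(b) as.matrix(b$Z))
  W <- if (length(Zs)) do.call(cbind, c(list(X), Zs)) else X
  C <- crossprod(W)
  p <- ncol(X); off <- p + c(0L, cumsum(vapply(Zs, ncol, integer(1))))
  for (k in seq_along(Zs)) {
    rng <- (off[k] + 1L):(off[k + 1L])
    C[rng, rng] <- C[rng, rng] + as.matrix(randomBlocks[[k]]$lambda)
  }
  solve(C, crossprod(W, y))
}

# One random small MME instance (<= 50 equations): two crossed fixed
# factors, one grouped random effect with a random SPD precision.
randomMMEInstance <- function(seed) {
  set.seed(seed)
  n <- sample(15:35, 1)
  f1 <- factor(sample(letters[1:3], n, replace = TRUE))
  f2 <- factor(sample(LETTERS[1:3], n, replace = TRUE))
  X <- Matrix::sparse.model.matrix(~ 0 + f1 + f2,
                                   data.frame(f1 = droplevels(f1), f2 = droplevels(f2)))
  q <- sample(3:8, 1)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = sample.int(q, n, replace = TRUE),
                            x = 1, dims = c(n, q))
  M <- matrix(stats::rnorm(q * q), q)
  lambda <- crossprod(M) + diag(q) * 0.5
  y <- stats::rnorm(n)
  list(X = X, y = y, blocks = list(list(Z = Z, lambda = Matrix::Matrix(lambda))))
}

# Memoised small simulated study shared across test files.
.simCache <- new.env(parent = emptyenv())

smallSim <- function() {
  if (is.null(.simCache$small)) {
    cfg <- simulationConfig(seed = 5L, nFarms = 2L, nCowsPerFarm = 25L,
                            nYears = 2L)
    .simCache$small <- simulateHerdData(cfg)
  }
  .simCache$small
}

# Memoised population-scale pipeline run shared by the pipeline smoke test
# and the acceptance suite (3 farms x 60 cows x 2 years, fixed seed).
pipelineRun <- function() {
  if (is.null(.simCache$pipe)) {
    cfg <- populationConfig(seed = 42L, nFarms = 3L, nCowsPerFarm = 60L,
                            nYears = 2L)
    .simCache$pipe <- runHeatStressPipeline(cfg)
  }
  .simCache$pipe
}

# Hot routine test days of a simulation: inside a wave window with windowed
# THI above the threshold.
hotWaveDays <- function(sim) {
  td <- testDayData(sim)
  hw <- sim@config@heatWaves
  inWave <- rep(FALSE, nrow(td))
  for (i in seq_len(nrow(hw))) {
    inWave <- inWave | (td$date >= as.Date(hw$start[i]) &
                          td$date <= as.Date(hw$start[i]) + hw$length[i] - 1)
  }
  inWave & td$thi_td3d > sim@config@thiThreshold
}
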