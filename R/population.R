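#' Record filters for the population model
#'
#' Keeps records with DIM between 5 and 365, 24 h milk yield of at least
#' 3 kg, and belonging to a herd test-day (HTD) with at least 10 records.
#' The HTD size criterion is evaluated after the DIM and milk filters and
#' then re-checked once, so the output is stable under refiltering.
#'
#' @param records data.frame with columns `htd` (herd test-day id), `dim`
#'   and `milk`.
#' @param minHtd minimum HTD size (default 10).
#' @return filtered data.frame with a `filter_report` attribute giving the
#'   records dropped per criterion.
#' @export
filterPopulationRecords <- function(records, minHtd = 10L) {
  stopifnot(all(c("htd", "dim", "milk") %in% names(records)))
  n0 <- nrow(records)
  okDim <- records$dim >= 5 & records$dim <= 365
  okMilk <- records$milk >= 3
  out <- records[okDim & okMilk, , drop = FALSE]
  dropHtd <- 0L
  for (pass in 1:2) {
    sizes <- table(out$htd)
    keep <- out$htd %in% names(sizes)[sizes >= minHtd]
    dropHtd <- dropHtd + sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  attr(out, "filter_report") <- c(
    input = n0, dropped_dim = sum(!okDim), dropped_milk = sum(okDim & !okMilk),
    dropped_htd = dropHtd, kept = nrow(out))
  out
}

#' 24 h milk-yield class (7 classes)
#'
#' Half-open bins: <15, \[15, 20), \[20, 25), \[25, 30), \[30, 35),
#' \[35, 40) and >= 40 kg; lower bounds inclusive.
#'
#' @param kg 24 h milk yield in kg (>= 3 after filtering).
#' @return integer class 1..7.
#' @export
milkYieldClass <- function(kg) {
  findInterval(kg, c(15, 20, 25, 30, 35, 40)) + 1L
}

#' 5-day DIM class
#'
#' Classes of 5 DIM starting at DIM 5 with a maximum of 365 DIM:
#' class = floor((DIM - 5)/5) + 1, so DIM 5-9 is class 1 and DIM 365
#' falls in the terminal class 73.
#'
#' @param dim days in milk within \[5, 365\].
#' @return integer class 1..73.
#' @export
dimClass5d <- function(dim) {
  if (any(dim < 5 | dim > 365))
    stop("DIM outside [5, 365]; records should be pre-filtered")
  as.integer(floor((dim - 5) / 5) + 1L)
}

# Antiderivative of x * dlogis(x): x*F(x) - log(1 + e^x), written stably.
.logisPartial <- function(x) {
  out <- numeric(length(x))
  fin <- is.finite(x)
  xf <- x[fin]
  out[fin] <- ifelse(xf > 0,
                     -xf * (1 - stats::plogis(xf)) - log1p(exp(-xf)),
                     xf * stats::plogis(xf) - log1p(exp(xf)))
  out[!fin] <- 0  # both tails vanish
  out
}

#' Snell scores for ordered categories
#'
#' Quasi-continuous scores for an ordered categorical trait under a
#' standard-logistic liability: the cumulative proportions place the
#' category boundaries at t_k = ln(P_k / (1 - P_k)), and each category's
#' score is the mean of the logistic variable truncated to its interval.
#' Scores are strictly increasing and invariant to rescaling the
#' frequencies.
#'
#' @param frequencies named positive counts (or proportions), in category
#'   order.
#' @return data.frame with `category`, `frequency`, `proportion`,
#'   `boundary_upper` and `score`.
#' @export
snellScores <- function(frequencies) {
  if (length(frequencies) < 2L) stop("need at least 2 categories")
  if (any(frequencies <= 0))
    stop("zero-frequency category; merge it with a neighbour before scoring")
  p <- frequencies / sum(frequencies)
  cum <- cumsum(p)
  t <- c(-Inf, stats::qlogis(cum[-length(cum)]), Inf)
  F <- stats::plogis(t)
  score <- (.logisPartial(t[-1]) - .logisPartial(t[-length(t)])) /
    (F[-1] - F[-length(t)])
  data.frame(category = names(frequencies) %||% as.character(seq_along(p)),
             frequency = as.numeric(frequencies), proportion = as.numeric(p),
             boundary_upper = t[-1], score = score, row.names = NULL)
}

#' Fit the population mixed model on Snell-scored phenotypes
#'
#' Solves, with the same sparse mixed-model machinery as the test-day
#' model, the model y = HTD + lactation class + DIM class (5-day bins) +
#' milk-yield class + animal + permanent environment + residual, where the
#' response is the Snell-scored combined heat-stress phenotype. The animal
#' effect is scalar with pedigree covariance (A), the permanent-environment
#' effect scalar i.i.d. Identifiability uses reference-level constraints
#' (first factor full, later factors drop their first observed level).
#'
#' @param records filtered records with columns `htd`, `lactation`, `dim`,
#'   `milk`, `animal` and `score` (the Snell-scored response).
#' @param pedigree pedigree covering all record animals.
#' @param varRatios named proportions `a`, `pe`, `e` of the score variance
#'   assigned to the three components (default 0.05/0.05/0.90).
#' @return list with `solutions` (data.frame factor/level/estimate),
#'   `random` (animal and permanent-environment solutions), `residuals`
#'   and the variance ratios used.
#' @export
fitPopulationModel <- function(records, pedigree,
                               varRatios = c(a = 0.05, pe = 0.05, e = 0.90)) {
  stopifnot(all(c("htd", "lactation", "dim", "milk", "animal", "score")
                %in% names(records)))
  y <- records$score
  X <- fixedDesign(list(
    htd = factor(records$htd),
    lact = factor(pmin(records$lactation, 3L), levels = 1:3),
    dimCl = factor(dimClass5d(records$dim), levels = 1:73),
    milkCl = factor(milkYieldClass(records$milk), levels = 1:7)))
  pedIds <- as.character(pedigree$animal)
  if (!all(records$animal %in% pedIds))
    stop("records contain animals absent from the pedigree")
  Ainv <- aInverse(pedigree)
  Za <- Matrix::sparseMatrix(i = seq_len(nrow(records)),
                             j = match(records$animal, pedIds), x = 1,
                             dims = c(nrow(records), length(pedIds)))
  colnames(Za) <- pedIds
  recIds <- sort(unique(as.character(records$animal)))
  Zp <- Matrix::sparseMatrix(i = seq_len(nrow(records)),
                             j = match(records$animal, recIds), x = 1,
                             dims = c(nrow(records), length(recIds)))
  colnames(Zp) <- recIds
  lambdaA <- (varRatios[["e"]] / varRatios[["a"]]) * Ainv
  lambdaP <- (varRatios[["e"]] / varRatios[["pe"]]) *
    Matrix::Diagonal(length(recIds))
  sol <- solveMME(X, y, list(
    list(Z = Za, lambda = lambdaA, name = "animal"),
    list(Z = Zp, lambda = lambdaP, name = "permEnv")))
  nm <- names(sol$beta)
  solutions <- data.frame(
    factor = sub("^(htd|lact|dimCl|milkCl).*$", "\\1", nm),
    level = sub("^(htd|lact|dimCl|milkCl)", "", nm),
    estimate = as.numeric(sol$beta))
  solutions$factor <- c(htd = "htd", lact = "lactation", dimCl = "dim_class",
                        milkCl = "milk_class")[solutions$factor]
  list(solutions = solutions, random = sol$u, residuals = sol$residuals,
       varRatios = varRatios)
}

#' Fixed-effect solution profile of one factor
#'
#' Convenience accessor: solutions of `factor` from [fitPopulationModel()],
#' with the dropped reference level restored at 0.
#'
#' @param fit result of [fitPopulationModel()].
#' @param factor one of `"lactation"`, `"dim_class"`, `"milk_class"`.
#' @return data.frame `level`, `estimate`, ordered by level.
#' @export
solutionProfile <- function(fit, factor = c("lactation", "dim_class", "milk_class")) {
  factor <- match.arg(factor)
  s <- fit$solutions[fit$solutions$factor == factor, , drop = FALSE]
  out <- data.frame(level = as.integer(s$level), estimate = s$estimate)
  ref <- setdiff(seq_len(max(out$level)), out$level)
  if (length(ref))
    out <- rbind(data.frame(level = min(ref), estimate = 0), out)
  out[order(out$level), , drop = FALSE]
}

#' THI-binned average predictions
#'
#' Groups records by integer windowed THI and reports the mean combined
#' phenotype (and mean predicted temperature when present) with the bin
#' count; bins with fewer than `minBin` records are suppressed.
#'
#' @param records data.frame with `thi_td3d`, `combined` and optionally
#'   `pred_temp`.
#' @param minBin minimum records per reported bin (default 1000; use a
#'   smaller value for desk-scale synthetic runs).
#' @return data.frame `thi`, `n`, `mean_combined`, `mean_pred_temp`.
#' @export
thiBinnedMeans <- function(records, minBin = 1000L) {
  stopifnot(all(c("thi_td3d", "combined") %in% names(records)))
  sp <- split(seq_len(nrow(records)), records$thi_td3d)
  out <- data.frame(
    thi = as.integer(names(sp)),
    n = vapply(sp, length, integer(1)),
    mean_combined = vapply(sp, function(i) mean(records$combined[i]), numeric(1)),
    mean_pred_temp = if ("pred_temp" %in% names(records))
      vapply(sp, function(i) mean(records$pred_temp[i]), numeric(1)) else NA_real_,
    row.names = NULL)
  out <- out[out$n >= minBin, , drop = FALSE]
  out[order(out$thi), , drop = FALSE]
}
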