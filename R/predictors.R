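#' Cow-period grouped cross-validation folds
#'
#' The cross-validation unit is the cow-temperature period: every record of
#' a given (cow, period) pair shares one fold, so the same cow may appear
#' in calibration and validation only when associated with distinct
#' periods. Groups are randomly permuted with the given seed and dealt
#' round-robin into `k` folds, so fold sizes (in groups) differ by at most
#' one.
#'
#' @param records data.frame with columns `animal` and `period`.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the permutation.
#' @return the input with an added integer `fold` column.
#' @export
makeGroupFolds <- function(records, k = 5L, seed = 1L) {
  stopifnot(all(c("animal", "period") %in% names(records)))
  key <- paste(records$animal, records$period, sep = "\r")
  groups <- unique(key)
  if (length(groups) < k)
    stop(sprintf("only %d cow-period groups for %d folds", length(groups), k))
  set.seed(seed)
  perm <- sample(groups)
  foldOf <- stats::setNames(rep_len(seq_len(k), length(perm)), perm)
  records$fold <- as.integer(foldOf[key])
  records
}

#' Month heat-stress-risk dummy
#'
#' 1 for months with a risk of heat stress (April through September), 0
#' for months without (October through March).
#'
#' @param month integer month (1-12) or a Date vector.
#' @return integer 0/1 vector.
#' @export
monthRiskDummy <- function(month) {
  if (inherits(month, "Date")) month <- as.integer(format(month, "%m"))
  if (any(is.na(month)) || any(month < 1L) || any(month > 12L))
    stop("month must be 1..12")
  as.integer(month %in% 4:9)
}

# Fit one mixOmics PLS and return out-of-sample predictions for 1..ncomp.
.plsPredictGrid <- function(Xcal, ycal, Xval, ncomp) {
  fit <- mixOmics::pls(Xcal, ycal, ncomp = ncomp, mode = "regression",
                       scale = TRUE)
  pr <- predict(fit, Xval)$predict[, 1, , drop = FALSE]
  matrix(pr, nrow = nrow(Xval), ncol = ncomp)
}

#' Calibrate the PLS surface-temperature model
#'
#' Grouped 5-fold cross-validated partial-least-squares regression of
#' udder surface temperature on the preprocessed spectral features. Within
#' each fold the correlation pre-selection (|r| >= `threshold` with the
#' calibration temperatures) is re-run on the calibration portion only, so
#' no information leaks into validation. The cross-validation report gives
#' pooled out-of-fold R2cv (about the global mean of the observed
#' temperatures) and RMSEcv for 1..`maxComponents` latent variables; the
#' final model is refit on all records, with the pre-selection applied to
#' the full set, at the best (or user-pinned) component count.
#'
#' @param features samples x points matrix (from `spectraMatrix()` of a
#'   region-selected [SpectraSet-class]); rownames are sample ids.
#' @param temperature observed surface temperature per sample (degrees C).
#' @param folds integer fold assignment per sample (e.g. from
#'   [makeGroupFolds()]).
#' @param maxComponents largest latent-variable count tried (default 50).
#' @param threshold correlation pre-selection threshold (default 0.3).
#' @param ncomp optional pinned component count; skips the CV-based choice
#'   but still reports the CV curve.
#' @param preselectPerFold redo pre-selection inside each fold (default
#'   `TRUE`); `FALSE` reproduces the simpler once-globally variant.
#' @return a [PlsTemperatureModel-class] object.
#' @export
fitPlsTemperature <- function(features, temperature, folds,
                              maxComponents = 50L, threshold = 0.3,
                              ncomp = NULL, preselectPerFold = TRUE) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(temperature) == n, length(folds) == n)
  globalSel <- correlationPreselect(features, temperature, threshold)
  if (ncol(globalSel$X) < 1L)
    stop("no spectral point passes the correlation pre-selection")
  kf <- sort(unique(folds))
  # leakage guard: calibration and validation index sets must be disjoint
  preds <- matrix(NA_real_, n, maxComponents)
  maxUsable <- maxComponents
  for (f in kf) {
    val <- which(folds == f); cal <- which(folds != f)
    stopifnot(length(intersect(val, cal)) == 0L)
    sel <- if (preselectPerFold)
      correlationPreselect(features[cal, , drop = FALSE], temperature[cal],
                           threshold) else globalSel
    cols <- match(sprintf("pt_%04d", sel$points), colnames(features))
    nc <- min(maxComponents, length(cols), length(cal) - 1L)
    maxUsable <- min(maxUsable, nc)
    pg <- .plsPredictGrid(features[cal, cols, drop = FALSE], temperature[cal],
                          features[val, cols, drop = FALSE], nc)
    preds[val, seq_len(nc)] <- pg
  }
  ybar <- mean(temperature)
  sst <- sum((temperature - ybar)^2)
  report <- data.frame(ncomp = seq_len(maxUsable))
  report$rmsecv <- vapply(report$ncomp, function(c)
    sqrt(mean((preds[, c] - temperature)^2)), numeric(1))
  report$r2cv <- vapply(report$ncomp, function(c)
    1 - sum((preds[, c] - temperature)^2) / sst, numeric(1))
  best <- if (is.null(ncomp)) report$ncomp[which.max(report$r2cv)] else
    min(as.integer(ncomp), maxUsable)
  cols <- match(sprintf("pt_%04d", globalSel$points), colnames(features))
  finalNc <- min(best, length(cols), n - 1L)
  if (finalNc < best)
    warning(sprintf("component count capped at %d by the selected features", finalNc))
  fit <- mixOmics::pls(features[, cols, drop = FALSE], temperature,
                       ncomp = finalNc, mode = "regression", scale = TRUE)
  cvPred <- data.frame(
    sample_id = rownames(features) %||% as.character(seq_len(n)),
    fold = folds, observed = temperature, predicted = preds[, finalNc])
  methods::new("PlsTemperatureModel",
               selectedPoints = as.integer(globalSel$points),
               ncomp = as.integer(finalNc), fit = fit, cvReport = report,
               cvPredictions = cvPred, threshold = threshold)
}

#' Predict surface temperature from spectra
#'
#' Applies a calibrated [PlsTemperatureModel-class] to new spectral
#' features. Exactly the pre-selected calibration points are used; no
#' re-selection happens at prediction time.
#'
#' @param model a [PlsTemperatureModel-class].
#' @param features samples x points matrix containing at least the model's
#'   selected `pt_*` columns.
#' @return numeric vector of predicted temperatures (degrees C).
#' @export
predictTemperature <- function(model, features) {
  features <- as.matrix(features)
  cols <- match(sprintf("pt_%04d", model@selectedPoints), colnames(features))
  if (anyNA(cols))
    stop("features lack ", sum(is.na(cols)), " of the model's selected points")
  pr <- predict(model@fit, features[, cols, drop = FALSE])$predict
  as.numeric(pr[, 1, model@ncomp])
}

#' Calibrate the two-stage random-forest heat-stress classifier
#'
#' Classifies records into the three reference classes (X0 < X0.5 < X1)
#' from the spectral features plus the month-risk dummy. A first forest
#' ranks variables by impurity importance; the final forest uses the top
#' `nTopVariables` (the month dummy is force-included). Forest parameters
#' follow the ranger defaults used for this problem: 500 trees, mtry =
#' floor(sqrt(p)), minimal node size 1, Gini splitting. The out-of-fold
#' confusion report uses the supplied grouped folds, with the two-stage
#' selection redone inside each fold.
#'
#' @param features samples x points matrix; rownames are sample ids.
#' @param month integer month of recording per sample (for the risk dummy).
#' @param labels factor of reference classes per sample.
#' @param folds integer fold assignment per sample.
#' @param nTrees,nTopVariables,minNodeSize,mtry forest configuration;
#'   `mtry = NULL` uses floor(sqrt(p)) of the actual stage feature count.
#' @param includeMonthDummy force the month dummy into stage 2
#'   (default `TRUE`).
#' @param seed RNG seed passed to every forest.
#' @return an [RfClassModel-class] object.
#' @export
fitRfClassifier <- function(features, month, labels, folds, nTrees = 500L,
                            nTopVariables = 50L, minNodeSize = 1L,
                            mtry = NULL, includeMonthDummy = TRUE, seed = 1L) {
  features <- as.matrix(features)
  labels <- droplevels(factor(as.character(labels)))
  if (nlevels(labels) < 2L)
    stop("need >= 2 classes; class counts: ",
         paste(sprintf("%s=%d", levels(labels), table(labels)), collapse = ", "))
  n <- nrow(features)
  stopifnot(length(labels) == n, length(folds) == n, length(month) == n)
  df <- as.data.frame(features)
  if (includeMonthDummy) df$month_risk <- monthRiskDummy(month)
  mtryOf <- function(p) if (is.null(mtry)) max(1L, floor(sqrt(p))) else
    min(mtry, p)
  twoStage <- function(idx) {
    d <- df[idx, , drop = FALSE]; y <- droplevels(labels[idx])
    st1 <- ranger::ranger(x = d, y = y, num.trees = nTrees,
                          mtry = mtryOf(ncol(d)), min.node.size = minNodeSize,
                          splitrule = "gini", importance = "impurity",
                          seed = seed)
    imp <- sort(st1$variable.importance, decreasing = TRUE)
    spec <- setdiff(names(imp), "month_risk")
    keep <- utils::head(spec, min(nTopVariables, length(spec)))
    if (includeMonthDummy) keep <- c(keep, "month_risk")
    st2 <- ranger::ranger(x = d[, keep, drop = FALSE], y = y,
                          num.trees = nTrees, mtry = mtryOf(length(keep)),
                          min.node.size = minNodeSize, splitrule = "gini",
                          importance = "impurity", seed = seed)
    list(fit = st2, keep = keep, importance = imp)
  }
  oof <- factor(rep(NA_character_, n), levels = levels(labels))
  for (f in sort(unique(folds))) {
    val <- which(folds == f); cal <- which(folds != f)
    if (nlevels(droplevels(labels[cal])) < 2L)
      stop("a class is absent from the calibration portion of fold ", f)
    ts <- twoStage(cal)
    oof[val] <- predict(ts$fit, df[val, ts$keep, drop = FALSE])$predictions
  }
  confusion <- table(truth = labels, predicted = oof)
  accuracy <- mean(as.character(oof) == as.character(labels))
  classStats <- do.call(rbind, lapply(levels(labels), function(cl) {
    tp <- sum(labels == cl & oof == cl); fn <- sum(labels == cl & oof != cl)
    tn <- sum(labels != cl & oof != cl); fp <- sum(labels != cl & oof == cl)
    data.frame(class = cl, sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp))
  }))
  final <- twoStage(seq_len(n))
  methods::new("RfClassModel", fit = final$fit, topVariables = final$keep,
               importance = final$importance, confusion = confusion,
               accuracy = accuracy, classStats = classStats,
               config = list(nTrees = nTrees, nTopVariables = nTopVariables,
                             minNodeSize = minNodeSize, mtry = mtry,
                             includeMonthDummy = includeMonthDummy,
                             seed = seed),
               oofPredictions = data.frame(
                 sample_id = rownames(features) %||% as.character(seq_len(n)),
                 fold = folds, truth = labels, predicted = oof))
}

#' Predict heat-stress class from spectra
#'
#' @param model an [RfClassModel-class].
#' @param features samples x points matrix with the model's `pt_*` columns.
#' @param month integer month of recording per sample.
#' @return factor of predicted classes (levels X0, X0.5, X1).
#' @export
predictClass <- function(model, features, month) {
  df <- as.data.frame(as.matrix(features))
  if (model@config$includeMonthDummy) df$month_risk <- monthRiskDummy(month)
  missing <- setdiff(model@topVariables, names(df))
  if (length(missing))
    stop("features lack required variable(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  predict(model@fit, df[, model@topVariables, drop = FALSE])$predictions
}

#' Combine the two model predictions into one phenotype
#'
#' A record counts as affected (value 1) when its predicted surface
#' temperature is at least 36 degrees C and it is classified `X1`; as
#' partially affected (0.5) at >= 36 degrees C with class `X0.5`; all
#' other records are non-affected (0). The rule is monotone in both
#' inputs.
#'
#' @param predTemp predicted surface temperature (degrees C).
#' @param predClass predicted class (factor or character, X0/X0.5/X1).
#' @return numeric vector with values in \{0, 0.5, 1\}.
#' @export
combineHeatStress <- function(predTemp, predClass) {
  predClass <- as.character(predClass)
  ifelse(predTemp >= 36 & predClass == "X1", 1,
         ifelse(predTemp >= 36 & predClass == "X0.5", 0.5, 0))
}
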