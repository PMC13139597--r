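#' Per-farm thermoneutral temperature statistics
#'
#' Mean and sample SD (n - 1 convention) of the udder surface temperatures
#' recorded during each farm's thermoneutral visit; the within-farm
#' baseline against which heat-wave temperatures are judged.
#'
#' @param surface surface-temperature records (needs `farm`, `period`,
#'   `mean_temp`).
#' @return data.frame with `farm`, `mean`, `sd`, `n`; one row per farm.
#' @export
thermoneutralStats <- function(surface) {
  ctrl <- surface[surface$period == "thermoneutral", , drop = FALSE]
  if (!nrow(ctrl)) stop("no thermoneutral records")
  sp <- split(ctrl$mean_temp, ctrl$farm)
  bad <- names(sp)[vapply(sp, length, integer(1)) < 2L]
  if (length(bad))
    stop("fewer than 2 thermoneutral records for farm(s): ",
         paste(bad, collapse = ", "))
  data.frame(farm = names(sp),
             mean = unname(vapply(sp, mean, numeric(1))),
             sd = unname(vapply(sp, stats::sd, numeric(1))),
             n = unname(vapply(sp, length, integer(1))),
             row.names = NULL)
}

#' Classify heat-wave records into reference heat-stress classes
#'
#' Applies the reference rules to each heat-wave surface-temperature
#' record, using that farm's thermoneutral statistics and the cow's
#' standardized protein-\% and Mg residuals on the same test day:
#' \itemize{
#'   \item `X1` (affected): mean temperature above farm mean + 3 SD AND
#'     both residuals below -0.1;
#'   \item `X0` (non-affected): mean temperature below farm mean + 2 SD
#'     AND both residuals at or above -0.1;
#'   \item `X0.5` (intermediate): everything else, including every record
#'     whose temperature falls in the 2-3 SD gap.
#' }
#' All inequalities are strict, so exact threshold hits fall to `X0.5`.
#'
#' @param heatRecords heat-wave surface records with columns `animal`,
#'   `farm`, `mean_temp` plus `r_protein`, `r_mg` (standardized residuals).
#' @param stats per-farm statistics from [thermoneutralStats()].
#' @return the input with an added ordered factor `class`
#'   (`X0 < X0.5 < X1`).
#' @export
classifyReference <- function(heatRecords, stats) {
  stopifnot(all(c("farm", "mean_temp", "r_protein", "r_mg") %in% names(heatRecords)))
  i <- match(heatRecords$farm, stats$farm)
  if (anyNA(i))
    stop("no thermoneutral statistics for farm(s): ",
         paste(unique(heatRecords$farm[is.na(i)]), collapse = ", "))
  m <- stats$mean[i]; s <- stats$sd[i]
  hot <- heatRecords$mean_temp > m + 3 * s
  cool <- heatRecords$mean_temp < m + 2 * s
  depressed <- heatRecords$r_protein < -0.1 & heatRecords$r_mg < -0.1
  normal <- heatRecords$r_protein >= -0.1 & heatRecords$r_mg >= -0.1
  cls <- ifelse(hot & depressed, "X1", ifelse(cool & normal, "X0", "X0.5"))
  heatRecords$class <- factor(cls, levels = c("X0", "X0.5", "X1"), ordered = TRUE)
  heatRecords
}

#' Control eligibility for training-set augmentation
#'
#' A historical record can augment the non-affected (`X0`) class only when
#' it was recorded outside the summer months (June, July, August excluded)
#' and its windowed THI is strictly below 60, the minimal heat-stress
#' threshold.
#'
#' @param month integer month of recording (1-12).
#' @param thi_td3d integer windowed THI.
#' @return logical vector.
#' @export
controlEligible <- function(month, thi_td3d) {
  !(month %in% 6:8) & thi_td3d < 60
}

#' Assemble the balanced reference training set
#'
#' Combines all rule-based `X1` records, the rule-based `X0` records
#' topped up with `nExtraControls` seeded uniform draws (without
#' replacement) from the eligible historical pool, and a seeded uniform
#' sample of `nIntermediate` intermediate records labelled `X0.5`.
#'
#' @param classified heat-wave records with `sample_id` and `class` from
#'   [classifyReference()].
#' @param eligiblePool data.frame of eligible historical records (needs
#'   `sample_id`), e.g. filtered with [controlEligible()].
#' @param nExtraControls number of augmented controls (default: top up
#'   `X0` to the size of `X1`).
#' @param nIntermediate intermediate sample size (default `|X1|`).
#' @param seed RNG seed for the two draws.
#' @return data.frame `sample_id`, `class`, `provenance` (rule|augmented).
#' @export
assembleTrainingSet <- function(classified, eligiblePool,
                                nExtraControls = NULL, nIntermediate = NULL,
                                seed = 1L) {
  stopifnot(all(c("sample_id", "class") %in% names(classified)))
  x1 <- classified[classified$class == "X1", , drop = FALSE]
  x0 <- classified[classified$class == "X0", , drop = FALSE]
  mid <- classified[classified$class == "X0.5", , drop = FALSE]
  if (!nrow(x1)) stop("no records classified X1; cannot assemble a training set")
  if (is.null(nExtraControls)) nExtraControls <- max(0L, nrow(x1) - nrow(x0))
  if (is.null(nIntermediate)) nIntermediate <- min(nrow(x1), nrow(mid))
  if (nExtraControls > nrow(eligiblePool))
    stop(sprintf("eligible pool (%d) smaller than requested controls (%d)",
                 nrow(eligiblePool), nExtraControls))
  set.seed(seed)
  extra <- if (nExtraControls > 0)
    eligiblePool$sample_id[sample.int(nrow(eligiblePool), nExtraControls)] else
    character(0)
  midSel <- if (nIntermediate > 0)
    mid$sample_id[sample.int(nrow(mid), nIntermediate)] else character(0)
  out <- rbind(
    data.frame(sample_id = x1$sample_id, class = "X1", provenance = "rule"),
    data.frame(sample_id = x0$sample_id, class = "X0", provenance = "rule"),
    if (length(extra)) data.frame(sample_id = extra, class = "X0",
                                  provenance = "augmented"),
    if (length(midSel)) data.frame(sample_id = midSel, class = "X0.5",
                                   provenance = "rule"))
  out$class <- factor(out$class, levels = c("X0", "X0.5", "X1"), ordered = TRUE)
  rownames(out) <- NULL
  out
}
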