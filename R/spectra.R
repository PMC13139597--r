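#' Wavenumber axis of the standardized 1,060-point grid
#'
#' Derives a linear wavenumber label for each original spectral point,
#' anchored at point 12 = 968.09 cm^-1 and point 170 = 1,577.49 cm^-1 (the
#' boundaries of the first informative region). Wavenumbers are reporting
#' labels only; all selection logic works on point numbers.
#'
#' @param points integer vector of 1-based point numbers (default all 1,060).
#' @return numeric vector of wavenumbers in cm^-1.
#' @export
#' @examples
#' wavenumberAxis(c(12, 170, 530))
wavenumberAxis <- function(points = 1:1060) {
  step <- (1577.49 - 968.09) / 158
  968.09 + (points - 12) * step
}

#' Default informative-region mask (212 points)
#'
#' The spectral regions retained after derivation, by original point
#' number: 12-170, 210-218, 223-230 and 495-530 (968.09-1,577.49,
#' 1,731.76-1,762.62, 1,781.90-1,808.90 and 2,830.99-2,965.98 cm^-1).
#' These 212 points carry the low-noise milk absorbance signal.
#'
#' @return strictly increasing integer vector of 212 point numbers.
#' @export
defaultRegionMask <- function() {
  as.integer(c(12:170, 210:218, 223:230, 495:530))
}

#' Gap first derivative of spectra
#'
#' Applies the gap-5 first derivative: at each point i the derivative is
#' the absorbance at i - 2 minus the absorbance at i + 2 (for the default
#' gap of 5, i.e. offsets of +/-2). A 1,060-point spectrum yields 1,056
#' derivative values spanning points 3..1,058. The operator is linear in
#' the spectra.
#'
#' @param x a [SpectraSet-class] at stage `"raw"`, or a numeric matrix /
#'   vector of raw absorbances (1,060 points).
#' @param gap odd integer gap width, >= 3 (default 5).
#' @return object of the same kind at stage `"derivative"`.
#' @export
firstDerivative <- function(x, gap = 5L) {
  gap <- as.integer(gap)
  if (gap < 3L || gap %% 2L == 0L) stop("gap must be an odd integer >= 3")
  h <- (gap - 1L) %/% 2L
  deriv <- function(m) {
    n <- nrow(m)
    m[seq_len(n - 2L * h), , drop = FALSE] - m[seq_len(n - 2L * h) + 2L * h, , drop = FALSE]
  }
  if (methods::is(x, "SpectraSet")) {
    if (!identical(spectraStage(x), "raw"))
      stop("firstDerivative expects raw spectra; got stage '", spectraStage(x), "'")
    if (nrow(x) != 1060L)
      stop(sprintf("expected 1,060 spectral points, got %d", nrow(x)))
    a <- assay(x, "absorbance")
    d <- deriv(a)
    pts <- pointNumbers(x)[seq_len(nrow(d)) + h]
    return(SpectraSet(d, sampleIds = colnames(a), points = pts,
                      stage = "derivative", samplesInRows = FALSE,
                      colData = colData(x)))
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  if (nrow(m) == 1060L) {
    d <- deriv(m)
  } else if (ncol(m) == 1060L) {
    d <- t(deriv(t(m)))
  } else {
    stop(sprintf("expected 1,060 spectral points, got %d x %d", nrow(m), ncol(m)))
  }
  if (vec) drop(d) else d
}

#' Select informative spectral regions
#'
#' Keeps the derivative values at the masked original point numbers, in
#' increasing point order. With the default mask exactly 212 values remain
#' per spectrum.
#'
#' @param x a [SpectraSet-class] at stage `"derivative"`.
#' @param mask strictly increasing integer point numbers, all within
#'   the derivative support of `x` (3..1,058 for the default gap).
#' @return a [SpectraSet-class] at stage `"selected"`.
#' @export
selectRegions <- function(x, mask = defaultRegionMask()) {
  stopifnot(methods::is(x, "SpectraSet"))
  if (identical(spectraStage(x), "raw"))
    stop("selectRegions expects derivative spectra; apply firstDerivative() first")
  mask <- as.integer(mask)
  if (is.unsorted(mask, strictly = TRUE)) stop("mask must be strictly increasing")
  pts <- pointNumbers(x)
  missing <- setdiff(mask, pts)
  if (length(missing))
    stop("mask point(s) outside the derivative range: ",
         paste(utils::head(missing, 10), collapse = ", "))
  out <- x[match(mask, pts), ]
  metadata(out)$stage <- "selected"
  out
}

#' Correlation-threshold variable pre-selection
#'
#' Keeps the spectral columns whose absolute Pearson correlation with the
#' target is at least `threshold`. Zero-variance columns (undefined
#' correlation) are dropped. The selected point list is returned so that
#' prediction uses exactly the calibration-time columns.
#'
#' @param X samples x points numeric matrix with `pt_*` column names (as
#'   from `spectraMatrix()` of a selected [SpectraSet-class]).
#' @param y numeric target (e.g. udder surface temperature), one per row.
#' @param threshold minimum |r| to keep a column (default 0.3).
#' @return list with `X` (reduced matrix), `points` (selected original
#'   point numbers) and `r` (the correlations of the kept columns).
#' @export
correlationPreselect <- function(X, y, threshold = 0.3) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 samples for correlation pre-selection")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (stats::sd(y) == 0) stop("target has zero variance; correlations undefined")
  sds <- apply(X, 2, stats::sd)
  r <- rep(NA_real_, ncol(X))
  ok <- sds > 0
  r[ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], y))
  keep <- ok & abs(r) >= threshold
  pts <- pointsFromLabels(colnames(X))
  list(X = X[, keep, drop = FALSE], points = pts[keep], r = r[keep])
}

pointsFromLabels <- function(labels) {
  if (is.null(labels)) return(NA_integer_)
  as.integer(sub("^pt_0*([0-9]+).*$", "\\1", labels))
}
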