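#' Protein amounts from an albumin standard curve
#'
#' Fits an ordinary least-squares line (absorbance ~ micrograms) through
#' the BSA standards and inverse-predicts the protein amount of each
#' sample absorbance.
#'
#' @param absorbances Sample absorbances.
#' @param standards A data.frame with columns \code{ug} and
#'   \code{absorbance}; at least two distinct standard amounts.
#' @return Numeric vector of protein amounts (micrograms BSA-equivalent).
#' @export
proteinFromStandardCurve <- function(absorbances, standards) {
  if (!all(c("ug", "absorbance") %in% names(standards)))
    stop("standards must have columns 'ug' and 'absorbance'")
  if (length(unique(standards$ug)) < 2L)
    stop("at least two distinct standard amounts are required")
  fit <- lm(absorbance ~ ug, data = standards)
  slope <- coef(fit)[["ug"]]
  if (!is.finite(slope) || slope == 0)
    stop("degenerate standard curve (zero slope)")
  (absorbances - coef(fit)[["(Intercept)"]]) / slope
}

#' Bulk reporter expression per microgram protein
#'
#' @param luminescence Luciferase luminescence (arbitrary units).
#' @param protein Total protein in micrograms BSA-equivalent (positive).
#' @return Luminescence per microgram, elementwise.
#' @export
bulkExpression <- function(luminescence, protein) {
  if (any(protein <= 0)) stop("protein amounts must be positive")
  luminescence / protein
}

#' Background fluorescence of a flow-cytometry sample
#'
#' A reporter sample is spiked with CFSE-marked cells of the promoter-only
#' line as an internal standard; unstained-Luciferase PUER cells calibrate
#' nonspecific staining. The sample's background is estimated as
#' \deqn{b_{sample} = f_{PUER} \cdot f_{samples} / f_{PUERs}}
#' where \eqn{f_{PUER}} is the median fluorescence of the Luciferase-free
#' cells, \eqn{f_{samples}} that of the internal standard spiked into the
#' sample, and \eqn{f_{PUERs}} that of the standard spiked with the
#' Luciferase-free cells.
#'
#' @param fPUER Median fluorescence of Luciferase-negative PUER cells.
#' @param fSamples Median fluorescence of the internal standard in the
#'   sample tube.
#' @param fPUERs Median fluorescence of the internal standard in the PUER
#'   tube (positive).
#' @return The background estimate b_sample.
#' @export
flowBackground <- function(fPUER, fSamples, fPUERs) {
  if (any(fPUERs <= 0)) stop("fPUERs must be positive")
  fPUER * fSamples / fPUERs
}

#' Single-cell reporter expression in internal-standard units
#'
#' Background-subtracted sample fluorescence divided by the
#' background-subtracted internal standard:
#' \deqn{L_{sample} = (f_{sample} - b_{sample}) / (f_{samples} - b_{sample})}
#' so pure background maps to 0 and the standard itself (undifferentiated
#' promoter-line expression) to 1. The same \eqn{b_{sample}} is subtracted
#' in numerator and denominator.
#'
#' @param fSample Median stained-Luciferase fluorescence of the sample.
#' @inheritParams flowBackground
#' @return Expression L_sample in units of undifferentiated promoter
#'   expression.
#' @export
flowExpression <- function(fSample, fSamples, fPUER, fPUERs) {
  b <- flowBackground(fPUER, fSamples, fPUERs)
  denom <- fSamples - b
  if (any(denom == 0))
    stop("internal standard equals background; expression undefined")
  (fSample - b) / denom
}

#' Enhancer fold change over the promoter-only reporter
#'
#' Pointwise ratio of an enhancer-bearing reporter's expression series to
#' the promoter-only series at matched timepoints — the measure of enhancer
#' activity.
#'
#' @param crm,promoter Data.frames with columns \code{time} and
#'   \code{value}, identical \code{time} vectors.
#' @return A data.frame (\code{time}, \code{value}) of fold changes;
#'   \code{NA} where the promoter value is 0.
#' @export
foldChange <- function(crm, promoter) {
  for (d in list(crm, promoter))
    if (!all(c("time", "value") %in% names(d)))
      stop("series must have columns 'time' and 'value'")
  if (!isTRUE(all.equal(crm$time, promoter$time)))
    stop("timepoints must match between the two series")
  v <- ifelse(promoter$value == 0, NA_real_, crm$value / promoter$value)
  if (any(promoter$value == 0))
    warning("promoter value 0 at some timepoints; fold change undefined there")
  data.frame(time = crm$time, value = v)
}

#' Normalize a series to its value in undifferentiated cells
#'
#' Divides a series by its value at the reference timepoint
#' (undifferentiated cells: 0 h in IL3 conditions, -48 h in GCSF
#' conditions, i.e. the moment of induction or the start of pretreatment),
#' so the reference maps to exactly 1.
#'
#' @param series A data.frame with columns \code{time} and \code{value}.
#' @param referenceTime The timepoint to normalize to.
#' @return The normalized series.
#' @export
normalizeToReference <- function(series, referenceTime) {
  i <- which(series$time == referenceTime)
  if (length(i) != 1L) stop("reference timepoint absent (or duplicated)")
  if (series$value[i] == 0) stop("reference value is 0; cannot normalize")
  data.frame(time = series$time, value = series$value / series$value[i])
}
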