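#' Interquartile-range outlier filter for technical replicates
#'
#' Removes values outside the Tukey fences
#' [Q1 - 1.5 IQR, Q3 + 1.5 IQR], with quartiles by linear interpolation
#' between order statistics (quantile type 7). With fewer than three values
#' the input is passed through unchanged with a warning. The alternative
#' reading of "outside 1.5 times the IQR" — |x - median| > 1.5 IQR — is
#' available via \code{method = "median"}.
#'
#' @param x Numeric values (e.g. per-replicate delta-Cq).
#' @param k Fence multiplier (default 1.5).
#' @param method \code{"tukey"} (default) or \code{"median"}.
#' @return The kept values, with a logical attribute \code{"kept"} marking
#'   each input value.
#' @export
iqrFilter <- function(x, k = 1.5, method = c("tukey", "median")) {
  method <- match.arg(method)
  if (length(x) < 3L) {
    warning("fewer than 3 replicates; outlier filter skipped")
    kept <- rep(TRUE, length(x))
  } else {
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    kept <- if (method == "tukey")
      x >= q[1] - k * iqr & x <= q[2] + k * iqr
    else abs(x - median(x)) <= k * iqr
  }
  out <- x[kept]
  attr(out, "kept") <- kept
  out
}

#' Delta-Cq accessibility relative to a loading control
#'
#' Location-specific ATAC-qPCR quantifies Tn5-generated fragments at one
#' genomic location; the quantification cycle difference to an internal
#' loading control (a region whose accessibility is stable, here a
#' promoter) converts to relative accessibility as 2^-delta-Cq. Technical
#' replicates are outlier-filtered on their per-replicate delta-Cq (target
#' Cq minus the sample's mean control Cq) before averaging; control
#' replicates are filtered on their own Cq.
#'
#' @param enhancerCqs Technical-replicate Cq values of the target location.
#' @param promoterCqs Technical-replicate Cq values of the loading control.
#' @param filter Apply \code{\link{iqrFilter}} to both groups first.
#' @param ... Passed to \code{\link{iqrFilter}}.
#' @return A list of class \code{"deltaCq"}: \code{deltaCq}, \code{fold}
#'   (= 2^-deltaCq), \code{keptEnhancer}, \code{keptPromoter}.
#' @export
deltaCq <- function(enhancerCqs, promoterCqs, filter = TRUE, ...) {
  if (!length(enhancerCqs) || !length(promoterCqs))
    stop("both Cq groups must be non-empty")
  if (any(c(enhancerCqs, promoterCqs) <= 0)) stop("Cq values must be positive")
  if (filter) {
    # per-replicate delta-Cq against the sample's mean control Cq; the
    # constant offset leaves the fences' verdict identical to filtering the
    # raw target Cqs
    dper <- enhancerCqs - mean(promoterCqs)
    keptE <- attr(iqrFilter(dper, ...), "kept")
    keptP <- attr(iqrFilter(promoterCqs, ...), "kept")
  } else {
    keptE <- rep(TRUE, length(enhancerCqs))
    keptP <- rep(TRUE, length(promoterCqs))
  }
  if (!any(keptE) || !any(keptP))
    stop("no replicates left after outlier filtering")
  d <- mean(enhancerCqs[keptE]) - mean(promoterCqs[keptP])
  structure(list(deltaCq = d, fold = 2^(-d),
                 keptEnhancer = keptE, keptPromoter = keptP),
            class = "deltaCq")
}

#' @export
print.deltaCq <- function(x, ...) {
  cat(sprintf("deltaCq: %.4f (fold 2^-dCq = %.4f); kept %d/%d target, %d/%d control replicates\n",
              x$deltaCq, x$fold, sum(x$keptEnhancer), length(x$keptEnhancer),
              sum(x$keptPromoter), length(x$keptPromoter)))
  invisible(x)
}

#' Accessibility ratio between two genomic copies over time
#'
#' Compares the delta-Cq series of a relocated (e.g. ROSA26 knock-in) copy
#' of an element with the endogenous copy at matched timepoints:
#' delta-delta-Cq = deltaCq_relocated - deltaCq_endogenous, converted to an
#' accessibility ratio 2^-ddCq. Each copy's fold series is additionally
#' normalized to its initial timepoint, so parallel dynamics show as a flat
#' ratio and overlapping normalized series.
#'
#' @param relocated,endogenous Data.frames with columns \code{time} and
#'   \code{deltaCq} at identical timepoints.
#' @return A data.frame per timepoint: \code{time}, \code{ddCq},
#'   \code{ratio} (2^-ddCq), \code{relocatedRel}, \code{endogenousRel}
#'   (each copy's 2^-deltaCq normalized to its first timepoint).
#' @export
locationRatioSeries <- function(relocated, endogenous) {
  for (d in list(relocated, endogenous))
    if (!all(c("time", "deltaCq") %in% names(d)))
      stop("series must have columns 'time' and 'deltaCq'")
  if (!isTRUE(all.equal(relocated$time, endogenous$time)))
    stop("timepoints must match between the two series")
  dd <- relocated$deltaCq - endogenous$deltaCq
  foldR <- 2^(-relocated$deltaCq)
  foldE <- 2^(-endogenous$deltaCq)
  data.frame(time = relocated$time, ddCq = dd, ratio = 2^(-dd),
             relocatedRel = foldR / foldR[1],
             endogenousRel = foldE / foldE[1])
}
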