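#' @import methods
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom Rsamtools BamFile
#' @importFrom stats dpois quantile lm coef wilcox.test cor sd median setNames
#' @importFrom utils write.table read.table
#' @importFrom tools md5sum
NULL

.PROFILE_STATES <- c("raw", "normalized", "pooled", "corrected")

#' CutProfile: per-nucleotide Tn5 cut counts over a genomic interval
#'
#' Container for the per-position Tn5 cut counts of one sample (or a pool of
#' samples) over a contiguous interval. Counts are integers in the \code{raw}
#' and \code{pooled} states and reals after library-size normalization or bias
#' correction. \code{librarySize} is the total number of retained cuts of the
#' sample genome-wide, not just inside the interval; it is the denominator of
#' cuts-per-million normalization and the numerator of the Poisson background
#' rate used by the gated bias correction.
#'
#' @slot contig Reference sequence name.
#' @slot start 1-based start coordinate of the interval.
#' @slot counts Numeric vector, one value per position.
#' @slot librarySize Total retained cuts genome-wide for the sample.
#' @slot state One of \code{"raw"}, \code{"normalized"}, \code{"pooled"},
#'   \code{"corrected"}.
#' @slot sampleId Sample identifier.
#' @slot metadata Free-form list (condition, timepoint, normalization scale,
#'   correction method, ...).
#' @exportClass CutProfile
setClass("CutProfile",
  representation(
    contig = "character",
    start = "integer",
    counts = "numeric",
    librarySize = "numeric",
    state = "character",
    sampleId = "character",
    metadata = "list"
  ),
  prototype(
    contig = "chr", start = 1L, counts = numeric(0), librarySize = 0,
    state = "raw", sampleId = "sample", metadata = list()
  )
)

setValidity("CutProfile", function(object) {
  msgs <- character(0)
  if (length(object@state) != 1L || !object@state %in% .PROFILE_STATES)
    msgs <- c(msgs, sprintf("state must be one of %s",
                            paste(.PROFILE_STATES, collapse = ", ")))
  if (any(!is.finite(object@counts)))
    msgs <- c(msgs, "counts must be finite")
  if (any(object@counts < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (length(object@state) == 1L && object@state %in% c("raw", "pooled") &&
      length(object@counts) &&
      any(abs(object@counts - round(object@counts)) > 1e-8))
    msgs <- c(msgs, "raw/pooled counts must be integers")
  if (length(object@librarySize) != 1L || object@librarySize < 0)
    msgs <- c(msgs, "librarySize must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CutProfile", function(object) {
  cat(sprintf("CutProfile [%s] %s:%d-%d (%d bp)\n",
              object@state, object@contig, object@start,
              object@start + length(object@counts) - 1L,
              length(object@counts)))
  cat(sprintf("  sample: %s | library size: %g | total in interval: %g\n",
              object@sampleId, object@librarySize, sum(object@counts)))
})

#' Construct a CutProfile
#'
#' @param counts Numeric vector of per-position cut counts.
#' @param contig Reference sequence name.
#' @param start 1-based start position of the interval.
#' @param librarySize Genome-wide total of retained cuts for the sample;
#'   defaults to \code{sum(counts)} (appropriate when the profile spans the
#'   whole reference, as for synthetic genomes).
#' @param state Profile state, \code{"raw"} by default.
#' @param sampleId Sample identifier.
#' @param metadata Optional list of sample annotations.
#' @return A \linkS4class{CutProfile}.
#' @export
CutProfile <- function(counts, contig = "chr", start = 1L,
                       librarySize = sum(counts), state = "raw",
                       sampleId = "sample", metadata = list()) {
  new("CutProfile", contig = as.character(contig), start = as.integer(start),
      counts = as.numeric(counts), librarySize = as.numeric(librarySize),
      state = state, sampleId = as.character(sampleId), metadata = metadata)
}

#' @describeIn CutProfile-accessors Per-position cut counts.
#' @export
cutCounts <- function(x) x@counts

#' Accessors for CutProfile slots
#'
#' @name CutProfile-accessors
#' @param x A \linkS4class{CutProfile}.
#' @return The corresponding slot value.
NULL

#' @describeIn CutProfile-accessors Genome-wide library size.
#' @export
librarySize <- function(x) x@librarySize

#' @describeIn CutProfile-accessors Profile state.
#' @export
profileState <- function(x) x@state

#' @describeIn CutProfile-accessors 1-based genomic positions of the profile.
#' @export
profilePositions <- function(x) seq(x@start, length.out = length(x@counts))

#' @describeIn CutProfile-accessors Contig name.
#' @export
profileContig <- function(x) x@contig

#' @describeIn CutProfile-accessors Sample identifier.
#' @export
sampleId <- function(x) x@sampleId

setMethod("length", "CutProfile", function(x) length(x@counts))

#' BiasTable: hexamer-level Tn5 cutting preference
#'
#' Maps each of the 4096 DNA hexamers w to a cutting-preference ratio
#' b(w) = pc(w) / p(w), the ratio of the hexamer's share of observed
#' naked-DNA Tn5 cuts to its share of genomic positions. A uniform table
#' (b = 1 everywhere) encodes no sequence preference. Hexamers absent from
#' the genome have no defined bias and are carried as NA with their names
#' recorded in \code{metadata$missing}; corrections treat NA as 1.
#'
#' @slot bias Named numeric vector, one entry per hexamer (4096 names).
#' @slot freqCuts Observed cut frequency pc(w) per hexamer (NA if unknown).
#' @slot freqGenome Genomic frequency p(w) per hexamer (NA if unknown).
#' @slot metadata Provenance list (source profile ids, genome, hexamer
#'   registration offset).
#' @exportClass BiasTable
setClass("BiasTable",
  representation(
    bias = "numeric",
    freqCuts = "numeric",
    freqGenome = "numeric",
    metadata = "list"
  )
)

setValidity("BiasTable", function(object) {
  msgs <- character(0)
  hx <- allHexamers()
  if (length(object@bias) != 4096L || !identical(sort(names(object@bias)), hx))
    msgs <- c(msgs, "bias must be a named vector over all 4096 hexamers")
  ok <- !is.na(object@bias)
  if (any(object@bias[ok] <= 0))
    msgs <- c(msgs, "bias values must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BiasTable", function(object) {
  ok <- !is.na(object@bias)
  cat(sprintf("BiasTable: 4096 hexamers (%d with defined bias)\n", sum(ok)))
  cat(sprintf("  b(w) range: %.4g - %.4g | uniform: %s\n",
              min(object@bias[ok]), max(object@bias[ok]),
              all(abs(object@bias[ok] - 1) < 1e-12)))
})

#' All DNA hexamers in lexicographic order
#'
#' @return Character vector of the 4096 hexamers over A/C/G/T.
#' @export
allHexamers <- function() {
  sort(Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6))
}

#' Construct a BiasTable
#'
#' @param bias Named numeric vector of preferences. Hexamers not named
#'   receive 1 (no preference), so \code{BiasTable()} is the uniform table.
#' @param freqCuts,freqGenome Optional per-hexamer cut and genomic
#'   frequencies (populated by \code{\link{estimateBias}}).
#' @param metadata Provenance list.
#' @return A \linkS4class{BiasTable}.
#' @export
BiasTable <- function(bias = numeric(0), freqCuts = NULL, freqGenome = NULL,
                      metadata = list()) {
  hx <- allHexamers()
  b <- rep(1, 4096L)
  names(b) <- hx
  if (length(bias)) {
    if (is.null(names(bias)) || !all(names(bias) %in% hx))
      stop("bias must be named by valid hexamers")
    b[names(bias)] <- bias
  }
  filled <- function(v) {
    if (is.null(v)) { v <- rep(NA_real_, 4096L); names(v) <- hx; v }
    else v[hx]
  }
  new("BiasTable", bias = b, freqCuts = filled(freqCuts),
      freqGenome = filled(freqGenome), metadata = metadata)
}

#' @describeIn BiasTable Bias values b(w), optionally for specific hexamers.
#' @param x A \linkS4class{BiasTable}.
#' @param hexamers Optional character vector of hexamers to look up.
#' @export
biasValues <- function(x, hexamers = NULL) {
  if (is.null(hexamers)) x@bias else unname(x@bias[hexamers])
}

#' AccessibilityLandscape: per-position transposition propensity
#'
#' The generator-side truth of a synthetic experiment: a non-negative
#' relative transposition propensity per position, with the planted
#' protected regions (footprints) and their depletion factors recorded.
#'
#' @slot propensity Non-negative numeric, one value per genome position.
#' @slot footprints \linkS4class{IRanges} of planted footprints.
#' @slot depletion Depletion factor in [0,1] per footprint (0 = fully
#'   protected).
#' @slot baseline Baseline propensity outside footprints.
#' @exportClass AccessibilityLandscape
setClass("AccessibilityLandscape",
  representation(
    propensity = "numeric",
    footprints = "IRanges",
    depletion = "numeric",
    baseline = "numeric"
  )
)

setValidity("AccessibilityLandscape", function(object) {
  msgs <- character(0)
  if (any(object@propensity < 0)) msgs <- c(msgs, "propensity must be >= 0")
  if (length(object@footprints) != length(object@depletion))
    msgs <- c(msgs, "one depletion factor per footprint required")
  if (length(object@depletion) &&
      (any(object@depletion < 0) || any(object@depletion > 1)))
    msgs <- c(msgs, "depletion factors must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AccessibilityLandscape", function(object) {
  cat(sprintf("AccessibilityLandscape: %d bp, baseline %g, %d planted footprint(s)\n",
              length(object@propensity), object@baseline,
              length(object@footprints)))
})

#' FragmentSet: simulated Tn5 transposition events and their read pairs
#'
#' Each transposition event is recorded by the 1-based position of the
#' central (5th) nucleotide of the 9 bp Tn5 overhang. The emitted read pair
#' places the + strand 5' end 4 bp left and the - strand 5' end 4 bp right
#' of the event, so the two 5' ends are always exactly 8 bp apart and the
#' downstream +4/-4 shift maps both back onto the event position.
#'
#' @slot events 1-based event center positions.
#' @slot plusStarts 5' (leftmost) coordinates of the + strand reads.
#' @slot minusStarts 5' (rightmost) coordinates of the - strand reads.
#' @slot contig Reference name.
#' @slot sampleId Sample identifier.
#' @slot librarySize Number of read pairs.
#' @exportClass FragmentSet
setClass("FragmentSet",
  representation(
    events = "integer",
    plusStarts = "integer",
    minusStarts = "integer",
    contig = "character",
    sampleId = "character",
    librarySize = "integer"
  )
)

setValidity("FragmentSet", function(object) {
  msgs <- character(0)
  n <- length(object@events)
  if (length(object@plusStarts) != n || length(object@minusStarts) != n)
    msgs <- c(msgs, "events, plusStarts and minusStarts must be parallel")
  if (n && any(object@minusStarts - object@plusStarts != 8L))
    msgs <- c(msgs, "read-pair 5' ends must be exactly 8 bp apart")
  if (object@librarySize != n)
    msgs <- c(msgs, "librarySize must equal the number of read pairs")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf("FragmentSet: %d transposition event(s) on %s (sample %s)\n",
              length(object@events), object@contig, object@sampleId))
})

setMethod("length", "FragmentSet", function(x) length(x@events))

#' @describeIn FragmentSet True event center positions (1-based).
#' @param x A \linkS4class{FragmentSet}.
#' @export
eventPositions <- function(x) x@events

#' BinSeries: per-bin accessibility summaries across samples
#'
#' A regulatory element divided into near-equal contiguous bins, with the
#' mean accessibility of each bin in each sample (typically ordered
#' timepoints). Bin widths differ by at most 1 bp; when the region length is
#' not divisible by the number of bins, the leading bins are 1 bp wider.
#'
#' @slot region Named list with contig, start, end of the binned region.
#' @slot bins \linkS4class{IRanges} of the bin boundaries.
#' @slot means Matrix of bin means, bins x samples.
#' @exportClass BinSeries
setClass("BinSeries",
  representation(region = "list", bins = "IRanges", means = "matrix")
)

setValidity("BinSeries", function(object) {
  msgs <- character(0)
  if (nrow(object@means) != length(object@bins))
    msgs <- c(msgs, "one row of means per bin required")
  w <- IRanges::width(object@bins)
  if (length(w) && diff(range(w)) > 1L)
    msgs <- c(msgs, "bin widths must differ by at most 1 bp")
  if (length(object@bins) > 1L &&
      any(IRanges::start(object@bins)[-1] !=
          IRanges::end(object@bins)[-length(object@bins)] + 1L))
    msgs <- c(msgs, "bins must tile the region contiguously")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BinSeries", function(object) {
  cat(sprintf("BinSeries: %s:%d-%d in %d bins x %d sample(s)\n",
              object@region$contig, object@region$start, object@region$end,
              length(object@bins), ncol(object@means)))
})

#' @describeIn BinSeries Bin boundaries as an IRanges.
#' @param x A \linkS4class{BinSeries}.
#' @export
binRanges <- function(x) x@bins

#' @describeIn BinSeries Matrix of per-bin, per-sample mean accessibility.
#' @export
binMeans <- function(x) x@means
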