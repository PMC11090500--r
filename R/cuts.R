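#' Count Tn5 cuts at single-nucleotide resolution
#'
#' Converts aligned paired-end reads into a per-nucleotide cut profile. Each
#' retained read is counted as one Tn5 cut at its shifted 5' end: + strand
#' reads at (5' start + 4), - strand reads at (5' end - 4), both 1-based.
#' Because Tn5 duplicates 9 bp at the insertion site, the two mates of one
#' transposition event start 8 bp apart and this +4/-4 shift places both
#' cuts on the same base, the central (5th) nucleotide of the overhang. The
#' often-used +4/-5 shift instead assigns the mates to two adjacent
#' positions; it is available through \code{minusShift = -5} for comparison.
#'
#' For BAM input, retained reads are properly paired, mapped, primary,
#' non-supplementary, non-duplicate records passing quality control, and
#' \code{librarySize} is the genome-wide number of such reads (one cut
#' each). For a \linkS4class{FragmentSet} the stored read-pair coordinates
#' are used directly.
#'
#' @param x An indexed BAM path / \code{BamFile}, or a
#'   \linkS4class{FragmentSet}.
#' @param contig Contig of the target interval.
#' @param start,end 1-based closed interval to profile.
#' @param minusShift Shift applied to - strand 5' ends (default \code{-4};
#'   \code{-5} reproduces the conventional shift for comparison).
#' @param librarySize Optional genome-wide retained-cut total; computed from
#'   the input when \code{NULL}.
#' @param sampleId Sample identifier for the profile.
#' @param metadata Optional annotation list.
#' @param ... Passed to methods.
#' @return A raw-state \linkS4class{CutProfile} over the interval.
#' @export
setGeneric("countCuts", function(x, contig, start, end, ...)
  standardGeneric("countCuts"))

.bamFilterFlags <- function() {
  Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                         isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isNotPassingQualityControls = FALSE,
                         isDuplicate = FALSE,
                         isSupplementaryAlignment = FALSE)
}

#' @rdname countCuts
setMethod("countCuts", "character", function(x, contig, start, end,
                                             minusShift = -4L,
                                             librarySize = NULL,
                                             sampleId = basename(x),
                                             metadata = list()) {
  countCuts(Rsamtools::BamFile(x), contig, start, end,
            minusShift = minusShift, librarySize = librarySize,
            sampleId = sampleId, metadata = metadata)
})

#' @rdname countCuts
setMethod("countCuts", "BamFile", function(x, contig, start, end,
                                           minusShift = -4L,
                                           librarySize = NULL,
                                           sampleId = basename(Rsamtools::path(x)),
                                           metadata = list()) {
  if (end < start) stop("invalid interval: end < start")
  sl <- Rsamtools::scanBamHeader(x)$targets
  if (!contig %in% names(sl))
    stop(sprintf("contig '%s' absent from the BAM header", contig))
  if (start < 1L || end > sl[[contig]])
    stop("interval falls off the contig")
  flags <- .bamFilterFlags()
  pad <- 8L
  which <- GenomicRanges::GRanges(contig, IRanges::IRanges(
    max(1L, start - pad), min(sl[[contig]], end + pad)))
  aln <- GenomicAlignments::readGAlignments(
    x, param = Rsamtools::ScanBamParam(flag = flags, which = which))
  st <- as.character(GenomicAlignments::strand(aln))
  cut <- ifelse(st == "+",
                GenomicAlignments::start(aln) + 4L,
                GenomicAlignments::end(aln) + as.integer(minusShift))
  cut <- cut[cut >= start & cut <= end]
  counts <- tabulate(cut - start + 1L, nbins = end - start + 1L)
  if (is.null(librarySize))
    librarySize <- Rsamtools::countBam(
      x, param = Rsamtools::ScanBamParam(flag = flags))$records
  CutProfile(counts, contig = contig, start = start,
             librarySize = librarySize, state = "raw", sampleId = sampleId,
             metadata = c(metadata, list(minusShift = as.integer(minusShift))))
})

#' @rdname countCuts
setMethod("countCuts", "FragmentSet", function(x, contig, start,
                                               end, minusShift = -4L,
                                               librarySize = NULL,
                                               sampleId = x@sampleId,
                                               metadata = list()) {
  if (missing(contig)) contig <- x@contig
  if (end < start) stop("invalid interval: end < start")
  cut <- c(x@plusStarts + 4L, x@minusStarts + as.integer(minusShift))
  if (is.null(librarySize)) librarySize <- 2L * length(x@events)
  cut <- cut[cut >= start & cut <= end]
  counts <- tabulate(cut - start + 1L, nbins = end - start + 1L)
  CutProfile(counts, contig = contig, start = start,
             librarySize = librarySize, state = "raw", sampleId = sampleId,
             metadata = c(metadata, list(minusShift = as.integer(minusShift))))
})

#' Library-size normalization of a cut profile
#'
#' Divides raw counts by the sample's genome-wide library size and
#' multiplies by \code{scale}; the default scale of 1e6 yields
#' cuts-per-million. Pooled profiles may be normalized by their pooled
#' library size.
#'
#' @param profile A raw or pooled \linkS4class{CutProfile}.
#' @param scale Normalization scale (default cuts-per-million).
#' @return A normalized-state \linkS4class{CutProfile}; the scale is
#'   recorded in the metadata.
#' @export
normalizeLibrary <- function(profile, scale = 1e6) {
  if (!profile@state %in% c("raw", "pooled"))
    stop("only raw or pooled profiles can be library-normalized")
  if (profile@librarySize <= 0)
    stop("librarySize must be positive for normalization")
  out <- profile
  out@counts <- profile@counts * (scale / profile@librarySize)
  out@state <- "normalized"
  out@metadata$normScale <- scale
  out
}

#' Pool raw profiles by positionwise summation
#'
#' @param profiles List of raw \linkS4class{CutProfile}s on identical
#'   intervals.
#' @return A pooled \linkS4class{CutProfile} whose counts and library size
#'   are the sums of the inputs'.
#' @export
poolProfiles <- function(profiles) {
  if (!length(profiles)) stop("cannot pool an empty list of profiles")
  ref <- profiles[[1]]
  for (p in profiles) {
    if (p@state != "raw") stop("only raw profiles can be pooled")
    if (p@contig != ref@contig || p@start != ref@start ||
        length(p@counts) != length(ref@counts))
      stop("profiles must cover identical intervals")
  }
  counts <- Reduce(`+`, lapply(profiles, cutCounts))
  CutProfile(counts, contig = ref@contig, start = ref@start,
             librarySize = sum(vapply(profiles, librarySize, numeric(1))),
             state = "pooled", sampleId = "pooled",
             metadata = list(pooledFrom = vapply(profiles, sampleId,
                                                 character(1))))
}

# Truncated-window centered moving average via cumulative sums.
.truncatedWindowMean <- function(y, half) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Sliding-window average of a cut profile
#'
#' Centered moving average with an odd window; positions near the interval
#' edges use the truncated (shrinking) window. Used at 100 bp for locus
#' overviews, 10 bp for inter-sample correlation and 3 bp for
#' single-nucleotide profile display.
#'
#' @param profile A \linkS4class{CutProfile}.
#' @param window Odd window width in bp.
#' @return A \linkS4class{CutProfile} with smoothed counts (state
#'   unchanged, smoothing recorded in metadata).
#' @export
slidingMean <- function(profile, window) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window > length(profile@counts))
    stop("window exceeds the interval length")
  out <- profile
  out@counts <- .truncatedWindowMean(profile@counts, (window - 1L) %/% 2L)
  out@metadata$slidingWindow <- as.integer(window)
  out
}

#' Pearson correlation between two window-averaged profiles
#'
#' @param a,b \linkS4class{CutProfile}s on identical intervals.
#' @param window Odd sliding-window width applied to both before
#'   correlating (1 = no smoothing).
#' @return Pearson r, or \code{NA} with a warning when either smoothed
#'   profile has zero variance.
#' @export
pearsonBetween <- function(a, b, window = 1L) {
  if (a@contig != b@contig || a@start != b@start ||
      length(a@counts) != length(b@counts))
    stop("profiles must cover identical intervals")
  xa <- cutCounts(slidingMean(a, window))
  xb <- cutCounts(slidingMean(b, window))
  if (sd(xa) == 0 || sd(xb) == 0) {
    warning("zero variance in a profile; correlation undefined")
    return(NA_real_)
  }
  cor(xa, xb, method = "pearson")
}

#' Total accessibility of an interval
#'
#' Sum of cuts over a regulatory element; the element-level accessibility
#' statistic used for dynamics comparisons. An empty interval
#' (\code{end < start}) sums to 0.
#'
#' @param profile A \linkS4class{CutProfile}.
#' @param start,end 1-based closed subinterval (default: whole profile).
#' @return The sum of counts over the interval.
#' @export
totalAccessibility <- function(profile, start = NULL, end = NULL) {
  if (is.null(start)) start <- profile@start
  if (is.null(end)) end <- profile@start + length(profile@counts) - 1L
  if (end < start) return(0)
  lo <- start - profile@start + 1L
  hi <- end - profile@start + 1L
  if (lo < 1L || hi > length(profile@counts))
    stop("interval falls outside the profile")
  sum(profile@counts[lo:hi])
}

#' Mean coverage in cuts per nucleotide
#'
#' @param profile A \linkS4class{CutProfile}.
#' @param start,end 1-based closed interval (default: whole profile); must
#'   be non-empty.
#' @return Total accessibility divided by the interval length.
#' @examples
#' # a 642 bp element carrying 39,691 pooled cuts has ~62 cuts/nt coverage
#' p <- CutProfile(c(39691, rep(0, 641)))
#' coveragePerNt(p)
#' @export
coveragePerNt <- function(profile, start = NULL, end = NULL) {
  if (is.null(start)) start <- profile@start
  if (is.null(end)) end <- profile@start + length(profile@counts) - 1L
  len <- end - start + 1L
  if (len <= 0L) stop("coverage is undefined on an empty interval")
  totalAccessibility(profile, start, end) / len
}

#' Write a cut profile as bedGraph
#'
#' Adjacent positions with equal counts are run-length merged; zero runs
#' are omitted.
#'
#' @param profile A \linkS4class{CutProfile}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeBedGraph <- function(profile, path) {
  r <- S4Vectors::Rle(profile@counts)
  ends <- cumsum(S4Vectors::runLength(r))
  starts <- ends - S4Vectors::runLength(r) + 1L
  keep <- S4Vectors::runValue(r) != 0
  gr <- GenomicRanges::GRanges(
    profile@contig,
    IRanges::IRanges(profile@start + starts[keep] - 1L,
                     profile@start + ends[keep] - 1L),
    score = S4Vectors::runValue(r)[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
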