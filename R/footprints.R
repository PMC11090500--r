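#' Call protected regions (TF footprints) on a pooled cut profile
#'
#' A protected region is a maximal run of consecutive positions whose cut
#' count is strictly below the threshold T, of length between
#' \code{minLen} and \code{maxLen} bp, immediately bordered on both sides
#' by positions with strictly more than T cuts. Such high-low-high
#' accessibility patterns indicate a bound transcription factor shielding
#' DNA from Tn5. A position with exactly T cuts neither belongs to a run
#' nor qualifies as a border, so it terminates and disqualifies a run. Runs
#' touching the interval edges have no border and are discarded. Calling is
#' intended for raw pooled counts, since thresholds are absolute cut counts
#' (e.g. 400 for a promoter, 100/40/200 for individual enhancers at very
#' deep pooled coverage).
#'
#' @param pooled A raw or pooled \linkS4class{CutProfile}.
#' @param threshold T, in cuts.
#' @param minLen,maxLen Admissible run length in bp (defaults 5 and 50).
#' @return A \code{GRanges} of called regions sorted by start, with
#'   metadata columns \code{leftBorder}, \code{rightBorder} (positions),
#'   \code{leftCount}, \code{rightCount}, \code{maxInternal} and
#'   \code{score} (the larger border count).
#' @export
callProtectedRegions <- function(pooled, threshold, minLen = 5L,
                                 maxLen = 50L) {
  if (threshold <= 0) stop("threshold must be positive")
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  y <- pooled@counts
  n <- length(y)
  empty <- GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    leftBorder = integer(0), rightBorder = integer(0),
    leftCount = numeric(0), rightCount = numeric(0),
    maxInternal = numeric(0), score = numeric(0))
  if (n < minLen + 2L) {
    warning("profile too short to contain a bordered protected region")
    return(empty)
  }
  r <- rle(y < threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= minLen & r$lengths <= maxLen &
                starts > 1L & ends < n)
  if (!length(cand)) return(empty)
  ls <- starts[cand]; le <- ends[cand]
  leftOk <- y[ls - 1L] > threshold
  rightOk <- y[le + 1L] > threshold
  keep <- leftOk & rightOk
  ls <- ls[keep]; le <- le[keep]
  if (!length(ls)) return(empty)
  off <- pooled@start - 1L
  maxInt <- vapply(seq_along(ls), function(i) max(y[ls[i]:le[i]]),
                   numeric(1))
  GenomicRanges::GRanges(
    pooled@contig, IRanges::IRanges(ls + off, le + off),
    leftBorder = ls + off - 1L, rightBorder = le + off + 1L,
    leftCount = y[ls - 1L], rightCount = y[le + 1L],
    maxInternal = maxInt, score = pmax(y[ls - 1L], y[le + 1L]))
}

#' Summarize accessibility dynamics in uniform bins
#'
#' Divides a region into \code{nBins} near-equal contiguous bins (when the
#' length is not divisible, the leading bins are 1 bp wider) and reports the
#' mean accessibility of each bin in each sample. Feeding the ordered
#' timepoints of a differentiation course yields the per-bin accessibility
#' time series used to localize which part of an enhancer responds.
#'
#' @param profiles List of \linkS4class{CutProfile}s (typically
#'   library-normalized, one per timepoint) on identical intervals covering
#'   the region.
#' @param start,end 1-based closed region to bin (default: whole profile).
#' @param nBins Number of bins (>= 1, <= region length).
#' @return A \linkS4class{BinSeries}.
#' @export
binRegion <- function(profiles, start = NULL, end = NULL, nBins) {
  if (!length(profiles)) stop("at least one profile required")
  ref <- profiles[[1]]
  for (p in profiles)
    if (p@contig != ref@contig || p@start != ref@start ||
        length(p@counts) != length(ref@counts))
      stop("profiles must cover identical intervals")
  if (is.null(start)) start <- ref@start
  if (is.null(end)) end <- ref@start + length(ref@counts) - 1L
  len <- end - start + 1L
  if (nBins < 1L) stop("nBins must be >= 1")
  if (nBins > len) stop("more bins than positions in the region")
  base <- len %/% nBins
  widths <- rep(base, nBins) + c(rep(1L, len %% nBins),
                                 rep(0L, nBins - len %% nBins))
  binEnd <- start - 1L + cumsum(widths)
  binStart <- binEnd - widths + 1L
  bins <- IRanges::IRanges(binStart, binEnd)
  means <- vapply(profiles, function(p) {
    idx <- rep.int(seq_len(nBins), widths)
    y <- p@counts[(start - p@start + 1L):(end - p@start + 1L)]
    as.numeric(rowsum(y, idx) / widths)
  }, numeric(nBins))
  means <- matrix(means, nrow = nBins)
  colnames(means) <- vapply(profiles, sampleId, character(1))
  new("BinSeries",
      region = list(contig = ref@contig, start = as.integer(start),
                    end = as.integer(end)),
      bins = bins, means = means)
}

#' Accessibility change near binding sites vs the remainder
#'
#' For each pair of consecutive timepoints, compares the mean absolute
#' change in accessibility over the positions within \code{flank} bp of any
#' site against the mean absolute change over the remainder of the region.
#' A ratio well above 1 indicates that accessibility dynamics concentrate
#' at the sites, the signature of changing TF occupancy (Tn5 accesses the
#' nucleotides immediately bordering a bound factor more readily when the
#' factor is present).
#'
#' @param profilesByTime Ordered list of \linkS4class{CutProfile}s
#'   (consecutive timepoints) on identical intervals.
#' @param sites \code{IRanges} of binding-site intervals (1-based genomic
#'   coordinates).
#' @param flank Flank width in bp added to each side of each site
#'   (default 5).
#' @return A data.frame with one row per consecutive pair: \code{from},
#'   \code{to}, \code{siteMean}, \code{remainderMean}, \code{ratio}
#'   (\code{NA} with a warning where the remainder change is zero).
#' @export
siteAdjacentChange <- function(profilesByTime, sites, flank = 5L) {
  if (length(profilesByTime) < 2L)
    stop("at least two timepoints are required")
  ref <- profilesByTime[[1]]
  n <- length(ref@counts)
  for (p in profilesByTime)
    if (p@contig != ref@contig || p@start != ref@start ||
        length(p@counts) != n)
      stop("profiles must cover identical intervals")
  if (!length(sites)) stop("at least one site required")
  pos <- profilePositions(ref)
  if (min(IRanges::start(sites)) < ref@start || max(IRanges::end(sites)) > max(pos))
    stop("sites must lie within the profiled region")
  grown <- IRanges::restrict(
    IRanges::IRanges(IRanges::start(sites) - flank,
                     IRanges::end(sites) + flank),
    start = ref@start, end = max(pos))
  inSite <- !is.na(IRanges::findOverlaps(
    IRanges::IRanges(pos, pos), grown, select = "first"))
  if (all(inSite))
    stop("sites plus flanks cover the whole region; remainder is empty")
  out <- lapply(seq_len(length(profilesByTime) - 1L), function(k) {
    d <- abs(cutCounts(profilesByTime[[k + 1L]]) -
             cutCounts(profilesByTime[[k]]))
    sMean <- mean(d[inSite])
    rMean <- mean(d[!inSite])
    ratio <- if (rMean == 0) {
      warning("zero accessibility change in the remainder; ratio undefined")
      NA_real_
    } else sMean / rMean
    data.frame(from = sampleId(profilesByTime[[k]]),
               to = sampleId(profilesByTime[[k + 1L]]),
               siteMean = sMean, remainderMean = rMean, ratio = ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare in-site vs out-of-site accessibility
#'
#' Wilcoxon rank-sum test on per-nucleotide cut counts inside validated
#' binding sites versus the remaining positions of the element. Protected
#' (bound) sites are expected to carry significantly fewer cuts.
#'
#' @param pooled A \linkS4class{CutProfile}.
#' @param sites \code{IRanges} of binding-site intervals.
#' @param alternative \code{"two.sided"} (default), \code{"less"} (in-site
#'   lower) or \code{"greater"}.
#' @param exact Whether to use the exact null distribution; by default
#'   (\code{NULL}) the exact distribution is used for small tie-free
#'   samples.
#' @return An \code{htest} object from \code{\link[stats]{wilcox.test}}.
#' @export
compareInOutSites <- function(pooled, sites, alternative = "two.sided",
                              exact = NULL) {
  if (!length(sites)) stop("at least one site required")
  pos <- profilePositions(pooled)
  inSite <- !is.na(IRanges::findOverlaps(
    IRanges::IRanges(pos, pos), sites, select = "first"))
  if (!any(inSite) || all(inSite))
    stop("both in-site and out-of-site positions are required")
  wilcox.test(pooled@counts[inSite], pooled@counts[!inSite],
              alternative = alternative, exact = exact)
}

#' Overlap of called footprints with known binding sites
#'
#' @param regions \code{GRanges} of called protected regions.
#' @param known \code{GRanges} of known binding sites (same contig).
#' @return A data.frame with one row per known site (\code{start},
#'   \code{end}, \code{overlaps}) and the overall overlapping fraction as
#'   attribute \code{"fraction"}.
#' @export
overlapKnownSites <- function(regions, known) {
  hit <- GenomicRanges::countOverlaps(known, regions) > 0L
  df <- data.frame(start = GenomicRanges::start(known),
                   end = GenomicRanges::end(known), overlaps = hit)
  attr(df, "fraction") <- if (length(hit)) mean(hit) else NA_real_
  df
}
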