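#' Generate a random synthetic genome
#'
#' Draws an i.i.d. nucleotide sequence with a target GC fraction. The
#' sequence stands in for a reference contig so that the cut-counting, bias
#' and footprint stages can be exercised with full ground truth.
#'
#' @param length Genome length in bp (>= 6, the hexamer width).
#' @param gcFraction Target GC content in [0, 1].
#' @param seed Integer seed; the same seed regenerates the identical
#'   sequence.
#' @return A \code{DNAString} of the requested length.
#' @examples
#' g <- generateGenome(1000, 0.42, seed = 1)
#' Biostrings::letterFrequency(g, "GC")
#' @export
generateGenome <- function(length, gcFraction = 0.5, seed = 1L) {
  if (length < 6) stop("genome length must be at least 6 bp")
  if (gcFraction < 0 || gcFraction > 1) stop("gcFraction must lie in [0, 1]")
  withSeed(seed, {
    p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
           G = gcFraction / 2, T = (1 - gcFraction) / 2)
    Biostrings::DNAString(paste(
      sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
  })
}

#' Plant an accessibility landscape with protected regions
#'
#' Builds the per-position transposition propensity of a synthetic
#' experiment: a constant baseline, reduced inside each planted footprint by
#' its depletion factor (0 = fully protected, exactly zero propensity).
#' Planted footprints emulate the 5-50 bp protected regions the footprint
#' caller must recover.
#'
#' @param genome A \code{DNAString} (or anything with a length).
#' @param footprints \code{IRanges} of footprint intervals (1-based,
#'   closed), non-overlapping and within the genome.
#' @param depletion Numeric vector in [0,1], one factor per footprint
#'   (recycled if length 1).
#' @param baseline Baseline propensity outside footprints.
#' @return An \linkS4class{AccessibilityLandscape}.
#' @export
plantLandscape <- function(genome, footprints = IRanges::IRanges(),
                           depletion = 0, baseline = 1) {
  L <- length(genome)
  if (length(footprints)) {
    depletion <- rep_len(depletion, length(footprints))
    if (min(IRanges::start(footprints)) < 1L ||
        max(IRanges::end(footprints)) > L)
      stop("footprint intervals must lie within the genome")
    if (!IRanges::isDisjoint(footprints))
      stop("footprint intervals must not overlap")
  } else depletion <- numeric(0)
  propensity <- rep(as.numeric(baseline), L)
  for (i in seq_along(footprints)) {
    idx <- IRanges::start(footprints)[i]:IRanges::end(footprints)[i]
    propensity[idx] <- baseline * depletion[i]
  }
  new("AccessibilityLandscape", propensity = propensity,
      footprints = footprints, depletion = as.numeric(depletion),
      baseline = as.numeric(baseline))
}

# Positions where both the hexamer window [p-3, p+2] and the read-pair 5'
# ends at p +/- 4 fit inside the genome; events are only drawn there.
.usablePositions <- function(L) {
  if (L < 9L) integer(0) else 5:(L - 4L)
}

#' Simulate Tn5 transposition events
#'
#' Draws \code{nEvents} transposition events with per-position probability
#' proportional to landscape propensity times the bias-model preference of
#' the local hexamer (the reference-strand hexamer on the window centered at
#' the event, shared with \code{\link{estimateBias}}). Each event at
#' position p emits one properly-paired read pair whose + strand 5' end is
#' at p - 4 and whose - strand 5' end is at p + 4, reflecting the 9 bp 5'
#' overhang Tn5 duplicates: the downstream +4/-4 shift maps both mates back
#' onto p. Positions whose hexamer window would leave the genome have zero
#' probability.
#'
#' @param genome A \code{DNAString}.
#' @param landscape An \linkS4class{AccessibilityLandscape} over the genome
#'   (default: uniform).
#' @param bias A \linkS4class{BiasTable} of generator-side hexamer
#'   preferences (default: uniform).
#' @param nEvents Number of transposition events to draw.
#' @param seed Integer seed.
#' @param contig Contig name recorded in the output.
#' @param sampleId Sample identifier.
#' @return A \linkS4class{FragmentSet}.
#' @export
simulateFragments <- function(genome, landscape = NULL, bias = NULL,
                              nEvents, seed = 1L, contig = "synth1",
                              sampleId = "sample") {
  if (nEvents < 0) stop("nEvents must be >= 0")
  L <- length(genome)
  if (is.null(landscape)) landscape <- plantLandscape(genome)
  if (length(landscape@propensity) != L)
    stop("landscape does not match the genome length")
  if (is.null(bias)) bias <- BiasTable()
  usable <- .usablePositions(L)
  prob <- numeric(L)
  prob[usable] <- landscape@propensity[usable]
  if (any(prob > 0)) {
    hex <- hexamerAt(genome, usable)
    bfac <- biasValues(bias, hex)
    bfac[is.na(bfac)] <- 1
    prob[usable] <- prob[usable] * bfac
  }
  if (nEvents > 0 && all(prob == 0))
    stop("no position has positive transposition probability")
  ev <- if (nEvents == 0) integer(0) else withSeed(seed, {
    sort(sample.int(L, nEvents, replace = TRUE, prob = prob))
  })
  new("FragmentSet", events = as.integer(ev),
      plusStarts = as.integer(ev - 4L), minusStarts = as.integer(ev + 4L),
      contig = contig, sampleId = sampleId,
      librarySize = length(ev))
}

#' Write simulated read pairs as SAM
#'
#' Emits a properly-paired SAM file in which each pair's 5' ends equal the
#' stored read-pair coordinates (+ strand POS = event - 4; - strand
#' rightmost aligned base = event + 4, both 1-based). Reads are clipped at
#' the genome edges so the 5' ends are always preserved. MAPQ is fixed at
#' 60; flags mark proper pairing. Use \code{\link[Rsamtools]{asBam}} to
#' obtain an indexed BAM for \code{\link{countCuts}}.
#'
#' @param fragments A \linkS4class{FragmentSet}.
#' @param genome The \code{DNAString} the fragments were simulated from
#'   (used for read sequences and the SAM header length).
#' @param path Output SAM path.
#' @param readLength Nominal read length in bp.
#' @return Invisibly, \code{path}.
#' @export
writeAlignments <- function(fragments, genome, path, readLength = 50L) {
  L <- length(genome)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", fragments@contig, L)), con)
  n <- length(fragments@events)
  if (n == 0L) return(invisible(path))
  gstr <- as.character(genome)
  plusStart <- fragments@plusStarts
  minusEnd <- fragments@minusStarts          # rightmost aligned base
  plusEnd <- pmin(plusStart + readLength - 1L, L)
  minusStart <- pmax(minusEnd - readLength + 1L, 1L)
  if (any(plusStart < 1L) || any(minusEnd > L))
    stop("read 5' ends fall outside the genome")
  plusLen <- plusEnd - plusStart + 1L
  minusLen <- minusEnd - minusStart + 1L
  tlen <- pmax(plusEnd, minusEnd) - pmin(plusStart, minusStart) + 1L
  qname <- sprintf("frag%06d", seq_len(n))
  plusSeq <- substring(gstr, plusStart, plusEnd)
  minusSeq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substring(gstr, minusStart, minusEnd))))
  rec1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                  qname, fragments@contig, plusStart, plusLen, minusStart,
                  tlen, plusSeq)
  rec2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                  qname, fragments@contig, minusStart, minusLen, plusStart,
                  -tlen, minusSeq)
  writeLines(as.vector(rbind(rec1, rec2)), con)
  invisible(path)
}

#' Write the synthetic genome as FASTA
#'
#' @param genome A \code{DNAString}.
#' @param path Output FASTA path.
#' @param contig Sequence name.
#' @return Invisibly, \code{path}.
#' @export
writeGenomeFasta <- function(genome, path, contig = "synth1") {
  s <- Biostrings::DNAStringSet(genome)
  names(s) <- contig
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write planted footprint truth as BED
#'
#' @param landscape An \linkS4class{AccessibilityLandscape}.
#' @param path Output BED path.
#' @param contig Contig name.
#' @return Invisibly, \code{path}.
#' @export
writeTruthBed <- function(landscape, path, contig = "synth1") {
  fp <- landscape@footprints
  gr <- GenomicRanges::GRanges(contig, fp)
  if (length(gr)) {
    S4Vectors::mcols(gr)$name <- sprintf("footprint%02d", seq_along(gr))
    S4Vectors::mcols(gr)$score <- landscape@depletion
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Evaluate expr under a local, restorable RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
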