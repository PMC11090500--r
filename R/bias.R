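#' Reference-strand hexamer at cut positions
#'
#' The hexamer w(i) assigned to a cut at position i is the reference-strand
#' sequence of the window [i-3, i+2] (1-based closed), so the cut falls on
#' the 4th base. This registration is shared between the fragment simulator,
#' the bias estimator and all three correctors; cuts on both strands are
#' attributed to the reference-strand hexamer because positions are already
#' strand-merged by the +4/-4 shift.
#'
#' @param genome A \code{DNAString} (or character scalar).
#' @param positions 1-based positions; those whose window leaves the genome
#'   yield \code{NA}.
#' @return Character vector of hexamers (NA where undefined or containing
#'   non-ACGT letters).
#' @export
hexamerAt <- function(genome, positions) {
  L <- length(genome)
  gstr <- as.character(genome)
  ok <- positions >= 4L & positions <= L - 2L
  out <- rep(NA_character_, length(positions))
  if (any(ok))
    out[ok] <- substring(gstr, positions[ok] - 3L, positions[ok] + 2L)
  out[!is.na(out) & grepl("[^ACGT]", out)] <- NA_character_
  out
}

#' Estimate the Tn5 hexamer cutting bias from naked-DNA cuts
#'
#' Computes, for every hexamer w, the cutting preference
#' b(w) = pc(w) / p(w): the fraction of observed naked-DNA Tn5 cuts whose
#' local hexamer is w, divided by the fraction of genomic hexamer windows
#' that are w. With cuts distributed uniformly over all positions carrying a
#' hexamer, b is identically 1. Several naked-DNA profiles may be merged
#' beforehand with \code{\link{poolProfiles}}.
#'
#' @param profile A raw or pooled \linkS4class{CutProfile} spanning the
#'   genome the bias is estimated on.
#' @param genome The \code{DNAString} underlying the profile.
#' @return A \linkS4class{BiasTable} with pc, p and b populated. Hexamers
#'   absent from the genome carry NA bias and are listed in
#'   \code{metadata$missing}.
#' @export
estimateBias <- function(profile, genome) {
  if (!profile@state %in% c("raw", "pooled"))
    stop("bias estimation requires raw (or pooled raw) counts")
  if (length(profile@counts) != length(genome) || profile@start != 1L)
    stop("profile must span the genome used for hexamer lookup")
  total <- sum(profile@counts)
  if (total == 0) stop("cannot estimate bias from zero total cuts")
  hx <- allHexamers()
  # genomic hexamer frequencies over all L-5 windows
  gcount <- Biostrings::oligonucleotideFrequency(genome, width = 6)[hx]
  p <- gcount / sum(gcount)
  # observed cut frequencies; cuts at positions without a full window are
  # dropped from the numerator (and counted)
  pos <- which(profile@counts > 0)
  hex <- hexamerAt(genome, pos)
  usable <- !is.na(hex)
  ccount <- rowsum(profile@counts[pos][usable], hex[usable])
  cuts <- rep(0, length(hx))
  names(cuts) <- hx
  cuts[rownames(ccount)] <- ccount[, 1]
  pc <- cuts / sum(cuts)
  if (any(pc > 0 & p == 0))
    stop("cuts observed at hexamers absent from the genome")
  b <- ifelse(p > 0, pc / p, NA_real_)
  b[!is.na(b) & b == 0] <- NA_real_  # unobserved hexamers: no defined ratio
  missing <- hx[is.na(b)]
  names(b) <- names(pc) <- names(p) <- hx
  new("BiasTable", bias = b, freqCuts = pc, freqGenome = p,
      metadata = list(
        source = profile@sampleId,
        totalCuts = total,
        cutsWithHexamer = sum(cuts),
        missing = missing,
        registration = "reference-strand window [i-3, i+2] around cut i"))
}

# b(w(i)) along a profile; NA (edge / unknown hexamer / undefined bias)
# becomes 1, i.e. those positions are left uncorrected.
.positionBias <- function(profile, bias, genome) {
  pos <- profilePositions(profile)
  b <- biasValues(bias, hexamerAt(genome, pos))
  b[is.na(b)] <- 1
  b
}

#' HINT-ATAC-style windowed bias correction
#'
#' Corrects cuts with a factor built from a 50 bp window: the corrected
#' count at position i is
#' \deqn{x_i = (y_i + 1) / (\hat y_i \hat b(w(i)) + 1)}
#' where \eqn{\hat y_i} is the mean of the observed cuts over the window
#' [i-25, i+24] and \eqn{\hat b(w(i))} is the bias at i divided by the
#' summed bias over the same window. At the profile edges the window
#' truncates and \eqn{\hat b} renormalizes over the truncated window. Note
#' the documented artifact of this scheme: a position with no cuts maps to
#' \eqn{1/(\hat y_i \hat b + 1) > 0}, so an all-zero profile becomes an
#' all-ones profile.
#'
#' By default the formula is applied exactly as printed, with
#' \eqn{\hat y_i} a window \emph{mean} multiplying a window-\emph{relative}
#' bias. \code{expectedCuts = TRUE} uses the window total instead of the
#' mean (so the denominator is the expected cuts at i under the window's
#' bias composition plus one), an alternative reading differing by a factor
#' of the window width.
#'
#' @param profile A raw or normalized \linkS4class{CutProfile}.
#' @param bias A \linkS4class{BiasTable}.
#' @param genome The underlying \code{DNAString}.
#' @param window Window width in bp (50 by default).
#' @param expectedCuts Use window-total rather than window-mean cuts.
#' @return A corrected-state \linkS4class{CutProfile}.
#' @export
correctHint <- function(profile, bias, genome, window = 50L,
                        expectedCuts = FALSE) {
  if (!profile@state %in% c("raw", "normalized", "pooled"))
    stop("profile must be raw, pooled or normalized")
  y <- profile@counts
  n <- length(y)
  half <- window %/% 2L                       # [i-25, i+24] for window 50
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half - 1L, n)
  csY <- c(0, cumsum(y))
  ySum <- csY[hi + 1L] - csY[lo]
  width <- hi - lo + 1L
  yhat <- if (expectedCuts) ySum else ySum / width
  b <- .positionBias(profile, bias, genome)
  csB <- c(0, cumsum(b))
  bWindow <- csB[hi + 1L] - csB[lo]
  bhat <- b / bWindow
  out <- profile
  out@counts <- (y + 1) / (yhat * bhat + 1)
  out@state <- "corrected"
  out@metadata$correction <- if (expectedCuts) "hint-expected" else "hint"
  out
}

#' Direct per-nucleotide bias division (BaGFoot-style)
#'
#' The corrected count is simply \eqn{x_i = y_i / b(w(i))}. No averaging is
#' involved, so single-nucleotide structure is preserved, at the cost of
#' amplifying noise at low-count positions (a count of 1 on a strongly
#' avoided hexamer can explode).
#'
#' @inheritParams correctHint
#' @return A corrected-state \linkS4class{CutProfile}.
#' @export
correctBagfoot <- function(profile, bias, genome) {
  if (!profile@state %in% c("raw", "normalized", "pooled"))
    stop("profile must be raw, pooled or normalized")
  b <- .positionBias(profile, bias, genome)
  out <- profile
  out@counts <- profile@counts / b
  out@state <- "corrected"
  out@metadata$correction <- "bagfoot"
  out
}

#' Poisson-gated per-nucleotide bias correction
#'
#' Divides the count at position i by the hexamer bias, but only where the
#' observed count is inconsistent with the genome-wide background: position
#' i is corrected when the Poisson probability mass
#' \eqn{P(y_i; \lambda) = \lambda^{y_i} e^{-\lambda} / y_i!} falls below
#' \eqn{\alpha / G} (a Bonferroni correction over the G positions of the
#' genome), with \eqn{\lambda} the mean cuts per position across the
#' genome. Positions at or below background are left untouched, so noise at
#' low-accessibility nucleotides is not amplified and protected regions are
#' preserved, while accessible positions are corrected at single-nucleotide
#' resolution. The mass is evaluated in log space.
#'
#' @inheritParams correctHint
#' @param genomeSize G, the genome size in bp (the Bonferroni divisor and
#'   the default denominator of \eqn{\lambda}).
#' @param alpha Familywise level (default 0.01).
#' @param lambda Background rate; defaults to
#'   \code{librarySize(profile) / genomeSize}.
#' @return A corrected-state \linkS4class{CutProfile}; the gate parameters
#'   are recorded in the metadata.
#' @export
correctPoissonGated <- function(profile, bias, genome, genomeSize,
                                alpha = 0.01, lambda = NULL) {
  if (profile@state != "raw" && profile@state != "pooled")
    stop("the Poisson gate operates on raw (or pooled raw) counts")
  if (is.null(lambda)) lambda <- profile@librarySize / genomeSize
  if (!is.finite(lambda) || lambda <= 0)
    stop("lambda must be positive; provide librarySize or lambda")
  y <- profile@counts
  logThresh <- log(alpha) - log(genomeSize)
  gate <- dpois(round(y), lambda, log = TRUE) < logThresh
  b <- .positionBias(profile, bias, genome)
  out <- profile
  out@counts <- ifelse(gate, y / b, y)
  out@state <- "corrected"
  out@metadata$correction <- "poisson-gated"
  out@metadata$gate <- list(lambda = lambda, genomeSize = genomeSize,
                            alpha = alpha)
  out
}

#' Minimal corrected count under the Poisson gate
#'
#' For a background rate below 1 cut per position the Poisson mass is
#' strictly decreasing in the count, so the gate reduces to a simple
#' threshold: the smallest integer count y* whose mass falls below
#' alpha / G. All positions with y >= y* are corrected; all others are left
#' untouched.
#'
#' @param lambda Mean cuts per position genome-wide (must be < 1; for
#'   larger rates use the per-position mass test in
#'   \code{\link{correctPoissonGated}}).
#' @param genomeSize Genome size G in bp.
#' @param alpha Familywise level (default 0.01).
#' @return The integer threshold y*.
#' @examples
#' gateThreshold(0.1, 2.73e9)  # 8
#' @export
gateThreshold <- function(lambda, genomeSize, alpha = 0.01) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  if (lambda >= 1)
    stop("the closed-form threshold assumes lambda < 1 (decreasing mass)")
  logThresh <- log(alpha) - log(genomeSize)
  y <- 0L
  while (dpois(y, lambda, log = TRUE) >= logThresh) {
    y <- y + 1L
    if (y > 1e6L) stop("no threshold found below 1e6 cuts")
  }
  y
}

#' Serialize a BiasTable as TSV
#'
#' Columns: hexamer, pc (cut frequency), p (genomic frequency), b (bias).
#'
#' @param bias A \linkS4class{BiasTable}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeBiasTable <- function(bias, path) {
  hx <- allHexamers()
  df <- data.frame(hexamer = hx, pc = bias@freqCuts[hx],
                   p = bias@freqGenome[hx], b = bias@bias[hx])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BiasTable from TSV
#'
#' @param path A file written by \code{\link{writeBiasTable}}.
#' @return A \linkS4class{BiasTable}.
#' @export
readBiasTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", rep("numeric", 3)))
  b <- df$b; pc <- df$pc; p <- df$p
  names(b) <- names(pc) <- names(p) <- df$hexamer
  new("BiasTable", bias = b[allHexamers()], freqCuts = pc[allHexamers()],
      freqGenome = p[allHexamers()],
      metadata = list(source = path,
                      missing = df$hexamer[is.na(df$b)]))
}
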