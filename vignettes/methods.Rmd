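---
title: "Methods: single-nucleotide ATAC-Seq footprinting with Tn5 bias correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-nucleotide ATAC-Seq footprinting with Tn5 bias correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ATACFootprints)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical conventions adopted
where the underlying methods leave choices open, and what the synthetic
benchmark does and does not establish about real data.

## Cut counting and the +4/−4 shift

ATAC-Seq measures DNA accessibility through the insertion density of the
Tn5 transposase: nucleosome-free, unbound DNA receives insertions
("cuts"), whereas DNA occluded by nucleosomes or shielded by a bound
transcription factor does not. Tn5 acts as a dimer and duplicates 9 bp at
each insertion site, so the two sequenced reads of a proper pair start on
the 1st (+ strand) and 9th (− strand) nucleotide of the duplicated
overhang — exactly 8 bp apart. Counting each read as one cut therefore
requires a strand-dependent shift to co-locate the two observations of the
same transposition event. The package shifts + strand 5′ ends by +4 and −
strand 5′ ends by −4, which places both cuts on the overhang's central
(5th) nucleotide. The +4/−5 shift in widespread use does *not* have this
property: the two mates of one event end up on adjacent positions, halving
the effective per-event signal at single-nucleotide resolution. Both
shifts are available in `countCuts()` (`minusShift = -4` is the default,
`-5` reproduces the conventional behavior), and a regression test pins
down the difference on simulated events with known positions.

Read retention follows the standard strict filter: properly paired,
mapped, primary, non-supplementary, non-duplicate, passing QC. The
library size of a profile is the genome-wide number of retained cuts, not
the interval total; it is the denominator of cuts-per-million
normalization and the numerator of the Poisson background rate.

**Coordinate convention.** Internally everything is 1-based and closed,
the native convention of R/Bioconductor (`IRanges`, SAM positions). BED
and bedGraph output is converted to 0-based half-open by `rtracklayer` at
the boundary. The shift arithmetic is convention-invariant — "the 5th
nucleotide of the overhang" is a base, not an offset — so the choice only
affects I/O, and keeping the ecosystem's convention avoids exactly the
off-by-one drift a mixed convention would invite around the ±4 shift.

**The − strand 5′ end** is the rightmost aligned base of the alignment,
per SAM semantics; the −4 shift applies to that coordinate.

## Hexamer bias: estimation

Tn5 prefers certain sequence motifs even on naked DNA. The package models
this preference at the hexamer level: the bias of hexamer $w$ is

$$b(w) = \frac{p_c(w)}{p(w)},$$

where $p_c(w)$ is the fraction of observed naked-DNA cuts whose local
hexamer is $w$ and $p(w)$ is the fraction of genomic hexamer windows that
are $w$. A value of 1 means no preference; the estimator reproduces this
exactly when cuts are uniform, because positions carrying a full hexamer
window and genomic windows are in one-to-one correspondence.

**Hexamer registration.** The hexamer assigned to a cut at position $i$ is
the reference-strand sequence of $[i-3, i+2]$, placing the cut on the 4th
base — a near-symmetric window centered on the overhang midpoint. The
registration offset is a free choice (any fixed offset yields a
self-consistent bias model); what matters is that the simulator, the
estimator and the correctors share one constant, which they do
(`hexamerAt()` is the single implementation, and the offset is recorded in
`BiasTable` metadata). Cuts on both strands are attributed to the
reference-strand hexamer, because cut positions are already strand-merged
by the +4/−4 shift.

**Degenerate hexamers.** Hexamers absent from the genome, or observed
never to be cut, have no defined ratio; they are carried as `NA`, listed
in the table's metadata, and treated as bias 1 (uncorrected) by all three
correctors. A hexamer with observed cuts but zero genomic occurrence is a
data inconsistency and raises an error. Positions too close to a contig
edge to carry a full window are likewise left uncorrected. Naked-DNA
libraries may be merged with `poolProfiles()` (raw-count summation) before
estimation.

## Hexamer bias: correction

Three corrections of an observed profile $y$ are implemented, all checked
against independent brute-force evaluation of their formulas:

1. **Windowed (HINT-ATAC-style)**:
   $x_i = (y_i + 1)\,/\,(\hat y_i\, \hat b(w(i)) + 1)$, with
   $\hat y_i$ the *mean* observed cuts over the 50 bp window $[i-25, i+24]$
   and $\hat b$ the bias at $i$ divided by the *summed* bias over the same
   window. Two properties are worth knowing: it smooths over the window, so
   single-nucleotide structure is attenuated, and the add-one terms map a
   zero count to a positive corrected value — an all-zero profile becomes
   an all-one profile. Both behaviors are reproduced and tested as stated.
   The printed formula multiplies a window *mean* by a window-*relative*
   bias, which differs by a factor of the window width from the
   alternative reading "expected cuts = window total × relative bias";
   the formula is implemented as printed, and the alternative is exposed
   as `correctHint(..., expectedCuts = TRUE)` for comparison.
   At interval edges the window truncates and $\hat b$ renormalizes over
   the truncated window.

2. **Direct division (BaGFoot-style)**: $x_i = y_i / b(w(i))$. Exact at
   single-nucleotide resolution, but a single spurious cut on a strongly
   avoided hexamer ($b \ll 1$) explodes, which can fill in exactly the
   low-count runs a footprint caller looks for.

3. **Poisson-gated**: divide by the bias only where the observed count is
   inconsistent with background. Counts are modeled as Poisson with rate
   $\lambda$ = library size / genome size $G$ (for pooled profiles, the
   pooled library size); position $i$ is corrected when
   $P(y_i; \lambda) < \alpha / G$ with $\alpha = 0.01$ by default — a
   Bonferroni correction over the $G$ positions tested. The criterion uses
   the probability *mass*, as printed, not an upper-tail probability; for
   $\lambda < 1$ the mass is strictly decreasing in the count, so the gate
   reduces to a count threshold $y^\*$ (`gateThreshold()`), e.g.
   $y^\* = 8$ at $\lambda = 0.1$, $G = 2.73\times 10^9$. For
   $\lambda \ge 1$ the closed-form threshold is refused and the
   per-position mass test in `correctPoissonGated()` (evaluated in log
   space via `dpois(log = TRUE)`) applies as printed. The gated correction
   is piecewise equal to direct division above the gate and to the
   identity below it — tested exactly — so zero-count positions, and with
   them protected regions, are never inflated.

## Footprint calling

A protected region is a maximal run of consecutive positions with counts
strictly below a threshold $T$, of length 5–50 bp, immediately bordered on
both sides by positions strictly above $T$. Conventions adopted where the
rule leaves room:

- **Ties**: a position with exactly $T$ cuts is neither run member nor
  border; it terminates a run and disqualifies it. ("Fewer than" and
  "more than" are read strictly; equality is the natural boundary case
  and excluding it on both sides is the conservative choice.)
- **Edges**: runs touching the profile boundary have no border and are
  discarded.
- **Internal spikes**: runs are strictly consecutive sub-threshold
  positions; a single above-threshold position splits a run. No secondary
  tolerance level is applied.
- **Input scale**: calling operates on **raw pooled** counts. Thresholds
  are absolute cut counts calibrated to deeply pooled coverage (of the
  order of 400 for a promoter and 40–200 for enhancers when pooled
  coverage reaches tens of cuts per nucleotide); normalized profiles would
  require rescaling the threshold. This is stated prominently because
  normalization happens per sample elsewhere in the workflow.

The caller is validated two ways: exact agreement with an
enumerate-all-runs oracle on 1,000 random Poisson profiles (lengths
60–150, thresholds 2–10, varying length bounds), and recall 1.0 with exact
boundaries on planted fully-protected footprints of every length 5–50 on a
simulated deep profile, with decoys of length 4 and 51 never called.

## Accessibility dynamics

`totalAccessibility()` sums cuts over an element; `coveragePerNt()`
divides by its length. `binRegion()` splits an element into $n$ near-equal
contiguous bins — when the length is not divisible by $n$, the leading
`length %% n` bins are 1 bp wider, a deterministic tie-break that keeps
widths within 1 bp — and reports per-bin, per-sample means; widths ×
means reconstruct the region total exactly. The bin count is a per-region
user choice (9 and 13 are natural for elements of a few hundred bp; no
rule is imposed). `siteAdjacentChange()` compares the mean absolute
change between consecutive timepoints over positions within `flank` bp of
a binding site against the remainder of the element; the default flank of
5 bp reflects that steric shielding by a bound factor extends only a few
nucleotides beyond the site, and the flank is a parameter because
"vicinity" has no canonical width. When the remainder changes by exactly
zero the ratio is undefined and reported as `NA` with a warning rather
than infinity. Smoothing for display and correlation uses centered
odd-width sliding windows with truncated (shrinking) edges; even widths
are rejected rather than silently decentered.

## The synthetic benchmark

The simulator generates: an i.i.d. random genome with adjustable GC
content; a per-position transposition propensity (baseline, reduced by a
depletion factor inside planted footprints — depletion 0 is full
protection); and transposition events drawn with probability proportional
to propensity × hexamer preference, each emitting a properly-paired read
pair with 5′ ends at event ± 4, written as SAM (MAPQ 60, proper-pair
flags) and convertible to indexed BAM via `Rsamtools::asBam`. Positions
whose hexamer window or read pair would leave the genome have zero
probability. A single integer seed makes every call reproducible.

Defaults were chosen once to resemble the regime the methods target:
elements of $10^3$–$10^5$ bp, planted footprints of 5–50 bp, event counts
giving tens to hundreds of cuts per nucleotide after pooling (deep
locus-level coverage), and a naked-DNA library of $2\times 10^5$ events
for bias estimation in the pipeline. Test problem sizes — $10^4$ events
for shift checks, $10^6$ for bias recovery, 1,000 random profiles for
oracle equivalence — are the package's choice of smallest sizes at which
the stochastic checks are decisively powered (e.g. the planted bias of 2
is tested within 3 binomial standard errors).

What the simulator deliberately omits: sequencing errors, PCR duplicates,
fragment-length structure beyond the single-event pair (so no
nucleosome-phasing signal), mappability variation, chromatin states
between "accessible" and "protected", and mitochondrial contamination.
Passing the synthetic suite therefore demonstrates correctness of the
*computations* — shift arithmetic, estimator consistency, formula
fidelity, caller semantics — not that footprint calls on real chromatin
are complete or pure; on real data, nucleosomes, partial occupancy and
unmodeled bias remain confounders.

## Reporter and qPCR formulas

Flow-cytometry expression is anchored by a spiked internal standard
(CFSE-marked promoter-line cells) and a Luciferase-free background
control. With median fluorescences $f_{sample}$, $f_{samples}$ (standard
in the sample tube), $f_{PUER}$ (background cells) and $f_{PUERs}$
(standard in the background tube):

$$b_{sample} = \frac{f_{PUER}\, f_{samples}}{f_{PUERs}}, \qquad
L_{sample} = \frac{f_{sample} - b_{sample}}{f_{samples} - b_{sample}}.$$

The same $b_{sample}$ is subtracted in numerator and denominator, as the
formulas are printed (one might imagine a standard-specific background for
the denominator; the printed form is kept). Medians, not means, summarize
the fluorescence distributions. The anchors $L = 0$ at pure background and
$L = 1$ at the standard define the unit system and are tested exactly.
Bulk expression is luminescence / protein, with protein inverse-predicted
from an OLS albumin standard curve; enhancer activity is the pointwise
fold change over the promoter-only line, scale-invariant by construction.
Replicate aggregation for bulk assays reports the mean with its standard
error alongside per-replicate values, a choice left open by the assay
description. Series are normalized to the undifferentiated reference
timepoint (0 h under IL3, −48 h under GCSF).

ATAC-qPCR accessibility is $\Delta C_q = C_q^{target} - C_q^{control}$
with fold $2^{-\Delta C_q}$. Technical replicates are filtered by Tukey
fences $[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ with type-7
(linear-interpolation) quartiles — the quartile convention is not
universal, so it is fixed and recorded; the alternative reading
$|x - \mathrm{median}| > 1.5\,\mathrm{IQR}$ is available via
`iqrFilter(method = "median")`. The fence is applied to per-replicate
$\Delta C_q$ values against the sample's mean control $C_q$ (a constant
offset, so the verdict equals filtering the raw target $C_q$s); control
replicates are filtered on their own $C_q$. Tukey filtering is not
idempotent for arbitrary samples (re-filtering a trimmed wide sample can
trim again); for the technical-triplicate clusters it is designed for —
with at most one gross outlier — one pass is stable, which is the tested
property. Fewer than three values pass through unfiltered with a warning.

## Pipeline

`runPipeline()` executes simulate → count → correct → footprint → dynamics
from one declarative JSON configuration (`validateConfig()` reports *all*
violations at once). Stage products flow in memory; outputs are FASTA,
SAM, truth BED, per-sample and pooled bedGraphs, the bias TSV, the
footprint BED, and dynamics TSVs, each MD5-hashed into a JSON manifest.
Hashing covers the text outputs, so a fixed seed yields hash-identical
manifests across runs — the tested determinism property. Stage failures
abort with the stage name. The per-stage operations are ordinary exported
functions; the pipeline is a convenience wrapper, not a separate code
path.

## Known limitations

- The bias model is hexamer-level only; dinucleotide, position-weighted or
  GC-smoothed models are out of scope.
- Footprint thresholds are absolute counts; there is no automatic
  calibration to coverage, by design (the intended regime is deeply pooled
  profiles where a scientist sets $T$ per element).
- The Poisson gate's closed-form threshold assumes $\lambda < 1$; deeply
  pooled profiles can exceed this, in which case the per-position mass
  test applies, and for large $\lambda$ the printed mass criterion gates
  both unusually high *and* unusually low counts — a documented
  consequence of using the mass rather than a tail.
- The simulator's independence assumptions (i.i.d. genome, independent
  events) understate the correlation structure of real libraries; standard
  errors on real data will be wider than the synthetic ones.
- PWM scanning of footprint sequences and ChIP-Seq co-localization beyond
  interval overlap are outside the package.
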