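---
title: "Quantifying histone-mark accumulation dynamics on the inactive X"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone-mark accumulation dynamics on the inactive X}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xidyn)
library(dplyr)
```

## The problem

During X-chromosome inactivation (XCI), the long non-coding RNA Xist coats
one X chromosome and triggers a cascade of chromatin changes, among them
the deposition of the repressive marks H3K27me3 and H4K20me1. In the hybrid
(C57BL/6 × *M. m. castaneus*) inducible-Xist ESC system, Xist is switched on
with doxycycline (DOX) from the B6 allele only, so the B6 haplotype becomes
the inactive X (Xi) and the Cast haplotype stays active. Because the two
haplotypes differ at many SNPs, sequencing fragments can be assigned to one
parental allele, and the accumulation of a histone mark on the Xi can be
followed allele-specifically along a DOX time course, window by window
along the chromosome. Live-cell mintbody imaging provides the complementary
minute-scale view: how soon after Xist RNA appears does a mark become
enriched in the Xist domain?

xidyn implements this analysis end to end as composable, data-frame-first
functions, driven by a synthetic-data generator with known ground truth, so
every statistical component can be validated by parameter recovery rather
than by eye.

## The accumulation model

Per 10-kb window, the normalized B6 signal as a function of induction time
`t` (hours) is modelled by the four-parameter log-logistic (LL.4) curve

$$ f(t) = c + \frac{d - c}{1 + \exp\{b(\log t - \log e)\}} $$

with lower asymptote `c`, upper asymptote `d`, slope `b` (negative for an
increasing curve) and inflection dose `e`. By construction `f(e) = (c+d)/2`,
so `e` is the ED50 — the time at which accumulation is half complete — and
it is the window-level summary used for comparing marks. The IC35, used for
clustering gene-silencing kinetics, is the dose at which 35% of the
response range has been traversed; in closed form
`e * ((1-p)/p)^(1/b)` with `p = 0.35` for an increasing curve (and
`e * (p/(1-p))^(1/b)` for a decreasing one), which is below the ED50 in
both orientations. Since `(b, c, d, e)` and `(-b, d, c, e)` describe the
same curve, fits are canonicalized so that `c` is always the lower
asymptote.

At `t = 0` the model is evaluated as its one-sided limit (`c` for `b < 0`,
`d` for `b > 0`) rather than through `log 0`.

### Fitting

`fit_ll4()` exploits that the model is linear in `(c, d)` once `(b, e)` are
fixed: a coarse grid over slopes and inflection doses with an exact inner
linear solve locates the optimum basin, L-BFGS-B refines the profiled
objective, and a full Levenberg–Marquardt pass polishes all four
parameters. Replicate observations at the same timepoint are fitted
jointly — the extra residual degrees of freedom stabilize `e`
substantially at a 5-timepoint design compared with fitting the replicate
mean.

Two identifiability guards flag windows with no usable response as
non-converged: the fitted range `|d - c|` must exceed twice the residual
RMSE, and the LL.4 fit must beat a constant-mean model in an F-test at
`alpha = 0.05`. Without them, windows that are flat within the time course
(truly late-accumulating regions) yield arbitrary small inflection doses
driven by noise. Non-convergence is a valid outcome, not an error.

Downstream, `filter_fits()` keeps fits with residual sum of squares
strictly below `mean + 1.5 SD` over converged fits (with the degenerate
all-equal case retaining everything, since a strict comparison against an
SD of zero would reject all), and `cap_ed50()` assigns exactly 24 h to
every window that is non-converged, filtered out, or fitted beyond 24 h —
the "late accumulation" convention. "Residuals" per fit means the sum of
squared residuals; the filter is scale-sensitive to this choice, which is
why tracks are normalized before fitting.

### Comparing marks

`compare_marks()` uses a paired two-sided Wilcoxon signed-rank test on
per-window ED50s, restricted to windows below the 24-h cap for both marks.
A signed-rank test is the only coherent reading of a paired design (a
rank-sum test is unpaired by definition); identical vectors return `p = 1`
by convention since there are no signed ranks. `category_correlation()`
reports Pearson correlations of log accumulation per feature category,
dropping non-positive values with an explicit count.

## Counting and normalization

Fragments are assigned to alleles from the SNP bases they cover (all
informative bases agreeing with the B6 allele → B6, with the Cast allele →
Cast; none → unassigned; a mixture → conflicting and excluded from allelic
totals). Window counting assigns each fragment once, to the window with
the largest overlap, ties to the leftmost — the deterministic analogue of
featureCounts against a complete tiling.

Between-sample normalization uses TMM factors computed from B6 counts over
autosomal consensus peaks (autosomes are untouched by Xist induction, so
composition changes there are technical). The implementation is a direct
transcription of the published TMM formulas — per-peak M and A values after
library-size scaling, 30%/5% two-sided trimming, precision-weighted mean —
reported relative to the reference sample without geometric-mean
rescaling; the test suite checks it against edgeR's implementation to four
decimals. Tracks are then scaled by `1e7 / library size / TMM factor`, the
t = 0 level is subtracted per window (the track is exactly zero at t = 0),
and a variant rescaled to the chromosome-mean 24-h accumulation is emitted
for cross-mark timing comparisons. Replicates are normalized first and
averaged afterwards for display; for fitting, replicate-level tracks
(`collapse_replicates = FALSE`) are used so both replicates enter the fit,
with the replicate-mean t0 as their common baseline (subtracting each
replicate's own noisy t0 would hand every replicate a different random
offset and inflate the fit noise).

## Window and gene annotation

The genome is tiled into fixed 10-kb windows (final partial window kept).
Consensus peaks are the base-pair intersection of per-replicate merged
peaks. A gene is initially active iff a transcript TSS (the exact
strand-aware 5' base) lies inside both an H3K9ac and an H3K4me3 consensus
peak, its t0 H3K27me3 signal is at or below the bivalency threshold, and
its mean TPM is at least 1; silent iff no TSS touches either mark and mean
TPM is at most 1; everything else is excluded with the reason recorded.
The bivalency threshold is found as the crossing of Gaussian kernel
densities (Scott's bandwidth, 1000-point grid between the group medians)
of the premarking signal in the active and inactive groups;
`h3k27me3_default_threshold` (0.035) ships as the documented constant for
data processed with matching normalization, for when the KDE step is
skipped. Intergenic windows are tiles free of any gene extent, its 2-kb
strand-aware upstream promoter, and (when provided) active enhancers.

## Metagene profiles

`metagene_profile()` implements scale-regions semantics: gene bodies are
rescaled to a fixed number of bins (body bin `j` of a length-`L` feature
covers bases `(floor((j-1)L/B), floor(jL/B)]`, an exact partition), flanks
are fixed 500-bp bins over ±30 kb, minus-strand features are
orientation-flipped, and flank bins falling off the chromosome are dropped
from the average rather than zero-filled.

## Live-imaging quantification

Per frame, the Xist channel is segmented by Otsu's threshold followed by
keeping the largest connected component with at least 10 px. The published
workflow segmented interactively; as a deterministic stand-in this package
adds a contrast guard (domain mean at least 1.2× the outside mean) so that
pre-onset pure-noise frames do not produce spurious domains — both knobs
are exposed as parameters. The mintbody enrichment ratio is the in-domain
mean divided by a whole-nucleus background sampled every 10th frame and
linearly interpolated between samples; the ratio is invariant to global
intensity gain. Traces are aligned to each cell's first frame with a
detected domain, aggregated as mean with interquartile shading, and the
enrichment onset is the first time-since-onset point whose one-sided
one-sample t-test against ratio 1.0 survives Benjamini–Hochberg adjustment
with its successor also significant (a run-of-2 rule against single-frame
flukes). Divergence between two marks uses per-timepoint Welch tests with
the same adjustment and run rule. Mitotic cells are excluded upstream by
the caller (an input decision, not detected automatically).

## What the generator emulates — and what it does not

`sim_config()` encodes the study conditions: a DOX time course at 0, 4, 8,
12 and 24 h in biological duplicate; two marks whose induced-allele counts
follow a steep LL.4 curve (slope −4, baseline 50 and plateau 150 expected
fragments per 10-kb window — roughly hundred-fragment windows, a
moderate-depth regime); negative-binomial count noise with dispersion 0.02
(mid-range technical dispersion for replicate window counts; dispersion 0
reduces to Poisson); 2 SNPs/kb between haplotypes so that a 150-bp
fragment covers at least one SNP about a quarter of the time, matching
realistic allelic-assignment rates; a default spreading gradient in which
the inflection dose grows with distance from the chromosome midpoint (the
Xist locus surrogate); planted tandem microsatellites for the sgRNA
search; and two-channel movies (15 min/frame) with a disk-shaped Xist
domain and a mintbody enrichment delayed by 3 frames (45 min) ramping to
its plateau ratio over 4 frames.

The generator does not emulate: mappability and alignment artefacts, PCR
duplicates, sequencing errors (available but off by default), fragment
length variation, chromatin contact geometry of Xist spreading, cell-cycle
oscillations of H4K20me1, 3-D imaging (frames are max-projection
surrogates), or cell movement. Passing tests therefore demonstrate the
correctness of the computational pipeline and its recovery properties
under its stated noise model — not the biological conclusions of any real
dataset.

## Numerical choices and degenerate inputs

* LL.4 bounds: `|b| ≤ 50`, `e ∈ (0.001, 10 × max t]`; grid over
  `b ∈ ±{0.5, 1, 2, 4, 8}` and the positive timepoints.
* Flat input (zero variance) returns a non-converged fit with `c = d`.
* The focal-region inequality `nR ≤ (fc − 20·Σoff − 20)/21` is evaluated in
  integer arithmetic (`21·nR ≤ …`) to avoid float boundary errors; a
  negative bound simply yields no regions.
* k-mer occurrences are counted per genomic interval with orientations
  collapsed; a palindromic k-mer counts once per interval; overlapping
  occurrences (tandem repeats) all count; `N` bases never match.
* k-means for IC35 classes runs 50 restarts under a caller-supplied seed
  and labels clusters by ascending centre, so results are deterministic.
* Wilcoxon on identical paired vectors returns `p = 1`; fewer than 10
  usable pairs is an error rather than a silent low-power test.
* All tables are written with fixed `write.table` settings and checksummed
  into a manifest; `run_pipeline()` is byte-identical under a fixed seed.

## Problem sizes used by the test-suite studies

The validation studies run at: 500 windows for ED50 recovery (plus 100
flat far-late windows, true `e` = 96 h); 100 replicate simulations of 300
shared windows for the mark-ordering test; 20 random two-chromosome
genomes (8–15 kb each) for exact oracle equivalence of the k-mer search,
plus a 2.5-Mb chromosome carrying planted targets and decoys; 50 random
count matrices for the TMM cross-check; and 100 thirty-cell imaging
experiments (24 frames of 48×48 px) each for the onset-recovery and null
false-positive studies. These sizes give the recovery statistics stable
sampling distributions while keeping the default suite quick on a single
CPU.

## Known limitations

* The sgRNA finder scores exact matches only; mismatch-tolerant off-target
  scoring is out of scope, as is reproducing any specific published
  candidate list (that depends on the full reference genome).
* ED50 is weakly identified when a curve does not approach saturation
  within the time course; such windows are deliberately absorbed into the
  24-h cap rather than reported with misleading precision. At the
  5-timepoint design, roughly 1% of truly flat windows still produce a
  chance apparent response that passes both guards — an irreducible
  noise-floor effect.
* The KDE threshold requires two clearly separated premarking modes; when
  the densities do not cross between the group medians the function
  instructs the user to set the threshold manually instead of guessing.
* The imaging segmentation is a deterministic surrogate for interactive
  segmentation and assumes one dominant domain per nucleus.
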