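# xidyn — allele-specific histone-mark accumulation dynamics on the inactive X

During X-chromosome inactivation, the Xist long non-coding RNA coats one X
chromosome and repressive histone marks (H3K27me3, H4K20me1) accumulate on
it. In the hybrid (B6 × Cast) inducible-Xist ESC system, Xist is switched
on with doxycycline from the B6 allele only, so sequencing fragments that
cover strain SNPs can be assigned to the inactive (B6) or active (Cast)
haplotype, and a mark's accumulation on the inactive X can be followed
allele-specifically through a DOX time course — and, at minute resolution,
by live-cell mintbody imaging of the Xist domain.

`xidyn` is an R package for epigenomicists analysing such data. It provides:

* a **synthetic-data generator** with full ground truth — diploid toy genome
  with SNPs and planted microsatellites, allele-tagged fragments whose B6
  counts follow a programmed sigmoid, gene/peak/TPM annotation layers, and
  two-channel Xist/mintbody movies;
* **allelic quantification** — SNP-based allele assignment, largest-overlap
  window counting, TMM normalization on autosomal consensus-peak counts,
  `1e7/library` scaling, t0 subtraction and 24-h rescaling, bedGraph
  coverage tracks;
* **accumulation dynamics** — four-parameter log-logistic (LL.4) fitting
  with ED50/IC35 extraction, residual filtering, 24-h capping, paired
  Wilcoxon mark comparison, IC35 k-means silencing classes, per-category
  log-scale Pearson correlations, and scale-regions metagene profiles;
* **window/gene annotation** — 10-kb tiling, consensus peaks, the
  KDE-crossing bivalency threshold, initially-active/silent/intergenic
  calls;
* an **sgRNA repeat-target search** — chromosome-specific 22/23-mer
  (`N{20,21}GG`) enumeration, the specificity ratio
  `f_c(s) / (1 + Σ_{i≠c} f_i(s)) > 19`, and sub-megabase focal regions
  satisfying `n_R ≤ (f_c − 20·Σoff − 20)/21`;
* **live-imaging quantification** — Xist-domain segmentation, background-
  normalized enrichment traces aligned to Xist onset, quartile aggregation,
  BH-adjusted onset and divergence tests.

## The model at the core

Per 10-kb window, normalized B6 accumulation over induction time `t` is

    f(t) = c + (d − c) / (1 + exp{ b (log t − log e) })

with lower/upper asymptotes `c`, `d`, slope `b` (< 0 for accumulation) and
inflection dose `e` = ED50 in hours (`f(e) = (c+d)/2`). Windows whose fit
fails, is filtered, or lands beyond 24 h are assigned exactly 24 h
("late-accumulating"). Mark timing is compared by a paired Wilcoxon
signed-rank test on per-window ED50s below the cap. See the methods
vignette (`vignettes/xi-accumulation-dynamics.Rmd`) for assumptions,
parameter defaults and numerical choices.

## Worked example

A deep-IP toy study: two autosomes plus a 400-kb X surrogate, two marks
whose true inflection dose grows with distance from the Xist locus, with
H3K27me3 delayed 2 h relative to H4K20me1 at every window.

```r
library(xidyn)
library(dplyr)

scfg <- sim_config(seed = 42,
  chromosomes = tibble::tibble(chrom = c("chr1", "chr2", "cX"),
                               length = c(60000L, 60000L, 400000L)),
  autosome_depth = 400)
scfg <- sim_config(seed = 42, chromosomes = scfg$chromosomes,
                   autosome_depth = 400,
                   windows_truth = mutate(scfg$windows_truth, c = 200, d = 600))

res <- run_pipeline(pipeline_config(seed = 42, sim = scfg), "demo_out")

res$comparison
#> Paired Wilcoxon signed-rank on 14 windows
#>   median ED50 difference (a - b): -2.746 h
#>   V = 10 , p = 0.005249
```

The paired test sees only windows with ED50 < 24 h for both marks; the
median per-window difference of −2.7 h recovers the programmed 2-h lead of
H4K20me1 (mark "a") over H3K27me3, significant at p ≈ 0.005.

```r
allelic_fraction(filter(res$counts, grepl("_24_", sample_id)),
                 scope = "chrom") |> filter(chrom == "cX")
#>   chrom     sample_id   b6 cast fraction_b6
#> 1    cX H3K27me3_24_1 5893 2003       0.746
#> 2    cX H3K27me3_24_2 5951 2065       0.742
#> 3    cX H4K20me1_24_1 5694 2125       0.728
#> 4    cX H4K20me1_24_2 5886 2077       0.739
```

After 24 h of induction ~74% of informative X-chromosome fragments map to
the B6 (inactive) allele — the accumulation of the marks on the Xi.

```r
head(res$sgrna$report[, c("sequence", "count", "specificity",
                          "region_start", "region_end")], 1)
#>                  sequence count specificity region_start region_end
#> 1 ATGCATTGACCTGAGTCAATAGG    30          30       199655     200345
```

The planted X-specific microsatellite (30 tandem copies, no off-chromosome
hits) is recovered at its exact planted coordinates with chromosome
specificity 30 and a 690-bp focal region.

Single windows fit and tidy in the usual way:

```r
f <- fit_ll4(rep(c(0, 4, 8, 12, 24), 2),
             c(52, 60, 99, 131, 148, 49, 63, 104, 128, 152))
glance(f)
#>   residual_sum converged  ed50  ic35     n
#> 1         34.1 TRUE       8.07  6.57    10
```

`run_pipeline()` writes every table as TSV plus `config.yaml` and a
`manifest.tsv` of MD5 checksums; re-running with the same config is
byte-identical.

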