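# rddmr

Windowed DMR calling and classification of RdDM- and MORC-dependent
transcriptional silencing in plant genomes.

## What this is for

In *Arabidopsis*, transposable elements (TEs) are silenced by
RNA-directed DNA methylation (RdDM): Pol IV-derived 24-nt siRNAs guide
de novo methylation of CG, CHG and CHH cytosines, which SUVH2/9 and
downstream effectors such as MORC6 maintain as a silent chromatin
state. Comparing mutant methylomes, transcriptomes and siRNA libraries
against wild type separates loci where silencing follows methylation
loss from loci that reactivate **without** any methylation change —
the signature of a methylation-independent silencing step. `rddmr`
packages that comparison for epigenomics researchers as tested,
scriptable functions rather than one-off analysis code.

The chain it implements:

1. **DMR calling** — per-cytosine counts (Bismark cytosine-report
   dialect) are pooled into non-overlapping 50-bp windows (sites with
   coverage < 5 excluded). Window methylation is the weighted level
   `sum(m) / sum(m + u)`. A window is differential when
   `|level_B − level_A| ≥ 0.10` **and** a two-sided Fisher exact test
   on the pooled 2×2 count table gives `p < 0.01`; same-direction
   windows with gaps ≤ 50 bp merge into DMRs.
2. **DMR comparison** — two DMRs overlap only when the overlap
   *exceeds* 50 bp; sets partition into shared (Class I) and specific
   (Class II) regions, with hypergeometric upper-tail enrichment
   `P(X ≥ k)` over an explicit universe, and composition by maximal
   overlap with genes/TEs.
3. **Differential expression** — per feature, fold-change of
   library-normalized counts with a 0.5 pseudocount plus a Fisher
   exact test on raw counts versus library totals; `up` iff
   fold > 2 and p < 0.01 (mirrored rule for `down`), then
   common/specific target partitions across mutants.
4. **Feature methylation** — pooled-count levels for TE bodies and
   1-kb strand-aware promoters; methylation classes (TE > 20%,
   promoter > 5%, strict); per-feature deltas with wild type set to 0;
   Welch t-tests with star annotation.
5. **siRNA profiling** — 24-nt read counts normalized to reads per
   ten million (RPTM = count × 10⁷ / library total); Pol IV / Pol V
   dependence from mutant/WT fold changes at an explicit cutoff
   (default 0.5).
6. **Synthetic data with planted truth** — a seeded generator of
   cytosine reports, annotations, expression and siRNA counts whose
   planted DMRs, up-regulated features and dependence labels let every
   stage be scored by recovery (`evaluate_against_truth()`).

See `vignettes/silencing-classification.Rmd` for the model, the
open-choice decisions and the generator's assumptions.

## Worked example

Simulate the default two-mutant scenario (60 planted 300-bp hypo-DMRs
in `suvh29`, 15 shared with `morc6`) and run the methylome arm:

```r
library(rddmr)
cfg <- te_silencing_scenario(seed = 1)
ann <- simulate_annotation(cfg)
wt     <- simulate_methylome(cfg, ann, "WT")
suvh29 <- simulate_methylome(cfg, ann, "suvh29")
morc6  <- simulate_methylome(cfg, ann, "morc6")

res_su <- call_dmrs(wt, suvh29)   # 50-bp windows, 5x, |d|>=0.10, p<0.01
res_mo <- call_dmrs(wt, morc6)
table(res_su$dmrs$direction)
#> hyper  hypo
#>     1    64
table(res_mo$dmrs$direction)
#> hyper  hypo
#>     2    17

part <- classify_overlap(res_su$dmrs[res_su$dmrs$direction == "hypo", ],
                         res_mo$dmrs[res_mo$dmrs$direction == "hypo", ])
part
#> DMR overlap partition (overlap > 50 bp)
#>   set A: 64 (15 shared, 49 specific)
#>   set B: 17 (15 shared, 2 specific)
#>   qualifying pairs: 15
dmr_overlap_enrichment(part, universe = res_su$n_tested)$p
#> [1] 6.08e-29

rec <- interval_recovery(res_su$dmrs, ground_truth(cfg)$dmrs)
c(sensitivity = rec$sensitivity, precision = rec$precision)
#> sensitivity   precision
#>   1.0000000   0.9230769
```

Reading the numbers: the caller finds 64 hypo-DMRs in the
`suvh29`-like genotype (60 planted, a handful of single-window false
calls) and 17 in `morc6`; exactly the 15 planted shared regions
overlap by more than 50 bp, an overlap far beyond chance for two sets
of this size drawn from ~6,000 tested windows (hypergeometric
p ≈ 6e-29). Against the planted truth, every planted DMR is recovered
and 92% of all calls are real.

`run_full_pipeline(cfg, "results/")` runs all six stages through
files (DMR BEDs, partition/enrichment tables, DE tables, methylation
and siRNA profiles, a key–value `summary.tsv`) and writes a
`manifest.json` with thresholds, checksums and runtimes. A thin CLI
over the same functions is installed at `inst/cli/rddmr`
(`rddmr pipeline --seed 1 --outdir results/`, `rddmr call-dmrs ...`).

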