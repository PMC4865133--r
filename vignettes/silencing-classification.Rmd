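---
title: "Classifying RdDM- and MORC-dependent silencing from methylome, transcriptome and siRNA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying RdDM- and MORC-dependent silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddmr)
```

## The analysis in one paragraph

In plants, transposable elements (TEs) are transcriptionally silenced by
RNA-directed DNA methylation (RdDM): Pol IV-derived 24-nt siRNAs guide
de novo methylation in CG, CHG and CHH contexts, which SU(VAR)3-9
homologs (SUVH2/9) and downstream effectors such as MORC proteins lock
into a silent state. Comparing mutant methylomes and transcriptomes
against wild type separates loci where silencing tracks methylation
loss from loci that reactivate *without* methylation change. `rddmr`
implements that comparison as a reusable chain: windowed differential
methylation, DMR-set partitioning, a replicate-free
differential-expression rule, feature-level methylation classes, and
24-nt siRNA dependence profiling — together with a seeded generator of
synthetic inputs carrying planted ground truth, so every stage can be
validated by recovery rather than by eye.

## Differential methylation

Per-cytosine counts (methylated reads $m_i$, unmethylated $u_i$) come
from a Bismark-dialect cytosine report. Sites with coverage
$m_i + u_i < 5$ are discarded. Each chromosome is tiled with
non-overlapping 50-bp windows anchored at coordinate 0, and window
methylation is the *weighted* level

$$ \hat{p} = \frac{\sum_i m_i}{\sum_i (m_i + u_i)}, $$

pooled read counts rather than a mean of per-site levels — the pooled
2×2 table $(\sum m, \sum u)$ per genotype is also what the test
consumes. A window is differentially methylated between genotypes when
the absolute level difference is at least 0.10 *and* a two-sided
Fisher exact test on the pooled table gives $p < 0.01$. Significant
windows of the same direction (hypo / hyper) separated by gaps of at
most 50 bp merge into DMRs; the region-level difference is recomputed
from counts pooled over the whole region. No multiple-testing
correction is applied by default, matching the thresholding procedure
this reimplements; a Benjamini–Hochberg mode is available
(`fdr = TRUE`).

Choices the original description leaves open, and what this package
does:

* **Window step.** "Every 50-bp window" is read as a non-overlapping
  tiling; the width is a parameter.
* **Test unit.** The Fisher test is applied to pooled window counts —
  the only construction that yields one p-value per window from
  per-site counts.
* **Strand pooling.** Symmetric CG sites on opposite strands are *not*
  collapsed; both report rows enter the window, so the coverage filter
  keeps per-row semantics.
* **Boundary readings.** "Difference of 10%" is inclusive
  (attained at exactly 0.10), "gaps no more than 50 bp" merges at
  exactly 50, "overlap exceeded 50 bp" is strict (51 bp is the
  smallest qualifying overlap). Each is a documented knob.
* **Context.** DMRs are called on all cytosines pooled
  (`context = "total"`) by default; per-context calling (CG/CHG/CHH)
  uses the same machinery.
* **Minimum sites per window.** Only the site-level coverage filter is
  stated; `min_sites` exists and defaults to 1.

### Numerical choices

The two-sided Fisher p-value follows the point-probability rule: the
sum of hypergeometric probabilities of all tables with the observed
margins that are no more probable than the observed table. Ties are
included with a relative tolerance of 1e-7, the same guard the
reference implementation in `stats::fisher.test()` uses, so exact ties
survive floating-point noise; the test suite checks agreement with a
full-enumeration oracle to 1e-12 and with `stats::fisher.test()`
directly. The $|\Delta| \ge 0.10$ comparison carries a 1e-9 guard for
the same reason: a difference of exactly 10% computed as
`level_b - level_a` may sit one ulp below the threshold. A window
table with all four counts zero is undefined and returns $p = 1$ with
a warning. $-\log_{10} p$ scores in BED output are capped at 300.

## DMR comparison and composition

Two DMRs overlap when their intersection exceeds 50 bp. Overlap is
evaluated against each single partner (not aggregated), a region with
several partners counts once in the shared/specific partition, and the
partition conserves totals by construction. The shared set corresponds
to the Class I / Class II split used for MORC-dependent loci: hypo-DMRs
shared between two mutants versus specific to one.

Enrichment of the overlap uses the hypergeometric upper tail. The
universe size is deliberately a **required argument**: depending on the
question it is the number of tested windows (for window-derived DMR
sets — `call_dmrs()` reports it as `n_tested`) or the number of
annotated features. The pipeline uses the smaller of the two mutants'
tested-window counts and echoes it in its output rather than guessing
silently.

Genomic composition assigns each DMR to gene, TE or unannotated
("other") space by maximal base-pair overlap, ties broken TE > gene >
other, so a DMR draped across a TE/gene boundary lands in the class
with the larger footprint.

## Differential expression without replicates

The expression rule mirrors a single-library-per-genotype design:
counts are scaled to the smaller library, the fold change is
$(n_B + 0.5)/(n_A + 0.5)$ on normalized counts, and significance comes
from a two-sided Fisher exact test on the raw 2×2 table
$(\text{count}, \text{library} - \text{count})$ across genotypes. A
feature is `up` when fold $> 2$ and $p < 0.01$; `down` uses the
mirrored rule. The pseudocount enters only the fold change, never the
test, which therefore stays exact. The same
`fisher_exact_two_sided()` implementation serves the methylation and
expression tests (property-tested to be identical on the same table).
Isoform-level quantification is out of scope: the package consumes a
count table, not alignments.

## Feature-level methylation and classes

Feature methylation pools reads of all ≥5× sites inside the interval,
per context and in total; contexts with no qualifying reads are
reported `NA`, never zero-filled. Promoters are the 1-kb interval
immediately upstream of the annotated 5′ end on the coding strand,
truncated at chromosome bounds, with overlaps into neighboring
features allowed — the simplest defensible definition given that only
the length is stated. Methylation classes use strict thresholds: TE
bodies > 20% total methylation, gene promoters > 5%. Group
comparisons use Welch's two-sided t-test (the safer default when only
"t-test" is specified), with the conventional star annotation and an
explicit degenerate branch for zero-variance groups. Delta tables set
the wild-type level to 0 and report per-feature, per-context
differences, `NA` wherever either level is undefined. The promoter
filter uses the total-cytosine level; per-context levels are reported
alongside so a context-specific reading remains possible.

## siRNA profiling

24-nt reads per feature are normalized to reads per ten million
(RPTM): $\text{count} \times 10^7 / \text{library total}$. Dependence
is a fold change $(\text{RPTM}_{mut} + 1)/(\text{RPTM}_{WT} + 1)$
against the corresponding polymerase mutant: a feature is Pol
IV-dependent when its `nrpd1` fold change falls below the cutoff and
Pol V-independent when its `nrpe1` fold change stays at or above it.
No numeric cutoff exists in the source procedure, which reports fold
changes graphically; the package refuses to hide that knob — the
default is 0.5 and it is echoed in every profile. Features below 5
RPTM in the wild type are flagged uninformative and not labeled.

## The synthetic-data generator

The generator emulates the statistical structure of multi-genotype
whole-genome bisulfite, RNA-seq and small-RNA inputs; it defines the
study conditions under which the package's recovery claims hold.

**Methylomes.** The cytosine landscape (positions at density 0.15
sites/bp, contexts at genomic proportions 17% CG / 17% CHG / 66% CHH,
strands) is drawn once per config and shared by all genotypes;
coverage is Poisson(20) per site and methylated reads are Binomial
given the site's generating level. Baseline levels depend on the
enclosing feature kind — TEs 0.85/0.45/0.30 for CG/CHG/CHH, gene
bodies 0.20/0.03/0.02, intergenic space 0.05/0.03/0.02 — a coarse but
recognizable caricature of the Arabidopsis methylome in which TEs are
heavily methylated in all contexts and euchromatin carries mostly
gene-body CG methylation. Planted hypo-DMRs subtract per-context
deltas (clamped to [0, 1]). Bisulfite non-conversion defaults to 0; a
rate parameter exists.

**Expression.** Counts are negative binomial marginally, but
constructed as latent Gamma–Poisson: each feature draws one latent
mean (Gamma, dispersion 0.1 around its kind's base mean — TEs 30,
genes 100), *shared across genotypes*, and each genotype draws Poisson
counts around latent mean × planted fold. The latent mean models
stable feature-to-feature variation (length, mappability, baseline
activity); between genotypes the null variation is pure counting
noise, which is exactly the regime an exact test on counts assumes.
The alternative — independent negative-binomial draws per genotype —
would inject 10% extra-Poisson variance *between* the two single
libraries, and no fold-change/exact-test rule can separate that from
signal: the null probability of a spurious 2-fold change alone is then
in the several-percent range, so a ≤1% false-positive operating point
would be unreachable by construction, not by implementation. The
latent construction is also the more faithful model of a single-plant,
single-library design, where biological replicate variance is simply
not observable.

**siRNAs.** Per-feature 24-nt counts are Poisson around a wild-type
mean (uniform 100–400 RPTM for labeled TEs, background 2 for the
rest), scaled by the genotype's planted dependence factor (0.02 for
dependent, 1 for independent) and by the library total; 21–23-nt
background strata are included so the 24-nt selection is actually
exercised.

**The default scenario** (`te_silencing_scenario()`) mirrors the
two-mutant study design at reduced scale: 2 × 150-kb chromosomes, 80
genes (1.5 kb) and 80 TEs (400 bp); 60 hypo-DMRs of 300 bp planted
inside distinct TEs of the `suvh29` genotype (deltas −0.10/−0.15/−0.30
by context), the first 15 shared with `morc6`; 30 TEs up-regulated
4-fold per mutant with 12 common, the `morc6` set drawn entirely from
TEs with *no* planted `morc6` methylation change — the synthetic
analogue of silencing release without methylation loss; and 60 TEs
with Pol IV-dependent siRNAs, half of them Pol V-dependent, half Pol
V-independent. Genome size and feature geometry were fixed by a design
power analysis before freezing the scenario: ~160 reads per genotype
per 50-bp window (8 sites × 20×) puts single-window power near 0.98
for the planted composite delta while the strict double threshold
holds the null window rate well under 1%, and the ~14 kb of
non-differential TE sequence bounds the expected number of false DMR
calls low enough for precision above 0.9. The null-calibration
scenario (`null_scenario()`) enlarges the genome to 2 × 255 kb so that
just over 10,000 windows are tested; the DE benchmark
(`de_benchmark_scenario()`) plants 4-fold up-regulation at 50 of 1,000
features.

**What the generator does not model** — and hence what passing
recovery tests do *not* show about real data: sequence-derived context
(contexts are sampled, not read from a genome), mappability and
coverage biases, bisulfite conversion failure (unless enabled),
chromosomal methylation gradients (pericentromeric enrichment),
overlapping or nested annotations, isoform structure, and biological
replicate variance. Recovery rates measured here are statements about
the planted construction under the stated noise model.

## Pipeline and reproducibility

`run_full_pipeline()` executes the stages strictly through files —
each stage reads only what a previous stage wrote — so any stage can
be re-run in isolation, and writes a manifest with the configuration
snapshot, every threshold, input/output MD5 checksums and per-stage
runtimes. Every random draw is a pure function of `(config seed,
stage tag, genotype)`, derived through a small deterministic hash, so
one integer seed fixes the entire run and two runs with the same seed
are byte-identical (the manifest, which records runtimes, is the one
deliberately non-reproducible file). `evaluate_against_truth()` scores
a simulated run: DMR sensitivity/precision under the strict >50-bp
overlap rule (wrong-direction calls count against precision),
expression sensitivity and false-positive rate, and siRNA label
accuracy over informative features.

Internally all coordinates are 1-based and closed — the
`GenomicRanges` convention this package builds on — and conversion
happens only at file boundaries (BED in/out, GFF3 in/out). Gap and
overlap arithmetic is convention-invariant, and the boundary tests pin
the intended readings (50-bp gap merges; 50-bp overlap does not
qualify).

## Known limitations

* The DMR caller is the windowed threshold procedure it set out to
  be: no smoothing, no HMM segmentation, no per-site tests, no
  between-library coverage normalization. Callers of that family will
  disagree with it at region boundaries.
* The expression rule is designed for replicate-free designs;
  with replicates available, a dispersion-modeling framework (DESeq2,
  edgeR) is strictly better and this rule should not be used.
* The hypergeometric enrichment treats regions as exchangeable draws;
  it ignores interval length and genomic clustering, and the choice of
  universe materially changes the p-value — which is why it must be
  supplied explicitly.
* Promoter intervals ignore neighboring-gene clipping and annotated
  TSSs; they are fixed-length flanks of the annotation.
* The siRNA dependence cutoff (0.5) is a convention, not an estimate;
  conclusions should be checked against the reported fold changes.
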