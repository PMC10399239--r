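---
title: "Methods: windowed methylation analysis of targeted bisulfite data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed methylation analysis of targeted bisulfite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methwindow)
```

## Scope and model

methwindow analyzes targeted bisulfite sequencing of TSS-anchored gene
regions: each gene contributes one 3 kb mini-contig holding 2 kb of promoter
followed by 1 kb of gene body, with the transcriptional start site (TSS) as
the first base of the body. Coordinates are 0-based and half-open
throughout, so the promoter is `[0, 2000)`, the body `[2000, 3000)`, and the
fifty-base tiling `[50k, 50(k+1))` is exact: sixty windows per gene, no gap,
no overlap. The pipeline starts from cytosine-level counts (a Bismark-style
CX report per sample: position, strand, methylated reads, unmethylated
reads); read trimming and alignment are upstream of this package.

Every forward-strand `C` is a `+` site; every forward-strand `G` is a `-`
site, i.e. a cytosine on the reverse complement, indexed by its
forward-strand coordinate. The context of a site is read from the two bases
downstream on its own strand: `CG*` is CpG, `CHG` is CHG and `CHH` is CHH
with H in {A, C, T}. Plant methylation machinery treats the three contexts
differently, which is why every statistic is stratified by context.

### Boundary convention

A site within two bases of the region end, or whose downstream dinucleotide
contains `N`, is labeled `ambiguous` and excluded from all statistics. The
targets are extracted subsequences, so the flanking genome is unknown and
guessing a context from it would be fabrication; `N` voids any context it
participates in, matching what bisulfite callers do. This is deliberately
conservative: a `C` one base from the edge followed by `G` is formally a
CpG, but we still drop it so that the rule is a single uniform predicate
(full 2-nt window, N-free). At 3 kb per region this discards at most a
handful of sites per gene.

## Methylation levels

Three estimators, all reported as percentages:

* **Per site**: methylated reads over total reads, `NA` below the coverage
  threshold (`min_coverage`, default 1 — the classification is a coverage
  property, so "missing" is a value, never an error).
* **Per gene (global)**: read-weighted, `sum(meth) / sum(meth + unmeth)`
  over interrogated sites in scope. Read weighting makes a site covered by
  100 reads count ten times a site covered by 10, which is what "averaged
  over all reads" means; the unweighted site mean can differ strongly (two
  sites 1/10 and 90/100 give 82.7% weighted vs 50% unweighted) and is not
  used.
* **Per context**: the default `weighted` mode is the read-weighted mean
  restricted to the context's sites. A `literal` mode additionally divides
  by the number of interrogated context sites in the gene. That double
  normalization produces a per-gene index rather than a methylation level
  (the two modes agree only when the context has exactly one site); it is
  retained behind an explicit flag because some published per-gene context
  indices are computed this way, and asserting either reading as the only
  correct one would be guesswork. Nothing downstream depends on the literal
  mode.

## Site classification and shared states

Replicate counts within a condition x part cell are pooled (summed per
site) before classification, because methylation states are a property of
the group, not of a replicate library; a consensus alternative (methylated
in at least k replicates) can be built from the per-replicate tables but is
not the default. A pooled site below `min_coverage` is `uninterrogated`;
otherwise `unmethylated` iff its methylation level is exactly zero, and
`methylated` for any positive level. Within each (group, region) stratum
the package reports which fraction of unmethylated sites each context
contributes — the three shares sum to 100 by construction, and the test
suite asserts the closure to 1e-9 — and the same for methylated sites.

Between two groups, the shared-state percentage for a context is the number
of sites methylated (or unmethylated) in *both* groups over a denominator
that the underlying definition leaves open. The default `union` mode uses
the sites methylated in either group — "commonly methylated" read as
intersection over union, which is symmetric in the two groups and bounded
by construction. The `either_group_mean` mode divides by the mean of the
two groups' totals instead and is kept for sensitivity analysis; it can
exceed neither 100 in practice but is not guaranteed symmetric-bounded the
same way. Sites uninterrogated in either group are excluded from numerator
and denominator.

## Window statistics and DMR calling

For each gene, window and context, the methylated and unmethylated read
counts of the two compared groups (replicates pooled) form a 2x2 table
tested with a two-tailed Fisher's exact test: the p-value is the sum of the
probabilities of all tables with the observed margins whose point
probability does not exceed the observed one, with ties admitted within a
relative tolerance of 1e-7. The implementation enumerates the
hypergeometric support directly and is checked in the test suite against an
independent binomial-coefficient enumeration (to 1e-9 over an exhaustive
sweep of all tables with row sums up to 40 plus random larger tables) and
against `stats::fisher.test`. A table with a zero margin carries no
information and returns p = 1; a window where either group has zero
coverage in the context is flagged `no_call` rather than tested.

A window is a differentially methylated region (DMR) iff p < `alpha`
(default 0.05, raw) **and** the absolute difference of the two groups'
window methylation percentages exceeds `delta_threshold` (default 20
percentage points, strict inequality — a delta of exactly 20.0 is not
called). The threshold is absolute points, not relative percent, consistent
with methylation being reported as percentages throughout. No
multiple-testing correction enters the call; a Benjamini-Hochberg column is
emitted alongside for the reader. A gene is a differentially methylated
gene (DMG) in a context iff it holds at least one DMR window there, and a
DMG overall iff that holds in at least one of CpG, CHG, CHH; the pooled
"all" track is reported separately.

Two counting levels exist for the Fisher table. The default `reads` level
pools read observations across the three replicates, matching the
read-weighted definition of the methylation level; the `sites` level lets
each interrogated site contribute one methylated-or-unmethylated unit per
its classification and is provided for sensitivity analysis, since counts
of "methylated and non-methylated cytosines" can be read either way.
Pooling replicates before testing (rather than testing replicate means) is
the documented default; the package does not model between-replicate
dispersion (no beta-binomial), does not smooth, and does not merge adjacent
DMR windows — each 50 bp window is tested independently.

## Metaprofiles

The TSS-anchored curve is, per window: the mean over genes of each
replicate's window methylation percentage, then the mean over replicates.
Windows with no coverage in a gene are excluded from that gene's
contribution rather than counted as zero, so sparse genes do not drag the
curve down.

## The synthetic generator

`sim_config()` / `simulate_bundle()` generate a complete, seeded input
bundle for the 2-condition (cool/warm) x 2-part (apical/basal) x
3-replicate design: i.i.d. sequences at a configurable GC content (default
0.40), a per-site methylation probability
`p = base_level[context] * spatial(position) * group factor`, clipped to
[0, 1], and per-replicate counts with Poisson coverage (mean 30 reads per
site) and binomial methylated reads. Defaults: base levels CpG 0.35,
CHG 0.12, CHH 0.03, preserving the CpG > CHG > CHH ordering of plant
methylomes at magnitudes inside the ranges such data show; a linear
promoter decline from multiplier 1.0 at the region start to 0.3 at the TSS
with a 0.25 body plateau, giving the high-promoter/declining-to-TSS/low-body
shape; warm-condition hypermethylation factor 1.4; an extra 1.2 factor for
warm-basal samples emulating the stronger basal-part response; planted
window-level deltas added (pre-clipping) to the warm condition for recovery
tests. Strand partners of a CpG dyad are simulated independently: the
analysis treats strands as independent observations, and coupling them
would only flatter the caller. A bisulfite conversion-failure rate can be
folded into p (default 0). The seed fully determines the bundle, including
the written files, byte for byte.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no permanently unmethylated site class (every
site's p is strictly positive, so at pooled coverage CpG and CHG sites are
essentially never classified unmethylated, and shared-unmethylated
percentages are informative only for the low-level CHH context); no spatial
autocorrelation beyond the deterministic profile; no coverage structure
from capture-probe efficiency; no conversion bias by context; no
between-replicate overdispersion. Conclusions about calibration on real
libraries with replicate heterogeneity do not follow from the binomial
simulation.

## Problem sizes and numerical choices

The test suite runs cohorts of 25-120 genes of 3 kb (60 genes for the
qualitative-shape checks, 40 for null calibration with 2,400 windows, 120
with 500 planted CpG windows for recovery), sizes at which every stage's
behaviour is measurable in seconds while window coverages (hundreds of
pooled observations) match the regime the test statistics assume. Planted
windows are chosen as the most CpG-rich windows of each planted gene —
decided from the simulated sequences before any counts are drawn — so the
per-window coverage condition of the recovery analysis holds by design.
Null calibration accepts up to 7% of windows at p < 0.05: Fisher's exact
test is conservative, so the observed fraction sits near 4-5%, and the
margin covers sampling noise. Ties in the two-sided tail sum use the 1e-7
relative tolerance noted above; percentages are computed in double
precision with no rounding until output.

## Limitations

Raw p-values with a fixed effect threshold (the reproduced rule) inflate
gene-level discovery as target counts grow; the emitted BH column should be
preferred for new analyses. Pooling replicates ignores biological
variance between them. The boundary convention drops a few edge sites per
region. Regions are independent mini-contigs: no genome-wide coordinates,
no probe design, no expression analysis.
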