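---
title: "Stroma-induced transcriptome and regulome analysis: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stroma-induced transcriptome and regulome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experimental design this package models

Bone-marrow stromal cells change myeloma cells through two separable
channels: soluble factors (cytokines such as IL-6 crossing a transwell
membrane) and direct adhesion. The three-condition coculture isolates
them — MONO (myeloma alone), TSW (transwell above stroma: soluble factors
only), CO (lower chamber: soluble factors plus adhesion). Two read-outs
are collected per condition: gene-level RNA counts and ATAC accessible
regions with their read support. Downstream, prognostic relevance of the
induced genes is screened in patient cohorts with expression and overall
survival.

`stromareg` implements the analysis chain for this design and a seeded
synthetic generator of the whole study, so that every statistical claim
the pipeline makes is checkable against planted ground truth.

# Models and procedures

## Differential expression and accessibility

Counts are modeled as negative binomial; testing is delegated to edgeR
(TMM normalization, tagwise dispersion, exact test), the standard tool
for small-replicate designs. A gene is called changed iff FDR < 0.05,
|fold change| > 1.5 and mean log2 CPM > 0; peaks use FDR < 0.01 and
|FC| > 1.5 without an expression floor. Both cutoffs are two-sided:
"fold change > 1.5" is interpreted as |log2FC| > log2(1.5) with the sign
giving the direction, since both induced and repressed features are
reported. The mean log2 CPM is computed with a 0.5 pseudo-count and is
averaged over the two conditions under test; applying the CPM floor to
the per-gene average (rather than per-sample values) is our reading of an
underspecified rule. When the dispersion cannot be estimated (degenerate
input with no within-group variance) a small fixed value (0.05) keeps the
test defined; such inputs produce no calls anyway.

## GFOLD-style posterior fold change

For designs with few replicates the pipeline also provides a
reliability-aware fold change: each group's normalized rate gets a
Gamma posterior under a Poisson likelihood with the Jeffreys prior
(shape 1/2), `rate | counts ~ Gamma(sum(counts)+1/2, sum(libsizes))`.
Because the ratio of two independent Gamma variables is a scaled F
variate, the central 99% credible interval of log2(rateB/rateA) has a
closed form; the reported value is the interval bound nearest zero
(zero when the interval spans it). The differential cutoff
|value| > log2(1.5) = 0.585 mirrors the fold-change rule. Credibility
0.99 and the Jeffreys prior are exposed as arguments.

## Reference peaks and read counting

Per-sample peak calls are merged into union intervals (overlapping or
directly abutting calls merge — the same contiguity a per-base coverage
sweep produces); an interval is kept iff calls from at least
`min_support = 3` distinct samples touch it. "Present" is thus
operationalized as merged-union support counting; the consensus summit is
the (lower) median of contributing call summits, so it always coincides
with an observed summit. Reads are assigned to peaks by the midpoint
rule — a read counts for the peak containing its midpoint — which makes
the assignment unambiguous for boundary-spanning reads and counts every
read at most once. Whether support should be counted across all samples
or within condition is not determined by the design; across-all is
implemented.

## Promoters, regulatory domains, target genes

Promoters are TSS ± 2500 bp; a peak overlapping any promoter window by
≥ 1 bp is a promoter peak, otherwise distal — a partition. Regulatory
domains follow the basal-plus-extension rule: a strand-aware basal domain
(5 kb upstream, 1 kb downstream of the TSS) grown up to 1 Mb per side,
stopping at the nearest other gene's basal boundary on that side. Basal
domains are never truncated, and a neighbor's basal domain that already
overlaps a gene's basal does not truncate the extension; extended domains
of neighboring genes share the intergenic space between their basal
domains, so one distal peak can target two genes. The multi-peak rule
keeps genes that are expressed (mean RPKM ≥ 1 in the comparison
condition — "expressed" is not defined upstream, so it is configurable)
and associated with more than two distinct gaining peaks; whether to
count only distal gaining peaks is a switch (`distal_only`, default off,
since both promoter and distal gains occur at such genes).

## Enrichment statistics

Preranked GSEA is the classic weighted running sum: ordered by score
(ties broken by gene id for determinism), hits add |score|^w / N_R and
misses subtract 1/(N − N_h); ES is the maximal signed excursion;
significance comes from gene-label permutations, NES divides ES by the
mean same-sign null |ES|, and collection-level FDR uses the sign-matched
NES-pooling recipe. The weighting exponent (1) and permutation count
(1000) are the classic defaults since the original run's settings are
unknown. Over-representation of discrete lists uses the upper-tail
hypergeometric with the observed/expected ratio. The K-S shift test
enumerates all label assignments when n·m ≤ 30 (exact p); beyond that it
delegates to `stats::ks.test`, which uses the exact D distribution at
moderate sizes and the asymptotic one for large samples — the plain
asymptotic formula alone is off by up to ~0.05 at n = m = 5, which is why
it is not used there. Concordance between two call vectors reports
observed consistent changes (up-up plus down-down) against the
margins-product expectation; because a pair of 3-level call vectors does
not collapse uniquely to one 2×2 table, significance uses the
overlap-style Fisher table whose first cell is the consistent count with
changed-gene margins.

## Motif model and scanning

Motifs are probability matrices with a 0.1 per-cell pseudo-count (then
renormalized) before forming log2-odds against the background
(uniform unless estimated). Scan p-values come from the exact
distribution of the discretized score: the log-odds matrix is rounded
onto an integer grid with 1/1000 of the score range per step, a dynamic
program accumulates the exact distribution of integer scores of
background sequences, and scanning scores sequences on the same grid so
the lookup is exact on the grid; discretized p-values converge to the
continuous enumeration values as the resolution grows (verified by
exhaustive k-mer enumeration for widths ≤ 6). Both strands are scanned by
default at the conventional p ≤ 1e-4 threshold; offsets containing N are
skipped. Enrichment compares the fraction of foreground (gaining-peak)
windows containing ≥ 1 hit against background windows — non-differential
peaks by default, which is the appropriate control because it shares the
accessible-chromatin sequence composition — with a Fisher exact test.

## Survival screen

For each gene and cohort, patients are split into the top
ceiling(0.25 n) by descending expression (ties broken by patient id;
n < 8 is rejected as degenerate) versus the rest; the log-rank test
(hypergeometric variance, no continuity correction) and a single
binary-covariate Cox model (Breslow ties; Efron behind a flag) give the
per-cohort p and hazard ratio. A cohort supports a gene iff p < 0.05 and
HR > 1; a gene is an unfavorable marker iff the primary cohort supports
it and at least one other cohort does. Monotone partial likelihoods
(one group's events all precede the other's) are flagged and reported as
unbounded rather than as a finite HR; cohorts where a split leaves a
group without events are treated as non-supporting. Each cohort is
analyzed in its own time units.

# The synthetic study generator

The generator is first-class, tested code; its defaults are the study
conditions every recovery claim refers to.

* **Toy genome** — one 10 Mb chromosome; 400 genes at uniform random
  TSSs with ≥ 15 kb spacing (so basal domains never overlap and each
  gene keeps an exclusive basal-side strip), random strand, lengths
  1–10 kb.
* **Expression** — NB counts (dispersion 0.1) around log-normal baseline
  means (median 100); three conditions × 3 replicates (the replicate
  count is a free parameter of the design; 3 is the typical choice).
  10% of genes carry a ±2 log2 effect in TSW and CO; half of those also
  get a +1 log2 same-sign shift in CO only, emulating adhesion acting on
  top of soluble factors (without it the CO-vs-TSW contrast would be
  empty and the concordance analysis degenerate). CO columns are a
  (1−f)/f mixture with a distinct stromal profile (f = 3% < 5%),
  realized as independent NB draws so the stromal share is tracked
  exactly. A 5% stromal-signature gene set is near-silent in the tumor
  (means ≪ 1 read) and very high in the stroma — at toy library depth a
  truly "silent" gene must have essentially zero counts, else a single
  stray read already exceeds RPKM 2.
* **Accessibility** — 1200 master regions: promoter peaks at every
  non-silent gene's TSS, four planted gaining distal peaks in the
  exclusive basal-side strip of each of 10 multi-peak genes (inside the
  domain, outside every promoter window; four, not three, so one missed
  differential call cannot push a gene below the > 2 rule), and
  background peaks ≥ 500 bp apart. Each sample calls each background
  master with probability 0.9 with ±10 bp edge jitter; reads are 50 bp
  intervals with NB counts per peak (mean 50) and Gaussian midpoint
  scatter around the summit, plus 5% uniform noise reads. Planted
  effects (±2 log2) apply in CO. Multi-peak genes are drawn
  preferentially from the expression-induced genes, as chromatin gains
  and induction co-occur in real data.
* **Sequences** — 101 bp summit windows of i.i.d. background bases; a
  PWM-sampled instance is planted with probability 0.25 in gaining
  windows and 0.05 elsewhere, at a random offset and strand. The bundled
  synthetic AP-1-like motif is 10 bp at 0.95 consensus probability —
  deliberately wide and sharp enough that sampled instances with up to
  one mismatch still pass the 1e-4 scan threshold, so planted instances
  are recoverable by construction (a 7 bp PWM cannot be: its 1-mismatch
  words have p ≈ 1.3e-3).
* **Cohorts** — five cohorts of 500 patients (first one primary);
  i.i.d. log-normal expression per screened gene (10 markers + 30
  nulls); exponential survival with baseline hazard 0.1, multiplied by
  HR = 2 for every marker gene in which the patient sits in the top
  quartile; 20% independent censoring (a censored time is uniform on
  (0, event time)). Because all markers share one survival time per
  patient, the marginal per-marker hazard ratio is attenuated below the
  conditional 2 (non-collapsibility) — visible in the screen's HR
  estimates of roughly 1.3–2.0 — but per-cohort support power remains
  ≈ 0.99 at these sizes.
* **Randomness** — a single seed feeds named substreams per data type,
  so regenerating one data type never perturbs another, and identical
  configurations produce byte-identical files.

What the generator does *not* emulate: base-level sequencing error or
FASTQ reads, real genome annotation or GC structure, correlated gene
expression, batch effects, cohort-specific censoring patterns, or a real
stromal expression profile. Passing recovery tests therefore shows the
statistics and integration logic are correct under the stated model, not
that thresholds are optimal for any particular real data set.

# Numerical and engineering choices

* Coordinates are 0-based half-open in all files (BED convention) and
  1-based closed in memory (GRanges); the two converters are exact
  inverses.
* z-scores use the sample (n−1) standard deviation; constant rows map to
  zero rows.
* Stromal-rank ties at position 1000 are all included, making the filter
  order-independent. In the pipeline the "silent in tumor" clause is
  evaluated on MONO/TSW samples only, since CO samples carry the very
  stromal admixture the filter removes.
* The closed-promoter exclusion defaults to "closed in all three
  conditions"; the stricter reading ("not open in all three") is a
  switch (`require_all_open`).
* GSEA ranking ties and quartile-boundary ties break on feature id;
  rnk files are sorted descending by fold change with excluded genes
  omitted.
* Motif width ≥ 3 is accepted (enumeration oracles need width 3);
  resolutions below 100 and permutation counts below 100 warn rather
  than fail.
* Problem sizes in the test-suite null-calibration and recovery runs
  (2000 replicate features for the callers, one default-scale pipeline
  run, 500-patient cohorts) were chosen as the smallest sizes at which
  the Monte-Carlo error of the checked rates is comfortably below the
  asserted bounds.

# Known limitations

* edgeR's moderated dispersions and exact test are used as-is; the
  package does not attempt bit-level reproduction of any particular
  edgeR version's output, only calibrated behavior (verified by null
  simulation).
* GREAT's curated regulatory-domain corrections and its ontology
  enrichment service are not replicated; gene-set enrichment is the
  generic hypergeometric test over user-supplied GMT collections.
* The GSEA collection FDR follows the sign-matched pooling recipe; with
  very few sets it is coarse.
* No BAM/FASTQ parsing: peak calls and read intervals enter as
  narrowPeak/BED, counts as TSV.
* The survival screen is single-covariate by design (the published rule
  it implements is marginal); no multivariate adjustment or
  proportional-hazards diagnostics.
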