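# stromareg

Multiple myeloma (MM) cells reprogram their transcriptome and their
accessible chromatin ("regulome") within days of contact with bone-marrow
stromal cells (BMSCs) — a non-genetic route to the stroma-induced drug
tolerance seen in the marrow niche. The canonical experiment separates the
two routes of communication with a three-condition coculture: myeloma cells
alone (**MONO**), myeloma cells in a transwell above the stroma so that only
soluble factors pass (**TSW**), and myeloma cells in direct contact in the
lower chamber (**CO**).

`stromareg` implements the complete analysis that turns that design into
regulatory biology, as a tested, reusable R package:

* **Differential transcriptome** — edgeR-based negative-binomial calls per
  contrast with the three-part rule FDR < 0.05, |FC| > 1.5, mean log2 CPM
  > 0; RPKM/CPM quantification; the stromal-signature filter (top stromal
  genes that are silent in the tumor, RPKM < 2 — needed because sorted CO
  cells carry < 5 % stromal contamination) and the closed-promoter filter.
* **Differential regulome** — consensus reference peaks ("present in at
  least three samples"), midpoint read counting, negative-binomial calls
  (FDR < 0.01, |FC| > 1.5) and a GFOLD-style posterior fold-change bound
  with |value| > log2(1.5) = 0.585, promoter (TSS ± 2.5 kb) vs distal
  classification, and summit ± 50 bp windows for motif work.
* **Integration** — GREAT-style basal-plus-extension regulatory domains
  (5 kb/1 kb basal, ≤ 1 Mb extension), peak→gene assignment, the
  multi-peak rule (expressed genes with > 2 peaks gaining accessibility),
  K-S expression-shift tests, call-concordance contingency analysis,
  preranked GSEA and hypergeometric gene-set enrichment, and PWM motif
  scanning with FIMO-style exact score distributions plus
  foreground/background motif enrichment.
* **Prognosis** — top-quartile expression splits, Kaplan–Meier/log-rank,
  single-covariate Cox hazard ratios, and the multi-cohort unfavorable
  marker rule (p < 0.05 & HR > 1 in the primary cohort and at least one
  other).
* **Synthetic study generator** — a seeded simulator that emulates the
  whole design (NB counts with planted fold changes and < 5 % stromal
  admixture in CO, per-sample peak calls and reads with planted
  accessibility gains, summit windows with planted motif instances,
  survival cohorts with planted hazards) together with truth tables, so
  every stage is validated by null calibration and parameter recovery.

## Worked example

```r
library(stromareg)

cfg <- pipeline_config(sim = sim_config(seed = 1))
run <- run_pipeline(cfg, outdir = "results")
print(run)
```

```
stromareg pipeline run
  genes: 400, reference peaks: 1200
  DE TSW_vs_MONO: 22 up / 20 down
  DE CO_vs_MONO: 42 up / 22 down
  DE CO_vs_TSW: 23 up / 2 down
  diff peaks CO vs MONO: 92 up / 54 down
  multi-peak genes: 11; markers: 9
  recovery: DE sens 1.00 (emp. FDR 0.09), multipeak 1.00/1.00, markers 0.90
  motif: fg 0.250 vs bg 0.046 (p = 7.4e-10)
  elapsed: 21.9 s
```

Reading the output: of 400 simulated genes, the planted expression effects
are recovered in the CO-vs-MONO contrast with sensitivity 1.0; all 1200
master peaks reach the 3-sample support threshold; the 10 genes planted
with > 2 gaining distal peaks are all found (plus genes whose domains
genuinely collect enough gaining background peaks — precision is scored
against that domain-level truth); 9 of 10 planted prognostic markers pass
the multi-cohort rule; and the planted motif appears in 25 % of gaining
summit windows versus 4.6 % of non-differential ones. `results/` holds the
per-stage tables (DE, rnk, reference peaks, differential peaks with GFOLD
values, peak–gene associations, multi-peak genes, GSEA, survival screen)
and a `manifest.json` with the seed, thresholds and stage counts needed to
reproduce the run.

Individual stages are exported directly, e.g.

```r
ref <- compile_reference_peaks(peak_call_list, min_support = 3)
counts <- count_reads_in_peaks(read_list, ref, condition)
dp <- differential_peaks(counts, "MONO", "CO")
gfold_value(c(50, 61), c(200, 188), rep(1e6, 2), rep(1e6, 2))
```

A thin command-line wrapper lives at `inst/cli/stromareg`
(`stromareg simulate|run|expr-de|atac-ref|gsea|motif-scan|survival-screen`).

## Vignette

`vignettes/coculture-regulome.Rmd` documents the model and its
assumptions, every tunable threshold with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical
design choices (tie-breaks, discretization, degenerate inputs).
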