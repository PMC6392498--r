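# stra8pipe

Integration of replicated promoter ChIP-seq peaks with staged expression
profiles at meiotic initiation.

When mouse male germ cells enter meiosis, the transcription factor STRA8 —
expressed only in mid-to-late preleptotene spermatocytes — binds thousands of
gene promoters and amplifies an already-active transcriptional program.
Defining which genes are *STRA8-bound* and *STRA8-activated* requires
integrating several independent data types: replicated ChIP-seq peak calls
with matched non-tagged controls, RNA-seq profiles of sorted preleptotene
cells with and without *Stra8*, the dose of the CNCCTCAG binding motif at
each promoter, a multi-tissue expression panel, and the histological
arithmetic of the seminiferous epithelium. `stra8pipe` implements that
integration as a reusable, fully tested R pipeline, together with a seeded
synthetic-data generator so every stage can be validated without any
sequencing download.

## The core definitions and statistics

* **Promoter assignment.** A peak belongs to a transcript when its summit
  *s* satisfies *s* ∈ [TSS − 1 kb, TSS + 1 kb); a summit within reach of
  several TSSs is assigned to all of them. All coordinates are 0-based,
  half-open.
* **Replicate-consensus target calling.** A gene is *bound* when its
  promoter carries a peak in ≥ 2 of 3 tagged-ChIP replicates and in none of
  the control replicates (control filtering precedes the consensus count).
* **Expression integration.** Genes expressed at ≥ 1 TPM in ≥ 1 sample are
  tested for differential expression between knockout and high-STRA8
  preleptotene samples (FDR *q* < 0.05); *activated* = bound ∧ upregulated.
  The bound × direction 2×2 table is tested with Fisher's exact test
  (odds ratio with Woolf CI), and set overlaps with one-tailed
  hypergeometric tests computed in log space (reported as log10 *p*, since
  genome-scale overlaps reach *p* < 10⁻³⁰⁰).
* **Motif dose-response.** The degenerate core motif CNCCTCAG is counted
  (perfect match, both strands, overlaps included) in the 2 kb promoter
  window (max over transcripts) and in 100 bp summit windows; motif count is
  related to peak score by Spearman's ρ with a permutation *p*, and to
  expression change by motif-count strata compared with Mann-Whitney U
  tests.
* **Cell census.** The closed-form estimate of the STRA8-expressing
  preleptotene fraction of the adult testis: spermatocytes are 25/133.3 of
  all testis cells; preleptotene cells occupy ~40 hr of the 326-hr
  spermatocyte lifespan (half of stage VI, all of VII, half of VIII); STRA8
  is expressed for ~25 hr of those 40; hence ~1.4% of all testis cells, and
  a 31-fold enrichment when synchronization raises the observed fraction to
  44%.

## Worked example

```r
library(stra8pipe)

# the cell-census worked example, with intermediates rounded as published
census_report(cell_census(), stage_table(), observed_2s_fraction = 0.44,
              rounding = "paper")
#> Testis cell-census report (paper mode)
#>   total cells per testis:            133.3 x 10^6
#>   spermatocytes:                     18.8% of all cells
#>   preleptotene lifespan:             40.00 hr
#>   preleptotene / spermatocytes:      12.3%
#>   preleptotene / all cells:          2.3% (3.07 x 10^6)
#>   STRA8 expression duration:         25.00 hr
#>   STRA8+ / preleptotene:             62.5%
#>   STRA8+ preleptotene per testis:    1.88 x 10^6
#>   STRA8+ preleptotene / all cells:   1.4%
#>   enrichment at observed 44% 2S:    31.3-fold

# a full synthetic run at the reference study conditions
report <- run_pipeline(pipeline_config(seed = 42))
report
#> Pipeline run report
#>   genes 1000 | expressed 1000 | up 254 | down 195 | bound 238 | activated 238
#>   promoter peak fraction: FLAG 82.4%, control 0.0%
#>   activated/up = 93.7%; OR = 5.65e+03 (Fisher log10 p -108.4)
#>   motif-score Spearman rho = 0.19 (permutation p 0.0001)
#>   recovery: bound sens 0.952, FPR 0.0000; activated sens 0.952, precision 1.000
```

The run simulates a 5 Mb genome with 1000 genes (250 truly bound, with
planted CNCCTCAG doses), three tagged and three control ChIP replicates at
0.9 per-replicate sensitivity, and a 3 + 2 + 2 knockout/low/high expression
design. The report shows that the consensus call recovers 95% of truly
bound genes with no false positives, that peaks concentrate at promoters in
the tagged replicates only, that essentially all upregulated genes are bound
(the synthetic program is purely STRA8-driven), and that motif dose
correlates with binding strength. `run_pipeline(..., outdir = "out/")`
additionally writes every stage's gene lists and tables plus a JSON report;
two runs with the same configuration are byte-identical.

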