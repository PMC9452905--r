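# icbsig

Signature discovery for immune checkpoint blockade (ICB) response in clear
cell renal cell carcinoma (ccRCC), from single-cell marker statistics to a
validated gene panel.

Only a minority of ccRCC patients respond to anti-PD-1/PD-L1 therapy.
`icbsig` implements, as a tested and reusable R pipeline, a workflow that
starts from subclustered single-cell expression, screens the gene sets
enriched in each subcluster's markers for outcome predictiveness in a bulk
cohort, localizes the predictive programs to specific cell subtypes, and
distills a compact prediction signature by greedy AUC-maximizing feature
elimination — validated by ROC analysis and survival stratification. A
synthetic-data generator with planted ground truth exercises every stage.

## The core statistics

* **Nearest-centroid multiple random validation.** For a gene panel $G$,
  genes are standardized on the training split and each class summarized by
  its centroid; a sample's continuous prediction score is
  $z = d(x, c_R) - d(x, c_{NR})$ (Euclidean distance, larger = more
  nonresponder-like). Over `n_rep` stratified 2/3–1/3 splits, held-out
  scores are averaged per sample; the AUC is the midrank Mann–Whitney
  statistic on these scores, the ROC p-value a Welch $t$ test, and
  sensitivity/specificity carry Wilson 95% intervals.
* **The cycle algorithm.** From a candidate list of $n$ genes, every
  leave-one-out subset is evaluated ($n$ validator runs), the max-AUC
  subset survives, and the cycle repeats down to 3 genes
  ($n + (n-1) + \dots + 4$ evaluations in total); the signature is the
  smallest panel within `delta` of the trace-maximum AUC.
* **Single-sample gene-set scores** (GSVA-style Gaussian-kernel CDF →
  symmetric rank statistics → weighted random walk) localize predictive
  sets to subclusters and score cohorts for survival analysis
  (Kaplan–Meier, log-rank, maximally selected cutpoints, univariate Cox).

## Worked example

```r
library(icbsig)

# synthetic ground truth: 3 subclusters, a 30-gene resistance program,
# NR-shifted subtype abundance
sc <- generate_single_cell_dataset(300, 200, 3,
                                   synthetic_truth_params(), seed = 1)
bulk <- generate_bulk_cohort(80, 0.3, sc$truth, seed = 1)

report <- multiple_random_validation(
  bulk$expr, bulk$sample_meta$response,
  genes = sc$truth$planted_genes$resistance, n_rep = 50, seed = 3)
report
#> <validation_report> n=80, AUC=0.931 (0.872-0.977), p(Welch)=6.18e-11
#>   sens=89.3% (78.5-95.0), spec=83.3% (64.1-93.3) at cutoff -0.013
```

The planted resistance panel separates nonresponders from responders with
AUC 0.93; sensitivity/specificity are reported at the Youden-optimal
cutoff with Wilson intervals. The full workflow — markers → enrichment →
screen → localization → candidate assembly → elimination → validation →
survival — runs on a synthetic fixture in one call:

```r
run <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
cat(report_summary(run), sep = "\n")
```

which writes per-stage TSV/JSON artifacts plus a hash manifest (re-running
the same configuration reproduces every number exactly).

## Documentation

The methods vignette (`vignettes/signature-discovery.Rmd`) documents the
models and their assumptions, the tunable parameters and defaults, what
the synthetic generator does and does not emulate, numerical edge cases,
and known limitations (including the anti-conservative Welch ROC p under
the null and the noise sensitivity of the delta selection rule).
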