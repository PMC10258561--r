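# egrnet

Inference and evaluation of **enhancer-mediated gene regulatory networks
(eGRNs)** from paired bulk RNA-seq and chromatin-accessibility cohorts.

Most trait-associated genetic variants sit in non-coding regulatory
regions. Interpreting them requires cell-type-specific maps of which
transcription factor (TF) acts through which accessible region ("peak")
on which gene. egrnet is for computational biologists with a cohort
(≈10–45 individuals or samples of one cell type) profiled with both
RNA-seq and ATAC-seq (or similar), plus precomputed TF binding-site
predictions — and for anyone with *any* TF–gene network who wants an
unbiased, prediction-based measure of its biological relevance.

## The method in brief

**TF–peak links** come from an empirical false discovery rate on
motif-stratified correlations. For each TF, peaks split into a foreground
(contains a predicted binding site) and background (does not). Pearson
correlations r between TF expression and peak accessibility are binned
(40 bins of width 0.05 on [−1, 1]) and each threshold k gets, per
direction (positive: r ≥ k; negative: r < k),

    efdr_k = nfp_k / (nfp_k + ntp_k),   nfp_k pre-scaled by ntp/nfp,

where ntp_k, nfp_k count foreground/background peaks past the threshold.
Motif-containing pairs take their bin's efdr; pairs at efdr ≤ 0.2
(default) become links, and the significant direction classifies TFs as
activators (positive) or repressors (negative).

**Peak–gene links** are Pearson correlations between peak accessibility
and expression of genes with a TSS within 250 kb (or within a shared TAD),
with t-based p-values, filtered to positive correlations, then
Benjamini–Hochberg adjusted (FDR ≤ 0.1 default). The two tables join on
the peak into a tripartite TF → peak → gene network, with community
detection, regulons, network statistics, and seeded randomized
backgrounds as quality controls.

**Evaluation**: a random-forest regression predicts an independent
differential-expression response (log2FC of genes passing adj. p < 0.1,
|log2FC| > 1) from the binary gene × TF wiring matrix, under 10-fold
cross-validation × 10 runs. Out-of-fold R² is compared against a
degree-preserving gene-label-permuted network (two-sample t-test) and a
random-signal control (Uniform(−5, 5) targets, which must score ≈ 0);
out-of-bag permutation importance ranks candidate driver TFs.

A seeded synthetic generator plants a ground-truth tripartite network on
a synthetic genome and emits exactly the files the pipeline consumes, so
the whole method is testable without downloads.

## Worked example

```r
library(egrnet)

params <- simulation_params(seed = 1)   # 30 samples, 20 TFs, 500 peaks, 300 genes
truth  <- simulate_truth(params)
cohort <- simulate_cohort(truth)
res <- run_egrn_pipeline(cohort$rna, cohort$atac, cohort$tfbs,
                         cohort$genes, background_seed = 42)
res$egrn
#> egrn: 20 TFs, 180 peaks, 199 genes, 344 TF-peak-gene triplets
nrow(res$background$tf_peak)
#> [1] 19
```

The pipeline calls 302 TF–peak links on this cohort while the twofold
randomized background (shuffled overlap matrix + permuted sample labels)
yields only 19 — the signal-to-noise check a real study should pass.
Evaluating the recovered TF–gene structure against a simulated knockout
of the three best-connected TFs:

```r
pert <- select_perturbed_tfs(truth)     # "TF07" "TF11" "TF15"
de   <- simulate_de(truth, pert, seed = 2)
net  <- truth_tf_gene_network(truth)
cv   <- fit_cv(build_feature_matrix(net, de), seed = 3)
cv
#> cv_result: 10 runs on 77 genes; mean R^2 = 0.820, AUROC = 0.998, AUPRC = 0.999
head(tf_importance(build_feature_matrix(net, de), seed = 3)[, 1:2], 5)
#>   tf_id importance
#> 1  TF15 6.78631071
#> 2  TF11 5.97528301
#> 3  TF07 3.67463906
#> 4  TF17 0.11427262
#> 5  TF10 0.05070093
```

The network predicts the response (mean out-of-fold R² 0.82) and the
permutation importance ranks exactly the three perturbed TFs first. On a
degree-preserving permuted network the same evaluation scores R² ≈ 0.

A thin command-line wrapper covers the same flow from a shell
(`inst/cli/egrnet.R`, subcommands `simulate`, `build`, `evaluate`), and
`vignettes/egrn-methods.Rmd` documents the model, parameters and design
choices.

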