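# coxfuse

Graph-guided fusion of matched mRNA and miRNA expression data into one Cox
risk-prediction model.

## What it does, and for whom

Cohort studies increasingly profile mRNA **and** miRNA expression on the
same patients, with a right-censored clinical endpoint (relapse, death).
miRNAs repress their target transcripts, so a prognostic miRNA tends to
leave two traces: its own expression and negatively correlated target
transcripts. `coxfuse` is for biostatisticians and computational biologists
who want one prediction model over both layers that *uses* this structure
instead of ignoring it.

The method has three ingredients:

1. **A bipartite weight graph.** For every (mRNA *i*, miRNA *j*) pair, the
   Pearson correlation across samples is tested against zero
   (t = r·√((n−2)/(1−r²)), two-sided, Benjamini–Hochberg corrected over all
   p₁·p₂ tests), giving p<sup>cor</sup>. Sequence-based target predictions
   contribute p<sup>pred</sup> (listed pairs keep their p-value; unlisted
   but covered pairs get 1; uncovered pairs fall back to correlation
   evidence alone). Covered pairs are combined by Stouffer's rule,
   p<sup>comb</sup> = 1 − Φ((Φ⁻¹(1−p<sup>cor</sup>) + Φ⁻¹(1−p<sup>pred</sup>))/√2),
   and w = 1 − p<sup>comb</sup> becomes the adjacency of a directed graph
   mRNA → miRNA.
2. **Componentwise likelihood-based Cox boosting.** Each step updates the
   single coefficient maximizing the penalized score statistic
   U²/(F + λ) by γ̂ = U/(F + λ) — implicit feature selection. The graph
   steers the penalties: a selected feature's penalty is escalated so its
   stepsize factor ν = F/(F+λ) shrinks by exactly c_f (default 0.9), and
   when an mRNA is selected, the penalties of its connected miRNAs are
   relaxed so their shrinkage fraction s = λ/(F+λ) shrinks by exactly
   c_w = 1 − w(1−c_f). Regulator miRNAs of prognostic transcripts thus
   become easier to select.
3. **Honest error estimation.** IPCW prediction error curves
   (Brier score reweighted by the reverse Kaplan–Meier censoring estimate),
   their integral (IPEC), the .632 bootstrap
   (0.368·apparent + 0.632·out-of-bag, per replicate), paired one-sided
   Wilcoxon comparison of IPEC distributions, and bootstrap
   feature-selection stability counts.

A seeded synthetic-data generator produces matched two-layer datasets with
a planted regulatory network, a sparse Cox signal and ~80% censoring, so
every claim the package makes about itself is checkable against known
ground truth.

## Worked example

```r
library(coxfuse)

ds    <- simulate_fusion_data(sim_config(seed = 1))
graph <- fusion_graph(ds$x_mrna, ds$x_mirna, ds$predictions)
fit   <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status,
                 steps = 50, graph = graph, cf = 0.9)
print(ds); print(graph); print(fit)
```

```
Synthetic two-layer survival dataset
  n = 100 samples, 300 mRNAs, 30 miRNAs
  events: 21 / censored: 79
  true edges: 150; prognostic miRNAs: miR009, miR013, miR024
Bipartite fusion graph (mRNA -> miRNA)
  300 mRNAs x 30 miRNAs; 900 correlation-only pairs
  prediction source: synthetic; correction: BH
  weights: min 0.000  median 0.000  q90 0.007  max 1.000
Componentwise Cox boosting fit (graph-guided)
  n = 100 (21 events), p = 330 (300 mRNA + 30 miRNA)
  steps = 50, initial penalty = 189, cf = 0.9
  nonzero coefficients: 15
```

The generator planted three prognostic miRNAs (miR009, miR013, miR024).
The fitted model's strongest coefficients are exactly those:

```r
head(summary(fit)$coefficients, 5)
```

```
   feature layer coefficient times_selected
1   miR009 mirna      1.2945             13
2   miR013 mirna      0.6384              9
3   miR024 mirna      0.5628              8
4 mRNA0029  mrna     -0.2042              3
5 mRNA0128  mrna      0.1853              4
```

Does the graph actually help prediction? Evaluate graph-guided and plain
fits on the *same* 50 bootstrap samples and compare IPECs:

```r
lambda <- 9 * sum(ds$status)
bg <- bootstrap_632(ds$x_mrna, ds$x_mirna, ds$time, ds$status,
        coxfuse_trainer(steps = 50, penalty = lambda, graph = graph, cf = 0.9),
        B = 50, seed = 2)
bp <- bootstrap_632(ds$x_mrna, ds$x_mirna, ds$time, ds$status,
        coxfuse_trainer(steps = 50, penalty = lambda), B = 50, seed = 2)
print(bg); print(bp)
compare_ipecs(bg$ipecs, bp$ipecs)$p_value
head(selection_counts(bg), 3)
```

```
.632 bootstrap evaluation: B = 50, tau = 0.9429924
  IPEC median 0.07216 (IQR 0.01762)
.632 bootstrap evaluation: B = 50, tau = 0.9429924
  IPEC median 0.07775 (IQR 0.02158)
paired one-sided Wilcoxon p = 4.8e-05
  feature layer count
1  miR009 mirna    50
2  miR013 mirna    50
3  miR024 mirna    50
```

The graph-guided model has a lower median integrated prediction error
(0.072 vs 0.078 on this time scale; smaller is better), the paired
difference is significant, and the true prognostic miRNAs are selected in
every bootstrap replicate. A covariate-free Kaplan–Meier reference curve
(`km_reference_curve()`) provides the upper benchmark any useful model must
beat.

Real data enter through TSV readers (`read_expression`, `read_clinical`,
`read_predictions` — the latter also accepts TargetScan-style files, using
1 − P_CT as the per-pair p-value). A small CLI wraps the same functions:

```sh
Rscript inst/cli/coxfuse.R simulate --seed 7 --out demo/
Rscript inst/cli/coxfuse.R evaluate --mrna demo/mrna.tsv --mirna demo/mirna.tsv \
    --clinical demo/clinical.tsv --graph build --predictions demo/predictions.tsv \
    --B 50 --seed 7 --out demo_eval/
```

## Documentation

The methods vignette (`vignettes/coxfuse-methods.Rmd`) describes the model,
the penalty-update algebra and its exact contracts, the IPCW estimator
conventions, what the synthetic generator does and does not emulate, and
all numerical choices.
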