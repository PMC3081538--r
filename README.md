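# mitoCombine

Which combination of protein localization predictors should you trust?

Identifying nuclear-encoded mitochondrial proteins is a standard step in
hunting mitochondrial disease genes, and dozens of evidence sources exist:
targeting-signal predictors, Pfam-domain tests, orthology and ancestry
tests, coexpression and induction data sets, MS/MS detection. The common
practice of fusing *all* available sources into one classifier rests on the
assumption that more independent evidence can only help. mitoCombine
provides the machinery to test that assumption: it evaluates **every
non-empty subset** of a tool roster under one fixed protocol and reports
which combinations actually perform.

For a roster of *n* tools the package:

- enumerates all 2^*n* − 1 subsets (2047 for the classic 11-tool roster);
- evaluates each subset by repeated stratified train/test resampling of a
  soft-margin RBF-kernel SVM (defaults: C = 10, γ = 0.1, test sets of
  exactly 100 mitochondrial / 630 non-mitochondrial proteins, 100 runs),
  with a support-vector overfitting gate (flagged when SVs ≥ 10% of the
  training set);
- computes per-run sensitivity SN = TP/(TP+FN), specificity
  Spec = TN/(TN+FP), FDR = FP/(FP+TP), and the class-prior-corrected
  cFDR = (1−Spec) / ((1−Spec) + SN·π) with π = 1500/21000, the approximate
  genome-wide fraction of mitochondrial genes;
- ranks combinations, computes per-tool contribution probabilities (the
  share of top-k combinations containing each tool), and contrasts the best
  small subset against the full roster with a Welch z test.

Everything is seeded and deterministic: identical configuration gives
byte-identical result files, serial or parallel. Because the curated
feature tables such studies use are rarely redistributable, the package
includes a first-class synthetic generator (`generateDataset()`,
`paradoxScenario()`) that emulates a 467 mitochondrial / 6352
non-mitochondrial benchmark with heterogeneous, correlated and low-coverage
tools.

## Worked example

```r
library(mitoCombine)

cfg <- paradoxScenario(seed = 1, nPos = 150, nNeg = 1350)  # desk-scale table
fs  <- imputeMissing(generateDataset(cfg))
fs
#> FeatureSet: 11 tools x 1500 proteins (150 mitochondrial, 1350 non-mitochondrial)
#> tools: MITODOMAIN, TargetP, MITOPRED, CisMotif, MsMsTissue, MitoProtII, SubLoc, ...
#> missing cells: 0.0%

roster <- c("MITODOMAIN", "TargetP", "MITOPRED", "MitoProtII",
            "YeastHomology", "Induction", "RickettsiaOrth", "Coexpression")
ss <- splitSpec(nTestPos = 50, nTestNeg = 315, nRuns = 10, baseSeed = 1)
summaries <- runSweep(fs[roster, ], ss)   # 255 subsets x 10 runs

head(rankCombinations(summaries, "sensitivity")[,
     c("tool_names", "size", "mean_sens", "sd_sens", "mean_spec")], 3)
#>                                                          tool_names size mean_sens    sd_sens mean_spec
#> 1            TargetP+MITOPRED+MitoProtII+YeastHomology+Coexpression    5     0.876 0.03627059 0.9857143
#> 2 MITODOMAIN+TargetP+MITOPRED+MitoProtII+YeastHomology+Coexpression    6     0.872 0.04341019 0.9828571
#> 3                          TargetP+MITOPRED+YeastHomology+Induction    4     0.870 0.03915780 0.9850794

cmp <- compareBestVsFull(summaries, maxSize = 7)
cmp[c("best_mean_sens", "full_mean_sens", "difference", "z", "p", "paradox")]
#> $best_mean_sens 0.876   $full_mean_sens 0.836
#> $difference 0.04        $z 2.22   $p 0.0266   $paradox TRUE
```

The reading: the best ≤7-tool combination recovers 87.6% of held-out
mitochondrial proteins on average while the full 8-tool roster recovers
83.6%, a gap of 4 percentage points (Welch z = 2.22) — fusing every
available tool is measurably worse than fusing a chosen few. Mean
specificity stays above 98% throughout, so the subsets differ almost
entirely in recall. `contributionTopK(summaries, "sensitivity", k = 100)`
shows which tools drive the top combinations (here TargetP appears in 96 of
the top 100, the designed weak tools in about half — chance level).

Metrics are kept on the [0, 1] scale in all data structures; multiply by
100 when you want percent.

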