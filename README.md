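# nephroSA

Structural-alert mining and model evaluation for drug-induced
nephrotoxicity (DIN).

Drug-induced kidney injury is a leading cause of safety failures in drug
development, and the structural basis of nephrotoxicity is poorly
understood. One practical line of attack is *structural alerts* (SAs):
substructures that occur far more often in nephrotoxic than in
non-nephrotoxic drugs, so that their presence flags a candidate molecule
for closer scrutiny. `nephroSA` implements that analysis end-to-end for
toxicologists and cheminformaticians:

- **Alert mining.** Every bit of a binary substructure-key fingerprint
  (Klekota–Roth-style SMARTS keys) is scored by its *positive rate*

  PR(b) = N<sub>fragment_positive</sub> / N<sub>fragment</sub>,

  the fraction of fragment-carrying drugs that are nephrotoxic, and by a
  Fisher discrimination *f-score*

  F(b) = [(x̄⁺ − x̄)² + (x̄⁻ − x̄)²] / (s²₊ + s²₋).

  Bits present in ≥ 6 drugs with F ≥ 0.005 and PR ≥ 0.75 (all inclusive)
  are selected as alerts; alerts absent from every non-toxic drug are
  flagged *exclusive*.
- **Alert screening.** A compound is predicted nephrotoxic iff it
  contains at least one selected alert; the screen report tallies
  accuracy among alert carriers, among alert-free compounds, and overall,
  with matched bits listed per compound for interpretability.
- **Classifier evaluation.** The confusion-matrix metric suite used in
  QSAR toxicity work — total accuracy Q, sensitivity SE, specificity SP,
  enrichment factor EF = [TN/(TN+FN)] / [(TN+FP)/N], Matthews correlation
  MCC, rank-based ROC/AUC — plus simple-average consensus modelling and
  an audit bridge (`reconstructConfusion`) that recovers exact integer
  confusion matrices from published SE/SP percentages and class sizes.
- **Compound handling.** CSV/SDF/SMILES input with salt stripping to the
  largest organic fragment, canonical-SMILES deduplication, stratified
  train/validation splitting, and a rejects report (nothing is dropped
  silently).
- **Chemical-space analysis.** Eight physicochemical properties (MW,
  MPSA, AlogP, LogS, nHBA, nHBD, nRotB, nAR), Welch t-tests between
  classes, PCA projection of the descriptor space, and ECFP4 mean
  pairwise Tanimoto similarity as a diversity summary.
- **Synthetic data.** A planted-alert generator (both abstract bit
  matrices and real SMILES built around a bundled 16-alert catalog) so
  the whole pipeline is testable without any external data set.

Chemistry (SMILES/SMARTS/SDF, descriptors, ECFP4) is handled by
ChemmineR/ChemmineOB (Open Babel); the mining, screening and evaluation
mathematics are implemented here.

## Worked example

A synthetic end-to-end run: 32 nephrotoxic compounds built around the
bundled alert substructures and 32 alert-free scaffolds, fingerprinted,
mined and screened.

```r
library(nephroSA)

cfg <- pipelineConfig(seed = 42, outdir = "demo_run", min_support = 2,
                      synthetic_n_pos = 32, synthetic_n_neg = 32)
res <- runPipeline(cfg)

res$mining
#> $min_support: 2   $f_min: 0.005   $pr_min: 0.75
#> $n_candidates: 16   $n_selected: 16   $n_exclusive: 16
res$screen$accuracy_overall
#> [1] 100
```

All 16 bundled alerts are recovered (the generator plants them only in
the toxic class, so each has positive rate 1 and is *exclusive*), and the
screen classifies the synthetic set perfectly — the generator guarantees
separability, so this is a correctness check, not a performance claim.
The mined table is written to `demo_run/alerts.csv`; its top rows:

```
 bit_id                               smarts n_pos n_neg positive_rate    f_score
 KR1798         [!#1]c1[cH][cH]c(F)[cH][cH]1     6     0             1 0.11177885
 KR3586                         Cc1cccc(F)c1     5     0             1 0.08969907
 KR3206                     c1nc2ccccc2[nH]1     4     0             1 0.06919643
```

Evaluating a published classifier from its printed sensitivity and
specificity (external validation set: 55 nephrotoxic / 54 non-toxic):

```r
cm <- reconstructConfusion(87.27, 87.04, n_pos = 55, n_neg = 54)
counts(cm)
#> tp fp tn fn
#> 48  7 47  7
formatMetrics(metricsReport(cm, auc = 0.91))
#>       q      se      sp      ef     mcc     auc
#> "87.16" "87.27" "87.04"  "1.76"  "0.74"  "0.91"
```

The reconstructed integer counts re-yield the printed Q/EF/MCC exactly —
the internal-consistency check the evaluation module is built around.

## Package layout

- `R/` — S4 classes (`CompoundSet`, `SmartsCatalog`,
  `FingerprintMatrix`, `AlertSet`, `ConfusionMatrix`, `ScreenReport`,
  `PredictionSet`, `SyntheticSpec`) and the module functions.
- `inst/extdata/nephrotoxicity_alerts.csv` — the bundled 16-alert SMARTS
  catalog.
- `inst/scripts/run_pipeline.R` — thin command-line wrapper over
  `runPipeline()`.
- `vignettes/alert-mining.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations.
- `tests/testthat/` — unit, property and reproduction tests, including a
  brute-force subgraph-embedding oracle for the SMARTS matcher.
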