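# pairedSDM

Ensemble species distribution modelling with a paired-scenario
validation rubric, built around the forest skink *Sphenomorphus
incognitus* in southern China. The package asks a concrete question:
when a land-use ("human disturbance") layer is added to an otherwise
climatic/terrain ensemble SDM, does the disturbance-aware habitat map
explain the species' occurrences better than the natural-only map —
and by how much habitat area?

It is written for ecologists who want the full workflow as tested,
reusable functions: occurrence thinning, predictor collinearity
filtering, pseudo-absence sampling, a nine-learner registry (GLM, GBM,
RF, CTA, ANN, FDA, MARS, MAXENT, XGBOOST) with TSS/AUC/kappa/CSI
screening, top-k ensembles, permutation variable importance,
Fisher–Jenks habitat grading with area/centroid accounting, and a
randomized paired-map scoring rubric tested with a likelihood-ratio
G-test. A seeded synthetic landscape and virtual-species generator
stands in for the original WorldClim/GEBCO/CNLUCC rasters, so every
step runs and is testable at desk scale.

## The statistics at the core

**Model screening.** Each fitted model is evaluated on held-out points
via the confusion matrix at the TSS-optimal threshold: TSS =
sensitivity + specificity − 1, Cohen's kappa, the critical success
index CSI = TP/(TP+FP+FN), and rank-based AUC. These combine into a
conditional composite score

γ = ¼ Σ<sub>m ∈ {CSI, KAPPA, ROC, TSS}</sub> K<sub>m</sub> · w(K<sub>m</sub>),  w(K<sub>m</sub>) = 0.5 if K<sub>m</sub> > t<sub>m</sub>, else 0.3

with thresholds t = (0.3, 0.4, 0.9, 0.7). A metric above its quality
bar earns weight 0.5, below it only 0.3, so a model cannot ride one
strong metric past a weak one. γ ∈ [0, 0.5].

**Paired-map rubric.** For each validation point, the natural-only map
(control) and disturbance map (test) are compared by five ordered
rules: suitable in only one map → that map scores; suitable in both at
different Jenks grade → higher grade scores; equal grade but evident
habitat fragmentation in the test map within a 50-km buffer
(patch-count increase *and* suitable-fraction drop ≥ 10%) → test
scores; otherwise no score. Tallies over repetitions form a
repetitions × {control, test} table tested with the likelihood-ratio
G-test, G = 2 Σ O ln(O/E), df = (r−1)(c−1).

## Worked example

```r
library(pairedSDM)

# composite score of a single model row: CSI .467, kappa .597, AUC .956, TSS .85
gamma_score(c(K_CSI = 0.467, K_KAPPA = 0.597, K_ROC = 0.956, K_TSS = 0.85))
#> [1] 0.35875     # printed as 0.359 in the published model table

# likelihood-ratio test on the published 10-repetition pairing tally
pub <- sincognitus_pairing_tally()
g_test(as.matrix(pub[, c("control", "test")]))
#> Likelihood-ratio G-test: G = 26.868, df = 9, p = 0.001471

# a small end-to-end run on the synthetic landscape
cfg <- pipeline_config(seed = 1, n_repetitions = 5)
manifest <- run_pipeline(cfg)
total_suitable(manifest$reports$scenario1_natural)   # 1e4 km^2 units
manifest$pairing$tally$shares
```

The G above says the control/test score frequencies differ across
repetitions far beyond chance (p < 0.01): the disturbance-aware map
systematically wins points, mostly through the fragmentation rule —
the published tally credits it 74 points (46.25% of 160) against the
control map's 34 (21.25%).

The `analysis/` directory holds the same workflow as numbered
narrative scripts (`01_worked_examples.R` … `06_pairing_gtest.R`),
writing tables under `results/`.

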