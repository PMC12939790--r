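# metstab

Yield-stability analysis for plant-breeding **multi-environment trials
(METs)**, aimed at breeders and biometricians screening early-generation
material laid out as an **augmented design**: many unreplicated test
lines grown beside a few check cultivars replicated in blocks within each
environment. The package answers the two questions such trials exist for
— *which genotypes yield well?* and *which yield predictably across
environments?* — with the field's standard statistics plus a single
aggregate selection score.

## What it computes

For the complete genotype × environment cell-mean matrix
`X_ij` (t/ha) with margins `X̄_i.`, `X̄_.j` (the environmental index
`E_j`) and grand mean `X̄`:

* **Univariate indices** (`stability()`): environmental variance
  `S²_i = Σ_j (X_ij − X̄_i.)² / (n−1)` and its SD, coefficient of
  variation `CV_i = 100·S_i/X̄_i.`, Wricke's ecovalence
  `W²_i = Σ_j (X_ij − X̄_i. − X̄_.j + X̄)²`, Shukla's stability variance
  (two estimators, reported side by side), the Finlay–Wilkinson
  joint-regression slope `b_i` on the environmental index, the
  Eberhart–Russell deviation mean square `S²d_i`, and `R²_i`.
* **SID / RSID** (`sid()`, also inside `stability()`): each index is
  oriented by the sign of its Pearson correlation with mean yield
  (negatively correlated indices are inverted via reciprocals), genotypes
  are ranked per index (greatest oriented value → rank 1, average-rank
  ties), and the per-genotype ranks are combined by their **harmonic
  mean** (SID); RSID is the rank of SID. A four-quadrant classification
  of the yield-vs-rank plane marks quadrant A (above-mean yield,
  better-than-mean rank) as the selection target.
* **AMMI** (`ammi()`): `Y_ij = μ + G_i + E_j + Σ_k λ_k γ_ik δ_jk + ρ_ij`
  — two-way main effects plus an SVD of the double-centred interaction,
  with the combined analysis of variance of the augmented design
  (replication stratum and error MS estimated from the replicated
  checks, Gollob component dfs, trial CV%), IPCA origin distances and
  biplot coordinates.
* **GGE** (`gge()`): SVD of the environment-centred matrix (genotype
  main effect + interaction retained), with **which-won-where**
  sectoring (`which_won_where()`): convex hull of the genotype score
  cloud, perpendicular rays, sector winners and per-environment
  mega-environment assignment, plus genotype–environment proximities.
* **Association & clustering** (`pearson_matrix()`, `met_cluster()`,
  `heatmap_layout()`): Pearson correlations among yield and the indices
  with t-based p-values, and two-way hierarchical clustering of the yield
  matrix (Euclidean/Ward defaults) for heatmap displays.
* **Synthetic METs** (`simulate_met()`, `simulate_fw()`): seeded
  augmented-design trials with known additive effects, an exact low-rank
  interaction with planted singular-value shares, planted perfectly
  stable genotypes and replicated checks — every estimator recovers its
  planted parameter exactly at zero noise.

`run_pipeline()` ties the steps together and writes CSV/JSON outputs plus
a run manifest; `inst/scripts/met-stab` is a command-line front end.

## Worked example

The package ships a small synthetic mock trial
(`inst/extdata/mock_met.csv`: 30 lines, 4 checks in quadruplicate, 4
environments; see `inst/extdata/README.txt`).

```r
library(metstab)
f <- system.file("extdata", "mock_met.csv", package = "metstab")
trial <- read_met_long(f)
mat <- as_met_matrix(trial)

ammi_fit <- ammi(trial)   # combined ANOVA uses the replicated checks
summary(ammi_fit)
```

```
AMMI analysis: 30 genotypes x 4 environments
Interaction SS: 91.42 | explained by components: 59%, 21.4%, 19.5%

Combined analysis of variance:
           Source Df      SS      MS       F         p signif Accumulated
      Environment  3  72.260 24.0900 59.3600 1.805e-07    ***          NA
 Replication(Env) 12   4.869  0.4057  0.4849 9.103e-01     ns          NA
         Genotype 29 136.200  4.6960  5.6130 1.098e-06    ***          NA
          Env:Gen 87  91.420  1.0510  1.2560 2.244e-01     ns          NA
              PC1 31  53.980  1.7410  2.0810 1.769e-02      *       59.05
              PC2 29  19.570  0.6748  0.8065 7.221e-01     ns       80.45
              PC3 27  17.870  0.6619  0.7910 7.338e-01     ns      100.00
              Sum 87  91.420  1.0510      NA        NA             100.00
        Residuals 36  30.120  0.8367      NA        NA                 NA
Coefficient of Variation (%): 12.9811

Most stable genotypes (smallest IPCA distance):
    G2    G13     G7    G26    G14
0.1049 0.1152 0.1350 0.1501 0.1622
```

Environment effects dominate (F = 59.4 against the replication stratum),
the genotype term is highly significant against the check-estimated
error, and the first interaction axis carries 59% of the interaction sum
of squares; genotypes G2, G13, G7 sit nearest the biplot origin, i.e.
interact least with environments.

```r
gge_fit <- gge(mat)
which_won_where(gge_fit)
```

```
Which-won-where partition: 5 sectors, hull: G13, G15, CHK4, G12, G24
 sector winner environments empty
      1    G13           E1 FALSE
      2    G15           E3 FALSE
      3   CHK4               TRUE
      4    G12               TRUE
      5    G24        E2,E4 FALSE
```

Three mega-environments emerge: E1 (won by G13), E3 (won by G15) and
{E2, E4} (won by G24); two hull genotypes win no tested environment.

```r
fit <- stability(mat)   # indices + SID/RSID + quadrants
fit$orientation         # how each index was oriented, with its r
head(fit$sid[order(fit$sid$rsid), c("genotype", "sid", "rsid", "quadrant")])
```

The orientation table shows each index's empirical yield correlation and
whether it was inverted before ranking — worth inspecting, because for
indices nearly uncorrelated with yield the data-driven orientation
decides which direction counts as favourable (see the methods vignette,
`vignettes/stability-methods.Rmd`, for discussion and for every modelling
choice).

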