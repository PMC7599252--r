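# proximarker

Network-proximity biomarker discovery from organoid pharmacogenomic screens.

`proximarker` is for computational biologists who have (i) a protein–protein
interaction network, (ii) a drug's protein targets, (iii) a pathway
collection, (iv) an organoid (or cell-line) screen with expression and IC50
per sample, and (v) a patient cohort with expression and survival — and who
want to know *which pathway's activity predicts response to that drug*, with
the feature space constrained by network biology instead of mined from the
whole transcriptome.

## The method

1. **Proximity filtering.** For drug targets $T$ and pathway genes $S$ on the
   PPI network (edges kept when confidence > 700; largest connected
   component), compute the closest distance

   $$d_c = \frac{1}{|T|}\sum_{t\in T}\min_{s\in S} d(s,t)$$

   and a z-score against a degree-matched random null (1000 iterations,
   joint draw over the union of both gene sets). Pathways with
   $z \le \Phi^{-1}(0.10) = -1.2816$ are *proximal* and become the candidate
   features.
2. **Pathway activity.** Expression is `log2(x+1)`-transformed, converted to
   per-sample pathway activity with single-sample GSEA (weight 0.25, NES by
   global ES-range normalization), and z-standardized per pathway within
   each dataset.
3. **Training.** Organoid IC50 is regressed on the proximal pathways'
   activities with ridge regression (penalty chosen over 0.1–1.0 by 3-fold
   CV). Pathways are ranked by coefficient magnitude; rank 1 is the
   biomarker.
4. **Patient scoring.** Each patient gets a predicted drug-resistance score
   $\mathrm{Score} = \sum_{p=1}^{N}\mathrm{Exp}_p\,\beta_p$ (default
   $N = 1$); a cohort median split labels responders (at or below the
   median) and non-responders.
5. **Validation.** Log-rank survival comparison of the classes in the
   treated cohort (and an untreated negative-control cohort), a
   pooled-variance t-test of biomarker activity in isogenic
   sensitive/resistant lines, a one-sided Mann–Whitney test against known
   mutation biomarkers, leave-up-to-3-organoids-out robustness, and a
   random-pathway bootstrap giving an empirical p for the biomarker's
   predictive rank.

A synthetic-data generator (`simulate_scenario()`) emulates every input —
network, pathways with one planted proximal biomarker, organoid screen with
a controlled activity–IC50 correlation, treated/untreated patient cohorts
with a treatment-specific hazard ratio, and isogenic lines — so the entire
pipeline runs and is tested without any external dataset.

## Worked example

```r
library(proximarker)

cfg <- scenario_config(seed = 7)        # 1000 genes, 50 pathways, 20 organoids
scn <- simulate_scenario(cfg)

disc <- run_discovery(list(
  network = scn$network, pathways = scn$pathways, targets = scn$targets,
  organoid_expr = scn$organoids$expression,
  organoid_ic50 = scn$organoids$response,
  n_iter = 1000, seed = 7))
#> 50 of 50 gene sets retained after network filtering (0 dropped)
#> 3 of 50 pathways proximal to drug_X targets at alpha = 0.1

head(subset(disc$proximity, proximal), 3)
#>    pathway d_c mu_null sigma_null         z proximal
#> 48   PW048 2.0  2.5252  0.2687698 -1.954089     TRUE
#> 4    PW004 0.2  0.4242  0.1221035 -1.836147     TRUE
#> 8    PW008 1.8  2.3428  0.2965402 -1.830443     TRUE

print(disc$ranking)
#> Coefficient ranking (ridge, alpha = 0.1)
#>  feature       beta rank
#>    PW004 -1.3548590    1
#>    PW048 -0.1318874    2
#>    PW008  0.1317207    3
```

`PW004` is the planted biomarker: it sits 0.2 hops from the drug targets
(z = −1.84 against its degree-matched null), and its negative coefficient
says high activity lowers IC50 — i.e. high activity sensitizes, the
direction the scenario planted. Validation on the patient cohorts:

```r
val <- run_validation(disc, list(
  patient_expr = scn$patients$expression,
  clinical = scn$patients$clinical,
  isogenic_expr = scn$isogenic$expression,
  isogenic_labels = scn$isogenic$labels,
  mutation_col = "mutation_marker", seed = 7))

print(val$survival)
#> treated   cohort: 57 responders vs 57 non-responders, log-rank chi2 = 20.559, p = 5.782e-06
#> untreated cohort: 149 responders vs 149 non-responders, log-rank chi2 = 0.003, p = 0.9531
```

Predicted responders survive markedly longer *only* in the treated cohort —
the untreated negative control shows no separation, which is exactly the
signature of a treatment-specific biomarker rather than a general
prognostic marker. The isogenic contrast (t = 13.2, p = 1.2e−07, sensitive
lines higher) and the mutation concordance (one-sided Mann–Whitney
p = 2.0e−06) agree in direction.

A thin command-line front end over the same functions lives in
`inst/scripts/proximarker` (`simulate` / `discover` / `validate`
subcommands, YAML config).

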