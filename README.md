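# exocargo

Differential exosomal cargo analysis for label-free proteomics of 2×2
factorial designs: **treatment × knockdown**. The package answers the
question *which proteins are loaded into stress-induced exosomes, and for
which of those does loading depend on a silenced factor* (here the ATE1
arginyl-transferase targeted by siRNA), going from peptide-level
intensities all the way to a ranked candidate list and term enrichment.

It is aimed at proteomics analysts who have MaxQuant-style peptide or
proteinGroups tables for a vehicle/oxidant × siCtrl/siATE1 design and want
a reproducible, scriptable version of the Perseus-style workflow plus the
Δ-fold-change cargo classification.

## The method

For protein *p* with peptide intensities *I* and *N*<sub>obs</sub>
theoretically observable fully-tryptic peptides (7–30 residues),

&nbsp;&nbsp;&nbsp;&nbsp;iBAQ(*p*, *s*) = Σ *I*(peptides of *p* in sample *s*) / *N*<sub>obs</sub>(*p*).

iBAQ values are log2-transformed, proteins are kept when every contrast
group has ≥ 2/3 valid values, and missing values are imputed from a
down-shifted normal, Normal(μ<sub>c</sub> − 1.8 σ<sub>c</sub>,
(0.3 σ<sub>c</sub>)²) per sample column. Each knockdown arm then gets an
oxidant-vs-vehicle geometric-mean fold change and a pooled two-sample
t-test (significant: p < 0.05). The central statistic is the **Δ fold
change**

&nbsp;&nbsp;&nbsp;&nbsp;Δ = FC<sub>kd</sub> − FC<sub>ctrl</sub>&nbsp;&nbsp;(linear scale),

with |Δ| > 0.3 marking knockdown-dependent loading/exclusion and the
candidate gate FC<sub>ctrl</sub> > 2 ∧ Δ < −1 singling out cargo whose
stress-induced loading collapses under knockdown. Up/down/candidate sets
are tested for term enrichment with a one-sided hypergeometric test and
BH correction. A synthetic-data generator with planted effects and
intensity-dependent (left-censored) missingness backs the validation
suite.

## Worked example

```r
library(exocargo)

# a synthetic experiment: 500 proteins, 3 replicates per cell,
# 5% transferase-dependent cargo, replicate noise 0.3 log2 units
sim <- simulate_cargo_experiment(n_proteins = 500, n_reps = 3,
                                 truth = truth_params(seed = 7))

ib    <- compute_ibaq(sim$peptides, sim$proteome)   # peptide -> protein iBAQ
lmat  <- log2_transform(ib)
cs    <- design_contrasts(sim$design)
ctrl  <- analyze_contrast(lmat, cs$ctrl)            # filter + impute + FC + t
kd    <- analyze_contrast(lmat, cs$kd)
delta <- classify_cargo(ctrl, kd)
head(select_candidates(delta)[c("protein", "fc_ctrl", "fc_kd", "delta", "ate1_class")], 3)
#>      protein fc_ctrl fc_kd delta  ate1_class
#> 297 SYNP0298    3.03 0.355 -2.67 ATE1_loaded
#> 474 SYNP0476    2.57 0.448 -2.13 ATE1_loaded
#> 217 SYNP0218    2.56 0.493 -2.07 ATE1_loaded
```

The top candidates are proteins induced ~3-fold by oxidant treatment in
the control arm whose induction collapses below 0.5-fold once the
transferase is silenced — exactly the planted `ATE1_loaded` signature.
`summarize_delta(delta)` reports 37 up- and 43 down-regulated proteins
(mean Δ −0.69 and +0.38), 25 up-regulated proteins with Δ < −0.3, and 11
candidates for this seed.

The same analysis runs end to end from files via a YAML config:

```r
run_pipeline("analysis.yaml")   # or: Rscript inst/scripts/run_pipeline.R --config analysis.yaml
```

writing per-stage TSVs (iBAQ matrix, per-contrast differential tables,
Δ table, candidates, enrichment, z-scored heatmap export) plus a
manifest; every file header carries the seed and a config hash, and
rerunning with the same seed reproduces the outputs byte-for-byte.

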