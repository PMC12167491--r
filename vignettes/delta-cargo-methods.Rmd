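---
title: "Methods: differential exosomal cargo analysis with exocargo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential exosomal cargo analysis with exocargo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exocargo)
```

## The analysis problem

Exosomes secreted by cancer cells under oxidative stress carry a cargo
proteome that shifts with the stress response, and some of that shift
depends on a loading factor — here the ATE1 arginyl-transferase, silenced
by siRNA in half of a 2×2 factorial design (treatment: vehicle vs oxidant;
knockdown: siCtrl vs siATE1; 3 replicates per cell). The question the
pipeline answers is: *which proteins are loaded into stress-induced
exosomes, and for which of those does loading require the transferase?*

The route from raw peptide intensities to an answer is:

1. **iBAQ quantification** — a protein's summed peptide intensity divided
   by its count of theoretically observable tryptic peptides.
2. **Perseus-style preprocessing** — log2 transform, a valid-value filter,
   and down-shifted normal imputation of left-censored missing values.
3. **Per-contrast differential statistics** — oxidant vs vehicle fold
   changes and two-sample t-tests, once within each knockdown arm.
4. **The Δ fold change cascade** — the knockdown-arm linear fold change
   minus the control-arm linear fold change, classifying each regulated
   protein as transferase-loaded, transferase-excluded, or independent,
   and gating a short candidate list.
5. **Term enrichment** — one-sided hypergeometric tests of the up, down
   and candidate sets against an annotation map.

## iBAQ and in-silico digestion

`digest_tryptic()` cleaves after K or R except before P. The observable
window for the iBAQ denominator defaults to fully cleaved peptides of
7–30 residues (`count_observable()`), the common convention for
Orbitrap-class label-free data; both bounds are arguments because the
window used by upstream search engines varies. iBAQ is homogeneous of
degree 1 in the intensities, so fold changes are invariant to global
intensity rescaling; the suite checks both properties.

Peptides assigned to more than one protein are dropped with a warning
rather than razor-assigned — protein grouping is out of scope, and the
synthetic generator essentially never produces shared sequences. Proteins
with no observable peptide are excluded and reported, never quantified as
zero. When a proteinGroups-style table with precomputed `iBAQ <sample>`
columns is available, `read_protein_groups()` bypasses the peptide stage
entirely (zero entries are treated as missing, the MaxQuant convention).

## Preprocessing

All statistics run on log2 iBAQ values. The valid-value filter keeps a
protein only if every group of the current contrast has at least
`ceiling(min_valid_frac × group size)` observed values; with the default
2/3 and triplicates that is ≥ 2 of 3, the only reading of a "2/3 valid
values" rule consistent with n = 3. Filtering is applied **per contrast**
using that contrast's two groups, because the design tests two contrasts
inside one experiment and the rule is stated per group.

Missing values are then imputed column-wise: for sample column *c* with
observed mean μ&#95;c and SD σ&#95;c, each missing entry is an independent
draw from Normal(μ&#95;c − 1.8 σ&#95;c, (0.3 σ&#95;c)²). The width 0.3 and
down-shift 1.8 are the standard Perseus defaults for left-censored
label-free data: missingness concentrates at the low-abundance end, so
plausible replacements sit below the observed distribution with a
narrowed spread. Column-wise statistics (rather than matrix-wide) follow
Perseus semantics. Numerical details: observed entries are never touched
(mask-checked in the tests); draws are assigned to missing cells in
row-major order under a single seeded RNG stream, so runs are exactly
reproducible; a constant column (σ = 0) imputes its mean; a column with
fewer than two observed values is a data error rather than a guess.

Fold changes are computed **after** imputation (the Perseus convention;
computing them before is possible by calling `contrast_fold_change()` on
the unimputed matrix, but is not the default path).

## Differential statistics

The linear fold change is the geometric-mean ratio `2^(Δ mean log2)`,
matching the log2 workflow; an arithmetic-of-linear-means alternative is
available via `fc_scale` since reported "x-fold" values could in
principle be either. The default test is Student's pooled-variance
two-sample t-test (the Perseus two-sample default); Welch's variant is
available and agrees with Student's to 1e-9 on the t statistic when group
variances are equal. Significance is the raw p-value strictly below α =
0.05 — no multiple-testing correction in the headline call, mirroring
the upstream workflow — but BH q-values are always reported alongside.
Degenerate zero-variance rows are resolved explicitly: equal means give
t = 0, p = 1; unequal means give p = 0 with a `degenerate` flag (this is
what makes the noise-free limit exactly recoverable).

## The Δ fold change cascade

For each protein, Δ = FC&#95;kd − FC&#95;ctrl on the **linear** scale.
Linear is the only scale on which the published worked example coheres: a
cargo whose fold change drops from 2.1 to 0.6 under knockdown has
Δ = −1.5, which passes a "Δ < −1" candidate gate; on the log2 scale it
would be −1.81 and the gate values would not match their stated
companions. A log2-scale mode exists (`delta_scale = "log2"`) but is
non-default.

Direction comes from the control arm: `up` requires significance and
FC&#95;ctrl > 1, `down` significance and FC&#95;ctrl < 1. Within the up
set, Δ < −0.3 marks `ATE1_loaded` (stress-induced loading requires the
transferase), Δ > +0.3 marks `ATE1_excluded`, and the band in between is
`ATE1_independent`. The down set mirrors this: depletion that is lost on
knockdown (Δ > +0.3) is `ATE1_excluded`, Δ < −0.3 is `ATE1_loaded`, else
independent. Candidates are up-regulated, significant, FC&#95;ctrl > 2
and Δ < −1, sorted by ascending Δ with lexicographic protein-id
tie-break. Every threshold comparison is **strict**, so a protein sitting
exactly on ±0.3 is independent and exactly 2 or −1 fails the candidate
gates.

Two knockdown-dependence tallies circulate for such designs — the count
with Δ < −0.3 *within the up set* and the count with |Δ| > 0.3 overall —
and they need not agree. `summarize_delta()` reports both
(`n_loaded_in_up`, `n_abs_delta_gt_sig`) instead of resolving the
ambiguity. Empty direction sets are reported as `NA` ("absent"), never as
a zero mean. Δ is treated as a descriptive statistic throughout: no
standard error or test is attached to it.

## Enrichment

No specific enrichment tool is assumed; the field-default one-sided
hypergeometric (Fisher) upper-tail test with BH correction across terms
is used and stated in the outputs. The universe defaults to the proteins
that survived quantification and filtering in both arms — using all
annotated proteins instead would count undetectable proteins against
every set and bias p-values. The hypergeometric tail is checked against
brute-force enumeration for every configuration of universes up to 25,
and BH against the step-up formula. `simulate_annotation()` plants
term enrichment into chosen protein sets so the module is testable
without external ontologies; GO-graph propagation and GAF parsing are
deliberately out of scope.

## What the synthetic generator emulates

`simulate_experiment()` generates, in order: per-protein base log2
abundance ~ Normal(base_mu, base_sigma²); planted condition effects
(log2 FC&#95;ctrl added to oxidant samples of the control arm, log2
FC&#95;kd in the knockdown arm); replicate noise ~ Normal(0, rep_sigma²);
per-peptide lognormal response factors fixed across samples; and
logistic left-censoring — a peptide measurement at log2 intensity *x* is
missing with probability `plogis((censor_mid − x) / censor_tau)`.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `base_mu`, `base_sigma` | 25, 2 (log2) | typical spread of log2 iBAQ values in Orbitrap exosome runs |
| `rep_sigma` | 0.3 (log2) | replicate CV ≈ 20–25%, realistic for label-free triplicates |
| `fc_ctrl_range` | [2.2, 3.5] | planted loaded-cargo induction straddling the FC > 2 candidate gate |
| `fc_kd_range` | [0.4, 0.8] | loss of loading under knockdown, Δ ≤ −1.4 for every loaded protein |
| `frac_ate1_dependent` | 0.05 | a small minority of cargo is loading-factor dependent |
| `frac_independent` | 0.10 | regulated but transferase-independent background |
| `censor_mid`, `censor_tau` | 17, 1 | ~8 log2 units below the abundance mode: missingness confined to the low tail |
| `peptide_efficiency_sigma` | 1 (sdlog) | order-of-magnitude spread of peptide ionization efficiency |
| replicates | 3 per cell | the design the pipeline targets |

Fixing peptide efficiencies across samples preserves within-protein
intensity ratios, so iBAQ fold changes are unbiased by construction —
which is what makes the noise-free limit (rep_sigma = 0, no censoring) an
exact identifiability check: estimated fold changes equal planted ones to
floating-point precision and every planted class label is reproduced.
The logistic missingness model is a choice, not an observation: real
acquisition gives only the remedy (down-shifted imputation), so the
generator uses the standard left-censoring emulation that makes that
remedy appropriate. Residue composition is uniform over the 20 residues
with a K/R weight knob controlling cleavage density.

What the generator does **not** emulate: chromatography and spectra,
charge states, identification errors, shared/razor peptides, batch
effects, or correlated protein co-regulation. Passing tests on synthetic
data therefore demonstrate the correctness and statistical behaviour of
the pipeline under its own model assumptions, not performance on any
particular deposited dataset.

## Validation at scale

The recovery suite runs 10 simulated experiments of 2000 proteins × 12
samples at rep_sigma = 0.3 with the planted ranges above and censoring
disabled, and scores the candidate list against ground truth pooled
across the 10 runs: sensitivity and specificity both exceed 0.9
(sensitivity is bounded by design — a planted fold change of 2.2 sits
close to the strict FC > 2 gate, so replicate noise pushes a few true
cargoes below it). The imputation model is verified by a moment test on
10^5 draws. These sizes keep the full suite under a minute per property
on a single CPU while leaving Monte-Carlo standard errors far below the
tested margins.

## Known limitations

* Observable-peptide windows of upstream search engines vary; absolute
  iBAQ values are therefore not comparable across tools, only ratios.
* The candidate cascade inherits the instability of strict thresholds:
  proteins near FC = 2 or Δ = −1 flip lists under resampling.
* Raw p < 0.05 is used for the headline significance call by design;
  q-values are reported but not gated on.
* Δ has no attached inference; ranking by Δ is descriptive.
* The proteinGroups bypass trusts upstream normalisation; none is applied
  here (deliberately — the workflow this mirrors applies none).
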