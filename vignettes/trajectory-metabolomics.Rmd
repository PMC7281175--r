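---
title: "Trajectory metabolomics and 13C tracer analysis with trajmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory metabolomics and 13C tracer analysis with trajmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmet)
```

## The scientific setting

trajmet analyzes staged three-group tumorigenesis designs: a baseline
tissue (W, wild-type liver), a precancerous stage (P) and tumor tissue
(T), each profiled by GC-MS metabolomics (peak intensity tables) and,
optionally, RNA-seq (FPKM tables) with about eight animals per group. The
questions it answers are (i) which analytes change, (ii) *along which
trajectory* they change across the W → P → T progression, (iii) which
pathways the changed analytes concentrate in, and (iv) how
[U-¹³C]glucose labeling patterns constrain the underlying fluxes through
glycolysis, the pentose phosphate pathway (PPP), the TCA cycle and the
citrate–malate shuttle.

## Preprocessing

Peak tables are screened by an interquartile-range rule: analytes with
zero IQR across all samples are always dropped, and `quantile_cut`
optionally removes the lowest tail of the nonzero-IQR distribution.
Because the appropriate cut is data-dependent, the default is 0 (drop
nothing but flat peaks) and the threshold actually applied is recorded in
the `denoise_report` (type-7 linear-interpolation quartiles). Re-running
with the recorded absolute threshold is idempotent.

Internal-standard normalization divides every intensity by the sample's
internal-standard peak and removes that analyte; the divisor vector is
retained so the operation is exactly invertible. Missing cells are never
silently zeroed: `impute_missing()` either applies half-minimum
imputation (the standard treatment of left-censored GC-MS missingness) or
flags incomplete analytes as test-ineligible.

## Differential calling and the fold-change convention

All pairwise comparisons are two-sided two-sample t-tests (pooled
variance by default; Welch optional) run on linear intensities, matching
the mean-ratio presentation of fold changes: `fold(A vs B) =
mean_A / mean_B`, the first-named group over the second. Metabolite calls
use `p < alpha` alone (default alpha 0.05, strict inequality); gene calls
additionally require fold ≥ 1.5 or ≤ 0.67. No multiple-testing
correction is applied by default, mirroring the per-test criterion used in
this study design; a Benjamini–Hochberg option (`adjust = TRUE`) is
available, as is testing on the log scale (`log = TRUE`), which leaves
the reported folds linear.

## The trajectory pattern classifier

Each analyte's trajectory is summarized by three relations at level
alpha — T vs P, T vs W, P vs W — each `>`, `<` or `=`, where `=` means
*not significant at alpha*, not numerically equal. Ten of the 27 triples
are named and grouped:

| category | subtypes | reading |
|---|---|---|
| HCC_pos | `T>P=W`, `T>W>P`, `W>T>P` | tumor-elevated |
| HCC_neg | `T<P=W`, `T<W<P`, `W<T<P` | tumor-depleted |
| RAS_pos | `T>P>W`, `T=P>W` | oncogene-elevated in both P and T |
| RAS_neg | `T<P<W`, `T=P<W` | oncogene-depleted in both P and T |

Classification is an exact lookup on the triple. This is the only
deterministic reading of chain subtypes under noise: `T>P>W` requires the
implied outer inequality T vs W to be significant too. When two adjacent
relations form a chain but the outer relation is `=` (a noise-truncated
chain), the profile is left unclassified and flagged `consistent =
FALSE`, so such cases are auditable rather than silently absorbed. The
`W>T>P` and `W<T<P` subtypes mix directions; they are encoded exactly as
named in the taxonomy, without reinterpretation. Analytes are classified
regardless of their differential-call status; intersecting pattern calls
with a DEM list is a reporting choice left to the caller (the pipeline
does both).

Group labels are configurable — W/P/T is a default trio, not a
hard-coded one — so the classifier applies to any
baseline/intermediate/endpoint design.

## PCA and PLS-DA

Both operate on samples × analytes with autoscaling (unit variance) as
the metabolomics default. PCA is a plain SVD with component signs fixed
so each loading vector's largest-magnitude entry is positive, making
results deterministic. PLS-DA regresses a ±1 class response on the scaled
matrix (PLS1; with a univariate response the NIPALS inner loop reduces to
a closed form per component). It reports R²Y, VIP scores (normalized so
`mean(VIP²) = 1`), and Q² from stratified k-fold cross-validation
(default 7 folds) with fold membership assigned deterministically
(round-robin within group) rather than randomly, so model QC is exactly
reproducible. Scaling is applied once to the full matrix and folds only
re-center: per-fold re-autoscaling was evaluated and rejected because it
makes Q² erratic on small tables, and one-pass scaling is the convention
of the standard PLS-DA workflow. The permutation test refits the model
under label permutations and reports
`p = (1 + #[Q²_perm ≥ Q²_obs]) / (1 + n_perm)`; this p-value is discrete,
so at `n_perm = 199` the achievable rejection rate at alpha 0.05 is
9/200 = 0.045, slightly conservative by construction.

This PLS-DA (optionally preceded by single-component orthogonal signal
correction, `osc_correct()`) is an open-math stand-in for proprietary
OPLS-DA implementations; for two-class problems the predictive component
and VIP ranking carry the same interpretation. The number of components
is a user choice (default 2); nothing in the package asserts a particular
published model dimensionality.

## Pathway over-representation

`enrich()` is a hypergeometric upper-tail test of a hit list against a
universe (by default, everything that survived denoising), BH-corrected
across pathways. The built-in map contains six curated central-carbon
sets (glycolysis, TCA + citrate–malate shuttle, PPP, lipid biosynthesis,
cholesterol/bile acid, glutathione) with metabolite and mouse-gene
members. Versioned web enrichment services cannot be reproduced exactly
offline; this compact map is an explicit, openly testable stand-in, and
arbitrary GMT-format set collections are accepted as well.

## The tracer model

Pool labeling is represented positionally: a metabolite with n carbons
carries a probability vector over its 2ⁿ labeling states. The largest
metabolite (sedoheptulose-7-phosphate) has 7 carbons, so state spaces
stay at or below 128 — small enough that the positional representation is
preferable to more elaborate decompositions, and every atom map is
directly auditable in the source. At steady state each pool's
distribution equals the flux-weighted mixture of its producers'
atom-mapped substrate distributions (substrate pools assumed
independent), mixed with a per-metabolite unlabeled dilution influx;
`simulate_isotopomers()` iterates this fixed point to `tolerance`
(default 1e-10, typically ~35 sweeps) and marginalizes to mass
isotopologues. A steady-state formalism, not kinetic ODEs, is the right
level for single-time-point enrichment data: flux *ratios*, not absolute
rates, are what such data constrain.

Key modeling choices:

* **Branch fractions.** `f_ppp` splits glucose-6-phosphate consumption
  between glycolysis and the oxidative PPP and therefore shapes the F6P
  and GAP mixing weights (the classic 3 Ru5P → 2 F6P + 1 GAP
  stoichiometry fixes the transketolase/transaldolase flux shares at
  `f_ppp/3` each). `f_shuttle` splits citrate consumption between TCA
  continuation and cytosolic export, and re-enters as the mitochondrial
  malate mixing weight. The pyruvate shares `f_lactate`, `f_pdh`, `f_pc`
  are validated and stored but cannot alter steady-state *distributions*
  of single-producer pools (lactate, acetyl-CoA); they matter for pool
  sizes and for the optional pyruvate-carboxylase route (`f_pc > 0`,
  default 0, since the canonical flux diagram omits it).
* **Atom maps** follow the standard ¹³C-MFA conventions: the oxidative
  PPP releases glucose carbon 1 as CO₂; aldolase sends F16BP C1–C3 to
  DHAP (reversed) and C4–C6 to GAP; pyruvate dehydrogenase releases
  pyruvate C1; citrate synthase assembles citrate from oxaloacetate and
  acetyl-CoA such that both CO₂ losses of the first TCA turn come from
  oxaloacetate carbons (so first-turn citrate from labeled acetyl-CoA
  and unlabeled oxaloacetate is M+2, the canonical tracer signature);
  succinate and fumarate are symmetric and modeled with explicit 50/50
  rotational scrambling; aconitate is prochiral and not scrambled.
* **Dilution.** Without unlabeled influxes, every pool converges to
  glucose-derived labeling and branch topology becomes invisible;
  anaplerotic dilution (e.g. `dilution = c(OAA = 0.4)`) is what makes
  shuttle and TCA fluxes identifiable in labeling patterns. Dilution
  values are deliberately explicit configuration, as is tracer purity —
  dose/timing normalization and natural-abundance treatment vary between
  laboratories.
* **Natural-abundance correction** (binomial convolution matrix, default
  p13 = 0.0107) is available but off by default, matching the common
  raw [labeled]/[total] presentation of labeled fractions.
* **No inverse problem.** The package simulates forward and compares;
  it does not fit fluxes to data. That bound keeps the tracer module a
  transparent interpretation aid rather than a full ¹³C-MFA engine.

`monte_carlo_oracle()` validates the solver by molecule-level stochastic
atom tracking through the same network: pools of individually tracked
molecules are synchronously resampled from their producers (40 burn-in
sweeps, then mass-isotopologue counts averaged over 20 further sweeps to
control resampling variance). Solver and oracle agree within
3/√n_molecules per fraction; at n = 10⁵ the measured maximum deviation is
~0.002–0.004 against a bound of 0.0095.

## The synthetic-data generator

`generate_peak_table()` plants trajectory patterns by walking a subtype's
inequalities in `effect_size` steps (equal groups share a mean) and
multiplying by log-normal noise with `sigma = sqrt(log(1 + cv²))`. The
defaults are the study conditions this package models: three groups of
eight, effect size 2, cv 0.25, 200 analytes. Planted-null analytes (all
groups equal) probe specificity. `cv = 0` is allowed as an exact
noise-free boundary; it is the only point where recovery is exact,
because t-test false positives on planted equalities are scale-invariant
and do not vanish for any positive cv. A pre-release calibration (50
replicates at the default conditions) measured category recovery at
0.989 ± 0.009 (minimum 0.962), supporting the ≥ 0.90 acceptance
threshold; the planted-null false-call rate per analyte was ~0.009,
comfortably below alpha, and is asserted on nulls pooled across
replicates because a single replicate contains only ~18 nulls.

What the generator does *not* emulate: retention-time structure,
co-eluting peaks, batch effects, heteroscedasticity beyond the
multiplicative model, and missingness mechanisms. Passing tests on
synthetic data therefore demonstrate correctness of the statistical
machinery under the stated noise model, not robustness to every artifact
of real GC-MS data.

`generate_isotopologue_table()` plays the same role for the tracer stage:
per-group networks (e.g. differing in `f_shuttle`) are solved exactly,
and per-sample areas are the true fractions times a total pool with
multiplicative noise, so `labeled_fraction()` estimates can be checked
against known ground truth.

## Numerical and degenerate-case choices

* t-tests on groups that are both constant return p = 1 when means are
  equal and p = 0 otherwise (the t statistic is undefined there).
* Fold changes with a zero denominator mean are `NA`, never infinite.
* PCA excludes zero-variance analytes under autoscaling with a warning.
* The tracer fixed point reports non-convergence with its residual
  instead of returning a partial answer.
* All simulation entry points take explicit integer seeds; cross-
  validation folds are assigned without randomness at all.

## Problem sizes used in the shipped checks

The test suite exercises the solver-vs-oracle comparison at 10⁵ molecules
on five random network configurations, the permutation-test calibration
on 400 pure-noise datasets (n_perm = 199), and pattern recovery on ten
200-analyte replicates at the default study conditions — sizes chosen so
the full suite completes in a few minutes on a single core while leaving
the Monte-Carlo bounds meaningful margin.

## Known limitations

* The IQR screen's global-versus-per-group and absolute-versus-relative
  variants are not distinguished by the method's name alone; this
  implementation screens on the global across-sample IQR and records the
  applied threshold rather than guessing alternatives.
* PLS-DA Q² on strongly separated but tiny tables is bounded away from 1
  by the ±1 dummy-response formulation; values ~0.9 indicate excellent
  models.
* The tracer network is the canonical central-carbon topology; reactions
  outside it (glutaminolysis, glycogen turnover, one-carbon metabolism)
  appear only implicitly as dilution.
* Technical replicates are not modeled; one column is one biological
  sample.
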