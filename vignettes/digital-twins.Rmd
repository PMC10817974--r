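---
title: "Digital twins of TCR-engineered T cell kinetics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital twins of TCR-engineered T cell kinetics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Adoptive T cell therapy infuses engineered T cells whose subsequent
cellular kinetics — distribution out of blood, antigen-driven
expansion, contraction, and long-term persistence or decline — vary
enormously between patients and correlate with clinical benefit.
`tcelltwin` implements a quantitative systems pharmacology (QSP) model
of these kinetics for TCR-engineered T cell products containing four
memory phenotypes, together with a digital-twin workflow: screening
large pools of virtual patients against each real (or synthetic)
patient's longitudinal blood measurements, keeping the
parameterizations that reproduce that patient, and then using the
resulting virtual population to simulate untested dose amounts and
dose compositions.

# The kinetic model

## State space

Five T cell species are tracked: the engineered subsets `scm` (stem
cell-like memory), `cm` (central memory), `em` (effector memory) and
`eff` (terminal effector), plus endogenous T cells `endo`. Four
compartments are represented: `blood`, `tdln` (tumour-draining lymph
node, the site of antigen presentation), `tissue` (one lumped
compartment for normal tissue and other lymph nodes) and `tumor`.
Occupancy is restricted by trafficking biology: `scm`/`cm` enter lymph
nodes (CD62L-dependent) but not tumour; `em`/`eff` enter tumour but
not the TDLN; `endo` occupies all non-tumour compartments. This yields
15 cell-count states plus one antigen state.

## Processes

For each valid (compartment `c`, species `s`) pair the count
$N_{c,s}$ (cells) obeys

$$\frac{dN_{c,s}}{dt} = G_{c,s} - k^{apop}_s N_{c,s} + D^{in}_{c,s} - D^{out}_{c,s} + J_{c,s}$$

* **Growth** is logistic with a shared compartment capacity and an
  antigen-driven term that acts only where antigen is presented
  (TDLN and tumour) and only on engineered cells:
  $G_{c,s} = \left(k^{base}_s + \mathbf{1}_{c \in \{tdln,tumor\}, s \neq endo}\, k^{atg}_s H(A)\right) N_{c,s} \left(1 - \tfrac{\sum_{s'} N_{c,s'}}{T^{cap}_c}\right)$
  with the saturating antigen drive $H(A) = A/(A + K_A)$. The shared
  capacity encodes competition between engineered and endogenous
  cells — the mechanism by which lymphodepletion promotes engraftment.
  `eff` is terminally differentiated: both its proliferation rates are
  structurally zero.
* **Differentiation** follows the strict linear chain
  scm → cm → em → eff at rate $k^{conv}_s H(A)$, only in antigen
  compartments and only where source and product can coexist; under
  the occupancy rules that means scm → cm in the TDLN and em → eff in
  tumour. A consequence is that the cm → em rate constant never enters
  the equations (no compartment hosts both conversion and cm+em);
  it is retained among the varied parameters and is reported as
  unidentifiable by `parameter_recovery()`.
* **Trafficking** exchanges each species between blood and its
  permitted compartments with a concentration-difference flux against
  the partition-scaled blood concentration,
  $J_c = k^{traffic}_s (C_{blood} Kp_{c,s} - C_c)\, V_c$ (cells/day).
  The flux is bidirectional, conserves cells exactly, and its steady
  state satisfies $C_c / C_{blood} = Kp_{c,s}$.
* **Antigen** is a lumped "effective antigen load" that decays
  exponentially, $dA/dt = -\lambda_A A$, standing in for antigen loss,
  exhaustion and immune escape; it is the clock that ends the
  expansion phase.

## Lymphodepletion and dosing

Conditioning chemotherapy and the infusion are collapsed into the
$t=0$ state: all infused cells start in blood split by the dose
composition; endogenous cells start at `ld_frac` times their
pre-depletion distribution (blood at `C_endo_baseline`, TDLN/tissue at
the Kp-scaled concentrations). The default `ld_frac` of 0.1
corresponds to intensive conditioning; 0.3 is a reasonable value for
reduced-dose regimens. The conditioning week before infusion is not
simulated.

## Reference parameterization

`tct_reference_params()` is the package's reference virtual patient.
Volumes (blood 5000 mL, TDLN 30 mL, tissue 60,000 mL, tumour 100 mL)
and partition coefficients (TDLN 30 for lymph-node-homing species,
tissue ≈ 1–5) are order-of-magnitude physiological stand-ins. Rates
were chosen so that the simulated blood kinetics show the canonical
four phases at the middle dose (10^10 cells, 1/3/48/48% composition):
a steep distribution decline over the first ~2 weeks, expansion to a
peak around day 90, contraction, and slow persistence/decline; and so
that intrinsic subset persistence is ordered scm > cm ≫ em > eff
(apoptosis 0.015, 0.018, 0.08, 0.2 /day against homeostatic
proliferation 0.02, 0.025, 0.01, 0 /day). The TDLN carrying capacity
is deliberately set high (10^12) so that antigen availability, not
space, limits expansion — this makes long-term persistence sensitive
to the infused scm seed, which is the behaviour the dose-composition
experiments probe. Two known consequences are accepted: the
endogenous compartment, after recovering from lymphodepletion,
equilibrates ~2.3-fold above its nominal pre-depletion baseline as
lymphoid tissue repopulates; and at carrying capacity the logistic
competition can exclude the weaker population entirely if one
population is driven very hard.

# Synthetic study conditions

The generator (`cohort_design()`, `synthesize_cohort()`) emulates the
structure of a first-in-human dose-escalation trial: 10 patients in
three cohorts of 2/3/5 receiving 10^9 / 10^10 / 10^11 engineered
cells; five observed species as blood concentrations (cells/mL);
irregular sampling on nominal days {7, 14, 21, 28, 42, 56, 90, 180,
270, 365} jittered ±3 days per patient; multiplicative lognormal
measurement noise (SD 0.2 on the log10 scale — a typical magnitude
for flow-count assays spanning decades, since the real assay error is
unreported); and a limit of quantification of 1 cell/mL below which
values are recorded as 0. All patients receive the representative
composition 1% scm / 3% cm / 48% em / 48% eff; the real trial's
per-patient compositions are available only as published figures.

Ground-truth parameters vary between patients within the central 15%
of each screening log-range (roughly ±40% around the reference). This
window was chosen for physiological plausibility: with much wider
interpatient variability the endogenous compartment goes extinct or
explodes in most virtual patients, unlike any observed trial
kinetics. Four dose-associated parameters (antigen-driven scm and cm
proliferation, homeostatic cm proliferation, scm trafficking) are
drawn from the lower/middle/upper third of that window per cohort,
emulating the reported association between dose cohort and
early-memory proliferation/trafficking biology.

What the generator does **not** emulate: per-patient dose
compositions, dropout and censoring beyond the LOQ, assay batch
effects, covariates (age, prior therapy), or any tumour-response
readout. Passing recovery tests on these synthetic cohorts therefore
demonstrates that the pipeline is correct and informative under the
stated noise and variability — not that the model is validated
against real clinical data.

# Digital-twin workflow

One shared pool of candidate virtual patients (default 20,000) is
drawn log-uniformly over 14 varied parameters spanning a factor of 10
either side of the reference: antigen-driven proliferation (scm, cm,
em), conversion (scm, cm, em), trafficking (scm, cm, em), homeostatic
proliferation (cm, endo), apoptosis (scm, em, endo). Every candidate
is simulated at each patient's recorded dose and scored by log-scale
RMSE over all (day, species) observations,
$\sqrt{\mathrm{mean}\left[(\log_{10}(pred + LOQ) - \log_{10}(obs + LOQ))^2\right]}$,
with equal weight per observation. The 10 best-scoring candidates per
patient become that patient's digital twins (ties broken toward the
earlier candidate; the selection is verified against a full-sort
oracle in the tests). The 100-twin superset is the virtual
population. A single "reference virtual patient" can also be built by
minimizing the cohort-pooled mean score, refined by deterministic
coordinate descent in log space (factor-1.2 steps, cycling until no
coordinate improves, at most 200 cycles).

Because only one composition and three dose levels appear in the
data, several varied parameters are practically unidentifiable and
twin values spread across their prior range; `parameter_recovery()`
reports per-parameter recovery ratios and a numerical
identifiability probe (a parameter is flagged unidentifiable when
sweeping it across its whole range leaves the predicted observations
unchanged).

# Virtual trials and analyses

* `run_trial()` re-simulates all twins at a common dose and reports
  median/IQR bands per species, per-twin %TCT (engineered cells as a
  fraction of all blood T cells), and the persister flag: strict
  majority (`tct_fraction > 0.5`) at day 50 — strict because
  "majority" is undefined at the boundary.
* `composition_sweep()` draws dose compositions from a flat Dirichlet
  (uniform on the 4-simplex — the natural "random composition"
  model), simulates every (twin, composition) pair at a fixed total
  dose of 10^10 cells (the virtual-trial dose; the swept total is
  configurable), and reports persistence (%TCT at day 365) plus a
  binned summary: per subset, left-closed 5%-wide bins of that
  subset's dose fraction, averaging across all twins and compositions
  in the bin.
* `prcc()` computes partial rank correlation coefficients of the
  twin parameters against the persister outcome (encoded 0/1; the
  rank transform handles the ties), with p-values from the t
  statistic with $n - 2 - \tilde p$ degrees of freedom and a
  Bonferroni-corrected $\alpha = 0.05$ — a conservative default since
  the original analysis does not state its correction.
* `pca_parameters()` standardizes log10 parameters (they span
  decades) and eigendecomposes the covariance; the sign convention
  makes the largest-magnitude loading of each component positive.
* `predict_external()` re-simulates the population at an external
  study's dose and picks the twin minimizing RMSE against the
  observed %TCT series on the untransformed percentage scale
  (values span 0–100; a log scale would overweight the tail).

# Numerical choices

The ODE system is integrated with `deSolve::lsoda` (stiff-capable,
adaptive) at `rtol = 1e-8`, `atol = 1e-4` cells; the right-hand side
is compiled C for throughput (a 20,000-candidate screen is ~60,000
solves), with a pure-R reference implementation (`tct_rhs`)
cross-checked against it in the tests. Solver output is clipped to
zero for negative values within `1e-6` of the trajectory scale;
larger negatives raise an error. Off-grid queries interpolate blood
concentrations linearly. `tct_fraction` returns 0 when blood holds no
T cells at all (a degenerate case arising only in tests). All
randomness derives from a single seed through named substreams
(truth, jitter, noise, screening, sweep, compositions, external), so
every pipeline stage reruns bit-identically.

# Problem sizes used in tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full screening
experiment at its default size (10 patients, 20,000 candidates, 10
twins each). The dose-composition experiments are run at a reduced
scale chosen to keep the whole analysis re-runnable in minutes on one
core: 20 twins (the two best per patient) × 200 random compositions,
rather than the full 100 × 5000 sweep. At that scale the monotone
dependence of persistence on the scm dose fraction is already
unambiguous (Spearman ρ = 1 across bins), but the extreme composition
bins (subset fraction ≥ 75%) contain only a handful of compositions,
so comparisons *between* the cm and em/eff high-fraction bins sit at
the level of composition-sampling noise: the model's true cm-over-em
persistence margin (measured on deterministic 85%-corner
compositions) is under 2 percentage points across plausible virtual
patients, and the high-fraction bin means can invert it. The severed
cm → em differentiation route (see above) is the structural reason
the cm margin is small; readers comparing against the large-sweep
subset ordering should rely on the corner-composition experiment or
increase `n_compositions`.

# Known limitations

* The expansion peak of the reference patient falls near day 90 —
  later than the 2–4 week peaks typical of clinical products; the
  expansion/contraction timing is controlled by `lambda_A` and the
  antigen-driven rates and can be re-calibrated per application.
* Endogenous recovery modestly overshoots its nominal baseline (see
  above).
* Tumour burden, T-cell-mediated killing, conditioning and cytokine
  pharmacokinetics, CD4+ lineages and exhaustion states are out of
  scope; antigen decay subsumes them empirically.
* The model equations here are an independent construction from the
  processes and compartment structure described for this model class;
  they are not a reconstruction of any published supplementary
  equation set.
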