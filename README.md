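# tcelltwin

Digital twins for the cellular kinetics of TCR-engineered T cell
therapy.

Adoptively transferred T cells follow a characteristic multiphasic
course in blood — distribution into tissue, antigen-driven expansion,
contraction, and long-term persistence or decline — with enormous
patient-to-patient variability that is linked to clinical benefit.
`tcelltwin` is for modellers and pharmacometricians who want to
dissect that variability mechanistically: it implements a
quantitative systems pharmacology (QSP) model of engineered T cell
kinetics and the digital-twin workflow built on it, with a
synthetic-data generator so the entire pipeline runs and is testable
without access to clinical data.

## The model

Five species — engineered T_scm, T_cm, T_em, T_eff and endogenous
T cells — move between blood, tumour-draining lymph node (TDLN),
lumped normal tissue, and tumour. For every valid compartment ×
species pair the cell count obeys

    dN/dt = (k_base + 1{c ∈ {TDLN, tumour}} · k_atg · H(A)) · N · (1 − ΣN/Tcap)
            − k_apop · N  +  conversion in − conversion out  +  trafficking,

with a saturating antigen drive `H(A) = A/(A + K_A)` fed by an
exponentially decaying effective antigen load (`dA/dt = −λ_A A`),
strict linear differentiation scm → cm → em → eff in the antigen
compartments, cell-conserving concentration-difference trafficking
(`J = k_traffic (C_blood · Kp − C_c) V_c`), and lymphodepletion plus
infusion encoded in the initial state. On top of the simulator the
package provides:

* **Synthetic cohorts** with the structure of a 3-cohort
  dose-escalation trial (10^9 / 10^10 / 10^11 cells; irregular
  sampling; lognormal noise; limit of quantification).
* **Digital-twin screening**: thousands of log-uniformly sampled
  virtual patients scored per patient by log-scale RMSE; the 10 best
  per patient form the virtual population.
* **Virtual trials**: median/IQR kinetic bands, %TCT (engineered
  fraction of blood T cells), persister stratification at day 50.
* **Dose-composition optimization**: flat-Dirichlet sweeps relating
  infused subset fractions to persistence at day 365.
* **Sensitivity analyses**: partial rank correlation coefficients
  (PRCC) against the persister outcome, and PCA of twin parameter
  space.
* **External prediction**: re-simulating the population at another
  study's dose and selecting the best-matching twin by RMSE.

## Worked example

```r
library(tcelltwin)

## the reference virtual patient at the middle dose
p    <- tct_reference_params()
dose <- tct_dose(1e10, c(scm = 0.01, cm = 0.03, em = 0.48, eff = 0.48))
traj <- simulate_kinetics(p, dose, t_end = 365)

eng <- rowSums(blood_concentrations(traj)[, tct_engineered()])
signif(eng[c(1, 15, 92, 366)], 3)    # cells/mL on days 0, 14, 91, 365
#> [1] 2000000   41300  909000  149000
round(100 * tct_fraction(traj, c(14, 50, 91, 365)), 1)   # %TCT
#> [1] 17.7 41.9 51.8  6.1
```

The engineered cells drop ~50-fold during distribution, expand back
to a peak near day 91, then contract — the four canonical phases —
while %TCT peaks around 52% and falls to ~6% at one year as the
endogenous compartment recovers from lymphodepletion.

```r
## a small synthetic cohort, screened for digital twins
design <- cohort_design(n_patients = 4,
                        cohort_assignment = c(1e9, 1e10, 1e10, 1e11),
                        seed = 7)
cohort <- synthesize_cohort(design)
twins  <- generate_twins(cohort, n_candidates = 500, k = 3, seed = 7)
twins
#> <tct_twins> 12 twins across 4 patients (k = 3, 500 candidates screened)

run_trial(twins, dose, t_end = 365)
#> <tct_trial> 12 twins (0 failed), dose 1e+10 cells, 6/12 persisters
```

Each twin is a full parameter set whose simulated kinetics match one
patient's observations at that patient's dose (scores here are
log10-scale RMSEs ≈ 0.65–0.85 against data with noise SD 0.2); the
trial splits them into persisters and non-persisters by whether
engineered cells hold a strict majority of blood T cells at day 50.
`composition_sweep()`, `prcc()`, `pca_parameters()` and
`predict_external()` continue the analysis; `vignettes/digital-twins.Rmd`
documents the model, its assumptions and every default.

A command-line interface wrapping the same functions is installed at
`inst/cli/tcelltwin.R`:

```sh
Rscript inst/cli/tcelltwin.R synth --out runs/cohort --seed 1
Rscript inst/cli/tcelltwin.R twins --data runs/cohort --out runs/twins --seed 1
Rscript inst/cli/tcelltwin.R trial --twins runs/twins --out runs/trial
```

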