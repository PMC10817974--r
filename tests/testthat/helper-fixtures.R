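# Shared fixtures: all built in code, no stored data.

ref_dose <- function(total = 1e10) {
  tct_dose(total, c(scm = 0.01, cm = 0.03, em = 0.48, eff = 0.48))
}

# A parameter set with every kinetic process switched off; individual
# processes are re-enabled per test.
frozen_params <- function(...) {
  tct_params(
    "kprolif_base.scm" = 0, "kprolif_base.cm" = 0, "kprolif_base.em" = 0,
    "kprolif_base.endo" = 0,
    "kprolif_atg.scm" = 0, "kprolif_atg.cm" = 0, "kprolif_atg.em" = 0,
    "kconv.scm" = 0, "kconv.cm" = 0, "kconv.em" = 0,
    "kapop.scm" = 0, "kapop.cm" = 0, "kapop.em" = 0, "kapop.eff" = 0,
    "kapop.endo" = 0,
    "ktraffic.scm" = 0, "ktraffic.cm" = 0, "ktraffic.em" = 0,
    "ktraffic.eff" = 0, "ktraffic.endo" = 0,
    "lambda_A" = 0,
    ...
  )
}

# Build a tct_trajectory object directly from prescribed blood
# concentrations (cells/mL); non-blood states stay 0.
make_blood_trajectory <- function(times, conc, params = tct_reference_params()) {
  states <- matrix(0, nrow = length(times), ncol = length(tct_state_names()),
                   dimnames = list(NULL, tct_state_names()))
  for (s in colnames(conc)) {
    states[, paste0("blood.", s)] <- conc[, s] * params$V[["blood"]]
  }
  structure(list(times = times, states = states, params = params,
                 dose = ref_dose()),
            class = "tct_trajectory")
}

# Small synthetic cohort for screening tests: few patients, few days.
small_design <- function(n_patients = 3, seed = 42,
                         noise_sd_log10 = 0.15) {
  cohort_design(
    n_patients = n_patients,
    cohort_assignment = rep(c(1e9, 1e10, 1e11), length.out = n_patients),
    base_days = c(7, 14, 28, 56, 120, 240, 365),
    noise_sd_log10 = noise_sd_log10,
    seed = seed
  )
}

# Rank-based partial correlation oracle: invert the correlation matrix
# of the ranked parameters plus outcome.
prcc_oracle <- function(x, y) {
  rx <- apply(x, 2, rank)
  ry <- rank(y)
  R <- stats::cor(cbind(rx, ry))
  P <- solve(R)
  k <- ncol(rx) + 1
  vapply(seq_len(ncol(rx)), function(j) {
    -P[j, k] / sqrt(P[j, j] * P[k, k])
  }, numeric(1))
}

# Manually assemble a tct_twins object from parameter sets.
make_twins <- function(params_list, patient_ids = NULL,
                       ranges = tct_screen_ranges()) {
  n <- length(params_list)
  if (is.null(patient_ids)) patient_ids <- rep("P01", n)
  ranks <- stats::ave(seq_len(n), patient_ids, FUN = seq_along)
  twins <- lapply(seq_len(n), function(i) {
    list(patient_id = patient_ids[i], rank = ranks[i], score = 0,
         candidate = i, params = params_list[[i]])
  })
  structure(list(twins = twins,
                 provenance = list(seed = 0L, n_candidates = n, k = max(ranks),
                                   ranges = ranges)),
            class = "tct_twins")
}
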