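test_that("a single-twin trial has degenerate bands equal to its own trajectory", {
  tw <- make_twins(list(tct_reference_params()))
  trial <- run_trial(tw, ref_dose(1e10), t_end = 120)
  traj <- simulate_kinetics(tct_reference_params(), ref_dose(1e10),
                            t_end = 120)
  conc <- blood_concentrations(traj)
  for (s in tct_species()) {
    sub <- trial$summary[trial$summary$species == s, ]
    expect_equal(sub$median, unname(conc[, s]))
    expect_equal(sub$q25, sub$q75)
  }
  expect_length(trial$persister, 1)
})

test_that("a zero-dose trial has no engineered cells and no persisters", {
  tw <- make_twins(sample_parameters(tct_screen_ranges(spread = 2), 3,
                                     seed = 3))
  trial <- run_trial(tw, tct_dose(0), t_end = 80)
  eng <- trial$summary[trial$summary$species %in% tct_engineered(), ]
  expect_true(all(eng$median == 0) && all(eng$q75 == 0))
  expect_true(all(!trial$persister))
  expect_true(all(trial$tct == 0))
})

test_that("persister classification uses a strict majority at the stratification day", {
  tt <- seq(0, 60, by = 10)
  mk <- function(f) {
    endo <- rep(1e5, length(tt))
    eng <- endo * f / (1 - f)
    make_blood_trajectory(tt, cbind(scm = eng, cm = 0 * eng, em = 0 * eng,
                                    eff = 0 * eng, endo = endo))
  }
  expect_true(classify_persister(mk(0.7)))
  expect_false(classify_persister(mk(0.5)))   # boundary is non-persister
  expect_false(classify_persister(mk(0)))
  short <- mk(0.7); short$times <- short$times / 2
  expect_error(classify_persister(short), "before the stratification day")
})

test_that("composition sampling is uniform on the simplex and seeded", {
  m <- sample_compositions(5000, seed = 9)
  expect_equal(dim(m), c(5000, 4))
  expect_equal(unname(rowSums(m)), rep(1, 5000), tolerance = 1e-12)
  expect_equal(unname(colMeans(m)), rep(0.25, 4), tolerance = 0.02)
  expect_identical(m, sample_compositions(5000, seed = 9))
})

test_that("the composition sweep is reproducible, bounded, and correctly binned", {
  tw <- make_twins(sample_parameters(tct_screen_ranges(spread = 2), 2,
                                     seed = 11))
  sw1 <- composition_sweep(tw, n_compositions = 15, total_cells = 1e10,
                           seed = 4)
  sw2 <- composition_sweep(tw, n_compositions = 15, total_cells = 1e10,
                           seed = 4)
  expect_identical(sw1, sw2)
  expect_equal(nrow(sw1$rows), 30)   # 15 compositions x 2 twins
  expect_true(all(sw1$rows$persistence >= 0 & sw1$rows$persistence <= 100))
  fr <- sw1$rows[, c("frac_scm", "frac_cm", "frac_em", "frac_eff")]
  expect_equal(unname(rowSums(fr)), rep(1, 30), tolerance = 1e-12)

  # binned means recompute from the rows
  for (i in unique(round(seq(1, nrow(sw1$bins), length.out = 5)))) {
    b <- sw1$bins[i, ]
    f <- sw1$rows[[paste0("frac_", b$species)]]
    sel <- f >= b$bin_lo & (f < b$bin_hi | (b$bin_hi == 1 & f <= 1))
    expect_equal(b$mean_persistence, mean(sw1$rows$persistence[sel]))
    expect_equal(b$n, sum(sel))
  }
})

test_that("enrichment comparison reports exact fold-changes in the linear regime", {
  tw <- make_twins(list(tct_reference_params()))
  orig <- ref_dose(1e10)
  same <- enrichment_comparison(tw, orig, list(orig), horizon = 90)
  alt <- same[same$dose_label == "alt1", ]
  expect_equal(alt$peak_fold, 1)
  expect_equal(alt$auc_fold, 1)
  expect_equal(alt$persistence_fold, 1)

  # pure decay (no antigen drive, no conversion, huge capacities): the
  # system is linear in the dose, so a 10x lower dose scales exactly
  lin <- frozen_params("kapop.scm" = 0.01, "kapop.cm" = 0.02,
                       "kapop.em" = 0.05, "kapop.eff" = 0.1,
                       "ktraffic.scm" = 0.05, "ktraffic.cm" = 0.05,
                       "ktraffic.em" = 0.05, "ktraffic.eff" = 0.05)
  twl <- make_twins(list(lin))
  cmp <- enrichment_comparison(twl, ref_dose(1e10), list(ref_dose(1e9)),
                               horizon = 60)
  altl <- cmp[cmp$dose_label == "alt1", ]
  expect_equal(altl$peak_fold, 0.1, tolerance = 1e-9)
  expect_equal(altl$auc_fold, 0.1, tolerance = 1e-9)

  # scm enrichment at equal total dose never hurts persistence
  tws <- make_twins(sample_parameters(tct_screen_ranges(spread = 2), 5,
                                      seed = 13))
  enriched <- tct_dose(1e10, c(scm = 0.85, cm = 0.05, em = 0.05, eff = 0.05))
  cmp2 <- enrichment_comparison(tws, ref_dose(1e10), list(enriched),
                                horizon = 365)
  alt2 <- cmp2[cmp2$dose_label == "alt1", ]
  expect_true(all(alt2$persistence_fold >= 1))
})

test_that("external prediction finds the best-matching twin by RMSE", {
  tws <- make_twins(sample_parameters(tct_screen_ranges(spread = 2), 6,
                                      seed = 15))
  dose <- tct_dose(14.8e9, c(scm = 0.05, cm = 0.15, em = 0.6, eff = 0.2))
  days <- c(10, 30, 60, 120, 200)

  # observed = twin 4's own prediction: it must be selected with RMSE ~ 0
  traj <- simulate_kinetics(tws$twins[[4]]$params, dose, t_end = 200,
                            output_times = days)
  observed <- data.frame(day = days, pct_tct = 100 * tct_fraction(traj, days))
  pred <- predict_external(tws, dose, observed)
  expect_equal(pred$best, 4)
  expect_lt(pred$best_rmse, 1e-6)
  expect_equal(nrow(pred$pct_tct), 6)

  # exhaustive oracle over the returned trajectories
  obs_idx <- match(days, pred$times)
  rmse_oracle <- apply(pred$pct_tct, 1, function(row) {
    sqrt(mean((row[obs_idx] - observed$pct_tct)^2))
  })
  expect_equal(pred$rmse, rmse_oracle)
  expect_equal(pred$best, which.min(rmse_oracle))

  expect_error(predict_external(tws, dose, observed[1, , drop = FALSE]),
               ">= 2 rows")
})
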