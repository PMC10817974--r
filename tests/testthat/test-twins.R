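test_that("the log-RMSE fit metric matches hand-computed values", {
  expect_equal(log_rmse(c(1e3, 1e4), c(1e4, 1e4), loq = 0), sqrt(0.5))
  expect_equal(log_rmse(c(1e3, 1e4), c(1e4, 1e4), loq = 1), sqrt(0.5),
               tolerance = 1e-3)
  expect_identical(log_rmse(c(5, 50), c(5, 50)), 0)
  # scale invariance (exact at loq = 0)
  o <- c(12, 340, 8e3); p <- c(20, 200, 1e4)
  expect_equal(log_rmse(10 * o, 10 * p, loq = 0), log_rmse(o, p, loq = 0))
  expect_error(log_rmse(1:3, 1:2), "equal length")
})

test_that("a perfect candidate scores zero against its own predictions", {
  p <- tct_reference_params()
  dose <- ref_dose(1e11)
  days <- c(7, 14, 28, 56, 120, 365)
  traj <- simulate_kinetics(p, dose, t_end = 365, output_times = days)
  conc <- blood_concentrations(traj)
  obs <- do.call(rbind, lapply(tct_species(), function(s) {
    data.frame(day = days, species = s, cells_per_mL = unname(conc[, s]))
  }))
  patient <- structure(list(patient_id = "PX", dose = dose,
                            observations = obs, ground_truth = p),
                       class = "tct_patient")
  expect_equal(fit_score(p, patient), 0, tolerance = 1e-10)
  expect_gt(fit_score(tct_params("kapop.em" = 0.4), patient), 0.01)
})

test_that("twin selection agrees with a brute-force sort oracle", {
  design <- small_design(1, seed = 23)
  cohort <- synthesize_cohort(design)
  cands <- sample_parameters(tct_screen_ranges(), 60, seed = 24)
  scores <- vapply(cands, function(p) {
    suppressWarnings(fit_score(p, cohort[[1]]))
  }, numeric(1))

  twins <- screen_and_select(cohort[[1]], cands, k = 10, scores = scores)
  oracle <- order(scores)[1:10]       # full sort, stable in ties
  expect_equal(vapply(twins, `[[`, numeric(1), "candidate"), oracle)
  expect_equal(vapply(twins, `[[`, numeric(1), "score"), sort(scores)[1:10])
  expect_false(is.unsorted(vapply(twins, `[[`, numeric(1), "score")))
  expect_equal(vapply(twins, `[[`, numeric(1), "rank"), 1:10)

  # ties broken by candidate index: duplicate the best candidate at the end
  best <- which.min(scores)
  scores2 <- c(scores, scores[best])
  t2 <- screen_and_select(cohort[[1]], c(cands, cands[best]), k = 1,
                          scores = scores2)
  expect_equal(t2[[1]]$candidate, best)

  # k = number of candidates returns everything
  tall <- screen_and_select(cohort[[1]], cands, k = 60, scores = scores)
  expect_length(tall, 60)

  # too few finite scores is an error naming the patient
  expect_error(
    screen_and_select(cohort[[1]], cands, k = 3,
                      scores = c(0.5, rep(Inf, 59))),
    cohort[[1]]$patient_id
  )
})

test_that("twin generation is deterministic and structured k per patient", {
  cohort <- synthesize_cohort(small_design(3, seed = 41))
  a <- generate_twins(cohort, n_candidates = 120, k = 3, seed = 41)
  b <- generate_twins(cohort, n_candidates = 120, k = 3, seed = 41)
  expect_identical(twin_ids <- vapply(a$twins, `[[`, character(1), "patient_id"),
                   vapply(b$twins, `[[`, character(1), "patient_id"))
  expect_identical(lapply(a$twins, function(tw) tct_flatten_params(tw$params)),
                   lapply(b$twins, function(tw) tct_flatten_params(tw$params)))
  expect_equal(as.vector(table(twin_ids)), rep(3, 3))

  # a patient without observations is refused by name
  empty <- cohort
  empty[[2]]$observations <- empty[[2]]$observations[0, ]
  expect_error(generate_twins(empty, n_candidates = 10, k = 2, seed = 1),
               empty[[2]]$patient_id)
})

test_that("twin scores improve stochastically with a larger candidate pool", {
  design <- small_design(1, seed = 55)
  cohort <- synthesize_cohort(design)
  best_small <- best_large <- numeric(3)
  for (i in 1:3) {
    small <- generate_twins(cohort, n_candidates = 50, k = 1, seed = i)
    large <- generate_twins(cohort, n_candidates = 400, k = 1, seed = i)
    best_small[i] <- small$twins[[1]]$score
    best_large[i] <- large$twins[[1]]$score
  }
  expect_lte(median(best_large), median(best_small))
})

test_that("the reference virtual patient is the pooled-score optimum, then refined", {
  cohort <- synthesize_cohort(small_design(2, seed = 61))
  cands <- sample_parameters(tct_screen_ranges(), 40, seed = 62)

  # single-patient cohort: unrefined reference = rank-1 twin
  one <- structure(cohort[1], class = "tct_cohort")
  ref0 <- build_reference_patient(one, cands, refine = FALSE)
  twin1 <- screen_and_select(cohort[[1]], cands, k = 1)[[1]]
  expect_equal(tct_flatten_params(ref0), tct_flatten_params(twin1$params))
  expect_equal(attr(ref0, "pooled_score"), twin1$score)

  # refinement never worsens the pooled score
  ref <- build_reference_patient(cohort, cands, max_iter = 4)
  expect_lte(attr(ref, "pooled_score"), attr(ref, "screen_score"))

  # in-model truth: with the truth among the candidates on its own
  # noiseless cohort, the reference cannot do worse than the truth
  design <- small_design(2, seed = 63, noise_sd_log10 = 0)
  truth <- tct_reference_params()
  shared <- generate_cohort(design, list(truth, truth))
  ref2 <- build_reference_patient(shared, c(cands[1:5], list(truth)),
                                  max_iter = 2)
  truth_pooled <- mean(vapply(shared, function(pt) fit_score(truth, pt),
                              numeric(1)))
  expect_lte(attr(ref2, "pooled_score"), truth_pooled + 1e-6)
})

test_that("parameter recovery reports ratios and identifiability", {
  cohort <- synthesize_cohort(small_design(2, seed = 71))
  truth_params <- lapply(cohort, `[[`, "ground_truth")
  twins <- make_twins(rep(truth_params, each = 3),
                      patient_ids = rep(vapply(cohort, `[[`, character(1),
                                               "patient_id"), each = 3))
  rec <- parameter_recovery(twins, cohort)
  expect_equal(rec$ratio, rep(1, nrow(rec)))
  expect_true(all(rec$recovered))
  # the cm conversion rate acts where no cm/em pair coexists: no signal
  expect_true(all(!rec$identifiable[rec$parameter == "kconv.cm"]))
  expect_true(all(rec$identifiable[rec$parameter == "kprolif_atg.scm"]))
})

test_that("twin populations round-trip through their CSV/JSON artifacts", {
  cohort <- synthesize_cohort(small_design(2, seed = 81))
  twins <- generate_twins(cohort, n_candidates = 60, k = 2, seed = 81)
  dir <- withr::local_tempdir()
  write_twins(twins, dir)
  back <- read_twins(dir)
  expect_equal(back$provenance$k, twins$provenance$k)
  expect_equal(back$provenance$ranges, twins$provenance$ranges)
  for (i in seq_along(twins$twins)) {
    expect_identical(back$twins[[i]]$patient_id, twins$twins[[i]]$patient_id)
    expect_equal(back$twins[[i]]$score, twins$twins[[i]]$score)
    expect_equal(tct_flatten_params(back$twins[[i]]$params),
                 tct_flatten_params(twins$twins[[i]]$params))
  }
})
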