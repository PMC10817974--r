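test_that("antigen load decays exponentially with the stated identities", {
  p <- tct_params(A0 = 2, lambda_A = 0.05)
  expect_identical(antigen_load(0, p), 2)
  expect_equal(antigen_load(log(2) / 0.05, p), 1, tolerance = 1e-12)
  p0 <- tct_params(A0 = 3, lambda_A = 0)
  expect_identical(antigen_load(c(0, 10, 1000), p0), rep(3, 3))
  tt <- seq(0, 400, by = 25)
  expect_false(is.unsorted(rev(antigen_load(tt, p))))
  expect_error(antigen_load(-1, p), "non-negative")
})

test_that("initial state places the dose in blood and depletes endogenous cells", {
  p <- tct_reference_params()
  dose <- tct_dose(1e11, c(scm = 0.01, cm = 0.03, em = 0.48, eff = 0.48))
  y <- initial_state(p, dose)
  expect_equal(y[["blood.scm"]], 1e9)
  expect_equal(y[["blood.cm"]], 3e9)
  expect_equal(y[["blood.em"]], 4.8e10)
  expect_equal(y[["blood.eff"]], 4.8e10)
  expect_equal(y[["antigen"]], p$A0)
  expect_true(all(y[c("tdln.scm", "tissue.em", "tumor.eff")] == 0))

  # endogenous cells: ld_frac times the Kp-scaled equilibrium
  expect_equal(y[["blood.endo"]],
               p$ld_frac * p$C_endo_baseline * p$V[["blood"]])
  expect_equal(y[["tissue.endo"]],
               p$ld_frac * p$C_endo_baseline * p$Kp$tissue[["endo"]] *
                 p$V[["tissue"]])

  y0 <- initial_state(p, tct_dose(0))
  expect_true(all(y0[paste0("blood.", tct_engineered())] == 0))

  pfull <- tct_params(ld_frac = 1)
  yf <- initial_state(pfull, tct_dose(0))
  expect_equal(yf[["blood.endo"]], pfull$C_endo_baseline * pfull$V[["blood"]])
})

test_that("derivatives vanish for a frozen system and R and C solvers agree", {
  p <- frozen_params()
  y <- initial_state(p, ref_dose())
  d <- tct_rhs(0, y, p)
  expect_equal(unname(d), rep(0, length(d)))

  pr <- tct_reference_params()
  tR <- simulate_kinetics(pr, ref_dose(), t_end = 90, output_times = 0:90,
                          compiled = FALSE)
  tC <- simulate_kinetics(pr, ref_dose(), t_end = 90, output_times = 0:90,
                          compiled = TRUE)
  expect_equal(tC$states, tR$states, tolerance = 1e-6)
})

test_that("pure apoptosis gives exponential decay at all output times", {
  k <- 0.07
  p <- frozen_params("kapop.scm" = k, "kapop.cm" = k, "kapop.em" = k,
                     "kapop.eff" = k)
  dose <- ref_dose(1e10)
  tt <- c(0, 1, 5, 20, 90, 365)
  traj <- simulate_kinetics(p, dose, t_end = 365, output_times = tt,
                            rtol = 1e-10, atol = 1e-6)
  for (s in tct_engineered()) {
    n0 <- dose$total_cells * dose$frac[[s]]
    expect_equal(traj$states[, paste0("blood.", s)], n0 * exp(-k * tt),
                 tolerance = 1e-6)
  }
})

test_that("pure trafficking matches the two-compartment analytic solution", {
  kt <- 0.11
  Kp <- 4
  p <- frozen_params("ktraffic.scm" = kt, "Kp.tissue.scm" = Kp,
                     "Kp.tdln.scm" = 0)
  dose <- tct_dose(1e9, c(scm = 1, cm = 0, em = 0, eff = 0))
  Vb <- p$V[["blood"]]; Vs <- p$V[["tissue"]]
  tt <- c(0, 0.5, 2, 10, 50, 365)
  traj <- simulate_kinetics(p, dose, t_end = 365, output_times = tt,
                            rtol = 1e-11, atol = 1e-4)

  # independent oracle: eigen-decomposition of the 2x2 linear system
  A <- matrix(c(-kt * Kp * Vs / Vb, kt * Kp * Vs / Vb,
                kt, -kt), nrow = 2)
  ev <- eigen(A)
  y0 <- c(1e9, 0)
  coef <- solve(ev$vectors, y0)
  expected <- t(vapply(tt, function(t) {
    Re(ev$vectors %*% (coef * exp(ev$values * t)))
  }, numeric(2)))

  expect_equal(traj$states[, "blood.scm"], expected[, 1], tolerance = 1e-6)
  expect_equal(traj$states[, "tissue.scm"], expected[, 2], tolerance = 1e-6)

  # partition equilibrium: C_tissue / C_blood -> Kp
  cb <- traj$states[6, "blood.scm"] / Vb
  cs <- traj$states[6, "tissue.scm"] / Vs
  expect_equal(unname(cs / cb), Kp, tolerance = 1e-6)
})

test_that("zero dose yields no engineered cells at any time", {
  traj <- simulate_kinetics(tct_reference_params(), tct_dose(0), t_end = 365)
  conc <- blood_concentrations(traj)
  expect_true(all(conc[, tct_engineered()] == 0))
  expect_true(all(conc[, "endo"] > 0))
})

test_that("the reference patient shows the four kinetic phases at the middle dose", {
  traj <- simulate_kinetics(tct_reference_params(), ref_dose(1e10),
                            t_end = 365)
  eng <- rowSums(blood_concentrations(traj)[, tct_engineered()])
  trough_i <- which.min(eng[2:61]) + 1
  peak_i <- which.max(eng[trough_i:366]) + trough_i - 1
  expect_lt(eng[trough_i], eng[1])              # distribution: initial decline
  expect_gt(eng[peak_i] / eng[trough_i], 3)     # expansion to a peak
  expect_true(peak_i - 1 >= 30 && peak_i - 1 <= 150)
  expect_lt(eng[366], eng[peak_i] / 2)          # contraction / decline
})

test_that("tct_fraction computes the engineered blood fraction with safe division", {
  tt <- c(0, 10)
  conc <- cbind(scm = c(1e5, 0), cm = c(1e5, 0), em = c(5e4, 0),
                eff = c(5e4, 0), endo = c(7e5, 0))
  traj <- make_blood_trajectory(tt, conc)
  expect_equal(tct_fraction(traj, 0), 0.3)
  expect_equal(tct_fraction(traj, 10), 0)       # empty blood convention
  expect_error(tct_fraction(traj, 11), "outside")

  conc2 <- cbind(scm = c(1e3, 1e3), cm = c(0, 0), em = c(0, 0),
                 eff = c(0, 0), endo = c(0, 0))
  expect_equal(tct_fraction(make_blood_trajectory(tt, conc2), 5), 1)
})

test_that("blood engineered exposure is monotone in total dose", {
  p <- tct_reference_params()
  aucs <- vapply(c(1e9, 1e10, 1e11), function(total) {
    traj <- simulate_kinetics(p, ref_dose(total), t_end = 365)
    sum(rowSums(blood_concentrations(traj)[, tct_engineered()]))
  }, numeric(1))
  expect_false(is.unsorted(aucs))
})

test_that("differentiation is unidirectional along the memory chain", {
  # only conversion + trafficking active, constant antigen
  p <- frozen_params("kconv.scm" = 0.2, "kconv.cm" = 0.2, "kconv.em" = 0.2,
                     "ktraffic.scm" = 0.1, "ktraffic.cm" = 0.1,
                     "ktraffic.em" = 0.1, "ktraffic.eff" = 0.1)
  dose <- tct_dose(1e9, c(scm = 0.7, cm = 0.1, em = 0.1, eff = 0.1))
  traj <- simulate_kinetics(p, dose, t_end = 200, output_times = seq(0, 200, 5),
                            rtol = 1e-10, atol = 1e-6)
  tot <- function(s) rowSums(traj$states[, grep(paste0("\\.", s, "$"),
                                                colnames(traj$states)),
                                         drop = FALSE])
  scm <- tot("scm")
  downstream <- tot("cm") + tot("em") + tot("eff")
  expect_true(all(diff(scm) <= 1e-6 * max(scm)))
  expect_true(all(diff(downstream) >= -1e-6 * max(downstream)))
  # conversion and trafficking conserve engineered cells
  total <- scm + downstream
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-8)
})

test_that("simulation stays non-negative across sampled virtual patients", {
  cands <- sample_parameters(tct_screen_ranges(spread = 3), 5, seed = 5)
  for (p in cands) {
    traj <- simulate_kinetics(p, ref_dose(1e10), t_end = 365,
                              output_times = seq(0, 365, 5))
    expect_true(all(traj$states >= 0))
  }
})

test_that("invalid simulation inputs are rejected", {
  p <- tct_reference_params()
  expect_error(simulate_kinetics(p, ref_dose(), t_end = -1), "t_end")
  expect_error(simulate_kinetics(p, ref_dose(), t_end = 10,
                                 output_times = c(0, 20)), "output_times")
  expect_error(simulate_kinetics(p, list(total_cells = 1), t_end = 10),
               "tct_dose")
})
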