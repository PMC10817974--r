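#' Effective antigen load
#'
#' The antigen drive of the model is a lumped "effective antigen load"
#' that decays exponentially from its initial value:
#' `A(t) = A0 * exp(-lambda_A * t)`.  It stands in for tumour antigen
#' availability and for processes (exhaustion, immune escape, antigen
#' loss) that dampen antigen-driven expansion over time.
#'
#' @param t time since infusion, days (non-negative; vectorised).
#' @param params a `tct_params` object.
#' @return Antigen load, same units as `params$A0`.
#' @export
antigen_load <- function(t, params) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  params$A0 * exp(-params$lambda_A * t)
}

#' Initial state at infusion
#'
#' Lymphodepletion and adoptive transfer are collapsed into the t = 0
#' state: all infused engineered cells start in blood, split by the dose
#' composition; endogenous cells start at `ld_frac` times their
#' pre-depletion equilibrium distribution (blood at `C_endo_baseline`,
#' TDLN and tissue at the Kp-scaled equilibrium concentrations); the
#' antigen load starts at `A0`.
#'
#' @param params a `tct_params` object.
#' @param dose a `tct_dose` object.
#' @return Named state vector (see [tct_state_names()]), cells and
#'   antigen units.
#' @export
initial_state <- function(params, dose) {
  y <- setNames(numeric(length(tct_state_names())), tct_state_names())
  for (s in tct_engineered()) {
    y[paste0("blood.", s)] <- dose$total_cells * dose$frac[[s]]
  }
  ce <- params$ld_frac * params$C_endo_baseline
  y["blood.endo"]  <- ce * params$V[["blood"]]
  y["tdln.endo"]   <- ce * params$Kp$tdln[["endo"]] * params$V[["tdln"]]
  y["tissue.endo"] <- ce * params$Kp$tissue[["endo"]] * params$V[["tissue"]]
  y["antigen"] <- params$A0
  y
}

#' Time derivative of the model state (reference implementation)
#'
#' Pure-R implementation of the ODE right-hand side; the compiled C
#' version used by [simulate_kinetics()] computes identical derivatives
#' (cross-checked in the test suite).  For each valid (compartment,
#' species) pair:
#' \deqn{dN/dt = G - kapop \cdot N + D_{in} - D_{out} + J}
#' with logistic growth
#' `G = (kprolif_base + [c in {tdln,tumor}, s != endo] * kprolif_atg * H(A)) * N * (1 - sumT(c)/Tcap(c))`,
#' saturating antigen drive `H(A) = A/(A+KA)`, antigen-driven
#' differentiation along scm -> cm -> em -> eff wherever source and
#' product coexist in an antigen compartment (scm -> cm in TDLN,
#' em -> eff in tumour), and trafficking flux
#' `J_c = ktraffic * (C_blood * Kp - C_c) * V_c` (compartment gains,
#' blood loses).  Trafficking and differentiation conserve total cells
#' exactly.  The antigen decays as `dA/dt = -lambda_A * A`.
#'
#' @param t time, days (unused; the system is autonomous).
#' @param state named state vector as from [initial_state()].
#' @param params a `tct_params` object.
#' @return Named derivative vector, cells/day.
#' @export
tct_rhs <- function(t, state, params) {
  occ <- tct_occupancy()
  A <- state[["antigen"]]
  H <- if (A + params$KA > 0) A / (A + params$KA) else 0
  d <- setNames(numeric(length(state)), names(state))

  # growth and apoptosis
  for (cc in names(occ)) {
    sumT <- sum(state[paste(cc, occ[[cc]], sep = ".")])
    cap <- 1 - sumT / params$Tcap[[cc]]
    for (s in occ[[cc]]) {
      key <- paste(cc, s, sep = ".")
      g <- params$kprolif_base[[s]]
      if (cc %in% c("tdln", "tumor") && s != "endo") {
        g <- g + params$kprolif_atg[[s]] * H
      }
      d[key] <- d[key] + (g * cap - params$kapop[[s]]) * state[[key]]
    }
  }

  # antigen-driven differentiation where source and product coexist
  chain <- tct_engineered()
  for (cc in c("tdln", "tumor")) {
    for (i in seq_len(length(chain) - 1)) {
      s <- chain[i]; s2 <- chain[i + 1]
      if (s %in% occ[[cc]] && s2 %in% occ[[cc]]) {
        f <- params$kconv[[s]] * H * state[[paste(cc, s, sep = ".")]]
        d[paste(cc, s, sep = ".")]  <- d[paste(cc, s, sep = ".")]  - f
        d[paste(cc, s2, sep = ".")] <- d[paste(cc, s2, sep = ".")] + f
      }
    }
  }

  # trafficking against Kp-scaled blood concentration
  targets <- tct_traffic_targets()
  for (s in tct_species()) {
    Cb <- state[[paste0("blood.", s)]] / params$V[["blood"]]
    for (cc in targets[[s]]) {
      key <- paste(cc, s, sep = ".")
      Cc <- state[[key]] / params$V[[cc]]
      flux <- params$ktraffic[[s]] *
        (Cb * params$Kp[[cc]][[s]] - Cc) * params$V[[cc]]
      d[key] <- d[key] + flux
      d[paste0("blood.", s)] <- d[paste0("blood.", s)] - flux
    }
  }

  d["antigen"] <- -params$lambda_A * A
  d
}

#' Simulate the kinetic model
#'
#' Integrates the model from [initial_state()] with a stiff-capable
#' adaptive solver (deSolve's `lsoda`), by default through the compiled
#' C right-hand side.  Small negative counts produced by the solver
#' (within `1e-6` of the trajectory's magnitude) are clipped to 0;
#' larger negatives raise an error.
#'
#' @param params a `tct_params` object.
#' @param dose a `tct_dose` object.
#' @param t_end end of integration, days (> 0).
#' @param output_times times at which to report the state, days, within
#'   `[0, t_end]`; default daily from 0 to `t_end`.
#' @param rtol,atol relative / absolute solver tolerances (cells).
#' @param compiled use the compiled C right-hand side (default) or the
#'   R reference implementation.
#' @return A `tct_trajectory`: list with `times` (days), `states`
#'   (matrix, one row per time, columns [tct_state_names()]), and the
#'   `params` and `dose` used.
#' @export
simulate_kinetics <- function(params, dose, t_end = 365,
                              output_times = NULL,
                              rtol = 1e-8, atol = 1e-4,
                              compiled = TRUE) {
  params <- validate_tct_params(params)
  if (!inherits(dose, "tct_dose")) stop("dose must be a tct_dose",
                                        call. = FALSE)
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (is.null(output_times)) output_times <- seq(0, t_end, by = 1)
  output_times <- sort(unique(as.numeric(output_times)))
  if (any(output_times < 0) || any(output_times > t_end)) {
    stop("output_times must lie within [0, t_end]", call. = FALSE)
  }
  solve_times <- sort(unique(c(0, output_times)))

  y0 <- initial_state(params, dose)
  # deSolve emits its own warnings on non-convergence; failure is
  # detected below via istate and raised as a proper error instead.
  out <- suppressWarnings(if (compiled) {
    deSolve::ode(
      y = y0, times = solve_times, func = "tct_derivs",
      parms = tct_pack_params(params), dllname = "tcelltwin",
      initfunc = "tct_init", method = "lsoda",
      rtol = rtol, atol = atol, maxsteps = 50000
    )
  } else {
    deSolve::ode(
      y = y0, times = solve_times,
      func = function(t, y, p) list(unname(tct_rhs(t, setNames(y, names(y0)), p))),
      parms = params, method = "lsoda",
      rtol = rtol, atol = atol, maxsteps = 50000
    )
  })
  istate <- attr(out, "istate")[1]
  if (istate < 0 || nrow(out) < length(solve_times)) {
    stop("ODE integration failed (istate = ", istate, ") for dose ",
         format(dose$total_cells), " cells; see deSolve diagnostics",
         call. = FALSE)
  }
  states <- out[, -1, drop = FALSE]
  colnames(states) <- tct_state_names()

  mx <- max(abs(states))
  if (min(states) < -1e-6 * mx) {
    stop("solver produced negative state values beyond tolerance (min ",
         format(min(states)), " vs scale ", format(mx), ")", call. = FALSE)
  }
  states[states < 0] <- 0

  keep <- match(output_times, solve_times)
  structure(
    list(times = output_times, states = states[keep, , drop = FALSE],
         params = params, dose = dose),
    class = "tct_trajectory"
  )
}

#' @export
print.tct_trajectory <- function(x, ...) {
  cat(sprintf(
    "<tct_trajectory> %d timepoints over [%.4g, %.4g] days, dose %.4g cells\n",
    length(x$times), min(x$times), max(x$times), x$dose$total_cells))
  invisible(x)
}

#' Blood concentrations of a trajectory
#'
#' @param traj a `tct_trajectory`.
#' @return Matrix (time x species) of blood concentrations in cells/mL,
#'   columns `scm`, `cm`, `em`, `eff`, `endo`.
#' @export
blood_concentrations <- function(traj) {
  m <- traj$states[, paste0("blood.", tct_species()), drop = FALSE] /
    traj$params$V[["blood"]]
  colnames(m) <- tct_species()
  rownames(m) <- NULL
  m
}

# Linear interpolation of blood concentrations at arbitrary times.
interp_blood_conc <- function(traj, t) {
  if (any(t < min(traj$times)) || any(t > max(traj$times))) {
    stop("t outside trajectory range [", min(traj$times), ", ",
         max(traj$times), "]", call. = FALSE)
  }
  conc <- blood_concentrations(traj)
  vapply(tct_species(), function(s) {
    if (length(traj$times) == 1) return(rep(conc[1, s], length(t)))
    approx(traj$times, conc[, s], xout = t)$y
  }, numeric(length(t)))
}

#' Engineered fraction of blood T cells (%TCT / 100)
#'
#' Fraction of all blood T cells that are TCR-engineered:
#' `sum(engineered blood conc) / (sum(engineered) + endogenous)` at time
#' `t`, interpolating linearly between stored timepoints.  Returns 0
#' when the blood holds no T cells at all.
#'
#' @param traj a `tct_trajectory`.
#' @param t time, days, within the trajectory's range (vectorised).
#' @return Fraction in `[0, 1]`.
#' @export
tct_fraction <- function(traj, t) {
  conc <- interp_blood_conc(traj, t)
  if (length(t) == 1) conc <- matrix(conc, nrow = 1,
                                     dimnames = list(NULL, tct_species()))
  eng <- rowSums(conc[, tct_engineered(), drop = FALSE])
  tot <- eng + conc[, "endo"]
  unname(ifelse(tot > 0, eng / tot, 0))
}

#' Write a trajectory as tidy CSVs
#'
#' Writes a tidy cell-count table (columns `day`, `compartment`,
#' `species`, `cells`, optionally prefixed by `patient_id`) and, when
#' `blood_path` is given, a companion blood-concentration table
#' (`day`, `species`, `cells_per_mL`).
#'
#' @param traj a `tct_trajectory`.
#' @param path output CSV path for the count table.
#' @param blood_path optional CSV path for blood concentrations.
#' @param patient_id optional id column value.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, blood_path = NULL,
                                 patient_id = NULL) {
  occ <- tct_occupancy()
  cols <- setdiff(tct_state_names(), "antigen")
  long <- do.call(rbind, lapply(cols, function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    data.frame(day = traj$times, compartment = parts[1], species = parts[2],
               cells = traj$states[, key])
  }))
  if (!is.null(patient_id)) long <- cbind(patient_id = patient_id, long)
  write_csv_exact(long, path)
  if (!is.null(blood_path)) {
    conc <- blood_concentrations(traj)
    bl <- do.call(rbind, lapply(tct_species(), function(s) {
      data.frame(day = traj$times, species = s, cells_per_mL = conc[, s])
    }))
    write_csv_exact(bl, blood_path)
  }
  invisible(path)
}
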