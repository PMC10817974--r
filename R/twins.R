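#' Log-scale RMSE between observed and predicted concentrations
#'
#' The goodness-of-fit metric of the twin screen:
#' `sqrt(mean((log10(pred + loq) - log10(obs + loq))^2))` with equal
#' weight per observation.  The additive limit of quantification keeps
#' zero observations finite; the score is invariant to rescaling both
#' series by a common factor (up to the LOQ offset).
#'
#' @param obs,pred non-negative concentration vectors, cells/mL.
#' @param loq limit of quantification, cells/mL.
#' @return Non-negative scalar.
#' @export
log_rmse <- function(obs, pred, loq = 1) {
  if (length(obs) != length(pred)) {
    stop("obs and pred must have equal length", call. = FALSE)
  }
  sqrt(mean((log10(pred + loq) - log10(obs + loq))^2))
}

#' Fit score of a parameter set against one patient
#'
#' Simulates the parameter set at the patient's recorded dose and
#' evaluates [log_rmse()] over all (day, species) observations.  A
#' failed simulation scores `+Inf` (the candidate is discarded by the
#' screen) with a warning.
#'
#' @param params a `tct_params`.
#' @param patient a `tct_patient` with at least one observation.
#' @param loq limit of quantification, cells/mL.
#' @return Non-negative scalar, possibly `Inf`.
#' @export
fit_score <- function(params, patient, loq = 1) {
  if (nrow(patient$observations) < 1) {
    stop("patient ", patient$patient_id, " has no observations",
         call. = FALSE)
  }
  obs <- patient$observations
  days <- sort(unique(obs$day))
  traj <- tryCatch(
    simulate_kinetics(params, patient$dose, t_end = max(days, 1),
                      output_times = days),
    error = function(e) NULL
  )
  if (is.null(traj)) {
    warning("simulation failed for patient ", patient$patient_id,
            "; candidate scored Inf", call. = FALSE)
    return(Inf)
  }
  conc <- blood_concentrations(traj)
  pred <- conc[cbind(match(obs$day, days), match(obs$species, tct_species()))]
  log_rmse(obs$cells_per_mL, pred, loq = loq)
}

# Score every candidate against every patient.  Patients sharing an
# identical dose specification are served by a single simulation per
# candidate (at the union of their sampling days), which is what makes
# screening tens of thousands of candidates tractable.
score_cohort <- function(candidates, cohort, loq = 1) {
  sig <- vapply(cohort, function(p) {
    paste(format(p$dose$total_cells, digits = 17),
          paste(format(p$dose$frac, digits = 17), collapse = "/"))
  }, character(1))
  groups <- split(seq_along(cohort), sig)

  group_info <- lapply(groups, function(idx) {
    days <- sort(unique(unlist(lapply(cohort[idx],
                                      function(p) p$observations$day))))
    maps <- lapply(cohort[idx], function(p) {
      cbind(match(p$observations$day, days),
            match(p$observations$species, tct_species()))
    })
    list(idx = idx, dose = cohort[[idx[1]]]$dose, days = days, maps = maps)
  })

  scores <- matrix(Inf, nrow = length(candidates), ncol = length(cohort))
  colnames(scores) <- vapply(cohort, `[[`, character(1), "patient_id")
  for (i in seq_along(candidates)) {
    for (g in group_info) {
      traj <- tryCatch(
        simulate_kinetics(candidates[[i]], g$dose, t_end = max(g$days, 1),
                          output_times = g$days),
        error = function(e) NULL
      )
      if (is.null(traj)) next
      conc <- blood_concentrations(traj)
      for (j in seq_along(g$idx)) {
        p <- cohort[[g$idx[j]]]
        pred <- conc[g$maps[[j]]]
        scores[i, g$idx[j]] <- log_rmse(p$observations$cells_per_mL, pred,
                                        loq = loq)
      }
    }
  }
  scores
}

#' Select the best-fitting digital twins for one patient
#'
#' Scores every candidate with [fit_score()] (or accepts precomputed
#' scores) and returns the `k` candidates with the lowest finite
#' scores, ranked ascending; ties are broken by candidate index (the
#' earlier candidate wins).
#'
#' @param patient a `tct_patient`.
#' @param candidates list of `tct_params`.
#' @param k number of twins to select (<= number of candidates).
#' @param scores optional precomputed score vector aligned with
#'   `candidates`.
#' @return List of digital twins: each a list with `patient_id`,
#'   `rank`, `score`, `candidate` (index) and `params`.
#' @export
screen_and_select <- function(patient, candidates, k = 10, scores = NULL) {
  if (k > length(candidates)) {
    stop("k must not exceed the number of candidates", call. = FALSE)
  }
  if (is.null(scores)) {
    scores <- vapply(candidates, fit_score, numeric(1), patient = patient)
  }
  finite <- which(is.finite(scores))
  if (length(finite) < k) {
    stop("patient ", patient$patient_id, ": only ", length(finite),
         " of ", length(candidates), " candidates produced finite scores",
         call. = FALSE)
  }
  ord <- finite[order(scores[finite])]   # order() is stable: ties by index
  sel <- ord[seq_len(k)]
  lapply(seq_along(sel), function(r) {
    list(patient_id = patient$patient_id, rank = r,
         score = scores[sel[r]], candidate = sel[r],
         params = candidates[[sel[r]]])
  })
}

#' Screen a shared candidate pool and build the twin population
#'
#' Samples one pool of candidate virtual patients (log-uniform on the
#' screening ranges), scores each candidate against every patient at
#' that patient's own dose, and keeps the `k` best-fitting candidates
#' per patient as its digital twins.  The superset of all twins forms
#' the virtual population used by the trial-simulation tools.
#'
#' @param cohort a `tct_cohort`.
#' @param n_candidates size of the shared candidate pool.
#' @param k twins per patient.
#' @param ranges screening ranges (default [tct_screen_ranges()]).
#' @param seed integer seed for candidate sampling.
#' @param base fixed structural parameter values.
#' @param candidates optional explicit candidate list (overrides
#'   `n_candidates`/`ranges`/`seed`).
#' @return A `tct_twins` object: `twins` (flat list of digital twins,
#'   `k` per patient) plus `provenance` (seed, n_candidates, ranges, k).
#' @export
generate_twins <- function(cohort, n_candidates = 20000, k = 10,
                           ranges = tct_screen_ranges(), seed = 1L,
                           base = tct_reference_params(),
                           candidates = NULL) {
  for (p in cohort) {
    if (nrow(p$observations) < 1) {
      stop("patient ", p$patient_id, " has no observations", call. = FALSE)
    }
  }
  if (is.null(candidates)) {
    candidates <- sample_parameters(ranges, n_candidates,
                                    seed = tct_substream(seed, "screening"),
                                    base = base)
  }
  scores <- score_cohort(candidates, cohort)
  twins <- list()
  for (j in seq_along(cohort)) {
    twins <- c(twins, screen_and_select(cohort[[j]], candidates, k = k,
                                        scores = scores[, j]))
  }
  structure(
    list(twins = twins,
         provenance = list(seed = as.integer(seed),
                           n_candidates = length(candidates),
                           k = k, ranges = ranges)),
    class = "tct_twins"
  )
}

#' @export
print.tct_twins <- function(x, ...) {
  ids <- vapply(x$twins, `[[`, character(1), "patient_id")
  cat(sprintf("<tct_twins> %d twins across %d patients (k = %d, %d candidates screened)\n",
              length(x$twins), length(unique(ids)), x$provenance$k,
              x$provenance$n_candidates))
  invisible(x)
}

#' Matrix of twin parameter values
#'
#' Extracts the varied parameters of every twin as a numeric matrix
#' (twins x parameters), the input shape expected by [prcc()] and
#' [pca_parameters()].
#'
#' @param twins a `tct_twins`.
#' @param keys parameter names to extract (default: the varied set from
#'   the twins' provenance).
#' @return Numeric matrix with one row per twin, named
#'   `"<patient>.<rank>"`.
#' @export
twin_param_matrix <- function(twins, keys = names(twins$provenance$ranges)) {
  m <- t(vapply(twins$twins, function(tw) {
    vapply(keys, function(key) tct_param_get(tw$params, key), numeric(1))
  }, numeric(length(keys))))
  colnames(m) <- keys
  rownames(m) <- paste0(vapply(twins$twins, `[[`, character(1), "patient_id"),
                        ".", vapply(twins$twins, `[[`, numeric(1), "rank"))
  m
}

#' Build the reference virtual patient
#'
#' Finds the single parameter set that best describes the whole cohort:
#' the candidate minimising the pooled score (mean per-patient
#' [fit_score()] across all patients at their own doses), refined by
#' deterministic coordinate descent in log space (multiplicative steps
#' of `step` per coordinate, cycling until no coordinate improves or
#' `max_iter` cycles).
#'
#' @param cohort a `tct_cohort` (non-empty).
#' @param candidates list of `tct_params` to screen.
#' @param refine run the coordinate-descent refinement.
#' @param vary parameter names refined (default: the screening set).
#' @param step multiplicative step factor.
#' @param max_iter maximal full cycles over the coordinates.
#' @return A `tct_params` with attributes `pooled_score` (after
#'   refinement) and `screen_score` (best candidate before refinement).
#' @export
build_reference_patient <- function(cohort, candidates, refine = TRUE,
                                    vary = names(tct_screen_ranges()),
                                    step = 1.2, max_iter = 200) {
  if (length(cohort) < 1) stop("cohort must be non-empty", call. = FALSE)
  scores <- score_cohort(candidates, cohort)
  pooled <- rowMeans(scores)
  if (!any(is.finite(pooled))) {
    stop("no candidate produced finite scores for every patient",
         call. = FALSE)
  }
  best_idx <- which.min(pooled)    # which.min takes the first tie
  cur <- candidates[[best_idx]]
  cur_score <- pooled[best_idx]
  screen_score <- cur_score

  pooled_of <- function(p) {
    sc <- score_cohort(list(p), cohort)
    mean(sc[1, ])
  }

  if (refine) {
    for (iter in seq_len(max_iter)) {
      improved <- FALSE
      for (key in vary) {
        v <- tct_param_get(cur, key)
        if (v <= 0) next
        for (fac in c(step, 1 / step)) {
          cand <- tct_param_set(cur, key, v * fac)
          sc <- pooled_of(cand)
          if (is.finite(sc) && sc < cur_score - 1e-12) {
            cur <- cand
            cur_score <- sc
            improved <- TRUE
            break
          }
        }
      }
      if (!improved) break
    }
  }
  attr(cur, "pooled_score") <- cur_score
  attr(cur, "screen_score") <- screen_score
  cur
}

#' Parameter recovery against known ground truth
#'
#' Validation harness for synthetic cohorts: per patient and varied
#' parameter, compares the median over that patient's twins with the
#' ground-truth value, flags recovery within a stated factor, and flags
#' parameters that carry no information about the observed species
#' (moving them across their whole range leaves the predicted blood
#' concentrations unchanged at the patient's dose).
#'
#' @param twins a `tct_twins` built on a cohort with ground truth.
#' @param cohort the `tct_cohort` the twins were fitted to (supplies
#'   ground truth and doses).
#' @param factor recovery tolerance: recovered iff the twin-median lies
#'   within `[truth/factor, truth*factor]`.
#' @param base parameter set used for the identifiability probe.
#' @return Data frame: `patient_id`, `parameter`, `truth`,
#'   `twin_median`, `ratio`, `recovered`, `identifiable`.
#' @export
parameter_recovery <- function(twins, cohort, factor = 3,
                               base = tct_reference_params()) {
  keys <- names(twins$provenance$ranges)
  ids <- vapply(twins$twins, `[[`, character(1), "patient_id")
  out <- list()
  for (p in cohort) {
    if (is.null(p$ground_truth)) {
      stop("patient ", p$patient_id, " has no ground truth", call. = FALSE)
    }
    mine <- twins$twins[ids == p$patient_id]
    pm <- t(vapply(mine, function(tw) {
      vapply(keys, function(key) tct_param_get(tw$params, key), numeric(1))
    }, numeric(length(keys))))
    ident <- vapply(keys, function(key) {
      probe_identifiable(key, twins$provenance$ranges[[key]], p, base)
    }, logical(1))
    med <- apply(pm, 2, median)
    tru <- vapply(keys, function(key) tct_param_get(p$ground_truth, key),
                  numeric(1))
    ratio <- med / tru
    out[[p$patient_id]] <- data.frame(
      patient_id = p$patient_id, parameter = keys, truth = tru,
      twin_median = med, ratio = ratio,
      recovered = ratio >= 1 / factor & ratio <= factor,
      identifiable = ident, row.names = NULL
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# A parameter is identifiable for a patient if sweeping it across its
# range (others at base) changes the predicted observations at all.
probe_identifiable <- function(key, range, patient, base, tol = 1e-6) {
  days <- sort(unique(patient$observations$day))
  pred <- lapply(range, function(v) {
    p <- validate_tct_params(tct_param_set(base, key, v))
    traj <- tryCatch(
      simulate_kinetics(p, patient$dose, t_end = max(days, 1),
                        output_times = days),
      error = function(e) NULL
    )
    if (is.null(traj)) return(NULL)
    log10(blood_concentrations(traj) + 1)
  })
  if (any(vapply(pred, is.null, logical(1)))) return(TRUE)
  max(abs(pred[[1]] - pred[[2]])) > tol
}

# ---- twin population I/O ----------------------------------------------

#' Write / read a twin population
#'
#' `write_twins` writes `twins.csv` (`patient_id`, `rank`, `score`, one
#' column per varied parameter), the shared non-varied base parameters
#' as `base_params.json`, and `provenance.json` (seed, n_candidates, k,
#' ranges).  `read_twins` reconstructs the `tct_twins` from such a
#' directory.
#'
#' @param twins a `tct_twins`.
#' @param dir directory (created if needed).
#' @param base base parameter set the varied columns are grafted onto.
#' @return `write_twins`: `dir` invisibly; `read_twins`: a `tct_twins`.
#' @export
write_twins <- function(twins, dir, base = tct_reference_params()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keys <- names(twins$provenance$ranges)
  tab <- data.frame(
    patient_id = vapply(twins$twins, `[[`, character(1), "patient_id"),
    rank = vapply(twins$twins, `[[`, numeric(1), "rank"),
    score = vapply(twins$twins, `[[`, numeric(1), "score")
  )
  pm <- twin_param_matrix(twins, keys)
  tab <- cbind(tab, as.data.frame(pm, row.names = FALSE))
  write_csv_exact(tab, file.path(dir, "twins.csv"))
  write_params_json(base, file.path(dir, "base_params.json"))
  jsonlite::write_json(
    list(seed = twins$provenance$seed,
         n_candidates = twins$provenance$n_candidates,
         k = twins$provenance$k,
         ranges = twins$provenance$ranges),
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_twins
#' @export
read_twins <- function(dir) {
  tab <- read.csv(file.path(dir, "twins.csv"), stringsAsFactors = FALSE)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  prov$ranges <- lapply(prov$ranges, as.numeric)
  base <- read_params_json(file.path(dir, "base_params.json"))
  keys <- setdiff(names(tab), c("patient_id", "rank", "score"))
  twins <- lapply(seq_len(nrow(tab)), function(i) {
    p <- base
    for (key in keys) p <- tct_param_set(p, key, tab[[key]][i])
    list(patient_id = tab$patient_id[i], rank = tab$rank[i],
         score = tab$score[i], candidate = NA_integer_,
         params = validate_tct_params(p))
  })
  structure(list(twins = twins, provenance = prov), class = "tct_twins")
}
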