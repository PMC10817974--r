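#' Simulate a virtual clinical trial on the twin population
#'
#' Re-simulates every digital twin at a common dose, summarises the
#' blood kinetics of each species across twins (median and interquartile
#' band, pointwise in time), tracks the engineered fraction of blood T
#' cells (%TCT) per twin, and classifies each twin as persister or
#' non-persister.  Twins whose simulation fails are recorded and
#' excluded from the summaries.
#'
#' @param twins a `tct_twins` (non-empty).
#' @param dose a `tct_dose` applied to every twin.
#' @param t_end trial horizon, days.
#' @param output_times reporting grid (default daily).
#' @param persister_day,persister_threshold stratification rule passed
#'   to [classify_persister()].
#' @return A `tct_trial`: `summary` (data frame day x species with
#'   `median`, `q25`, `q75` cells/mL), `tct` (matrix twins x times of
#'   engineered fractions), `persister` (logical per twin), `twin_ids`,
#'   `failures` (indices of failed twins), `times`, `dose`.
#' @export
run_trial <- function(twins, dose, t_end = 365, output_times = NULL,
                      persister_day = 50, persister_threshold = 0.5) {
  if (length(twins$twins) < 1) stop("twin population is empty", call. = FALSE)
  if (is.null(output_times)) output_times <- seq(0, t_end, by = 1)
  trajs <- lapply(twins$twins, function(tw) {
    tryCatch(
      simulate_kinetics(tw$params, dose, t_end = t_end,
                        output_times = output_times),
      error = function(e) NULL
    )
  })
  failures <- which(vapply(trajs, is.null, logical(1)))
  ok <- setdiff(seq_along(trajs), failures)
  if (!length(ok)) stop("every twin simulation failed", call. = FALSE)

  conc <- lapply(trajs[ok], blood_concentrations)
  summ <- do.call(rbind, lapply(tct_species(), function(s) {
    m <- vapply(conc, function(x) x[, s], numeric(length(output_times)))
    data.frame(
      day = output_times, species = s,
      median = apply(m, 1, median),
      q25 = apply(m, 1, quantile, probs = 0.25, names = FALSE),
      q75 = apply(m, 1, quantile, probs = 0.75, names = FALSE)
    )
  }))
  tct <- t(vapply(trajs[ok], function(tr) tct_fraction(tr, output_times),
                  numeric(length(output_times))))
  persister <- vapply(trajs[ok], classify_persister, logical(1),
                      day = persister_day, threshold = persister_threshold)
  structure(
    list(summary = summ, tct = tct, persister = persister,
         twin_ids = vapply(twins$twins[ok], function(tw) {
           paste0(tw$patient_id, ".", tw$rank)
         }, character(1)),
         failures = failures, times = output_times, dose = dose),
    class = "tct_trial"
  )
}

#' @export
print.tct_trial <- function(x, ...) {
  cat(sprintf(
    "<tct_trial> %d twins (%d failed), dose %.3g cells, %d/%d persisters\n",
    length(x$persister) + length(x$failures), length(x$failures),
    x$dose$total_cells, sum(x$persister), length(x$persister)))
  invisible(x)
}

#' Classify a trajectory as persister or non-persister
#'
#' A twin is a persister under a regimen when engineered cells hold a
#' strict majority of blood T cells at the stratification day:
#' `tct_fraction(traj, day) > threshold`.
#'
#' @param traj a `tct_trajectory` spanning `day`.
#' @param day stratification day (default 50).
#' @param threshold strict-majority threshold (default 0.5).
#' @return Logical flag.
#' @export
classify_persister <- function(traj, day = 50, threshold = 0.5) {
  if (max(traj$times) < day) {
    stop("trajectory ends at day ", max(traj$times),
         ", before the stratification day ", day, call. = FALSE)
  }
  tct_fraction(traj, day) > threshold
}

#' Sample random dose compositions on the simplex
#'
#' Draws compositions over the four engineered subsets from a flat
#' Dirichlet (uniform on the simplex), seeded.
#'
#' @param n number of compositions.
#' @param seed integer seed.
#' @return Matrix n x 4 with columns `scm`, `cm`, `em`, `eff`, rows
#'   summing to 1.
#' @export
sample_compositions <- function(n, seed) {
  m <- with_seed(seed, {
    g <- matrix(rgamma(n * 4, shape = 1), nrow = n)
    g / rowSums(g)
  })
  colnames(m) <- tct_engineered()
  m
}

#' Dose-composition sweep
#'
#' Simulates every (twin, composition) pair at a fixed total dose to
#' day 365 and records the persistence metric: %TCT in blood at day
#' 365.  Compositions are drawn from a flat Dirichlet (seeded).  The
#' binned summary averages persistence per subset over 5%-wide,
#' left-closed bins of that subset's dose fraction, across all twins
#' and compositions falling in the bin.
#'
#' @param twins a `tct_twins`.
#' @param n_compositions number of random compositions.
#' @param total_cells total dose, cells.
#' @param seed integer seed for the composition draw.
#' @param bin_width fraction bin width (default 0.05).
#' @param horizon persistence readout day (default 365).
#' @return A `tct_sweep`: `rows` (data frame: composition id, the four
#'   fractions, `twin_id`, `persistence` in [0, 100]), `bins` (data
#'   frame: `species`, `bin_lo`, `bin_hi`, `mean_persistence`, `n`),
#'   `failures` count.
#' @export
composition_sweep <- function(twins, n_compositions = 5000,
                              total_cells = 1e10, seed = 1L,
                              bin_width = 0.05, horizon = 365) {
  if (n_compositions < 1) stop("n_compositions must be >= 1", call. = FALSE)
  comps <- sample_compositions(n_compositions, seed)
  twin_ids <- vapply(twins$twins, function(tw) {
    paste0(tw$patient_id, ".", tw$rank)
  }, character(1))

  rows <- vector("list", n_compositions)
  failures <- 0L
  for (ci in seq_len(n_compositions)) {
    dose <- tct_dose(total_cells, comps[ci, ])
    pers <- vapply(twins$twins, function(tw) {
      traj <- tryCatch(
        simulate_kinetics(tw$params, dose, t_end = horizon,
                          output_times = c(0, horizon)),
        error = function(e) NULL
      )
      if (is.null(traj)) return(NA_real_)
      100 * tct_fraction(traj, horizon)
    }, numeric(1))
    failures <- failures + sum(is.na(pers))
    rows[[ci]] <- data.frame(
      composition = ci,
      frac_scm = unname(comps[ci, "scm"]), frac_cm = unname(comps[ci, "cm"]),
      frac_em = unname(comps[ci, "em"]), frac_eff = unname(comps[ci, "eff"]),
      twin_id = twin_ids, persistence = unname(pers)
    )
  }
  rows <- do.call(rbind, rows)
  rows <- rows[!is.na(rows$persistence), ]
  rownames(rows) <- NULL

  edges <- seq(0, 1, by = bin_width)
  bins <- do.call(rbind, lapply(tct_engineered(), function(s) {
    f <- rows[[paste0("frac_", s)]]
    bi <- pmin(findInterval(f, edges, left.open = FALSE), length(edges) - 1)
    agg <- tapply(rows$persistence, bi, mean)
    cnt <- tapply(rows$persistence, bi, length)
    idx <- as.integer(names(agg))
    data.frame(species = s, bin_lo = edges[idx], bin_hi = edges[idx + 1],
               mean_persistence = as.numeric(agg), n = as.integer(cnt))
  }))
  rownames(bins) <- NULL
  structure(list(rows = rows, bins = bins, failures = failures,
                 total_cells = total_cells, seed = as.integer(seed)),
            class = "tct_sweep")
}

#' @export
print.tct_sweep <- function(x, ...) {
  cat(sprintf("<tct_sweep> %d (composition, twin) pairs at %.3g cells\n",
              nrow(x$rows), x$total_cells))
  invisible(x)
}

#' Compare an original dose against enriched alternatives
#'
#' Simulates each twin under the original dose and each alternative
#' (e.g. the scm-enriched 85/5/5/5 composition at the same or lower
#' total dose) and reports, per twin and dose: peak total engineered
#' blood concentration, area under the total engineered concentration
#' curve to the horizon, the persistence metric (%TCT at the horizon),
#' and fold-changes versus the original dose.
#'
#' @param twins a `tct_twins`.
#' @param original the reference `tct_dose`.
#' @param enriched list of alternative `tct_dose` objects.
#' @param horizon readout day (default 365).
#' @return Data frame: `dose_label`, `twin_id`, `peak_conc`, `auc`,
#'   `persistence`, `peak_fold`, `auc_fold`, `persistence_fold`.
#' @export
enrichment_comparison <- function(twins, original, enriched,
                                  horizon = 365) {
  if (inherits(enriched, "tct_dose")) enriched <- list(enriched)
  doses <- c(list(original = original),
             setNames(enriched, paste0("alt", seq_along(enriched))))
  times <- seq(0, horizon, by = 1)
  twin_ids <- vapply(twins$twins, function(tw) {
    paste0(tw$patient_id, ".", tw$rank)
  }, character(1))

  per_dose <- lapply(doses, function(dose) {
    t(vapply(twins$twins, function(tw) {
      traj <- simulate_kinetics(tw$params, dose, t_end = horizon,
                                output_times = times)
      conc <- blood_concentrations(traj)
      eng <- rowSums(conc[, tct_engineered(), drop = FALSE])
      auc <- sum(diff(times) * (head(eng, -1) + tail(eng, -1)) / 2)
      c(peak = max(eng), auc = auc,
        persistence = 100 * tct_fraction(traj, horizon))
    }, numeric(3)))
  })
  ref <- per_dose$original
  out <- do.call(rbind, lapply(names(per_dose), function(lab) {
    m <- per_dose[[lab]]
    data.frame(
      dose_label = lab, twin_id = twin_ids,
      peak_conc = m[, "peak"], auc = m[, "auc"],
      persistence = m[, "persistence"],
      peak_fold = m[, "peak"] / ref[, "peak"],
      auc_fold = m[, "auc"] / ref[, "auc"],
      persistence_fold = m[, "persistence"] / ref[, "persistence"]
    )
  }))
  rownames(out) <- NULL
  out
}

#' Predict an external study and find the best-matching twin
#'
#' Re-simulates every twin at an external study's dose and returns the
#' predicted %TCT trajectories together with the single twin minimising
#' the RMSE (untransformed percentage scale) against the observed %TCT
#' series at the observed days.
#'
#' @param twins a `tct_twins`.
#' @param dose the external study's `tct_dose`.
#' @param observed data frame with columns `day` and `pct_tct`
#'   (>= 2 points).
#' @param output_times prediction grid (default daily to the last
#'   observed day).
#' @return A `tct_prediction`: `times`, `pct_tct` (matrix twins x
#'   times), `twin_ids`, `rmse` (per twin), `best` (index of the best
#'   match), `best_id`, `best_rmse`, `failures`.
#' @export
predict_external <- function(twins, dose, observed, output_times = NULL) {
  need <- c("day", "pct_tct")
  if (!all(need %in% names(observed)) || nrow(observed) < 2) {
    stop("observed must have columns day, pct_tct and >= 2 rows",
         call. = FALSE)
  }
  t_end <- max(observed$day)
  if (is.null(output_times)) output_times <- seq(0, t_end, by = 1)
  output_times <- sort(unique(c(output_times, observed$day)))

  twin_ids <- vapply(twins$twins, function(tw) {
    paste0(tw$patient_id, ".", tw$rank)
  }, character(1))
  preds <- lapply(twins$twins, function(tw) {
    traj <- tryCatch(
      simulate_kinetics(tw$params, dose, t_end = t_end,
                        output_times = output_times),
      error = function(e) NULL
    )
    if (is.null(traj)) return(NULL)
    100 * tct_fraction(traj, output_times)
  })
  failures <- which(vapply(preds, is.null, logical(1)))
  ok <- setdiff(seq_along(preds), failures)
  if (!length(ok)) stop("every twin simulation failed", call. = FALSE)

  mat <- t(vapply(preds[ok], identity, numeric(length(output_times))))
  obs_idx <- match(observed$day, output_times)
  rmse <- apply(mat, 1, function(row) {
    sqrt(mean((row[obs_idx] - observed$pct_tct)^2))
  })
  best <- which.min(rmse)
  structure(
    list(times = output_times, pct_tct = mat, twin_ids = twin_ids[ok],
         rmse = rmse, best = best, best_id = twin_ids[ok][best],
         best_rmse = rmse[best], failures = failures),
    class = "tct_prediction"
  )
}

#' @export
print.tct_prediction <- function(x, ...) {
  cat(sprintf("<tct_prediction> %d twins; best match %s (RMSE %.3g %%TCT)\n",
              nrow(x$pct_tct), x$best_id, x$best_rmse))
  invisible(x)
}
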