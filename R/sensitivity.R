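#' Partial rank correlation coefficients
#'
#' Monotone, confounder-adjusted global sensitivity measure.  All
#' parameter columns and the outcome are rank-transformed; the PRCC of
#' parameter j is the Pearson correlation between the residuals of the
#' ranked parameter and the ranked outcome after each is linearly
#' regressed on all other ranked parameters.  The p-value comes from
#' the t statistic `t = r * sqrt((n - 2 - p) / (1 - r^2))` with `p`
#' controlled parameters and `n - 2 - p` degrees of freedom;
#' significance is called at a Bonferroni-adjusted `alpha`.
#'
#' @param param_matrix numeric matrix (observations x parameters) with
#'   column names.
#' @param outcome numeric or logical vector (non-constant), one value
#'   per row; a persister flag is encoded 0/1 (ranks handle the ties).
#' @param alpha family-wise significance level before the Bonferroni
#'   adjustment (default 0.05).
#' @return A data frame of class `tct_prcc`: `parameter`, `prcc`,
#'   `p_value`, `significant`.
#' @export
prcc <- function(param_matrix, outcome, alpha = 0.05) {
  x <- as.matrix(param_matrix)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("p", seq_len(ncol(x)))
  }
  y <- as.numeric(outcome)
  n <- nrow(x)
  np <- ncol(x)
  if (length(y) != n) stop("outcome length must match rows", call. = FALSE)
  if (n < np + 3) {
    stop("need at least ", np + 3, " observations for ", np, " parameters",
         call. = FALSE)
  }
  if (sd(y) == 0) stop("outcome is constant", call. = FALSE)

  rx <- apply(x, 2, rank)
  ry <- rank(y)
  qrx <- qr(cbind(1, rx))
  if (qrx$rank < np + 1) {
    drop <- colnames(rx)[setdiff(seq_len(np), qrx$pivot[seq_len(qrx$rank)] - 1)]
    stop("rank-degenerate (collinear) parameters: ",
         paste(drop, collapse = ", "), call. = FALSE)
  }

  res <- lapply(seq_len(np), function(j) {
    z <- cbind(1, rx[, -j, drop = FALSE])
    ej <- lm.fit(z, rx[, j])$residuals
    ey <- lm.fit(z, ry)$residuals
    r <- sum(ej * ey) / sqrt(sum(ej^2) * sum(ey^2))
    r <- min(1, max(-1, r))   # guard against floating-point overshoot
    df <- n - 2 - (np - 1)
    pval <- if (1 - r^2 < 1e-12) 0 else {
      2 * pt(-abs(r * sqrt(df / (1 - r^2))), df)
    }
    c(r = r, p = pval)
  })
  out <- data.frame(
    parameter = colnames(rx),
    prcc = vapply(res, `[[`, numeric(1), "r"),
    p_value = vapply(res, `[[`, numeric(1), "p")
  )
  out$significant <- out$p_value < alpha / np
  class(out) <- c("tct_prcc", "data.frame")
  out
}

#' Principal component analysis of twin parameter space
#'
#' Log10-transforms the varied parameters of every twin, standardises
#' each column (mean 0, SD 1), and eigendecomposes the covariance.
#' Zero-variance columns are dropped with a warning.  Sign convention:
#' the largest-magnitude loading of each component is made positive, so
#' repeated runs and different decomposition back-ends agree.
#'
#' @param twins a `tct_twins` with at least 3 twins, or a bare numeric
#'   matrix (twins x parameters, already on the natural scale).
#' @return A `tct_pca`: `scores` (twins x components), `loadings`
#'   (parameters x components, orthonormal), `explained` (variance
#'   fractions, non-increasing, summing to 1), `parameters`.
#' @export
pca_parameters <- function(twins) {
  m <- if (inherits(twins, "tct_twins")) twin_param_matrix(twins) else
    as.matrix(twins)
  if (nrow(m) < 3) stop("need at least 3 twins", call. = FALSE)
  lx <- log10(m)
  sds <- apply(lx, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance parameters: ",
            paste(colnames(lx)[sds == 0], collapse = ", "), call. = FALSE)
    lx <- lx[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(lx, center = TRUE, scale. = TRUE)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(scores = scores, loadings = load,
         explained = pc$sdev^2 / sum(pc$sdev^2),
         parameters = colnames(lx)),
    class = "tct_pca"
  )
}

#' @export
print.tct_pca <- function(x, ...) {
  cat(sprintf("<tct_pca> %d twins x %d parameters; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), length(x$parameters),
              100 * x$explained[1],
              if (length(x$explained) > 1) 100 * x$explained[2] else 0))
  invisible(x)
}

#' Per-patient parameter distribution summaries
#'
#' For each patient and varied parameter: minimum, quartiles, maximum,
#' and a Gaussian kernel density estimate (Silverman's rule bandwidth)
#' of the log10 parameter values on a grid shared across patients, so
#' the densities can be rendered as aligned ridgelines.
#'
#' @param twins a `tct_twins`.
#' @param grid_n grid resolution per parameter (default 256).
#' @return List with `stats` (data frame: `patient_id`, `parameter`,
#'   `min`, `q25`, `median`, `q75`, `max` on the natural scale) and
#'   `density` (data frame: `patient_id`, `parameter`, `log10_value`,
#'   `density`; each patient's KDE integrates to 1 on the grid, and is
#'   `NA` for degenerate zero-spread distributions).
#' @export
parameter_summaries <- function(twins, grid_n = 256) {
  keys <- names(twins$provenance$ranges)
  m <- twin_param_matrix(twins, keys)
  ids <- vapply(twins$twins, `[[`, character(1), "patient_id")
  patients <- unique(ids)

  stats_rows <- list()
  dens_rows <- list()
  for (key in keys) {
    lx_all <- log10(m[, key])
    bws <- vapply(patients, function(pid) {
      v <- lx_all[ids == pid]
      if (length(unique(v)) < 2) return(NA_real_)
      stats::bw.nrd0(v)
    }, numeric(1))
    pad <- if (any(!is.na(bws))) 3 * max(bws, na.rm = TRUE) else 0
    lo <- min(lx_all) - pad
    hi <- max(lx_all) + pad
    for (pid in patients) {
      v <- m[ids == pid, key]
      q <- quantile(v, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        patient_id = pid, parameter = key,
        min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5]
      )
      lv <- log10(v)
      if (length(unique(lv)) >= 2 && hi > lo) {
        d <- density(lv, bw = "nrd0", from = lo, to = hi, n = grid_n)
        dens <- d$y
        xs <- d$x
      } else {
        xs <- seq(lo, hi, length.out = grid_n)
        if (lo == hi) xs <- rep(lo, grid_n)
        dens <- rep(NA_real_, grid_n)
      }
      dens_rows[[length(dens_rows) + 1]] <- data.frame(
        patient_id = pid, parameter = key, log10_value = xs, density = dens
      )
    }
  }
  list(stats = do.call(rbind, stats_rows),
       density = do.call(rbind, dens_rows))
}
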