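#' Model parameters for one virtual patient
#'
#' Builds a validated parameter set for the kinetic model.  Values are
#' given as nested components (below) or overridden individually through
#' flat dotted names such as `"kprolif_atg.scm"` or `"Kp.tdln.cm"`.
#'
#' Components (all rates in 1/day, volumes in mL, capacities in cells):
#' \describe{
#'   \item{kprolif_base}{homeostatic proliferation rate constant per
#'     species; `eff` is a terminally differentiated phenotype and its
#'     rate is structurally fixed to 0.}
#'   \item{kprolif_atg}{maximal antigen-driven proliferation rate
#'     constant per engineered subset (active in TDLN and tumour only;
#'     `eff` fixed to 0).}
#'   \item{kconv}{maximal antigen-driven differentiation rate constant
#'     for scm -> cm, cm -> em and em -> eff.}
#'   \item{kapop}{apoptosis rate constant per species.}
#'   \item{ktraffic}{trafficking rate constant per species, shared
#'     across all tissues for that species.}
#'   \item{Kp}{tissue:blood partition coefficients, one per valid
#'     non-blood (compartment, species) pair.}
#'   \item{V}{compartment volumes.}
#'   \item{A0, lambda_A, KA}{initial effective antigen load, its
#'     exponential decay rate, and the half-saturation constant of the
#'     antigen drive `H(A) = A / (A + KA)`.}
#'   \item{Tcap}{carrying capacity per compartment limiting total T cell
#'     proliferation.}
#'   \item{C_endo_baseline}{pre-lymphodepletion endogenous blood
#'     concentration, cells/mL.}
#'   \item{ld_frac}{fraction of endogenous cells surviving
#'     lymphodepletion, in (0, 1].}
#' }
#'
#' @param ... flat named overrides, e.g. `tct_params("kapop.em" = 0.1)`.
#' @param base parameter set to start from (default: the reference
#'   virtual patient, [tct_reference_params()]).
#' @return A validated object of class `tct_params`.
#' @export
tct_params <- function(..., base = tct_reference_params()) {
  overrides <- list(...)
  p <- base
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    for (i in seq_along(overrides)) {
      # positional access: later duplicates of a name override earlier ones
      p <- tct_param_set(p, names(overrides)[i], overrides[[i]])
    }
  }
  validate_tct_params(p)
}

#' Reference virtual patient
#'
#' The default parameterisation: a single parameter set whose simulated
#' blood kinetics show the canonical four phases (distribution,
#' expansion, contraction, persistence/decline) at the middle dose, and
#' dose-dependent expansion across the three cohort dose levels.  All
#' defaults are configurable; volumes and partition coefficients are
#' order-of-magnitude physiological stand-ins.
#'
#' @return An object of class `tct_params`.
#' @export
tct_reference_params <- function() {
  p <- list(
    kprolif_base = c(scm = 0.02, cm = 0.025, em = 0.01, eff = 0, endo = 0.11),
    kprolif_atg  = c(scm = 0.8, cm = 0.4, em = 0.15, eff = 0),
    kconv        = c(scm = 0.10, cm = 0.10, em = 0.10),
    kapop        = c(scm = 0.015, cm = 0.018, em = 0.08, eff = 0.20,
                     endo = 0.055),
    ktraffic     = c(scm = 0.15, cm = 0.06, em = 0.06, eff = 0.06,
                     endo = 0.02),
    Kp = list(
      tdln   = c(scm = 30, cm = 30, endo = 30),
      tissue = c(scm = 1, cm = 1, em = 1, eff = 1, endo = 5),
      tumor  = c(em = 2, eff = 2)
    ),
    V    = c(blood = 5000, tdln = 30, tissue = 60000, tumor = 100),
    A0 = 1, lambda_A = 0.04, KA = 0.5,
    Tcap = c(blood = 2e10, tdln = 1e12, tissue = 6e11, tumor = 5e8),
    C_endo_baseline = 1e6,
    ld_frac = 0.1
  )
  class(p) <- "tct_params"
  p
}

#' @export
print.tct_params <- function(x, ...) {
  cat("<tct_params> virtual-patient parameter set\n")
  flat <- tct_flatten_params(x)
  cat(paste0("  ", format(names(flat), width = 22), " ",
             signif(unlist(flat), 4), collapse = "\n"), "\n")
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks non-negativity of all rates, capacities and antigen
#' parameters, strict positivity of volumes, the structural constraints
#' `kprolif_base["eff"] = kprolif_atg["eff"] = 0`, and
#' `ld_frac` in (0, 1].
#'
#' @param p a `tct_params` object (or bare list with the same shape).
#' @return The validated object, invisibly classed as `tct_params`.
#' @export
validate_tct_params <- function(p) {
  need <- c("kprolif_base", "kprolif_atg", "kconv", "kapop", "ktraffic",
            "Kp", "V", "A0", "lambda_A", "KA", "Tcap",
            "C_endo_baseline", "ld_frac")
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    stop("parameter set lacks components: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  flat <- tct_flatten_params(p)
  vals <- unlist(flat)
  if (any(!is.finite(vals))) {
    stop("non-finite parameter values: ",
         paste(names(flat)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("negative parameter values: ",
         paste(names(flat)[vals < 0], collapse = ", "), call. = FALSE)
  }
  if (any(p$V <= 0)) stop("compartment volumes must be > 0", call. = FALSE)
  if (p$ld_frac <= 0 || p$ld_frac > 1) {
    stop("ld_frac must lie in (0, 1]", call. = FALSE)
  }
  if (p$kprolif_base[["eff"]] != 0 || p$kprolif_atg[["eff"]] != 0) {
    stop("eff is terminally differentiated: kprolif_base.eff and ",
         "kprolif_atg.eff must be 0", call. = FALSE)
  }
  class(p) <- "tct_params"
  p
}

# ---- flat-name access --------------------------------------------------

#' Flatten a parameter set to dotted names
#'
#' @param p a `tct_params` object.
#' @return Named list of scalars, keys like `"kapop.em"`, `"Kp.tdln.cm"`,
#'   `"V.blood"`, `"A0"`.
#' @export
tct_flatten_params <- function(p) {
  out <- list()
  for (nm in c("kprolif_base", "kprolif_atg", "kconv", "kapop", "ktraffic")) {
    v <- p[[nm]]
    out[paste(nm, names(v), sep = ".")] <- as.list(unname(v))
  }
  for (cc in names(p$Kp)) {
    v <- p$Kp[[cc]]
    out[paste("Kp", cc, names(v), sep = ".")] <- as.list(unname(v))
  }
  out[paste("V", names(p$V), sep = ".")] <- as.list(unname(p$V))
  out[paste("Tcap", names(p$Tcap), sep = ".")] <- as.list(unname(p$Tcap))
  out$A0 <- p$A0
  out$lambda_A <- p$lambda_A
  out$KA <- p$KA
  out$C_endo_baseline <- p$C_endo_baseline
  out$ld_frac <- p$ld_frac
  out
}

#' Get or set one parameter by flat dotted name
#'
#' @param p a `tct_params` object.
#' @param key flat name, e.g. `"ktraffic.scm"` or `"Kp.tissue.em"`.
#' @param value replacement scalar (for `tct_param_set`).
#' @return `tct_param_get`: the scalar value. `tct_param_set`: the
#'   modified parameter set (not re-validated; validate after a batch).
#' @export
tct_param_get <- function(p, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  v <- switch(length(parts),
    `1` = p[[parts[1]]],
    `2` = p[[parts[1]]][[parts[2]]],
    `3` = p[[parts[1]]][[parts[2]]][[parts[3]]]
  )
  if (is.null(v)) stop("unknown parameter: ", key, call. = FALSE)
  v
}

#' @rdname tct_param_get
#' @export
tct_param_set <- function(p, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  tct_param_get(p, key)  # errors on unknown names
  if (length(parts) == 1) {
    p[[parts[1]]] <- value
  } else if (length(parts) == 2) {
    p[[parts[1]]][[parts[2]]] <- value
  } else {
    p[[parts[1]]][[parts[2]]][[parts[3]]] <- value
  }
  p
}

# Pack into the fixed-order numeric vector consumed by the compiled RHS.
tct_pack_params <- function(p) {
  c(
    p$kprolif_base[c("scm", "cm", "em", "eff", "endo")],
    p$kprolif_atg[c("scm", "cm", "em", "eff")],
    p$kconv[c("scm", "cm", "em")],
    p$kapop[c("scm", "cm", "em", "eff", "endo")],
    p$ktraffic[c("scm", "cm", "em", "eff", "endo")],
    p$Kp$tdln[c("scm", "cm", "endo")],
    p$Kp$tissue[c("scm", "cm", "em", "eff", "endo")],
    p$Kp$tumor[c("em", "eff")],
    p$V[c("blood", "tdln", "tissue", "tumor")],
    p$A0, p$lambda_A, p$KA,
    p$Tcap[c("blood", "tdln", "tissue", "tumor")],
    p$C_endo_baseline, p$ld_frac
  )
}

# ---- JSON I/O ----------------------------------------------------------

#' Read / write parameter sets as flat-key JSON
#'
#' Parameter documents are flat JSON objects keyed by the dotted names
#' of [tct_flatten_params()]; unknown keys are rejected.
#'
#' @param path file path.
#' @param p a `tct_params` object.
#' @return `read_params_json` returns a validated `tct_params`;
#'   `write_params_json` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  flat <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- tct_reference_params()
  for (key in names(flat)) {
    val <- flat[[key]]
    if (!is.numeric(val) || length(val) != 1) {
      stop("parameter '", key, "' in ", path, " is not a scalar number",
           call. = FALSE)
    }
    p <- tct_param_set(p, key, val)
  }
  validate_tct_params(p)
}

#' @rdname read_params_json
#' @export
write_params_json <- function(p, path) {
  jsonlite::write_json(tct_flatten_params(p), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- screening ranges --------------------------------------------------

#' Default screening ranges for the varied parameters
#'
#' The digital-twin workflow varies 14 parameters — antigen-driven
#' proliferation (scm, cm, em), differentiation (scm, cm, em),
#' trafficking (scm, cm, em), homeostatic proliferation (cm, endo) and
#' apoptosis (scm, em, endo) — and holds everything else at the
#' reference values.  Each range spans a factor of 10 either side of
#' the reference value and is sampled log-uniformly.
#'
#' @param base reference parameter set supplying the range centres.
#' @param spread multiplicative half-width of each range (default 10).
#' @return Named list of `c(lo, hi)` ranges.
#' @export
tct_screen_ranges <- function(base = tct_reference_params(), spread = 10) {
  varied <- c(
    "kprolif_atg.scm", "kprolif_atg.cm", "kprolif_atg.em",
    "kconv.scm", "kconv.cm", "kconv.em",
    "ktraffic.scm", "ktraffic.cm", "ktraffic.em",
    "kprolif_base.cm", "kprolif_base.endo",
    "kapop.scm", "kapop.em", "kapop.endo"
  )
  ranges <- lapply(varied, function(key) {
    v <- tct_param_get(base, key)
    c(v / spread, v * spread)
  })
  names(ranges) <- varied
  ranges
}

# Validate a ranges list: positive, lo <= hi.
validate_ranges <- function(ranges) {
  for (key in names(ranges)) {
    r <- ranges[[key]]
    if (length(r) != 2 || !all(is.finite(r)) || any(r <= 0)) {
      stop("range for '", key, "' must be two positive numbers",
           call. = FALSE)
    }
    if (r[1] > r[2]) {
      stop("range for '", key, "' has lo > hi", call. = FALSE)
    }
  }
  ranges
}
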