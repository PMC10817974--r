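#' Dose specification for an infusion of engineered T cells
#'
#' @param total_cells total number of infused engineered cells (>= 0).
#' @param frac named fractions over the engineered subsets
#'   (`scm`, `cm`, `em`, `eff`); must be non-negative and sum to 1
#'   within 1e-9.
#' @return An object of class `tct_dose`.
#' @examples
#' tct_dose(1e10, c(scm = 0.01, cm = 0.03, em = 0.48, eff = 0.48))
#' @export
tct_dose <- function(total_cells,
                     frac = c(scm = 0.01, cm = 0.03, em = 0.48, eff = 0.48)) {
  if (!is.numeric(total_cells) || length(total_cells) != 1 ||
      !is.finite(total_cells) || total_cells < 0) {
    stop("total_cells must be a single non-negative number", call. = FALSE)
  }
  if (!all(tct_engineered() %in% names(frac))) {
    stop("frac must be named with: ", paste(tct_engineered(), collapse = ", "),
         call. = FALSE)
  }
  frac <- frac[tct_engineered()]
  if (any(frac < 0)) stop("dose fractions must be >= 0", call. = FALSE)
  if (abs(sum(frac) - 1) > 1e-9) {
    stop("dose fractions must sum to 1 (got ", format(sum(frac)), ")",
         call. = FALSE)
  }
  structure(list(total_cells = total_cells, frac = frac),
            class = "tct_dose")
}

#' @export
print.tct_dose <- function(x, ...) {
  cat(sprintf("<tct_dose> %.4g cells (%s)\n", x$total_cells,
              paste(sprintf("%s %.1f%%", names(x$frac), 100 * x$frac),
                    collapse = ", ")))
  invisible(x)
}

#' Read / write a dose specification as JSON
#'
#' The sidecar format has keys `total_cells`, `frac_scm`, `frac_cm`,
#' `frac_em`, `frac_eff`.
#'
#' @param path file path.
#' @param dose a `tct_dose`.
#' @return `read_dose_json` returns a `tct_dose`; `write_dose_json`
#'   returns `path` invisibly.
#' @export
read_dose_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("total_cells", paste0("frac_", tct_engineered()))
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("dose file ", path, " lacks fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  frac <- unlist(x[paste0("frac_", tct_engineered())])
  names(frac) <- tct_engineered()
  tct_dose(x$total_cells, frac)
}

#' @rdname read_dose_json
#' @export
write_dose_json <- function(dose, path) {
  out <- c(list(total_cells = dose$total_cells),
           as.list(setNames(dose$frac, paste0("frac_", names(dose$frac)))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
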