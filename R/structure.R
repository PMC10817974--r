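#' @useDynLib tcelltwin
#' @importFrom stats approx cor density lm.fit median pt quantile rnorm
#'   runif prcomp sd setNames rgamma
#' @importFrom utils read.csv write.csv head tail
NULL

#' T cell species and compartment identifiers
#'
#' The model tracks five T cell species: the four engineered memory
#' phenotypes `scm` (stem cell-like memory), `cm` (central memory), `em`
#' (effector memory) and `eff` (terminally differentiated effector), plus
#' `endo` (endogenous, non-engineered T cells).  Engineered subsets
#' differentiate along the strict linear chain scm -> cm -> em -> eff.
#'
#' Four physiological compartments are represented: `blood`, `tdln`
#' (tumour-draining lymph node), `tissue` (lumped normal tissue and
#' other lymph nodes) and `tumor`.  Occupancy is restricted: endogenous
#' cells are present in all non-tumour compartments; scm and cm traffic
#' to TDLN but never to tumour (CD62L-dependent lymph-node entry); em
#' and eff traffic to tumour but never to TDLN.
#'
#' @return Character vectors of identifiers.
#' @export
tct_species <- function() c("scm", "cm", "em", "eff", "endo")

#' @rdname tct_species
#' @export
tct_engineered <- function() c("scm", "cm", "em", "eff")

#' @rdname tct_species
#' @export
tct_compartments <- function() c("blood", "tdln", "tissue", "tumor")

# Valid (compartment, species) occupancy, fixed by the model structure.
tct_occupancy <- function() {
  list(
    blood  = c("scm", "cm", "em", "eff", "endo"),
    tdln   = c("scm", "cm", "endo"),
    tissue = c("scm", "cm", "em", "eff", "endo"),
    tumor  = c("em", "eff")
  )
}

#' State-vector layout of the kinetic model
#'
#' Names of the dynamic variables in their fixed order: one cell count
#' per valid (compartment, species) pair, named `"compartment.species"`,
#' followed by the effective antigen load `"antigen"`.
#'
#' @return Character vector of length 16.
#' @export
tct_state_names <- function() {
  occ <- tct_occupancy()
  c(
    unlist(lapply(names(occ), function(cc) paste(cc, occ[[cc]], sep = "."))),
    "antigen"
  )
}

# Non-blood compartments a species traffics to (shares its blood exchange).
tct_traffic_targets <- function() {
  list(
    scm  = c("tdln", "tissue"),
    cm   = c("tdln", "tissue"),
    em   = c("tissue", "tumor"),
    eff  = c("tissue", "tumor"),
    endo = c("tdln", "tissue")
  )
}
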