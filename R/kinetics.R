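#' Kinetic parameters for the six-species diagenetic network
#'
#' Bundles the rate constants of the five-reaction network: aerobic
#' respiration (R1), heterotrophic denitrification (R2), manganese reduction
#' (R3), nitrification (R4) and Mn2+ oxidation (R5).  Primary reactions
#' (R1-R3) oxidise organic matter with Monod limitation on the terminal
#' electron acceptor and hyperbolic inhibition by the more favourable
#' oxidants; secondary reactions (R4, R5) are bimolecular.
#'
#' Units: solute concentrations are micromolar (uM), solids (OM, MnO2) are
#' mol per m^3 of total sediment, and all reaction rates are mol m^-3 (total
#' sediment) yr^-1.  The bimolecular constants \code{k_nit} and \code{k_mnox}
#' are defined so that \code{k * [A uM] * [B uM]} is a rate in
#' 1e-3 mol m^-3 yr^-1 (the constants absorb porosity).
#'
#' @param k_OM first-order organic-matter decay constant, 1/yr.
#' @param K_O2 O2 half-saturation for aerobic respiration, uM.
#' @param K_NO3 NO3- half-saturation for denitrification, uM.
#' @param h1 O2 inhibition constant for denitrification, uM: the inhibition
#'   factor \code{h1/(h1 + O2)} equals 1/2 at \code{O2 == h1}.
#' @param K_MnO2 MnO2 half-saturation for Mn reduction, mol m^-3.
#' @param h2 O2 inhibition constant for Mn reduction, uM.
#' @param h3 NO3- inhibition constant for Mn reduction, uM.
#' @param k_nit bimolecular nitrification constant, 1/(uM yr).
#' @param k_mnox bimolecular Mn2+ oxidation constant, 1/(uM yr).
#' @param rN mol N released as NH4+ per mol organic C oxidised
#'   (Redfield 16/106 by default).
#'
#' @return An object of class \code{kinetic_params} (a named list).
#' @export
kinetic_params <- function(k_OM = 3.3e-8,
                           K_O2 = 1,
                           K_NO3 = 700,
                           h1 = 10,
                           K_MnO2 = 5,
                           h2 = 1,
                           h3 = 5,
                           k_nit = 6e-6,
                           k_mnox = 2e-6,
                           rN = 16 / 106) {
  p <- list(k_OM = k_OM, K_O2 = K_O2, K_NO3 = K_NO3, h1 = h1,
            K_MnO2 = K_MnO2, h2 = h2, h3 = h3,
            k_nit = k_nit, k_mnox = k_mnox, rN = rN)
  bad <- names(p)[!vapply(p, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("kinetic parameters must be single finite positive numbers; bad: ",
         paste(bad, collapse = ", "))
  class(p) <- "kinetic_params"
  p
}

# canonical species order used throughout the package
.species_names <- c("OM", "O2", "NO3", "NH4", "Mn2", "MnO2")
.species_phase <- c(OM = "solid", O2 = "solute", NO3 = "solute",
                    NH4 = "solute", Mn2 = "solute", MnO2 = "solid")

#' Stoichiometry of the five-reaction network
#'
#' Per mol organic C oxidised: R1 consumes 1 O2 and releases rN NH4+;
#' R2 consumes 4/5 NO3-; R3 consumes 2 MnO2 and releases 2 Mn2+; R2 and R3
#' also release rN NH4+.  R4 (nitrification) consumes 1 NH4+ and 2 O2 and
#' produces 1 NO3-; R5 consumes 1 Mn2+ and 1/2 O2 and produces 1 MnO2.
#'
#' @param rN mol N per mol C in organic matter.
#' @return 6 x 5 matrix (species x reactions R1..R5) of stoichiometric
#'   coefficients (positive = produced).
#' @export
nitrogen_stoichiometry <- function(rN = 16 / 106) {
  S <- matrix(0, 6, 5, dimnames = list(.species_names, paste0("R", 1:5)))
  S["OM",  1:3] <- -1
  S["O2",  ] <- c(-1, 0, 0, -2, -0.5)
  S["NO3", ] <- c(0, -4 / 5, 0, 1, 0)
  S["NH4", ] <- c(rN, rN, rN, -1, 0)
  S["Mn2", ] <- c(0, 0, 2, 0, -1)
  S["MnO2", ] <- c(0, 0, -2, 0, 1)
  S
}

# internal rate evaluation; clamps negative concentrations to zero so the
# solver can evaluate trial iterates safely
.rates_clamped <- function(conc, params) {
  cc <- pmax(conc, 0)
  OM <- cc[, "OM"]; O2 <- cc[, "O2"]; NO3 <- cc[, "NO3"]
  NH4 <- cc[, "NH4"]; Mn2 <- cc[, "Mn2"]; MnO2 <- cc[, "MnO2"]
  p <- params
  R <- cbind(
    R1 = p$k_OM * OM * O2 / (p$K_O2 + O2),
    R2 = p$k_OM * OM * NO3 / (p$K_NO3 + NO3) * p$h1 / (p$h1 + O2),
    R3 = p$k_OM * OM * MnO2 / (p$K_MnO2 + MnO2) *
      p$h2 / (p$h2 + O2) * p$h3 / (p$h3 + NO3),
    R4 = p$k_nit * NH4 * O2 * 1e-3,
    R5 = p$k_mnox * Mn2 * O2 * 1e-3
  )
  R
}

#' Volumetric reaction rates of the diagenetic network
#'
#' Evaluates R1..R5 at every node of a species state.  Rates are in mol m^-3
#' (total sediment) yr^-1; each rate is zero whenever any of its substrate
#' concentrations is zero, and all rates are nonnegative for nonnegative
#' input.
#'
#' @param state matrix or data.frame with columns \code{OM, O2, NO3, NH4,
#'   Mn2, MnO2} (one row per depth node); solutes in uM, solids in mol m^-3.
#' @param params a [kinetic_params()] object.
#' @return matrix with columns \code{R1..R5}, one row per node.
#' @export
reaction_rates <- function(state, params) {
  stopifnot(inherits(params, "kinetic_params"))
  conc <- as.matrix(as.data.frame(state)[, .species_names, drop = FALSE])
  if (anyNA(conc)) stop("NA concentration in state")
  if (any(conc < 0)) {
    idx <- which(conc < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative concentration: species '%s' at node %d",
                 colnames(conc)[idx[2]], idx[1]))
  }
  .rates_clamped(conc, params)
}

#' Build the six-species five-reaction network for the column solver
#'
#' @param params a [kinetic_params()] object.
#' @return a \code{reaction_network} object (see [reaction_network()]).
#' @export
nitrogen_network <- function(params) {
  reaction_network(species = .species_names,
                   phase = .species_phase,
                   stoich = nitrogen_stoichiometry(params$rN),
                   rate_fn = .rates_clamped,
                   params = params)
}

#' Generic reaction network for the 1-D column solver
#'
#' A small container pairing species definitions with a stoichiometry matrix
#' and a rate function, so that the steady-state solver can also be driven by
#' reduced networks (e.g. a single solute with zeroth- or first-order
#' consumption, used for analytic verification).
#'
#' @param species character vector of species names.
#' @param phase named character vector, \code{"solute"} (diffused, uM) or
#'   \code{"solid"} (advected with burial, mol m^-3 total sediment).
#' @param stoich species x reactions matrix of stoichiometric coefficients;
#'   units mol per mol reaction turnover.
#' @param rate_fn \code{function(conc, params)} returning a nodes x reactions
#'   matrix of nonnegative rates in mol m^-3 (total sediment) yr^-1;
#'   \code{conc} has one column per species.
#' @param params parameter object passed through to \code{rate_fn}.
#' @return object of class \code{reaction_network}.
#' @export
reaction_network <- function(species, phase, stoich, rate_fn, params = NULL) {
  stopifnot(is.character(species), length(species) >= 1,
            all(species %in% names(phase)) || length(phase) == length(species),
            nrow(stoich) == length(species), is.function(rate_fn))
  if (is.null(names(phase))) names(phase) <- species
  stopifnot(all(phase[species] %in% c("solute", "solid")))
  structure(list(species = species, phase = phase[species],
                 stoich = stoich, rate_fn = rate_fn, params = params),
            class = "reaction_network")
}
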