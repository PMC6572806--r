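# Conversion of volumetric reaction rates and functional-gene abundances
# into cell-specific rates, electron-normalized power, carbon metabolic
# rates and biomass turnover times.

.valid_processes <- c(O2_respiration = 4, nitrification = 8,
                      denitrification = 5, nitrate_reduction = 2)

#' Convert gene copies per gram wet sediment to cells per cubic metre
#'
#' cells m^-3 = copies g^-1 * wet bulk density (g cm^-3) * 1e6 /
#' copies_per_cell.  Because genomes can carry multiple copies of a marker
#' gene, cell densities derived with \code{copies_per_cell = 1} are upper
#' bounds, which makes the downstream cell-specific rates minimum estimates.
#'
#' @param copies_per_g_wet gene copies per g wet sediment (>= 0).
#' @param wet_bulk_density wet bulk density, g cm^-3 (default 1.7, typical
#'   deep-sea pelagic clay).
#' @param copies_per_cell marker-gene copies per genome (>= 1).
#' @param below_detection optional logical flag(s); propagated as an
#'   attribute on the result.
#' @return cells m^-3 (numeric, same length as input), with attribute
#'   \code{below_detection} when flags were supplied.
#' @export
copies_to_cell_density <- function(copies_per_g_wet, wet_bulk_density = 1.7,
                                   copies_per_cell = 1,
                                   below_detection = NULL) {
  stopifnot(all(copies_per_g_wet >= 0), wet_bulk_density > 0,
            copies_per_cell >= 1)
  dens <- copies_per_g_wet * wet_bulk_density * 1e6 / copies_per_cell
  if (!is.null(below_detection)) attr(dens, "below_detection") <- below_detection
  dens
}

#' Cell-specific substrate turnover rate
#'
#' Divides a bulk volumetric reaction rate by the density of the cells
#' mediating it: fmol substrate cell^-1 d^-1 =
#' (mol m^-3 yr^-1) / (cells m^-3) / 365.25 * 1e15.
#'
#' @param volumetric_rate mol substrate m^-3 (total sediment) yr^-1 (>= 0).
#' @param cell_density cells m^-3; zero densities yield NA (flagged missing,
#'   not infinity).
#' @return fmol substrate cell^-1 d^-1.
#' @export
cell_specific_rate <- function(volumetric_rate, cell_density) {
  stopifnot(all(volumetric_rate >= 0, na.rm = TRUE),
            all(cell_density >= 0, na.rm = TRUE))
  out <- ifelse(cell_density > 0,
                volumetric_rate / cell_density / 365.25 * 1e15,
                NA_real_)
  if (any(cell_density == 0, na.rm = TRUE))
    attr(out, "zero_density") <- which(cell_density == 0)
  out
}

#' Normalize a cell-specific substrate rate to electrons transferred
#'
#' Electron equivalents per mol substrate: O2 respiration 4 e-/O2,
#' nitrification 8 e-/NH4+ (full oxidation to NO3-; use
#' \code{electrons = 6} for the ammonia-oxidation step alone),
#' denitrification 5 e-/NO3- (to N2), nitrate reduction 2 e-/NO3- (to NO2-).
#'
#' @param rate_substrate fmol substrate cell^-1 d^-1.
#' @param process one of \code{"O2_respiration"}, \code{"nitrification"},
#'   \code{"denitrification"}, \code{"nitrate_reduction"}.
#' @param electrons optional electron count overriding the process default.
#' @return fmol e- cell^-1 d^-1.
#' @export
electron_normalize <- function(rate_substrate, process, electrons = NULL) {
  if (is.null(electrons)) {
    if (length(process) != 1L || !process %in% names(.valid_processes))
      stop("unknown process '", paste(process, collapse = ","),
           "'; valid processes: ",
           paste(names(.valid_processes), collapse = ", "))
    electrons <- .valid_processes[[process]]
  }
  stopifnot(all(rate_substrate >= 0, na.rm = TRUE), electrons > 0)
  rate_substrate * electrons
}

#' Absolute electrons transferred per cell per day
#'
#' Converts an electron-normalized rate to an absolute electron count via
#' Avogadro's number and reports its order of magnitude.  The basal power
#' requirement discussed for deep sedimentary life, ~1e-5 fmol e- cell^-1
#' d^-1, corresponds to a daily transfer on the order of 1e3 electrons.
#'
#' @param rate_electrons fmol e- cell^-1 d^-1 (>= 0).
#' @return list with \code{electrons_per_day} and \code{order_of_magnitude}
#'   (floor(log10); NA for a zero rate).
#' @export
electrons_per_day <- function(rate_electrons) {
  stopifnot(all(rate_electrons >= 0, na.rm = TRUE))
  avogadro <- 6.02214076e23
  n <- rate_electrons * 1e-15 * avogadro
  # round at the 1e-12 level so values sitting on a power of ten by
  # construction are not floored into the decade below
  list(electrons_per_day = n,
       order_of_magnitude = ifelse(n > 0, floor(round(log10(n), 12)),
                                   NA_real_))
}

#' Carbon metabolic rate and biomass turnover time of nitrifiers
#'
#' Converts a cell-specific ammonium-oxidation rate into a carbon-specific
#' metabolic rate, assuming a fixed mole ratio of ammonium oxidized per mole
#' carbon fixed and a fixed carbon mass per cell:
#' rate = (rate_nh4 * 1e-15 / mol_nh4_per_mol_c) * 12.011 /
#' (cell_carbon * 1e-15) / 24, in g C (g C cell)^-1 hr^-1.  The turnover
#' time of cellular carbon is its reciprocal.
#'
#' @param rate_nh4 fmol NH4+ cell^-1 d^-1 (>= 0).
#' @param mol_nh4_per_mol_c moles NH4+ oxidized per mole C fixed
#'   (default 10).
#' @param cell_carbon carbon mass per cell, fg (default 14).
#' @return data.frame with \code{rate_gC_per_gC_hr}, \code{turnover_hr},
#'   \code{turnover_yr}; zero input rates give \code{Inf} turnover.
#' @export
carbon_metabolic_rate <- function(rate_nh4, mol_nh4_per_mol_c = 10,
                                  cell_carbon = 14) {
  stopifnot(all(rate_nh4 >= 0, na.rm = TRUE), mol_nh4_per_mol_c > 0,
            cell_carbon > 0)
  rate <- (rate_nh4 * 1e-15 / mol_nh4_per_mol_c) * 12.011 /
    (cell_carbon * 1e-15) / 24
  data.frame(rate_gC_per_gC_hr = rate,
             turnover_hr = 1 / rate,
             turnover_yr = 1 / rate / (24 * 365.25))
}

#' Classify metabolic state against survival/growth threshold curves
#'
#' Compares a carbon-specific metabolic rate with user-supplied temperature-
#' dependent threshold lines (log10 rate as a linear function of
#' temperature): below the survival line the state is \code{"survival"},
#' between the lines \code{"maintenance"}, at or above the growth line
#' \code{"growth"}.  A rate exactly on a line is assigned to the state above
#' it.
#'
#' @param rate_gC_per_gC_hr carbon metabolic rate(s), g C (g C cell)^-1
#'   hr^-1 (> 0).
#' @param temperature in-situ temperature, degrees C.
#' @param curves list with elements \code{survival} and \code{growth}, each
#'   \code{c(intercept, slope)} giving log10(rate) = intercept +
#'   slope * temperature.  No defaults: when NULL the state is NA rather
#'   than guessed.
#' @return character vector of states (NA when curves are missing).
#' @export
classify_metabolic_state <- function(rate_gC_per_gC_hr, temperature,
                                     curves = NULL) {
  stopifnot(all(rate_gC_per_gC_hr > 0, na.rm = TRUE))
  if (is.null(curves) || is.null(curves$survival) || is.null(curves$growth))
    return(rep(NA_character_, length(rate_gC_per_gC_hr)))
  lr <- log10(rate_gC_per_gC_hr)
  surv <- curves$survival[1] + curves$survival[2] * temperature
  grow <- curves$growth[1] + curves$growth[2] * temperature
  if (any(grow < surv)) stop("growth curve lies below survival curve")
  ifelse(lr < surv, "survival", ifelse(lr < grow, "maintenance", "growth"))
}

#' Cell-specific rate table from model rates and gene abundances
#'
#' The bulk-to-cell conversion used throughout the analysis: nitrification
#' rate (R4) is divided by the ammonia-oxidizer abundance (archaeal +
#' bacterial amoA), denitrification (R2) by the nitrite-reductase abundance
#' (nirK + nirS), and O2 respiration (R1 + 2 R4 + 0.5 R5 consumption) by the
#' total 16S count, at each depth where abundances were measured.
#'
#' @param solution a converged \code{solution_field}.
#' @param abundances data.frame with columns \code{depth_m, marker,
#'   copies_per_g} (and optional \code{below_detection}); markers among
#'   16S_bac, 16S_arc, amoA_AOA, amoA_AOB, nxrB, narG, nirK, nirS.
#' @param wet_bulk_density g cm^-3.
#' @param copies_per_cell marker copies per genome.
#' @param process_markers named list mapping process -> marker set whose
#'   summed copies represent the mediating population.
#' @param mol_nh4_per_mol_c,cell_carbon passed to [carbon_metabolic_rate()]
#'   for the nitrification rows.
#' @param temperature,curves passed to [classify_metabolic_state()].
#' @return data.frame with one row per (depth, process): columns
#'   \code{depth_m, process, fmol_substrate_cell_d, fmol_e_cell_d,
#'   gC_per_gC_hr, turnover_yr, state}.
#' @export
cell_rate_table <- function(solution, abundances, wet_bulk_density = 1.7,
                            copies_per_cell = 1,
                            process_markers = list(
                              nitrification = c("amoA_AOA", "amoA_AOB"),
                              denitrification = c("nirK", "nirS"),
                              O2_respiration = c("16S_bac", "16S_arc")),
                            mol_nh4_per_mol_c = 10, cell_carbon = 14,
                            temperature = solution$config$temperature,
                            curves = NULL) {
  stopifnot(inherits(solution, "solution_field"))
  ab <- as.data.frame(abundances)
  stopifnot(all(c("depth_m", "marker", "copies_per_g") %in% names(ab)))
  depths <- sort(unique(ab$depth_m))
  # volumetric substrate-consumption rates at the sampled depths
  vol <- function(expr_rates) stats::approx(solution$z, expr_rates, depths)$y
  R <- solution$rates
  proc_rate <- list(
    nitrification = vol(R[, "R4"]),
    denitrification = vol(R[, "R2"] * 4 / 5),
    O2_respiration = vol(R[, "R1"] + 2 * R[, "R4"] + 0.5 * R[, "R5"]))
  out <- list()
  for (proc in names(process_markers)) {
    mk <- process_markers[[proc]]
    cp <- vapply(depths, function(d) {
      rows <- ab$depth_m == d & ab$marker %in% mk
      if (!any(rows)) NA_real_ else sum(ab$copies_per_g[rows])
    }, numeric(1))
    dens <- copies_to_cell_density(ifelse(is.na(cp), 0, cp),
                                   wet_bulk_density, copies_per_cell)
    dens[is.na(cp)] <- NA_real_
    rs <- cell_specific_rate(proc_rate[[proc]], dens)
    re <- electron_normalize(rs, proc)
    df <- data.frame(depth_m = depths, process = proc,
                     fmol_substrate_cell_d = as.numeric(rs),
                     fmol_e_cell_d = as.numeric(re),
                     gC_per_gC_hr = NA_real_, turnover_yr = NA_real_,
                     state = NA_character_)
    if (proc == "nitrification") {
      ok <- !is.na(rs) & rs > 0
      cm <- carbon_metabolic_rate(ifelse(ok, rs, NA), mol_nh4_per_mol_c,
                                  cell_carbon)
      df$gC_per_gC_hr <- cm$rate_gC_per_gC_hr
      df$turnover_yr <- cm$turnover_yr
      if (!is.null(curves))
        df$state[ok] <- classify_metabolic_state(cm$rate_gC_per_gC_hr[ok],
                                                 temperature, curves)
    }
    out[[proc]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$depth_m, res$process), ]
}
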