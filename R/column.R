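#' Free-solution diffusion coefficients at in situ temperature
#'
#' Linear temperature fits for infinite-dilution diffusion coefficients of
#' the modelled solutes (O2, NO3-, NH4+, Mn2+), returned in m^2/yr.  The
#' coefficients are the standard seawater tracer-diffusion linear fits
#' D0(1e-6 cm^2/s) = m0 + m1*T with T in degrees C.
#'
#' @param temperature temperature in degrees C (default 1.5, typical deep
#'   bottom water).
#' @return named numeric vector of D0 in m^2/yr for O2, NO3, NH4, Mn2.
#' @export
default_D0 <- function(temperature = 1.5) {
  m0 <- c(O2 = 11.70, NO3 = 9.50, NH4 = 9.50, Mn2 = 3.04)
  m1 <- c(O2 = 0.3439, NO3 = 0.388, NH4 = 0.413, Mn2 = 0.153)
  # 1e-6 cm^2/s = 1e-10 m^2/s; 1 yr = 3.15576e7 s
  (m0 + m1 * temperature) * 1e-10 * 3.15576e7
}

#' Tortuosity-corrected sediment diffusion coefficient
#'
#' Applies the standard porewater correction Ds = D0 / (1 - ln(phi^2)).
#'
#' @param D0 free-solution diffusion coefficient (any unit).
#' @param porosity sediment porosity, in (0, 1).
#' @return effective diffusivity Ds in the units of \code{D0}.
#' @export
sediment_diffusivity <- function(D0, porosity) {
  stopifnot(all(porosity > 0 & porosity < 1))
  D0 / (1 - log(porosity^2))
}

#' Configuration of a 1-D sediment column
#'
#' Grid, porosity, temperature, burial velocity, diffusion coefficients and
#' boundary conditions for the steady-state column model.  Solutes take
#' Dirichlet concentrations (uM) at both boundaries; solids enter as a
#' prescribed depositional flux at the sediment surface and obey a
#' zero-gradient condition at the base.
#'
#' Defaults describe an oligotrophic ridge-flank sediment pond whose basement
#' aquifer is oxic: oxygen is supplied both from the overlying bottom water
#' and from below, and crustal-fluid nitrate is ~21.1 uM.  The default burial
#' velocity spreads the column over ~8 Myr of deposition.
#'
#' @param depth_max column depth, m (> 0).
#' @param n_nodes number of grid nodes (>= 10).
#' @param porosity scalar or per-node vector in (0, 1).
#' @param temperature bottom-water temperature, degrees C.
#' @param burial_velocity sediment burial velocity, m/yr.
#' @param D0 named vector of free-solution diffusivities (m^2/yr) for the
#'   solutes present in the network.
#' @param bc boundary conditions: for each solute a numeric
#'   \code{c(top =, bottom =)} Dirichlet pair (uM, >= 0); for each solid a
#'   \code{list(flux_top =)} depositional flux in mol m^-2 yr^-1.  Entries
#'   given here override the defaults.
#' @param solute_advection logical; advect solutes with burial (default
#'   FALSE: burial is slow relative to diffusion over the column).
#' @return object of class \code{column_config}.
#' @export
column_config <- function(depth_max = 80,
                          n_nodes = 200,
                          porosity = 0.7,
                          temperature = 1.5,
                          burial_velocity = depth_max / 8e6,
                          D0 = default_D0(temperature),
                          bc = list(),
                          solute_advection = FALSE) {
  stopifnot(depth_max > 0, n_nodes >= 10, burial_velocity > 0)
  if (length(porosity) == 1L) porosity <- rep(porosity, n_nodes)
  stopifnot(length(porosity) == n_nodes, all(porosity > 0 & porosity < 1))
  bc_default <- list(
    O2   = c(top = 250, bottom = 160),
    NO3  = c(top = 21,  bottom = 21.1),
    NH4  = c(top = 0,   bottom = 0),
    Mn2  = c(top = 0,   bottom = 0),
    OM   = list(flux_top = 1.5e-3),
    MnO2 = list(flux_top = 2e-7)
  )
  bc <- utils::modifyList(bc_default, bc)
  for (s in names(bc)) {
    if (is.numeric(bc[[s]])) {
      if (any(bc[[s]] < 0))
        stop("Dirichlet boundary values must be >= 0 (species ", s, ")")
    }
  }
  z <- seq(0, depth_max, length.out = n_nodes)
  structure(list(depth_max = depth_max, n_nodes = n_nodes,
                 z = z, dz = z[2] - z[1],
                 porosity = porosity, temperature = temperature,
                 burial_velocity = burial_velocity, D0 = D0, bc = bc,
                 solute_advection = solute_advection),
            class = "column_config")
}

#' @export
print.column_config <- function(x, ...) {
  cat(sprintf("<column_config> %.4g m, %d nodes, phi = %.3g-%.3g, T = %.3g C, w = %.3g m/yr\n",
              x$depth_max, x$n_nodes, min(x$porosity), max(x$porosity),
              x$temperature, x$burial_velocity))
  invisible(x)
}
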