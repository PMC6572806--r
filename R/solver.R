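# Steady-state solver for the 1-D advection-diffusion-reaction column.
#
# Discretization: node-centred finite volumes on a uniform grid, central
# differences for diffusion, first-order upwind for (slow) burial advection.
# Solutes carry Dirichlet conditions at both boundaries; solids enter with a
# prescribed depositional flux at the surface and leave by burial at the
# base.  The nonlinear system is solved by damped Newton iteration on the
# discretized residual, with a pseudo-transient (implicit Euler) fallback
# when the steady problem is too far from the initial guess.

# transport coefficients: per solute, phi*Ds at the n-1 cell faces
.face_coefs <- function(config, network) {
  phi <- config$porosity
  phi_f <- (phi[-1] + phi[-length(phi)]) / 2
  solutes <- network$species[network$phase == "solute"]
  a <- lapply(solutes, function(s) {
    D0 <- config$D0[[s]]
    if (is.null(D0) || !is.finite(D0))
      stop("no free-solution diffusivity D0 for solute ", s)
    phi_f * sediment_diffusivity(D0, phi_f)
  })
  names(a) <- solutes
  a
}

# residual of the discretized steady-state equations, stacked node-major
# (all species at node 1, then node 2, ...).  Units: solutes 1e-3 mol m^-3
# (total sediment) yr^-1 (i.e. "uM-equivalent" per year), solids mol m^-3
# yr^-1.
.residual_fun <- function(config, network) {
  n <- config$n_nodes
  ns <- length(network$species)
  dz <- config$dz
  w <- config$burial_velocity
  phi <- config$porosity
  a <- .face_coefs(config, network)
  stoich <- network$stoich
  bc <- config$bc

  function(x) {
    conc <- matrix(x, nrow = n, ncol = ns, byrow = TRUE)
    colnames(conc) <- network$species
    R <- network$rate_fn(conc, network$params)
    S <- R %*% t(stoich)                       # nodes x species, mol m-3 yr-1
    Fm <- matrix(0, n, ns)
    for (k in seq_len(ns)) {
      s <- network$species[k]
      C <- conc[, k]
      if (network$phase[k] == "solute") {
        ak <- a[[s]]
        diff_term <- (ak * (C[-1] - C[-n]))          # face fluxes * dz... a*(dC)
        interior <- (diff_term[-1] - diff_term[-(n - 1)]) / dz^2
        adv <- 0
        if (isTRUE(config$solute_advection)) {
          up <- phi * w * C
          adv <- (up[2:(n - 1)] - up[1:(n - 2)]) / dz
        }
        Fm[2:(n - 1), k] <- interior - adv + 1e3 * S[2:(n - 1), k]
        Fm[1, k] <- C[1] - bc[[s]][["top"]]
        Fm[n, k] <- C[n] - bc[[s]][["bottom"]]
      } else {
        Ftop <- bc[[s]][["flux_top"]]
        Fm[1, k] <- (Ftop - w * C[1]) / (dz / 2) + S[1, k]
        Fm[2:(n - 1), k] <- w * (C[1:(n - 2)] - C[2:(n - 1)]) / dz +
          S[2:(n - 1), k]
        Fm[n, k] <- w * (C[n - 1] - C[n]) / (dz / 2) + S[n, k]
      }
    }
    as.vector(t(Fm))
  }
}

# per-equation normalization scales so residuals of solutes (uM/yr) and
# solids (mol m-3 yr-1) are comparable; recomputed from the current iterate
.residual_scales <- function(x, config, network) {
  n <- config$n_nodes
  ns <- length(network$species)
  dz <- config$dz
  conc <- matrix(x, nrow = n, ncol = ns, byrow = TRUE)
  a <- .face_coefs(config, network)
  sc <- matrix(1, n, ns)
  for (k in seq_len(ns)) {
    s <- network$species[k]
    C <- conc[, k]
    cmax <- max(abs(C), 1)
    if (network$phase[k] == "solute") {
      ref <- max(max(a[[s]]) * cmax / dz^2, 1e-12)
      sc[, k] <- ref
      sc[c(1, n), k] <- max(1, cmax)            # Dirichlet rows
    } else {
      ref <- max(config$burial_velocity * cmax / dz, 1e-12)
      sc[, k] <- ref
    }
  }
  as.vector(t(sc))
}

# finite-difference banded Jacobian; bw = number of species (coupling is
# within-node plus nearest-neighbour same-species)
.fd_jacobian <- function(f, x, F0, bw) {
  nx <- length(x)
  stride <- 2L * bw + 1L
  ii <- jj <- vector("list", nx)
  vv <- vector("list", nx)
  for (g in seq_len(min(stride, nx))) {
    cols <- seq.int(g, nx, by = stride)
    h <- 1e-7 * pmax(abs(x[cols]), 1e-2)
    xp <- x
    xp[cols] <- xp[cols] + h
    dF <- f(xp) - F0
    for (m in seq_along(cols)) {
      cc <- cols[m]
      rows <- max(1L, cc - bw):min(nx, cc + bw)
      ii[[cc]] <- rows
      jj[[cc]] <- rep.int(cc, length(rows))
      vv[[cc]] <- dF[rows] / h[m]
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(nx, nx))
}

# damped Newton on G(x) = f(x) - M*(x - x_ref)/dt (plain Newton when
# dt = Inf); returns list(x, converged, norm, iters)
.newton <- function(f, x0, scales_fn, bw, tol, max_iter,
                    M = NULL, x_ref = NULL, dt = Inf) {
  g <- if (is.finite(dt)) {
    function(x) f(x) - M * (x - x_ref) / dt
  } else f
  x <- x0
  Fx <- g(x)
  if (anyNA(Fx)) stop("NaN in residual at initial iterate")
  nrm <- function(x, Fx) max(abs(Fx) / scales_fn(x))
  r0 <- nrm(x, Fx)
  for (it in seq_len(max_iter)) {
    if (r0 <= tol)
      return(list(x = x, converged = TRUE, norm = r0, iters = it - 1L))
    J <- .fd_jacobian(g, x, Fx, bw)
    dx <- tryCatch(as.numeric(Matrix::solve(J, -Fx)),
                   error = function(e) NULL)
    if (is.null(dx) || anyNA(dx))
      return(list(x = x, converged = FALSE, norm = r0, iters = it))
    lambda <- 1
    repeat {
      xn <- x + lambda * dx
      Fn <- g(xn)
      rn <- if (anyNA(Fn)) Inf else nrm(xn, Fn)
      if (rn < r0 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (!is.finite(rn) || rn >= r0)
      return(list(x = x, converged = FALSE, norm = r0, iters = it))
    x <- xn; Fx <- Fn; r0 <- rn
  }
  list(x = x, converged = r0 <= tol, norm = r0, iters = max_iter)
}

# default initial guess: solutes linear between their Dirichlet values,
# solids from the advection-only balance (exponential decay for first-order
# decaying OM if the params expose k_OM, otherwise constant)
.initial_guess <- function(config, network) {
  n <- config$n_nodes
  z <- config$z
  w <- config$burial_velocity
  conc <- matrix(0, n, length(network$species),
                 dimnames = list(NULL, network$species))
  for (k in seq_along(network$species)) {
    s <- network$species[k]
    if (network$phase[k] == "solute") {
      bc <- config$bc[[s]]
      conc[, k] <- seq(bc[["top"]], bc[["bottom"]], length.out = n)
    } else {
      G0 <- config$bc[[s]][["flux_top"]] / w
      kdec <- if (s == "OM" && !is.null(network$params$k_OM))
        network$params$k_OM else 0
      conc[, k] <- G0 * exp(-kdec * z / w)
    }
  }
  conc
}

#' Solve the steady-state 1-D reaction-transport problem
#'
#' Solves, at every interior node, 0 = d/dz(phi Ds dC/dz) - d(phi v C)/dz +
#' sum(nu R) for solutes and the advection-reaction analogue for solids,
#' with the boundary conditions held exactly.  Uses damped Newton iteration
#' with a pseudo-transient continuation fallback.
#'
#' @param config a [column_config()].
#' @param params a [kinetic_params()] (ignored when \code{network} is given).
#' @param network a [reaction_network()]; default [nitrogen_network()] built
#'   from \code{params}.
#' @param init optional nodes x species matrix used as initial guess
#'   (e.g. a previous solution for warm starts).
#' @param tol convergence tolerance on the normalized residual.
#' @param max_iter maximum Newton iterations per attempt.
#' @param quiet suppress progress messages.
#' @return object of class \code{solution_field}: list with \code{z},
#'   \code{concentrations} (nodes x species; solutes uM, solids mol m^-3),
#'   \code{rates} (nodes x reactions, mol m^-3 yr^-1), \code{converged},
#'   \code{residual_norm}, \code{iterations}.
#' @export
solve_steady_state <- function(config, params = NULL,
                               network = nitrogen_network(params),
                               init = NULL, tol = 1e-10, max_iter = 40,
                               quiet = TRUE) {
  stopifnot(inherits(config, "column_config"),
            inherits(network, "reaction_network"))
  ns <- length(network$species)
  f <- .residual_fun(config, network)
  scales_fn <- function(x) .residual_scales(x, config, network)
  conc0 <- if (is.null(init)) .initial_guess(config, network) else {
    stopifnot(nrow(init) == config$n_nodes)
    as.matrix(init[, network$species, drop = FALSE])
  }
  x <- as.vector(t(conc0))
  iters <- 0L

  res <- .newton(f, x, scales_fn, ns, tol, max_iter)
  iters <- iters + res$iters
  if (!res$converged) {
    # pseudo-transient continuation: implicit Euler with growing time step
    phi <- config$porosity
    M <- as.vector(t(vapply(seq_len(ns), function(k) {
      if (network$phase[k] == "solute") {
        m <- phi; m[c(1, config$n_nodes)] <- 0; m
      } else rep(1, config$n_nodes)
    }, numeric(config$n_nodes))))
    x <- res$x
    dt <- 1
    t_diff <- config$depth_max^2 / max(unlist(config$D0))  # diffusion time scale
    for (step in seq_len(120)) {
      st <- .newton(f, pmax(x, 0), scales_fn, ns, tol = 1e-6, max_iter = 15,
                    M = M, x_ref = pmax(x, 0), dt = dt)
      iters <- iters + st$iters
      if (st$converged) {
        x <- st$x
        dt <- dt * 4
        if (dt > 0.2 * t_diff) {
          res <- .newton(f, pmax(x, 0), scales_fn, ns, tol, max_iter)
          iters <- iters + res$iters
          if (res$converged) break
        }
      } else {
        dt <- dt / 16
        if (dt < 1e-6) break
      }
      if (!quiet) message(sprintf("pseudo-transient step %d, dt = %g, iters = %d",
                                  step, dt, iters))
    }
  }

  conc <- matrix(res$x, nrow = config$n_nodes, ncol = ns, byrow = TRUE,
                 dimnames = list(NULL, network$species))
  if (res$converged) {
    # clamp roundoff-level negatives; genuine negatives void convergence
    for (k in seq_len(ns)) {
      cmax <- max(abs(conc[, k]), 1)
      neg <- conc[, k] < 0
      if (any(conc[neg, k] < -1e-6 * cmax)) {
        res$converged <- FALSE
        warning("negative concentrations at convergence for ",
                network$species[k])
      } else conc[neg, k] <- 0
    }
  }
  rates <- network$rate_fn(conc, network$params)
  structure(list(z = config$z, concentrations = conc, rates = rates,
                 converged = res$converged, residual_norm = res$norm,
                 iterations = iters, config = config, network = network),
            class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf("<solution_field> %d nodes, %s (residual %.3g, %d iterations)\n",
              length(x$z),
              if (x$converged) "converged" else "NOT converged",
              x$residual_norm, x$iterations))
  invisible(x)
}

#' Boundary fluxes of a converged solution
#'
#' Diffusive solute fluxes across the top and bottom boundaries (3-point
#' one-sided derivatives) and advective solid fluxes, in mol m^-2 yr^-1,
#' positive into the sediment column.
#'
#' @param solution a converged \code{solution_field}.
#' @return data.frame with columns species, influx_top, influx_bottom.
#' @export
boundary_fluxes <- function(solution) {
  config <- solution$config
  network <- solution$network
  n <- config$n_nodes
  dz <- config$dz
  phi <- config$porosity
  out <- lapply(seq_along(network$species), function(k) {
    s <- network$species[k]
    C <- solution$concentrations[, k]
    if (network$phase[k] == "solute") {
      Ds_top <- sediment_diffusivity(config$D0[[s]], phi[1])
      Ds_bot <- sediment_diffusivity(config$D0[[s]], phi[n])
      dtop <- (-3 * C[1] + 4 * C[2] - C[3]) / (2 * dz)
      dbot <- (3 * C[n] - 4 * C[n - 1] + C[n - 2]) / (2 * dz)
      # uM * m/yr = 1e-3 mol m-2 yr-1
      top <- -phi[1] * Ds_top * dtop * 1e-3
      bot <- phi[n] * Ds_bot * dbot * 1e-3
    } else {
      top <- config$bc[[s]][["flux_top"]]
      bot <- -config$burial_velocity * C[n]
    }
    data.frame(species = s, influx_top = top, influx_bottom = bot)
  })
  do.call(rbind, out)
}

#' Steady-state mass-balance closure per species
#'
#' Compares transport into the column (boundary fluxes) with the
#' depth-integrated net reaction sink, independently of the solver's own
#' discrete balance: boundary fluxes use one-sided 3-point derivatives and
#' the sink uses trapezoidal quadrature of nu*R.  At steady state
#' influx_top + influx_bottom + integral(sum nu R) = 0.
#'
#' @param solution a converged \code{solution_field}.
#' @param config the column configuration (defaults to the one stored in the
#'   solution).
#' @return data.frame with per-species boundary influxes, integrated net
#'   source (all mol m^-2 yr^-1) and the normalized closure residual.
#' @export
mass_balance <- function(solution, config = solution$config) {
  stopifnot(inherits(solution, "solution_field"))
  if (!solution$converged)
    stop("mass_balance requires a converged solution")
  network <- solution$network
  bf <- boundary_fluxes(solution)
  S <- solution$rates %*% t(network$stoich)     # nodes x species
  z <- solution$z
  integ <- apply(S, 2, function(s)
    sum((s[-1] + s[-length(s)]) / 2 * diff(z)))
  scale <- pmax(abs(bf$influx_top), abs(bf$influx_bottom), abs(integ), 1e-30)
  data.frame(species = bf$species,
             influx_top = bf$influx_top,
             influx_bottom = bf$influx_bottom,
             net_source = integ,
             residual = abs(bf$influx_top + bf$influx_bottom + integ) / scale)
}
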