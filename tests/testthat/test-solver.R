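# Verification of the steady-state column solver against closed-form
# solutions, a transient integrator, and conservation diagnostics.

test_that("zeroth-order consumption matches the analytic parabola", {
  # Ds C'' = R0 in porewater units; C(z) = C0(1 - z/L) - R0/(2 Ds) z (L - z)
  phi <- 0.8; L <- 10; Ds <- 0.01; R0 <- 0.02; C0 <- 250
  cfg <- single_solute_config(L, 200, phi, Ds, top = C0, bottom = 0)
  net <- zeroth_order_network(R0tot = phi * R0 * 1e-3)
  sol <- solve_steady_state(cfg, network = net)
  expect_true(sol$converged)
  analytic <- C0 * (1 - sol$z / L) - R0 / (2 * Ds) * sol$z * (L - sol$z)
  mid <- approx(sol$z, sol$concentrations[, 1], 5)$y
  expect_equal(mid, 100, tolerance = 1e-3)
  interior <- 2:199
  expect_lt(max(abs(sol$concentrations[interior, 1] - analytic[interior]) /
                  analytic[interior]), 1e-3)
  # boundary conditions are honored exactly
  expect_equal(unname(sol$concentrations[1, 1]), C0)
  expect_equal(unname(sol$concentrations[200, 1]), 0)
})

test_that("first-order decay matches the semi-infinite exponential", {
  phi <- 0.8; Ds <- 0.01; k <- 1e-4; C0 <- 250
  cfg <- single_solute_config(120, 400, phi, Ds, top = C0, bottom = 0)
  sol <- solve_steady_state(cfg, network = first_order_network(k, phi))
  expect_true(sol$converged)
  got <- approx(sol$z, sol$concentrations[, 1], 10)$y
  expect_equal(got, C0 * exp(-10 * sqrt(k / Ds)), tolerance = 1e-3)
})

test_that("solutions converge with grid refinement at first order or better", {
  phi <- 0.8; L <- 10; Ds <- 0.01; R0 <- 0.02; C0 <- 250
  analytic <- function(z) C0 * (1 - z / L) - R0 / (2 * Ds) * z * (L - z)
  err <- vapply(c(100, 200), function(n) {
    cfg <- single_solute_config(L, n, phi, Ds, top = C0, bottom = 0)
    sol <- solve_steady_state(cfg, network = zeroth_order_network(phi * R0 * 1e-3))
    max(abs(sol$concentrations[, 1] - analytic(sol$z))) / C0
  }, numeric(1))
  expect_lt(err[2], 1e-3)                      # < 0.1% at 200 nodes
  # doubling the grid cannot make things worse (observed order >= 1 unless
  # already at roundoff)
  expect_true(err[2] <= err[1] / 2 || err[2] < 1e-10)

  # full network: self-convergence order from 100/200/400-node solutions
  spec <- shipped_spec()
  sols <- lapply(c(100, 200, 400), function(n) {
    cfg <- spec$column
    cfg2 <- column_config(depth_max = cfg$depth_max, n_nodes = n,
                          porosity = cfg$porosity[1],
                          temperature = cfg$temperature,
                          burial_velocity = cfg$burial_velocity,
                          D0 = cfg$D0, bc = cfg$bc)
    solve_steady_state(cfg2, spec$kinetics)
  })
  zz <- seq(1, 79, by = 0.5)
  on_grid <- function(s) approx(s$z, s$concentrations[, "NO3"], zz)$y
  d1 <- max(abs(on_grid(sols[[1]]) - on_grid(sols[[2]])))
  d2 <- max(abs(on_grid(sols[[2]]) - on_grid(sols[[3]])))
  expect_gte(log2(d1 / d2), 1)
})

test_that("steady solution agrees with a long transient integration (deSolve)", {
  skip_if_not_installed("deSolve")
  spec <- shipped_spec()
  cfg <- column_config(depth_max = spec$column$depth_max, n_nodes = 50,
                       porosity = spec$column$porosity[1],
                       burial_velocity = spec$column$burial_velocity,
                       D0 = spec$column$D0, bc = spec$column$bc)
  net <- nitrogen_network(spec$kinetics)
  sol <- solve_steady_state(cfg, network = net)
  expect_true(sol$converged)

  f <- sednitro:::.residual_fun(cfg, net)
  ns <- length(net$species)
  n <- cfg$n_nodes
  phase <- net$phase
  M <- rep(1, n * ns)
  dirichlet <- rep(FALSE, n * ns)
  for (k in seq_len(ns)) {
    idx <- (seq_len(n) - 1L) * ns + k
    if (phase[k] == "solute") {
      M[idx] <- cfg$porosity
      dirichlet[idx[c(1, n)]] <- TRUE
    }
  }
  rhs <- function(t, y, parms) {
    Fv <- f(y)
    dy <- Fv / M
    dy[dirichlet] <- -Fv[dirichlet]       # relax Dirichlet rows onto the BC
    list(dy)
  }
  y0 <- as.vector(t(sednitro:::.initial_guess(cfg, net)))
  out <- deSolve::lsoda(y0, times = c(0, 3e7), func = rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-9, maxsteps = 1e5)
  yT <- matrix(out[nrow(out), -1], nrow = n, ncol = ns, byrow = TRUE)
  for (k in seq_len(ns)) {
    scale <- max(abs(sol$concentrations[, k]), 1e-6)
    expect_lt(max(abs(yT[, k] - sol$concentrations[, k])) / scale, 1e-4)
  }
})

test_that("the converged shipped column is physical", {
  sol <- shipped_solution()
  expect_true(sol$converged)
  expect_true(all(sol$concentrations >= 0))
  expect_true(all(sol$rates >= 0))
  expect_lt(sol$residual_norm, 1e-10)
  # C-shaped O2 with an interior minimum, mirror-image NO3 with an interior
  # maximum
  o2 <- sol$concentrations[, "O2"]; no3 <- sol$concentrations[, "NO3"]
  expect_gt(which.min(o2), 10)
  expect_lt(which.min(o2), 190)
  expect_lt(min(o2), 3)
  expect_gt(which.max(no3), 10)
  expect_lt(which.max(no3), 190)
  expect_gt(max(no3), max(no3[1], no3[200]))
  # shipped calibration: nitrate maximum within the observed 40-50 uM window
  expect_gt(max(no3), 40)
  expect_lt(max(no3), 50)
})

test_that("mass balance closes for the analytic and full columns", {
  # zeroth-order column: integrated consumption R0*L equals the boundary
  # flux difference to < 0.1% at 200 nodes
  phi <- 0.8; L <- 10; Ds <- 0.01; R0 <- 0.02; C0 <- 250
  cfg <- single_solute_config(L, 200, phi, Ds, top = C0, bottom = 0)
  net <- zeroth_order_network(phi * R0 * 1e-3)
  sol <- solve_steady_state(cfg, network = net)
  mb <- mass_balance(sol)
  expect_lt(mb$residual, 1e-3)
  expect_equal(-mb$net_source, phi * R0 * 1e-3 * L, tolerance = 1e-6)

  # pure diffusion between equal Dirichlet values: zero flux, zero residual
  cfg0 <- single_solute_config(L, 50, phi, Ds, top = 100, bottom = 100)
  net0 <- zeroth_order_network(0)
  sol0 <- solve_steady_state(cfg0, network = net0)
  mb0 <- mass_balance(sol0)
  expect_equal(mb0$influx_top, 0, tolerance = 1e-12)
  expect_equal(mb0$influx_bottom, 0, tolerance = 1e-12)
  expect_equal(mb0$residual, 0, tolerance = 1e-12)

  # full shipped column: every species closes to <= 1%
  mbf <- mass_balance(shipped_solution())
  expect_true(all(mbf$residual <= 0.01))

  # nitrogen closure: N transported in (NO3 + NH4 + Redfield N in OM)
  # balances the N2 loss through denitrification to <= 1%
  solf <- shipped_solution()
  rN <- shipped_spec()$kinetics$rN
  bf <- mbf  # influxes in mol m-2 yr-1
  n_in <- with(bf, sum(influx_top[species %in% c("NO3", "NH4")],
                       influx_bottom[species %in% c("NO3", "NH4")]) +
                 rN * sum(influx_top[species == "OM"],
                          influx_bottom[species == "OM"]))
  z <- solf$z
  r2 <- solf$rates[, "R2"]
  n2_loss <- (4 / 5) * sum((r2[-1] + r2[-length(r2)]) / 2 * diff(z))
  expect_equal(n_in, n2_loss, tolerance = 0.01)
})

test_that("weaker O2 inhibition (larger h1) never decreases integrated denitrification", {
  spec <- shipped_spec()
  integ <- vapply(c(1, 10, 40), function(h1) {
    p <- spec$kinetics; p$h1 <- h1
    sol <- solve_steady_state(spec$column, p)
    expect_true(sol$converged)
    r2 <- sol$rates[, "R2"]
    sum((r2[-1] + r2[-length(r2)]) / 2 * diff(sol$z))
  }, numeric(1))
  expect_true(all(diff(integ) >= 0))
})
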