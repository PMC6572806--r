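#' Grid-search fit of the denitrification O2-inhibition constant h1
#'
#' Solves the column model for every candidate h1 and scores it against
#' observed depth profiles by a range-normalized root-mean-square error:
#' for each observed species the model is interpolated to the observed
#' depths, the RMSE is divided by the observed concentration range, and
#' species are weighted equally.  The grid minimizer and the full misfit
#' curve are returned, so the sensitivity of the fit can be inspected.
#'
#' @param config a [column_config()].
#' @param params a [kinetic_params()]; its \code{h1} is replaced by each
#'   candidate in turn.
#' @param observed data.frame with columns \code{depth_m, species, value}
#'   (uM), holding at least O2 and NO3 profiles within the model domain.
#' @param h1_grid numeric vector of candidate h1 values, uM (> 0).
#' @param species which observed species enter the misfit.
#' @return list with \code{best_h1}, \code{misfit} (data.frame \code{h1,
#'   misfit, converged}), \code{at_grid_edge} (TRUE when the minimizer is the
#'   first or last candidate, i.e. the optimum may not be bracketed), and
#'   \code{solutions = NULL} unless \code{keep_solutions}.
#' @param keep_solutions keep the solution for every candidate (memory-heavy).
#' @export
fit_h1 <- function(config, params, observed, h1_grid,
                   species = c("O2", "NO3"), keep_solutions = FALSE) {
  stopifnot(is.numeric(h1_grid), all(h1_grid > 0), length(h1_grid) >= 1)
  observed <- as.data.frame(observed)
  stopifnot(all(c("depth_m", "species", "value") %in% names(observed)))
  observed <- observed[observed$species %in% species, ]
  if (!all(species %in% observed$species))
    stop("observed profiles missing for: ",
         paste(setdiff(species, observed$species), collapse = ", "))
  if (any(observed$depth_m < 0 | observed$depth_m > config$depth_max))
    stop("observed depths outside the model domain")

  h1_grid <- sort(h1_grid)
  misfit <- rep(NA_real_, length(h1_grid))
  conv <- logical(length(h1_grid))
  sols <- if (keep_solutions) vector("list", length(h1_grid)) else NULL
  warm <- NULL
  for (i in seq_along(h1_grid)) {
    p <- params
    p$h1 <- h1_grid[i]
    sol <- tryCatch(
      solve_steady_state(config, p, init = warm),
      error = function(e) NULL)
    if (is.null(sol) || !sol$converged) next
    warm <- sol$concentrations
    conv[i] <- TRUE
    if (keep_solutions) sols[[i]] <- sol
    ms <- vapply(species, function(s) {
      obs <- observed[observed$species == s, ]
      mod <- stats::approx(sol$z, sol$concentrations[, s], obs$depth_m)$y
      rng <- diff(range(obs$value))
      if (rng <= 0) rng <- max(abs(obs$value), 1)
      sqrt(mean((mod - obs$value)^2)) / rng
    }, numeric(1))
    misfit[i] <- mean(ms)
  }
  if (!any(conv)) stop("no h1 candidate converged")
  best <- which.min(misfit)
  list(best_h1 = h1_grid[best],
       misfit = data.frame(h1 = h1_grid, misfit = misfit, converged = conv),
       at_grid_edge = best %in% c(1L, length(h1_grid)),
       solutions = sols)
}
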