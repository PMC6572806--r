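# Synthetic North-Pond-like data generator: geochemical profiles from the
# forward model plus noise, functional-gene abundance profiles, and OTU
# tables with a planted surface-community resurrection signal.

#' Scenario specification for the synthetic-data generator
#'
#' Bundles a column configuration and kinetic parameters (the ground truth)
#' with the statistical structure of the observation process: measurement
#' noise, the abundance model (exponential decay with transition-zone
#' peaks), and the community model (log-series rank-abundance with per-OTU
#' detectability decay and OATZ resurrection).
#'
#' @param column a [column_config()].
#' @param kinetics a [kinetic_params()] (ground truth, incl. the true h1).
#' @param profile_depths depths (m) at which concentration profiles are
#'   sampled.
#' @param sample_depths depths (m) of the sediment horizons used for
#'   abundance and community data (~3 m spacing, as in typical core
#'   subsampling).
#' @param noise list: \code{profile} relative sd of multiplicative
#'   (lognormal) concentration noise; \code{abundance_log10} sd of the
#'   log10 abundance noise; \code{abundance_rel_sd} relative sd reported as
#'   the qPCR uncertainty column.
#' @param abundance list: \code{surface} total 16S copies g^-1 at the
#'   surface; \code{decay_length} m per decade of exponential decline --
#'   either one number for all markers or a named vector with a
#'   \code{default} element plus per-marker overrides (functional genes
#'   decline faster than the 16S pool);
#'   \code{peak_fold} fold-increase at transition-zone centres;
#'   \code{peak_width} Gaussian width (m) of the peaks;
#'   \code{marker_fractions} named surface fractions per marker;
#'   \code{detection_limit} copies g^-1.
#' @param community list: \code{n_otus} size of the regional OTU pool;
#'   \code{shape} log-series parameter in (0,1); \code{decay_scale} median
#'   e-folding depth (m) of per-OTU detectability decay; \code{decay_sdlog}
#'   lognormal spread of per-OTU decay rates; \code{resurrection_p}
#'   probability that a surface OTU is restored to its surface relative
#'   abundance in OATZ samples; \code{reads} reads per sample.
#' @param o2_detection_limit uM; simulated O2 below this is flagged.
#' @param seed default RNG seed used when none is passed to the generators.
#' @return object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(column = column_config(),
                          kinetics = kinetic_params(),
                          profile_depths = seq(0.5, column$depth_max - 0.5, by = 1),
                          sample_depths = seq(0.5, column$depth_max - 0.5, by = 3),
                          noise = list(profile = 0.02, abundance_log10 = 0.15,
                                       abundance_rel_sd = 0.2),
                          abundance = list(surface = 1e8,
                                           decay_length = c(default = 30,
                                                            amoA_AOA = 16,
                                                            amoA_AOB = 16,
                                                            nxrB = 16,
                                                            narG = 22,
                                                            nirK = 18,
                                                            nirS = 22),
                                           peak_fold = 100, peak_width = 2,
                                           marker_fractions = c(
                                             "16S_bac" = 0.5, "16S_arc" = 0.5,
                                             amoA_AOA = 0.4, amoA_AOB = 0.004,
                                             nxrB = 0.004, narG = 0.01,
                                             nirK = 0.01, nirS = 0.005),
                                           detection_limit = 100),
                          community = list(n_otus = 600, shape = 0.9995,
                                           decay_scale = 2.5, decay_sdlog = 0.8,
                                           resurrection_p = 0.75,
                                           reads = 8000),
                          o2_detection_limit = 3,
                          seed = 1L) {
  stopifnot(inherits(column, "column_config"),
            inherits(kinetics, "kinetic_params"),
            all(profile_depths >= 0 & profile_depths <= column$depth_max),
            noise$profile >= 0, abundance$peak_fold >= 1,
            community$shape > 0, community$shape < 1,
            community$resurrection_p >= 0, community$resurrection_p <= 1)
  structure(list(column = column, kinetics = kinetics,
                 profile_depths = profile_depths,
                 sample_depths = sample_depths,
                 noise = noise, abundance = abundance, community = community,
                 o2_detection_limit = o2_detection_limit, seed = seed),
            class = "scenario_spec")
}

#' Simulated geochemical profiles with observation noise
#'
#' Solves the scenario's column model (the ground truth) and samples the
#' solute profiles at the scenario's observation depths with multiplicative
#' lognormal noise.  O2 values below the detection limit are flagged.
#'
#' @param spec a [scenario_spec()].
#' @param seed RNG seed (default the scenario's).
#' @param truth optionally, a precomputed solution for this scenario (saves
#'   re-solving when generating many noise realizations).
#' @return list with \code{truth} (a \code{solution_field}) and
#'   \code{observed} (data.frame \code{depth_m, species, value, unit,
#'   below_detection}).
#' @export
generate_profiles <- function(spec, seed = spec$seed, truth = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(truth)) {
    truth <- tryCatch(solve_steady_state(spec$column, spec$kinetics),
                      error = function(e)
                        stop("column model failed for this scenario ",
                             "(check kinetics/boundary conditions): ",
                             conditionMessage(e)))
    if (!truth$converged)
      stop("column model did not converge for this scenario; ",
           "the kinetics (k_OM, bimolecular constants) are the usual cause")
  }
  set.seed(seed)
  solutes <- truth$network$species[truth$network$phase == "solute"]
  obs <- do.call(rbind, lapply(solutes, function(s) {
    tv <- stats::approx(truth$z, truth$concentrations[, s],
                        spec$profile_depths)$y
    v <- tv * exp(stats::rnorm(length(tv), 0, spec$noise$profile))
    bd <- if (s == "O2") v < spec$o2_detection_limit else rep(FALSE, length(v))
    data.frame(depth_m = spec$profile_depths, species = s, value = v,
               unit = "uM", below_detection = bd)
  }))
  rownames(obs) <- NULL
  list(truth = truth, observed = obs)
}

#' Zone labels for sample depths given detected transition zones
#'
#' @param depths sample depths, m.
#' @param zones data.frame from [detect_transition_zones()] with one OATZ
#'   and one AOTZ.
#' @param surface_max depth (m) down to which samples are labelled
#'   \code{"surface"}.
#' @return character vector of labels: surface, oxic, OATZ, anoxic, AOTZ,
#'   basal.
#' @export
zone_labels <- function(depths, zones, surface_max = 2) {
  oatz <- zones[zones$kind == "OATZ", ][1, ]
  aotz <- zones[zones$kind == "AOTZ", ][1, ]
  if (is.na(oatz$top) || is.na(aotz$top))
    stop("zone_labels needs one OATZ and one AOTZ")
  ifelse(depths <= surface_max, "surface",
    ifelse(depths < oatz$top, "oxic",
      ifelse(depths <= oatz$bottom, "OATZ",
        ifelse(depths < aotz$top, "anoxic",
          ifelse(depths <= aotz$bottom, "AOTZ", "basal")))))
}

#' Simulated functional-gene abundance profiles
#'
#' log10(copies) declines linearly with depth from the surface level (one
#' decade per \code{decay_length} metres) and carries Gaussian peaks centred
#' in the supplied redox transition zones with log-amplitude
#' log10(peak_fold), plus lognormal noise.  Values at or below the qPCR
#' detection limit are flagged.
#'
#' @param spec a [scenario_spec()].
#' @param zones transition zones (data.frame with kind/top/bottom) whose
#'   centres receive abundance peaks.
#' @param seed RNG seed.
#' @return data.frame \code{depth_m, marker, copies_per_g, sd,
#'   below_detection}.
#' @export
generate_abundances <- function(spec, zones, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (nrow(zones) && (any(zones$top < 0) ||
                      any(zones$bottom > spec$column$depth_max)))
    stop("zones outside the column")
  set.seed(seed)
  ab <- spec$abundance
  depths <- spec$sample_depths
  bump <- rep(0, length(depths))
  for (i in seq_len(nrow(zones))) {
    mid <- (zones$top[i] + zones$bottom[i]) / 2
    bump <- bump + log10(ab$peak_fold) *
      exp(-(depths - mid)^2 / (2 * ab$peak_width^2))
  }
  dl <- ab$decay_length
  decay_for <- function(m) {
    if (length(dl) == 1L && is.null(names(dl))) return(dl)
    if (m %in% names(dl)) dl[[m]] else dl[["default"]]
  }
  out <- do.call(rbind, lapply(names(ab$marker_fractions), function(m) {
    lg <- log10(ab$surface * ab$marker_fractions[[m]]) -
      depths / decay_for(m) + bump +
      stats::rnorm(length(depths), 0, spec$noise$abundance_log10)
    copies <- 10^lg
    data.frame(depth_m = depths, marker = m, copies_per_g = copies,
               sd = copies * spec$noise$abundance_rel_sd,
               below_detection = copies <= ab$detection_limit)
  }))
  rownames(out) <- NULL
  out
}

#' Simulated OTU table with a planted resurrection signal
#'
#' The surface community follows a log-series rank-abundance distribution.
#' Each OTU's relative weight decays exponentially with depth at its own
#' rate (lognormally distributed across OTUs), reproducing the loss of
#' richness with depth.  In OATZ samples, each OTU is restored to its
#' surface weight with the scenario's resurrection probability; the set of
#' resurrected OTUs is returned as planted truth.  Counts are multinomial
#' at the scenario's read depth.
#'
#' @param spec a [scenario_spec()].
#' @param zones transition zones used to label samples (one OATZ, one
#'   AOTZ).
#' @param seed RNG seed.
#' @return list with \code{table} (an [otu_table()]; the taxonomy marks
#'   every 10th OTU rank as Nitrosopumilales, the rest as generic bacteria)
#'   and \code{resurrected} (character vector of planted resurrected OTU
#'   ids).
#' @export
generate_otu_table <- function(spec, zones, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  cm <- spec$community
  n <- cm$n_otus
  ranks <- seq_len(n)
  p_surface <- cm$shape^ranks / ranks
  p_surface <- p_surface / sum(p_surface)
  decay <- stats::rlnorm(n, meanlog = log(1 / cm$decay_scale),
                         sdlog = cm$decay_sdlog)
  resurrected <- stats::runif(n) < cm$resurrection_p

  depths <- spec$sample_depths
  labels <- zone_labels(depths, zones)
  counts <- matrix(0L, n, length(depths))
  for (j in seq_along(depths)) {
    w <- p_surface * exp(-decay * depths[j])
    if (labels[j] == "OATZ") w[resurrected] <- p_surface[resurrected]
    counts[, j] <- stats::rmultinom(1, cm$reads, w)
  }
  ids <- sprintf("OTU_%04d", ranks)
  rownames(counts) <- ids
  # every 10th rank is an AOA, so ammonia oxidizers span the whole
  # rank-abundance spectrum rather than only the dominants
  is_aoa <- ranks %% 10L == 1L
  taxonomy <- ifelse(is_aoa,
    "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrosopumilales;Nitrosopumilaceae",
    "Bacteria;Proteobacteria;Gammaproteobacteria;unclassified")
  meta <- data.frame(sample = sprintf("S%02d", seq_along(depths)),
                     site = "synthetic", depth_m = depths, zone = labels)
  colnames(counts) <- meta$sample
  list(table = otu_table(counts, taxonomy, meta),
       resurrected = ids[resurrected])
}

#' Parameter-recovery experiment for the O2-inhibition constant h1
#'
#' Generates noisy profiles from the scenario's ground truth (one noise
#' realization per seed) and refits h1 by grid search, reporting the
#' recovery error per seed.  The truth is solved once and shared across
#' seeds.
#'
#' @param spec a [scenario_spec()]; its kinetics hold the true h1.
#' @param h1_grid candidate h1 values (uM).
#' @param seeds integer vector of RNG seeds (one replicate each).
#' @param species observed species used in the misfit.
#' @return list with \code{results} (data.frame \code{seed, true_h1,
#'   recovered_h1, log10_error, at_grid_edge}) and \code{misfits} (list of
#'   per-seed misfit curves).
#' @export
recovery_experiment <- function(spec, h1_grid, seeds,
                                species = c("O2", "NO3")) {
  stopifnot(inherits(spec, "scenario_spec"))
  truth <- solve_steady_state(spec$column, spec$kinetics)
  if (!truth$converged) stop("ground-truth solve did not converge")
  res <- vector("list", length(seeds))
  misfits <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    gp <- generate_profiles(spec, seed = seeds[i], truth = truth)
    obs <- gp$observed[!gp$observed$below_detection, ]
    fit <- fit_h1(spec$column, spec$kinetics, obs, h1_grid, species = species)
    res[[i]] <- data.frame(seed = seeds[i], true_h1 = spec$kinetics$h1,
                           recovered_h1 = fit$best_h1,
                           log10_error = abs(log10(fit$best_h1) -
                                             log10(spec$kinetics$h1)),
                           at_grid_edge = fit$at_grid_edge)
    misfits[[i]] <- fit$misfit
  }
  list(results = do.call(rbind, res), misfits = misfits)
}
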