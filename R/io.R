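# Readers and writers for the package's table formats, configuration
# loading, and the orchestrating pipeline.

.valid_units <- c("uM", "mol_m3", "mmol_m2_yr")

#' Read / write depth-profile tables
#'
#' CSV with columns \code{depth_m, species, value, unit} (optional
#' \code{below_detection}).  Units must be in the whitelist (uM, mol_m3,
#' mmol_m2_yr); depths must be strictly increasing within each species and
#' (depth, species) pairs unique.  write then read is the identity up to
#' float formatting (values are written with 10 significant digits).
#'
#' @param path file path.
#' @return data.frame of profiles.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("depth_m", "species", "value", "unit")
  if (!all(need %in% names(df)))
    stop("profile file must have columns ", paste(need, collapse = ", "))
  bad_unit <- !df$unit %in% .valid_units
  if (any(bad_unit))
    stop("unknown unit '", df$unit[which(bad_unit)[1]], "' at row ",
         which(bad_unit)[1], " (valid: ", paste(.valid_units, collapse = ", "), ")")
  for (s in unique(df$species)) {
    d <- df$depth_m[df$species == s]
    if (anyDuplicated(d)) {
      row <- which(df$species == s)[anyDuplicated(d)]
      stop("duplicate (depth, species) at row ", row, " for species ", s)
    }
    if (is.unsorted(d, strictly = TRUE)) {
      row <- which(df$species == s)[which(diff(d) <= 0)[1] + 1L]
      stop("depths not increasing for species ", s, " at row ", row)
    }
  }
  if (!"below_detection" %in% names(df)) df$below_detection <- FALSE
  df
}

#' @rdname read_profiles
#' @param profiles data.frame with the profile columns.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(all(c("depth_m", "species", "value", "unit") %in% names(profiles)))
  out <- profiles
  out$value <- signif(out$value, 10)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write qPCR abundance tables
#'
#' CSV with columns \code{depth_m, marker, copies_per_g, sd,
#' below_detection}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_abundances <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("depth_m", "marker", "copies_per_g")
  if (!all(need %in% names(df)))
    stop("abundance file must have columns ", paste(need, collapse = ", "))
  if (any(df$copies_per_g < 0)) stop("negative copies_per_g")
  df
}

#' @rdname read_abundances
#' @param abundances data.frame.
#' @export
write_abundances <- function(abundances, path) {
  out <- abundances
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "depth_m"
  out[num] <- lapply(out[num], signif, 10)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write OTU tables in the classic tab-separated layout
#'
#' TSV with the OTU id in the first column, one column per sample, and the
#' taxonomy string in the last column; sample metadata in a separate CSV
#' with columns \code{sample, depth_m} (optional \code{site, zone}).
#'
#' @param counts_path TSV path.
#' @param meta_path metadata CSV path.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(counts_path, meta_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("OTU table needs id, >=1 sample, taxonomy columns")
  ids <- df[[1]]
  taxonomy <- df[[ncol(df)]]
  counts <- as.matrix(df[, -c(1, ncol(df)), drop = FALSE])
  rownames(counts) <- ids
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  if (anyNA(meta$sample)) stop("metadata missing for some samples")
  otu_table(counts, taxonomy, meta)
}

#' @rdname read_otu_table
#' @param table an \code{otu_table}.
#' @export
write_otu_table <- function(table, counts_path, meta_path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(OTU_ID = rownames(table$counts), table$counts,
                   taxonomy = table$taxonomy, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(table$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}

#' Write a steady-state solution as a CSV table
#'
#' One row per depth node: depth, every species concentration, and R1..R5.
#'
#' @param solution a \code{solution_field}.
#' @param path file path.
#' @export
write_solution <- function(solution, path) {
  df <- data.frame(depth_m = solution$z,
                   signif(as.data.frame(solution$concentrations), 10),
                   signif(as.data.frame(solution$rates), 10))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a scenario configuration from YAML
#'
#' The YAML mirrors the constructor arguments: top-level sections
#' \code{column} (depth_max, n_nodes, porosity, temperature,
#' burial_velocity, D0, bc, solute_advection), \code{kinetics}, and the
#' scenario sections \code{noise, abundance, community, seed}.  Every
#' default used by the shipped example appears explicitly in
#' \code{inst/extdata/northpond_like.yaml}.
#'
#' @param path YAML file.
#' @return a [scenario_spec()].
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  col_args <- y$column %||% list()
  if (!is.null(col_args$D0)) col_args$D0 <- unlist(col_args$D0)
  if (!is.null(col_args$bc))
    col_args$bc <- lapply(col_args$bc, function(b)
      if (is.list(b) && !is.null(b$flux_top)) b else unlist(b))
  column <- do.call(column_config, col_args)
  kinetics <- do.call(kinetic_params, y$kinetics %||% list())
  args <- list(column = column, kinetics = kinetics)
  for (nm in c("noise", "abundance", "community", "profile_depths",
               "sample_depths", "o2_detection_limit", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(args$abundance$marker_fractions))
    args$abundance$marker_fractions <- unlist(args$abundance$marker_fractions)
  if (!is.null(args$abundance$decay_length))
    args$abundance$decay_length <- unlist(args$abundance$decay_length)
  if (!is.null(args$profile_depths)) args$profile_depths <-
    do.call(seq, as.list(unlist(args$profile_depths)))
  if (!is.null(args$sample_depths)) args$sample_depths <-
    do.call(seq, as.list(unlist(args$sample_depths)))
  do.call(scenario_spec, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to the shipped example configuration
#' @return file path of the northpond_like YAML config.
#' @export
northpond_config <- function() {
  system.file("extdata", "northpond_like.yaml", package = "sednitro",
              mustWork = TRUE)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Chains the stages synth (profiles, abundances, OTU table) -> simulate
#' (steady-state solution) -> zones -> fluxes -> cellrates -> community,
#' writing every product as CSV/TSV under \code{out_dir} and an
#' execution manifest (config hash, seed, file digests) as JSON.
#'
#' @param config_path YAML scenario configuration.
#' @param out_dir output directory (created if missing).
#' @param seed seed overriding the configured one (optional).
#' @return the manifest (invisibly), also written to
#'   \code{out_dir/manifest.json}.
#' @export
run_pipeline <- function(config_path, out_dir, seed = NULL) {
  spec <- load_config(config_path)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)

  gp <- generate_profiles(spec)
  write_profiles(gp$observed, fp("profiles.csv"))
  write_solution(gp$truth, fp("solution.csv"))

  o2 <- gp$observed[gp$observed$species == "O2", ]
  zones <- detect_transition_zones(
    data.frame(depth_m = o2$depth_m, value = o2$value))
  utils::write.csv(cbind(site = "synthetic", zones), fp("zones.csv"),
                   row.names = FALSE, quote = FALSE)

  phi <- spec$column$porosity[1]
  fluxes <- do.call(rbind, lapply(c("O2", "NO3"), function(s) {
    prof <- gp$observed[gp$observed$species == s, ]
    jt <- fick_flux(prof, min(prof$depth_m), phi, spec$column$D0[[s]],
                    side = "below")
    jb <- fick_flux(prof, max(prof$depth_m), phi, spec$column$D0[[s]],
                    side = "above")
    data.frame(interface = c("top", "bottom"), species = s,
               flux_mmol_m2_yr = c(jt$flux, jb$flux),
               window = c(paste(signif(jt$window, 4), collapse = "|"),
                          paste(signif(jb$window, 4), collapse = "|")))
  }))
  utils::write.csv(fluxes, fp("fluxes.csv"), row.names = FALSE, quote = FALSE)

  ab <- generate_abundances(spec, zones)
  write_abundances(ab, fp("abundances.csv"))
  cr <- cell_rate_table(gp$truth, ab)
  num <- vapply(cr, is.numeric, logical(1))
  cr[num] <- lapply(cr[num], signif, 6)
  utils::write.csv(cr, fp("cellrates.csv"), row.names = FALSE, quote = FALSE)

  ot <- generate_otu_table(spec, zones)
  write_otu_table(ot$table, fp("otu_table.tsv"), fp("otu_meta.csv"))
  writeLines(ot$resurrected, fp("resurrected_truth.txt"))

  rich <- data.frame(sample = colnames(ot$table$counts),
                     depth_m = ot$table$meta$depth_m,
                     zone = ot$table$meta$zone,
                     richness_raw = as.integer(richness(ot$table)))
  rt <- rarefy_counts(ot$table, depth = 1000, seed = spec$seed)
  rich$richness_rarefied <-
    as.integer(richness(rt))[match(rich$sample, colnames(rt$counts))]
  utils::write.csv(rich, fp("richness.csv"), row.names = FALSE, quote = FALSE)

  reap <- reappearance_fraction(ot$table, taxa = "Nitrosopumilales",
                                rarefy_depth = 1000, seed = spec$seed)
  utils::write.csv(as.data.frame(reap), fp("reappearance.csv"),
                   row.names = FALSE, quote = FALSE)

  outputs <- c("profiles.csv", "solution.csv", "zones.csv", "fluxes.csv",
               "abundances.csv", "cellrates.csv", "otu_table.tsv",
               "otu_meta.csv", "resurrected_truth.txt", "richness.csv",
               "reappearance.csv")
  manifest <- list(
    config = unname(tools::md5sum(config_path)),
    seed = spec$seed,
    package_version = as.character(utils::packageVersion("sednitro")),
    outputs = as.list(tools::md5sum(vapply(outputs, fp, character(1)))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
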