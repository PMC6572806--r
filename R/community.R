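# Community statistics on OTU tables: rarefaction, richness,
# functional-group assignment, total-sum scaling, and the surface-community
# reappearance statistic at redox transition zones.

#' Construct an OTU table with sample metadata and taxonomy
#'
#' @param counts integer matrix, OTUs x samples, with OTU ids as rownames
#'   and sample ids as colnames.
#' @param taxonomy character vector (one rank-delimited string per OTU,
#'   ranks separated by ";").
#' @param meta data.frame with one row per sample: columns \code{sample},
#'   \code{depth_m} and optionally \code{site} and \code{zone} (one of
#'   surface, oxic, OATZ, anoxic, AOTZ, basal).
#' @return object of class \code{otu_table} (a list).
#' @export
otu_table <- function(counts, taxonomy, meta) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be >= 0")
  if (anyNA(counts)) stop("counts must not contain NA")
  stopifnot(length(taxonomy) == nrow(counts),
            all(c("sample", "depth_m") %in% names(meta)),
            nrow(meta) == ncol(counts))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("OTU_", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- meta$sample
  stopifnot(identical(colnames(counts), as.character(meta$sample)))
  structure(list(counts = counts, taxonomy = taxonomy,
                 meta = as.data.frame(meta)),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d samples, depths %.3g-%.3g m\n",
              nrow(x$counts), ncol(x$counts),
              min(x$meta$depth_m), max(x$meta$depth_m)))
  invisible(x)
}

#' Rarefy count vectors to a fixed sequencing depth
#'
#' Random subsampling without replacement to exactly \code{depth} reads,
#' the standard normalization before comparing richness across samples.
#' Samples with fewer than \code{depth} reads are dropped with a message.
#'
#' @param x integer vector of counts (one sample), or an OTUs x samples
#'   matrix, or an \code{otu_table}.
#' @param depth target number of reads (> 0).
#' @param seed RNG seed for reproducibility (optional).
#' @return the same shape as the input, with every retained sample summing
#'   to exactly \code{depth}.
#' @export
rarefy_counts <- function(x, depth = 1000, seed = NULL) {
  stopifnot(depth > 0)
  if (!is.null(seed)) set.seed(seed)
  rar1 <- function(v) {
    tot <- sum(v)
    if (tot == depth) return(v)
    picked <- sample.int(tot, depth)   # positions among the expanded reads
    cs <- cumsum(v)
    tabulate(findInterval(picked, c(0, cs), left.open = TRUE),
             nbins = length(v))
  }
  if (inherits(x, "otu_table")) {
    keep <- colSums(x$counts) >= depth
    if (any(!keep))
      message(sum(!keep), " sample(s) with fewer than ", depth,
              " reads excluded from rarefaction")
    counts <- apply(x$counts[, keep, drop = FALSE], 2, rar1)
    rownames(counts) <- rownames(x$counts)
    return(otu_table(counts, x$taxonomy, x$meta[keep, , drop = FALSE]))
  }
  if (is.matrix(x)) {
    keep <- colSums(x) >= depth
    if (any(!keep))
      message(sum(!keep), " sample(s) with fewer than ", depth,
              " reads excluded from rarefaction")
    out <- apply(x[, keep, drop = FALSE], 2, rar1)
    rownames(out) <- rownames(x)
    return(out)
  }
  if (sum(x) < depth) stop("sample total below rarefaction depth")
  out <- rar1(as.integer(x))
  names(out) <- names(x)
  out
}

#' Observed OTU richness
#'
#' @param x count vector, OTUs x samples matrix, or \code{otu_table}.
#' @return number of OTUs with count > 0 (per sample for matrix input).
#' @export
richness <- function(x) {
  if (inherits(x, "otu_table")) x <- x$counts
  if (is.matrix(x)) colSums(x > 0) else sum(x > 0)
}

# does a rank-delimited taxonomy string contain the exact taxon name at any
# rank?
.tax_match <- function(taxonomy, taxa) {
  ranks <- strsplit(taxonomy, "\\s*;\\s*")
  vapply(ranks, function(r) any(trimws(r) %in% taxa), logical(1))
}

#' Default functional-group map for nitrogen-cycling taxa
#'
#' Ammonia-oxidizing archaea (the order Nitrosopumilales), ammonia-oxidizing
#' bacteria, nitrite-oxidizing bacteria, and common putative denitrifier
#' taxa.
#'
#' @return named list: group -> character vector of taxon names (matched at
#'   any rank of the taxonomy string).
#' @export
default_functional_groups <- function() {
  list(AOA = "Nitrosopumilales",
       AOB = c("Nitrosospira", "Nitrosomonas", "Nitrosococcus"),
       NOB = c("Nitrospira", "Nitrospina"),
       denitrifiers = c("Pseudomonas", "Arcobacter", "Aeromonas",
                        "Woeseiaceae"))
}

#' Per-sample relative abundance of functional groups
#'
#' Assigns OTUs to functional groups by exact taxon-name match at any rank
#' of the taxonomy string, then reports each group's share of the total
#' sample reads (percent).  OTUs matching no group are pooled as
#' \code{"other"}; an OTU matching two groups is an error (the map must be
#' disjoint).
#'
#' @param table an \code{otu_table}.
#' @param map named list group -> taxon names; default
#'   [default_functional_groups()].
#' @return matrix (groups + "other") x samples of percentages; columns sum
#'   to 100.
#' @export
assign_functional_groups <- function(table, map = default_functional_groups()) {
  stopifnot(inherits(table, "otu_table"))
  hits <- vapply(map, function(taxa) .tax_match(table$taxonomy, taxa),
                 logical(nrow(table$counts)))
  if (!is.matrix(hits)) hits <- matrix(hits, nrow = nrow(table$counts))
  multi <- rowSums(hits) > 1
  if (any(multi))
    stop("OTU(s) matching more than one functional group: ",
         paste(rownames(table$counts)[multi], collapse = ", "),
         " (the group map must be disjoint)")
  tot <- colSums(table$counts)
  if (any(tot == 0)) stop("sample(s) with zero total reads: ",
                          paste(colnames(table$counts)[tot == 0], collapse = ", "))
  grp <- t(hits) %*% table$counts            # groups x samples read sums
  out <- rbind(grp, other = tot - colSums(grp))
  sweep(out, 2, tot, "/") * 100
}

#' Total-sum scaling of counts restricted to a taxon set
#'
#' Normalizes each sample's counts (optionally restricted to OTUs matching
#' a taxon filter) to relative abundances summing to 1, the usual
#' preparation for heatmap display.  Samples with zero total within the
#' restriction are dropped with a message.
#'
#' @param table an \code{otu_table}.
#' @param taxa optional character vector of taxon names; only OTUs matching
#'   one of them (at any rank) are kept.
#' @return matrix of relative abundances (restricted OTUs x retained
#'   samples), columns summing to 1.
#' @export
total_sum_scale <- function(table, taxa = NULL) {
  stopifnot(inherits(table, "otu_table"))
  counts <- table$counts
  if (!is.null(taxa)) counts <- counts[.tax_match(table$taxonomy, taxa), ,
                                       drop = FALSE]
  tot <- colSums(counts)
  if (any(tot == 0))
    message(sum(tot == 0), " sample(s) with zero reads in the restriction dropped")
  counts <- counts[, tot > 0, drop = FALSE]
  sweep(counts, 2, colSums(counts), "/")
}

#' Fraction of vanished surface OTUs that reappear in a target zone
#'
#' Among OTUs detected in the surface zone but undetected in every sample of
#' the intervening gap zones, computes the fraction detected again in the
#' target zone (e.g. the OATZ).  "Detected" means at least
#' \code{detection_threshold} reads, optionally after rarefaction.
#'
#' @param table an \code{otu_table} whose metadata has a \code{zone} column.
#' @param taxa optional taxon filter (e.g. "Nitrosopumilales" for the AOA).
#' @param surface_zone,gap_zones,target_zone zone labels.
#' @param rarefy_depth rarefy samples to this depth first (NULL = raw
#'   counts).
#' @param seed RNG seed used when rarefying.
#' @param detection_threshold minimum reads for detection (default 1).
#' @return list with \code{fraction} (NA when no candidate OTUs),
#'   \code{n_surface} (OTUs detected in the surface zone),
#'   \code{n_candidates} (surface OTUs undetected in all gap samples) and
#'   \code{n_reappeared}.
#' @export
reappearance_fraction <- function(table, taxa = NULL,
                                  surface_zone = "surface",
                                  gap_zones = c("oxic", "anoxic"),
                                  target_zone = "OATZ",
                                  rarefy_depth = NULL, seed = NULL,
                                  detection_threshold = 1) {
  stopifnot(inherits(table, "otu_table"))
  if (!"zone" %in% names(table$meta))
    stop("otu_table metadata has no 'zone' column")
  if (!is.null(rarefy_depth))
    table <- rarefy_counts(table, rarefy_depth, seed)
  counts <- table$counts
  if (!is.null(taxa)) counts <- counts[.tax_match(table$taxonomy, taxa), ,
                                       drop = FALSE]
  zone <- table$meta$zone
  det <- function(zones) {
    cols <- zone %in% zones
    if (!any(cols)) stop("no samples in zone(s): ",
                         paste(zones, collapse = ", "))
    rowSums(counts[, cols, drop = FALSE] >= detection_threshold) > 0
  }
  surface <- det(surface_zone)
  in_gap <- det(gap_zones)
  target <- det(target_zone)
  candidates <- surface & !in_gap
  if (!any(surface))
    return(list(fraction = NA_real_, n_surface = 0L, n_candidates = 0L,
                n_reappeared = 0L))
  list(fraction = if (any(candidates))
         sum(candidates & target) / sum(candidates) else NA_real_,
       n_surface = sum(surface),
       n_candidates = sum(candidates),
       n_reappeared = sum(candidates & target))
}
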