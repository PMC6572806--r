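# Shared fixtures.  The shipped scenario solve is memoized because several
# files inspect the same steady state.

.cache <- new.env(parent = emptyenv())

shipped_spec <- function() {
  if (is.null(.cache$spec)) .cache$spec <- load_config(northpond_config())
  .cache$spec
}

shipped_solution <- function() {
  if (is.null(.cache$sol)) {
    spec <- shipped_spec()
    .cache$sol <- solve_steady_state(spec$column, spec$kinetics)
  }
  .cache$sol
}

shipped_zones <- function() {
  if (is.null(.cache$zones)) {
    sol <- shipped_solution()
    .cache$zones <- detect_transition_zones(
      data.frame(depth_m = sol$z, value = sol$concentrations[, "O2"]))
  }
  .cache$zones
}

# single-solute network with constant (zeroth-order) volumetric sink R0tot,
# in mol m-3 total sediment yr-1
zeroth_order_network <- function(R0tot) {
  reaction_network(
    species = "X", phase = c(X = "solute"),
    stoich = matrix(-1, 1, 1, dimnames = list("X", "R")),
    rate_fn = function(conc, p) matrix(p$R0tot, nrow(conc), 1),
    params = list(R0tot = R0tot))
}

# single-solute network with first-order decay (rate constant k, 1/yr,
# applied to porewater concentration; phi converts to a per-total-volume
# rate in mol m-3 yr-1)
first_order_network <- function(k, phi) {
  reaction_network(
    species = "X", phase = c(X = "solute"),
    stoich = matrix(-1, 1, 1, dimnames = list("X", "R")),
    rate_fn = function(conc, p) matrix(p$k * p$phi * 1e-3 * pmax(conc[, 1], 0),
                                       nrow(conc), 1),
    params = list(k = k, phi = phi))
}

# column with a prescribed sediment diffusivity Ds (tortuosity pre-applied)
single_solute_config <- function(L, n, phi, Ds, top, bottom) {
  column_config(depth_max = L, n_nodes = n, porosity = phi,
                D0 = c(X = Ds * (1 - log(phi^2))),
                bc = list(X = c(top = top, bottom = bottom)))
}

# random small OTU table for property tests
random_otu_table <- function(n_otu = 40, n_samp = 9, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_otu * n_samp, lambda = rexp(n_otu * n_samp, 1 / 8)),
                   n_otu, n_samp)
  zones <- c("surface", "surface", "oxic", "oxic", "anoxic", "OATZ", "OATZ",
             "AOTZ", "basal")
  meta <- data.frame(sample = paste0("S", seq_len(n_samp)),
                     depth_m = seq(0.5, by = 4, length.out = n_samp),
                     zone = zones)
  tax <- ifelse(seq_len(n_otu) %% 3 == 0,
                "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrosopumilales;g",
                "Bacteria;Proteobacteria;x")
  otu_table(counts, tax, meta)
}
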