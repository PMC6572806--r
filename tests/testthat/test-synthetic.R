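test_that("zero-noise observations equal the truth at the sampled depths", {
  spec <- shipped_spec()
  spec$noise$profile <- 0
  gp <- generate_profiles(spec, truth = shipped_solution())
  o2 <- gp$observed[gp$observed$species == "O2", ]
  truth_o2 <- approx(gp$truth$z, gp$truth$concentrations[, "O2"],
                     o2$depth_m)$y
  expect_equal(o2$value, truth_o2)
  expect_equal(o2$below_detection, truth_o2 < 3)
})

test_that("seeds control the noise but not the truth", {
  spec <- shipped_spec()
  truth <- shipped_solution()
  a <- generate_profiles(spec, seed = 1, truth = truth)
  b <- generate_profiles(spec, seed = 1, truth = truth)
  c <- generate_profiles(spec, seed = 2, truth = truth)
  expect_identical(a$observed, b$observed)       # bit-identical under a seed
  expect_identical(a$truth, c$truth)
  expect_false(identical(a$observed$value, c$observed$value))
})

test_that("generated profiles carry the study's geochemical structure", {
  spec <- shipped_spec()
  gp <- generate_profiles(spec, truth = shipped_solution())
  o2 <- gp$observed[gp$observed$species == "O2", ]
  zz <- detect_transition_zones(
    data.frame(depth_m = o2$depth_m, value = o2$value))
  expect_setequal(zz$kind, c("OATZ", "AOTZ"))
  expect_true(all(zz$top[zz$kind == "AOTZ"] >
                    zz$bottom[zz$kind == "OATZ"]))
  no3 <- gp$observed[gp$observed$species == "NO3", ]
  expect_gt(max(no3$value), 40)
  expect_lt(max(no3$value), 50)
  # the maximum sits mid-column, not at a boundary
  zmax <- no3$depth_m[which.max(no3$value)]
  expect_gt(zmax, 10)
  expect_lt(zmax, 70)
})

test_that("abundance profiles decay exponentially with transition-zone peaks", {
  spec <- shipped_spec()
  zones <- shipped_zones()
  spec$noise$abundance_log10 <- 0
  ab <- generate_abundances(spec, zones)
  tot <- ab[ab$marker == "16S_bac", ]
  # surface value equals the configured level exactly with zero noise
  expect_equal(tot$copies_per_g[tot$depth_m == 0.5],
               spec$abundance$surface * 0.5 * 10^(-0.5 / 30 +
                 sum(vapply(seq_len(nrow(zones)), function(i) {
                   mid <- (zones$top[i] + zones$bottom[i]) / 2
                   log10(100) * exp(-(0.5 - mid)^2 / (2 * 4))
                 }, numeric(1)))))
  # fold-change 1 gives pure exponential decay in linear space
  spec1 <- spec
  spec1$abundance$peak_fold <- 1
  ab1 <- generate_abundances(spec1, zones)
  t1 <- ab1[ab1$marker == "16S_bac", ]
  expect_equal(t1$copies_per_g[1], spec$abundance$surface * 0.5 * 10^(-0.5 / 30))
  lg <- log10(t1$copies_per_g)
  expect_equal(diff(lg), rep(-3 / 30, length(lg) - 1), tolerance = 1e-10)
  # peak amplitude: value at the OATZ centre is ~peak_fold times the
  # no-peak baseline at that depth
  mid <- (zones$top[zones$kind == "OATZ"] + zones$bottom[zones$kind == "OATZ"]) / 2
  near <- which.min(abs(tot$depth_m - mid))
  ratio <- tot$copies_per_g[near] / t1$copies_per_g[near]
  bump_at <- function(d) sum(vapply(seq_len(nrow(zones)), function(i) {
    ctr <- (zones$top[i] + zones$bottom[i]) / 2
    log10(spec$abundance$peak_fold) *
      exp(-(d - ctr)^2 / (2 * spec$abundance$peak_width^2))
  }, numeric(1)))
  expect_equal(ratio, 10^bump_at(tot$depth_m[near]))
  # the peak is of the configured order (up to 100-fold over baseline)
  expect_gt(ratio, 10)
  expect_lte(ratio, 100)
  # detection-limit flagging
  expect_true(all((ab$copies_per_g <= 100) == ab$below_detection))
})

test_that("planted resurrection probability drives the reappearance statistic", {
  spec <- shipped_spec()
  zones <- shipped_zones()
  # limits: probability 0 -> no reappearance; probability 1 with deep reads
  # -> near-total reappearance
  s0 <- spec; s0$community$resurrection_p <- 0
  t0 <- generate_otu_table(s0, zones, seed = 4)
  expect_equal(length(t0$resurrected), 0)
  r0 <- reappearance_fraction(t0$table, gap_zones = "anoxic")
  expect_lt(r0$fraction, 0.1)
  s1 <- spec; s1$community$resurrection_p <- 1
  t1 <- generate_otu_table(s1, zones, seed = 4)
  r1 <- reappearance_fraction(t1$table, gap_zones = "anoxic")
  expect_gt(r1$fraction, 0.9)
  # bit-identical under a fixed seed
  expect_identical(generate_otu_table(spec, zones, seed = 7)$table$counts,
                   generate_otu_table(spec, zones, seed = 7)$table$counts)
  # planted truth is emitted and matches the table's ids
  tt <- generate_otu_table(spec, zones, seed = 7)
  expect_true(all(tt$resurrected %in% rownames(tt$table$counts)))
})

test_that("OTU tables show surface-like richness resurgence in the OATZ", {
  spec <- shipped_spec()
  ot <- generate_otu_table(spec, shipped_zones(), seed = 2)
  rt <- rarefy_counts(ot$table, 1000, seed = 2)
  rich <- richness(rt)
  zone <- rt$meta$zone
  expect_gt(mean(rich[zone == "OATZ"]), 2 * mean(rich[zone == "anoxic"]))
  expect_gt(mean(rich[zone == "OATZ"]), 0.7 * mean(rich[zone == "surface"]))
  expect_gt(mean(rich[zone == "surface"]), mean(rich[zone == "basal"]))
})

test_that("zone labels partition the column in depth order", {
  zones <- data.frame(kind = c("OATZ", "AOTZ"), top = c(30, 50),
                      bottom = c(34, 55))
  lab <- zone_labels(c(0.5, 10, 31, 40, 52, 70), zones)
  expect_equal(lab, c("surface", "oxic", "OATZ", "anoxic", "AOTZ", "basal"))
  expect_error(zone_labels(1, zones[1, ]), "one OATZ and one AOTZ")
})

test_that("recovery_experiment reports exact on-grid recovery without noise", {
  spec <- shipped_spec()
  spec$noise$profile <- 0
  re <- recovery_experiment(spec, h1_grid = c(2, 10, 30), seeds = 1)
  expect_equal(re$results$recovered_h1, 10)
  expect_equal(re$results$log10_error, 0)
  expect_false(re$results$at_grid_edge)
  expect_equal(nrow(re$misfits[[1]]), 3)
})
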