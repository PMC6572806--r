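test_that("rarefaction subsamples without replacement to the exact depth", {
  x <- c(a = 600, b = 300, c = 100)
  r <- rarefy_counts(x, 1000)
  expect_equal(r, x)                       # exactly 1000 reads: unchanged
  r2 <- rarefy_counts(c(a = 5000L), 1000)
  expect_equal(unname(r2), 1000L)          # single OTU keeps all reads
  set.seed(1)
  big <- c(rmultinom(1, 5000, c(0.5, 0.3, 0.15, 0.04, 0.01)))
  r3 <- rarefy_counts(big, 1000, seed = 9)
  expect_equal(sum(r3), 1000)
  expect_true(all(r3 <= big))              # without replacement
  expect_identical(r3, rarefy_counts(big, 1000, seed = 9))  # reproducible
  expect_error(rarefy_counts(c(10, 5), 100), "below rarefaction depth")
  expect_error(rarefy_counts(big, 0))
})

test_that("mean rarefied richness matches the hypergeometric expectation", {
  # rare OTUs (counts 8 and 2) make the expectation genuinely fractional
  counts <- c(40, 30, 20, 8, 2)
  N <- sum(counts); d <- 50
  # exact combinatorial expectation: sum_i 1 - C(N - n_i, d)/C(N, d)
  expected <- sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
  set.seed(11)
  mc <- mean(vapply(1:1000, function(i) richness(rarefy_counts(counts, d)),
                    numeric(1)))
  expect_equal(mc, expected, tolerance = 0.012)
  # the same expectation computed by an independent implementation
  if (requireNamespace("vegan", quietly = TRUE))
    expect_equal(expected,
                 as.numeric(suppressWarnings(vegan::rarefy(counts, d))),
                 tolerance = 1e-10)
})

test_that("richness counts detected OTUs and never rises under rarefaction", {
  expect_equal(richness(c(0, 0, 0)), 0)
  expect_equal(richness(c(1, 5, 0, 2, 8, 1)), 5)
  set.seed(5)
  m <- matrix(rpois(60, 3), 10, 6)
  expect_equal(richness(m), colSums(m > 0))
  big <- c(rmultinom(1, 3000, rexp(50)))
  for (s in 1:5)
    expect_lte(richness(rarefy_counts(big, 800, seed = s)), richness(big))
  # stochastically nondecreasing in rarefaction depth (paired subsamples)
  r500 <- vapply(1:30, function(s) richness(rarefy_counts(big, 500, seed = s)),
                 numeric(1))
  r1500 <- vapply(1:30, function(s) richness(rarefy_counts(big, 1500, seed = s)),
                  numeric(1))
  expect_gt(mean(r1500), mean(r500))
})

test_that("functional-group abundances sum to 100 and respect the map", {
  counts <- matrix(c(21, 10,
                     4,  0,
                     25, 40,
                     50, 50), 4, 2, byrow = TRUE,
                   dimnames = list(paste0("o", 1:4), c("s1", "s2")))
  tax <- c("Archaea;Nitrosopumilales;x",
           "Bacteria;Nitrosospira;y",
           "Bacteria;Pseudomonas;z",
           "Bacteria;other;w")
  meta <- data.frame(sample = c("s1", "s2"), depth_m = c(1, 2))
  tab <- otu_table(counts, tax, meta)
  g <- assign_functional_groups(tab)
  expect_equal(g["AOA", "s1"], 21)        # 21 of 100 reads
  expect_equal(g["AOB", "s1"], 4)
  expect_equal(g["denitrifiers", "s2"], 40)
  expect_equal(unname(colSums(g)), c(100, 100))
  # no mapped taxa -> all groups zero
  tab2 <- otu_table(counts, rep("Bacteria;plain", 4), meta)
  g2 <- assign_functional_groups(tab2)
  expect_true(all(g2[setdiff(rownames(g2), "other"), ] == 0))
  # permutation invariance to OTU ordering
  perm <- c(3, 1, 4, 2)
  g3 <- assign_functional_groups(otu_table(counts[perm, ], tax[perm], meta))
  expect_equal(g3, g)
  # overlapping map rejected
  expect_error(assign_functional_groups(tab,
    map = list(A = "Nitrosopumilales", B = c("Nitrosopumilales", "Q"))),
    "disjoint")
})

test_that("total-sum scaling yields per-sample proportions", {
  tab <- random_otu_table()
  tss <- total_sum_scale(tab)
  expect_equal(unname(colSums(tss)), rep(1, ncol(tss)))
  # single OTU -> 1; equal counts -> 1/k
  one <- otu_table(matrix(7, 1, 1, dimnames = list("o1", "s1")),
                   "t", data.frame(sample = "s1", depth_m = 0))
  expect_equal(unname(total_sum_scale(one)[1, 1]), 1)
  eq <- otu_table(matrix(5L, 4, 1, dimnames = list(paste0("o", 1:4), "s1")),
                  rep("t", 4), data.frame(sample = "s1", depth_m = 0))
  expect_equal(unname(total_sum_scale(eq)[, 1]), rep(0.25, 4))
  # scale invariance
  tab2 <- tab
  tab2$counts <- tab2$counts * 3L
  expect_equal(total_sum_scale(tab2), total_sum_scale(tab))
  # taxon restriction keeps only matching OTUs
  aoa <- total_sum_scale(tab, taxa = "Nitrosopumilales")
  expect_true(all(grepl("Nitrosopumilales",
                        tab$taxonomy[match(rownames(aoa),
                                           rownames(tab$counts))])))
})

test_that("reappearance fraction matches construction and the set-algebra oracle", {
  # constructed table: 32 surface OTUs, all undetected mid-column, 24 of
  # them detected again in the OATZ -> 75%
  n <- 40
  counts <- matrix(0L, n, 4,
                   dimnames = list(sprintf("o%02d", 1:n),
                                   c("surf", "gap1", "gap2", "oatz")))
  counts[1:32, "surf"] <- 10L
  counts[1:24, "oatz"] <- 5L
  counts[33:40, c("gap1", "gap2")] <- 3L
  meta <- data.frame(sample = colnames(counts), depth_m = c(0.5, 10, 20, 30),
                     zone = c("surface", "oxic", "anoxic", "OATZ"))
  tab <- otu_table(counts, rep("t", n), meta)
  r <- reappearance_fraction(tab)
  expect_equal(r$fraction, 0.75)
  expect_equal(r$n_surface, 32)
  expect_equal(r$n_candidates, 32)
  expect_equal(r$n_reappeared, 24)
  # target zone holding no surface OTUs -> 0
  counts2 <- counts; counts2[, "oatz"] <- 0L; counts2[40, "oatz"] <- 2L
  r0 <- reappearance_fraction(otu_table(counts2, rep("t", n), meta))
  expect_equal(r0$fraction, 0)

  # random tables against a brute-force three-set computation
  for (s in 1:10) {
    tab <- random_otu_table(n_otu = 30, n_samp = 9, seed = s)
    got <- reappearance_fraction(tab, gap_zones = c("oxic", "anoxic"))
    cts <- tab$counts; zone <- tab$meta$zone
    surf <- rownames(cts)[rowSums(cts[, zone == "surface", drop = FALSE] > 0) > 0]
    gap <- rownames(cts)[rowSums(cts[, zone %in% c("oxic", "anoxic"),
                                     drop = FALSE] > 0) > 0]
    targ <- rownames(cts)[rowSums(cts[, zone == "OATZ", drop = FALSE] > 0) > 0]
    cand <- setdiff(surf, gap)
    want <- if (length(cand)) length(intersect(cand, targ)) / length(cand)
            else NA_real_
    expect_equal(got$fraction, want)
    expect_equal(got$n_candidates, length(cand))
    if (!is.na(want)) expect_true(got$fraction >= 0 && got$fraction <= 1)
  }
})

test_that("reappearance detection is monotone in target-zone sequencing depth", {
  set.seed(21)
  n <- 60
  counts <- matrix(0L, n, 3, dimnames = list(sprintf("o%02d", 1:n), NULL))
  counts[1:50, 1] <- 20L
  counts[, 3] <- c(rmultinom(1, 4000, rexp(n)))
  meta <- data.frame(sample = c("s1", "s2", "s3"), depth_m = c(0.5, 15, 30),
                     zone = c("surface", "anoxic", "OATZ"))
  colnames(counts) <- meta$sample
  fr <- vapply(c(200, 1000, 4000), function(d) {
    tab <- otu_table(counts, rep("t", n), meta)
    tab$counts[, "s3"] <- rarefy_counts(counts[, "s3"], d, seed = 1)
    reappearance_fraction(tab, gap_zones = "anoxic")$fraction
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})
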