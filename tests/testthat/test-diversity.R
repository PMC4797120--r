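test_that("colonization_frequency follows the segment ratio and guards its domain", {
  expect_equal(colonization_frequency(0, 45), 0)
  expect_equal(colonization_frequency(45, 45), 100)
  expect_equal(colonization_frequency(9, 45), 20)
  expect_error(colonization_frequency(5, 0), "total")
  expect_error(colonization_frequency(46, 45), "exceed")
})

test_that("index formulas reproduce hand-computed values", {
  expect_equal(gleason(17, 762), 16 / log(762))
  expect_equal(gleason(1, 100), 0)
  expect_error(gleason(2, 1), "n_isolates")
  expect_equal(relative_gleason(17, 762), 16 / 762)
  expect_equal(relative_gleason(22, 320), 21 / 320)
  expect_equal(simpson_dominance(c(5)), 1)
  expect_equal(simpson_dominance(c(3, 3)), 0.5)
  expect_equal(simpson_dominance(c(1, 2, 3)), 14 / 36)
  expect_equal(simpson_diversity(14 / 36), 22 / 36)
  expect_error(simpson_diversity(1.2), "\\[0, 1\\]")
  expect_equal(shannon(c(7)), 0)
  expect_equal(shannon(rep(3, 4)), log(4))
  expect_equal(shannon(c(1, 2, 3)), 1.0114, tolerance = 1e-4)
  expect_equal(pielou(shannon(c(1, 2, 3)), 3), 0.9206, tolerance = 1e-4)
  expect_equal(pielou(log(11), 11), 1)
  expect_error(pielou(0.5, 1), "undefined")
  expect_warning(p <- pielou(3, 2), "clamped")
  expect_equal(p, 1)
})

test_that("diversity_profile assembles a consistent row, with the degenerate case", {
  row <- diversity_profile(c(1, 2, 3), "toy")
  expect_equal(row$S, 6)
  expect_equal(row$Np, 3)
  expect_equal(row$D + row$one_minus_D, 1)
  expect_equal(row$H, shannon_brute(c(1, 2, 3)))
  expect_equal(row$E, row$H / log(3))
  uniform <- diversity_profile(rep(10, 10), "even")
  expect_equal(uniform$D, 0.1)
  expect_equal(uniform$H, log(10))
  expect_equal(uniform$E, 1)
  expect_warning(single <- diversity_profile(c(0, 8), "one"), "single-species")
  expect_equal(single[, c("Np", "G", "GR", "D", "one_minus_D", "H", "E")],
               tibble::tibble(Np = 1L, G = 0, GR = 0, D = 1, one_minus_D = 0,
                              H = 0, E = 1))
  expect_error(diversity_profile(c(0, 0)), "positive")
})

test_that("Shannon and Simpson match brute-force oracles on random vectors", {
  set.seed(101)
  for (i in 1:300) {
    counts <- random_abundance()
    expect_equal(shannon(counts), shannon_brute(counts))
    expect_equal(simpson_dominance(counts), simpson_brute(counts))
  }
})

test_that("indices respect their analytic bounds and permutation invariance", {
  set.seed(202)
  for (i in 1:100) {
    counts <- random_abundance()
    Np <- species_richness(counts)
    D <- simpson_dominance(counts)
    H <- shannon(counts)
    expect_gte(D, 1 / Np - 1e-12)
    expect_lte(D, 1)
    expect_gte(H, 0)
    expect_lte(H, log(max(Np, 1)) + 1e-12)
    perm <- counts[sample.int(length(counts))]
    expect_equal(shannon(perm), H)
    expect_equal(simpson_dominance(perm), D)
    expect_equal(species_richness(perm), Np)
  }
})

test_that("merging two species never increases H and never decreases D", {
  set.seed(303)
  for (i in 1:100) {
    counts <- random_abundance(n_species = sample(2:20, 1))
    keep <- counts[-(1:2)]
    merged <- c(counts[1] + counts[2], keep)
    expect_lte(shannon(merged), shannon(counts) + 1e-12)
    expect_gte(simpson_dominance(merged), simpson_dominance(counts) - 1e-12)
  }
})

test_that("diversity indices agree with vegan on random vectors", {
  skip_if_not_installed("vegan")
  set.seed(404)
  for (i in 1:50) {
    counts <- random_abundance()
    expect_equal(shannon(counts), unname(vegan::diversity(counts, "shannon")))
    expect_equal(simpson_dominance(counts),
                 unname(1 - vegan::diversity(counts, "simpson")))
  }
})

test_that("diversity_table reproduces the per-season survey summary shape", {
  dt <- diversity_table(load_survey_cf(), "season")
  expect_equal(dt$label, c("winter", "summer", "rainy"))
  expect_equal(dt$Np, c(17, 22, 24))
  expect_true(all(dt$D + dt$one_minus_D == 1))
  expect_true(all(dt$E >= 0 & dt$E <= 1))
  expect_true(all(dt$H <= log(dt$Np)))
})
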