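test_that("wide fixture reads to 24 species x 18 cells with zeros for blanks", {
  cf <- read_cf_matrix(mycodiv_example("table2_winter.csv"), "wide")
  expect_s3_class(cf, "tbl_df")
  expect_equal(nlevels(cf$species), 24)
  expect_equal(nrow(cf), 24 * 18)
  expect_true(all(cf$cf >= 0 & cf$cf <= 100))
  expect_false(anyNA(cf$cf))
  # dashes decode to exact zero
  expect_equal(sum(cf$cf[cf$species == "JP44MY9"]), 0)
  # species order preserved from the file
  expect_equal(levels(cf$species)[1:3], c("JP44MY2", "JP44MY3", "JP44MY4"))
})

test_that("long/wide round-trips reproduce the identical matrix", {
  cf <- read_cf_matrix(mycodiv_example("table3_summer.csv"), "wide")
  long_path <- withr::local_tempfile(fileext = ".csv")
  wide_path <- withr::local_tempfile(fileext = ".csv")
  write_cf_matrix(cf, long_path, "long")
  write_cf_matrix(cf, wide_path, "wide")
  again_long <- read_cf_matrix(long_path, "long")
  again_wide <- read_cf_matrix(wide_path, "wide")
  key <- c("species", "season", "site", "tissue")
  ord <- function(x) x[do.call(order, x[key]), ]
  expect_equal(ord(as.data.frame(again_long)), ord(as.data.frame(cf)),
               ignore_attr = TRUE)
  expect_equal(ord(as.data.frame(again_wide)), ord(as.data.frame(cf)),
               ignore_attr = TRUE)
})

test_that("empty table body gives an empty matrix", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,winter_site1_leaf", path)
  cf <- read_cf_matrix(path, "wide")
  expect_equal(nrow(cf), 0)
})

test_that("malformed headers and out-of-range CF values are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,winter_site1_root", "a,5"), path)
  expect_error(read_cf_matrix(path, "wide"), "winter_site1_root")
  writeLines(c("species,winter_site1_leaf", "a,120"), path)
  expect_error(read_cf_matrix(path, "wide"), "out of \\[0, 100\\]")
  writeLines(c("species,season,site,cf", "a,winter,1,5"), path)
  expect_error(read_cf_matrix(path, "long"), "tissue")
})

test_that("cf_to_counts rounds to the segment grain and flags off-grain values", {
  mk <- function(cf) tibble::tibble(species = "a", season = "winter",
                                    site = 1L, tissue = "leaf", cf = cf)
  expect_equal(cf_to_counts(mk(0))$count, 0L)
  expect_equal(cf_to_counts(mk(100), 45, 1)$count, 45L)
  out <- cf_to_counts(mk(0.74), 45, 3)  # 135 segments
  expect_equal(out$count, 1L)
  expect_false(out$flagged)
  expect_true(cf_to_counts(mk(0.5), 45, 3)$flagged)
  expect_error(cf_to_counts(dplyr::mutate(mk(1), cf = -1)), "negative")
})

test_that("count -> CF back-conversion agrees within 0.01 pp for unflagged entries", {
  cf <- read_cf_matrix(mycodiv_example("table4_rainy.csv"), "wide")
  out <- cf_to_counts(cf, 45, 3)
  back <- out$count * 100 / 135
  unflagged <- !out$flagged
  # zeros and exact-grain entries (0.74 = 1/135, 3.7 = 5/135, ...) pass;
  # printed one-decimal truncations (1.4 for 1.48, 2.9 for 2.96) are flagged
  expect_true(all(abs(back[unflagged] - cf$cf[unflagged]) <= 0.01))
  expect_true(all(out$flagged[cf$cf %in% c(1.4, 2.9, 4.4)]))
  expect_false(any(out$flagged[cf$cf %in% c(0, 0.74, 3.7)]))
})

test_that("marginalize conserves the grand total for every factor", {
  counts <- cf_to_counts(load_survey_cf())
  total <- sum(counts$count)
  for (by in c("season", "site", "tissue")) {
    expect_equal(sum(marginalize(counts, by)$count), total)
  }
  expect_error(marginalize(counts, "elevation"), "must be one of")
})

test_that("marginalize adds counts across cells (hand-checked toy)", {
  toy <- tibble::tibble(
    species = rep(c("a", "b"), 2), season = "winter",
    site = rep(1:2, each = 2), tissue = "leaf",
    count = c(1, 2, 3, 4)
  )
  out <- marginalize(toy, "season")
  expect_equal(out$count[match(c("a", "b"), out$species)], c(4, 6))
  # single-cell input marginalized by any factor is itself
  one <- toy[toy$site == 1, ]
  expect_equal(sort(marginalize(one, "tissue")$count), sort(one$count))
})

test_that("presence_absence thresholds at CF > 0 and is monotone", {
  cf <- toy_cf()
  sets <- presence_absence(cf, "site")
  expect_setequal(sets[["1"]], c("a", "b"))
  expect_equal(sets[["2"]], "b")
  # all-zero matrix gives empty sets
  zero <- dplyr::mutate(cf, cf = 0)
  expect_true(all(lengths(presence_absence(zero, "site")) == 0))
  # adding a nonzero entry never shrinks a presence set
  grown <- cf
  grown$cf[2] <- 5  # species "a" appears at site 2
  sets2 <- presence_absence(grown, "site")
  expect_setequal(sets2[["2"]], c("a", "b"))
  expect_true(all(sets[["1"]] %in% sets2[["1"]]))
  expect_true(all(sets[["2"]] %in% sets2[["2"]]))
})
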