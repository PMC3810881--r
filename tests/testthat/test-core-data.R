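test_that("occurrence tables round-trip through delimited text", {
  occ <- toy_occ()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_occurrence_matrix(occ, path)
  back <- read_occurrence_matrix(path)
  expect_identical(back$incidence, occ$incidence)
  expect_identical(back$range_flag, occ$range_flag)
  expect_identical(back$range_class, occ$range_class)
  expect_identical(dim(back$incidence), c(4L, 3L))
})

test_that("the reader rejects duplicates and non-binary cells by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tA\tB\trange_flag",
               "t1\t1\t0\tendemic",
               "t1\t0\t1\tnonendemic"), path)
  expect_error(read_occurrence_matrix(path), "t1")
  writeLines(c("taxon\tA\tB\trange_flag",
               "t1\t1\t2\tnonendemic"), path)
  expect_error(read_occurrence_matrix(path), "non-binary.*'B'")
})

test_that("rows flagged excluded are dropped on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tA\tB\trange_flag\texcluded",
               "t1\t1\t0\tnonendemic\t0",
               "t2\t0\t1\tnonendemic\t1"), path)
  occ <- read_occurrence_matrix(path)
  expect_identical(occ$taxa, "t1")
})

test_that("missing or invalid range flags name the offending taxon", {
  inc <- matrix(TRUE, 2L, 1L, dimnames = list(c("t1", "t2"), "A"))
  expect_error(occurrence_matrix(inc, c("endemic", NA)), "t2")
  inc2 <- matrix(TRUE, 1L, 1L, dimnames = list("tx", "A"))
  expect_error(occurrence_matrix(inc2, "endemic", NA_character_),
               "range_class")
})

test_that("merging ecoregions ORs incidence and sums areas", {
  occ <- toy_occ()
  merged <- merge_ecoregions(occ, c("A", "B"), "AB")
  expect_identical(merged$ecoregions, c("AB", "C"))
  # t1 present in A only, t2 in B (and C): both present in AB
  expect_true(merged$incidence["t1", "AB"])
  expect_true(merged$incidence["t2", "AB"])
  # absent from both stays absent
  inc <- occ$incidence; inc["t3", ] <- c(FALSE, FALSE, TRUE)
  occ2 <- occurrence_matrix(inc, occ$range_flag, occ$range_class)
  expect_false(merge_ecoregions(occ2, c("A", "B"), "AB")$incidence["t3", "AB"])
  info <- data.frame(id = c("A", "B", "C"), name = c("a", "b", "c"),
                     region = "r", in_hotspot = TRUE, in_baetic = TRUE,
                     area_km2 = c(100, 250, 50))
  mi <- merge_ecoregion_info(info, c("A", "B"), "AB")
  expect_equal(mi$area_km2[mi$id == "AB"], 350)
  grid <- data.frame(x_km = 1:3, y_km = 1, ecoregion = c("A", "B", "C"),
                     elev_m = 0)
  expect_identical(merge_cell_grid(grid, c("A", "B"), "AB")$ecoregion,
                   c("AB", "AB", "C"))
  expect_error(merge_ecoregions(occ, c("A", "Z"), "AZ"), "Z")
  expect_error(merge_ecoregions(occ, "A", "C"), "collides")
  # single-id merge acts as a rename
  expect_identical(merge_ecoregions(occ, "A", "A2")$ecoregions,
                   c("A2", "B", "C"))
})

test_that("endemism split partitions the flora exhaustively", {
  occ <- toy_occ()
  parts <- split_by_endemism(occ)
  expect_identical(sort(c(parts$endemic$taxa, parts$nonendemic$taxa)),
                   sort(occ$taxa))
  expect_identical(parts$endemic$ecoregions, parts$nonendemic$ecoregions)
  expect_identical(parts$endemic$ecoregions, occ$ecoregions)
  expect_true(all(parts$endemic$range_flag == "endemic"))
  pool <- printed_count_pool()
  pp <- split_by_endemism(pool$occ)
  expect_identical(length(pp$endemic$taxa), 667L)
  expect_identical(length(pp$endemic$taxa) + length(pp$nonendemic$taxa),
                   length(pool$occ$taxa))
  # all-endemic corner: empty nonendemic element
  inc <- matrix(TRUE, 2L, 1L, dimnames = list(c("t1", "t2"), "A"))
  all_end <- occurrence_matrix(inc, c("endemic", "endemic"),
                               c("both", "both"))
  expect_identical(length(split_by_endemism(all_end)$nonendemic$taxa), 0L)
})

test_that("merge and endemism split commute", {
  withr::local_seed(31)
  inc <- matrix(stats::runif(60) < 0.5, 12L, 5L,
                dimnames = list(sprintf("t%02d", 1:12),
                                LETTERS[1:5]))
  inc[1, ] <- TRUE
  occ <- occurrence_matrix(
    inc, rep(c("endemic", "nonendemic"), 6L),
    ifelse(rep(c(TRUE, FALSE), 6L), "both", NA))
  a <- split_by_endemism(merge_ecoregions(occ, c("B", "D"), "BD"))
  b <- lapply(split_by_endemism(occ), function(el)
    merge_ecoregions(el, c("B", "D"), "BD"))
  expect_identical(a$endemic$incidence, b$endemic$incidence)
  expect_identical(a$nonendemic$incidence, b$nonendemic$incidence)
})

test_that("high-elevation filtering applies the stated fractions", {
  grid <- rbind(
    data.frame(x_km = 1:10, y_km = 1, ecoregion = "high",
               elev_m = 2000),
    data.frame(x_km = 1:10, y_km = 2, ecoregion = "low",
               elev_m = 100),
    # 4% of 100 cells above 1500 m, 40% below 500 m: removed (needs 5%)
    data.frame(x_km = rep(1:10, 10), y_km = rep(3:12, each = 10),
               ecoregion = "marginal",
               elev_m = c(rep(1600, 4), rep(300, 40), rep(800, 56))))
  kept <- filter_high_elevation(grid)
  expect_identical(kept, "high")
  # marginal passes once the required fraction above drops to 4%
  expect_setequal(filter_high_elevation(grid, min_frac_above = 0.04),
                  c("high", "marginal"))
  # idempotence: filtering the retained subset keeps it unchanged
  sub <- grid[grid$ecoregion %in% kept, , drop = FALSE]
  expect_identical(filter_high_elevation(sub), kept)
})

test_that("pool summary reproduces the printed-count arithmetic", {
  pool <- printed_count_pool()
  s <- summarize_pool(pool$occ, pool$info)
  expect_identical(s$n_taxa, 4450L)
  expect_identical(s$n_hotspot, 4051L)
  expect_equal(s$hotspot_pct, 91)
  expect_identical(s$n_endemic, 667L)
  expect_equal(s$endemic_pct, 16.5)
  expect_equal(unname(as.vector(s$range_class_counts)),
               c(485L, 129L, 53L))
  expect_identical(sum(s$range_class_counts), s$n_endemic)
  # percentages recompute exactly from the summary's own counts
  expect_equal(s$hotspot_pct, round(100 * s$n_hotspot / s$n_taxa))
  expect_equal(s$endemic_pct,
               round(100 * s$n_endemic / s$n_hotspot, 1L))
})

test_that("distance matrices round-trip and enforce invariants", {
  d <- random_geo_dm(6L, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, path)
  expect_equal(unclass(read_distance_matrix(path)), unclass(d),
               tolerance = 1e-12)
  bad <- unclass(d); bad[1L, 2L] <- bad[1L, 2L] + 1
  expect_error(distance_matrix(bad), "symmetric")
  bad2 <- unclass(d); diag(bad2) <- 1
  expect_error(distance_matrix(bad2), "diagonal")
})
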