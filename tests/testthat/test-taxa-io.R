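test_that("a well-formed wcvp checklist reads row-for-row", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_wcvp_fixture(f)
  rec <- read_checklist(f, "wcvp")
  expect_equal(nrow(rec), 3L)
  rep <- read_report(rec)
  expect_equal(rep$dropped_numeric_region, 0L)
  expect_equal(rep$rows_kept, rep$rows_in)
  expect_equal(rec$is_hybrid, c(FALSE, TRUE, FALSE))
  expect_equal(rec$rank, c("species", "hybrid_species", "species"))
  expect_true(all(rec$name_status == "accepted"))
})

test_that("numeric region codes are dropped and counted, not errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- tibble::tibble(
    taxon_name = c("Aus bus", "Aus cus"), genus = "Aus", rank = "Species",
    species_hybrid = "", taxon_status = "Accepted",
    region_code = c("GER", "2"), introduced = 0L
  )
  write_wcvp_fixture(f, rows)
  rec <- read_checklist(f, "wcvp")
  expect_equal(nrow(rec), 1L)
  expect_equal(read_report(rec)$dropped_numeric_region, 1L)
  expect_equal(read_report(rec)$rows_kept + 1L, read_report(rec)$rows_in)
})

test_that("a missing hybrid-flag column is a format error naming it", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- tibble::tibble(taxon_name = "Aus bus", genus = "Aus",
                         rank = "Species", taxon_status = "Accepted",
                         region_code = "GER")
  readr::write_csv(rows, f)
  expect_error(read_checklist(f, "wcvp"), "species_hybrid")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("", f2)
  expect_error(read_checklist(f2, "wcvp"), "empty")
})

test_that("glonaf dialect maps statuses and artificial implies hybrid", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_glonaf_fixture(f)
  rec <- read_checklist(f, "glonaf")
  expect_equal(rec$naturalization_status, c("naturalized", "alien"))
  expect_false(any(rec$is_artificial_hybrid & !rec$is_hybrid))
})

test_that("tab-delimited checklists are auto-detected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- tibble::tibble(
    taxon_name = "Aus bus", genus = "Aus", rank = "Species",
    species_hybrid = "", taxon_status = "Accepted", region_code = "GER"
  )
  readr::write_tsv(rows, f)
  expect_equal(nrow(read_checklist(f, "wcvp")), 1L)
})

test_that("newick trees read with validation of tips and branch lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", f)
  tr <- read_tree(f)
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(sum(tr$edge.length), 6)

  writeLines("((A:1,A:1):1,B:2);", f)
  expect_error(read_tree(f), "duplicate tip")

  writeLines("((A:0,B:1):1,C:2);", f)
  tr0 <- read_tree(f)
  expect_equal(read_report(tr0)$n_zero_length_terminal, 1L)

  writeLines("((A:1,B:1", f)
  expect_error(read_tree(f), "parse|Newick")
})

test_that("ascii rasters read, validate the HFI range, and round-trip", {
  f <- withr::local_tempfile(fileext = ".asc")
  g <- toy_grid(matrix(10, 10, 10))
  write_raster(g, f)
  g2 <- read_raster(f)
  expect_equal(range(g2$values), c(10, 10))
  expect_equal(g2$values, g$values)
  expect_equal(g2$cell_size, g$cell_size)
  expect_equal(g2$origin, g$origin)

  m <- matrix(10, 3, 3); m[2, 2] <- 51
  write_raster(toy_grid(m), f)
  expect_error(read_raster(f), "\\[0, 50\\]")

  m <- matrix(c(NA, 10, 20, 30, NA, 40, 5, 15, 25), 3, 3)
  write_raster(toy_grid(m), f)
  g3 <- read_raster(f)
  expect_equal(min(g3$values, na.rm = TRUE), 5)
  expect_equal(max(g3$values, na.rm = TRUE), 40)
  expect_equal(sum(is.na(g3$values)), 2L)

  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "3 abc"), f)
  expect_error(read_raster(f), "non-numeric")
})

test_that("occupancy pairs deduplicate on read with an accounting report", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    taxon_name = c("Aus bus", "Aus bus", "Aus bus"),
    hectad_code = c("AA00", "AA00", "AA01")
  ), f)
  occ <- read_occurrences(f)
  expect_equal(nrow(occ), 2L)
  expect_equal(read_report(occ)$dropped_duplicate, 1L)
})

test_that("hectad rectangles validate their geometry", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(hectad_code = "AA00", xmin = 0, ymin = 0,
                                  xmax = 10, ymax = 10), f)
  expect_equal(nrow(read_hectad_polygons(f)), 1L)
  readr::write_csv(tibble::tibble(hectad_code = "AA00", xmin = 10, ymin = 0,
                                  xmax = 0, ymax = 10), f)
  expect_error(read_hectad_polygons(f), "degenerate")
})

test_that("name normalization squeezes whitespace and genus extraction strips the hybrid sign", {
  expect_equal(normalize_taxon_name("  Aus   bus "), "Aus bus")
  expect_equal(genus_from_name(c("Aus bus", "× Aus bus", "×Aus bus")),
               c("Aus", "Aus", "Aus"))
})
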