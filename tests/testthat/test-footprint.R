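test_that("hectad zonal means honour the cell-center containment rule", {
  g <- toy_grid(matrix(10, 20, 20))
  poly <- toy_polygons(tibble::tibble(hectad_code = "AA00", xmin = 0,
                                      ymin = 0, xmax = 10000, ymax = 10000))
  hf <- hectad_mean_hfi(g, poly)
  expect_equal(hf$mean_hfi, 10)
  expect_equal(hf$n_cells, 100L)

  # a 2x2-cell hectad over values 0/10/20/30 averages to 15
  m <- matrix(c(0, 20, 10, 30), 2, 2)
  g2 <- toy_grid(m, cell_size = 1000)
  poly2 <- toy_polygons(tibble::tibble(hectad_code = "Q", xmin = 0,
                                       ymin = 0, xmax = 2000, ymax = 2000))
  expect_equal(hectad_mean_hfi(g2, poly2)$mean_hfi, 15)

  # straddling polygon containing only the center of the 10-valued cell
  g3 <- toy_grid(matrix(c(10, 30), 1, 2), cell_size = 1000)
  poly3 <- toy_polygons(tibble::tibble(hectad_code = "S", xmin = 0,
                                       ymin = 0, xmax = 1200, ymax = 1000))
  expect_equal(hectad_mean_hfi(g3, poly3)$mean_hfi, 10)
})

test_that("shared edges assign a cell to exactly one hectad (half-open rule)", {
  g <- toy_grid(matrix(1, 4, 4), cell_size = 1000)
  poly <- toy_polygons(tibble::tibble(
    hectad_code = c("L", "R"),
    xmin = c(0, 2000), ymin = 0, xmax = c(2000, 4000), ymax = 4000
  ))
  hf <- hectad_mean_hfi(g, poly)
  expect_equal(sum(hf$n_cells), 16L)
  expect_equal(hf$n_cells, c(8L, 8L))
})

test_that("missing cells are excluded and empty hectads reported, CRS mismatch errors", {
  m <- matrix(c(NA, NA, 10, 30), 2, 2)
  g <- toy_grid(m, cell_size = 1000)
  poly <- toy_polygons(tibble::tibble(
    hectad_code = c("H1", "H2"),
    xmin = c(0, 5000), ymin = c(0, 5000), xmax = c(2000, 6000),
    ymax = c(2000, 6000)
  ))
  hf <- hectad_mean_hfi(g, poly)
  expect_equal(nrow(hf), 1L)
  expect_equal(hf$mean_hfi, 20)  # mean of 10 and 30, NAs dropped
  expect_equal(read_report(hf)$dropped_no_cells, 1L)

  poly_bad <- poly
  attr(poly_bad, "crs_tag") <- "mollweide"
  expect_error(hectad_mean_hfi(g, poly_bad), "mismatch")
})

test_that("the occupancy rule includes hybrids in strictly more than 10 hectads", {
  occ <- purrr::map_dfr(list(c("H ten", 10), c("H eleven", 11),
                             c("H common", 34)),
                        function(p) tibble::tibble(
                          taxon_name = p[1],
                          hectad_code = sprintf("X%02d", seq_len(as.integer(p[2])))
                        ))
  trips <- tibble::tibble(
    triplet_id = c("T1", "T2", "T3"),
    hybrid_name = c("H ten", "H eleven", "H common"),
    native_name = paste("N", 1:3), neophyte_name = paste("E", 1:3)
  )
  out <- apply_occupancy_rule(trips, occ)
  expect_equal(out$included, c(FALSE, TRUE, TRUE))
  expect_equal(out$n_hectads_hybrid, c(10L, 11L, 34L))
})

test_that("triplet observations join occupied hectads to footprint values", {
  trips <- tibble::tibble(triplet_id = "T1", hybrid_name = "H a",
                          native_name = "N a", neophyte_name = "E a",
                          included = TRUE)
  occ <- tibble::tibble(
    taxon_name = c("H a", "H a", "H a", "N a", "E a"),
    hectad_code = c("AA", "BB", "CC", "AA", "ZZ")
  )
  hfi <- tibble::tibble(hectad_code = c("AA", "BB"),
                        mean_hfi = c(20, 30), n_cells = 100L)
  obs <- triplet_observations(trips, occ, hfi)
  expect_equal(nrow(obs[obs$taxon_type == "hybrid", ]), 2L)  # CC has no HFI
  # the shared hectad yields one observation per member
  expect_equal(sum(obs$hectad_code == "AA"), 2L)
  # the neophyte's only hectad has no footprint value: reported
  expect_equal(read_report(obs)$taxa_empty_join, 1L)
  expect_match(read_report(obs)$empty_taxa, "E a")
  # join integrity: every observation carries its hectad's mean
  expect_equal(obs$hfi,
               hfi$mean_hfi[match(obs$hectad_code, hfi$hectad_code)])
})

test_that("range coverage flags use strict exceedance and skip incomplete triplets", {
  mk_obs <- function(id, type, vals) tibble::tibble(
    triplet_id = id, taxon_type = type,
    hectad_code = sprintf("%s%02d", type, seq_along(vals)), hfi = vals
  )
  obs <- dplyr::bind_rows(
    mk_obs("T1", "hybrid", c(20, 30)), mk_obs("T1", "native", c(5, 25)),
    mk_obs("T1", "neophyte", c(10, 28)),
    mk_obs("T2", "hybrid", c(10, 30)), mk_obs("T2", "native", c(10, 35)),
    mk_obs("T2", "neophyte", c(12, 28)),
    mk_obs("T3", "hybrid", c(10, 30)), mk_obs("T3", "native", c(10, 30)),
    mk_obs("T3", "neophyte", c(10, 30)),
    mk_obs("T4", "hybrid", c(15, 22))  # parents unobserved: skipped
  )
  st <- range_coverage_stats(obs)
  expect_equal(nrow(st), 3L)
  expect_true(st$hybrid_min_above_native_min[st$triplet_id == "T1"])
  expect_true(st$hybrid_max_above_both_parents[st$triplet_id == "T1"])
  expect_false(st$hybrid_min_above_native_min[st$triplet_id == "T2"])
  expect_false(st$hybrid_max_above_both_parents[st$triplet_id == "T2"])
  # identical distributions: equality is not exceedance
  expect_false(any(unlist(st[st$triplet_id == "T3", -1])))
  counts <- attr(st, "counts")
  expect_equal(counts$n_triplets, 3L)
  expect_lte(counts$n_min_above, counts$n_triplets)
  expect_equal(attr(st, "read_report")$skipped_missing_type, 1L)
})
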