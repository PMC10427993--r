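test_that("GDP crosswalk averages years, copies to split regions, averages shared ones", {
  gdp <- tibble::tibble(
    political_code = c("P1", "P1", "P2", "P3"),
    year = c(2000, 2010, 2005, 2005),
    gdp = c(100, 200, 100, 300)
  )
  mapping <- tibble::tibble(
    political_code = c("P1", "P1", "P2", "P3"),
    region_code = c("AAA", "AAB", "SHR", "SHR")
  )
  out <- gdp_crosswalk(gdp, mapping)
  expect_equal(out$gdp_per_capita[out$region_code == "AAA"], 150)
  expect_equal(out$gdp_per_capita[out$region_code == "AAB"], 150)
  expect_equal(out$gdp_per_capita[out$region_code == "SHR"], 200)
})

test_that("an unmapped region is flagged missing, never zero-filled", {
  gdp <- tibble::tibble(political_code = "P1", year = 2000, gdp = 100)
  mapping <- tibble::tibble(political_code = c("P1", "P9"),
                            region_code = c("AAA", "ZZZ"))
  out <- gdp_crosswalk(gdp, mapping)
  z <- out[out$region_code == "ZZZ", ]
  expect_true(is.na(z$gdp_per_capita))
  expect_true(z$gdp_missing)
})

test_that("taxonomist effort weights authors by reciprocal mean range size", {
  # one author, one single-region taxon: the region scores exactly 1
  d1 <- tibble::tibble(author = "Smith", taxon_name = "Aus bus")
  p1 <- tibble::tibble(taxon_name = "Aus bus", region_code = "AAA")
  out <- taxonomist_effort(d1, p1)
  expect_equal(out$taxonomist_effort, 1)

  # one author, two taxa present in the focal region with range sizes 2
  # and 4: contribution 1 / mean(2, 4) = 1/3
  d2 <- tibble::tibble(author = "Smith",
                       taxon_name = c("Aus bus", "Aus cus"))
  p2 <- tibble::tibble(
    taxon_name = c("Aus bus", "Aus bus", "Aus cus", "Aus cus", "Aus cus",
                   "Aus cus"),
    region_code = c("AAA", "BBB", "AAA", "BBB", "CCC", "DDD")
  )
  out2 <- taxonomist_effort(d2, p2)
  expect_equal(out2$taxonomist_effort[out2$region_code == "AAA"], 1 / 3,
               tolerance = 1e-12)

  # an author with no described taxon in a region contributes nothing there
  expect_false("EEE" %in% out2$region_code)
})

test_that("described taxa without presence records are a validation error", {
  d <- tibble::tibble(author = "Smith", taxon_name = "Ghostus nullus")
  p <- tibble::tibble(taxon_name = "Aus bus", region_code = "AAA")
  expect_error(taxonomist_effort(d, p), "range size 0")
})

test_that("author contributions lie in (0, 1] and shrink with growing ranges", {
  set.seed(7)
  regions <- sprintf("R%02d", 1:8)
  taxa <- sprintf("Taxon %02d", 1:20)
  d <- tibble::tibble(author = sample(c("A", "B", "C"), 20, TRUE),
                      taxon_name = taxa)
  presence <- purrr::map_dfr(taxa, function(t) tibble::tibble(
    taxon_name = t,
    region_code = sample(regions, sample(1:5, 1))
  ))
  out <- taxonomist_effort(d, presence)
  per_author <- d |>
    dplyr::inner_join(presence, by = "taxon_name",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$author, .data$region_code)
  # region score is a sum of per-author contributions each in (0, 1]
  expect_true(all(out$taxonomist_effort > 0))
  expect_true(all(out$taxonomist_effort <=
                    out$n_authors + 1e-12))

  # shrinking every range to a single region can only raise every score
  shrunk <- presence |> dplyr::group_by(taxon_name) |> dplyr::slice(1) |>
    dplyr::ungroup()
  out_shrunk <- taxonomist_effort(d, shrunk)
  joined <- dplyr::inner_join(out, out_shrunk, by = "region_code",
                              suffix = c("", "_shrunk"))
  expect_true(all(joined$taxonomist_effort_shrunk >=
                    joined$taxonomist_effort - 1e-12))
})

test_that("covariate assembly keeps missing GDP flagged and zero-fills only effort", {
  gdp <- gdp_crosswalk(
    tibble::tibble(political_code = "P1", year = 2000, gdp = 100),
    tibble::tibble(political_code = "P1", region_code = "AAA")
  )
  eff <- taxonomist_effort(
    tibble::tibble(author = "Smith", taxon_name = "Aus bus"),
    tibble::tibble(taxon_name = "Aus bus", region_code = "AAA")
  )
  areas <- tibble::tibble(region_code = c("AAA", "BBB"),
                          area_km2 = c(1000, 2000))
  cov <- effort_covariates(gdp, eff, areas)
  expect_equal(nrow(cov), 2L)
  b <- cov[cov$region_code == "BBB", ]
  expect_true(is.na(b$gdp_per_capita) && b$gdp_missing)
  expect_equal(b$taxonomist_effort, 0)
  expect_error(
    effort_covariates(gdp, eff, tibble::tibble(region_code = "AAA",
                                               area_km2 = -1)),
    "positive")
})
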