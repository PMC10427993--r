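test_that("hybrid filter keeps accepted natural hybrids only", {
  rec <- toy_taxon_records(
    list(taxon_name = "A ×a", is_hybrid = TRUE),
    list(taxon_name = "A ×b", is_hybrid = TRUE,
         is_artificial_hybrid = TRUE),
    list(taxon_name = "A ×c", is_hybrid = TRUE,
         name_status = "not_accepted"),
    list(taxon_name = "A d")
  )
  out <- filter_hybrids(rec)
  expect_equal(out$taxon_name, "A ×a")
})

test_that("neophyte filter keeps accepted naturalized non-hybrids, including varieties", {
  rec <- toy_taxon_records(
    list(taxon_name = "N a", naturalization_status = "naturalized"),
    list(taxon_name = "N b", naturalization_status = "alien"),
    list(taxon_name = "N ×c", naturalization_status = "naturalized",
         is_hybrid = TRUE),
    list(taxon_name = "N d", naturalization_status = "naturalized",
         name_status = "not_accepted"),
    list(taxon_name = "N a var. v", rank = "variety",
         naturalization_status = "naturalized")
  )
  out <- filter_neophytes(rec)
  expect_setequal(out$taxon_name, c("N a", "N a var. v"))
})

test_that("both filters are idempotent on generated record tables", {
  set.seed(11)
  for (i in 1:5) {
    rec <- toy_taxon_records()[0, ]
    rec <- purrr::map_dfr(1:50, function(j) {
      toy_taxon_records(list(
        taxon_name = paste("T", j),
        is_hybrid = runif(1) < 0.4,
        is_artificial_hybrid = runif(1) < 0.1,
        name_status = sample(c("accepted", "not_accepted"), 1),
        naturalization_status = sample(c("naturalized", "alien",
                                         "native"), 1)
      ))
    })
    rec$is_hybrid <- rec$is_hybrid | rec$is_artificial_hybrid
    expect_identical(filter_hybrids(filter_hybrids(rec)),
                     filter_hybrids(rec))
    expect_identical(filter_neophytes(filter_neophytes(rec)),
                     filter_neophytes(rec))
  }
})

test_that("country tallies count distinct names and drop double-absent regions", {
  hyb <- toy_taxon_records(
    list(taxon_name = "H a", region_code = "GER"),
    list(taxon_name = "H b", region_code = "GER"),
    list(taxon_name = "H b", region_code = "GER")  # duplicate listing
  )
  neo <- purrr::map_dfr(1:3, function(i)
    toy_taxon_records(list(taxon_name = paste("N", i),
                           region_code = "GER")))
  nat <- dplyr::bind_rows(
    purrr::map_dfr(1:10, function(i)
      toy_taxon_records(list(taxon_name = paste("S", i),
                             region_code = "GER"))),
    toy_taxon_records(list(taxon_name = "S x", region_code = "FRA"))
  )
  tal <- tally_by_country(hyb, neo, nat)
  expect_equal(nrow(tal), 1L)  # FRA has neither hybrids nor neophytes
  expect_equal(tal$region_code, "GER")
  expect_equal(tal$n_hybrids, 2L)
  expect_equal(tal$n_neophytes, 3L)
  expect_equal(tal$n_natives, 10L)
  expect_equal(tal$hybrid_ratio, 0.2)
  expect_equal(tal$neophyte_ratio, 0.3)
  expect_equal(read_report(tal)$dropped_no_hybrid_no_neophyte, 1L)
  expect_true(all(tal$region_code %in%
                    c(hyb$region_code, neo$region_code, nat$region_code)))
})

test_that("genus tallies reproduce the published ratio examples and may exceed 1", {
  equisetum_hyb <- purrr::map_dfr(1:26, function(i)
    toy_taxon_records(list(taxon_name = sprintf("Equisetum ×h%02d", i),
                           genus = "Equisetum", is_hybrid = TRUE)))
  equisetum_sp <- purrr::map_dfr(1:18, function(i)
    toy_taxon_records(list(taxon_name = sprintf("Equisetum s%02d", i),
                           genus = "Equisetum")))
  robinia_sp <- purrr::map_dfr(1:4, function(i)
    toy_taxon_records(list(taxon_name = sprintf("Robinia s%02d", i),
                           genus = "Robinia")))
  robinia_neo <- purrr::map_dfr(1:6, function(i)
    toy_taxon_records(list(taxon_name = sprintf("Robinia n%02d", i),
                           genus = "Robinia",
                           rank = ifelse(i > 4, "variety", "species"),
                           naturalization_status = "naturalized")))
  quietus_sp <- purrr::map_dfr(1:10, function(i)
    toy_taxon_records(list(taxon_name = sprintf("Quietus s%02d", i),
                           genus = "Quietus")))

  tal <- tally_by_genus(
    hybrids = equisetum_hyb,
    neophytes = robinia_neo,
    accepted_species = dplyr::bind_rows(equisetum_sp, robinia_sp,
                                        quietus_sp, equisetum_hyb)
  )
  eq <- tal[tal$genus == "Equisetum", ]
  expect_equal(eq$n_species_accepted, 18L)   # hybrids never counted as species
  expect_equal(eq$n_hybrids, 26L)
  expect_equal(eq$hybrid_ratio, 26 / 18, tolerance = 1e-12)
  rb <- tal[tal$genus == "Robinia", ]
  expect_equal(rb$neophyte_ratio, 1.5)
  qu <- tal[tal$genus == "Quietus", ]
  expect_equal(c(qu$hybrid_ratio, qu$neophyte_ratio), c(0, 0))

  # species totals reconcile with distinct accepted species-rank names
  pool <- dplyr::bind_rows(equisetum_sp, robinia_sp, quietus_sp)
  expect_equal(sum(tal$n_species_accepted),
               dplyr::n_distinct(pool$taxon_name))
})

test_that("a genus with hybrids but no accepted species is flagged, not dropped", {
  hyb <- toy_taxon_records(list(taxon_name = "Ghost ×a", genus = "Ghost",
                                is_hybrid = TRUE))
  tal <- tally_by_genus(hyb, hyb[0, ], hyb[0, ])
  expect_equal(nrow(tal), 1L)
  expect_true(tal$ratio_undefined)
  expect_true(is.na(tal$hybrid_ratio))
})
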