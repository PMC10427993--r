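# In-code fixture builders shared across the suite. Everything is generated
# at test time; nothing is read from disk except files the tests write.

toy_taxon_records <- function(...) {
  rows <- list(...)
  defaults <- list(taxon_name = "Aus bus", genus = "Aus", rank = "species",
                   is_hybrid = FALSE, is_artificial_hybrid = FALSE,
                   name_status = "accepted",
                   naturalization_status = "native", region_code = "ABC")
  purrr::map_dfr(rows, function(r) {
    out <- defaults
    out[names(r)] <- r
    tibble::as_tibble(out)
  })
}

write_wcvp_fixture <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- tibble::tibble(
      taxon_name = c("Aus bus", "Aus cus", "Bus dus"),
      genus = c("Aus", "Aus", "Bus"),
      rank = "Species",
      species_hybrid = c("", "×", ""),
      taxon_status = "Accepted",
      region_code = c("GER", "GER", "FRA"),
      introduced = 0L
    )
  }
  readr::write_csv(rows, path)
  path
}

write_glonaf_fixture <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- tibble::tibble(
      taxon_name = c("Cus eus", "Cus fus"),
      genus = "Cus",
      name_status = "accepted",
      status = c("naturalized", "alien"),
      hybrid = 0L,
      region_code = c("GER", "FRA")
    )
  }
  readr::write_csv(rows, path)
  path
}

# balanced 4-tip tree used in the hand-solved Blomberg's K example
balanced4 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

toy_grid <- function(values, cell_size = 1000, origin = c(x = 0, y = 0),
                     nodata = -9999) {
  structure(list(values = values, cell_size = cell_size, origin = origin,
                 nodata = nodata, crs_tag = "planar"),
            class = "footprint_grid")
}

toy_polygons <- function(df) {
  attr(df, "crs_tag") <- "planar"
  df
}

small_world_config <- function(seed = 42L) {
  world_config(n_regions = 60L, n_genera = 240L, n_triplets = 12L,
               n_excluded_triplets = 2L, n_hectads_x = 15L,
               n_hectads_y = 15L, seed = seed)
}
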