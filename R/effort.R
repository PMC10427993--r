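#' Crosswalk political-country GDP onto botanical countries
#'
#' Per-capita GDP series are recorded for political countries; the analysis
#' units are botanical countries (TDWG Level 3). GDP is first averaged over
#' the available years within each political country; every botanical region
#' mapped to a single political country inherits that mean, and a botanical
#' region spanning several political countries receives the unweighted mean
#' of their means. Regions with no mapped political country are flagged
#' missing (`NA`), never zero-filled.
#'
#' @param gdp_table Tibble with columns `political_code`, `year`, `gdp`
#'   (gaps as missing rows or `NA` values are tolerated).
#' @param mapping Tibble with columns `political_code`, `region_code`
#'   (many-to-many pairs).
#' @return A tibble `region_code`, `gdp_per_capita`, `n_political`,
#'   `gdp_missing`; one row per region in `mapping`.
#' @export
gdp_crosswalk <- function(gdp_table, mapping) {
  stopifnot(all(c("political_code", "year", "gdp") %in% names(gdp_table)),
            all(c("political_code", "region_code") %in% names(mapping)))
  pol <- gdp_table |>
    dplyr::filter(!is.na(.data$gdp)) |>
    dplyr::group_by(.data$political_code) |>
    dplyr::summarise(gdp_mean = mean(.data$gdp), .groups = "drop")
  mapping |>
    dplyr::distinct(.data$political_code, .data$region_code) |>
    dplyr::left_join(pol, by = "political_code") |>
    dplyr::group_by(.data$region_code) |>
    dplyr::summarise(
      gdp_per_capita = if (all(is.na(.data$gdp_mean))) NA_real_
                       else mean(.data$gdp_mean, na.rm = TRUE),
      n_political = dplyr::n_distinct(.data$political_code),
      .groups = "drop"
    ) |>
    dplyr::mutate(gdp_missing = is.na(.data$gdp_per_capita)) |>
    dplyr::arrange(.data$region_code)
}

#' Range-weighted taxonomist effort per botanical country
#'
#' Counts the authors who first described plant species present in a region,
#' weighting each author by the reciprocal of the mean range size of the
#' species they described that occur there. An author is credited to a
#' region if at least one species they described is present; their
#' contribution to that region is `1 / mean(range sizes of their described
#' species present there)`, where a species' range size is the number of
#' regions it occupies. The reciprocal weighting damps the spillage effect
#' of wide-ranged species crediting an author to many regions; every
#' individual contribution lies in (0, 1].
#'
#' @param descriptions Tibble with columns `author`, `taxon_name`: who first
#'   described what.
#' @param presence Tibble with columns `taxon_name`, `region_code`: where
#'   each described taxon occurs.
#' @return A tibble `region_code`, `taxonomist_effort`, `n_authors`.
#' @export
taxonomist_effort <- function(descriptions, presence) {
  stopifnot(all(c("author", "taxon_name") %in% names(descriptions)),
            all(c("taxon_name", "region_code") %in% names(presence)))
  descriptions <- dplyr::distinct(descriptions, .data$author, .data$taxon_name)
  presence <- dplyr::distinct(presence, .data$taxon_name, .data$region_code)
  ranges <- presence |>
    dplyr::count(.data$taxon_name, name = "range_size")
  orphans <- setdiff(descriptions$taxon_name, ranges$taxon_name)
  if (length(orphans) > 0L) {
    stop("described taxa with range size 0 (no presence records): ",
         paste(head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  descriptions |>
    dplyr::inner_join(presence, by = "taxon_name",
                      relationship = "many-to-many") |>
    dplyr::inner_join(ranges, by = "taxon_name") |>
    dplyr::group_by(.data$author, .data$region_code) |>
    dplyr::summarise(contribution = 1 / mean(.data$range_size),
                     .groups = "drop") |>
    dplyr::group_by(.data$region_code) |>
    dplyr::summarise(taxonomist_effort = sum(.data$contribution),
                     n_authors = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$region_code)
}

#' Assemble the per-region effort covariates
#'
#' Joins the GDP crosswalk, the taxonomist-effort scores, and the region
#' areas into one covariate table. Regions present in `areas` but absent
#' from the effort table score zero effort (no credited author); missing GDP
#' stays `NA` and is flagged.
#'
#' @param gdp Output of [gdp_crosswalk()].
#' @param effort Output of [taxonomist_effort()].
#' @param areas Tibble with columns `region_code`, `area_km2`.
#' @return A tibble `region_code`, `gdp_per_capita`, `gdp_missing`,
#'   `taxonomist_effort`, `area_km2`.
#' @export
effort_covariates <- function(gdp, effort, areas) {
  stopifnot(all(c("region_code", "area_km2") %in% names(areas)))
  if (any(!is.finite(areas$area_km2)) || any(areas$area_km2 <= 0)) {
    stop("region areas must be positive and finite", call. = FALSE)
  }
  areas |>
    dplyr::distinct(.data$region_code, .data$area_km2) |>
    dplyr::left_join(dplyr::select(gdp, "region_code", "gdp_per_capita",
                                   "gdp_missing"),
                     by = "region_code") |>
    dplyr::left_join(dplyr::select(effort, "region_code",
                                   "taxonomist_effort"),
                     by = "region_code") |>
    dplyr::mutate(
      gdp_missing = dplyr::coalesce(.data$gdp_missing, TRUE),
      taxonomist_effort = dplyr::coalesce(.data$taxonomist_effort, 0)
    ) |>
    dplyr::arrange(.data$region_code)
}
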