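#' Retain accepted natural interspecific hybrids
#'
#' Applies the hybrid inclusion rule to a WCVP-dialect record table: keep
#' records that are interspecific hybrids, are not of artificial
#' (cultivation) origin, and carry an accepted name. Idempotent.
#'
#' @param records A taxon-record tibble from [read_checklist()].
#' @return The retained rows.
#' @export
filter_hybrids <- function(records) {
  dplyr::filter(records,
                .data$is_hybrid,
                !.data$is_artificial_hybrid,
                .data$name_status == "accepted")
}

#' Retain accepted, naturalized, non-hybrid neophytes
#'
#' Applies the neophyte inclusion rule to a GloNaF-dialect record table:
#' keep accepted names whose status is naturalized (records listed merely as
#' aliens — taxa not known to be established and self-sustaining — are
#' removed) and that are not themselves hybrids, so that hybrid incidence is
#' never regressed on hybrids. Infraspecific ranks (e.g. naturalized
#' varieties) are retained, since their naturalizations equally present
#' hybridization opportunities. Idempotent.
#'
#' @param records A taxon-record tibble from [read_checklist()].
#' @return The retained rows.
#' @export
filter_neophytes <- function(records) {
  dplyr::filter(records,
                .data$name_status == "accepted",
                .data$naturalization_status == "naturalized",
                !.data$is_hybrid)
}

#' Tally hybrids, neophytes and natives per botanical country
#'
#' Counts distinct taxon names per TDWG Level-3 region in each of the three
#' inputs and forms incidence ratios against the native count. Regions that
#' record neither hybrids nor neophytes are dropped: absence from both
#' sources more likely reflects a data-mobilization gap than a true zero.
#'
#' @param hybrids,neophytes,natives Taxon-record tibbles (typically the
#'   outputs of [filter_hybrids()], [filter_neophytes()], and the accepted
#'   native species of the checklist).
#' @return A tibble with one row per retained region: `region_code`,
#'   `n_hybrids`, `n_neophytes`, `n_natives`, `hybrid_ratio`,
#'   `neophyte_ratio`. Ratios are `NA` where `n_natives` is zero. A
#'   `read_report` attribute counts the dropped regions.
#' @export
tally_by_country <- function(hybrids, neophytes, natives) {
  count_regions <- function(x, nm) {
    x |>
      dplyr::distinct(.data$region_code, .data$taxon_name) |>
      dplyr::count(.data$region_code, name = nm)
  }
  tal <- count_regions(hybrids, "n_hybrids") |>
    dplyr::full_join(count_regions(neophytes, "n_neophytes"),
                     by = "region_code") |>
    dplyr::full_join(count_regions(natives, "n_natives"),
                     by = "region_code") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                \(v) dplyr::coalesce(v, 0L)))
  n_all <- nrow(tal)
  tal <- dplyr::filter(tal, .data$n_hybrids > 0 | .data$n_neophytes > 0)
  tal <- tal |>
    dplyr::mutate(
      hybrid_ratio = ifelse(.data$n_natives > 0,
                            .data$n_hybrids / .data$n_natives, NA_real_),
      neophyte_ratio = ifelse(.data$n_natives > 0,
                              .data$n_neophytes / .data$n_natives, NA_real_)
    ) |>
    dplyr::arrange(.data$region_code)
  attr(tal, "read_report") <- tibble(
    regions_in = n_all, regions_kept = nrow(tal),
    dropped_no_hybrid_no_neophyte = n_all - nrow(tal)
  )
  tal
}

#' Tally hybrids, neophytes and accepted species per genus
#'
#' `n_species_accepted` counts distinct accepted names of rank species,
#' excluding hybrids and all infraspecific ranks (varieties, subvarieties,
#' convarieties, forms, subforms, subspecies). Hybrid and neophyte counts
#' come from the filtered WCVP and GloNaF records (neophyte varieties are
#' included). Incidence ratios use the accepted-species count as
#' denominator; they may exceed 1 (e.g. a genus with 18 accepted species and
#' 26 hybrids has hybrid ratio 1.44) and are reported as-is, never clamped.
#'
#' @param hybrids Filtered hybrid records ([filter_hybrids()]).
#' @param neophytes Filtered neophyte records ([filter_neophytes()]).
#' @param accepted_species WCVP-dialect records from which accepted species
#'   are counted.
#' @return A tibble: `genus`, `n_species_accepted`, `n_hybrids`,
#'   `n_neophytes`, `hybrid_ratio`, `neophyte_ratio`, `ratio_undefined`
#'   (TRUE where the species denominator is zero).
#' @export
tally_by_genus <- function(hybrids, neophytes, accepted_species) {
  count_genus <- function(x, nm) {
    x |>
      dplyr::distinct(.data$genus, .data$taxon_name) |>
      dplyr::count(.data$genus, name = nm)
  }
  species <- accepted_species |>
    dplyr::filter(.data$name_status == "accepted",
                  .data$rank == "species",
                  !.data$is_hybrid)
  tal <- count_genus(species, "n_species_accepted") |>
    dplyr::full_join(count_genus(hybrids, "n_hybrids"), by = "genus") |>
    dplyr::full_join(count_genus(neophytes, "n_neophytes"), by = "genus") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                \(v) dplyr::coalesce(v, 0L))) |>
    dplyr::mutate(
      ratio_undefined = .data$n_species_accepted == 0L,
      hybrid_ratio = ifelse(.data$ratio_undefined, NA_real_,
                            .data$n_hybrids / .data$n_species_accepted),
      neophyte_ratio = ifelse(.data$ratio_undefined, NA_real_,
                              .data$n_neophytes / .data$n_species_accepted)
    ) |>
    dplyr::arrange(.data$genus)
  tal
}
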