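#' Summarise congener-encounter opportunities at naturalization events
#'
#' A naturalization event is one (neophyte taxon, region) pair. The event
#' offers a hybridization opportunity when a native congener — a species of
#' the same genus — is present in the invaded botanical country. The summary
#' reports both the event-level fraction and the species-level fraction (a
#' neophyte species counts as soon as at least one of its events meets a
#' congener).
#'
#' @param neophyte_events Tibble with columns `taxon_name`, `genus`,
#'   `region_code`: one row per naturalization event (duplicates collapsed).
#' @param native_presence Tibble with columns `genus`, `region_code`: where
#'   native members of each genus occur. Must not include the neophyte
#'   itself.
#' @return A one-row tibble: `n_events`, `n_events_with_congener`,
#'   `event_fraction`, `n_species`, `n_species_with_congener`,
#'   `species_fraction`.
#' @export
encounter_summary <- function(neophyte_events, native_presence) {
  stopifnot(all(c("taxon_name", "genus", "region_code") %in%
                  names(neophyte_events)),
            all(c("genus", "region_code") %in% names(native_presence)))
  ev <- dplyr::distinct(neophyte_events, .data$taxon_name, .data$genus,
                        .data$region_code)
  np <- native_presence |>
    dplyr::distinct(.data$genus, .data$region_code) |>
    dplyr::mutate(with_congener = TRUE)
  ev <- ev |>
    dplyr::left_join(np, by = c("genus", "region_code")) |>
    dplyr::mutate(with_congener = dplyr::coalesce(.data$with_congener, FALSE))
  sp <- ev |>
    dplyr::group_by(.data$taxon_name) |>
    dplyr::summarise(any_congener = any(.data$with_congener),
                     .groups = "drop")
  n_events <- nrow(ev)
  n_species <- nrow(sp)
  tibble(
    n_events = n_events,
    n_events_with_congener = sum(ev$with_congener),
    event_fraction = if (n_events > 0) mean(ev$with_congener) else NA_real_,
    n_species = n_species,
    n_species_with_congener = sum(sp$any_congener),
    species_fraction = if (n_species > 0) mean(sp$any_congener) else NA_real_
  )
}

#' Project the number of hybridization events expected from naturalizations
#'
#' Multiplies the number of naturalized neophyte species by the fraction
#' that could have encountered a congener and by a bracketing range of
#' per-species hybridization propensities (literature estimates put the
#' fraction of plant species that hybridize between roughly 9% and 25%).
#' Results are rounded half-away-from-zero to whole events.
#'
#' @param n_neophytes Positive integer count of neophyte species.
#' @param encounter_fraction Fraction in \[0, 1\] of neophytes with a
#'   potential congener encounter.
#' @param rate_low,rate_high Hybridization propensities in \[0, 1\] with
#'   `rate_low <= rate_high`.
#' @return A one-row tibble with integer columns `low`, `high`.
#' @examples
#' projected_hybridizations(11987, 0.73, 0.09, 0.25)
#' @export
projected_hybridizations <- function(n_neophytes, encounter_fraction,
                                     rate_low, rate_high) {
  if (!is.finite(n_neophytes) || n_neophytes < 0) {
    stop("n_neophytes must be a nonnegative number", call. = FALSE)
  }
  for (f in c(encounter_fraction, rate_low, rate_high)) {
    if (!is.finite(f) || f < 0 || f > 1) {
      stop("fractions and rates must lie in [0, 1]", call. = FALSE)
    }
  }
  if (rate_low > rate_high) {
    stop("rate_low must not exceed rate_high", call. = FALSE)
  }
  half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  tibble(
    low = as.integer(half_away(n_neophytes * encounter_fraction * rate_low)),
    high = as.integer(half_away(n_neophytes * encounter_fraction * rate_high))
  )
}
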