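#' Stem-age method-of-moments net diversification rate
#'
#' Estimates the net diversification rate of a clade from its present-day
#' species richness, its stem age, and an assumed relative extinction
#' fraction `e` (the ratio of extinction to speciation rates):
#' `rate = ln(richness * (1 - e) + e) / stem_age` (natural logarithm), in
#' species per Myr when ages are in Myr. Monotypic clades (richness 1) have
#' rate exactly 0. The estimator assumes rates constant through time and
#' across the clade; it is used here for its minimal data requirements, not
#' as a birth-death likelihood fit.
#'
#' @param richness Integer vector of species counts, each >= 1.
#' @param stem_age Positive numeric vector of stem ages (Myr). Recycled
#'   against `richness`.
#' @param extinction_fraction Relative extinction fraction in `[0, 1)`;
#'   0.9 by default, with 0.5 the conventional sensitivity setting.
#' @return Numeric vector of rates (species/Myr).
#' @examples
#' mom_rate(217, 0.00371, 0.9)  # ~840 species/Myr
#' mom_rate(1, 25, 0.9)         # monotypic: 0
#' @export
mom_rate <- function(richness, stem_age, extinction_fraction = 0.9) {
  if (any(!is.finite(richness)) || any(richness < 1)) {
    stop("richness must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(stem_age)) || any(stem_age <= 0)) {
    stop("stem_age must be > 0", call. = FALSE)
  }
  if (any(!is.finite(extinction_fraction)) ||
      any(extinction_fraction < 0) || any(extinction_fraction >= 1)) {
    stop("extinction_fraction must lie in [0, 1)", call. = FALSE)
  }
  e <- extinction_fraction
  log(richness * (1 - e) + e) / stem_age
}

#' Assign genera to hybrid/neophyte incidence groups
#'
#' Group 1: neither hybrids nor neophytes; group 2: neophytes only; group 3:
#' hybrids only; group 4: both. Determined solely by whether the counts are
#' positive.
#'
#' @param n_hybrids,n_neophytes Nonnegative integer vectors.
#' @return An ordered factor with levels `neither`, `neophytes_only`,
#'   `hybrids_only`, `both` whose integer codes are the group numbers 1-4.
#' @export
assign_group <- function(n_hybrids, n_neophytes) {
  if (any(n_hybrids < 0) || any(n_neophytes < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  code <- 1L + 1L * (n_neophytes > 0) + 2L * (n_hybrids > 0)
  factor(group_levels()[code], levels = group_levels())
}

group_levels <- function() c("neither", "neophytes_only", "hybrids_only", "both")

#' Configuration for the diversification-rate table
#'
#' @param extinction_fraction Relative extinction fraction used in
#'   [mom_rate()]; default 0.9.
#' @param alternative_fraction Sensitivity value reported alongside; default
#'   0.5.
#' @param exclude_monotypic Should downstream modelling drop monotypic
#'   genera (whose rate is exactly zero and whose log10 rate is undefined)?
#'   The table itself is always complete.
#' @param extreme_rate_threshold Rate (species/Myr) above which a genus is
#'   flagged as an extreme-rate outlier; `NULL` (default) flags rates above
#'   the 99.9th percentile of the table being built.
#' @return A list of class `rate_config`.
#' @export
rate_config <- function(extinction_fraction = 0.9,
                        alternative_fraction = 0.5,
                        exclude_monotypic = TRUE,
                        extreme_rate_threshold = NULL) {
  if (!is.null(extreme_rate_threshold) &&
      (!is.finite(extreme_rate_threshold) || extreme_rate_threshold <= 0)) {
    stop("extreme_rate_threshold must be positive", call. = FALSE)
  }
  structure(
    list(extinction_fraction = extinction_fraction,
         alternative_fraction = alternative_fraction,
         exclude_monotypic = exclude_monotypic,
         extreme_rate_threshold = extreme_rate_threshold),
    class = "rate_config"
  )
}

#' Build the per-genus diversification-rate table
#'
#' Joins genus tallies to stem ages, computes the method-of-moments rate and
#' its log10 transform (defined only for positive rates), assigns the four
#' incidence groups, and flags monotypic and extreme-rate genera. Exclusion
#' flags are carried in the table but applied only at the modelling stage,
#' so the table is always complete. Genera without a stem age are dropped
#' and counted in the attached report.
#'
#' @param tallies Output of [tally_by_genus()]; `richness` is taken from
#'   `n_species_accepted` (genera with a zero species count are dropped and
#'   reported, since the estimator needs richness >= 1).
#' @param ages Tibble with columns `genus`, `stem_age` (Myr; the stem branch
#'   length of the genus in a dated phylogeny).
#' @param cfg A [rate_config()].
#' @return A tibble: `genus`, `richness`, `stem_age`, `extinction_fraction`,
#'   `rate`, `log10_rate`, `group`, `monotypic`, `extreme`; `read_report`
#'   attribute counts dropped genera.
#' @export
build_rate_table <- function(tallies, ages, cfg = rate_config()) {
  stopifnot(inherits(cfg, "rate_config"),
            all(c("genus", "stem_age") %in% names(ages)))
  ages <- dplyr::distinct(ages, .data$genus, .data$stem_age)
  if (any(ages$stem_age <= 0)) {
    stop("stem ages must be positive", call. = FALSE)
  }
  n_in <- nrow(tallies)
  joined <- dplyr::inner_join(tallies, ages, by = "genus")
  n_no_age <- n_in - nrow(joined)
  n_zero_rich <- sum(joined$n_species_accepted < 1L)
  joined <- dplyr::filter(joined, .data$n_species_accepted >= 1L)
  out <- joined |>
    dplyr::mutate(
      richness = .data$n_species_accepted,
      extinction_fraction = cfg$extinction_fraction,
      rate = mom_rate(.data$richness, .data$stem_age,
                      cfg$extinction_fraction),
      log10_rate = ifelse(.data$rate > 0, log10(.data$rate), NA_real_),
      group = assign_group(.data$n_hybrids, .data$n_neophytes),
      monotypic = .data$richness == 1L
    )
  thr <- cfg$extreme_rate_threshold %||%
    as.numeric(quantile(out$rate, 0.999, names = FALSE))
  out <- out |>
    dplyr::mutate(extreme = .data$rate > thr) |>
    dplyr::select("genus", "richness", "stem_age", "extinction_fraction",
                  "rate", "log10_rate", "group", "monotypic", "extreme",
                  "n_hybrids", "n_neophytes") |>
    dplyr::arrange(.data$genus)
  attr(out, "read_report") <- tibble(
    genera_in = n_in, genera_kept = nrow(out),
    dropped_no_age = n_no_age, dropped_zero_richness = n_zero_rich,
    extreme_rate_threshold = thr
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
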