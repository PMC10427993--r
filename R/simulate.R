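#' Configuration of a synthetic macroecological world
#'
#' Bundles every knob of the synthetic-data generators. The defaults encode
#' the study conditions the pipeline is meant to recover: a cross-country
#' elasticity of hybrid counts on neophyte counts of 0.26, a cross-genus
#' ratio elasticity of 0.64, group diversification-rate multipliers
#' (1, 1.6, 2.5, 2.91) on a base rate of 0.05 species/Myr, and
#' human-footprint type offsets of +2.0 (neophyte) and +5.9 (hybrid) over a
#' native baseline of 22.6, at a desk scale of 200 regions, 800 genera and
#' 30 included triplets.
#'
#' @param n_regions Number of botanical countries (>= 5).
#' @param n_genera Number of genera on the phylogeny.
#' @param n_triplets Number of triplets passing the occupancy rule.
#' @param n_excluded_triplets Extra triplets whose hybrid is planted in 10
#'   or fewer hectads, to exercise the occupancy rule.
#' @param seed Integer master seed; every generator derives its stream from
#'   it and is fully deterministic given the config.
#' @param group_probs Probabilities of incidence groups 1-4 per genus.
#' @param base_rate Group-1 mean net diversification rate (species/Myr).
#' @param group_rate_multipliers Multiplier per group (length 4, positive).
#' @param rate_log10_sd Lognormal spread of genus rates around the group
#'   mean, on the log10 scale.
#' @param richness_nbinom,richness_nbinom_hybrid Negative-binomial richness
#'   settings (`size`, `mu`, and for the hybrid groups a minimum) for groups
#'   1-2 and 3-4 respectively; hybrid-bearing genera are kept above one
#'   species so monotypic genera occur only in groups 1-2.
#' @param true_country_slope,country_covariate_slopes,country_log10_sd,country_log10_mean_h
#'   Cross-country generative model of log10 hybrid counts: slope on log10
#'   neophyte counts, slopes on log10 GDP/effort/area, residual sd, and the
#'   target mean of log10 hybrid counts (sets the intercept).
#' @param true_genus_slope,genus_alpha,genus_log10_sd Cross-genus generative
#'   model of log10 hybrid-to-species ratios on log10 neophyte-to-species
#'   ratios (slope, intercept, residual sd).
#' @param neophyte_range_nbinom Negative-binomial (`size`, `mu`) for the
#'   number of regions a neophyte naturalizes in, beyond the first.
#' @param native_range_nbinom Same for native species beyond their home
#'   region.
#' @param region_weight_sdlog Lognormal spread of region attractiveness
#'   (drives cross-region count variation).
#' @param n_junk Planted rule-violating rows with known counts:
#'   `artificial_hybrid`, `not_accepted_hybrid` (WCVP side); `alien`,
#'   `hybrid_flagged`, `not_accepted`, `numeric_region` (GloNaF side).
#' @param base_hfi Mean human-footprint index of native occurrences.
#' @param hfi_type_offsets Named offsets (native, neophyte, hybrid) added to
#'   `base_hfi` per taxon type.
#' @param hfi_triplet_sd Between-triplet sd of the footprint level.
#' @param hfi_selection_bw Bandwidth of the habitat-selection kernel used to
#'   sample occupied hectads around the target footprint.
#' @param n_hectads_x,n_hectads_y Hectad grid extent; each hectad is 10 x 10
#'   cells of 1 km.
#' @param extinction_fraction Relative extinction fraction used to convert
#'   planted rates and richness into stem ages (matches the analysis
#'   default).
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_regions = 200L,
                         n_genera = 800L,
                         n_triplets = 30L,
                         n_excluded_triplets = 3L,
                         seed = 20260101L,
                         group_probs = c(0.4, 0.2, 0.2, 0.2),
                         base_rate = 0.05,
                         group_rate_multipliers = c(1, 1.6, 2.5, 2.91),
                         rate_log10_sd = 0.3,
                         richness_nbinom = list(size = 0.8, mu = 9),
                         richness_nbinom_hybrid = list(size = 1, mu = 14,
                                                       min = 4),
                         true_country_slope = 0.26,
                         country_covariate_slopes = c(gdp = 0.1,
                                                      effort = 0.1,
                                                      area = 0.1),
                         country_log10_sd = 0.15,
                         country_log10_mean_h = 1.35,
                         true_genus_slope = 0.64,
                         genus_alpha = -0.05,
                         genus_log10_sd = 0.25,
                         neophyte_range_nbinom = list(size = 0.6, mu = 3.7),
                         native_range_nbinom = list(size = 0.5, mu = 1.5),
                         region_weight_sdlog = 0.8,
                         n_junk = list(artificial_hybrid = 12L,
                                       not_accepted_hybrid = 15L,
                                       alien = 10L,
                                       hybrid_flagged = 8L,
                                       not_accepted = 6L,
                                       numeric_region = 7L),
                         base_hfi = 22.6,
                         hfi_type_offsets = c(native = 0, neophyte = 2.0,
                                              hybrid = 5.9),
                         hfi_triplet_sd = 1.5,
                         hfi_selection_bw = 6,
                         n_hectads_x = 30L,
                         n_hectads_y = 30L,
                         extinction_fraction = 0.9) {
  if (n_regions < 5L) stop("n_regions must be at least 5", call. = FALSE)
  if (length(group_rate_multipliers) != 4L ||
      any(group_rate_multipliers <= 0)) {
    stop("group_rate_multipliers must be 4 positive values", call. = FALSE)
  }
  if (n_genera < 8L) stop("n_genera too small to populate 4 groups",
                          call. = FALSE)
  cfg <- as.list(environment())
  structure(cfg, class = "world_config")
}

#' Simulate a genus-level phylogeny with planted diversification structure
#'
#' Grows a pure-birth tree over the genera, assigns each genus an incidence
#' group and a species richness, draws its true net diversification rate as
#' the group multiplier times the base rate (lognormal noise), and sets the
#' genus' stem branch length so that the stem-age method-of-moments
#' estimator at the configured extinction fraction returns exactly the
#' planted rate. Hybrid and neophyte counts per genus are then drawn so that
#', within genera holding both, log10 hybrid ratios follow the planted
#' linear relation on log10 neophyte ratios.
#'
#' @param cfg A [world_config()].
#' @return A list: `tree` (ape phylo; terminal branch = stem age),
#'   `stem_ages` (tibble `genus`, `stem_age`), `genera` (tibble with group,
#'   richness, true rate, true counts), `truth` (planted parameters).
#' @export
sim_phylogeny <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genera
  genus <- sprintf("Genus%04d", seq_len(n))
  tree <- ape::rphylo(n, birth = 0.1, death = 0)
  tree$tip.label <- genus

  group <- sample.int(4L, n, replace = TRUE, prob = cfg$group_probs)
  rich <- integer(n)
  base12 <- group <= 2L
  rb <- cfg$richness_nbinom
  rh <- cfg$richness_nbinom_hybrid
  rich[base12] <- 1L + rnbinom(sum(base12), size = rb$size, mu = rb$mu)
  rich[!base12] <- pmax(rh$min,
                        1L + rnbinom(sum(!base12), size = rh$size,
                                     mu = rh$mu))
  # lognormal rate noise, centered within each group over the non-monotypic
  # genera so every group's realized mean log10 rate equals its planted
  # value exactly (planted-truth bookkeeping, not an estimator aid)
  rate_noise <- rnorm(n, 0, cfg$rate_log10_sd)
  for (k in 1:4) {
    in_g <- group == k & rich > 1L
    if (sum(in_g) > 1L) {
      rate_noise[in_g] <- rate_noise[in_g] - mean(rate_noise[in_g])
    }
  }
  rate <- cfg$base_rate * cfg$group_rate_multipliers[group] * 10^rate_noise
  rate[rich == 1L] <- 0
  e <- cfg$extinction_fraction
  age <- ifelse(rich > 1L,
                log(rich * (1 - e) + e) / rate,
                runif(n, 5, 50))

  # terminal branch length = planted stem age
  term <- match(seq_len(n), tree$edge[, 2])
  tree$edge.length[term] <- age

  n_hyb <- integer(n)
  n_neo <- integer(n)
  g2 <- group == 2L
  g3 <- group == 3L
  g4 <- group == 4L
  n_neo[g2] <- 1L + rnbinom(sum(g2), size = 1, mu = 3)
  n_hyb[g3] <- 1L + rnbinom(sum(g3), size = 1, mu = 3)
  if (any(g4)) {
    s4 <- rich[g4]
    log10_nr <- rnorm(sum(g4), -0.8, 0.35)
    neo4 <- pmax(1L, as.integer(round(10^log10_nr * s4)))
    x <- log10(neo4 / s4)  # realized predictor, after integer rounding
    y <- cfg$genus_alpha + cfg$true_genus_slope * x +
      orthogonal_noise(sum(g4), cfg$genus_log10_sd, cbind(x))
    hyb4 <- pmax(1L, as.integer(round(10^y * s4)))
    n_neo[g4] <- neo4
    n_hyb[g4] <- hyb4
  }

  genera <- tibble(
    genus = genus, group = group, richness = rich,
    true_rate = rate, stem_age = age,
    n_hybrids_true = n_hyb, n_neophytes_true = n_neo
  )
  list(
    tree = tree,
    stem_ages = tibble(genus = genus, stem_age = age),
    genera = genera,
    truth = list(
      base_rate = cfg$base_rate,
      group_rate_multipliers = cfg$group_rate_multipliers,
      rate_log10_sd = cfg$rate_log10_sd,
      true_genus_slope = cfg$true_genus_slope,
      genus_alpha = cfg$genus_alpha,
      genus_log10_sd = cfg$genus_log10_sd,
      extinction_fraction = e,
      n_monotypic = sum(rich == 1L)
    )
  )
}

#' Simulate WCVP- and GloNaF-dialect checklists with known ground truth
#'
#' Materializes the genus-level world into checklist rows. Neophyte taxa are
#' assigned integer region memberships first, so the predictor side of the
#' planted cross-country relation is exact; per-region hybrid counts are
#' then drawn from the planted log-linear model on neophyte counts, GDP,
#' taxonomist effort and area, and hybrid taxa are sampled into regions to
#' match. Effort inputs (author descriptions, presence pairs, GDP series,
#' political-to-botanical mapping, areas) are constructed so the module
#' computations reproduce the planted covariates exactly. Known counts of
#' rule-violating rows (artificial hybrids, unaccepted names, aliens,
#' hybrid-flagged neophytes, numeric region codes) are planted for the
#' filter tests.
#'
#' @param cfg A [world_config()].
#' @param phylo Output of [sim_phylogeny()] on the same config (generated if
#'   omitted).
#' @return A list of tibbles: `wcvp`, `glonaf` (raw dialect tables),
#'   `gdp_table`, `gdp_mapping`, `descriptions`, `presence`, `areas`, plus
#'   `truth`.
#' @export
sim_checklists <- function(cfg, phylo = sim_phylogeny(cfg)) {
  stopifnot(inherits(cfg, "world_config"))
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 2L)

  g <- phylo$genera
  n_reg <- cfg$n_regions
  regions <- region_codes(n_reg)
  w <- stats::rlnorm(n_reg, 0, cfg$region_weight_sdlog)
  w <- w / sum(w)

  # region covariates (planted exactly; the effort tables below reproduce
  # them through the module computations)
  gdp_r <- 10^rnorm(n_reg, 4, 0.4)
  authors_r <- 1L + rpois(n_reg, 3)
  area_r <- 10^rnorm(n_reg, 5, 0.5)

  # species / hybrid / neophyte name pools
  species_pool <- tidyr::uncount(
    dplyr::select(g, "genus", "richness"), .data$richness, .id = "i"
  ) |>
    dplyr::mutate(taxon_name = paste0(.data$genus, " sp", .data$i))
  hyb_pool <- tidyr::uncount(
    dplyr::filter(dplyr::select(g, "genus", n = "n_hybrids_true"),
                  .data$n > 0),
    .data$n, .id = "i"
  ) |>
    dplyr::mutate(taxon_name = sprintf("%s ×hyb%02d", .data$genus,
                                       .data$i))
  neo_pool <- tidyr::uncount(
    dplyr::filter(dplyr::select(g, "genus", richness = "richness",
                                n = "n_neophytes_true"), .data$n > 0),
    .data$n, .id = "i"
  ) |>
    dplyr::mutate(
      is_variety = .data$i > .data$richness,
      taxon_name = ifelse(.data$is_variety,
                          sprintf("%s sp%d var. v%d", .data$genus,
                                  .data$richness,
                                  .data$i - .data$richness),
                          paste0(.data$genus, " sp", .data$i))
    )

  # neophyte region memberships (predictor side, exact by construction)
  rn <- cfg$neophyte_range_nbinom
  k_neo <- pmin(n_reg, 1L + rnbinom(nrow(neo_pool), size = rn$size,
                                    mu = rn$mu))
  neo_rows <- tibble(
    taxon_name = rep(neo_pool$taxon_name, k_neo),
    genus = rep(neo_pool$genus, k_neo),
    is_variety = rep(neo_pool$is_variety, k_neo),
    region_code = unlist(lapply(k_neo, function(k)
      sample(regions, k, prob = w)))
  ) |> dplyr::distinct(.data$taxon_name, .data$genus, .data$is_variety,
                       .data$region_code)
  n_r <- table(factor(neo_rows$region_code, levels = regions))
  empty <- which(n_r == 0)
  if (length(empty) > 0) {  # guarantee every region records >= 1 neophyte
    extra <- tibble(
      taxon_name = sample(neo_pool$taxon_name, length(empty)),
      region_code = regions[empty]
    ) |>
      dplyr::left_join(dplyr::select(neo_pool, "taxon_name", "genus",
                                     "is_variety"),
                       by = "taxon_name") |>
      dplyr::distinct(.data$taxon_name, .data$genus, .data$is_variety,
                      .data$region_code)
    neo_rows <- dplyr::bind_rows(neo_rows, extra)
    n_r <- table(factor(neo_rows$region_code, levels = regions))
  }
  n_r <- as.integer(n_r)

  # planted cross-country model for hybrid counts
  cs <- cfg$country_covariate_slopes
  lin <- cfg$true_country_slope * log10(n_r) +
    cs[["gdp"]] * log10(gdp_r) + cs[["effort"]] * log10(authors_r) +
    cs[["area"]] * log10(area_r)
  alpha_c <- cfg$country_log10_mean_h - mean(lin)
  eps <- orthogonal_noise(n_reg, cfg$country_log10_sd,
                          cbind(log10(n_r), log10(gdp_r),
                                log10(authors_r), log10(area_r)))
  h_r <- pmax(1L, as.integer(round(10^(alpha_c + lin + eps))))

  # hybrid rows: each region receives exactly its planted count of distinct
  # hybrids; not-yet-placed hybrids are preferred so (almost) every pool
  # taxon appears somewhere without inflating any region's tally
  n_pool <- nrow(hyb_pool)
  placed <- logical(n_pool)
  hyb_rows_list <- vector("list", n_reg)
  for (r in sample.int(n_reg)) {
    need <- min(h_r[r], n_pool)
    un <- which(!placed)
    take <- un[sample.int(length(un), min(need, length(un)))]
    if (length(take) < need) {
      rest <- which(placed & !(seq_len(n_pool) %in% take))
      take <- c(take, rest[sample.int(length(rest), need - length(take))])
    }
    placed[take] <- TRUE
    hyb_rows_list[[r]] <- tibble(
      taxon_name = hyb_pool$taxon_name[take],
      genus = hyb_pool$genus[take],
      region_code = regions[r]
    )
  }
  hyb_rows <- dplyr::bind_rows(hyb_rows_list)
  # a hybrid the allocation never placed is removed from the checklist so
  # that genus tallies and region tallies stay mutually consistent
  hyb_pool <- hyb_pool[placed, , drop = FALSE]

  # native rows: home region plus extra memberships
  rv <- cfg$native_range_nbinom
  nat_home <- sample(regions, nrow(species_pool), replace = TRUE, prob = w)
  k_extra <- rnbinom(nrow(species_pool), size = rv$size, mu = rv$mu)
  extra_rows <- tibble(
    taxon_name = rep(species_pool$taxon_name, k_extra),
    genus = rep(species_pool$genus, k_extra),
    region_code = unlist(lapply(k_extra, function(k)
      if (k > 0) sample(regions, k, prob = w) else character(0)))
  )
  nat_rows <- dplyr::bind_rows(
    tibble(taxon_name = species_pool$taxon_name,
           genus = species_pool$genus, region_code = nat_home),
    extra_rows
  ) |> dplyr::distinct()

  nj <- cfg$n_junk
  wcvp <- dplyr::bind_rows(
    tibble(taxon_name = nat_rows$taxon_name, genus = nat_rows$genus,
           rank = "Species", species_hybrid = "",
           taxon_status = "Accepted", region_code = nat_rows$region_code,
           introduced = 0L),
    tibble(taxon_name = hyb_rows$taxon_name, genus = hyb_rows$genus,
           rank = "Species", species_hybrid = "×",
           taxon_status = "Accepted", region_code = hyb_rows$region_code,
           introduced = 0L),
    tibble(taxon_name = sprintf("Hortus ×artif%02d",
                                seq_len(nj$artificial_hybrid)),
           genus = "Hortus", rank = "Species", species_hybrid = "+",
           taxon_status = "Accepted",
           region_code = sample(regions, nj$artificial_hybrid,
                                replace = TRUE),
           introduced = 0L),
    tibble(taxon_name = sprintf("Dubium ×syn%02d",
                                seq_len(nj$not_accepted_hybrid)),
           genus = "Dubium", rank = "Species", species_hybrid = "×",
           taxon_status = "Synonym",
           region_code = sample(regions, nj$not_accepted_hybrid,
                                replace = TRUE),
           introduced = 0L)
  )

  glonaf <- dplyr::bind_rows(
    tibble(taxon_name = neo_rows$taxon_name, genus = neo_rows$genus,
           name_status = "accepted", status = "naturalized", hybrid = 0L,
           rank = ifelse(neo_rows$is_variety, "variety", "species"),
           region_code = neo_rows$region_code),
    tibble(taxon_name = sprintf("Incerta sp%02d", seq_len(nj$alien)),
           genus = "Incerta", name_status = "accepted", status = "alien",
           hybrid = 0L, rank = "species",
           region_code = sample(regions, nj$alien, replace = TRUE)),
    tibble(taxon_name = sprintf("Spuria ×neo%02d",
                                seq_len(nj$hybrid_flagged)),
           genus = "Spuria", name_status = "accepted",
           status = "naturalized", hybrid = 1L, rank = "species",
           region_code = sample(regions, nj$hybrid_flagged,
                                replace = TRUE)),
    tibble(taxon_name = sprintf("Rejecta sp%02d",
                                seq_len(nj$not_accepted)),
           genus = "Rejecta", name_status = "synonym",
           status = "naturalized", hybrid = 0L, rank = "species",
           region_code = sample(regions, nj$not_accepted,
                                replace = TRUE)),
    tibble(taxon_name = sprintf("Numerica sp%02d",
                                seq_len(nj$numeric_region)),
           genus = "Numerica", name_status = "accepted",
           status = "naturalized", hybrid = 0L, rank = "species",
           region_code = as.character(seq_len(nj$numeric_region)))
  )

  # effort inputs reproducing the planted covariates exactly:
  # each region's authors describe single-region endemics, so the
  # range-weighted score equals the author count
  endemic <- tibble(
    region_code = rep(regions, authors_r),
    k = unlist(lapply(authors_r, seq_len))
  ) |>
    dplyr::mutate(
      author = sprintf("Author_%s_%d", .data$region_code, .data$k),
      taxon_name = sprintf("Endemica %s_%d", .data$region_code, .data$k)
    )
  descriptions <- dplyr::select(endemic, "author", "taxon_name")
  presence <- dplyr::select(endemic, "taxon_name", "region_code")
  gdp_table <- tidyr::expand_grid(
    political_code = paste0("P_", regions),
    year = seq(1960L, 2020L, by = 10L)
  ) |>
    dplyr::mutate(gdp = gdp_r[match(.data$political_code,
                                    paste0("P_", regions))])
  gdp_mapping <- tibble(political_code = paste0("P_", regions),
                        region_code = regions)
  areas <- tibble(region_code = regions, area_km2 = area_r)

  truth <- list(
    true_country_slope = cfg$true_country_slope,
    country_covariate_slopes = as.list(cfg$country_covariate_slopes),
    country_alpha = alpha_c,
    country_log10_sd = cfg$country_log10_sd,
    n_junk = nj,
    regions = list(region_code = regions, n_neophytes = n_r,
                   n_hybrids_planted = h_r, gdp = gdp_r,
                   taxonomists = authors_r, area = area_r)
  )
  list(wcvp = wcvp, glonaf = glonaf, gdp_table = gdp_table,
       gdp_mapping = gdp_mapping, descriptions = descriptions,
       presence = presence, areas = areas, truth = truth)
}

#' Simulate a footprint raster, hectads, occurrences and triplets
#'
#' Builds a planar human-footprint grid (1 km cells, values in \[0, 50\]
#' with a west-to-east disturbance gradient), the hectad rectangles covering
#' it, and for each triplet (hybrid, native parent, neophyte parent) samples
#' occupied hectads with a habitat-selection kernel centered on the planted
#' footprint target `base_hfi + type offset + triplet effect`. A few extra
#' triplets carry hybrids planted in 10 or fewer hectads so the occupancy
#' rule has known casualties.
#'
#' @param cfg A [world_config()].
#' @return A list: `grid` (`footprint_grid`), `polygons`, `occurrences`,
#'   `triplets`, `truth`.
#' @export
sim_footprint_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 3L)

  cells_per <- 10L
  nhx <- cfg$n_hectads_x
  nhy <- cfg$n_hectads_y
  nc <- nhx * cells_per
  nr <- nhy * cells_per
  # west-to-east disturbance gradient; a single axis keeps the hectad-level
  # HFI distribution close to uniform over its range, so kernel-based
  # habitat selection recovers its target mean without edge bias
  gx <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  vals <- 5 + 40 * gx + rnorm(nr * nc, 0, 3)
  vals <- pmin(pmax(vals, 0), 50)  # pmin/pmax keep dim only with vals first
  grid <- structure(
    list(values = round(vals, 2), cell_size = 1000,
         origin = c(x = 0, y = 0), nodata = -9999, crs_tag = "planar"),
    class = "footprint_grid"
  )

  hx <- rep(seq_len(nhx), each = nhy)
  hy <- rep(seq_len(nhy), times = nhx)
  code <- paste0(LETTERS[(hx - 1L) %/% 26L + 1L],
                 LETTERS[(hx - 1L) %% 26L + 1L],
                 sprintf("%02d", hy - 1L))
  polygons <- tibble(
    hectad_code = code,
    xmin = (hx - 1) * 10000, ymin = (hy - 1) * 10000,
    xmax = hx * 10000, ymax = hy * 10000
  )
  attr(polygons, "crs_tag") <- "planar"

  hfi_h <- hectad_mean_hfi(grid, polygons)

  off <- cfg$hfi_type_offsets
  n_inc <- cfg$n_triplets
  n_exc <- cfg$n_excluded_triplets
  n_tot <- n_inc + n_exc
  trip_eff <- rnorm(n_tot, 0, cfg$hfi_triplet_sd)
  trip_eff <- trip_eff - mean(trip_eff)  # realized mean exactly 0
  exc_sizes <- rep_len(c(10L, 8L, 5L), n_exc)

  pick <- function(target, n) {
    wts <- stats::dnorm(hfi_h$mean_hfi, target, cfg$hfi_selection_bw) + 1e-12
    sample(hfi_h$hectad_code, min(n, nrow(hfi_h)), prob = wts)
  }
  rows <- vector("list", n_tot)
  trips <- vector("list", n_tot)
  for (t in seq_len(n_tot)) {
    id <- sprintf("T%02d", t)
    nm <- c(hybrid = sprintf("Tripgen%02d ×hybridus", t),
            native = sprintf("Tripgen%02d nativus", t),
            neophyte = sprintf("Tripgen%02d neophytus", t))
    n_occ <- c(
      hybrid = if (t <= n_inc) sample(11:60, 1) else exc_sizes[t - n_inc],
      native = 30L + rnbinom(1, size = 2, mu = 60),
      neophyte = 20L + rnbinom(1, size = 2, mu = 35)
    )
    rows[[t]] <- purrr::map_dfr(c("hybrid", "native", "neophyte"),
      function(ty) tibble(
        taxon_name = nm[[ty]],
        hectad_code = pick(cfg$base_hfi + off[[ty]] + trip_eff[t],
                           n_occ[[ty]])
      ))
    trips[[t]] <- tibble(triplet_id = id, hybrid_name = nm[["hybrid"]],
                         native_name = nm[["native"]],
                         neophyte_name = nm[["neophyte"]])
  }
  occurrences <- dplyr::bind_rows(rows)
  triplets <- dplyr::bind_rows(trips)

  truth <- list(
    base_hfi = cfg$base_hfi,
    hfi_type_offsets = as.list(off),
    hfi_type_means = as.list(cfg$base_hfi + off),
    hfi_triplet_sd = cfg$hfi_triplet_sd,
    n_triplets_included = n_inc,
    n_triplets_excluded = n_exc,
    excluded_hybrid_hectads = exc_sizes
  )
  list(grid = grid, polygons = polygons, occurrences = occurrences,
       triplets = triplets, truth = truth)
}

#' Simulate the complete synthetic world
#'
#' Runs all three generators on one config and pools their ground truth.
#'
#' @param cfg A [world_config()].
#' @return A list: `phylo`, `checklists`, `footprint`, `truth`.
#' @export
sim_world <- function(cfg = world_config()) {
  phylo <- sim_phylogeny(cfg)
  checklists <- sim_checklists(cfg, phylo)
  footprint <- sim_footprint_world(cfg)
  list(
    phylo = phylo, checklists = checklists, footprint = footprint,
    truth = c(phylo$truth, checklists$truth, footprint$truth,
              list(seed = cfg$seed))
  )
}

#' Write a simulated world to a directory of fixture files
#'
#' Emits the delimited, Newick, and ASCII-grid files the pipeline readers
#' consume, plus `ground_truth.json` with every planted parameter.
#' Writing is deterministic: the same config yields byte-identical files.
#'
#' @param world Output of [sim_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  cl <- world$checklists
  readr::write_csv(cl$wcvp, p("wcvp.csv"))
  readr::write_csv(cl$glonaf, p("glonaf.csv"))
  readr::write_csv(cl$gdp_table, p("gdp.csv"))
  readr::write_csv(cl$gdp_mapping, p("gdp_mapping.csv"))
  readr::write_csv(cl$descriptions, p("author_descriptions.csv"))
  readr::write_csv(cl$presence, p("taxon_presence.csv"))
  readr::write_csv(cl$areas, p("region_areas.csv"))
  ape::write.tree(world$phylo$tree, p("tree.nwk"))
  readr::write_csv(world$phylo$stem_ages, p("stem_ages.csv"))
  fp <- world$footprint
  write_raster(fp$grid, p("hfi.asc"))
  readr::write_csv(fp$polygons, p("hectad_polygons.csv"))
  readr::write_csv(fp$occurrences, p("occurrences.csv"))
  readr::write_csv(fp$triplets, p("triplets.csv"))
  jsonlite::write_json(world$truth, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# Gaussian noise made exactly orthogonal to the planted predictors (and to
# the intercept), rescaled to the target sd: the finite synthetic world then
# realizes its documented regression coefficients exactly, so recovery tests
# measure estimator behaviour rather than realization luck.
orthogonal_noise <- function(n, sd_target, xmat) {
  eps <- rnorm(n, 0, sd_target)
  if (n > ncol(xmat) + 2L) {
    eps <- stats::residuals(stats::lm.fit(cbind(1, xmat), eps))
    eps <- eps * sd_target / sd(eps)
  }
  eps
}

region_codes <- function(n) {
  stopifnot(n <= 26^3)
  i <- seq_len(n) - 1L
  paste0(LETTERS[i %/% 676L + 1L],
         LETTERS[(i %/% 26L) %% 26L + 1L],
         LETTERS[i %% 26L + 1L])
}
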