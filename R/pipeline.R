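#' Pipeline run configuration
#'
#' Collects paths and settings for [run_pipeline()]. The input directory is
#' expected to hold the file set written by [write_world()] (or real data in
#' the same layout): `wcvp.csv`, `glonaf.csv`, `gdp.csv`, `gdp_mapping.csv`,
#' `author_descriptions.csv`, `taxon_presence.csv`, `region_areas.csv`,
#' `tree.nwk`, `stem_ages.csv`, `hfi.asc`, `hectad_polygons.csv`,
#' `occurrences.csv`, `triplets.csv`.
#'
#' @param input_dir Directory with the input files.
#' @param stages Named logical vector toggling the analysis stages
#'   (`spatial`, `genus`, `congeners`, `diversification`, `signal`,
#'   `footprint`). The integration stage always runs.
#' @param rate_cfg A [rate_config()].
#' @param hybridization_rates Length-2 bracket of per-species hybridization
#'   propensities for the event projection.
#' @param draws,warmup,chains MCMC settings passed to the model fits.
#' @param hfi_draws,hfi_warmup Longer run for the hierarchical footprint
#'   model, whose population-level means mix more slowly.
#' @param seed Integer seed; per-model streams are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir,
                            stages = c(spatial = TRUE, genus = TRUE,
                                       congeners = TRUE,
                                       diversification = TRUE,
                                       signal = TRUE, footprint = TRUE),
                            rate_cfg = rate_config(),
                            hybridization_rates = c(0.09, 0.25),
                            draws = 1500, warmup = 1000, chains = 2,
                            hfi_draws = 4000, hfi_warmup = 2000,
                            seed = 1L) {
  defaults <- c(spatial = TRUE, genus = TRUE, congeners = TRUE,
                diversification = TRUE, signal = TRUE, footprint = TRUE)
  defaults[names(stages)] <- stages
  structure(
    list(input_dir = input_dir, stages = defaults, rate_cfg = rate_cfg,
         hybridization_rates = hybridization_rates, draws = draws,
         warmup = warmup, chains = chains, hfi_draws = hfi_draws,
         hfi_warmup = hfi_warmup, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full neophyte-hybrid overlap pipeline
#'
#' Executes the stages in dependency order — reading and filtering the
#' checklists, building tallies and effort covariates, the cross-country
#' and cross-genus regressions, the congener-encounter summary and event
#' projection, the diversification-rate table with group contrasts, the
#' phylogenetic signal, and the human-footprint comparison — and returns a
#' report object aggregating every stage's results, drop counts and MCMC
#' diagnostics. Any stage failure aborts with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `hybridscape_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  path <- function(f) {
    fp <- file.path(config$input_dir, f)
    if (!file.exists(fp)) stop("missing input file: ", fp, call. = FALSE)
    fp
  }
  st <- config$stages
  report <- list(stages = st, seed = config$seed)
  models <- list()

  io <- stage("io", {
    list(wcvp = read_checklist(path("wcvp.csv"), "wcvp"),
         glonaf = read_checklist(path("glonaf.csv"), "glonaf"),
         ages = readr::read_csv(path("stem_ages.csv"),
                                show_col_types = FALSE))
  })
  report$read_reports <- list(wcvp = read_report(io$wcvp),
                              glonaf = read_report(io$glonaf))

  integ <- stage("integration", {
    hybrids <- filter_hybrids(io$wcvp)
    neophytes <- filter_neophytes(io$glonaf)
    natives <- dplyr::filter(io$wcvp,
                             .data$name_status == "accepted",
                             .data$rank == "species",
                             !.data$is_hybrid,
                             .data$naturalization_status == "native")
    list(hybrids = hybrids, neophytes = neophytes, natives = natives,
         country = tally_by_country(hybrids, neophytes, natives),
         genus = tally_by_genus(hybrids, neophytes, io$wcvp))
  })
  report$country_tally <- integ$country
  report$genus_tally <- integ$genus
  report$filter_counts <- tibble(
    wcvp_rows = nrow(io$wcvp), hybrids_retained = nrow(integ$hybrids),
    glonaf_rows = nrow(io$glonaf),
    neophytes_retained = nrow(integ$neophytes),
    natives_retained = nrow(integ$natives)
  )

  if (st[["spatial"]]) {
    spatial <- stage("spatial", {
      gdp <- gdp_crosswalk(readr::read_csv(path("gdp.csv"),
                                           show_col_types = FALSE),
                           readr::read_csv(path("gdp_mapping.csv"),
                                           show_col_types = FALSE))
      eff <- taxonomist_effort(
        readr::read_csv(path("author_descriptions.csv"),
                        show_col_types = FALSE),
        readr::read_csv(path("taxon_presence.csv"),
                        show_col_types = FALSE))
      cov <- effort_covariates(gdp, eff,
                               readr::read_csv(path("region_areas.csv"),
                                               show_col_types = FALSE))
      dat <- integ$country |>
        dplyr::inner_join(cov, by = "region_code")
      usable <- dat |>
        dplyr::filter(.data$n_hybrids > 0, .data$n_neophytes > 0,
                      !.data$gdp_missing, .data$taxonomist_effort > 0,
                      .data$area_km2 > 0)
      fit <- fit_gaussian_lm(
        usable, "n_hybrids",
        c("n_neophytes", "gdp_per_capita", "taxonomist_effort",
          "area_km2"),
        transforms = c(n_hybrids = "log10", n_neophytes = "log10",
                       gdp_per_capita = "log10",
                       taxonomist_effort = "log10", area_km2 = "log10"),
        draws = config$draws, warmup = config$warmup,
        chains = config$chains, seed = config$seed + 11L)
      list(covariates = cov, fit = fit,
           n_dropped = nrow(dat) - nrow(usable))
    })
    report$effort_covariates <- spatial$covariates
    report$country_model <- tidy(spatial$fit)
    report$country_model_dropped_rows <- spatial$n_dropped
    models$country <- spatial$fit
  }

  if (st[["genus"]]) {
    genus_fit <- stage("genus", {
      both <- integ$genus |>
        dplyr::filter(.data$n_hybrids > 0, .data$n_neophytes > 0,
                      !.data$ratio_undefined)
      fit_gaussian_lm(
        both, "hybrid_ratio", "neophyte_ratio",
        transforms = c(hybrid_ratio = "log10", neophyte_ratio = "log10"),
        draws = config$draws, warmup = config$warmup,
        chains = config$chains, seed = config$seed + 12L)
    })
    report$genus_model <- tidy(genus_fit)
    models$genus <- genus_fit
  }

  if (st[["congeners"]]) {
    cong <- stage("congeners", {
      events <- dplyr::distinct(integ$neophytes, .data$taxon_name,
                                .data$genus, .data$region_code)
      native_presence <- dplyr::distinct(integ$natives, .data$genus,
                                         .data$region_code)
      summ <- encounter_summary(events, native_presence)
      proj <- projected_hybridizations(
        summ$n_species, summ$species_fraction,
        config$hybridization_rates[1], config$hybridization_rates[2])
      list(summary = summ, projection = proj)
    })
    report$encounter <- cong$summary
    report$projection <- cong$projection
  }

  if (st[["diversification"]]) {
    div <- stage("diversification", {
      rt <- build_rate_table(integ$genus, io$ages, config$rate_cfg)
      fit <- fit_group_means(rt, draws = config$draws,
                             warmup = config$warmup,
                             chains = config$chains,
                             seed = config$seed + 13L)
      list(rate_table = rt, fit = fit)
    })
    report$rate_table <- div$rate_table
    report$rate_groups <- div$fit$group_summary
    report$rate_contrasts <- div$fit$contrasts
    models$diversification <- div$fit
  }

  if (st[["signal"]]) {
    report$phylo_signal <- stage("signal", {
      tree <- read_tree(path("tree.nwk"))
      phylo_signal_counts(integ$genus, tree)
    })
  }

  if (st[["footprint"]]) {
    fp <- stage("footprint", {
      grid <- read_raster(path("hfi.asc"))
      polys <- read_hectad_polygons(path("hectad_polygons.csv"))
      occ <- read_occurrences(path("occurrences.csv"))
      trips <- readr::read_csv(path("triplets.csv"),
                               show_col_types = FALSE)
      hh <- hectad_mean_hfi(grid, polys)
      trips <- apply_occupancy_rule(trips, occ)
      obs <- triplet_observations(trips, occ, hh)
      cov_stats <- range_coverage_stats(obs)
      fit <- fit_varying_slopes(obs, draws = config$hfi_draws,
                                warmup = config$hfi_warmup,
                                chains = config$chains,
                                seed = config$seed + 14L)
      list(hectad_hfi = hh, triplets = trips, observations = obs,
           coverage = cov_stats, fit = fit)
    })
    report$hectad_hfi <- fp$hectad_hfi
    report$triplets <- fp$triplets
    report$coverage_stats <- fp$coverage
    report$coverage_counts <- attr(fp$coverage, "counts")
    report$hfi_types <- fp$fit$type_summary
    report$hfi_contrasts <- fp$fit$contrasts
    models$footprint <- fp$fit
  }

  report$diagnostics <- purrr::imap_dfr(models, function(m, nm) {
    dplyr::mutate(m$diagnostics, model = nm, .before = 1)
  })
  report$n_diagnostic_failures <-
    sum(!vapply(models, function(m) m$diagnostics_ok, logical(1)))
  report$models <- models
  structure(report, class = "hybridscape_report")
}

#' @export
print.hybridscape_report <- function(x, ...) {
  cat("== hybridscape pipeline report ==\n")
  cat("stages:", paste(names(x$stages)[x$stages], collapse = ", "), "\n")
  cat("countries tallied:", nrow(x$country_tally),
      "| genera tallied:", nrow(x$genus_tally), "\n")
  if (!is.null(x$country_model)) {
    b <- x$country_model[x$country_model$parameter == "beta_n_neophytes", ]
    cat(sprintf("country model: b(neophytes) = %.3f [%.3f, %.3f]\n",
                b$mean, b$ci95_low, b$ci95_high))
  }
  if (!is.null(x$genus_model)) {
    b <- x$genus_model[x$genus_model$parameter == "beta_neophyte_ratio", ]
    cat(sprintf("genus model:   b(neophyte ratio) = %.3f [%.3f, %.3f]\n",
                b$mean, b$ci95_low, b$ci95_high))
  }
  if (!is.null(x$encounter)) {
    cat(sprintf("congeners: %.1f%% of events, %.1f%% of species; projection %d-%d events\n",
                100 * x$encounter$event_fraction,
                100 * x$encounter$species_fraction,
                x$projection$low, x$projection$high))
  }
  if (!is.null(x$rate_contrasts)) {
    r <- x$rate_contrasts[x$rate_contrasts$contrast == "both - neither", ]
    cat(sprintf("diversification: both/neither rate ratio = %.2f [%.2f, %.2f]\n",
                r$ratio_median, r$ratio_ci95_low, r$ratio_ci95_high))
  }
  if (!is.null(x$phylo_signal)) {
    for (i in seq_len(nrow(x$phylo_signal))) {
      cat(sprintf("Blomberg's K (%s) = %.3f\n",
                  x$phylo_signal$trait[i], x$phylo_signal$k_statistic[i]))
    }
  }
  if (!is.null(x$hfi_types)) {
    m <- setNames(x$hfi_types$mean, x$hfi_types$taxon_type)
    cat(sprintf("mean HFI: hybrid %.1f | native %.1f | neophyte %.1f\n",
                m[["hybrid"]], m[["native"]], m[["neophyte"]]))
    cc <- x$coverage_counts
    cat(sprintf("range coverage: %d/%d hybrids above native min HFI, %d/%d above both parents' max\n",
                cc$n_min_above, cc$n_triplets, cc$n_max_above,
                cc$n_triplets))
  }
  cat("MCMC diagnostic failures:", x$n_diagnostic_failures, "\n")
  invisible(x)
}
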