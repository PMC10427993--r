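#' Mean human-footprint value per hectad
#'
#' Zonal statistics of the footprint grid over hectad rectangles: a grid
#' cell contributes to a hectad when its center lies inside the rectangle,
#' with half-open bounds on the max edges (`xmin <= x < xmax`,
#' `ymin <= y < ymax`) so a cell on a shared boundary is never counted
#' twice. The hectad value is the mean over contributing non-missing cells;
#' hectads with no contributing cell are omitted and reported.
#'
#' @param grid A `footprint_grid` from [read_raster()].
#' @param polygons Hectad rectangles from [read_hectad_polygons()]; their
#'   `crs_tag` must match the grid's.
#' @return A tibble `hectad_code`, `mean_hfi`, `n_cells` with a
#'   `read_report` attribute.
#' @export
hectad_mean_hfi <- function(grid, polygons) {
  stopifnot(inherits(grid, "footprint_grid"))
  poly_crs <- attr(polygons, "crs_tag")
  if (!is.null(poly_crs) && !identical(poly_crs, grid$crs_tag)) {
    stop("coordinate system mismatch: raster '", grid$crs_tag,
         "' vs polygons '", poly_crs, "'", call. = FALSE)
  }
  m <- grid$values
  cs <- grid$cell_size
  x0 <- grid$origin[["x"]]
  y0 <- grid$origin[["y"]]
  nr <- nrow(m)
  nc <- ncol(m)
  # cell centers: column j -> x0 + (j - 0.5) cs; matrix row 1 is the top row,
  # so row i -> y0 + (nr - i + 0.5) cs
  res <- purrr::pmap_dfr(
    polygons[c("hectad_code", "xmin", "ymin", "xmax", "ymax")],
    function(hectad_code, xmin, ymin, xmax, ymax) {
      j_lo <- max(1L, ceiling((xmin - x0) / cs + 0.5))
      j_hi <- min(nc, ceiling((xmax - x0) / cs - 0.5))
      i_hi <- min(nr, floor(nr - (ymin - y0) / cs + 0.5))
      i_lo <- max(1L, floor(nr - (ymax - y0) / cs + 1.5))
      if (j_lo > j_hi || i_lo > i_hi) {
        return(tibble(hectad_code = hectad_code, mean_hfi = NA_real_,
                      n_cells = 0L))
      }
      vals <- m[i_lo:i_hi, j_lo:j_hi]
      vals <- vals[!is.na(vals)]
      tibble(hectad_code = hectad_code,
             mean_hfi = if (length(vals)) mean(vals) else NA_real_,
             n_cells = length(vals))
    }
  )
  n_in <- nrow(res)
  out <- dplyr::filter(res, .data$n_cells > 0L)
  attr(out, "read_report") <- tibble(
    hectads_in = n_in, hectads_kept = nrow(out),
    dropped_no_cells = n_in - nrow(out)
  )
  out
}

#' Flag triplets passing the hybrid occupancy rule
#'
#' The footprint comparison includes only hybrids recorded in strictly more
#' than 10 hectads (i.e. at least `min_hectads = 11`): rarer hybrids yield
#' too few grid values for a within-triplet contrast.
#'
#' @param triplets Tibble with columns `triplet_id`, `hybrid_name`,
#'   `native_name`, `neophyte_name`.
#' @param occurrences Occupancy tibble (`taxon_name`, `hectad_code`).
#' @param min_hectads Minimum occupied hectads for inclusion (default 11,
#'   i.e. "more than 10").
#' @return `triplets` with added `n_hectads_hybrid` and logical `included`.
#' @export
apply_occupancy_rule <- function(triplets, occurrences, min_hectads = 11L) {
  stopifnot(all(c("triplet_id", "hybrid_name", "native_name",
                  "neophyte_name") %in% names(triplets)))
  counts <- occurrences |>
    dplyr::distinct(.data$taxon_name, .data$hectad_code) |>
    dplyr::count(.data$taxon_name, name = "n_hectads_hybrid")
  triplets |>
    dplyr::left_join(counts, by = c(hybrid_name = "taxon_name")) |>
    dplyr::mutate(
      n_hectads_hybrid = dplyr::coalesce(.data$n_hectads_hybrid, 0L),
      included = .data$n_hectads_hybrid >= min_hectads
    )
}

#' Per-occurrence footprint observations for included triplets
#'
#' Expands each included triplet into its three member taxa (hybrid, native,
#' neophyte), joins each taxon's occupied hectads, and attaches the hectad
#' mean footprint value. Occurrences in hectads without footprint coverage
#' are dropped; a taxon with no joinable hectad at all is reported.
#'
#' @param triplets Output of [apply_occupancy_rule()] (only rows with
#'   `included = TRUE` are used).
#' @param occurrences Occupancy tibble (`taxon_name`, `hectad_code`).
#' @param hectad_hfi Output of [hectad_mean_hfi()].
#' @return A tibble `triplet_id`, `taxon_type`, `taxon_name`, `hectad_code`,
#'   `hfi`; `read_report` attribute lists taxa with an empty join.
#' @export
triplet_observations <- function(triplets, occurrences, hectad_hfi) {
  inc <- dplyr::filter(triplets, .data$included)
  long <- inc |>
    dplyr::select("triplet_id", hybrid = "hybrid_name",
                  native = "native_name", neophyte = "neophyte_name") |>
    tidyr::pivot_longer(cols = c("hybrid", "native", "neophyte"),
                        names_to = "taxon_type", values_to = "taxon_name")
  obs <- long |>
    dplyr::inner_join(dplyr::distinct(occurrences, .data$taxon_name,
                                      .data$hectad_code),
                      by = "taxon_name", relationship = "many-to-many") |>
    dplyr::inner_join(dplyr::select(hectad_hfi, "hectad_code",
                                    hfi = "mean_hfi"),
                      by = "hectad_code")
  joined_taxa <- unique(obs$taxon_name)
  empty <- dplyr::filter(long, !(.data$taxon_name %in% joined_taxa))
  attr(obs, "read_report") <- tibble(
    taxa_in = nrow(long), taxa_joined = nrow(long) - nrow(empty),
    taxa_empty_join = nrow(empty),
    empty_taxa = paste(empty$taxon_name, collapse = ";")
  )
  obs
}

#' Range-coverage comparisons between hybrid and parents
#'
#' For each triplet observed for all three types, tests whether the hybrid's
#' footprint range avoids the most natural habitat of its native parent
#' (`hybrid_min_above_native_min`: the hybrid's minimum HFI is strictly
#' above the native's minimum) and whether the hybrid reaches more
#' human-dominated ground than either parent (`hybrid_max_above_both_parents`:
#' the hybrid's maximum HFI strictly exceeds both parents' maxima). Ties are
#' not exceedances. Triplets missing a type are skipped and reported.
#'
#' @param observations Output of [triplet_observations()].
#' @return A tibble with one row per scored triplet and the two logical
#'   flags; a `counts` attribute holds the one-row summary
#'   (`n_triplets`, `n_min_above`, `n_max_above`) and a `read_report`
#'   attribute the skipped triplets.
#' @export
range_coverage_stats <- function(observations) {
  per_type <- observations |>
    dplyr::group_by(.data$triplet_id, .data$taxon_type) |>
    dplyr::summarise(min_hfi = min(.data$hfi), max_hfi = max(.data$hfi),
                     .groups = "drop")
  wide <- per_type |>
    tidyr::pivot_wider(names_from = "taxon_type",
                       values_from = c("min_hfi", "max_hfi"))
  need <- c("min_hfi_hybrid", "min_hfi_native", "min_hfi_neophyte",
            "max_hfi_hybrid", "max_hfi_native", "max_hfi_neophyte")
  for (nm in setdiff(need, names(wide))) wide[[nm]] <- NA_real_
  complete <- stats::complete.cases(wide[need])
  out <- wide[complete, , drop = FALSE] |>
    dplyr::transmute(
      .data$triplet_id,
      hybrid_min_above_native_min = .data$min_hfi_hybrid > .data$min_hfi_native,
      hybrid_max_above_both_parents =
        .data$max_hfi_hybrid > .data$max_hfi_native &
        .data$max_hfi_hybrid > .data$max_hfi_neophyte
    )
  attr(out, "counts") <- tibble(
    n_triplets = nrow(out),
    n_min_above = sum(out$hybrid_min_above_native_min),
    n_max_above = sum(out$hybrid_max_above_both_parents)
  )
  attr(out, "read_report") <- tibble(
    triplets_in = nrow(wide), triplets_scored = nrow(out),
    skipped_missing_type = nrow(wide) - nrow(out)
  )
  out
}
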