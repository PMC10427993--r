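#' Read a species checklist in WCVP or GloNaF dialect
#'
#' Reads a delimited checklist file and maps its dialect-specific columns onto
#' a unified taxon-record table. The two dialects mirror the layouts of the
#' World Checklist of Vascular Plants distribution export and the Global
#' Naturalized Alien Flora regional lists.
#'
#' Required columns per dialect:
#' \describe{
#'   \item{wcvp}{`taxon_name`, `genus`, `rank`, `species_hybrid`,
#'     `taxon_status`, `region_code`. The `species_hybrid` column carries the
#'     hybrid sign: `"×"` (or `"x"`) marks a natural interspecific
#'     hybrid, `"+"` an artificial (cultivation-origin) hybrid, empty means
#'     not a hybrid. An optional `introduced` column (0/1) distinguishes
#'     native from alien occurrences; when absent the naturalization status
#'     is `not_applicable`.}
#'   \item{glonaf}{`taxon_name`, `genus`, `name_status`, `status`, `hybrid`,
#'     `region_code`. `status` is `naturalized` or `alien`; `hybrid` is 0/1.
#'     An optional `rank` column is honoured; otherwise rank is `species`.}
#' }
#'
#' Rows whose region code is purely numeric are dropped and counted in the
#' read report (such mis-coded regions cannot be matched to a botanical
#' country). The delimiter is auto-detected from comma and tab.
#'
#' @param path Path to a UTF-8 delimited text file with a header.
#' @param dialect `"wcvp"` or `"glonaf"`.
#' @return A tibble with columns `taxon_name`, `genus`, `rank`, `is_hybrid`,
#'   `is_artificial_hybrid`, `name_status`, `naturalization_status`,
#'   `region_code`, carrying a `read_report` attribute (see
#'   [read_report()]).
#' @seealso [filter_hybrids()], [filter_neophytes()]
#' @export
read_checklist <- function(path, dialect = c("wcvp", "glonaf")) {
  dialect <- match.arg(dialect)
  raw <- read_delim_auto(path)
  if (nrow(raw) == 0L) {
    stop("checklist file is empty: ", path, call. = FALSE)
  }
  required <- switch(dialect,
    wcvp = c("taxon_name", "genus", "rank", "species_hybrid",
             "taxon_status", "region_code"),
    glonaf = c("taxon_name", "genus", "name_status", "status", "hybrid",
               "region_code")
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("checklist is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  if (dialect == "wcvp") {
    sign <- str_squish_chr(as.character(raw$species_hybrid))
    is_hybrid <- sign %in% c("×", "x", "X", "+")
    is_artificial <- sign == "+"
    rank <- normalize_rank(raw$rank, is_hybrid)
    name_status <- ifelse(tolower(str_squish_chr(raw$taxon_status)) == "accepted",
                          "accepted", "not_accepted")
    if ("introduced" %in% names(raw)) {
      nat <- ifelse(as.integer(raw$introduced) == 0L, "native", "alien")
    } else {
      nat <- rep("not_applicable", nrow(raw))
    }
  } else {
    is_hybrid <- as.integer(raw$hybrid) == 1L
    is_artificial <- rep(FALSE, nrow(raw))
    if ("rank" %in% names(raw)) {
      rank <- normalize_rank(raw$rank, is_hybrid)
    } else {
      rank <- ifelse(is_hybrid, "hybrid_species", "species")
    }
    name_status <- ifelse(tolower(str_squish_chr(raw$name_status)) == "accepted",
                          "accepted", "not_accepted")
    status <- tolower(str_squish_chr(raw$status))
    nat <- dplyr::case_match(status,
      "naturalized" ~ "naturalized",
      "alien" ~ "alien",
      "native" ~ "native",
      .default = "not_applicable"
    )
  }

  out <- tibble(
    taxon_name = normalize_taxon_name(raw$taxon_name),
    genus = str_squish_chr(raw$genus),
    rank = rank,
    is_hybrid = is_hybrid,
    is_artificial_hybrid = is_artificial,
    name_status = name_status,
    naturalization_status = nat,
    region_code = str_squish_chr(as.character(raw$region_code))
  )

  numeric_region <- grepl("^[0-9]+$", out$region_code)
  empty_region <- is.na(out$region_code) | out$region_code == ""
  keep <- !numeric_region & !empty_region
  report <- tibble(
    rows_in = nrow(out),
    rows_kept = sum(keep),
    dropped_numeric_region = sum(numeric_region),
    dropped_empty_region = sum(empty_region)
  )
  out <- out[keep, , drop = FALSE]
  attr(out, "read_report") <- report
  out
}

#' Retrieve the read report attached to an object
#'
#' Readers and join stages attach a small accounting table (rows read, rows
#' kept, rows dropped and why) so that drop counts plus retained rows always
#' reconcile with the input.
#'
#' @param x An object returned by one of the package's readers or joins.
#' @return A tibble, or `NULL` when no report is attached.
#' @export
read_report <- function(x) attr(x, "read_report")

#' Read a rooted phylogeny from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()]. Duplicate tip labels
#' are rejected; zero-length terminal branches are accepted but flagged in
#' the read report.
#'
#' @param path Path to a Newick file containing a single tree.
#' @return An [ape::phylo] object with a `read_report` attribute.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("cannot parse Newick file ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) {
    stop("cannot parse Newick file ", path, call. = FALSE)
  }
  if (inherits(tree, "multiPhylo")) {
    stop("expected a single tree in ", path, call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label) > 0L) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  terminal <- tree$edge[, 2] <= ape::Ntip(tree)
  n_zero_terminal <- sum(tree$edge.length[terminal] == 0)
  attr(tree, "read_report") <- tibble(
    n_tips = ape::Ntip(tree),
    n_zero_length_terminal = n_zero_terminal
  )
  tree
}

#' Read a human-footprint grid from an ESRI ASCII raster
#'
#' Parses the plain-text ESRI ASCII-grid dialect (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by rows
#' of cell values, top row first). Values are validated against the human
#' footprint index scale: every non-missing cell must lie in `[0, 50]`.
#'
#' @param path Path to an `.asc` file.
#' @param crs_tag Label for the planar coordinate reference system the grid
#'   is expressed in; compared against the polygon table's tag during zonal
#'   extraction.
#' @return A `footprint_grid` object: a list with `values` (numeric matrix,
#'   row 1 = northernmost), `cell_size`, `origin` (x, y of the lower-left
#'   corner), `nodata`, and `crs_tag`.
#' @export
read_raster <- function(path, crs_tag = "planar") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 7L) stop("raster file too short: ", path, call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L) {
      stop("malformed raster header line: ", lines[[i]], call. = FALSE)
    }
    hdr[[tolower(parts[[1]])]] <- parts[[2]]
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("raster header is missing: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  }
  ncols <- as.integer(hdr$ncols)
  nrows <- as.integer(hdr$nrows)
  nodata <- as.numeric(hdr$nodata_value)
  body <- paste(lines[-(1:6)], collapse = " ")
  vals <- strsplit(trimws(body), "[[:space:]]+")[[1]]
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num)) {
    stop("non-numeric raster cell value: ",
         paste(head(vals[is.na(num)], 3), collapse = ", "), call. = FALSE)
  }
  if (length(num) != ncols * nrows) {
    stop("raster body has ", length(num), " cells, header promises ",
         ncols * nrows, call. = FALSE)
  }
  m <- matrix(num, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  bad <- !is.na(m) & (m < 0 | m > 50)
  if (any(bad)) {
    stop(sum(bad), " raster cell(s) outside the human-footprint scale [0, 50]",
         call. = FALSE)
  }
  structure(
    list(values = m,
         cell_size = as.numeric(hdr$cellsize),
         origin = c(x = as.numeric(hdr$xllcorner),
                    y = as.numeric(hdr$yllcorner)),
         nodata = nodata,
         crs_tag = crs_tag),
    class = "footprint_grid"
  )
}

#' Write a footprint grid as an ESRI ASCII raster
#'
#' Inverse of [read_raster()]: writing and re-reading yields an identical
#' grid.
#'
#' @param grid A `footprint_grid` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "footprint_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  hdr <- c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(grid$origin[["x"]], scientific = FALSE)),
    paste("yllcorner", format(grid$origin[["y"]], scientific = FALSE)),
    paste("cellsize", format(grid$cell_size, scientific = FALSE)),
    paste("NODATA_value", format(grid$nodata, scientific = FALSE))
  )
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @export
print.footprint_grid <- function(x, ...) {
  v <- x$values
  cat("<footprint_grid> ", nrow(v), " x ", ncol(v), " cells, cell size ",
      x$cell_size, ", crs '", x$crs_tag, "'\n", sep = "")
  rng <- range(v, na.rm = TRUE)
  cat("  values in [", rng[1], ", ", rng[2], "], ", sum(is.na(v)),
      " missing\n", sep = "")
  invisible(x)
}

#' Read taxon-by-hectad occupancy records
#'
#' Reads a CSV of `taxon_name`, `hectad_code` pairs (the layout of BSBI-style
#' hectad validation exports). Duplicate pairs are collapsed and counted in
#' the read report; hectad codes are opaque keys joined by exact string
#' match.
#'
#' @param path Path to a CSV file.
#' @return A tibble with unique (`taxon_name`, `hectad_code`) rows and a
#'   `read_report` attribute.
#' @export
read_occurrences <- function(path) {
  raw <- read_delim_auto(path)
  need <- c("taxon_name", "hectad_code")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("occupancy file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble(
    taxon_name = normalize_taxon_name(raw$taxon_name),
    hectad_code = str_squish_chr(as.character(raw$hectad_code))
  )
  n_in <- nrow(out)
  out <- dplyr::distinct(out)
  attr(out, "read_report") <- tibble(
    rows_in = n_in, rows_kept = nrow(out),
    dropped_duplicate = n_in - nrow(out)
  )
  out
}

#' Read hectad rectangle geometries
#'
#' Hectads are 10 x 10 km grid squares; their geometry is supplied as an
#' axis-aligned rectangle per code (`hectad_code`, `xmin`, `ymin`, `xmax`,
#' `ymax`) in the same planar coordinate system as the footprint raster.
#'
#' @param path Path to a CSV file.
#' @param crs_tag Planar CRS label, compared with the raster's tag.
#' @return A tibble with a `crs_tag` attribute.
#' @export
read_hectad_polygons <- function(path, crs_tag = "planar") {
  raw <- read_delim_auto(path)
  need <- c("hectad_code", "xmin", "ymin", "xmax", "ymax")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("hectad polygon file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble(
    hectad_code = str_squish_chr(as.character(raw$hectad_code)),
    xmin = as.numeric(raw$xmin), ymin = as.numeric(raw$ymin),
    xmax = as.numeric(raw$xmax), ymax = as.numeric(raw$ymax)
  )
  if (any(out$xmax <= out$xmin) || any(out$ymax <= out$ymin)) {
    stop("degenerate hectad rectangle (max edge not beyond min edge)",
         call. = FALSE)
  }
  attr(out, "crs_tag") <- crs_tag
  out
}

#' Normalize a taxon name for joins
#'
#' Trims outer whitespace and collapses internal runs of spaces; matching is
#' case-sensitive thereafter. This deterministic normalization replaces live
#' taxonomy harmonization against name services, which the package does not
#' attempt.
#'
#' @param x Character vector of taxon names.
#' @return Character vector of normalized names.
#' @export
normalize_taxon_name <- function(x) {
  str_squish_chr(as.character(x))
}

#' Extract the genus token from a taxon name
#'
#' Strips a leading hybrid sign ("×" or "+") and returns the first
#' whitespace-delimited token.
#'
#' @param x Character vector of taxon names.
#' @return Character vector of genus names.
#' @export
genus_from_name <- function(x) {
  x <- normalize_taxon_name(x)
  x <- sub("^[×+]\\s*", "", x)
  vapply(strsplit(x, "\\s+"), function(p) if (length(p)) p[[1]] else NA_character_,
         character(1))
}

## -- internal helpers --------------------------------------------------------

str_squish_chr <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- NA_character_
  stringr::str_squish(x)
}

normalize_rank <- function(rank, is_hybrid) {
  r <- tolower(str_squish_chr(as.character(rank)))
  known <- c("species", "variety", "subvariety", "convariety", "form",
             "subform", "subspecies")
  r <- ifelse(r %in% known, r, "other")
  ifelse(is_hybrid & r == "species", "hybrid_species", r)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("file is empty: ", path, call. = FALSE)
  delim <- if (lengths(regmatches(first, gregexpr("\t", first))) >
               lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}
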