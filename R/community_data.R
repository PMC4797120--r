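#' Path to a packaged example table
#'
#' The package ships the colonization-frequency and bioassay tables of a
#' three-season, six-site, three-tissue endophyte survey as plain CSV files.
#' `mycodiv_example()` returns the full path to one of them, or lists all of
#' them when called without arguments.
#'
#' @param file File name, e.g. `"table2_winter.csv"`. `NULL` lists available
#'   files.
#' @return A file path, or a character vector of file names.
#' @examples
#' mycodiv_example()
#' mycodiv_example("table2_winter.csv")
#' @export
mycodiv_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "mycodiv")))
  }
  path <- system.file("extdata", file, package = "mycodiv")
  if (!nzchar(path)) {
    stop("no packaged file called '", file, "'", call. = FALSE)
  }
  path
}

wide_col_rx <- "^(winter|summer|rainy)_site([1-9][0-9]*)_(leaf|stem|petiole)$"

new_cf_tbl <- function(x) {
  x <- as_tibble(x)
  class(x) <- c("cf_tbl", class(x))
  x
}

validate_cf_values <- function(cf) {
  if (any(is.na(cf))) {
    stop("colonization frequencies contain missing values after decoding",
         call. = FALSE)
  }
  if (any(cf < 0 | cf > 100)) {
    bad <- cf[cf < 0 | cf > 100][1]
    stop("colonization frequency out of [0, 100]: ", bad, call. = FALSE)
  }
  invisible(cf)
}

#' Read a colonization-frequency matrix
#'
#' Reads a species-by-cell percent colonization-frequency (CF) table from CSV.
#' Two dialects are supported:
#'
#' * `"wide"`: one `species` column followed by one column per survey cell,
#'   named `<season>_site<k>_<tissue>` (e.g. `winter_site1_leaf`).  This is
#'   the layout of the printed survey tables; blank cells (the tables' dashes,
#'   meaning "not isolated") decode to exact 0.
#' * `"long"`: columns `species`, `season`, `site`, `tissue`, `cf`.
#'
#' Either way the result is the canonical long form: a tibble with columns
#' `species` (factor, file order preserved), `season`, `site`, `tissue` and
#' `cf` (percent, in \[0, 100\]).
#'
#' @param path Path to a CSV file (RFC 4180, UTF-8, header row).
#' @param dialect `"wide"` or `"long"`.
#' @return A long-format CF tibble (classes `cf_tbl`/`tbl_df`).
#' @seealso [write_cf_matrix()], [cf_to_counts()], [load_survey_cf()]
#' @examples
#' cf <- read_cf_matrix(mycodiv_example("table2_winter.csv"), "wide")
#' dplyr::count(cf, season)
#' @export
read_cf_matrix <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  if (dialect == "wide") {
    if (!identical(names(raw)[1], "species")) {
      stop("wide CF file must have 'species' as its first column, found '",
           names(raw)[1], "'", call. = FALSE)
    }
    cells <- names(raw)[-1]
    bad <- cells[!grepl(wide_col_rx, cells)]
    if (length(bad)) {
      stop("malformed wide CF header column: '", bad[1],
           "' (expected <season>_site<k>_<tissue>)", call. = FALSE)
    }
    out <- raw |>
      tidyr::pivot_longer(-"species", names_to = "cell", values_to = "cf") |>
      tidyr::extract("cell", into = c("season", "site", "tissue"),
                     regex = wide_col_rx) |>
      dplyr::mutate(
        species = factor(.data$species, levels = unique(raw$species)),
        season  = factor(.data$season, levels = season_levels),
        site    = as.integer(.data$site),
        tissue  = factor(.data$tissue, levels = tissue_levels),
        cf      = dplyr::coalesce(as.numeric(.data$cf), 0)
      )
  } else {
    need <- c("species", "season", "site", "tissue", "cf")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols)) {
      stop("long CF file lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    out <- raw |>
      dplyr::mutate(
        species = factor(.data$species, levels = unique(raw$species)),
        season  = factor(.data$season, levels = season_levels),
        site    = as.integer(.data$site),
        tissue  = factor(.data$tissue, levels = tissue_levels),
        cf      = dplyr::coalesce(as.numeric(.data$cf), 0)
      ) |>
      dplyr::select(dplyr::all_of(need))
    if (any(is.na(out$season)) || any(is.na(out$tissue))) {
      stop("unrecognized season or tissue level in long CF file", call. = FALSE)
    }
  }
  validate_cf_values(out$cf)
  new_cf_tbl(out)
}

#' Write a colonization-frequency matrix
#'
#' Inverse of [read_cf_matrix()]: writes the canonical long tibble back to CSV
#' in either dialect, so a long file and its wide re-export round-trip to the
#' identical table.
#'
#' @param x A long CF tibble (as returned by [read_cf_matrix()]).
#' @param path Output CSV path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_cf_matrix <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    readr::write_csv(x[, c("species", "season", "site", "tissue", "cf")], path)
  } else {
    wide <- x |>
      dplyr::mutate(cell = paste0(.data$season, "_site", .data$site, "_",
                                  .data$tissue)) |>
      dplyr::select("species", "cell", "cf") |>
      tidyr::pivot_wider(names_from = "cell", values_from = "cf")
    readr::write_csv(wide, path)
  }
  invisible(path)
}

#' Load the packaged three-season survey
#'
#' Binds the winter, summer and rainy CF fixtures into one long tibble
#' covering the full 24-species x 54-cell survey design.
#'
#' @return A long CF tibble with all three seasons.
#' @examples
#' cf <- load_survey_cf()
#' nrow(cf)  # 24 species x 54 cells
#' @export
load_survey_cf <- function() {
  files <- c("table2_winter.csv", "table3_summer.csv", "table4_rainy.csv")
  out <- purrr::map(files, \(f) read_cf_matrix(mycodiv_example(f), "wide")) |>
    purrr::list_rbind()
  out$species <- factor(as.character(out$species),
                        levels = unique(as.character(out$species)))
  out$season <- factor(as.character(out$season), levels = season_levels)
  new_cf_tbl(out)
}

#' Convert percent CF values to isolate counts
#'
#' The survey's CF values are percentages of colonized tissue segments; with a
#' known number of incubated segments per cell the isolate count is recovered
#' as `round(cf * n_total / 100)`.  Entries whose CF is not consistent with an
#' integer count at that grain (deviation above 0.01 percentage points after
#' back-conversion) are flagged rather than silently accepted.
#'
#' @param x A long CF tibble.
#' @param segments_per_replicate Incubated segments per replicate sample.
#' @param replicates_per_cell Replicate samples per (season, site, tissue)
#'   cell.  The default design is 45 x 3 = 135 segments per cell.
#' @return The input with `cf` replaced by integer `count` plus a logical
#'   `flagged` column marking off-grain CF values.
#' @examples
#' cf <- read_cf_matrix(mycodiv_example("table2_winter.csv"), "wide")
#' counts <- cf_to_counts(cf)
#' sum(counts$count)
#' @export
cf_to_counts <- function(x, segments_per_replicate = 45,
                         replicates_per_cell = 3) {
  stopifnot(segments_per_replicate >= 1, replicates_per_cell >= 1)
  if (any(x$cf < 0)) stop("negative CF value", call. = FALSE)
  n_total <- segments_per_replicate * replicates_per_cell
  x |>
    dplyr::mutate(
      count = as.integer(round(.data$cf * n_total / 100)),
      flagged = abs(.data$cf - .data$count * 100 / n_total) > 0.01
    ) |>
    dplyr::select(-"cf")
}

#' Marginal abundance vectors
#'
#' Sums per-species counts (or CF values) over all factors except `by`,
#' producing one abundance vector per level of that factor — the inputs from
#' which per-season, per-site and per-tissue diversity rows are built.  The
#' grand total of isolates is conserved across the choice of `by`.
#'
#' @param x A long tibble with a `count` (or `cf`) value column.
#' @param by One of `"season"`, `"site"`, `"tissue"`.
#' @return A tibble with columns `by`, `species` and the summed value column.
#' @examples
#' load_survey_cf() |> cf_to_counts() |> marginalize("season")
#' @export
marginalize <- function(x, by) {
  if (!is.character(by) || length(by) != 1 ||
      !by %in% c("season", "site", "tissue")) {
    stop("`by` must be one of \"season\", \"site\", \"tissue\"", call. = FALSE)
  }
  value <- if ("count" %in% names(x)) "count" else if ("cf" %in% names(x)) "cf"
  else stop("no 'count' or 'cf' column to marginalize", call. = FALSE)
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "species")))) |>
    dplyr::summarise("{value}" := sum(.data[[value]]), .groups = "drop")
}

#' Presence/absence sets per factor level
#'
#' A species is present at a level (a season, a site, or a tissue) if any of
#' its CF values in any cell of that level is positive.  The per-site sets
#' (union over seasons and tissues) are the inputs to the Jaccard similarity
#' matrix.
#'
#' @inheritParams marginalize
#' @return A named list mapping each level to a character vector of species.
#' @examples
#' presence_absence(load_survey_cf(), "site") |> lengths()
#' @export
presence_absence <- function(x, by) {
  if (!by %in% c("season", "site", "tissue")) {
    stop("`by` must be one of \"season\", \"site\", \"tissue\"", call. = FALSE)
  }
  value <- if ("cf" %in% names(x)) "cf" else "count"
  levs <- if (is.factor(x[[by]])) levels(droplevels(x[[by]]))
  else sort(unique(x[[by]]))
  present <- x |>
    dplyr::filter(.data[[value]] > 0) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c(by, "species"))))
  out <- purrr::map(levs, \(l) {
    as.character(present$species[present[[by]] == l])
  })
  setNames(out, as.character(levs))
}
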