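#' Survey tables
#'
#' A survey table holds one row per quadrat: identifiers (`quadrat_id`,
#' `transect_id`, optional `stage`), the plant and soil covariates
#' (`agb`, `bgb`, `plant_density`, `plant_height`, `sbd`, `sm`, `st`,
#' `stc`, `stn`, `stp`, `sts`), and one column per species prefixed
#' `"sp:"` giving dry aboveground biomass in g per 0.25 m2 quadrat.
#'
#' A species biomass of exactly 0 means "recorded absent" and is distinct
#' from a missing cell (`NA`), which means the species was not assessed in
#' that quadrat. Missing cells are flagged at read time, never imputed.
#'
#' @param x A data frame with the columns described above.
#' @return `as_survey_table()` returns a validated tibble of class
#'   `survey_table`.
#' @examples
#' tbl <- as_survey_table(tibble::tibble(
#'   quadrat_id = c("q1", "q2"), transect_id = "t1", stage = c(1L, 2L),
#'   agb = c(3, 2), bgb = 10, plant_density = 50, plant_height = 12,
#'   sbd = 0.9, sm = 30, st = 12, stc = 50, stn = 4, stp = 0.9, sts = 0.8,
#'   `sp:Kobresia graminifolia` = c(2, 0), `sp:Elymus nutans` = c(1, 2)
#' ))
#' species_universe(tbl)
#' @export
as_survey_table <- function(x) {
  x <- tibble::as_tibble(x)
  validate_survey_table(x)
  if (!inherits(x, "survey_table")) {
    class(x) <- c("survey_table", class(x))
  }
  x
}

#' @rdname as_survey_table
#' @export
is_survey_table <- function(x) inherits(x, "survey_table")

#' @rdname as_survey_table
#' @export
species_universe <- function(x) {
  sub(paste0("^", .species_prefix), "", species_cols(x))
}

species_cols <- function(x) {
  grep(paste0("^", .species_prefix), names(x), value = TRUE)
}

#' Extract the quadrat-by-species biomass matrix
#'
#' @param x A `survey_table`.
#' @return Numeric matrix, rows named by `quadrat_id`, columns by species
#'   name (without the `"sp:"` prefix). `NA` marks unassessed cells.
#' @export
species_biomass_matrix <- function(x) {
  cols <- species_cols(x)
  m <- as.matrix(x[cols])
  colnames(m) <- sub(paste0("^", .species_prefix), "", cols)
  rownames(m) <- x$quadrat_id
  storage.mode(m) <- "double"
  m
}

validate_survey_table <- function(x, agb_tol = 1e-6) {
  required <- c("quadrat_id", "transect_id", .covariate_cols)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort_schema(paste0(
      "survey table is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(x$quadrat_id)) {
    dup <- unique(x$quadrat_id[duplicated(x$quadrat_id)])
    abort_validation(paste0(
      "duplicated quadrat_id: ", paste(dup, collapse = ", ")
    ))
  }
  sp <- species_cols(x)
  if (length(sp) > 0) {
    m <- as.matrix(x[sp])
    neg <- which(rowSums(m < 0, na.rm = TRUE) > 0)
    if (length(neg) > 0) {
      abort_validation(paste0(
        "negative species biomass in quadrat(s): ",
        paste(x$quadrat_id[neg], collapse = ", ")
      ))
    }
  }
  num_cols <- c(.covariate_cols)
  for (col in num_cols) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      abort_schema(paste0("column '", col, "' must be numeric"))
    }
    if (any(v < 0, na.rm = TRUE) &&
        col %in% c("agb", "bgb", "plant_density", "plant_height",
                   "sbd", "sm", "stc", "stn", "stp", "sts")) {
      bad <- x$quadrat_id[which(v < 0)]
      abort_validation(paste0(
        "negative value in '", col, "' for quadrat(s): ",
        paste(bad, collapse = ", ")
      ))
    }
  }
  # AGB recorded alongside a full species census must agree with its sum.
  if (length(sp) > 0) {
    m <- as.matrix(x[sp])
    complete <- rowSums(is.na(m)) == 0 & !is.na(x$agb)
    if (any(complete)) {
      sums <- rowSums(m[complete, , drop = FALSE])
      agb <- x$agb[complete]
      off <- abs(agb - sums) > agb_tol * pmax(1, abs(agb))
      if (any(off)) {
        abort_validation(paste0(
          "agb does not match the species biomass sum for quadrat(s): ",
          paste(x$quadrat_id[complete][off], collapse = ", ")
        ))
      }
    }
  }
  invisible(x)
}

#' Read a quadrat survey table from CSV
#'
#' Two layouts are accepted. `"wide"` has one row per quadrat with species
#' biomass columns prefixed `"sp:"`. `"long"` has one row per quadrat x
#' species with columns `quadrat_id`, `species`, `biomass`, plus the
#' covariates repeated on each row of a quadrat; it is pivoted to the wide
#' internal representation. Files are comma-separated UTF-8 with a header
#' row and `.` decimals.
#'
#' Missing numeric cells are kept as `NA` and flagged via the
#' `"missing_cells"` attribute (a tibble of quadrat/column positions);
#' they are never imputed.
#'
#' @param path Path to a CSV file.
#' @param layout `"wide"` or `"long"`.
#' @return A `survey_table`.
#' @export
read_survey_table <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    abort_schema(paste0("file not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (layout == "long") {
    for (col in c("quadrat_id", "species", "biomass")) {
      if (!col %in% names(raw)) {
        abort_schema(paste0("long layout is missing required column: ", col))
      }
    }
    raw <- tidyr::pivot_wider(
      raw,
      names_from = "species",
      values_from = "biomass",
      names_prefix = .species_prefix
    )
  }
  if ("stage" %in% names(raw)) {
    raw$stage <- as.integer(raw$stage)
  }
  raw$quadrat_id <- as.character(raw$quadrat_id)
  if ("transect_id" %in% names(raw)) {
    raw$transect_id <- as.character(raw$transect_id)
  }
  tbl <- as_survey_table(raw)
  miss <- which(is.na(as.matrix(tbl[c(.covariate_cols, species_cols(tbl))])),
                arr.ind = TRUE)
  if (nrow(miss) > 0) {
    cols <- c(.covariate_cols, species_cols(tbl))
    flagged <- tibble::tibble(
      quadrat_id = tbl$quadrat_id[miss[, 1]],
      column = cols[miss[, 2]]
    )
    attr(tbl, "missing_cells") <- flagged
    inform(paste0(
      nrow(flagged), " missing cell(s) flagged in ", basename(path),
      " (kept as NA, not imputed)"
    ))
  }
  tbl
}

#' Write result tables with a run manifest
#'
#' Writes each table in `tables` as `<name>.csv` under `out_dir` (full
#' numeric precision, so a re-read reproduces values to at least 12
#' significant digits) plus a `manifest.json` recording the configuration
#' echo, seed, package and R versions, and per-file MD5 checksums.
#'
#' @param tables Named list of data frames. May be empty.
#' @param out_dir Output directory, created if needed.
#' @param config Optional configuration object echoed into the manifest.
#' @param seed Optional integer seed echoed into the manifest.
#' @return The manifest, invisibly.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  if (length(tables) > 0 && (is.null(names(tables)) || any(names(tables) == ""))) {
    abort_schema("'tables' must be a named list")
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    abort(paste0("output directory is not writable: ", out_dir),
          class = "meadowsucc_io_error")
  }
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], f, progress = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    package = "meadowsucc",
    version = as.character(packageVersion("meadowsucc")),
    r_version = as.character(getRversion()),
    seed = seed,
    config = config_echo(config),
    tables = names(tables) %||% character(0),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(manifest)
}

config_echo <- function(config) {
  strip <- function(x) {
    if (is.data.frame(x)) as.list(as.data.frame(x)) else
      if (is.list(x)) lapply(unclass(x), strip) else x
  }
  if (is.null(config)) NULL else strip(config)
}
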