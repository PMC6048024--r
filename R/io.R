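#' Read and write the pipeline's CSV dialects
#'
#' All tables are UTF-8 CSV with a header row and `.` decimal separator.
#' Censoring is always encoded as a logical `censored` column with `NA` in
#' the numeric half-life column, never as a sentinel value. Readers validate
#' the column set and types and report malformed rows by line number; an
#' empty file is an explicit error.
#'
#' Dialects: volume tables (`particle_id`, `time_h`, one of `area_px2`,
#' `volume_um3`, `volume_norm`); dose tables (`strain`,
#' `b0_cells_per_ml`, `replicate`, `tau_half_h`, `censored`); phase-plane
#' grids (`bp0_cells_per_ml`, `bs0_cells_per_ml`, `replicate`, `tau_half_h`,
#' `censored`); CFU tables (`strain`, `role`, `condition`, `time_h`,
#' `cfu_per_ml`); model trajectories (`time_h`, `b`, `R`, `source`).
#'
#' @param path File path.
#' @param data Tibble to write (package-internal column names; writers map
#'   them to the dialect's column names).
#' @return Readers return tibbles with package-internal column names
#'   (`b0`, `tau_half`, ...); writers return `path` invisibly.
#' @name pipeline_io
NULL

read_checked <- function(path, col_types, required) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (file.size(path) == 0) abort(paste0("Empty input file: ", path))
  x <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  )
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed CSV %s: line %d, column %s (expected %s).",
                  path, probs$row[1], probs$col[1], probs$expected[1]))
  }
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) abort(paste0("No data rows in ", path))
  as_tibble(x)
}

#' @rdname pipeline_io
#' @export
read_volume_csv <- function(path) {
  x <- read_checked(path, readr::cols(particle_id = readr::col_character(),
                                      .default = readr::col_double()),
                    c("particle_id", "time_h"))
  if (!any(c("area_px2", "volume_um3", "volume_norm") %in% names(x))) {
    abort(paste0(path, " needs one of: area_px2, volume_um3, volume_norm."))
  }
  x
}

#' @rdname pipeline_io
#' @export
write_volume_csv <- function(data, path) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_dose_csv <- function(path) {
  x <- read_checked(
    path,
    readr::cols(strain = readr::col_character(),
                censored = readr::col_logical(),
                .default = readr::col_double()),
    c("strain", "b0_cells_per_ml", "replicate", "tau_half_h", "censored")
  )
  dplyr::rename(x, b0 = "b0_cells_per_ml", tau_half = "tau_half_h")
}

#' @rdname pipeline_io
#' @export
write_dose_csv <- function(data, path) {
  out <- as_tibble(data)
  if (!"strain" %in% names(out)) out$strain <- "unknown"
  out <- out |>
    dplyr::select("strain", b0_cells_per_ml = "b0", "replicate",
                  tau_half_h = "tau_half", "censored")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_grid_csv <- function(path) {
  x <- read_checked(
    path,
    readr::cols(censored = readr::col_logical(),
                .default = readr::col_double()),
    c("bp0_cells_per_ml", "bs0_cells_per_ml", "replicate", "tau_half_h",
      "censored")
  )
  dplyr::rename(x, bp0 = "bp0_cells_per_ml", bs0 = "bs0_cells_per_ml",
                tau_half = "tau_half_h")
}

#' @rdname pipeline_io
#' @export
write_grid_csv <- function(data, path) {
  out <- as_tibble(data) |>
    dplyr::select(bp0_cells_per_ml = "bp0", bs0_cells_per_ml = "bs0",
                  "replicate", tau_half_h = "tau_half", "censored")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_cfu_csv <- function(path) {
  read_checked(
    path,
    readr::cols(strain = readr::col_character(),
                role = readr::col_character(),
                condition = readr::col_character(),
                .default = readr::col_double()),
    c("strain", "role", "condition", "time_h", "cfu_per_ml")
  )
}

#' @rdname pipeline_io
#' @export
write_cfu_csv <- function(data, path) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_trajectory_csv <- function(path) {
  read_checked(path,
               readr::cols(source = readr::col_character(),
                           .default = readr::col_double()),
               c("time_h", "b", "R", "source"))
}

#' @rdname pipeline_io
#' @export
write_trajectory_csv <- function(data, path) {
  readr::write_csv(as_tibble(data)[, c("time_h", "b", "R", "source")],
                   path, progress = FALSE)
  invisible(path)
}
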