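#' Convert particle cross-section area to volume
#'
#' Particles are assumed spherical, so a cross-section of area `A` (through
#' the equator) implies radius `sqrt(A / pi)` and volume
#' `(4/3) * pi * (A / pi)^(3/2)`. When `pixel_size_um` is supplied, `area`
#' is taken in pixel^2 and converted to um^2 first (the imaging scale of the
#' time-lapse setup is 0.4545 um/pixel); otherwise `area` is already um^2.
#'
#' @param area Cross-section area(s), pixel^2 or um^2; must be >= 0.
#' @param pixel_size_um Pixel edge length in um/pixel, or `NULL` if `area`
#'   is already in um^2.
#' @return Volume(s) in um^3.
#' @examples
#' area_to_volume(pi * 15^2) # sphere of radius 15 um
#' area_to_volume(1000, pixel_size_um = 0.4545)
#' @export
area_to_volume <- function(area, pixel_size_um = NULL) {
  if (any(!is.finite(area)) || any(area < 0)) {
    abort("`area` must be finite and non-negative.")
  }
  if (!is.null(pixel_size_um)) {
    if (pixel_size_um <= 0) abort("`pixel_size_um` must be positive.")
    area <- area * pixel_size_um^2
  }
  (4 / 3) * pi * (area / pi)^(3 / 2)
}

#' Normalize particle volume trajectories to initial volume
#'
#' Divides each particle's volume series by its volume at the first time
#' point, so trajectories from particles of different sizes are comparable
#' and `volume_norm` starts at exactly 1. Values above 1 (pre-collapse
#' swelling of the hydrogel) are retained, not clipped. If the input carries
#' `area_px2` but no `volume_um3`, areas are converted with
#' [area_to_volume()] first.
#'
#' @param data A data frame with columns `particle_id`, `time_h` and one of
#'   `volume_um3` or `area_px2`.
#' @param pixel_size_um Pixel scale used when converting `area_px2`;
#'   default 0.4545 um/pixel.
#' @return A tibble with the input columns plus `volume_um3` (if derived)
#'   and `volume_norm`, ordered by particle and time.
#' @examples
#' d <- tibble::tibble(particle_id = "p1", time_h = c(0, 2, 4, 6),
#'                     volume_um3 = c(8000, 8000, 4000, 400))
#' normalize_trajectory(d)
#' @export
normalize_trajectory <- function(data, pixel_size_um = 0.4545) {
  data <- as_tibble(data)
  if (!all(c("particle_id", "time_h") %in% names(data))) {
    abort("`data` needs columns `particle_id` and `time_h`.")
  }
  if (!"volume_um3" %in% names(data)) {
    if (!"area_px2" %in% names(data)) {
      abort("`data` needs a `volume_um3` or `area_px2` column.")
    }
    data$volume_um3 <- area_to_volume(data$area_px2, pixel_size_um)
  }
  if (any(data$volume_um3 < 0)) abort("Volumes must be non-negative.")
  data <- dplyr::arrange(data, .data$particle_id, .data$time_h)
  bad_t <- data |>
    dplyr::summarise(ok = all(diff(.data$time_h) > 0),
                     .by = "particle_id")
  if (!all(bad_t$ok)) abort("Times must be strictly increasing per particle.")
  out <- data |>
    dplyr::mutate(volume_norm = {
      v0 <- .data$volume_um3[1]
      if (v0 <= 0) abort("Initial volume must be strictly positive.")
      .data$volume_um3 / v0
    }, .by = "particle_id")
  out
}
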