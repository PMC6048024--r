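#' Consumer-to-degrader inoculum ratio
#'
#' The key control variable of the coculture phase plane is
#' `gamma = [Bs]0 / [Bp]0`, the ratio of secondary consumer to primary
#' degrader inoculum. Blocking of degradation depends on this ratio, not on
#' the absolute consumer concentration.
#'
#' @param bs0 Secondary consumer inoculum (cells/ml, >= 0; 0 denotes a
#'   degrader monoculture).
#' @param bp0 Primary degrader inoculum (cells/ml, > 0).
#' @return `gamma` (dimensionless), vectorized.
#' @examples
#' compute_gamma(2e5, 1.25e5) # 1.6
#' @export
compute_gamma <- function(bs0, bp0) {
  if (any(bp0 <= 0)) abort("`bp0` must be strictly positive.")
  if (any(bs0 < 0)) abort("`bs0` must be non-negative.")
  bs0 / bp0
}

check_grid <- function(grid) {
  grid <- as_tibble(grid)
  need <- c("bp0", "bs0", "tau_half")
  if (!all(need %in% names(grid))) {
    abort("Grid needs columns `bp0`, `bs0`, `tau_half` (and optionally `replicate`, `censored`).")
  }
  if (!"censored" %in% names(grid)) grid$censored <- is.na(grid$tau_half)
  grid$censored <- grid$censored | is.na(grid$tau_half)
  if (any(grid$bp0 <= 0) || any(grid$bs0 < 0)) {
    abort("Inoculum levels must be positive (`bp0`) / non-negative (`bs0`).")
  }
  grid
}

#' Classify phase-plane cells as blocked, delayed or degraded
#'
#' A cell (one `bp0 x bs0` condition) is `blocked` when every replicate is
#' censored at the horizon — degradation did not occur. Cells where only
#' some replicates are censored are `delayed`, not blocked; cells with no
#' censoring are `degraded`.
#'
#' @param grid A long-format data frame with columns `bp0`, `bs0`,
#'   `tau_half` and optionally `replicate`, `censored` (`NA` half-lives also
#'   count as censored).
#' @return A tibble with one row per cell: `bp0`, `bs0`, `gamma`, `n_rep`,
#'   `n_censored`, `mean_tau_half` (over observed collapses, `NA` if none),
#'   `blocked`, `status`.
#' @export
classify_blocked <- function(grid) {
  grid <- check_grid(grid)
  grid |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      n_censored = sum(.data$censored),
      mean_tau_half = if (any(!.data$censored))
        mean(.data$tau_half[!.data$censored]) else NA_real_,
      .by = c("bp0", "bs0")
    ) |>
    dplyr::mutate(
      gamma = compute_gamma(.data$bs0, .data$bp0),
      blocked = .data$n_censored == .data$n_rep,
      status = dplyr::case_when(
        blocked ~ "blocked",
        n_censored > 0 ~ "delayed",
        TRUE ~ "degraded"
      )
    ) |>
    dplyr::relocate("gamma", .after = "bs0") |>
    dplyr::arrange(.data$bp0, .data$bs0)
}

#' Estimate the critical blocking ratio gamma*
#'
#' Pools phase-plane cells by their inoculum ratio `gamma` and brackets the
#' critical ratio above which degradation is blocked: the lower edge is the
#' largest `gamma` at which any cell still degraded (or was merely delayed),
#' the upper edge the smallest `gamma` at which every cell was blocked. The
#' point estimate is the geometric midpoint of the bracket, appropriate for
#' the multiplicative grids on which such experiments are run. Monotonicity
#' violations (an unblocked cell at a ratio above some blocked cell) are
#' counted and reported.
#'
#' With `by_row = TRUE` the estimate is computed separately for each `bp0`
#' row, which allows testing the ratio-only hypothesis itself.
#'
#' @inheritParams classify_blocked
#' @param by_row Estimate per `bp0` row instead of pooling. Default `FALSE`.
#' @return A tibble (one row, or one per `bp0` when `by_row`): `gamma_star`,
#'   `gamma_lower` (largest unblocked gamma), `gamma_upper` (smallest
#'   all-blocked gamma), `bound` (`"point"`, `"lower"` or `"upper"`),
#'   `monotone_violations`.
#' @export
estimate_critical_gamma <- function(grid, by_row = FALSE) {
  cells <- classify_blocked(grid)
  if (by_row) {
    return(cells |>
             dplyr::group_by(.data$bp0) |>
             dplyr::group_modify(function(d, key) gamma_bracket(d)) |>
             dplyr::ungroup())
  }
  gamma_bracket(cells)
}

gamma_bracket <- function(cells) {
  unblocked_g <- cells$gamma[!cells$blocked]
  blocked_g <- cells$gamma[cells$blocked]

  # gammas at which *every* cell is blocked
  by_g <- cells |>
    dplyr::summarise(all_blocked = all(.data$blocked), .by = "gamma")
  fully_blocked_g <- by_g$gamma[by_g$all_blocked]

  violations <- if (length(blocked_g) > 0) {
    sum(unblocked_g > min(blocked_g))
  } else 0L

  if (length(blocked_g) == 0L) {
    return(tibble(gamma_star = NA_real_,
                  gamma_lower = max(cells$gamma), gamma_upper = NA_real_,
                  bound = "lower", monotone_violations = violations))
  }
  if (length(unblocked_g) == 0L) {
    return(tibble(gamma_star = NA_real_,
                  gamma_lower = NA_real_, gamma_upper = min(cells$gamma),
                  bound = "upper", monotone_violations = violations))
  }
  lo <- max(unblocked_g)
  hi <- suppressWarnings(min(fully_blocked_g[fully_blocked_g > lo]))
  if (!is.finite(hi)) hi <- suppressWarnings(min(blocked_g[blocked_g > lo]))
  if (!is.finite(hi)) hi <- min(blocked_g) # heavy violations: bracket degenerates
  tibble(gamma_star = sqrt(lo * hi), gamma_lower = lo, gamma_upper = hi,
         bound = "point", monotone_violations = as.integer(violations))
}

#' Export a phase-plane grid as a heat-map table
#'
#' Produces the matrix form of the phase plane: rows are degrader levels
#' `bp0`, columns consumer levels `bs0`, and each cell the mean half-life of
#' the observed collapses. Blocked cells (all replicates censored) are
#' emitted as the horizon value with a `">"` censoring marker, e.g.
#' `">240"`. The inverse, [heatmap_table_to_grid()], parses such a table
#' back into long format, so export and import round-trip.
#'
#' @inheritParams classify_blocked
#' @param horizon_h Observation horizon (h) used for the blocked marker.
#'   Default 240.
#' @return A tibble: first column `bp0`, remaining character columns named
#'   by the `bs0` levels.
#' @export
export_heatmap_table <- function(grid, horizon_h = 240) {
  cells <- classify_blocked(grid)
  cells |>
    dplyr::mutate(
      cell = ifelse(.data$blocked,
                    paste0(">", format(horizon_h)),
                    as.character(round(.data$mean_tau_half, 6))),
      bs0 = format(.data$bs0, scientific = FALSE, trim = TRUE)
    ) |>
    dplyr::select("bp0", "bs0", "cell") |>
    tidyr::pivot_wider(names_from = "bs0", values_from = "cell") |>
    dplyr::arrange(.data$bp0)
}

#' @rdname export_heatmap_table
#' @param table A table as produced by [export_heatmap_table()].
#' @return `heatmap_table_to_grid()`: a long tibble with columns `bp0`,
#'   `bs0`, `replicate`, `tau_half`, `censored` (one pseudo-replicate per
#'   cell; censored cells carry `NA` half-life).
#' @export
heatmap_table_to_grid <- function(table, horizon_h = 240) {
  long <- table |>
    tidyr::pivot_longer(-"bp0", names_to = "bs0", values_to = "cell") |>
    dplyr::mutate(
      bs0 = as.numeric(.data$bs0),
      censored = startsWith(.data$cell, ">"),
      tau_half = ifelse(.data$censored, NA_real_,
                        suppressWarnings(as.numeric(.data$cell))),
      replicate = 1L
    ) |>
    dplyr::select("bp0", "bs0", "replicate", "tau_half", "censored")
  long
}

#' Heat-map plot of a phase-plane grid
#'
#' @inheritParams export_heatmap_table
#' @return A ggplot object; blocked cells are drawn at the horizon value and
#'   outlined.
#' @export
plot_phase_plane <- function(grid, horizon_h = 240) {
  cells <- classify_blocked(grid) |>
    dplyr::mutate(fill_tau = ifelse(.data$blocked, horizon_h,
                                    .data$mean_tau_half))
  ggplot2::ggplot(cells, ggplot2::aes(x = factor(.data$bs0),
                                      y = factor(.data$bp0),
                                      fill = .data$fill_tau)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$blocked),
                       linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = NA),
                                 guide = "none") +
    ggplot2::scale_fill_viridis_c(name = expression(tau[1 / 2] ~ "(h)")) +
    ggplot2::labs(x = expression(group("[", B[s], "]")[0] ~ "(cells/ml)"),
                  y = expression(group("[", B[p], "]")[0] ~ "(cells/ml)"))
}
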