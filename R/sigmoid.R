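#' Fit a collapse sigmoid to a normalized volume trajectory
#'
#' Estimates the particle half-life `tau_half` and collapse steepness `k` by
#' nonlinear least squares of
#' \deqn{v(t) = 1 / (1 + e^{k (t - \tau_{1/2})})}
#' to the normalized volume series, with both parameters constrained
#' positive (Levenberg-Marquardt with box bounds). At `t = tau_half` the
#' fitted curve equals exactly 0.5, matching the definition of the half-life
#' as the time of the half-volume crossing.
#'
#' A trajectory that never drops below 0.5 within the observation window
#' contains no half-volume crossing, so no interior estimate exists: the fit
#' is declared censored and the last observation time is reported as a lower
#' bound on `tau_half`. Pre-collapse swelling (values above 1) is retained
#' and simply contributes residuals, since the upper asymptote is fixed at 1.
#'
#' Optimization is ordinary least squares with up to 5 deterministic
#' restarts from a jittered grid of starting values; the best converged fit
#' by residual sum of squares is kept.
#'
#' @param data A data frame with columns `time_h` and `volume_norm` (one
#'   particle), at least 5 time points.
#' @param init_k Starting value for the steepness `k` (1/h). Default 0.5.
#' @param init_tau Starting value for `tau_half` (h). Default: the last time
#'   at which the normalized volume is above 0.5 (strain-dependent in
#'   practice, data-driven here).
#' @return An object of class `sigmoid_fit` with fields `k`, `tau_half`,
#'   `rss`, `converged`, `censored`, `tau_lower` (horizon bound when
#'   censored), `n_points`, and the fitting data. Use [tidy()] / [glance()]
#'   to extract tibbles.
#' @examples
#' t <- seq(0, 240, by = 2)
#' d <- tibble::tibble(time_h = t, volume_norm = 1 / (1 + exp(0.5 * (t - 100))))
#' glance(fit_sigmoid(d))
#' @export
fit_sigmoid <- function(data, init_k = 0.5, init_tau = NULL) {
  data <- as_tibble(data)
  if (!all(c("time_h", "volume_norm") %in% names(data))) {
    abort("`data` needs columns `time_h` and `volume_norm`.")
  }
  data <- dplyr::arrange(data, .data$time_h)
  t <- data$time_h
  v <- data$volume_norm
  if (length(t) < 5L) abort("At least 5 time points are required.")
  if (any(diff(t) <= 0)) abort("Times must be strictly increasing.")

  horizon <- max(t)
  if (min(v) > 0.5) {
    return(new_sigmoid_fit(k = NA_real_, tau_half = NA_real_, rss = NA_real_,
                           converged = FALSE, censored = TRUE,
                           tau_lower = horizon, n_points = length(t),
                           data = data))
  }

  if (is.null(init_tau)) {
    above <- t[v > 0.5]
    init_tau <- if (length(above) > 0) max(above) else t[1]
    init_tau <- max(init_tau, 1e-3)
  }

  # deterministic restart grid: no RNG, reproducible by construction
  starts <- tibble(
    k = init_k * c(1, 0.5, 2, 0.25, 4, 1),
    tau = pmax(init_tau + c(0, -10, 10, -20, 20, 0.5 * init_tau), 1e-3)
  )

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ 1 / (1 + exp(k * (t - tau))),
        start = list(k = starts$k[i], tau = starts$tau[i]),
        lower = c(k = 1e-9, tau = 1e-9),
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ftol = 1e-14, ptol = 1e-14
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    return(new_sigmoid_fit(k = NA_real_, tau_half = NA_real_, rss = NA_real_,
                           converged = FALSE, censored = FALSE,
                           tau_lower = NA_real_, n_points = length(t),
                           data = data))
  }
  cf <- coef(best$fit)
  new_sigmoid_fit(k = unname(cf["k"]), tau_half = unname(cf["tau"]),
                  rss = best$rss, converged = TRUE, censored = FALSE,
                  tau_lower = NA_real_, n_points = length(t), data = data)
}

new_sigmoid_fit <- function(k, tau_half, rss, converged, censored, tau_lower,
                            n_points, data) {
  structure(
    list(k = k, tau_half = tau_half, rss = rss, converged = converged,
         censored = censored, tau_lower = tau_lower, n_points = n_points,
         data = data),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit>\n")
  if (x$censored) {
    cat(sprintf("  censored: no collapse observed; tau_half > %g h\n",
                x$tau_lower))
  } else if (!x$converged) {
    cat("  did not converge\n")
  } else {
    cat(sprintf("  k = %.4g 1/h, tau_half = %.4g h (rss %.3g, n %d)\n",
                x$k, x$tau_half, x$rss, x$n_points))
  }
  invisible(x)
}

#' @rdname fit_sigmoid
#' @param x A `sigmoid_fit` object.
#' @param ... Unused.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("k", "tau_half"), estimate = c(x$k, x$tau_half))
}

#' @rdname fit_sigmoid
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(k = x$k, tau_half = x$tau_half, rss = x$rss,
         converged = x$converged, censored = x$censored,
         tau_lower = x$tau_lower, n_points = x$n_points)
}

#' Predicted normalized volume from a sigmoid fit
#' @param object A `sigmoid_fit` object.
#' @param newdata Optional data frame with a `time_h` column.
#' @param ... Unused.
#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_h else newdata$time_h
  if (object$censored || !object$converged) {
    abort("No point estimate available (censored or unconverged fit).")
  }
  1 / (1 + exp(object$k * (t - object$tau_half)))
}

#' Extract particle half-lives from a table of volume trajectories
#'
#' Applies [fit_sigmoid()] to each particle in a long-format table. With
#' `method = "per_particle"` (default) each particle is fitted separately;
#' with `method = "mean_curve"` the normalized volumes are averaged across
#' particles at each time point and a single fit is returned (with
#' `particle_id = "mean"`).
#'
#' @param data A data frame with columns `particle_id`, `time_h`,
#'   `volume_norm` (run [normalize_trajectory()] first if starting from raw
#'   volumes or areas).
#' @param method `"per_particle"` or `"mean_curve"`.
#' @inheritParams fit_sigmoid
#' @return A tibble with one row per fit: `particle_id`, `k`, `tau_half`,
#'   `rss`, `converged`, `censored`, `tau_lower`, `n_points`.
#' @export
fit_halflife <- function(data, method = c("per_particle", "mean_curve"),
                         init_k = 0.5, init_tau = NULL) {
  method <- match.arg(method)
  data <- as_tibble(data)
  if (!all(c("particle_id", "time_h", "volume_norm") %in% names(data))) {
    abort("`data` needs columns `particle_id`, `time_h`, `volume_norm`.")
  }
  if (method == "mean_curve") {
    data <- data |>
      dplyr::summarise(volume_norm = mean(.data$volume_norm),
                       .by = "time_h") |>
      dplyr::mutate(particle_id = "mean")
  }
  data |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::group_modify(function(d, key) {
      glance(fit_sigmoid(d, init_k = init_k, init_tau = init_tau))
    }) |>
    dplyr::ungroup()
}

#' Pool half-life fits from replicate particles of one condition
#'
#' Summarizes replicate sigmoid fits: mean and standard deviation of
#' `tau_half` over non-censored converged replicates, plus the censored
#' count. A condition in which every replicate is censored is classified
#' `blocked` (degradation did not occur within the horizon). Mixed censoring
#' is reported, never imputed: the mean is over the observed collapses only,
#' with a warning.
#'
#' @param fits A tibble as returned by [fit_halflife()] (columns `tau_half`,
#'   `censored`, `converged`).
#' @param min_replicates Expected number of replicates; fewer triggers a
#'   warning. Default 3.
#' @return A one-row tibble: `mean_tau_half`, `sd_tau_half`, `n`,
#'   `n_censored`, `blocked`.
#' @export
pooled_half_life <- function(fits, min_replicates = 3) {
  fits <- as_tibble(fits)
  if (nrow(fits) == 0L) abort("`fits` is empty.")
  if (!all(c("tau_half", "censored") %in% names(fits))) {
    abort("`fits` needs columns `tau_half` and `censored`.")
  }
  ok <- !fits$censored & (if ("converged" %in% names(fits)) fits$converged else TRUE)
  n_cens <- sum(fits$censored)
  if (nrow(fits) < min_replicates) {
    warn(sprintf("Only %d replicate fit(s); expected at least %d.",
                 nrow(fits), min_replicates))
  }
  if (n_cens > 0 && any(ok)) {
    warn(sprintf("%d of %d replicates censored; mean is over observed collapses only.",
                 n_cens, nrow(fits)))
  }
  tibble(
    mean_tau_half = if (any(ok)) mean(fits$tau_half[ok]) else NA_real_,
    sd_tau_half = if (sum(ok) > 1) sd(fits$tau_half[ok]) else NA_real_,
    n = sum(ok),
    n_censored = n_cens,
    blocked = !any(ok) && n_cens == nrow(fits)
  )
}

#' Plot a volume trajectory and its sigmoid fit
#'
#' @param object A `sigmoid_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_h, y = .data$volume_norm)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Time (h)", y = "Normalized particle volume")
  if (!object$censored && object$converged) {
    grid <- tibble(time_h = seq(min(object$data$time_h),
                                max(object$data$time_h), length.out = 200))
    grid$fit <- predict(object, grid)
    p <- p +
      ggplot2::geom_line(data = grid,
                         ggplot2::aes(y = .data$fit), colour = "firebrick") +
      ggplot2::geom_vline(xintercept = object$tau_half, linetype = 2)
  }
  p
}
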