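#' Closed-form kinetic trajectory for the non-cooperative model
#'
#' For `n = 1` the rescaled model
#' \deqn{db/dt = \alpha + \beta b, \quad dR/dt = -\beta b}
#' with `b(0) = 0`, `R(0) = r0` has the closed-form solution
#' \deqn{b(t) = (\alpha/\beta)(e^{\beta t} - 1), \quad
#'       R(t) = r_0 - (\alpha/\beta)(e^{\beta t} - 1) + \alpha t.}
#' `R` is evaluated as written and may go negative past full depletion;
#' callers truncate at the depletion time if they need a physical resource.
#'
#' @param params A [degradation_params()] object with `n = 1`.
#' @param times Numeric vector of times (h), strictly increasing, starting
#'   at 0.
#' @return A tibble with columns `time_h`, `b`, `R`, `source`
#'   (`"closed_form"`).
#' @examples
#' p <- degradation_params(alpha = 2, beta = 0.5, r0 = 100)
#' closed_form_trajectory(p, times = c(0, 1, 2))
#' @export
closed_form_trajectory <- function(params, times) {
  stopifnot(inherits(params, "degradation_params"))
  if (params$n != 1) {
    abort("Closed-form solution exists only for n = 1; use `integrate_trajectory()`.")
  }
  check_time_grid(times)
  b <- params$alpha / params$beta * (expm1(params$beta * times))
  R <- params$r0 - b + params$alpha * times
  tibble(time_h = times, b = b, R = R, source = "closed_form")
}

check_time_grid <- function(times) {
  if (length(times) < 1L || times[1] != 0 || any(diff(times) <= 0)) {
    abort("`times` must start at 0 and be strictly increasing.")
  }
  invisible(times)
}

#' Numerically integrate the degradation model
#'
#' Solves `db/dt = alpha + beta * b^n`, `dR/dt = -beta * b` with
#' `b(0) = 0`, `R(0) = r0` using an adaptive stiff-capable integrator
#' (deSolve's `lsoda`/`lsodar`, rtol 1e-8, atol 1e-10). For `n > 1` the
#' bacterial load `b` blows up in finite time; because the resource is
#' finite, `b` is capped at the `r0`-equivalent load: integration stops at
#' the capping time and the trajectory continues with constant `b = r0`,
#' under which `R` declines linearly and exactly. If the cap is reached
#' before `t_end`, the returned trajectory covers the full grid; the capping
#' time is recorded in the `t_cap` attribute.
#'
#' @param params A [degradation_params()] object.
#' @param t_end End of the integration window (h).
#' @param dt Output grid spacing (h); default `t_end / 400`.
#' @param times Optional explicit output grid (overrides `dt`).
#' @return A tibble with columns `time_h`, `b`, `R`, `source` (`"numeric"`),
#'   with attribute `t_cap` (`NA` if the cap was never hit).
#' @examples
#' p <- degradation_params(alpha = 2, beta = 0.5, r0 = 100, n = 1)
#' integrate_trajectory(p, t_end = 2, dt = 0.5)
#' @export
integrate_trajectory <- function(params, t_end, dt = NULL, times = NULL) {
  stopifnot(inherits(params, "degradation_params"))
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    abort("`t_end` must be a single positive number.")
  }
  if (is.null(times)) {
    if (is.null(dt)) dt <- t_end / 400
    times <- seq(0, t_end, by = dt)
    if (tail(times, 1) < t_end) times <- c(times, t_end)
  }
  check_time_grid(times)

  alpha <- params$alpha
  beta <- params$beta
  n <- params$n
  r0 <- params$r0
  deriv <- function(t, y, parms) {
    list(c(alpha + beta * y[1]^n, -beta * y[1]))
  }
  y0 <- c(b = 0, R = r0)

  if (n == 1) {
    sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    out <- tibble(time_h = sol[, "time"], b = sol[, "b"], R = sol[, "R"],
                  source = "numeric")
    attr(out, "t_cap") <- NA_real_
    return(out)
  }

  # n > 1: integrate to the cap b = r0 (terminal root), then linear phase
  cap <- r0
  rootfun <- function(t, y, parms) y[1] - cap
  sol <- deSolve::lsodar(y0, times, deriv, parms = NULL,
                         rootfunc = rootfun, rtol = 1e-8, atol = 1e-10)
  t_cap <- attr(sol, "troot")
  tm <- sol[, "time"]
  out <- tibble(time_h = tm, b = pmin(sol[, "b"], cap), R = sol[, "R"])
  if (length(t_cap) == 1L && !is.na(t_cap)) {
    # continue on the remaining grid: b constant at cap, R linear
    R_cap <- sol[nrow(sol), "R"]
    rest <- times[times > t_cap]
    if (length(rest) > 0) {
      out <- dplyr::bind_rows(
        out,
        tibble(time_h = rest, b = cap, R = R_cap - beta * cap * (rest - t_cap))
      )
    }
    out <- dplyr::filter(out, !duplicated(.data$time_h))
  } else {
    t_cap <- NA_real_
  }
  out$source <- "numeric"
  attr(out, "t_cap") <- t_cap
  out
}

# time at which the consumed resource r0 - R(t) first equals `amount`;
# returns list(time, censored)
time_to_consume <- function(params, amount, horizon) {
  alpha <- params$alpha
  beta <- params$beta
  r0 <- params$r0

  if (params$n == 1) {
    # consumed(t) = (alpha/beta) (e^{beta t} - 1) - alpha t, monotone increasing
    f <- function(t) {
      v <- alpha / beta * expm1(beta * t) - alpha * t - amount
      pmin(v, .Machine$double.xmax)
    }
    upper <- 1
    while (f(upper) <= 0 && upper < horizon) upper <- upper * 2
    upper <- min(upper, horizon)
    if (!is.finite(upper) || f(upper) <= 0) {
      return(list(time = NA_real_, censored = TRUE))
    }
    t <- uniroot(f, c(0, upper), tol = 1e-6)$root
    return(list(time = t, censored = t > horizon))
  }

  # n > 1: integrate with terminal roots at consumption target and at the cap
  cap <- r0
  target_R <- r0 - amount
  deriv <- function(t, y, parms) {
    list(c(alpha + beta * min(y[1], cap)^params$n, -beta * min(y[1], cap)))
  }
  rootfun <- function(t, y, parms) c(y[2] - target_R, y[1] - cap)
  sol <- deSolve::lsodar(c(b = 0, R = r0), c(0, horizon), deriv, parms = NULL,
                         rootfunc = rootfun, rtol = 1e-8, atol = 1e-10)
  troot <- attr(sol, "troot")
  if (length(troot) == 0L || is.na(troot[1])) {
    return(list(time = NA_real_, censored = TRUE))
  }
  b_end <- unname(sol[nrow(sol), "b"])
  R_end <- unname(sol[nrow(sol), "R"])
  if (abs(R_end - target_R) < 1e-6 * r0) {
    return(list(time = unname(troot[1]), censored = FALSE))
  }
  if (b_end >= cap * (1 - 1e-8)) {
    # cap reached first; R declines at the exact rate beta * cap afterwards
    t_half <- unname(troot[1]) + (R_end - target_R) / (beta * cap)
    if (t_half > horizon) return(list(time = NA_real_, censored = TRUE))
    return(list(time = t_half, censored = FALSE))
  }
  list(time = unname(troot[1]), censored = FALSE)
}

#' Model particle half-life
#'
#' The half-life is the smallest time at which the remaining resource has
#' dropped to half its initial value, `R(t) = r0 / 2`. For `n = 1` it is
#' found by bracketed root finding on the closed-form solution (absolute
#' time tolerance 1e-6 h); for `n > 1` on the numerical trajectory with the
#' finite-time blow-up of `b` capped at the `r0`-equivalent load. If half
#' depletion is not reached within `horizon`, the result is censored
#' (`tau_half = NA`) rather than extrapolated.
#'
#' @param params A [degradation_params()] object with `alpha > 0`.
#' @param horizon Search horizon (h); default `1e5`.
#' @return A one-row tibble with columns `tau_half` (h, `NA` when censored),
#'   `censored`, `horizon`.
#' @examples
#' model_half_life(degradation_params(alpha = 1, beta = 0.1, r0 = 1000))
#' @export
model_half_life <- function(params, horizon = 1e5) {
  stopifnot(inherits(params, "degradation_params"))
  if (params$alpha <= 0) abort("`alpha` must be positive.")
  res <- time_to_consume(params, params$r0 / 2, horizon)
  tibble(tau_half = if (res$censored) NA_real_ else res$time,
         censored = res$censored, horizon = horizon)
}

#' Numeric full-depletion time
#'
#' Smallest time at which the particle is fully consumed, `R(T) = 0`,
#' computed the same way as [model_half_life()] but for the full resource.
#'
#' @inheritParams model_half_life
#' @return A one-row tibble with columns `t_depletion`, `censored`,
#'   `horizon`.
#' @export
depletion_time <- function(params, horizon = 1e5) {
  stopifnot(inherits(params, "degradation_params"))
  res <- time_to_consume(params, params$r0, horizon)
  tibble(t_depletion = if (res$censored) NA_real_ else res$time,
         censored = res$censored, horizon = horizon)
}

#' Analytical approximation of the total degradation time
#'
#' Under slow attachment relative to growth (`alpha << beta * r0`) and
#' `beta * T >> 0`, the time to fully degrade the particle is approximately
#' \deqn{T = (1/\beta)(\ln r_0 + \ln \beta + \ln(1/\alpha)),}
#' i.e. linear in `ln(1/alpha)` and hence in `-ln b0`. A tenfold dilution of
#' the inoculum therefore delays degradation by `(1/beta) * ln 10` hours,
#' independent of `r0`.
#'
#' @param alpha Rescaled attachment rate (> 0).
#' @param beta Rescaled degradation-growth rate (1/h, > 0).
#' @param r0 Initial resource (> 0). Requires `beta * r0 / alpha > 1`.
#' @return Approximate total degradation time (h).
#' @examples
#' degradation_time_approx(alpha = 1, beta = 0.1, r0 = 1000) # ~46.05
#' @export
degradation_time_approx <- function(alpha, beta, r0) {
  if (!all(is.finite(c(alpha, beta, r0))) || alpha <= 0 || beta <= 0 || r0 <= 0) {
    abort("`alpha`, `beta` and `r0` must be finite and strictly positive.")
  }
  if (beta * r0 / alpha <= 1) {
    abort("Approximation invalid: requires beta * r0 / alpha > 1 (slow attachment).")
  }
  (1 / beta) * (log(r0) + log(beta) + log(1 / alpha))
}

#' Model half-life across an inoculum dilution series
#'
#' Computes the model half-life for each planktonic concentration in `b0`,
#' with attachment rate `a = a0 * b0` at each point. For `n = 1` the
#' `(ln b0, tau_half)` points are affine up to the approximation error of
#' the analytical degradation time; for `n > 1` they curve.
#'
#' @param b0 Numeric vector of planktonic concentrations (cells/ml).
#' @param a0 Per-cell attachment rate. Default 0.01.
#' @param beta Rescaled degradation-growth rate (1/h). Default 0.005.
#' @param r0 Initial resource. Default `1e6`.
#' @param n Cooperativity exponent. Default 1.
#' @param r Conversion factor. Default 1 (so `alpha = a0 * b0`).
#' @param horizon Half-life search horizon (h).
#' @return A tibble with columns `b0`, `alpha`, `tau_half`, `censored`.
#' @examples
#' half_life_curve(b0 = 10^(3:7))
#' @export
half_life_curve <- function(b0, a0 = 0.01, beta = 0.005, r0 = 1e6, n = 1,
                            r = 1, horizon = 1e5) {
  if (any(b0 <= 0)) abort("`b0` values must be positive.")
  purrr::map_dfr(b0, function(bb) {
    p <- degradation_params(a0 = a0, b0 = bb, r = r, p = beta / r, n = n,
                            r0 = r0)
    hl <- model_half_life(p, horizon = horizon)
    tibble(b0 = bb, alpha = p$alpha, tau_half = hl$tau_half,
           censored = hl$censored)
  })
}
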