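#' Configuration for the synthetic measurement generator
#'
#' Bundles the observation-model settings shared by all generators. The
#' defaults emulate the time-lapse protocol the pipeline is built for:
#' images every 2 h for at most 240 h, multiplicative measurement noise of
#' 5% on normalized volume, three replicate particles per condition.
#' The optional swell bump reproduces the transient volume increase some
#' particles show immediately before collapse (hydrogel swelling); it is off
#' by default.
#'
#' @param seed Integer seed; every stochastic generator draw derives from
#'   it, so equal seeds give bit-identical outputs.
#' @param frame_interval_h Imaging interval (h). Default 2.
#' @param horizon_h Observation horizon (h). Default 240.
#' @param noise_sd Multiplicative Gaussian noise SD on normalized volume.
#'   Default 0.05.
#' @param swell_amplitude Fractional amplitude of the pre-collapse swell
#'   bump. Default 0 (off); 0.1 is a realistic visible swell.
#' @param swell_width_h Width (SD, h) of the swell bump; the bump is
#'   centred one width before the collapse midpoint. Default 10.
#' @param replicates Replicate particles per condition. Default 3.
#' @param k Collapse steepness used by the observation model (1/h).
#'   Default 0.5.
#' @param v0_um3 Nominal initial particle volume (um^3), used to emit raw
#'   volumes alongside normalized ones. Default `(4/3) pi 15^3` (a 30 um
#'   diameter bead).
#' @param effect_slope Coculture delay per unit gamma (dimensionless, the
#'   `c` in `tau = tau_mono (1 + c gamma)`). Default 1.
#' @param gamma_star Blocking threshold ratio for coculture grids.
#'   Default 16.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, frame_interval_h = 2,
                             horizon_h = 240, noise_sd = 0.05,
                             swell_amplitude = 0, swell_width_h = 10,
                             replicates = 3, k = 0.5,
                             v0_um3 = (4 / 3) * pi * 15^3,
                             effect_slope = 1, gamma_star = 16) {
  stopifnot(noise_sd >= 0, horizon_h > 0, replicates >= 1,
            frame_interval_h > 0, swell_amplitude >= 0, swell_width_h > 0,
            k > 0, v0_um3 > 0, effect_slope >= 0, gamma_star > 0)
  structure(
    list(seed = as.integer(seed), frame_interval_h = frame_interval_h,
         horizon_h = horizon_h, noise_sd = noise_sd,
         swell_amplitude = swell_amplitude, swell_width_h = swell_width_h,
         replicates = replicates, k = k, v0_um3 = v0_um3,
         effect_slope = effect_slope, gamma_star = gamma_star),
    class = "generator_config"
  )
}

obs_times <- function(config) {
  seq(0, config$horizon_h, by = config$frame_interval_h)
}

#' Generate a synthetic particle volume trajectory
#'
#' Emits the observation model of the time-lapse assay: normalized volume
#' follows the collapse sigmoid `1 / (1 + exp(k (t - tau_half)))`, optionally
#' multiplied by a Gaussian-shaped swell bump ending at collapse, and by
#' multiplicative Gaussian noise `1 + eps`, `eps ~ N(0, noise_sd)`. Values
#' are clipped at 0. A `tau_half` beyond the horizon yields a trajectory
#' that never crosses 0.5 and is classified censored downstream.
#'
#' @param k Collapse steepness (1/h, > 0).
#' @param tau_half True half-life (h, > 0).
#' @param config A [generator_config()].
#' @param particle_id Label for the particle. Default `"p1"`.
#' @param seed_offset Integer added to `config$seed` so replicate particles
#'   draw independent noise while remaining reproducible. Default 0.
#' @return A tibble `particle_id`, `time_h`, `volume_um3`, `volume_norm`
#'   with attributes `k_true` and `tau_half_true`.
#' @export
generate_volume_trajectory <- function(k, tau_half, config,
                                       particle_id = "p1", seed_offset = 0) {
  stopifnot(inherits(config, "generator_config"), k > 0, tau_half > 0)
  t <- obs_times(config)
  v <- 1 / (1 + exp(k * (t - tau_half)))
  if (config$swell_amplitude > 0) {
    centre <- tau_half - config$swell_width_h
    bump <- config$swell_amplitude *
      exp(-0.5 * ((t - centre) / (config$swell_width_h / 2))^2)
    v <- v * (1 + bump)
  }
  if (config$noise_sd > 0) {
    eps <- withr::with_seed(config$seed + as.integer(seed_offset),
                            stats::rnorm(length(t), 0, config$noise_sd))
    v <- v * (1 + eps)
  }
  v <- pmax(v, 0)
  out <- tibble(particle_id = particle_id, time_h = t,
                volume_um3 = v * config$v0_um3, volume_norm = v)
  attr(out, "k_true") <- k
  attr(out, "tau_half_true") <- tau_half
  out
}

#' Generate a trajectory whose half-life comes from the kinetic model
#'
#' Computes the model half-life for the given kinetic parameters via
#' [model_half_life()], then emits the observation model of
#' [generate_volume_trajectory()] with that half-life and the config's
#' collapse steepness. This links the mechanistic model to the measurement
#' process: depolymerization is continuous, but the observable is the
#' plateau-collapse volume curve.
#'
#' @param params A [degradation_params()] object.
#' @inheritParams generate_volume_trajectory
#' @param model_horizon Search horizon for the model half-life (h).
#' @return As [generate_volume_trajectory()]; attribute `tau_half_true`
#'   carries the model half-life. If the model half-life is beyond
#'   `model_horizon` the trajectory is flat (censoring propagates).
#' @export
generate_mechanistic_trajectory <- function(params, config,
                                            particle_id = "p1",
                                            seed_offset = 0,
                                            model_horizon = 1e5) {
  hl <- model_half_life(params, horizon = model_horizon)
  if (hl$censored) {
    t <- obs_times(config)
    out <- tibble(particle_id = particle_id, time_h = t,
                  volume_um3 = config$v0_um3, volume_norm = 1)
    if (config$noise_sd > 0) {
      eps <- withr::with_seed(config$seed + as.integer(seed_offset),
                              stats::rnorm(length(t), 0, config$noise_sd))
      out$volume_norm <- pmax(1 + eps, 0)
      out$volume_um3 <- out$volume_norm * config$v0_um3
    }
    attr(out, "tau_half_true") <- NA_real_
    attr(out, "k_true") <- config$k
    return(out)
  }
  generate_volume_trajectory(config$k, hl$tau_half, config,
                             particle_id = particle_id,
                             seed_offset = seed_offset)
}

#' Generate a dose series of fitted half-lives across inoculum levels
#'
#' For each planktonic concentration in `b0_levels` and each replicate, a
#' mechanistic trajectory is generated and its half-life re-estimated with
#' [fit_sigmoid()], emulating the full measurement pipeline. Ground-truth
#' model half-lives are carried in the `tau_true` column and the generating
#' `beta` in an attribute, so recovery can be tested downstream.
#'
#' @param b0_levels Planktonic concentrations (cells/ml), >= 2 values.
#' @param config A [generator_config()].
#' @param a0,beta,r0,n Kinetic parameters of the generating model (see
#'   [half_life_curve()]).
#' @param strain Label carried into the output. Default `"synthetic"`.
#' @return A tibble `strain`, `b0`, `replicate`, `tau_half`, `censored`,
#'   `tau_true`, with attributes `beta_true`, `a0_true`.
#' @export
generate_dose_series <- function(b0_levels, config, a0 = 0.01, beta = 0.005,
                                 r0 = 1e6, n = 1, strain = "synthetic") {
  stopifnot(inherits(config, "generator_config"))
  if (length(b0_levels) < 1L || any(b0_levels <= 0)) {
    abort("`b0_levels` must be positive.")
  }
  if (length(b0_levels) < 2L) {
    warn("A single inoculum level cannot support scaling fits.")
  }
  rows <- purrr::imap_dfr(b0_levels, function(b0, i) {
    params <- degradation_params(a0 = a0, b0 = b0, p = beta, n = n, r0 = r0)
    hl <- model_half_life(params, horizon = 1e5)
    purrr::map_dfr(seq_len(config$replicates), function(rep) {
      traj <- generate_mechanistic_trajectory(
        params, config, particle_id = sprintf("b0_%g_r%d", b0, rep),
        seed_offset = 1000L * i + rep
      )
      fit <- glance(fit_sigmoid(traj))
      tibble(strain = strain, b0 = b0, replicate = rep,
             tau_half = fit$tau_half, censored = fit$censored,
             tau_true = hl$tau_half)
    })
  })
  attr(rows, "beta_true") <- beta
  attr(rows, "a0_true") <- a0
  rows
}

#' Generate a coculture phase-plane grid with a known blocking threshold
#'
#' Phenomenological coculture model: at inoculum ratio
#' `gamma = bs0 / bp0` below the threshold `gamma_star`, the half-life is
#' the monoculture half-life inflated linearly in the ratio,
#' `tau = tau_mono(bp0) (1 + c gamma)`, with multiplicative noise; at or
#' above the threshold all replicates are censored (degradation blocked).
#' This emulates the observed "roughly linear delay, then abrupt blocking"
#' phenomenology and provides a known `gamma_star` for recovery tests; it
#' does not claim a mechanism.
#'
#' @param bp_levels,bs_levels Degrader / consumer inoculum levels
#'   (cells/ml), ascending.
#' @param config A [generator_config()]; `effect_slope` is `c`,
#'   `gamma_star` the threshold.
#' @param tau_mono Monoculture half-life: a single number or a function of
#'   `bp0`. Default 50 h.
#' @return A long tibble `bp0`, `bs0`, `replicate`, `tau_half`, `censored`
#'   with attribute `gamma_star_true`. Half-lives exceeding the horizon are
#'   also censored.
#' @export
generate_coculture_grid <- function(bp_levels, bs_levels, config,
                                    tau_mono = 50) {
  stopifnot(inherits(config, "generator_config"))
  if (any(bp_levels <= 0) || any(bs_levels < 0)) {
    abort("Inoculum levels must be positive (`bp_levels`) / non-negative (`bs_levels`).")
  }
  tau_fn <- if (is.function(tau_mono)) tau_mono else function(bp0) tau_mono
  cells <- tidyr::expand_grid(bp0 = sort(bp_levels), bs0 = sort(bs_levels))
  n_cells <- nrow(cells)
  eps <- withr::with_seed(
    config$seed,
    stats::rnorm(n_cells * config$replicates, 0, config$noise_sd)
  )
  rows <- purrr::pmap_dfr(
    list(cells$bp0, cells$bs0, seq_len(n_cells)),
    function(bp0, bs0, idx) {
      gamma <- compute_gamma(bs0, bp0)
      purrr::map_dfr(seq_len(config$replicates), function(rep) {
        if (gamma >= config$gamma_star) {
          tibble(bp0 = bp0, bs0 = bs0, replicate = rep,
                 tau_half = NA_real_, censored = TRUE)
        } else {
          e <- eps[(idx - 1L) * config$replicates + rep]
          tau <- tau_fn(bp0) * (1 + config$effect_slope * gamma) * (1 + e)
          cens <- tau > config$horizon_h
          tibble(bp0 = bp0, bs0 = bs0, replicate = rep,
                 tau_half = if (cens) NA_real_ else tau, censored = cens)
        }
      })
    })
  attr(rows, "gamma_star_true") <- config$gamma_star
  attr(rows, "effect_slope_true") <- config$effect_slope
  rows
}

#' Generate CFU time series with parasitic yield transfer
#'
#' Emits four logistic-shaped colony-count series (degrader and consumer,
#' each in monoculture and coculture) in which a fraction
#' `yield_transfer_fraction` of the degrader's monoculture yield is lost in
#' coculture, the consumer gains exactly `consumer_doublings` doublings in
#' coculture (and none in monoculture), and total coculture yield never
#' exceeds total monoculture yield. The consumer inoculum is sized as
#' `transfer_efficiency` times the transferred degrader yield divided by the
#' consumer's fold growth, which enforces the conservation constraint by
#' construction for any `transfer_efficiency <= 1`.
#'
#' @param yield_mono Degrader final CFU/ml in monoculture. Default `1e8`.
#' @param yield_transfer_fraction Fraction of degrader yield lost in
#'   coculture, in `[0, 1]`.
#' @param consumer_doublings Consumer doublings in coculture (>= 0).
#' @param config A [generator_config()].
#' @param transfer_efficiency Fraction of the transferred yield that becomes
#'   consumer biomass, in `(0, 1]`. Default 0.5.
#' @param sampling_interval_h Spacing of CFU samples (h). Default 24
#'   (daily plating).
#' @return A long tibble `strain`, `role`, `condition`, `time_h`,
#'   `cfu_per_ml` covering all four series.
#' @export
generate_cfu_series <- function(yield_mono = 1e8, yield_transfer_fraction,
                                consumer_doublings, config,
                                transfer_efficiency = 0.5,
                                sampling_interval_h = 24) {
  stopifnot(inherits(config, "generator_config"),
            yield_transfer_fraction >= 0, yield_transfer_fraction <= 1,
            consumer_doublings >= 0, transfer_efficiency > 0,
            transfer_efficiency <= 1, yield_mono > 0)
  t <- seq(0, config$horizon_h, by = sampling_interval_h)
  logistic_series <- function(c0, cf) {
    if (cf == c0) return(rep(c0, length(t)))
    tm <- config$horizon_h / 2
    g <- 10 / config$horizon_h
    s <- 1 / (1 + exp(-g * (t - tm)))
    c0 + (cf - c0) * (s - s[1]) / (s[length(s)] - s[1])
  }
  if (consumer_doublings > 0 && yield_transfer_fraction == 0) {
    abort("Consumer doublings without yield transfer would violate conservation.")
  }
  d0 <- yield_mono / 1000
  fold <- 2^consumer_doublings
  c0 <- if (consumer_doublings > 0) {
    transfer_efficiency * yield_transfer_fraction * yield_mono / (fold - 1)
  } else {
    yield_mono / 1e4
  }

  dplyr::bind_rows(
    tibble(strain = "degrader", role = "degrader", condition = "monoculture",
           time_h = t, cfu_per_ml = logistic_series(d0, yield_mono)),
    tibble(strain = "degrader", role = "degrader", condition = "coculture",
           time_h = t,
           cfu_per_ml = logistic_series(
             d0, yield_mono * (1 - yield_transfer_fraction))),
    tibble(strain = "consumer", role = "consumer", condition = "monoculture",
           time_h = t, cfu_per_ml = rep(c0, length(t))),
    tibble(strain = "consumer", role = "consumer", condition = "coculture",
           time_h = t, cfu_per_ml = logistic_series(c0, c0 * fold))
  )
}
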