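test_that("rescaling to canonical parameters is exact and validated", {
  expect_equal(rescale_params(a = 0.02, r = 2, p = 0.004),
               list(alpha = 0.01, beta = 0.008))
  expect_equal(rescale_params(a = 1, r = 1, p = 1),
               list(alpha = 1, beta = 1))
  # default r = 1 convention: alpha = a0 * b0
  p <- degradation_params(a0 = 0.01, b0 = 1e6, p = 0.005, r0 = 1e6)
  expect_equal(p$alpha, 1e4)
  expect_equal(p$beta, 0.005)
  expect_error(rescale_params(a = -1, r = 1, p = 1), "positive")
  expect_error(rescale_params(a = 1, r = 0, p = 1), "positive")
  expect_error(degradation_params(alpha = 1, beta = 0.1, r0 = -5), "positive")
  expect_error(degradation_params(alpha = 1, beta = 0.1, r0 = 10, n = 0.5),
               ">= 1")
})

test_that("closed form matches direct numerical integration of the raw ODEs", {
  p <- degradation_params(alpha = 2, beta = 0.5, r0 = 100)
  tr <- closed_form_trajectory(p, times = c(0, 2))
  # frozen values checked against the deSolve oracle (rtol 1e-10)
  expect_equal(tr$b[2], 6.8731273, tolerance = 1e-7)
  expect_equal(tr$R[2], 97.1268727, tolerance = 1e-8)
  # initial conditions
  expect_equal(tr$b[1], 0)
  expect_equal(tr$R[1], 100)

  times <- seq(0, 20, by = 0.5)
  oracle <- oracle_ode_n1(2, 0.5, 100, times)
  tr2 <- closed_form_trajectory(p, times)
  expect_equal(tr2$b, unname(oracle$b), tolerance = 1e-8)
  expect_equal(tr2$R, unname(oracle$R), tolerance = 1e-8)

  expect_error(closed_form_trajectory(
    degradation_params(alpha = 1, beta = 1, r0 = 10, n = 2), c(0, 1)),
    "n = 1")
})

test_that("numeric integration agrees with the closed form for n = 1", {
  withr::with_seed(42, {
    for (i in 1:20) {
      alpha <- 10^runif(1, -2, 1)
      beta <- 10^runif(1, -3, 0)
      r0 <- 10^runif(1, 2, 6)
      p <- degradation_params(alpha = alpha, beta = beta, r0 = r0)
      t_end <- min(oracle_half_life_n1(alpha, beta, r0) * 2, 1e4)
      num <- integrate_trajectory(p, t_end = t_end, dt = t_end / 50)
      cf <- closed_form_trajectory(p, num$time_h)
      expect_equal(num$b, cf$b, tolerance = 1e-6)
      expect_equal(num$R, cf$R, tolerance = 1e-6)
    }
  })
})

test_that("mass accounting r0 - R = b - alpha*t holds to machine precision", {
  withr::with_seed(7, {
    for (i in 1:10) {
      alpha <- 10^runif(1, -2, 2)
      beta <- 10^runif(1, -3, 0)
      r0 <- 10^runif(1, 2, 6)
      p <- degradation_params(alpha = alpha, beta = beta, r0 = r0)
      tr <- closed_form_trajectory(p, seq(0, 50, by = 1))
      resid <- (r0 - tr$R) - (tr$b - alpha * tr$time_h)
      expect_lt(max(abs(resid)), 1e-9 * max(1, r0))
    }
  })
})

test_that("cooperative dynamics exceed mass-action dynamics once b > 1", {
  p1 <- degradation_params(alpha = 1, beta = 0.001, r0 = 1e5, n = 1)
  p2 <- degradation_params(alpha = 1, beta = 0.001, r0 = 1e5, n = 2)
  t1 <- integrate_trajectory(p1, t_end = 30, dt = 1)
  t2 <- integrate_trajectory(p2, t_end = 30, dt = 1)
  sel <- t1$b > 1.5 & t1$time_h > 2
  expect_true(all(t2$b[sel] > t1$b[sel]))
  # b non-decreasing, R non-increasing in both
  for (tr in list(t1, t2)) {
    expect_true(all(diff(tr$b) >= -1e-9))
    expect_true(all(diff(tr$R) <= 1e-9))
  }
})

test_that("model half-life matches the root-finding oracle and is monotone", {
  hl <- model_half_life(degradation_params(alpha = 1, beta = 0.1, r0 = 1000))
  expect_false(hl$censored)
  expect_equal(hl$tau_half, 40.0746898, tolerance = 1e-6) # frozen from oracle
  expect_equal(hl$tau_half, oracle_half_life_n1(1, 0.1, 1000),
               tolerance = 1e-6)

  # doubling alpha strictly shortens the half-life
  h1 <- model_half_life(degradation_params(alpha = 1, beta = 0.1, r0 = 1000))
  h2 <- model_half_life(degradation_params(alpha = 2, beta = 0.1, r0 = 1000))
  expect_lt(h2$tau_half, h1$tau_half)

  # huge attachment: very small but positive
  h3 <- model_half_life(degradation_params(alpha = 10 * 1000 * 0.1,
                                           beta = 0.1, r0 = 1000))
  expect_gt(h3$tau_half, 0)
  expect_lt(h3$tau_half, h2$tau_half)

  # unreachable within horizon -> censored flag, no number
  h4 <- model_half_life(degradation_params(alpha = 1e-9, beta = 1e-6,
                                           r0 = 1e6), horizon = 100)
  expect_true(h4$censored)
  expect_true(is.na(h4$tau_half))
})

test_that("n = 2 half-life follows the Riccati blow-up + capped-consumption form", {
  # independent closed-form oracle: before the cap, b = sqrt(a/b) tan(s t)
  # consumes -ln cos(s t) which is negligible vs r0/2; after b caps at r0,
  # consumption is linear at rate beta * r0
  alpha <- 10; beta <- 0.005; r0 <- 1e6
  s <- sqrt(alpha * beta)
  t_cap_oracle <- atan(r0 / sqrt(alpha / beta)) / s
  consumed_at_cap <- -log(cos(s * t_cap_oracle))
  expected <- t_cap_oracle + (r0 / 2 - consumed_at_cap) / (beta * r0)
  hl <- model_half_life(degradation_params(alpha = alpha, beta = beta,
                                           r0 = r0, n = 2))
  expect_equal(hl$tau_half, expected, tolerance = 1e-4)
})

test_that("analytical degradation time approximates the numeric depletion time", {
  T_approx <- degradation_time_approx(alpha = 1, beta = 0.1, r0 = 1000)
  expect_equal(T_approx, 10 * log(100), tolerance = 1e-12)
  T_num <- depletion_time(degradation_params(alpha = 1, beta = 0.1,
                                             r0 = 1000))$t_depletion
  expect_equal(T_num, 46.6022855, tolerance = 1e-6) # frozen from oracle
  expect_lt(abs(T_approx - T_num) / T_num, 0.02)

  # ln collapses to 1 when alpha = beta * r0 / e
  expect_equal(degradation_time_approx(0.1 * 1000 / exp(1), 0.1, 1000),
               1 / 0.1, tolerance = 1e-12)
  # tenfold dilution shift is (1/beta) ln 10, independent of r0
  d <- degradation_time_approx(0.1, 0.2, 5000) -
    degradation_time_approx(1, 0.2, 5000)
  expect_equal(d, log(10) / 0.2, tolerance = 1e-12)
  expect_error(degradation_time_approx(100, 0.1, 10), "invalid")
})

test_that("approximation error is below 5% throughout the slow-attachment regime", {
  withr::with_seed(11, {
    for (i in 1:10) {
      beta <- 10^runif(1, -3, -0.5)
      r0 <- 10^runif(1, 3, 6)
      alpha <- 10^runif(1, -4, 0) * 1e-3 * beta * r0 # alpha <= 1e-3 beta r0
      T_a <- degradation_time_approx(alpha, beta, r0)
      T_n <- depletion_time(degradation_params(alpha = alpha, beta = beta,
                                               r0 = r0))$t_depletion
      expect_lt(abs(T_a - T_n) / T_n, 0.05)
    }
  })
})

test_that("half-life vs inoculum sweep is log-linear for n = 1, curved for n > 1", {
  b0 <- 10^seq(-1, 3, by = 0.5)
  hc1 <- half_life_curve(b0, n = 1)
  expect_equal(nrow(hc1), length(b0))
  expect_true(all(diff(hc1$tau_half) < 0)) # strictly decreasing in b0

  fit <- glance(fit_inoculum_scaling(hc1[, c("b0", "tau_half")]))
  expect_gte(fit$r_squared, 0.999)
  # tenfold shift converges to (1/beta) ln 10 = 460.5 h
  expect_equal(fit$slope_per_decade, -log(10) / 0.005, tolerance = 0.01)

  hc2 <- half_life_curve(b0, n = 2)
  coop <- test_cooperativity(
    hc2[, c("b0", "tau_half")])
  expect_lt(coop$curvature_pvalue, 0.05)
  expect_gt(coop$quad_coef, 0) # convex

  # degenerate single point: no fit attempted, value still returned
  single <- half_life_curve(5e5)
  expect_equal(nrow(single), 1L)
  expect_false(single$censored)
})

test_that("kinetic parameter JSON round-trips", {
  p <- degradation_params(a0 = 0.01, b0 = 5e5, p = 0.005, r0 = 1e6, n = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_params_json(p, path)
  q <- read_params_json(path)
  expect_equal(q$alpha, p$alpha)
  expect_equal(q$beta, p$beta)
  expect_equal(q$r0, p$r0)
  # unknown keys rejected
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(alpha = 1, beta = 0.1, r0 = 10, bogus = 1),
                       bad, auto_unbox = TRUE)
  expect_error(read_params_json(bad), "Unknown")
})
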