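test_that("scaling fit reproduces the closed-form OLS on collinear points", {
  d <- tibble::tibble(b0 = c(1e3, 1e4, 1e5, 1e6),
                      tau_half = c(200, 170, 140, 110))
  fit <- fit_inoculum_scaling(d)
  # frozen from the closed-form OLS on these exactly collinear points
  expect_equal(fit$slope, -30 / log(10), tolerance = 1e-10)
  expect_equal(fit$t0, 290, tolerance = 1e-10)
  expect_equal(fit$beta_hat, log(10) / 30, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(tidy(fit)$estimate[1], 290, tolerance = 1e-10)
})

test_that("scaling fit recovers the generating beta from model data", {
  hc <- half_life_curve(10^seq(-1, 3, by = 0.5), a0 = 0.01, beta = 0.005,
                        r0 = 1e6)
  fit <- glance(fit_inoculum_scaling(hc[, c("b0", "tau_half")]))
  expect_lt(abs(fit$beta_hat - 0.005) / 0.005, 0.05)
})

test_that("scaling fit handles censoring, degeneracy and bad slopes", {
  # censored points are excluded, not substituted
  d <- tibble::tibble(b0 = c(1e3, 1e4, 1e5, 1e6),
                      tau_half = c(NA, 170, 140, 110),
                      censored = c(TRUE, FALSE, FALSE, FALSE))
  fit <- fit_inoculum_scaling(d)
  expect_equal(fit$n_points, 3L)
  expect_equal(fit$n_censored, 1L)

  # all half-lives equal: slope 0, beta unidentifiable
  flat <- tibble::tibble(b0 = c(1e3, 1e4, 1e5), tau_half = 100)
  expect_warning(f2 <- fit_inoculum_scaling(flat), "not identifiable")
  expect_true(is.na(f2$beta_hat))

  # increasing half-life: warn about model violation
  up <- tibble::tibble(b0 = c(1e3, 1e4, 1e5), tau_half = c(100, 140, 180))
  expect_warning(fit_inoculum_scaling(up), "Positive slope")

  expect_error(fit_inoculum_scaling(
    tibble::tibble(b0 = c(1e3, 1e4), tau_half = c(1, 2))), "3 distinct")
})

test_that("pooled and means fitting modes agree on balanced noiseless data", {
  d <- tidyr::expand_grid(b0 = 10^(3:6), replicate = 1:3) |>
    dplyr::mutate(tau_half = 290 - 13.0288344571 * log(b0))
  f1 <- fit_inoculum_scaling(d, mode = "means")
  f2 <- fit_inoculum_scaling(d, mode = "pooled")
  expect_equal(f1$slope, f2$slope, tolerance = 1e-9)
  expect_equal(f1$t0, f2$t0, tolerance = 1e-9)
})

test_that("cooperativity test is silent on collinear data and calibrated on noise", {
  line <- tibble::tibble(b0 = 10^(3:7),
                         tau_half = 500 - 40 * log(10^(3:7)))
  res <- test_cooperativity(line)
  expect_equal(res$curvature_pvalue, 1)
  expect_equal(res$verdict, "no cooperativity detected")

  # type-I rate at the nominal 5% level on noisy lines (3 replicates/level)
  rejections <- withr::with_seed(101, {
    vapply(1:200, function(i) {
      d <- tidyr::expand_grid(b0 = 10^(3:7), replicate = 1:3) |>
        dplyr::mutate(tau_half = 500 - 40 * log(b0) + rnorm(15, 0, 5))
      test_cooperativity(d)$curvature_pvalue < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.04)

  expect_error(test_cooperativity(
    tibble::tibble(b0 = 10^(3:5), tau_half = c(1, 2, 3))), "4 distinct")
})

test_that("cooperativity is detected on n = 2 model sweeps", {
  hc2 <- half_life_curve(10^seq(-1, 3, by = 0.5), n = 2)
  res <- test_cooperativity(hc2[, c("b0", "tau_half")])
  expect_lt(res$curvature_pvalue, 0.05)
  expect_equal(res$verdict, "cooperativity detected")
})

test_that("coculture ANOVA matches hand-computed sums of squares", {
  out <- coculture_effect(c(100, 102, 98), c(200, 202, 198))
  # SSB = 15000, SSW = 16, df = (1, 4): F = 15000 / 4 = 3750
  expect_equal(out$f_stat, 3750, tolerance = 1e-10)
  expect_lt(out$anova_p, 0.001)
  expect_equal(out$inhibition_ratio, 2, tolerance = 1e-12)
  expect_equal(out$edge_class, "p<0.05")

  # all-censored coculture: complete inhibition
  blocked <- coculture_effect(c(100, 102, 98), c(NA, NA, NA))
  expect_equal(blocked$edge_class, "complete inhibition")
  expect_true(is.na(blocked$inhibition_ratio))
  expect_equal(blocked$n_censored_co, 3L)

  # identical groups: no effect
  null <- coculture_effect(c(100, 102, 98), c(100, 102, 98))
  expect_equal(null$inhibition_ratio, 1)
  expect_equal(null$edge_class, "none")

  # degenerate equal constants: p = 1 by convention
  flat <- coculture_effect(c(100, 100), c(100, 100))
  expect_equal(flat$anova_p, 1)
  expect_equal(flat$edge_class, "none")

  expect_error(coculture_effect(100, c(1, 2)), "2 replicates")
})

test_that("coculture comparison is order-symmetric and unit-invariant", {
  m <- c(101, 99, 100)
  co <- c(150, 149, 151)
  a <- coculture_effect(m, co)
  b <- coculture_effect(rev(m), rev(co))
  expect_equal(a$anova_p, b$anova_p)
  # rescaling time units on both groups leaves F and p unchanged
  c_ <- coculture_effect(m * 24, co * 24)
  expect_equal(a$f_stat, c_$f_stat, tolerance = 1e-9)
  expect_equal(a$anova_p, c_$anova_p, tolerance = 1e-12)
  expect_equal(c_$inhibition_ratio, a$inhibition_ratio, tolerance = 1e-12)
})

test_that("three-tier edge classification follows the p thresholds", {
  # means differ but variance is large: expect class to move with p
  set.seed(2)
  weak <- coculture_effect(c(100, 140, 90), c(130, 180, 120))
  expect_true(weak$edge_class %in% c("none", "p<0.1"))
  strong <- coculture_effect(c(100, 101, 99), c(300, 301, 299))
  expect_equal(strong$edge_class, "p<0.05")
})

test_that("parasitism accounting reports doublings, yield loss and conservation", {
  t <- c(0, 48, 96, 144)
  mk <- function(role, condition, series) {
    tibble::tibble(strain = role, role = role, condition = condition,
                   time_h = t, cfu_per_ml = series)
  }
  d <- dplyr::bind_rows(
    mk("degrader", "monoculture", c(1e5, 1e7, 8e7, 1e8)),
    mk("degrader", "coculture", c(1e5, 5e6, 1.5e7, 2e7)),
    mk("consumer", "monoculture", rep(1e4, 4)),
    mk("consumer", "coculture", c(1e4, 5e4, 2e5, 3.2e5))
  )
  s <- parasitism_summary(d)
  expect_equal(s$consumer_doublings_co, 5) # log2(32)
  expect_equal(s$consumer_doublings_mono, 0)
  expect_equal(s$degrader_yield_ratio, 0.2)
  expect_true(s$total_yield_le_mono)
  expect_equal(s$classification, "parasitic")

  # zero initial CFU is undefined
  bad <- d
  bad$cfu_per_ml[bad$role == "consumer" & bad$condition == "coculture" &
                   bad$time_h == 0] <- 0
  expect_error(parasitism_summary(bad), "Zero initial")
})
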