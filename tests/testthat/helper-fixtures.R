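# Shared fixture builders for the test suite (all generated in code).

# exact sigmoid samples on the standard imaging grid
sigmoid_samples <- function(k = 0.5, tau = 100, t = seq(0, 240, by = 2)) {
  tibble::tibble(time_h = t, volume_norm = 1 / (1 + exp(k * (t - tau))))
}

# independent numerical oracle for the n = 1 model: direct deSolve call on
# the raw ODEs, bypassing the package's trajectory functions
oracle_ode_n1 <- function(alpha, beta, r0, times) {
  f <- function(t, y, p) list(c(alpha + beta * y[1], -beta * y[1]))
  sol <- deSolve::lsoda(c(b = 0, R = r0), times, f, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  list(b = sol[, "b"], R = sol[, "R"])
}

# oracle half-life: uniroot directly on the closed-form consumption
oracle_half_life_n1 <- function(alpha, beta, r0) {
  f <- function(t) pmin(alpha / beta * expm1(beta * t) - alpha * t - r0 / 2,
                        1e308)
  uniroot(f, c(0, 1e5), tol = 1e-9)$root
}

# oracle full-depletion time, same closed-form root finding
oracle_depletion_time_n1 <- function(alpha, beta, r0) {
  f <- function(t) pmin(alpha / beta * expm1(beta * t) - alpha * t - r0,
                        1e308)
  uniroot(f, c(0, 1e5), tol = 1e-9)$root
}
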