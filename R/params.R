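#' Kinetic parameters of one strain-particle system
#'
#' Bundles the parameters of the attachment-growth degradation model. A
#' planktonic population at concentration `b0` (cells/ml) attaches to the
#' particle at per-cell rate `a0`, so the bulk attachment rate is
#' `a = a0 * b0`. Attached cells depolymerize the particle at per-cell rate
#' `p` and monomers convert to biomass with factor `r`. The canonical
#' rescaling used throughout is alpha = a/r (attachment) and
#' beta = r·p (combined degradation-growth rate, 1/h). The cooperativity
#' exponent `n` makes on-particle growth density dependent (`n = 1` is plain
#' mass action; `n > 1` is cooperative). `r0` is the initial particle
#' resource in abstract resource units.
#'
#' Either (`a0`, `b0`, `r`, `p`) or (`alpha`, `beta`) may be supplied;
#' whichever pair is missing is derived. With the default convention r = 1,
#' `alpha` equals `a0 * b0`.
#'
#' @param a0 Per-cell attachment rate, 1/(h * cells/ml).
#' @param b0 Planktonic cell concentration, cells/ml.
#' @param r Monomer-to-biomass conversion factor (dimensionless), default 1.
#' @param p Per-attached-cell degradation rate, resource units/h.
#' @param n Cooperativity exponent, >= 1. Default 1 (no cooperativity).
#' @param r0 Initial particle resource, resource units.
#' @param alpha Rescaled attachment rate `a0 * b0 / r`. Derived if missing.
#' @param beta Rescaled degradation-growth rate r·p (1/h). Derived if
#'   missing.
#'
#' @return An object of class `degradation_params`: a named list with fields
#'   `a0`, `b0`, `r`, `p`, `a`, `alpha`, `beta`, `n`, `r0`.
#' @examples
#' degradation_params(a0 = 0.01, b0 = 5e5, p = 0.005, r0 = 1e6)
#' degradation_params(alpha = 1, beta = 0.1, r0 = 1000)
#' @export
degradation_params <- function(a0 = NULL, b0 = NULL, r = 1, p = NULL, n = 1,
                               r0, alpha = NULL, beta = NULL) {
  if (!is.numeric(r0) || length(r0) != 1L || r0 <= 0) {
    abort("`r0` must be a single positive number.")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a single number >= 1.")
  }
  if (!is.numeric(r) || length(r) != 1L || r <= 0) {
    abort("`r` must be a single positive number.")
  }

  have_raw <- !is.null(a0) && !is.null(b0) && !is.null(p)
  have_rescaled <- !is.null(alpha) && !is.null(beta)
  if (!have_raw && !have_rescaled) {
    abort("Supply either (`a0`, `b0`, `p`) or (`alpha`, `beta`).")
  }

  if (have_raw) {
    if (a0 <= 0 || b0 <= 0 || p <= 0) {
      abort("`a0`, `b0` and `p` must be strictly positive.")
    }
    sc <- rescale_params(a = a0 * b0, r = r, p = p)
    if (have_rescaled &&
        (abs(alpha - sc$alpha) > 1e-9 * sc$alpha ||
         abs(beta - sc$beta) > 1e-9 * sc$beta)) {
      abort("Supplied `alpha`/`beta` disagree with `a0 * b0 / r` and `r * p`.")
    }
    alpha <- sc$alpha
    beta <- sc$beta
  } else {
    if (alpha <= 0 || beta <= 0) {
      abort("`alpha` and `beta` must be strictly positive.")
    }
    p <- beta / r
    # back out a0/b0 only when one of them is pinned down
    if (!is.null(b0)) {
      a0 <- alpha * r / b0
    } else if (!is.null(a0)) {
      b0 <- alpha * r / a0
    }
  }

  structure(
    list(a0 = a0, b0 = b0, r = r, p = p,
         a = alpha * r, alpha = alpha, beta = beta, n = n, r0 = r0),
    class = "degradation_params"
  )
}

#' @export
print.degradation_params <- function(x, ...) {
  cat("<degradation_params>\n")
  cat(sprintf("  alpha = %g (attachment, rescaled)\n", x$alpha))
  cat(sprintf("  beta  = %g 1/h (degradation-growth)\n", x$beta))
  cat(sprintf("  n     = %g (cooperativity)\n", x$n))
  cat(sprintf("  r0    = %g resource units\n", x$r0))
  if (!is.null(x$a0) && !is.null(x$b0)) {
    cat(sprintf("  a0 = %g, b0 = %g cells/ml, r = %g, p = %g\n",
                x$a0, x$b0, x$r, x$p))
  }
  invisible(x)
}

#' Rescale raw kinetic rates to the canonical parametrization
#'
#' Converts the bulk attachment rate `a`, conversion factor `r` and per-cell
#' degradation rate `p` into `alpha = a / r` and `beta = r * p`, the two
#' parameters that fully determine the rescaled dynamics
#' `db/dt = alpha + beta * b^n`, `dR/dt = -beta * b`.
#'
#' @param a Bulk attachment rate (cells-on-particle/h), `a = a0 * b0`.
#' @param r Monomer-to-biomass conversion factor.
#' @param p Per-attached-cell degradation rate.
#' @return A list with elements `alpha` and `beta`.
#' @examples
#' rescale_params(a = 0.02, r = 2, p = 0.004) # alpha 0.01, beta 0.008
#' @export
rescale_params <- function(a, r, p) {
  if (!all(is.finite(c(a, r, p))) || a <= 0 || r <= 0 || p <= 0) {
    abort("`a`, `r` and `p` must be finite and strictly positive.")
  }
  list(alpha = a / r, beta = r * p)
}

#' Read or write kinetic parameters as JSON
#'
#' @param path File path.
#' @return `read_params_json()` returns a [degradation_params()] object;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("a0", "b0", "B0", "r", "p", "alpha", "beta", "n", "r0", "R0")
  extra <- setdiff(names(x), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown parameter keys in ", path, ": ",
                 paste(extra, collapse = ", ")))
  }
  degradation_params(
    a0 = x$a0,
    b0 = if (!is.null(x$b0)) x$b0 else x$B0,
    r = if (!is.null(x$r)) x$r else 1,
    p = x$p,
    n = if (!is.null(x$n)) x$n else 1,
    r0 = if (!is.null(x$r0)) x$r0 else x$R0,
    alpha = x$alpha,
    beta = x$beta
  )
}

#' @rdname read_params_json
#' @param params A [degradation_params()] object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "degradation_params"))
  keep <- params[c("a0", "b0", "r", "p", "alpha", "beta", "n", "r0")]
  keep <- keep[!vapply(keep, is.null, logical(1))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
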