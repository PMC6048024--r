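#' Effect of a secondary consumer on degradation half-life
#'
#' Compares replicate half-lives of a primary degrader in monoculture
#' against coculture with a secondary consumer, by one-way ANOVA on the two
#' groups (equivalent to a two-sample equal-variance t-test). The edge class
#' follows a three-tier rule: `"complete inhibition"` when every coculture
#' replicate is censored (no collapse within the horizon), `"p<0.05"` and
#' `"p<0.1"` for significant delays, `"none"` otherwise. The inhibition
#' ratio `tau_co / tau_mono` uses replicate means of the observed
#' (non-censored) half-lives; it is `NA` under complete inhibition, where
#' only a lower bound exists.
#'
#' @param tau_mono Numeric vector of monoculture half-lives (h); `NA` marks
#'   a censored replicate.
#' @param tau_co Numeric vector of coculture half-lives (h); `NA` marks a
#'   censored replicate.
#' @param censored_mono,censored_co Optional logical vectors flagging
#'   censored replicates explicitly (combined with the `NA` convention).
#' @param degrader,consumer Optional strain labels carried into the output.
#' @return A one-row tibble: `degrader`, `consumer`, `tau_mono`, `tau_co`
#'   (means), `inhibition_ratio`, `f_stat`, `anova_p`, `edge_class`,
#'   `n_mono`, `n_co`, `n_censored_co`.
#' @examples
#' coculture_effect(c(100, 102, 98), c(200, 202, 198))
#' @export
coculture_effect <- function(tau_mono, tau_co,
                             censored_mono = NULL, censored_co = NULL,
                             degrader = NA_character_,
                             consumer = NA_character_) {
  if (length(tau_mono) < 2L || length(tau_co) < 2L) {
    abort("At least 2 replicates per condition are required.")
  }
  if (is.null(censored_mono)) censored_mono <- rep(FALSE, length(tau_mono))
  if (is.null(censored_co)) censored_co <- rep(FALSE, length(tau_co))
  censored_mono <- censored_mono | is.na(tau_mono)
  censored_co <- censored_co | is.na(tau_co)

  m <- tau_mono[!censored_mono]
  co <- tau_co[!censored_co]
  n_cens_co <- sum(censored_co)

  mean_m <- if (length(m) > 0) mean(m) else NA_real_
  mean_co <- if (length(co) > 0) mean(co) else NA_real_

  if (length(co) == 0L) {
    return(tibble(degrader = degrader, consumer = consumer,
                  tau_mono = mean_m, tau_co = NA_real_,
                  inhibition_ratio = NA_real_, f_stat = NA_real_,
                  anova_p = NA_real_, edge_class = "complete inhibition",
                  n_mono = length(m), n_co = 0L, n_censored_co = n_cens_co))
  }

  y <- c(m, co)
  g <- factor(rep(c("mono", "co"), c(length(m), length(co))),
              levels = c("mono", "co"))
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- 1L
  df2 <- length(y) - 2L
  if (ssw == 0) {
    # degenerate: no within-group variance
    if (ssb == 0) { f <- 0; p <- 1 } else { f <- Inf; p <- 0 }
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }

  edge_class <- if (p < 0.05) "p<0.05" else if (p < 0.1) "p<0.1" else "none"
  tibble(degrader = degrader, consumer = consumer,
         tau_mono = mean_m, tau_co = mean_co,
         inhibition_ratio = mean_co / mean_m,
         f_stat = f, anova_p = p, edge_class = edge_class,
         n_mono = length(m), n_co = length(co), n_censored_co = n_cens_co)
}

#' Parasitic yield transfer from colony-count time series
#'
#' Quantifies the trophic interaction between a primary degrader and a
#' secondary consumer from CFU time series in monoculture and coculture.
#' Reports the consumer's doublings in coculture
#' (`log2(final / initial CFU)`), the degrader's coculture/monoculture final
#' yield ratio, and whether the total coculture yield stays at or below the
#' total monoculture yield. The interaction is classified parasitic when the
#' consumer gains doublings while the degrader loses yield.
#'
#' @param data A data frame with columns `strain`, `role` (`"degrader"` or
#'   `"consumer"`), `condition` (`"monoculture"` or `"coculture"`), `time_h`,
#'   `cfu_per_ml`. All four role-by-condition series must be present.
#' @return A one-row tibble: `consumer_doublings_co`,
#'   `consumer_doublings_mono`, `degrader_yield_ratio`,
#'   `total_yield_le_mono` (logical), `classification` (`"parasitic"`,
#'   `"neutral"` or `"other"`).
#' @export
parasitism_summary <- function(data) {
  data <- as_tibble(data)
  need <- c("role", "condition", "time_h", "cfu_per_ml")
  if (!all(need %in% names(data))) {
    abort(paste0("`data` needs columns: ", paste(need, collapse = ", "), "."))
  }
  if (any(data$cfu_per_ml < 0)) abort("CFU counts must be non-negative.")
  ends <- data |>
    dplyr::arrange(.data$time_h) |>
    dplyr::summarise(initial = dplyr::first(.data$cfu_per_ml),
                     final = dplyr::last(.data$cfu_per_ml),
                     .by = c("role", "condition"))
  pick <- function(role, condition, what) {
    v <- ends[[what]][ends$role == role & ends$condition == condition]
    if (length(v) != 1L) {
      abort(sprintf("Missing or duplicated series: %s / %s.", role, condition))
    }
    v
  }
  doublings <- function(initial, final) {
    if (initial <= 0) abort("Zero initial CFU: doublings are undefined.")
    log2(final / initial)
  }
  d_co <- doublings(pick("consumer", "coculture", "initial"),
                    pick("consumer", "coculture", "final"))
  d_mono <- doublings(pick("consumer", "monoculture", "initial"),
                      pick("consumer", "monoculture", "final"))
  deg_mono_final <- pick("degrader", "monoculture", "final")
  deg_co_final <- pick("degrader", "coculture", "final")
  if (deg_mono_final <= 0) abort("Degrader monoculture final yield is zero.")
  yield_ratio <- deg_co_final / deg_mono_final
  total_co <- deg_co_final + pick("consumer", "coculture", "final")
  total_mono <- deg_mono_final + pick("consumer", "monoculture", "final")

  classification <- if (d_co > 0 && yield_ratio < 1) "parasitic"
    else if (abs(d_co) < 1e-9 && abs(yield_ratio - 1) < 1e-9) "neutral"
    else "other"
  tibble(
    consumer_doublings_co = d_co,
    consumer_doublings_mono = d_mono,
    degrader_yield_ratio = yield_ratio,
    total_yield_le_mono = total_co <= total_mono * (1 + 1e-12),
    classification = classification
  )
}

#' Plot CFU time series by strain and condition
#'
#' @param data A data frame as accepted by [parasitism_summary()].
#' @return A ggplot object (log10 CFU axis).
#' @export
plot_cfu <- function(data) {
  ggplot2::ggplot(as_tibble(data),
                  ggplot2::aes(x = .data$time_h, y = .data$cfu_per_ml,
                               colour = .data$role,
                               linetype = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "CFU/ml")
}
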