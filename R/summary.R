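## Cohort-level summaries: per-area parameter tables, between-area paired
## comparisons, Spearman correlation matrices, and FDR control.

## paired two-sided test across recordings: Wilcoxon signed rank with at
## least 6 pairs, paired t below that (small-n fallback)
paired_area_test <- function(x, y, min_wilcoxon = 6) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || all(x == y))
    return(list(p = if (length(x) && all(x == y)) 1 else NA_real_,
                test = "none", n = length(x)))
  if (length(x) >= min_wilcoxon) {
    p <- suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value)
    list(p = p, test = "wilcoxon", n = length(x))
  } else {
    p <- tryCatch(t.test(x, y, paired = TRUE)$p.value,
                  error = function(e) NA_real_)
    list(p = p, test = "paired_t", n = length(x))
  }
}

#' Summary table of evoked-response parameters by area
#'
#' Unit-level values are averaged within each recording, the per-recording
#' means are averaged across recordings (mean +/- s.d.), and S1 and M1 are
#' compared with a paired test across recordings contributing both areas
#' (Wilcoxon signed rank with >= 6 pairs, paired t below). The difference
#' column is the mean +/- s.d. of per-recording M1 - S1 differences over the
#' same intersection.
#'
#' @param metrics Per-unit metrics table (one row per unit), as produced by
#'   [analyze_cohort()]: columns `recording_id`, `area`, `responsive`,
#'   `baseline_hz`, `onset_ms`, `peak_ms`, `duration_ms`, `amplitude_hz`,
#'   `is_suppressed`, `supp_rate_hz`, `supp_pct_baseline`, `has_rebound`,
#'   `rebound_latency_ms`, `rebound_amp_hz`.
#' @param params [analysis_params()].
#' @return A data frame of class `response_summary`, one row per parameter.
#' @export
summarize_responses <- function(metrics, params = analysis_params()) {
  m <- metrics
  resp <- m[m$responsive %in% TRUE, , drop = FALSE]
  supp <- resp[resp$is_suppressed %in% TRUE, , drop = FALSE]
  reb <- resp[resp$has_rebound %in% TRUE, , drop = FALSE]
  specs <- list(
    list("Baseline firing rate (Hz)", resp, "baseline_hz"),
    list("Stimulus-responsive units (%)",
         transform(m, value = 100 * (responsive %in% TRUE)), "value"),
    list("Onset latency (ms)", resp, "onset_ms"),
    list("Peak latency (ms)", resp, "peak_ms"),
    list("Duration (ms)", resp, "duration_ms"),
    list("Amplitude (Hz)", resp, "amplitude_hz"),
    list("Responsive units with suppression (%)",
         transform(resp, value = 100 * (is_suppressed %in% TRUE)), "value"),
    list("Suppression amplitude (Hz)", supp, "supp_rate_hz"),
    list("Suppression amplitude (% of baseline)", supp, "supp_pct_baseline"),
    list("Responsive units with rebound (%)",
         transform(resp, value = 100 * (has_rebound %in% TRUE)), "value"),
    list("Rebound peak latency (ms)", reb, "rebound_latency_ms"),
    list("Rebound amplitude (Hz)", reb, "rebound_amp_hz"))
  rows <- lapply(specs, function(sp) {
    df <- sp[[2]]; col <- sp[[3]]
    s1 <- two_level_mean(df[[col]][df$area == "S1"],
                         df$recording_id[df$area == "S1"])
    m1 <- two_level_mean(df[[col]][df$area == "M1"],
                         df$recording_id[df$area == "M1"])
    shared <- intersect(names(s1$per_recording), names(m1$per_recording))
    tt <- paired_area_test(s1$per_recording[shared], m1$per_recording[shared])
    d <- m1$per_recording[shared] - s1$per_recording[shared]
    data.frame(parameter = sp[[1]],
               s1_mean = s1$mean, s1_sd = s1$sd, s1_n_rec = s1$n,
               m1_mean = m1$mean, m1_sd = m1$sd, m1_n_rec = m1$n,
               p_value = tt$p, test = tt$test, n_pairs = tt$n,
               diff_mean = if (length(d)) mean(d) else NA_real_,
               diff_sd = if (length(d) > 1) sd(d) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("response_summary", "data.frame")
  out
}

#' Area difference on printed per-area means
#'
#' Convenience for recomputing difference columns (M1 - S1) directly from
#' per-area summary means.
#'
#' @param s1,m1 Numeric vectors of per-area parameter means.
#' @return `m1 - s1`.
#' @export
area_difference <- function(s1, m1) m1 - s1

#' Spearman correlation matrix across recordings
#'
#' Computes Spearman's rho for every pair of properties over per-recording
#' mean values, with p-values from the t transform
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Pairs involving a constant vector are undefined and flagged.
#'
#' @param rec_means Data frame, one row per recording, numeric property
#'   columns.
#' @param properties Optional character vector selecting/ordering columns.
#' @param alpha Significance level for the `significant` flag matrix.
#' @return List of class `property_correlations`: `rho`, `p`, `significant`,
#'   `n`.
#' @export
correlate_properties <- function(rec_means, properties = NULL, alpha = 0.05) {
  num <- rec_means[vapply(rec_means, is.numeric, TRUE)]
  if (!is.null(properties)) num <- num[properties]
  n <- nrow(num)
  if (n < 4) stop("at least 4 recordings are required for correlations")
  k <- ncol(num)
  rho <- matrix(NA_real_, k, k, dimnames = list(names(num), names(num)))
  pmat <- rho
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- num[[i]]; y <- num[[j]]
    ok <- complete.cases(x, y)
    if (sum(ok) < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    r <- cor(x[ok], y[ok], method = "spearman")
    rho[i, j] <- r
    pmat[i, j] <- if (abs(r) >= 1) 0 else {
      tv <- r * sqrt((sum(ok) - 2) / (1 - r^2))
      2 * pt(-abs(tv), df = sum(ok) - 2)
    }
  }
  structure(list(rho = rho, p = pmat, significant = !is.na(pmat) & pmat < alpha,
                 n = n), class = "property_correlations")
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Standard step-up procedure at level `q`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs tolerated, never
#'   rejected).
#' @param q FDR level.
#' @return List: `adjusted` (BH-adjusted p-values), `reject` (logical).
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.9))$reject  # TRUE TRUE TRUE FALSE
#' @export
adjust_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= q)
}
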