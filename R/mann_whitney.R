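# Exact small-sample Mann-Whitney machinery by full enumeration, and the
# OLS trendline helper used for the proximity-by-day series.

# all values of sum(ranks chosen for sample a) over the C(n, n_a) equally
# likely rank assignments, given the pooled (mid)ranks
rank_sum_distribution <- function(ranks, n_a) {
  sel <- utils::combn(length(ranks), n_a)
  colSums(matrix(ranks[sel], nrow = n_a))
}

#' Exact Mann-Whitney U test
#'
#' Computes `U = min(U_a, U_b)` and the exact two-sided p-value by
#' exhaustive enumeration of all `choose(n_a + n_b, n_a)` equally likely
#' assignments of the pooled (mid)ranks to the first sample — no normal
#' approximation, appropriate for the very small per-treatment sample sizes
#' (e.g. four sessions per treatment, where U = 0 has exact two-sided
#' p = 2/70). Ties are handled with midranks and enumerated as observed.
#'
#' @param sample_a,sample_b numeric vectors (combined length at most 20).
#' @return An object of class `htest` with `statistic` (U), `p.value`, and
#'   `estimate` holding both one-sided U statistics.
#' @examples
#' mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))  # U = 0, p = 2/70
#' @export
mann_whitney_exact <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n_a <- length(sample_a); n_b <- length(sample_b)
  if (n_a + n_b > 20) {
    stop("exact enumeration supported for n_a + n_b <= 20", call. = FALSE)
  }
  r <- rank(c(sample_a, sample_b))   # midranks under ties
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  dist_a <- rank_sum_distribution(r, n_a) - n_a * (n_a + 1) / 2
  eps <- 1e-9
  p_le <- mean(dist_a <= u_a + eps)
  p_ge <- mean(dist_a >= u_a - eps)
  p <- min(1, 2 * min(p_le, p_ge))
  structure(
    list(statistic = c(U = min(u_a, u_b)),
         estimate = c(U_a = u_a, U_b = u_b),
         p.value = p,
         alternative = "two.sided",
         method = sprintf(
           "Exact Mann-Whitney U test (full enumeration of %d assignments)",
           choose(n_a + n_b, n_a)),
         data.name = sprintf("sample_a (n = %d) vs sample_b (n = %d)",
                             n_a, n_b)),
    class = "htest"
  )
}

#' Exact Mann-Whitney critical value
#'
#' The largest `u` such that the exact null probability `P(U <= u)` is at
#' most `alpha / 2` (two-sided) or `alpha` (one-sided), computed by full
#' enumeration of untied rank assignments. For `n_a = n_b = 4` at two-sided
#' `alpha = 0.05` the critical value is 0: `P(U <= 0) = 1/70 <= 0.025` but
#' `P(U <= 1) = 2/70 > 0.025`. Returns `-1` (sentinel) when no rejection
#' region exists, i.e. even `u = 0` exceeds the bound.
#'
#' @param n_a,n_b sample sizes (each at least 1, combined at most 20).
#' @param alpha significance level in (0, 1).
#' @param two_sided if `TRUE` (default) use `alpha / 2` in each tail.
#' @return Integer critical value, or `-1` if no rejection region exists.
#' @examples
#' mann_whitney_critical_value(4, 4, 0.05)  # 0
#' @export
mann_whitney_critical_value <- function(n_a, n_b, alpha = 0.05,
                                        two_sided = TRUE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(n_a >= 1, n_b >= 1)
  if (n_a + n_b > 20) {
    stop("exact enumeration supported for n_a + n_b <= 20", call. = FALSE)
  }
  bound <- if (two_sided) alpha / 2 else alpha
  u <- rank_sum_distribution(seq_len(n_a + n_b), n_a) -
    n_a * (n_a + 1) / 2
  tab <- table(u)
  vals <- as.numeric(names(tab))          # distinct U values, ascending
  cdf <- cumsum(as.numeric(tab)) / length(u)
  ok <- vals[cdf <= bound + 1e-12]
  if (!length(ok)) return(-1L)
  as.integer(max(ok))
}

#' OLS trendline of a per-day series
#'
#' Ordinary least-squares slope of a daily series on the day index, with
#' the two-sided p-value from the slope's t statistic. Missing days (e.g.
#' proximity on days with fewer than two nesters) are excluded, not
#' imputed.
#'
#' @param values numeric per-day values (may contain `NA`).
#' @param days day indices; default `0, 1, 2, ...`.
#' @return A list with `slope` (units per day), `intercept`, `p.value`,
#'   and `n` (points used).
#' @examples
#' ols_trend(2 * (0:9) + 5)$slope  # 2
#' @export
ols_trend <- function(values, days = seq_along(values) - 1) {
  ok <- is.finite(values) & is.finite(days)
  if (sum(ok) < 3) {
    stop("need at least 3 non-missing points for a trend", call. = FALSE)
  }
  fit <- stats::lm(values[ok] ~ days[ok])
  # an exact fit (zero residual variance) is legitimate here, e.g. a
  # constant series; the t-based p-value is then meaningless but defined
  sm <- suppressWarnings(stats::summary.lm(fit))$coefficients
  p <- if (nrow(sm) == 2L) sm[2L, 4L] else NA_real_  # constant series: slope 0
  slope <- if (nrow(sm) == 2L) sm[2L, 1L] else 0
  list(slope = unname(slope),
       intercept = unname(sm[1L, 1L]),
       p.value = unname(p),
       n = sum(ok))
}

#' Full analysis report for one session log
#'
#' Bundles every per-session statistic: the nesting-proximity series and
#' its OLS trend, the three activity histograms, the attack tally by
#' coalition size and session half, and the session summary.
#'
#' @param log a `session_log`.
#' @param split_day see [attack_tally()].
#' @param bin_width see [activity_histogram()].
#' @return A list of class `session_report`.
#' @export
analyze_log <- function(log, split_day = 18, bin_width = 1) {
  stopifnot(inherits(log, "session_log"))
  prox <- nesting_proximity(log)
  trend <- if (sum(is.finite(prox$proximity)) >= 3) {
    ols_trend(prox$proximity, prox$day)
  } else {
    NULL
  }
  structure(
    list(fingerprint = log$fingerprint,
         seed = log$seed,
         treatment = log$config$treatment$name,
         proximity = prox,
         proximity_trend = trend,
         histograms = list(
           groom = activity_histogram(log, "groom", bin_width),
           forage_grass_unit = activity_histogram(log, "forage_grass_unit",
                                                  bin_width),
           forage_fruit = activity_histogram(log, "forage_fruit", bin_width)),
         attack_tally = attack_tally(log, split_day = split_day),
         summary = session_summary(log, split_day = split_day),
         final_points = log$final_points),
    class = "session_report"
  )
}

#' @export
print.session_report <- function(x, ...) {
  cat("<session_report>", x$treatment, "treatment, seed", x$seed, "\n")
  cat("  mean proximity:", round(x$summary$mean_proximity, 1), "px")
  if (!is.null(x$proximity_trend)) {
    cat(sprintf("; trend %.1f px/day (p = %.3g)",
                x$proximity_trend$slope, x$proximity_trend$p.value))
  }
  cat("\n  attacks first/second half:", x$summary$attacks_first_half, "/",
      x$summary$attacks_second_half, "\n")
  invisible(x)
}
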