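# Figure helpers (ggplot2, Suggests): the daily activity histograms, the
# nesting-proximity-by-day trend, and the attack tally by coalition size
# and session half.

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
}

#' Plot grooming and foraging over the course of the day
#'
#' Event counts per time-of-day bin, summed over all days, facetted by
#' activity (grooming, grass foraging, fruit foraging).
#'
#' @param log a `session_log`.
#' @param bin_width bin width in seconds.
#' @return A ggplot object.
#' @export
plot_activity <- function(log, bin_width = 1) {
  need_ggplot2()
  types <- c(groom = "grooming", forage_grass_unit = "grass foraging",
             forage_fruit = "fruit foraging")
  dat <- do.call(rbind, lapply(names(types), function(ty) {
    h <- activity_histogram(log, ty, bin_width)
    h$activity <- types[[ty]]
    h
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_start, y = .data$count)) +
    ggplot2::geom_col(width = bin_width) +
    ggplot2::facet_wrap(~activity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time of day (s)",
                  y = sprintf("events per %g s (all days)", bin_width),
                  title = sprintf("Daily activity, %s treatment",
                                  log$config$treatment$name)) +
    ggplot2::theme_minimal()
}

#' Plot nesting proximity by day with its OLS trendline
#'
#' @param ... one or more `session_log`s (dashed lines); their average is
#'   drawn solid with the fitted trend.
#' @return A ggplot object.
#' @export
plot_proximity <- function(...) {
  need_ggplot2()
  logs <- list(...)
  series <- lapply(seq_along(logs), function(k) {
    pr <- nesting_proximity(logs[[k]])
    pr$session <- paste0("session ", k)
    pr
  })
  dat <- do.call(rbind, series)
  avg <- stats::aggregate(proximity ~ day, dat, mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$proximity)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$session),
                       linetype = "dashed", alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_line(data = avg, linewidth = 1, na.rm = TRUE) +
    ggplot2::geom_smooth(data = avg, method = "lm", se = FALSE,
                         formula = y ~ x, na.rm = TRUE) +
    ggplot2::labs(x = "day", y = "mean pairwise nest distance (px)",
                  title = "Nesting proximity by day") +
    ggplot2::theme_minimal()
}

#' Plot the attack tally by coalition size and session half
#'
#' @param log a `session_log`.
#' @param split_day see [attack_tally()].
#' @return A ggplot object.
#' @export
plot_attack_tally <- function(log, split_day = 18) {
  need_ggplot2()
  tal <- attack_tally(log, split_day = split_day)
  ggplot2::ggplot(tal, ggplot2::aes(x = .data$coalition, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~half) +
    ggplot2::labs(x = "attackers per coalition", y = "attacks",
                  title = sprintf("Attacks on the pirate, %s treatment",
                                  log$config$treatment$name)) +
    ggplot2::theme_minimal()
}
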