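# Analysis layer: every statistic the study design calls for, computed from
# typed event logs.

#' Extract per-day nesting positions from a session log
#'
#' @param log a `session_log` (or its `events` data frame).
#' @return A list of length `n_days`; element `d + 1` is an `n x 2` matrix
#'   of the (x, y) positions of the avatars that nested on day `d`.
#' @export
nest_positions <- function(log) {
  ev <- if (inherits(log, "session_log")) log$events else log
  n_days <- if (inherits(log, "session_log")) log$config$n_days
            else max(ev$day) + 1L
  ns <- ev[ev$type == "nest_start", , drop = FALSE]
  lapply(0:(n_days - 1L), function(d) {
    dd <- ns[ns$day == d, , drop = FALSE]
    cbind(x = dd$x, y = dd$y)
  })
}

#' Nesting-proximity series
#'
#' The model's cohesion statistic: for each day, the sum of the unique
#' pairwise Euclidean distances among the avatars that nested, divided by
#' the number of nest combinations `choose(n, 2)` — 66 when all 12 nest, 45
#' when 10 do — so the measure is comparable across days with different
#' numbers of nesters. Days with fewer than two nesters are flagged missing
#' (`NA`) and excluded from trend fits. Lower values mean closer nesting.
#'
#' @param x a `session_log`, or a list of per-day `n x 2` position matrices.
#' @return A data frame with columns `day` (0-based), `n_nested`,
#'   `proximity` (pixels; `NA` when `n_nested < 2`).
#' @examples
#' pos <- list(rbind(c(0, 0), c(300, 0)))
#' nesting_proximity(pos)$proximity  # 300
#' @export
nesting_proximity <- function(x) {
  days <- if (inherits(x, "session_log")) nest_positions(x) else x
  out <- data.frame(day = seq_along(days) - 1L,
                    n_nested = vapply(days, nrow, integer(1)),
                    proximity = NA_real_)
  for (k in seq_along(days)) {
    p <- days[[k]]
    n <- nrow(p)
    if (n >= 2) {
      out$proximity[k] <- sum(stats::dist(p)) / choose(n, 2)
    }
  }
  out
}

#' Partition avatars into vision-overlap groups
#'
#' A group is any set of avatars connected by overlapping viewing windows:
#' two windows (each `view_width` x `view_height`, centred on the avatar)
#' overlap when the centres differ by at most `view_width` in x and
#' `view_height` in y (closed bounds), and groups are the connected
#' components of that overlap graph (so A-B and B-C overlapping chains A, B
#' and C into one group even if A and C do not overlap).
#'
#' @param positions an `n x 2` matrix of (x, y) positions.
#' @param config a `world_config` (supplies the window size).
#' @return An integer vector of group labels (1, 2, ...), one per row.
#' @export
group_partition <- function(positions, config) {
  n <- nrow(positions)
  if (n == 0L) return(integer(0))
  dx <- abs(outer(positions[, 1], positions[, 1], "-")) <= config$view_width
  dy <- abs(outer(positions[, 2], positions[, 2], "-")) <= config$view_height
  adj <- dx & dy
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Daily activity histogram
#'
#' Counts events of one type per time-of-day bin, summed over all days of
#' the session — the "shape of the day" for grooming, grass foraging or
#' fruit foraging. The default 1-s bins cover the 75 s of daylight (no
#' groom/forage events can occur at night).
#'
#' @param log a `session_log`.
#' @param event_type one of `"groom"`, `"forage_grass_unit"`,
#'   `"forage_fruit"` (any logged type is accepted).
#' @param bin_width bin width in seconds; must divide `daylight_length`.
#' @return A data frame with columns `bin_start`, `bin_end`, `count`.
#' @export
activity_histogram <- function(log, event_type, bin_width = 1) {
  stopifnot(inherits(log, "session_log"))
  if (!event_type %in% c("groom", "forage_grass_unit", "forage_fruit",
                         unique(log$events$type))) {
    stop("unknown event type '", event_type, "'", call. = FALSE)
  }
  dl <- log$config$daylight_length
  if (abs(dl / bin_width - round(dl / bin_width)) > 1e-9) {
    stop("bin_width must divide daylight_length (", dl, " s)", call. = FALSE)
  }
  breaks <- seq(0, dl, by = bin_width)
  ev <- log$events[log$events$type == event_type, , drop = FALSE]
  counts <- if (nrow(ev)) {
    tabulate(pmin(floor(ev$t / bin_width) + 1L, length(breaks) - 1L),
             nbins = length(breaks) - 1L)
  } else {
    integer(length(breaks) - 1L)
  }
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1L],
             count = counts)
}

#' Tally attacks by coalition size and session half
#'
#' Classifies every resolved attack by the concurrent-beam count of its
#' outcome — single (a lone beam that expired at a 10-point cost), pair
#' (drove the pirate off for the day) or triplet (killed it) — and splits
#' the tallies into the first and second half of the session. With the
#' default `split_day`, a 35-day session splits as days 1-17 versus 18-35
#' (1-based). `unit = "attacks"` counts individual attack events (a triple
#' coalition contributes 3), matching a bar-height reading of total attacks;
#' `unit = "coalitions"` counts each resolution once.
#'
#' @param log a `session_log`.
#' @param split_day first (1-based) day of the second half; default 18.
#' @param unit `"attacks"` (default) or `"coalitions"`.
#' @return A data frame with columns `half` (`"first"`/`"second"`),
#'   `coalition` (`"single"`/`"pair"`/`"triplet"`), `count`.
#' @export
attack_tally <- function(log, split_day = 18, unit = c("attacks",
                                                       "coalitions")) {
  stopifnot(inherits(log, "session_log"))
  unit <- match.arg(unit)
  ev <- log$events
  n_attacks <- sum(ev$type == "attack")
  out <- ev[ev$type == "attack_outcome", , drop = FALSE]
  if (sum(out$value) != n_attacks) {
    stop("corrupt log: ", n_attacks, " attack events but outcomes account ",
         "for ", sum(out$value), call. = FALSE)
  }
  sizes <- c("single", "pair", "triplet")
  cls <- factor(ifelse(out$value >= 3, "triplet",
                       ifelse(out$value == 2, "pair", "single")),
                levels = sizes)
  half <- factor(ifelse(out$day + 1L < split_day, "first", "second"),
                 levels = c("first", "second"))
  wt <- if (unit == "attacks") out$value else rep(1, nrow(out))
  tab <- tapply(wt, list(half, cls), sum, default = 0)
  data.frame(half = rep(rownames(tab), times = ncol(tab)),
             coalition = rep(colnames(tab), each = nrow(tab)),
             count = as.vector(tab))
}

#' Summarise a session for between-treatment comparison
#'
#' The per-session quantities used in treatment contrasts: the mean nesting
#' proximity over all days (missing days excluded), total attacks in each
#' session half, and mean final points (convertible 1:1 to dollars).
#'
#' @param log a `session_log`.
#' @param split_day see [attack_tally()].
#' @return A one-row data frame.
#' @export
session_summary <- function(log, split_day = 18) {
  pr <- nesting_proximity(log)
  at <- attack_tally(log, split_day = split_day)
  data.frame(
    treatment = log$config$treatment$name,
    seed = log$seed,
    mean_proximity = mean(pr$proximity, na.rm = TRUE),
    attacks_first_half = sum(at$count[at$half == "first"]),
    attacks_second_half = sum(at$count[at$half == "second"]),
    mean_final_points = mean(log$final_points),
    dollars_per_point = 1
  )
}
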