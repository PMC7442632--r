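#' Treatment parameter bundles
#'
#' The two feeding-ecology treatments differ only in how much fruit the world
#' offers per day and how long it takes to graze the caloric equivalent of
#' one piece of fruit; everything else is shared. "chimpanzee" is the
#' abundant-fruit / slow-grass world (120 pieces, grazing 10x one fruit's
#' handling time); "bonobo" is the scarce-fruit / fast-grass world (40
#' pieces, 3.33x). The compensating differences hold the aggregate amount of
#' food roughly constant between treatments.
#'
#' @param name `"chimpanzee"` or `"bonobo"` (case-insensitive).
#' @param fruit_per_day,grass_time_multiplier,fruit_handle_time optional
#'   overrides of the preset values; `fruit_handle_time` is the seconds an
#'   avatar needs between successive fruit-eating actions (one piece each).
#' @return A list of class `treatment_params`.
#' @export
treatment_params <- function(name,
                             fruit_per_day = NULL,
                             grass_time_multiplier = NULL,
                             fruit_handle_time = 1.0) {
  presets <- list(
    chimpanzee = list(fruit_per_day = 120, grass_time_multiplier = 10),
    bonobo     = list(fruit_per_day = 40,  grass_time_multiplier = 3.33)
  )
  key <- tolower(as.character(name)[1L])
  if (!key %in% names(presets)) {
    stop("unknown treatment preset '", name, "'; valid presets: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[key]]
  out <- list(
    name = key,
    fruit_per_day = if (is.null(fruit_per_day)) p$fruit_per_day else fruit_per_day,
    grass_time_multiplier = if (is.null(grass_time_multiplier)) p$grass_time_multiplier else grass_time_multiplier,
    fruit_handle_time = fruit_handle_time
  )
  class(out) <- "treatment_params"
  out
}

# canonical field set; config files may not introduce keys outside this list
world_config_fields <- function() {
  c("world_width", "world_height", "view_width", "view_height", "call_radius",
    "day_length", "daylight_length", "dusk_length", "night_length",
    "n_days", "n_avatars",
    "n_trees_per_grove", "n_fruiting_trees_per_grove", "n_grass_patches",
    "digest_midday", "digest_predawn",
    "stock_cap", "low_threshold", "high_threshold",
    "point_cap", "nest_rate", "attack_cost", "attack_window",
    "n_pirates", "pirate_eat_mean_interval", "pirate_eat_law",
    "groom_cooldown", "tick_length", "walk_speed",
    "point_gain_rate", "point_loss_rate", "groom_walk_depletion",
    "interaction_range", "fruit_handle_time", "message_display",
    "initial_food_stock", "initial_groom_stock", "initial_points",
    "treatment")
}

#' Construct a world configuration
#'
#' Bundles every fixed parameter of a session: geometry (pixels), the day
#' clock (seconds), food economics, the grooming economy, point accrual and
#' the pirate rules. Defaults are the published session conditions; see the
#' methods vignette for the handful of free parameters (walking speed,
#' handling time, point rates, groom depletion, interaction range) that the
#' experiment's description leaves open and this model fixes explicitly.
#'
#' `walk_speed = NULL` (the default) calibrates the speed so that walking
#' from the southernmost northern tree to the northernmost southern tree
#' takes 20 s (about 22% of the 90-s day) under the default tree layout; see
#' [traversal_time()].
#'
#' @param treatment a [treatment_params()] bundle (or preset name).
#' @param world_width,world_height world rectangle, pixels.
#' @param view_width,view_height an avatar's viewing window, pixels.
#' @param call_radius radius (pixels) within which a call's bearing is seen.
#' @param day_length,daylight_length,dusk_length,night_length day clock,
#'   seconds; daylight includes the final `dusk_length` seconds of setting
#'   light, and `daylight_length + night_length` must equal `day_length`.
#' @param n_days days per session.
#' @param n_avatars group size.
#' @param n_trees_per_grove,n_fruiting_trees_per_grove trees per grove and
#'   how many of them bear fruit on a given day.
#' @param n_grass_patches grass patches scattered daily.
#' @param digest_midday,digest_predawn food units digested at the two daily
#'   digestion instants.
#' @param stock_cap,low_threshold,high_threshold stock cap and the point
#'   accrual thresholds shared by the food and grooming stocks.
#' @param point_cap maximum cash-earning points.
#' @param nest_rate points per second earned while nested.
#' @param attack_cost points lost by a lone attacker; also the minimum
#'   points required to attack.
#' @param attack_window seconds an attack beam stays linked to the pirate.
#' @param n_pirates pirates available per session (no respawn after the
#'   last is killed).
#' @param pirate_eat_mean_interval mean seconds between pirate fruit eats.
#' @param pirate_eat_law `"exponential"` (default) or `"fixed"` interval law.
#' @param groom_cooldown seconds between grooming actions by one avatar.
#' @param tick_length simulation step, seconds.
#' @param walk_speed pixels per second, or `NULL` to calibrate (see above).
#' @param point_gain_rate,point_loss_rate points per second gained (stock
#'   above `high_threshold`) or lost (below `low_threshold`), per resource.
#' @param groom_walk_depletion groom units lost per pixel walked.
#' @param interaction_range pixels within which foraging, grooming and
#'   attacking are possible.
#' @param fruit_handle_time seconds to eat one piece of fruit.
#' @param message_display seconds a broadcast outcome message stays visible.
#' @param initial_food_stock,initial_groom_stock,initial_points avatar state
#'   at the start of day 1.
#' @return A validated list of class `world_config`.
#' @seealso [make_treatment_config()], [validate_config()],
#'   [assign_daily_food()]
#' @export
world_config <- function(treatment = treatment_params("chimpanzee"),
                         world_width = 6720, world_height = 10500,
                         view_width = 1584, view_height = 947,
                         call_radius = 2200,
                         day_length = 90, daylight_length = 75,
                         dusk_length = 5, night_length = 15,
                         n_days = 35, n_avatars = 12,
                         n_trees_per_grove = 5, n_fruiting_trees_per_grove = 3,
                         n_grass_patches = 8,
                         digest_midday = 4, digest_predawn = 7,
                         stock_cap = 10, low_threshold = 4, high_threshold = 7,
                         point_cap = 100, nest_rate = 0.3,
                         attack_cost = 10, attack_window = 10,
                         n_pirates = 3, pirate_eat_mean_interval = 4,
                         pirate_eat_law = "exponential",
                         groom_cooldown = 4,
                         tick_length = 0.1, walk_speed = NULL,
                         point_gain_rate = 0.1, point_loss_rate = 0.1,
                         groom_walk_depletion = 0.002,
                         interaction_range = 60,
                         fruit_handle_time = 1.0,
                         message_display = 17,
                         initial_food_stock = 5, initial_groom_stock = 5,
                         initial_points = 0) {
  if (is.character(treatment)) treatment <- treatment_params(treatment)
  cfg <- mget(setdiff(world_config_fields(), "treatment"))
  cfg$treatment <- treatment
  class(cfg) <- "world_config"
  if (is.null(cfg$walk_speed)) {
    lay <- tree_layout(cfg)
    cfg$walk_speed <- inter_grove_distance(lay) / 20
  }
  validate_config(cfg)
}

#' Build a full treatment preset configuration
#'
#' @param name `"chimpanzee"` or `"bonobo"` (case-insensitive).
#' @param ... overrides forwarded to [world_config()].
#' @return A validated `world_config`.
#' @examples
#' cfg <- make_treatment_config("bonobo")
#' cfg$treatment$fruit_per_day  # 40
#' @export
make_treatment_config <- function(name, ...) {
  world_config(treatment = treatment_params(name), ...)
}

#' Validate a world configuration
#'
#' Checks every type invariant (positivity, clock consistency, threshold
#' ordering, grove arithmetic, attack affordability) and reports all
#' violations at once, naming the offending fields.
#'
#' @param config a `world_config`.
#' @return `config`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "world_config")) stop("not a world_config", call. = FALSE)
  bad <- character()
  pos <- c("world_width", "world_height", "view_width", "view_height",
           "call_radius", "day_length", "daylight_length", "dusk_length",
           "night_length", "n_days", "n_avatars", "n_trees_per_grove",
           "n_fruiting_trees_per_grove", "n_grass_patches",
           "digest_midday", "digest_predawn", "stock_cap",
           "low_threshold", "high_threshold", "point_cap", "nest_rate",
           "attack_cost", "attack_window", "pirate_eat_mean_interval",
           "groom_cooldown", "tick_length", "walk_speed",
           "point_gain_rate", "point_loss_rate",
           "interaction_range", "fruit_handle_time", "message_display")
  for (f in pos) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      bad <- c(bad, paste0(f, " must be a single positive number"))
    }
  }
  num_ok <- function(f) is.numeric(config[[f]]) && length(config[[f]]) == 1L &&
    is.finite(config[[f]])
  for (f in c("groom_walk_depletion", "n_pirates",
              "initial_food_stock", "initial_groom_stock", "initial_points")) {
    if (!num_ok(f) || config[[f]] < 0) {
      bad <- c(bad, paste0(f, " must be a single non-negative number"))
    }
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  if (num_ok("daylight_length") && num_ok("night_length") && num_ok("day_length")) {
    chk(isTRUE(all.equal(config$daylight_length + config$night_length,
                         config$day_length)),
        "daylight_length + night_length must equal day_length")
  }
  if (num_ok("dusk_length") && num_ok("daylight_length")) {
    chk(config$dusk_length < config$daylight_length,
        "dusk_length must be smaller than daylight_length")
  }
  if (num_ok("low_threshold") && num_ok("high_threshold") && num_ok("stock_cap")) {
    chk(config$low_threshold < config$high_threshold &&
          config$high_threshold < config$stock_cap,
        "thresholds must satisfy low_threshold < high_threshold < stock_cap")
  }
  chk(config$n_fruiting_trees_per_grove <= config$n_trees_per_grove,
      "n_fruiting_trees_per_grove must not exceed n_trees_per_grove")
  if (num_ok("attack_cost") && num_ok("point_cap")) {
    chk(config$attack_cost <= config$point_cap,
        "attack_cost must not exceed point_cap")
  }
  tr <- config$treatment
  if (!inherits(tr, "treatment_params")) {
    bad <- c(bad, "treatment must be a treatment_params bundle")
  } else {
    chk(tr$fruit_per_day > 0, "treatment$fruit_per_day must be positive")
    chk(tr$grass_time_multiplier > 1,
        "treatment$grass_time_multiplier must exceed 1")
    chk(tr$fruit_handle_time > 0, "treatment$fruit_handle_time must be positive")
  }
  if (!config$pirate_eat_law %in% c("exponential", "fixed")) {
    bad <- c(bad, "pirate_eat_law must be 'exponential' or 'fixed'")
  }
  if (length(bad)) {
    stop("invalid world_config:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(config)
}

#' Default tree layout
#'
#' Trees keep fixed positions for a whole session: one northern and one
#' southern grove, each a horizontal band of `n_trees_per_grove` trees evenly
#' spaced in x at `world_width * i / (n + 1)`, with band centres at 15% and
#' 85% of `world_height` ("north" is smaller y under the top-left-origin
#' convention). Matching x-columns across groves make the inter-grove
#' traversal distance exactly the band separation, which is what the 20-s
#' walking-time calibration uses.
#'
#' @param config a `world_config`.
#' @return A data frame with columns `tree`, `x`, `y`, `grove`.
#' @export
tree_layout <- function(config) {
  n <- config$n_trees_per_grove
  xs <- config$world_width * seq_len(n) / (n + 1)
  data.frame(
    tree = seq_len(2L * n),
    x = c(xs, xs),
    y = c(rep(config$world_height * 0.15, n),
          rep(config$world_height * 0.85, n)),
    grove = rep(c("north", "south"), each = n),
    stringsAsFactors = FALSE
  )
}

# distance from the southernmost northern tree to the northernmost southern
# tree (ties in y broken by smallest x, which pairs aligned columns)
inter_grove_distance <- function(layout) {
  no <- layout[layout$grove == "north", ]
  so <- layout[layout$grove == "south", ]
  a <- no[order(-no$y, no$x), ][1L, ]
  b <- so[order(so$y, so$x), ][1L, ]
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Avatar starting positions
#'
#' Day-1 starting positions: a regular 4 x 3 grid spanning the central region
#' of the world (x from 12.5% to 87.5% of the width, y within +/- 1600 px of
#' the vertical midpoint), so the group begins dispersed, with every avatar
#' within calling range of a neighbour but outside everyone's viewing window.
#'
#' @param config a `world_config`.
#' @return An `n_avatars` x 2 matrix of (x, y) pixels.
#' @export
avatar_start_positions <- function(config) {
  n <- config$n_avatars
  ncol_grid <- ceiling(sqrt(n * config$world_width / config$world_height * 2))
  ncol_grid <- max(2L, min(n, ncol_grid))
  nrow_grid <- ceiling(n / ncol_grid)
  xs <- config$world_width * (seq_len(ncol_grid) - 0.5) / ncol_grid
  ys <- config$world_height / 2 + (seq_len(nrow_grid) - (nrow_grid + 1) / 2) * 1600
  pos <- as.matrix(expand.grid(x = xs, y = ys))[seq_len(n), , drop = FALSE]
  rownames(pos) <- NULL
  pos
}

# per-day derived seed for the food substream (kept below 2^31)
daily_food_seed <- function(food_seed, day) {
  as.integer((as.numeric(food_seed) + as.numeric(day) * 10007) %% 2147483647)
}

#' Assign the day's food
#'
#' Each day a different set of `n_fruiting_trees_per_grove` (3 of 5) trees
#' per grove bears fruit; the day's fruit is divided equally between the
#' northern and southern groves, and within a grove in fixed 3:2:1
#' proportions across its fruiting trees (floored, remainder to the largest),
#' so a unique "largest fruit-bearing tree" exists in each grove — that tree
#' is where the pirate may appear. Flowers shown today are exactly tomorrow's
#' fruit allocation. Grass patches are placed uniformly at random inside the
#' world, fresh each day.
#'
#' @param config a `world_config`.
#' @param day 0-based day index in `[0, n_days)`.
#' @param food_seed integer seed of the food substream (derive from the
#'   session master seed with [substream_seed()]`(seed, "food")`).
#' @return A list of class `daily_food` with elements `day`,
#'   `fruiting_trees` (tree ids), `fruit_on_tree` (length `2 * n_trees`
#'   vector), `flower_display` (same shape; tomorrow's allocation) and
#'   `grass_xy` (`n_grass_patches` x 2 matrix).
#' @export
assign_daily_food <- function(config, day, food_seed) {
  if (day < 0 || day >= config$n_days) {
    stop("day ", day, " out of range [0, ", config$n_days, ")", call. = FALSE)
  }
  a <- daily_fruit_allocation(config, day, food_seed)
  b <- daily_fruit_allocation(config, day + 1, food_seed)
  s <- rng_stream(daily_food_seed(food_seed, day))
  grass <- cbind(
    x = stream_draw(s, runif, config$n_grass_patches, 0, config$world_width),
    y = stream_draw(s, runif, config$n_grass_patches, 0, config$world_height)
  )
  structure(
    list(day = day,
         fruiting_trees = which(a > 0),
         fruit_on_tree = a,
         flower_display = b,
         grass_xy = grass),
    class = "daily_food"
  )
}

# fruit allocation for one day (independent of grass placement so the flower
# display for day d can be computed without consuming day d+1's grass draws)
daily_fruit_allocation <- function(config, day, food_seed) {
  n <- config$n_trees_per_grove
  k <- config$n_fruiting_trees_per_grove
  per_grove <- config$treatment$fruit_per_day / 2
  s <- rng_stream(daily_food_seed(food_seed, day) + 1L)
  alloc <- numeric(2L * n)
  props <- rev(seq_len(k))              # 3:2:1 for k = 3
  for (g in 0:1) {
    ids <- g * n + stream_draw(s, sample.int, n, k)
    amounts <- floor(per_grove * props / sum(props))
    amounts[1L] <- amounts[1L] + (per_grove - sum(amounts))
    alloc[ids] <- amounts
  }
  alloc
}

#' Load a world configuration from a JSON file
#'
#' Every `world_config` field can be overridden; the treatment is selected by
#' name via `"treatment"` (a string, or an object with `name` and optional
#' `fruit_per_day` / `grass_time_multiplier` / `fruit_handle_time`). Unknown
#' keys are rejected.
#'
#' @param path path to a JSON file.
#' @param overrides optional named list applied on top of the file's values
#'   (used by the CLI's `--override KEY=VALUE`).
#' @return A validated `world_config`.
#' @examples
#' load_config(system.file("extdata", "example-config.json",
#'                         package = "apeworld"))
#' @export
load_config <- function(path, overrides = list()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- utils::modifyList(as.list(raw), as.list(overrides))
  unknown <- setdiff(names(raw), world_config_fields())
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$treatment)) {
    tr <- raw$treatment
    raw$treatment <- if (is.character(tr)) {
      treatment_params(tr)
    } else {
      do.call(treatment_params, as.list(tr))
    }
  }
  do.call(world_config, raw)
}

#' Fingerprint a configuration
#'
#' A stable short hash of the canonicalised configuration, embedded in every
#' session log so the analysis layer can refuse logs produced under a
#' different configuration than expected.
#'
#' @param config a `world_config`.
#' @return A character scalar.
#' @export
config_fingerprint <- function(config) {
  canon <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = 12)
  bytes <- utf8ToInt(canon)
  h1 <- 5381; h2 <- 52711
  for (b in bytes) {
    h1 <- (h1 * 33 + b) %% 2147483629
    h2 <- (h2 * 31 + b) %% 2147483587
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_deep)
  x
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config> treatment:", x$treatment$name,
      sprintf("(%d fruit/day, grass %.3gx)",
              x$treatment$fruit_per_day, x$treatment$grass_time_multiplier),
      "\n")
  cat(sprintf("  world %d x %d px, window %d x %d px, %d days of %g s\n",
              x$world_width, x$world_height, x$view_width, x$view_height,
              x$n_days, x$day_length))
  cat(sprintf("  %d avatars, %d pirates, walk %.1f px/s, tick %g s\n",
              x$n_avatars, x$n_pirates, x$walk_speed, x$tick_length))
  invisible(x)
}
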