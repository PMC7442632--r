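# ---- event collector ---------------------------------------------------

ev_new <- function(cap = 8192L) {
  e <- new.env(parent = emptyenv())
  e$day <- integer(cap); e$t <- numeric(cap)
  e$type <- character(cap); e$actor <- integer(cap); e$target <- integer(cap)
  e$x <- numeric(cap); e$y <- numeric(cap)
  e$detail <- character(cap); e$value <- numeric(cap)
  e$n <- 0L; e$cap <- cap
  e
}

ev_add <- function(w, type, actor = NA_integer_, target = NA_integer_,
                   x = NA_real_, y = NA_real_,
                   detail = NA_character_, value = NA_real_) {
  e <- w$ev
  n <- e$n + 1L
  if (n > e$cap) {
    e$cap <- e$cap * 2L
    length(e$day) <- e$cap; length(e$t) <- e$cap; length(e$type) <- e$cap
    length(e$actor) <- e$cap; length(e$target) <- e$cap
    length(e$x) <- e$cap; length(e$y) <- e$cap
    length(e$detail) <- e$cap; length(e$value) <- e$cap
  }
  e$day[n] <- w$day; e$t[n] <- w$t; e$type[n] <- type
  e$actor[n] <- actor; e$target[n] <- target
  e$x[n] <- x; e$y[n] <- y; e$detail[n] <- detail; e$value[n] <- value
  e$n <- n
  invisible(NULL)
}

ev_frame <- function(e) {
  i <- seq_len(e$n)
  data.frame(day = e$day[i], t = e$t[i], type = e$type[i],
             actor = e$actor[i], target = e$target[i],
             x = e$x[i], y = e$y[i],
             detail = e$detail[i], value = e$value[i],
             stringsAsFactors = FALSE)
}

# ---- world construction ------------------------------------------------

#' Create a fresh world
#'
#' Builds the mutable world state for a session: tree layout, avatar state
#' vectors, pirate slot, beam and message queues, named RNG substreams and
#' the event collector. [run_session()] drives a full session; tests and
#' scripted scenarios can instead call [world_begin_day()] / [world_step()]
#' and mutate the returned environment directly.
#'
#' @param config a validated [world_config()].
#' @param seed integer master seed for the session.
#' @return An environment of class `ape_world`.
#' @export
new_world <- function(config, seed) {
  validate_config(config)
  w <- new.env(parent = emptyenv())
  w$cfg <- config
  w$seed <- as.integer(seed)
  w$tl <- config$tick_length
  w$tpd <- as.integer(round(config$day_length / config$tick_length))
  w$night_tick <- as.integer(round(config$daylight_length / config$tick_length))
  w$dusk_tick <- as.integer(round(
    (config$daylight_length - config$dusk_length) / config$tick_length))
  w$midday_tick <- as.integer(round(
    (config$daylight_length / 2) / config$tick_length))
  w$predawn_tick <- w$tpd - 1L
  w$hw <- config$view_width / 2
  w$hh <- config$view_height / 2
  w$ir <- config$interaction_range
  w$handle_ticks <- as.integer(round(
    config$treatment$fruit_handle_time / config$tick_length))
  w$groom_ticks <- as.integer(round(config$groom_cooldown / config$tick_length))
  w$grass_unit_time <- config$treatment$grass_time_multiplier *
    config$treatment$fruit_handle_time

  lay <- tree_layout(config)
  w$trees <- lay
  w$tx <- lay$x; w$ty <- lay$y; w$tgrove <- lay$grove
  w$n_trees <- nrow(lay)
  w$fruit <- numeric(w$n_trees)
  w$flowers <- numeric(w$n_trees)
  w$gx <- numeric(config$n_grass_patches)
  w$gy <- numeric(config$n_grass_patches)

  n <- config$n_avatars
  start <- avatar_start_positions(config)
  w$ax <- start[, 1]; w$ay <- start[, 2]
  w$food <- rep(config$initial_food_stock, n)
  w$groom <- rep(config$initial_groom_stock, n)
  w$points <- rep(config$initial_points, n)
  w$nested <- rep(FALSE, n)
  w$gp <- numeric(n)                 # grazing progress, seconds
  w$gpatch <- integer(n)             # patch being grazed, 0 = none
  w$last_groom_tick <- rep(-1e9, n)
  w$last_forage_tick <- rep(-1e9, n)
  w$day_dist <- numeric(n)
  w$total_dist <- numeric(n)

  w$p_status <- "absent"             # absent|scheduled|present|fled|dead|done
  w$p_idx <- 0L; w$p_x <- NA_real_; w$p_y <- NA_real_
  w$p_tree <- NA_integer_; w$p_next_eat <- Inf; w$p_spawn_t <- Inf
  w$p_grove <- NA_character_
  w$kills <- 0L

  w$b_att <- integer(0); w$b_start <- numeric(0); w$b_expiry <- numeric(0)
  w$m_text <- character(0); w$m_x <- numeric(0); w$m_y <- numeric(0)
  w$m_expiry <- numeric(0)
  w$calls_prev <- NULL; w$calls_cur <- NULL

  w$food_seed <- substream_seed(seed, "food")
  w$rng_spawn <- rng_stream(substream_seed(seed, "pirate_spawn"))
  w$rng_eat <- rng_stream(substream_seed(seed, "pirate_eat"))

  w$map_obs <- list(id = lay$tree, x = lay$x, y = lay$y, grove = lay$grove)
  w$world_obs <- list(width = config$world_width, height = config$world_height)

  w$policy_fns <- NULL
  w$policy_blind <- rep(FALSE, n)
  w$policy_needs <- vector("list", n)   # NULL entries = full observation
  w$acting <- NA_integer_
  w$day <- 0L; w$tick <- 0L; w$t <- 0; w$phase <- "daylight"
  w$ev <- ev_new()
  class(w) <- "ape_world"
  w
}

phase_of <- function(w, t) {
  if (t < w$cfg$daylight_length - w$cfg$dusk_length) "daylight"
  else if (t < w$cfg$daylight_length) "dusk"
  else "night"
}

# ---- day boundaries ----------------------------------------------------

#' Start a new day
#'
#' Applies the day's food assignment (fruiting trees, fruit amounts, flower
#' display, fresh grass patches), wakes all avatars, clears beams, messages
#' and calls, and schedules the pirate (grove chosen uniformly, spawn time
#' uniform over full daylight) unless the outgroup has been exhausted.
#'
#' @param w an `ape_world`.
#' @param day 0-based day index.
#' @export
world_begin_day <- function(w, day) {
  cfg <- w$cfg
  w$day <- as.integer(day); w$tick <- 0L; w$t <- 0; w$phase <- "daylight"
  food <- assign_daily_food(cfg, day, w$food_seed)
  w$fruit <- food$fruit_on_tree
  w$flowers <- food$flower_display
  w$gx <- food$grass_xy[, 1]; w$gy <- food$grass_xy[, 2]
  w$nested[] <- FALSE
  w$gp[] <- 0; w$gpatch[] <- 0L
  w$last_groom_tick[] <- -1e9; w$last_forage_tick[] <- -1e9
  w$day_dist[] <- 0
  w$b_att <- integer(0); w$b_start <- numeric(0); w$b_expiry <- numeric(0)
  w$m_text <- character(0); w$m_x <- numeric(0); w$m_y <- numeric(0)
  w$m_expiry <- numeric(0)
  w$calls_prev <- NULL; w$calls_cur <- NULL
  if (w$kills >= cfg$n_pirates) {
    w$p_status <- "done"
  } else {
    w$p_status <- "scheduled"
    w$p_grove <- stream_draw(w$rng_spawn, function() {
      if (runif(1) < 0.5) "north" else "south"
    })
    w$p_spawn_t <- stream_draw(w$rng_spawn, runif, 1, 0,
                               cfg$daylight_length - cfg$dusk_length)
  }
  invisible(w)
}

world_end_day <- function(w) {
  w$t <- w$cfg$day_length - w$tl
  for (i in seq_len(w$cfg$n_avatars)) {
    ev_add(w, "move_summary", actor = i, value = w$day_dist[i])
    ev_add(w, "points_snapshot", actor = i, value = w$points[i])
  }
  w$total_dist <- w$total_dist + w$day_dist
  invisible(w)
}

# ---- observation -------------------------------------------------------

build_obs_light <- function(w, i) {
  list(day = w$day, t = w$t, phase = w$phase,
       self = list(id = i, x = w$ax[i], y = w$ay[i],
                   food = w$food[i], groom = w$groom[i],
                   points = w$points[i], nested = w$nested[i],
                   groom_ready = (w$tick - w$last_groom_tick[i]) >= w$groom_ticks,
                   forage_ready = (w$tick - w$last_forage_tick[i]) >= w$handle_ticks))
}

OBS_COMPONENTS <- c("avatars", "trees", "patches", "pirate", "calls",
                    "messages")

build_obs <- function(w, i, needs = NULL) {
  ax <- w$ax; ay <- w$ay
  x <- ax[i]; y <- ay[i]
  hw <- w$hw; hh <- w$hh
  tick <- w$tick
  all_c <- is.null(needs)

  avatars <- NULL
  if (all_c || needs[1L]) {
    ia <- which(abs(ax - x) <= hw & abs(ay - y) <= hh)
    ia <- ia[ia != i]
    avatars <- list(id = ia, x = ax[ia], y = ay[ia], nested = w$nested[ia])
  }

  trees <- NULL
  if (all_c || needs[2L]) {
    it <- which(abs(w$tx - x) <= hw & abs(w$ty - y) <= hh)
    trees <- list(id = it, x = w$tx[it], y = w$ty[it],
                  grove = w$tgrove[it],
                  fruit = w$fruit[it], flowers = w$flowers[it])
  }

  patches <- NULL
  if (all_c || needs[3L]) {
    ig <- which(abs(w$gx - x) <= hw & abs(w$gy - y) <= hh)
    patches <- list(id = ig, x = w$gx[ig], y = w$gy[ig])
  }

  pirate <- NULL
  if (all_c || needs[4L]) {
    ps <- w$p_status
    if ((ps == "present" || (ps == "dead" && w$phase != "night")) &&
        abs(w$p_x - x) <= hw && abs(w$p_y - y) <= hh) {
      pirate <- list(index = w$p_idx, x = w$p_x, y = w$p_y, status = ps)
    }
  }

  calls <- list()
  if (all_c || needs[5L]) {
    cp <- w$calls_prev
    if (!is.null(cp)) {
      for (k in seq_len(nrow(cp))) {
        dx <- cp[k, 1L] - x; dy <- cp[k, 2L] - y
        d <- sqrt(dx * dx + dy * dy)
        if (d > 0 && d <= w$cfg$call_radius) {
          calls[[length(calls) + 1L]] <- c(dx / d, dy / d)
        }
      }
    }
  }

  messages <- character(0)
  if ((all_c || needs[6L]) && length(w$m_text)) {
    keep <- w$m_expiry > w$t & abs(w$m_x - x) <= hw & abs(w$m_y - y) <= hh
    messages <- w$m_text[keep]
  }

  list(day = w$day, t = w$t, phase = w$phase,
       self = list(id = i, x = x, y = y,
                   food = w$food[i], groom = w$groom[i],
                   points = w$points[i], nested = FALSE,
                   groom_ready = (tick - w$last_groom_tick[i]) >= w$groom_ticks,
                   forage_ready = (tick - w$last_forage_tick[i]) >= w$handle_ticks),
       avatars = avatars,
       trees = trees,
       patches = patches,
       pirate = pirate,
       messages = messages,
       calls = calls,
       map_trees = w$map_obs,
       world = w$world_obs)
}

#' Entities inside an avatar's viewing window
#'
#' Everything the avatar can currently see: other avatars, trees with their
#' fruit/flower state, grass patches, the pirate (a dead pirate remains
#' visible until night) and active broadcast messages, restricted to the
#' `view_width` x `view_height` window centred on the avatar (closed
#' bounds). The map overlay (`map_trees`) lists all tree locations
#' regardless of distance but carries no fruiting state, mirroring the
#' on-screen minimap.
#'
#' @param w an `ape_world`.
#' @param i avatar id.
#' @return A list with elements `avatars`, `trees`, `patches`, `pirate`,
#'   `messages`, `calls`, `map_trees`, `world`, plus the clock and own state.
#' @export
visible_entities <- function(w, i) build_obs(w, i)

# ---- actions -----------------------------------------------------------

#' Move an avatar
#'
#' Advances the avatar `walk_speed * tick_length` pixels along `direction`
#' (normalised internally), clamped to the world rectangle. Grooming units
#' deplete in proportion to the distance actually covered — standing still
#' costs nothing. Any grazing progress is forfeited on moving.
#'
#' @param w an `ape_world`.
#' @param i avatar id.
#' @param direction numeric length-2 vector; the zero vector means stay.
#' @export
world_move <- function(w, i, direction) {
  dx <- direction[1]; dy <- direction[2]
  len <- sqrt(dx * dx + dy * dy)
  if (!is.finite(len) || len == 0) return(invisible(w))
  step <- w$cfg$walk_speed * w$tl / len
  nx <- min(max(w$ax[i] + dx * step, 0), w$cfg$world_width)
  ny <- min(max(w$ay[i] + dy * step, 0), w$cfg$world_height)
  ddx <- nx - w$ax[i]; ddy <- ny - w$ay[i]
  dist <- sqrt(ddx * ddx + ddy * ddy)
  if (dist > 0) {
    w$ax[i] <- nx; w$ay[i] <- ny
    w$groom[i] <- max(w$groom[i] - w$cfg$groom_walk_depletion * dist, 0)
    w$day_dist[i] <- w$day_dist[i] + dist
    w$gp[i] <- 0; w$gpatch[i] <- 0L
  }
  invisible(w)
}

#' Eat one piece of fruit
#'
#' Succeeds if the avatar is within interaction range of the tree, the tree
#' still has fruit, it is not night, and the avatar's handling time has
#' elapsed since its last fruit eaten. The fruit is removed from the tree
#' even if the avatar's food stock is already at the cap (the surplus is
#' wasted; consumption is irreversible).
#'
#' @param w an `ape_world`.
#' @param i avatar id.
#' @param tree tree id.
#' @return `TRUE` if a fruit was eaten, else `FALSE` (no-op).
#' @export
world_forage_fruit <- function(w, i, tree) {
  if (w$phase == "night") return(FALSE)
  if (is.na(tree) || tree < 1 || tree > w$n_trees) return(FALSE)
  if (w$fruit[tree] < 1) return(FALSE)
  dx <- w$tx[tree] - w$ax[i]; dy <- w$ty[tree] - w$ay[i]
  if (dx * dx + dy * dy > w$ir^2) return(FALSE)
  if ((w$tick - w$last_forage_tick[i]) < w$handle_ticks) return(FALSE)
  w$fruit[tree] <- w$fruit[tree] - 1
  w$food[i] <- min(w$food[i] + 1, w$cfg$stock_cap)
  w$last_forage_tick[i] <- w$tick
  ev_add(w, "forage_fruit", actor = i, target = tree,
         x = w$ax[i], y = w$ay[i], value = w$fruit[tree])
  TRUE
}

#' Graze a grass patch for one tick
#'
#' Grazing accumulates continuously; each time accumulated grazing reaches
#' `grass_time_multiplier * fruit_handle_time` seconds, one food unit is
#' gained (capped) and a `forage_grass_unit` event is emitted. Patches never
#' deplete within a day and any number of avatars may graze one patch
#' simultaneously at full rate. Progress is forfeited on moving or switching
#' patches; partial units are never banked across interruptions of place.
#'
#' @param w an `ape_world`.
#' @param i avatar id.
#' @param patch grass patch id.
#' @export
world_graze <- function(w, i, patch) {
  if (w$phase == "night") return(invisible(w))
  if (is.na(patch) || patch < 1 || patch > w$cfg$n_grass_patches) {
    return(invisible(w))
  }
  dx <- w$gx[patch] - w$ax[i]; dy <- w$gy[patch] - w$ay[i]
  if (dx * dx + dy * dy > w$ir^2) return(invisible(w))
  if (w$gpatch[i] != patch) {
    w$gpatch[i] <- as.integer(patch); w$gp[i] <- 0
  }
  w$gp[i] <- w$gp[i] + w$tl
  if (w$gp[i] >= w$grass_unit_time - 1e-9) {
    w$gp[i] <- w$gp[i] - w$grass_unit_time
    w$food[i] <- min(w$food[i] + 1, w$cfg$stock_cap)
    ev_add(w, "forage_grass_unit", actor = i, target = patch,
           x = w$ax[i], y = w$ay[i])
  }
  invisible(w)
}

#' Groom another avatar
#'
#' Raises the target's grooming stock by one unit (capped at the stock cap;
#' the event is still recorded at the cap). Self-grooming is rejected, as is
#' grooming again before the 4-s cooldown has elapsed or outside interaction
#' range.
#'
#' @param w an `ape_world`.
#' @param i actor avatar id.
#' @param target recipient avatar id.
#' @return `TRUE` if the groom happened, else `FALSE`.
#' @export
world_groom <- function(w, i, target) {
  if (w$phase == "night") return(FALSE)
  if (is.na(target) || target == i || target < 1 ||
      target > w$cfg$n_avatars) return(FALSE)
  if ((w$tick - w$last_groom_tick[i]) < w$groom_ticks) return(FALSE)
  dx <- w$ax[target] - w$ax[i]; dy <- w$ay[target] - w$ay[i]
  if (dx * dx + dy * dy > w$ir^2) return(FALSE)
  w$groom[target] <- min(w$groom[target] + 1, w$cfg$stock_cap)
  w$last_groom_tick[i] <- w$tick
  ev_add(w, "groom", actor = i, target = as.integer(target),
         x = w$ax[i], y = w$ay[i])
  TRUE
}

#' Call out
#'
#' Appends a call event; on the next tick every avatar within `call_radius`
#' pixels observes the unit bearing towards the caller — nothing else (no
#' identity, no content).
#'
#' @param w an `ape_world`.
#' @param i caller avatar id.
#' @export
world_call <- function(w, i) {
  ev_add(w, "call", actor = i, x = w$ax[i], y = w$ay[i])
  w$calls_cur <- rbind(w$calls_cur, c(w$ax[i], w$ay[i]))
  invisible(w)
}

#' Nest for the night
#'
#' Only possible at night (the last 15 s of the day); the avatar then stays
#' nested, stationary, until dawn, accruing `nest_rate` points per second.
#' The recorded nest position feeds the nesting-proximity statistic.
#'
#' @param w an `ape_world`.
#' @param i avatar id.
#' @return `TRUE` if the avatar nested, `FALSE` if rejected (not night).
#' @export
world_nest <- function(w, i) {
  if (w$phase != "night" || w$nested[i]) return(FALSE)
  w$nested[i] <- TRUE
  ev_add(w, "nest_start", actor = i, x = w$ax[i], y = w$ay[i])
  TRUE
}

world_digest <- function(w, which_one) {
  amt <- if (which_one == "midday") w$cfg$digest_midday else w$cfg$digest_predawn
  for (i in seq_len(w$cfg$n_avatars)) {
    lost <- min(w$food[i], amt)
    w$food[i] <- w$food[i] - lost
    ev_add(w, "digest", actor = i, detail = which_one, value = lost)
  }
  invisible(w)
}

update_points_tick <- function(w) {
  cfg <- w$cfg
  if (w$phase == "night") {
    # stock-driven accrual is suspended at night: nested avatars earn the
    # nesting rate, night walkers earn (and lose) nothing
    gain <- ifelse(w$nested, cfg$nest_rate, 0)
  } else {
    gain <- cfg$point_gain_rate *
      ((w$food > cfg$high_threshold) + (w$groom > cfg$high_threshold)) -
      cfg$point_loss_rate *
      ((w$food < cfg$low_threshold) + (w$groom < cfg$low_threshold))
  }
  w$points <- pmin(pmax(w$points + gain * w$tl, 0), cfg$point_cap)
  invisible(w)
}

# ---- tick driver -------------------------------------------------------

apply_action <- function(w, i, act) {
  k <- act[["kind"]]
  if (is.null(k)) {
    stop("malformed action (no kind)", call. = FALSE)
  } else if (k == "idle") {
  } else if (k == "move") {
    world_move(w, i, act$direction)
  } else if (k == "graze") {
    world_graze(w, i, act$patch)
  } else if (k == "groom") {
    world_groom(w, i, act$target)
  } else if (k == "forage_fruit") {
    world_forage_fruit(w, i, act$tree)
  } else if (k == "call") {
    world_call(w, i)
  } else if (k == "attack") {
    world_attack(w, i)
  } else if (k == "nest") {
    world_nest(w, i)
  } else {
    stop("malformed action (unknown kind '", k, "')", call. = FALSE)
  }
  invisible(NULL)
}

#' Advance the world by one tick
#'
#' One `tick_length`-second step: phase update, pirate spawn, policy actions
#' (collected and applied in ascending avatar id — the documented tie-break
#' for contested resources), pirate feeding, attack-beam resolution,
#' digestion at the two daily instants, and point accrual. Worlds without
#' policies (scripted scenarios) simply skip the action stage.
#'
#' @param w an `ape_world`.
#' @export
world_step <- function(w) {
  tick <- w$tick
  t <- tick * w$tl
  w$t <- t
  w$phase <- phase_of(w, t)
  if (tick == w$night_tick) on_nightfall(w)
  if (w$p_status == "scheduled" && t >= w$p_spawn_t && w$phase != "night") {
    world_spawn_pirate(w)
  }
  fns <- w$policy_fns
  if (!is.null(fns)) {
    nested <- w$nested
    blind <- w$policy_blind
    needs <- w$policy_needs
    for (i in seq_len(w$cfg$n_avatars)) {
      if (nested[i]) next
      w$acting <- i   # for error context in run_session
      obs <- if (blind[i]) build_obs_light(w, i)
             else build_obs(w, i, needs[[i]])
      apply_action(w, i, fns[[i]](obs))
    }
  }
  if (w$p_status == "present") pirate_eat_tick(w)
  if (length(w$b_att)) resolve_beams_tick(w)
  if (tick == w$midday_tick) world_digest(w, "midday")
  if (tick == w$predawn_tick) world_digest(w, "predawn")
  update_points_tick(w)
  w$calls_prev <- w$calls_cur   # calls become audible on the next tick
  w$calls_cur <- NULL
  w$tick <- tick + 1L
  invisible(w)
}

# ---- session driver ----------------------------------------------------

#' Run a full session
#'
#' Simulates `n_days` 90-second days of the virtual world under the supplied
#' per-avatar policies and master seed, and returns the complete typed event
#' log. Identical `(config, policies, seed)` reproduce the log exactly: all
#' environment randomness flows through named substreams of the master seed,
#' and policies draw only from their own substreams.
#'
#' @param config a validated [world_config()].
#' @param policies a list of `n_avatars` [new_policy()] objects (or a
#'   profile name accepted by [assign_policies()]).
#' @param seed integer master seed.
#' @return A list of class `session_log` with elements `config`,
#'   `fingerprint`, `seed`, `events` (data frame: `day`, `t`, `type`,
#'   `actor`, `target`, `x`, `y`, `detail`, `value`) and `final_points`.
#' @examples
#' cfg <- make_treatment_config("bonobo", n_days = 2)
#' log <- run_session(cfg, rep(list(policy_stationary()), 12), seed = 1)
#' table(log$events$type)
#' @export
run_session <- function(config, policies, seed) {
  validate_config(config)
  if (is.character(policies)) policies <- assign_policies(policies, config)
  if (length(policies) != config$n_avatars) {
    stop("exactly ", config$n_avatars, " policies required, got ",
         length(policies), call. = FALSE)
  }
  w <- new_world(config, seed)
  w$policy_fns <- vector("list", config$n_avatars)
  for (i in seq_along(policies)) {
    p <- policies[[i]]
    if (!inherits(p, "ape_policy")) {
      stop("policies[[", i, "]] is not an ape_policy", call. = FALSE)
    }
    ps <- rng_stream(substream_seed(seed, paste0("policy_", i, "_", p$name)))
    w$policy_fns[[i]] <- p$make(i, config, ps)
    w$policy_blind[i] <- isTRUE(p$blind)
    if (!is.null(p$needs)) {
      w$policy_needs[[i]] <- OBS_COMPONENTS %in% p$needs
    }
  }
  tryCatch(
    for (day in 0:(config$n_days - 1L)) {
      world_begin_day(w, day)
      for (k in seq_len(w$tpd)) world_step(w)
      world_end_day(w)
    },
    error = function(e) {
      stop("session aborted (avatar ", w$acting, ", day ", w$day,
           ", t = ", w$t, " s): ", conditionMessage(e), call. = FALSE)
    })
  structure(
    list(config = config,
         fingerprint = config_fingerprint(config),
         seed = as.integer(seed),
         events = ev_frame(w$ev),
         final_points = w$points),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat("<session_log>", x$config$treatment$name, "treatment,",
      x$config$n_days, "days, seed", x$seed, "\n")
  cat(" ", nrow(x$events), "events; final points:",
      paste(round(x$final_points, 1), collapse = " "), "\n")
  invisible(x)
}

#' Inter-grove traversal time
#'
#' Seconds needed to walk from the southernmost tree of the northern grove
#' to the northernmost tree of the southern grove at the configured walking
#' speed. Under the default layout and the calibrated default speed this is
#' 20 s — about 22% of the 90-s day — which is the single constraint the
#' world's geometry places on avatar speed.
#'
#' @param config a `world_config`.
#' @return Seconds (numeric scalar).
#' @examples
#' traversal_time(make_treatment_config("chimpanzee"))  # 20
#' @export
traversal_time <- function(config) {
  inter_grove_distance(tree_layout(config)) / config$walk_speed
}
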