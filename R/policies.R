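# Pluggable agent policies. A policy is a pure function of its observation
# and its own RNG substream; the engine enforces information parity by
# passing only the observation an on-screen player would have (viewing
# window, minimap tree locations, call bearings, broadcast messages).

#' Define an agent policy
#'
#' @param name short policy name (also used to derive its RNG substream).
#' @param make a factory `function(id, config, rng)` returning the per-session
#'   decision function `function(obs) action`, where `obs` is the observation
#'   described in [visible_entities()] and the action is one of
#'   `list(kind = "move", direction = c(dx, dy))`,
#'   `list(kind = "forage_fruit", tree = id)`,
#'   `list(kind = "graze", patch = id)`,
#'   `list(kind = "groom", target = id)`,
#'   `list(kind = "call")`, `list(kind = "attack")`,
#'   `list(kind = "nest")` or `list(kind = "idle")`.
#' @param params named list of policy parameters (documentation only).
#' @param blind if `TRUE` the policy only receives the clock and its own
#'   state, letting the engine skip visibility computation (used by
#'   policies that never look around).
#' @param needs which observation components the policy reads, a subset of
#'   `c("avatars", "trees", "patches", "pirate", "calls", "messages")`;
#'   `NULL` (default) delivers everything. Declaring needs only narrows the
#'   observation — it never adds information — so it is a performance hint,
#'   not a capability.
#' @return An object of class `ape_policy`.
#' @export
new_policy <- function(name, make, params = list(), blind = FALSE,
                       needs = NULL) {
  if (!is.null(needs)) {
    bad <- setdiff(needs, OBS_COMPONENTS)
    if (length(bad)) {
      stop("unknown observation component(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, make = make, params = params, blind = blind,
                 needs = needs),
            class = "ape_policy")
}

#' @export
print.ape_policy <- function(x, ...) {
  cat("<ape_policy>", x$name, "\n")
  invisible(x)
}

act_idle <- list(kind = "idle")
act_move <- function(dx, dy) list(kind = "move", direction = c(dx, dy))
act_move_to <- function(s, tx, ty) act_move(tx - s$x, ty - s$y)

# groom the nearest visible avatar if the cooldown allows and one is in
# range; NULL otherwise
try_groom <- function(obs, ir) {
  if (!obs$self$groom_ready || !length(obs$avatars$id)) return(NULL)
  d2 <- (obs$avatars$x - obs$self$x)^2 + (obs$avatars$y - obs$self$y)^2
  j <- which.min(d2)
  if (d2[j] <= ir^2) list(kind = "groom", target = obs$avatars$id[j]) else NULL
}

#' Baseline policies
#'
#' Scripted policies acting as the synthetic stand-in for human players.
#' They are demonstrative foraging/social heuristics, not models of human
#' cognition; their parameters are documented constants.
#'
#' * `policy_stationary()` never moves or acts (useful for clock/digestion
#'   checks).
#' * `policy_random_walk()` wanders with occasional random turns, grazes or
#'   eats whatever it stumbles into, grooms neighbours, and nests at night
#'   with probability `p_nest` per tick; exercises the engine under
#'   unstructured behaviour.
#' * `policy_grazer_groomer()` is the herd-following grazer: it stays within
#'   `herd_radius` px of the (slightly personally offset) centroid of
#'   visible group-mates, feeds as a unit on the grass patch nearest the
#'   group centroid, grooms whoever is in reach, calls periodically and
#'   homes in on heard calls when alone, searches along a shared
#'   slowly-rotating per-day sweep heading when there is nothing better to
#'   do (so whole clusters travel coherently and eventually meet), and
#'   nests in place — i.e. near the group — at nightfall. It never attacks.
#' * `policy_greedy_frugivore()` works one grove: it patrols the grove's
#'   trees, remembers yesterday's flower display to predict today's
#'   fruiting trees, eats fruit until satiated, grooms co-foragers, rallies
#'   to the grove's band centre at dusk and nests there; if `do_attack` it
#'   joins coalitionary attacks on a visible pirate, attacking only when at
#'   least `min_allies` other avatars are also within interaction range of
#'   the pirate (so attacks land simultaneously and in force).
#' * `policy_pirate_hunter()` guards its grove: a morning scan of the
#'   grove's trees locates the day's largest fruit-bearing tree — exactly
#'   where a pirate can appear — and the hunter then camps there, eating
#'   fruit and grooming its co-sentries (so its points grow and attacks
#'   stay affordable), recruiting by calling when it has the pirate in
#'   view, following heard calls, and using the same coalition-attack rule.
#'
#' @param home_grove `"north"` or `"south"`.
#' @param do_attack join coalition attacks on the pirate?
#' @param min_allies minimum number of other avatars that must be within
#'   interaction range of the pirate before this avatar attacks.
#' @param herd_radius cohesion distance to the visible-group centroid, px.
#' @param hunger_threshold food stock below which feeding/searching takes
#'   priority over socialising.
#' @param call_period minimum seconds between own calls.
#' @param p_turn,p_nest random-walk turn probability per tick and nesting
#'   probability per night tick.
#' @return An `ape_policy`.
#' @name baseline_policies
NULL

#' @rdname baseline_policies
#' @export
policy_stationary <- function() {
  new_policy("stationary", blind = TRUE,
             make = function(id, config, rng) function(obs) act_idle)
}

#' @rdname baseline_policies
#' @export
policy_random_walk <- function(p_turn = 0.03, p_nest = 0.05) {
  new_policy("random_walk", params = list(p_turn = p_turn, p_nest = p_nest),
    needs = c("avatars", "trees", "patches"),
    make = function(id, config, rng) {
      st <- new.env(parent = emptyenv())
      st$dir <- stream_draw(rng, function() {
        a <- runif(1, 0, 2 * pi); c(cos(a), sin(a))
      })
      ir <- config$interaction_range
      function(obs) {
        if (obs$phase == "night") {
          if (stream_draw(rng, runif, 1) < p_nest) return(list(kind = "nest"))
          return(act_idle)
        }
        g <- try_groom(obs, ir)
        if (!is.null(g)) return(g)
        if (length(obs$trees$id) && obs$self$forage_ready) {
          d2 <- (obs$trees$x - obs$self$x)^2 + (obs$trees$y - obs$self$y)^2
          j <- which.min(d2)
          if (d2[j] <= ir^2 && obs$trees$fruit[j] > 0) {
            return(list(kind = "forage_fruit", tree = obs$trees$id[j]))
          }
        }
        if (length(obs$patches$id)) {
          d2 <- (obs$patches$x - obs$self$x)^2 + (obs$patches$y - obs$self$y)^2
          j <- which.min(d2)
          if (d2[j] <= ir^2 && stream_draw(rng, runif, 1) < 0.5) {
            return(list(kind = "graze", patch = obs$patches$id[j]))
          }
        }
        if (stream_draw(rng, runif, 1) < p_turn) {
          st$dir <- stream_draw(rng, function() {
            a <- runif(1, 0, 2 * pi); c(cos(a), sin(a))
          })
        }
        act_move(st$dir[1], st$dir[2])
      }
    })
}

#' @rdname baseline_policies
#' @export
policy_grazer_groomer <- function(herd_radius = 400, call_period = 20,
                                  hunger_threshold = 8) {
  new_policy("grazer_groomer",
    params = list(herd_radius = herd_radius, call_period = call_period,
                  hunger_threshold = hunger_threshold),
    needs = c("avatars", "patches", "calls"),
    make = function(id, config, rng) {
      st <- new.env(parent = emptyenv())
      st$last_call <- -Inf
      st$jit <- stream_draw(rng, runif, 1, -0.35, 0.35)
      # personal offset from shared targets keeps herd members spread out
      # instead of stacking on one pixel (stays within interaction range)
      st$off <- stream_draw(rng, function() {
        r <- runif(1, 15, 50); a <- runif(1, 0, 2 * pi)
        c(r * cos(a), r * sin(a))
      })
      ir <- config$interaction_range
      # every grazer computes the same slowly rotating per-day heading, so a
      # whole cluster sweeps the world coherently instead of dissolving;
      # steering turns inward near the world edge
      sweep <- function(obs, jitter) {
        a <- 2 * pi * ((0.381966 * (obs$day + 1)) %% 1) +
          (obs$t / config$daylight_length) * pi / 2 + jitter
        dx <- cos(a); dy <- sin(a)
        s <- obs$self
        if (s$x < 500) dx <- abs(dx)
        else if (s$x > config$world_width - 500) dx <- -abs(dx)
        if (s$y < 500) dy <- abs(dy)
        else if (s$y > config$world_height - 500) dy <- -abs(dy)
        act_move(dx, dy)
      }
      function(obs) {
        if (obs$phase == "night") return(list(kind = "nest"))
        s <- obs$self
        g <- try_groom(obs, ir)
        if (!is.null(g)) return(g)
        nvis <- length(obs$avatars$id)
        if (nvis > 0L) {
          cx <- sum(obs$avatars$x) / nvis; cy <- sum(obs$avatars$y) / nvis
          dc <- sqrt((cx + st$off[1] - s$x)^2 + (cy + st$off[2] - s$y)^2)
          if (dc > herd_radius) {
            return(act_move_to(s, cx + st$off[1], cy + st$off[2]))
          }
          if (s$food < config$stock_cap && length(obs$patches$id)) {
            # the whole group heads for the patch nearest the group's
            # centroid, so feeding moves the herd rather than splitting it
            d2c <- (obs$patches$x - cx)^2 + (obs$patches$y - cy)^2
            j <- which.min(d2c)
            dme <- (obs$patches$x[j] - s$x)^2 + (obs$patches$y[j] - s$y)^2
            if (dme <= ir^2) {
              return(list(kind = "graze", patch = obs$patches$id[j]))
            }
            return(act_move_to(s, obs$patches$x[j] + st$off[1],
                               obs$patches$y[j] + st$off[2]))
          }
          if (s$food < hunger_threshold) return(sweep(obs, 0))
          if (obs$t - st$last_call >= call_period) {
            st$last_call <- obs$t
            return(list(kind = "call"))
          }
          return(act_idle)
        }
        # alone: join whoever can be heard, else feed, advertise, search
        if (length(obs$calls)) {
          b <- Reduce(`+`, obs$calls)
          if (sqrt(sum(b^2)) > 0) return(act_move(b[1], b[2]))
        }
        if (s$food < config$stock_cap && length(obs$patches$id)) {
          d2 <- (obs$patches$x - s$x)^2 + (obs$patches$y - s$y)^2
          j <- which.min(d2)
          if (d2[j] <= ir^2) {
            return(list(kind = "graze", patch = obs$patches$id[j]))
          }
          if (s$food < hunger_threshold) {
            return(act_move_to(s, obs$patches$x[j], obs$patches$y[j]))
          }
        }
        if (obs$t - st$last_call >= call_period) {
          st$last_call <- obs$t
          return(list(kind = "call"))
        }
        sweep(obs, st$jit)
      }
    })
}

# shared coalition-attack engagement; returns an action or NULL when there is
# no pirate to engage. Attacks only land when >= min_allies other avatars
# are simultaneously within interaction range of the pirate, so beams form
# in force (a lone beam is a pure 10-point loss).
engage_pirate <- function(obs, st, config, min_allies) {
  p <- obs$pirate
  if (is.null(p) || p$status != "present") return(NULL)
  s <- obs$self
  if (s$points < config$attack_cost) return(NULL)
  ir <- config$interaction_range
  d <- sqrt((p$x - s$x)^2 + (p$y - s$y)^2)
  if (d > ir * 0.8) return(act_move_to(s, p$x, p$y))
  allies <- sum((obs$avatars$x - p$x)^2 + (obs$avatars$y - p$y)^2 <= ir^2)
  # attacks are launched only on whole-second ticks: every coalition member
  # that sees enough allies commits in the same tick, so beams land
  # simultaneously instead of trickling in (which would trigger the
  # two-attacker flee before the third beam exists)
  sync <- abs(obs$t - round(obs$t)) < 1e-9
  if (allies >= min_allies && sync && obs$t >= st$beam_until) {
    st$beam_until <- obs$t + config$attack_window + 0.5
    return(list(kind = "attack"))
  }
  act_idle   # hold position until the coalition is big enough
}

# grove geography shared by the frugivore-type policies
grove_info <- function(config, home_grove) {
  lay <- tree_layout(config)
  mine <- lay[lay$grove == home_grove, ]
  list(ids = mine$tree, x = mine$x, y = mine$y,
       rally = c(mean(mine$x), mine$y[1]))
}

#' @rdname baseline_policies
#' @export
policy_greedy_frugivore <- function(home_grove, do_attack = TRUE,
                                    min_allies = 2) {
  new_policy(paste0("frugivore_", home_grove),
    params = list(home_grove = home_grove, do_attack = do_attack,
                  min_allies = min_allies),
    needs = c("avatars", "trees", "pirate"),
    make = function(id, config, rng) {
      gv <- grove_info(config, home_grove)
      ir <- config$interaction_range
      st <- new.env(parent = emptyenv())
      st$day <- -1L
      st$fruit_known <- rep(NA_real_, 2L * config$n_trees_per_grove)
      st$flowers_seen <- rep(NA_real_, 2L * config$n_trees_per_grove)
      st$patrol <- 1L + (id %% length(gv$ids))
      st$beam_until <- -Inf
      function(obs) {
        s <- obs$self
        if (obs$day != st$day) {
          # yesterday's flower display predicts today's fruit
          st$fruit_known <- st$flowers_seen
          st$flowers_seen <- rep(NA_real_, length(st$flowers_seen))
          st$day <- obs$day
        }
        if (length(obs$trees$id)) {
          st$fruit_known[obs$trees$id] <- obs$trees$fruit
          st$flowers_seen[obs$trees$id] <- obs$trees$flowers
        }
        if (obs$phase == "night") {
          d <- sqrt((gv$rally[1] - s$x)^2 + (gv$rally[2] - s$y)^2)
          if (d > 150) return(act_move_to(s, gv$rally[1], gv$rally[2]))
          return(list(kind = "nest"))
        }
        if (obs$phase == "dusk") {
          return(act_move_to(s, gv$rally[1], gv$rally[2]))
        }
        if (do_attack) {
          a <- engage_pirate(obs, st, config, min_allies)
          if (!is.null(a)) return(a)
        }
        g <- try_groom(obs, ir)
        if (!is.null(g)) return(g)
        if (s$food < config$stock_cap) {
          known <- which(!is.na(st$fruit_known) & st$fruit_known > 0)
          known <- known[known %in% gv$ids]
          if (length(known)) {
            kx <- obs$map_trees$x[known]; ky <- obs$map_trees$y[known]
            j <- which.min((kx - s$x)^2 + (ky - s$y)^2)
            tgt <- known[j]
            d <- sqrt((kx[j] - s$x)^2 + (ky[j] - s$y)^2)
            if (d <= ir) {
              if (s$forage_ready) {
                return(list(kind = "forage_fruit", tree = tgt))
              }
              return(act_idle)
            }
            return(act_move_to(s, kx[j], ky[j]))
          }
          # nothing known to fruit: patrol the grove's trees to scout
          px <- gv$x[st$patrol]; py <- gv$y[st$patrol]
          d <- sqrt((px - s$x)^2 + (py - s$y)^2)
          if (d < 100) {
            st$patrol <- 1L + st$patrol %% length(gv$ids)
            px <- gv$x[st$patrol]; py <- gv$y[st$patrol]
          }
          return(act_move_to(s, px, py))
        }
        act_idle
      }
    })
}

#' @rdname baseline_policies
#' @export
policy_pirate_hunter <- function(home_grove, min_allies = 2,
                                 call_period = 6) {
  new_policy(paste0("hunter_", home_grove),
    params = list(home_grove = home_grove, min_allies = min_allies),
    needs = c("avatars", "trees", "pirate", "calls"),
    make = function(id, config, rng) {
      gv <- grove_info(config, home_grove)
      ir <- config$interaction_range
      st <- new.env(parent = emptyenv())
      st$day <- -1L
      st$fruit_known <- rep(NA_real_, 2L * config$n_trees_per_grove)
      st$patrol <- 1L
      st$beam_until <- -Inf
      st$last_call <- -Inf
      function(obs) {
        s <- obs$self
        if (obs$day != st$day) {
          st$fruit_known <- rep(NA_real_, length(st$fruit_known))
          st$day <- obs$day
          st$patrol <- 1L
        }
        if (length(obs$trees$id)) {
          st$fruit_known[obs$trees$id] <- obs$trees$fruit
        }
        if (obs$phase == "night") return(list(kind = "nest"))
        a <- engage_pirate(obs, st, config, min_allies)
        if (!is.null(a)) {
          # recruit grove-mates while holding the pirate in view
          if (identical(a, act_idle) && obs$t - st$last_call >= call_period) {
            st$last_call <- obs$t
            return(list(kind = "call"))
          }
          return(a)
        }
        if (length(obs$calls)) {
          b <- Reduce(`+`, obs$calls)
          if (sqrt(sum(b^2)) > 0) return(act_move(b[1], b[2]))
        }
        mine <- st$fruit_known[gv$ids]
        if (anyNA(mine)) {
          # morning scan: walk the grove band until every tree is assessed
          while (!is.na(mine[st$patrol]) && st$patrol < length(mine)) {
            st$patrol <- st$patrol + 1L
          }
          return(act_move_to(s, gv$x[st$patrol], gv$y[st$patrol]))
        }
        # camp on the largest fruit-bearing tree: that is where a pirate
        # can appear, and its fruit keeps the sentries fed meanwhile
        camp <- which.max(mine)
        cx <- gv$x[camp]; cy <- gv$y[camp]
        d2 <- (cx - s$x)^2 + (cy - s$y)^2
        if (d2 > (0.7 * ir)^2) return(act_move_to(s, cx, cy))
        g <- try_groom(obs, ir)
        if (!is.null(g)) return(g)
        if (s$food < config$stock_cap && s$forage_ready &&
            mine[camp] > 0) {
          return(list(kind = "forage_fruit", tree = gv$ids[camp]))
        }
        act_idle
      }
    })
}

policy_registry <- function() {
  list(
    stationary = policy_stationary,
    random_walk = policy_random_walk,
    grazer_groomer = policy_grazer_groomer,
    greedy_frugivore = policy_greedy_frugivore,
    pirate_hunter = policy_pirate_hunter
  )
}

#' Build a named policy profile
#'
#' Profiles are whole-group policy assignments used to generate synthetic
#' sessions:
#'
#' * `"split_grove_frugivores"` — half the avatars work the northern grove
#'   and half the southern, with greedy fruit foraging and coalition
#'   attacking (a chimpanzee-like division into two subgroups);
#' * `"herd_grazers"` — all avatars follow the herd, graze, groom and nest
#'   near the group; no avatar ever attacks (bonobo-like cohesion);
#' * `"mixed"` — half split-grove frugivores, half herd grazers;
#' * `"pirate_hunters"` — half the avatars guard each grove and kill every
#'   pirate they can coordinate against (scripted outgroup scenarios).
#'
#' @param profile profile name (above).
#' @param config a `world_config` (determines the number of avatars).
#' @return A list of `n_avatars` policies.
#' @export
assign_policies <- function(profile, config) {
  n <- config$n_avatars
  half <- n %/% 2
  grove_of <- function(i) if (i <= half) "north" else "south"
  switch(profile,
    split_grove_frugivores = lapply(seq_len(n), function(i) {
      policy_greedy_frugivore(grove_of(i))
    }),
    herd_grazers = replicate(n, policy_grazer_groomer(), simplify = FALSE),
    mixed = lapply(seq_len(n), function(i) {
      if (i %% 2 == 0) policy_greedy_frugivore(grove_of(i))
      else policy_grazer_groomer()
    }),
    pirate_hunters = lapply(seq_len(n), function(i) {
      policy_pirate_hunter(grove_of(i))
    }),
    stop("unknown policy profile '", profile, "'; valid profiles: ",
         "split_grove_frugivores, herd_grazers, mixed, pirate_hunters",
         call. = FALSE)
  )
}

#' Load a policy assignment file
#'
#' JSON mapping avatars to named policies with parameters, e.g.
#' `{"avatars": [{"id": 1, "policy": "grazer_groomer",
#' "params": {"herd_radius": 400}}, ...]}`, or simply
#' `{"profile": "herd_grazers"}`.
#'
#' @param path path to the JSON file.
#' @param config a `world_config`.
#' @return A list of `n_avatars` policies.
#' @export
load_policy_assignment <- function(path, config) {
  doc <- jsonlite::read_json(path)
  if (!is.null(doc$profile)) return(assign_policies(doc$profile, config))
  if (is.null(doc$avatars)) {
    stop("policy file must contain 'profile' or 'avatars'", call. = FALSE)
  }
  reg <- policy_registry()
  out <- vector("list", config$n_avatars)
  for (entry in doc$avatars) {
    i <- entry$id
    if (is.null(i) || i < 1 || i > config$n_avatars) {
      stop("policy entry with bad avatar id", call. = FALSE)
    }
    ctor <- reg[[entry$policy]]
    if (is.null(ctor)) {
      stop("unknown policy '", entry$policy, "'", call. = FALSE)
    }
    out[[i]] <- do.call(ctor, if (is.null(entry$params)) list()
                        else entry$params)
  }
  missing <- which(vapply(out, is.null, logical(1)))
  if (length(missing)) {
    stop("no policy assigned to avatar(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' Generate a synthetic fixture session
#'
#' Runs a full session under a named policy profile — the package's
#' synthetic stand-in for human play. `("chimpanzee",
#' "split_grove_frugivores")` yields two grove subgroups with coalitionary
#' pirate attacks; `("bonobo", "herd_grazers")` yields one coalescing herd
#' whose nesting proximity falls over days and which never attacks.
#'
#' @param treatment `"chimpanzee"` or `"bonobo"`.
#' @param policy_profile a profile name accepted by [assign_policies()].
#' @param seed integer master seed.
#' @param ... configuration overrides forwarded to [make_treatment_config()].
#' @return A `session_log`.
#' @export
generate_fixture_session <- function(treatment, policy_profile, seed, ...) {
  config <- make_treatment_config(treatment, ...)
  run_session(config, assign_policies(policy_profile, config), seed)
}

#' Maximum attainable daily food intake (calibration)
#'
#' Simulates a single omniscient greedy agent — full knowledge of fruit and
#' grass locations, eats the fastest available food whenever below the stock
#' cap, wastes nothing — and measures its mean daily intake in steady state
#' (warm-up day excluded). Because the stock cap and the two digestion
#' events bound useful intake at `digest_midday + digest_predawn` units per
#' day, both treatment presets admit the same attainable intake: this is the
#' model's check of the "equal aggregate food" design goal. This helper
#' deliberately bypasses the policy observation interface.
#'
#' @param config a `world_config`.
#' @param n_days days to simulate (>= 2; day 1 is warm-up).
#' @param seed integer seed (grass/tree draws).
#' @return Mean food units ingested per steady-state day.
#' @export
attainable_daily_intake <- function(config, n_days = 4, seed = 1) {
  stopifnot(n_days >= 2)
  cfg <- config
  cfg$n_avatars <- 1L
  cfg$n_pirates <- 0L
  cfg$n_days <- as.integer(n_days)
  cfg <- validate_config(cfg)
  w <- new_world(cfg, seed)
  for (day in 0:(n_days - 1L)) {
    world_begin_day(w, day)
    for (k in seq_len(w$tpd)) {
      w$t <- w$tick * w$tl
      w$phase <- phase_of(w, w$t)
      if (w$tick == w$night_tick) on_nightfall(w)
      if (w$phase != "night" && w$food[1] < cfg$stock_cap) {
        stocked <- which(w$fruit > 0)
        if (length(stocked)) {
          j <- stocked[which.min((w$tx[stocked] - w$ax[1])^2 +
                                   (w$ty[stocked] - w$ay[1])^2)]
          d <- sqrt((w$tx[j] - w$ax[1])^2 + (w$ty[j] - w$ay[1])^2)
          if (d <= w$ir) world_forage_fruit(w, 1, j)
          else world_move(w, 1, c(w$tx[j] - w$ax[1], w$ty[j] - w$ay[1]))
        } else {
          j <- which.min((w$gx - w$ax[1])^2 + (w$gy - w$ay[1])^2)
          d <- sqrt((w$gx[j] - w$ax[1])^2 + (w$gy[j] - w$ay[1])^2)
          if (d <= w$ir) world_graze(w, 1, j)
          else world_move(w, 1, c(w$gx[j] - w$ax[1], w$gy[j] - w$ay[1]))
        }
      }
      if (w$tick == w$midday_tick) world_digest(w, "midday")
      if (w$tick == w$predawn_tick) world_digest(w, "predawn")
      update_points_tick(w)
      w$tick <- w$tick + 1L
    }
  }
  ev <- ev_frame(w$ev)
  eats <- ev[ev$type %in% c("forage_fruit", "forage_grass_unit"), ]
  mean(tabulate(eats$day + 1L, nbins = n_days)[-1L])
}
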