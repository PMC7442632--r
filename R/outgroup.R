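# Outgroup ("pirate") lifecycle: spawn at the richest tree, stochastic fruit
# stealing, and the one/two/three-attacker beam resolution with its exact
# broadcast messages.

MSG_SOLO <- paste0("Pirates will be scared away if 2 avatars attack it ",
                   "simultaneously, and you will incur no damage.")
MSG_PAIR <- paste0("3 simultaneous attackers will kill this pirate, ",
                   "and you will incur no damage.")

# interval to the pirate's next fruit eat; the engine and the calibration
# helper share this sampler
sample_eat_interval <- function(config, stream) {
  m <- config$pirate_eat_mean_interval
  if (config$pirate_eat_law == "fixed") m
  else stream_draw(stream, stats::rexp, 1, rate = 1 / m)
}

#' Spawn the day's pirate
#'
#' Places the pirate at the largest fruit-bearing tree of its grove (chosen
#' uniformly at day start) and starts its feeding clock. The pirate index is
#' `kills + 1`; the first is labelled `"1 of 3 pirates"`. No pirate ever
#' spawns once all `n_pirates` have been killed.
#'
#' Normally called by [world_step()] when the scheduled spawn time arrives;
#' scripted scenarios may call it directly with explicit `grove`/`time`.
#'
#' @param w an `ape_world`.
#' @param grove `"north"` or `"south"`; default the grove drawn at day start.
#' @param time spawn time (seconds into the day); default the scheduled one.
#' @export
world_spawn_pirate <- function(w, grove = NULL, time = NULL) {
  if (w$kills >= w$cfg$n_pirates) {
    w$p_status <- "done"
    return(invisible(w))
  }
  if (!is.null(grove)) w$p_grove <- grove
  if (!is.null(time)) w$p_spawn_t <- time
  ids <- which(w$tgrove == w$p_grove)
  tree <- ids[which.max(w$fruit[ids])]
  w$p_idx <- w$kills + 1L
  w$p_status <- "present"
  w$p_tree <- tree
  w$p_x <- w$tx[tree]; w$p_y <- w$ty[tree]
  w$p_next_eat <- w$t + sample_eat_interval(w$cfg, w$rng_eat)
  ev_add(w, "pirate_spawn", target = w$p_idx, x = w$p_x, y = w$p_y,
         detail = sprintf("%d of %d pirates;%s", w$p_idx,
                          w$cfg$n_pirates, w$p_grove))
  invisible(w)
}

# one tick of pirate feeding: eats one fruit at stochastic intervals with the
# configured mean; never eats grass; idles if its tree has been emptied
pirate_eat_tick <- function(w) {
  if (w$t < w$p_next_eat) return(invisible(w))
  if (w$fruit[w$p_tree] >= 1) {
    w$fruit[w$p_tree] <- w$fruit[w$p_tree] - 1
    ev_add(w, "pirate_eat", target = w$p_idx, x = w$p_x, y = w$p_y,
           value = w$fruit[w$p_tree])
    w$p_next_eat <- w$t + sample_eat_interval(w$cfg, w$rng_eat)
  } else {
    w$p_next_eat <- Inf
  }
  invisible(w)
}

#' Attack the pirate
#'
#' Creates an attack beam linking the avatar to the pirate for the next
#' `attack_window` (10) seconds. The attacker must have at least
#' `attack_cost` (10) points, be within interaction range of a present
#' pirate, and not already have an active beam. Beam outcomes are resolved
#' each tick; see [world_step()].
#'
#' @param w an `ape_world`.
#' @param i attacker avatar id.
#' @return `TRUE` if a beam was created, else `FALSE` (attack rejected).
#' @export
world_attack <- function(w, i) {
  if (w$p_status != "present") return(FALSE)
  if (w$points[i] < w$cfg$attack_cost) return(FALSE)
  dx <- w$p_x - w$ax[i]; dy <- w$p_y - w$ay[i]
  if (dx * dx + dy * dy > w$ir^2) return(FALSE)
  if (i %in% w$b_att) return(FALSE)
  w$b_att <- c(w$b_att, as.integer(i))
  w$b_start <- c(w$b_start, w$t)
  w$b_expiry <- c(w$b_expiry, w$t + w$cfg$attack_window)
  ev_add(w, "attack", actor = i, target = w$p_idx, x = w$p_x, y = w$p_y)
  TRUE
}

post_message <- function(w, text) {
  w$m_text <- c(w$m_text, text)
  w$m_x <- c(w$m_x, w$p_x); w$m_y <- c(w$m_y, w$p_y)
  w$m_expiry <- c(w$m_expiry, w$t + w$cfg$message_display)
  invisible(w)
}

clear_beams <- function(w) {
  w$b_att <- integer(0); w$b_start <- numeric(0); w$b_expiry <- numeric(0)
  invisible(w)
}

# per-tick beam resolution; "simultaneous" means beam windows concurrently
# active. Checked most-lethal-first so a third beam landing the same tick a
# two-beam flee would trigger produces a kill.
resolve_beams_tick <- function(w, force_expire = FALSE) {
  if (!length(w$b_att)) return(invisible(w))
  if (w$p_status != "present") {
    clear_beams(w)
    return(invisible(w))
  }
  nb <- length(w$b_att)
  if (nb >= 3L) {
    ev_add(w, "attack_outcome", target = w$p_idx, x = w$p_x, y = w$p_y,
           detail = "kill", value = nb)
    ev_add(w, "pirate_death", target = w$p_idx, x = w$p_x, y = w$p_y)
    w$p_status <- "dead"          # corpse stays visible until night
    w$kills <- w$kills + 1L
    clear_beams(w)
  } else if (nb == 2L) {
    ev_add(w, "attack_outcome", target = w$p_idx, x = w$p_x, y = w$p_y,
           detail = "flee", value = 2)
    ev_add(w, "pirate_flee", target = w$p_idx, x = w$p_x, y = w$p_y)
    post_message(w, MSG_PAIR)
    w$p_status <- "fled"          # gone for the rest of the day only
    clear_beams(w)
  } else if (w$t >= w$b_expiry[1L] || force_expire) {
    att <- w$b_att[1L]
    w$points[att] <- max(w$points[att] - w$cfg$attack_cost, 0)
    ev_add(w, "attack_outcome", actor = att, target = w$p_idx,
           x = w$p_x, y = w$p_y, detail = "penalty", value = 1)
    post_message(w, MSG_SOLO)
    clear_beams(w)                # the pirate keeps eating
  }
  invisible(w)
}

# nightfall (t = 75 s): a still-pending solo beam resolves as a penalty (its
# window is truncated by the day's end), the live pirate leaves until the
# next day, and a corpse stops being visible
on_nightfall <- function(w) {
  if (length(w$b_att)) resolve_beams_tick(w, force_expire = TRUE)
  if (w$p_status %in% c("present", "scheduled")) w$p_status <- "absent"
  invisible(w)
}

#' Simulate the pirate's feeding process in isolation
#'
#' Draws successive inter-eat intervals from the configured eating law
#' (exponential with mean `pirate_eat_mean_interval` by default) at a
#' notionally always-stocked tree, using the same sampler the engine uses.
#' Intended for calibration checks of the "one fruit every 4 s on average"
#' rule.
#'
#' @param config a `world_config`.
#' @param n_events number of eat events to draw.
#' @param seed integer seed.
#' @return Numeric vector of `n_events` inter-eat intervals (seconds).
#' @examples
#' mean(simulate_pirate_feeding(make_treatment_config("chimpanzee"), 1e4, 1))
#' @export
simulate_pirate_feeding <- function(config, n_events, seed) {
  s <- rng_stream(substream_seed(seed, "pirate_eat"))
  vapply(seq_len(n_events), function(k) sample_eat_interval(config, s),
         numeric(1))
}
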