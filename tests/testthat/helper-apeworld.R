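# shared helpers: small configs, scripted worlds, brute-force oracles, and a
# cache so expensive sessions are simulated once per test run

the_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = the_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = the_cache)
  }
  get(name, envir = the_cache, inherits = FALSE)
}

stationary_policies <- function(n = 12) {
  rep(list(policy_stationary()), n)
}

# a combat sandbox: day 0 begun, pirate spawned at the north grove's largest
# tree at t = 0, the first `n_attackers` avatars placed on the pirate with
# `points` points and neutral stocks
combat_world <- function(n_attackers = 1, points = 50,
                         treatment = "chimpanzee") {
  cfg <- make_treatment_config(treatment, n_days = 2)
  w <- new_world(cfg, seed = 99)
  world_begin_day(w, 0)
  world_spawn_pirate(w, grove = "north", time = 0)
  for (i in seq_len(n_attackers)) {
    w$ax[i] <- w$p_x + 5 * i
    w$ay[i] <- w$p_y
    w$points[i] <- points
  }
  w
}

# independent connected-components oracle: breadth-first reachability over an
# adjacency matrix, no graph library involved
cc_oracle <- function(adj) {
  n <- nrow(adj)
  label <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (label[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    label[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & label == 0L)
      label[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  label
}

window_adjacency <- function(pos, cfg) {
  dx <- abs(outer(pos[, 1], pos[, 1], "-")) <= cfg$view_width
  dy <- abs(outer(pos[, 2], pos[, 2], "-")) <= cfg$view_height
  adj <- dx & dy
  diag(adj) <- FALSE
  adj
}

# hand-built observation for direct policy-contract tests
make_obs <- function(day = 0, t = 10, phase = "daylight",
                     self = list(), avatars = NULL, trees = NULL,
                     patches = NULL, pirate = NULL, calls = list(),
                     messages = character(0),
                     config = make_treatment_config("chimpanzee")) {
  self_def <- list(id = 1L, x = 1000, y = 1000, food = 5, groom = 5,
                   points = 50, nested = FALSE, groom_ready = TRUE,
                   forage_ready = TRUE)
  self_def[names(self)] <- self
  lay <- tree_layout(config)
  empty <- list(id = integer(0), x = numeric(0), y = numeric(0))
  list(day = day, t = t, phase = phase, self = self_def,
       avatars = if (is.null(avatars)) c(empty, list(nested = logical(0)))
                 else avatars,
       trees = if (is.null(trees)) {
         c(empty, list(grove = character(0), fruit = numeric(0),
                       flowers = numeric(0)))
       } else trees,
       patches = if (is.null(patches)) empty else patches,
       pirate = pirate, messages = messages, calls = calls,
       map_trees = list(id = lay$tree, x = lay$x, y = lay$y,
                        grove = lay$grove),
       world = list(width = config$world_width,
                    height = config$world_height))
}

# scripted single-purpose policy from a plain decision function
policy_scripted <- function(fn, blind = FALSE) {
  new_policy("scripted", blind = blind,
             make = function(id, config, rng) fn)
}

# the scripted outgroup-extermination session: pirate hunters guarding both
# groves with enough starting points to afford attacks from day one
hunter_session <- function() {
  cached("hunter_session", {
    cfg <- make_treatment_config("chimpanzee", n_days = 6,
                                 initial_points = 50)
    run_session(cfg, assign_policies("pirate_hunters", cfg), seed = 303)
  })
}

fixture_seeds <- function() 1:5

herd_fixture <- function(seed) {
  cached(paste0("herd_", seed),
         generate_fixture_session("bonobo", "herd_grazers", seed))
}

frugivore_fixture <- function(seed) {
  cached(paste0("frug_", seed),
         generate_fixture_session("chimpanzee", "split_grove_frugivores",
                                  seed))
}
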