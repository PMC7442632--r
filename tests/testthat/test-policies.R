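# policy contract and the scripted baseline policies

instantiate <- function(policy, id = 1L,
                        config = make_treatment_config("chimpanzee")) {
  policy$make(id, config, rng_stream(1))
}

test_that("a frugivore moves to a fruiting tree and eats in range", {
  cfg <- make_treatment_config("chimpanzee")
  fn <- instantiate(policy_greedy_frugivore("north"), config = cfg)
  lay <- tree_layout(cfg)
  tree <- list(id = 1L, x = lay$x[1], y = lay$y[1], grove = "north",
               fruit = 10, flowers = 0)
  far <- make_obs(self = list(x = lay$x[1] + 500, y = lay$y[1], food = 3),
                  trees = tree, config = cfg)
  act <- fn(far)
  expect_equal(act$kind, "move")
  expect_lt(act$direction[1], 0)                  # towards the tree (west)
  near <- make_obs(self = list(x = lay$x[1] + 30, y = lay$y[1], food = 3),
                   trees = tree, config = cfg)
  act <- fn(near)
  expect_equal(act$kind, "forage_fruit")
  expect_equal(act$tree, 1L)
})

test_that("a grazer-groomer grooms a neighbour in reach when sated", {
  cfg <- make_treatment_config("bonobo")
  fn <- instantiate(policy_grazer_groomer(), config = cfg)
  obs <- make_obs(self = list(food = 8, groom_ready = TRUE),
                  avatars = list(id = 4L, x = 1030, y = 1000,
                                 nested = FALSE),
                  config = cfg)
  act <- fn(obs)
  expect_equal(act$kind, "groom")
  expect_equal(act$target, 4L)
  # and nests wherever it stands at night
  expect_equal(fn(make_obs(phase = "night", config = cfg))$kind, "nest")
})

test_that("coalition attackers strike only with enough allies in place", {
  cfg <- make_treatment_config("chimpanzee")
  fn <- instantiate(policy_greedy_frugivore("north"), config = cfg)
  pirate <- list(index = 1L, x = 1040, y = 1000, status = "present")
  two_allies <- list(id = c(2L, 3L), x = c(1060, 1020), y = c(1000, 1000),
                     nested = c(FALSE, FALSE))
  act <- fn(make_obs(t = 10, self = list(points = 50),
                     avatars = two_allies, pirate = pirate, config = cfg))
  expect_equal(act$kind, "attack")
  fn2 <- instantiate(policy_greedy_frugivore("north"), config = cfg)
  one_ally <- list(id = 2L, x = 1060, y = 1000, nested = FALSE)
  act2 <- fn2(make_obs(t = 10, self = list(points = 50),
                       avatars = one_ally, pirate = pirate, config = cfg))
  expect_false(identical(act2$kind, "attack"))    # holds position instead
  # too poor to attack: ignores the pirate entirely
  fn3 <- instantiate(policy_greedy_frugivore("north"), config = cfg)
  act3 <- fn3(make_obs(t = 10, self = list(points = 5),
                       avatars = two_allies, pirate = pirate, config = cfg))
  expect_false(identical(act3$kind, "attack"))
})

test_that("policies receive only the windowed observation surface", {
  # the engine hands policies a fixed observation contract; check the
  # fields and that out-of-window state is absent
  cfg <- make_treatment_config("chimpanzee", n_days = 1)
  w <- new_world(cfg, 3)
  world_begin_day(w, 0)
  o <- visible_entities(w, 1)
  expect_setequal(
    names(o),
    c("day", "t", "phase", "self", "avatars", "trees", "patches",
      "pirate", "messages", "calls", "map_trees", "world"))
  far <- which(sqrt((w$ax - w$ax[1])^2 + (w$ay - w$ay[1])^2) > 2000)
  expect_false(any(far %in% o$avatars$id))
})

test_that("a malformed policy aborts the session naming the avatar", {
  cfg <- make_treatment_config("bonobo", n_days = 1)
  bad <- policy_scripted(function(obs) list(kind = "fly"))
  pols <- c(stationary_policies(11), list(bad))
  expect_error(run_session(cfg, pols, seed = 1), "avatar 12")
  broken <- policy_scripted(function(obs) stop("boom"))
  pols2 <- c(stationary_policies(11), list(broken))
  expect_error(run_session(cfg, pols2, seed = 1), "avatar 12.*boom")
})

test_that("profiles assemble full groups and unknown profiles fail", {
  cfg <- make_treatment_config("chimpanzee")
  pols <- assign_policies("split_grove_frugivores", cfg)
  expect_length(pols, 12)
  groves <- vapply(pols, function(p) p$params$home_grove, character(1))
  expect_equal(sum(groves == "north"), 6)
  expect_equal(sum(groves == "south"), 6)
  expect_error(assign_policies("lone_wolves", cfg), "unknown policy profile")
  expect_error(generate_fixture_session("bonobo", "lone_wolves", 1),
               "unknown policy profile")
})

test_that("policy assignment files map avatars to policies", {
  cfg <- make_treatment_config("bonobo", n_days = 1)
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"profile": "herd_grazers"}', path)
  pols <- load_policy_assignment(path, cfg)
  expect_length(pols, 12)
  expect_true(all(vapply(pols, inherits, logical(1), "ape_policy")))
  entries <- paste0(
    '{"id": ', 1:12, ', "policy": "grazer_groomer", ',
    '"params": {"herd_radius": 350}}', collapse = ",")
  writeLines(paste0('{"avatars": [', entries, ']}'), path)
  pols2 <- load_policy_assignment(path, cfg)
  expect_equal(pols2[[5]]$params$herd_radius, 350)
  writeLines('{"avatars": [{"id": 1, "policy": "grazer_groomer"}]}', path)
  expect_error(load_policy_assignment(path, cfg), "no policy assigned")
  writeLines('{"avatars": [{"id": 1, "policy": "psychic"}]}', path)
  expect_error(load_policy_assignment(path, cfg), "unknown policy")
})

test_that("the omniscient greedy agent attains the digestion-bound intake", {
  ch <- attainable_daily_intake(make_treatment_config("chimpanzee"),
                                n_days = 3)
  cfg <- make_treatment_config("chimpanzee")
  expect_equal(ch, cfg$digest_midday + cfg$digest_predawn)
})
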