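# day clock, movement, foraging, grooming, digestion, points, nesting,
# calling, visibility -- exercised through the exported world operations on
# small scripted worlds

fresh_world <- function(treatment = "chimpanzee", day = 0, ...) {
  cfg <- make_treatment_config(treatment, n_days = 2, ...)
  w <- new_world(cfg, seed = 5)
  world_begin_day(w, day)
  w
}

step_to <- function(w, t) {
  while (w$tick * w$cfg$tick_length < t - 1e-9) world_step(w)
  invisible(w)
}

test_that("a stationary group digests twice daily across all 35 days", {
  log <- cached("stationary35", {
    run_session(make_treatment_config("chimpanzee"),
                stationary_policies(), seed = 1)
  })
  dig <- log$events[log$events$type == "digest", ]
  expect_equal(nrow(dig), 12 * 2 * 35)          # 70 digest events per avatar
  expect_equal(as.vector(table(dig$actor)), rep(70, 12))
  expect_setequal(unique(dig$detail), c("midday", "predawn"))
  # digestion instants: mid-daylight and the last tick of the day
  expect_equal(unique(dig$t[dig$detail == "midday"]), 37.5)
  expect_equal(unique(dig$t[dig$detail == "predawn"]), 89.9)
  expect_equal(max(log$events$day), 34)
})

test_that("identical config, policies and seed reproduce the log exactly", {
  cfg <- make_treatment_config("bonobo", n_days = 2)
  pols <- assign_policies("mixed", cfg)
  a <- run_session(cfg, pols, seed = 17)
  b <- run_session(cfg, assign_policies("mixed", cfg), seed = 17)
  expect_identical(a, b)
  c <- run_session(cfg, assign_policies("mixed", cfg), seed = 18)
  expect_false(identical(a$events, c$events))
})

test_that("movement clamps at bounds and depletes grooming with distance", {
  w <- fresh_world()
  w$ax[1] <- 0; w$ay[1] <- 5000; w$groom[1] <- 5
  world_move(w, 1, c(-1, 0))                    # due west at the west edge
  expect_equal(w$ax[1], 0)
  expect_equal(w$groom[1], 5)                   # no actual movement, no cost
  world_move(w, 1, c(0, 0))                     # standing still is free
  expect_equal(w$groom[1], 5)
  d <- w$cfg$walk_speed * w$cfg$tick_length
  world_move(w, 1, c(1, 0))
  expect_equal(w$ax[1], d)
  expect_equal(w$groom[1], 5 - w$cfg$groom_walk_depletion * d)
  # walking the inter-grove path costs depletion proportional to its length
  w$groom[2] <- 10; w$ax[2] <- 1120; w$ay[2] <- 1575
  total <- 0
  while (w$ay[2] < 8925 - 1) {
    y0 <- w$ay[2]
    world_move(w, 2, c(0, 1))
    total <- total + (w$ay[2] - y0)
  }
  expect_equal(w$groom[2],
               max(10 - w$cfg$groom_walk_depletion * total, 0))
})

test_that("fruit foraging respects range, supply, cap and handling time", {
  w <- fresh_world()
  tree <- which(w$fruit > 0)[1]
  w$ax[1] <- w$tx[tree]; w$ay[1] <- w$ty[tree]
  n0 <- w$fruit[tree]
  w$food[1] <- 10                               # already at the cap
  expect_true(world_forage_fruit(w, 1, tree))
  expect_equal(w$food[1], 10)                   # surplus wasted...
  expect_equal(w$fruit[tree], n0 - 1)           # ...but the fruit is gone
  # handling time: an immediate second bite is refused
  expect_false(world_forage_fruit(w, 1, tree))
  for (k in 1:10) world_step(w)                 # 1 s = fruit_handle_time
  expect_true(world_forage_fruit(w, 1, tree))
  # empty tree is a no-op
  empty <- which(w$fruit == 0)[1]
  w$ax[2] <- w$tx[empty]; w$ay[2] <- w$ty[empty]
  expect_false(world_forage_fruit(w, 2, empty))
  # out of range is a no-op
  w$ax[3] <- w$tx[tree] + 100; w$ay[3] <- w$ty[tree]
  expect_false(world_forage_fruit(w, 3, tree))
  ev <- w$ev
  expect_equal(sum(ev$type[seq_len(ev$n)] == "forage_fruit"), 2)
})

test_that("contested last fruit goes to exactly one avatar", {
  w <- fresh_world()
  tree <- which(w$fruit > 0)[1]
  w$fruit[tree] <- 1
  for (i in 1:12) { w$ax[i] <- w$tx[tree]; w$ay[i] <- w$ty[tree] }
  got <- vapply(1:12, function(i) world_forage_fruit(w, i, tree), logical(1))
  expect_equal(sum(got), 1)
  expect_true(got[1])                            # ascending-id tie-break
})

test_that("grazing takes the treatment's full grazing time per unit", {
  for (case in list(list("chimpanzee", 10), list("bonobo", 3.33))) {
    w <- fresh_world(case[[1]])
    w$ax[1] <- w$gx[1]; w$ay[1] <- w$gy[1]
    w$ax[2] <- w$gx[1]; w$ay[2] <- w$gy[1]      # same patch, same time
    w$food[1] <- 0; w$food[2] <- 0
    need_ticks <- ceiling(case[[2]] * 1.0 / 0.1)
    for (k in seq_len(need_ticks - 1)) {
      world_graze(w, 1, 1); world_graze(w, 2, 1)
      world_step(w)
    }
    expect_equal(w$food[1], 0)                  # one tick short of a unit
    world_graze(w, 1, 1); world_graze(w, 2, 1)
    expect_equal(w$food[1], 1)                  # both graze at full rate
    expect_equal(w$food[2], 1)
  }
})

test_that("grazing progress is forfeited on moving away", {
  w <- fresh_world("bonobo")
  w$ax[1] <- w$gx[1]; w$ay[1] <- w$gy[1]; w$food[1] <- 0
  for (k in 1:20) { world_graze(w, 1, 1); world_step(w) }  # 2 s of 3.33
  world_move(w, 1, c(1, 0))                      # step off the spot
  expect_equal(w$gp[1], 0)
  w$ax[1] <- w$gx[1]                             # come straight back
  for (k in 1:20) { world_graze(w, 1, 1); world_step(w) }
  expect_equal(w$food[1], 0)                     # partial units not banked
})

test_that("grooming obeys cooldown, bans self-grooming, caps the stock", {
  w <- fresh_world()
  w$ax[1] <- 1000; w$ay[1] <- 1000
  w$ax[2] <- 1020; w$ay[2] <- 1000
  expect_false(world_groom(w, 1, 1))             # self-grooming rejected
  g0 <- w$groom[2]
  expect_true(world_groom(w, 1, 2))
  expect_equal(w$groom[2], g0 + 1)
  for (k in 1:20) world_step(w)                  # 2 s < 4 s cooldown
  expect_false(world_groom(w, 1, 2))
  for (k in 1:20) world_step(w)                  # now 4 s since the groom
  expect_true(world_groom(w, 1, 2))
  w$groom[2] <- 10
  w$last_groom_tick[1] <- -1e9
  expect_true(world_groom(w, 1, 2))              # event recorded at the cap
  expect_equal(w$groom[2], 10)
})

test_that("digestion floors at zero stock", {
  w <- fresh_world()
  w$food <- c(10, 3, 0, rep(5, 9))
  world_digest(w, "midday")
  expect_equal(w$food[1:3], c(6, 0, 0))
  w$food <- c(10, 3, 0, rep(5, 9))
  world_digest(w, "predawn")
  expect_equal(w$food[1:3], c(3, 0, 0))
  ev <- w$ev
  i <- seq_len(ev$n)
  lost <- ev$value[i][ev$type[i] == "digest" & ev$detail[i] == "predawn"]
  expect_equal(lost[1:3], c(7, 3, 0))            # "whatever stock they had"
})

test_that("points accrue by stock thresholds by day and nesting by night", {
  w <- fresh_world()
  cfg <- w$cfg
  # both stocks neutral: no change
  w$food[] <- 5; w$groom[] <- 5; w$points[] <- 50
  world_step(w)
  expect_equal(w$points[1], 50)
  # exactly at the thresholds: still no change (inclusive band)
  w$food[1] <- 4; w$groom[1] <- 7
  world_step(w)
  expect_equal(w$points[1], 50)
  # both stocks high: +2 * gain_rate per second; both low: -2 * loss_rate
  w$food[1] <- 10; w$groom[1] <- 8
  w$food[2] <- 2; w$groom[2] <- 0
  world_step(w)
  expect_equal(w$points[1], 50 + 2 * cfg$point_gain_rate * 0.1)
  expect_equal(w$points[2], 50 - 2 * cfg$point_loss_rate * 0.1)
  # cap and floor
  w$points[1] <- cfg$point_cap
  world_step(w)
  expect_equal(w$points[1], cfg$point_cap)
})

test_that("a nested avatar earns exactly nest_rate over the night", {
  w <- fresh_world()
  w$food[] <- 10; w$groom[] <- 10                 # stocks do not matter at night
  step_to(w, 75)                                  # ticks before nightfall done
  w$t <- 75; w$phase <- "night"                   # first night tick, pre-action
  expect_true(world_nest(w, 1))
  w$points[1] <- 50; w$points[2] <- 50
  while (w$tick < w$tpd) world_step(w)
  expect_equal(w$points[1], 50 + 0.3 * 15)        # 4.5 points per night
  expect_equal(w$points[2], 50)                   # night walkers earn nothing
})

test_that("nesting is rejected during daylight and dusk", {
  w <- fresh_world()
  step_to(w, 60)
  expect_false(world_nest(w, 1))
  step_to(w, 72)
  expect_equal(w$phase, "dusk")
  expect_false(world_nest(w, 1))
  step_to(w, 76)
  expect_true(world_nest(w, 1))
  ev <- w$ev; i <- seq_len(ev$n)
  ns <- which(ev$type[i] == "nest_start")
  expect_length(ns, 1)
  expect_equal(ev$x[ns], w$ax[1])
})

test_that("night locks out foraging and grooming", {
  w <- fresh_world()
  tree <- which(w$fruit > 0)[1]
  w$ax[1] <- w$tx[tree]; w$ay[1] <- w$ty[tree]
  w$ax[2] <- w$tx[tree]; w$ay[2] <- w$ty[tree]
  step_to(w, 80)
  expect_false(world_forage_fruit(w, 1, tree))
  expect_false(world_groom(w, 1, 2))
  f0 <- w$food[1]
  world_graze(w, 1, 1)
  expect_equal(w$food[1], f0)
})

test_that("calls deliver only a bearing, only within the call radius", {
  w <- fresh_world()
  w$ax[1] <- 3000; w$ay[1] <- 5000                # caller
  w$ax[2] <- 3000; w$ay[2] <- 7100                # 2100 px: hears
  w$ax[3] <- 3000; w$ay[3] <- 7300                # 2300 px: does not
  world_call(w, 1)
  world_step(w)                                   # delivery is next tick
  o2 <- visible_entities(w, 2)
  o3 <- visible_entities(w, 3)
  expect_length(o2$calls, 1)
  expect_equal(o2$calls[[1]], c(0, -1))           # caller due north
  expect_length(o3$calls, 0)
})

test_that("the viewing window is closed at its edges and map shows all trees", {
  w <- fresh_world()
  w$ax[1] <- 3000; w$ay[1] <- 5000
  w$ax[2] <- 3000 + 792; w$ay[2] <- 5000          # exactly the half-width
  w$ax[3] <- 3000 + 800; w$ay[3] <- 5000          # just beyond
  o <- visible_entities(w, 1)
  expect_true(2 %in% o$avatars$id)
  expect_false(3 %in% o$avatars$id)
  expect_equal(length(o$map_trees$id), 10)        # all trees, everywhere
  expect_null(o$map_trees$fruit)                  # ...but no fruiting state
})

test_that("stocks, points and positions stay in bounds under random play", {
  cfg <- make_treatment_config("bonobo", n_days = 1)
  for (seed in 1:3) {
    w <- new_world(cfg, seed)
    pols <- replicate(12, policy_random_walk(), simplify = FALSE)
    for (i in 1:12) {
      w$policy_fns[[i]] <- pols[[i]]$make(
        i, cfg, rng_stream(substream_seed(seed, paste0("p", i))))
    }
    world_begin_day(w, 0)
    for (k in seq_len(w$tpd)) {
      world_step(w)
      if (k %% 90 == 0) {
        expect_true(all(w$food >= 0 & w$food <= 10))
        expect_true(all(w$groom >= 0 & w$groom <= 10))
        expect_true(all(w$points >= 0 & w$points <= 100))
        expect_true(all(w$ax >= 0 & w$ax <= cfg$world_width))
        expect_true(all(w$ay >= 0 & w$ay <= cfg$world_height))
        expect_true(all(!w$nested | w$phase == "night"))
      }
    }
  }
})

test_that("traversal between the groves is calibrated to 20 s", {
  cfg <- make_treatment_config("chimpanzee")
  expect_equal(traversal_time(cfg), 20)
  expect_equal(traversal_time(cfg) / cfg$day_length, 0.222, tolerance = 0.01)
  fast <- make_treatment_config("chimpanzee",
                                walk_speed = cfg$walk_speed * 2)
  expect_equal(traversal_time(fast), 10)
})
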