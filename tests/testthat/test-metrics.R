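# analysis statistics: proximity, group partition, histograms, tallies,
# exact Mann-Whitney machinery, OLS trends

fake_log <- function(events, treatment = "chimpanzee", n_days = 35) {
  cfg <- make_treatment_config(treatment, n_days = n_days)
  structure(list(config = cfg, fingerprint = config_fingerprint(cfg),
                 seed = 1L, events = events,
                 final_points = rep(0, cfg$n_avatars)),
            class = "session_log")
}

ev_row <- function(day, t, type, actor = NA_integer_, target = NA_integer_,
                   x = NA_real_, y = NA_real_, detail = NA_character_,
                   value = NA_real_) {
  data.frame(day = day, t = t, type = type, actor = actor, target = target,
             x = x, y = y, detail = detail, value = value,
             stringsAsFactors = FALSE)
}

test_that("nesting proximity divides summed pair distances by C(n,2)", {
  set.seed(42)
  brute <- function(p) {
    s <- 0; n <- nrow(p)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- s + sqrt(sum((p[i, ] - p[j, ])^2))
    }
    s
  }
  p12 <- cbind(runif(12, 0, 6000), runif(12, 0, 10000))
  expect_equal(nesting_proximity(list(p12))$proximity, brute(p12) / 66)
  p10 <- p12[1:10, ]
  expect_equal(nesting_proximity(list(p10))$proximity, brute(p10) / 45)
  same <- matrix(c(500, 500), nrow = 12, ncol = 2, byrow = TRUE)
  expect_equal(nesting_proximity(list(same))$proximity, 0)
  pair <- rbind(c(0, 0), c(300, 0))
  expect_equal(nesting_proximity(list(pair))$proximity, 300)
})

test_that("proximity is invariant to relabeling/translation, scales linearly", {
  set.seed(7)
  for (k in 1:20) {
    n <- sample(3:12, 1)
    p <- cbind(runif(n, 0, 6720), runif(n, 0, 10500))
    v <- nesting_proximity(list(p))$proximity
    expect_equal(nesting_proximity(list(p[sample(n), ]))$proximity, v)
    shift <- cbind(p[, 1] + 123, p[, 2] - 456)
    expect_equal(nesting_proximity(list(shift))$proximity, v)
    expect_equal(nesting_proximity(list(p * 2.5))$proximity, v * 2.5)
  }
})

test_that("days with fewer than two nesters are flagged missing", {
  one <- matrix(c(10, 10), nrow = 1)
  none <- matrix(numeric(0), ncol = 2)
  res <- nesting_proximity(list(one, none, rbind(c(0, 0), c(0, 400))))
  expect_true(is.na(res$proximity[1]))
  expect_true(is.na(res$proximity[2]))
  expect_equal(res$proximity[3], 400)
  expect_equal(res$n_nested, c(1, 0, 2))
})

test_that("vision-overlap groups are transitive connected components", {
  cfg <- make_treatment_config("chimpanzee")
  expect_equal(group_partition(rbind(c(1, 1), c(1, 1)), cfg), c(1L, 1L))
  expect_equal(max(group_partition(rbind(c(0, 0), c(5000, 0)), cfg)), 2L)
  # chain: A-B overlap, B-C overlap, A-C do not -> one group
  chain <- rbind(c(0, 0), c(1500, 0), c(3000, 0))
  expect_equal(max(group_partition(chain, cfg)), 1L)
  expect_equal(length(unique(group_partition(chain, cfg))), 1L)
})

test_that("group partition matches a brute-force reachability oracle", {
  cfg <- make_treatment_config("chimpanzee")
  set.seed(11)
  for (k in 1:200) {
    n <- sample(2:12, 1)
    pos <- cbind(runif(n, 0, cfg$world_width), runif(n, 0, cfg$world_height))
    got <- group_partition(pos, cfg)
    want <- cc_oracle(window_adjacency(pos, cfg))
    # same partition up to label permutation
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("activity histograms bin by time of day and conserve counts", {
  empty <- fake_log(ev_row(0L, 0, "groom")[0, ])
  h <- activity_histogram(empty, "groom", 5)
  expect_equal(sum(h$count), 0)
  expect_equal(nrow(h), 15)                       # 75 s / 5 s
  ev <- rbind(ev_row(0, 12, "groom", 1, 2),
              ev_row(3, 12.9, "groom", 2, 1),
              ev_row(5, 40, "groom", 1, 3),
              ev_row(5, 41, "forage_fruit", 1, 1))
  log <- fake_log(ev)
  h5 <- activity_histogram(log, "groom", 5)
  expect_equal(h5$count[h5$bin_start == 10], 2)   # both land in [10, 15)
  expect_equal(sum(h5$count), 3)                  # fruit event not counted
  h1 <- activity_histogram(log, "forage_fruit", 1)
  expect_equal(sum(h1$count), 1)
  expect_error(activity_histogram(log, "napping", 1), "unknown event type")
  expect_error(activity_histogram(log, "groom", 2), "divide")
})

test_that("attack tallies classify coalitions and split session halves", {
  ev <- rbind(
    ev_row(2, 10, "attack", 1, 1), ev_row(2, 20, "attack_outcome",
                                          detail = "penalty", value = 1),
    ev_row(29, 30, "attack", 2, 3), ev_row(29, 30, "attack", 3, 3),
    ev_row(29, 30, "attack", 4, 3),
    ev_row(29, 30, "attack_outcome", detail = "kill", value = 3))
  log <- fake_log(ev)
  tal <- attack_tally(log)
  get <- function(h, cz) tal$count[tal$half == h & tal$coalition == cz]
  expect_equal(get("first", "single"), 1)
  expect_equal(get("second", "triplet"), 3)       # 3 attack events, 1 coalition
  expect_equal(sum(tal$count), 4)
  coal <- attack_tally(log, unit = "coalitions")
  expect_equal(sum(coal$count), 2)
  expect_equal(coal$count[coal$half == "second" &
                            coal$coalition == "triplet"], 1)
  # a custom split day moves the kill into the first half
  tal31 <- attack_tally(log, split_day = 31)
  expect_equal(tal31$count[tal31$half == "first" &
                             tal31$coalition == "triplet"], 3)
  # halves partition the total
  expect_equal(sum(tal$count[tal$half == "first"]) +
                 sum(tal$count[tal$half == "second"]), 4)
  # an attack with no resolution marks the log as corrupt
  orphan <- fake_log(rbind(ev, ev_row(30, 10, "attack", 5, 3)))
  expect_error(attack_tally(orphan), "corrupt")
})

test_that("exact Mann-Whitney: U, enumeration p-values and symmetry", {
  res <- mann_whitney_exact(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 2 / 70)
  swapped <- mann_whitney_exact(c(10, 20, 30, 40), c(1, 2, 3, 4))
  expect_equal(unname(swapped$statistic), 0)
  expect_equal(swapped$p.value, res$p.value)
  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("enumeration agrees with the exact Wilcoxon oracle for n <= 6", {
  set.seed(99)
  for (k in 1:30) {
    n_a <- sample(2:6, 1); n_b <- sample(2:6, 1)
    a <- round(rnorm(n_a, 0, 10), 6); b <- round(rnorm(n_b, 3, 10), 6)
    ours <- mann_whitney_exact(a, b)
    oracle <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(unname(ours$estimate["U_a"]), unname(oracle$statistic))
    expect_equal(ours$p.value, oracle$p.value, tolerance = 1e-12)
  }
})

test_that("the U null distribution is symmetric about n_a * n_b / 2", {
  u <- apeworld:::rank_sum_distribution(1:9, 4) - 4 * 5 / 2
  expect_equal(sort(u), sort(4 * 5 - u))
  expect_equal(mean(u), 4 * 5 / 2)
})

test_that("exact critical values match the enumerated tail probabilities", {
  expect_identical(mann_whitney_critical_value(4, 4, 0.05), 0L)
  # P(U <= 0) = 1/70 <= 0.025 < P(U <= 1) = 2/70: alpha just above 2*2/70
  # admits u = 1
  expect_identical(mann_whitney_critical_value(4, 4, 4 / 70 + 1e-9), 1L)
  expect_identical(mann_whitney_critical_value(1, 1, 0.05), -1L)
  expect_identical(mann_whitney_critical_value(2, 2, 0.05), -1L)
  expect_error(mann_whitney_critical_value(4, 4, 1.2), "alpha")
})

test_that("OLS trends recover exact fits and match normal equations", {
  exact <- ols_trend(2 * (0:9) + 5)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 5)
  expect_equal(ols_trend(rep(3.5, 10))$slope, 0)
  set.seed(5)
  y <- 1.7 * (0:9) + rnorm(10)
  X <- cbind(1, 0:9)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  got <- ols_trend(y)
  expect_equal(got$slope, beta[2], tolerance = 1e-10)
  expect_equal(got$intercept, beta[1], tolerance = 1e-10)
  # missing days are excluded, not imputed
  y_na <- y; y_na[c(3, 7)] <- NA
  expect_equal(ols_trend(y_na)$n, 8)
  expect_error(ols_trend(c(NA, NA, 1, 2)), "at least 3")
})
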