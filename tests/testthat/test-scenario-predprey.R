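pp_mem <- function() make_memory(3, 6, 144,
                                 what_names = c("crab", "shrimp", "predator"),
                                 width = 12, height = 12)

test_that("pp_config validates the stated world", {
  cfg <- pp_config()
  expect_equal(cfg$alpha, 0.10)
  expect_equal(cfg$predator_penalty, -8)
  expect_equal(cfg$crab_region, 8L)
  expect_equal(cfg$shrimp_region, 6L)
  expect_error(pp_config(alpha = 1.5), "alpha")
  expect_error(pp_config(predator_penalty = 8), "signed")
  expect_error(pp_config(shrimp_hours = c(2, 6)), "window")
  expect_error(pp_config(width = 8, height = 8), "12x12")
})

test_that("hourly placement follows the schedule and zones", {
  cfg <- pp_config()
  set.seed(2)
  for (i in 1:50) {
    p0 <- pp_place_objects(0, cfg)
    expect_false(is.null(p0$crab)); expect_null(p0$shrimp)
    expect_null(p0$predator)
    p2 <- pp_place_objects(2, cfg)
    expect_false(is.null(p2$crab) || is.null(p2$shrimp) ||
                   is.null(p2$predator))
    expect_identical(region_of(p2$shrimp), 6L)
    expect_identical(region_of(p2$crab), 8L)
    expect_lt(p2$predator[1], 6)
    p4 <- pp_place_objects(4, cfg)
    expect_null(p4$predator)
    expect_false(is.null(p4$crab) || is.null(p4$shrimp))
  }
})

test_that("what-query values are summed slices with a danger-valued hide", {
  cfg <- pp_config(query_mode = "what")
  mem <- pp_mem()
  expect_equal(unname(pp_action_values(mem, 0, cfg)), c(0, 0, 0, 0.5))
  # predator slice summing to -6 makes hide worth +6
  mem[3, 3, 5] <- -4; mem[3, 3, 100] <- -2
  v <- pp_action_values(mem, 2, cfg)
  expect_equal(unname(v["hide"]), 6)
  p <- softmax_probs(v, cfg$beta)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  set.seed(1)
  expect_true(select_action_what(mem, 2, cfg) %in%
                c("hunt_crab", "hunt_shrimp", "hide", "roam"))
})

test_that("where-query values are signed region sums", {
  cfg <- pp_config(query_mode = "where")
  mem <- pp_mem()
  v0 <- pp_action_values(mem, 0, cfg)
  expect_length(v0, 10)                      # 9 regions + roam (no hide)
  expect_equal(unname(v0["roam"]), 0.5)
  expect_true(all(v0[1:9] == 0))
  # crab value 1 and a predator penalty -8 in the same region sum to -7
  cell <- 9 + 12 * 9                         # (9, 9), region 8
  mem[1, 1, cell + 1] <- 1
  mem[3, 1, cell + 1] <- -8
  v <- pp_action_values(mem, 0, cfg)
  expect_equal(unname(v["region_8"]), -7)
  # the optional 11-action variant stays available behind the config switch
  cfg11 <- pp_config(query_mode = "where", where_hide = TRUE)
  v11 <- pp_action_values(mem, 0, cfg11)
  expect_length(v11, 11)
  expect_equal(unname(v11["hide"]), 8)
  # identical memory and seed give an identical sampled action
  set.seed(31); a1 <- pp_select_action(mem, 0, cfg)
  set.seed(31); a2 <- pp_select_action(mem, 0, cfg)
  expect_identical(a1, a2)
})

test_that("predator_step chases visible agents and wanders otherwise", {
  cfg <- pp_config()
  set.seed(6)
  # visible at distance 3: strictly approaches
  for (i in 1:20) {
    nxt <- predator_step(c(2, 2), c(5, 2), hidden = FALSE, cfg)
    expect_equal(distance(nxt, c(5, 2)), 2)
  }
  # hidden at distance 2: random step (stays within one step of origin)
  moves <- t(replicate(200, predator_step(c(5, 5), c(6, 6), hidden = TRUE,
                                          cfg)))
  expect_true(all(abs(moves[, 1] - 5) <= 1 & abs(moves[, 2] - 5) <= 1))
  expect_gt(nrow(unique(moves)), 4)   # not deterministic chasing
  # visible but out of vision (distance 5): random step
  moves <- t(replicate(100, predator_step(c(0, 0), c(5, 0), hidden = FALSE,
                                          cfg)))
  expect_true(any(moves[, 1] != 1 | moves[, 2] != 1))
})

test_that("hiding produces no event and no memory change", {
  cfg <- pp_config(query_mode = "what", beta = 50)
  mem <- pp_mem()
  mem[3, 3, 40] <- -8   # strong danger memory at hour 2 -> hide wins
  set.seed(3)
  res <- run_pp_hour(mem, day = 0, hour = 2, cfg)
  expect_equal(res$record$action, "hide")
  expect_equal(res$record$outcome, "none")
  expect_equal(unclass(res$mem), unclass(mem))
})

test_that("a forced crab hunt reaches region 8 and writes the first reward", {
  cfg <- pp_config(query_mode = "what", beta = 50, extinction = FALSE)
  mem <- pp_mem()
  mem[1, 1, 9 + 12 * 9 + 1] <- 0.6   # crab memory at (9,9), hour 0
  set.seed(11)
  res <- run_pp_hour(mem, day = 0, hour = 0, cfg)
  expect_equal(res$record$action, "hunt_crab")
  expect_equal(res$record$outcome, "ate_crab")
  # the reward lands on the crab's actual cell in region 8 as 0 -> 0.1
  # (or tops up the seeded cell if the crab happened to sit on it)
  diff <- which(unclass(res$mem) != unclass(mem), arr.ind = TRUE)
  expect_identical(nrow(diff), 1L)
  expect_identical(diff[1, 1][[1]], 1L)            # crab axis
  expect_identical(diff[1, 2][[1]], 1L)            # hour 0
  cell <- diff[1, 3][[1]] - 1L
  expect_identical(region_of(c(cell %% 12, cell %/% 12)), 8L)
  expect_equal(as.numeric(query(res$mem, "crab", 0, cell)), 0.1)
})

test_that("run_pp logs are complete, reproducible and sign-correct", {
  cfg <- pp_config(n_runs = 2, days = 15, base_seed = 5)
  res <- run_pp(cfg)
  expect_identical(nrow(res$records), 2L * 15L * 6L)
  expect_identical(nrow(unique(res$records[, c("run", "day", "hour")])),
                   nrow(res$records))
  # captures only while the predator is in the environment (hours 1-3)
  eaten <- res$records[res$records$outcome == "eaten", ]
  expect_true(all(eaten$hour %in% 1:3))
  # hidden agents are never caught
  hid <- res$records[res$records$action == "hide", ]
  expect_true(all(hid$outcome == "none"))
  for (m in res$memories) {
    expect_true(all(unclass(m)[1:2, , ] >= 0))     # prey memory nonnegative
    expect_true(all(unclass(m)[3, , ] <= 0))       # predator nonpositive
    expect_true(all(unclass(m) >= -8 & unclass(m) <= 4))
  }
  res2 <- run_pp(cfg)
  expect_identical(res$records, res2$records)
})

test_that("outcome_means computes per-day run means and standard errors", {
  # synthetic: 3 runs, 2 days; run r eats r crabs on day 0, 1 shrimp day 1
  rec <- do.call(rbind, lapply(0:2, function(r) {
    data.frame(run = r, day = rep(0:1, each = 6), hour = rep(0:5, 2),
               mode = "what",
               action = "roam",
               outcome = c(rep("ate_crab", r), rep("none", 6 - r),
                           "ate_shrimp", rep("none", 5)),
               stringsAsFactors = FALSE)
  }))
  om <- outcome_means(rec)
  crab0 <- om[om$event == "ate_crab" & om$day == 0, ]
  expect_equal(crab0$mean, 1)                        # (0 + 1 + 2) / 3
  expect_equal(crab0$se, stats::sd(0:2) / sqrt(3))
  shr1 <- om[om$event == "ate_shrimp" & om$day == 1, ]
  expect_equal(shr1$mean, 1); expect_equal(shr1$se, 0)
  expect_true(all(om$mean <= 6))                     # one event per hour max
})

test_that("actions_per_hour counts days per window and action", {
  rec <- expand.grid(hour = 0:5, day = 0:49, run = 0:1)
  rec$mode <- "what"
  rec$action <- ifelse(rec$day < 25, "roam", "hunt_crab")
  rec$outcome <- "none"
  first <- actions_per_hour(rec, "first", n_days = 20)
  expect_equal(first$mean[first$action == "roam"], rep(20, 6))
  expect_equal(first$sd[first$action == "roam"], rep(0, 6))
  last <- actions_per_hour(rec, "last", n_days = 20)
  expect_equal(last$mean[last$action == "hunt_crab"], rep(20, 6))
  expect_equal(last$mean[last$action == "roam"], rep(0, 6))
  # counts partition the window
  agg <- tapply(first$mean, first$hour, sum)
  expect_true(all(agg == 20))
  expect_error(actions_per_hour(rec[rec$day < 5, ], "first"), "fewer days")
})
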