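# Predator-prey foraging experiment on a 12x12 grid split into nine 4x4
# regions. Shrimp (reward 4) appear in region 6 at hours 2-5, crabs
# (reward 1) in region 8 all day, and a predator roams from hour 1 to 3,
# chasing the agent when it sees it (vision < 4) and catching it within
# < 2 steps (penalty -8, stored signed). Two memory-query policies:
#   "what"  — softmax over per-object value sums (hunt crab / hunt shrimp /
#             hide / roam); hiding is valued by the remembered predator
#             danger at this hour, -sum(predator slice).
#   "where" — softmax over the nine per-region value sums (all objects,
#             signed) plus roam and hide.
# While hiding the agent is camouflaged: it cannot be caught and performs
# no memory updates.

PP_WHAT <- c("crab", "shrimp", "predator")
PP_OUTCOMES <- c("none", "ate_crab", "ate_shrimp", "eaten")
PP_ACTIONS_WHAT <- c("hunt_crab", "hunt_shrimp", "hide", "roam")
PP_ACTIONS_WHERE <- c(paste0("region_", 0:8), "roam", "hide")

# the where-mode action set; hide is off by default (see pp_config)
pp_where_actions <- function(cfg) {
  if (isTRUE(cfg$where_hide)) PP_ACTIONS_WHERE
  else PP_ACTIONS_WHERE[1:10]
}

#' Configuration of the predator-prey scenario
#'
#' Defaults are the published parameterization: 100 runs of 200 days x 6
#' hours x 100 timesteps on a 12x12 grid; shrimp in region 6 at hours 2-5,
#' crab in region 8 at hours 0-5, predator at hours 1-3 entering on the left
#' side (x < 6) with vision < 4; rewards 1 (crab) and 4 (shrimp), predator
#' penalty of magnitude 8 stored as -8; `alpha = 0.10`, `beta = 1.0`, roam
#' value 0.5, cuttlefish vision < 2.
#'
#' @inheritParams elm_config
#' @param shrimp_region,crab_region Region ids (0..8) where each prey is
#'   placed uniformly anew every hour it is available.
#' @param shrimp_hours,crab_hours,predator_hours Inclusive 0-based
#'   `c(first, last)` hour windows of availability/presence.
#' @param predator_xmax Largest x (inclusive) of the predator's uniform
#'   entry zone.
#' @param predator_vision Exclusive Chebyshev bound at which the predator
#'   sees a non-hidden agent and starts chasing.
#' @param catch_radius Exclusive Chebyshev bound at which a non-hidden agent
#'   is caught.
#' @param predator_penalty Signed reward applied on capture (negative).
#' @param query_mode `"what"` (object-centric) or `"where"`
#'   (region-centric) action selection.
#' @param where_hide Include a hide action in the region-centric action set
#'   (default `FALSE`). Because no learning occurs while hiding, a
#'   danger-valued hide is an absorbing state under region queries and
#'   suppresses the opportunistic crab hunting this mode is known for; see
#'   the methods vignette.
#' @return A validated list of class `pp_config`.
#' @export
pp_config <- function(days = 200L, hours_per_day = 6L, steps_per_hour = 100L,
                      n_runs = 100L, width = 12L, height = 12L,
                      start = c(6L, 0L),
                      shrimp_region = 6L, shrimp_hours = c(2L, 5L),
                      crab_region = 8L, crab_hours = c(0L, 5L),
                      predator_hours = c(1L, 3L), predator_xmax = 5L,
                      predator_vision = 4L, catch_radius = 2L,
                      crab_reward = 1.0, shrimp_reward = 4.0,
                      predator_penalty = -8.0,
                      alpha = 0.10, beta = 1.0, roam_value = 0.5,
                      vision = 2L, query_mode = c("what", "where"),
                      where_hide = FALSE, extinction = TRUE,
                      base_seed = 42L) {
  cfg <- list(days = as.integer(days),
              hours_per_day = as.integer(hours_per_day),
              steps_per_hour = as.integer(steps_per_hour),
              n_runs = as.integer(n_runs),
              width = as.integer(width), height = as.integer(height),
              start = as.integer(start),
              shrimp_region = as.integer(shrimp_region),
              shrimp_hours = as.integer(shrimp_hours),
              crab_region = as.integer(crab_region),
              crab_hours = as.integer(crab_hours),
              predator_hours = as.integer(predator_hours),
              predator_xmax = as.integer(predator_xmax),
              predator_vision = as.integer(predator_vision),
              catch_radius = as.integer(catch_radius),
              crab_reward = crab_reward, shrimp_reward = shrimp_reward,
              predator_penalty = predator_penalty,
              alpha = alpha, beta = beta, roam_value = roam_value,
              vision = as.integer(vision),
              query_mode = match.arg(query_mode),
              where_hide = isTRUE(where_hide),
              extinction = isTRUE(extinction),
              base_seed = as.integer(base_seed))
  validate_scenario_common(cfg)
  if (cfg$predator_penalty > 0)
    stop("predator_penalty must be stored signed (<= 0)", call. = FALSE)
  for (w in list(cfg$shrimp_hours, cfg$crab_hours, cfg$predator_hours)) {
    if (length(w) != 2L || w[1L] > w[2L] || w[1L] < 0 ||
        w[2L] >= cfg$hours_per_day)
      stop("availability window out of range", call. = FALSE)
  }
  check_region_id(cfg$shrimp_region); check_region_id(cfg$crab_region)
  if (cfg$width != 12L || cfg$height != 12L)
    stop("the region partition requires a 12x12 grid", call. = FALSE)
  if (any(cfg$start < 0) || cfg$start[1L] >= cfg$width ||
      cfg$start[2L] >= cfg$height)
    stop("start position out of bounds", call. = FALSE)
  structure(cfg, class = "pp_config")
}

in_window <- function(hour, w) hour >= w[1L] && hour <= w[2L]

#' Hourly object placement
#'
#' Places each object anew for the hour it is available: prey uniformly
#' within their region, the predator uniformly in its left-side entry zone.
#' Uses R's global RNG.
#'
#' @param hour 0-based hour of day.
#' @param config A [pp_config()].
#' @return List with `crab`, `shrimp`, `predator`: each a cell `c(x, y)` or
#'   `NULL` when absent that hour.
#' @export
pp_place_objects <- function(hour, config = pp_config()) {
  stopifnot(hour >= 0, hour < config$hours_per_day)
  list(
    crab = if (in_window(hour, config$crab_hours))
      place_in_region(config$crab_region),
    shrimp = if (in_window(hour, config$shrimp_hours))
      place_in_region(config$shrimp_region),
    predator = if (in_window(hour, config$predator_hours))
      place_predator(config$predator_xmax, config$height)
  )
}

# flat 1-based cell indices of each region, in region order 0..8
region_flat1 <- function(width) {
  lapply(0:8, function(r) {
    cells <- region_cells(r)
    cells[, 2L] * width + cells[, 1L] + 1L
  })
}

#' Action values under the two query modes
#'
#' `pp_action_values()` returns the value vector the softmax sees:
#' object-centric ("what") — the summed memory slice of each prey at this
#' hour, the hide value `-sum(predator slice)` and the fixed roam value;
#' region-centric ("where") — the signed per-region sums over all objects
#' (predator entries repel) plus roam, and hide only when the config enables
#' it.
#'
#' @param mem An `epimem` with what axis (crab, shrimp, predator).
#' @param hour 0-based hour of day.
#' @param config A [pp_config()]; its `query_mode` picks the policy.
#' @return `pp_action_values()`: named numeric vector.
#'   `pp_select_action()`: one sampled action name (global RNG).
#' @export
pp_action_values <- function(mem, hour, config = pp_config()) {
  h <- hour + 1L
  v <- unclass(mem)
  if (config$query_mode == "what") {
    c(hunt_crab = sum(v[1L, h, ]), hunt_shrimp = sum(v[2L, h, ]),
      hide = -sum(v[3L, h, ]), roam = config$roam_value)
  } else {
    rf <- region_flat1(config$width)
    rs <- vapply(rf, function(k) sum(v[, h, k]), numeric(1))
    vals <- c(rs, config$roam_value,
              if (isTRUE(config$where_hide)) -sum(v[3L, h, ]))
    stats::setNames(vals, pp_where_actions(config))
  }
}

#' @rdname pp_action_values
#' @export
pp_select_action <- function(mem, hour, config = pp_config()) {
  acts <- if (config$query_mode == "what") PP_ACTIONS_WHAT
          else pp_where_actions(config)
  acts[softmax_choice(pp_action_values(mem, hour, config), config$beta)]
}

#' Backwards-compatible per-mode selectors
#' @inheritParams pp_action_values
#' @return A sampled action name.
#' @export
select_action_what <- function(mem, hour, config = pp_config()) {
  config$query_mode <- "what"
  pp_select_action(mem, hour, config)
}

#' @rdname select_action_what
#' @export
select_action_where <- function(mem, hour, config = pp_config()) {
  config$query_mode <- "where"
  pp_select_action(mem, hour, config)
}

#' One predator movement step
#'
#' The predator chases a visible (non-hidden, within `predator_vision`)
#' agent with a greedy step, otherwise takes a uniform random 8-directional
#' step clipped to the grid.
#'
#' @param pred,cuttle Cells as `c(x, y)`.
#' @param hidden Is the agent camouflaged?
#' @param config A [pp_config()].
#' @return The predator's next cell.
#' @export
predator_step <- function(pred, cuttle, hidden = FALSE,
                          config = pp_config()) {
  if (!hidden && distance(pred, cuttle) < config$predator_vision) {
    step_toward(pred, cuttle)
  } else {
    random_step(pred, grid_spec(config$width, config$height))
  }
}

# One hour of the predator-prey task on the raw value array (hot path).
# vals: 3 x n_when x 144; what axis crab = 1, shrimp = 2, predator = 3.
# Returns list(vals, action, outcome, steps, x, y).
pp_hour <- function(vals, hour, cfg) {
  h <- hour + 1L
  W <- cfg$width; Hh <- cfg$height
  vz <- cfg$vision; alpha <- cfg$alpha
  what_mode <- cfg$query_mode == "what"

  # hourly placements (drawn even for objects the agent never meets)
  avail <- c(in_window(hour, cfg$crab_hours), in_window(hour, cfg$shrimp_hours))
  px <- c(NA_integer_, NA_integer_); py <- px; pcell1 <- px
  if (avail[1L]) {
    p <- place_in_region(cfg$crab_region)
    px[1L] <- p[1L]; py[1L] <- p[2L]; pcell1[1L] <- p[2L] * W + p[1L] + 1L
  }
  if (avail[2L]) {
    p <- place_in_region(cfg$shrimp_region)
    px[2L] <- p[1L]; py[2L] <- p[2L]; pcell1[2L] <- p[2L] * W + p[1L] + 1L
  }
  pred_on <- in_window(hour, cfg$predator_hours)
  if (pred_on) {
    p <- place_predator(cfg$predator_xmax, Hh)
    qx <- p[1L]; qy <- p[2L]
  }
  reward <- c(cfg$crab_reward, cfg$shrimp_reward)

  # --- action selection ---------------------------------------------------
  if (what_mode) {
    v <- c(sum(vals[1L, h, ]), sum(vals[2L, h, ]), -sum(vals[3L, h, ]),
           cfg$roam_value)
    a <- softmax_choice(v, cfg$beta)        # 1 crab, 2 shrimp, 3 hide, 4 roam
    hide <- a == 3L
    hunting <- a <= 2L
    target_region <- if (hunting)
      region_of(flat_to_cell(which.max(vals[a, h, ]) - 1L, W))
  } else {
    rs <- vapply(REGION_FLAT1, function(k) sum(vals[, h, k]), numeric(1))
    v <- c(rs, cfg$roam_value,
           if (cfg$where_hide) -sum(vals[3L, h, ]))
    a <- softmax_choice(v, cfg$beta)        # 1..9 regions, 10 roam, [11 hide]
    hide <- a == 11L
    hunting <- a <= 9L                       # "go to region" plays the hunt role
    target_region <- if (hunting) a - 1L
  }

  # camouflaged: invisible to the predator, no updates of any kind, and the
  # hour cannot produce an event, so it is recorded without stepping
  if (hide) {
    return(list(vals = vals, action = a, outcome = 0L,
                steps = cfg$steps_per_hour,
                x = cfg$start[1L], y = cfg$start[2L]))
  }

  eat_order <- if (what_mode && a == 2L) c(2L, 1L) else c(1L, 2L)
  if (hunting) {
    ctr <- region_center(target_region)
    tx <- ctr[1L]; ty <- ctr[2L]
    rb <- region_bounds(target_region)
    rx0 <- rb$xlim[1L]; rx1 <- rb$xlim[2L]
    ry0 <- rb$ylim[1L]; ry1 <- rb$ylim[2L]
  }

  # Extinction (one r = 0 update per cell per hour, never while hiding):
  #  - prey memory decays only at remembered cells of the *hunted* object
  #    seen empty — a failed search is the informative null trial;
  #  - predator memory decays at any remembered danger cell the non-hidden
  #    agent passes safely; a remembered cell with the predator actually on
  #    it triggers a capture instead (catch radius < 2 = vision).
  ex <- ey <- ecell1 <- vector("list", 3L)
  nex <- integer(3L)
  if (cfg$extinction) {
    sought <- if (what_mode && hunting) a else 0L
    for (o in c(if (sought) sought, 3L)) {
      nz <- which(vals[o, h, ] != 0)
      if (o <= 2L && avail[o]) nz <- nz[nz != pcell1[o]]
      nex[o] <- length(nz)
      if (nex[o]) {
        ecell1[[o]] <- nz
        ex[[o]] <- (nz - 1L) %% W
        ey[[o]] <- (nz - 1L) %/% W
      }
    }
  }

  x <- cfg$start[1L]; y <- cfg$start[2L]
  in_region <- hunting && region_of(c(x, y)) == target_region
  outcome <- 0L
  steps <- cfg$steps_per_hour
  for (t in seq_len(cfg$steps_per_hour)) {
    # cuttlefish moves: travel greedily to the region center, then roam the
    # region; a plain roam action wanders the whole grid
    if (hunting && !in_region) {
      x <- x + sign(tx - x); y <- y + sign(ty - y)
      if (x >= rx0 && x <= rx1 && y >= ry0 && y <= ry1) in_region <- TRUE
    } else {
      d <- DIRS[sample.int(8L, 1L), ]
      if (hunting) {  # clipped to the region block
        x <- min(max(x + d[1L], rx0), rx1)
        y <- min(max(y + d[2L], ry0), ry1)
      } else {
        x <- min(max(x + d[1L], 0L), W - 1L)
        y <- min(max(y + d[2L], 0L), Hh - 1L)
      }
    }
    # predator moves: chase if it sees the agent, otherwise wander
    if (pred_on) {
      if (abs(qx - x) < cfg$predator_vision &&
          abs(qy - y) < cfg$predator_vision) {
        qx <- qx + sign(x - qx); qy <- qy + sign(y - qy)
      } else {
        d <- DIRS[sample.int(8L, 1L), ]
        qx <- min(max(qx + d[1L], 0L), W - 1L)
        qy <- min(max(qy + d[2L], 0L), Hh - 1L)
      }
    }
    # events: at most one per hour; prey first, then capture
    for (o in eat_order) {
      if (avail[o] && abs(x - px[o]) < vz && abs(y - py[o]) < vz) {
        k <- pcell1[o]
        vals[o, h, k] <- vals[o, h, k] + alpha * (reward[o] - vals[o, h, k])
        outcome <- o
        break
      }
    }
    if (!outcome && pred_on && abs(qx - x) < cfg$catch_radius &&
        abs(qy - y) < cfg$catch_radius) {
      k <- y * W + x + 1L  # the agent remembers where it was attacked
      vals[3L, h, k] <- vals[3L, h, k] +
        alpha * (cfg$predator_penalty - vals[3L, h, k])
      outcome <- 3L
    }
    if (outcome) { steps <- t; break }
    if (nex[1L] || nex[2L] || nex[3L]) {
      for (o in 1:3) {
        if (nex[o]) {
          hit <- abs(x - ex[[o]]) < vz & abs(y - ey[[o]]) < vz
          if (any(hit)) {
            k <- ecell1[[o]][hit]
            vals[o, h, k] <- vals[o, h, k] * (1 - alpha)
            keep <- !hit
            ecell1[[o]] <- ecell1[[o]][keep]
            ex[[o]] <- ex[[o]][keep]; ey[[o]] <- ey[[o]][keep]
            nex[o] <- sum(keep)
          }
        }
      }
    }
  }
  list(vals = vals, action = a, outcome = outcome, steps = steps,
       x = x, y = y)
}

# fixed 12-wide region index cache for the hot loop (collation: gridworld.R
# defines region_cells first)
REGION_FLAT1 <- region_flat1(12L)

#' Simulate one hour of the predator-prey task
#'
#' Places the hour's objects, selects an action under the configured query
#' mode and steps the agent (and predator) for up to `steps_per_hour`
#' timesteps, using R's global RNG. The agent is re-placed at the start
#' cell.
#'
#' @param mem An `epimem` with three objects (crab, shrimp, predator).
#' @param day 0-based day (recorded only).
#' @param hour 0-based hour of day.
#' @param config A [pp_config()].
#' @return List with `record` (one-row data.frame: day, hour, mode, action,
#'   outcome, steps, end_x, end_y) and `mem` (updated memory).
#' @export
run_pp_hour <- function(mem, day, hour, config = pp_config()) {
  stopifnot(inherits(mem, "epimem"))
  res <- pp_hour(unclass(mem), hour, config)
  acts <- if (config$query_mode == "what") PP_ACTIONS_WHAT
          else pp_where_actions(config)
  out <- mem
  out[] <- res$vals
  list(record = data.frame(day = day, hour = hour,
                           mode = config$query_mode,
                           action = acts[res$action],
                           outcome = PP_OUTCOMES[res$outcome + 1L],
                           steps = res$steps,
                           end_x = res$x, end_y = res$y,
                           stringsAsFactors = FALSE),
       mem = out)
}

#' Run the full predator-prey experiment
#'
#' Executes `n_runs` independent runs of `days` x `hours_per_day` hours
#' under the configured query mode; memory persists across the whole run.
#' Run `k` (0-based) seeds R's RNG with `base_seed + k`.
#'
#' @param config A [pp_config()].
#' @param progress Print a dot every 10 runs.
#' @return A `pp_result` list: `records` (one row per run, day, hour: run,
#'   day, hour, mode, action, outcome, steps, end_x, end_y), `memories`
#'   (final `epimem` per run) and `config`.
#' @export
run_pp <- function(config = pp_config(), progress = FALSE) {
  stopifnot(inherits(config, "pp_config"))
  cfg <- config
  acts <- if (cfg$query_mode == "what") PP_ACTIONS_WHAT
          else pp_where_actions(cfg)
  n_hours <- cfg$days * cfg$hours_per_day
  n <- cfg$n_runs * n_hours
  run_v <- integer(n); day_v <- integer(n); hour_v <- integer(n)
  act_v <- integer(n); out_v <- integer(n); steps_v <- integer(n)
  x_v <- integer(n); y_v <- integer(n)
  memories <- vector("list", cfg$n_runs)
  i <- 0L
  for (run in seq_len(cfg$n_runs) - 1L) {
    set.seed(cfg$base_seed + run)
    vals <- array(0, dim = c(3L, cfg$hours_per_day, cfg$width * cfg$height))
    for (day in seq_len(cfg$days) - 1L) {
      for (hour in seq_len(cfg$hours_per_day) - 1L) {
        res <- pp_hour(vals, hour, cfg)
        vals <- res$vals
        i <- i + 1L
        run_v[i] <- run; day_v[i] <- day; hour_v[i] <- hour
        act_v[i] <- res$action; out_v[i] <- res$outcome
        steps_v[i] <- res$steps; x_v[i] <- res$x; y_v[i] <- res$y
      }
    }
    mem <- make_memory(3L, cfg$hours_per_day, cfg$width * cfg$height,
                       what_names = PP_WHAT,
                       width = cfg$width, height = cfg$height)
    mem[] <- vals
    memories[[run + 1L]] <- mem
    if (progress && (run + 1L) %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  records <- data.frame(run = run_v, day = day_v, hour = hour_v,
                        mode = cfg$query_mode,
                        action = acts[act_v],
                        outcome = PP_OUTCOMES[out_v + 1L],
                        steps = steps_v, end_x = x_v, end_y = y_v,
                        stringsAsFactors = FALSE)
  structure(list(records = records, memories = memories, config = cfg),
            class = "pp_result")
}

#' Per-day outcome rates across runs
#'
#' Mean and standard error over runs of the number of times per day the
#' agent ate a crab, ate a shrimp, or was eaten — the published
#' learning-curve summary. Optionally averages days into bins of `bin`
#' consecutive days (per run, before taking the mean and SE).
#'
#' @param records The `records` data.frame of [run_pp()] (or a `pp_result`).
#' @param bin Days per aggregation window (1 = daily points).
#' @return Data.frame with columns day (window start), event, mean, se.
#' @export
outcome_means <- function(records, bin = 1L) {
  if (inherits(records, "pp_result")) records <- records$records
  events <- c("ate_crab", "ate_shrimp", "eaten")
  runs <- sort(unique(records$run))
  days <- sort(unique(records$day))
  out <- list()
  for (ev in events) {
    tab <- table(factor(records$run[records$outcome == ev], levels = runs),
                 factor(records$day[records$outcome == ev], levels = days))
    m <- matrix(as.numeric(tab), nrow = length(runs))  # runs x days
    grp <- (seq_along(days) - 1L) %/% bin
    for (g in unique(grp)) {
      cols <- which(grp == g)
      per_run <- rowMeans(m[, cols, drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        day = days[cols[1L]], event = ev,
        mean = mean(per_run),
        se = stats::sd(per_run) / sqrt(length(per_run)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$day, res$event), , drop = FALSE]
}

#' Actions chosen per hour over a day window
#'
#' For each hour of the day and each action, the mean and standard deviation
#' over runs of the number of days in the window on which that action was
#' chosen at that hour — the published per-hour action histograms for early
#' versus late training.
#'
#' @param records A records data.frame (`run_pp()` or `run_elm()` style) or
#'   result object.
#' @param window `"first"` or `"last"` `n_days` of the simulation.
#' @param n_days Window length in days.
#' @return Data.frame with columns hour, action, mean, sd. For every
#'   (run, hour) the action counts sum to `n_days`.
#' @export
actions_per_hour <- function(records, window = c("first", "last"),
                             n_days = 20L) {
  if (inherits(records, "pp_result") || inherits(records, "elm_result"))
    records <- records$records
  window <- match.arg(window)
  days <- sort(unique(records$day))
  if (length(days) < n_days) stop("fewer days than the window", call. = FALSE)
  keep <- if (window == "first") days[seq_len(n_days)]
          else days[(length(days) - n_days + 1L):length(days)]
  rec <- records[records$day %in% keep, , drop = FALSE]
  lv <- action_levels(records$action)
  tab <- table(run = rec$run, hour = rec$hour,
               action = factor(rec$action, levels = lv))
  # tab: runs x hours x actions of day-counts
  mu <- apply(tab, c(2L, 3L), mean)
  sdv <- apply(tab, c(2L, 3L), stats::sd)
  df <- expand.grid(hour = as.integer(dimnames(tab)$hour),
                    action = lv, stringsAsFactors = FALSE)
  df$mean <- as.vector(mu)
  df$sd <- as.vector(sdv)
  df[order(df$hour, match(df$action, lv)), , drop = FALSE]
}

# stable display order for whichever action set the records use
action_levels <- function(actions) {
  u <- unique(actions)
  for (lv in list(PP_ACTIONS_WHERE, PP_ACTIONS_WHAT, ELM_ACTIONS)) {
    if (all(u %in% lv)) return(lv)
  }
  sort(u)
}
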