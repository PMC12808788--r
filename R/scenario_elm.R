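# Two-phase episodic-like-memory foraging experiment on an 8x8 grid.
#
# A cuttlefish agent starts each hour at (0, 4). A crab (reward 1) sits at
# (7, 0) and is available every hour; a shrimp (reward 4) sits at (7, 7) and
# is available every hour in phase 1 but only at the last hour of the day in
# phase 2. Each hour the agent queries its memory at the current hour, picks
# hunt_crab / hunt_shrimp / roam by softmax over the per-object maxima (roam
# has a fixed value), and acts for up to 100 timesteps. Reaching within
# vision (< 2 steps) of an available prey triggers a delta-rule reward
# update at the prey's cell and ends the hour.

ELM_ACTIONS <- c("hunt_crab", "hunt_shrimp", "roam")
ELM_OUTCOMES <- c("none", "ate_crab", "ate_shrimp")

#' Configuration of the episodic-like-memory scenario
#'
#' Defaults are the published parameterization of the task: 100 runs of 100
#' days x 3 hours x 100 timesteps on an 8x8 grid, phase 2 starting at day
#' 50, learning rate `alpha = 0.10`, softmax inverse temperature
#' `beta = 1.0`, roam value 0.5 and vision radius < 2 (Chebyshev).
#'
#' @param days Simulated days per run.
#' @param phase2_start_day First (0-based) day of phase 2; must be `< days`.
#' @param hours_per_day Hours per day (the `when` axis size).
#' @param steps_per_hour Timesteps per hour.
#' @param n_runs Number of independent runs.
#' @param width,height Grid dimensions.
#' @param start Agent start cell `c(x, y)`, re-entered at every hour.
#' @param crab_pos,shrimp_pos Stationary prey cells.
#' @param crab_reward,shrimp_reward Rewards applied on eating.
#' @param shrimp_phase2_hour The only hour (0-based) at which shrimp is
#'   available in phase 2.
#' @param alpha Delta-rule learning rate in (0, 1].
#' @param beta Softmax inverse temperature, >= 0.
#' @param roam_value Fixed action value of roaming.
#' @param vision Exclusive Chebyshev vision bound (`< vision` sees prey).
#' @param extinction Apply r = 0 updates to remembered prey cells seen empty
#'   (see the methods vignette); needed for the phase-2 behavioural switch.
#' @param base_seed Seed of run 0; run `k` uses `base_seed + k`.
#' @return A validated list of class `elm_config`.
#' @export
elm_config <- function(days = 100L, phase2_start_day = 50L,
                       hours_per_day = 3L, steps_per_hour = 100L,
                       n_runs = 100L, width = 8L, height = 8L,
                       start = c(0L, 4L),
                       crab_pos = c(7L, 0L), shrimp_pos = c(7L, 7L),
                       crab_reward = 1.0, shrimp_reward = 4.0,
                       shrimp_phase2_hour = 2L,
                       alpha = 0.10, beta = 1.0, roam_value = 0.5,
                       vision = 2L, extinction = TRUE, base_seed = 42L) {
  cfg <- list(days = as.integer(days),
              phase2_start_day = as.integer(phase2_start_day),
              hours_per_day = as.integer(hours_per_day),
              steps_per_hour = as.integer(steps_per_hour),
              n_runs = as.integer(n_runs),
              width = as.integer(width), height = as.integer(height),
              start = as.integer(start),
              crab_pos = as.integer(crab_pos),
              shrimp_pos = as.integer(shrimp_pos),
              crab_reward = crab_reward, shrimp_reward = shrimp_reward,
              shrimp_phase2_hour = as.integer(shrimp_phase2_hour),
              alpha = alpha, beta = beta, roam_value = roam_value,
              vision = as.integer(vision),
              extinction = isTRUE(extinction),
              base_seed = as.integer(base_seed))
  validate_scenario_common(cfg)
  if (cfg$phase2_start_day >= cfg$days || cfg$phase2_start_day < 1)
    stop("phase2_start_day must lie in [1, days)", call. = FALSE)
  if (cfg$shrimp_phase2_hour < 0 || cfg$shrimp_phase2_hour >= cfg$hours_per_day)
    stop("shrimp_phase2_hour out of range", call. = FALSE)
  for (p in list(cfg$start, cfg$crab_pos, cfg$shrimp_pos)) {
    if (length(p) != 2L || any(p < 0) || p[1L] >= cfg$width ||
        p[2L] >= cfg$height)
      stop("position out of grid bounds", call. = FALSE)
  }
  structure(cfg, class = "elm_config")
}

# shared range checks for both scenario configs
validate_scenario_common <- function(cfg) {
  if (!is.finite(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  if (!is.finite(cfg$beta) || cfg$beta < 0)
    stop("beta must be >= 0", call. = FALSE)
  if (!is.finite(cfg$roam_value))
    stop("roam_value must be finite", call. = FALSE)
  for (nm in c("days", "hours_per_day", "steps_per_hour", "n_runs",
               "width", "height", "vision")) {
    if (cfg[[nm]] < 1) stop(nm, " must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Prey availability schedule of the two-phase task
#'
#' The crab is available at every hour of both phases. The shrimp is
#' available at every hour in phase 1 but only at the configured delay
#' (hour index 2, the "3-hour delay") in phase 2.
#'
#' @param phase Phase, 1 or 2.
#' @param hour 0-based hour of day.
#' @param object `"crab"` or `"shrimp"`.
#' @param config An [elm_config()].
#' @return Logical.
#' @export
availability <- function(phase, hour, object, config = elm_config()) {
  stopifnot(phase %in% c(1L, 2L),
            hour >= 0, hour < config$hours_per_day)
  switch(match.arg(object, c("crab", "shrimp")),
         crab = TRUE,
         shrimp = phase == 1L || hour == config$shrimp_phase2_hour)
}

#' Action values and softmax choice at the start of an hour
#'
#' The hunt value of each prey is the maximum of its memory slice at the
#' current hour over all cells; roaming has the fixed configured value.
#'
#' @param mem An `epimem` (crab on the first `what` index, shrimp second).
#' @param hour 0-based hour of day.
#' @param config An [elm_config()].
#' @return `elm_action_values()`: named numeric vector
#'   (hunt_crab, hunt_shrimp, roam). `elm_select_action()`: one action name
#'   sampled by softmax (uses R's global RNG).
#' @export
elm_action_values <- function(mem, hour, config = elm_config()) {
  h <- hour + 1L
  v <- unclass(mem)
  c(hunt_crab = max(v[1L, h, ]), hunt_shrimp = max(v[2L, h, ]),
    roam = config$roam_value)
}

#' @rdname elm_action_values
#' @export
elm_select_action <- function(mem, hour, config = elm_config()) {
  ELM_ACTIONS[softmax_choice(elm_action_values(mem, hour, config),
                             config$beta)]
}

# One hour of the ELM task on the raw value array (hot path).
# vals: n_what x n_when x n_cells array, crab = 1, shrimp = 2.
# Returns list(vals, action, outcome, steps, x, y) with integer codes.
elm_hour <- function(vals, phase, hour, cfg) {
  h <- hour + 1L
  W <- cfg$width; H <- cfg$height; vz <- cfg$vision
  alpha <- cfg$alpha
  avail <- c(TRUE, phase == 1L || hour == cfg$shrimp_phase2_hour)
  px <- c(cfg$crab_pos[1L], cfg$shrimp_pos[1L])
  py <- c(cfg$crab_pos[2L], cfg$shrimp_pos[2L])
  pcell1 <- py * W + px + 1L
  reward <- c(cfg$crab_reward, cfg$shrimp_reward)

  a <- softmax_choice(c(max(vals[1L, h, ]), max(vals[2L, h, ]),
                        cfg$roam_value), cfg$beta)
  hunting <- a < 3L
  if (hunting) {
    tf <- which.max(vals[a, h, ]) - 1L
    tx <- tf %% W; ty <- tf %/% W
  }
  eat_order <- if (a == 2L) c(2L, 1L) else c(1L, 2L)

  # Extinction: remembered cells of the hunted object that the agent sees
  # empty receive one r = 0 update per hour. Scoped to the hunted object —
  # searching where you remember prey and finding none is the informative
  # null trial; roaming past a remembered site is not a search failure.
  ex <- ey <- ecell1 <- vector("list", 2L)
  nex <- integer(2L)
  if (cfg$extinction && hunting) {
    o <- a
    nz <- which(vals[o, h, ] != 0)
    if (avail[o]) nz <- nz[nz != pcell1[o]]  # prey really is there
    nex[o] <- length(nz)
    if (nex[o]) {
      ecell1[[o]] <- nz
      ex[[o]] <- (nz - 1L) %% W
      ey[[o]] <- (nz - 1L) %/% W
    }
  }

  x <- cfg$start[1L]; y <- cfg$start[2L]
  arrived <- FALSE
  outcome <- 0L
  steps <- cfg$steps_per_hour
  for (t in seq_len(cfg$steps_per_hour)) {
    if (hunting && !arrived) {
      x <- x + sign(tx - x); y <- y + sign(ty - y)
      if (x == tx && y == ty) arrived <- TRUE
    } else {
      d <- DIRS[sample.int(8L, 1L), ]
      x <- min(max(x + d[1L], 0L), W - 1L)
      y <- min(max(y + d[2L], 0L), H - 1L)
    }
    for (o in eat_order) {
      if (avail[o] && abs(x - px[o]) < vz && abs(y - py[o]) < vz) {
        k <- pcell1[o]
        vals[o, h, k] <- vals[o, h, k] + alpha * (reward[o] - vals[o, h, k])
        outcome <- o
        break
      }
    }
    if (outcome) { steps <- t; break }
    if (nex[1L] || nex[2L]) {
      for (o in 1:2) {
        if (nex[o]) {
          hit <- abs(x - ex[[o]]) < vz & abs(y - ey[[o]]) < vz
          if (any(hit)) {
            k <- ecell1[[o]][hit]
            vals[o, h, k] <- vals[o, h, k] * (1 - alpha)  # r = 0 extinction
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

#' Simulate one hour of the two-phase task
#'
#' Runs action selection and up to `steps_per_hour` timesteps of movement,
#' eating and extinction against the supplied memory, using R's global RNG.
#' The agent is re-placed at the configured start cell.
#'
#' @param mem An `epimem` from [make_memory()] with two objects
#'   (crab, shrimp).
#' @param day 0-based day (determines the phase).
#' @param hour 0-based hour of day.
#' @param config An [elm_config()].
#' @return List with `record` (one-row data.frame: day, hour, phase, action,
#'   outcome, steps, end_x, end_y) and `mem` (the updated memory).
#' @export
run_elm_hour <- function(mem, day, hour, config = elm_config()) {
  stopifnot(inherits(mem, "epimem"))
  phase <- if (day < config$phase2_start_day) 1L else 2L
  res <- elm_hour(unclass(mem), phase, hour, config)
  out <- mem
  out[] <- res$vals
  list(record = data.frame(day = day, hour = hour, phase = phase,
                           action = ELM_ACTIONS[res$action],
                           outcome = ELM_OUTCOMES[res$outcome + 1L],
                           steps = res$steps,
                           end_x = res$x, end_y = res$y,
                           stringsAsFactors = FALSE),
       mem = out)
}

#' Run the full two-phase episodic-like-memory experiment
#'
#' Executes `n_runs` independent runs of `days` x `hours_per_day` hours.
#' Run `k` (0-based) seeds R's RNG with `base_seed + k`, so runs are
#' order-independent and the whole experiment is reproducible.
#'
#' @param config An [elm_config()].
#' @param progress Print a dot every 10 runs.
#' @return An `elm_result` list: `records`, a tidy data.frame with one row
#'   per (run, day, hour) holding run, day, hour, phase, action, outcome,
#'   steps, end_x, end_y; `memories`, the final `epimem` of each run;
#'   `config`.
#' @export
run_elm <- function(config = elm_config(), progress = FALSE) {
  stopifnot(inherits(config, "elm_config"))
  cfg <- config
  n_hours <- cfg$days * cfg$hours_per_day
  n <- cfg$n_runs * n_hours
  run_v <- integer(n); day_v <- integer(n); hour_v <- integer(n)
  phase_v <- integer(n); act_v <- integer(n); out_v <- integer(n)
  steps_v <- integer(n); x_v <- integer(n); y_v <- integer(n)
  memories <- vector("list", cfg$n_runs)
  i <- 0L
  for (run in seq_len(cfg$n_runs) - 1L) {
    set.seed(cfg$base_seed + run)
    vals <- array(0, dim = c(2L, cfg$hours_per_day, cfg$width * cfg$height))
    for (day in seq_len(cfg$days) - 1L) {
      phase <- if (day < cfg$phase2_start_day) 1L else 2L
      for (hour in seq_len(cfg$hours_per_day) - 1L) {
        res <- elm_hour(vals, phase, hour, cfg)
        vals <- res$vals
        i <- i + 1L
        run_v[i] <- run; day_v[i] <- day; hour_v[i] <- hour
        phase_v[i] <- phase; act_v[i] <- res$action; out_v[i] <- res$outcome
        steps_v[i] <- res$steps; x_v[i] <- res$x; y_v[i] <- res$y
      }
    }
    mem <- make_memory(2L, cfg$hours_per_day, cfg$width * cfg$height,
                       what_names = c("crab", "shrimp"),
                       width = cfg$width, height = cfg$height)
    mem[] <- vals
    memories[[run + 1L]] <- mem
    if (progress && (run + 1L) %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  records <- data.frame(run = run_v, day = day_v, hour = hour_v,
                        phase = phase_v,
                        action = ELM_ACTIONS[act_v],
                        outcome = ELM_OUTCOMES[out_v + 1L],
                        steps = steps_v, end_x = x_v, end_y = y_v,
                        stringsAsFactors = FALSE)
  structure(list(records = records, memories = memories, config = cfg),
            class = "elm_result")
}

#' Per-run choice percentages over the last days of a phase
#'
#' For every run and hour-of-day (delay), the percentage of the last
#' `last_n_days` days' choices at that hour going to each action — the
#' quantity summarized per delay in the published boxplots.
#'
#' @param records The `records` data.frame of [run_elm()] (or an
#'   `elm_result`).
#' @param phase Phase to summarize, 1 or 2.
#' @param last_n_days Number of trailing days of the phase to keep.
#' @return Data.frame with columns run, hour, action, pct; for each
#'   (run, hour) the three action percentages sum to 100.
#' @export
choice_percentages <- function(records, phase, last_n_days = 10L) {
  if (inherits(records, "elm_result")) records <- records$records
  rec <- records[records$phase == phase, , drop = FALSE]
  days_in <- sort(unique(rec$day))
  if (length(days_in) < last_n_days)
    stop(sprintf("phase %d has only %d days, need %d", phase,
                 length(days_in), last_n_days), call. = FALSE)
  keep_days <- days_in[(length(days_in) - last_n_days + 1L):length(days_in)]
  rec <- rec[rec$day %in% keep_days, , drop = FALSE]
  tab <- table(run = rec$run, hour = rec$hour,
               action = factor(rec$action, levels = ELM_ACTIONS))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  data.frame(run = as.integer(df$run), hour = as.integer(df$hour),
             action = df$action,
             pct = 100 * df$Freq / last_n_days,
             stringsAsFactors = FALSE)
}

#' Boxplot-style summary of choice percentages per (hour, action)
#'
#' @param pct Output of [choice_percentages()].
#' @return Data.frame with one row per (hour, action): median, q1, q3,
#'   whisker_lo, whisker_hi (1.5 x IQR rule, clipped to data), n_outliers, n.
#' @export
choice_summary <- function(pct) {
  groups <- unique(pct[, c("hour", "action")])
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- pct$hour == groups$hour[g] & pct$action == groups$action[g]
    s <- boxplot_summary(pct$pct[sel])
    data.frame(hour = groups$hour[g], action = groups$action[g],
               median = s$median, q1 = s$q1, q3 = s$q3,
               whisker_lo = s$whisker_lo, whisker_hi = s$whisker_hi,
               n_outliers = length(s$outliers), n = s$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$hour, out$action), , drop = FALSE]
}
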