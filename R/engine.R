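#' Simulation state
#'
#' Bundle of everything the stepper advances: absolute time, step counter,
#' the agent table, the stimulus field and the arena.
#'
#' @param agents agent data.frame from [initial_agents()].
#' @param arena a [build_arena()] object.
#' @param field a [make_field()] object.
#' @param time absolute time (s).
#' @param step step counter.
#' @return object of class `wb_state`.
#' @export
sim_state <- function(agents, arena, field, time = 0, step = 0L) {
  structure(list(time = time, step = as.integer(step), agents = agents,
                 arena = arena, field = field),
            class = "wb_state")
}

#' @export
print.wb_state <- function(x, ...) {
  cat("<wb_state> t = ", x$time, " s (step ", x$step, "), ",
      nrow(x$agents), " agents\n", sep = "")
  invisible(x)
}

#' Advance the coupled system
#'
#' One (or `n`) full update(s) of length `dt`: refresh the random-torque
#' schedule, recompute contacts, advance the repellent field, sample
#' stimulus and activity, integrate position/velocity/heading with the
#' two-stage exponential Runge-Kutta scheme (contacts, field and activity
#' frozen across the two stages), then the explicit Euler length update and
#' the head wall-clamp. Uses R's RNG: call `set.seed()` for reproducible
#' trajectories.
#'
#' @param state a [sim_state()] object.
#' @param params a [wb_params()] object.
#' @param n number of steps to advance.
#' @return the advanced `wb_state`.
#' @export
sim_step <- function(state, params, n = 1L) {
  stopifnot(inherits(state, "wb_state"), inherits(params, "wb_params"))
  res <- cpp_run(agents_to_matrix(state$agents), unclass(params),
                 unclass(state$arena), unclass(state$field),
                 as.integer(n), as.integer(n), state$time, state$step)
  ag <- as.data.frame(res$agents)
  names(ag) <- c("x", "y", "vx", "vy", "theta", "l", "zeta", "t_refresh")
  state$agents <- ag
  state$field$a <- res$field_a
  state$time <- state$time + n * params$dt
  state$step <- state$step + as.integer(n)
  state
}

#' Per-agent force and torque breakdown
#'
#' Diagnostic decomposition of the model's right-hand sides at a given
#' state: per-agent propulsion, pair, peg and wall forces, the five torque
#' terms, and the cached quantities (stimulus, gradient, activity, contact
#' counts, target length). The `fx, fy, W` totals equal the sum of their
#' breakdown terms.
#'
#' @param agents agent data.frame.
#' @param arena a [build_arena()] object.
#' @param field a [make_field()] object.
#' @param params a [wb_params()] object.
#' @return named list of per-agent vectors.
#' @export
force_breakdown <- function(agents, arena, field, params) {
  stopifnot(inherits(params, "wb_params"))
  cpp_force_breakdown(agents_to_matrix(agents), unclass(params),
                      unclass(arena), unclass(field))
}

#' Scenario specification
#'
#' A seeded, reproducible description of one simulation trial. The five
#' named scenarios default to their standard study conditions:
#' \describe{
#'   \item{blob_formation}{square box (side 0.183 m), 1000 agents uniform
#'     over the box, 1e4 steps, no external stimulus.}
#'   \item{escape}{open dish, 250 agents in a disc of radius 0.0125 m at
#'     the origin, mustard gradient on, 1e5 steps.}
#'   \item{oval}{oval arena, 250 agents in a radius-0.0125 m disc in the
#'     left half, 4e5 steps.}
#'   \item{dumbbell, dumbbell_pegs}{two-room arena (with or without pegs),
#'     same placement in the left room, 4e5 steps.}
#' }
#' Any default can be overridden (scaled-down study sizes, custom arenas).
#'
#' @param name scenario tag.
#' @param seed RNG seed for the trial.
#' @param n_agents,n_steps overrides of the scenario defaults.
#' @param record_stride snapshot interval in steps (must not exceed
#'   `n_steps`).
#' @param mustard override of the scenario's stimulus setting.
#' @param arena_args named list passed on to [build_arena()].
#' @param placement placement override (see [initial_agents()]).
#' @return object of class `wb_scenario`.
#' @export
scenario_spec <- function(name = c("blob_formation", "escape", "oval",
                                   "dumbbell", "dumbbell_pegs"),
                          seed = 1L, n_agents = NULL, n_steps = NULL,
                          record_stride = 500L, mustard = NULL,
                          arena_args = list(), placement = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    blob_formation = list(kind = "square", n = 1000L, steps = 10000L,
                          mustard = FALSE),
    escape = list(kind = "open", n = 250L, steps = 100000L, mustard = TRUE),
    oval = list(kind = "oval", n = 250L, steps = 400000L, mustard = FALSE),
    dumbbell = list(kind = "dumbbell", n = 250L, steps = 400000L,
                    mustard = FALSE),
    dumbbell_pegs = list(kind = "dumbbell_pegs", n = 250L, steps = 400000L,
                         mustard = FALSE))
  n_agents <- if (is.null(n_agents)) def$n else as.integer(n_agents)
  n_steps <- if (is.null(n_steps)) def$steps else as.integer(n_steps)
  mustard <- if (is.null(mustard)) def$mustard else isTRUE(mustard)
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (record_stride < 1 || record_stride > n_steps)
    stop("record_stride must be in [1, n_steps] (no recorded strides otherwise)")
  if (n_agents < 1) stop("n_agents must be >= 1")
  structure(list(name = name, kind = def$kind, seed = as.integer(seed),
                 n_agents = n_agents, n_steps = n_steps,
                 record_stride = as.integer(record_stride),
                 mustard = mustard, arena_args = arena_args,
                 placement = placement),
            class = "wb_scenario")
}

default_placement <- function(spec, arena) {
  switch(spec$name,
    blob_formation = {
      h <- arena$bbox
      list(kind = "rect", xmin = h[1], xmax = h[2], ymin = h[3], ymax = h[4])
    },
    escape = list(kind = "disc", center = c(0, 0), radius = 0.0125),
    oval = list(kind = "disc", center = c(-0.0125, 0), radius = 0.0125),
    list(kind = "disc", center = c(arena$rooms$centers[1, 1], 0),
         radius = 0.0125))
}

#' Run one seeded scenario
#'
#' Builds the arena, field and initial agents from the spec, seeds the RNG,
#' advances the full system, and post-processes the recorded frames into a
#' trial record: blob-centre trajectory, cluster-count time series and (for
#' the two-room arenas) the one-way-trip count. Identical seed and spec
#' give identical records.
#'
#' @param spec a [scenario_spec()] object.
#' @param params a [wb_params()] object.
#' @return object of class `wb_trial`: list with `scenario`, `seed`,
#'   `frames` (data.frame `step, id, x, y, theta, l, G, N`), `centers`
#'   (data.frame `time, x, y`), `cluster_counts` (data.frame
#'   `time, n_clusters, n_blobs`), `trips` (integer or `NA`),
#'   `final_agents`, `field_a`, `arena`.
#' @export
run_scenario <- function(spec, params = wb_params()) {
  stopifnot(inherits(spec, "wb_scenario"), inherits(params, "wb_params"))
  arena <- do.call(build_arena, c(list(kind = spec$kind),
                                  lapply(spec$arena_args, identity)))
  field <- make_field(arena, params, mustard = spec$mustard)
  set.seed(spec$seed)
  placement <- if (is.null(spec$placement)) default_placement(spec, arena)
               else spec$placement
  agents <- initial_agents(spec$n_agents, placement, params, arena = arena)
  res <- cpp_run(agents_to_matrix(agents), unclass(params), unclass(arena),
                 unclass(field), spec$n_steps, spec$record_stride, 0, 0L)
  frames <- as.data.frame(res$frames)
  steps <- res$recorded_steps
  centers <- matrix(NA_real_, length(steps), 2)
  ncl <- integer(length(steps)); nbl <- integer(length(steps))
  for (k in seq_along(steps)) {
    fr <- frames[frames$step == steps[k], , drop = FALSE]
    cl <- blob_clusters(fr, params)
    ncl[k] <- length(cl$clusters)
    nbl[k] <- cl$n_blobs
    centers[k, ] <- blob_center_from_clusters(fr, cl)
  }
  centers_df <- data.frame(time = steps * params$dt,
                           x = centers[, 1], y = centers[, 2])
  trips <- if (!is.null(arena$rooms))
    count_one_way_trips(centers_df, arena) else NA_integer_
  structure(list(scenario = spec$name, seed = spec$seed,
                 n_agents = spec$n_agents, n_steps = spec$n_steps,
                 record_stride = spec$record_stride,
                 frames = frames, centers = centers_df,
                 cluster_counts = data.frame(time = steps * params$dt,
                                             n_clusters = ncl,
                                             n_blobs = nbl),
                 trips = trips,
                 final_agents = as.data.frame(res$agents),
                 field_a = res$field_a, arena = arena),
            class = "wb_trial")
}

#' @export
print.wb_trial <- function(x, ...) {
  cat("<wb_trial> ", x$scenario, " | seed ", x$seed, " | ", x$n_agents,
      " agents x ", x$n_steps, " steps\n", sep = "")
  cat("  clusters: ", x$cluster_counts$n_clusters[1], " -> ",
      utils::tail(x$cluster_counts$n_clusters, 1), sep = "")
  if (!is.na(x$trips)) cat(" | one-way trips: ", x$trips, sep = "")
  cat("\n")
  invisible(x)
}
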