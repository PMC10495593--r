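#' Blob clustering of one frame
#'
#' Connected components of the inter-agent contact graph; a component is a
#' "blob" iff it has at least `blob_min_size` members.
#'
#' @param frame agent table (needs `x, y, theta, l`).
#' @param params a [wb_params()] object.
#' @param blob_min_size minimum component size to count as a blob.
#' @return list with `clusters` (list of member index vectors, largest
#'   first), `sizes`, `n_blobs` and `blob_min_size`.
#' @export
blob_clusters <- function(frame, params, blob_min_size = 5) {
  n <- nrow(frame)
  ct <- detect_contacts(frame, params)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(ct$edges) > 0)
    g <- igraph::add_edges(g, t(ct$edges))
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  clusters <- lapply(ord, function(k) which(comp$membership == k))
  list(clusters = clusters,
       sizes = comp$csize[ord],
       n_blobs = sum(comp$csize >= blob_min_size),
       blob_min_size = blob_min_size)
}

# centroid of all agents belonging to qualifying blobs (all agents as
# fallback). Using blob mass rather than the single largest cluster keeps
# the centre continuous when the collective transiently splits: a
# largest-cluster centroid teleports between rooms whenever two fragments
# trade rank, which fabricates one-way trips.
blob_center_from_clusters <- function(frame, cl) {
  keep <- cl$sizes >= cl$blob_min_size
  idx <- if (any(keep)) unlist(cl$clusters[keep]) else seq_len(nrow(frame))
  c(mean(frame$x[idx]), mean(frame$y[idx]))
}

#' Blob centre of one frame
#'
#' Centroid of all agents belonging to blobs (clusters of at least
#' `blob_min_size` members), falling back to all agents when no cluster
#' qualifies -- the agent-space analogue of the centre of mass of the
#' pixel area covered by blobs.
#'
#' @inheritParams blob_clusters
#' @return length-2 centre (m).
#' @export
blob_center <- function(frame, params, blob_min_size = 5) {
  if (nrow(frame) < 1) stop("empty frame")
  blob_center_from_clusters(frame, blob_clusters(frame, params, blob_min_size))
}

#' Count one-way trips of a centre trajectory
#'
#' Finite-state counter over a two-room arena: the state starts at the room
#' containing the first decisive sample; a trip is counted each time the
#' centre enters the *opposite* room's core region -- a disc of radius
#' `core_frac` x room half-width around the room centre. Passage samples
#' never change the state, and entering the opposite room without reaching
#' its core does not count (hysteresis against jitter at the passage
#' mouth).
#'
#' @param centers data.frame or matrix with columns `x, y`.
#' @param env a [build_arena()] object with room metadata.
#' @param core_frac core-disc radius as a fraction of the room half-width
#'   (the default 0.5 reproduces the standard core radius).
#' @return integer trip count.
#' @export
count_one_way_trips <- function(centers, env, core_frac = 0.5) {
  stopifnot(inherits(env, "wb_arena"))
  if (is.null(env$rooms)) stop("rooms undefined for arena kind ", env$kind)
  xs <- if (is.data.frame(centers)) centers$x else centers[, 1]
  ys <- if (is.data.frame(centers)) centers$y else centers[, 2]
  ctr <- env$rooms$centers
  core_r <- core_frac / 0.5 * env$rooms$core_radius
  in_core <- function(x, y, room)
    (x - ctr[room, 1])^2 + (y - ctr[room, 2])^2 <= core_r^2
  state <- NA_integer_   # 1 = left, 2 = right
  trips <- 0L
  for (k in seq_along(xs)) {
    if (is.na(state)) {
      rm <- room_of(env, c(xs[k], ys[k]))
      if (rm == "left") state <- 1L
      if (rm == "right") state <- 2L
      next
    }
    opp <- 3L - state
    if (in_core(xs[k], ys[k], opp)) {
      trips <- trips + 1L
      state <- opp
    }
  }
  trips
}

#' Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum comparison with midrank tie handling. For small
#' samples (both below 8) the p-value is computed by exact enumeration of
#' all group assignments of the pooled observations; otherwise by the
#' tie-corrected normal approximation with continuity correction. The
#' reported `U` follows the min-U convention (complete separation gives
#' `U = 0`); `U1` counts wins of the first sample.
#'
#' @param counts_a,counts_b numeric vectors (nonempty).
#' @param alternative `"two.sided"`, `"greater"` (first sample tends
#'   larger) or `"less"`.
#' @return list with `U`, `U1`, `p_value`, `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12))$U   # 0
#' @export
rank_sum_test <- function(counts_a, counts_b,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(counts_a); b <- as.numeric(counts_b)
  if (length(a) < 1 || length(b) < 1) stop("both samples must be nonempty")
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  u1_of <- function(idx_a) {
    ra <- rank(pooled)[idx_a]
    sum(ra) - m * (m + 1) / 2
  }
  U1 <- u1_of(seq_len(m))
  U <- min(U1, m * n - U1)
  if (m < 8 && n < 8) {
    splits <- utils::combn(m + n, m)
    r_all <- rank(pooled)
    u_perm <- apply(splits, 2, function(idx) sum(r_all[idx]) - m * (m + 1) / 2)
    mu <- m * n / 2
    p <- switch(alternative,
      two.sided = mean(abs(u_perm - mu) >= abs(U1 - mu) - 1e-12),
      greater = mean(u_perm >= U1 - 1e-12),
      less = mean(u_perm <= U1 + 1e-12))
    method <- "exact enumeration"
  } else {
    N <- m + n
    ties <- table(pooled)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    mu <- m * n / 2
    cc <- 0.5
    z <- switch(alternative,
      two.sided = (U1 - mu - sign(U1 - mu) * cc) / sqrt(sigma2),
      greater = (U1 - mu - cc) / sqrt(sigma2),
      less = (U1 - mu + cc) / sqrt(sigma2))
    if (sigma2 == 0) z <- 0
    p <- switch(alternative,
      two.sided = min(1, 2 * stats::pnorm(-abs(z))),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z))
    method <- "normal approximation with tie correction"
  }
  list(U = U, U1 = U1, p_value = p, method = method)
}

#' Batch experiment over arena conditions
#'
#' Runs `n_trials` seeded trials for each condition, collects one-way-trip
#' counts, builds integer-bin histograms and computes rank-sum tests
#' between the configured condition pairs. Trial k of every condition uses
#' seed `base_seed + 7919 (k - 1)` so conditions are compared across a
#' common seed ladder.
#'
#' @param conditions character vector of scenario names (two-room arenas).
#' @param n_trials trials per condition.
#' @param base_seed base RNG seed.
#' @param params a [wb_params()] object.
#' @param n_agents,n_steps,record_stride scenario overrides applied to all
#'   conditions.
#' @param pairs list of length-2 character vectors naming condition pairs
#'   to test; defaults to (oval, dumbbell) and (dumbbell, dumbbell_pegs)
#'   where present.
#' @param alternative sidedness passed to [rank_sum_test()].
#' @return object of class `wb_experiment`: list with `trips` (named list
#'   of per-trial counts), `summary` (data.frame `condition, seed, trips`),
#'   `histograms`, `tests`.
#' @export
run_experiment <- function(conditions = c("oval", "dumbbell",
                                          "dumbbell_pegs"),
                           n_trials, base_seed = 1L, params = wb_params(),
                           n_agents = NULL, n_steps = NULL,
                           record_stride = 500L, pairs = NULL,
                           alternative = "two.sided") {
  if (n_trials < 1) stop("n_trials must be >= 1")
  trips <- stats::setNames(vector("list", length(conditions)), conditions)
  rows <- list()
  for (cond in conditions) {
    tc <- integer(n_trials)
    for (k in seq_len(n_trials)) {
      sd <- base_seed + 7919L * (k - 1L)
      spec <- scenario_spec(cond, seed = sd, n_agents = n_agents,
                            n_steps = n_steps,
                            record_stride = record_stride)
      tr <- run_scenario(spec, params)
      tc[k] <- tr$trips
      rows[[length(rows) + 1L]] <- data.frame(condition = cond, seed = sd,
                                              trips = tr$trips)
    }
    trips[[cond]] <- tc
  }
  maxt <- max(unlist(trips), 0)
  hist_list <- lapply(trips, function(tc)
    table(factor(tc, levels = 0:max(maxt, 1))))
  if (is.null(pairs)) {
    pairs <- list(c("oval", "dumbbell"), c("dumbbell", "dumbbell_pegs"))
    pairs <- Filter(function(p) all(p %in% conditions), pairs)
  }
  tests <- lapply(pairs, function(p) {
    tst <- rank_sum_test(trips[[p[1]]], trips[[p[2]]],
                         alternative = alternative)
    c(list(pair = paste(p, collapse = " vs ")), tst)
  })
  structure(list(trips = trips,
                 summary = do.call(rbind, rows),
                 histograms = hist_list,
                 tests = tests,
                 n_trials = n_trials, base_seed = base_seed),
            class = "wb_experiment")
}

#' @export
print.wb_experiment <- function(x, ...) {
  cat("<wb_experiment> ", x$n_trials, " trials per condition\n", sep = "")
  for (cond in names(x$trips))
    cat(sprintf("  %-14s median trips %.1f  (range %d-%d)\n", cond,
                stats::median(x$trips[[cond]]), min(x$trips[[cond]]),
                max(x$trips[[cond]])))
  for (tst in x$tests)
    cat(sprintf("  %s: U = %.1f, p = %.3g\n", tst$pair, tst$U, tst$p_value))
  invisible(x)
}
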