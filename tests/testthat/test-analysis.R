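p0 <- wb_params()

frame_at <- function(xy, theta = 0, l = p0$a) {
  data.frame(x = xy[, 1], y = xy[, 2], theta = theta, l = l)
}

test_that("blob clustering finds connected components of the contact graph", {
  # all pairwise distant: singletons, no blobs
  far <- frame_at(cbind(seq(0, 1, length.out = 8), 0))
  cl <- blob_clusters(far, p0)
  expect_equal(length(cl$clusters), 8)
  expect_equal(cl$n_blobs, 0)

  # all on one point: a single blob of size n
  one <- frame_at(matrix(0, 10, 2))
  cl1 <- blob_clusters(one, p0)
  expect_equal(length(cl1$clusters), 1)
  expect_equal(cl1$sizes, 10)
  expect_equal(cl1$n_blobs, 1)

  # two well-separated dense discs of 20 agents each: two blobs
  set.seed(77)
  mk_disc <- function(cx) cbind(cx + runif(20, -2e-3, 2e-3),
                                runif(20, -2e-3, 2e-3))
  two <- frame_at(rbind(mk_disc(-0.1), mk_disc(0.1)))
  cl2 <- blob_clusters(two, p0)
  expect_equal(cl2$n_blobs, 2)
  expect_equal(sort(cl2$sizes[1:2]), c(20, 20))
})

test_that("blob centre is the dominant-cluster centroid", {
  expect_equal(blob_center(frame_at(rbind(c(0.3, -0.2))), p0), c(0.3, -0.2))
  pair <- frame_at(rbind(c(-1e-3, 0), c(1e-3, 0)))
  expect_equal(blob_center(pair, p0), c(0, 0))
  tri <- frame_at(rbind(c(0, 0), c(2e-3, 0), c(0, 2e-3)))
  expect_equal(blob_center(tri, p0), c(2e-3 / 3, 2e-3 / 3))
  # big cluster dominates; a far singleton is ignored
  set.seed(5)
  big <- cbind(runif(10, -1e-3, 1e-3), runif(10, -1e-3, 1e-3))
  mix <- frame_at(rbind(big, c(0.5, 0.5)))
  expect_equal(blob_center(mix, p0), c(mean(big[, 1]), mean(big[, 2])))
  empty <- data.frame(x = numeric(0), y = numeric(0), theta = numeric(0),
                      l = numeric(0))
  expect_error(blob_center(empty, p0), "empty")
})

test_that("one-way trips follow the core-entry state machine", {
  db <- build_arena("dumbbell")
  L <- db$rooms$centers[1, ]
  R <- db$rooms$centers[2, ]
  constant <- data.frame(x = rep(L[1], 20), y = rep(L[2], 20))
  expect_equal(count_one_way_trips(constant, db), 0L)

  # left core -> right core -> left core: 2 trips
  path <- data.frame(x = c(L[1], -0.007, 0, 0.007, R[1], 0.007, 0, -0.007, L[1]),
                     y = 0)
  expect_equal(count_one_way_trips(path, db), 2L)

  # reaches the passage and retreats: hysteresis, 0 trips
  retreat <- data.frame(x = c(L[1], -0.006, 0, -0.006, L[1]), y = 0)
  expect_equal(count_one_way_trips(retreat, db), 0L)

  # entering the far room but not its core does not count
  shy <- data.frame(x = c(L[1], 0, 0.007, 0, L[1]), y = 0)
  expect_equal(count_one_way_trips(shy, db), 0L)

  expect_error(count_one_way_trips(constant, build_arena("square")),
               "rooms undefined")
})

test_that("trip count is invariant to oversampling and x-reflection", {
  db <- build_arena("dumbbell")
  xs <- c(-0.015, -0.008, -0.002, 0.004, 0.015, 0.006, -0.001, -0.015)
  path <- data.frame(x = xs, y = 0)
  base <- count_one_way_trips(path, db)
  expect_equal(base, 2L)
  # insert linear interpolants between consecutive samples
  dense <- data.frame(
    x = unlist(lapply(seq_len(length(xs) - 1), function(i)
      seq(xs[i], xs[i + 1], length.out = 21)[-21])),
    y = 0)
  dense <- rbind(dense, data.frame(x = xs[length(xs)], y = 0))
  expect_equal(count_one_way_trips(dense, db), base)
  # mirror the trajectory about x = 0 (the arena is symmetric)
  expect_equal(count_one_way_trips(transform(path, x = -x), db), base)
})

test_that("rank-sum test handles separation, identity and ties", {
  sep <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_value, 2 * 1 / choose(6, 3))   # exact two-sided

  same <- rank_sum_test(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$p_value, 1)

  one_sided <- rank_sum_test(c(10, 11, 12), c(1, 2, 3),
                             alternative = "greater")
  expect_equal(one_sided$p_value, 1 / choose(6, 3))
})

test_that("large-sample p-values match the reference implementation", {
  set.seed(202)
  for (k in 1:100) {
    m <- sample(8:20, 1); n <- sample(8:20, 1)
    a <- sample(0:8, m, replace = TRUE)
    b <- sample(0:10, n, replace = TRUE)
    got <- rank_sum_test(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$U1, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    g1 <- rank_sum_test(a, b, alternative = "greater")
    r1 <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE,
                                              alternative = "greater"))
    expect_equal(g1$p_value, r1$p.value, tolerance = 1e-10)
  }
})

test_that("experiments collect per-trial trips and histograms", {
  ex <- run_experiment(conditions = c("oval", "dumbbell"), n_trials = 2,
                       base_seed = 3, params = p0, n_agents = 12,
                       n_steps = 300, record_stride = 100)
  expect_equal(names(ex$trips), c("oval", "dumbbell"))
  expect_length(ex$trips$oval, 2)
  expect_equal(nrow(ex$summary), 4)
  expect_true(all(vapply(ex$histograms, sum, numeric(1)) == 2))
  expect_length(ex$tests, 1)
  expect_equal(ex$tests[[1]]$pair, "oval vs dumbbell")
  # trial k shares its seed across conditions
  expect_equal(ex$summary$seed[ex$summary$condition == "oval"],
               ex$summary$seed[ex$summary$condition == "dumbbell"])
})
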