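p0 <- wb_params()

test_that("cross segments realize the four-armed geometry", {
  seg <- cross_segments(list(x = 0, y = 0, theta = 0, l = 0.0525), 0.0025)
  expect_equal(unname(seg["head", c("x2", "y2")]), c(0.0525, 0))
  expect_equal(unname(seg["tail", c("x2", "y2")]), c(-0.0025, 0))
  expect_true(all(seg[, "x1"] == 0 & seg[, "y1"] == 0))

  segr <- cross_segments(list(x = 1, y = 2, theta = pi / 2, l = 0.03), 0.0025)
  expect_equal(unname(segr["head", c("x2", "y2")]), c(1, 2.03))

  # fully coiled: all four arms have length a
  segc <- cross_segments(list(x = 0, y = 0, theta = 0.3, l = 0.0025), 0.0025)
  lens <- sqrt((segc[, "x2"] - segc[, "x1"])^2 +
               (segc[, "y2"] - segc[, "y1"])^2)
  expect_equal(unname(lens), rep(0.0025, 4))

  expect_error(cross_segments(list(x = 0, y = 0, theta = 0, l = 1e-3),
                              0.0025), "l must be >=")
})

test_that("contact graph matches the brute-force oracle on random states", {
  for (seed in 1:5) {
    set.seed(seed)
    ag <- random_agents(50, p0, span = 0.008)
    got <- detect_contacts(ag, p0)
    ref <- oracle_contact_graph(ag, p0$d_contact)
    expect_equal(got$N, ref$N)
    if (!is.null(ref$edges)) {
      o1 <- got$edges[order(got$edges[, 1], got$edges[, 2]), , drop = FALSE]
      o2 <- ref$edges[order(ref$edges[, 1], ref$edges[, 2]), , drop = FALSE]
      expect_equal(unname(o1), unname(o2))
    } else {
      expect_equal(nrow(got$edges), 0)
    }
  }
})

test_that("contact relation is symmetric, irreflexive and boundary-inclusive", {
  set.seed(11)
  ag <- random_agents(40, p0, span = 0.006)
  ct <- detect_contacts(ag, p0)
  expect_true(all(ct$edges[, 1] < ct$edges[, 2]))   # unordered, no self
  expect_equal(sum(ct$N), 2 * nrow(ct$edges))       # each edge counts twice

  # far pair / coincident pair / exact-threshold pair
  far <- data.frame(x = c(0, 1), y = 0, vx = 0, vy = 0, theta = 0,
                    l = p0$a, zeta = 0, t_refresh = 0)
  expect_equal(detect_contacts(far, p0)$N, c(0, 0))
  same <- far; same$x <- c(0, 0)
  expect_equal(detect_contacts(same, p0)$N, c(1, 1))
  onb <- far; onb$x <- c(0, p0$d_contact)
  expect_equal(detect_contacts(onb, p0)$N, c(1, 1))
})

test_that("a chain with consecutive-only contacts counts N = (1, 2, 1)", {
  d <- 0.9 * p0$d_contact
  chain <- data.frame(x = c(0, d, 2 * d), y = 0, vx = 0, vy = 0,
                      theta = c(0, 1, 2), l = p0$a, zeta = 0, t_refresh = 0)
  got <- detect_contacts(chain, p0)
  expect_equal(got$N, c(1L, 2L, 1L))
  expect_equal(oracle_contact_graph(chain, p0$d_contact)$N, c(1L, 2L, 1L))
})

test_that("peg contacts follow the segment-to-centre rule", {
  ar <- build_arena("dumbbell_pegs")
  peg <- ar$pegs[1, ]
  # head endpoint exactly at the peg centre
  ag <- data.frame(x = peg[1] - 0.01, y = peg[2], vx = 0, vy = 0,
                   theta = 0, l = 0.01, zeta = 0, t_refresh = 0)
  hit <- detect_peg_contacts(ag, ar, p0)
  expect_true(1 %in% hit[[1]])
  # everything farther than l_a + r_c + d_contact: no contact
  ag2 <- ag; ag2$x <- peg[1] - (p0$l_a + ar$peg_r + p0$d_touch + 1e-3)
  ag2$l <- p0$a
  expect_length(detect_peg_contacts(ag2, ar, p0)[[1]], 0)
  # grazing a lateral arm at exactly r_c + d_contact (boundary inclusive)
  ag3 <- data.frame(x = peg[1], y = peg[2] - (ar$peg_r + p0$d_touch),
                    vx = 0, vy = 0, theta = pi / 2, l = p0$a,
                    zeta = 0, t_refresh = 0)
  # lateral arm runs along x through the centre; peg centre is offset in y
  expect_true(1 %in% detect_peg_contacts(ag3, ar, p0)[[1]])
})

test_that("wall contact record captures penetration and head hits", {
  sq <- build_arena("square", side = 0.183)
  inside <- list(x = 0, y = 0, theta = 0, l = 0.02)
  rec <- detect_wall_contact(inside, sq, p0)
  expect_equal(rec$penetration, 0)
  expect_false(rec$contact)
  expect_false(rec$head_hit)
  expect_equal(rec$clamp_length, 0.02)

  outside <- list(x = 0.0925, y = 0, theta = 0, l = p0$a)
  rec2 <- detect_wall_contact(outside, sq, p0)
  expect_equal(rec2$penetration, 0.001, tolerance = 1e-12)
  expect_true(rec2$contact)

  # heading straight into the wall from 0.01 m away with l = 0.02
  head_on <- list(x = 0.0815, y = 0, theta = 0, l = 0.02)
  rec3 <- detect_wall_contact(head_on, sq, p0)
  expect_true(rec3$head_hit)
  expect_equal(rec3$clamp_length, 0.01, tolerance = 1e-12)
  expect_gte(rec3$clamp_length, p0$a)

  # open arena: no record
  expect_null(detect_wall_contact(inside, build_arena("open"), p0))
})

test_that("clamp length always lies in [a, l]", {
  sq <- build_arena("square", side = 0.02)
  set.seed(3)
  for (k in 1:50) {
    ag <- list(x = runif(1, -0.011, 0.011), y = runif(1, -0.011, 0.011),
               theta = runif(1, -pi, pi), l = runif(1, p0$a, p0$l_a))
    rec <- detect_wall_contact(ag, sq, p0)
    cl <- clamp_head(ag, rec, p0)
    expect_gte(cl, p0$a)
    expect_lte(cl, ag$l)
  }
})
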