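p0 <- wb_params()

test_that("target length shortens with crowding and floors at a", {
  expect_equal(target_length(0, p0), 0.05250)
  expect_equal(target_length(10, p0), 0.0275)
  expect_equal(target_length(20, p0), 0.0025)   # (l_a - a)/l_b = 20
  expect_equal(target_length(50, p0), 0.0025)
  expect_equal(target_length(0:100, p0), pmax(0.0525 - 0.0025 * 0:100, 0.0025))
})

test_that("saturation is the clamped linear ramp", {
  expect_equal(saturation(0), 0.5)
  expect_equal(saturation(2), 1)
  expect_equal(saturation(1), 1)
  expect_equal(saturation(-1), 0)
  expect_equal(saturation(-5), 0)
  expect_equal(saturation(0.5), 0.75)
})

test_that("activity combines stimulus drive and crowding suppression", {
  expect_equal(activity(0, 0, p0), 0.5)
  expect_equal(activity(0, 20, p0), 0)          # beta * 20 = 1
  expect_equal(activity(1, 0, p0), 1)           # alpha * 1 = 1.2 > 1
  expect_equal(activity(0.5, 10, p0), saturation(1.2 * 0.5 - 0.5))
})

test_that("propulsion scales with activity and length, along the heading", {
  expect_equal(propulsion_force(0, 0.03, 1.1, p0), c(0, 0))
  f <- propulsion_force(0.5, 0.0525, 0, p0)
  expect_equal(f, c(p0$speed_scale * p0$eta * 0.5 * 0.0525, 0))
  # rotational equivariance
  phi <- 0.7
  f0 <- propulsion_force(0.8, 0.04, 0.3, p0)
  f1 <- propulsion_force(0.8, 0.04, 0.3 + phi, p0)
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  expect_equal(as.numeric(R %*% f0), f1, tolerance = 1e-14)
})

test_that("pair force balances at the equilibrium separation", {
  deq <- p0$r0 * p0$rho2    # 0.0019 m for the default exponents
  mk <- function(x, vx = 0) list(x = x, y = 0, vx = vx, vy = 0)
  f <- pair_force(mk(0), mk(deq), p0)
  expect_equal(f, c(0, 0), tolerance = 1e-18)
  # inside equilibrium: repulsion (force on i points away from j)
  f_in <- pair_force(mk(0), mk(0.8 * deq), p0)
  expect_lt(f_in[1], 0)
  # outside: attraction
  f_out <- pair_force(mk(0), mk(0.005), p0)
  expect_gt(f_out[1], 0)
  # viscous part follows the velocity difference
  fv <- pair_force(mk(0, vx = 0), mk(deq, vx = 2e-5), p0)
  expect_equal(fv, c(p0$q1 * 2e-5, 0), tolerance = 1e-10)
})

test_that("pair force is antisymmetric and capped near coincidence", {
  set.seed(2)
  for (k in 1:20) {
    ai <- list(x = runif(1), y = runif(1), vx = runif(1, -1e-4, 1e-4),
               vy = runif(1, -1e-4, 1e-4))
    aj <- list(x = ai$x + runif(1, -5e-3, 5e-3),
               y = ai$y + runif(1, -5e-3, 5e-3),
               vx = runif(1, -1e-4, 1e-4), vy = runif(1, -1e-4, 1e-4))
    expect_equal(pair_force(ai, aj, p0), -pair_force(aj, ai, p0),
                 tolerance = 1e-16)
  }
  # below the 0.1 r0 floor the radial magnitude stops growing
  mk <- function(x) list(x = x, y = 0, vx = 0, vy = 0)
  f_floor <- pair_force(mk(0), mk(0.1 * p0$r0), p0)
  f_below <- pair_force(mk(0), mk(0.01 * p0$r0), p0)
  expect_equal(abs(f_below[1]), abs(f_floor[1]), tolerance = 1e-12)
  # coincident centres: no radial direction, zero force at rest
  expect_equal(pair_force(mk(0), mk(0), p0), c(0, 0))
})

test_that("nematic torque has the stated zeros and magnitude", {
  mk <- function(theta, l) list(theta = theta, l = l)
  expect_equal(nematic_torque(mk(0.3, 0.03), mk(0.3, 0.03), 1, p0), 0)
  expect_equal(nematic_torque(mk(0.3, 0.03), mk(0.3 + pi, 0.03), 1, p0), 0,
               tolerance = 1e-15)
  expect_equal(nematic_torque(mk(0, p0$a), mk(1, 0.03), 1, p0), 0)
  expect_equal(nematic_torque(mk(0.2, 0.03), mk(0.9, 0.03), 0, p0), 0)
  # full activity, fully elongated, relative angle pi/4
  w <- nematic_torque(mk(0, 0.0525), mk(pi / 4, 0.0525), 1, p0)
  expect_equal(w, 53.3 * 0.05^2, tolerance = 1e-12)   # 0.13325 rad/s
})

test_that("random torque is bounded and refreshes on schedule", {
  ag <- list(zeta = 0.7, t_refresh = 100)
  out <- random_torque(ag, 50, p0)
  expect_equal(out$torque, p0$d_R * 0.7)
  expect_equal(out$zeta, 0.7)
  pz <- wb_params(list(d_R = 0))
  expect_equal(random_torque(ag, 50, pz)$torque, 0)
  # refresh: new zeta in [-1, 1], new deadline in (t, t + t_max]
  set.seed(6)
  out2 <- random_torque(ag, 150, p0)
  expect_true(abs(out2$zeta) <= 1)
  expect_true(out2$t_refresh > 150 + p0$t_min &&
              out2$t_refresh <= 150 + p0$t_max)
  expect_lte(abs(out2$torque), p0$d_R)
})

test_that("refresh intervals are uniform on [t_min, t_max]", {
  set.seed(99)
  ag <- list(zeta = 0, t_refresh = 0)
  t <- 0
  gaps <- numeric(600)
  for (k in seq_along(gaps)) {
    out <- random_torque(ag, t, p0)
    gaps[k] <- out$t_refresh - t
    t <- out$t_refresh
    ag <- out
  }
  ks <- suppressWarnings(stats::ks.test(gaps, "punif", p0$t_min, p0$t_max))
  expect_gt(ks$p.value, 0.01)
})

test_that("chemotactic torque turns the heading down-gradient", {
  expect_equal(chemo_torque(pi, c(1, 0), 0.5, p0), 0, tolerance = 1e-15)
  expect_equal(chemo_torque(0.3, NULL, 0.5, p0), 0)
  expect_equal(chemo_torque(0.3, c(0, 0), 0.5, p0), 0)
  expect_equal(chemo_torque(0.3, c(1, 0), 0, p0), 0)
  # gradient along +x, heading +y: positive torque rotates toward -x
  w <- chemo_torque(pi / 2, c(1, 0), 0.6, p0)
  expect_equal(w, p0$d_C * 0.6 * sin(pi - pi / 2))
  expect_gt(w, 0)
  # 2 pi periodicity in the relative angle
  expect_equal(chemo_torque(0.2, c(cos(1), sin(1)), 1, p0),
               chemo_torque(0.2 + 2 * pi, c(cos(1), sin(1)), 1, p0),
               tolerance = 1e-12)
})

test_that("peg force keeps only viscous drag when coiled", {
  ag <- list(x = 0, y = 0, vx = 3e-5, vy = -1e-5, l = p0$a)
  f <- peg_force(ag, c(0.002, 0), p0)
  expect_equal(f, -p0$q2 * c(3e-5, -1e-5))
  # static elongated agent at the shared equilibrium root: zero force
  ag2 <- list(x = 0, y = 0, vx = 0, vy = 0, l = 0.03)
  expect_equal(peg_force(ag2, c(p0$r0 * p0$rho2, 0), p0), c(0, 0),
               tolerance = 1e-18)
  # beyond equilibrium: pulled toward the peg
  f3 <- peg_force(ag2, c(0.005, 0), p0)
  expect_gt(f3[1], 0)
})

test_that("wall force is a spring on the penetration depth", {
  sq <- build_arena("square", side = 0.183)
  inside <- list(x = 0.05, y = 0, theta = 0, l = p0$a)
  expect_equal(wall_force(inside, detect_wall_contact(inside, sq, p0), p0),
               c(0, 0))
  out <- list(x = 0.0915 + 0.002, y = 0, theta = 0, l = p0$a)
  f <- wall_force(out, detect_wall_contact(out, sq, p0), p0)
  expect_equal(f, c(-p0$k_W * 0.002, 0), tolerance = 1e-12)
  expect_equal(wall_force(inside, NULL, p0), c(0, 0))
})

test_that("peg and wall alignment torques are nematic in the angle", {
  expect_equal(peg_align_torque(0.4, 0.4, p0), 0)
  expect_equal(peg_align_torque(0, pi / 4, p0), p0$d_P)
  expect_equal(peg_align_torque(0, pi / 2, p0), 0, tolerance = 1e-15)
  expect_equal(wall_align_torque(0, pi / 4, p0), p0$d_W)
  expect_equal(wall_align_torque(0.1, 0.1 + pi, p0), 0, tolerance = 1e-12)
  # pi-periodicity
  th <- seq(-3, 3, by = 0.37)
  expect_equal(peg_align_torque(th, th * 0 + 1, p0),
               peg_align_torque(th + pi, th * 0 + 1, p0), tolerance = 1e-12)
})

test_that("head clamp shortens only on a head hit and floors at a", {
  ag <- list(l = 0.02)
  expect_equal(clamp_head(ag, NULL, p0), 0.02)
  rec <- list(head_hit = TRUE, clamp_length = 0.01)
  expect_equal(clamp_head(ag, rec, p0), 0.01)
  rec2 <- list(head_hit = TRUE, clamp_length = 1e-4)
  expect_equal(clamp_head(ag, rec2, p0), p0$a)
  rec3 <- list(head_hit = FALSE, clamp_length = 0.001)
  expect_equal(clamp_head(ag, rec3, p0), 0.02)
})

test_that("summed pair forces cancel over all ordered contacting pairs", {
  set.seed(31)
  for (rep in 1:5) {
    ag <- random_agents(30, p0, span = 0.005)
    ct <- detect_contacts(ag, p0)
    tot <- c(0, 0)
    for (e in seq_len(nrow(ct$edges))) {
      i <- ct$edges[e, 1]; j <- ct$edges[e, 2]
      tot <- tot + pair_force(ag[i, ], ag[j, ], p0) +
        pair_force(ag[j, ], ag[i, ], p0)
    }
    expect_equal(tot, c(0, 0), tolerance = 1e-18)
  }
})
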