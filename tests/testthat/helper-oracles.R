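# Independent reference implementations used as oracles. These are written
# from the definitions, deliberately naive (O(n^2) loops, direct formulas),
# and share no code with the production paths they check.

# brute-force contact graph: centre-centre distance <= d_contact
oracle_contact_graph <- function(agents, d_contact) {
  n <- nrow(agents)
  N <- integer(n)
  edges <- NULL
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt((agents$x[i] - agents$x[j])^2 +
                  (agents$y[i] - agents$y[j])^2)
        if (d <= d_contact) {
          edges <- rbind(edges, c(i, j))
          N[i] <- N[i] + 1L
          N[j] <- N[j] + 1L
        }
      }
    }
  }
  list(edges = edges, N = N)
}

# reference field step: decay + grid-native 5-point Laplacian with mirror
# (zero-flux) boundaries at grid edges and mask walls, then deposits
oracle_field_step <- function(a, mask, pos, x0, y0, dx, k0, k1, DA, dt) {
  nx <- nrow(a); ny <- ncol(a)
  out <- a
  for (ix in 1:nx) {
    for (iy in 1:ny) {
      if (!mask[ix, iy]) next
      c0 <- a[ix, iy]
      nb <- function(i, j) if (i >= 1 && i <= nx && j >= 1 && j <= ny &&
                                mask[i, j]) a[i, j] else c0
      lap <- nb(ix + 1, iy) + nb(ix - 1, iy) + nb(ix, iy + 1) +
             nb(ix, iy - 1) - 4 * c0
      out[ix, iy] <- c0 + dt * (-k0 * c0 + DA * lap)
    }
  }
  if (nrow(pos) > 0) {
    for (k in seq_len(nrow(pos))) {
      ix <- floor((pos[k, 1] - x0) / dx) + 1
      iy <- floor((pos[k, 2] - y0) / dx) + 1
      if (ix >= 1 && ix <= nx && iy >= 1 && iy <= ny)
        out[ix, iy] <- out[ix, iy] + k1 * dt
    }
  }
  out
}

# winding-number point-in-polygon (different algorithm from the ray caster)
oracle_in_poly <- function(poly, px, py) {
  n <- nrow(poly)
  wn <- 0
  for (i in 1:n) {
    j <- if (i == n) 1 else i + 1
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    if (y1 <= py) {
      if (y2 > py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) > 0)
        wn <- wn + 1
    } else {
      if (y2 <= py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) < 0)
        wn <- wn - 1
    }
  }
  wn != 0
}

# bilinear interpolation of a cell-centred grid + interpolated
# central-difference gradient, straight from the definition
oracle_sample <- function(a, x0, y0, dx, p) {
  nx <- nrow(a); ny <- ncol(a)
  u <- (p[1] - x0) / dx - 0.5
  v <- (p[2] - y0) / dx - 0.5
  ix <- min(max(floor(u), 0), nx - 2)
  iy <- min(max(floor(v), 0), ny - 2)
  fx <- min(max(u - ix, 0), 1)
  fy <- min(max(v - iy, 0), 1)
  val <- function(i, j) a[i + 1, j + 1]
  ndg <- function(i, j) {
    gx <- if (i > 0 && i < nx - 1) (val(i + 1, j) - val(i - 1, j)) / (2 * dx)
          else if (i == 0) (val(1, j) - val(0, j)) / dx
          else (val(nx - 1, j) - val(nx - 2, j)) / dx
    gy <- if (j > 0 && j < ny - 1) (val(i, j + 1) - val(i, j - 1)) / (2 * dx)
          else if (j == 0) (val(i, 1) - val(i, 0)) / dx
          else (val(i, ny - 1) - val(i, ny - 2)) / dx
    c(gx, gy)
  }
  bl <- function(f00, f10, f01, f11)
    (1 - fx) * (1 - fy) * f00 + fx * (1 - fy) * f10 +
    (1 - fx) * fy * f01 + fx * fy * f11
  A <- bl(val(ix, iy), val(ix + 1, iy), val(ix, iy + 1), val(ix + 1, iy + 1))
  g <- bl(ndg(ix, iy)[1], ndg(ix + 1, iy)[1], ndg(ix, iy + 1)[1],
          ndg(ix + 1, iy + 1)[1])
  g2 <- bl(ndg(ix, iy)[2], ndg(ix + 1, iy)[2], ndg(ix, iy + 1)[2],
           ndg(ix + 1, iy + 1)[2])
  list(A = A, grad = c(g, g2))
}

# random agent table spanning a region, with velocities and lengths
random_agents <- function(n, params, span = 0.02, vmax = 1e-4) {
  data.frame(
    x = stats::runif(n, -span, span), y = stats::runif(n, -span, span),
    vx = stats::runif(n, -vmax, vmax), vy = stats::runif(n, -vmax, vmax),
    theta = stats::runif(n, -pi, pi),
    l = stats::runif(n, params$a, params$l_a),
    zeta = stats::runif(n, -1, 1),
    t_refresh = stats::runif(n, 100, 200))
}

scaled_tol <- function(ref, rel = 1e-12) {
  rel * max(abs(ref), 1e-300)
}

# naive point-to-segment distance
oracle_pt_seg <- function(p, a, b) {
  ab <- b - a
  t <- if (sum(ab^2) == 0) 0 else
    min(1, max(0, sum((p - a) * ab) / sum(ab^2)))
  sqrt(sum((a + t * ab - p)^2))
}

# peg contacts from the definition: any arm within r_c + d_contact of the
# peg centre
oracle_peg_contacts <- function(agents, arena, params) {
  lapply(seq_len(nrow(agents)), function(i) {
    segs <- cross_segments(agents[i, ], params$a)
    hits <- integer(0)
    for (q in seq_len(nrow(arena$pegs))) {
      dmin <- min(vapply(1:4, function(k)
        oracle_pt_seg(arena$pegs[q, ], segs[k, 1:2], segs[k, 3:4]),
        numeric(1)))
      if (dmin <= arena$peg_r + params$d_touch) hits <- c(hits, q)
    }
    hits
  })
}
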