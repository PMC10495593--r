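#' Cross geometry of one agent
#'
#' The four body segments of a cross-shaped agent, all sharing the axis
#' intersection point: the variable head arm of length `l` along the
#' heading, the fixed tail arm of length `a` opposite it, and the two
#' lateral arms of length `a` perpendicular to the heading.
#'
#' @param agent list or one-row data.frame with `x, y, theta, l`.
#' @param a minor/fixed arm length (m).
#' @return 4 x 4 matrix with rows `head, tail, left, right` and columns
#'   `x1, y1, x2, y2`; each segment starts at the intersection point.
#' @examples
#' seg <- cross_segments(list(x = 0, y = 0, theta = 0, l = 0.0525), 0.0025)
#' seg["head", c("x2", "y2")]   # (0.0525, 0)
#' @export
cross_segments <- function(agent, a) {
  ag <- as.list(agent)
  if (ag$l < a) stop("head length l must be >= a")
  ct <- cos(ag$theta); st <- sin(ag$theta)
  ends <- rbind(head  = c(ag$x + ag$l * ct, ag$y + ag$l * st),
                tail  = c(ag$x - a * ct, ag$y - a * st),
                left  = c(ag$x - a * st, ag$y + a * ct),
                right = c(ag$x + a * st, ag$y - a * ct))
  out <- cbind(x1 = rep(ag$x, 4), y1 = rep(ag$y, 4),
               x2 = ends[, 1], y2 = ends[, 2])
  rownames(out) <- rownames(ends)
  out
}

# coerce an agent data.frame to the 8-column state matrix the C++ kernels
# expect, filling columns a recorded frame does not carry with zeros
agents_to_matrix <- function(agents) {
  n <- nrow(agents)
  cols <- c("x", "y", "vx", "vy", "theta", "l", "zeta", "t_refresh")
  m <- matrix(0, n, 8, dimnames = list(NULL, cols))
  for (cl in cols) if (cl %in% names(agents)) m[, cl] <- agents[[cl]]
  m
}

#' Inter-agent contact graph
#'
#' Two agents are in contact iff their axis-intersection points (body
#' cores) are within `d_contact` of each other (inclusive). The contact
#' radius represents the body-core overlap through which worms entangle
#' and exchange forces; see the vignette for why core distance, rather
#' than arm proximity, is the counted criterion. Detection uses a uniform
#' spatial hash, so cost is near-linear for dilute configurations.
#'
#' @param agents data.frame of agent states (needs `x, y`).
#' @param params a [wb_params()] object.
#' @return object of class `wb_contacts`: list with `edges` (E x 2 integer
#'   matrix, each row an unordered contacting pair i < j) and `N`
#'   (per-agent contact counts).
#' @export
detect_contacts <- function(agents, params) {
  stopifnot(inherits(params, "wb_params"))
  g <- cpp_contact_graph(agents_to_matrix(agents), params$d_contact)
  structure(list(edges = cbind(i = g$i, j = g$j), N = g$N),
            class = "wb_contacts")
}

#' @export
print.wb_contacts <- function(x, ...) {
  cat("<wb_contacts> ", nrow(x$edges), " contacting pairs among ",
      length(x$N), " agents\n", sep = "")
  invisible(x)
}

#' Agent-peg contacts
#'
#' An agent contacts a peg iff the minimum distance from any of its four
#' body segments to the peg centre is at most `r_c + d_touch` (boundary
#' inclusive).
#'
#' @param agents data.frame of agent states.
#' @param env a [build_arena()] object.
#' @param params a [wb_params()] object.
#' @return list, one integer vector of contacted peg indices per agent.
#' @export
detect_peg_contacts <- function(agents, env, params) {
  stopifnot(inherits(env, "wb_arena"), inherits(params, "wb_params"))
  if (nrow(env$pegs) == 0) return(rep(list(integer(0)), nrow(agents)))
  cpp_peg_contacts(agents_to_matrix(agents), env$pegs, env$peg_r,
                   params$a, params$d_touch)
}

# minimum distance between two segments (used by the wall-contact record)
seg_seg_dist <- function(a1, a2, b1, b2) {
  u <- a2 - a1; v <- b2 - b1; w <- a1 - b1
  A <- sum(u * u); B <- sum(u * v); C <- sum(v * v)
  D <- sum(u * w); E <- sum(v * w)
  den <- A * C - B * B
  s <- if (den > 1e-30) min(1, max(0, (B * E - C * D) / den)) else 0
  t <- if (C > 1e-30) min(1, max(0, (B * s + E) / C)) else 0
  s <- if (A > 1e-30) min(1, max(0, (B * t - D) / A)) else 0
  sqrt(sum((a1 + s * u - b1 - t * v)^2))
}

#' Agent-wall contact record
#'
#' Geometric record of one agent's interaction with the arena walls:
#' the nearest wall point and its tangent angle, the penetration depth
#' (distance from the centre to the nearest wall when the centre lies
#' outside the domain, else 0), whether any body segment is within
#' `d_touch` of a wall, and whether the head arm crosses a wall, with
#' the head-clamp length (distance along the heading to the first
#' crossing, floored at `a`).
#'
#' @param agent list or one-row data.frame with `x, y, theta, l`.
#' @param env a [build_arena()] object.
#' @param params a [wb_params()] object.
#' @return `NULL` for a wall-less arena, else a list with `point`,
#'   `tangent_angle`, `penetration`, `contact`, `head_hit`, `clamp_length`.
#' @export
detect_wall_contact <- function(agent, env, params) {
  stopifnot(inherits(env, "wb_arena"), inherits(params, "wb_params"))
  if (nrow(env$walls) == 0) return(NULL)
  ag <- as.list(agent)
  r <- c(ag$x, ag$y)
  nw <- nearest_wall_point(env, r)
  pen <- if (nw$inside) 0 else nw$dist
  segs <- cross_segments(ag, params$a)
  contact <- pen > 0
  if (!contact) {
    for (k in 1:4) {
      for (w in seq_len(nrow(env$walls))) {
        d <- seg_seg_dist(segs[k, 1:2], segs[k, 3:4],
                          env$walls[w, 1:2], env$walls[w, 3:4])
        if (d <= params$d_touch) { contact <- TRUE; break }
      }
      if (contact) break
    }
  }
  dir <- c(cos(ag$theta), sin(ag$theta))
  tmin <- Inf
  for (w in seq_len(nrow(env$walls))) {
    t <- ray_segment_hit(r, dir, env$walls[w, 1:2], env$walls[w, 3:4])
    if (!is.na(t) && t < tmin) tmin <- t
  }
  head_hit <- is.finite(tmin) && tmin <= ag$l
  list(point = nw$point, tangent_angle = nw$tangent_angle,
       penetration = pen, contact = contact, head_hit = head_hit,
       clamp_length = if (head_hit) max(params$a, tmin) else ag$l)
}

ray_segment_hit <- function(p, d, a, b) {
  s <- b - a
  den <- d[1] * s[2] - d[2] * s[1]
  if (abs(den) < 1e-30) return(NA_real_)
  t <- ((a[1] - p[1]) * s[2] - (a[2] - p[2]) * s[1]) / den
  u <- ((a[1] - p[1]) * d[2] - (a[2] - p[2]) * d[1]) / den
  if (t >= 0 && u >= 0 && u <= 1) t else NA_real_
}
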