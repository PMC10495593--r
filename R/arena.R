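#' Build a simulation arena
#'
#' Construct one of the five arena geometries as an ordered wall polyline
#' plus an optional peg set:
#' \describe{
#'   \item{`"square"`}{closed square box, default side 0.183 m.}
#'   \item{`"open"`}{unbounded dish: no walls, every point is inside.}
#'   \item{`"oval"`}{polygonized ellipse, default semi-axes 0.025 x 0.0125 m.}
#'   \item{`"dumbbell"`}{two regular octagonal rooms (flat-to-flat width
#'     `room_w`) joined by a short rectangular passage of width `passage_w`.}
#'   \item{`"dumbbell_pegs"`}{dumbbell plus `pegs_per_room` pegs arranged on
#'     a ring around each room centre (or explicit coordinates via `peg_xy`).}
#' }
#' Two-room arenas (and the oval, split at x = 0) carry room metadata used
#' by [room_of()] and [count_one_way_trips()].
#'
#' @param kind arena tag, one of `"square"`, `"open"`, `"oval"`,
#'   `"dumbbell"`, `"dumbbell_pegs"`.
#' @param side square side length (m).
#' @param semi_x,semi_y oval semi-axes (m).
#' @param n_vertices polygonization count for the oval boundary.
#' @param room_w octagon flat-to-flat width (m); default 0.02, the
#'   experimental room diameter.
#' @param room_cx octagon centre offset from the origin (m); the passage
#'   spans `|x| <= room_cx - room_w/2` (defaults give a 0.01 m aisle and a
#'   0.05 m overall span, the experimental proportions).
#' @param passage_w passage width (m); must be narrower than the octagon
#'   flat.
#' @param pegs_per_room pegs per room for `"dumbbell_pegs"`.
#' @param peg_ring_frac ring radius of the peg triangle as a fraction of the
#'   room half-width.
#' @param peg_r peg radius (m).
#' @param peg_xy optional explicit peg coordinate matrix (n x 2), overriding
#'   the default layout.
#' @return object of class `wb_arena`: list with `kind`, `walls` (n x 4
#'   matrix of segment endpoints `x1,y1,x2,y2`), `poly` (closed boundary
#'   polygon, or NULL for `"open"`), `pegs` (n x 2 matrix), `peg_r`,
#'   `rooms` (list or NULL) and `bbox`.
#' @examples
#' sq <- build_arena("square")
#' sum(sqrt((sq$walls[,3]-sq$walls[,1])^2 + (sq$walls[,4]-sq$walls[,2])^2))
#' db <- build_arena("dumbbell_pegs")
#' nrow(db$pegs)
#' @export
build_arena <- function(kind = c("square", "open", "oval", "dumbbell",
                                 "dumbbell_pegs"),
                        side = 0.183,
                        semi_x = 0.025, semi_y = 0.0125, n_vertices = 128,
                        room_w = 0.020, room_cx = 0.015, passage_w = 0.008,
                        pegs_per_room = 3, peg_ring_frac = 0.3,
                        peg_r = 0.75e-3, peg_xy = NULL) {
  kind <- match.arg(kind)
  pegs <- matrix(numeric(0), 0, 2)
  rooms <- NULL
  if (kind == "square") {
    if (side <= 0) stop("side must be positive")
    h <- side / 2
    poly <- rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))
    bbox <- c(-h, h, -h, h)
  } else if (kind == "open") {
    poly <- NULL
    bbox <- c(-Inf, Inf, -Inf, Inf)
  } else if (kind == "oval") {
    if (semi_x <= 0 || semi_y <= 0) stop("semi-axes must be positive")
    if (n_vertices < 8) stop("n_vertices too small")
    ang <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
    poly <- cbind(semi_x * cos(ang), semi_y * sin(ang))
    bbox <- c(-semi_x, semi_x, -semi_y, semi_y)
    rooms <- list(centers = rbind(c(-semi_x / 2, 0), c(semi_x / 2, 0)),
                  core_radius = 0.5 * (semi_x / 2), passage_halflen = 0)
  } else { # dumbbell kinds
    if (room_w <= 0 || passage_w <= 0) stop("dimensions must be positive")
    g <- room_cx - room_w / 2            # passage half-length
    if (g < 0) stop("room_cx must be >= room_w/2 (rooms must not overlap)")
    f <- (room_w / 2) * tan(pi / 8)      # octagon flat half-length
    h <- passage_w / 2
    if (h >= f) stop("passage_w must be narrower than the octagon flat")
    R <- (room_w / 2) / cos(pi / 8)
    lv <- t(vapply(0:7, function(k) {
      a <- (22.5 + 45 * k) * pi / 180
      c(-room_cx + R * cos(a), R * sin(a))
    }, numeric(2)))                      # left octagon CCW from (-g, f)
    mirror <- function(m) cbind(-m[, 1], m[, 2])
    poly <- rbind(
      c(-g, h), c(-g, f),
      lv[2:7, ],                         # over the top, around, underneath
      c(-g, -f), c(-g, -h),
      c(g, -h), c(g, -f),
      mirror(lv[7:2, ]),
      c(g, f), c(g, h))
    bbox <- c(-(room_cx + room_w / 2), room_cx + room_w / 2,
              -room_w / 2, room_w / 2)
    rooms <- list(centers = rbind(c(-room_cx, 0), c(room_cx, 0)),
                  core_radius = 0.5 * (room_w / 2), passage_halflen = g)
    if (kind == "dumbbell_pegs") {
      if (is.null(peg_xy)) {
        ring <- peg_ring_frac * (room_w / 2)
        if (pegs_per_room < 1) stop("pegs_per_room must be >= 1")
        ang <- pi / 2 + 2 * pi * (seq_len(pegs_per_room) - 1) / pegs_per_room
        left <- cbind(-room_cx + ring * cos(ang), ring * sin(ang))
        pegs <- rbind(left, cbind(-left[, 1], left[, 2]))
      } else {
        pegs <- as.matrix(peg_xy)
        if (ncol(pegs) != 2) stop("peg_xy must have two columns")
      }
    }
  }
  walls <- if (is.null(poly)) matrix(numeric(0), 0, 4) else {
    nxt <- c(2:nrow(poly), 1)
    cbind(poly[, 1], poly[, 2], poly[nxt, 1], poly[nxt, 2])
  }
  env <- structure(list(kind = kind, walls = walls, poly = poly,
                        pegs = pegs, peg_r = peg_r, rooms = rooms,
                        bbox = bbox),
                   class = "wb_arena")
  if (nrow(pegs) > 0) {
    ok <- arena_inside(env, pegs[, 1], pegs[, 2])
    if (!all(ok)) stop("peg(s) outside the arena domain")
  }
  env
}

#' @export
print.wb_arena <- function(x, ...) {
  cat("<wb_arena> kind:", x$kind, "|", nrow(x$walls), "wall segments |",
      nrow(x$pegs), "pegs\n")
  invisible(x)
}

#' Inside-domain test
#'
#' Even-odd (ray casting) point-in-polygon test against the arena boundary;
#' always `TRUE` for the open arena. Vectorized over points.
#'
#' @param env a [build_arena()] object.
#' @param x,y point coordinates (m).
#' @return logical vector.
#' @export
arena_inside <- function(env, x, y) {
  stopifnot(inherits(env, "wb_arena"))
  if (is.null(env$poly)) return(rep(TRUE, length(x)))
  vapply(seq_along(x), function(i)
    point_in_poly(env$poly, x[i], y[i]), logical(1))
}

point_in_poly <- function(poly, px, py) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Nearest wall point
#'
#' Closest point on any wall segment to `p`, the absolute angle of that
#' segment (mod pi, in `[0, pi)`), the distance, and whether `p` lies inside
#' the domain. For the open arena (no walls) returns `NULL`: callers treat
#' all wall terms as zero.
#'
#' @param env a [build_arena()] object.
#' @param p numeric length-2 point (m).
#' @return `NULL` for the open arena, else a list with `point`,
#'   `tangent_angle`, `dist`, `inside`.
#' @export
nearest_wall_point <- function(env, p) {
  stopifnot(inherits(env, "wb_arena"), length(p) == 2)
  if (nrow(env$walls) == 0) return(NULL)
  best <- Inf; bp <- c(NA, NA); bang <- NA
  for (i in seq_len(nrow(env$walls))) {
    s <- env$walls[i, ]
    cp <- closest_point_on_segment(p, s[1:2], s[3:4])
    d2 <- sum((p - cp)^2)
    if (d2 < best) {
      best <- d2; bp <- cp
      bang <- atan2(s[4] - s[2], s[3] - s[1]) %% pi
    }
  }
  list(point = bp, tangent_angle = bang, dist = sqrt(best),
       inside = arena_inside(env, p[1], p[2]))
}

closest_point_on_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  a + t * ab
}

#' Room membership
#'
#' Label a point as belonging to the left room, the right room, the
#' connecting passage, or none (outside the domain). Defined for the
#' two-room arenas (`"dumbbell"`, `"dumbbell_pegs"`) and for the oval,
#' whose halves are split at x = 0.
#'
#' @param env a [build_arena()] object with room metadata.
#' @param p numeric length-2 point (m).
#' @return one of `"left"`, `"right"`, `"passage"`, `"none"`.
#' @export
room_of <- function(env, p) {
  stopifnot(inherits(env, "wb_arena"))
  if (is.null(env$rooms)) stop("rooms undefined for arena kind ", env$kind)
  if (!arena_inside(env, p[1], p[2])) return("none")
  g <- env$rooms$passage_halflen
  if (abs(p[1]) <= g) return("passage")
  if (p[1] < 0) "left" else "right"
}
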