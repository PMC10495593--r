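#' Create the aversive-stimulus field
#'
#' Regular cell-centred grid carrying the self-released repellent
#' concentration `a_s`, plus a flag enabling the static mustard gradient
#' `a_m(x) = D exp(E x')` (x' in grid units). The grid covers the arena
#' bounding box inflated by `margin` cells; for the open arena it defaults
#' to a square of side `open_extent` centred on the origin (the dish of the
#' collective-escape setup).
#'
#' @param arena a [build_arena()] object.
#' @param params a [wb_params()] object (supplies `grid_dx` and the field
#'   constants).
#' @param mustard logical; enable the static gradient.
#' @param extent optional `c(xmin, xmax, ymin, ymax)` override (m).
#' @param margin cells of padding around the arena bounding box.
#' @param open_extent side (m) of the default grid for the open arena.
#' @return object of class `wb_field`: list with matrix `a` (nx x ny, cell
#'   centres, initially zero), origin `x0, y0`, spacing `dx`, `nx, ny`,
#'   and `mustard`.
#' @export
make_field <- function(arena, params, mustard = FALSE, extent = NULL,
                       margin = 3, open_extent = 0.15) {
  stopifnot(inherits(arena, "wb_arena"), inherits(params, "wb_params"))
  dx <- params$grid_dx
  if (is.null(extent)) {
    if (arena$kind == "open") {
      h <- open_extent / 2
      extent <- c(-h, h, -h, h)
    } else {
      extent <- arena$bbox + c(-1, 1, -1, 1) * margin * dx
    }
  }
  nx <- max(1L, as.integer(ceiling((extent[2] - extent[1]) / dx)))
  ny <- max(1L, as.integer(ceiling((extent[4] - extent[3]) / dx)))
  # domain mask: the repellent lives inside the arena walls (zero-flux
  # there); everything is in-domain for the open arena
  cx <- extent[1] + (seq_len(nx) - 0.5) * dx
  cy <- extent[3] + (seq_len(ny) - 0.5) * dx
  mask <- if (is.null(arena$poly)) matrix(TRUE, nx, ny) else {
    pts <- expand.grid(x = cx, y = cy)
    matrix(arena_inside(arena, pts$x, pts$y), nx, ny)
  }
  structure(list(a = matrix(0, nx, ny), mask = mask, x0 = extent[1],
                 y0 = extent[3], dx = dx, nx = nx, ny = ny,
                 mustard = isTRUE(mustard)),
            class = "wb_field")
}

#' @export
print.wb_field <- function(x, ...) {
  cat("<wb_field> ", x$nx, "x", x$ny, " grid, dx = ", x$dx,
      if (x$mustard) " m, mustard gradient on\n" else " m\n", sep = "")
  invisible(x)
}

#' Advance the repellent field one step
#'
#' Explicit Euler update of the reaction-diffusion equation for `a_s`:
#' decay at rate `k_A0`, diffusion `D_A` through a grid-native 5-point
#' Laplacian with zero-flux (mirror) boundaries, then a deposit of
#' `k_A1 * dt` into each agent's containing cell.
#'
#' @param field a [make_field()] object.
#' @param agent_positions n x 2 matrix of positions (m); may have 0 rows.
#' @param params a [wb_params()] object.
#' @return the updated `wb_field`.
#' @export
step_field <- function(field, agent_positions, params) {
  stopifnot(inherits(field, "wb_field"), inherits(params, "wb_params"))
  pos <- matrix(as.numeric(agent_positions), ncol = 2)
  if (nrow(pos) > 0) {
    inx <- pos[, 1] >= field$x0 & pos[, 1] <= field$x0 + field$nx * field$dx &
           pos[, 2] >= field$y0 & pos[, 2] <= field$y0 + field$ny * field$dx
    if (!all(inx)) stop("agent position(s) outside the field grid")
  }
  field$a <- cpp_field_step(field$a, field$mask, pos, field$x0, field$y0,
                            field$dx, params$k_A0, params$k_A1, params$D_A,
                            params$dt)
  field
}

#' Mustard concentration profile
#'
#' The static externally imposed gradient `a_m(x) = D exp(E x')`, with the
#' coordinate expressed in grid units (`x' = x / grid_dx`). Returns 0 when
#' disabled.
#'
#' @param x x-coordinate(s), metres.
#' @param params a [wb_params()] object.
#' @param enabled logical; when `FALSE` the profile is identically zero.
#' @return concentration value(s).
#' @examples
#' mustard_conc(0, wb_params())   # 0.61
#' @export
mustard_conc <- function(x, params, enabled = TRUE) {
  stopifnot(inherits(params, "wb_params"))
  if (!enabled) return(rep(0, length(x)))
  params$D_mustard * exp(params$E_mustard * x / params$grid_dx)
}

#' Sample the stimulus field
#'
#' Value and gradient of the total aversive stimulus `A = a_s + a_m` at a
#' point: bilinear interpolation of the grid for `a_s`, an interpolated
#' central-difference gradient, and the analytic mustard contribution when
#' the field has it enabled.
#'
#' @param field a [make_field()] object.
#' @param p length-2 point (m); must lie inside the grid.
#' @param params a [wb_params()] object.
#' @return list with `A` (value), `grad` (length-2 gradient, SI 1/m) and
#'   `null_grad` (`TRUE` when the gradient is exactly zero, e.g. a uniform
#'   field with mustard off).
#' @export
sample_stimulus <- function(field, p, params) {
  stopifnot(inherits(field, "wb_field"), length(p) == 2)
  s <- cpp_sample_as(field$a, field$x0, field$y0, field$dx,
                     matrix(as.numeric(p), 1, 2))
  if (!s$ok[1]) stop("point outside the field grid")
  A <- s$a_s[1]
  g <- c(s$gx[1], s$gy[1])
  if (field$mustard) {
    A <- A + mustard_conc(p[1], params)
    g[1] <- g[1] + params$D_mustard * params$E_mustard / params$grid_dx *
      exp(params$E_mustard * p[1] / params$grid_dx)
  }
  list(A = A, grad = g, null_grad = all(g == 0))
}
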