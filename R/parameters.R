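#' Model parameters
#'
#' Construct the full parameter set of the worm-blob agent model: every
#' constant of the deformation/translation/rotation equations and of the
#' repellent field, plus the numerical settings of the solver. Defaults are
#' the hand-tuned simulation values of the source model; see the package
#' vignette for units and for the reasoning behind the numerical defaults
#' (`speed_scale`, `d_contact`, `r_c`, `grid_dx`).
#'
#' Parameters (SI units unless noted):
#' \describe{
#'   \item{m, c}{agent mass (kg) and ground viscous friction (kg/s).}
#'   \item{a, tau, l_a, l_b}{minor/fixed arm length (m), head-arm response
#'     time (s), and the target-length constants (m): the contact-free target
#'     length is `l_a` and each contacting neighbour shortens it by `l_b`.}
#'   \item{alpha, beta}{activity coefficients: G = f(alpha*A - beta*N).}
#'   \item{eta}{propulsion coefficient; the propulsion force is
#'     `speed_scale * eta * G * l` along the heading.}
#'   \item{d_R, t_min, t_max}{random-torque magnitude (rad/s) and the bounds
#'     (s) of the uniform refresh interval of its piecewise-constant drive.}
#'   \item{d_C}{chemotactic torque coefficient (rad/s).}
#'   \item{q1, rho1, rho2, rho3, lambda1, lambda2, r0}{pair/peg interaction
#'     constants: viscous friction between touching agents (kg/s) and the
#'     power-law bracket `(d/r0)^-lambda1 - rho2 (d/r0)^-lambda2` scaled by
#'     `rho1` (agent-agent) or `rho3 * (l - a)` (agent-peg).}
#'   \item{d_A}{nematic alignment torque coefficient (1/m^2 s).}
#'   \item{q2, d_P, d_W, k_W}{peg friction (kg/s), peg/wall alignment torque
#'     coefficients (rad/s), wall spring coefficient.}
#'   \item{D_mustard, E_mustard}{static mustard gradient `D exp(E x')` with
#'     x' in grid units.}
#'   \item{k_A0, k_A1, D_A}{decay, emission and diffusion constants of the
#'     self-released repellent (grid-native units, see vignette).}
#'   \item{dt}{integration step (s).}
#'   \item{d_contact}{inter-agent contact radius between body cores
#'     (axis-intersection points), m.}
#'   \item{d_touch}{arm proximity threshold (~worm thickness, m) of the
#'     segment-based peg and wall contact tests.}
#'   \item{r_c}{peg radius (m).}
#'   \item{grid_dx}{repellent grid spacing (m).}
#'   \item{speed_scale}{dimension-repair factor applied to the propulsion
#'     term only; default calibrated so a free, half-active, fully elongated
#'     agent traverses 0.05 m in ~1e3 s.}
#' }
#'
#' @param overrides named list (or named vector) of parameter values to
#'   override. Unknown names are an error.
#' @return object of class `wb_params` (a validated named list).
#' @examples
#' p <- wb_params()
#' p$l_a
#' p2 <- wb_params(list(dt = 0.1, d_R = 0))
#' @export
wb_params <- function(overrides = list()) {
  p <- wb_default_params()
  if (length(overrides)) {
    overrides <- as.list(overrides)
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be named")
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown))
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) p[[nm]] <- as.numeric(overrides[[nm]])
  }
  validate_params(p)
  structure(p, class = "wb_params")
}

wb_default_params <- function() {
  list(
    m = 1.0e-3, c = 0.10,
    a = 2.5e-3, tau = 100.0, l_a = 0.05250, l_b = 2.5e-3,
    alpha = 1.2, beta = 0.05,
    eta = 5.0e3,
    d_R = 0.0124, t_min = 2.0, t_max = 20.0,
    d_C = 7.5e-3,
    q1 = 1.88e-3,
    rho1 = 0.165e-6, rho2 = 0.19, rho3 = 11.6e-6,
    lambda1 = 1.0, lambda2 = 2.0, r0 = 0.01,
    d_A = 53.3,
    q2 = 0.125e-3, d_P = 0.333e-3, d_W = 1.0e-3, k_W = 3.0e-3,
    D_mustard = 0.61, E_mustard = 0.125,
    k_A0 = 5.71e-3, k_A1 = 1.0e-3, D_A = 0.07,
    dt = 0.2,
    d_contact = 3.25e-3, d_touch = 1.0e-3, r_c = 0.75e-3,
    grid_dx = 2.0e-3,
    speed_scale = 4.0e-8
  )
}

validate_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("parameters must be finite scalars: ",
         paste(names(p)[!num], collapse = ", "))
  # coupling magnitudes may be zero (disabling a term); structural
  # constants must be strictly positive
  nonneg <- c("eta", "d_R", "d_C", "q1", "rho1", "rho3", "d_A", "q2",
              "d_P", "d_W", "k_W", "D_mustard", "E_mustard",
              "k_A0", "k_A1", "D_A", "speed_scale")
  pos <- setdiff(names(p), nonneg)
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "))
  badn <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(badn))
    stop("parameter(s) must be non-negative: ", paste(badn, collapse = ", "))
  if (p$t_min >= p$t_max) stop("t_min must be < t_max")
  if (p$lambda2 <= p$lambda1) stop("lambda2 must be > lambda1")
  if (p$l_a <= p$a) stop("l_a must be > a")
  if (p$dt <= 0) stop("dt must be positive")
  # explicit diffusion stability; the Laplacian is grid-native (unit spacing)
  if (p$D_A * p$dt > 0.25)
    stop("explicit-scheme stability violated: D_A * dt = ",
         format(p$D_A * p$dt), " > 0.25")
  invisible(p)
}

#' @export
print.wb_params <- function(x, ...) {
  cat("<wb_params> ", length(x), " parameters\n", sep = "")
  df <- data.frame(value = unlist(x))
  print(df)
  invisible(x)
}

#' Write/read a parameter configuration file
#'
#' Flat key-value YAML mirroring the parameter names of [wb_params()].
#' Reading validates exactly as the constructor does; unknown keys are
#' rejected.
#'
#' @param params a `wb_params` object.
#' @param path file path.
#' @return `read_params` returns a `wb_params`; `write_params` returns
#'   `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "wb_params"))
  yaml::write_yaml(lapply(unclass(params), as.numeric), path,
                   precision = 17L)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  wb_params(x)
}

#' Initial agent states
#'
#' Draw `n` agents for the start of a trial: positions i.i.d. uniform over
#' the placement region (optionally rejection-sampled to lie inside an
#' arena's domain), headings uniform on (-pi, pi], zero velocity, head arm
#' fully coiled (`l = a`), and a freshly sampled random-torque state.
#'
#' @param n number of agents (>= 1).
#' @param placement region spec: `list(kind = "disc", center = c(x, y),
#'   radius = r)` or `list(kind = "rect", xmin=, xmax=, ymin=, ymax=)`.
#' @param params a [wb_params()] object.
#' @param arena optional [build_arena()] environment; when given, positions
#'   are rejection-sampled until inside its domain.
#' @return data.frame with one row per agent and columns
#'   `x, y, vx, vy, theta, l, zeta, t_refresh`.
#' @examples
#' p <- wb_params()
#' set.seed(1)
#' ag <- initial_agents(10, list(kind = "disc", center = c(0, 0),
#'                               radius = 0.0125), p)
#' @export
initial_agents <- function(n, placement, params, arena = NULL) {
  stopifnot(inherits(params, "wb_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive count")
  n <- as.integer(n)
  draw_point <- switch(placement$kind,
    disc = {
      ctr <- placement$center; rad <- placement$radius
      if (!is.numeric(rad) || rad <= 0) stop("empty region: radius must be > 0")
      function() {
        r <- rad * sqrt(stats::runif(1))
        a <- stats::runif(1, -pi, pi)
        c(ctr[1] + r * cos(a), ctr[2] + r * sin(a))
      }
    },
    rect = {
      if (placement$xmax <= placement$xmin || placement$ymax <= placement$ymin)
        stop("empty region: rectangle has non-positive extent")
      function() c(stats::runif(1, placement$xmin, placement$xmax),
                   stats::runif(1, placement$ymin, placement$ymax))
    },
    stop("unknown placement kind: ", placement$kind)
  )
  inside <- if (is.null(arena)) function(p) TRUE else function(p) arena_inside(arena, p[1], p[2])
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    for (tries in 1:10000) {
      pt <- draw_point()
      if (inside(pt)) break
      if (tries == 10000) stop("placement region does not intersect the arena domain")
    }
    xs[i] <- pt[1]; ys[i] <- pt[2]
  }
  theta <- stats::runif(n, -pi, pi)
  theta[theta == -pi] <- pi   # convention (-pi, pi]
  zeta <- stats::runif(n, -1, 1)
  t_refresh <- stats::runif(n, params$t_min, params$t_max)
  data.frame(x = xs, y = ys, vx = 0, vy = 0, theta = theta,
             l = params$a, zeta = zeta, t_refresh = t_refresh)
}
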