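#' Contact-dependent target length
#'
#' The head arm relaxes toward `max(l_a - l_b * N, a)`: crowded agents coil
#' (target shrinks to the minor-axis length `a`), isolated agents elongate
#' to `l_a`.
#'
#' @param N contact count(s), >= 0.
#' @param params a [wb_params()] object.
#' @return target length(s), m.
#' @examples
#' target_length(0, wb_params())    # 0.0525
#' target_length(10, wb_params())   # 0.0275
#' @export
target_length <- function(N, params) {
  pmax(params$l_a - params$l_b * N, params$a)
}

#' Saturation function
#'
#' Piecewise-linear saturation: 0 below -1, `(1 + x)/2` on `[-1, 1]`,
#' 1 above 1. Maps the activity argument onto `[0, 1]`.
#'
#' @param x numeric vector.
#' @return values in `[0, 1]`.
#' @export
saturation <- function(x) {
  pmin(1, pmax(0, (1 + x) / 2))
}

#' Activity level
#'
#' `G = f(alpha * A - beta * N)`: aversive stimulus excites, crowding
#' suppresses. G multiplies propulsion, chemotactic turning and nematic
#' alignment.
#'
#' @param A stimulus intensity(ies), >= 0.
#' @param N contact count(s), >= 0.
#' @param params a [wb_params()] object.
#' @return activity value(s) in `[0, 1]`.
#' @examples
#' activity(0, 0, wb_params())    # 0.5
#' activity(0, 20, wb_params())   # 0
#' @export
activity <- function(A, N, params) {
  saturation(params$alpha * A - params$beta * N)
}

#' Propulsion force
#'
#' Self-driving force along the heading, `speed_scale * eta * G * l *
#' (cos theta, sin theta)`: stronger when the agent is active and
#' elongated. `speed_scale` repairs the propulsion coefficient's units
#' (see the vignette); it multiplies this term only.
#'
#' @param G activity in `[0, 1]`.
#' @param l head-arm length (m).
#' @param theta heading (rad).
#' @param params a [wb_params()] object.
#' @return length-2 force vector (N).
#' @export
propulsion_force <- function(G, l, theta, params) {
  params$speed_scale * params$eta * G * l * c(cos(theta), sin(theta))
}

# power-law bracket shared by the pair and peg radial forces, capped at its
# value at 0.1*r0 so coincident placements cannot blow up
force_bracket <- function(d, params) {
  s <- pmax(d, 0.1 * params$r0) / params$r0
  s^(-params$lambda1) - params$rho2 * s^(-params$lambda2)
}

#' Pairwise physical interaction force
#'
#' Force on agent i from contacting agent j: viscous friction
#' `q1 (v_j - v_i)` plus the entanglement distance-keeping term
#' `rho1 [ (d/r0)^-lambda1 - rho2 (d/r0)^-lambda2 ] r_hat`, attractive
#' beyond the equilibrium separation `r0 * rho2^(1/(lambda2-lambda1))` and
#' repulsive inside it. For separations below `0.1 * r0` the bracket is
#' capped at its value there; exactly coincident centres get no radial
#' force (undefined direction).
#'
#' @param agent_i,agent_j lists or one-row data.frames with
#'   `x, y, vx, vy`.
#' @param params a [wb_params()] object.
#' @return length-2 force vector on agent i (N).
#' @export
pair_force <- function(agent_i, agent_j, params) {
  ai <- as.list(agent_i); aj <- as.list(agent_j)
  f <- params$q1 * c(aj$vx - ai$vx, aj$vy - ai$vy)
  dvec <- c(aj$x - ai$x, aj$y - ai$y)
  d <- sqrt(sum(dvec^2))
  if (d > 0)
    f <- f + params$rho1 * force_bracket(d, params) * dvec / d
  f
}

#' Nematic alignment torque
#'
#' `d_A * G_i * (l_i - a) * (l_j - a) * sin(2 (theta_j - theta_i))`:
#' elongated, active agents align head-to-head or head-to-tail (relative
#' angle driven to 0 or pi); coiled agents (`l = a`) do not align.
#'
#' @param agent_i,agent_j lists or one-row data.frames with `theta, l`.
#' @param G_i activity of agent i.
#' @param params a [wb_params()] object.
#' @return angular rate contribution (rad/s).
#' @export
nematic_torque <- function(agent_i, agent_j, G_i, params) {
  ai <- as.list(agent_i); aj <- as.list(agent_j)
  params$d_A * G_i * (ai$l - params$a) * (aj$l - params$a) *
    sin(2 * (aj$theta - ai$theta))
}

#' Random turning torque
#'
#' Piecewise-constant random drive `d_R * zeta`, `zeta ~ U(-1, 1)` held for
#' a random interval `T ~ U(t_min, t_max)`. If the refresh time has been
#' reached, `zeta` is resampled (from R's RNG) and a new refresh time
#' scheduled before the torque is returned.
#'
#' @param agent list or one-row data.frame with `zeta, t_refresh`.
#' @param t current absolute time (s).
#' @param params a [wb_params()] object.
#' @return list with `torque` (rad/s) and the updated `zeta`, `t_refresh`.
#' @export
random_torque <- function(agent, t, params) {
  ag <- as.list(agent)
  if (t >= ag$t_refresh) {
    ag$zeta <- stats::runif(1, -1, 1)
    ag$t_refresh <- t + stats::runif(1, params$t_min, params$t_max)
  }
  list(torque = params$d_R * ag$zeta, zeta = ag$zeta,
       t_refresh = ag$t_refresh)
}

#' Chemotactic turning torque
#'
#' `d_C * G * sin(theta_bar - theta)` with `theta_bar = arg(-grad A)`:
#' turns the heading toward decreasing aversive stimulus; zero when the
#' gradient is null or the agent is inactive.
#'
#' @param theta heading (rad).
#' @param gradA length-2 stimulus gradient, or `NULL` for a null gradient.
#' @param G activity in `[0, 1]`.
#' @param params a [wb_params()] object.
#' @return angular rate contribution (rad/s).
#' @export
chemo_torque <- function(theta, gradA, G, params) {
  if (is.null(gradA) || all(gradA == 0) || G == 0) return(0)
  theta_bar <- atan2(-gradA[2], -gradA[1])
  params$d_C * G * sin(theta_bar - theta)
}

#' Agent-peg interaction force
#'
#' Force on an agent contacting a peg: viscous drag `-q2 v` plus the
#' dragging term `rho3 (l - a) [bracket] r_hat` toward/away from the peg
#' centre -- stronger as the agent elongates, sharing the equilibrium
#' separation of [pair_force()].
#'
#' @param agent list or one-row data.frame with `x, y, vx, vy, l`.
#' @param peg length-2 peg centre (m).
#' @param params a [wb_params()] object.
#' @return length-2 force vector (N).
#' @export
peg_force <- function(agent, peg, params) {
  ag <- as.list(agent)
  f <- -params$q2 * c(ag$vx, ag$vy)
  dvec <- c(peg[1] - ag$x, peg[2] - ag$y)
  d <- sqrt(sum(dvec^2))
  if (d > 0)
    f <- f + params$rho3 * (ag$l - params$a) * force_bracket(d, params) *
      dvec / d
  f
}

#' Wall repulsion force
#'
#' Spring-like pushback `k_W (r_W - r)` proportional to the penetration
#' depth, zero while the agent centre is inside the domain.
#'
#' @param agent list or one-row data.frame with `x, y`.
#' @param wall_record a [detect_wall_contact()] record (or `NULL`).
#' @param params a [wb_params()] object.
#' @return length-2 force vector (N).
#' @export
wall_force <- function(agent, wall_record, params) {
  if (is.null(wall_record) || wall_record$penetration == 0) return(c(0, 0))
  ag <- as.list(agent)
  params$k_W * (wall_record$point - c(ag$x, ag$y))
}

#' Peg and wall alignment torques
#'
#' Nematic-style alignment to the direction of a contacted peg
#' (`d_P sin 2(theta_ip - theta)`) or to a contacted wall's tangent
#' (`d_W sin 2(theta_u - theta)`); both vanish without contact (callers
#' apply them only for contacting agents).
#'
#' @param theta heading (rad).
#' @param theta_ip absolute angle from the agent to the peg centre (rad).
#' @param theta_u absolute angle of the contacted wall (rad).
#' @param params a [wb_params()] object.
#' @return angular rate contribution (rad/s).
#' @export
peg_align_torque <- function(theta, theta_ip, params) {
  params$d_P * sin(2 * (theta_ip - theta))
}

#' @rdname peg_align_torque
#' @export
wall_align_torque <- function(theta, theta_u, params) {
  params$d_W * sin(2 * (theta_u - theta))
}

#' Head-length wall clamp
#'
#' When the head arm crosses a wall, the head length is forcibly shortened
#' to the distance from the centre to the first wall crossing (floored at
#' `a`) so agents cannot penetrate walls; applied after the Euler length
#' update each step.
#'
#' @param agent list or one-row data.frame with `l`.
#' @param wall_record a [detect_wall_contact()] record (or `NULL`).
#' @param params a [wb_params()] object.
#' @return the updated head length (m).
#' @export
clamp_head <- function(agent, wall_record, params) {
  ag <- as.list(agent)
  if (is.null(wall_record) || !isTRUE(wall_record$head_hit)) return(ag$l)
  max(params$a, min(ag$l, wall_record$clamp_length))
}
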