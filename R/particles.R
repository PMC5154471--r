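#' Acceptance-rejection sampling of particle state transitions
#'
#' Core one-step update of the discrete subsystem.  For each particle the
#' total outgoing rate \eqn{k_{tot}} is formed from all rules leaving its
#' current state, all evaluated from the state of the system at time t; the
#' particle transitions with the exact one-step probability
#' \eqn{1 - e^{-k_{tot}\Delta t}}, and when several destinations compete the
#' single uniform draw is partitioned proportionally to the individual
#' rates (equivalent to first-event-wins at first order in \eqn{\Delta t};
#' at most one transition per particle per step).
#'
#' @param state integer vector (length n) of current state indices.
#' @param rule_from,rule_to integer vectors (length m) giving each rule's
#'   source and destination state index.
#' @param rates n x m matrix of per-particle per-rule rates (s\eqn{^{-1}}),
#'   evaluated at time t; entries for rules not leaving a particle's
#'   current state are ignored.
#' @param dt time step (s).
#' @param guard largest admissible value of rate x dt for any applicable
#'   rule (default 0.5); a violation is a hard error naming the rule,
#'   since silently inaccurate sampling is forbidden.
#' @param rule_names optional rule labels used in the guard error.
#' @return integer vector of updated state indices.
#' @export
sample_transitions <- function(state, rule_from, rule_to, rates, dt,
                               guard = 0.5, rule_names = NULL) {
  n <- length(state)
  m <- length(rule_from)
  if (is.null(dim(rates))) rates <- matrix(rates, n, m)
  tryCatch(
    transition_sweep(as.integer(state), as.integer(rule_from),
                     as.integer(rule_to), rates, dt, guard),
    error = function(e) {
      msg <- conditionMessage(e)
      j <- suppressWarnings(
        as.integer(sub(".*for rule (\\d+):.*", "\\1", msg)))
      if (!is.null(rule_names) && isTRUE(j >= 1L) && j <= length(rule_names))
        msg <- sub(sprintf("rule %d", j), rule_names[j], msg, fixed = TRUE)
      stop(msg, call. = FALSE)
    })
}

# triangle-wave fold implementing exact specular reflection at box walls
.reflect_fold <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  lo + ifelse(y > L, 2 * L - y, y)
}

#' Brownian displacement of volume particles
#'
#' Mobile particles take independent Gaussian steps with variance
#' \eqn{2D\Delta t} per axis (the exact free diffusion propagator) and are
#' specularly reflected at the box walls; the triangle-wave fold used here
#' handles arbitrarily many reflections exactly.  Particles whose state
#' has zero diffusivity do not move.
#'
#' @param positions n x 3 matrix (\eqn{\mu m}).
#' @param D per-particle diffusivity vector (\eqn{\mu m^2/s}), typically
#'   looked up from the per-state mobility table.
#' @param dt time step (s).
#' @param lower,upper length-3 box bounds (\eqn{\mu m}).
#' @return updated n x 3 position matrix.
#' @export
diffuse_positions <- function(positions, D, dt, lower, upper) {
  if (dt <= 0) stop("dt must be positive")
  mobile <- D > 0
  if (!any(mobile)) return(positions)
  nm <- sum(mobile)
  sd <- sqrt(2 * D[mobile] * dt)
  step <- matrix(stats::rnorm(3L * nm), nm, 3L) * sd
  pos <- positions
  pos[mobile, ] <- pos[mobile, , drop = FALSE] + step
  for (k in 1:3) pos[mobile, k] <-
      .reflect_fold(pos[mobile, k], lower[k], upper[k])
  pos
}

#' Brownian displacement of surface particles
#'
#' Mobile particles take an isotropic Gaussian step in the tangent plane of
#' their current element (a 3D Gaussian displacement projected onto the
#' plane, variance \eqn{2D\Delta t} per tangent axis) and are reprojected
#' onto the mesh by walking to the triangle containing the new direction;
#' their barycentric coordinates are recomputed there, so particles remain
#' exactly on the membrane.  The step size should satisfy
#' \eqn{\sqrt{4D\Delta t} <} local edge length; the engine warns at build
#' time when it does not.
#'
#' @param mesh a [surface_mesh] with walk info ([surface_walk_info()]).
#' @param tri,bary current particle coordinates.
#' @param D per-particle diffusivity vector (\eqn{\mu m^2/s}).
#' @param dt time step (s).
#' @return list with updated `tri` and `bary`.
#' @export
diffuse_on_surface <- function(mesh, tri, bary, D, dt) {
  mobile <- which(D > 0)
  if (!length(mobile)) return(list(tri = tri, bary = bary))
  p <- surface_points(mesh, tri[mobile], bary[mobile, , drop = FALSE])
  nrm <- mesh$normals[tri[mobile], , drop = FALSE]
  xi <- matrix(stats::rnorm(3L * length(mobile)), length(mobile), 3L) *
    sqrt(2 * D[mobile] * dt)
  step <- xi - rowSums(xi * nrm) * nrm
  loc <- surface_locate(mesh, p + step, tri[mobile])
  tri[mobile] <- loc$tri
  bary[mobile, ] <- loc$bary
  list(tri = tri, bary = bary)
}
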