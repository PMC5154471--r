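#' Define a hybrid deterministic-stochastic model
#'
#' A `hybrid_model` bundles everything the engine needs: geometry,
#' continuous fields with their PDE terms, discrete particle species with
#' states, transition rules and mobilities, the couplings between the two
#' subsystems, and the integration parameters.  Validation checks that
#' every rule and coupling references declared fields, species and states.
#'
#' @param name model name (used in output metadata).
#' @param grid optional [build_box_grid()] volume grid.
#' @param surface optional [surface_mesh] (e.g. [icosphere()]).
#' @param fields named list; each element a list with `domain`
#'   (`"volume"`, `"surface"`, or `"pool"` for a spatially uniform,
#'   exactly conserved cytosolic pool), diffusivity `D` (\eqn{\mu m^2/s};
#'   ignored for pools), boundary condition `bc` (`"no-flux"` or
#'   `"dirichlet"` with `bc_value`), initial value `init` (scalar or
#'   per-cell vector), and for pools the pool `volume` (\eqn{\mu m^3}).
#' @param species named list; each element a list with `domain`
#'   (`"volume"` or `"surface"`), particle count `n`, `states` (character
#'   vector), `positions` (n x 3 matrix, or `"uniform"` to sample a
#'   uniform spatial distribution at initialization), `init_state`
#'   (single label or length-n vector), and `diffusivity` (named per-state
#'   vector, \eqn{\mu m^2/s}; omitted states are immobile).
#' @param transitions list of rules, each
#'   `list(species =, from =, to =, rate = <rate_spec>)` (see
#'   [rate_constant()] and friends).
#' @param couplings list of [coupling_spec] objects.
#' @param dt fixed time step (s).
#' @param T duration (s); the engine takes `round(T/dt)` steps.
#' @param step_order `"pde_first"` (default: fields are updated from the
#'   time-t particle binning before particles move) or `"particles_first"`
#'   (the reverse; the two orderings differ at \eqn{O(\Delta t)}).
#' @param rate_dt_guard hard cap on rate x dt (default 0.5).
#' @return An object of class `hybrid_model`.
#' @export
hybrid_model <- function(name, grid = NULL, surface = NULL, fields = list(),
                         species = list(), transitions = list(),
                         couplings = list(), dt, T,
                         step_order = c("pde_first", "particles_first"),
                         rate_dt_guard = 0.5) {
  step_order <- match.arg(step_order)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (!is.finite(T) || T <= 0) stop("duration T must be positive")
  if (length(fields) && is.null(names(fields))) stop("fields must be named")
  if (length(species) && is.null(names(species))) stop("species must be named")

  for (fn in names(fields)) {
    f <- fields[[fn]]
    if (!f$domain %in% c("volume", "surface", "pool"))
      stop(sprintf("field '%s': unknown domain '%s'", fn, f$domain))
    if (f$domain == "volume" && is.null(grid))
      stop(sprintf("field '%s' needs a volume grid", fn))
    if (f$domain == "surface" && is.null(surface))
      stop(sprintf("field '%s' needs a surface mesh", fn))
    if (f$domain == "pool" && is.null(f$volume))
      stop(sprintf("pool field '%s' needs a pool volume", fn))
    if (is.null(f$init)) stop(sprintf("field '%s' has no initial value", fn))
  }
  for (sn in names(species)) {
    s <- species[[sn]]
    if (!s$domain %in% c("volume", "surface"))
      stop(sprintf("species '%s': unknown domain '%s'", sn, s$domain))
    if (s$domain == "volume" && is.null(grid))
      stop(sprintf("species '%s' needs a volume grid", sn))
    if (s$domain == "surface" && is.null(surface))
      stop(sprintf("species '%s' needs a surface mesh", sn))
    if (is.null(s$states) || !length(s$states))
      stop(sprintf("species '%s' declares no states", sn))
    init <- s$init_state
    if (is.null(init)) stop(sprintf("species '%s' has no init_state", sn))
    if (!all(init %in% s$states))
      stop(sprintf("species '%s': init_state outside declared state set", sn))
    if (!is.null(s$diffusivity) &&
        !all(names(s$diffusivity) %in% s$states))
      stop(sprintf("species '%s': diffusivity for unknown state", sn))
    if (is.matrix(s$positions)) {
      if (nrow(s$positions) != s$n || ncol(s$positions) != 3L)
        stop(sprintf("species '%s': positions must be n x 3", sn))
      dimnames(species[[sn]]$positions) <- NULL   # canonical form
    }
  }
  for (r in transitions) {
    if (is.null(species[[r$species]]))
      stop(sprintf("transition references unknown species '%s'", r$species))
    st <- species[[r$species]]$states
    if (!r$from %in% st || !r$to %in% st)
      stop(sprintf("transition %s -> %s outside state set of '%s'",
                   r$from, r$to, r$species))
    if (!inherits(r$rate, "rate_spec")) stop("transition rate must be a rate_spec")
    for (fn in .rate_fields(r$rate))
      if (is.null(fields[[fn]]))
        stop(sprintf("rate reads unknown field '%s'", fn))
  }
  for (cp in couplings) {
    if (!inherits(cp, "coupling_spec")) stop("couplings must be coupling_spec objects")
    refs <- switch(cp$type,
      particle_source = list(f = cp$field, s = cp$species, st = cp$state),
      relax = list(f = cp$field),
      binding_exchange = list(f = cp$field, s = cp$species,
                              st = c(cp$bound_state, cp$complex_state)),
      surface_recruitment = list(f = c(cp$volume_field, cp$surface_field),
                                 s = cp$species, st = cp$state))
    for (fn in refs$f) if (is.null(fields[[fn]]))
      stop(sprintf("coupling references unknown field '%s'", fn))
    if (!is.null(refs$s)) {
      if (is.null(species[[refs$s]]))
        stop(sprintf("coupling references unknown species '%s'", refs$s))
      if (!all(refs$st %in% species[[refs$s]]$states))
        stop(sprintf("coupling references unknown state of '%s'", refs$s))
    }
  }
  structure(list(name = name, grid = grid, surface = surface,
                 fields = fields, species = species,
                 transitions = transitions, couplings = couplings,
                 dt = dt, T = T, step_order = step_order,
                 rate_dt_guard = rate_dt_guard),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("<hybrid_model> '%s': %d field(s), %d species, %d rule(s), %d coupling(s)\n",
              x$name, length(x$fields), length(x$species),
              length(x$transitions), length(x$couplings)))
  cat(sprintf("  dt = %g s, T = %g s (%d steps), %s\n", x$dt, x$T,
              round(x$T / x$dt), x$step_order))
  invisible(x)
}
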