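#' Transition rate specifications
#'
#' Transition rules carry a declarative rate specification so that models
#' serialize cleanly to configuration files.  Three forms cover the
#' package's models:
#'
#' * `rate_constant(k)` — a fixed rate `k` (s\eqn{^{-1}}).
#' * `rate_linear(field, coef, offset = 0)` — `coef * F + offset`, where
#'   `F` is the value of the named field in the particle's subvolume or
#'   surface element (piecewise-constant, no interpolation, matching the
#'   binning convention).  Negative field values are clamped to zero for
#'   the rate evaluation, with a warning and an event count, since a rate
#'   must stay non-negative.
#' * `rate_pulse_linear(field, coef, k0, tau)` — `coef * F + k0 * exp(-t/tau)`:
#'   a field-proportional rate plus a transient pre-activation pulse.
#'
#' @param k,coef,offset,k0,tau numeric parameters; `tau` must be positive.
#' @param field name of the field the rate reads.
#' @return An object of class `rate_spec`.
#' @name rate_spec
NULL

#' @rdname rate_spec
#' @export
rate_constant <- function(k) {
  stopifnot(is.numeric(k), k >= 0)
  structure(list(type = "constant", k = k), class = "rate_spec")
}

#' @rdname rate_spec
#' @export
rate_linear <- function(field, coef, offset = 0) {
  stopifnot(is.character(field), is.numeric(coef), is.numeric(offset))
  structure(list(type = "linear", field = field, coef = coef,
                 offset = offset), class = "rate_spec")
}

#' @rdname rate_spec
#' @export
rate_pulse_linear <- function(field, coef, k0, tau) {
  if (tau <= 0) stop("pulse time constant tau must be positive")
  structure(list(type = "pulse_linear", field = field, coef = coef,
                 k0 = k0, tau = tau), class = "rate_spec")
}

#' @export
print.rate_spec <- function(x, ...) {
  cat(switch(x$type,
    constant = sprintf("<rate> %g /s\n", x$k),
    linear = sprintf("<rate> %g * %s + %g /s\n", x$coef, x$field, x$offset),
    pulse_linear = sprintf("<rate> %g * %s + %g exp(-t/%g) /s\n",
                           x$coef, x$field, x$k0, x$tau)))
  invisible(x)
}

# fields a rate spec reads (character vector, possibly empty)
.rate_fields <- function(spec) {
  if (spec$type %in% c("linear", "pulse_linear")) spec$field else character(0)
}

# Evaluate a rate spec for a vector of particles.
# `local` is a named list of per-particle local field values; `t` is the
# start of the sampling interval.  Returns list(rate, n_negative).
.eval_rate <- function(spec, local, t, np) {
  neg <- 0L
  val <- switch(spec$type,
    constant = rep.int(spec$k, np),
    linear = {
      F <- local[[spec$field]]
      neg <- sum(F < 0)
      spec$coef * pmax(F, 0) + spec$offset
    },
    pulse_linear = {
      F <- local[[spec$field]]
      neg <- sum(F < 0)
      spec$coef * pmax(F, 0) + spec$k0 * exp(-t / spec$tau)
    },
    stop(sprintf("unknown rate spec type '%s'", spec$type)))
  list(rate = val, n_negative = neg)
}

#' Field-coupling specifications
#'
#' Couplings connect the discrete and continuous subsystems inside a
#' [hybrid_model()]:
#'
#' * `coupling_particle_source(field, species, state, J)` — each particle of
#'   `species` in `state` releases into the subvolume containing it at rate
#'   `J` (\eqn{\mu M \cdot \mu m^3/s}); the source density in cell j is
#'   \eqn{J\, n_j / |\omega_j|}, the binned point-source convention.
#' * `coupling_relax(field, rate, target)` — first-order relaxation
#'   \eqn{-\mathrm{rate}\,(F - \mathrm{target})}, e.g. a pump term.
#' * `coupling_binding_exchange(field, species, bound_state, complex_state,
#'   kf, kr)` — reversible consumption of a concentration field by binding
#'   to discrete particles: sink \eqn{-k_f F \rho_{bound}} and source
#'   \eqn{+k_r \rho_{complex} / 602} (\eqn{\mu M/s}), with particle
#'   densities binned on the shared grid.
#' * `coupling_surface_recruitment(volume_field, surface_field, species,
#'   state, k_on, k_off)` — recruitment of a well-mixed cytosolic pool onto
#'   the membrane: per-element flux
#'   \eqn{k_{on} U \gamma_e - k_{off} S_e} (\eqn{\mu m^{-2} s^{-1}}) where
#'   \eqn{\gamma_e} is the binned surface density of `species` particles in
#'   `state`; the same number of molecules leaves the pool, so the exchange
#'   conserves total protein exactly per step.
#'
#' @param field,volume_field,surface_field field names.
#' @param species,state,bound_state,complex_state species and state labels.
#' @param J,rate,target,kf,kr,k_on,k_off numeric parameters (units above).
#' @return An object of class `coupling_spec`.
#' @name coupling_spec
NULL

#' @rdname coupling_spec
#' @export
coupling_particle_source <- function(field, species, state, J) {
  structure(list(type = "particle_source", field = field, species = species,
                 state = state, J = J), class = "coupling_spec")
}

#' @rdname coupling_spec
#' @export
coupling_relax <- function(field, rate, target) {
  structure(list(type = "relax", field = field, rate = rate,
                 target = target), class = "coupling_spec")
}

#' @rdname coupling_spec
#' @export
coupling_binding_exchange <- function(field, species, bound_state,
                                      complex_state, kf, kr) {
  structure(list(type = "binding_exchange", field = field, species = species,
                 bound_state = bound_state, complex_state = complex_state,
                 kf = kf, kr = kr), class = "coupling_spec")
}

#' @rdname coupling_spec
#' @export
coupling_surface_recruitment <- function(volume_field, surface_field,
                                         species, state, k_on, k_off) {
  structure(list(type = "surface_recruitment", volume_field = volume_field,
                 surface_field = surface_field, species = species,
                 state = state, k_on = k_on, k_off = k_off),
            class = "coupling_spec")
}
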