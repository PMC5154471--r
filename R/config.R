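#' Serialize a model to a plain configuration list
#'
#' Converts a [hybrid_model()] to a nested list of plain R types suitable
#' for YAML, and back.  The round trip
#' `model_from_config(model_to_config(m))` reproduces the model exactly
#' (geometry is stored by its generating parameters: box bounds and
#' spacing, or sphere radius and subdivision level).
#'
#' @param model a [hybrid_model()].
#' @return `model_to_config`: a plain nested list.
#' @export
model_to_config <- function(model) {
  cfg <- list(name = model$name, dt = model$dt, T = model$T,
              step_order = model$step_order,
              rate_dt_guard = model$rate_dt_guard)
  if (!is.null(model$grid))
    cfg$grid <- list(lower = as.numeric(model$grid$lower),
                     upper = as.numeric(model$grid$upper),
                     spacing = as.numeric(model$grid$spacing))
  if (!is.null(model$surface)) {
    s <- model$surface
    if (is.null(s$radius))
      stop("only sphere surfaces (icosphere) are serializable")
    cfg$surface <- list(radius = s$radius, subdivisions = s$subdivisions,
                        center = as.numeric(s$center))
  }
  cfg$fields <- lapply(model$fields, function(f) f[!vapply(f, is.null, TRUE)])
  cfg$species <- lapply(model$species, function(s) {
    out <- s
    if (is.matrix(s$positions)) {
      out$positions <- list(kind = "matrix",
                            values = as.numeric(s$positions),
                            n = nrow(s$positions))
    } else if (is.list(s$positions)) {
      out$positions <- list(kind = "surface", tri = as.integer(s$positions$tri),
                            bary = as.numeric(s$positions$bary),
                            n = length(s$positions$tri))
    }
    if (!is.null(s$diffusivity)) out$diffusivity <- as.list(s$diffusivity)
    out
  })
  cfg$transitions <- lapply(model$transitions, function(r) {
    r$rate <- unclass(r$rate)
    r
  })
  cfg$couplings <- lapply(model$couplings, unclass)
  cfg
}

#' @rdname model_to_config
#' @param cfg a configuration list as produced by `model_to_config` (or
#'   parsed from YAML).
#' @return `model_from_config`: the reconstructed [hybrid_model()].
#' @export
model_from_config <- function(cfg) {
  grid <- NULL
  surface <- NULL
  if (!is.null(cfg$grid))
    grid <- build_box_grid(rbind(unlist(cfg$grid$lower),
                                 unlist(cfg$grid$upper)),
                           unlist(cfg$grid$spacing))
  if (!is.null(cfg$surface))
    surface <- icosphere(cfg$surface$radius, cfg$surface$subdivisions,
                         center = unlist(cfg$surface$center))
  species <- lapply(cfg$species, function(s) {
    if (is.list(s$positions) && !is.null(s$positions$kind)) {
      if (s$positions$kind == "matrix") {
        s$positions <- matrix(unlist(s$positions$values), s$positions$n, 3L)
      } else {
        s$positions <- list(tri = unlist(s$positions$tri),
                            bary = matrix(unlist(s$positions$bary),
                                          s$positions$n, 3L))
      }
    }
    if (!is.null(s$diffusivity)) s$diffusivity <- unlist(s$diffusivity)
    if (!is.null(s$init_state)) s$init_state <- unlist(s$init_state)
    s$states <- unlist(s$states)
    s
  })
  fields <- lapply(cfg$fields, function(f) {
    if (!is.null(f$init)) f$init <- unlist(f$init)
    f
  })
  transitions <- lapply(cfg$transitions, function(r) {
    r$rate <- structure(r$rate, class = "rate_spec")
    r
  })
  couplings <- lapply(cfg$couplings, function(cp)
    structure(cp, class = "coupling_spec"))
  hybrid_model(name = cfg$name, grid = grid, surface = surface,
               fields = fields, species = species,
               transitions = transitions, couplings = couplings,
               dt = cfg$dt, T = cfg$T, step_order = cfg$step_order,
               rate_dt_guard = cfg$rate_dt_guard)
}

#' Read and write model configurations as YAML
#'
#' @param model a [hybrid_model()].
#' @param path file path.
#' @return `write_model_yaml` returns `path` invisibly;
#'   `read_model_yaml` returns the [hybrid_model()].
#' @export
write_model_yaml <- function(model, path) {
  yaml::write_yaml(model_to_config(model), path, precision = 15L)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  model_from_config(yaml::read_yaml(path))
}
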