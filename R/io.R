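#' Write a field snapshot as a legacy VTK structured-points file
#'
#' Cell-centred field values on a [build_box_grid()] are written as ASCII
#' legacy VTK `STRUCTURED_POINTS` cell data, in the package's canonical
#' cell order (x fastest), so files are reproducible bit-for-bit.
#'
#' @param path output file.
#' @param grid the grid.
#' @param fields named list of per-cell vectors.
#' @param title dataset title line.
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(path, grid, fields, title = "hybridrd field") {
  stopifnot(inherits(grid, "box_grid"), length(fields) > 0)
  con <- file(path, "w")
  on.exit(close(con))
  n <- grid$dims
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1] + 1L, n[2] + 1L, n[3] + 1L),
               sprintf("ORIGIN %.10g %.10g %.10g", grid$lower[1],
                       grid$lower[2], grid$lower[3]),
               sprintf("SPACING %.10g %.10g %.10g", grid$spacing[1],
                       grid$spacing[2], grid$spacing[3]),
               sprintf("CELL_DATA %d", grid$ncell)), con)
  for (fn in names(fields)) {
    v <- fields[[fn]]
    if (length(v) != grid$ncell) stop("field length must equal ncell")
    writeLines(c(sprintf("SCALARS %s double 1", fn),
                 "LOOKUP_TABLE default"), con)
    writeLines(formatC(v, format = "g", digits = 15), con)
  }
  invisible(path)
}

#' Write a particle snapshot as CSV
#'
#' Columns: `id, species, state, x, y, z, t`.
#'
#' @param path output file.
#' @param particles a [particle_set()] or [surface_particle_set()] (the
#'   latter needs `mesh` to resolve coordinates).
#' @param t snapshot time (s).
#' @param mesh surface mesh for surface particles.
#' @return `path`, invisibly.
#' @export
write_particles_csv <- function(path, particles, t = 0, mesh = NULL) {
  if (inherits(particles, "surface_particle_set")) {
    if (is.null(mesh)) stop("surface particles need `mesh`")
    pos <- surface_points(mesh, particles$tri, particles$bary)
  } else {
    pos <- particles$positions
  }
  df <- data.frame(id = seq_len(particles$n), species = particles$species,
                   state = particles$state, x = pos[, 1], y = pos[, 2],
                   z = pos[, 3], t = t)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ensemble record to a directory of CSV files
#'
#' Writes `times.csv`, per-field ensemble mean/variance series, and
#' per-species mean state counts; metadata (model name, n, dt, seed) goes
#' to `meta.csv` for provenance.
#'
#' @param ens a [run_ensemble()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble_csv <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fm <- do.call(cbind, ens$field_mean)
  fv <- do.call(cbind, ens$field_var)
  colnames(fv) <- paste0(colnames(fv), "_var")
  utils::write.csv(cbind(t = ens$times, fm, fv),
                   file.path(dir, "fields.csv"), row.names = FALSE)
  for (sn in names(ens$state_mean))
    utils::write.csv(cbind(t = ens$times, ens$state_mean[[sn]]),
                     file.path(dir, paste0("states_", sn, ".csv")),
                     row.names = FALSE)
  meta <- data.frame(model = ens$model_name, n = ens$n, dt = ens$dt,
                     mode = ens$mode %||% "collective",
                     base_seed = ens$base_seed %||% NA)
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}
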