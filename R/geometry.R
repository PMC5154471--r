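#' Build a regular rectangular finite-volume grid
#'
#' Partitions an axis-aligned box into equal rectangular subvolumes
#' \eqn{\omega_j}.  Cells are ordered lexicographically with x fastest,
#' then y, then z, so that cell \eqn{j} (1-based) has integer coordinates
#' `ix = (j-1) %% nx`, `iy = ((j-1) %/% nx) %% ny`, `iz = (j-1) %/% (nx*ny)`.
#' This ordering is part of the package contract: field vectors and field
#' files are reproducible bit-for-bit.
#'
#' @param extents 2 x 3 numeric matrix of box bounds in \eqn{\mu m};
#'   column k holds `c(lower, upper)` for axis k.  A length-6 vector
#'   `c(x0, x1, y0, y1, z0, z1)` is also accepted.
#' @param spacing length-3 numeric vector of mesh sizes
#'   \eqn{\Delta x, \Delta y, \Delta z} in \eqn{\mu m} (a scalar is
#'   recycled).  Each box side must be an integer multiple of its spacing
#'   to within relative tolerance `1e-9`; non-divisible extents are an
#'   error, never silently rounded.
#' @return An object of class `box_grid`: a list with elements `lower`,
#'   `upper`, `spacing`, `dims` (cells per axis), `ncell`, and
#'   `cell_volume` (\eqn{\mu m^3}).
#' @seealso [locate_cell()], [bin_particles()], [cell_centers()]
#' @export
#' @examples
#' g <- build_box_grid(rbind(c(0, 0, 0), c(10.1, 2.1, 0.5)),
#'                     c(0.1, 0.1, 0.5))
#' g$ncell        # 2121
#' g$cell_volume  # 0.005
build_box_grid <- function(extents, spacing) {
  if (is.numeric(extents) && length(extents) == 6L && is.null(dim(extents)))
    extents <- matrix(extents, nrow = 2L)
  extents <- as.matrix(extents)
  if (!all(dim(extents) == c(2L, 3L)))
    stop("`extents` must be a 2 x 3 matrix of box bounds")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive mesh sizes")
  lower <- extents[1L, ]
  upper <- extents[2L, ]
  if (any(upper <= lower))
    stop("each upper bound must exceed the lower bound")
  side <- upper - lower
  n_exact <- side / spacing
  n <- round(n_exact)
  bad <- which(n < 1 | abs(n_exact - n) > 1e-9 * pmax(1, n_exact))
  if (length(bad)) {
    stop(sprintf(
      "box side %s (%.10g) is not an integer multiple of spacing %.10g",
      c("x", "y", "z")[bad[1L]], side[bad[1L]], spacing[bad[1L]]))
  }
  structure(
    list(lower = lower, upper = upper, spacing = spacing,
         dims = as.integer(n), ncell = as.integer(prod(n)),
         cell_volume = prod(spacing)),
    class = "box_grid")
}

#' @export
print.box_grid <- function(x, ...) {
  cat(sprintf(
    "<box_grid> [%g,%g]x[%g,%g]x[%g,%g] um^3, %d x %d x %d cells (|w_j| = %g um^3)\n",
    x$lower[1], x$upper[1], x$lower[2], x$upper[2], x$lower[3], x$upper[3],
    x$dims[1], x$dims[2], x$dims[3], x$cell_volume))
  invisible(x)
}

#' Cell centers of a box grid
#'
#' @param grid a [build_box_grid()] object.
#' @return `ncell` x 3 matrix of subvolume centers \eqn{r_j}
#'   (\eqn{\mu m}), in lexicographic cell order (x fastest).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "box_grid"))
  n <- grid$dims
  ix <- (seq_len(grid$ncell) - 1L) %% n[1L]
  iy <- ((seq_len(grid$ncell) - 1L) %/% n[1L]) %% n[2L]
  iz <- (seq_len(grid$ncell) - 1L) %/% (n[1L] * n[2L])
  cbind(x = grid$lower[1L] + (ix + 0.5) * grid$spacing[1L],
        y = grid$lower[2L] + (iy + 0.5) * grid$spacing[2L],
        z = grid$lower[3L] + (iz + 0.5) * grid$spacing[3L])
}

#' Locate points in grid cells
#'
#' Maps positions to the index of the subvolume containing them.  Cells are
#' half-open, `[low, high)` on every axis, so a point exactly on an interior
#' face belongs to the cell on the higher-index side; the global upper
#' boundary of the box is closed so that every point of the domain maps to
#' exactly one cell.
#'
#' @param grid a [build_box_grid()] object.
#' @param pos numeric length-3 vector, or n x 3 matrix of positions
#'   (\eqn{\mu m}).
#' @return integer vector of 1-based cell indices in lexicographic order.
#' @export
locate_cell <- function(grid, pos) {
  stopifnot(inherits(grid, "box_grid"))
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3L)
  n <- grid$dims
  idx <- matrix(0L, nrow(pos), 3L)
  for (k in 1:3) {
    x <- pos[, k]
    out <- which(x < grid$lower[k] | x > grid$upper[k])
    if (length(out)) {
      stop(sprintf(
        "position %d outside the grid on the %s axis (%.6g not in [%.6g, %.6g])",
        out[1L], c("x", "y", "z")[k], x[out[1L]], grid$lower[k], grid$upper[k]))
    }
    i <- floor((x - grid$lower[k]) / grid$spacing[k])
    i[i >= n[k]] <- n[k] - 1    # closed global upper boundary
    idx[, k] <- as.integer(i)
  }
  idx[, 1L] + n[1L] * (idx[, 2L] + n[2L] * idx[, 3L]) + 1L
}

#' Create a set of volume particles
#'
#' A `particle_set` is the discrete stochastic subsystem: point particles
#' with positions, a species label, one state per particle drawn from the
#' species' declared state set, and a per-state diffusivity.
#'
#' @param positions n x 3 matrix of positions (\eqn{\mu m}).
#' @param state character or integer vector of per-particle states
#'   (recycled if scalar); must be drawn from `states`.
#' @param states character vector naming the species' state set.
#' @param species species label (single string).
#' @param diffusivity named numeric vector of per-state diffusivities
#'   (\eqn{\mu m^2/s}); missing states default to 0 (immobile).
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(positions, state, states, species = "particle",
                         diffusivity = NULL) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3L)
  n <- nrow(positions)
  if (length(state) == 1L) state <- rep(state, n)
  if (is.numeric(state)) state <- states[state]
  if (length(state) != n) stop("one state per particle is required")
  if (!all(state %in% states))
    stop(sprintf("unknown state label '%s' (declared: %s)",
                 setdiff(state, states)[1L], paste(states, collapse = ", ")))
  D <- stats::setNames(rep(0, length(states)), states)
  if (!is.null(diffusivity)) D[names(diffusivity)] <- diffusivity
  if (any(D < 0)) stop("diffusivities must be >= 0")
  structure(list(positions = positions, state = state, states = states,
                 species = species, diffusivity = D, n = n),
            class = "particle_set")
}

#' Bin particles into a per-cell density field
#'
#' Converts point particles in a given state into a piecewise-constant
#' density on the finite-volume grid: the value in cell \eqn{\omega_j} is
#' the number of particles in that state inside \eqn{\omega_j} divided by
#' \eqn{|\omega_j|}.  The binning satisfies the exact mass identity
#' \eqn{\sum_j \mathrm{value}_j |\omega_j| = } (integer count of particles
#' in the state).
#'
#' @param particles a [particle_set()].
#' @param grid a [build_box_grid()] object.
#' @param state state label to bin (must belong to the declared state set).
#' @return numeric vector of length `grid$ncell` with densities in
#'   \eqn{\mu m^{-3}}.
#' @export
bin_particles <- function(particles, grid, state) {
  stopifnot(inherits(particles, "particle_set"), inherits(grid, "box_grid"))
  if (!state %in% particles$states)
    stop(sprintf("unknown state label '%s' (declared: %s)", state,
                 paste(particles$states, collapse = ", ")))
  counts <- numeric(grid$ncell)
  keep <- particles$state == state
  if (any(keep)) {
    j <- locate_cell(grid, particles$positions[keep, , drop = FALSE])
    counts <- tabulate(j, nbins = grid$ncell)
  }
  counts / grid$cell_volume
}
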