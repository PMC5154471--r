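#' Assemble the finite-volume diffusion operator on a box grid
#'
#' Builds the sparse discrete diffusion operator \eqn{L} (units s\eqn{^{-1}})
#' such that \eqn{\partial_t U = L U + \mathrm{sources}}.  With no-flux
#' boundaries, rows of \eqn{L} sum to zero exactly (interior and boundary),
#' so the scheme conserves discrete mass \eqn{\sum_j U_j |\omega_j|} by
#' construction.  With Dirichlet boundaries the boundary face is held at a
#' fixed value, discretized at half-cell distance.
#'
#' @param grid a [build_box_grid()] object.
#' @param D diffusivity (\eqn{\mu m^2/s}), must be \eqn{\ge 0}.
#' @param bc `"no-flux"` (default) or `"dirichlet"`.
#' @param value boundary value for `bc = "dirichlet"`.
#' @return An object of class `diffusion_operator`: list with the sparse
#'   matrix `L`, a constant source vector `rhs_const` (zero for no-flux),
#'   and the assembly parameters.
#' @export
diffusion_operator <- function(grid, D, bc = c("no-flux", "dirichlet"),
                               value = NULL) {
  stopifnot(inherits(grid, "box_grid"))
  bc <- match.arg(bc)
  if (!is.finite(D) || D < 0) stop("diffusivity D must be finite and >= 0")
  if (bc == "dirichlet" && is.null(value))
    stop("bc = 'dirichlet' requires a boundary `value`")
  n <- grid$dims
  N <- grid$ncell
  idx <- seq_len(N) - 1L
  ix <- idx %% n[1L]
  iy <- (idx %/% n[1L]) %% n[2L]
  iz <- idx %/% (n[1L] * n[2L])
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs_const <- numeric(N)
  coords <- list(ix, iy, iz)
  strides <- c(1L, n[1L], n[1L] * n[2L])
  for (k in 1:3) {
    c_k <- D / grid$spacing[k]^2
    if (c_k == 0) next
    has_up <- coords[[k]] < n[k] - 1L
    j0 <- which(has_up)
    j1 <- j0 + strides[k]
    ii <- c(ii, j0, j1, j0, j1)
    jj <- c(jj, j1, j0, j0, j1)
    xx <- c(xx, rep(c_k, 2L * length(j0)), rep(-c_k, 2L * length(j0)))
    if (bc == "dirichlet") {
      # each boundary face contributes a half-cell-distance fixed value;
      # duplicate triplets (one-cell-thick axes) are summed by sparseMatrix
      for (face in list(which(coords[[k]] == 0L),
                        which(coords[[k]] == n[k] - 1L))) {
        ii <- c(ii, face); jj <- c(jj, face)
        xx <- c(xx, rep(-2 * c_k, length(face)))
        rhs_const[face] <- rhs_const[face] + 2 * c_k * value
      }
    }
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  structure(list(L = L, rhs_const = rhs_const, grid = grid, D = D, bc = bc,
                 value = value),
            class = "diffusion_operator")
}

#' Cache the factorization of the semi-implicit system
#'
#' Factorizes \eqn{A = I - \Delta t\, L} once (sparse Cholesky), so that
#' repeated [semi_implicit_step()] calls are back-substitutions.  \eqn{A}
#' is a symmetric M-matrix for both supported boundary conditions.
#'
#' @param op a [diffusion_operator()] or [surface_operator()].
#' @param dt time step (s), must be positive.
#' @return An object of class `pde_stepper`.
#' @export
pde_stepper <- function(op, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (inherits(op, "surface_operator")) {
    # symmetrized system: (diag(a) - dt W) S^{t+dt} = a * rhs
    A <- Matrix::Diagonal(x = op$areas) - dt * op$W
    fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
    return(structure(list(factor = fac, dt = dt, op = op, surface = TRUE),
                     class = "pde_stepper"))
  }
  stopifnot(inherits(op, "diffusion_operator"))
  A <- Matrix::Diagonal(nrow(op$L)) - dt * op$L
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  structure(list(factor = fac, dt = dt, op = op, surface = FALSE),
            class = "pde_stepper")
}

#' One semi-implicit update of a field
#'
#' Solves \eqn{(I - \Delta t\, L)\, U^{t+\Delta t} = U^t + \Delta t\, s(t)}:
#' the diffusion operator acts on the unknown at \eqn{t + \Delta t} while
#' reaction and flux sources `s` are evaluated from the state at time
#' \eqn{t} (the semi-implicit contract).  `U` may be a matrix with one
#' column per realization; the factorized solve is applied to all columns
#' at once.
#'
#' @param stepper a [pde_stepper()].
#' @param U field values (vector of length `ncell`, or `ncell` x n matrix).
#' @param sources explicit source rates evaluated at time t (same shape as
#'   `U`, or scalar 0); Dirichlet boundary terms are added automatically.
#' @param check if `TRUE`, verify the relative residual of the linear
#'   solve against `tol` and error with a residual report if exceeded.
#' @param tol relative residual tolerance (default `1e-10`).
#' @return updated field, same shape as `U`.
#' @export
semi_implicit_step <- function(stepper, U, sources = 0, check = FALSE,
                               tol = 1e-10) {
  stopifnot(inherits(stepper, "pde_stepper"))
  dt <- stepper$dt
  if (stepper$surface) {
    a <- stepper$op$areas
    rhs <- U + dt * sources
    rhs <- if (is.matrix(rhs)) rhs * a else rhs * a
    out <- Matrix::solve(stepper$factor, rhs, system = "A")
  } else {
    rhs <- U + dt * sources
    if (any(stepper$op$rhs_const != 0)) rhs <- rhs + dt * stepper$op$rhs_const
    out <- Matrix::solve(stepper$factor, rhs, system = "A")
  }
  out <- as.matrix(out)
  if (check) {
    A <- if (stepper$surface)
      Matrix::Diagonal(x = stepper$op$areas) - dt * stepper$op$W
    else
      Matrix::Diagonal(nrow(stepper$op$L)) - dt * stepper$op$L
    res <- max(abs(A %*% out - rhs)) / max(abs(rhs), 1e-300)
    if (!is.finite(res) || res > tol)
      stop(sprintf("linear solve residual %.3e exceeds tolerance %.3e",
                   res, tol))
  }
  if (is.null(dim(U))) drop(out) else out
}

#' Assemble the finite-volume Laplace-Beltrami operator on a surface mesh
#'
#' Element-centred finite-volume discretization of surface diffusion:
#' the flux between two adjacent triangles is
#' \eqn{D\,\ell_e / d_e \,(S_k - S_j)} where \eqn{\ell_e} is the shared
#' edge length and \eqn{d_e} the centroid-to-centroid distance through the
#' edge midpoint.  The scheme conserves total surface mass
#' \eqn{\sum_e S_e\,\mathrm{area}_e} exactly, by antisymmetry of the edge
#' fluxes, matching the finite-volume treatment of the volume PDEs.
#'
#' @param mesh a [surface_mesh] object.
#' @param D surface diffusivity (\eqn{\mu m^2/s}).
#' @param min_area triangles with area below this threshold (\eqn{\mu m^2})
#'   are rejected at assembly as degenerate.
#' @return An object of class `surface_operator` with the symmetric edge
#'   weight matrix `W` (so that \eqn{\partial_t S = \mathrm{diag}(a)^{-1} W S}),
#'   per-element `areas`, and `L`, the density-form operator
#'   \eqn{\mathrm{diag}(a)^{-1} W} (s\eqn{^{-1}}).
#' @export
surface_operator <- function(mesh, D, min_area = 1e-12) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is.finite(D) || D < 0) stop("diffusivity D must be finite and >= 0")
  if (any(mesh$areas < min_area))
    stop(sprintf("degenerate triangle: area %.3e below threshold %.3e",
                 min(mesh$areas), min_area))
  e <- mesh$edges
  w <- D * e$length / e$dist
  N <- mesh$ncell
  W <- Matrix::sparseMatrix(
    i = c(e$t1, e$t2, e$t1, e$t2),
    j = c(e$t2, e$t1, e$t1, e$t2),
    x = c(w, w, -w, -w), dims = c(N, N))
  structure(list(W = W, areas = mesh$areas,
                 L = Matrix::Diagonal(x = 1 / mesh$areas) %*% W,
                 mesh = mesh, D = D),
            class = "surface_operator")
}

#' One semi-implicit update of a surface field
#'
#' Convenience wrapper: [semi_implicit_step()] applied to a surface
#' stepper.  Total surface mass is conserved in the absence of sources.
#'
#' @inheritParams semi_implicit_step
#' @export
surface_step <- function(stepper, S, sources = 0, check = FALSE,
                         tol = 1e-10) {
  stopifnot(stepper$surface)
  semi_implicit_step(stepper, S, sources, check = check, tol = tol)
}

#' Exchange mass between a volume pool and a surface field
#'
#' Applies a membrane flux evaluated at time t: the surface field gains
#' `flux` (\eqn{\mu m^{-2} s^{-1}}) per element over \eqn{\Delta t}, and
#' the same number of molecules leaves the volume pool, so the exchange
#' conserves total molecule count to rounding error.
#'
#' @param U volume concentration (\eqn{\mu M}; scalar pool or vector per
#'   realization).
#' @param S surface density field (per element, \eqn{\mu m^{-2}};
#'   matrix with one column per realization allowed).
#' @param flux per-element flux at time t, positive toward the surface
#'   (same shape as `S`).
#' @param areas per-element areas (\eqn{\mu m^2}).
#' @param volume volume of the pool (\eqn{\mu m^3}).
#' @param dt time step (s).
#' @return list with updated `U` and `S`.
#' @export
apply_membrane_flux <- function(U, S, flux, areas, volume, dt) {
  dS <- dt * flux
  moved <- if (is.matrix(dS)) colSums(dS * areas) else sum(dS * areas)
  list(U = U - moved / (MOLECULES_PER_UMOLAR_UM3 * volume), S = S + dS)
}
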