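#' Triangulated closed surface meshes
#'
#' A `surface_mesh` represents the cell membrane \eqn{\partial\Omega} as a
#' closed, outward-oriented triangulation.  Surface fields are stored as
#' per-element (per-triangle) averages, and surface particles as
#' `(triangle index, barycentric coordinates)` pairs, so "on the membrane"
#' is exact by construction.
#'
#' @section Structure:
#' A `surface_mesh` is a list with `vertices` (nv x 3, \eqn{\mu m}),
#' `triangles` (nt x 3 vertex indices, counter-clockwise seen from
#' outside), `areas` (\eqn{\mu m^2}), `normals` (nt x 3 outward unit
#' normals), `centroids` (nt x 3), and `edges`, a data frame of interior
#' edges with the two adjacent triangles, the edge length and the
#' centroid-to-centroid distance through the edge midpoint used by the
#' finite-volume Laplace-Beltrami operator.
#'
#' @name surface_mesh
NULL

.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v / sqrt(1 + phi^2), triangles = f)
}

.subdivide_sphere <- function(v, f) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e1 <- key(f[, 1], f[, 2]); e2 <- key(f[, 2], f[, 3]); e3 <- key(f[, 3], f[, 1])
  edges <- unique(c(e1, e2, e3))
  mid_of <- function(k) {
    ij <- do.call(rbind, strsplit(k, " "))
    i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
    m <- (v[i, , drop = FALSE] + v[j, , drop = FALSE]) / 2
    m / sqrt(rowSums(m^2))
  }
  mids <- mid_of(edges)
  midx <- nrow(v) + match(cbind(e1, e2, e3), edges)
  dim(midx) <- dim(f)
  a <- f[, 1]; b <- f[, 2]; c <- f[, 3]
  ab <- midx[, 1]; bc <- midx[, 2]; ca <- midx[, 3]
  list(vertices = rbind(v, mids),
       triangles = rbind(cbind(a, ab, ca), cbind(b, bc, ab),
                         cbind(c, ca, bc), cbind(ab, bc, ca)))
}

.finalize_mesh <- function(v, f, center) {
  nt <- nrow(f)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- cr(p2 - p1, p3 - p1)
  len <- sqrt(rowSums(nrm^2))
  centroids <- (p1 + p2 + p3) / 3
  # orient outward with respect to the interior point `center`
  flip <- rowSums(nrm * (centroids - matrix(center, nt, 3, byrow = TRUE))) < 0
  if (any(flip)) {
    f[flip, 2:3] <- f[flip, 3:2]
    tmp <- p2[flip, , drop = FALSE]
    p2[flip, ] <- p3[flip, , drop = FALSE]; p3[flip, ] <- tmp
    nrm <- cr(p2 - p1, p3 - p1)
    len <- sqrt(rowSums(nrm^2))
  }
  areas <- len / 2
  normals <- nrm / len
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- c(key(f[, 1], f[, 2]), key(f[, 2], f[, 3]), key(f[, 3], f[, 1]))
  tri <- rep(seq_len(nt), 3L)
  ord <- order(ek)
  ek <- ek[ord]; tri <- tri[ord]
  first <- !duplicated(ek)
  if (!all(table(ek) == 2L))
    stop("surface is not closed: an edge is not shared by exactly 2 triangles")
  t1 <- tri[first]; t2 <- tri[!first]
  vij <- do.call(rbind, strsplit(ek[first], " "))
  i <- as.integer(vij[, 1]); j <- as.integer(vij[, 2])
  elen <- sqrt(rowSums((v[i, , drop = FALSE] - v[j, , drop = FALSE])^2))
  emid <- (v[i, , drop = FALSE] + v[j, , drop = FALSE]) / 2
  dist <- sqrt(rowSums((centroids[t1, , drop = FALSE] - emid)^2)) +
    sqrt(rowSums((centroids[t2, , drop = FALSE] - emid)^2))
  structure(
    list(vertices = v, triangles = f, areas = areas, normals = normals,
         centroids = centroids, ncell = nt, center = center,
         edges = data.frame(t1 = t1, t2 = t2, length = elen, dist = dist)),
    class = "surface_mesh")
}

#' Triangulated sphere by refined-icosahedron subdivision
#'
#' Generates a closed, outward-oriented triangulation of a sphere by
#' recursively subdividing an icosahedron and projecting new vertices to
#' the sphere.  Total triangle area converges to \eqn{4\pi R^2} from below
#' as the subdivision level increases.
#'
#' @param radius sphere radius (\eqn{\mu m}).
#' @param subdivisions number of 4-to-1 refinement passes (level s gives
#'   \eqn{20 \cdot 4^s} triangles).  Alternatively supply
#'   `edge_length` and the level is chosen as the coarsest one whose
#'   typical edge is below it.
#' @param edge_length optional target edge length (\eqn{\mu m}).
#' @param center sphere center (default origin).
#' @return A [surface_mesh] object.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, edge_length = NULL,
                      center = c(0, 0, 0)) {
  if (!is.null(edge_length)) {
    # icosahedron edge for unit sphere is about 1.0515; halves per level
    subdivisions <- max(0L, ceiling(log2(1.05146 * radius / edge_length)))
  }
  ico <- .icosahedron()
  v <- ico$vertices; f <- ico$triangles
  for (s in seq_len(subdivisions)) {
    sub <- .subdivide_sphere(v, f)
    v <- sub$vertices; f <- sub$triangles
  }
  v <- v * radius
  v <- sweep(v, 2L, center, "+")
  m <- .finalize_mesh(v, f, center)
  m$radius <- radius
  m$subdivisions <- subdivisions
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, area %.4g um^2\n",
              nrow(x$vertices), x$ncell, sum(x$areas)))
  invisible(x)
}

#' Total area of a surface mesh
#' @param mesh a [surface_mesh] object.
#' @return total triangle area (\eqn{\mu m^2}).
#' @export
surface_area <- function(mesh) sum(mesh$areas)

#' Convert (triangle, barycentric) coordinates to 3D points
#'
#' @param mesh a [surface_mesh] object.
#' @param tri integer vector of triangle indices.
#' @param bary n x 3 matrix of barycentric coordinates (rows sum to 1).
#' @return n x 3 matrix of positions (\eqn{\mu m}).
#' @export
surface_points <- function(mesh, tri, bary) {
  f <- mesh$triangles
  v <- mesh$vertices
  bary[, 1] * v[f[tri, 1], , drop = FALSE] +
    bary[, 2] * v[f[tri, 2], , drop = FALSE] +
    bary[, 3] * v[f[tri, 3], , drop = FALSE]
}

# Barycentric coordinates of the central projection of points onto triangle
# planes: solves w = a v1 + b v2 + c v3 for each (point, triangle) pair and
# normalizes to a+b+c = 1.  Rows of `w` are positions relative to the mesh
# center.  Valid for meshes that are star-shaped about their center.
.central_bary <- function(mesh, tri, w) {
  f <- mesh$triangles
  v <- sweep(mesh$vertices, 2L, mesh$center)
  v1 <- v[f[tri, 1], , drop = FALSE]
  v2 <- v[f[tri, 2], , drop = FALSE]
  v3 <- v[f[tri, 3], , drop = FALSE]
  # Cramer's rule, vectorized over rows
  det3 <- function(a, b, c) {
    a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  }
  d <- det3(v1, v2, v3)
  # unnormalized: the ray through w hits the triangle iff all three are
  # >= 0 AND their sum is > 0 (a negative sum means the antipodal side)
  cbind(det3(w, v2, v3) / d, det3(v1, w, v3) / d, det3(v1, v2, w) / d)
}

# Triangle neighbor table: nb[t, k] is the triangle across the edge opposite
# vertex k... here indexed by local edge (1: v1-v2, 2: v2-v3, 3: v3-v1).
.neighbor_table <- function(mesh) {
  f <- mesh$triangles
  nt <- mesh$ncell
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- cbind(key(f[, 1], f[, 2]), key(f[, 2], f[, 3]), key(f[, 3], f[, 1]))
  all_keys <- c(ek)
  tri <- rep(seq_len(nt), 3L)
  nb <- matrix(NA_integer_, nt, 3L)
  sp <- split(tri, all_keys)
  pair <- do.call(rbind, sp[match(c(ek), names(sp))])
  other <- ifelse(pair[, 1] == tri, pair[, 2], pair[, 1])
  nb[] <- other
  nb
}

#' Locate directions on a star-shaped mesh by walking
#'
#' Given points (or directions from the mesh center) and starting
#' triangles, finds the triangle whose central projection contains each
#' point, walking across edges toward the target.  Intended for small
#' displacements (one Brownian step), where the walk terminates in O(1)
#' hops.
#'
#' @param mesh a [surface_mesh] object with neighbor table (see
#'   [surface_walk_info()]).
#' @param points n x 3 matrix of target positions.
#' @param start integer vector of starting triangle indices.
#' @param max_hops walk cap; exceeding it is an error (diagnostic for a
#'   step size too large for the mesh).
#' @return list with `tri` (containing triangles) and `bary`
#'   (barycentric coordinates of the centrally projected points).
#' @export
surface_locate <- function(mesh, points, start, max_hops = 200L) {
  if (is.null(mesh$neighbors)) stop("mesh lacks a neighbor table; call surface_walk_info()")
  w <- sweep(points, 2L, mesh$center)
  tri <- start
  n <- nrow(w)
  act <- seq_len(n)
  bary <- matrix(0, n, 3L)
  for (hop in seq_len(max_hops)) {
    b <- .central_bary(mesh, tri[act], w[act, , drop = FALSE])
    s <- rowSums(b)
    bad <- b < -1e-12 * pmax(abs(s), 1)
    inside <- s > 0 & !(bad[, 1] | bad[, 2] | bad[, 3])
    if (any(inside)) {
      bary[act[inside], ] <- pmax(b[inside, , drop = FALSE], 0)
      bary[act[inside], ] <- bary[act[inside], , drop = FALSE] /
        rowSums(bary[act[inside], , drop = FALSE])
    }
    stay <- !inside
    if (!any(stay)) { act <- integer(0); break }
    bmin <- max.col(-b[stay, , drop = FALSE], ties.method = "first")
    # local edge opposite the most negative barycentric coordinate:
    # coordinate 1 negative -> cross edge v2-v3 (local edge 2), etc.
    edge <- c(2L, 3L, 1L)[bmin]
    tri[act[stay]] <- mesh$neighbors[cbind(tri[act[stay]], edge)]
    act <- act[stay]
  }
  if (length(act))
    stop("surface walk did not terminate; displacement too large for mesh")
  list(tri = tri, bary = bary)
}

#' Precompute walk adjacency for a surface mesh
#'
#' @param mesh a [surface_mesh] object.
#' @return the mesh with a `neighbors` table attached.
#' @export
surface_walk_info <- function(mesh) {
  if (is.null(mesh$neighbors)) mesh$neighbors <- .neighbor_table(mesh)
  mesh
}

#' Create a set of surface particles
#'
#' Surface particles are stored as (triangle index, barycentric
#' coordinates) so their membership of the membrane is exact.
#'
#' @param mesh a [surface_mesh] object.
#' @param tri integer vector of triangle indices.
#' @param bary n x 3 barycentric coordinates.
#' @param state,states,species,diffusivity as in [particle_set()].
#' @return An object of class `surface_particle_set`.
#' @export
surface_particle_set <- function(mesh, tri, bary, state, states,
                                 species = "particle", diffusivity = NULL) {
  n <- length(tri)
  if (length(state) == 1L) state <- rep(state, n)
  if (is.numeric(state)) state <- states[state]
  if (!all(state %in% states))
    stop(sprintf("unknown state label '%s'", setdiff(state, states)[1L]))
  D <- stats::setNames(rep(0, length(states)), states)
  if (!is.null(diffusivity)) D[names(diffusivity)] <- diffusivity
  structure(list(tri = as.integer(tri), bary = bary, state = state,
                 states = states, species = species, diffusivity = D, n = n),
            class = "surface_particle_set")
}

#' Sample uniformly distributed points on a surface mesh
#'
#' Triangles are chosen with probability proportional to area and points
#' uniformly within each triangle.
#'
#' @param mesh a [surface_mesh] object.
#' @param n number of points.
#' @return list with `tri` and `bary` suitable for
#'   [surface_particle_set()].
#' @export
surface_sample_uniform <- function(mesh, n) {
  tri <- sample.int(mesh$ncell, n, replace = TRUE, prob = mesh$areas)
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  bary <- cbind(1 - r1, r1 * (1 - r2), r1 * r2)
  list(tri = tri, bary = bary)
}

#' Bin surface particles into per-element densities
#'
#' @param particles a [surface_particle_set()].
#' @param mesh the [surface_mesh] the particles live on.
#' @param state state label to bin.
#' @return numeric vector of per-element densities (\eqn{\mu m^{-2}})
#'   satisfying the exact mass identity
#'   \eqn{\sum_e \mathrm{value}_e \cdot \mathrm{area}_e = } count.
#' @export
bin_surface_particles <- function(particles, mesh, state) {
  stopifnot(inherits(particles, "surface_particle_set"))
  if (!state %in% particles$states)
    stop(sprintf("unknown state label '%s'", state))
  keep <- particles$state == state
  tabulate(particles$tri[keep], nbins = mesh$ncell) / mesh$areas
}
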