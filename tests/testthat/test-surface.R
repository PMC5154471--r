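test_that("icosphere meshes are closed and their area converges to 4 pi R^2", {
  R <- 2
  errs <- vapply(1:3, function(s) {
    m <- icosphere(R, s)
    # closedness is asserted at construction; re-check the edge count here
    expect_equal(nrow(m$edges), 3 * m$ncell / 2)
    abs(1 - surface_area(m) / (4 * pi * R^2))
  }, 0)
  expect_true(all(diff(errs) < 0))          # monotone error decrease
  m3 <- icosphere(R, 3)                     # default resolution
  expect_lt(abs(1 - surface_area(m3) / (4 * pi * R^2)), 0.02)
  # outward normals
  expect_true(all(rowSums(m3$normals * m3$centroids) > 0))
})

test_that("surface point location by walking agrees with brute force", {
  m <- surface_walk_info(icosphere(1.5, 2))
  set.seed(3)
  dirs <- matrix(rnorm(90), 30, 3)
  dirs <- 1.5 * dirs / sqrt(rowSums(dirs^2))
  loc <- surface_locate(m, dirs, start = rep(1L, 30), max_hops = 500L)
  brute <- vapply(seq_len(30), function(i) {
    b <- hybridrd:::.central_bary(m, seq_len(m$ncell),
                                  matrix(dirs[i, ], m$ncell, 3, byrow = TRUE))
    s <- rowSums(b)
    which(s > 0 & b[, 1] >= -1e-9 & b[, 2] >= -1e-9 & b[, 3] >= -1e-9)[1]
  }, 1L)
  expect_identical(loc$tri, brute)
  pts <- surface_points(m, loc$tri, loc$bary)
  # located points are the central projections of the directions
  expect_lt(max(abs(pts / sqrt(rowSums(pts^2)) - dirs / 1.5)), 1e-9)
})

test_that("uniform surface sampling and binning respect areas exactly", {
  m <- icosphere(3, 2)
  set.seed(11)
  u <- surface_sample_uniform(m, 4000)
  sp <- surface_particle_set(m, u$tri, u$bary, "on", states = c("on", "off"))
  dens <- bin_surface_particles(sp, m, "on")
  expect_equal(sum(dens * m$areas), 4000, tolerance = 1e-12)
  expect_equal(sum(bin_surface_particles(sp, m, "off")), 0)
  # sampled points lie on the triangulated membrane (inside the sphere)
  pts <- surface_points(m, u$tri, u$bary)
  r <- sqrt(rowSums(pts^2))
  expect_true(all(r <= 3 + 1e-12) && all(r > 3 * 0.9))
  expect_error(surface_particle_set(m, u$tri, u$bary, "nope",
                                    states = c("on", "off")),
               "unknown state")
})
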