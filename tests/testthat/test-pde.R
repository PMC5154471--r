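test_that("diffusion operator is conservative and reduces correctly", {
  # D = 0 -> identity semi-implicit update
  g1 <- build_box_grid(c(0, 1, 0, 1, 0, 1), c(0.5, 1, 1))
  op0 <- diffusion_operator(g1, D = 0)
  st0 <- pde_stepper(op0, 0.1)
  u <- c(1, 3)
  expect_equal(semi_implicit_step(st0, u), u, tolerance = 1e-14)

  # 1D 3-cell no-flux chain: zero row sums, (-1, 1)/dx^2 end rows
  g3 <- build_box_grid(c(0, 3, 0, 1, 0, 1), c(1, 1, 1))
  L <- as.matrix(diffusion_operator(g3, D = 2)$L)
  expect_equal(rowSums(L), rep(0, 3))
  expect_equal(L[1, ], c(-2, 2, 0))
  expect_equal(L[2, ], c(2, -4, 2))

  set.seed(1)
  g <- build_box_grid(c(0, 1, 0, 1, 0, 1), rep(0.1, 3))
  op <- diffusion_operator(g, D = 1.3)
  U <- runif(g$ncell)
  expect_lt(abs(sum((op$L %*% U) * g$cell_volume)), 1e-12)
  expect_error(diffusion_operator(g, D = -1), "D must be")
})

test_that("semi-implicit stepping conserves mass, is stable, and is first order in dt", {
  g <- build_box_grid(c(0, 1, 0, 1, 0, 1), rep(0.25, 3))
  op <- diffusion_operator(g, D = 1)
  stp <- pde_stepper(op, 0.05)
  set.seed(2)
  U <- runif(g$ncell)
  # uniform field is a fixed point
  expect_equal(semi_implicit_step(stp, rep(2, g$ncell)), rep(2, g$ncell),
               tolerance = 1e-12)
  U1 <- U
  for (i in 1:300) U1 <- semi_implicit_step(stp, U1)
  expect_lt(abs(sum(U1) - sum(U)) / sum(U), 1e-10)
  # unconditional stability at dt * D / dx^2 = 1e3
  g2 <- build_box_grid(c(0, 1, 0, 1, 0, 1), c(0.01, 1, 1))
  stp2 <- pde_stepper(diffusion_operator(g2, D = 1), dt = 0.1)
  V <- runif(g2$ncell)
  vmax <- max(V)
  for (i in 1:20) V <- semi_implicit_step(stp2, V)
  expect_true(all(is.finite(V)))
  expect_lte(max(V), vmax + 1e-12)   # M-matrix: no overshoot, no blow-up
})

test_that("relaxation fixed point and decay convergence follow the closed form", {
  g <- build_box_grid(c(0, 1, 0, 1, 0, 1), c(1, 1, 1))
  stp <- pde_stepper(diffusion_operator(g, D = 0), 0.01)
  # pure decay toward U0: U(0) = U0 stays put
  u <- 0.1
  for (i in 1:50) u <- semi_implicit_step(stp, u, sources = 1 * (0.1 - u))
  expect_equal(u, 0.1, tolerance = 1e-12)
  v <- validate_pde_convergence()
  expect_equal(v$order_dt, 1, tolerance = 0.1)
  expect_equal(v$order_dx, 2, tolerance = 0.3)
  # explicit halving check: error ratio 2.0 +/- 0.2
  r <- v$decay$error[2] / v$decay$error[3]
  expect_equal(r, 2, tolerance = 0.1)
})

test_that("dirichlet boundaries hold the boundary value", {
  g <- build_box_grid(c(0, 1, 0, 1, 0, 1), rep(0.2, 3))
  op <- diffusion_operator(g, D = 1, bc = "dirichlet", value = 1)
  stp <- pde_stepper(op, 0.01)
  # uniform field at the boundary value is a fixed point
  U <- rep(1, g$ncell)
  for (i in 1:20) U <- semi_implicit_step(stp, U)
  expect_equal(U, rep(1, g$ncell), tolerance = 1e-12)
  # a depleted interior relaxes back to the boundary value
  U <- rep(0.2, g$ncell)
  for (i in 1:2000) U <- semi_implicit_step(stp, U)
  expect_equal(U, rep(1, g$ncell), tolerance = 1e-6)
})

test_that("surface diffusion conserves mass and decays harmonics at l(l+1) D/R^2", {
  R <- 2; Ds <- 0.1
  rates <- vapply(2:3, function(s) {
    m <- icosphere(R, s)
    so <- surface_operator(m, Ds)
    S0 <- m$centroids[, 3] / R            # degree-1 spherical harmonic
    stp <- pde_stepper(so, 0.002)
    S <- S0
    for (i in 1:250) S <- drop(surface_step(stp, S))
    expect_lt(abs(sum(S * m$areas) - sum(S0 * m$areas)), 1e-9)
    -log(sum(S * m$areas * S0) / sum(S0 * m$areas * S0)) / (250 * 0.002)
  }, 0)
  exact <- 2 * Ds / R^2
  errs <- abs(rates - exact) / exact
  expect_lt(errs[2], errs[1])             # converges under refinement
  expect_lt(errs[2], 0.01)
  # uniform surface field is a fixed point
  m <- icosphere(R, 2)
  stp <- pde_stepper(surface_operator(m, Ds), 0.01)
  expect_equal(drop(surface_step(stp, rep(3, m$ncell))), rep(3, m$ncell),
               tolerance = 1e-12)
})

test_that("membrane exchange moves the exact molecule count between pool and surface", {
  m <- icosphere(1, 1)
  A <- surface_area(m)
  V <- 4 / 3 * pi
  S <- rep(0, m$ncell)
  U <- 1
  flux <- rep(0.25, m$ncell)    # um^-2 s^-1 toward the surface
  out <- apply_membrane_flux(U, S, flux, m$areas, V, dt = 0.1)
  gained <- sum(out$S * m$areas)
  lost <- (U - out$U) * 602 * V
  expect_equal(gained, lost, tolerance = 1e-12)
  expect_equal(gained, 0.25 * 0.1 * A, tolerance = 1e-12)
})
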