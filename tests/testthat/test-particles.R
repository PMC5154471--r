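test_that("transition sampling uses the exact exponential one-step probability", {
  set.seed(1)
  n <- 2e5
  # all rates zero -> states unchanged (and n uniforms still consumed)
  st <- rep(1L, n)
  expect_identical(sample_transitions(st, 1L, 2L, matrix(0, n, 1), 0.002), st)
  # closed channel, kon = 1/s, dt = 2 ms: opening probability 1 - e^-0.002
  out <- sample_transitions(st, 1L, 2L, matrix(1, n, 1), 0.002)
  p_hat <- mean(out == 2L)
  p_exact <- -expm1(-0.002)
  expect_lt(abs(p_hat - p_exact), 4 * sqrt(p_exact / n))

  expect_error(
    sample_transitions(rep(1L, 3), 1L, 2L, matrix(300, 3, 1), 0.002,
                       rule_names = "channel: closed -> open"),
    "channel: closed -> open")
  expect_error(
    sample_transitions(rep(1L, 3), 1L, 2L, matrix(-1, 3, 1), 0.01),
    "negative")
})

test_that("a two-state particle reaches its stationary distribution and matrix-exponential marginals", {
  # dt small enough that the one-transition-per-step O(dt) bias in the
  # discrete chain (~ kon koff dt / (kon + koff)) is below Monte-Carlo error
  kon <- 1; koff <- 5; dt <- 5e-4
  n <- 1e5
  rates <- cbind(rep(kon, n), rep(koff, n))
  set.seed(2)
  st <- rep(1L, n)
  for (k in 1:2000) st <- sample_transitions(st, c(1L, 2L), c(2L, 1L), rates, dt)
  # occupancy at t = 1 against the closed-form two-state solution
  p_exact <- kon / (kon + koff) * (1 - exp(-(kon + koff) * 1))
  p_hat <- mean(st == 2L)
  expect_lt(abs(p_hat - p_exact), 4 * sqrt(p_exact * (1 - p_exact) / n))
  # long-run time-average open fraction -> kon / (kon + koff)
  occ <- 0; nsteps <- 2000
  for (k in seq_len(nsteps)) {
    st <- sample_transitions(st, c(1L, 2L), c(2L, 1L), rates, dt)
    occ <- occ + mean(st == 2L)
  }
  expect_equal(occ / nsteps, 1 / 6, tolerance = 0.02)
})

test_that("sojourn times are geometric with parameter 1 - exp(-k dt)", {
  k <- 1; dt <- 0.1
  n <- 2000; nsteps <- 1500
  rates <- cbind(rep(k, n), rep(k, n))
  set.seed(3)
  st <- matrix(0L, nsteps + 1, n)
  st[1, ] <- 1L
  s <- st[1, ]
  for (i in seq_len(nsteps)) {
    s <- sample_transitions(s, c(1L, 2L), c(2L, 1L), rates, dt)
    st[i + 1, ] <- s
  }
  p <- -expm1(-k * dt)
  soj <- unlist(apply(st, 2, function(x) {
    r <- rle(x)
    if (length(r$lengths) > 2) r$lengths[2:(length(r$lengths) - 1)] else integer(0)
  }))
  expect_gt(length(soj), 5e4)
  kmax <- 40L
  obs <- tabulate(pmin(soj, kmax), kmax)
  pr <- dgeom(0:(kmax - 2), p)
  pr <- c(pr, 1 - sum(pr))
  chi2 <- sum((obs - length(soj) * pr)^2 / (length(soj) * pr))
  expect_lt(chi2, qchisq(0.99, df = kmax - 1))
})

test_that("volume Brownian steps have the exact propagator moments and reflect at walls", {
  set.seed(4)
  n <- 2e4; D <- 1; dt <- 0.01; nsteps <- 10
  big <- c(-1e3, 1e3)
  pos0 <- matrix(0, n, 3)
  pos <- pos0
  for (i in seq_len(nsteps))
    pos <- diffuse_positions(pos, rep(D, n), dt, rep(big[1], 3), rep(big[2], 3))
  msd <- mean(rowSums((pos - pos0)^2))
  expect_equal(msd, 6 * D * dt * nsteps, tolerance = 0.05)
  # D = 0 never moves
  expect_identical(diffuse_positions(pos0, rep(0, n), dt, rep(-1, 3), rep(1, 3)),
                   pos0)
  # mixed mobility: immobile entries unchanged
  Dm <- rep(c(1, 0), length.out = n)
  pos2 <- diffuse_positions(pos0, Dm, dt, rep(big[1], 3), rep(big[2], 3))
  expect_identical(pos2[Dm == 0, ], pos0[Dm == 0, ])
  expect_false(any(pos2[Dm == 1, 1] == 0))
  # reflection keeps particles inside even for steps comparable to the box
  posr <- matrix(0.5, 500, 3)
  for (i in 1:50)
    posr <- diffuse_positions(posr, rep(5, 500), 0.01, rep(0, 3), rep(1, 3))
  expect_true(all(posr >= 0 & posr <= 1))
})

test_that("surface Brownian steps stay on the membrane with MSD ~ 4 D t", {
  R <- 50                                    # near-planar limit
  m <- surface_walk_info(icosphere(R, 4))
  set.seed(5)
  n <- 2000; D <- 1; dt <- 0.01; nsteps <- 10
  u <- surface_sample_uniform(m, n)
  tri <- u$tri; bary <- u$bary
  p0 <- surface_points(m, tri, bary)
  for (i in seq_len(nsteps)) {
    mv <- diffuse_on_surface(m, tri, bary, rep(D, n), dt)
    tri <- mv$tri; bary <- mv$bary
  }
  p1 <- surface_points(m, tri, bary)
  # geodesic displacement on the sphere
  cosang <- pmin(1, rowSums(p0 * p1) / (R * R) /
                   (sqrt(rowSums(p0^2)) / R) / (sqrt(rowSums(p1^2)) / R))
  geo2 <- (R * acos(cosang))^2
  expect_equal(mean(geo2), 4 * D * dt * nsteps, tolerance = 0.1)
  # particles remain on the mesh by construction
  expect_true(all(abs(rowSums(bary) - 1) < 1e-9) && all(bary >= 0))
  # immobile particles do not move
  mv0 <- diffuse_on_surface(m, tri, bary, rep(0, n), dt)
  expect_identical(mv0$tri, tri)
  expect_identical(mv0$bary, bary)
})
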