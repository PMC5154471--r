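test_that("the closed-form spark expectation matches an independent ODE integration", {
  expect_equal(analytic_mean_spark(0), 0.1)
  expect_equal(analytic_mean_spark(c(0, 1, 7), J = 0), rep(0.1, 3))
  # late-time limit U0 + J Nch pinf / (Vp |Omega|)
  expect_equal(analytic_mean_spark(1e3),
               0.1 + 10 * 24 / 6 / 10.605, tolerance = 1e-12)
  skip_if_not_installed("deSolve")
  tt <- c(0, 0.3, 1, 2.5, 5, 20)
  rhs <- function(t, y, p) {
    pbar <- (1 / 6) * (1 - exp(-6 * t))
    list(10 * 24 * pbar / 10.605 - (y - 0.1))
  }
  ode <- deSolve::ode(c(U = 0.1), tt, rhs, NULL, rtol = 1e-11, atol = 1e-13)
  expect_equal(analytic_mean_spark(tt), unname(ode[, 2]), tolerance = 1e-9)
  # confluent case Vp = kon + koff
  expect_equal(analytic_mean_spark(2, kon = 0.5, koff = 0.5, Vp = 1),
               analytic_mean_spark(2, kon = 0.5, koff = 0.5, Vp = 1 + 1e-9),
               tolerance = 1e-6)
})

test_that("the next-reaction simulator reproduces exponential firing and stationary laws", {
  # single molecule A -> B at rate 2: survival is exp(-2t)
  mdl <- list(species = c("A", "B"), x0 = c(A = 1, B = 0), k = 2,
              react1 = 0L, react2 = -1L, stoich = rbind(c(-1, 1)))
  tt <- seq(0, 3, by = 0.05)
  out <- gibson_bruck_simulate(mdl, tt, nreal = 20000, seed = 1)
  fA <- apply(out[, "A", ], 1, mean)
  se <- sqrt(exp(-2 * tt) * (1 - exp(-2 * tt)) / 20000)
  expect_true(all(abs(fA - exp(-2 * tt)) < 4 * se + 1e-12))
  # mean firing time 1/k within 3 standard errors
  fired <- apply(out[, "A", ] == 0, 2, function(x) tt[which(x)[1]])
  expect_lt(abs(mean(fired, na.rm = TRUE) - 0.5), 3 * 0.5 / sqrt(20000) + 0.05)

  # two-state channel kon = 1, koff = 5: stationary open probability 1/6
  mdl2 <- list(species = c("C", "O"), x0 = c(C = 1, O = 0), k = c(1, 5),
               react1 = c(0L, 1L), react2 = c(-1L, -1L),
               stoich = rbind(c(-1, 1), c(1, -1)))
  out2 <- gibson_bruck_simulate(mdl2, seq(0, 60, 0.5), nreal = 400, seed = 2)
  expect_equal(mean(out2[21:121, "O", ]), 1 / 6, tolerance = 0.03)
})

test_that("the fast-diffusion Fokker-Planck solver conserves probability and converges", {
  # alpha = 0 decouples the components: p1 stays empty
  s0 <- fp_fast_solve(alpha = 0, beta = 1, a = 5, tau_end = 2, drho = 0.02)
  expect_equal(sum(s0$p1), 0)
  expect_equal(fp_moments(s0)$total, 1, tolerance = 1e-6)

  s <- fp_fast_solve(alpha = 1, beta = 1, a = 5, tau_end = 12, drho = 0.02)
  mo <- fp_moments(s)
  expect_equal(mo$total, 1, tolerance = 1e-6)
  # stationary moment identity E[rho] = a P(xi = 1)
  expect_equal(mo$mean_rho, 5 * mo$p_open, tolerance = 0.01)

  # Monte-Carlo oracle for the reduced jump-ODE process
  set.seed(4)
  nmc <- 2e4; dtau <- 0.01
  rho <- numeric(nmc); xi <- integer(nmc)
  for (i in seq_len(round(12 / dtau))) {
    rate <- ifelse(xi == 1L, 1, 1 * (rho + 1))
    flip <- runif(nmc) < -expm1(-rate * dtau)
    rho <- rho + dtau * (5 * xi - rho)
    xi[flip] <- 1L - xi[flip]
  }
  expect_equal(mo$mean_rho, mean(rho), tolerance = 0.03)

  # first-order convergence in drho (three-level refinement of E[rho])
  ms <- vapply(c(0.08, 0.04, 0.02), function(h)
    fp_moments(fp_fast_solve(1, 1, 5, tau_end = 12, drho = h))$mean_rho, 0)
  expect_gt(abs(ms[1] - ms[2]) / abs(ms[2] - ms[3]), 1.5)

  expect_error(fp_fast_solve(1, 1, 5, tau_end = 1, drho = 0.02, dtau = 0.5),
               "CFL")
  expect_error(fp_fast_solve(1, 1, 5, tau_end = 1, rho_max = 3), "rho_max")
})

test_that("next-reaction and Fokker-Planck references agree on the coupled single channel", {
  # well-mixed coupled single-channel model in counts (N0 = 500 per rho unit)
  N0 <- 500; a <- 5
  mdl <- list(
    species = c("Ca", "C", "O"),
    x0 = c(Ca = N0, C = 1, O = 0),
    k = c(open = 1 / N0, close = 1, rel = a * N0, pump = 1, base = N0),
    react1 = c(0L, 2L, 2L, 0L, -1L), react2 = c(1L, -1L, -1L, -1L, -1L),
    stoich = rbind(c(0, -1, 1), c(0, 1, -1), c(1, 0, 0), c(-1, 0, 0),
                   c(1, 0, 0)))
  out <- gibson_bruck_simulate(mdl, times = 12, nreal = 400, seed = 5)
  rho_s <- out[1, "Ca", ] / N0 - 1
  fp <- fp_fast_solve(1, 1, a, tau_end = 12, drho = 0.02)
  h <- density_histogram(pmax(rho_s, 0), range = c(0, max(fp$rho) + 0.01))
  bin_of <- pmin(ceiling(seq_along(fp$rho) / (length(fp$rho) / 20)), 20L)
  ref <- as.numeric(tapply(fp$p0 + fp$p1, bin_of, mean))
  d <- l2_difference(h$density, ref, h$width)
  # combined Monte-Carlo (400 realizations) + copy-number + binning error
  expect_lt(d$pct_of_max, 20)
  expect_equal(mean(rho_s), fp_moments(fp)$mean_rho, tolerance = 0.1)
})

test_that("the functional Fokker-Planck solver decouples at d = 0 and conserves probability", {
  f2 <- fp_functional_solve(alpha = 10, beta = 1, a = 20 / 3, d = 0,
                            imax = 2, dx = 2, tau_end = 1, drho = 0.01)
  expect_equal(f2$total, 1, tolerance = 1e-5)
  # node 1 never receives mass: its marginal stays the initial delta
  expect_equal(f2$marginal[[2]][1] * f2$drho, 1, tolerance = 1e-9)
  # node 0 marginal equals the well-mixed solution with a -> a/dx
  ff <- fp_fast_solve(10, 1, 20 / 3 / 2, tau_end = 1, drho = 0.01,
                      rho_max = f2$rho_max[1])
  expect_lt(l2_difference(f2$marginal[[1]], ff$p0 + ff$p1, 0.01)$l2, 1e-3)

  expect_error(fp_functional_solve(1, 1, 1, 1, imax = 4), "imax")
  expect_error(fp_functional_solve(10, 1, 20 / 3, 1, imax = 3, drho = 1e-4,
                                   mem_cap = 1e6), "memory cap")
})

test_that("Richardson extrapolation is exact on polynomial sequences", {
  expect_equal(richardson_extrapolate(rep(3.5, 4), c(0.4, 0.3, 0.2, 0.1))$value,
               3.5, tolerance = 1e-12)
  # exactly linear at two steps: intercept recovered to machine precision
  f <- function(h) 1.25 + 2 * h
  expect_equal(richardson_extrapolate(f(c(0.2, 0.1)), c(0.2, 0.1))$value,
               1.25, tolerance = 1e-12)
  # quadratic sampled at (1.5)^-s
  h <- 1.5^-(0:5)
  r <- richardson_extrapolate(1 + h^2, h)
  expect_lt(abs(r$value - 1), 1e-10)
  expect_error(richardson_extrapolate(c(1, 2), c(0.1, 0.1)), "duplicate")
  # vector-valued (bin-wise) extrapolation
  V <- rbind(1 + h, 2 - h^2)
  rv <- richardson_extrapolate(V, h)
  expect_equal(rv$value, c(1, 2), tolerance = 1e-10)
})
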