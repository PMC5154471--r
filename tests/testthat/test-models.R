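test_that("spark model builders wire the benchmark parameter sets", {
  m <- build_spark_model("separable")
  expect_identical(m$species$channel$n, 24)
  expect_equal(m$dt, 2e-3)
  expect_equal(m$T, 5)
  expect_equal(m$fields$U$D, 1)
  expect_equal(m$grid$ncell, 2121L)
  expect_identical(m$transitions[[1]]$rate$type, "constant")

  mc <- build_spark_model("coupled")
  expect_equal(mc$fields$U$D, 1000)
  expect_equal(mc$dt, 2e-4)
  expect_identical(mc$transitions[[1]]$rate$type, "linear")
  expect_equal(mc$transitions[[1]]$rate$coef, 0.1 / 0.1)  # kon/U0
  expect_error(build_spark_model("coupled", U0 = 0), "U0 > 0")

  mm <- build_spark_model("membrane")
  expect_true(all(mm$species$channel$positions[, 3] == 0))

  mr <- build_rho_model(alpha = 1, beta = 1, a = 24, d = 1e4,
                        extents = rbind(c(-0.5, -0.5, -0.5),
                                        c(0.5, 0.5, 0.5)),
                        spacing = rep(0.1, 3))
  expect_equal(mr$grid$ncell, 1000L)
  expect_equal(mr$couplings[[1]]$J, 24)
})

test_that("gated model guards its step size and degenerates correctly at kf = 0", {
  expect_error(build_gated_model(N = 10, dt = 0.01,
                                 extents = rbind(c(0, 0, 0), c(1, 1, 1)),
                                 h = 0.5),
               "decrease dt")
  m0 <- build_gated_model(N = 40, kf = 0, kr = 0,
                          extents = rbind(c(0, 0, 0), c(1, 1, 1)), h = 0.25,
                          dt = 1e-4, T = 5e-3)
  ens <- run_ensemble(m0, n = 3, base_seed = 1, record_every = 10)
  expect_true(all(ens$state_mean$macro[, "complex"] == 0))
  expect_equal(ens$field_mean$L, rep(1, length(ens$times)), tolerance = 1e-12)
  # default build matches the full-scale benchmark configuration
  m <- build_gated_model()
  expect_identical(m$species$macro$n, 20000)
  expect_equal(m$grid$ncell, 125000L)
  expect_equal(m$fields$L$bc, "dirichlet")
  expect_equal(sum(m$species$macro$init_state == "inert"), 10000L)
})

test_that("polarity model is absorbing without the pulse and validates its pulse", {
  expect_error(build_polarity_model(k0 = 10, tau = 0), "tau")
  m <- build_polarity_model(Nr = 30, k0 = 0, subdivisions = 1, dt = 0.01,
                            T = 0.5)
  ens <- run_ensemble(m, n = 3, base_seed = 2, record_every = 10)
  expect_true(all(ens$state_mean$receptor[, "active"] == 0))
  expect_true(all(ens$field_mean$S == 0))
  expect_true(all(ens$field_mean$U == 1))
})

test_that("built-in models round-trip through the configuration format", {
  models <- list(
    build_spark_model("separable",
                      extents = rbind(c(0, 0, 0), c(2, 1, 0.5)),
                      spacing = 0.5, Nch = 4),
    build_gated_model(N = 20, extents = rbind(c(0, 0, 0), c(1, 1, 1)),
                      h = 0.5,
                      positions = matrix(runif(60), 20, 3)),
    build_polarity_model(Nr = 10, subdivisions = 1, T = 1),
    build_rho_model())
  for (m in models) {
    m2 <- model_from_config(model_to_config(m))
    expect_equal(m2$fields, m$fields)
    expect_equal(m2$transitions, m$transitions)
    expect_equal(m2$couplings, m$couplings)
    expect_equal(m2$species, m$species)
    expect_equal(m2$dt, m$dt)
    expect_equal(m2$grid$dims, m$grid$dims)
    if (!is.null(m$surface))
      expect_equal(m2$surface$vertices, m$surface$vertices)
  }
  # and through YAML on disk
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(models[[4]], path)
  m4 <- read_model_yaml(path)
  expect_equal(m4$transitions, models[[4]]$transitions)
  expect_equal(m4$grid$dims, models[[4]]$grid$dims)
  expect_equal(m4$species$channel$positions, models[[4]]$species$channel$positions)
})

test_that("density histograms follow the 20-bin density convention", {
  h <- density_histogram(rep(2.5, 100), range = c(0, 5))
  expect_equal(sum(h$density > 0), 1L)
  expect_equal(max(h$density), 1 / h$width)
  expect_equal(sum(h$density * h$width), 1)

  set.seed(6)
  hu <- density_histogram(runif(2e4), range = c(0, 1))
  expect_true(all(abs(hu$density - 1) < 4 * sqrt(20 / 2e4)))

  he <- density_histogram(rexp(1e5), range = c(0, 10))
  mids <- he$mids
  p_bin <- pexp(he$breaks[-1]) - pexp(he$breaks[-21])
  se <- sqrt(p_bin * (1 - p_bin) / 1e5) / he$width
  dens_clipped <- p_bin / he$width
  expect_true(all(abs(he$density - dens_clipped) < 4 * se + 1e-8))
  expect_error(density_histogram(numeric(0)), "empty")
  # clipping is reported
  hc <- density_histogram(c(0.5, 1.5), range = c(0, 1))
  expect_identical(hc$clipped, 1L)
})

test_that("the L2 difference convention matches hand arithmetic", {
  expect_equal(l2_difference(c(1, 2), c(1, 2), 0.5)$l2, 0)
  d <- l2_difference(c(2, 0), c(0, 2), 0.5)
  expect_equal(d$l2, 2)
  expect_equal(d$pct_of_max, 100)
  set.seed(8)
  a <- runif(20); b <- runif(20)
  expect_equal(l2_difference(a, b, 0.3)$l2, l2_difference(b, a, 0.3)$l2)
})

test_that("solution error is the max absolute deviation on the common grid", {
  x <- sin(seq(0, 1, 0.1))
  expect_equal(solution_error(x, x), 0)
  expect_equal(solution_error(x + 0.07, x), 0.07)
  expect_error(solution_error(x, x[-1]), "common time grid")
})

test_that("relaxation analysis reproduces the closed-form asymptote arithmetic", {
  pars <- gated_parameters()
  times <- seq(1e-4, 0.15, by = 1e-4)
  C <- rep(100, length(times)); C[1] <- 0
  r <- relaxation_analysis(times, C, kf = pars$kf, kr = pars$kr,
                           a = 1, b = 1, L0 = 1, D = 1)
  expect_true(all(r$relaxation[-1] == 0))
  # independent evaluation of the prefactor: kr = kf L0 makes the
  # denominator kr (1 + a/b + 1)^2 = 9 kr, numerator 2 kf
  t0 <- 0.01
  expected <- (2 * pars$kf / (9 * pars$kr)) * (4 * pi * t0)^(-3 / 2)
  i0 <- which.min(abs(times - t0))
  expect_equal(r$asymptote[i0], expected, tolerance = 1e-10)
})

test_that("cluster counting by distance linkage finds connected components", {
  pts <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(5, 0, 0), c(5, 0.1, 0),
               c(10, 10, 0))
  expect_identical(cluster_count(pts, 0.5), 3L)
  expect_identical(cluster_count(pts, 100), 1L)
  expect_identical(cluster_count(pts[1, , drop = FALSE], 1), 1L)
  expect_identical(cluster_count(pts[0, , drop = FALSE], 1), 0L)
})
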