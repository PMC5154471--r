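# small spark variant used throughout: coarse quasi-2D box, 4 channels
tiny_spark <- function(variant = "separable", dt = 0.01, T = 0.5, ...) {
  build_spark_model(variant, Nch = 4,
                    extents = rbind(c(0, 0, 0), c(2, 1, 0.5)),
                    spacing = c(0.5, 0.5, 0.5), dt = dt, T = T, ...)
}

test_that("a model without particles reduces to the bare PDE step", {
  g <- build_box_grid(c(0, 2, 0, 1, 0, 1), c(0.5, 0.5, 1))
  m <- hybrid_model("bare", grid = g,
                    fields = list(U = list(domain = "volume", D = 1,
                                           init = 0)),
                    dt = 0.01, T = 0.1)
  set.seed(1)
  st <- hybrid_init(m, n = 1)
  st$fields$U[] <- seq_len(g$ncell)
  ref <- semi_implicit_step(pde_stepper(diffusion_operator(g, 1), 0.01),
                            matrix(seq_len(g$ncell)))
  st2 <- hybrid_step(st)
  expect_equal(st2$fields$U, ref, tolerance = 1e-13)
})

test_that("separable channel statistics are independent of the field", {
  # same seed, different flux J: identical channel state trajectories
  run_states <- function(J) {
    m <- tiny_spark(J = J, T = 0.3)
    set.seed(99)
    st <- hybrid_init(m, n = 2)
    states <- list()
    for (k in 1:30) { st <- hybrid_step(st); states[[k]] <- st$species$channel$state }
    states
  }
  a <- run_states(10)
  b <- run_states(0)
  expect_identical(a, b)
})

test_that("one step with one open channel matches a hand-assembled linear solve", {
  m <- tiny_spark()
  m$species$channel$init_state <- c("open", "closed", "closed", "closed")
  set.seed(7)
  st <- hybrid_init(m, n = 1)
  st1 <- hybrid_step(st)
  g <- m$grid
  op <- diffusion_operator(g, D = 1)
  j <- locate_cell(g, m$species$channel$positions[1, , drop = FALSE])
  src <- numeric(g$ncell)
  src[j] <- 10 / g$cell_volume                     # J n_j / |w_j|
  src <- src + 1 * (0.1 - rep(0.1, g$ncell))       # pump at U = U0
  A <- Matrix::Diagonal(g$ncell) - m$dt * op$L
  ref <- as.numeric(Matrix::solve(A, rep(0.1, g$ncell) + m$dt * src))
  expect_equal(drop(st1$fields$U), ref, tolerance = 1e-12)
})

test_that("stream-mode ensembles are reproducible and order-independent", {
  m <- tiny_spark(T = 0.2)
  e1 <- run_ensemble(m, n = 2, base_seed = 5, mode = "stream",
                     per_realization = TRUE)
  e2 <- run_ensemble(m, n = 2, base_seed = 5, mode = "stream",
                     per_realization = TRUE)
  expect_identical(e1$field_real, e2$field_real)
  expect_identical(e1$state_real, e2$state_real)
  # realization r of base seed b is realization 1 of base seed b + r - 1...
  # i.e. trajectories depend only on (base_seed + id), not on ensemble layout
  e3 <- run_ensemble(m, n = 1, base_seed = 6, mode = "stream",
                     per_realization = TRUE)
  expect_identical(e1$field_real$U[, 2], e3$field_real$U[, 1])
  # collective n = 1 equals a manual step loop under the same seed
  set.seed(11)
  st <- hybrid_init(m, n = 1)
  means <- numeric(21); means[1] <- mean(st$fields$U)
  for (k in 1:20) { st <- hybrid_step(st); means[k + 1] <- mean(st$fields$U) }
  e4 <- run_ensemble(m, n = 1, base_seed = 11, mode = "collective")
  expect_equal(e4$field_mean$U, means, tolerance = 1e-14)
})

test_that("particle counts are conserved while states change", {
  m <- tiny_spark(T = 0.5)
  ens <- run_ensemble(m, n = 5, base_seed = 3, per_realization = TRUE)
  counts <- apply(ens$state_real$channel, c(1, 3), sum)  # time x realization
  expect_true(all(counts == 4))
  expect_gt(max(ens$state_mean$channel[, "open"]), 0)    # transitions happen
})

test_that("swapping field and particle updates changes results at O(dt) only", {
  run_once <- function(dt, order) {
    nstep <- round(0.4 / dt)
    m <- tiny_spark(dt = dt, T = 0.4)
    m$step_order <- order
    set.seed(21)
    s <- hybrid_init(m, n = 40)
    for (k in seq_len(nstep)) s <- hybrid_step(s)
    s
  }
  mean_absdiff <- function(dt) {
    s1 <- run_once(dt, "pde_first")
    s2 <- run_once(dt, "particles_first")
    # separable model + common seed: identical channel paths, so the
    # field difference isolates the ordering error
    expect_identical(s1$species$channel$state, s2$species$channel$state)
    mean(abs(s1$fields$U - s2$fields$U))
  }
  r <- mean_absdiff(0.02) / mean_absdiff(0.01)
  expect_gt(r, 1.4)
  expect_lt(r, 3.0)
})

test_that("negative local field values clamp rates with a warning", {
  g <- build_box_grid(c(0, 1, 0, 1, 0, 1), c(1, 1, 1))
  m <- hybrid_model(
    "neg", grid = g,
    fields = list(U = list(domain = "volume", D = 0, init = 0.1)),
    species = list(p = list(domain = "volume", n = 1,
                            states = c("a", "b"),
                            positions = matrix(0.5, 1, 3),
                            init_state = "a")),
    transitions = list(list(species = "p", from = "a", to = "b",
                            rate = rate_linear("U", coef = 1))),
    couplings = list(coupling_relax("U", rate = 40, target = -2)),
    dt = 0.01, T = 0.2)
  expect_warning(run_ensemble(m, n = 1, base_seed = 1), "clamped")
})
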