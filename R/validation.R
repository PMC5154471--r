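#' Validation studies
#'
#' Each `validate_*` function runs one of the package's standard
#' validation computations end to end — generating its own inputs,
#' running the hybrid engine and the relevant independent reference —
#' and returns the measured quantities.  They are the single
#' implementation behind the test suite, the command line
#' (`hybridrd validate <suite>`) and the acceptance script, so every
#' consumer sees the same numbers.  Problem sizes default to "desk scale":
#' runs sized to minutes on one CPU; the full-scale study parameters are
#' documented in the methods vignette.
#'
#' @name validation
NULL

#' @describeIn validation Time-step convergence of the semi-implicit
#'   integrator on a pure-decay problem (first order: halving the step
#'   halves the error) and mesh convergence of a 1D source-decay steady
#'   state (second order in \eqn{\Delta x}).
#' @param dts time steps for the decay test.
#' @param nx_values 1D mesh resolutions for the steady-state test.
#' @return `validate_pde_convergence`: list with `decay` (data frame of
#'   dt, error) and `steady` (data frame of nx, error), plus the
#'   empirical orders.
#' @export
validate_pde_convergence <- function(dts = c(0.02, 0.01, 0.005, 0.0025),
                                     nx_values = c(10, 20, 40, 80)) {
  g1 <- build_box_grid(c(0, 1, 0, 1, 0, 1), c(1, 1, 1))
  op <- diffusion_operator(g1, D = 0)
  decay_err <- vapply(dts, function(dt) {
    st <- pde_stepper(op, dt)
    u <- 1
    for (i in seq_len(round(1 / dt))) u <- semi_implicit_step(st, u, -u)
    abs(u - exp(-1))
  }, 0)
  ord_t <- stats::coef(stats::lm(log(decay_err) ~ log(dts)))[2]
  # 1D steady state of D u'' - Vp u + cos(pi x) = 0 on [0,1], no-flux:
  # exact u = cos(pi x) / (Vp + D pi^2)
  D <- 0.3; Vp <- 1
  steady_err <- vapply(nx_values, function(nx) {
    g <- build_box_grid(c(0, 1, 0, 1, 0, 1), c(1 / nx, 1, 1))
    x <- cell_centers(g)[, 1]
    opx <- diffusion_operator(g, D = D)
    A <- Vp * Matrix::Diagonal(g$ncell) - opx$L
    u <- as.numeric(Matrix::solve(A, cos(pi * x)))
    max(abs(u - cos(pi * x) / (Vp + D * pi^2)))
  }, 0)
  ord_x <- stats::coef(stats::lm(log(steady_err) ~ log(1 / nx_values)))[2]
  list(decay = data.frame(dt = dts, error = decay_err),
       steady = data.frame(nx = nx_values, error = steady_err),
       order_dt = unname(ord_t), order_dx = unname(ord_x))
}

#' @describeIn validation Convergence of the separable spark model:
#'   ensemble means of the spatial average are compared with the closed
#'   form [analytic_mean_spark()] at several ensemble sizes, and the
#'   scaling exponent of the solution error \eqn{\varepsilon} with the
#'   number of realizations is fitted (Monte-Carlo statistics predict
#'   \eqn{-1/2} once the time step is small).
#' @param n_values ensemble sizes.
#' @param reps replicate ensembles per size (averaged before the fit).
#' @param dt time step (s) for the spark runs.
#' @param spacing spark mesh (defaults to the coarsened half-micron mesh,
#'   adjusted to divide the box).
#' @param base_seed seed.
#' @return `validate_spark_convergence`: list with `eps` (data frame of
#'   n, mean error), `slope` of log eps vs log n, and the largest-n error.
#' @export
validate_spark_convergence <- function(n_values = c(100, 1000, 10000),
                                       reps = c(4, 2, 1), dt = 2e-3,
                                       spacing = c(10.1 / 20, 2.1 / 4, 0.5),
                                       base_seed = 1L) {
  model <- build_spark_model("separable", spacing = spacing, dt = dt, T = 5)
  eps <- numeric(length(n_values))
  for (i in seq_along(n_values)) {
    e_i <- vapply(seq_len(reps[i]), function(r) {
      ens <- run_ensemble(model, n = n_values[i],
                          base_seed = base_seed + 1000L * i + r)
      exact <- analytic_mean_spark(ens$times)
      solution_error(ens$field_mean$U, exact)
    }, 0)
    eps[i] <- mean(e_i)
  }
  fit <- stats::lm(log(eps) ~ log(n_values))
  list(eps = data.frame(n = n_values, eps = eps),
       slope = unname(stats::coef(fit)[2]),
       eps_largest_n = eps[length(eps)])
}

#' @describeIn validation Fully coupled spark model in the fast-diffusion
#'   limit versus the Gibson-Bruck well-mixed reference: 20-bin histograms
#'   of the spatially averaged concentration \eqn{p(U,t)} and of the
#'   open-channel number \eqn{P(n,t)} at time `t_compare`, compared in L2
#'   together with the bootstrap scale of the reference's own sampling
#'   error.
#' @param n realizations per solver.
#' @param t_compare comparison time (s).
#' @param spacing hybrid mesh; the default coarsens the quasi-2D box,
#'   which at \eqn{D = 1000\,\mu m^2/s} leaves the solution unchanged.
#' @return `validate_fast_diffusion`: list with `l2_pU`, `l2_Pn`, the
#'   bootstrap scales `se_pU`, `se_Pn`, and the two histogram objects.
#' @export
validate_fast_diffusion <- function(n = 500, t_compare = 1,
                                    spacing = c(10.1 / 20, 2.1 / 4, 0.5),
                                    base_seed = 1L) {
  model <- build_spark_model("coupled", spacing = spacing, T = t_compare)
  ens <- run_ensemble(model, n = n, base_seed = base_seed,
                      record_every = round(t_compare / model$dt),
                      snapshot_times = t_compare)
  snap <- ens$snapshots[[length(ens$snapshots)]]
  U_h <- colMeans(snap$fields$U)
  n_h <- colSums(matrix(snap$species$channel$state == 2L, 24L))
  wm <- well_mixed_spark_model()
  ref <- gibson_bruck_simulate(wm, times = t_compare, nreal = n,
                               seed = base_seed + 555L)
  U_g <- ref[1, "Ca", ] * wm$uM_per_molecule
  n_g <- ref[1, "Co", ]
  rngU <- c(0, max(U_h, U_g))
  hU_h <- density_histogram(U_h, rngU)
  hU_g <- density_histogram(U_g, rngU)
  l2U <- l2_difference(hU_h$density, hU_g$density, hU_g$width)
  # open-channel distribution over the integers 0..Nch (unit bin width)
  Pn_h <- tabulate(n_h + 1L, 25L) / n
  Pn_g <- tabulate(n_g + 1L, 25L) / n
  l2n <- l2_difference(Pn_h, Pn_g, 1)
  se_pU <- histogram_bootstrap_l2(U_g, rngU)
  B <- 200L
  se_Pn <- sqrt(mean(vapply(seq_len(B), function(b) {
    rb <- sample(n_g, replace = TRUE)
    sum((tabulate(rb + 1L, 25L) / n - Pn_g)^2)
  }, 0)))
  list(l2_pU = l2U$l2, l2_Pn = l2n$l2, se_pU = se_pU, se_Pn = se_Pn,
       hist_U_hybrid = hU_h, hist_U_ref = hU_g,
       Pn_hybrid = Pn_h, Pn_ref = Pn_g,
       mean_U_hybrid = mean(U_h), mean_U_ref = mean(U_g))
}

#' @describeIn validation Single-channel hybrid in the fast-diffusion
#'   limit (`d = 1e4`) versus the direct Fokker-Planck solution
#'   [fp_fast_solve()]: stationary mean \eqn{E[\rho]} of both, their
#'   relative difference, and the L2 difference of the 20-bin stationary
#'   density estimate against the reference density.
#' @param d dimensionless diffusivity.
#' @param tau_end stationary sampling time.
#' @return `validate_fp_stationary`: list with `mean_hybrid`, `mean_fp`,
#'   `rel_diff`, `l2`, `pct_of_max`.
#' @export
validate_fp_stationary <- function(n = 2000, d = 1e4, tau_end = 30,
                                   base_seed = 1L) {
  model <- build_rho_model(alpha = 1, beta = 1, a = 24, d = d,
                           extents = rbind(c(-0.5, -0.5, -0.5),
                                           c(0.5, 0.5, 0.5)),
                           spacing = rep(0.25, 3),
                           channel_pos = matrix(c(0, 0, 0), 1),
                           dt = 0.002, T = tau_end)
  ens <- run_ensemble(model, n = n, base_seed = base_seed,
                      record_every = round(tau_end / 0.002),
                      snapshot_times = tau_end)
  rho_h <- colMeans(ens$snapshots[[1]]$fields$rho)
  fp <- fp_fast_solve(1, 1, 24, tau_end = tau_end, drho = 0.05)
  mo <- fp_moments(fp)
  hh <- density_histogram(rho_h, range = c(0, max(fp$rho) + fp$drho / 2))
  # average the fine FP density within each of the 20 bins
  bin_of <- pmin(ceiling(seq_along(fp$rho) / (length(fp$rho) / 20)), 20L)
  ref <- as.numeric(tapply(fp$p0 + fp$p1, bin_of, mean))
  l2 <- l2_difference(hh$density, ref, hh$width)
  list(mean_hybrid = mean(rho_h), mean_fp = mo$mean_rho,
       rel_diff = abs(mean(rho_h) - mo$mean_rho) / mo$mean_rho,
       l2 = l2$l2, pct_of_max = l2$pct_of_max, fp_total = mo$total)
}

#' @describeIn validation Spatially resolved single-channel model at
#'   finite diffusion: the two-node hybrid ensemble versus direct
#'   solutions of the functional Fokker-Planck equations at a sequence of
#'   \eqn{\Delta\rho}, reporting the L2 discrepancy (as % of the
#'   reference maximum) of both nodal marginals at each refinement level.
#' @param drho_levels decreasing \eqn{\Delta\rho} sequence for the
#'   reference solves.
#' @param alpha,beta,a,d model parameters.
#' @return `validate_functional_fp`: list with `pct` (matrix levels x
#'   nodes), `finest` (per-node % at the finest level), and the hybrid
#'   histograms.
#' @export
validate_functional_fp <- function(n = 12500,
                                   drho_levels = c(1.125e-2, 7.5e-3, 5e-3),
                                   alpha = 10, beta = 1, a = 20 / 3, d = 1,
                                   base_seed = 1L) {
  model <- build_rho_model(alpha = alpha, beta = beta, a = a, d = d,
                           dt = 1e-4, T = 1)
  ens <- run_ensemble(model, n = n, base_seed = base_seed,
                      record_every = 10000L, snapshot_times = 1)
  rho_fin <- ens$snapshots[[1]]$fields$rho    # 2 x n
  pct <- matrix(NA_real_, length(drho_levels), 2L,
                dimnames = list(NULL, c("i0", "i1")))
  hists <- NULL
  for (l in seq_along(drho_levels)) {
    fp <- fp_functional_solve(alpha, beta, a, d, imax = 2, dx = 2,
                              tau_end = 1, drho = drho_levels[l])
    hists <- lapply(1:2, function(i)
      density_histogram(rho_fin[i, ], range = c(0, fp$rho_max[i])))
    for (i in 1:2) {
      K <- length(fp$marginal[[i]])
      bin_of <- pmin(ceiling(seq_len(K) / (K / 20)), 20L)
      ref <- as.numeric(tapply(fp$marginal[[i]], bin_of, mean))
      pct[l, i] <- l2_difference(hists[[i]]$density, ref,
                                 hists[[i]]$width)$pct_of_max
    }
  }
  list(pct = cbind(drho = drho_levels, pct),
       finest = pct[length(drho_levels), ], hist = hists)
}

#' @describeIn validation Stochastically gated reversible binding on a
#'   scaled domain: the relaxation function of the ensemble-mean complex
#'   count, its late-time log-log slope, and the ratio to the closed-form
#'   power-law asymptote.
#' @param N macromolecule count; the default keeps the full model's
#'   number density on the scaled domain.
#' @param extents,h domain and mesh.
#' @return `validate_gated`: the [relaxation_analysis()] result plus the
#'   recomputed parameter identities.
#' @export
validate_gated <- function(N = 312, extents = rbind(c(0, 0, 0),
                                                    c(2.5, 2.5, 2.5)),
                           h = 0.25, n = 200, base_seed = 1L) {
  pars <- gated_parameters(N = N, volume = prod(extents[2, ] - extents[1, ]))
  model <- build_gated_model(N = N, extents = extents, h = h)
  ens <- run_ensemble(model, n = n, base_seed = base_seed,
                      record_every = 16L)
  C <- ens$state_mean$macro[, "complex"]
  rel <- relaxation_analysis(
    ens$times, C, kf = pars$kf, kr = pars$kr, a = 1 / pars$tauD,
    b = 1 / pars$tauD, L0 = 1, D = 1,
    c_eq_window = 10 * pars$tauD)
  c(rel, list(pars = pars, n = n, N = N))
}

#' @describeIn validation Spontaneous polarization on a scaled sphere:
#'   runs the pulse-driven model, counts active-receptor clusters on a
#'   snapshot grid, and checks the pool-membrane mass bookkeeping and
#'   the absorbing property of the inactive state without the pulse.
#' @param Nr receptor count (scaled); `k3` is scaled inversely so the
#'   feedback loop gain `k3 * Nr` of the full model is preserved.
#' @param snapshot_times cluster-count times (s).
#' @param cluster_radius linkage radius (\eqn{\mu m}) of the cluster
#'   diagnostic.
#' @return `validate_polarity`: list with `cluster_mean` (per snapshot
#'   time), `active_mean`, `S_series`, `conservation_drift`, and
#'   `absorbing_ok`.
#' @export
validate_polarity <- function(Nr = 200, n = 8, T = 80,
                              snapshot_times = seq(10, 80, by = 10),
                              cluster_radius = 1, base_seed = 1L) {
  k3 <- 0.01 * 1000 / Nr    # preserve the full model's k3 * Nr
  model <- build_polarity_model(Nr = Nr, k3 = k3, T = T)
  ens <- run_ensemble(model, n = n, base_seed = base_seed,
                      record_every = 100L, per_realization = TRUE,
                      snapshot_times = snapshot_times)
  mesh <- model$surface
  clus <- vapply(ens$snapshots, function(s) {
    sp <- s$species$receptor
    mean(vapply(seq_len(n), function(r) {
      sel <- sp$real == r & sp$state == 2L
      if (!any(sel)) return(0)
      pts <- surface_points(mesh, sp$tri[sel], sp$bary[sel, , drop = FALSE])
      as.numeric(cluster_count(pts, cluster_radius))
    }, 0))
  }, 0)
  V <- model$fields$U$volume
  A <- surface_area(mesh)
  tot <- ens$field_real$U * V * MOLECULES_PER_UMOLAR_UM3 +
    ens$field_real$S * A
  drift <- max(abs(tot - tot[1, 1]) / tot[1, 1])
  m0 <- build_polarity_model(Nr = 50, k3 = k3, k0 = 0, subdivisions = 2,
                             T = 5)
  e0 <- run_ensemble(m0, n = 4, base_seed = base_seed + 1L,
                     record_every = 100L)
  list(times = snapshot_times, cluster_mean = clus,
       active_mean = ens$state_mean$receptor[, "active"],
       active_final = utils::tail(ens$state_mean$receptor[, "active"], 1),
       S_series = ens$field_mean$S, rec_times = ens$times,
       conservation_drift = drift,
       absorbing_ok = max(e0$state_mean$receptor[, "active"]) == 0 &&
         max(e0$field_mean$S) == 0)
}
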