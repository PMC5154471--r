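#' Exact expectation of the spatial-average calcium concentration
#'
#' For the calcium-spark model with a separable stochastic subsystem
#' (channel rates independent of the field), the expectation of the
#' spatial average of the concentration has a closed form.  With all
#' channels initially closed, the mean open probability is
#' \eqn{\bar p(t) = p_\infty (1 - e^{-\lambda t})} with
#' \eqn{\lambda = k_{on} + k_{off}} and
#' \eqn{p_\infty = k_{on}/\lambda}; the spatial average obeys the linear
#' ODE \eqn{d\bar U/dt = J N_{ch}\, \bar p(t) / |\Omega| -
#' V_p(\bar U - U_0)} (diffusion integrates to zero under no-flux
#' boundaries), which integrates to
#' \deqn{\bar U(t) = U_0 + \frac{J N_{ch} p_\infty}{|\Omega|}
#'   \left[\frac{1 - e^{-V_p t}}{V_p}
#'   - \frac{e^{-\lambda t} - e^{-V_p t}}{V_p - \lambda}\right].}
#' The result is independent of the diffusivity.
#'
#' @param t time(s) (s), vectorized.
#' @param J open-channel flux (\eqn{\mu M\,\mu m^3/s}).
#' @param U0 resting concentration (\eqn{\mu M}).
#' @param kon,koff channel opening/closing rates (s\eqn{^{-1}}).
#' @param Vp pump rate constant (s\eqn{^{-1}}).
#' @param Nch number of channels.
#' @param volume domain volume \eqn{|\Omega|} (\eqn{\mu m^3}).
#' @return expected spatial-average concentration (\eqn{\mu M}) at `t`.
#' @export
analytic_mean_spark <- function(t, J = 10, U0 = 0.1, kon = 1, koff = 5,
                                Vp = 1, Nch = 24,
                                volume = 10.1 * 2.1 * 0.5) {
  stopifnot(all(t >= 0), J >= 0, kon >= 0, koff >= 0, Vp > 0, volume > 0)
  lam <- kon + koff
  pinf <- if (lam > 0) kon / lam else 0
  cc <- J * Nch / volume
  if (abs(Vp - lam) > 1e-12 * max(Vp, lam)) {
    f <- (1 - exp(-Vp * t)) / Vp - (exp(-lam * t) - exp(-Vp * t)) / (Vp - lam)
  } else {
    # confluent case Vp = lambda
    f <- (1 - exp(-Vp * t)) / Vp - t * exp(-Vp * t)
  }
  U0 + cc * pinf * f
}

#' Direct Fokker-Planck solution of the well-mixed single-channel model
#'
#' Solves the two-component hyperbolic system for the probability
#' densities \eqn{p_0(\rho,\tau)} (channel closed) and
#' \eqn{p_1(\rho,\tau)} (channel open) of the nondimensional well-mixed
#' single-channel model
#' \eqn{d\rho/d\tau = a\xi - \rho}: component 0 is advected with drift
#' \eqn{-\rho}, component 1 with drift \eqn{a - \rho}, and the exchange
#' term is \eqn{R = \alpha(p_1 - \beta(\rho+1)p_0)}.  Discretization is
#' donor-cell upwind finite volume (positive and conservative) with
#' explicit Euler in \eqn{\tau} at CFL 0.5; initial condition
#' \eqn{p_0 = \delta(\rho)}, \eqn{p_1 = 0}; zero-flux boundaries.
#'
#' @param alpha,beta,a dimensionless parameters (off-rate, on/off ratio,
#'   source strength).
#' @param tau_end final dimensionless time.
#' @param drho mesh size of the \eqn{\rho} grid.
#' @param rho_max upper end of the \eqn{\rho} range; defaults to `1.2 * a`
#'   (the drift vanishes at \eqn{\rho = a}, so the default bound is
#'   invariant).  Must be at least `a`.
#' @param dtau optional explicit time step; the default satisfies CFL 0.5
#'   and the exchange-term stability bound.  A supplied value violating
#'   CFL is an error.
#' @return An object of class `fp_solution`: list with cell centers
#'   `rho`, `drho`, densities `p0`, `p1`, time `tau` and parameters.
#' @export
fp_fast_solve <- function(alpha, beta, a, tau_end, drho = a / 400,
                          rho_max = 1.2 * a, dtau = NULL) {
  if (rho_max < a) stop("rho_max must be >= a (support bound)")
  K <- ceiling(rho_max / drho)
  rho_max <- K * drho
  rho <- (seq_len(K) - 0.5) * drho
  faces <- seq_len(K - 1) * drho       # interior faces
  vmax <- max(abs(-rho), abs(a - rho))
  rate_max <- max(alpha, alpha * beta * (rho_max + 1))
  dt_cfl <- 0.5 * drho / vmax
  if (is.null(dtau)) dtau <- min(dt_cfl, 0.5 / rate_max)
  if (dtau > drho / vmax)
    stop(sprintf("CFL violation: |drift| dtau / drho = %.3g > 1",
                 vmax * dtau / drho))
  nstep <- ceiling(tau_end / dtau)
  dtau <- tau_end / nstep
  p0 <- numeric(K); p1 <- numeric(K)
  p0[1] <- 1 / drho                     # delta at rho = 0
  v0 <- -faces                          # drift of component 0 at faces
  v1 <- a - faces
  up0 <- ifelse(v0 > 0, seq_len(K - 1), seq_len(K - 1) + 1L)
  up1 <- ifelse(v1 > 0, seq_len(K - 1), seq_len(K - 1) + 1L)
  for (s in seq_len(nstep)) {
    F0 <- v0 * p0[up0]
    F1 <- v1 * p1[up1]
    div0 <- (c(F0, 0) - c(0, F0)) / drho   # zero-flux boundary faces
    div1 <- (c(F1, 0) - c(0, F1)) / drho
    R <- alpha * (p1 - beta * (rho + 1) * p0)
    p0 <- p0 + dtau * (-div0 + R)
    p1 <- p1 + dtau * (-div1 - R)
  }
  structure(list(rho = rho, drho = drho, p0 = p0, p1 = p1, tau = tau_end,
                 alpha = alpha, beta = beta, a = a),
            class = "fp_solution")
}

#' Moments and normalization of a Fokker-Planck solution
#'
#' @param sol an `fp_solution` from [fp_fast_solve()].
#' @return list with `total` (should be 1), `mean_rho`
#'   (\eqn{E[\rho]}), and `p_open` (\eqn{P(\xi = 1)}).
#' @export
fp_moments <- function(sol) {
  w <- sol$drho
  list(total = sum(sol$p0 + sol$p1) * w,
       mean_rho = sum(sol$rho * (sol$p0 + sol$p1)) * w,
       p_open = sum(sol$p1) * w)
}

#' Direct solution of the functional Fokker-Planck equations
#'
#' Solves the spatially resolved generalization of the single-channel
#' Fokker-Planck system on a coarse spatial grid of `imax` nodes: each
#' node i contributes one advection coordinate \eqn{\rho_i} with drift
#' \eqn{b_i = d\,(\hat L\rho)_i - \rho_i + \xi\,(a/\Delta x)\,\delta_{i0}},
#' where \eqn{\hat L} is the reflecting discrete Laplacian in x and the
#' point source is discretized as \eqn{a/\Delta x} in node 0, exactly
#' mirroring the hybrid engine's binning so that both sides of a
#' comparison share one spatial discretization.  The channel-state
#' exchange is \eqn{R = \alpha(p_1 - \beta(\rho_0+1)p_0)}.  Transport is
#' dimension-by-dimension donor-cell upwind with explicit Euler at CFL
#' 0.5; boundaries are zero-flux in every \eqn{\rho_i}.
#'
#' @param alpha,beta,a,d dimensionless parameters (`d` is the
#'   dimensionless diffusivity; its units are length squared since x
#'   carries length).
#' @param imax number of spatial nodes (2 or 3).
#' @param dx spatial mesh size.
#' @param tau_end final time.
#' @param drho mesh size of every \eqn{\rho_i} axis.
#' @param rho_max optional vector of per-axis ranges; the default is 1.2
#'   times the all-open steady state of the binned deterministic system,
#'   which the drift field cannot leave.
#' @param mem_cap refuse grids whose state exceeds this many doubles
#'   (default 2.5e8, about 2 GB); the refusal reports the grid size.
#' @return list with per-axis centers `rho` (list), `drho`, arrays `p0`,
#'   `p1`, marginals `marginal` (list of per-axis densities of
#'   \eqn{p_0 + p_1}), `tau`, and parameters.
#' @export
fp_functional_solve <- function(alpha, beta, a, d, imax = 2, dx = 2,
                                tau_end = 1, drho = 5e-3, rho_max = NULL,
                                mem_cap = 2.5e8) {
  if (!imax %in% c(2L, 3L)) stop("imax must be 2 or 3")
  # reflecting discrete Laplacian (matrix), and all-open steady state
  Lx <- matrix(0, imax, imax)
  for (i in seq_len(imax)) {
    if (i > 1) { Lx[i, i - 1] <- 1 / dx^2; Lx[i, i] <- Lx[i, i] - 1 / dx^2 }
    if (i < imax) { Lx[i, i + 1] <- 1 / dx^2; Lx[i, i] <- Lx[i, i] - 1 / dx^2 }
  }
  e0 <- c(a / dx, rep(0, imax - 1))
  rho_ss <- solve(diag(imax) - d * Lx, e0)
  if (is.null(rho_max)) rho_max <- 1.2 * rho_ss
  K <- pmax(2L, ceiling(rho_max / drho))
  rho_max <- K * drho
  if (2 * prod(K) > mem_cap)
    stop(sprintf("grid of %s cells x 2 components exceeds the memory cap",
                 paste(K, collapse = " x ")))
  centers <- lapply(seq_len(imax), function(i) (seq_len(K[i]) - 0.5) * drho)
  p0 <- array(0, K); p1 <- array(0, K)
  first <- as.list(rep(1L, imax))
  p0[do.call(cbind, first)] <- 1 / drho^imax   # delta at rho = 0
  cdx <- d / dx^2
  # face drift along axis i for channel state xi, as a function of the
  # face coordinate f and the center coordinates of the other axes
  drift <- function(i, f, xi) {
    # returns an array of dim c(length(f), K[-i]) in axis order (i, others)
    if (imax == 2L) {
      if (i == 1L) outer(f, centers[[2]],
                         function(x, y) cdx * (y - x) - x + xi * a / dx)
      else outer(centers[[1]], f,
                 function(x, y) cdx * (x - y) - y)
    } else {
      if (i == 1L) {
        o <- outer(f, centers[[2]], function(x, y) cdx * (y - x) - x + xi * a / dx)
        array(rep(o, K[3]), c(length(f), K[2], K[3]))
      } else if (i == 2L) {
        o1 <- outer(centers[[1]], rep(1, length(f)))
        arr <- array(0, c(K[1], length(f), K[3]))
        for (k3 in seq_len(K[3]))
          arr[, , k3] <- outer(centers[[1]], f, function(x, y)
            cdx * (x + centers[[3]][k3] - 2 * y) - y)
        arr
      } else {
        arr <- array(0, c(K[1], K[2], length(f)))
        for (k2 in seq_len(K[2]))
          arr[, k2, ] <- outer(centers[[1]], f, function(x, y)
            cdx * (centers[[2]][k2] - y) - y)
        arr
      }
    }
  }
  faces <- lapply(seq_len(imax), function(i) seq_len(K[i] - 1) * drho)
  V <- list()
  for (xi in 0:1) for (i in seq_len(imax))
    V[[paste(xi, i)]] <- drift(i, faces[[i]], xi)
  vmax <- max(vapply(V, function(v) max(abs(v)), 0))
  rate_max <- max(alpha, alpha * beta * (rho_max[1] + 1))
  dtau <- min(0.5 * drho / vmax, 0.5 / rate_max)
  nstep <- ceiling(tau_end / dtau)
  dtau <- tau_end / nstep
  upwind_div <- function(p, v, axis) {
    # donor-cell divergence along `axis` given face velocities v
    Kx <- dim(p)[axis]
    idx_lo <- function(arr, take) {
      # slice arr along `axis` with indices `take`
      ix <- rep(list(quote(expr = )), imax)
      ix[[axis]] <- take
      do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
    }
    pl <- idx_lo(p, seq_len(Kx - 1L))
    pr <- idx_lo(p, seq_len(Kx - 1L) + 1L)
    FF <- ifelse(v > 0, pl, pr) * v
    zero <- idx_lo(p, 1L) * 0
    Fr <- abind_along(FF, zero, axis, after = TRUE)
    Fl <- abind_along(FF, zero, axis, after = FALSE)
    (Fr - Fl) / drho
  }
  rho0 <- centers[[1]]   # broadcast along axis 1
  for (s in seq_len(nstep)) {
    R <- alpha * (p1 - beta * (rho0 + 1) * p0)
    d0 <- 0; d1 <- 0
    for (i in seq_len(imax)) {
      d0 <- d0 + upwind_div(p0, V[[paste(0, i)]], i)
      d1 <- d1 + upwind_div(p1, V[[paste(1, i)]], i)
    }
    p0 <- p0 - dtau * d0 + dtau * R
    p1 <- p1 - dtau * d1 - dtau * R
  }
  w <- drho^(imax - 1)
  marg <- lapply(seq_len(imax), function(i)
    apply(p0 + p1, i, sum) * w)
  structure(list(rho = centers, drho = drho, p0 = p0, p1 = p1,
                 marginal = marg, tau = tau_end, alpha = alpha, beta = beta,
                 a = a, d = d, imax = imax, dx = dx, rho_max = rho_max,
                 rho_ss = rho_ss, total = sum(p0 + p1) * drho^imax),
            class = "fp_functional_solution")
}

# concatenate a boundary slice of zeros onto an array along `axis`
abind_along <- function(x, zero, axis, after) {
  dn <- dim(x)
  dz <- dn; dz[axis] <- 1L
  dim(zero) <- dz
  out_dim <- dn; out_dim[axis] <- dn[axis] + 1L
  perm <- c(axis, seq_along(dn)[-axis])
  xa <- aperm(x, perm)
  za <- aperm(zero, perm)
  m <- if (after) rbind(matrix(xa, dn[axis]), matrix(za, 1L))
       else rbind(matrix(za, 1L), matrix(xa, dn[axis]))
  out <- array(m, c(out_dim[axis], dn[-axis]))
  aperm(out, order(perm))
}

#' Richardson extrapolation to zero mesh size
#'
#' Least-squares polynomial fit of a sequence of numerical solutions
#' against their mesh sizes; the constant term is the extrapolated value
#' at \eqn{\Delta\rho = 0}.  Values may be scalars or vectors (e.g. whole
#' binned densities, extrapolated bin-wise).
#'
#' @param values numeric vector (one value per step), or a matrix with one
#'   column per step.
#' @param steps strictly decreasing mesh sizes, same length as the number
#'   of values/columns; duplicates are an error.
#' @param degree polynomial degree; default `min(2, n - 1)`.
#' @return list with `value` (extrapolated constant term), `coef` (full
#'   polynomial coefficients), and `residuals` of the fit.
#' @export
richardson_extrapolate <- function(values, steps,
                                   degree = min(2L, length(steps) - 1L)) {
  if (anyDuplicated(steps)) stop("duplicate steps")
  if (length(steps) < 2) stop("need at least 2 (value, step) pairs")
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  if (ncol(values) != length(steps))
    stop("one value (column) per step required")
  X <- outer(steps, 0:degree, `^`)
  fit <- qr.solve(X, t(values))
  pred <- X %*% fit
  list(value = drop(fit[1L, ]), coef = t(fit),
       residuals = t(values) - pred)
}
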