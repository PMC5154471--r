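#' Built-in model: calcium sparks
#'
#' Builds the calcium-spark testbed: a quasi-2D box with `Nch` immobile
#' two-state channels releasing calcium at flux `J` when open, calcium
#' diffusing with diffusivity `D` and removed by a first-order pump toward
#' the resting level `U0`.  Three variants:
#'
#' * `"separable"` — constant channel rates (`kon`, `koff`); the channel
#'   statistics are independent of the field, so the ensemble mean of the
#'   spatial average has the closed form [analytic_mean_spark()].
#' * `"coupled"` — the opening rate is `kon * U(r,t)/U0`, evaluated in the
#'   channel's subvolume, fully coupling the subsystems.  The default
#'   coupled parameters (`kon = 0.1` s\eqn{^{-1}}, `D = 1000`
#'   \eqn{\mu m^2/s}, `dt = 2e-4` s) put the model in the fast-diffusion
#'   (well-mixed) regime used for validation against the Gibson-Bruck
#'   reference.
#' * `"membrane"` — as `"separable"`, but the channels sit on the z = 0
#'   face of the box, so the stochastic source acts through the boundary
#'   subvolumes (the finite-volume form of a boundary-flux source).
#'
#' Channel positions default to a regular 12 x 2 grid spanning the box, a
#' fixture standing in for the clustered layouts of real cells; the
#' separable statistics do not depend on channel positions.
#'
#' @param variant `"separable"`, `"coupled"`, or `"membrane"`.
#' @param J open-channel flux (\eqn{\mu M\,\mu m^3/s}).
#' @param U0 resting concentration (\eqn{\mu M}).
#' @param kon,koff channel rates (s\eqn{^{-1}}); for `"coupled"`, `kon`
#'   is the rate at `U = U0`.
#' @param Vp pump rate (s\eqn{^{-1}}).
#' @param D calcium diffusivity (\eqn{\mu m^2/s}).
#' @param Nch channel count.
#' @param extents,spacing grid geometry (defaults: the
#'   \eqn{[0,10.1]\times[0,2.1]\times[0,0.5]\,\mu m^3} quasi-2D box at
#'   \eqn{\Delta x = \Delta y = 0.1}, \eqn{\Delta z = 0.5\,\mu m}).
#' @param channel_positions optional `Nch` x 3 matrix overriding the
#'   regular layout.
#' @param dt,T time step and duration (s).
#' @return a [hybrid_model()].
#' @export
build_spark_model <- function(variant = c("separable", "coupled", "membrane"),
                              J = 10, U0 = 0.1, kon = NULL, koff = 5,
                              Vp = 1, D = NULL, Nch = 24,
                              extents = rbind(c(0, 0, 0), c(10.1, 2.1, 0.5)),
                              spacing = c(0.1, 0.1, 0.5),
                              channel_positions = NULL,
                              dt = NULL, T = 5) {
  variant <- match.arg(variant)
  kon <- kon %||% if (variant == "coupled") 0.1 else 1
  D <- D %||% if (variant == "coupled") 1000 else 1
  dt <- dt %||% if (variant == "coupled") 2e-4 else 2e-3
  if (variant == "coupled" && U0 <= 0)
    stop("coupled variant requires U0 > 0 (opening rate is kon * U/U0)")
  grid <- build_box_grid(extents, spacing)
  if (is.null(channel_positions)) {
    nx <- ceiling(Nch / 2); ny <- ceiling(Nch / nx)
    gx <- grid$lower[1] + (seq_len(nx) - 0.5) / nx * (grid$upper[1] - grid$lower[1])
    gy <- grid$lower[2] + (seq_len(ny) - 0.5) / ny * (grid$upper[2] - grid$lower[2])
    gz <- if (variant == "membrane") grid$lower[3] else
      (grid$lower[3] + grid$upper[3]) / 2
    channel_positions <- cbind(rep(gx, ny), rep(gy, each = nx), gz)[seq_len(Nch), ,
                                                                   drop = FALSE]
  }
  open_rate <- if (variant == "coupled")
    rate_linear("U", coef = kon / U0) else rate_constant(kon)
  hybrid_model(
    name = paste0("spark_", variant),
    grid = grid,
    fields = list(U = list(domain = "volume", D = D, bc = "no-flux",
                           init = U0)),
    species = list(channel = list(
      domain = "volume", n = Nch, states = c("closed", "open"),
      positions = channel_positions, init_state = "closed",
      diffusivity = c(closed = 0, open = 0))),
    transitions = list(
      list(species = "channel", from = "closed", to = "open",
           rate = open_rate),
      list(species = "channel", from = "open", to = "closed",
           rate = rate_constant(koff))),
    couplings = list(
      coupling_particle_source("U", "channel", "open", J),
      coupling_relax("U", rate = Vp, target = U0)),
    dt = dt, T = T)
}

#' Built-in model: nondimensional single-channel spark
#'
#' The nondimensionalized single-channel testbed used for cross-validation
#' against the direct Fokker-Planck solvers: field
#' \eqn{\rho = (U - U_0)/U_0} obeying
#' \eqn{\partial_\tau \rho = d\,\nabla^2\rho + a\,\delta(r)\,\xi - \rho},
#' with channel opening rate \eqn{\alpha\beta(\rho(0)+1)} and closing rate
#' \eqn{\alpha} (time in units of \eqn{1/V_p}).
#'
#' @param alpha,beta,a dimensionless parameters.
#' @param d dimensionless diffusivity.
#' @param extents,spacing grid geometry; the default is the quasi-1D
#'   two-node domain (\eqn{[0,4]} at \eqn{\Delta x = 2}, unit
#'   cross-section) of the finite-diffusion validation; pass the unit box
#'   \eqn{[-0.5,0.5]^3} for the fast-diffusion variant.
#' @param channel_pos channel location (default: in the first cell).
#' @param dt,T time step and duration (dimensionless time).
#' @return a [hybrid_model()].
#' @export
build_rho_model <- function(alpha = 10, beta = 1, a = 20 / 3, d = 1,
                            extents = rbind(c(0, 0, 0), c(4, 1, 1)),
                            spacing = c(2, 1, 1),
                            channel_pos = NULL, dt = 1e-4, T = 1) {
  grid <- build_box_grid(extents, spacing)
  channel_pos <- channel_pos %||%
    matrix(grid$lower + 1e-9 * grid$spacing, 1L)
  # point source a * delta(r): its spatial integral is a, so the channel
  # flux is J = a and the engine bins it to a/|cell| in the subvolume
  hybrid_model(
    name = "rho_single_channel",
    grid = grid,
    fields = list(rho = list(domain = "volume", D = d, bc = "no-flux",
                             init = 0)),
    species = list(channel = list(
      domain = "volume", n = 1L, states = c("closed", "open"),
      positions = channel_pos, init_state = "closed",
      diffusivity = c(closed = 0, open = 0))),
    transitions = list(
      list(species = "channel", from = "closed", to = "open",
           rate = rate_linear("rho", coef = alpha * beta,
                              offset = alpha * beta)),
      list(species = "channel", from = "open", to = "closed",
           rate = rate_constant(alpha))),
    couplings = list(
      coupling_particle_source("rho", "channel", "open", J = a),
      coupling_relax("rho", rate = 1, target = 0)),
    dt = dt, T = T)
}

#' Analytic parameters of the stochastically gated binding model
#'
#' Recomputes the derived constants of the gated reversible-binding
#' benchmark from their defining formulas: the contact radius
#' \eqn{r_c = (0.3/(4\pi L_0))^{1/3}} (with \eqn{L_0} as a number
#' density), the diffusional time \eqn{\tau_D = r_c^2/D}, the
#' diffusion-limited forward constant \eqn{\kappa_f = 4\pi D r_c}, the
#' reverse constant \eqn{\kappa_r = \kappa_f L_0 = 0.3\,\tau_D^{-1}}, and
#' the molar equivalent of `N` macromolecules in `volume`.
#'
#' @param L0 bulk ligand concentration (\eqn{\mu M}).
#' @param D relative diffusivity (\eqn{\mu m^2/s}).
#' @param N macromolecule count.
#' @param volume domain volume (\eqn{\mu m^3}).
#' @return list with `rc` (\eqn{\mu m}), `tauD` (s), `kf`
#'   (\eqn{\mu m^3/s}), `kr` (s\eqn{^{-1}}), and `conc_uM`
#'   (\eqn{\mu M}).
#' @export
gated_parameters <- function(L0 = 1, D = 1, N = 20000, volume = 1000) {
  L0_dens <- L0 * MOLECULES_PER_UMOLAR_UM3
  rc <- (0.3 / (4 * pi * L0_dens))^(1 / 3)
  tauD <- rc^2 / D
  kf <- 4 * pi * D * rc
  kr <- kf * L0_dens
  list(rc = rc, tauD = tauD, kf = kf, kr = kr,
       conc_uM = N / (MOLECULES_PER_UMOLAR_UM3 * volume))
}

#' Built-in model: stochastically gated reversible binding
#'
#' Immobile macromolecules switch between inert and reactive
#' configurations at rates `a` and `b`; a reactive macromolecule binds
#' ligand at rate \eqn{\kappa_f L(r,t)} (with the ligand treated as a
#' continuous field, locally depleted by the binding) and the complex
#' releases it at rate \eqn{\kappa_r}.  The ligand field obeys a
#' diffusion equation with the binned sink/source terms and a Dirichlet
#' boundary \eqn{L = L_0}.  Macromolecules start unbound, split equally
#' between inert and reactive states.
#'
#' @param N macromolecule count.
#' @param L0 bulk/initial ligand concentration (\eqn{\mu M}).
#' @param D ligand diffusivity (\eqn{\mu m^2/s}).
#' @param extents,h domain bounds and mesh size (\eqn{\mu m}).
#' @param a,b activation/inactivation rates (s\eqn{^{-1}}); default
#'   \eqn{1/\tau_D}.
#' @param kf,kr binding constants; defaults from [gated_parameters()].
#' @param dt,T time step and duration (s); `T` defaults to
#'   \eqn{110\,\tau_D}, the horizon used to estimate the binding
#'   equilibrium.
#' @param positions optional fixed macromolecule positions.
#' @return a [hybrid_model()].
#' @export
build_gated_model <- function(N = 20000, L0 = 1, D = 1,
                              extents = rbind(c(0, 0, 0), c(10, 10, 10)),
                              h = 0.2, a = NULL, b = NULL, kf = NULL,
                              kr = NULL, dt = 1e-5, T = NULL,
                              positions = "uniform") {
  pars <- gated_parameters(L0 = L0, D = D)
  a <- a %||% (1 / pars$tauD)
  b <- b %||% (1 / pars$tauD)
  kf <- kf %||% pars$kf
  kr <- kr %||% pars$kr
  T <- T %||% (110 * pars$tauD)
  if (kf * L0 * MOLECULES_PER_UMOLAR_UM3 * dt >= 0.5)
    stop(sprintf(
      "kf * L0 * dt = %.3g >= 0.5 at the bulk concentration: decrease dt",
      kf * L0 * MOLECULES_PER_UMOLAR_UM3 * dt))
  grid <- build_box_grid(extents, rep(h, 3))
  init_state <- rep(c("inert", "reactive"), length.out = N)
  hybrid_model(
    name = "gated_binding",
    grid = grid,
    fields = list(L = list(domain = "volume", D = D, bc = "dirichlet",
                           bc_value = L0, init = L0)),
    species = list(macro = list(
      domain = "volume", n = N,
      states = c("inert", "reactive", "complex"),
      positions = positions, init_state = init_state,
      diffusivity = c(inert = 0, reactive = 0, complex = 0))),
    transitions = list(
      list(species = "macro", from = "inert", to = "reactive",
           rate = rate_constant(a)),
      list(species = "macro", from = "reactive", to = "inert",
           rate = rate_constant(b)),
      list(species = "macro", from = "reactive", to = "complex",
           rate = rate_linear("L", coef = kf * MOLECULES_PER_UMOLAR_UM3)),
      list(species = "macro", from = "complex", to = "reactive",
           rate = rate_constant(kr))),
    couplings = list(
      coupling_binding_exchange("L", "macro", bound_state = "reactive",
                                complex_state = "complex",
                                kf = kf, kr = kr)),
    dt = dt, T = T)
}

#' Built-in model: spontaneous cell polarization
#'
#' A hybrid positive-feedback model of polarity establishment on a
#' spherical cell: discrete membrane receptors switch between a mobile
#' inactive state and an immobile active state; active receptors recruit
#' a cytosolic protein onto the membrane (surface density `S`), and the
#' local surface density in turn activates receptors (rate `k3 * S`,
#' optionally boosted by a transient pre-activation pulse
#' `k0 * exp(-t/tau)`).  The cytosolic pool is treated as spatially
#' uniform (the cytosolic diffusivity is fast compared with the
#' recruitment kinetics), exchanging mass with the membrane conservatively.
#' Without the pulse, the inactive state (all receptors inactive,
#' `S = 0`, `U = U0`) is an exact fixed point of every realization.
#'
#' The conventional unit quoted for `k3` (\eqn{\mu m^{-2} s^{-1}}) is not consistent
#' with `k3 * S` being a rate when `S` is a surface density; here `k3`
#' carries \eqn{\mu m^2 s^{-1}} so that `k3 * S` is s\eqn{^{-1}}.
#'
#' @param R cell radius (\eqn{\mu m}).
#' @param Nr receptor count.
#' @param U0 initial cytosolic concentration (\eqn{\mu M}).
#' @param DS surface diffusivity of the recruited protein
#'   (\eqn{\mu m^2/s}).
#' @param DG diffusivity of inactive receptors (\eqn{\mu m^2/s});
#'   active receptors are immobile.
#' @param k1 recruitment rate (\eqn{\mu M^{-1} s^{-1}}).
#' @param k2 membrane dissociation rate (s\eqn{^{-1}}).
#' @param k3 receptor activation rate per unit surface density
#'   (\eqn{\mu m^2 s^{-1}}).
#' @param k4 receptor deactivation rate (s\eqn{^{-1}}).
#' @param k0,tau pre-activation pulse rate (s\eqn{^{-1}}) and time
#'   constant (s); `k0 = 0` disables the pulse (`tau` must be positive
#'   when a pulse is declared).
#' @param subdivisions icosphere refinement level.
#' @param dt,T time step and duration (s).
#' @return a [hybrid_model()].
#' @export
build_polarity_model <- function(R = 4, Nr = 1000, U0 = 1, DS = 0.1,
                                 DG = 0.1, k1 = 0.01, k2 = 0.01,
                                 k3 = 0.01, k4 = 0.1, k0 = 10, tau = 1,
                                 subdivisions = 3, dt = 0.01, T = 80) {
  if (k0 > 0 && tau <= 0) stop("pulse declared with tau <= 0")
  mesh <- icosphere(R, subdivisions)
  volume <- 4 / 3 * pi * R^3
  act_rate <- if (k0 > 0)
    rate_pulse_linear("S", coef = k3, k0 = k0, tau = tau)
  else rate_linear("S", coef = k3)
  hybrid_model(
    name = "polarity",
    surface = mesh,
    fields = list(
      U = list(domain = "pool", volume = volume, init = U0),
      S = list(domain = "surface", D = DS, init = 0)),
    species = list(receptor = list(
      domain = "surface", n = Nr, states = c("inactive", "active"),
      positions = "uniform", init_state = "inactive",
      diffusivity = c(inactive = DG, active = 0))),
    transitions = list(
      list(species = "receptor", from = "inactive", to = "active",
           rate = act_rate),
      list(species = "receptor", from = "active", to = "inactive",
           rate = rate_constant(k4))),
    couplings = list(
      coupling_surface_recruitment("U", "S", "receptor", "active",
                                   k_on = k1, k_off = k2)),
    dt = dt, T = T)
}

#' Well-mixed calcium-spark model for the Gibson-Bruck reference
#'
#' The well-mixed (fast diffusion) limit of the coupled spark model as a
#' fully stochastic reaction network in molecule counts: calcium `Ca`
#' (initially `round(U0 * 602 * volume)` molecules), `Nch` channels as
#' `Cc` (closed) / `Co` (open).  Reactions: coupled opening
#' (`kon/ (U0 * 602 * volume)` per Ca-channel pair), closing (`koff`),
#' release (`J * 602` per open channel), pump (`Vp` per ion), and the
#' basal source `Vp * U0 * 602 * volume` that holds the resting level.
#'
#' @inheritParams build_spark_model
#' @param volume domain volume (\eqn{\mu m^3}).
#' @return list with `x0`, reaction tables ready for
#'   [gibson_bruck_simulate()], and the count-to-concentration factor
#'   `uM_per_molecule`.
#' @export
well_mixed_spark_model <- function(J = 10, U0 = 0.1, kon = 0.1, koff = 5,
                                   Vp = 1, Nch = 24,
                                   volume = 10.1 * 2.1 * 0.5) {
  nCa0 <- round(U0 * MOLECULES_PER_UMOLAR_UM3 * volume)
  scale <- U0 * MOLECULES_PER_UMOLAR_UM3 * volume
  list(
    species = c("Ca", "Cc", "Co"),
    x0 = c(Ca = nCa0, Cc = Nch, Co = 0),
    k = c(open = kon / scale, close = koff, release = J * MOLECULES_PER_UMOLAR_UM3,
          pump = Vp, basal = Vp * U0 * MOLECULES_PER_UMOLAR_UM3 * volume),
    react1 = c(0L, 2L, 2L, 0L, -1L),   # 0-based reactant indices; -1 = none
    react2 = c(1L, -1L, -1L, -1L, -1L),
    stoich = rbind(c(0, -1, 1),    # opening consumes no calcium (catalytic)
                   c(0, 1, -1),
                   c(1, 0, 0),
                   c(-1, 0, 0),
                   c(1, 0, 0)),
    uM_per_molecule = 1 / (MOLECULES_PER_UMOLAR_UM3 * volume))
}

#' Simulate a well-mixed model with the Gibson-Bruck next-reaction method
#'
#' Statistically exact continuous-time trajectories of a mass-action
#' network, free of time-discretization error; the standard reference for
#' the hybrid solver in its well-mixed limit.  Unfired reaction times are
#' reused in absolute time as prescribed by the next-reaction method.
#'
#' @param model a list as returned by [well_mixed_spark_model()]:
#'   `species`, `x0`, `k`, `react1`/`react2` (0-based reactant indices,
#'   -1 for none), `stoich`.
#' @param times output times (states are sampled from the
#'   piecewise-constant trajectory).
#' @param nreal number of realizations.
#' @param seed optional RNG seed.
#' @return array `times` x species x realizations.
#' @export
gibson_bruck_simulate <- function(model, times, nreal = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- gb_simulate(as.integer(model$x0), as.numeric(model$k),
                     as.integer(model$react1), as.integer(model$react2),
                     as.matrix(model$stoich), as.numeric(times),
                     as.integer(nreal))
  dimnames(out) <- list(NULL, model$species, NULL)
  out
}
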