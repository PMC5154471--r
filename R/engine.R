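#' @keywords internal
#' Compile a model: cached operators, rule tables and coupling lookups.
.compile_model <- function(model, dt = model$dt) {
  rt <- list(dt = dt)
  rt$steppers <- list()
  for (fn in names(model$fields)) {
    f <- model$fields[[fn]]
    if (f$domain == "volume") {
      op <- diffusion_operator(model$grid, D = f$D %||% 0,
                               bc = f$bc %||% "no-flux",
                               value = f$bc_value)
      rt$steppers[[fn]] <- pde_stepper(op, dt)
    } else if (f$domain == "surface") {
      op <- surface_operator(model$surface, D = f$D %||% 0)
      rt$steppers[[fn]] <- pde_stepper(op, dt)
    }
  }
  # per-species rule tables
  rt$rules <- list()
  for (sn in names(model$species)) {
    rules <- Filter(function(r) r$species == sn, model$transitions)
    if (!length(rules)) { rt$rules[[sn]] <- NULL; next }
    st <- model$species[[sn]]$states
    specs <- lapply(rules, `[[`, "rate")
    rt$rules[[sn]] <- list(
      from = vapply(rules, function(r) match(r$from, st), 1L),
      to = vapply(rules, function(r) match(r$to, st), 1L),
      specs = specs,
      dynamic = which(vapply(specs, function(s) s$type != "constant", TRUE)),
      names = vapply(rules, function(r)
        sprintf("%s: %s -> %s", sn, r$from, r$to), ""),
      fields = unique(unlist(lapply(rules, function(r) .rate_fields(r$rate)))))
  }
  if (!is.null(model$surface)) rt$surface <- surface_walk_info(model$surface)
  rt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# binned densities of species `sp` in state `stname`, re-derived from the
# particle arrays (ncell x n matrix of per-cell counts / cell measure)
binned_density <- function(state, sp, stname) {
  model <- state$model
  ss <- state$species[[sp]]
  si <- match(stname, model$species[[sp]]$states)
  if (ss$domain == "volume") {
    ncell <- model$grid$ncell
    cnt <- accumulate_particles(ncell, state$n, ss$cell, ss$real, ss$state,
                                si, 1, numeric(0), numeric(0),
                                matrix(0, 1, 1), FALSE)
    cnt / model$grid$cell_volume
  } else {
    cnt <- accumulate_particles(state$rt$surface$ncell, state$n, ss$cell,
                                ss$real, ss$state, si, 1, numeric(0),
                                numeric(0), matrix(0, 1, 1), FALSE)
    cnt / state$rt$surface$areas
  }
}

# gather per-particle local values of field `fn` for species entry ss
.local_field <- function(state, model, ss, fn) {
  f <- model$fields[[fn]]
  F <- state$fields[[fn]]
  if (f$domain == "pool") return(F[ss$real])
  F[ss$cell + nrow(F) * (ss$real - 1L)]
}

.refresh_rates <- function(state, model, rt) {
  for (sn in names(rt$rules)) {
    tab <- rt$rules[[sn]]
    ss <- state$species[[sn]]
    np <- length(ss$state)
    R <- state$rates[[sn]]
    if (is.null(R)) {         # first call: allocate, fill constant columns
      R <- matrix(0, np, length(tab$from))
      for (j in setdiff(seq_along(tab$specs), tab$dynamic))
        R[, j] <- tab$specs[[j]]$k
      redo <- tab$dynamic
    } else redo <- tab$dynamic
    for (j in redo) {
      spec <- tab$specs[[j]]
      fn <- spec$field
      if (model$fields[[fn]]$domain == "pool") {
        local <- stats::setNames(list(.local_field(state, model, ss, fn)), fn)
        ev <- .eval_rate(spec, local, state$t, np)
        R[, j] <- ev$rate
        state$neg_rate_events <- state$neg_rate_events + ev$n_negative
      } else {
        offset <- if (spec$type == "pulse_linear")
          spec$k0 * exp(-state$t / spec$tau) else spec$offset
        ev <- gather_linear_rate(state$fields[[fn]], ss$cell, ss$real,
                                 spec$coef, offset)
        R[, j] <- ev$rate
        state$neg_rate_events <- state$neg_rate_events + ev$n_negative
      }
    }
    state$rates[[sn]] <- R
  }
  state
}

#' Initialize a simulation state
#'
#' Performs the initialization phase of the hybrid algorithm: fields are
#' set from their initial conditions, particle positions are sampled
#' (uniformly over the volume or surface where so declared) or copied,
#' transition rates are initialized from the t = 0 fields, and the initial
#' binned densities are computed.  Randomness (position sampling) is drawn
#' from the current RNG stream; seed it before calling for reproducibility.
#'
#' @param model a [hybrid_model()].
#' @param n number of realizations propagated together (the state is
#'   vectorized across realizations).
#' @return An object of class `hybrid_state`.
#' @export
hybrid_init <- function(model, n = 1L) {
  rt <- .compile_model(model)
  state <- list(t = 0, step = 0L, n = as.integer(n), fields = list(),
                species = list(), rates = list(),
                neg_rate_events = 0L)
  for (fn in names(model$fields)) {
    f <- model$fields[[fn]]
    state$fields[[fn]] <- switch(f$domain,
      volume = matrix(f$init, model$grid$ncell, n),
      surface = matrix(f$init, model$surface$ncell, n),
      pool = rep(f$init, length.out = n))
  }
  for (sn in names(model$species)) {
    s <- model$species[[sn]]
    np <- s$n
    states <- s$states
    D <- stats::setNames(rep(0, length(states)), states)
    if (!is.null(s$diffusivity)) D[names(s$diffusivity)] <- s$diffusivity
    init <- s$init_state
    st1 <- match(rep(init, length.out = np), states)
    stv <- rep.int(st1, n)
    real <- rep(seq_len(n), each = np)
    if (s$domain == "volume") {
      if (identical(s$positions, "uniform")) {
        lo <- model$grid$lower; hi <- model$grid$upper
        pos <- cbind(stats::runif(np * n, lo[1], hi[1]),
                     stats::runif(np * n, lo[2], hi[2]),
                     stats::runif(np * n, lo[3], hi[3]))
      } else {
        pos <- s$positions[rep(seq_len(np), n), , drop = FALSE]
      }
      entry <- list(domain = "volume", np = np, real = real, state = stv,
                    pos = pos, cell = locate_cell(model$grid, pos),
                    D_by_state = D)
    } else {
      if (identical(s$positions, "uniform")) {
        u <- surface_sample_uniform(rt$surface, np * n)
        tri <- u$tri; bary <- u$bary
      } else {
        tri <- rep(s$positions$tri, n)
        bary <- s$positions$bary[rep(seq_len(np), n), , drop = FALSE]
      }
      if (any(D > 0)) {
        step_len <- sqrt(4 * max(D) * model$dt)
        if (step_len > min(rt$surface$edges$length))
          warning(sprintf(
            "surface step %.3g um exceeds the smallest mesh edge %.3g um; refine dt or mesh",
            step_len, min(rt$surface$edges$length)))
      }
      entry <- list(domain = "surface", np = np, real = real, state = stv,
                    tri = tri, bary = bary, cell = tri, D_by_state = D)
    }
    state$species[[sn]] <- entry
  }
  state <- .refresh_rates(state, model, rt)
  structure(c(state, list(rt = rt, model = model)), class = "hybrid_state")
}

# assemble explicit source terms (time t) for every non-pool field, and
# pool increments; returns list(src = list per field, pool = list per pool)
.assemble_sources <- function(state, model, rt) {
  src <- list()
  pool <- list()
  n <- state$n
  add <- function(lst, fn, x) {
    lst[[fn]] <- if (is.null(lst[[fn]])) x else lst[[fn]] + x
    lst
  }
  none <- numeric(0); noF <- matrix(0, 1, 1)
  ensure <- function(lst, fn) {
    if (is.null(lst[[fn]])) {
      F <- state$fields[[fn]]
      lst[[fn]] <- matrix(0, nrow(F), ncol(F))
    }
    lst
  }
  for (cp in model$couplings) {
    if (cp$type == "particle_source") {
      ss <- state$species[[cp$species]]
      si <- match(cp$state, model$species[[cp$species]]$states)
      src <- ensure(src, cp$field)
      accumulate_particles_into(src[[cp$field]], ss$cell, ss$real, ss$state,
                                si, cp$J / model$grid$cell_volume,
                                none, none, noF, FALSE)
    } else if (cp$type == "relax") {
      F <- state$fields[[cp$field]]
      if (model$fields[[cp$field]]$domain == "pool") {
        pool <- add(pool, cp$field, cp$rate * (cp$target - F))
      } else {
        src <- ensure(src, cp$field)
        add_relax_into(src[[cp$field]], F, cp$rate, cp$target)
      }
    } else if (cp$type == "binding_exchange") {
      vol <- model$grid$cell_volume
      ss <- state$species[[cp$species]]
      states <- model$species[[cp$species]]$states
      F <- state$fields[[cp$field]]
      src <- ensure(src, cp$field)
      # sink -kf * F * (bound density); source +kr * (complex density)/602
      accumulate_particles_into(src[[cp$field]], ss$cell, ss$real, ss$state,
                                match(cp$bound_state, states),
                                -cp$kf / vol, none, none, F, TRUE)
      accumulate_particles_into(src[[cp$field]], ss$cell, ss$real, ss$state,
                                match(cp$complex_state, states),
                                cp$kr / (MOLECULES_PER_UMOLAR_UM3 * vol),
                                none, none, noF, FALSE)
    } else if (cp$type == "surface_recruitment") {
      areas <- rt$surface$areas
      ss <- state$species[[cp$species]]
      si <- match(cp$state, model$species[[cp$species]]$states)
      S <- state$fields[[cp$surface_field]]
      U <- state$fields[[cp$volume_field]]   # pool, length n
      flux <- accumulate_particles(nrow(S), n, ss$cell, ss$real, ss$state,
                                   si, cp$k_on, 1 / areas, U, noF, FALSE)
      flux <- flux - cp$k_off * S
      src <- add(src, cp$surface_field, flux)
      Vp <- model$fields[[cp$volume_field]]$volume
      pool <- add(pool, cp$volume_field,
                  -colSums(flux * areas) / (MOLECULES_PER_UMOLAR_UM3 * Vp))
    }
  }
  list(src = src, pool = pool)
}

.pde_update <- function(state, model, rt) {
  asm <- .assemble_sources(state, model, rt)
  for (fn in names(model$fields)) {
    f <- model$fields[[fn]]
    if (f$domain == "pool") {
      inc <- asm$pool[[fn]]
      if (!is.null(inc)) state$fields[[fn]] <- state$fields[[fn]] + rt$dt * inc
    } else {
      s <- asm$src[[fn]] %||% 0
      state$fields[[fn]] <-
        semi_implicit_step(rt$steppers[[fn]], state$fields[[fn]], s)
    }
    if (anyNA(state$fields[[fn]]))
      stop(sprintf(
        "non-finite values in field '%s' at t = %.6g (step %d): reduce dt",
        fn, state$t, state$step))
  }
  state
}

.particle_update <- function(state, model, rt) {
  dt <- rt$dt
  for (sn in names(model$species)) {
    ss <- state$species[[sn]]
    tab <- rt$rules[[sn]]
    if (!is.null(tab)) {
      ss$state <- sample_transitions(ss$state, tab$from, tab$to,
                                     state$rates[[sn]], dt,
                                     guard = model$rate_dt_guard,
                                     rule_names = tab$names)
    }
    D <- ss$D_by_state[ss$state]
    if (any(D > 0)) {
      if (ss$domain == "volume") {
        ss$pos <- diffuse_positions(ss$pos, D, dt,
                                    model$grid$lower, model$grid$upper)
        ss$cell <- locate_cell(model$grid, ss$pos)
      } else {
        moved <- diffuse_on_surface(rt$surface, ss$tri, ss$bary, D, dt)
        ss$tri <- moved$tri; ss$bary <- moved$bary; ss$cell <- moved$tri
      }
    }
    state$species[[sn]] <- ss
  }
  state
}

#' Advance a hybrid state by one time step
#'
#' Executes one fixed-\eqn{\Delta t} cycle of the hybrid loop, in this
#' exact order (the order is part of the contract): (iv) the PDE fields are
#' advanced semi-implicitly using the time-t binned particle densities and
#' time-t reaction terms as explicit sources; (v) particle transitions are
#' sampled from the rates cached at the end of the previous step (i.e.
#' evaluated from the time-t fields), then mobile particles take their
#' Brownian step; (vi) field-dependent transition rates are refreshed from
#' the new fields at the new particle locations; (vii) particle densities
#' are re-binned on the shared grid.  With
#' `step_order = "particles_first"` phases (iv) and (v) are swapped; the
#' two orderings differ by \eqn{O(\Delta t)}.
#'
#' @param state a [hybrid_init()] state.
#' @return the updated state at \eqn{t + \Delta t}.
#' @export
hybrid_step <- function(state) {
  model <- state$model; rt <- state$rt
  if (model$step_order == "pde_first") {
    state <- .pde_update(state, model, rt)
    state <- .particle_update(state, model, rt)
  } else {
    state <- .particle_update(state, model, rt)
    state <- .pde_update(state, model, rt)
  }
  state$step <- state$step + 1L
  state$t <- state$step * rt$dt   # exact multiples of dt
  state <- .refresh_rates(state, model, rt)
  state
}

# spatial mean of a field per realization (volume-weighted)
.spatial_mean <- function(state, model, fn) {
  f <- model$fields[[fn]]
  F <- state$fields[[fn]]
  switch(f$domain,
    volume = colMeans(F),
    surface = colSums(F * state$rt$surface$areas) / sum(state$rt$surface$areas),
    pool = F)
}

# per-realization state counts for one species: nstates x n
.state_counts <- function(state, model, sn) {
  ss <- state$species[[sn]]
  k <- length(model$species[[sn]]$states)
  matrix(tabulate(ss$state + k * (ss$real - 1L), nbins = k * state$n),
         k, state$n)
}

#' Run a seeded ensemble of hybrid realizations
#'
#' Generates `n` Monte Carlo realizations of the model and records
#' ensemble observables.  Two execution modes are provided:
#'
#' * `"collective"` (default): all realizations are propagated together in
#'   one vectorized state (fields as `ncell` x `n` matrices, one
#'   factorized multi-right-hand-side linear solve per field per step).
#'   The ensemble is reproducible as a whole from `(base_seed, n)`.
#' * `"stream"`: realizations run one at a time, each on its own RNG
#'   stream seeded `base_seed + realization id`, so a single realization
#'   is bit-reproducible in isolation and the result is independent of
#'   the order (or machine distribution) in which realizations are run.
#'
#' Both modes execute the identical step code; `"collective"` is the
#' throughput mode for large ensembles, `"stream"` the reproducibility
#' contract for individual trajectories.
#'
#' @param model a [hybrid_model()].
#' @param n number of realizations (\eqn{\ge 1}).
#' @param base_seed integer seed.
#' @param mode `"collective"` or `"stream"`.
#' @param record_every record observables every this many steps.
#' @param per_realization if `TRUE`, keep per-realization time series
#'   (spatial means and state counts) in addition to ensemble mean/var.
#' @param snapshot_times times (s) at which to store full field values and
#'   particle states per realization (rounded to the nearest step).
#' @return An object of class `hybrid_ensemble`: list with `times`,
#'   `field_mean` / `field_var` (per field: ensemble mean and variance of
#'   the spatial average at each time), `state_mean` (per species:
#'   times x states matrix of mean counts), optional `field_real` /
#'   `state_real` per-realization arrays, `snapshots`, and metadata.
#' @export
run_ensemble <- function(model, n, base_seed = 1L,
                         mode = c("collective", "stream"),
                         record_every = 1L, per_realization = FALSE,
                         snapshot_times = numeric(0)) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  if (mode == "stream") {
    runs <- lapply(seq_len(n), function(r) {
      set.seed(base_seed + r)
      .run_block(model, 1L, record_every, per_realization = TRUE,
                 snapshot_times = snapshot_times)
    })
    return(.merge_stream(runs, model, n, base_seed, record_every))
  }
  set.seed(base_seed)
  out <- .run_block(model, n, record_every, per_realization, snapshot_times)
  out$mode <- "collective"; out$base_seed <- base_seed
  out
}

.run_block <- function(model, n, record_every, per_realization,
                       snapshot_times) {
  nstep <- round(model$T / model$dt)
  rec_steps <- seq(0L, nstep, by = record_every)
  snap_steps <- unique(pmin(pmax(round(snapshot_times / model$dt), 0L), nstep))
  state <- hybrid_init(model, n)
  nt <- length(rec_steps)
  fm <- fv <- lapply(model$fields, function(f) numeric(nt))
  fr <- if (per_realization)
    lapply(model$fields, function(f) matrix(NA_real_, nt, n)) else NULL
  sm <- lapply(model$species, function(s)
    matrix(NA_real_, nt, length(s$states),
           dimnames = list(NULL, s$states)))
  sr <- if (per_realization)
    lapply(model$species, function(s)
      array(NA_real_, c(nt, length(s$states), n))) else NULL
  snapshots <- list()
  irec <- 0L
  record <- function(state) {
    for (fn in names(model$fields)) {
      v <- .spatial_mean(state, model, fn)
      fm[[fn]][irec] <<- mean(v)
      fv[[fn]][irec] <<- if (n > 1) stats::var(v) else 0
      if (per_realization) fr[[fn]][irec, ] <<- v
    }
    for (sn in names(model$species)) {
      cnt <- .state_counts(state, model, sn)
      sm[[sn]][irec, ] <<- rowMeans(cnt)
      if (per_realization) sr[[sn]][irec, , ] <<- cnt
    }
  }
  snap <- function(state) {
    snapshots[[length(snapshots) + 1L]] <<- list(
      t = state$t,
      fields = state$fields,
      species = lapply(state$species, function(ss)
        ss[intersect(names(ss), c("state", "pos", "tri", "bary", "real"))]))
  }
  rec_flag <- logical(nstep + 1L); rec_flag[rec_steps + 1L] <- TRUE
  snap_flag <- logical(nstep + 1L); snap_flag[snap_steps + 1L] <- TRUE
  if (rec_flag[1L]) { irec <- 1L; record(state) }
  if (snap_flag[1L]) snap(state)
  for (k in seq_len(nstep)) {
    state <- hybrid_step(state)
    if (rec_flag[k + 1L]) { irec <- irec + 1L; record(state) }
    if (snap_flag[k + 1L]) snap(state)
  }
  if (state$neg_rate_events > 0)
    warning(sprintf(
      "%d rate evaluations clamped at 0 due to negative local field values",
      state$neg_rate_events))
  structure(list(times = rec_steps * model$dt, field_mean = fm,
                 field_var = fv, field_real = fr, state_mean = sm,
                 state_real = sr, snapshots = snapshots, n = n,
                 model_name = model$name, dt = model$dt,
                 neg_rate_events = state$neg_rate_events,
                 final = state),
            class = "hybrid_ensemble")
}

.merge_stream <- function(runs, model, n, base_seed, record_every) {
  nt <- length(runs[[1]]$times)
  fm <- fv <- list(); fr <- list()
  for (fn in names(model$fields)) {
    M <- sapply(runs, function(r) r$field_real[[fn]][, 1])
    if (nt == 1L) M <- matrix(M, 1L)
    fm[[fn]] <- rowMeans(M)
    fv[[fn]] <- if (n > 1) apply(M, 1, stats::var) else numeric(nt)
    fr[[fn]] <- M
  }
  sm <- list(); sr <- list()
  for (sn in names(model$species)) {
    k <- length(model$species[[sn]]$states)
    A <- array(NA_real_, c(nt, k, n))
    for (r in seq_len(n)) A[, , r] <- runs[[r]]$state_real[[sn]][, , 1]
    sm[[sn]] <- apply(A, c(1, 2), mean)
    colnames(sm[[sn]]) <- model$species[[sn]]$states
    sr[[sn]] <- A
  }
  snapshots <- do.call(c, lapply(runs, `[[`, "snapshots"))
  structure(list(times = runs[[1]]$times, field_mean = fm, field_var = fv,
                 field_real = fr, state_mean = sm, state_real = sr,
                 snapshots = snapshots, n = n, model_name = model$name,
                 dt = model$dt, mode = "stream", base_seed = base_seed,
                 neg_rate_events = sum(vapply(runs, `[[`, 0L,
                                              "neg_rate_events"))),
            class = "hybrid_ensemble")
}

#' @export
print.hybrid_ensemble <- function(x, ...) {
  cat(sprintf("<hybrid_ensemble> '%s': n = %d, %d recorded times (dt = %g s)\n",
              x$model_name, x$n, length(x$times), x$dt))
  invisible(x)
}
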