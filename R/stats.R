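#' Normalized binned density estimate
#'
#' The package-wide histogram convention: `bins` equal-width bins over
#' `range`, frequencies divided by the bin width so that
#' \eqn{\sum_k \mathrm{value}_k \cdot \mathrm{width} = 1} exactly.
#' Samples above the range are reported as a clipped count (and excluded
#' from the normalization); an empty sample set is an error.
#'
#' @param samples numeric vector.
#' @param range length-2 range; defaults to `c(0, max(samples))`.
#' @param bins number of bins (default 20, the validation convention).
#' @return list with `breaks`, `mids`, `density`, `width`, `n`
#'   (samples used) and `clipped`.
#' @export
density_histogram <- function(samples, range = NULL, bins = 20L) {
  if (!length(samples)) stop("empty sample set")
  range <- range %||% c(0, max(samples))
  if (diff(range) <= 0) range <- range + c(-0.5, 0.5)  # degenerate samples
  clipped <- sum(samples > range[2] | samples < range[1])
  use <- samples[samples <= range[2] & samples >= range[1]]
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  width <- diff(range) / bins
  idx <- pmin(pmax(floor((use - range[1]) / width), 0), bins - 1L) + 1L
  counts <- tabulate(idx, nbins = bins)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-(bins + 1L)]) / 2,
       density = counts / (length(use) * width), width = width,
       n = length(use), clipped = clipped)
}

#' L2 difference between binned densities
#'
#' \eqn{\sqrt{\sum_k (\Delta p_k)^2 w_k}} over a common binning, reported
#' both as an absolute value and as a percentage of the maximum of the
#' reference density `pdf_b` (the convention used when quoting
#' discrepancies between solvers as "% of the respective maximum").
#'
#' @param pdf_a,pdf_b density vectors on identical bins.
#' @param width bin width(s), scalar or per-bin vector.
#' @return list with `l2` and `pct_of_max`.
#' @export
l2_difference <- function(pdf_a, pdf_b, width = 1) {
  if (length(pdf_a) != length(pdf_b)) stop("identical binning required")
  l2 <- sqrt(sum((pdf_a - pdf_b)^2 * width))
  list(l2 = l2, pct_of_max = 100 * l2 / max(pdf_b))
}

#' Bootstrap scale of the sampling error of a binned density
#'
#' Resamples `samples` with replacement `B` times and returns the
#' root-mean-square L2 distance between the resampled and the original
#' histograms: the Monte-Carlo uncertainty of the density estimate in
#' the same metric used to compare solvers.
#'
#' @inheritParams density_histogram
#' @param B bootstrap replicates.
#' @return RMS bootstrap L2 distance.
#' @export
histogram_bootstrap_l2 <- function(samples, range, bins = 20L, B = 200L) {
  h0 <- density_histogram(samples, range, bins)
  l2 <- vapply(seq_len(B), function(i) {
    hb <- density_histogram(sample(samples, replace = TRUE), range, bins)
    l2_difference(hb$density, h0$density, h0$width)$l2
  }, 0)
  sqrt(mean(l2^2))
}

#' Solution error of an ensemble mean against an exact curve
#'
#' \eqn{\varepsilon = \max_t |\bar U_{exact}(t) - \langle \bar U(t)
#' \rangle_N|}: the maximum over the common time grid of the absolute
#' deviation of the ensemble mean of the spatial average from the exact
#' expectation.
#'
#' @param mean_series ensemble mean of the spatial average at each time.
#' @param exact exact expectation on the same time grid.
#' @return the error \eqn{\varepsilon}.
#' @export
solution_error <- function(mean_series, exact) {
  if (length(mean_series) != length(exact)) stop("common time grid required")
  max(abs(exact - mean_series))
}

#' Relaxation analysis of gated reversible binding
#'
#' Builds the relaxation function \eqn{(C_{eq} - C(t))/(C_{eq} - C(0))}
#' from a complex-count time series (with the convention \eqn{C(0) = 0}
#' it reduces to \eqn{1 - C(t)/C_{eq}}), together with the closed-form
#' late-time power-law asymptote
#' \deqn{\frac{\kappa_f (1 + a/b) (4\pi D t)^{-3/2}}
#'            {\kappa_r (1 + a/b + L_0 \kappa_f/\kappa_r)^2},}
#' and estimates the log-log slope of the tail over a time window.
#' \eqn{C_{eq}} is estimated from the simulation itself at the configured
#' late time, \eqn{t = 110\,\tau_D} by default, optionally averaged over
#' a trailing window to reduce Monte-Carlo noise.
#'
#' @param times time grid (s).
#' @param C complex counts (ensemble mean) on `times`.
#' @param kf,kr,a,b,L0,D model parameters ([gated_parameters()]); `L0` in
#'   \eqn{\mu M}.
#' @param c_eq_time time at which \eqn{C_{eq}} is read off (default
#'   \eqn{110\,\tau_D}).
#' @param c_eq_window if positive, \eqn{C_{eq}} is the mean of `C` over
#'   `[c_eq_time - c_eq_window, c_eq_time]`.
#' @param tail_window length-2 time window for the slope fit.
#' @return list with `relaxation` (series), `asymptote` (series),
#'   `C_eq`, `tail_slope`, `prefactor_ratio` (mean relaxation /
#'   asymptote over the window) and the window used.
#' @export
relaxation_analysis <- function(times, C, kf, kr, a, b, L0, D,
                                c_eq_time = NULL, c_eq_window = 0,
                                tail_window = NULL) {
  pars <- gated_parameters(L0 = L0, D = D)
  tauD <- pars$tauD
  c_eq_time <- c_eq_time %||% (110 * tauD)
  if (c_eq_window > 0) {
    keep <- times >= c_eq_time - c_eq_window & times <= c_eq_time
    C_eq <- mean(C[keep])
  } else {
    C_eq <- C[which.min(abs(times - c_eq_time))]
  }
  relax <- (C_eq - C) / (C_eq - C[1L])
  L0_dens <- L0 * MOLECULES_PER_UMOLAR_UM3
  pref <- kf * (1 + a / b) / (kr * (1 + a / b + L0_dens * kf / kr)^2)
  asym <- pref * (4 * pi * D * pmax(times, .Machine$double.xmin))^(-3 / 2)
  # default window: where the closed-form asymptote exceeds the ideal
  # initial exponential exp(-(kf L0 + kr) t) for the benchmark parameters
  tail_window <- tail_window %||% (c(13, 30) * tauD)
  win <- times >= tail_window[1] & times <= tail_window[2] & relax > 0
  slope <- NA_real_
  if (sum(win) >= 3) {
    fit <- stats::lm(log(relax[win]) ~ log(times[win]))
    slope <- unname(stats::coef(fit)[2L])
  }
  list(relaxation = relax, asymptote = asym, C_eq = C_eq,
       tail_slope = slope,
       prefactor_ratio = mean(relax[win] / asym[win]),
       tail_window = tail_window, times = times)
}

#' Count clusters of points by distance linkage
#'
#' Density-based diagnostic for polarization runs: two particles belong to
#' the same cluster when their (chord) distance is at most `radius`;
#' clusters are the connected components of the resulting graph.  The
#' radius is a documented diagnostic choice, not a model parameter.
#'
#' @param points n x 3 matrix of positions.
#' @param radius linkage distance (\eqn{\mu m}).
#' @return number of clusters (0 for an empty point set).
#' @export
cluster_count <- function(points, radius) {
  n <- nrow(points)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  d2 <- radius^2
  for (i in seq_len(n - 1L)) {
    di <- (points[(i + 1L):n, 1] - points[i, 1])^2 +
          (points[(i + 1L):n, 2] - points[i, 2])^2 +
          (points[(i + 1L):n, 3] - points[i, 3])^2
    for (j in which(di <= d2)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}
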