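#' Hodgkin-Huxley structural core
#'
#' Gating variables relax toward their voltage- and temperature-dependent
#' steady state: dm_i/dt = (m_inf_i(V,T) - m_i) / tau_i(V,T). The observable
#' is the normalized current
#' I(t)/Imax = (V(t) - E) * prod_i m_i^{n_i} / (Vmax - E),
#' in which the maximal conductance cancels.
#'
#' @name hh_core
NULL

#' HH model constants
#'
#' @param G number of gates (default 2)
#' @param powers gating exponents n_i (positive integers, recycled to G)
#' @param E reversal potential in mV (default -90)
#' @param V_max normalization voltage in mV (default 80)
#' @return an \code{hh_params} list
#' @export
hh_params <- function(G = 2L, powers = 1L, E = -90, V_max = 80) {
  G <- as.integer(G)
  powers <- as.integer(rep_len(powers, G))
  stopifnot(G >= 1L, all(powers >= 1L), V_max != E)
  structure(list(G = G, powers = powers, E = E, V_max = V_max),
            class = "hh_params")
}

#' Gating functions container
#'
#' Bundles per-gate steady-state and time-constant functions. Each element of
#' \code{m_inf} and \code{tau} is a function of (V, T) returning a value in
#' (0,1) and (0, Inf) ms respectively.
#'
#' @param m_inf list of G functions f(V, T) in (0,1)
#' @param tau list of G functions f(V, T) in (0, Inf), ms
#' @return a \code{gating_functions} object
#' @export
gating_functions <- function(m_inf, tau) {
  stopifnot(length(m_inf) == length(tau), length(m_inf) >= 1L)
  structure(list(m_inf = m_inf, tau = tau, G = length(m_inf)),
            class = "gating_functions")
}

#' Convert transition rates to steady state and time constant
#'
#' @param alpha opening rate, 1/ms (>= 0)
#' @param beta closing rate, 1/ms (>= 0); alpha + beta must be > 0
#' @return list(m_inf, tau): m_inf = alpha/(alpha+beta), tau = 1/(alpha+beta)
#' @export
rates_to_steady <- function(alpha, beta) {
  if (any(alpha < 0) || any(beta < 0)) stop("rates must be non-negative", call. = FALSE)
  s <- alpha + beta
  if (any(s <= 0)) stop("alpha + beta must be positive", call. = FALSE)
  list(m_inf = alpha / s, tau = 1 / s)
}

#' Convert steady state and time constant to transition rates
#'
#' Inverse of \code{\link{rates_to_steady}}.
#'
#' @param m_inf steady state in [0,1]
#' @param tau time constant in ms (> 0)
#' @return list(alpha, beta)
#' @export
steady_to_rates <- function(m_inf, tau) {
  if (any(tau <= 0)) stop("tau must be positive", call. = FALSE)
  if (any(m_inf < 0 | m_inf > 1)) stop("m_inf must lie in [0,1]", call. = FALSE)
  list(alpha = m_inf / tau, beta = (1 - m_inf) / tau)
}

#' Right-hand side of the gating ODE system
#'
#' @param m gating state vector (length G)
#' @param V voltage, mV
#' @param Temp temperature, degrees C
#' @param funcs a \code{gating_functions} object
#' @return dm/dt vector
#' @export
gating_rhs <- function(m, V, Temp, funcs) {
  vapply(seq_along(m), function(i) {
    (funcs$m_inf[[i]](V, Temp) - m[i]) / funcs$tau[[i]](V, Temp)
  }, numeric(1))
}

#' Normalized current from gating state
#'
#' @param m gating vector (length G) or matrix (rows = time, cols = gates)
#' @param V voltage, mV (scalar or vector matching rows of m)
#' @param params an \code{hh_params} object
#' @return dimensionless normalized current
#' @export
normalized_current <- function(m, V, params) {
  if (is.matrix(m)) {
    prod_m <- rep(1, nrow(m))
    for (i in seq_len(params$G)) prod_m <- prod_m * m[, i]^params$powers[i]
  } else {
    prod_m <- prod(m^params$powers)
  }
  (V - params$E) * prod_m / (params$V_max - params$E)
}

# Exact gate trajectory under a piecewise-constant command.
# Returns matrix of gating values (rows = grid points, cols = gates) using the
# per-segment closed form m(t) = m_inf + (m0 - m_inf) exp(-(t - t0)/tau).
exact_gate_trajectory <- function(sweep, funcs, Temp, grid) {
  seg <- sweep$segments
  S <- nrow(seg)
  G <- funcs$G
  minf <- vapply(seq_len(G), function(i)
    vapply(seg$voltage, function(v) funcs$m_inf[[i]](v, Temp), numeric(1)),
    numeric(S))
  tau <- vapply(seq_len(G), function(i)
    vapply(seg$voltage, function(v) funcs$tau[[i]](v, Temp), numeric(1)),
    numeric(S))
  minf <- matrix(minf, nrow = S); tau <- matrix(tau, nrow = S)
  if (any(!is.finite(minf)) || any(!is.finite(tau)) || any(tau <= 0)) {
    stop("gating functions returned invalid values for sweep ",
         sweep$protocol_name, " ", sweep$sweep_index, call. = FALSE)
  }
  m0 <- minf[1L, ]  # steady state at the initial -80 mV holding
  out <- matrix(NA_real_, length(grid), G)
  # half-open assignment; grid points at duration belong to the last segment
  idx <- findInterval(grid, seg$t_start)
  idx[idx > S] <- S
  for (s in seq_len(S)) {
    sel <- which(idx == s)
    if (s > 1L) {
      dt_end <- seg$t_end[s - 1L] - seg$t_start[s - 1L]
      m0 <- minf[s - 1L, ] + (m0 - minf[s - 1L, ]) * exp(-dt_end / tau[s - 1L, ])
    }
    if (length(sel)) {
      dt <- grid[sel] - seg$t_start[s]
      for (i in seq_len(G)) {
        out[sel, i] <- minf[s, i] + (m0[i] - minf[s, i]) * exp(-dt / tau[s, i])
      }
    }
  }
  out
}

#' Simulate the normalized current of one sweep
#'
#' Integrates the gating ODEs under the sweep's piecewise-constant voltage
#' command and returns the normalized current on the requested grid. The gate
#' starts at its steady state for the initial -80 mV holding level. Because
#' the command is constant within each segment, the default method uses the
#' exact per-segment exponential solution (the integrator is restarted at
#' every voltage step); \code{method = "lsoda"} integrates the same system
#' with an adaptive solver (rtol 1e-6, atol 1e-8), also restarted at each
#' segment boundary.
#'
#' @param sweep a \code{sweep_protocol}
#' @param funcs a \code{gating_functions} object
#' @param params an \code{hh_params} object (G must match funcs)
#' @param Temp temperature, degrees C
#' @param grid output times in ms within [0, duration]
#' @param method "exact" (default) or "lsoda"
#' @param rtol,atol solver tolerances for \code{method = "lsoda"}
#' @return list(times, current, gating) where gating is a length(grid) x G matrix
#' @export
simulate_sweep <- function(sweep, funcs, params, Temp, grid = NULL,
                           method = c("exact", "lsoda"),
                           rtol = 1e-6, atol = 1e-8) {
  method <- match.arg(method)
  stopifnot(inherits(sweep, "sweep_protocol"), inherits(funcs, "gating_functions"))
  if (params$G != funcs$G) stop("params$G must match number of gating functions", call. = FALSE)
  if (is.null(grid)) grid <- sample_grid(sweep, 0.1)
  if (any(grid < 0 | grid > sweep$duration)) {
    stop("grid outside sweep duration", call. = FALSE)
  }
  if (method == "exact") {
    gm <- exact_gate_trajectory(sweep, funcs, Temp, grid)
  } else {
    gm <- lsoda_gate_trajectory(sweep, funcs, Temp, grid, rtol, atol)
  }
  vi <- findInterval(grid, sweep$segments$t_start)
  vi[vi < 1L] <- 1L
  vi[vi > nrow(sweep$segments)] <- nrow(sweep$segments)
  V <- sweep$segments$voltage[vi]
  list(times = grid, current = normalized_current(gm, V, params), gating = gm)
}

lsoda_gate_trajectory <- function(sweep, funcs, Temp, grid, rtol, atol) {
  seg <- sweep$segments
  G <- funcs$G
  m <- vapply(seq_len(G), function(i) funcs$m_inf[[i]](seg$voltage[1L], Temp), numeric(1))
  out <- matrix(NA_real_, length(grid), G)
  idx <- findInterval(grid, seg$t_start)
  idx[idx > nrow(seg)] <- nrow(seg)
  for (s in seq_len(nrow(seg))) {
    v <- seg$voltage[s]
    rhs <- function(t, y, parms) {
      list(vapply(seq_len(G), function(i)
        (funcs$m_inf[[i]](v, Temp) - y[i]) / funcs$tau[[i]](v, Temp), numeric(1)))
    }
    sel <- which(idx == s)
    times <- unique(c(seg$t_start[s], grid[sel], seg$t_end[s]))
    sol <- deSolve::lsoda(y = m, times = times, func = rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop("ODE solver failure in sweep ", sweep$protocol_name, " ",
           sweep$sweep_index, call. = FALSE)
    }
    if (length(sel)) {
      pos <- match(round(grid[sel], 12), round(sol[, 1L], 12))
      out[sel, ] <- sol[pos, -1L, drop = FALSE]
    }
    m <- as.numeric(sol[nrow(sol), -1L])
  }
  out
}

#' Boltzmann steady-state function
#'
#' m_inf(V) = 1 / (1 + exp(-(V - V_half)/k)); negative k gives an
#' inactivation-type (decreasing) curve.
#'
#' @param V voltage, mV
#' @param V_half half-activation voltage, mV
#' @param k slope factor, mV (sign sets direction)
#' @return value in (0,1)
#' @export
boltzmann <- function(V, V_half, k) 1 / (1 + exp(-(V - V_half) / k))

#' Bell-shaped time-constant function with Q10 temperature scaling
#'
#' tau(V, T) = (tau_base + tau_amp * exp(-((V - V_peak)/w)^2)) *
#' Q10^(-(T - 25)/10); all times in ms.
#'
#' @param V voltage, mV
#' @param Temp temperature, degrees C
#' @param tau_base baseline time constant, ms (> 0)
#' @param tau_amp peak amplitude above baseline, ms
#' @param V_peak voltage of the maximum, mV
#' @param w width, mV (> 0)
#' @param Q10 temperature coefficient (> 0)
#' @return time constant in ms
#' @export
bell_tau <- function(V, Temp, tau_base, tau_amp, V_peak, w, Q10 = 3) {
  (tau_base + tau_amp * exp(-((V - V_peak) / w)^2)) * Q10^(-(Temp - 25) / 10)
}
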