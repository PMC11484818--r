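# Single-compartment pump-leak model.
#
# Internal state vector (SI): y = (Na, K, Cl, HCO3, X) in mol/m^3 (numerically
# mM) and w in m^3. Membrane potential is not integrated: it is computed from
# the intracellular charge imbalance (charge-difference formulation), so charge
# and concentration bookkeeping cannot diverge.

y_from_state <- function(state) {
  c(Na = state$Na_i, K = state$K_i, Cl = state$Cl_i,
    HCO3 = state$HCO3_i, X = state$X_i, w = state$w * 1e-15)
}

state_from_y <- function(y, params, t = 0) {
  vm <- vm_internal(y, params_si(params), z_i = NULL)
  ion_state(Na_i = y[[1]], K_i = y[[2]], Cl_i = y[[3]], HCO3_i = y[[4]],
            X_i = y[[5]], Vm = vm * 1e3, w = y[[6]] * 1e15, t = t)
}

vm_internal <- function(y, ps, z_i = NULL) {
  if (is.null(z_i)) z_i <- ps$z_i
  ps$F * y[[6]] * (y[[1]] + y[[2]] - y[[3]] - y[[4]] + z_i * y[[5]]) /
    (ps$Cm * ps$SA)
}

#' Membrane potential from the charge-difference relation
#'
#' `Vm = F * w * sum(z_i * c_i) / (Cm * SA)`: the membrane potential implied by
#' the net intracellular charge, the compartment volume and the membrane
#' capacitance. An exactly electroneutral interior gives 0 mV; at the default
#' steady state a net charge of about -0.0056 mM produces -67 mV.
#'
#' @param state An [ion_state()].
#' @param params A [model_params()] object.
#' @return Membrane potential in mV.
#' @export
membrane_voltage <- function(state, params) {
  ps <- params_si(params)
  dq <- state$Na_i + state$K_i - state$Cl_i - state$HCO3_i +
    params$z_i * state$X_i
  1e3 * ps$F * (state$w * 1e-15) * dq / (ps$Cm * ps$SA)
}

#' Transmembrane molar fluxes and total membrane current
#'
#' Evaluates, per species, the sum of (a) ohmic leak currents
#' `g_ion * (Vm - E_ion)`; (b) the Na+/K+-ATPase with cubic sodium dependence,
#' `Jp = P * (Na_i/Na_o)^3`, moving 3 Na+ out and 2 K+ in; (c) the
#' electroneutral KCC2 flux `g_KCC2 * (E_K - E_Cl)` moving K+ and Cl- equally
#' and in the same direction; (d) GABA-A chloride and bicarbonate currents for
#' the supplied conductance. Impermeant anions never cross the membrane.
#'
#' @param state An [ion_state()].
#' @param params A [model_params()] object.
#' @param g_gabaa_now Instantaneous GABA-A conductance (nS).
#' @param chi_now Chloride fraction of the GABA-A current; `NULL` (default)
#'   recomputes it from the instantaneous reversal potentials.
#' @return A list with `flux` (named vector, mol/s, positive = into the cell),
#'   `current_A` (net membrane current, outward positive), `Jp` (pump rate,
#'   C/(m^2 s)) and `chi`.
#' @export
transmembrane_fluxes <- function(state, params, g_gabaa_now = 0,
                                 chi_now = NULL) {
  stopifnot(g_gabaa_now >= 0)
  if (!is.null(chi_now)) stopifnot(chi_now >= 0, chi_now <= 1)
  ps <- params_si(params)
  y <- y_from_state(state)
  parts <- flux_parts(y, ps, g_gaba = g_gabaa_now * 1e-9, chi_fix = chi_now)
  list(flux = c(Na = parts$dnNa, K = parts$dnK, Cl = parts$dnCl,
                HCO3 = parts$dnHCO3, X = 0),
       current_A = parts$I_total, Jp = parts$Jp, chi = parts$chi)
}

# shared flux arithmetic; y in SI, g_gaba in S; returns mol/s and A
flux_parts <- function(y, ps, g_gaba = 0, chi_fix = NULL) {
  cNa <- y[[1]]; cK <- y[[2]]; cCl <- y[[3]]; cHCO3 <- y[[4]]; w <- y[[6]]
  Vm <- vm_internal(y, ps)
  E_Na <- ps$RTF * log(ps$Na_o / cNa)
  E_K <- ps$RTF * log(ps$K_o / cK)
  E_Cl <- ps$RTF * log(cCl / ps$Cl_o)
  E_HCO3 <- ps$RTF * log(cHCO3 / ps$HCO3_o)
  Jp <- ps$P * (cNa / ps$Na_o)^3
  Jkcc2 <- ps$g_KCC2 * (E_K - E_Cl)
  chem <- ps$Kf * ps$H2CO3_i - ps$Kr * ps$H_i * cHCO3   # mol/m^3/s
  I_Na <- ps$g_Na * (Vm - E_Na) * ps$SA
  I_K <- ps$g_K * (Vm - E_K) * ps$SA
  I_Cl <- ps$g_Cl * (Vm - E_Cl) * ps$SA
  I_HCO3 <- ps$g_HCO3 * (Vm - E_HCO3) * ps$SA
  chi <- NA_real_
  I_g_Cl <- 0
  I_g_HCO3 <- 0
  if (g_gaba > 0) {
    E_gaba <- ps$RTF *
      log((0.8 * cCl + 0.2 * cHCO3) / (0.8 * ps$Cl_o + 0.2 * ps$HCO3_o))
    chi <- if (is.null(chi_fix)) (E_HCO3 - E_gaba) / (E_HCO3 - E_Cl) else chi_fix
    I_g_Cl <- chi * g_gaba * (Vm - E_Cl)
    I_g_HCO3 <- (1 - chi) * g_gaba * (Vm - E_HCO3)
  }
  dnNa <- (-I_Na - 3 * Jp * ps$SA) / ps$F + w * chem
  dnK <- (-I_K + 2 * Jp * ps$SA + Jkcc2 * ps$SA) / ps$F
  dnCl <- (I_Cl + Jkcc2 * ps$SA + I_g_Cl) / ps$F
  dnHCO3 <- (I_HCO3 + I_g_HCO3) / ps$F + w * chem
  # KCC2 and NHE are electroneutral; net current = leaks + pump + GABA-A
  I_total <- I_Na + I_K + I_Cl + I_HCO3 + Jp * ps$SA + I_g_Cl + I_g_HCO3
  list(dnNa = dnNa, dnK = dnK, dnCl = dnCl, dnHCO3 = dnHCO3,
       I_total = I_total, Jp = Jp, chi = chi, Vm = Vm)
}

#' Osmotic volume derivative
#'
#' `dw/dt = pw * vw * SA * (Pi_i - Pi_o)`: water follows the difference in
#' total solute concentration (all intracellular species against the full
#' bath, impermeant anions included). A hyperosmotic interior swells the
#' compartment; zero osmotic permeability freezes the volume.
#'
#' @inheritParams membrane_voltage
#' @return Volume derivative in pL/s.
#' @export
volume_derivative <- function(state, params) {
  ps <- params_si(params)
  Pi_i <- state$Na_i + state$K_i + state$Cl_i + state$HCO3_i + state$X_i
  1e15 * ps$pw * ps$vw * ps$SA * (Pi_i - ps$Pi_o)
}

make_rhs <- function(params, protocol = stim_protocol()) {
  ps <- params_si(params)
  gfun <- protocol_conductance(protocol)
  tv <- compile_time_varying(protocol, params)
  bath_fields <- c("Na_o", "K_o", "Cl_o", "HCO3_o", "X_o")
  bath_varies <- length(tv) > 0 &&
    any(vapply(tv, function(m) m$field %in% bath_fields, logical(1)))
  function(t, y, parms = NULL) {
    p <- ps
    for (m in tv) p[[m$field]] <- m$value(t) * m$scale
    if (bath_varies) p$Pi_o <- p$Na_o + p$K_o + p$Cl_o + p$HCO3_o + p$X_o
    parts <- flux_parts(y, p, g_gaba = gfun(t))
    w <- y[[6]]
    dw <- p$pw * p$vw * p$SA *
      (y[[1]] + y[[2]] + y[[3]] + y[[4]] + y[[5]] - p$Pi_o)
    dn <- c(parts$dnNa, parts$dnK, parts$dnCl, parts$dnHCO3, 0)
    list(c((dn - y[1:5] * dw) / w, dw))
  }
}

#' Charge-consistent initial state
#'
#' Builds the simulation starting point from the published default values.
#' Because the published concentrations are rounded to 0.1 mM they are not
#' exactly consistent with the published membrane potential under the
#' charge-difference relation, so the impermeant-anion concentration is
#' refined (by ~0.16 mM) to make the net intracellular charge match the target
#' membrane potential at the geometric volume. All other values are taken
#' verbatim from `params$init`.
#'
#' @param params A [model_params()] object.
#' @param Vm_target_mV Membrane potential the refined charge must reproduce;
#'   defaults to `params$init$Vm_mV`.
#' @return An [ion_state()] at `t = 0`.
#' @export
initial_state <- function(params, Vm_target_mV = params$init$Vm_mV) {
  ps <- params_si(params)
  init <- params$init
  if (params$z_i == 0) stop("z_i must be non-zero to balance charge", call. = FALSE)
  dq <- (Vm_target_mV * 1e-3) * ps$Cm * ps$SA / (ps$F * ps$w0)
  X_i <- (dq - (init$Na_i + init$K_i - init$Cl_i - init$HCO3_i)) / params$z_i
  if (X_i <= 0) stop("charge balancing produced non-positive X_i", call. = FALSE)
  ion_state(Na_i = init$Na_i, K_i = init$K_i, Cl_i = init$Cl_i,
            HCO3_i = init$HCO3_i, X_i = X_i, Vm = Vm_target_mV,
            w = ps$w0 * 1e15, t = 0)
}

#' Advance the model by one fixed explicit step
#'
#' Classical fourth-order Runge-Kutta step of the full system (concentrations,
#' volume, derived membrane potential). This is the reference integrator used
#' to cross-check the adaptive solver; [simulate()] with `method = "lsoda"` is
#' preferred for production runs. The step size must resolve the fastest
#' timescale present (the carbonate relaxation at ~160/s and, during GABA-A
#' conductance events, the membrane charge relaxation).
#'
#' @param state An [ion_state()].
#' @param params A [model_params()] object.
#' @param dt Step size (s), > 0.
#' @param protocol Optional [stim_protocol()] evaluated at the state's clock.
#' @return The advanced [ion_state()] at `t + dt`.
#' @export
step_state <- function(state, params, dt, protocol = stim_protocol()) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  rhs <- make_rhs(params, protocol)
  y <- y_from_state(state)
  t <- state$t
  k1 <- rhs(t, y)[[1]]
  k2 <- rhs(t + dt / 2, y + dt / 2 * k1)[[1]]
  k3 <- rhs(t + dt / 2, y + dt / 2 * k2)[[1]]
  k4 <- rhs(t + dt, y + dt * k3)[[1]]
  y1 <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(y1[1:5] < 0) || y1[[6]] <= 0) {
    stop("negative concentration or volume after step; reduce dt", call. = FALSE)
  }
  state_from_y(y1, params, t = t + dt)
}

default_output_times <- function(duration, dt_out, dense) {
  times <- seq(0, duration, by = dt_out)
  for (d in dense) {
    a <- max(0, d[1]); b <- min(duration, d[2])
    if (a < b) times <- c(times, seq(a, b, by = 0.02))
  }
  sort(unique(c(times, duration)))
}

#' Simulate the pump-leak model
#'
#' Integrates the full system from a charge-consistent initial state under an
#' optional stimulus protocol. The default integrator is the adaptive
#' stiff-switching solver from \pkg{deSolve} (`lsoda`), run piecewise between
#' protocol breakpoints so that ramps and conductance events are never stepped
#' over; `method = "rk4"` runs the fixed-step explicit reference integrator.
#'
#' @param params A [model_params()] object.
#' @param protocol A [stim_protocol()]; events must lie inside
#'   `[0, duration]`.
#' @param duration Simulated time (s).
#' @param dt_out Output grid spacing (s) away from conductance events (a
#'   finer 20 ms grid is used inside them).
#' @param times Optional explicit output time grid overriding `dt_out`.
#' @param state0 Optional starting [ion_state()]; defaults to
#'   [initial_state()].
#' @param method `"lsoda"` (default) or `"rk4"`.
#' @param dt Fixed step size for `method = "rk4"` (s).
#' @param rtol,atol Tolerances for the adaptive solver.
#' @return An object of class `ion_sim`: a list with `trajectory` (tibble of
#'   per-step state, reversal potentials, `df_gabaa = Vm - E_GABAA`,
#'   conductance and chloride fraction), `params`, `protocol`, `events`,
#'   and solver settings.
#' @export
#' @examples
#' sim <- simulate_model(model_params(), duration = 60)
#' dplyr::last(sim$trajectory$Cl_i)
simulate_model <- function(params, protocol = stim_protocol(), duration,
                           dt_out = 1, times = NULL, state0 = NULL,
                           method = c("lsoda", "rk4"), dt = 5e-4,
                           rtol = 1e-8, atol = 1e-8) {
  method <- match.arg(method)
  stopifnot(duration > 0)
  ev_t <- vapply(unclass(protocol), `[[`, numeric(1), "t")
  if (length(ev_t) && (min(ev_t) < 0 || max(ev_t) > duration)) {
    stop("protocol events must lie within [0, duration]", call. = FALSE)
  }
  if (is.null(state0)) state0 <- initial_state(params)
  bp <- protocol_breakpoints(protocol, duration)
  if (is.null(times)) times <- default_output_times(duration, dt_out, bp$dense)
  times <- sort(unique(pmin(pmax(times, 0), duration)))
  rhs <- make_rhs(params, protocol)
  y0 <- y_from_state(state0)

  if (method == "rk4") {
    out <- integrate_rk4(rhs, y0, times, dt)
  } else {
    out <- integrate_segments(rhs, y0, times, bp, duration, rtol, atol)
  }
  traj <- trajectory_tibble(out, params, protocol)
  structure(list(trajectory = traj, params = params, protocol = protocol,
                 events = protocol_events(protocol),
                 method = method,
                 settings = list(dt_out = dt_out, dt = dt, rtol = rtol,
                                 atol = atol)),
            class = "ion_sim")
}

integrate_rk4 <- function(rhs, y0, times, dt) {
  grid <- sort(unique(c(times, seq(min(times), max(times), by = dt))))
  y <- y0
  out <- matrix(NA_real_, nrow = length(times), ncol = 7)
  keep <- 1L
  if (times[1] <= min(grid)) {
    out[1, ] <- c(min(grid), y)
    keep <- 2L
  }
  for (i in seq_len(length(grid) - 1)) {
    t <- grid[i]
    h <- grid[i + 1] - t
    k1 <- rhs(t, y)[[1]]
    k2 <- rhs(t + h / 2, y + h / 2 * k1)[[1]]
    k3 <- rhs(t + h / 2, y + h / 2 * k2)[[1]]
    k4 <- rhs(t + h, y + h * k3)[[1]]
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(y[1:5] < 0) || y[[6]] <= 0) {
      stop("negative concentration during fixed-step integration; reduce dt",
           call. = FALSE)
    }
    if (keep <= length(times) && isTRUE(all.equal(grid[i + 1], times[keep]))) {
      out[keep, ] <- c(grid[i + 1], y)
      keep <- keep + 1L
    }
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

integrate_segments <- function(rhs, y0, times, bp, duration, rtol, atol) {
  breaks <- sort(unique(c(0, bp$breaks, duration)))
  dense <- bp$dense
  rows <- list()
  y <- y0
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; b <- breaks[i + 1]
    seg_times <- sort(unique(c(a, times[times > a & times < b], b)))
    in_dense <- length(dense) > 0 &&
      any(vapply(dense, function(d) a < d[2] && b > d[1], logical(1)))
    hmax <- if (in_dense) 0.05 else (b - a)
    sol <- deSolve::lsoda(y, seg_times, rhs, parms = NULL,
                          rtol = rtol, atol = atol, hmax = hmax)
    if (attr(sol, "istate")[1] < 0) {
      stop("integration failed in segment [", a, ", ", b, "] s", call. = FALSE)
    }
    y <- as.numeric(sol[nrow(sol), -1])
    names(y) <- names(y0)
    keep <- sol[, 1] %in% times
    if (i > 1) keep[1] <- FALSE   # segment start already emitted
    rows[[i]] <- sol[keep, , drop = FALSE]
  }
  do.call(rbind, rows)
}

trajectory_tibble <- function(out, params, protocol) {
  ps <- params_si(params)
  gfun <- protocol_conductance(protocol)
  tv <- compile_time_varying(protocol, params)
  t <- out[, 1]
  z_i <- rep(params$z_i, length(t))
  for (m in tv) {
    if (m$field == "z_i") z_i <- vapply(t, m$value, numeric(1))
  }
  Na <- out[, 2]; K <- out[, 3]; Cl <- out[, 4]; HCO3 <- out[, 5]
  X <- out[, 6]; w <- out[, 7]
  Vm <- 1e3 * ps$F * w * (Na + K - Cl - HCO3 + z_i * X) / (ps$Cm * ps$SA)
  rtf <- ps$RTF * 1e3
  E_Cl <- rtf * log(Cl / ps$Cl_o)
  E_HCO3 <- rtf * log(HCO3 / ps$HCO3_o)
  E_K <- rtf * log(ps$K_o / K)
  E_Na <- rtf * log(ps$Na_o / Na)
  E_GABAA <- rtf * log((0.8 * Cl + 0.2 * HCO3) /
                         (0.8 * ps$Cl_o + 0.2 * ps$HCO3_o))
  g <- vapply(t, gfun, numeric(1)) * 1e9
  chi <- (E_HCO3 - E_GABAA) / (E_HCO3 - E_Cl)
  tibble::tibble(t = t, Na_i = Na, K_i = K, Cl_i = Cl, HCO3_i = HCO3,
                 X_i = X, w_pL = w * 1e15, Vm = Vm,
                 E_Cl = E_Cl, E_HCO3 = E_HCO3, E_K = E_K, E_Na = E_Na,
                 E_GABAA = E_GABAA, df_gabaa = Vm - E_GABAA,
                 g_gabaa_nS = g, chi = chi, z_i = z_i)
}

#' Steady state of the pump-leak model
#'
#' Finds the state at which all fluxes, the osmotic volume change and the net
#' membrane current vanish, by long integration from [initial_state()]
#' followed by a damped Newton refinement on the full right-hand side. With the
#' default parameters the result reproduces the published default steady-state
#' column (Vm ~ -67.2 mV, Cl_i ~ 5.3 mM, K_i ~ 122.6 mM, HCO3_i ~ 9.7 mM).
#'
#' @param params A [model_params()] object.
#' @param state0 Optional starting [ion_state()].
#' @param t_relax Integration horizon per attempt (s).
#' @param max_attempts Maximum number of `t_relax` blocks.
#' @param tol Residual tolerance: largest relative rate of change (1/s)
#'   accepted as stationary.
#' @return An [ion_state()] with attributes `residual` (named derivative
#'   vector) and `converged`.
#' @export
#' @examples
#' ss <- steady_state(model_params())
#' ss$Cl_i
steady_state <- function(params, state0 = NULL, t_relax = 3600,
                         max_attempts = 3, tol = 1e-10) {
  rhs <- make_rhs(params, stim_protocol())
  if (is.null(state0)) state0 <- initial_state(params)
  y <- y_from_state(state0)
  scale <- function(y) c(pmax(abs(y[1:5]), 1), abs(y[[6]]))
  resid <- function(y) max(abs(rhs(0, y)[[1]]) / scale(y))
  for (i in seq_len(max_attempts)) {
    sol <- deSolve::lsoda(y, c(0, t_relax), rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-10)
    y <- as.numeric(sol[nrow(sol), -1])
    names(y) <- names(y_from_state(state0))
    y <- newton_polish(rhs, y)
    if (resid(y) < tol) {
      st <- state_from_y(y, params, t = 0)
      attr(st, "residual") <- rhs(0, y)[[1]]
      attr(st, "converged") <- TRUE
      return(st)
    }
  }
  r <- rhs(0, y)[[1]]
  stop("steady_state did not converge; residuals (d/dt): ",
       paste(sprintf("%.3g", r), collapse = ", "), call. = FALSE)
}

newton_polish <- function(rhs, y, iters = 8, damp = 0.7) {
  n <- length(y)
  for (k in seq_len(iters)) {
    f <- rhs(0, y)[[1]]
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(abs(y[j]) * 1e-7, 1e-12)
      yp <- y; yp[j] <- yp[j] + h
      ym <- y; ym[j] <- ym[j] - h
      J[, j] <- (rhs(0, yp)[[1]] - rhs(0, ym)[[1]]) / (2 * h)
    }
    delta <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(delta)) break
    y_new <- y + damp * delta
    if (any(y_new[1:5] <= 0) || y_new[n] <= 0) break
    y <- y_new
  }
  y
}

#' Driving-force samples from a simulation
#'
#' Linear interpolation of the simulated `df_gabaa = Vm - E_GABAA` trace at
#' arbitrary probe times.
#'
#' @param result An `ion_sim` from [simulate_model()].
#' @param probe_times Times (s) inside the simulated range.
#' @return A numeric vector of driving forces (mV).
#' @export
df_timecourse <- function(result, probe_times) {
  traj <- result$trajectory
  rng <- range(traj$t)
  if (any(probe_times < rng[1] | probe_times > rng[2])) {
    stop("probe times outside the simulated range [", rng[1], ", ", rng[2],
         "] s", call. = FALSE)
  }
  stats::approx(traj$t, traj$df_gabaa, xout = probe_times)$y
}
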