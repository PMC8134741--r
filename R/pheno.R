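# ---------------------------------------------------------------------------
# Phenomenological 2D models: an integrator (type 1 excitability, cubic
# voltage nullcline with three roots, spiking onset through a saddle-node on
# an invariant circle) and a resonator (type 2, cubic with a double root,
# onset through a subcritical Hopf bifurcation). Voltage in mV, the slow
# variable w dimensionless, currents in model units.
# ---------------------------------------------------------------------------

#' Integrator model parameters
#'
#' Defaults are the reference phenomenological set: cubic roots `v0 < v1 <
#' v2`, cubic scale `a0` with left-branch steepening slope `a1` (knot at
#' `v0`, aligned with the cubic root so the right-hand side stays smooth),
#' voltage time constant as a one-knot piecewise-linear function (`v3`,
#' `r0` ms, left slope `r1` ms/mV, flat above), `w` steady state ramping 0
#' to 1 between `v4` and `v5`, `w` time constant as a two-threshold step
#' (`v6`, `v7`; levels `s0`, `s1`, `s2` ms), and power `k` on `w` in the
#' voltage equation.
#'
#' @param v0,v1,v2 cubic roots, mV.
#' @param a0 cubic scale; `a1` left-branch slope of the scale factor, 1/mV.
#' @param a1 see `a0`.
#' @param v3,r0,r1 voltage time-constant knot (mV), value (ms), left slope (ms/mV).
#' @param v4,v5 `w` steady-state ramp endpoints, mV.
#' @param v6,v7 `w` time-constant thresholds, mV.
#' @param s0,s1,s2 `w` time-constant levels, ms.
#' @param k integer power on `w`.
#' @return an object of class `pheno_params`.
#' @export
integrator_params <- function(v0 = -65, v1 = -45, v2 = 55, a0 = 3.5e-6,
                              a1 = -1e-4, v3 = -35, r0 = 0.04, r1 = -0.004,
                              v4 = -40, v5 = -5, v6 = -55.45, v7 = 18.78,
                              s0 = 5, s1 = 7.6, s2 = 1.8, k = 2L) {
  p <- list(v0 = v0, v1 = v1, v2 = v2, a0 = a0, a1 = a1, v3 = v3, r0 = r0,
            r1 = r1, v4 = v4, v5 = v5, v6 = v6, v7 = v7, s0 = s0, s1 = s1,
            s2 = s2, k = as.integer(k))
  .check_pheno(p)
  structure(p, class = "pheno_params")
}

#' Resonator model parameters
#'
#' Same structure as [integrator_params()] minus the middle root `v1` (the
#' cubic has a double root at `v0`), with rescaled `a0` and a shifted `w`
#' nullcline/time constant.
#'
#' @inheritParams integrator_params
#' @return an object of class `pheno_params`.
#' @export
resonator_params <- function(v0 = -65, v2 = 55, a0 = 3.25e-6, a1 = -1e-4,
                             v3 = -35, r0 = 0.04, r1 = -0.004,
                             v4 = -75, v5 = -5, v6 = -55.5, v7 = 18,
                             s0 = 5, s1 = 7.6, s2 = 1.8, k = 2L) {
  p <- list(v0 = v0, v1 = NA_real_, v2 = v2, a0 = a0, a1 = a1, v3 = v3,
            r0 = r0, r1 = r1, v4 = v4, v5 = v5, v6 = v6, v7 = v7, s0 = s0,
            s1 = s1, s2 = s2, k = as.integer(k))
  .check_pheno(p)
  structure(p, class = "pheno_params")
}

.check_pheno <- function(p) {
  vv <- seq(-100, 60, by = 0.5)
  tauv <- ifelse(vv <= p$v3, p$r0 + p$r1 * (vv - p$v3), p$r0)
  if (any(tauv <= 0)) stop("voltage time constant not positive on [-100, 60]")
  if (any(c(p$s0, p$s1, p$s2) <= 0)) stop("w time-constant levels must be positive")
  if (p$v4 >= p$v5) stop("need v4 < v5")
  invisible(p)
}

#' Phenomenological model object
#'
#' @param type `"integrator"` or `"resonator"`.
#' @param params a matching parameter set; defaults to the reference set.
#' @return an object of class `pheno_model`.
#' @export
pheno_model <- function(type = c("integrator", "resonator"), params = NULL) {
  type <- match.arg(type)
  if (is.null(params))
    params <- if (type == "integrator") integrator_params() else resonator_params()
  structure(list(type = type, params = params),
            class = c("pheno_model", "pls_model"))
}

#' @export
parameter_count.pheno_model <- function(x, ...) {
  # stored reals; k is an integer power, v1 absent for the resonator
  if (x$type == "integrator") 15L else 14L
}

# cubic term P(v) * scale-factor(v); also its left-branch derivative
.pheno_G <- function(m, v) {
  p <- m$params
  lfac <- ifelse(v <= p$v0, p$a0 + p$a1 * (v - p$v0), p$a0)
  P <- if (m$type == "integrator")
    (p$v0 - v) * (p$v1 - v) * (p$v2 - v)
  else
    (p$v0 - v)^2 * (p$v2 - v)
  P * lfac
}

.pheno_Gprime <- function(m, v) {
  p <- m$params
  lfac <- ifelse(v <= p$v0, p$a0 + p$a1 * (v - p$v0), p$a0)
  dlfac <- ifelse(v <= p$v0, p$a1, 0)
  if (m$type == "integrator") {
    P <- (p$v0 - v) * (p$v1 - v) * (p$v2 - v)
    dP <- -((p$v1 - v) * (p$v2 - v) + (p$v0 - v) * (p$v2 - v) +
              (p$v0 - v) * (p$v1 - v))
  } else {
    P <- (p$v0 - v)^2 * (p$v2 - v)
    dP <- -2 * (p$v0 - v) * (p$v2 - v) - (p$v0 - v)^2
  }
  dP * lfac + P * dlfac
}

.pheno_winf <- function(m, v) pmin(1, pmax(0, (v - m$params$v4) / (m$params$v5 - m$params$v4)))

.pheno_winf_prime <- function(m, v, side = "left") {
  p <- m$params
  inside <- if (side == "left") (v > p$v4 & v <= p$v5) else (v >= p$v4 & v < p$v5)
  ifelse(inside, 1 / (p$v5 - p$v4), 0)
}

.pheno_tauv <- function(m, v) {
  p <- m$params
  ifelse(v <= p$v3, p$r0 + p$r1 * (v - p$v3), p$r0)
}

.pheno_tauw <- function(m, v) {
  p <- m$params
  eval_step(step_spec(c(p$v6, p$v7), c(p$s0, p$s1, p$s2)), v)
}

#' Right-hand side of the integrator model
#'
#' `tau_v(v) dv/dt = P3(v) Lfac(v) + I - w^k`,
#' `tau_w(v) dw/dt = w_inf(v) - w`.
#'
#' @param state numeric `c(v, w)`.
#' @param I applied current (model units).
#' @param p an [integrator_params()].
#' @return numeric `c(dv, dw)`.
#' @export
rhs_integrator <- function(state, I, p = integrator_params()) {
  .rhs_pheno(pheno_model("integrator", p), state, I)
}

#' Right-hand side of the resonator model
#'
#' As [rhs_integrator()] with the double-root cubic `P32`.
#'
#' @param state numeric `c(v, w)`.
#' @param I applied current.
#' @param p a [resonator_params()].
#' @return numeric `c(dv, dw)`.
#' @export
rhs_resonator <- function(state, I, p = resonator_params()) {
  .rhs_pheno(pheno_model("resonator", p), state, I)
}

.rhs_pheno <- function(m, state, I) {
  v <- state[1]; w <- state[2]
  dv <- (.pheno_G(m, v) + I - w^m$params$k) / .pheno_tauv(m, v)
  dw <- (.pheno_winf(m, v) - w) / .pheno_tauw(m, v)
  c(dv, dw)
}

#' Nullclines of a phenomenological model
#'
#' The voltage nullcline solved for `w`, `w = (G(v) + I)^(1/k)` where the
#' radicand is non-negative (gaps are `NA`), and the `w` nullcline
#' `w = w_inf(v)`.
#'
#' @param model a [pheno_model()].
#' @param I applied current.
#' @param v_grid voltage grid, mV.
#' @return data frame with columns `v`, `w_vnull`, `w_wnull`.
#' @export
nullclines <- function(model, I, v_grid = seq(-100, 60, by = 0.1)) {
  rad <- .pheno_G(model, v_grid) + I
  k <- model$params$k
  # tolerate rounding-level negative radicands (exact fixed points sit at 0)
  w_vnull <- ifelse(rad >= -1e-12, pmax(rad, 0)^(1 / k), NA_real_)
  data.frame(v = v_grid, w_vnull = w_vnull, w_wnull = .pheno_winf(model, v_grid))
}

#' Fixed points of a phenomenological model
#'
#' All real solutions of `w_inf(v)^k = G(v) + I` found by a sign-change scan
#' at 0.001 mV resolution with bisection refinement; stability from the
#' eigenvalues of the analytic Jacobian.
#'
#' @param model a [pheno_model()].
#' @param I applied current.
#' @param v_range scan range, mV.
#' @return data frame with columns `v`, `w`, `stable`, `re1`, `re2`
#'   (eigenvalue real parts).
#' @export
fixed_points <- function(model, I, v_range = c(-100, 60)) {
  g <- function(v) .pheno_G(model, v) + I - .pheno_winf(model, v)^model$params$k
  vg <- seq(v_range[1], v_range[2], by = 0.001)
  gv <- g(vg)
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(flips, function(i)
    uniroot(g, c(vg[i], vg[i + 1]), tol = 1e-12)$root, numeric(1))
  roots <- c(roots, vg[gv == 0])
  roots <- sort(unique(roots))
  if (length(roots) == 0)
    return(data.frame(v = numeric(), w = numeric(), stable = logical(),
                      re1 = numeric(), re2 = numeric()))
  out <- lapply(roots, function(v) {
    w <- .pheno_winf(model, v)
    ei <- jacobian_eigs(model, c(v, w), I)
    data.frame(v = v, w = w, stable = all(Re(ei) < 0),
               re1 = Re(ei[1]), re2 = Re(ei[2]))
  })
  do.call(rbind, out)
}

#' Jacobian eigenvalues at a fixed point
#'
#' Analytic piecewise derivatives (the left branch applies exactly at a knot
#' or threshold, consistent with the `x <= x0` convention); step-function
#' time constants contribute zero slope.
#'
#' @param model a [pheno_model()].
#' @param point numeric `c(v, w)`; should satisfy the fixed-point equations.
#' @param I applied current.
#' @return complex vector of the two eigenvalues.
#' @export
jacobian_eigs <- function(model, point, I) {
  v <- point[1]; w <- point[2]
  k <- model$params$k
  tauv <- .pheno_tauv(model, v)
  tauw <- .pheno_tauw(model, v)
  # left-branch slope of tau_v
  p <- model$params
  dtauv <- if (v <= p$v3) p$r1 else 0
  N <- .pheno_G(model, v) + I - w^k
  A <- .pheno_Gprime(model, v) / tauv - N * dtauv / tauv^2
  B <- -k * w^(k - 1) / tauv
  C <- .pheno_winf_prime(model, v) / tauw
  D <- -1 / tauw
  eigen(matrix(c(A, C, B, D), 2, 2), only.values = TRUE)$values
}

#' Finite-difference Jacobian eigenvalues (cross-check)
#'
#' @param model a [pheno_model()].
#' @param point numeric `c(v, w)`.
#' @param I applied current.
#' @param h central-difference step.
#' @return complex vector of the two eigenvalues.
#' @export
jacobian_eigs_fd <- function(model, point, I, h = 1e-6) {
  f <- function(s) .rhs_pheno(model, s, I)
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    J[, j] <- (f(point + e) - f(point - e)) / (2 * h)
  }
  eigen(J, only.values = TRUE)$values
}

#' Locate a saddle-node (fold) bifurcation in the applied current
#'
#' Bisects on the change of the fixed-point count across `I_range` down to
#' `tol` in current.
#'
#' @param model a [pheno_model()].
#' @param I_range current bracket with different fixed-point counts at its ends.
#' @param tol bisection tolerance in current.
#' @return the fold current, or `NA` (with a message) if the count does not
#'   change over the range.
#' @export
find_saddle_node <- function(model, I_range, tol = 1e-5) {
  count <- function(I) nrow(fixed_points(model, I))
  c_lo <- count(I_range[1]); c_hi <- count(I_range[2])
  if (c_lo == c_hi) {
    message("find_saddle_node: fixed-point count does not change over the range")
    return(NA_real_)
  }
  lo <- I_range[1]; hi <- I_range[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count(mid) == c_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Locate a Hopf bifurcation in the applied current
#'
#' Tracks the fixed point nearest `track_near` (or the unique one) and
#' bisects on the sign of the maximum eigenvalue real part.
#'
#' @param model a [pheno_model()].
#' @param I_range current bracket.
#' @param tol bisection tolerance in current.
#' @param track_near voltage near which to track the fixed point (default:
#'   the most hyperpolarised fixed point).
#' @return the Hopf current, or `NA` if the eigenvalue sign does not change.
#' @export
find_hopf <- function(model, I_range, tol = 1e-5, track_near = NULL) {
  maxre <- function(I) {
    fp <- fixed_points(model, I)
    if (nrow(fp) == 0) return(NA_real_)
    i <- if (is.null(track_near)) 1L else which.min(abs(fp$v - track_near))
    max(fp$re1[i], fp$re2[i])
  }
  r_lo <- maxre(I_range[1]); r_hi <- maxre(I_range[2])
  if (is.na(r_lo) || is.na(r_hi) || sign(r_lo) == sign(r_hi)) {
    message("find_hopf: no eigenvalue sign change over the range")
    return(NA_real_)
  }
  lo <- I_range[1]; hi <- I_range[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(maxre(mid)) == sign(r_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Spiking onset current of a phenomenological model
#'
#' Saddle-node search for the integrator, eigenvalue (Hopf) search for the
#' resonator.
#'
#' @param model a [pheno_model()].
#' @param I_range search range.
#' @return onset current.
#' @export
onset_current <- function(model, I_range = c(0, 0.15)) {
  if (model$type == "integrator") find_saddle_node(model, I_range)
  else find_hopf(model, I_range)
}

#' Depolarisation-block current
#'
#' The second fold, where a stable high-voltage fixed point appears and
#' pacing stops. The fixed-point count typically goes 1 -> 3 -> 1 across the
#' fold pair, so the range is first scanned on a grid and the bisection runs
#' on the first sub-interval whose count changes.
#'
#' @param model a [pheno_model()].
#' @param I_range search range.
#' @param n_scan grid points of the initial count scan.
#' @return block current.
#' @export
block_current <- function(model, I_range = c(0.05, 0.5), n_scan = 26L) {
  Is <- seq(I_range[1], I_range[2], length.out = n_scan)
  counts <- vapply(Is, function(I) nrow(fixed_points(model, I)), integer(1))
  chg <- which(counts[-1] != counts[-length(counts)])
  if (length(chg) == 0) {
    message("block_current: fixed-point count constant over the range")
    return(NA_real_)
  }
  find_saddle_node(model, c(Is[chg[1]], Is[chg[1] + 1]))
}

#' Hold-step-ramp protocol around the two bifurcation currents
#'
#' Holds just below the onset current `I0` for 500 ms (factor 0.999), steps
#' just above it (factor 1.001) for 9 s, then ramps from `0.9 I1` to
#' `1.1 I1` over the final second to traverse the depolarisation block.
#'
#' @param model a [pheno_model()].
#' @param I0,I1 onset and block currents (computed if `NULL`).
#' @param hold_factor,step_factor multipliers for the hold and step phases.
#' @param dt Euler step, ms.
#' @param record_every trace thinning.
#' @return a `pls_trace` of the full 10.5 s protocol.
#' @export
fig_protocol <- function(model, I0 = NULL, I1 = NULL, hold_factor = 0.999,
                         step_factor = 1.001, dt = 0.01, record_every = 5L) {
  if (is.null(I0)) I0 <- onset_current(model)
  if (is.null(I1)) I1 <- block_current(model)
  proto <- seg_protocol(c(hold_factor * I0, hold_factor * I0, 500),
                        c(step_factor * I0, step_factor * I0, 9000),
                        c(0.9 * I1, 1.1 * I1, 1000))
  simulate_model(model, proto, dt = dt, record_every = record_every)
}

#' Lowest sustained firing rate just above onset
#'
#' Simulates 10 s at `onset * (1 + eps)` and reports the spike rate after a
#' 1 s transient. For the integrator (fold on an invariant circle) the rate
#' approaches zero as `eps` does; for the resonator it saturates at the
#' limit-cycle frequency born at the Hopf point.
#'
#' @param model a [pheno_model()].
#' @param onset onset current (computed if `NULL`).
#' @param eps relative distance above onset (default 1e-3).
#' @param duration_s,transient_s simulation and discard windows, s.
#' @param dt Euler step, ms.
#' @return firing rate, spikes/s.
#' @export
min_sustained_rate <- function(model, onset = NULL, eps = 1e-3,
                               duration_s = 10, transient_s = 1, dt = 0.01) {
  if (is.null(onset)) onset <- onset_current(model)
  tr <- simulate_model(model, const_protocol(onset * (1 + eps),
                                             duration_s * 1000),
                       dt = dt, record_every = 5L)
  sp <- detect_spikes(tr)
  sp <- sp[sp > transient_s * 1000]
  length(sp) / (duration_s - transient_s)
}
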