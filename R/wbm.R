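# ---------------------------------------------------------------------------
# Fully computed Wang-Buzsaki conductance-based model (fast-spiking
# hippocampal interneuron): Hodgkin-Huxley formalism with instantaneous
# sodium activation m_inf(v) and first-order h, n gating kinetics.
# ---------------------------------------------------------------------------

#' Wang-Buzsaki model parameters
#'
#' Membrane capacitance `c` (uF/cm^2), conductances (mS/cm^2), reversal
#' potentials (mV), and the gating-rate temperature scale `phi`. The defaults
#' are the published fast-spiking interneuron set; `phi = 5` is the standard
#' value for this model.
#'
#' @param c capacitance, uF/cm^2.
#' @param g_l,g_Na,g_K leak, sodium, potassium conductances, mS/cm^2.
#' @param E_l,E_Na,E_K reversal potentials, mV.
#' @param phi dimensionless gating-rate scale.
#' @return an object of class `wbm_params`.
#' @export
wbm_params <- function(c = 1, g_l = 0.1, g_Na = 35, g_K = 9,
                       E_l = -65, E_Na = 55, E_K = -90, phi = 5) {
  if (any(c(g_l, g_Na, g_K) <= 0)) stop("conductances must be positive")
  if (!(E_K < E_l && E_l < E_Na)) stop("expected E_K < E_l < E_Na")
  structure(list(c = c, g_l = g_l, g_Na = g_Na, g_K = g_K,
                 E_l = E_l, E_Na = E_Na, E_K = E_K, phi = phi),
            class = "wbm_params")
}

#' @export
parameter_count.wbm_params <- function(x, ...) 8L

# x/(exp(x)-1) continued through the removable singularity at 0
.xexpm1 <- function(z) ifelse(abs(z) < 1e-7, 1 - z / 2, z / expm1(z))

#' Voltage-dependent gating rate functions
#'
#' The six alpha/beta rates of the model (one pair per gate m, h, n), in
#' 1/ms, using the standard published functional forms:
#' \deqn{\alpha_m = \frac{-0.1(v+35)}{e^{-0.1(v+35)}-1},\quad \beta_m = 4 e^{-(v+60)/18}}
#' \deqn{\alpha_h = 0.07 e^{-(v+58)/20},\quad \beta_h = \frac{1}{e^{-0.1(v+28)}+1}}
#' \deqn{\alpha_n = \frac{-0.01(v+34)}{e^{-0.1(v+34)}-1},\quad \beta_n = 0.125 e^{-(v+44)/80}}
#' The removable singularities of \eqn{\alpha_m} and \eqn{\alpha_n} are
#' evaluated by their analytic limits.
#'
#' @param v voltage, mV (vectorised).
#' @return a data frame with columns `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`.
#' @export
gating_rates <- function(v) {
  data.frame(
    alpha_m = .xexpm1(-0.1 * (v + 35)),
    beta_m  = 4 * exp(-(v + 60) / 18),
    alpha_h = 0.07 * exp(-(v + 58) / 20),
    beta_h  = 1 / (exp(-0.1 * (v + 28)) + 1),
    alpha_n = 0.1 * .xexpm1(-0.1 * (v + 34)),
    beta_n  = 0.125 * exp(-(v + 44) / 80)
  )
}

#' Gating steady states and effective time constants
#'
#' Steady states `x_inf = alpha/(alpha + beta)` and effective time constants
#' `tau_x = 1/(phi (alpha + beta))` (ms), so the gating kinetics read
#' `dx/dt = (x_inf - x)/tau_x` with the rate scale `phi` already folded in.
#'
#' @param v voltage, mV (vectorised).
#' @param phi gating-rate scale, default 5.
#' @return data frame with columns `m_inf`, `h_inf`, `n_inf`, `tau_h`, `tau_n`.
#' @export
wbm_steady <- function(v, phi = 5) {
  r <- gating_rates(v)
  data.frame(
    m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
    h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
    n_inf = r$alpha_n / (r$alpha_n + r$beta_n),
    tau_h = 1 / (phi * (r$alpha_h + r$beta_h)),
    tau_n = 1 / (phi * (r$alpha_n + r$beta_n))
  )
}

#' Right-hand side of the Wang-Buzsaki model
#'
#' @param state numeric `c(v, h, n)`.
#' @param I applied current, uA/cm^2.
#' @param p a [wbm_params()].
#' @return numeric `c(dv, dh, dn)` in mV/ms and 1/ms.
#' @export
rhs_wbm <- function(state, I, p = wbm_params()) {
  v <- state[1]; h <- state[2]; n <- state[3]
  s <- wbm_steady(v, p$phi)
  dv <- (I + p$g_l * (p$E_l - v) + p$g_K * n^4 * (p$E_K - v) +
           p$g_Na * s$m_inf^3 * h * (p$E_Na - v)) / p$c
  c(dv, (s$h_inf - h) / s$tau_h, (s$n_inf - n) / s$tau_n)
}

#' Resting state of the Wang-Buzsaki model
#'
#' Root-solves the voltage equation with gates at steady state.
#'
#' @param p a [wbm_params()].
#' @param I applied current, uA/cm^2.
#' @param interval voltage bracket for the root search.
#' @return numeric `c(v, h, n)` at rest.
#' @export
wbm_rest <- function(p = wbm_params(), I = 0, interval = c(-80, -60)) {
  f <- function(v) {
    s <- wbm_steady(v, p$phi)
    I + p$g_l * (p$E_l - v) + p$g_K * s$n_inf^4 * (p$E_K - v) +
      p$g_Na * s$m_inf^3 * s$h_inf * (p$E_Na - v)
  }
  v <- uniroot(f, interval, tol = 1e-12)$root
  s <- wbm_steady(v, p$phi)
  c(v = v, h = s$h_inf, n = s$n_inf)
}

#' Wang-Buzsaki model object
#'
#' Wraps the parameter set together with an approximation route for the five
#' gating curves: `"exact"` (all rate functions computed), `"table"` (lookup
#' table with linear interpolation), `"poly"` (least-squares polynomial
#' fits), or `"pl"` (on-curve piecewise-linear fits).
#'
#' @param params a [wbm_params()].
#' @param route one of `"exact"`, `"table"`, `"poly"`, `"pl"`.
#' @param approx route data: a [build_table()] result for `"table"`, a named
#'   list of coefficient vectors for `"poly"`, a named list of [pl_spec()]s
#'   for `"pl"`. Ignored for `"exact"`.
#' @return an object of class `wbm_model`.
#' @export
wbm_model <- function(params = wbm_params(),
                      route = c("exact", "table", "poly", "pl"),
                      approx = NULL) {
  route <- match.arg(route)
  if (route != "exact" && is.null(approx))
    stop("route '", route, "' requires approximation data")
  structure(list(params = params, route = route, approx = approx),
            class = c("wbm_model", "pls_model"))
}

#' @export
parameter_count.wbm_model <- function(x, ...) {
  base <- parameter_count(x$params)
  extra <- switch(x$route,
    exact = 0L,
    table = x$approx$n_rows * ncol(x$approx$values) + 3L,
    poly = sum(vapply(x$approx, length, 1L)),
    pl = sum(vapply(x$approx, parameter_count, 1L)))
  base + extra
}
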