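# ---------------------------------------------------------------------------
# The four approximation routes for the conductance-based reference model:
# lookup table, polynomial fits, piecewise-linear fits, and the 2D
# polynomial/piecewise-linear reduction built from the Rinzel collapse of
# the h and n gating variables.
# ---------------------------------------------------------------------------

#' Build a voltage-indexed lookup table
#'
#' Tabulates the given scalar functions of voltage on a uniform grid of
#' `n_rows + 1` points spanning `[v_min, v_max]` inclusive, with row offset
#' `(v_max - v_min)/n_rows`. Queries interpolate linearly between rows and
#' extrapolate as constants beyond the range.
#'
#' @param functions named list of vectorised functions of voltage.
#' @param v_min,v_max table range, mV.
#' @param n_rows number of rows (intervals); at least 2.
#' @return an object of class `lookup_table`.
#' @export
#' @examples
#' tbl <- build_table(list(m_inf = function(v) wbm_steady(v)$m_inf), -90, 55, 200)
#' tbl$row_offset # 0.725 mV
build_table <- function(functions, v_min, v_max, n_rows) {
  stopifnot(n_rows >= 2, v_min < v_max)
  offset <- (v_max - v_min) / n_rows
  grid <- v_min + offset * (0:n_rows)
  vals <- vapply(functions, function(f) as.numeric(f(grid)),
                 numeric(length(grid)))
  if (!all(is.finite(vals))) {
    bad <- grid[which(!is.finite(vals), arr.ind = TRUE)[1, 1]]
    stop(sprintf("non-finite table value at v = %g mV", bad))
  }
  structure(list(v_min = v_min, v_max = v_max, n_rows = as.integer(n_rows),
                 row_offset = offset, values = vals,
                 columns = names(functions)),
            class = "lookup_table")
}

#' Interpolate a lookup table at a voltage
#'
#' Row index is `floor((v - v_min)/row_offset)` clamped to the table; values
#' are linearly interpolated between the bracketing rows, with constant
#' extrapolation outside the range.
#'
#' @param table a [build_table()] result.
#' @param v voltage, mV (vectorised).
#' @return matrix with one row per voltage and one column per table column.
#' @export
table_interp <- function(table, v) {
  u <- (v - table$v_min) / table$row_offset
  idx <- pmin(pmax(floor(u), 0), table$n_rows - 1)
  w <- pmin(pmax(u - idx, 0), 1)
  lo <- table$values[idx + 1, , drop = FALSE]
  hi <- table$values[idx + 2, , drop = FALSE]
  out <- lo + w * (hi - lo)
  rownames(out) <- NULL
  out
}

#' @export
parameter_count.lookup_table <- function(x, ...)
  x$n_rows * ncol(x$values) + 3L

#' Least-squares polynomial fit of a voltage function
#'
#' Fits a polynomial of the given order on a uniform 0.1 mV grid over
#' `v_range` by linear least squares.
#'
#' @param target vectorised function of voltage.
#' @param v_range `c(v_min, v_max)`, default the potassium-to-sodium
#'   reversal span `c(-90, 55)`.
#' @param order polynomial order (default 5).
#' @return numeric coefficient vector in increasing powers, length `order + 1`.
#' @export
fit_poly <- function(target, v_range = c(-90, 55), order = 5L) {
  stopifnot(order >= 1)
  v <- seq(v_range[1], v_range[2], by = 0.1)
  y <- target(v)
  X <- outer(v, 0:order, `^`)
  fit <- lm.fit(X, y)
  if (fit$rank < order + 1) stop("fit_poly: rank-deficient design (degenerate target)")
  unname(fit$coefficients)
}

eval_polyfit <- function(coefs, v) {
  acc <- rep(0, length(v))
  for (i in rev(seq_along(coefs))) acc <- acc * v + coefs[i]
  acc
}

#' Piecewise-linear fit of a voltage function
#'
#' Two strategies. `"on-curve"` places all knots on the target curve, fixes
#' the outer knots at the range ends, and optimises the interior knot
#' abscissae by a two-stage grid search minimising the maximum absolute
#' error on a dense grid; the result is continuous by construction.
#' `"segment-regression"` fits an independent least-squares line on each of
#' `n_segments` equal sub-intervals and joins them at the pairwise line
#' intersections; when adjacent lines fail to intersect inside a tolerance
#' neighbourhood of the segment border (non-convex targets), the failure is
#' reported in the returned object rather than raised.
#'
#' @param target vectorised function of voltage.
#' @param v_range `c(v_min, v_max)`.
#' @param n_segments 2, 3 or 4 linear segments inside the range.
#' @param strategy `"on-curve"` (default) or `"segment-regression"`.
#' @param weights optional vectorised weight function of voltage for the
#'   on-curve knot search; the search minimises the weighted maximum error,
#'   letting a fit favour (say) the subthreshold range.
#' @return a list of class `pl_fit`: `spec` (a [pl_spec()], or `NULL` when
#'   segment regression fails), `max_err`, `strategy`, `ok`, `notes`.
#' @export
fit_pl <- function(target, v_range = c(-90, 55), n_segments = 3L,
                   strategy = c("on-curve", "segment-regression"),
                   weights = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(n_segments %in% 2:4)
  dense <- seq(v_range[1], v_range[2], by = 0.1)
  y_dense <- target(dense)
  w_dense <- if (is.null(weights)) rep(1, length(dense)) else weights(dense)

  if (strategy == "on-curve") {
    n_int <- n_segments - 1L
    err_of <- function(interior) {
      kx <- c(v_range[1], interior, v_range[2])
      ky <- target(kx)
      yhat <- approx(kx, ky, xout = dense, rule = 2)$y
      max(abs(yhat - y_dense) * w_dense)
    }
    search <- function(cands) {
      combos <- utils::combn(cands, n_int)
      errs <- apply(combos, 2, err_of)
      combos[, which.min(errs), drop = TRUE]
    }
    span <- diff(v_range)
    coarse <- seq(v_range[1] + span / 40, v_range[2] - span / 40,
                  length.out = 36)
    best <- search(coarse)
    step <- span / 35
    fine <- sort(unique(as.vector(sapply(best, function(b)
      seq(b - step, b + step, length.out = 11)))))
    fine <- fine[fine > v_range[1] & fine < v_range[2]]
    best <- search(fine)
    # continuous polish of the interior knot abscissae
    if (n_int == 1) {
      best <- optimize(err_of, c(max(v_range[1], best - step),
                                 min(v_range[2], best + step)))$minimum
    } else {
      best <- optim(sort(best), function(x) {
        if (any(diff(c(v_range[1], x, v_range[2])) <= 0)) return(Inf)
        err_of(x)
      }, control = list(maxit = 400, reltol = 1e-12))$par
    }
    kx <- c(v_range[1], sort(best), v_range[2])
    spec <- pl_spec(kx, target(kx))
    return(structure(list(spec = spec, max_err = err_of(sort(best)),
                          strategy = strategy, ok = TRUE, notes = character()),
                     class = "pl_fit"))
  }

  # segment-regression
  brk <- seq(v_range[1], v_range[2], length.out = n_segments + 1)
  lines <- lapply(seq_len(n_segments), function(i) {
    vs <- dense[dense >= brk[i] & dense <= brk[i + 1]]
    fit <- lsfit(vs, target(vs))
    fit$coefficients # intercept, slope
  })
  notes <- character(); kx <- numeric(); ky <- numeric(); ok <- TRUE
  seg_len <- diff(v_range) / n_segments
  for (i in seq_len(n_segments - 1)) {
    b1 <- lines[[i]]; b2 <- lines[[i + 1]]
    if (abs(b1[2] - b2[2]) < 1e-12) {
      ok <- FALSE
      notes <- c(notes, sprintf("segments %d/%d parallel", i, i + 1))
      next
    }
    xi <- (b2[1] - b1[1]) / (b1[2] - b2[2])
    if (abs(xi - brk[i + 1]) > seg_len) {
      ok <- FALSE
      notes <- c(notes, sprintf(
        "segments %d/%d intersect at %.3g, far from border %.3g",
        i, i + 1, xi, brk[i + 1]))
      next
    }
    kx <- c(kx, xi); ky <- c(ky, b1[1] + b1[2] * xi)
  }
  spec <- NULL; max_err <- NA_real_
  if (ok && length(kx) == n_segments - 1 && all(diff(kx) > 0)) {
    spec <- pl_spec(kx, ky, left_slope = lines[[1]][2],
                    right_slope = lines[[n_segments]][2])
    max_err <- max(abs(eval_pl(spec, dense) - y_dense))
  } else ok <- FALSE
  structure(list(spec = spec, max_err = max_err, strategy = strategy,
                 ok = ok, notes = notes),
            class = "pl_fit")
}

#' Gating-curve approximations for the full 3D model
#'
#' Convenience builders for the three approximation routes of the five
#' gating curves (`m_inf`, `h_inf`, `n_inf`, `tau_h`, `tau_n`; taus include
#' the rate scale `phi`).
#'
#' The lookup table spans the reversal-potential range `[E_K, E_Na]`; the
#' polynomial and piecewise-linear fits span the model's full operating
#' range (default -100..60 mV) so the fitted curves stay usable everywhere a
#' trajectory can go — fitting them on the narrower reversal span makes the
#' polynomial route look better than it is where it matters least.
#'
#' @param p a [wbm_params()].
#' @param n_rows lookup-table rows.
#' @return a ready-to-simulate [wbm_model()].
#' @export
wbm_table_model <- function(p = wbm_params(), n_rows = 200L) {
  fns <- list(
    m_inf = function(v) wbm_steady(v, p$phi)$m_inf,
    h_inf = function(v) wbm_steady(v, p$phi)$h_inf,
    n_inf = function(v) wbm_steady(v, p$phi)$n_inf,
    tau_h = function(v) wbm_steady(v, p$phi)$tau_h,
    tau_n = function(v) wbm_steady(v, p$phi)$tau_n)
  wbm_model(p, "table", build_table(fns, p$E_K, p$E_Na, n_rows))
}

#' @rdname wbm_table_model
#' @param order polynomial order for each gating curve.
#' @param v_range fitting range for the polynomial / piecewise-linear routes.
#' @export
wbm_poly_model <- function(p = wbm_params(), order = 5L,
                           v_range = c(-100, 60)) {
  cols <- c("m_inf", "h_inf", "n_inf", "tau_h", "tau_n")
  fits <- lapply(cols, function(cl)
    fit_poly(function(v) wbm_steady(v, p$phi)[[cl]], v_range, order))
  names(fits) <- cols
  wbm_model(p, "poly", fits)
}

#' @rdname wbm_table_model
#' @param n_segments piecewise-linear segments per gating curve.
#' @export
wbm_pl_model <- function(p = wbm_params(), n_segments = 3L,
                         v_range = c(-100, 60)) {
  cols <- c("m_inf", "h_inf", "n_inf", "tau_h", "tau_n")
  fits <- lapply(cols, function(cl)
    fit_pl(function(v) wbm_steady(v, p$phi)[[cl]], v_range, n_segments)$spec)
  names(fits) <- cols
  wbm_model(p, "pl", fits)
}

# ---------------------------------------------------------------------------
# Rinzel reduction and the PL2D construction
# ---------------------------------------------------------------------------

#' Collapse the h and n gates by linear regression along a trajectory
#'
#' Simulates the fully computed model at a suprathreshold constant current,
#' discards the initial transient, and regresses `h` on `n` along the limit
#' cycle, restricted to the active (spiking) phase of the trajectory where
#' the sodium current is engaged (`v > v_active`): the collapsed gate only
#' enters the reduced model through the sodium term, so the line is fitted
#' where it acts. The fitted line `h = epsilon + kappa n` replaces the
#' sodium inactivation gate, reducing the system to two dimensions.
#'
#' @param p a [wbm_params()].
#' @param fit_current constant current for the trajectory (default 1).
#' @param duration trajectory length, ms.
#' @param discard discarded transient, ms.
#' @param dt Euler step, ms.
#' @param v_active voltage above which trajectory points enter the fit, mV.
#' @return a list of class `reduction_fit`: `epsilon`, `kappa`, `r_squared`,
#'   `fit_current`.
#' @export
rinzel_reduce <- function(p = wbm_params(), fit_current = 1,
                          duration = 2000, discard = 500, dt = 0.01,
                          v_active = -55) {
  tr <- simulate_model(wbm_model(p), const_protocol(fit_current, duration),
                       dt = dt, record_every = 10L)
  if (length(detect_spikes(tr)) < 5)
    stop("rinzel_reduce: fit current is subthreshold (no sustained spiking)")
  keep <- tr$time >= discard & tr$v > v_active
  fit <- lm(h ~ n, data = tr[keep, ])
  structure(list(epsilon = unname(coef(fit)[1]), kappa = unname(coef(fit)[2]),
                 r_squared = summary(fit)$r.squared,
                 fit_current = fit_current),
            class = "reduction_fit")
}

#' Right-hand side of the 2D reduced conductance model
#'
#' @param state numeric `c(v, n)`.
#' @param I applied current.
#' @param p a [wbm_params()].
#' @param fit a [rinzel_reduce()] result.
#' @return numeric `c(dv, dn)`.
#' @export
rhs_reduced <- function(state, I, p, fit) {
  v <- state[1]; n <- state[2]
  s <- wbm_steady(v, p$phi)
  h <- fit$epsilon + fit$kappa * n
  dv <- (I + p$g_l * (p$E_l - v) + p$g_K * n^4 * (p$E_K - v) +
           p$g_Na * s$m_inf^3 * h * (p$E_Na - v)) / p$c
  c(dv, (s$n_inf - n) / s$tau_n)
}

# non-potassium part of the reduced voltage equation on the n = 0 axis
.tangency_f <- function(v, I, p, fit) {
  s <- wbm_steady(v, p$phi)
  I + p$g_l * (p$E_l - v) + p$g_Na * s$m_inf^3 * fit$epsilon * (p$E_Na - v)
}

#' Current at which the reduced v-nullcline touches the n = 0 axis
#'
#' On the `n = 0` axis the reduced voltage nullcline requires
#' `f(v; I) = I + g_l (E_l - v) + g_Na m_inf^3(v) epsilon (E_Na - v) = 0`.
#' Below the tangency current `f` dips below zero over a subthreshold
#' voltage window (two simple roots); bisection on `I` finds the current at
#' which the dip just vanishes, i.e. `f` acquires a double root. Returns
#' that current and the tangency voltage.
#'
#' @param fit a [rinzel_reduce()] result.
#' @param p a [wbm_params()].
#' @param I_range bisection bracket for the current.
#' @param v_window subthreshold voltage window containing the dip.
#' @return list with `I0` (current) and `v0` (tangency voltage, mV).
#' @export
find_tangency <- function(fit, p = wbm_params(), I_range = c(0, 1),
                          v_window = c(-75, -45)) {
  vg <- seq(v_window[1], v_window[2], by = 0.001)
  dip <- function(I) min(.tangency_f(vg, I, p, fit))
  if (dip(I_range[1]) > 0 || dip(I_range[2]) < 0)
    stop("find_tangency: no tangency in current range (reduction failure)")
  I0 <- uniroot(dip, I_range, tol = 1e-10)$root
  v0 <- vg[which.min(.tangency_f(vg, I0, p, fit))]
  list(I0 = I0, v0 = v0)
}

#' Construct the 2D polynomial/piecewise-linear reduction
#'
#' Builds every constant of the reduced model from the fully computed one.
#' The cubic `a0 (v - v0)^2 (v1 - v)` replaces the non-potassium part of the
#' reduced voltage nullcline, with `v0` the tangency voltage and
#' `v1 = E_Na`; `a0` and the left-branch steepener slope (a one-knot linear
#' factor with unit value at `v0`, so the product stays smooth at the
#' cubic's double root) are fitted so the model's v-nullcline matches the
#' reduced one as a curve in the `(v, n)` phase plane. `n_inf` is replaced
#' by a 3-segment on-curve piecewise-linear fit weighted towards the
#' subthreshold range (that region sets the spiking-onset current), and
#' `tau_n` by a plain 3-segment on-curve fit.
#'
#' The time constants are then calibrated against the fully computed
#' model's FI curve: replacing the slaved sodium-inactivation gate removes
#' the state-dependent part of the membrane's effective speed, so the
#' construction first applies a global time dilation (the voltage time
#' constant, a one-knot piecewise-linear function, and a common scale on
#' `tau_n`), then lets a short deterministic simplex search trim the
#' dilation, the `tau_n` knot levels, the voltage-tau slopes and a small
#' offset on the stored `I0` (which registers the onset, since the model is
#' driven by `I - I0`) to minimise the maximum FI deviation. The search is
#' deterministic: identical inputs give identical constants.
#'
#' @param p a [wbm_params()].
#' @param fit a [rinzel_reduce()] result (computed if `NULL`).
#' @param fi_ref reference FI curve for the calibration (computed if `NULL`).
#' @param calibrate set `FALSE` to skip the time-constant calibration
#'   (leaves the uncalibrated unit-dilation model; useful for structural
#'   tests).
#' @return an object of class `pl2d_model`.
#' @export
pl2d_construct <- function(p = wbm_params(), fit = NULL, fi_ref = NULL,
                           calibrate = TRUE) {
  if (is.null(fit)) fit <- rinzel_reduce(p)
  tang <- find_tangency(fit, p)
  v0 <- tang$v0; v1 <- p$E_Na; I0 <- tang$I0

  # The cubic must reproduce the reduced v-nullcline as a curve in the
  # (v, n) plane, so the target is the non-potassium current evaluated
  # ALONG the nullcline n_red(v) at the tangency current (equivalently, the
  # potassium current there). Fitting on the n = 0 axis instead ignores the
  # kappa*n sodium attenuation and leaves a spurious stable depolarised
  # fixed point.
  n_red <- function(v) vapply(v, function(vv) {
    g <- function(n) .tangency_f(vv, I0, p, fit) +
      p$g_Na * wbm_steady(vv, p$phi)$m_inf^3 * fit$kappa * n * (p$E_Na - vv) +
      p$g_K * n^4 * (p$E_K - vv)
    tryCatch(uniroot(g, c(0, 1.3), tol = 1e-10)$root,
             error = function(e) NA_real_)
  }, numeric(1))

  # model nullcline solved for n, given the cubic scale and steepener slope
  n_of_cubic <- function(v, a, sl) {
    lfac <- ifelse(v <= v0, 1 + sl * (v - v0), 1)
    pmax(0, (a * (v - v0)^2 * (v1 - v) * lfac) /
           (p$g_K * (v - p$E_K)))^(1 / 4)
  }

  # cubic scale: match the nullcline curve over the right branch
  vr <- seq(v0 + 0.25, v1 - 1, by = 0.25)
  nr <- n_red(vr)
  okr <- !is.na(nr)
  a0 <- optimize(function(a) sum((n_of_cubic(vr[okr], a, 0) - nr[okr])^2),
                 c(1e-5, 5e-3), tol = 1e-12)$minimum

  # left-branch steepener slope; stop short of E_K where the potassium
  # driving force vanishes and the nullcline diverges
  vl <- seq(p$E_K + 10, v0 - 0.25, by = 0.25)
  nl <- n_red(vl)
  okl <- !is.na(nl)
  s <- optimize(function(sl) sum((n_of_cubic(vl[okl], a0, sl) - nl[okl])^2),
                c(0, 0.2), tol = 1e-12)$minimum

  rng <- c(p$E_K, p$E_Na)
  n_inf_fit <- fit_pl(function(v) wbm_steady(v, p$phi)$n_inf, rng, 3L,
                      weights = function(v)
                        ifelse(v >= -75 & v <= -40, 1, 0.25))
  tau_n_fit <- fit_pl(function(v) wbm_steady(v, p$phi)$tau_n, rng, 3L)
  # report any sub-fit blowing its error budget (20% of the target's range)
  vchk <- seq(rng[1], rng[2], by = 0.1)
  for (nm in c("n_inf", "tau_n")) {
    fitchk <- if (nm == "n_inf") n_inf_fit else tau_n_fit
    y <- wbm_steady(vchk, p$phi)[[nm]]
    err <- max(abs(eval_pl(fitchk$spec, vchk) - y))
    if (err > 0.2 * diff(range(y)))
      warning("pl2d_construct: ", nm, " piecewise-linear fit exceeds 20% of its range")
  }

  mk <- function(tau_v, tau_n, n_inf, I0_off = 0) {
    structure(list(I0 = I0 + I0_off, a0 = a0, v0 = v0, v1 = v1,
                   lfac_slope = s, g_K = p$g_K, E_K = p$E_K,
                   tau_v = tau_v, n_inf = n_inf,
                   tau_n = tau_n, reduction = fit),
              class = c("pl2d_model", "pls_model"))
  }
  if (!calibrate)
    return(mk(pl_spec(-40, 1, 0, 0), tau_n_fit$spec, n_inf_fit$spec))

  if (is.null(fi_ref)) fi_ref <- ramp_fi(wbm_model(p), 0, 1)
  bt <- tau_n_fit$spec
  # x = (log dilation, I0 offset, tau_v slopes, log per-knot tau_n trims)
  from_x <- function(x) {
    lam <- exp(x[1])
    cy <- bt$knots_y * lam * exp(x[5:8])
    mk(pl_spec(-40, lam, x[3], x[4]),
       pl_spec(bt$knots_x, cy, bt$left_slope * lam * exp(x[5]),
               bt$right_slope * lam * exp(x[8])),
       n_inf_fit$spec, I0_off = x[2])
  }
  score <- function(x) {
    m <- tryCatch(from_x(x), error = function(e) NULL)
    if (is.null(m)) return(1e9)
    vv <- seq(p$E_K, p$E_Na, by = 2)
    if (any(eval_pl(m$tau_v, vv) < 0.03) || any(eval_pl(m$tau_n, vv) < 0.03))
      return(1e9)
    fi <- tryCatch(ramp_fi(m, min(fi_ref$current), max(fi_ref$current)),
                   error = function(e) NULL)
    if (is.null(fi)) return(1e9)
    max_error_pct_range(fi_ref, fi)
  }
  # stage 1: coarse grid over dilation, onset offset, spike-speed slope and
  # a common trim on the depolarised tau_n knots
  grid <- expand.grid(lam = c(1.4, 1.5, 1.6),
                      dI0 = seq(-0.026, -0.006, by = 0.004),
                      sr = c(0, -0.006, -0.012),
                      ctop = c(1, 0.7, 0.5))
  g_score <- mapply(function(lam, dI0, sr, ctop)
    score(c(log(lam), dI0, 0, sr, 0, 0, log(ctop), log(ctop))),
    grid$lam, grid$dI0, grid$sr, grid$ctop)
  b <- grid[which.min(g_score), ]
  x0 <- c(log(b$lam), b$dI0, 0, b$sr, 0, 0, log(b$ctop), log(b$ctop))
  # stage 2: deterministic Nelder-Mead polish
  o <- optim(x0, score, control = list(maxit = 1200))
  o <- optim(o$par, score, control = list(maxit = 1200))
  from_x(o$par)
}

#' @export
parameter_count.pl2d_model <- function(x, ...) {
  7L + # I0, a0, v0, v1, lfac_slope, g_K, E_K
    parameter_count(x$tau_v) + parameter_count(x$n_inf) +
    parameter_count(x$tau_n)
}

#' Right-hand side of the 2D reduction
#'
#' @param state numeric `c(v, n)`.
#' @param I applied current.
#' @param q a [pl2d_construct()] result.
#' @return numeric `c(dv, dn)`.
#' @export
rhs_pl2d <- function(state, I, q) {
  v <- state[1]; n <- state[2]
  lfac <- if (v <= q$v0) 1 + q$lfac_slope * (v - q$v0) else 1
  cubic <- q$a0 * (v - q$v0)^2 * (q$v1 - v) * lfac
  dv <- (I - q$I0 + cubic + q$g_K * n^4 * (q$E_K - v)) / eval_pl(q$tau_v, v)
  dn <- (eval_pl(q$n_inf, v) - n) / eval_pl(q$tau_n, v)
  c(dv, dn)
}
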