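#' @useDynLib plsneuro, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef lm lsfit optimize rpois runif setNames uniroot
#' @importFrom utils modifyList read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# The three function families: Polynomial (P), piecewise-Linear (L), Step (S).
#
# P_n is a product of linear root factors (x0 - x)(x1 - x)..., optionally with
# repeated roots (P32 has a double root) and a scale. L_n is continuous and
# piecewise linear with the convention that x exactly at a knot belongs to the
# left branch (x <= x0). S_n is piecewise constant; exactly at a threshold it
# takes the mean of the two adjacent levels.
# ---------------------------------------------------------------------------

#' Polynomial spec: product of linear root factors
#'
#' Represents `scale * prod_i (root_i - x)^mult_i`. The first-order factor
#' `(x0 - x)` is the core of the family; higher orders are products of such
#' factors, so the polynomial is stored by its roots rather than by monomial
#' coefficients. A cubic with a double root (used by the resonator model and
#' the 2D reduction) is `poly_spec(c(x0, x1), multiplicities = c(2, 1))`.
#'
#' @param roots strictly ascending real roots.
#' @param multiplicities positive integer multiplicity per root.
#' @param scale real multiplier applied to the product.
#' @return an object of class `poly_spec`.
#' @export
#' @examples
#' p3 <- poly_spec(c(-65, -45, 55))
#' eval_poly(p3, -45) # 0, a root
poly_spec <- function(roots, multiplicities = rep(1L, length(roots)), scale = 1) {
  roots <- as.numeric(roots)
  multiplicities <- as.integer(multiplicities)
  if (length(roots) != length(multiplicities))
    stop("roots and multiplicities must have equal length")
  if (length(roots) > 1L && any(diff(roots) <= 0))
    stop("poly_spec: roots must be strictly ascending")
  if (any(multiplicities < 1L))
    stop("poly_spec: multiplicities must be >= 1")
  structure(list(roots = roots, multiplicities = multiplicities,
                 scale = as.numeric(scale)[1]),
            class = "poly_spec")
}

#' Evaluate a polynomial spec
#'
#' Exact product `scale * prod_i (root_i - x)^mult_i`; vectorised over `x`.
#'
#' @param spec a [poly_spec()].
#' @param x numeric vector of abscissae.
#' @return numeric vector of values.
#' @export
eval_poly <- function(spec, x) {
  stopifnot(inherits(spec, "poly_spec"))
  out <- rep(spec$scale, length(x))
  for (i in seq_along(spec$roots))
    out <- out * (spec$roots[i] - x)^spec$multiplicities[i]
  out
}

#' Piecewise-linear spec
#'
#' A continuous piecewise-linear function through the given knots, extended
#' with `left_slope` below the first knot and `right_slope` above the last.
#' Evaluation exactly at a knot uses the left branch (the `x <= x0`
#' convention of the family's case definitions); because the function is
#' continuous this only matters for one-sided derivative queries.
#'
#' @param knots_x strictly ascending knot abscissae.
#' @param knots_y knot ordinates.
#' @param left_slope slope for `x <= knots_x[1]`.
#' @param right_slope slope for `x > knots_x[length(knots_x)]`.
#' @return an object of class `pl_spec`.
#' @export
#' @examples
#' # unit ramp between -40 and -5, flat outside (an activation curve)
#' w_inf <- pl_spec(c(-40, -5), c(0, 1))
#' eval_pl(w_inf, c(-60, -22.5, 20)) # 0, 0.5, 1
pl_spec <- function(knots_x, knots_y, left_slope = 0, right_slope = 0) {
  knots_x <- as.numeric(knots_x); knots_y <- as.numeric(knots_y)
  if (length(knots_x) < 1L) stop("pl_spec: at least one knot required")
  if (length(knots_x) != length(knots_y))
    stop("pl_spec: knots_x and knots_y must have equal length")
  if (length(knots_x) > 1L && any(diff(knots_x) <= 0))
    stop("pl_spec: knot abscissae must be strictly ascending")
  structure(list(knots_x = knots_x, knots_y = knots_y,
                 left_slope = as.numeric(left_slope)[1],
                 right_slope = as.numeric(right_slope)[1]),
            class = "pl_spec")
}

#' Evaluate a piecewise-linear spec
#'
#' @param spec a [pl_spec()].
#' @param x numeric vector.
#' @return numeric vector of values.
#' @export
eval_pl <- function(spec, x) {
  stopifnot(inherits(spec, "pl_spec"))
  kx <- spec$knots_x; ky <- spec$knots_y
  n <- length(kx)
  out <- numeric(length(x))
  lo <- x <= kx[1]
  out[lo] <- ky[1] + spec$left_slope * (x[lo] - kx[1])
  hi <- x > kx[n]
  out[hi] <- ky[n] + spec$right_slope * (x[hi] - kx[n])
  mid <- !lo & !hi
  if (any(mid)) {
    # interval i: (kx[i], kx[i+1]]; at kx[i+1] the left segment applies
    idx <- findInterval(x[mid], kx, left.open = TRUE, rightmost.closed = FALSE)
    a <- (ky[idx + 1] - ky[idx]) / (kx[idx + 1] - kx[idx])
    out[mid] <- ky[idx] + a * (x[mid] - kx[idx])
  }
  # a knot evaluates to its ordinate exactly, not to the rounded segment value
  hit <- match(x, kx)
  out[!is.na(hit)] <- ky[hit[!is.na(hit)]]
  out
}

#' One-sided derivative of a piecewise-linear spec
#'
#' @param spec a [pl_spec()].
#' @param x numeric vector.
#' @param side `"left"` (default, the family's convention) or `"right"`.
#' @return numeric vector of slopes.
#' @export
pl_slope <- function(spec, x, side = c("left", "right")) {
  side <- match.arg(side)
  kx <- spec$knots_x; ky <- spec$knots_y
  n <- length(kx)
  seg_slopes <- c(spec$left_slope,
                  if (n > 1) diff(ky) / diff(kx),
                  spec$right_slope)
  # segment index for the open/closed convention
  idx <- findInterval(x, kx, left.open = (side == "left"),
                      rightmost.closed = FALSE) + 1L
  seg_slopes[idx]
}

#' Step-function spec
#'
#' Piecewise-constant with `n` thresholds and `n + 1` levels; evaluation
#' exactly at threshold `i` returns the mean of the two adjacent levels
#' (the family's midpoint rule).
#'
#' @param thresholds strictly ascending threshold abscissae.
#' @param levels numeric vector, one longer than `thresholds`.
#' @return an object of class `step_spec`.
#' @export
#' @examples
#' tau_w <- step_spec(c(-55.45, 18.78), c(5, 7.6, 1.8)) # ms
#' eval_step(tau_w, c(-60, 0, 30)) # 5, 7.6, 1.8
step_spec <- function(thresholds, levels) {
  thresholds <- as.numeric(thresholds); levels <- as.numeric(levels)
  if (length(levels) != length(thresholds) + 1L)
    stop("step_spec: need exactly one more level than thresholds")
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0))
    stop("step_spec: thresholds must be strictly ascending")
  structure(list(thresholds = thresholds, levels = levels,
                 at_threshold_rule = "midpoint"),
            class = "step_spec")
}

#' Evaluate a step spec
#'
#' @param spec a [step_spec()].
#' @param x numeric vector.
#' @return numeric vector of values.
#' @export
eval_step <- function(spec, x) {
  stopifnot(inherits(spec, "step_spec"))
  idx <- findInterval(x, spec$thresholds, left.open = TRUE) + 1L
  out <- spec$levels[idx]
  at <- match(x, spec$thresholds)
  hit <- !is.na(at)
  if (any(hit))
    out[hit] <- (spec$levels[at[hit]] + spec$levels[at[hit] + 1L]) / 2
  out
}

# ---------------------------------------------------------------------------
# Nested smooth sigmoid: a step of a cubic, S3(v, V0, V1, 0, psi*P32, 1)
# ---------------------------------------------------------------------------

#' Smooth sigmoid built from a step of a scaled cubic
#'
#' Returns a function of voltage equal to 0 below `V0`, 1 above `V1`, and a
#' scaled cubic with a double root at `V0` in between. The scale `psi` is
#' chosen analytically so the cubic spans [0, 1]: the extremum of
#' `(V2 - v)(V0 - v)^2` sits at `v* = (V0 + 2 V2)/3`, and `psi = 1/P32(v*)`
#' when `v*` lies in `[V0, V1]`, else `1/P32(V1)`. With the default
#' `V2 = V0 + 1.5 (V1 - V0)` the extremum falls exactly at `V1`, making the
#' result continuously differentiable at both window edges — the drop-in
#' smooth replacement for a Boltzmann activation curve.
#'
#' @param V0 onset voltage (value 0 below).
#' @param V1 saturation voltage (value 1 above); must exceed `V0`.
#' @param V2 free cubic root, `V1 <= V2`; default places the cubic maximum at `V1`.
#' @return a vectorised function `f(v)` with values in [0, 1].
#' @export
#' @examples
#' f <- sigmoid_spline(-60, -30)
#' f(c(-70, -60, -45, -30, 0)) # 0, 0, mid, 1, 1
sigmoid_spline <- function(V0, V1, V2 = V0 + 1.5 * (V1 - V0)) {
  if (V0 >= V1) stop("sigmoid_spline: need V0 < V1")
  if (V1 > V2) stop("sigmoid_spline: need V1 <= V2")
  p32 <- function(v) (V2 - v) * (V0 - v)^2
  vstar <- (V0 + 2 * V2) / 3
  psi <- if (vstar >= V0 && vstar <= V1) 1 / p32(vstar) else 1 / p32(V1)
  force(psi)
  function(v) {
    out <- numeric(length(v))
    out[v > V1] <- 1
    mid <- v >= V0 & v <= V1
    out[mid] <- pmin(1, pmax(0, psi * p32(v[mid])))
    out
  }
}

# ---------------------------------------------------------------------------
# Continuity audit
# ---------------------------------------------------------------------------

#' Audit a right-hand side for continuity at its L/S specific points
#'
#' The framework's well-posedness rule: the right-hand side of a model must be
#' continuous everywhere, and no knot of a piecewise-linear term or threshold
#' of a step term may itself create a fixed or bifurcation point — unless it
#' is aligned with an extremum of a polynomial factor, in which case the kink
#' is invisible (the polynomial slope is zero there). This audit checks value
#' continuity by extrapolated two-sided limits at every specific point, and
#' flags any supplied fixed point lying within `prox_tol` of a specific point
#' that is not aligned (within `prox_tol`) to a polynomial extremum.
#'
#' @param rhs function of a scalar (e.g. voltage) returning a numeric vector
#'   of right-hand-side values; typically the model RHS with the other state
#'   variables held at their fixed-point values.
#' @param specific_points numeric vector of L knots / S thresholds used by `rhs`.
#' @param fixed_points numeric vector of fixed-point abscissae (may be empty).
#' @param p_extrema abscissae of polynomial extrema that legitimise an aligned
#'   specific point.
#' @param prox_tol proximity tolerance (same units as the abscissa), default 1e-6.
#' @param jump_tol relative tolerance for the value-continuity check.
#' @return a list of class `pls_audit` with elements `points` (data frame of
#'   per-point diagnostics), `pass` (logical) and `messages`.
#' @export
continuity_audit <- function(rhs, specific_points, fixed_points = numeric(),
                             p_extrema = numeric(), prox_tol = 1e-6,
                             jump_tol = 1e-6) {
  specific_points <- sort(unique(as.numeric(specific_points)))
  res <- lapply(specific_points, function(s) {
    h <- max(1e-6, abs(s) * 1e-9)
    # linear extrapolation of each side to s itself
    fl <- rhs(s - h); fl2 <- rhs(s - h / 2)
    fr <- rhs(s + h); fr2 <- rhs(s + h / 2)
    left_lim <- 2 * fl2 - fl
    right_lim <- 2 * fr2 - fr
    scale <- pmax(1, abs(left_lim), abs(right_lim))
    jump <- max(abs(left_lim - right_lim) / scale)
    near_fp <- length(fixed_points) > 0 &&
      min(abs(fixed_points - s)) <= prox_tol
    aligned <- length(p_extrema) > 0 && min(abs(p_extrema - s)) <= prox_tol
    data.frame(point = s, rel_jump = jump,
               continuous = jump <= jump_tol,
               near_fixed_point = near_fp,
               aligned_extremum = aligned,
               flagged = (jump > jump_tol) || (near_fp && !aligned))
  })
  points <- do.call(rbind, res)
  msgs <- character()
  if (!is.null(points)) {
    bad <- points[points$flagged, , drop = FALSE]
    if (nrow(bad) > 0)
      msgs <- sprintf(
        "specific point %.6g: %s", bad$point,
        ifelse(!bad$continuous, "value discontinuity",
               "coincides with a fixed point without an aligned polynomial extremum"))
  }
  structure(list(points = points,
                 pass = is.null(points) || !any(points$flagged),
                 messages = msgs),
            class = "pls_audit")
}

#' @export
print.pls_audit <- function(x, ...) {
  cat(if (x$pass) "continuity audit: PASS\n" else "continuity audit: FLAGGED\n")
  if (length(x$messages)) cat(paste0("  - ", x$messages, collapse = "\n"), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parameter counting (memory footprint in stored real constants)
# ---------------------------------------------------------------------------

#' Count stored real constants of a model or function spec
#'
#' Footprint accounting: the number of real numbers a spec needs to keep in
#' memory (roots, knots, slopes, thresholds, levels, conductances, reversal
#' potentials, scales). Integer bookkeeping fields (multiplicities, row
#' counts) are not counted.
#'
#' @param x a spec object.
#' @param ... unused.
#' @return integer count.
#' @export
parameter_count <- function(x, ...) UseMethod("parameter_count")

#' @export
parameter_count.default <- function(x, ...) {
  if (is.null(x) || length(x) == 0) return(0L)
  if (is.numeric(x)) return(length(x))
  stop("parameter_count: no method for class ", paste(class(x), collapse = "/"))
}

#' @export
parameter_count.poly_spec <- function(x, ...)
  length(x$roots) + 1L  # roots + scale

#' @export
parameter_count.pl_spec <- function(x, ...)
  2L * length(x$knots_x) + 2L  # knots + two outer slopes

#' @export
parameter_count.step_spec <- function(x, ...)
  length(x$thresholds) + length(x$levels)

# ---------------------------------------------------------------------------
# Serialization of function specs
# ---------------------------------------------------------------------------

#' Convert a spec to a plain list (for JSON/YAML configs)
#' @param spec a `poly_spec`, `pl_spec` or `step_spec`.
#' @return a named list with a single top-level key `poly`, `pl` or `step`.
#' @export
spec_to_list <- function(spec) {
  if (inherits(spec, "poly_spec"))
    return(list(poly = list(roots = spec$roots,
                            multiplicities = spec$multiplicities,
                            scale = spec$scale)))
  if (inherits(spec, "pl_spec"))
    return(list(pl = list(knots = Map(c, spec$knots_x, spec$knots_y),
                          left_slope = spec$left_slope,
                          right_slope = spec$right_slope)))
  if (inherits(spec, "step_spec"))
    return(list(step = list(thresholds = spec$thresholds,
                            levels = spec$levels)))
  stop("spec_to_list: unsupported class")
}

#' Rebuild a spec from its plain-list form
#' @param x a list as produced by [spec_to_list()].
#' @return the corresponding spec object.
#' @export
spec_from_list <- function(x) {
  if (!is.null(x$poly))
    return(poly_spec(x$poly$roots,
                     if (is.null(x$poly$multiplicities))
                       rep(1L, length(x$poly$roots)) else x$poly$multiplicities,
                     if (is.null(x$poly$scale)) 1 else x$poly$scale))
  if (!is.null(x$pl)) {
    k <- x$pl$knots
    km <- if (is.matrix(k)) k
          else if (is.numeric(k)) matrix(k, ncol = 2, byrow = TRUE)
          else do.call(rbind, lapply(k, as.numeric))
    return(pl_spec(km[, 1], km[, 2],
                   if (is.null(x$pl$left_slope)) 0 else x$pl$left_slope,
                   if (is.null(x$pl$right_slope)) 0 else x$pl$right_slope))
  }
  if (!is.null(x$step))
    return(step_spec(x$step$thresholds, x$step$levels))
  stop("spec_from_list: expected a 'poly', 'pl' or 'step' key")
}
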