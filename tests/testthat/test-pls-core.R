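# The three function families: exact evaluation, boundary conventions,
# recursion consistency with the hierarchical definitions.

test_that("polynomial specs evaluate as exact root products", {
  p1 <- poly_spec(-65)
  expect_identical(eval_poly(p1, -65), 0)
  expect_equal(eval_poly(p1, -70), 5)

  p3 <- poly_spec(c(-65, -45, 55))
  expect_identical(eval_poly(p3, -45), 0)
  expect_identical(eval_poly(p3, -65), 0)
  expect_identical(eval_poly(p3, 55), 0)

  # double root: value and first derivative vanish
  p32 <- poly_spec(c(-65, 55), multiplicities = c(2L, 1L))
  expect_identical(eval_poly(p32, -65), 0)
  h <- 1e-6
  deriv <- (eval_poly(p32, -65 + h) - eval_poly(p32, -65 - h)) / (2 * h)
  expect_lt(abs(deriv), 1e-3) # O(h) residual of an exact double root

  # brute-force product oracle, all multiplicities 1
  set.seed(42)
  for (rep in 1:20) {
    roots <- sort(runif(sample(2:5, 1), -80, 60))
    sc <- runif(1, -2, 2)
    spec <- poly_spec(roots, scale = sc)
    xs <- runif(50, -100, 80)
    oracle <- sapply(xs, function(x) sc * prod(roots - x))
    expect_equal(eval_poly(spec, xs), oracle, tolerance = 1e-14)
  }

  expect_error(poly_spec(c(0, -1)), "ascending")
  expect_error(poly_spec(c(0, 1), multiplicities = c(0L, 1L)), "multiplicities")
})

test_that("piecewise-linear specs hit their knots and extend linearly", {
  w_inf <- pl_spec(c(-40, -5), c(0, 1))
  expect_identical(eval_pl(w_inf, -40), 0)
  expect_identical(eval_pl(w_inf, -5), 1)
  expect_equal(eval_pl(w_inf, -22.5), 0.5)
  expect_identical(eval_pl(w_inf, 20), 1)  # flat right extension
  expect_identical(eval_pl(w_inf, -60), 0) # flat left extension

  sloped <- pl_spec(c(0, 1), c(0, 2), left_slope = -1, right_slope = 3)
  expect_equal(eval_pl(sloped, -2), 2)
  expect_equal(eval_pl(sloped, 2), 5)

  expect_error(pl_spec(c(0, 0), c(1, 2)), "ascending")
})

test_that("piecewise-linear evaluation is continuous at every knot", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    spec <- pl_spec(sort(runif(n, -90, 55)), runif(n, -3, 3),
                    left_slope = runif(1, -1, 1), right_slope = runif(1, -1, 1))
    for (k in seq_len(n)) {
      xk <- spec$knots_x[k]; yk <- spec$knots_y[k]
      h <- 1e-9 * (1 + abs(xk))
      left <- eval_pl(spec, xk - h)
      right <- eval_pl(spec, xk + h)
      expect_lt(abs(left - right), 1e-6 * (1 + abs(yk)))
      # the knot itself is exact, via the left branch
      expect_identical(eval_pl(spec, xk), yk)
    }
  }
})

# recursive hierarchy oracle, written from the case definitions
.L0 <- function(x, x0, y0, a0) y0 + a0 * (x - x0)
.L1 <- function(x, x0, y0, a0, a1)
  ifelse(x <= x0, .L0(x, x0, y0, a0), .L0(x, x0, y0, a1))
.L2 <- function(x, x0, y0, x1, y1, a0, a2)
  ifelse(x <= x0, .L0(x, x0, y0, a0),
         .L1(x, x1, y1, (y1 - y0) / (x1 - x0), a2))
.L3 <- function(x, x0, y0, x1, y1, x2, y2, a0, a3)
  ifelse(x <= x0, .L0(x, x0, y0, a0),
         .L2(x, x1, y1, x2, y2, (y1 - y0) / (x1 - x0), a3))

test_that("direct evaluation equals the recursive hierarchy on dense grids", {
  set.seed(11)
  for (rep in 1:5) {
    kx <- sort(runif(3, -80, 50)); ky <- runif(3, -2, 2)
    a0 <- runif(1, -1, 1); a3 <- runif(1, -1, 1)
    spec <- pl_spec(kx, ky, a0, a3)
    xs <- seq(-100, 70, length.out = 1e4)
    oracle <- .L3(xs, kx[1], ky[1], kx[2], ky[2], kx[3], ky[3], a0, a3)
    expect_equal(eval_pl(spec, xs), oracle, tolerance = 1e-12)
  }
})

.S1 <- function(x, x0, y0, y1)
  ifelse(x < x0, y0, ifelse(x == x0, (y0 + y1) / 2, y1))
.S2 <- function(x, x0, x1, y0, y1, y2) .S1(x, x0, y0, .S1(x, x1, y1, y2))

test_that("step specs follow the midpoint rule and the nested definition", {
  tau_w <- step_spec(c(-55.45, 18.78), c(5, 7.6, 1.8))
  expect_identical(eval_step(tau_w, -60), 5)
  expect_identical(eval_step(tau_w, 0), 7.6)
  expect_identical(eval_step(tau_w, 30), 1.8)
  expect_equal(eval_step(tau_w, -55.45), (5 + 7.6) / 2)
  expect_equal(eval_step(tau_w, 18.78), (7.6 + 1.8) / 2)

  s1 <- step_spec(0, c(-1, 1))
  expect_identical(eval_step(s1, 0), 0) # (y0 + y1)/2

  flat <- step_spec(c(-10, 10), c(2, 2, 2))
  expect_identical(eval_step(flat, c(-20, -10, 0, 10, 20)), rep(2, 5))

  set.seed(3)
  for (rep in 1:10) {
    th <- sort(runif(2, -50, 50)); lv <- runif(3, -2, 2)
    spec <- step_spec(th, lv)
    xs <- c(seq(-60, 60, length.out = 500), th)
    expect_equal(eval_step(spec, xs),
                 .S2(xs, th[1], th[2], lv[1], lv[2], lv[3]))
  }
})

test_that("the nested sigmoid spline is a smooth 0-1 transition", {
  V0 <- -60; V1 <- -30
  f <- sigmoid_spline(V0, V1)
  expect_identical(f(V0), 0)
  expect_identical(f(V1), 1)
  v <- seq(V0 - 20, V1 + 20, by = 0.01)
  y <- f(v)
  expect_all_true(diff(y) >= -1e-12)        # monotone non-decreasing
  expect_all_true(y >= 0 & y <= 1)
  # continuously differentiable at the window edges
  h <- 1e-4
  for (edge in c(V0, V1)) {
    d_in <- (f(edge + h) - f(edge)) / h
    d_out <- (f(edge) - f(edge - h)) / h
    expect_lt(abs(d_in - d_out), 1e-2 * max(1, abs(d_in)))
  }
  expect_error(sigmoid_spline(-30, -60), "V0 < V1")
})

test_that("the sigmoid spline tracks a fitted logistic to within 0.05", {
  V0 <- -60; V1 <- -30
  f <- sigmoid_spline(V0, V1)
  v <- seq(V0 - 10, V1 + 10, by = 0.05)
  y <- f(v)
  sse <- function(par) sum((y - 1 / (1 + exp(-(v - par[1]) / par[2])))^2)
  par <- optim(c((V0 + V1) / 2, (V1 - V0) / 8), sse)$par
  expect_lt(max(abs(y - 1 / (1 + exp(-(v - par[1]) / par[2])))), 0.05)
})

test_that("continuity audit flags knot-created extrema and passes smooth models", {
  # a deliberately broken construction: the nullcline minimum is an L knot
  broken <- pl_spec(c(-60, -40), c(0, 1), left_slope = -1, right_slope = 2)
  rhs_broken <- function(v) eval_pl(broken, v)
  rep_bad <- continuity_audit(rhs_broken, specific_points = c(-60, -40),
                              fixed_points = -60)
  expect_false(rep_bad$pass)

  # aligned with a polynomial extremum: the same point is legitimate
  rep_ok <- continuity_audit(rhs_broken, specific_points = c(-60, -40),
                             fixed_points = -60, p_extrema = -60)
  expect_true(rep_ok$pass)

  # a genuinely discontinuous right-hand side is caught
  rep_disc <- continuity_audit(function(v) ifelse(v <= 0, 0, 1),
                               specific_points = 0)
  expect_false(rep_disc$pass)

  # integrator right-hand side at rest: smooth by construction
  m <- pheno_model("integrator")
  fp <- fixed_points(m, 0)
  pars <- m$params
  rhs_v <- function(v) rhs_integrator(c(v, fp$w[1]), 0, pars)[1]
  aud <- continuity_audit(rhs_v,
                          specific_points = c(pars$v0, pars$v3, pars$v4,
                                              pars$v5, pars$v6, pars$v7),
                          fixed_points = fp$v,
                          p_extrema = c(pars$v0, pars$v1, pars$v2))
  expect_true(aud$pass)
})

test_that("parameter counting reflects stored real constants", {
  expect_identical(parameter_count(numeric()), 0L)
  expect_identical(parameter_count(poly_spec(c(-65, -45, 55))), 4L)
  expect_identical(parameter_count(pl_spec(c(-40, -5), c(0, 1))), 6L)
  expect_identical(parameter_count(step_spec(c(-55, 18), c(5, 7.6, 1.8))), 5L)
  tbl <- build_table(list(a = identity, b = sqrt), 0, 10, 200)
  expect_identical(parameter_count(tbl), 200L * 2L + 3L)
})

test_that("specs round-trip through their plain-list config form", {
  specs <- list(poly_spec(c(-65, 55), c(2L, 1L), scale = 3.25e-6),
                pl_spec(c(-40, -5), c(0, 1), -0.1, 0.2),
                step_spec(c(-55.45, 18.78), c(5, 7.6, 1.8)))
  for (s in specs) {
    back <- spec_from_list(spec_to_list(s))
    expect_equal(back, s)
  }
})
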