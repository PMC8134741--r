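# Phenomenological integrator and resonator: phase-plane structure,
# Jacobians, bifurcation currents, protocols.

fx_onset_int <- function() fixture("onset_int", function()
  find_saddle_node(pheno_model("integrator"), c(0, 0.15)))
fx_block_int <- function() fixture("block_int", function()
  block_current(pheno_model("integrator")))
fx_onset_res <- function() fixture("onset_res", function()
  find_hopf(pheno_model("resonator"), c(0, 0.15)))

test_that("the cubic term and its alignment behave at the roots", {
  p <- integrator_params()
  # at v = v0 with w = 0, I = 0 the voltage derivative vanishes
  expect_equal(rhs_integrator(c(p$v0, 0), 0, p)[1], 0)
  # resonator: double root — value and v-derivative both vanish
  pr <- resonator_params()
  d0 <- rhs_resonator(c(pr$v0, 0), 0, pr)[1]
  h <- 1e-5
  d1 <- (rhs_resonator(c(pr$v0 + h, 0), 0, pr)[1] -
           rhs_resonator(c(pr$v0 - h, 0), 0, pr)[1]) / (2 * h)
  expect_equal(d0, 0)
  expect_lt(abs(d1), 1e-2)
})

test_that("the w time constant steps through its printed levels", {
  m <- pheno_model("integrator")
  tr <- function(v) plsneuro:::.pheno_tauw(m, v)
  expect_identical(tr(-70), 5)
  expect_identical(tr(0), 7.6)
  expect_identical(tr(30), 1.8)
})

test_that("integrator has three fixed points at rest, leftmost stable", {
  fp <- fixed_points(pheno_model("integrator"), 0)
  expect_identical(nrow(fp), 3L)
  expect_identical(fp$stable, c(TRUE, FALSE, FALSE))
  expect_equal(fp$v[1], -65, tolerance = 1e-6)
  expect_equal(fp$v[2], -45, tolerance = 1e-6)
})

test_that("resonator has exactly one fixed point at rest, stable", {
  fp <- fixed_points(pheno_model("resonator"), 0)
  expect_identical(nrow(fp), 1L)
  expect_true(fp$stable)
})

test_that("every reported fixed point satisfies both equations to 1e-9", {
  for (type in c("integrator", "resonator")) {
    m <- pheno_model(type)
    for (I in c(0, 0.02, 0.1, 0.25, 0.45)) {
      fp <- fixed_points(m, I)
      for (i in seq_len(nrow(fp))) {
        resid <- plsneuro:::.rhs_pheno(m, c(fp$v[i], fp$w[i]), I)
        expect_lt(max(abs(resid)), 1e-9)
      }
    }
  }
})

test_that("nullcline intersections coincide with fixed points", {
  m <- pheno_model("integrator")
  fp <- fixed_points(m, 0.02)
  expect_gt(nrow(fp), 0)
  # the two returned curves meet exactly at every fixed point
  nc_at_fp <- nullclines(m, 0.02, fp$v)
  expect_lt(max(abs(nc_at_fp$w_vnull - nc_at_fp$w_wnull)), 1e-6)
  # and nowhere else: away from the fixed points the curves stay apart
  nc <- nullclines(m, 0.02, seq(-100, 60, by = 0.01))
  gap <- abs(nc$w_vnull - nc$w_wnull)
  far <- !is.na(gap) & vapply(nc$v, function(v) min(abs(v - fp$v)) > 1,
                              logical(1))
  expect_gt(min(gap[far]), 1e-4)
  # the w-nullcline hits its printed anchor points
  anchors <- nullclines(m, 0, c(-40, -5))
  expect_identical(anchors$w_wnull, c(0, 1))
  # raising I raises the v-nullcline pointwise where defined
  lo <- nullclines(m, 0.0, seq(-60, 50, by = 0.5))$w_vnull
  hi <- nullclines(m, 0.1, seq(-60, 50, by = 0.5))$w_vnull
  ok <- !is.na(lo) & !is.na(hi)
  expect_all_true(hi[ok] >= lo[ok])
})

test_that("analytic and finite-difference Jacobians agree away from specific points", {
  for (type in c("integrator", "resonator")) {
    m <- pheno_model(type)
    for (I in c(0, 0.05, 0.2)) {
      fp <- fixed_points(m, I)
      for (i in seq_len(nrow(fp))) {
        pt <- c(fp$v[i], fp$w[i])
        sp <- c(m$params$v0, m$params$v3, m$params$v4, m$params$v5,
                m$params$v6, m$params$v7)
        if (min(abs(pt[1] - sp)) < 1e-4) next
        ea <- sort(Re(jacobian_eigs(m, pt, I)))
        ef <- sort(Re(jacobian_eigs_fd(m, pt, I)))
        expect_lt(max(abs(ea - ef)), 1e-4 * max(1, abs(ea)))
      }
    }
  }
})

test_that("the middle fixed point at rest is a saddle", {
  m <- pheno_model("integrator")
  fp <- fixed_points(m, 0)
  ei <- jacobian_eigs(m, c(fp$v[2], fp$w[2]), 0)
  expect_true(any(Re(ei) > 0) && any(Re(ei) < 0))
  expect_all_true(abs(Im(ei)) < 1e-12)
})

test_that("integrator folds sit at the known onset and block currents", {
  expect_equal(fx_onset_int(), 0.039, tolerance = 0.05)
  expect_equal(fx_block_int(), 0.32, tolerance = 0.05)
})

test_that("no fold is reported when the count never changes", {
  expect_message(
    out <- find_saddle_node(pheno_model("resonator"), c(0, 0.04)),
    "does not change")
  expect_true(is.na(out))
})

test_that("the resonator loses stability through a complex pair (Hopf)", {
  Ih <- fx_onset_res()
  expect_false(is.na(Ih))
  m <- pheno_model("resonator")
  fp <- fixed_points(m, Ih)
  expect_lt(abs(max(fp$re1[1], fp$re2[1])), 1e-3)
  just_past <- fixed_points(m, Ih + 0.002)
  ei <- jacobian_eigs(m, c(just_past$v[1], just_past$w[1]), Ih + 0.002)
  expect_all_true(Re(ei) > 0)
  expect_all_true(abs(Im(ei)) > 0)
  # the integrator shows no eigenvalue sign change below its SNIC onset
  expect_message(
    none <- find_hopf(pheno_model("integrator"), c(0, 0.9 * fx_onset_int())),
    "no eigenvalue sign change")
  expect_true(is.na(none))
})

test_that("integrator rate is monotone in current between onset and block", {
  # monotone over the pacing range; close to the block fold the spike
  # amplitude declines and the rate genuinely falls, so stop at 0.75 I1
  m <- pheno_model("integrator")
  Is <- seq(fx_onset_int() * 1.02, 0.75 * fx_block_int(), length.out = 8)
  rates <- vapply(Is, function(I) {
    tr <- simulate_model(m, const_protocol(I, 3000), record_every = 5L)
    sp <- detect_spikes(tr)
    length(sp[sp > 500]) / 2.5
  }, numeric(1))
  # 2.5 s counting windows quantise the rate at 0.4 spikes/s
  expect_all_true(diff(rates) > -0.45)
  expect_gt(rates[8], rates[1])
})

test_that("w stays inside [0, 1] along trajectories started there", {
  for (type in c("integrator", "resonator")) {
    m <- pheno_model(type)
    tr <- simulate_model(m, const_protocol(0.15, 2000), record_every = 5L)
    expect_all_true(tr$w >= -1e-9 & tr$w <= 1 + 1e-9)
  }
})

test_that("the hold-step-ramp protocol shows pacing onset and block", {
  m <- pheno_model("integrator")
  tr <- fig_protocol(m, I0 = fx_onset_int(), I1 = fx_block_int())
  sp <- detect_spikes(tr)
  expect_length(sp[sp < 500], 0)                   # silent during the hold
  expect_gt(length(sp[sp >= 500 & sp < 9500]), 1)  # slow pacing after the step
  expect_lt(max(sp), 10400)                        # firing ceases before the end
  expect_gt(tr$v[nrow(tr)], -20)                   # ends in depolarisation block

  mr <- pheno_model("resonator")
  trr <- fig_protocol(mr, I0 = fx_onset_res(),
                      I1 = block_current(mr, c(0.06, 0.4)))
  spr <- detect_spikes(trr)
  # abrupt onset: the step phase fires at the limit-cycle rate
  expect_gt(length(spr[spr >= 500 & spr < 9500]), 20)
  expect_gt(trr$v[nrow(trr)], -20)
})

test_that("SNIC scaling: integrator rate vanishes continuously at onset", {
  m <- pheno_model("integrator")
  I0 <- fx_onset_int()
  r3 <- min_sustained_rate(m, onset = I0, eps = 1e-3)
  r4 <- min_sustained_rate(m, onset = I0, eps = 1e-4)
  expect_lt(r4, 2)
  expect_lte(r4, r3)
  facs <- c(1.001, 1.005, 1.01, 1.02, 1.035, 1.05)
  rates <- vapply(facs, function(f)
    min_sustained_rate(m, onset = I0, eps = f - 1), numeric(1))
  fit <- lm(log(rates) ~ log(I0 * facs - I0))
  expect_gt(coef(fit)[2], 0.4)
  expect_lt(coef(fit)[2], 0.6)
})

test_that("the resonator cannot fire slower than its limit-cycle floor", {
  rate <- min_sustained_rate(pheno_model("resonator"), onset = fx_onset_res())
  expect_gt(rate, 3)
  expect_lt(rate, 5)
})
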