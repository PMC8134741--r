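# plsneuro

Neuron models whose right-hand sides are built from three cheap function
families — **P**olynomials stored as root products, continuous
piecewise-**L**inear functions, and **S**tep functions — so that a
conductance-based or phenomenological model can run with a handful of
multiplications, comparisons and additions per time step instead of
hundreds of exponentials, without resets and without giving up phase-plane
analysis. The package is for computational neuroscientists who need long
simulations of many neurons (developmental timescales, embedded hardware,
GPUs) but want dynamics that stay continuous and analysable.

It provides:

* the three function families with validation, evaluation, serialization,
  a smooth nested sigmoid (a step of a scaled double-root cubic), a
  continuity audit implementing the framework's well-posedness rule (no
  L/S knot may itself create a fixed or bifurcation point), and footprint
  accounting;
* a fully computed Wang–Buzsáki fast-spiking interneuron model
  (`c dv/dt = I + g_l(E_l−v) + g_K n⁴(E_K−v) + g_Na m∞³(v) h (E_Na−v)`,
  with first-order `h`, `n` kinetics and rate scale φ = 5), compiled
  fixed-step Euler simulation at dt = 0.01 ms, spike detection, and a 10 s
  current-ramp FI protocol;
* four approximation routes: lookup table (200 rows from E_K to E_Na,
  3.9 kB), order-5 polynomial fits, 3-segment piecewise-linear fits, and a
  2D reduction built by collapsing `h` onto `n` (Rinzel's argument),
  replacing the voltage nullcline by a cubic times a left-branch
  steepener, and calibrating the time constants against the full model's
  FI curve;
* phenomenological integrator (type 1, fold-on-circle onset) and resonator
  (type 2, subcritical Hopf onset) models with nullclines, fixed points,
  analytic Jacobians, and bisection searches for fold and Hopf currents;
* an NMDA plateau-potential experiment: 30 Poisson sources stepping from
  0.9 Hz to 13 Hz for 1 s, AMPA + magnesium-blocked NMDA synapses, a
  conductance tuner targeting a 0.7–1 Hz baseline, a plateau detector, and
  an Izhikevich hard-reset baseline for contrast;
* FI-error metrics (squared error; maximum deviation as % of the reference
  dynamic range), CSV/JSON/YAML I/O, and a CLI
  (`inst/cli/plsneuro.R`).

## Worked example

```r
library(plsneuro)

p <- wbm_params()                      # c=1, g_l=0.1, g_Na=35, g_K=9 ...
fi_ref <- ramp_fi(wbm_model(p), 0, 1)  # 10 s ramp, dt = 0.01 ms
max(fi_ref$rate)
#> [1] 57.82221                         # spikes/s at 1 uA/cm^2

fit <- rinzel_reduce(p)                # collapse h onto n
round(c(fit$epsilon, fit$kappa, fit$r_squared), 3)
#> [1]  0.635 -0.897  0.935             # h = 0.635 - 0.897 n, R^2 = 0.935

find_tangency(fit, p)                  # v-nullcline touches n = 0
#> $I0
#> [1] 0.1327078                        # tangency current, uA/cm^2
#> $v0
#> [1] -60.802                          # tangency voltage, mV

q <- pl2d_construct(p, fit, fi_ref)    # build + calibrate the 2D reduction
parameter_count(q)
#> [1] 31                               # stored real constants
max_error_pct_range(fi_ref, ramp_fi(q, 0, 1))
#> [1] 3.125591                         # % of the reference dynamic range

m <- pheno_model("integrator")
find_saddle_node(m, c(0, 0.15))        # spiking onset (fold)
#> [1] 0.03857574
block_current(m)                       # depolarisation block (second fold)
#> [1] 0.322606
min_sustained_rate(pheno_model("resonator"))
#> [1] 4                                # spikes/s floor above the Hopf onset
```

The reduction's 3.1% FI error places it between the lookup table (~0.14%)
and the single-family routes (piecewise-linear ~36%, polynomial ~65%, which
even fires at zero current) at a thirtieth of the table's footprint.

## Command line

```sh
Rscript inst/cli/plsneuro.R fi --model wbm --out fi.csv
Rscript inst/cli/plsneuro.R bifurcate --model integrator --scan 0:0.5
Rscript inst/cli/plsneuro.R plateau --model integrator --seed 7 --gampa auto
Rscript inst/cli/plsneuro.R compare --routes table,poly,pl,pl2d
```

Models can also be loaded from structured-text configs (JSON or YAML; see
the examples under `inst/extdata/`) with `--config`, or programmatically
with `load_model()` / `save_model()`.

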