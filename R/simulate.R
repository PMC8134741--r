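# ---------------------------------------------------------------------------
# Protocols, traces, simulation front-ends, spike detection, FI protocol
# ---------------------------------------------------------------------------

#' Constant-current protocol
#' @param I applied current.
#' @param duration duration, ms.
#' @return protocol object.
#' @export
const_protocol <- function(I, duration)
  structure(list(segments = list(c(I, I, duration)),
                 descriptor = sprintf("const I=%g, %g ms", I, duration)),
            class = "pls_protocol")

#' Linear current-ramp protocol
#' @param I_min,I_max ramp endpoints.
#' @param duration duration, ms.
#' @return protocol object.
#' @export
ramp_protocol <- function(I_min, I_max, duration)
  structure(list(segments = list(c(I_min, I_max, duration)),
                 descriptor = sprintf("ramp %g->%g, %g ms", I_min, I_max, duration)),
            class = "pls_protocol")

#' Piecewise protocol from (I_start, I_end, duration) segments
#' @param ... numeric triples `c(I_start, I_end, duration_ms)`.
#' @return protocol object.
#' @export
seg_protocol <- function(...)
  structure(list(segments = list(...), descriptor = "segments"),
            class = "pls_protocol")

#' Materialise a protocol as a per-step current vector
#' @param proto a protocol object.
#' @param dt time step, ms.
#' @return numeric vector, one current value per Euler step.
#' @export
protocol_current <- function(proto, dt) {
  unlist(lapply(proto$segments, function(s) {
    n <- round(s[3] / dt)
    if (n == 0) return(numeric())
    s[1] + (s[2] - s[1]) * (seq_len(n) - 1) / max(1, n - 1)
  }), use.names = FALSE)
}

new_trace <- function(mat, cols, dt, protocol, extra = list()) {
  n <- attr(mat, "n_recorded")
  df <- as.data.frame(mat[seq_len(n), , drop = FALSE])
  names(df) <- cols
  attr(df, "dt") <- dt
  attr(df, "protocol") <- protocol
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("pls_trace", "data.frame")
  df
}

#' Forward-Euler integration of an arbitrary right-hand side
#'
#' Reference integrator in plain R: fixed-step forward Euler on a uniform
#' grid. Model-specific compiled steppers are used by [simulate_model()]; this
#' function serves small cross-checks and user-defined systems.
#'
#' @param rhs function `(state, I) -> dstate`.
#' @param state0 initial state vector (named names are kept).
#' @param proto a protocol object or numeric per-step current vector.
#' @param dt step, ms (default 0.01).
#' @param record_every record every k-th step.
#' @return a `pls_trace` data frame (time plus one column per state variable).
#' @export
euler_sim <- function(rhs, state0, proto, dt = 0.01, record_every = 1L) {
  Iv <- if (inherits(proto, "pls_protocol")) protocol_current(proto, dt) else proto
  n_steps <- length(Iv)
  nm <- if (is.null(names(state0))) paste0("x", seq_along(state0)) else names(state0)
  n_rec <- n_steps %/% record_every + 1L
  out <- matrix(NA_real_, n_rec, 1 + length(state0))
  state <- as.numeric(state0)
  rec <- 0L
  for (i in seq_len(n_steps)) {
    if ((i - 1L) %% record_every == 0L) {
      rec <- rec + 1L
      out[rec, ] <- c((i - 1L) * dt, state)
    }
    state <- state + dt * rhs(state, Iv[i])
    if (!all(is.finite(state)))
      stop(sprintf("simulation diverged at t = %g ms; state = %s",
                   i * dt, paste(signif(state, 4), collapse = ", ")))
  }
  attr(out, "n_recorded") <- rec
  new_trace(out, c("time", nm), dt,
            if (inherits(proto, "pls_protocol")) proto$descriptor else "custom")
}

#' Simulate a model with its compiled fixed-step Euler stepper
#'
#' Dispatches on the model class: the Wang-Buzsaki model (any gating route),
#' the 2D reduction, the phenomenological integrator/resonator (optionally
#' with synaptic drive) and the Izhikevich baseline all advance in compiled
#' code at the given step.
#'
#' @param model a model object (`wbm_model`, `pl2d_model`, `pheno_model`,
#'   `izhi_model`).
#' @param proto protocol object or per-step current vector.
#' @param dt step, ms (default 0.01 as used by all protocols here).
#' @param init initial state; default is the model's resting state.
#' @param record_every record every k-th step (thins the returned trace).
#' @param synapse optional compiled-synapse drive (see [plateau_protocol()]).
#' @return a `pls_trace`.
#' @export
simulate_model <- function(model, proto, dt = 0.01, init = NULL,
                           record_every = 1L, synapse = NULL)
  UseMethod("simulate_model")

#' @export
simulate_model.wbm_model <- function(model, proto, dt = 0.01, init = NULL,
                                     record_every = 1L, synapse = NULL) {
  Iv <- if (inherits(proto, "pls_protocol")) protocol_current(proto, dt) else proto
  desc <- if (inherits(proto, "pls_protocol")) proto$descriptor else "custom"
  if (is.null(init)) init <- model_rest(model)
  route_id <- match(model$route, c("exact", "table", "poly", "pl")) - 1L
  approx <- model$approx
  if (model$route == "table")
    approx <- list(values = approx$values, v_min = approx$v_min,
                   row_offset = approx$row_offset, n_rows = approx$n_rows)
  if (model$route == "pl") approx <- lapply(approx, unclass)
  mat <- sim_wbm_cpp(Iv, dt, as.numeric(init), route_id,
                     if (is.null(approx)) list() else approx,
                     unclass(model$params), as.integer(record_every))
  new_trace(mat, c("time", "v", "h", "n"), dt, desc,
            list(clips = attr(mat, "clips")))
}

#' @export
simulate_model.pl2d_model <- function(model, proto, dt = 0.01, init = NULL,
                                      record_every = 1L, synapse = NULL) {
  Iv <- if (inherits(proto, "pls_protocol")) protocol_current(proto, dt) else proto
  desc <- if (inherits(proto, "pls_protocol")) proto$descriptor else "custom"
  if (is.null(init)) init <- model_rest(model)
  q <- unclass(model)
  q$tau_v <- unclass(q$tau_v); q$n_inf <- unclass(q$n_inf)
  q$tau_n <- unclass(q$tau_n)
  mat <- sim_pl2d_cpp(Iv, dt, as.numeric(init), q, as.integer(record_every))
  new_trace(mat, c("time", "v", "n"), dt, desc)
}

#' @export
simulate_model.pheno_model <- function(model, proto, dt = 0.01, init = NULL,
                                       record_every = 1L, synapse = NULL) {
  Iv <- if (inherits(proto, "pls_protocol")) protocol_current(proto, dt) else proto
  desc <- if (inherits(proto, "pls_protocol")) proto$descriptor else "custom"
  if (is.null(init)) init <- model_rest(model)
  m <- unclass(model$params)
  m$type <- if (model$type == "integrator") 1L else 2L
  mat <- sim_pheno_cpp(Iv, dt, as.numeric(init), m, as.integer(record_every),
                       synapse)
  new_trace(mat, c("time", "v", "w"), dt, desc)
}

#' @export
simulate_model.izhi_model <- function(model, proto, dt = 0.01, init = NULL,
                                      record_every = 1L, synapse = NULL) {
  Iv <- if (inherits(proto, "pls_protocol")) protocol_current(proto, dt) else proto
  desc <- if (inherits(proto, "pls_protocol")) proto$descriptor else "custom"
  if (is.null(init)) init <- model_rest(model)
  mat <- sim_izhi_cpp(Iv, dt, as.numeric(init), unclass(model),
                      as.integer(record_every), synapse)
  new_trace(mat, c("time", "v", "u"), dt, desc)
}

#' Resting state of a model
#' @param model a model object.
#' @return numeric initial-state vector.
#' @export
model_rest <- function(model) UseMethod("model_rest")

#' @export
model_rest.wbm_model <- function(model) wbm_rest(model$params)

#' @export
model_rest.pl2d_model <- function(model) {
  # relax to rest at I = 0 from below the cubic's double root
  tr <- simulate_model(model, const_protocol(0, 300), init = c(model$v0 - 3, 0),
                       record_every = 100L)
  as.numeric(tr[nrow(tr), c("v", "n")])
}

#' @export
model_rest.pheno_model <- function(model) {
  fp <- fixed_points(model, 0)
  st <- fp[fp$stable, , drop = FALSE]
  if (nrow(st) == 0) stop("no stable fixed point at I = 0")
  as.numeric(st[1, c("v", "w")])
}

#' @export
model_rest.izhi_model <- function(model) c(-70, model$b * -70)

#' Detect spikes as upward threshold crossings
#'
#' Crossing times are linearly interpolated inside the step; a minimum
#' inter-spike interval of `min_isi` ms suppresses double counts.
#'
#' @param trace a `pls_trace` with a `v` column.
#' @param threshold crossing threshold, mV (default 0).
#' @param min_isi minimum inter-spike interval, ms.
#' @return numeric vector of spike times (ms).
#' @export
detect_spikes <- function(trace, threshold = 0, min_isi = 1) {
  v <- trace$v; t <- trace$time
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (length(up) == 0) return(numeric())
  frac <- (threshold - v[up]) / (v[up + 1] - v[up])
  times <- t[up] + frac * (t[up + 1] - t[up])
  keep <- c(TRUE, diff(times) >= min_isi)
  # enforce the refractory rule sequentially
  out <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= min_isi) { out <- c(out, tt); last <- tt }
  }
  out
}

#' F-I curve from a current-ramp protocol
#'
#' Runs a linear ramp, detects spikes, assigns each inter-spike interval's
#' reciprocal (in spikes/s) to the ramp current at the interval's midpoint
#' time, and interpolates the result onto a uniform current grid. Currents
#' below the first measured interval are reported as 0 (no sustained firing).
#'
#' @param model a model object.
#' @param I_min,I_max ramp endpoints.
#' @param duration_s ramp duration in seconds (default 10).
#' @param dt Euler step, ms.
#' @param n_grid points of the uniform output current grid.
#' @param record_every trace thinning for spike detection (0.05 ms default
#'   resolution at `dt = 0.01`).
#' @return an `fi_curve` data frame with columns `current` and `rate`.
#' @export
ramp_fi <- function(model, I_min = 0, I_max = 1, duration_s = 10, dt = 0.01,
                    n_grid = 200L, record_every = 5L) {
  stopifnot(I_min < I_max)
  dur <- duration_s * 1000
  tr <- simulate_model(model, ramp_protocol(I_min, I_max, dur), dt = dt,
                       record_every = record_every)
  sp <- detect_spikes(tr)
  grid <- seq(I_min, I_max, length.out = n_grid)
  if (length(sp) < 2) {
    fi <- data.frame(current = grid, rate = 0)
  } else {
    tm <- (sp[-1] + sp[-length(sp)]) / 2
    rate <- 1000 / diff(sp)
    Im <- I_min + (I_max - I_min) * tm / dur
    r <- approx(Im, rate, xout = grid, rule = 2)$y
    r[grid < min(Im)] <- 0
    fi <- data.frame(current = grid, rate = r)
  }
  attr(fi, "protocol") <- sprintf("FI ramp %g->%g over %g s", I_min, I_max, duration_s)
  class(fi) <- c("fi_curve", "data.frame")
  fi
}

#' F-I curve from constant-current steps
#'
#' Oracle counterpart of [ramp_fi()]: one constant-current simulation per
#' grid point, rate = spike count over the window after a transient.
#'
#' @param model a model object.
#' @param currents current grid.
#' @param duration_s per-step duration, s.
#' @param transient_s discarded initial transient, s.
#' @param dt Euler step, ms.
#' @return an `fi_curve`.
#' @export
step_fi <- function(model, currents, duration_s = 2, transient_s = 0.5,
                    dt = 0.01) {
  rate <- vapply(currents, function(I) {
    tr <- simulate_model(model, const_protocol(I, duration_s * 1000), dt = dt,
                         record_every = 5L)
    sp <- detect_spikes(tr)
    sp <- sp[sp > transient_s * 1000]
    length(sp) / (duration_s - transient_s)
  }, numeric(1))
  fi <- data.frame(current = currents, rate = rate)
  class(fi) <- c("fi_curve", "data.frame")
  fi
}
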