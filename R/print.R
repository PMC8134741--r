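# Compact print methods for the package's main objects.

#' @export
print.wbm_model <- function(x, ...) {
  cat("Conductance-based interneuron model; gating route:", x$route, "\n")
  cat("  ", parameter_count(x), "stored constants\n")
  invisible(x)
}

#' @export
print.reduction_fit <- function(x, ...) {
  cat(sprintf("Gating collapse: h = %.4f %+.4f n  (R^2 = %.4f, fit at I = %g)\n",
              x$epsilon, x$kappa, x$r_squared, x$fit_current))
  invisible(x)
}

#' @export
print.pl2d_model <- function(x, ...) {
  cat("2D polynomial/piecewise-linear reduction\n")
  cat(sprintf("  cubic: a0 = %.4g, roots v0 = %.2f (double), v1 = %.1f mV\n",
              x$a0, x$v0, x$v1))
  cat(sprintf("  left-branch slope %.4g; driven by I - I0, I0 = %.4g\n",
              x$lfac_slope, x$I0))
  cat("  ", parameter_count(x), "stored constants\n")
  invisible(x)
}

#' @export
print.pheno_model <- function(x, ...) {
  p <- x$params
  cat(sprintf("Phenomenological %s (cubic %s, w power %d)\n", x$type,
              if (x$type == "integrator") "with three roots"
              else "with a double root", p$k))
  cat(sprintf("  roots: %s mV; a0 = %.3g\n",
              paste(stats::na.omit(c(p$v0, p$v1, p$v2)), collapse = ", "), p$a0))
  invisible(x)
}

#' @export
print.pls_trace <- function(x, ...) {
  cat(sprintf("Trace: %d samples, %.4g ms (%s)\n", nrow(x),
              if (nrow(x)) max(x$time) else 0,
              attr(x, "protocol") %||% "unspecified"))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf("FI curve: %d currents in [%.3g, %.3g], rates %.3g-%.3g spikes/s\n",
              nrow(x), min(x$current), max(x$current),
              min(x$rate), max(x$rate)))
  invisible(x)
}
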