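# ---------------------------------------------------------------------------
# Accuracy and footprint metrics for comparing approximation routes
# ---------------------------------------------------------------------------

.on_ref_grid <- function(fi_ref, fi_app) {
  if (max(fi_app$current) < min(fi_ref$current) ||
      min(fi_app$current) > max(fi_ref$current))
    stop("FI curves cover disjoint current ranges")
  approx(fi_app$current, fi_app$rate, xout = fi_ref$current, rule = 2)$y
}

#' Squared error between two FI curves
#'
#' The approximation curve is linearly interpolated onto the reference
#' current grid; returns the sum of squared rate differences.
#'
#' @param fi_ref,fi_app `fi_curve` data frames.
#' @return non-negative squared error, (spikes/s)^2.
#' @export
fi_sse <- function(fi_ref, fi_app) {
  sum((fi_ref$rate - .on_ref_grid(fi_ref, fi_app))^2)
}

#' Maximum absolute FI error as a percentage of the dynamic range
#'
#' `100 * max|rate_ref - rate_app| / (max(rate_ref) - min(rate_ref))`, the
#' fidelity readout used throughout the route comparison.
#'
#' @param fi_ref,fi_app `fi_curve` data frames.
#' @return percentage of the reference dynamic range.
#' @export
max_error_pct_range <- function(fi_ref, fi_app) {
  rng <- max(fi_ref$rate) - min(fi_ref$rate)
  if (rng <= 0) stop("reference FI curve has zero dynamic range")
  100 * max(abs(fi_ref$rate - .on_ref_grid(fi_ref, fi_app))) / rng
}

#' Memory footprint of a lookup table
#'
#' `n_rows * n_columns * bytes_per_value`; the voltage grid is reconstructed
#' from the offset, not stored.
#'
#' @param table a [build_table()] result.
#' @param precision `"single"` (4 bytes), `"double"` (8) or `"long-double"` (16).
#' @return size in bytes.
#' @export
table_memory <- function(table, precision = c("single", "double", "long-double")) {
  precision <- match.arg(precision)
  bytes <- c(single = 4, double = 8, `long-double` = 16)[[precision]]
  table$n_rows * ncol(table$values) * bytes
}

#' Compare approximation routes against the fully computed model
#'
#' Builds the requested routes, runs the FI ramp for each, and reports the
#' squared error, the maximum-error percentage of the reference dynamic
#' range, the stored-constant count, and (for the table route) the table
#' bytes.
#'
#' @param p a [wbm_params()].
#' @param routes character subset of `c("table", "poly", "pl", "pl2d")`.
#' @param I_min,I_max,duration_s FI ramp settings.
#' @param fi_ref precomputed reference FI curve (computed if `NULL`).
#' @param pl2d an already-constructed `pl2d_model` (constructed if needed).
#' @return a `comparison_report` data frame, one row per route.
#' @export
compare_routes <- function(p = wbm_params(),
                           routes = c("table", "poly", "pl", "pl2d"),
                           I_min = 0, I_max = 1, duration_s = 10,
                           fi_ref = NULL, pl2d = NULL) {
  routes <- match.arg(routes, several.ok = TRUE)
  if (is.null(fi_ref))
    fi_ref <- ramp_fi(wbm_model(p), I_min, I_max, duration_s)
  rows <- lapply(routes, function(r) {
    model <- switch(r,
      table = wbm_table_model(p),
      poly = wbm_poly_model(p),
      pl = wbm_pl_model(p),
      pl2d = if (is.null(pl2d)) pl2d_construct(p, fi_ref = fi_ref) else pl2d)
    fi <- ramp_fi(model, I_min, I_max, duration_s)
    data.frame(reference = "wbm-exact", route = r,
               sse = fi_sse(fi_ref, fi),
               max_abs_pct_range = max_error_pct_range(fi_ref, fi),
               n_params = parameter_count(model),
               table_bytes = if (r == "table")
                 table_memory(model$approx) else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_report", "data.frame")
  out
}
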