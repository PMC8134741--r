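# ---------------------------------------------------------------------------
# Model configs (JSON/YAML), CSV readers/writers with metadata headers
# ---------------------------------------------------------------------------

.known_models <- c("wbm", "wbm-table", "wbm-poly", "wbm-pl", "pl2d",
                   "integrator", "resonator", "izhikevich")

.default_param_names <- function(id) {
  switch(id,
    wbm = , `wbm-table` = , `wbm-poly` = , `wbm-pl` = names(wbm_params()),
    integrator = names(unclass(integrator_params())),
    resonator = names(unclass(resonator_params())),
    izhikevich = names(unclass(izhikevich_model())),
    pl2d = character())
}

#' Load a model from a structured-text config
#'
#' The config (JSON or YAML, by file extension) must contain a `model` key
#' naming one of `wbm`, `wbm-table`, `wbm-poly`, `wbm-pl`, `pl2d`,
#' `integrator`, `resonator`, `izhikevich`, plus an optional `params` block
#' of overrides. Unknown model ids and unknown parameter keys are rejected
#' by name. `pl2d` configs carry the full constant set as written by
#' [save_model()].
#'
#' @param path config file path (`.json`, `.yaml` or `.yml`).
#' @return an instantiated model object.
#' @export
load_model <- function(path) {
  cfg <- .read_config(path)
  if (is.null(cfg$model)) stop("config lacks a 'model' key")
  id <- cfg$model
  if (!id %in% .known_models)
    stop("unknown model id '", id, "' (known: ",
         paste(.known_models, collapse = ", "), ")")
  ov <- cfg$params
  if (length(ov)) {
    legal <- .default_param_names(id)
    bad <- setdiff(names(ov), legal)
    if (length(bad) && id != "pl2d")
      stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  }
  build <- function(ctor) do.call(ctor, ov %||% list())
  switch(id,
    wbm = wbm_model(build(wbm_params)),
    `wbm-table` = wbm_table_model(build(wbm_params)),
    `wbm-poly` = wbm_poly_model(build(wbm_params)),
    `wbm-pl` = wbm_pl_model(build(wbm_params)),
    integrator = pheno_model("integrator", build(integrator_params)),
    resonator = pheno_model("resonator", build(resonator_params)),
    izhikevich = build(izhikevich_model),
    pl2d = {
      q <- cfg$params
      structure(list(I0 = q$I0, a0 = q$a0, v0 = q$v0, v1 = q$v1,
                     lfac_slope = q$lfac_slope, g_K = q$g_K, E_K = q$E_K,
                     tau_v = spec_from_list(q$tau_v),
                     n_inf = spec_from_list(q$n_inf),
                     tau_n = spec_from_list(q$tau_n),
                     reduction = NULL),
                class = c("pl2d_model", "pls_model"))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a model to a structured-text config
#'
#' Writes a config that [load_model()] round-trips. Parameter values are
#' written in full (no rounding).
#'
#' @param model a model object.
#' @param path output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  cfg <- if (inherits(model, "wbm_model")) {
    list(model = switch(model$route, exact = "wbm", table = "wbm-table",
                        poly = "wbm-poly", pl = "wbm-pl"),
         params = unclass(model$params))
  } else if (inherits(model, "pheno_model")) {
    pars <- unclass(model$params)
    if (model$type == "resonator") pars$v1 <- NULL
    list(model = model$type, params = pars)
  } else if (inherits(model, "izhi_model")) {
    list(model = "izhikevich", params = unclass(model))
  } else if (inherits(model, "pl2d_model")) {
    list(model = "pl2d",
         params = list(I0 = model$I0, a0 = model$a0, v0 = model$v0,
                       v1 = model$v1, lfac_slope = model$lfac_slope,
                       g_K = model$g_K, E_K = model$E_K,
                       tau_v = spec_to_list(model$tau_v),
                       n_inf = spec_to_list(model$n_inf),
                       tau_n = spec_to_list(model$tau_n)))
  } else stop("save_model: unsupported model class")
  .write_config(cfg, path)
  invisible(path)
}

.read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("unsupported config extension: .", ext)
}

.write_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else if (ext %in% c("yaml", "yml"))
    yaml::write_yaml(cfg, path, precision = 17)
  else stop("unsupported config extension: .", ext)
}

#' Write a trace or FI curve as CSV with metadata headers
#'
#' Metadata (package version, protocol, time step) is written as
#' `#`-prefixed comment lines above the CSV body, so two runs with the same
#' configuration produce byte-identical files.
#'
#' @param x a `pls_trace` or `fi_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# plsneuro %s", as.character(utils::packageVersion("plsneuro"))),
    sprintf("# protocol: %s", attr(x, "protocol") %||% "unspecified"),
    if (!is.null(attr(x, "dt"))) sprintf("# dt_ms: %g", attr(x, "dt"))),
    con)
  write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_trace_csv()]
#'
#' @param path input path.
#' @return a data frame; metadata lines are attached as the `header` attribute.
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  df <- read.csv(text = lines[!startsWith(lines, "#")])
  attr(df, "header") <- meta
  df
}
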