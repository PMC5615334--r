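## Run configuration: YAML/JSON in, defaults filled, unknown keys rejected.

.config_defaults <- list(
  organ = "lung",
  params_file = NULL,
  course = list(type = "chemo", K_R = 10L, d_R = 2, fractions_per_week = 5L,
                start_day = 0, K_C = 5L, d_C = 12, cycle_length = 30,
                epsilon = 0, interaction_mode = "dose_multiplier"),
  integrator = "discrete",
  evaluation = "plateau",
  rtol = 1e-8,
  atol = 1e-10,
  seed = NULL,
  err_data = NULL,
  rr_data = NULL,
  concurrent_data = NULL,
  fit_epsilon = FALSE,
  forward_only = FALSE,
  output_dir = "iirisk-output")

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration, fills defaults (2 Gy fractions,
#' 30-day cycles, discrete integrator, plateau evaluation) and rejects
#' unknown keys by name.
#'
#' @param path configuration file.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  raw <- .read_structured(path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' @rdname load_config
#' @param x a named list of configuration values.
#' @export
as_run_config <- function(x) {
  unknown <- setdiff(names(x), names(.config_defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(x$course)) {
    bad <- setdiff(names(x$course), names(.config_defaults$course))
    if (length(bad))
      stop("unknown course key(s): ", paste(bad, collapse = ", "))
  }
  cfg <- .config_defaults
  for (k in names(x)) {
    if (is.null(x[[k]])) next  # an explicit null means "use the default"
    cfg[[k]] <- if (k == "course")
      modifyList(.config_defaults$course, x$course) else x[[k]]
  }
  if (!cfg$course$type %in% c("radiation", "chemo", "concurrent"))
    stop("course type must be radiation, chemo or concurrent")
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' Serializes a configuration in canonical key order, so that
#' load-dump-load is the identity.
#'
#' @param config a `run_config`.
#' @param path output file (YAML or JSON by extension).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  .write_structured(unclass(config), path)
  invisible(path)
}

# Course object from the config's course description.
config_course <- function(cfg) {
  cs <- cfg$course
  switch(cs$type,
    radiation = radiation_course(cs$K_R, cs$d_R, cs$fractions_per_week,
                                 cs$start_day),
    chemo = chemo_course(cs$K_C, cs$d_C, cs$cycle_length, cs$start_day),
    concurrent = concurrent_course(
      radiation_course(cs$K_R, cs$d_R, cs$fractions_per_week, cs$start_day),
      chemo_course(cs$K_C, cs$d_C, cs$cycle_length, cs$start_day),
      epsilon = cs$epsilon, interaction_mode = cs$interaction_mode))
}

config_params <- function(cfg) {
  if (!is.null(cfg$params_file)) read_organ_params(cfg$params_file)
  else organ_params(cfg$organ)
}
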