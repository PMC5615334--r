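## Organ-level kinetic and risk parameters.

# Built-in parameter sets for the three organs studied in Hodgkin-lymphoma /
# childhood-cancer survivor cohorts.  Rates shared across organs: lam (normal
# cell proliferation, per day), N (homeostatic cell number), gamma_R
# (radiation mutation induction, per Gy), alpha_C (chemotherapy cell kill,
# per mg/m^2 per cycle) and alpha_d (drug clearance, per day).
.organ_defaults <- list(
  breast  = list(lam = 0.4, r = 0.76, N = 1e6, alpha_R = 0.18, gamma_R = 1e-6,
                 alpha_C = 0.2, gamma_C = 1e-9,   alpha_d = 0.1333, g = 1.2),
  lung    = list(lam = 0.4, r = 0.96, N = 1e6, alpha_R = 0.18, gamma_R = 1e-6,
                 alpha_C = 0.2, gamma_C = 0.5e-6, alpha_d = 0.1333, g = 0.18),
  thyroid = list(lam = 0.4, r = 0.68, N = 1e6, alpha_R = 0.25, gamma_R = 1e-6,
                 alpha_C = 0.2, gamma_C = 0.9e-7, alpha_d = 0.1333, g = 1.0)
)

.organ_param_fields <- c("organ", "lam", "r", "N", "alpha_R", "gamma_R",
                         "alpha_C", "gamma_C", "alpha_d", "g")

#' Organ parameter set
#'
#' Construct the per-organ rate constants of the
#' initiation-inactivation-repopulation model.  Built-in values for
#' `"breast"`, `"lung"` and `"thyroid"` reproduce the published
#' parameterization for Hodgkin-lymphoma and childhood-cancer survivor
#' cohorts; any field can be overridden, and `organ = "custom"` requires all
#' fields to be supplied.
#'
#' @param organ one of `"breast"`, `"lung"`, `"thyroid"` or `"custom"`.
#' @param lam proliferation rate of normal cells, per day.
#' @param r relative growth rate of premalignant cells (dimensionless); the
#'   premalignant proliferation rate is \code{r * lam}.
#' @param N homeostatic (carrying-capacity) cell number.
#' @param alpha_R radiation cell kill, per Gy.
#' @param gamma_R radiation mutation induction, per Gy.
#' @param alpha_C chemotherapy cell kill, per mg/m^2 of cycle dose.
#' @param gamma_C chemotherapy mutation induction, per mg/m^2 of cycle dose.
#' @param alpha_d chemotherapy drug clearance rate, per day.
#' @param g ERR proportionality factor absorbing demographic modifiers
#'   (attained age, exposure age, sex); dimensionless.
#'
#' @return An object of class `organ_params`.
#' @examples
#' organ_params("lung")
#' organ_params("thyroid", alpha_C = 0.3)
#' @export
organ_params <- function(organ = c("breast", "lung", "thyroid", "custom"),
                         lam = NULL, r = NULL, N = NULL, alpha_R = NULL,
                         gamma_R = NULL, alpha_C = NULL, gamma_C = NULL,
                         alpha_d = NULL, g = NULL) {
  organ <- match.arg(organ)
  given <- list(lam = lam, r = r, N = N, alpha_R = alpha_R, gamma_R = gamma_R,
                alpha_C = alpha_C, gamma_C = gamma_C, alpha_d = alpha_d,
                g = g)
  given <- given[!vapply(given, is.null, logical(1))]
  if (organ == "custom") {
    missing <- setdiff(setdiff(.organ_param_fields, "organ"), names(given))
    if (length(missing))
      stop("custom organ requires all fields; missing: ",
           paste(missing, collapse = ", "))
    p <- given
  } else {
    p <- modifyList(.organ_defaults[[organ]], given)
  }
  p <- c(list(organ = organ), p)[.organ_param_fields]
  validate_organ_params(structure(p, class = "organ_params"))
}

#' Validate an organ parameter set
#'
#' Checks positivity constraints and warns when a mutation-induction rate is
#' not small relative to the corresponding cell-kill rate (mutation is a rare
#' outcome of a hit compared with inactivation).
#'
#' @param p an `organ_params` object.
#' @return `p`, invisibly checked.
#' @export
validate_organ_params <- function(p) {
  stopifnot(inherits(p, "organ_params"))
  num <- p[setdiff(.organ_param_fields, "organ")]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad))
    stop("non-numeric or non-finite parameter(s): ",
         paste(bad, collapse = ", "))
  if (p$lam <= 0) stop("lam must be > 0")
  if (p$N <= 0) stop("N must be > 0")
  if (p$r <= 0) stop("r must be > 0")
  nonneg <- c("alpha_R", "alpha_C", "alpha_d", "g", "gamma_R", "gamma_C")
  for (f in nonneg)
    if (p[[f]] < 0) stop(f, " must be >= 0")
  if (p$gamma_R >= p$alpha_R && p$alpha_R > 0)
    warning("gamma_R is not small relative to alpha_R; ",
            "mutation should be rare relative to cell kill")
  if (p$gamma_C > p$alpha_C && p$alpha_C > 0)
    warning("gamma_C exceeds alpha_C; ",
            "mutation should be rare relative to cell kill")
  p
}

#' @export
print.organ_params <- function(x, ...) {
  cat("Organ parameters (", x$organ, ")\n", sep = "")
  cat(sprintf("  lam = %g /day, r = %g, N = %g\n", x$lam, x$r, x$N))
  cat(sprintf("  radiotherapy: alpha_R = %g /Gy, gamma_R = %g /Gy\n",
              x$alpha_R, x$gamma_R))
  cat(sprintf("  chemotherapy: alpha_C = %g, gamma_C = %g per mg/m^2, alpha_d = %g /day\n",
              x$alpha_C, x$gamma_C, x$alpha_d))
  cat(sprintf("  ERR factor g = %g\n", x$g))
  invisible(x)
}

#' Read or write organ parameters
#'
#' Serialize an `organ_params` object to YAML or JSON (chosen by file
#' extension) with keys exactly matching the field names, or read one back.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param p an `organ_params` object (for writing).
#' @return `read_organ_params()` returns an `organ_params` object.
#' @export
read_organ_params <- function(path) {
  raw <- .read_structured(path)
  unknown <- setdiff(names(raw), .organ_param_fields)
  if (length(unknown))
    stop("unknown organ parameter key(s): ", paste(unknown, collapse = ", "))
  organ <- raw$organ %||% "custom"
  raw$organ <- NULL
  do.call(organ_params, c(list(organ = organ), raw))
}

#' @rdname read_organ_params
#' @export
write_organ_params <- function(p, path) {
  stopifnot(inherits(p, "organ_params"))
  .write_structured(unclass(p), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported extension: .", ext, " (use yaml or json)"))
}

.write_structured <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported extension: .", ext, " (use yaml or json)"))
  invisible(path)
}
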