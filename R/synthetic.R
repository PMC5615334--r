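## Synthetic cohort-style summary datasets with known ground truth, for
## parameter-recovery studies of the fitting pipeline.

#' Specification of a synthetic summary dataset
#'
#' Describes how to generate cohort-style ERR(dose) or RR(cycles) summaries:
#' the true organ parameters, the design points, and the noise model.  Noise
#' is multiplicative lognormal on the *excess* risk with a stated coefficient
#' of variation, `sigma = sqrt(log(1 + cv^2))` and median 1, so an RR
#' observation can fall below 1 (as unexposed-comparable cohorts do) but the
#' RR = 1 floor of the model itself is respected in expectation.
#'
#' @param params true [organ_params()].
#' @param design numeric vector of design points (total doses in Gy, or cycle
#'   counts).
#' @param noise `"none"` or `"lognormal_cv"`.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param n_replicates observations generated per design point.
#' @param seed RNG seed; mandatory when `noise != "none"`.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(params, design, noise = c("none", "lognormal_cv"),
                           cv = 0.3, n_replicates = 1, seed = NULL) {
  stopifnot(inherits(params, "organ_params"), is.numeric(design),
            cv >= 0, n_replicates >= 1)
  noise <- match.arg(noise)
  if (noise != "none" && is.null(seed))
    stop("seed is mandatory when noise is not 'none'")
  structure(list(params = params, design = design, noise = noise, cv = cv,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "synthetic_spec")
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.apply_excess_noise <- function(excess, spec) {
  if (spec$noise == "none") return(excess)
  sigma <- sqrt(log(1 + spec$cv^2))
  excess * exp(rnorm(length(excess), mean = 0, sd = sigma))
}

#' Generate a synthetic ERR-vs-dose dataset
#'
#' Evaluates the radiotherapy-only dose response at the design doses under
#' the true parameters and applies the noise model of the [synthetic_spec()],
#' `ERR_obs = ERR_model * LogNormal(0, sigma)`.  The noise-free model curve
#' and the true parameters are attached as the `truth` attribute (and can be
#' written to a sidecar JSON by [write_synthetic_dataset()]) so tests never
#' re-derive them.
#'
#' @param spec a [synthetic_spec()] whose `design` is total doses in Gy.
#' @param d_R,fractions_per_week fractionation rule.
#' @return A data frame with columns `dose`, `err`, `replicate`; attribute
#'   `truth` holds the generating parameters and model curve.
#' @export
generate_err_dataset <- function(spec, d_R = 2, fractions_per_week = 5) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!length(spec$design)) {
    d <- data.frame(dose = numeric(0), err = numeric(0),
                    replicate = integer(0))
    attr(d, "truth") <- list(params = unclass(spec$params),
                             model = data.frame(dose = numeric(0),
                                                err = numeric(0)))
    return(d)
  }
  curve <- dose_response_curve(spec$params, spec$design, d_R = d_R,
                               fractions_per_week = fractions_per_week)
  d <- with_local_seed(spec$seed, {
    rows <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(rep) {
      data.frame(dose = curve$dose,
                 err = .apply_excess_noise(curve$err, spec),
                 replicate = rep)
    }))
    rows
  })
  attr(d, "truth") <- list(params = unclass(spec$params),
                           noise = spec$noise, cv = spec$cv,
                           seed = spec$seed,
                           model = curve[, c("dose", "err")])
  d
}

#' Generate a synthetic RR-vs-cycles dataset
#'
#' As [generate_err_dataset()], for the chemotherapy-only (or concurrent)
#' model: `RR_obs = 1 + (RR_model - 1) * LogNormal(0, sigma)`.  The excess
#' risk carries the noise, so observed RR values are positive but are not
#' forced above 1.
#'
#' @param spec a [synthetic_spec()] whose `design` is cycle counts.
#' @param course_template function mapping a cycle count to a course object.
#' @return A data frame with columns `cycles`, `rr`, `replicate`; attribute
#'   `truth` as in [generate_err_dataset()].
#' @export
generate_rr_dataset <- function(spec,
                                course_template = function(K)
                                  chemo_course(K_C = K)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!length(spec$design)) {
    d <- data.frame(cycles = numeric(0), rr = numeric(0),
                    replicate = integer(0))
    attr(d, "truth") <- list(params = unclass(spec$params),
                             model = data.frame(cycles = numeric(0),
                                                rr = numeric(0)))
    return(d)
  }
  rr_model <- vapply(spec$design, function(K)
    relative_risk(spec$params, course_template(K)), numeric(1))
  model <- data.frame(cycles = spec$design, rr = rr_model)
  d <- with_local_seed(spec$seed, {
    do.call(rbind, lapply(seq_len(spec$n_replicates), function(rep) {
      data.frame(cycles = spec$design,
                 rr = 1 + .apply_excess_noise(rr_model - 1, spec),
                 replicate = rep)
    }))
  })
  attr(d, "truth") <- list(params = unclass(spec$params),
                           noise = spec$noise, cv = spec$cv,
                           seed = spec$seed, model = model)
  d
}

#' Write a synthetic dataset with its truth sidecar
#'
#' Writes the dataset as CSV (the schema the fitting module reads) and the
#' `truth` attribute as `<path>.truth.json`.
#'
#' @param data output of [generate_err_dataset()] or [generate_rr_dataset()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic_dataset <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  truth <- attr(data, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
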