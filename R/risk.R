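## Excess relative risk and relative risk from a simulated trajectory.

#' Risk estimate from a trajectory
#'
#' Maps the premalignant cell count produced by a simulated course to excess
#' relative risk, `ERR = g * M`, and relative risk, `RR = 1 + ERR`.
#'
#' By default `M` is evaluated at the post-treatment regrowth plateau: after
#' the last treatment event both compartments follow pure logistic
#' repopulation, along which `d log m = r d log n`, so the plateau value is
#' available in closed form as `M = m_end * (N / n_end)^r`.  Premalignant
#' repopulation continues past the end of treatment while the normal
#' compartment refills, and the published risk tables are only reached with
#' this regrowth included.  `evaluation = "treatment_end"` instead takes `m`
#' at the last treatment event.
#'
#' @param params an [organ_params()] object.
#' @param trajectory a `trajectory` from [simulate_course()]; must cover the
#'   full course.
#' @param evaluation `"plateau"` (default) or `"treatment_end"`.
#' @return A `risk_estimate` with fields `ERR`, `RR`, `M`, `organ`, `course`
#'   and `evaluation`.
#' @examples
#' p <- organ_params("thyroid")
#' risk(p, simulate_course(p, chemo_course(K_C = 5)))
#' @export
risk <- function(params, trajectory,
                 evaluation = c("plateau", "treatment_end")) {
  stopifnot(inherits(params, "organ_params"),
            inherits(trajectory, "trajectory"))
  evaluation <- match.arg(evaluation)
  te <- attr(trajectory, "treatment_end")
  if (max(trajectory$t) < te)
    stop("trajectory does not cover the full course")
  if (evaluation == "treatment_end") {
    i <- which(trajectory$t >= te)[1]
    M <- trajectory$m[i]
  } else {
    last <- trajectory[nrow(trajectory), ]
    if (last$n <= 0) stop("normal compartment extinct; no regrowth plateau")
    # invariant along the untreated logistic flow, so the final recorded row
    # gives the same plateau as the treatment-end row
    M <- last$m * (params$N / last$n)^params$r
  }
  err <- params$g * M
  structure(list(ERR = err, RR = 1 + err, M = M, organ = params$organ,
                 course = course_label(attr(trajectory, "course")),
                 evaluation = evaluation),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("Risk estimate (%s; %s)\n", x$organ, x$course))
  cat(sprintf("  M = %.4g premalignant cells (%s)\n", x$M, x$evaluation))
  cat(sprintf("  ERR = %.4g, RR = %.4g\n", x$ERR, x$RR))
  invisible(x)
}

#' Relative risk of a course
#'
#' Convenience wrapper: simulate a course and return the relative risk.
#'
#' @inheritParams simulate_course
#' @param evaluation passed to [risk()].
#' @param ... further arguments to [simulate_course()].
#' @return The relative risk `RR = 1 + g * M` (a number).
#' @examples
#' relative_risk(organ_params("lung"), chemo_course(K_C = 6))
#' @export
relative_risk <- function(params, course, evaluation = "plateau", ...) {
  risk(params, simulate_course(params, course, ...),
       evaluation = evaluation)$RR
}

#' Excess relative risk as a function of total dose
#'
#' Evaluates the radiotherapy-only dose-response curve.  Each total dose is
#' delivered as a whole number of fractions, `K = round(D / d_R)` (ties
#' rounded to even), at `d_R` Gy per fraction.  For thyroid parameters the
#' curve is bell-shaped (cell kill eventually outweighs initiation and
#' repopulation), whereas for breast and lung it keeps rising over the
#' clinical dose range.
#'
#' @param params an [organ_params()] object.
#' @param doses vector of total doses, Gy.
#' @param d_R dose per fraction, Gy.
#' @param fractions_per_week fractions per week (5 = weekday schedule).
#' @param evaluation passed to [risk()].
#' @param ... further arguments to [simulate_course()].
#' @return A data frame with columns `dose`, `fractions`, `err`.
#' @examples
#' dose_response_curve(organ_params("thyroid"), seq(0, 40, by = 4))
#' @export
dose_response_curve <- function(params, doses, d_R = 2,
                                fractions_per_week = 5,
                                evaluation = "plateau", ...) {
  stopifnot(all(doses >= 0))
  K <- round(doses / d_R)
  err <- vapply(K, function(k) {
    if (k == 0) return(0)
    course <- radiation_course(K_R = k, d_R = d_R,
                               fractions_per_week = fractions_per_week)
    risk(params, simulate_course(params, course, ...),
         evaluation = evaluation)$ERR
  }, numeric(1))
  data.frame(dose = doses, fractions = K, err = err)
}
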