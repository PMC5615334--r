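## Treatment course descriptions.

#' Radiotherapy course
#'
#' A fractionated external-beam course: `K_R` fractions of `d_R` Gy delivered
#' `fractions_per_week` days per week (weekends are skipped when
#' `fractions_per_week = 5`; day 0 is a Monday by convention, and `start_day`
#' shifts the weekday phase).
#'
#' @param K_R number of fractions (non-negative integer).
#' @param d_R dose per fraction, Gy.
#' @param fractions_per_week fractions delivered per 7-day week (1-7);
#'   5 gives the clinical Monday-Friday pattern.
#' @param start_day day offset of the first candidate treatment day.
#' @param tau pulse duration in minutes (used by the continuous integrator;
#'   the dose rate during a pulse is `d_R / tau`).
#' @return An object of class `radiation_course`.
#' @examples
#' radiation_course(K_R = 20)            # 40 Gy in 2 Gy weekday fractions
#' @export
radiation_course <- function(K_R, d_R = 2, fractions_per_week = 5,
                             start_day = 0, tau = 1) {
  stopifnot(length(K_R) == 1, K_R >= 0, K_R == round(K_R),
            length(d_R) == 1, d_R >= 0,
            fractions_per_week %in% 1:7,
            length(start_day) == 1, start_day >= 0,
            length(tau) == 1, tau > 0)
  structure(list(K_R = as.integer(K_R), d_R = d_R,
                 fractions_per_week = as.integer(fractions_per_week),
                 start_day = start_day, tau = tau),
            class = "radiation_course")
}

#' Chemotherapy course
#'
#' A cyclic chemotherapy course: `K_C` cycles of `d_C` mg/m^2 (mechlorethamine
#' dose-equivalent per cycle), one cycle every `cycle_length` days.  Within a
#' cycle the drug's cytotoxic effect decays exponentially at the organ's
#' clearance rate `alpha_d`.
#'
#' @param K_C number of cycles (non-negative integer).
#' @param d_C dose per cycle, mg/m^2.
#' @param cycle_length days per cycle.
#' @param start_day day offset of the first cycle.
#' @return An object of class `chemo_course`.
#' @examples
#' chemo_course(K_C = 6)                 # six 30-day MOPP-equivalent cycles
#' @export
chemo_course <- function(K_C, d_C = 12, cycle_length = 30, start_day = 0) {
  stopifnot(length(K_C) == 1, K_C >= 0, K_C == round(K_C),
            length(d_C) == 1, d_C >= 0,
            length(cycle_length) == 1, cycle_length > 0,
            length(start_day) == 1, start_day >= 0)
  structure(list(K_C = as.integer(K_C), d_C = d_C,
                 cycle_length = cycle_length, start_day = start_day),
            class = "chemo_course")
}

#' Concurrent chemo-radiation course
#'
#' Combines a radiotherapy and a chemotherapy course.  Radiotherapy starts
#' with the first chemotherapy cycle (the radiation `start_day` is aligned to
#' the chemo `start_day`).  The interaction term quantifies
#' radio-sensitization by the drug and is active only on days when a
#' radiation fraction is delivered while a chemotherapy cycle is ongoing.
#'
#' Two interaction parameterizations are supported:
#' \describe{
#'   \item{`dose_multiplier`}{(default, the calibrated mode) `epsilon`
#'     multiplies the radiation dose in the cell-kill exponent only; the
#'     mutation-induction term keeps the physical dose.  `epsilon = 0` turns
#'     the interaction off (equivalent to a multiplier of 1).}
#'   \item{`extra_kill_rate`}{each fraction delivered during an active cycle
#'     applies an additional kill impulse `exp(-epsilon)` to both
#'     compartments; `epsilon = 0` is the additive (no-interaction) limit.}
#' }
#'
#' @param radiation a [radiation_course()].
#' @param chemo a [chemo_course()].
#' @param epsilon interaction strength (dimensionless, `>= 0`); 0 disables
#'   the interaction in either mode.
#' @param interaction_mode `"dose_multiplier"` or `"extra_kill_rate"`.
#' @return An object of class `concurrent_course`.
#' @examples
#' concurrent_course(radiation_course(10), chemo_course(5), epsilon = 2.6)
#' @export
concurrent_course <- function(radiation, chemo, epsilon = 0,
                              interaction_mode = c("dose_multiplier",
                                                   "extra_kill_rate")) {
  stopifnot(inherits(radiation, "radiation_course"),
            inherits(chemo, "chemo_course"),
            length(epsilon) == 1, epsilon >= 0)
  interaction_mode <- match.arg(interaction_mode)
  radiation$start_day <- chemo$start_day
  rt_span <- if (radiation$K_R > 0) {
    days <- rt_fraction_days(radiation)
    max(days) - chemo$start_day + 1
  } else 0
  chemo_span <- chemo$K_C * chemo$cycle_length
  if (radiation$K_R > 0 && chemo$K_C > 0 && rt_span > chemo_span)
    warning("radiotherapy course extends past the last chemotherapy cycle")
  structure(list(radiation = radiation, chemo = chemo, epsilon = epsilon,
                 interaction_mode = interaction_mode),
            class = "concurrent_course")
}

#' @export
print.radiation_course <- function(x, ...) {
  cat(sprintf("Radiotherapy: %d x %g Gy, %d fx/week, start day %g (tau %g min)\n",
              x$K_R, x$d_R, x$fractions_per_week, x$start_day, x$tau))
  invisible(x)
}

#' @export
print.chemo_course <- function(x, ...) {
  cat(sprintf("Chemotherapy: %d cycles x %g mg/m^2, every %g days, start day %g\n",
              x$K_C, x$d_C, x$cycle_length, x$start_day))
  invisible(x)
}

#' @export
print.concurrent_course <- function(x, ...) {
  cat("Concurrent course\n  ")
  print(x$radiation)
  cat("  ")
  print(x$chemo)
  cat(sprintf("  interaction: epsilon = %g (%s)\n", x$epsilon,
              x$interaction_mode))
  invisible(x)
}

# Short human-readable label used in risk estimates and reports.
course_label <- function(course) {
  if (inherits(course, "radiation_course"))
    sprintf("RT %d x %g Gy", course$K_R, course$d_R)
  else if (inherits(course, "chemo_course"))
    sprintf("CT %d x %g mg/m^2", course$K_C, course$d_C)
  else if (inherits(course, "concurrent_course"))
    sprintf("%s + %s, eps = %g (%s)", course_label(course$radiation),
            course_label(course$chemo), course$epsilon,
            course$interaction_mode)
  else stop("not a course object")
}
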