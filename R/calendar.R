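## Treatment calendars: pure functions of the course description.
## Day 0 is a Monday; weekday index is day %% 7 (0 = Monday .. 6 = Sunday).

# Days on which radiotherapy fractions are delivered.
rt_fraction_days <- function(course) {
  stopifnot(inherits(course, "radiation_course"))
  K <- course$K_R
  if (K == 0) return(numeric(0))
  fpw <- course$fractions_per_week
  weeks <- ceiling(K / fpw) + 1
  cand <- course$start_day + 0:(7 * weeks)
  cand <- cand[cand %% 7 < fpw]
  cand[seq_len(K)]
}

# Days on which chemotherapy cycles start.
chemo_cycle_days <- function(course) {
  stopifnot(inherits(course, "chemo_course"))
  if (course$K_C == 0) return(numeric(0))
  course$start_day + (seq_len(course$K_C) - 1) * course$cycle_length
}

#' Build a treatment event calendar
#'
#' Expands a course description into an ordered calendar of treatment events.
#' Radiotherapy fractions follow the weekday pattern (no fractions on
#' weekends when `fractions_per_week = 5`; day 0 is a Monday).  Chemotherapy
#' cycles start every `cycle_length` days.  For a concurrent course the two
#' sub-calendars are merged, with radiotherapy starting at the first
#' chemotherapy cycle.
#'
#' @param course a [radiation_course()], [chemo_course()] or
#'   [concurrent_course()].
#' @return An `event_calendar`: a data frame with columns `t` (day), `kind`
#'   (`"rt_fraction"` or `"chemo_cycle_start"`) and `magnitude` (Gy per
#'   fraction or mg/m^2 per cycle), sorted by `t`.
#' @examples
#' build_calendar(radiation_course(K_R = 20))   # spans 26 calendar days
#' @export
build_calendar <- function(course) UseMethod("build_calendar")

#' @export
build_calendar.radiation_course <- function(course) {
  days <- rt_fraction_days(course)
  new_event_calendar(data.frame(
    t = days,
    kind = rep("rt_fraction", length(days)),
    magnitude = rep(course$d_R, length(days)),
    stringsAsFactors = FALSE))
}

#' @export
build_calendar.chemo_course <- function(course) {
  days <- chemo_cycle_days(course)
  new_event_calendar(data.frame(
    t = days,
    kind = rep("chemo_cycle_start", length(days)),
    magnitude = rep(course$d_C, length(days)),
    stringsAsFactors = FALSE))
}

#' @export
build_calendar.concurrent_course <- function(course) {
  cal <- rbind(build_calendar.radiation_course(course$radiation),
               build_calendar.chemo_course(course$chemo))
  new_event_calendar(cal)
}

new_event_calendar <- function(df) {
  df <- df[order(df$t, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  rt <- df$t[df$kind == "rt_fraction"]
  if (anyDuplicated(rt)) stop("two radiotherapy fractions on the same day")
  structure(df, class = c("event_calendar", "data.frame"))
}

#' Write a calendar to CSV
#'
#' @param cal an `event_calendar`.
#' @param path output file.
#' @export
write_calendar <- function(cal, path) {
  stopifnot(inherits(cal, "event_calendar"))
  write.csv(as.data.frame(cal), path, row.names = FALSE)
  invisible(path)
}

# TRUE if a chemotherapy cycle is ongoing at time t.
chemo_active_at <- function(t, chemo) {
  if (!inherits(chemo, "chemo_course") || chemo$K_C == 0) return(FALSE)
  starts <- chemo_cycle_days(chemo)
  any(t >= starts & t < starts + chemo$cycle_length)
}
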