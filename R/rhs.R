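## Right-hand sides of the two-compartment model, in the continuous
## (finite-pulse) representation used by the deSolve cross-check integrator.
##
## State: (n, m) = (normal cells, premalignant cells).
## Off-pulse both compartments follow logistic repopulation coupled through
## the normal-cell occupancy:
##   dn/dt = lam * n * (1 - n/N)
##   dm/dt = r * lam * m * (1 - n/N)
## During a radiotherapy pulse of width tau (minutes) the dose rate is
## d_R/tau, adding cell kill alpha_R*(d_R/tau) to both compartments and a
## mutation flux gamma_R*(d_R/tau)*n that leaves n and enters m.  During a
## chemotherapy cycle the per-cycle coefficients are spread over the cycle as
## daily rates: kill (alpha_C*d_C/L)*exp(-alpha_d*(t - t_i)) with the decay
## clock reset at each cycle start t_i, and a constant mutation flux
## (gamma_C*d_C/L)*n.

.check_state <- function(state) {
  if (any(!is.finite(state))) stop("non-finite state components")
  if (any(state < 0)) stop("negative state components")
  invisible(state)
}

# Radiotherapy pulse rates at time t: list(kill, mut) in per-day units,
# optionally enhanced by a concurrent interaction.
.rt_rates <- function(t, course, params, chemo = NULL, epsilon = 0,
                      interaction_mode = "dose_multiplier") {
  days <- rt_fraction_days(course)
  tau_d <- course$tau / (24 * 60)
  on <- any(t >= days & t < days + tau_d)
  if (!on) return(list(kill = 0, mut = 0, extra = 0))
  interacting <- epsilon > 0 && !is.null(chemo) && chemo_active_at(t, chemo)
  d_kill <- course$d_R
  extra <- 0
  if (interacting) {
    if (interaction_mode == "dose_multiplier") d_kill <- epsilon * course$d_R
    else extra <- epsilon / tau_d
  }
  list(kill = params$alpha_R * d_kill / tau_d,
       mut = params$gamma_R * course$d_R / tau_d,
       extra = extra)
}

# Chemotherapy rates at time t: list(kill, mut) in per-day units.
.chemo_rates <- function(t, course, params) {
  if (course$K_C == 0) return(list(kill = 0, mut = 0))
  starts <- chemo_cycle_days(course)
  L <- course$cycle_length
  s <- t - starts
  act <- s >= 0 & s < L
  if (!any(act)) return(list(kill = 0, mut = 0))
  list(kill = sum(params$alpha_C * course$d_C / L *
                    exp(-params$alpha_d * s[act])),
       mut = sum(rep(params$gamma_C * course$d_C / L, sum(act))))
}

.logistic_terms <- function(state, params) {
  gro <- 1 - state[1] / params$N
  c(params$lam * state[1] * gro, params$r * params$lam * state[2] * gro)
}

#' Model right-hand sides (continuous pulse representation)
#'
#' Time derivatives `(dn/dt, dm/dt)` of the two-compartment
#' initiation-inactivation-repopulation system for a radiotherapy-only,
#' chemotherapy-only, or concurrent course.  These functions use the
#' continuous finite-pulse representation (radiation delivered at dose rate
#' `d_R/tau` over `tau` minutes) and have the `(t, state, ...)` signature
#' expected by [deSolve::ode()].  The event-driven impulse integrator used by
#' [simulate_course()] is their `tau -> 0` limit.
#'
#' @param t time, days.
#' @param state numeric vector `c(n, m)`; must be non-negative.
#' @param params an [organ_params()] object.
#' @param course the matching course object.
#' @return A list whose first element is `c(dn, dm)`.
#' @examples
#' p <- organ_params("breast")
#' rt_rhs(10, c(p$N, 0), p, radiation_course(20))  # off-pulse: c(0, 0)
#' @export
rt_rhs <- function(t, state, params, course) {
  .check_state(state)
  stopifnot(inherits(course, "radiation_course"))
  g <- .logistic_terms(state, params)
  rr <- .rt_rates(t, course, params)
  list(c(g[1] - (rr$kill + rr$mut) * state[1],
         g[2] - rr$kill * state[2] + rr$mut * state[1]))
}

#' @rdname rt_rhs
#' @export
chemo_rhs <- function(t, state, params, course) {
  .check_state(state)
  stopifnot(inherits(course, "chemo_course"))
  g <- .logistic_terms(state, params)
  cr <- .chemo_rates(t, course, params)
  list(c(g[1] - (cr$kill + cr$mut) * state[1],
         g[2] - cr$kill * state[2] + cr$mut * state[1]))
}

#' @rdname rt_rhs
#' @export
concurrent_rhs <- function(t, state, params, course) {
  .check_state(state)
  stopifnot(inherits(course, "concurrent_course"))
  g <- .logistic_terms(state, params)
  rr <- .rt_rates(t, course$radiation, params, chemo = course$chemo,
                  epsilon = course$epsilon,
                  interaction_mode = course$interaction_mode)
  cr <- .chemo_rates(t, course$chemo, params)
  kill_n <- rr$kill + rr$extra + cr$kill
  kill_m <- rr$kill + rr$extra + cr$kill
  mut <- rr$mut + cr$mut
  list(c(g[1] - (kill_n + mut) * state[1],
         g[2] - kill_m * state[2] + mut * state[1]))
}
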