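# Core dynamics: logistic repopulation, the radiotherapy impulse map, the
# chemotherapy forcing, and agreement between the two integrators.

test_that("homeostasis is a fixed point of the untreated system", {
  p <- organ_params("lung")
  tr <- simulate_course(p, radiation_course(K_R = 0), t_end = 200)
  expect_equal(final_m(tr), 0)
  expect_equal(tr$n[nrow(tr)], p$N, tolerance = 1e-10)
  # the RHS vanishes exactly at (N, 0)
  d <- rt_rhs(10, c(p$N, 0), p, radiation_course(K_R = 0))[[1]]
  expect_equal(d, c(0, 0))
})

test_that("untreated normal cells follow the logistic closed form", {
  p <- tiny_params()
  n0 <- p$N / 2
  tr <- simulate_course(p, radiation_course(K_R = 0), t_end = 5,
                        initial = c(n0, 0), record_dt = 1)
  expect_equal(tr$t, 0:5)
  expected <- p$N * n0 * exp(p$lam * tr$t) /
    (p$N + n0 * (exp(p$lam * tr$t) - 1))
  expect_equal(tr$n, expected, tolerance = 1e-7)
  # and n -> N from below without overshoot
  long <- simulate_course(p, radiation_course(K_R = 0), t_end = 100,
                          initial = c(n0, 0))
  expect_lt(abs(long$n[nrow(long)] - p$N), 1)
  expect_true(all(diff(tr$n) > 0))
})

test_that("premalignant regrowth obeys the logistic power-law invariant", {
  # untreated flow: d log m = r d log n, so m(t) = m0 * (n(t)/n0)^r
  p <- tiny_params()
  n0 <- 0.3 * p$N
  m0 <- 5
  tr <- simulate_course(p, radiation_course(K_R = 0), t_end = 30,
                        initial = c(n0, m0), record_dt = 5)
  expect_equal(tr$m, m0 * (tr$n / n0)^p$r, tolerance = 1e-7)
})

test_that("a single fraction applies the exact impulse map", {
  p <- organ_params("lung")
  d_R <- 2
  tr <- simulate_course(p, radiation_course(K_R = 1, d_R = d_R))
  post <- tr[which(tr$event == "rt_fraction")[1], ]
  expect_equal(post$t, 0)
  expect_equal(post$n,
               p$N * exp(-(p$alpha_R * d_R + p$gamma_R * d_R)))
  # newly created premalignant cells also see the pulse's own cell kill
  expect_equal(post$m,
               p$gamma_R * d_R * p$N * exp(-p$alpha_R * d_R))
})

test_that("the impulse map is the small-pulse limit of the continuous model", {
  p <- organ_params("thyroid")
  course1 <- radiation_course(K_R = 3, tau = 10)
  course2 <- radiation_course(K_R = 3, tau = 0.1)
  m_disc <- final_m(simulate_course(p, course1, t_end = 10))
  m_10 <- final_m(simulate_course(p, course1, t_end = 10,
                                  integrator = "continuous"))
  m_01 <- final_m(simulate_course(p, course2, t_end = 10,
                                  integrator = "continuous"))
  # error shrinks with pulse width and is already tiny at 6-minute pulses
  expect_lt(abs(m_01 - m_disc) / m_disc, abs(m_10 - m_disc) / m_disc + 1e-12)
  expect_lt(abs(m_10 - m_disc) / m_disc, 1e-3)
})

test_that("chemotherapy kill decays at the clearance rate within a cycle", {
  p <- organ_params("lung")
  course <- chemo_course(K_C = 2)
  k0 <- p$alpha_C * course$d_C / course$cycle_length
  r0 <- iirisk:::.chemo_rates(0, course, p)
  r1 <- iirisk:::.chemo_rates(1 / p$alpha_d, course, p)
  expect_equal(r0$kill, k0)
  expect_equal(r1$kill / r0$kill, exp(-1))
  # decay clock resets at the second cycle start
  r30 <- iirisk:::.chemo_rates(30, course, p)
  expect_equal(r30$kill, k0)
  # mutation flux is constant within the cycle and stops after the last one
  expect_equal(r1$mut, r0$mut)
  expect_equal(iirisk:::.chemo_rates(61, course, p)$kill, 0)
})

test_that("mutation bookkeeping conserves cells at the impulse", {
  # cells leaving n by mutation arrive in m before the pulse kill acts
  p <- organ_params("breast")
  tr <- simulate_course(p, radiation_course(K_R = 1))
  pre <- tr[1, ]
  post <- tr[2, ]
  mutated <- p$gamma_R * 2 * pre$n
  expect_equal(post$m / exp(-p$alpha_R * 2), mutated, tolerance = 1e-9)
  expect_lt(post$n + post$m, pre$n + pre$m) # the pulse only removes cells
})

test_that("discrete and continuous integrators agree for all organs", {
  for (org in c("breast", "lung", "thyroid")) {
    p <- organ_params(org)
    course <- concurrent_course(radiation_course(K_R = 10),
                                chemo_course(K_C = 3), epsilon = 2.6)
    m_d <- final_m(simulate_course(p, course))
    m_c <- final_m(simulate_course(p, course, integrator = "continuous"))
    expect_lt(abs(m_c - m_d) / m_d, 0.005)
  }
})

test_that("risk increases monotonically with the mutation rates", {
  p <- organ_params("thyroid")
  course <- chemo_course(K_C = 5)
  rr <- vapply(c(0.5, 1, 2) * p$gamma_C, function(gc)
    relative_risk(organ_params("thyroid", gamma_C = gc), course), numeric(1))
  expect_true(all(diff(rr) > 0))
  rcourse <- radiation_course(K_R = 10)
  err <- vapply(c(0.5, 1, 2) * 1e-6, function(gr)
    relative_risk(organ_params("thyroid", gamma_R = gr), rcourse),
    numeric(1))
  expect_true(all(diff(err) > 0))
})

test_that("concurrent model reduces to single modalities in the limits", {
  p <- organ_params("lung")
  rt <- radiation_course(K_R = 10)
  ct <- chemo_course(K_C = 4)
  # no chemo cycles: concurrent == radiotherapy-only
  m_rt <- final_m(simulate_course(p, rt, t_end = 150))
  m_cc <- final_m(simulate_course(
    p, concurrent_course(rt, chemo_course(K_C = 0)), t_end = 150))
  expect_equal(m_cc, m_rt, tolerance = 1e-10)
  # no fractions: concurrent == chemotherapy-only
  m_ct <- final_m(simulate_course(p, ct))
  m_cc2 <- final_m(suppressWarnings(simulate_course(
    p, concurrent_course(radiation_course(K_R = 0), ct))))
  expect_equal(m_cc2, m_ct, tolerance = 1e-10)
  # epsilon = 0 equals an unset interaction
  c0 <- concurrent_course(rt, ct, epsilon = 0)
  c_off <- concurrent_course(rt, ct)
  expect_equal(final_m(simulate_course(p, c0)),
               final_m(simulate_course(p, c_off)))
})

test_that("interaction modes share the additive baseline and differ when on", {
  p <- organ_params("thyroid")
  rt <- radiation_course(K_R = 10)
  ct <- chemo_course(K_C = 5)
  base <- relative_risk(p, concurrent_course(rt, ct))
  dm <- relative_risk(
    p, concurrent_course(rt, ct, epsilon = 0, "extra_kill_rate"))
  expect_equal(dm, base, tolerance = 1e-12)
  on1 <- relative_risk(
    p, concurrent_course(rt, ct, epsilon = 2.6, "dose_multiplier"))
  on2 <- relative_risk(
    p, concurrent_course(rt, ct, epsilon = 2.6, "extra_kill_rate"))
  expect_lt(on1, base)  # extra kill during active cycles lowers the risk
  expect_lt(on2, base)
  expect_false(isTRUE(all.equal(on1, on2)))
})

test_that("invalid states and times raise errors", {
  p <- organ_params("lung")
  expect_error(simulate_course(p, chemo_course(K_C = 2), t_end = 10),
               "earlier than the last treatment event")
  expect_error(simulate_course(p, chemo_course(K_C = 2),
                               initial = c(-1, 0)), "non-negative")
  expect_error(simulate_course(p, chemo_course(K_C = 2),
                               initial = c(NA, 0)), "non-negative")
  expect_error(simulate_course(p, chemo_course(K_C = 2),
                               initial = c(2e6, 0)), "homeostatic")
  expect_error(rt_rhs(0, c(-1, 0), p, radiation_course(1)), "negative")
})

test_that("the C++ segment integrator reports failures", {
  expect_error(
    iirisk:::.iir_segment(c(1e6, 0), c(0, 1), 0.4, 0.8, 1e6,
                          0, 30, NaN, 0, 0.1, 1e-8, 1e-10),
    "integration failure")
})
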