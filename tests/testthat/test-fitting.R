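# Deterministic least-squares parameter extraction.

test_that("data validators enforce schema and bounds", {
  expect_error(validate_err_data(data.frame(dose = 1)), "err")
  expect_error(validate_err_data(data.frame(dose = -1, err = 0.5)), ">= 0")
  expect_error(validate_rr_data(data.frame(rr = 2)), "cycles")
  expect_error(validate_rr_data(data.frame(cycles = 3, rr = 0)), "> 0")
  expect_error(
    validate_rr_data(data.frame(cycles = 3, rr = 2, ci_low = 3, ci_high = 4)),
    "bracket")
  ok <- validate_rr_data(data.frame(cycles = 3, rr = 2, ci_low = 1,
                                    ci_high = 4))
  expect_equal(ok$rr, 2)
})

test_that("CSV readers accept a generic value column", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(cycles = c(3, 6), value = c(4, 6)), f,
            row.names = FALSE)
  d <- read_rr_data(f)
  expect_equal(d$rr, c(4, 6))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(dose = c(10, 20), value = c(2, 4)), f2,
            row.names = FALSE)
  expect_equal(read_err_data(f2)$err, c(2, 4))
})

test_that("noise-free recovery of the relative growth rate", {
  for (truth in c(0.68, 0.96)) {
    p <- organ_params("thyroid", r = truth)
    spec <- synthetic_spec(p, design = c(10, 20, 30), noise = "none")
    d <- generate_err_dataset(spec)
    names(d)[names(d) == "err"] <- "err"
    fit <- fit_relative_growth(d, organ_params("thyroid", r = 0.5),
                               n_grid = 24)
    expect_false(fit$non_identifiable)
    expect_lt(abs(fit$estimate - truth), 0.01)
  }
})

test_that("noise-free recovery of the chemotherapy mutation rate", {
  p <- organ_params("lung")
  spec <- synthetic_spec(p, design = c(3, 6, 10), noise = "none")
  d <- generate_rr_dataset(spec)
  fit <- fit_chemo_mutation_rate(d, organ_params("lung", gamma_C = 1e-7),
                                 n_grid = 24)
  expect_lt(abs(fit$estimate - p$gamma_C) / p$gamma_C, 0.05)
})

test_that("noise-free recovery of the interaction strength", {
  p <- organ_params("thyroid")
  truth <- 2.6
  course5 <- concurrent_course(radiation_course(10), chemo_course(5),
                               epsilon = truth)
  course10 <- concurrent_course(radiation_course(10), chemo_course(10),
                                epsilon = truth)
  d <- data.frame(scenario = c("low", "high"),
                  rr = c(relative_risk(p, course5),
                         relative_risk(p, course10)))
  fit <- fit_interaction(
    d, scenarios = list(low = list(params = p, course = course5),
                        high = list(params = p, course = course10)),
    bounds = c(1, 5), n_grid = 16)
  expect_lt(abs(fit$estimate - truth) / truth, 0.10)
})

test_that("fits are bitwise deterministic", {
  p <- organ_params("lung")
  d <- data.frame(cycles = c(3, 6, 10), rr = c(4.0, 6.2, 13.0))
  f1 <- fit_chemo_mutation_rate(d, p, n_grid = 16)
  f2 <- fit_chemo_mutation_rate(d, p, n_grid = 16)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$objective, f2$objective)
})

test_that("the refined optimum is no worse than any grid point", {
  p <- organ_params("lung")
  d <- data.frame(cycles = c(3, 6, 10), rr = c(4.0, 6.2, 13.0))
  fit <- fit_chemo_mutation_rate(d, p, n_grid = 16)
  expect_lte(fit$objective, min(fit$grid$objective))
})

test_that("flat objectives are flagged as non-identifiable", {
  # a gamma_C fit against radiotherapy-free, chemo-free pseudo-data where the
  # model output does not depend on the parameter at all
  p <- organ_params("lung")
  d <- data.frame(cycles = c(0, 0), rr = c(1, 1))
  fit <- fit_chemo_mutation_rate(d, p, n_grid = 8)
  expect_true(fit$non_identifiable)
  expect_false(fit$converged)
})

test_that("baseline RR = 1 data drive the mutation rate to the lower bound", {
  p <- organ_params("lung")
  d <- data.frame(cycles = c(3, 6, 10), rr = c(1, 1, 1))
  fit <- fit_chemo_mutation_rate(d, p, bounds = c(1e-10, 1e-6), n_grid = 16)
  expect_lt(fit$estimate, 2e-10)
})

test_that("inverse-variance weighting uses the CI widths", {
  p <- organ_params("lung")
  d <- data.frame(cycles = c(3, 6, 10), rr = c(4.0, 6.2, 13.0),
                  ci_low = c(3.4, 4.8, 7.4), ci_high = c(4.7, 8.1, 23.0))
  fw <- fit_chemo_mutation_rate(d, p, n_grid = 16,
                                weights = "inverse_variance")
  fu <- fit_chemo_mutation_rate(d, p, n_grid = 16)
  expect_false(isTRUE(all.equal(fw$estimate, fu$estimate)))
  d2 <- d[, c("cycles", "rr")]
  expect_error(fit_chemo_mutation_rate(d2, p, weights = "inverse_variance"),
               "ci_low")
})

test_that("sensitivity scan keeps the order of magnitude of gamma_C", {
  p <- organ_params("lung")
  d <- data.frame(cycles = c(3, 6, 10), rr = c(4.0, 6.2, 13.0))
  scan <- sensitivity_scan(d, p, parameter = "alpha_C",
                           values = c(0.1, 0.2, 0.3), n_grid = 16)
  expect_equal(nrow(scan), 3)
  expect_lt(max(scan$log10_gamma_C) - min(scan$log10_gamma_C), 1)
  empty <- sensitivity_scan(d, p, values = numeric(0), n_grid = 8)
  expect_equal(nrow(empty), 0)
  expect_error(sensitivity_scan(d, p, parameter = "nope"), "unknown")
})

test_that("unknown scenarios are reported by name", {
  p <- organ_params("thyroid")
  course <- concurrent_course(radiation_course(10), chemo_course(5))
  d <- data.frame(scenario = c("low", "mystery"), rr = c(4, 5))
  expect_error(
    fit_interaction(d, scenarios = list(low = list(params = p,
                                                   course = course))),
    "mystery")
})
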