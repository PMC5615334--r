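# Synthetic cohort-summary generator.

test_that("a seed is mandatory whenever noise is requested", {
  p <- organ_params("lung")
  expect_error(synthetic_spec(p, 1:3, noise = "lognormal_cv"), "seed")
  expect_s3_class(synthetic_spec(p, 1:3, noise = "none"), "synthetic_spec")
})

test_that("noise-free datasets lie exactly on the model curve", {
  p <- organ_params("thyroid")
  spec <- synthetic_spec(p, design = c(4, 12, 20), noise = "none")
  d <- generate_err_dataset(spec)
  truth <- attr(d, "truth")
  expect_equal(d$err, truth$model$err)
  expect_equal(d$err, dose_response_curve(p, c(4, 12, 20))$err)
  drr <- generate_rr_dataset(synthetic_spec(p, c(5, 10), noise = "none"))
  expect_equal(drr$rr, attr(drr, "truth")$model$rr)
})

test_that("generation is bitwise reproducible for a fixed seed", {
  p <- organ_params("lung")
  spec <- synthetic_spec(p, design = c(3, 6, 10), noise = "lognormal_cv",
                         cv = 0.2, n_replicates = 4, seed = 123)
  d1 <- generate_rr_dataset(spec)
  d2 <- generate_rr_dataset(spec)
  expect_identical(d1$rr, d2$rr)
  d3 <- generate_rr_dataset(synthetic_spec(p, design = c(3, 6, 10),
                                           noise = "lognormal_cv", cv = 0.2,
                                           n_replicates = 4, seed = 124))
  expect_false(identical(d1$rr, d3$rr))
})

test_that("generation does not disturb the caller's RNG stream", {
  p <- organ_params("lung")
  spec <- synthetic_spec(p, design = c(3, 6), noise = "lognormal_cv",
                         cv = 0.2, seed = 7)
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  generate_rr_dataset(spec)
  b <- runif(1)
  expect_identical(a, b)
})

test_that("noisy excess risks are unbiased at small cv", {
  p <- organ_params("lung")
  spec <- synthetic_spec(p, design = 6, noise = "lognormal_cv", cv = 0.1,
                         n_replicates = 50, seed = 2024)
  d <- generate_rr_dataset(spec)
  truth <- attr(d, "truth")$model$rr
  ratio <- mean(d$rr - 1) / (truth - 1)
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)
})

test_that("empirical dispersion matches the requested cv", {
  p <- organ_params("lung")
  spec <- synthetic_spec(p, design = 6, noise = "lognormal_cv", cv = 0.3,
                         n_replicates = 500, seed = 31)
  d <- generate_rr_dataset(spec)
  excess <- d$rr - 1
  emp_cv <- sd(excess) / mean(excess)
  expect_lt(abs(emp_cv - 0.3) / 0.3, 0.2)
})

test_that("datasets are written with a machine-readable truth sidecar", {
  p <- organ_params("thyroid")
  spec <- synthetic_spec(p, design = c(5, 10), noise = "lognormal_cv",
                         cv = 0.1, seed = 5)
  d <- generate_rr_dataset(spec)
  f <- withr::local_tempfile(fileext = ".csv")
  write_synthetic_dataset(d, f)
  expect_true(file.exists(f))
  sidecar <- paste0(f, ".truth.json")
  expect_true(file.exists(sidecar))
  truth <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  expect_equal(truth$params$gamma_C, p$gamma_C)
  expect_equal(truth$seed, 5)
  expect_equal(truth$model$rr, attr(d, "truth")$model$rr)
  back <- read_rr_data(f)
  expect_equal(back$rr, d$rr)
})

test_that("empty designs yield empty, well-formed datasets", {
  p <- organ_params("lung")
  spec <- synthetic_spec(p, design = numeric(0), noise = "none")
  d <- generate_err_dataset(spec)
  expect_equal(nrow(d), 0)
  expect_named(d, c("dose", "err", "replicate"))
})
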