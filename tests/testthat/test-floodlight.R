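no_covs <- character()

# Zero-noise fixtures with known closed-form difference curves.
make_additive <- function(n = 200) {
  set.seed(61)
  d <- data.frame(age = runif(n, 20, 75), m = rnorm(n, 10, 2))
  d$y <- 0.5 * d$age + 3 * d$m
  d
}

make_bilinear <- function(n = 200) {
  set.seed(62)
  d <- data.frame(age = runif(n, 20, 75), m = rnorm(n, 0, 1))
  d$y <- d$age * d$m
  d
}

test_that("no interaction gives a constant quartile-contrast curve", {
  d <- make_additive()
  fit <- fit_model(d, model_spec("y", term_tensor("m", "age"),
                                 covariates = no_covs))
  cv <- difference_curve(fit, "m", data = d, grid_n = 101)
  gap <- stats::quantile(d$m, 0.75) - stats::quantile(d$m, 0.25)
  expect_equal(cv$difference, rep(3 * unname(gap), 101), tolerance = 1e-4)
  expect_equal(attr(cv, "q_low"), unname(stats::quantile(d$m, 0.25)))
})

test_that("a pure bilinear interaction gives a linear-in-age curve", {
  d <- make_bilinear()
  fit <- fit_model(d, model_spec("y", term_tensor("m", "age"),
                                 covariates = no_covs))
  cv <- difference_curve(fit, "m", data = d, grid_n = 101)
  gap <- unname(diff(stats::quantile(d$m, c(0.25, 0.75))))
  expect_equal(cv$difference, cv$age * gap, tolerance = 1e-3)
})

test_that("swapping the quartiles negates the difference curve exactly", {
  set.seed(63)
  d <- data.frame(age = runif(150, 20, 75), m = rnorm(150))
  d$y <- 0.01 * d$age * d$m + rnorm(150, 0, 0.3)
  fit <- fit_model(d, model_spec("y", term_tensor("m", "age"),
                                 covariates = no_covs))
  a <- difference_curve(fit, "m", data = d, probs = c(0.25, 0.75))
  b <- difference_curve(fit, "m", data = d, probs = c(0.75, 0.25))
  expect_equal(a$difference, -b$difference)
  expect_equal(a$se, b$se)
})

# Hand-built curve for exact region arithmetic.
synthetic_curve <- function(d, se = 1, age = seq_along(d)) {
  z <- stats::qnorm(0.975)
  out <- tibble::tibble(
    age = age, difference = d, se = se,
    ci_low = d - z * se, ci_high = d + z * se
  )
  attr(out, "moderator") <- "m"
  attr(out, "along") <- "age"
  class(out) <- c("difference_curve", class(out))
  out
}

test_that("regions of significance merge runs and interpolate endpoints", {
  crit <- stats::qnorm(0.975)
  # |z| ramps across ages 1..5 and crosses the critical value at age 3.5
  cv <- synthetic_curve(d = crit * c(0, 0.25, 0.75, 1.25, 1.75), se = 1, age = 1:5)
  rg <- regions_of_significance(cv)
  expect_equal(nrow(rg$intervals), 1)
  expect_equal(rg$intervals$age_lo, 3.5)  # interpolated between grid points 3 and 4
  expect_lt(rg$intervals$age_lo, 4)
  expect_equal(rg$intervals$age_hi, 5)
  expect_equal(rg$intervals$sign, 1)
  # grid-value endpoints when interpolation is off
  rg2 <- regions_of_significance(cv, interpolate = FALSE)
  expect_equal(rg2$intervals$age_lo, 4)
  # null curve: no regions
  expect_equal(nrow(regions_of_significance(synthetic_curve(rep(0, 9)))$intervals), 0)
  # everywhere significant: one interval spanning the grid
  rg3 <- regions_of_significance(synthetic_curve(rep(-5, 9), age = 11:19))
  expect_equal(rg3$intervals$age_lo, 11)
  expect_equal(rg3$intervals$age_hi, 19)
  expect_equal(rg3$intervals$sign, -1)
})

test_that("one-sided testing widens the detected region", {
  z2 <- stats::qnorm(0.975)
  z1 <- stats::qnorm(0.95)
  d <- rep((z1 + z2) / 2, 9)   # between the two critical values
  cv <- synthetic_curve(d)
  expect_equal(nrow(regions_of_significance(cv, sidedness = "two_sided")$intervals), 0)
  rg <- regions_of_significance(cv, sidedness = "one_sided")
  expect_equal(nrow(rg$intervals), 1)
  expect_equal(rg$sidedness, "one_sided")
})

test_that("a constant moderator is a degenerate contrast", {
  d <- make_additive()
  fit <- fit_model(d, model_spec("y", term_tensor("m", "age"),
                                 covariates = no_covs))
  d$m <- 1
  expect_error(difference_curve(fit, "m", data = d), "degenerate contrast")
})

test_that("prediction surfaces honour additive and bilinear structure", {
  d <- make_additive()
  fit <- fit_model(d, model_spec("y", term_tensor("m", "age"),
                                 covariates = no_covs))
  sf <- contour_surface(fit, "m", grid_n = c(21, 17))
  expect_equal(dim(sf$values), c(21, 17))
  # additivity: all rows are parallel (each column differs by a constant)
  shifts <- sweep(sf$values, 2, sf$values[1, ])
  expect_lt(max(abs(shifts - shifts[, 1])), 1e-4)

  db <- make_bilinear()
  fitb <- fit_model(db, model_spec("y", term_tensor("m", "age"),
                                   covariates = no_covs))
  sfb <- contour_surface(fitb, "m", grid_n = c(21, 17))
  expect_equal(sfb$values, outer(sfb$age, sfb$moderator), tolerance = 1e-3)

  expect_error(contour_surface(fit, "m", age_range = c(50, 50)), "empty")
  long <- as.data.frame(sfb)
  expect_equal(nrow(long), 21 * 17)
})

test_that("floodlight artefacts serialize to CSV and JSON", {
  set.seed(64)
  d <- data.frame(age = runif(250, 20, 75), m = rnorm(250))
  d$y <- 0.05 * d$age * d$m + rnorm(250)
  fit <- fit_model(d, model_spec("y", term_tensor("m", "age"),
                                 covariates = no_covs))
  cv <- difference_curve(fit, "m", data = d, grid_n = 51)
  rg <- regions_of_significance(cv)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_difference_curve(cv, f1)
  write_region_result(rg, f2)
  expect_equal(nrow(utils::read.csv(f1)), 51)
  rg_rt <- jsonlite::read_json(f2, simplifyVector = TRUE)
  expect_equal(rg_rt$alpha, 0.05)
  expect_gte(nrow(rg$intervals), 1)
  expect_equal(nrow(rg_rt$intervals), nrow(rg$intervals))
})
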