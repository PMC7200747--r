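no_covs <- character()

test_that("model specs validate their structure and parse from strings", {
  expect_error(
    model_spec("y", list(term_linear("x"), term_smooth("x"))),
    "more than one term"
  )
  expect_error(term_smooth("x", k = 2), "k >= 3")
  sp <- parse_model_spec("ldi ~ te(age, dg_left_vol) + sex + education")
  expect_equal(sp$outcome, "ldi")
  expect_equal(sp$terms[[1]]$kind, "tensor")
  expect_equal(sp$terms[[1]]$vars, c("age", "dg_left_vol"))
  expect_equal(sp$covariates, c("sex", "education"))
  sp2 <- parse_model_spec("y ~ s(x, k = 12) + s(age, by = vol)",
                          covariates = no_covs)
  expect_equal(sp2$terms[[1]]$k, 12)
  expect_equal(sp2$terms[[2]]$kind, "varying")
  expect_equal(sp2$terms[[2]]$by, "vol")
})

test_that("a smooth of noise-free linear data collapses to the linear fit", {
  d <- data.frame(x = seq(0, 10, length.out = 200))
  d$y <- 2 * d$x
  fit <- fit_model(d, model_spec("y", term_smooth("x"), covariates = no_covs))
  expect_lt(abs(fit$edf_per_term[["s(x)"]] - 1), 0.01)
  ols <- stats::lm(y ~ x, d)
  expect_lt(max(abs(fit$fitted - stats::fitted(ols))), 1e-6)
})

test_that("a smooth recovers a sine function from noise-free data", {
  d <- data.frame(x = seq(0, 2 * pi, length.out = 500))
  d$y <- sin(d$x)
  fit <- fit_model(d, model_spec("y", term_smooth("x", k = 20),
                                 covariates = no_covs))
  expect_lt(sqrt(mean((fit$fitted - sin(d$x))^2)), 1e-2)
  expect_gt(fit$edf_per_term[["s(x)"]], 3)
})

test_that("fits are deterministic and satisfy edf and covariance invariants", {
  set.seed(31)
  for (rep in 1:4) {
    n <- 150
    d <- data.frame(x = runif(n, 0, 10))
    d$y <- sin(d$x) + rnorm(n, 0, 0.3)
    f1 <- fit_model(d, model_spec("y", term_smooth("x", k = 10),
                                  covariates = no_covs))
    f2 <- fit_model(d, model_spec("y", term_smooth("x", k = 10),
                                  covariates = no_covs))
    expect_identical(f1$aic, f2$aic)
    edf <- f1$edf_per_term[["s(x)"]]
    expect_gte(edf, 1 - 1e-6)
    expect_lte(edf, 9)
    V <- f1$vcov
    expect_lt(max(abs(V - t(V))), 1e-10)
    expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("data problems raise informative errors", {
  d <- data.frame(x = 1:50, z = 1, y = rnorm(50))
  expect_error(
    fit_model(d, model_spec("y", term_linear("z"), covariates = no_covs)),
    "degenerate contrast"
  )
  d2 <- data.frame(x = 1:50, y = rnorm(50))
  d2$x2 <- 2 * d2$x
  expect_error(
    fit_model(d2, model_spec("y", list(term_linear("x"), term_linear("x2")),
                             covariates = no_covs)),
    "collinear"
  )
  d3 <- data.frame(x = c(1:49, NA), y = rnorm(50))
  expect_error(
    fit_model(d3, model_spec("y", term_linear("x"), covariates = no_covs)),
    "non-finite"
  )
  expect_error(
    fit_model(d2, model_spec("y", term_linear("missing"), covariates = no_covs)),
    "not in data"
  )
})

test_that("identical models compare as a degenerate tie", {
  set.seed(5)
  d <- data.frame(x = runif(100))
  d$y <- d$x + rnorm(100, 0, 0.2)
  f1 <- fit_model(d, model_spec("y", term_linear("x"), covariates = no_covs))
  f2 <- fit_model(d, model_spec("y", term_linear("x"), covariates = no_covs))
  cmp <- compare_models(f1, f2)
  expect_true(cmp$degenerate)
  expect_equal(cmp$selected, "linear")
  expect_equal(cmp$delta_aic, 0)
  expect_true(is.na(cmp$p_value))
})

test_that("strongly curved truth is selected as smooth", {
  set.seed(17)
  picks <- vapply(1:20, function(i) {
    d <- data.frame(x = runif(300, 0, 10))
    d$y <- 1 + 0.1 * (d$x - 5)^2 + rnorm(300)
    fl <- fit_model(d, model_spec("y", term_linear("x"), covariates = no_covs))
    fs <- fit_model(d, model_spec("y", term_smooth("x"), covariates = no_covs))
    compare_models(fl, fs)$selected
  }, character(1))
  expect_gte(sum(picks == "smooth"), 19)
})

test_that("comparisons require matching outcomes and data size", {
  set.seed(6)
  d <- data.frame(x = runif(60), y = rnorm(60), z = rnorm(60))
  f1 <- fit_model(d, model_spec("y", term_linear("x"), covariates = no_covs))
  f2 <- fit_model(d, model_spec("z", term_linear("x"), covariates = no_covs))
  expect_error(compare_models(f1, f2), "different outcomes")
  f3 <- fit_model(d[1:50, ], model_spec("y", term_linear("x"), covariates = no_covs))
  expect_error(compare_models(f3, f1), "different numbers of rows")
})

test_that("predictions carry correct means, leverage-ordered ses and flags", {
  d <- data.frame(x = seq(0, 10, length.out = 100))
  d$y <- 1 + 2 * d$x
  fit <- fit_model(d, model_spec("y", term_linear("x"), covariates = no_covs))
  pr <- predict_with_se(fit, data.frame(x = d$x[7]))
  expect_equal(pr$fit, d$y[7], tolerance = 1e-8)
  set.seed(12)
  d2 <- data.frame(x = runif(200, 0, 10))
  d2$y <- sin(d2$x) + rnorm(200, 0, 0.2)
  f2 <- fit_model(d2, model_spec("y", term_smooth("x"), covariates = no_covs))
  pr2 <- predict_with_se(f2, data.frame(x = c(stats::median(d2$x), max(d2$x))))
  expect_lt(pr2$se[1], pr2$se[2])
  expect_warning(
    pr3 <- predict_with_se(f2, data.frame(x = c(5, 30))),
    "outside the training range"
  )
  expect_equal(pr3$extrapolated, c(FALSE, TRUE))
})

test_that("covariates missing from newdata are fixed at reference values", {
  set.seed(14)
  d <- data.frame(
    x = runif(100), sex = factor(sample(c("female", "male"), 100, TRUE)),
    education = sample(2:8, 100, TRUE)
  )
  d$y <- d$x + 0.2 * (d$sex == "male") + 0.05 * d$education + rnorm(100, 0, 0.1)
  fit <- fit_model(d, model_spec("y", term_linear("x")))
  pr <- predict_with_se(fit, data.frame(x = 0.5))
  expect_equal(nrow(pr), 1)
  expect_true(is.finite(pr$fit))
})

test_that("the fitted age smooth recovers the generating LDI trajectory", {
  cfg <- default_config()
  cfg$n <- 5000
  co <- simulate_cohort(cfg, seed = 5)
  fit <- fit_model(co, model_spec("ldi", term_smooth("age")))
  truth <- expected_ldi(cfg, co$age)
  centred_err <- (fit$fitted - mean(fit$fitted)) - (truth - mean(truth))
  expect_lt(max(abs(centred_err)), 0.02)
  expect_gt(fit$edf_per_term[["s(age)"]], 3)  # decidedly nonlinear
})
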