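test_that("default configuration carries the published structural values", {
  cfg <- default_config()
  expect_equal(cfg$crs_model$age_slope, -0.007)
  expect_equal(cfg$volume_models$ca1_left$age_slope, -0.06)
  expect_equal(cfg$volume_models$dg_left$age_slope, -0.02)
  expect_equal(cfg$volume_models$dg_right$age_slope, -0.03)
  expect_equal(strata_counts(cfg), c(18L, 18L, 17L))
  expect_equal(cfg$ldi_model$mean, 0.16)
  expect_equal(cfg$crs_model$mean, 0.58)
})

test_that("volume normalization is raw / ICV x 1000", {
  expect_equal(volume_normalize(4500, 1450000), 4500 / 1450000 * 1000)
  expect_equal(volume_normalize(0, 1.5e6), 0)
  expect_equal(volume_normalize(0.03063 * 1.4e6, 1.4e6), 30.63)
  expect_error(volume_normalize(4500, 0), "positive")
  expect_error(volume_normalize(-1, 1.4e6), "non-negative")
})

test_that("simulation is deterministic in (config, seed)", {
  cfg <- default_config()
  a <- simulate_cohort(cfg, seed = 42)
  b <- simulate_cohort(cfg, seed = 42)
  c <- simulate_cohort(cfg, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$ldi, c$ldi))
  # seed restoration: the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_cohort(cfg, seed = 9)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero residual noise collapses scores onto their expectations", {
  cfg <- calibrate_config(default_config(10))
  for (key in names(cfg$derived$volumes)) cfg$derived$volumes[[key]]$resid_sd <- 0
  for (key in names(cfg$derived$activations)) cfg$derived$activations[[key]]$resid_sd <- 0
  cfg$derived$ldi$resid_sd <- 0
  cfg$derived$crs$resid_sd <- 0
  co <- simulate_cohort(cfg, seed = 3)
  expect_equal(
    co$ldi,
    expected_ldi(cfg, co$age, co$dg_left_vol, co$dg_right_vol, co$ca3_left_act),
    tolerance = 1e-12
  )
  expect_equal(co$crs, pmin(expected_crs(cfg, co$age), 1), tolerance = 1e-12)
  # with noiseless volumes the moderators sit at their age-conditional means,
  # so the latent LDI is exactly the age trajectory
  expect_equal(co$ldi, expected_ldi(cfg, co$age), tolerance = 1e-12)
})

test_that("sample moments converge to the configured moments", {
  cfg <- default_config()
  cfg$n <- 20000
  co <- simulate_cohort(cfg, seed = 7)
  for (key in names(cfg$volume_models)) {
    m <- cfg$volume_models[[key]]
    col <- paste0(key, "_vol")
    expect_lt(abs(mean(co[[col]]) - m$mean), 4 * m$sd / sqrt(cfg$n))
    expect_equal(stats::sd(co[[col]]), m$sd, tolerance = 0.05)
  }
  for (key in names(cfg$activation_models)) {
    m <- cfg$activation_models[[key]]
    col <- paste0(key, "_act")
    expect_lt(abs(mean(co[[col]]) - m$mean), 4 * m$sd / sqrt(cfg$n))
  }
  expect_lt(abs(mean(co$ldi) - 0.16), 4 * 0.18 / sqrt(cfg$n))
  expect_equal(mean(co$education), 5.51, tolerance = 0.15)
  expect_equal(mean(co$sex == "female"), 0.574, tolerance = 0.02)
  expect_gt(sum(attr(co, "clipped")), 0)  # CRS truncation at 1 is logged
})

test_that("simulated sessions have the designed trial structure", {
  tr <- simulate_trials(list(ldi = 0.3, crs = 0.5), seed = 11)
  retr <- tr[tr$phase == "retrieval", ]
  expect_equal(as.vector(table(retr$trial_type)[c("target", "lure", "foil")]),
               c(50L, 100L, 50L))
  expect_equal(sum(tr$phase == "encoding"), 150)
  # missingness flags responses, never deletes rows
  tcfg <- trial_sim_config(missing_p = 0.2)
  tr2 <- simulate_trials(list(ldi = 0.3, crs = 0.5), tcfg, seed = 11)
  retr2 <- tr2[tr2$phase == "retrieval", ]
  expect_equal(nrow(retr2), 200)
  expect_gt(sum(retr2$response == "none"), 0)
  tab <- tabulate_responses(tr2)
  expect_equal(unname(tab$valid_n + tab$n_missing), c(50, 100, 50))
})

test_that("impossible response rates raise an error naming the trial type", {
  expect_error(
    simulate_trials(list(ldi = 0.9, crs = 0.5), seed = 1),
    "lure"
  )
  expect_error(
    simulate_trials(list(ldi = 0.2, crs = 0.8), seed = 1),
    "target"
  )
  expect_error(
    simulate_trials(list(ldi = 1.2, crs = 0.5), seed = 1),
    "\\[-1, 1\\]"
  )
})

test_that("session scoring is an unbiased estimator of the latent scores", {
  nrep <- 600
  scores <- vapply(seq_len(nrep), function(i) {
    tr <- simulate_trials(list(ldi = 0.40, crs = 0.50),
                          trial_sim_config(foil_similar_rate = 0.20),
                          seed = 5000 + i)
    s <- score_session(tr)
    c(s$ldi, s$crs)
  }, numeric(2))
  expect_lt(abs(mean(scores[1, ]) - 0.40),
            3 * stats::sd(scores[1, ]) / sqrt(nrep))
  expect_lt(abs(mean(scores[2, ]) - 0.50),
            3 * stats::sd(scores[2, ]) / sqrt(nrep))
})

test_that("cohort configs round-trip through YAML and reject unknown keys", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  cfg2 <- read_cohort_config(path)
  expect_identical(simulate_cohort(cfg, seed = 2), simulate_cohort(cfg2, seed = 2))
  raw <- yaml::read_yaml(path)
  raw$ldi_model$typo_field <- 1
  yaml::write_yaml(raw, path)
  expect_error(read_cohort_config(path), "unknown key.*typo_field")
})

test_that("cohort CSV round-trips through the analysis schema", {
  co <- simulate_cohort(default_config(), seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(as.data.frame(co2)[-1], as.data.frame(co)[-1], tolerance = 1e-12)
  expect_s3_class(co2$sex, "factor")
})
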