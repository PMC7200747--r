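# Simulation of participants and trial-level task sessions.

#' Simulate a synthetic lifespan cohort
#'
#' Draws `config$n` participants: stratified (or continuous) ages, sex,
#' ordinal education, six subfield volumes with linear age trends, six
#' activation contrasts with optional age-varying volume coupling, and
#' latent LDI/CRS scores with the configured age trajectories, moderation
#' and residual noise. Latent scores are truncated to \[-1, 1\]; the number
#' of truncated values is recorded in the `clipped` attribute.
#'
#' @param config A `cohort_config`, e.g. [default_config()].
#' @param seed Integer seed; identical `(config, seed)` give identical
#'   tables.
#' @return Tibble with one row per participant: `id`, `age`, `sex`,
#'   `education`, the 12 imaging columns (`ca1_left_vol` ... `dg_right_act`),
#'   `ldi`, `crs`.
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.numeric(config$n) || config$n < 1) {
    stop_patsep("cohort size n must be a positive integer", "bad_config")
  }
  if (is.null(config$derived)) config <- calibrate_config(config)
  d <- config$derived
  n <- as.integer(config$n)

  with_seed(seed, {
    age <- sample_ages(config$age_sampler, n)
    sex <- factor(
      ifelse(stats::runif(n) < config$sex_p_female, "female", "male"),
      levels = c("female", "male")
    )
    edu <- sample_education(config$education, n)

    vols <- lapply(SUBFIELD_KEYS, function(key) {
      vm <- d$volumes[[key]]
      vm$intercept + vm$age_slope * age + stats::rnorm(n, 0, vm$resid_sd)
    })
    names(vols) <- SUBFIELD_KEYS

    acts <- lapply(SUBFIELD_KEYS, function(key) {
      am <- d$activations[[key]]
      out <- am$mean + stats::rnorm(n, 0, am$resid_sd)
      if (!is.null(config$coupling_models[[key]])) {
        cf <- ramp_fun(config$coupling_models[[key]])
        vm <- d$volumes[[key]]
        centred <- vols[[key]] - (vm$intercept + vm$age_slope * age)
        out <- out + cf(age) * centred
      }
      out
    })
    names(acts) <- SUBFIELD_KEYS

    ldi_mu <- expected_ldi(
      config, age,
      dg_left_vol = vols$dg_left, dg_right_vol = vols$dg_right,
      ca3_left_act = acts$ca3_left
    )
    ldi <- ldi_mu + stats::rnorm(n, 0, d$ldi$resid_sd)
    crs <- expected_crs(config, age) + stats::rnorm(n, 0, d$crs$resid_sd)
    clipped <- c(ldi = sum(ldi < -1 | ldi > 1), crs = sum(crs < -1 | crs > 1))
    ldi <- pmin(pmax(ldi, -1), 1)
    crs <- pmin(pmax(crs, -1), 1)

    out <- tibble::tibble(
      id = sprintf("S%05d", seq_len(n)),
      age = age, sex = sex, education = edu,
      ca1_left_vol = vols$ca1_left, ca1_right_vol = vols$ca1_right,
      ca3_left_vol = vols$ca3_left, ca3_right_vol = vols$ca3_right,
      dg_left_vol = vols$dg_left, dg_right_vol = vols$dg_right,
      ca1_left_act = acts$ca1_left, ca1_right_act = acts$ca1_right,
      ca3_left_act = acts$ca3_left, ca3_right_act = acts$ca3_right,
      dg_left_act = acts$dg_left, dg_right_act = acts$dg_right,
      ldi = ldi, crs = crs
    )
    attr(out, "clipped") <- clipped
    out
  })
}

# Stratified sampling keeps the designed strata counts exact (scaled to n);
# remainders after scaling are assigned largest-fraction first.
sample_ages <- function(sampler, n) {
  if (identical(sampler$kind, "continuous")) {
    rng <- range(unlist(sampler$strata))
    return(stats::runif(n, rng[1], rng[2]))
  }
  w <- sampler$weights / sum(sampler$weights)
  counts <- floor(w * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- w * n - counts
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  ages <- unlist(lapply(seq_along(sampler$strata), function(i) {
    b <- sampler$strata[[i]]
    stats::runif(counts[i], b[1], b[2])
  }))
  sample(ages)
}

sample_education <- function(edu, n) {
  support <- seq(edu$min, edu$max)
  probs <- stats::dnorm(support, edu$mean, edu$sd)
  sample(support, n, replace = TRUE, prob = probs / sum(probs))
}

#' Stratum counts implied by a configuration
#'
#' @param config A `cohort_config`.
#' @return Integer vector of per-stratum counts summing to `config$n`
#'   (at the study scale of n = 53: 18, 18, 17).
#' @export
strata_counts <- function(config) {
  sampler <- config$age_sampler
  w <- sampler$weights / sum(sampler$weights)
  n <- config$n
  counts <- floor(w * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- w * n - counts
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

#' Trial-simulation configuration
#'
#' Response model per retrieval type, designed so that session scoring is
#' unbiased by construction: for lures p("similar") is the foil
#' false-"similar" rate plus the latent LDI, for targets p("old") is the
#' foil false-"old" rate plus the latent CRS. The remaining probability
#' mass is split between the other two responses by fixed fractions that do
#' not enter either score.
#'
#' @param n_targets,n_lures,n_foils Designed retrieval trial counts
#'   (defaults 50 / 100 / 50).
#' @param n_encoding Encoding trials (kept for completeness; never scored).
#' @param foil_similar_rate Base rate of "similar" responses to foils.
#' @param foil_old_rate Base rate of "old" responses to foils.
#' @param missing_p Probability a trial has no behavioural response
#'   (`response = "none"`); missing trials are flagged, never deleted.
#' @return A `trial_sim_config`.
#' @export
trial_sim_config <- function(n_targets = 50, n_lures = 100, n_foils = 50,
                             n_encoding = 150,
                             foil_similar_rate = 0.30, foil_old_rate = 0.32,
                             missing_p = 0) {
  stopifnot(missing_p >= 0, missing_p < 1)
  structure(
    list(
      n_targets = n_targets, n_lures = n_lures, n_foils = n_foils,
      n_encoding = n_encoding,
      foil_similar_rate = foil_similar_rate, foil_old_rate = foil_old_rate,
      missing_p = missing_p
    ),
    class = "trial_sim_config"
  )
}

#' Simulate one task session for a participant
#'
#' Generates encoding and retrieval trial records under the response model
#' of [trial_sim_config()]. The expectation of [compute_ldi()] over sessions
#' equals the participant's latent LDI, and likewise for CRS.
#'
#' @param participant One-row data frame with columns `ldi` and `crs`
#'   (e.g. a row of [simulate_cohort()] output), or a list with those
#'   elements.
#' @param tcfg A `trial_sim_config`.
#' @param seed Integer seed.
#' @return Tibble of trial records (columns `trial_id`, `phase`,
#'   `trial_type`, `response`, `second_judgement`).
#' @export
simulate_trials <- function(participant, tcfg = trial_sim_config(), seed) {
  ldi <- participant$ldi
  crs <- participant$crs
  stopifnot(length(ldi) == 1, length(crs) == 1)
  if (ldi < -1 || ldi > 1 || crs < -1 || crs > 1) {
    stop_patsep("latent scores must lie in [-1, 1]", "bad_config")
  }
  p_sim_lure <- tcfg$foil_similar_rate + ldi
  p_old_target <- tcfg$foil_old_rate + crs
  check_rate <- function(p, type) {
    if (p < 0 || p > 1) {
      stop_patsep(
        sprintf("response model implies p = %.3f outside [0, 1] for %s trials",
                p, type),
        "bad_rates"
      )
    }
  }
  check_rate(p_sim_lure, "lure")
  check_rate(p_old_target, "target")
  check_rate(tcfg$foil_similar_rate + tcfg$foil_old_rate, "foil")

  # response distributions over (old, similar, new); off-score mass split
  # evenly between the two non-diagnostic responses
  p_lure <- c((1 - p_sim_lure) / 2, p_sim_lure, (1 - p_sim_lure) / 2)
  p_target <- c(p_old_target, (1 - p_old_target) / 2, (1 - p_old_target) / 2)
  p_foil <- c(tcfg$foil_old_rate, tcfg$foil_similar_rate,
              1 - tcfg$foil_old_rate - tcfg$foil_similar_rate)

  with_seed(seed, {
    enc <- tibble::tibble(
      trial_id = seq_len(tcfg$n_encoding),
      phase = "encoding",
      trial_type = "none",
      response = sample(c("indoor", "outdoor"), tcfg$n_encoding, replace = TRUE),
      second_judgement = "none"
    )
    types <- rep(c("target", "lure", "foil"),
                 c(tcfg$n_targets, tcfg$n_lures, tcfg$n_foils))
    types <- sample(types)
    resp <- character(length(types))
    for (ty in c("target", "lure", "foil")) {
      idx <- which(types == ty)
      p <- switch(ty, target = p_target, lure = p_lure, foil = p_foil)
      resp[idx] <- sample(c("old", "similar", "new"), length(idx),
                          replace = TRUE, prob = p)
    }
    if (tcfg$missing_p > 0) {
      resp[stats::runif(length(resp)) < tcfg$missing_p] <- "none"
    }
    second <- vapply(resp, function(r) {
      switch(r,
        old = , similar = sample(paste0("quadrant", 1:4), 1),
        new = sample(c("sure", "unsure"), 1),
        "none"
      )
    }, character(1), USE.NAMES = FALSE)
    ret <- tibble::tibble(
      trial_id = tcfg$n_encoding + seq_along(types),
      phase = "retrieval",
      trial_type = types,
      response = resp,
      second_judgement = second
    )
    rbind(enc, ret)
  })
}

#' Normalize a raw subfield volume by intracranial volume
#'
#' Expresses a raw volume in arbitrary units: `raw / icv * 1000`.
#'
#' @param raw_volume Raw volume in mm^3 (non-negative).
#' @param icv Intracranial volume in mm^3 (positive).
#' @return Normalized volume in arbitrary units.
#' @export
volume_normalize <- function(raw_volume, icv) {
  if (any(icv <= 0)) {
    stop_patsep("intracranial volume must be positive", "bad_input")
  }
  if (any(raw_volume < 0)) {
    stop_patsep("raw volume must be non-negative", "bad_input")
  }
  raw_volume / icv * 1000
}

#' Write / read a cohort table as CSV
#'
#' Tidy one-row-per-participant CSV with the analysis-table schema used by
#' [run_full_analysis()].
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_patsep("no rows in cohort table", "bad_input")
  if ("sex" %in% names(df)) {
    df$sex <- factor(df$sex, levels = c("female", "male"))
  }
  tibble::as_tibble(df)
}
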