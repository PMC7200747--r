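# Configuration and moment calibration for the synthetic lifespan cohort.
#
# The generator emulates the statistical structure of a stratified lifespan
# study of behavioural pattern separation: three recruitment strata
# (young / middle-aged / older), six hippocampal subfield volumes (CA1, CA3,
# dentate gyrus per hemisphere, in arbitrary units of volume/ICV x 1000),
# six subfield activation contrasts (successful > unsuccessful lure
# discrimination), and the two task scores (LDI, CRS). Defaults are
# calibrated so that the implied population moments match the cohort
# descriptives being emulated, and the structural coefficients equal the
# published linear age slopes.

SUBFIELD_KEYS <- c(
  "ca1_left", "ca1_right", "ca3_left", "ca3_right", "dg_left", "dg_right"
)

#' Default synthetic-cohort configuration
#'
#' Returns the fully parameterized generator configuration. Population
#' targets: LDI mean 0.16 (SD 0.18), CRS mean 0.58 (SD 0.25), subfield
#' volume and activation means/SDs as in the emulated cohort table, linear
#' age slopes of -0.06 (left CA1 volume), -0.02 (left DG), -0.03 (right DG)
#' and -0.007 (CRS) per year, and a smooth logistic decline of LDI with age
#' centred in the early 50s. Age-varying moderation of LDI by dentate gyrus
#' volume (negative in midlife, positive after 60) and left CA3 activation
#' (positive before ~45, negative after ~60), and age-varying coupling of
#' volume to activation in left CA1 and left DG, are built in with
#' piecewise-linear coefficient functions.
#'
#' @param n Cohort size (default 53, the study scale: strata 18/18/17).
#' @return A `cohort_config` list; see sections in the vignette for field
#'   meanings. Pass to [simulate_cohort()].
#' @export
default_config <- function(n = 53) {
  cfg <- list(
    n = n,
    age_sampler = list(
      kind = "stratified",
      strata = list(c(21, 30), c(40, 50), c(60, 73)),
      weights = c(18, 18, 17)
    ),
    sex_p_female = 0.574,
    education = list(min = 2, max = 8, mean = 5.51, sd = 1.6),
    volume_models = list(
      ca1_left  = list(mean = 30.63, sd = 3.2, age_slope = -0.06),
      ca1_right = list(mean = 31.19, sd = 3.3, age_slope = 0),
      ca3_left  = list(mean = 9.69,  sd = 1.1, age_slope = 0),
      ca3_right = list(mean = 10.48, sd = 1.2, age_slope = 0),
      dg_left   = list(mean = 13.88, sd = 1.3, age_slope = -0.02),
      dg_right  = list(mean = 14.29, sd = 1.4, age_slope = -0.03)
    ),
    activation_models = list(
      ca1_left  = list(mean = 3.09,  sd = 21.5),
      ca1_right = list(mean = 1.98,  sd = 17.1),
      ca3_left  = list(mean = -0.81, sd = 29.1),
      ca3_right = list(mean = 2.31,  sd = 27.1),
      dg_left   = list(mean = 8.11,  sd = 47.4),
      dg_right  = list(mean = 5.51,  sd = 34.3)
    ),
    # volume -> activation coupling, coefficient (act au per vol au) varying
    # with age: positive in the 20s, negative from the late 50s (left CA1);
    # negative from ~50 onwards (left DG).
    coupling_models = list(
      ca1_left = data.frame(
        age = c(21, 30, 45, 55, 73), value = c(2.5, 2.5, 0, -2.5, -3)
      ),
      dg_left = data.frame(
        age = c(21, 45, 60, 73), value = c(0, 0, -12, -12)
      )
    ),
    ldi_model = list(
      mean = 0.16,
      sd = 0.18,
      # latent age trajectory g(age) = alpha + span * logistic decline:
      # plateau through the 20s-30s, decline through midlife, low in older age
      shape = list(center = 52, scale = 5),
      age_span = 0.28,
      # age-varying moderation, coefficient = LDI units per unit of the
      # (age-centred) moderator; negative DG-volume effect in midlife,
      # positive in older age; CA3-activation effect positive young,
      # negative old
      moderators = list(
        dg_left_vol = data.frame(
          age = c(21, 42, 51, 60, 66, 73),
          value = c(0, 0, -0.08, 0, 0.04, 0.04)
        ),
        dg_right_vol = data.frame(
          age = c(21, 42, 51, 60, 66, 73),
          value = c(0, 0, -0.08, 0, 0.04, 0.04)
        ),
        ca3_left_act = data.frame(
          age = c(21, 40, 52, 60, 73),
          value = c(0.0025, 0.002, 0, -0.002, -0.0025)
        )
      )
    ),
    crs_model = list(mean = 0.58, sd = 0.25, age_slope = -0.007)
  )
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic lifespan cohort configuration\n")
  cat("  n:", x$n, " sampler:", x$age_sampler$kind, "\n")
  cat("  LDI target mean (sd):", x$ldi_model$mean,
      sprintf("(%s)", x$ldi_model$sd), "\n")
  cat("  CRS target mean (sd):", x$crs_model$mean,
      sprintf("(%s)", x$crs_model$sd),
      " age slope:", x$crs_model$age_slope, "/yr\n")
  invisible(x)
}

#' Age density of the sampler
#'
#' Discretized density of the configured age sampler (fine grid within each
#' stratum), used for closed-form moment calibration.
#'
#' @param config A `cohort_config`.
#' @param points Grid points per stratum.
#' @return Tibble with columns `age` and `weight` (weights sum to 1).
#' @export
age_density <- function(config, points = 512) {
  s <- config$age_sampler
  if (identical(s$kind, "continuous")) {
    rng <- range(unlist(s$strata))
    ages <- seq(rng[1], rng[2], length.out = points)
    return(tibble::tibble(age = ages, weight = rep(1 / points, points)))
  }
  w <- s$weights / sum(s$weights)
  parts <- lapply(seq_along(s$strata), function(i) {
    b <- s$strata[[i]]
    tibble::tibble(
      age = seq(b[1], b[2], length.out = points),
      weight = rep(w[i] / points, points)
    )
  })
  do.call(rbind, parts)
}

# Normalized latent age trajectory: 1 in youth -> 0 in older age.
ldi_shape_fun <- function(shape) {
  function(age) 1 / (1 + exp((age - shape$center) / shape$scale))
}

#' Calibrate a cohort configuration
#'
#' Converts the marginal targets (means, SDs, slopes) into generator
#' parameters: per-variable intercepts at the sampler's mean age, residual
#' SDs obtained by subtracting the variance explained by age trends,
#' moderation and coupling from the target variance, and the affine
#' coefficients of the latent LDI age trajectory. All moments are computed
#' by numerical integration over the age density, so calibration is
#' deterministic.
#'
#' @param config A `cohort_config`.
#' @return The config with a `derived` element holding the calibrated
#'   parameters.
#' @export
calibrate_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  dens <- age_density(config)
  age_mean <- sum(dens$age * dens$weight)
  age_var <- sum(dens$age^2 * dens$weight) - age_mean^2

  vol <- lapply(config$volume_models, function(m) {
    resid_var <- m$sd^2 - m$age_slope^2 * age_var
    if (resid_var < 0) {
      stop_patsep(
        "volume age slope implies more variance than the target SD allows",
        "bad_config"
      )
    }
    list(
      intercept = m$mean - m$age_slope * age_mean,
      age_slope = m$age_slope,
      resid_sd = sqrt(resid_var)
    )
  })

  # coupling consumes part of the activation variance budget
  act <- lapply(SUBFIELD_KEYS, function(key) {
    m <- config$activation_models[[key]]
    coup_var <- 0
    if (!is.null(config$coupling_models[[key]])) {
      cf <- ramp_fun(config$coupling_models[[key]])
      e_c2 <- sum(cf(dens$age)^2 * dens$weight)
      coup_var <- e_c2 * vol[[key]]$resid_sd^2
    }
    resid_var <- m$sd^2 - coup_var
    if (resid_var < 0) {
      stop_patsep(
        paste0("activation coupling for ", key,
               " implies more variance than the target SD allows"),
        "bad_config"
      )
    }
    list(mean = m$mean, resid_sd = sqrt(resid_var))
  })
  names(act) <- SUBFIELD_KEYS

  # latent LDI: alpha + span * shape(age) + sum_m b_m(age) * centred moderator
  sh <- ldi_shape_fun(config$ldi_model$shape)
  s_vals <- sh(dens$age)
  s_mean <- sum(s_vals * dens$weight)
  s_var <- sum(s_vals^2 * dens$weight) - s_mean^2
  span <- config$ldi_model$age_span
  g_var <- span^2 * s_var
  mod_var <- 0
  for (mn in names(config$ldi_model$moderators)) {
    b <- ramp_fun(config$ldi_model$moderators[[mn]])
    e_b2 <- sum(b(dens$age)^2 * dens$weight)
    mod_var <- mod_var + e_b2 * moderator_resid_var(mn, vol, act)
  }
  ldi_resid_var <- config$ldi_model$sd^2 - g_var - mod_var
  if (ldi_resid_var < 0) {
    stop_patsep(
      "LDI age span and moderation imply more variance than the target SD allows",
      "bad_config"
    )
  }

  crs <- config$crs_model
  crs_resid_var <- crs$sd^2 - crs$age_slope^2 * age_var
  if (crs_resid_var < 0) {
    stop_patsep(
      "CRS age slope implies more variance than the target SD allows",
      "bad_config"
    )
  }

  config$derived <- list(
    age_mean = age_mean,
    age_var = age_var,
    volumes = vol,
    activations = act,
    ldi = list(
      alpha = config$ldi_model$mean - span * s_mean,
      span = span,
      resid_sd = sqrt(ldi_resid_var)
    ),
    crs = list(
      intercept = crs$mean - crs$age_slope * age_mean,
      age_slope = crs$age_slope,
      resid_sd = sqrt(crs_resid_var)
    )
  )
  config
}

# Residual variance of a moderator at fixed age (its age-conditional
# variance), looked up from calibrated volume/activation components.
moderator_resid_var <- function(name, vol, act) {
  key <- sub("_(vol|act)$", "", name)
  kind <- sub("^.*_", "", name)
  if (!key %in% SUBFIELD_KEYS || !kind %in% c("vol", "act")) {
    stop_patsep(paste0("unknown moderator '", name, "'"), "bad_config")
  }
  if (kind == "vol") vol[[key]]$resid_sd^2 else act[[key]]$resid_sd^2
}

#' Expected latent LDI given age and moderators
#'
#' The deterministic part of the latent LDI model:
#' `g(age) + sum_m b_m(age) * (moderator - E[moderator | age])`, i.e. the
#' value every participant attains when all residual SDs are zero.
#'
#' @param config A `cohort_config` (calibrated automatically if needed).
#' @param age,dg_left_vol,dg_right_vol,ca3_left_act Vectors (recycled).
#' @return Expected latent LDI before truncation to \[-1, 1\].
#' @export
expected_ldi <- function(config, age, dg_left_vol = NULL, dg_right_vol = NULL,
                         ca3_left_act = NULL) {
  if (is.null(config$derived)) config <- calibrate_config(config)
  d <- config$derived
  sh <- ldi_shape_fun(config$ldi_model$shape)
  out <- d$ldi$alpha + d$ldi$span * sh(age)
  mods <- list(
    dg_left_vol = dg_left_vol, dg_right_vol = dg_right_vol,
    ca3_left_act = ca3_left_act
  )
  for (mn in names(config$ldi_model$moderators)) {
    if (is.null(mods[[mn]])) next
    b <- ramp_fun(config$ldi_model$moderators[[mn]])
    key <- sub("_(vol|act)$", "", mn)
    centre <- if (grepl("_vol$", mn)) {
      d$volumes[[key]]$intercept + d$volumes[[key]]$age_slope * age
    } else {
      d$activations[[key]]$mean
    }
    out <- out + b(age) * (mods[[mn]] - centre)
  }
  out
}

#' Expected latent CRS given age
#'
#' @inheritParams expected_ldi
#' @return Expected latent CRS before truncation to \[-1, 1\].
#' @export
expected_crs <- function(config, age) {
  if (is.null(config$derived)) config <- calibrate_config(config)
  config$derived$crs$intercept + config$derived$crs$age_slope * age
}

#' Read / write a cohort configuration as YAML
#'
#' The document mirrors the `cohort_config` structure one section per model
#' block. Unknown keys raise an error so typos cannot silently change a
#' simulation.
#'
#' @param path File path.
#' @return `read_cohort_config()`: a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- unclass(default_config())
  check_keys(raw, ref, "config")
  cfg <- utils::modifyList(ref, raw)
  # yaml round-trips data frames as lists of columns; restore them
  cfg$coupling_models <- lapply(cfg$coupling_models, as.data.frame)
  cfg$ldi_model$moderators <- lapply(cfg$ldi_model$moderators, as.data.frame)
  cfg$age_sampler$strata <- lapply(cfg$age_sampler$strata, as.numeric)
  cfg$derived <- NULL
  structure(cfg, class = "cohort_config")
}

#' @rdname read_cohort_config
#' @param config A `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$derived <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

check_keys <- function(x, ref, where) {
  if (!is.list(x) || !is.list(ref) || is.null(names(x))) return(invisible())
  unknown <- setdiff(names(x), c(names(ref), "derived"))
  if (length(unknown) > 0) {
    stop_patsep(
      paste0("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", ")),
      "bad_config"
    )
  }
  for (nm in intersect(names(x), names(ref))) {
    if (is.list(ref[[nm]]) && !is.data.frame(ref[[nm]])) {
      check_keys(x[[nm]], ref[[nm]], paste0(where, "$", nm))
    }
  }
  invisible()
}
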