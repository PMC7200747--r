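# Full analysis pipeline over a cohort table.
#
# Reproduces the study's model sequence for every subfield/hemisphere and
# predictor kind: Model 1, main effects (linear predictor + smooth age);
# Model 2, tensor-product smooth-by-smooth interaction with age; Model 3,
# linear-by-smooth (varying-coefficient) interaction. Smooth interactions
# are kept only when they beat the main-effects model under the
# most-parsimonious selection rule, and every selected interaction model
# gets a floodlight analysis. Additional blocks cover age main effects on
# all outcomes, age-varying volume-to-activation coupling, and linear
# volume-by-activation synergy on LDI.

SUBFIELD_GRID <- expand.grid(
  field = c("ca1", "ca3", "dg"),
  hemisphere = c("left", "right"),
  stringsAsFactors = FALSE
)

subfield_column <- function(field, hemisphere, kind) {
  suffix <- if (kind == "volume") "vol" else "act"
  paste(field, hemisphere, suffix, sep = "_")
}

#' Analysis plan
#'
#' Declares which model blocks to run and the smoothing setup.
#'
#' @param blocks Any of `"ldi_models"` (the three-model sequence per
#'   subfield and predictor kind), `"age_effects"` (smooth-vs-linear age
#'   main effects on LDI, CRS and all imaging columns),
#'   `"volume_activation"` (age-varying volume-to-activation coupling) and
#'   `"volume_by_activation"` (linear volume x activation synergy on LDI).
#' @param kinds Predictor kinds for the LDI models.
#' @param k_smooth Basis dimension of univariate age smooths (the observed
#'   nonlinear age trajectory needs k of at least 8).
#' @param k_tensor Per-margin basis dimensions of tensor interactions.
#' @param grid_n Floodlight age-grid size.
#' @param alpha Selection and floodlight significance level.
#' @param covariates Linear covariates added to every model.
#' @return An `analysis_plan`.
#' @export
analysis_plan <- function(blocks = c("ldi_models", "age_effects",
                                     "volume_activation",
                                     "volume_by_activation"),
                          kinds = c("volume", "activation"),
                          k_smooth = 10, k_tensor = c(5, 5),
                          grid_n = 201, alpha = 0.05,
                          covariates = c("sex", "education")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  structure(
    list(blocks = blocks, kinds = kinds, k_smooth = k_smooth,
         k_tensor = k_tensor, grid_n = grid_n, alpha = alpha,
         covariates = covariates),
    class = "analysis_plan"
  )
}

COHORT_SCHEMA <- list(
  required = c(
    "age", "sex", "education",
    as.vector(outer(
      paste(SUBFIELD_GRID$field, SUBFIELD_GRID$hemisphere, sep = "_"),
      c("vol", "act"), paste, sep = "_"
    )),
    "ldi", "crs"
  ),
  ranges = list(
    ldi = c(-1, 1), crs = c(-1, 1), education = c(1, 8), age = c(0, 130)
  )
)

#' Validate a cohort table against the analysis schema
#'
#' Checks for the required columns (age, sex, education, the 12 imaging
#' columns, ldi, crs), finiteness, and value ranges (scores in \[-1, 1\],
#' education 1-8, positive volumes). All violations are reported before any
#' model is fitted.
#'
#' @param x A data frame or a CSV path.
#' @return A `schema_report`: tibble of violations (columns `row`,
#'   `column`, `problem`; zero rows when valid) with attributes `n_rows`
#'   and `valid`.
#' @export
validate_cohort_table <- function(x) {
  df <- if (is.character(x)) read_cohort(x) else x
  if (nrow(df) == 0) stop_patsep("no rows in cohort table", "bad_input")
  probs <- list()
  add <- function(row, column, problem) {
    probs[[length(probs) + 1]] <<- tibble::tibble(
      row = row, column = column, problem = problem
    )
  }
  for (col in setdiff(COHORT_SCHEMA$required, names(df))) {
    add(NA_integer_, col, "missing column")
  }
  for (col in intersect(COHORT_SCHEMA$required, names(df))) {
    if (col == "sex") next
    x_ <- df[[col]]
    bad <- which(!is.finite(x_))
    for (r in bad) add(r, col, "non-finite value")
    rng <- COHORT_SCHEMA$ranges[[col]]
    if (!is.null(rng)) {
      out <- which(is.finite(x_) & (x_ < rng[1] | x_ > rng[2]))
      for (r in out) {
        add(r, col, sprintf("value %g outside [%g, %g]", x_[r], rng[1], rng[2]))
      }
    }
    if (grepl("_vol$", col)) {
      neg <- which(is.finite(x_) & x_ <= 0)
      for (r in neg) add(r, col, "non-positive volume")
    }
  }
  out <- if (length(probs) > 0) {
    do.call(rbind, probs)
  } else {
    tibble::tibble(row = integer(), column = character(), problem = character())
  }
  attr(out, "n_rows") <- nrow(df)
  attr(out, "valid") <- nrow(out) == 0
  class(out) <- c("schema_report", class(out))
  out
}

#' Run the full model sequence over a cohort
#'
#' Fits every planned model with sex and education covariates, applies the
#' smooth-versus-linear selection rule, runs a floodlight analysis on every
#' selected interaction model, and assembles a regenerable report. Model
#' failures (e.g. a degenerate column) are quarantined per combination so
#' one bad fit cannot void the run.
#'
#' @param cohort Cohort tibble or CSV path (see [validate_cohort_table()]).
#' @param plan An [analysis_plan()].
#' @return A `run_report`: list with `models` (per-fit summaries: F and edf
#'   of the age smooth and the predictor/interaction, AIC), `comparisons`,
#'   `best` (best-model flag per combination), `floodlight` (named list of
#'   curve + regions for selected interactions), `errors` and `provenance`.
#' @export
run_full_analysis <- function(cohort, plan = analysis_plan()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  report <- validate_cohort_table(cohort)
  if (!attr(report, "valid")) {
    msg <- utils::capture.output(print(utils::head(as.data.frame(report), 20)))
    stop_patsep(
      paste0("cohort table fails schema validation (", nrow(report),
             " violation(s)):\n", paste(msg, collapse = "\n")),
      "bad_input"
    )
  }
  cohort <- as.data.frame(cohort)
  cohort$sex <- factor(cohort$sex)

  models <- list(); comparisons <- list(); best <- list()
  floodlight <- list(); errors <- list()
  note_error <- function(combo, stage, e) {
    errors[[length(errors) + 1]] <<- tibble::tibble(
      combo = combo, stage = stage, message = conditionMessage(e)
    )
  }
  add_model <- function(row) models[[length(models) + 1]] <<- row
  covs <- plan$covariates

  if ("ldi_models" %in% plan$blocks) {
    for (i in seq_len(nrow(SUBFIELD_GRID))) {
      for (kind in plan$kinds) {
        field <- SUBFIELD_GRID$field[i]
        hemi <- SUBFIELD_GRID$hemisphere[i]
        pred <- subfield_column(field, hemi, kind)
        combo <- paste(field, hemi, kind, sep = "_")
        fits <- vector("list", 3)
        specs <- list(
          model1 = model_spec("ldi", list(
            term_linear(pred), term_smooth("age", k = plan$k_smooth)
          ), covs),
          model2 = model_spec("ldi", list(
            term_tensor(pred, "age", k = plan$k_tensor)
          ), covs),
          model3 = model_spec("ldi", list(
            term_smooth("age", k = plan$k_smooth),
            term_varying(pred, over = "age", k = plan$k_smooth)
          ), covs)
        )
        ok <- TRUE
        for (m in 1:3) {
          fit <- tryCatch(fit_model(cohort, specs[[m]]),
                          error = function(e) {
                            note_error(combo, names(specs)[m], e)
                            NULL
                          })
          fits[[m]] <- fit
          if (is.null(fit)) ok <- FALSE
          if (!is.null(fit)) {
            add_model(summarize_fit(fit, combo, names(specs)[m], pred))
          }
        }
        if (!ok) next
        cmp2 <- compare_models(fits[[1]], fits[[2]], alpha = plan$alpha)
        cmp3 <- compare_models(fits[[1]], fits[[3]], alpha = plan$alpha)
        comparisons[[length(comparisons) + 1]] <-
          summarize_comparison(cmp2, combo, "model1_vs_model2")
        comparisons[[length(comparisons) + 1]] <-
          summarize_comparison(cmp3, combo, "model1_vs_model3")
        pick <- select_best(fits, cmp2, cmp3)
        best[[length(best) + 1]] <- tibble::tibble(
          combo = combo, block = "ldi_models", best_model = pick
        )
        if (pick != "model1") {
          idx <- if (pick == "model2") 2 else 3
          fl <- tryCatch({
            curve <- difference_curve(fits[[idx]], moderator = pred,
                                      data = cohort, grid_n = plan$grid_n)
            list(curve = curve,
                 regions = regions_of_significance(curve, alpha = plan$alpha))
          }, error = function(e) { note_error(combo, "floodlight", e); NULL })
          if (!is.null(fl)) floodlight[[combo]] <- fl
        }
      }
    }
  }

  if ("age_effects" %in% plan$blocks) {
    outcomes <- c("ldi", "crs", vapply(seq_len(nrow(SUBFIELD_GRID)), function(i) {
      c(subfield_column(SUBFIELD_GRID$field[i], SUBFIELD_GRID$hemisphere[i], "volume"),
        subfield_column(SUBFIELD_GRID$field[i], SUBFIELD_GRID$hemisphere[i], "activation"))
    }, character(2)))
    for (y in outcomes) {
      combo <- paste0("age_", y)
      res <- tryCatch({
        f_lin <- fit_model(cohort, model_spec(y, list(term_linear("age")), covs))
        f_smo <- fit_model(cohort,
                           model_spec(y, list(term_smooth("age", k = plan$k_smooth)), covs))
        cmp <- compare_models(f_lin, f_smo, alpha = plan$alpha)
        add_model(summarize_fit(f_lin, combo, "linear", "age"))
        add_model(summarize_fit(f_smo, combo, "smooth", "age"))
        comparisons[[length(comparisons) + 1]] <-
          summarize_comparison(cmp, combo, "linear_vs_smooth")
        best[[length(best) + 1]] <- tibble::tibble(
          combo = combo, block = "age_effects",
          best_model = if (cmp$selected == "smooth") "smooth" else "linear"
        )
      }, error = function(e) note_error(combo, "age_effects", e))
    }
  }

  if ("volume_activation" %in% plan$blocks) {
    for (i in seq_len(nrow(SUBFIELD_GRID))) {
      field <- SUBFIELD_GRID$field[i]
      hemi <- SUBFIELD_GRID$hemisphere[i]
      vol <- subfield_column(field, hemi, "volume")
      act <- subfield_column(field, hemi, "activation")
      combo <- paste0("coupling_", field, "_", hemi)
      res <- tryCatch({
        f_main <- fit_model(cohort, model_spec(act, list(
          term_linear(vol), term_smooth("age", k = plan$k_smooth)
        ), covs))
        f_int <- fit_model(cohort, model_spec(act, list(
          term_tensor(vol, "age", k = plan$k_tensor)
        ), covs))
        cmp <- compare_models(f_main, f_int, alpha = plan$alpha)
        add_model(summarize_fit(f_main, combo, "main_effects", vol))
        add_model(summarize_fit(f_int, combo, "tensor", vol))
        comparisons[[length(comparisons) + 1]] <-
          summarize_comparison(cmp, combo, "main_vs_tensor")
        pick <- if (cmp$selected == "smooth") "tensor" else "main_effects"
        best[[length(best) + 1]] <- tibble::tibble(
          combo = combo, block = "volume_activation", best_model = pick
        )
        if (pick == "tensor") {
          curve <- difference_curve(f_int, moderator = vol, data = cohort,
                                    grid_n = plan$grid_n)
          floodlight[[combo]] <- list(
            curve = curve,
            regions = regions_of_significance(curve, alpha = plan$alpha)
          )
        }
      }, error = function(e) note_error(combo, "volume_activation", e))
    }
  }

  if ("volume_by_activation" %in% plan$blocks) {
    for (i in seq_len(nrow(SUBFIELD_GRID))) {
      field <- SUBFIELD_GRID$field[i]
      hemi <- SUBFIELD_GRID$hemisphere[i]
      vol <- subfield_column(field, hemi, "volume")
      act <- subfield_column(field, hemi, "activation")
      combo <- paste0("synergy_", field, "_", hemi)
      res <- tryCatch({
        d <- cohort
        d$vol_by_act <- d[[vol]] * d[[act]]
        f <- fit_model(d, model_spec("ldi", list(
          term_linear(vol), term_linear(act), term_linear("vol_by_act"),
          term_smooth("age", k = plan$k_smooth)
        ), covs))
        add_model(summarize_fit(f, combo, "linear_interaction", "vol_by_act"))
      }, error = function(e) note_error(combo, "volume_by_activation", e))
    }
  }

  res <- list(
    models = bind_or_empty(models, tibble::tibble(
      combo = character(), model = character(), formula = character(),
      predictor = character(), f_predictor = numeric(),
      edf_predictor = numeric(), p_predictor = numeric(),
      f_age = numeric(), edf_age = numeric(), aic = numeric(),
      deviance = numeric(), total_edf = numeric()
    )),
    comparisons = bind_or_empty(comparisons, NULL),
    best = bind_or_empty(best, NULL),
    floodlight = floodlight,
    errors = bind_or_empty(errors, tibble::tibble(
      combo = character(), stage = character(), message = character()
    )),
    provenance = list(
      n = nrow(cohort),
      n_models = length(models),
      input_hash = rlang::hash(cohort),
      plan = unclass(plan),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
  )
  class(res) <- "run_report"
  res
}

bind_or_empty <- function(rows, empty) {
  if (length(rows) > 0) do.call(rbind, rows) else empty
}

# One summary row per fitted model: the interaction/predictor statistic and
# the age-smooth statistic where present.
summarize_fit <- function(fit, combo, model, predictor) {
  st <- smooth_term_stats(fit)
  pt <- parametric_term_stats(fit)
  f_pred <- edf_pred <- p_pred <- NA_real_
  # interaction or predictor term: a smooth mentioning the predictor, else
  # the parametric coefficient (t^2 reported on the F scale)
  hit <- grepl(predictor, st$term, fixed = TRUE)
  if (any(hit)) {
    k <- which(hit)[1]
    f_pred <- st$f[k]; edf_pred <- st$edf[k]; p_pred <- st$p_value[k]
  } else if (predictor %in% pt$term) {
    k <- which(pt$term == predictor)
    f_pred <- pt$t[k]^2; edf_pred <- 1; p_pred <- pt$p_value[k]
  }
  f_age <- edf_age <- NA_real_
  age_hit <- which(st$term == "s(age)")
  if (length(age_hit) > 0) {
    f_age <- st$f[age_hit[1]]; edf_age <- st$edf[age_hit[1]]
  }
  tibble::tibble(
    combo = combo, model = model, formula = fit$formula,
    predictor = predictor, f_predictor = f_pred, edf_predictor = edf_pred,
    p_predictor = p_pred, f_age = f_age, edf_age = edf_age,
    aic = fit$aic, deviance = fit$deviance, total_edf = fit$total_edf
  )
}

summarize_comparison <- function(cmp, combo, label) {
  tibble::tibble(
    combo = combo, comparison = label, delta_aic = cmp$delta_aic,
    f_statistic = cmp$f_statistic, p_value = cmp$p_value, d_df = cmp$d_df,
    selected = cmp$selected, degenerate = cmp$degenerate
  )
}

# Most-parsimonious rule over the three-model sequence: an interaction
# model is eligible only if selected over the main-effects model; among
# eligible interactions the lower conditional AIC wins.
select_best <- function(fits, cmp2, cmp3) {
  eligible <- c(
    if (cmp2$selected == "smooth") "model2",
    if (cmp3$selected == "smooth") "model3"
  )
  if (length(eligible) == 0) return("model1")
  if (length(eligible) == 1) return(eligible)
  if (fits[[2]]$aic <= fits[[3]]$aic) "model2" else "model3"
}

#' @export
print.run_report <- function(x, ...) {
  cat("Analysis run:", x$provenance$n, "participants,",
      x$provenance$n_models, "fitted models\n")
  if (!is.null(x$best) && nrow(x$best) > 0) {
    sel <- x$best[x$best$best_model != "model1" & x$best$best_model != "linear" &
                    x$best$best_model != "main_effects", ]
    cat("Smooth/interaction models selected:",
        if (nrow(sel) > 0) paste(sel$combo, collapse = ", ") else "none", "\n")
  }
  if (nrow(x$errors) > 0) {
    cat("Quarantined failures:", nrow(x$errors), "\n")
  }
  cat("Uncorrected p-values across", x$provenance$n_models,
      "models; consider the model count when interpreting significance.\n")
  invisible(x)
}

#' Write a run report to a directory
#'
#' Emits a JSON summary (model table, comparisons, best-model flags,
#' regions, provenance), one CSV per table, and per-combination curve CSVs.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$models, file.path(dir, "models.csv"),
                   row.names = FALSE)
  if (!is.null(report$comparisons)) {
    utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$best)) {
    utils::write.csv(report$best, file.path(dir, "best_models.csv"),
                     row.names = FALSE)
  }
  regions <- lapply(report$floodlight, function(fl) {
    list(alpha = fl$regions$alpha, sidedness = fl$regions$sidedness,
         intervals = fl$regions$intervals)
  })
  for (combo in names(report$floodlight)) {
    write_difference_curve(
      report$floodlight[[combo]]$curve,
      file.path(dir, paste0("curve_", combo, ".csv"))
    )
  }
  jsonlite::write_json(
    list(
      best = report$best, comparisons = report$comparisons,
      regions = regions, errors = report$errors,
      provenance = report$provenance
    ),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
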