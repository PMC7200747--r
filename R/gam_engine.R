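# Generalized additive model engine.
#
# Declarative model specifications (linear terms, penalized cubic regression
# spline smooths, tensor-product interactions, varying-coefficient terms)
# fitted with mgcv, plus the smooth-versus-linear selection rule used
# throughout the pipeline: a smooth alternative replaces the linear
# (restricted) model only when it improves conditional AIC AND the
# analysis-of-deviance F-test rejects at alpha = 0.05 — otherwise the more
# parsimonious model is kept.

#' Model term constructors
#'
#' Build the terms of a [model_spec()]: `term_linear()` a parametric linear
#' term, `term_smooth()` a penalized cubic regression spline with basis
#' dimension `k`, `term_tensor()` a tensor-product smooth interaction with
#' per-margin basis dimensions, and `term_varying()` a varying-coefficient
#' term (linear in `by`, with a coefficient that is a smooth function of
#' `over`).
#'
#' @param var,var1,var2,by,over Variable (column) names.
#' @param k Basis dimension(s); at least 3 per margin.
#' @return A `model_term`.
#' @export
term_linear <- function(var) {
  new_term("linear", vars = var, label = var)
}

#' @rdname term_linear
#' @export
term_smooth <- function(var, k = 10) {
  stopifnot(k >= 3)
  new_term("smooth", vars = var, k = k,
           label = sprintf("s(%s)", var))
}

#' @rdname term_linear
#' @export
term_tensor <- function(var1, var2, k = c(5, 5)) {
  stopifnot(length(k) == 2, all(k >= 3))
  new_term("tensor", vars = c(var1, var2), k = k,
           label = sprintf("te(%s,%s)", var1, var2))
}

#' @rdname term_linear
#' @export
term_varying <- function(by, over = "age", k = 10) {
  stopifnot(k >= 3)
  new_term("varying", vars = c(over, by), k = k, by = by,
           label = sprintf("s(%s,by=%s)", over, by))
}

new_term <- function(kind, vars, k = NULL, by = NULL, label) {
  structure(list(kind = kind, vars = vars, k = k, by = by, label = label),
            class = "model_term")
}

#' Declarative GAM model specification
#'
#' @param outcome Outcome column name.
#' @param terms List of [term_linear()]/[term_smooth()]/[term_tensor()]/
#'   [term_varying()] terms. No variable may appear in two terms.
#' @param covariates Character vector of linear covariate columns added to
#'   every model (default sex and education).
#' @return A `model_spec`.
#' @export
model_spec <- function(outcome, terms, covariates = c("sex", "education")) {
  if (inherits(terms, "model_term")) terms <- list(terms)
  stopifnot(all(vapply(terms, inherits, logical(1), "model_term")))
  main_vars <- unlist(lapply(terms, function(t) {
    # a varying-coefficient term "owns" its by-variable, not the index
    if (t$kind == "varying") t$by else t$vars
  }))
  dup <- main_vars[duplicated(main_vars)]
  if (length(dup) > 0) {
    stop_patsep(
      paste0("variable(s) in more than one term: ", paste(unique(dup), collapse = ", ")),
      "bad_spec"
    )
  }
  structure(list(outcome = outcome, terms = terms, covariates = covariates),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(deparse_spec(x), "\n")
  invisible(x)
}

deparse_spec <- function(spec) {
  rhs <- c(
    vapply(spec$terms, term_formula_text, character(1)),
    spec$covariates
  )
  paste(spec$outcome, "~", paste(rhs, collapse = " + "))
}

term_formula_text <- function(t) {
  switch(t$kind,
    linear = t$vars,
    smooth = sprintf("s(%s, bs = 'cr', k = %d)", t$vars, t$k),
    tensor = sprintf("te(%s, %s, bs = 'cr', k = c(%d, %d))",
                     t$vars[1], t$vars[2], t$k[1], t$k[2]),
    varying = sprintf("s(%s, bs = 'cr', k = %d, by = %s)",
                      t$vars[1], t$k, t$by)
  )
}

#' Parse a compact model formula string into a model spec
#'
#' Accepts the grammar used in run-configuration documents, e.g.
#' `"ldi ~ te(age, dg_left_vol) + sex + education"` or
#' `"ldi ~ s(age) + s(age, by = dg_left_vol)"`. Bare names listed in
#' `covariates` are treated as covariates, other bare names as linear terms.
#'
#' @param text Formula string.
#' @param covariates Names recognized as covariates.
#' @param k,k_tensor Default basis dimensions.
#' @return A `model_spec`.
#' @export
parse_model_spec <- function(text, covariates = c("sex", "education"),
                             k = 10, k_tensor = c(5, 5)) {
  parts <- strsplit(text, "~", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop_patsep("model formula must contain exactly one '~'", "bad_spec")
  }
  outcome <- trimws(parts[1])
  rhs <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
  rhs <- trimws(rhs)
  terms <- list()
  covs <- character()
  for (tok in rhs) {
    if (grepl("^te\\(", tok)) {
      args <- parse_args(sub("^te\\((.*)\\)$", "\\1", tok))
      terms <- c(terms, list(term_tensor(args$pos[1], args$pos[2], k = k_tensor)))
    } else if (grepl("^s\\(", tok)) {
      args <- parse_args(sub("^s\\((.*)\\)$", "\\1", tok))
      kk <- if (!is.null(args$named$k)) as.numeric(args$named$k) else k
      if (!is.null(args$named$by)) {
        terms <- c(terms, list(term_varying(args$named$by, over = args$pos[1], k = kk)))
      } else {
        terms <- c(terms, list(term_smooth(args$pos[1], k = kk)))
      }
    } else if (tok %in% covariates) {
      covs <- c(covs, tok)
    } else {
      terms <- c(terms, list(term_linear(tok)))
    }
  }
  model_spec(outcome, terms, covariates = covs)
}

parse_args <- function(text) {
  toks <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  named <- list()
  pos <- character()
  for (tk in toks) {
    if (grepl("=", tk, fixed = TRUE)) {
      kv <- trimws(strsplit(tk, "=", fixed = TRUE)[[1]])
      named[[kv[1]]] <- kv[2]
    } else {
      pos <- c(pos, tk)
    }
  }
  list(pos = pos, named = named)
}

#' Fit a penalized-spline additive model
#'
#' Fits the specified model with a Gaussian likelihood, cubic regression
#' spline bases with second-derivative penalties, and smoothing parameters
#' chosen by REML (default) or GCV. Two documented conventions: the
#' conditional AIC uses the total effective degrees of freedom (plus one for
#' the scale) as the parameter count, and the reference degrees of freedom
#' stored for deviance testing are the smoothing-uncertainty-corrected
#' `edf1` of mgcv, which calibrate the smooth-versus-linear test close to
#' its nominal level.
#'
#' If a fit's residual variance is numerically zero (noise-free data fully
#' explained by the penalty null space, where the smoothing parameter is
#' unidentified because every value of it yields the same perfect fit), the
#' model is refitted at the upper smoothing limit so the most parsimonious
#' representation (e.g. edf 1 for a univariate smooth of exactly linear
#' data) is reported.
#'
#' @param data Data frame containing all model variables (finite values).
#' @param spec A [model_spec()].
#' @param method Smoothing-parameter criterion, `"REML"` or `"GCV.Cp"`.
#' @return A `gam_fit`: list with `model` (the mgcv fit), `spec`,
#'   `coefficients`, `vcov` (Bayesian posterior covariance of the
#'   coefficients), `edf_per_term`, `total_edf`, `total_edf1`, `aic`
#'   (conditional), `deviance`, `residual_df`, `scale`, `sp`, `n` and the
#'   training ranges used for extrapolation flagging.
#' @export
fit_model <- function(data, spec, method = c("REML", "GCV.Cp")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "model_spec"))
  vars <- unique(c(
    spec$outcome, unlist(lapply(spec$terms, `[[`, "vars")), spec$covariates
  ))
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0) {
    stop_patsep(
      paste0("variable(s) not in data: ", paste(missing, collapse = ", ")),
      "bad_spec"
    )
  }
  df <- as.data.frame(data)[vars]
  num <- vapply(df, is.numeric, logical(1))
  if (any(vapply(df[num], function(x) any(!is.finite(x)), logical(1)))) {
    bad <- names(df[num])[vapply(df[num], function(x) any(!is.finite(x)), logical(1))]
    stop_patsep(
      paste0("non-finite values in: ", paste(bad, collapse = ", ")),
      "bad_data"
    )
  }
  check_degenerate_columns(df, spec)
  basis_dim <- sum(vapply(spec$terms, function(t) {
    switch(t$kind, linear = 1, smooth = t$k, varying = t$k, tensor = prod(t$k))
  }, numeric(1))) + length(spec$covariates) + 1
  if (nrow(df) <= basis_dim) {
    stop_patsep("fewer rows than total basis dimension", "bad_data")
  }

  fml <- stats::as.formula(deparse_spec(spec))
  wrns <- list()
  g <- withCallingHandlers(
    mgcv::gam(fml, data = df, method = method),
    warning = function(w) {
      wrns[[length(wrns) + 1]] <<- w
      invokeRestart("muffleWarning")
    }
  )

  # degenerate noise-free case: smoothing parameter unidentified (every sp
  # yields the same perfect fit); report the most parsimonious representation
  # and drop the optimizer's step-failure warnings, which are its symptom
  y <- df[[spec$outcome]]
  perfect <- g$sig2 <= 1e-10 * max(stats::var(y), .Machine$double.eps)
  if (perfect && length(g$sp) > 0) {
    g <- mgcv::gam(fml, data = df, sp = rep(1e10, length(g$sp)))
  } else if (!perfect) {
    for (w in wrns) warning(w)
  }

  new_gam_fit(g, spec, df)
}

# Rank/degeneracy pre-checks with informative errors.
check_degenerate_columns <- function(df, spec) {
  term_vars <- lapply(spec$terms, `[[`, "vars")
  for (i in seq_along(spec$terms)) {
    for (v in term_vars[[i]]) {
      x <- df[[v]]
      if (is.numeric(x) && stats::sd(x) == 0) {
        stop_patsep(
          paste0("degenerate contrast: '", v, "' is constant (term ",
                 spec$terms[[i]]$label, ")"),
          "rank_deficient"
        )
      }
    }
  }
  # collinearity among parametric columns
  lin <- c(unlist(term_vars[vapply(spec$terms, function(t) t$kind == "linear",
                                   logical(1))]),
           spec$covariates)
  lin <- lin[vapply(df[lin], is.numeric, logical(1))]
  if (length(lin) >= 2) {
    X <- cbind(1, as.matrix(df[lin]))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop_patsep(
        paste0("rank-deficient design; collinear term(s): ",
               paste(dropped, collapse = ", ")),
        "rank_deficient"
      )
    }
  }
  invisible()
}

new_gam_fit <- function(g, spec, df) {
  per_term <- term_edf(g)
  fit <- list(
    model = g,
    spec = spec,
    formula = deparse_spec(spec),
    coefficients = stats::coef(g),
    vcov = g$Vp,
    edf_per_term = per_term$edf,
    edf1_per_term = per_term$edf1,
    total_edf = sum(g$edf),
    total_edf1 = sum(g$edf1 %||% g$edf),
    deviance = stats::deviance(g),
    residual_df = stats::df.residual(g),
    scale = g$sig2,
    sp = g$sp,
    aic = -2 * as.numeric(stats::logLik(g)) + 2 * (sum(g$edf) + 1),
    fitted = stats::fitted(g),
    n = nrow(df),
    var_ranges = lapply(df[vapply(df, is.numeric, logical(1))], range),
    covariate_reference = covariate_reference(df, spec$covariates)
  )
  class(fit) <- "gam_fit"
  fit
}

covariate_reference <- function(df, covariates) {
  refs <- lapply(covariates, function(v) {
    x <- df[[v]]
    if (is.numeric(x)) mean(x) else factor(sample_mode(x), levels = levels(factor(x)))
  })
  names(refs) <- covariates
  refs
}

# Per-term effective degrees of freedom (smooths: sum over their
# coefficients; parametric terms: 1 per coefficient).
term_edf <- function(g) {
  edf <- numeric(0); edf1 <- numeric(0)
  for (sm in g$smooth) {
    idx <- sm$first.para:sm$last.para
    edf <- c(edf, stats::setNames(sum(g$edf[idx]), sm$label))
    edf1 <- c(edf1, stats::setNames(sum((g$edf1 %||% g$edf)[idx]), sm$label))
  }
  n_par <- length(stats::coef(g)) -
    sum(vapply(g$smooth, function(s) s$last.para - s$first.para + 1, numeric(1)))
  if (n_par > 0) {
    edf <- c(stats::setNames(rep(1, 0), character(0)), parametric = n_par, edf)
    edf1 <- c(parametric = n_par, edf1)
  }
  list(edf = edf, edf1 = edf1)
}

#' @export
print.gam_fit <- function(x, ...) {
  cat("GAM fit:", x$formula, "\n")
  cat(sprintf("  n = %d, total edf = %.2f, AIC = %.2f, deviance = %.4g, scale = %.4g\n",
              x$n, x$total_edf, x$aic, x$deviance, x$scale))
  if (length(x$edf_per_term) > 0) {
    cat("  per-term edf:",
        paste(names(x$edf_per_term), round(x$edf_per_term, 2),
              sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' F statistics of smooth terms
#'
#' Wald-type F statistics of each smooth term against zero, as reported in
#' model summary tables.
#'
#' @param fit A `gam_fit`.
#' @return Tibble with `term`, `edf`, `f`, `p_value`.
#' @export
smooth_term_stats <- function(fit) {
  s <- summary(fit$model)
  st <- s$s.table
  if (is.null(st) || nrow(st) == 0) {
    return(tibble::tibble(term = character(), edf = numeric(),
                          f = numeric(), p_value = numeric()))
  }
  tibble::tibble(
    term = rownames(st), edf = st[, "edf"],
    f = st[, "F"], p_value = st[, "p-value"]
  )
}

#' Parametric term statistics
#'
#' @param fit A `gam_fit`.
#' @return Tibble with `term`, `estimate`, `se`, `t`, `p_value`.
#' @export
parametric_term_stats <- function(fit) {
  s <- summary(fit$model)
  pt <- s$p.table
  tibble::tibble(
    term = rownames(pt), estimate = pt[, "Estimate"], se = pt[, "Std. Error"],
    t = pt[, "t value"], p_value = pt[, "Pr(>|t|)"]
  )
}

#' Compare a restricted (more parsimonious) model with a smooth alternative
#'
#' Analysis of deviance between nested fits on the same data:
#' `F = (d_deviance / d_df) / scale_full` referred to an F distribution on
#' `(d_df, residual_df_full)`, where `d_df` is the difference in
#' smoothing-uncertainty-corrected reference degrees of freedom. The smooth
#' (full) model is selected only if it both lowers the conditional AIC and
#' rejects at `alpha`; otherwise the restricted model is kept (the
#' most-parsimonious-model rule). When the penalized alternative collapses
#' onto the restricted model (difference in reference df at or below 0.1,
#' including non-positive differences), there is no extra flexibility left
#' to test: the comparison is declared degenerate, `p_value` is `NA` and
#' the restricted model is kept. Without this guard the F reference
#' distribution on a vanishing numerator df produces spuriously small
#' p-values for comparisons that are for all purposes ties.
#'
#' @param fit_restricted,fit_full `gam_fit` objects on the same outcome and
#'   data, restricted nested in full.
#' @param alpha Test level.
#' @return A `model_comparison`: list with `delta_aic`
#'   (`AIC(full) - AIC(restricted)`), `f_statistic`, `p_value`, `d_df`,
#'   `d_edf`, `selected` (`"linear"` for restricted, `"smooth"` for full)
#'   and `degenerate`.
#' @export
compare_models <- function(fit_restricted, fit_full, alpha = 0.05) {
  stopifnot(inherits(fit_restricted, "gam_fit"), inherits(fit_full, "gam_fit"))
  if (!identical(fit_restricted$spec$outcome, fit_full$spec$outcome)) {
    stop_patsep("models have different outcomes", "bad_comparison")
  }
  if (fit_restricted$n != fit_full$n) {
    stop_patsep("models fitted to different numbers of rows", "bad_comparison")
  }
  delta_aic <- fit_full$aic - fit_restricted$aic
  d_dev <- fit_restricted$deviance - fit_full$deviance
  d_df <- fit_full$total_edf1 - fit_restricted$total_edf1
  d_edf <- fit_full$total_edf - fit_restricted$total_edf
  if (!is.finite(d_df) || d_df <= 0.1) {
    res <- list(
      delta_aic = delta_aic, f_statistic = NA_real_, p_value = NA_real_,
      d_df = d_df, d_edf = d_edf, selected = "linear", degenerate = TRUE
    )
    class(res) <- "model_comparison"
    return(res)
  }
  f_stat <- (d_dev / d_df) / fit_full$scale
  p <- stats::pf(f_stat, d_df, fit_full$residual_df, lower.tail = FALSE)
  selected <- if (delta_aic < 0 && p < alpha) "smooth" else "linear"
  res <- list(
    delta_aic = delta_aic, f_statistic = f_stat, p_value = p,
    d_df = d_df, d_edf = d_edf, selected = selected, degenerate = FALSE
  )
  class(res) <- "model_comparison"
  res
}

#' @export
print.model_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate comparison (d_df <= 0): restricted model kept\n")
  } else {
    cat(sprintf("dAIC = %.2f, F = %.2f on (%.2f, ...), p = %.4g -> %s\n",
                x$delta_aic, x$f_statistic, x$d_df, x$p_value, x$selected))
  }
  invisible(x)
}

#' Predict with pointwise standard errors
#'
#' Linear-predictor mean and standard error per row of `newdata`, from the
#' Bayesian posterior covariance of the spline coefficients. Covariates
#' absent from `newdata` are fixed at their reference values (numeric:
#' training mean; factor: training mode). Rows outside the training range
#' of any numeric model variable are flagged (with a warning), not refused.
#'
#' @param fit A `gam_fit`.
#' @param newdata Data frame of prediction points.
#' @param terms Optional character vector restricting the prediction to a
#'   subset of terms (passed to the underlying predict method).
#' @return Tibble with `fit`, `se`, `extrapolated`.
#' @export
predict_with_se <- function(fit, newdata, terms = NULL) {
  newdata <- as.data.frame(newdata)
  for (cv in names(fit$covariate_reference)) {
    if (!cv %in% names(newdata)) {
      newdata[[cv]] <- fit$covariate_reference[[cv]]
    }
  }
  extrap <- rep(FALSE, nrow(newdata))
  for (v in intersect(names(fit$var_ranges), names(newdata))) {
    if (v == fit$spec$outcome) next
    r <- fit$var_ranges[[v]]
    extrap <- extrap | newdata[[v]] < r[1] | newdata[[v]] > r[2]
  }
  if (any(extrap)) {
    warning(sprintf("%d prediction row(s) outside the training range", sum(extrap)))
  }
  pr <- if (is.null(terms)) {
    stats::predict(fit$model, newdata = newdata, se.fit = TRUE)
  } else {
    p <- stats::predict(fit$model, newdata = newdata, type = "terms",
                        terms = terms, se.fit = TRUE)
    list(fit = rowSums(as.matrix(p$fit)), se.fit = rowSums(as.matrix(p$se.fit)))
  }
  tibble::tibble(
    fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit), extrapolated = extrap
  )
}

#' Required sample size from an R-squared effect size
#'
#' Converts `R^2` to Cohen's `f^2 = R^2 / (1 - R^2)` and returns the
#' smallest total N whose noncentral-F power reaches the target for a
#' fixed-effects test with noncentrality `f^2 * N`. Two conventions for the
#' degrees of freedom: `"anova"`, a one-way comparison of `n_groups` groups
#' (numerator df `n_groups - 1`, denominator `N - n_groups`), and
#' `"regression"`, an `R^2` test of `n_predictors` regressors (numerator
#' `n_predictors`, denominator `N - n_predictors - 1`).
#'
#' @param r_squared Effect size as a squared multiple correlation, in (0, 1).
#' @param alpha Type-I error level.
#' @param power Target power, in (0, 1).
#' @param n_groups Number of groups (anova convention).
#' @param convention `"anova"` or `"regression"`.
#' @param n_predictors Number of predictors (regression convention;
#'   defaults to `n_groups - 1`).
#' @return Smallest total N with power at or above target.
#' @export
power_sample_size <- function(r_squared, alpha = 0.05, power = 0.80,
                              n_groups = 3,
                              convention = c("anova", "regression"),
                              n_predictors = n_groups - 1) {
  convention <- match.arg(convention)
  stopifnot(r_squared > 0, r_squared < 1, alpha > 0, alpha < 1,
            power > 0, power < 1)
  f2 <- r_squared / (1 - r_squared)
  u <- if (convention == "anova") n_groups - 1 else n_predictors
  v_of <- function(n) {
    if (convention == "anova") n - n_groups else n - n_predictors - 1
  }
  pow <- function(n) {
    v <- v_of(n)
    if (v < 1) return(0)
    stats::pf(stats::qf(1 - alpha, u, v), u, v, ncp = f2 * n,
              lower.tail = FALSE)
  }
  # power is monotone increasing in N: exponential then binary search
  n_min <- if (convention == "anova") n_groups + 1 else n_predictors + 2
  if (pow(n_min) >= power) return(n_min)
  hi <- n_min
  repeat {
    hi <- hi * 2
    if (hi > 1e6) {
      if (pow(1e6) >= power) { hi <- 1e6; break }
      stop_patsep("target power unattainable with N <= 1e6", "unattainable_power")
    }
    if (pow(hi) >= power) break
  }
  lo <- max(n_min, hi %/% 2)
  while (lo < hi - 1) {
    mid <- (lo + hi) %/% 2
    if (pow(mid) >= power) hi <- mid else lo <- mid
  }
  hi
}
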