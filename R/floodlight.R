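# Floodlight (region-of-significance) analysis.
#
# For a fitted age-by-moderator interaction model, the difference curve
# d(age) contrasts the predicted outcome at the moderator's third and first
# quartile while sweeping age over a fine grid, with pointwise standard
# errors from the coefficient posterior covariance. The region of
# significance is the set of ages where the confidence interval for d(age)
# excludes zero (the Johnson-Neyman idea, evaluated numerically so it
# applies to penalized smooths as well as linear interactions).

#' Quartile-contrast difference curve over the age axis
#'
#' Computes `d(age) = E[y | age, m = Q3] - E[y | age, m = Q1]` on an even
#' age grid, with the moderator fixed at its 25th and 75th percentile
#' values in `data` and covariates fixed at reference levels (numeric:
#' mean; factor: mode). The standard error at each grid point is
#' `sqrt(c' V c)` for the contrast vector `c` between the two prediction
#' rows and `V` the posterior covariance of the coefficients.
#'
#' @param fit A `gam_fit` containing an age-by-moderator interaction term.
#' @param moderator Moderator column name.
#' @param data Data frame for quantile and grid computation (defaults to
#'   the training data).
#' @param along Name of the sweep variable (default `"age"`).
#' @param grid_n Number of grid points (endpoints included).
#' @param probs Quantile pair defining the low/high moderator levels.
#' @param ci_level Level of the `ci_low`/`ci_high` columns.
#' @return A `difference_curve`: tibble with columns `age`, `difference`,
#'   `se`, `ci_low`, `ci_high`; attributes `moderator`, `along`, `q_low`,
#'   `q_high`, `ci_level`.
#' @export
difference_curve <- function(fit, moderator, data = NULL, along = "age",
                             grid_n = 201, probs = c(0.25, 0.75),
                             ci_level = 0.95) {
  stopifnot(inherits(fit, "gam_fit"))
  data <- data %||% fit$model$model
  if (!moderator %in% names(data)) {
    stop_patsep(paste0("moderator '", moderator, "' not found in data"),
                "bad_input")
  }
  used <- unlist(lapply(fit$spec$terms, `[[`, "vars"))
  if (!moderator %in% used || !along %in% used) {
    stop_patsep(
      paste0("fit has no term involving '", moderator, "' and '", along, "'"),
      "bad_input"
    )
  }
  q <- stats::quantile(data[[moderator]], probs, names = FALSE, na.rm = TRUE)
  if (diff(range(q)) == 0) {
    stop_patsep(
      paste0("degenerate contrast: quartiles of '", moderator, "' coincide"),
      "degenerate_contrast"
    )
  }
  grid <- seq(min(data[[along]]), max(data[[along]]), length.out = grid_n)
  base <- data.frame(grid)
  names(base) <- along
  for (cv in names(fit$covariate_reference)) {
    base[[cv]] <- fit$covariate_reference[[cv]]
  }
  # any other numeric model variables fixed at their training means
  others <- setdiff(used, c(along, moderator))
  for (v in others) {
    base[[v]] <- mean(data[[v]], na.rm = TRUE)
  }
  lo <- hi <- base
  lo[[moderator]] <- q[1]
  hi[[moderator]] <- q[2]
  Xlo <- stats::predict(fit$model, newdata = lo, type = "lpmatrix")
  Xhi <- stats::predict(fit$model, newdata = hi, type = "lpmatrix")
  C <- Xhi - Xlo
  d <- as.numeric(C %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((C %*% fit$vcov) * C), 0))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- tibble::tibble(
    age = grid, difference = d, se = se,
    ci_low = d - z * se, ci_high = d + z * se
  )
  attr(out, "moderator") <- moderator
  attr(out, "along") <- along
  attr(out, "q_low") <- q[1]
  attr(out, "q_high") <- q[2]
  attr(out, "ci_level") <- ci_level
  class(out) <- c("difference_curve", class(out))
  out
}

#' Regions of significance of a difference curve
#'
#' Finds the contiguous age intervals on which the confidence interval for
#' the quartile-contrast difference excludes zero: two-sided,
#' `|d|/se > z(1 - alpha/2)`; one-sided, a directional test at
#' `z(1 - alpha)` applied in the local sign direction of the difference.
#' Interval endpoints are linearly interpolated between the grid points
#' bracketing each significance change (set `interpolate = FALSE` to report
#' the grid values instead).
#'
#' @param curve A [difference_curve()].
#' @param alpha Significance level.
#' @param sidedness `"two_sided"` or `"one_sided"`.
#' @param interpolate Interpolate interval endpoints between grid points.
#' @return A `region_result`: list with `intervals` (tibble `age_lo`,
#'   `age_hi`, `sign`), `alpha`, `sidedness`.
#' @export
regions_of_significance <- function(curve, alpha = 0.05,
                                    sidedness = c("two_sided", "one_sided"),
                                    interpolate = TRUE) {
  sidedness <- match.arg(sidedness)
  stopifnot(inherits(curve, "difference_curve"))
  crit <- if (sidedness == "two_sided") {
    stats::qnorm(1 - alpha / 2)
  } else {
    stats::qnorm(1 - alpha)
  }
  z <- curve$difference / curve$se
  z[!is.finite(z)] <- 0
  h <- abs(z) - crit          # > 0 where significant
  sig <- h > 0
  n <- length(sig)
  intervals <- list()
  i <- 1
  while (i <= n) {
    if (!sig[i]) { i <- i + 1; next }
    j <- i
    while (j < n && sig[j + 1]) j <- j + 1
    lo <- curve$age[i]
    hi <- curve$age[j]
    if (interpolate) {
      if (i > 1) lo <- interp_crossing(curve$age, h, i - 1, i)
      if (j < n) hi <- interp_crossing(curve$age, h, j + 1, j)
    }
    k <- which.max(abs(z[i:j])) + i - 1
    intervals[[length(intervals) + 1]] <- tibble::tibble(
      age_lo = lo, age_hi = hi, sign = sign(curve$difference[k])
    )
    i <- j + 1
  }
  res <- list(
    intervals = if (length(intervals) > 0) {
      do.call(rbind, intervals)
    } else {
      tibble::tibble(age_lo = numeric(), age_hi = numeric(), sign = numeric())
    },
    alpha = alpha, sidedness = sidedness
  )
  class(res) <- "region_result"
  res
}

# Linear interpolation of the zero crossing of h between a non-significant
# grid point (out) and a significant one (in).
interp_crossing <- function(age, h, out, inn) {
  h0 <- h[out]; h1 <- h[inn]
  if (!is.finite(h0) || !is.finite(h1) || h1 == h0) return(age[inn])
  age[out] + (0 - h0) / (h1 - h0) * (age[inn] - age[out])
}

#' @export
print.region_result <- function(x, ...) {
  cat(sprintf("Regions of significance (alpha = %g, %s):\n", x$alpha,
              x$sidedness))
  if (nrow(x$intervals) == 0) {
    cat("  none\n")
  } else {
    for (i in seq_len(nrow(x$intervals))) {
      cat(sprintf("  %.2f - %.2f (%s)\n", x$intervals$age_lo[i],
                  x$intervals$age_hi[i],
                  if (x$intervals$sign[i] > 0) "positive" else "negative"))
    }
  }
  invisible(x)
}

#' Predicted-outcome surface over age and moderator
#'
#' Evaluates the fitted model on an age-by-moderator grid with covariates
#' at reference levels, the prediction surface drawn as a contour
#' (topographic) plot in the figures.
#'
#' @param fit A `gam_fit`.
#' @param moderator Moderator column name.
#' @param age_range,moderator_range Numeric length-2 ranges (default: the
#'   training data range).
#' @param grid_n Length-2 grid sizes (age, moderator).
#' @param along Name of the age axis variable.
#' @return A `prediction_surface`: list with `age`, `moderator` (axis
#'   vectors), `values` (matrix, ages in rows) and `moderator_name`.
#' @export
contour_surface <- function(fit, moderator, age_range = NULL,
                            moderator_range = NULL, grid_n = c(41, 41),
                            along = "age") {
  stopifnot(inherits(fit, "gam_fit"))
  data <- fit$model$model
  age_range <- age_range %||% range(data[[along]])
  moderator_range <- moderator_range %||% range(data[[moderator]])
  if (diff(age_range) <= 0 || diff(moderator_range) <= 0) {
    stop_patsep("empty prediction range", "bad_input")
  }
  ages <- seq(age_range[1], age_range[2], length.out = grid_n[1])
  mods <- seq(moderator_range[1], moderator_range[2], length.out = grid_n[2])
  nd <- expand.grid(ages, mods)
  names(nd) <- c(along, moderator)
  for (cv in names(fit$covariate_reference)) {
    nd[[cv]] <- fit$covariate_reference[[cv]]
  }
  used <- unlist(lapply(fit$spec$terms, `[[`, "vars"))
  for (v in setdiff(used, c(along, moderator))) {
    nd[[v]] <- mean(data[[v]], na.rm = TRUE)
  }
  pred <- as.numeric(stats::predict(fit$model, newdata = nd))
  res <- list(
    age = ages, moderator = mods,
    values = matrix(pred, nrow = length(ages)),
    moderator_name = moderator
  )
  class(res) <- "prediction_surface"
  res
}

#' @export
as.data.frame.prediction_surface <- function(x, ...) {
  data.frame(
    age = rep(x$age, times = length(x$moderator)),
    moderator = rep(x$moderator, each = length(x$age)),
    predicted = as.numeric(x$values)
  )
}

#' Minimal plot helpers
#'
#' `plot_difference_curve()` draws the quartile-contrast difference with
#' its confidence ribbon and a zero line; `plot_contour_surface()` draws
#' the filled-contour prediction surface.
#'
#' @param curve A [difference_curve()].
#' @return A ggplot object.
#' @export
plot_difference_curve <- function(curve) {
  df <- as.data.frame(curve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$difference)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "age (years)",
      y = sprintf("Q3 - Q1 difference in predicted outcome (%s)",
                  attr(curve, "moderator"))
    )
}

#' @rdname plot_difference_curve
#' @param surface A [contour_surface()].
#' @export
plot_contour_surface <- function(surface) {
  df <- as.data.frame(surface)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$moderator,
                                   z = .data$predicted)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(x = "age (years)", y = surface$moderator_name,
                  fill = "predicted")
}

#' Serialize floodlight results
#'
#' The curve is written as a CSV of grid rows; regions as JSON with the
#' intervals and metadata; a surface as a long-format CSV.
#'
#' @param curve,regions,surface Objects to write.
#' @param path Output file path.
#' @export
write_difference_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_difference_curve
#' @export
write_region_result <- function(regions, path) {
  jsonlite::write_json(
    list(
      alpha = regions$alpha, sidedness = regions$sidedness,
      intervals = regions$intervals
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_difference_curve
#' @export
write_surface <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}
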