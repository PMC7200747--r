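# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so simulation functions are
#' reproducible without clobbering the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Piecewise-linear coefficient function from knots
#'
#' Age-varying coefficients (moderation and coupling) are parameterized as
#' piecewise-linear interpolants through (age, value) knots, held constant
#' beyond the outermost knots.
#' @noRd
ramp_fun <- function(knots) {
  stopifnot(is.data.frame(knots), all(c("age", "value") %in% names(knots)))
  if (nrow(knots) == 1) {
    v <- knots$value
    return(function(age) rep(v, length(age)))
  }
  stats::approxfun(knots$age, knots$value, rule = 2)
}

#' Sample mode (most frequent value) used for covariate reference levels
#' @noRd
sample_mode <- function(x) {
  tab <- table(x)
  names(tab)[which.max(tab)]
}

stop_patsep <- function(msg, class) {
  rlang::abort(msg, class = paste0("patsep_", class))
}
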