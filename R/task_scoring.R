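# Scoring of mnemonic similarity task sessions.
#
# A retrieval session presents exact repeats (targets), perceptually similar
# objects (lures) and novel objects (foils); the participant answers "old",
# "similar" or "new". Discrimination of lures from repeats indexes
# behavioural pattern separation and is summarized by the Lure
# Discrimination Index, LDI = p("similar" | lure) - p("similar" | foil),
# which subtracts the base rate of calling anything "similar" and so
# controls for response bias. Target recognition is summarized by the
# Corrected Recognition Score, CRS = p("old" | target) - p("old" | foil).

RETRIEVAL_TYPES <- c("target", "lure", "foil")
RETRIEVAL_RESPONSES <- c("old", "similar", "new", "none")
ENCODING_RESPONSES <- c("indoor", "outdoor", "none")
SECOND_JUDGEMENTS <- c(paste0("quadrant", 1:4), "sure", "unsure", "none")

#' Tabulate retrieval responses by trial type
#'
#' Counts responses per retrieval condition, excluding trials without a
#' behavioural response (`response = "none"`) from both numerator and
#' denominator. Encoding-phase rows are carried in the trial table for
#' completeness but never scored.
#'
#' @param trials A data frame of trial records with columns `trial_id`,
#'   `phase` (`"encoding"`/`"retrieval"`), `trial_type` (`"target"`,
#'   `"lure"`, `"foil"`; `"none"` for encoding rows), `response` and
#'   `second_judgement`. Enum values are case-insensitive.
#' @return A `response_table`: a list with `counts` (3 x 3 integer matrix of
#'   trial type by response, missing responses excluded), `n_missing`
#'   (missing-response count per type) and `valid_n` (responded trials per
#'   type).
#' @export
tabulate_responses <- function(trials) {
  trials <- normalize_trials(trials)
  retr <- trials[trials$phase == "retrieval", , drop = FALSE]
  if (nrow(retr) == 0) {
    stop_patsep("empty session: no retrieval trials to score", "empty_session")
  }
  counts <- matrix(
    0L, nrow = 3, ncol = 3,
    dimnames = list(trial_type = RETRIEVAL_TYPES, response = c("old", "similar", "new"))
  )
  tab <- table(factor(retr$trial_type, RETRIEVAL_TYPES),
               factor(retr$response, RETRIEVAL_RESPONSES))
  counts[, ] <- tab[, c("old", "similar", "new")]
  n_missing <- as.integer(tab[, "none"])
  names(n_missing) <- RETRIEVAL_TYPES
  valid_n <- rowSums(counts)
  structure(
    list(counts = counts, n_missing = n_missing, valid_n = valid_n),
    class = "response_table"
  )
}

#' @export
print.response_table <- function(x, ...) {
  cat("Retrieval response table (missing responses excluded)\n")
  print(x$counts)
  cat("valid n:", paste(names(x$valid_n), x$valid_n, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Validate and canonicalize a raw trial table; enum values case-insensitive.
normalize_trials <- function(trials) {
  required <- c("trial_id", "phase", "trial_type", "response", "second_judgement")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    stop_patsep(
      paste0("malformed record: missing column(s) ", paste(missing, collapse = ", ")),
      "malformed_record"
    )
  }
  out <- trials
  for (col in c("phase", "trial_type", "response", "second_judgement")) {
    out[[col]] <- tolower(trimws(as.character(out[[col]])))
  }
  bad_phase <- !out$phase %in% c("encoding", "retrieval")
  if (any(bad_phase)) {
    stop_patsep(
      paste0("malformed record: unknown phase '", out$phase[which(bad_phase)[1]], "'"),
      "malformed_record"
    )
  }
  retr <- out$phase == "retrieval"
  bad_type <- retr & !out$trial_type %in% RETRIEVAL_TYPES
  if (any(bad_type)) {
    stop_patsep(
      paste0("malformed record: unknown trial_type '",
             out$trial_type[which(bad_type)[1]], "' in retrieval phase"),
      "malformed_record"
    )
  }
  bad_resp <- retr & !out$response %in% RETRIEVAL_RESPONSES
  if (any(bad_resp)) {
    stop_patsep(
      paste0("malformed record: unknown response '",
             out$response[which(bad_resp)[1]], "' in retrieval phase"),
      "malformed_record"
    )
  }
  bad_enc <- !retr & !out$response %in% ENCODING_RESPONSES
  if (any(bad_enc)) {
    stop_patsep(
      paste0("malformed record: unknown response '",
             out$response[which(bad_enc)[1]], "' in encoding phase"),
      "malformed_record"
    )
  }
  out
}

cond_prob <- function(table, type, response) {
  if (table$valid_n[[type]] == 0) {
    stop_patsep(
      paste0("undefined probability: no valid ", type, " trials"),
      "undefined_probability"
    )
  }
  unname(table$counts[type, response] / table$valid_n[[type]])
}

#' Lure Discrimination Index
#'
#' `LDI = p("similar" | lure) - p("similar" | foil)`, conditioned on valid
#' (responded) trials per type. The foil term subtracts the participant's
#' base rate of "similar" responses, so pure response bias cancels.
#'
#' @param table A `response_table` from [tabulate_responses()].
#' @return A number in \[-1, 1\].
#' @export
compute_ldi <- function(table) {
  stopifnot(inherits(table, "response_table"))
  cond_prob(table, "lure", "similar") - cond_prob(table, "foil", "similar")
}

#' Corrected Recognition Score
#'
#' `CRS = p("old" | target) - p("old" | foil)`, conditioned on valid trials
#' per type: hit rate corrected by the false alarm rate on novel foils.
#'
#' @inheritParams compute_ldi
#' @return A number in \[-1, 1\].
#' @export
compute_crs <- function(table) {
  stopifnot(inherits(table, "response_table"))
  cond_prob(table, "target", "old") - cond_prob(table, "foil", "old")
}

#' Score a full task session
#'
#' Tabulates the retrieval responses and computes both summary scores at
#' full floating precision. Second judgements (source-location quadrants,
#' confidence) are carried in the trial table but never enter the scores.
#'
#' @inheritParams tabulate_responses
#' @return A `score_result`: list with `ldi`, `crs`, `probabilities`
#'   (response fractions per trial type, conditioned on valid trials),
#'   `valid_n` and `n_missing`.
#' @export
score_session <- function(trials) {
  tab <- tabulate_responses(trials)
  probs <- sweep(tab$counts, 1, pmax(tab$valid_n, 1), "/")
  probs[tab$valid_n == 0, ] <- NA_real_
  structure(
    list(
      ldi = compute_ldi(tab),
      crs = compute_crs(tab),
      probabilities = probs,
      valid_n = tab$valid_n,
      n_missing = tab$n_missing
    ),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("LDI = %.4f  CRS = %.4f\n", x$ldi, x$crs))
  cat("valid n:", paste(names(x$valid_n), x$valid_n, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read a trial CSV
#'
#' Expects columns `trial_id`, `phase`, `trial_type`, `response`,
#' `second_judgement` (header required, one row per trial, enum values
#' case-insensitive).
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated trial records.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(normalize_trials(df))
}

#' Score a set of session files into one table
#'
#' @param paths Named character vector of trial CSV paths; names are used as
#'   participant ids (defaults to file base names).
#' @return Tibble with one row per session: `participant_id`, `ldi`, `crs`,
#'   `valid_n_target`, `valid_n_lure`, `valid_n_foil`.
#' @export
score_sessions <- function(paths) {
  ids <- names(paths) %||% tools::file_path_sans_ext(basename(paths))
  rows <- lapply(seq_along(paths), function(i) {
    s <- score_session(read_trials(paths[[i]]))
    tibble::tibble(
      participant_id = ids[[i]], ldi = s$ldi, crs = s$crs,
      valid_n_target = s$valid_n[["target"]],
      valid_n_lure = s$valid_n[["lure"]],
      valid_n_foil = s$valid_n[["foil"]]
    )
  })
  do.call(rbind, rows)
}
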