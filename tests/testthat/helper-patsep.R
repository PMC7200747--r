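# Builders for deterministic trial sessions used across scoring tests.

# Build retrieval trial records from per-type response vectors.
make_session <- function(target = character(), lure = character(),
                         foil = character(), encoding = 0) {
  rows <- list()
  if (encoding > 0) {
    rows[[1]] <- data.frame(
      trial_id = seq_len(encoding), phase = "encoding", trial_type = "none",
      response = rep(c("indoor", "outdoor"), length.out = encoding),
      second_judgement = "none"
    )
  }
  types <- rep(c("target", "lure", "foil"),
               c(length(target), length(lure), length(foil)))
  if (length(types) > 0) {
    rows[[length(rows) + 1]] <- data.frame(
      trial_id = encoding + seq_along(types), phase = "retrieval",
      trial_type = types, response = c(target, lure, foil),
      second_judgement = "none"
    )
  }
  do.call(rbind, rows)
}

# Responses with exact counts per category, e.g. resp_counts(old = 3, new = 2).
resp_counts <- function(...) {
  counts <- c(...)
  rep(names(counts), counts)
}
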