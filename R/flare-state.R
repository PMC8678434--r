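#' Binarize the flare petal score
#'
#' The flare petal is scored 1-5 like every other petal (1 = least healthy,
#' i.e. worst flare; 5 = no flare). A day counts as flare-on when the score
#' is at or below a threshold; the default threshold of 3 splits the scale
#' at its midpoint. The threshold is a run-level parameter: every downstream
#' statistic is reproducible under any choice in 1..5. A missing flare score
#' yields `NA` ("state undefined"), and such days are excluded from all
#' flare-conditioned aggregation.
#'
#' @param score integer vector of flare petal scores (1..5, `NA` allowed).
#' @param threshold integer in 1..5; flare-on iff `score <= threshold`.
#' @return logical vector, `NA` where `score` is missing.
#' @export
derive_flare_state <- function(score, threshold = 3L) {
  abort_if(!is_count(threshold) || threshold < 1 || threshold > 5,
           "threshold must be a single integer in 1..5")
  ok <- is.na(score) | (score %in% 1:5)
  abort_if(!all(ok), "flare scores must be integers in 1..5 or NA")
  score <= threshold
}

#' Per-day flare states for a diary
#'
#' Collapses a diary to one row per participant-day and attaches the binary
#' flare state derived from that day's flare petal score. Days where the
#' participant entered data but did not score the flare petal get an `NA`
#' state; they still count as "data entered" for the episode gap logic.
#'
#' @param diary a `flare_diary`.
#' @param threshold passed to [derive_flare_state()].
#' @return data frame with columns `participant_id`, `date`, `flare_score`
#'   (integer or `NA`), `flare_on` (logical or `NA`), one row per
#'   participant-day with any entry, sorted by participant then date.
#' @export
flare_states <- function(diary, threshold = 3L) {
  stopifnot(inherits(diary, "flare_diary"))
  days <- unique(diary[c("participant_id", "date")])
  fl <- diary[diary$variable == "flare", c("participant_id", "date", "score")]
  names(fl)[3] <- "flare_score"
  out <- merge(days, fl, by = c("participant_id", "date"), all.x = TRUE)
  out$flare_on <- derive_flare_state(out$flare_score, threshold)
  out <- out[order(out$participant_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}
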