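#' Read a daily diary CSV
#'
#' Reads a diary of daily Likert-scored petal entries, in either long format
#' (columns `participant_id, date, variable, score`; one row per scored
#' petal) or wide format (columns `participant_id, date` plus one column per
#' petal). The dialect is auto-detected from the header. Validation is
#' strict: out-of-range scores, unknown variable names, malformed dates and
#' duplicate (participant, date, variable) cells are errors, never silently
#' dropped, and empty cells become missing values, never imputed.
#'
#' @param path path to a UTF-8 CSV file with ISO-8601 dates.
#' @param catalogue a [petal_catalogue()] defining the admissible variables.
#' @param format `"auto"` (default), `"long"` or `"wide"`.
#' @return A `flare_diary`: a data frame with columns `participant_id`
#'   (character), `date` (`Date`), `variable` (character), `score` (integer
#'   in 1..5), sorted by participant, date, variable. One row per scored
#'   petal; a participant-day with an unscored petal simply has no row for
#'   that petal.
#' @seealso [write_diary()], [flare_states()]
#' @export
read_diary <- function(path, catalogue = petal_catalogue(),
                       format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  abort_if(!file.exists(path), "diary file does not exist: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = c("", "NA"))
  hdr <- tolower(names(raw))
  long_cols <- c("participant_id", "date", "variable", "score")
  if (format == "auto") {
    format <- if (all(long_cols %in% hdr)) "long" else "wide"
  }
  if (format == "long") {
    abort_if(!all(long_cols %in% hdr),
             "long-format diary must have columns %s",
             paste(long_cols, collapse = ", "))
    names(raw) <- hdr
    df <- raw[long_cols]
    # a long row with an empty score cell records nothing for that petal
    df <- df[!is.na(df$score), , drop = FALSE]
  } else {
    abort_if(!all(c("participant_id", "date") %in% hdr),
             "wide-format diary must have participant_id and date columns")
    names(raw)[match(c("participant_id", "date"), hdr)] <-
      c("participant_id", "date")
    var_cols <- setdiff(names(raw), c("participant_id", "date"))
    abort_if(length(var_cols) == 0L, "wide-format diary has no petal columns")
    vars <- canonical_variables(var_cols, catalogue)
    pieces <- lapply(seq_along(var_cols), function(j) {
      data.frame(
        participant_id = raw$participant_id,
        date = raw$date,
        variable = vars[[j]],
        score = raw[[var_cols[[j]]]],
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, pieces)
    df <- df[!is.na(df$score), , drop = FALSE]
  }
  as_flare_diary(df, catalogue = catalogue, source = path)
}

#' Construct and validate a flare diary
#'
#' Validates a long-format data frame of diary entries and returns it as a
#' `flare_diary`. Used both by [read_diary()] and by the synthetic cohort
#' generator, so every diary entering the pipeline passes the same checks.
#'
#' @param df data frame with columns `participant_id`, `date`, `variable`,
#'   `score`.
#' @param catalogue a [petal_catalogue()].
#' @param source optional label used in error messages.
#' @return a validated `flare_diary` (see [read_diary()]).
#' @export
as_flare_diary <- function(df, catalogue = petal_catalogue(), source = "diary") {
  need <- c("participant_id", "date", "variable", "score")
  abort_if(!all(need %in% names(df)), "%s: missing columns %s", source,
           paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  df$participant_id <- as.character(df$participant_id)

  if (!inherits(df$date, "Date")) {
    parsed <- as.Date(as.character(df$date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(df$date))
    abort_if(length(bad) > 0L, "%s: malformed date %s in row %d", source,
             as.character(df$date[bad[1]]), bad[1])
    abort_if(anyNA(df$date), "%s: missing date in row %d", source,
             which(is.na(df$date))[1])
    df$date <- parsed
  }

  df$variable <- canonical_variables(as.character(df$variable), catalogue)

  sc_num <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(df$score) | is.na(sc_num) | sc_num != as.integer(sc_num) |
                 sc_num < 1 | sc_num > 5)
  abort_if(length(bad) > 0L,
           "%s: score '%s' outside the 1-5 Likert range in row %d",
           source, as.character(df$score[bad[1]]), bad[1])
  df$score <- as.integer(sc_num)

  key <- paste(df$participant_id, df$date, df$variable, sep = "\r")
  dup <- which(duplicated(key))
  abort_if(length(dup) > 0L,
           "%s: duplicate entry for participant %s, %s, variable '%s' (row %d)",
           source, df$participant_id[dup[1]], as.character(df$date[dup[1]]),
           df$variable[dup[1]], dup[1])

  df <- df[order(df$participant_id, df$date, df$variable), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("flare_diary", "data.frame"), catalogue = catalogue)
}

#' Write a diary in canonical long CSV format
#'
#' @param diary a `flare_diary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diary <- function(diary, path) {
  stopifnot(inherits(diary, "flare_diary"))
  out <- as.data.frame(diary)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# column dictionary for the baseline covariate table
baseline_continuous <- function() {
  c(
    "basmi", "basdai", "basfi", "eq5d", "pain_discomfort",
    "anxiety_depression", "patient_global", "asqol",
    "work_productivity_impairment", "activity_impairment"
  )
}

baseline_binary <- function() {
  c(
    "employed", "female", "male", "hla_b27_positive", "current_smoker",
    "ex_smoker", "never_smoker", "bdmard_ever", "chronic_widespread_pain"
  )
}

#' Read a baseline clinical covariate table
#'
#' Reads the per-participant baseline table used for cluster
#' characterization: continuous clinical indices (BASMI, BASDAI, BASFI,
#' EQ-5D and its pain/anxiety components, patient global, ASQoL, work
#' productivity and activity impairment) and 0/1 indicators (employment,
#' sex, HLA-B27 status, smoking category, prior bDMARD treatment, chronic
#' widespread pain). Empty cells become missing values. Smoking categories
#' must be mutually exclusive and the sex indicators complementary whenever
#' both are present.
#'
#' @param path path to a CSV keyed by `participant_id`.
#' @return data frame of class `baseline_table` with one row per
#'   participant; unknown columns raise an error.
#' @export
read_baseline <- function(path) {
  abort_if(!file.exists(path), "baseline file does not exist: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = c("", "NA"))
  names(raw) <- tolower(gsub("[ .-]", "_", names(raw)))
  abort_if(!"participant_id" %in% names(raw),
           "baseline table must have a participant_id column")
  known <- c("participant_id", baseline_continuous(), baseline_binary())
  extra <- setdiff(names(raw), known)
  abort_if(length(extra) > 0L, "unknown baseline column(s): %s",
           paste(extra, collapse = ", "))
  out <- data.frame(participant_id = as.character(raw$participant_id),
                    stringsAsFactors = FALSE)
  for (v in baseline_continuous()) {
    out[[v]] <- if (v %in% names(raw)) as.numeric(raw[[v]]) else NA_real_
  }
  for (v in baseline_binary()) {
    x <- if (v %in% names(raw)) as.numeric(raw[[v]]) else NA_real_
    abort_if(any(!is.na(x) & !x %in% c(0, 1)),
             "baseline column %s must be 0/1", v)
    out[[v]] <- x
  }
  smoke <- as.matrix(out[c("current_smoker", "ex_smoker", "never_smoker")])
  ssum <- rowSums(smoke, na.rm = TRUE)
  bad <- which(ssum > 1)
  abort_if(length(bad) > 0L,
           "participant %s: smoking categories are not mutually exclusive",
           out$participant_id[bad[1]])
  both <- !is.na(out$female) & !is.na(out$male)
  bad <- which(both & out$female + out$male != 1)
  abort_if(length(bad) > 0L,
           "participant %s: female/male indicators must be complementary",
           out$participant_id[bad[1]])
  structure(out, class = c("baseline_table", "data.frame"))
}
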