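#' Petal variable catalogue
#'
#' The diary interface presents each tracked variable as one "petal" of a
#' flower. Eight fixed petals are tracked by every participant; each
#' participant additionally chooses two of thirteen optional petals. Every
#' petal is scored daily on a 1-5 Likert scale where 1 is the least healthy
#' and 5 the most healthy outcome; scores are stored exactly as entered and
#' never reoriented.
#'
#' @return An object of class `petal_catalogue`: a list with character
#'   vectors `fixed` (8 names, including `"flare"`) and `optional`
#'   (13 names).
#' @examples
#' cat <- petal_catalogue()
#' length(cat$fixed)     # 8
#' length(cat$optional)  # 13
#' @export
petal_catalogue <- function() {
  out <- list(
    fixed = c(
      "pain", "mood", "fatigue", "sleep quality", "stress", "flare",
      "recommended exercise", "anti-inflammatory use"
    ),
    optional = c(
      "caffeine intake", "hot flushes", "adherence to medication",
      "screen time", "confidence in self-management", "eyesight",
      "hydration", "chest pain", "flare of psoriasis",
      "impact of menstrual cycle", "red painful eyes", "smoking habits",
      "blood in stool"
    )
  )
  stopifnot(
    length(out$fixed) == 8L, length(out$optional) == 13L,
    !anyDuplicated(c(out$fixed, out$optional)), "flare" %in% out$fixed
  )
  structure(out, class = "petal_catalogue")
}

#' All variable names in a catalogue
#' @param catalogue a [petal_catalogue()].
#' @return character vector of the 21 petal names, fixed first.
#' @export
all_variables <- function(catalogue = petal_catalogue()) {
  c(catalogue$fixed, catalogue$optional)
}

#' Default clustering variable set
#'
#' The seven fixed symptom/behaviour petals used for phenotype clustering:
#' every participant tracks them, so their difference features form a
#' complete-case matrix. The flare petal itself is excluded (it defines the
#' flare state), and optional petals are reported descriptively only because
#' each is chosen by too few participants for a complete matrix.
#'
#' @return character vector of 7 variable names.
#' @export
clustering_variables <- function() {
  c(
    "pain", "fatigue", "sleep quality", "recommended exercise",
    "mood", "anti-inflammatory use", "stress"
  )
}

# Map user-supplied variable labels (e.g. "Sleep.Quality", "sleep_quality")
# onto catalogue names. Unknown labels raise an error naming them.
canonical_variables <- function(x, catalogue = petal_catalogue()) {
  norm <- function(v) gsub("\\s+", " ", trimws(gsub("[._-]", " ", tolower(v))))
  known <- all_variables(catalogue)
  idx <- match(norm(x), norm(known))
  if (anyNA(idx)) {
    stop(
      "unknown variable name(s): ",
      paste(unique(x[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  known[idx]
}

#' @export
print.petal_catalogue <- function(x, ...) {
  cat("Petal catalogue: 8 fixed + 13 optional variables\n")
  cat("  fixed:   ", paste(x$fixed, collapse = ", "), "\n", sep = "")
  cat("  optional:", paste(x$optional, collapse = ", "), "\n", sep = "")
  invisible(x)
}
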