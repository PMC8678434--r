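#' Per-participant flare-on / flare-off symptom features
#'
#' Aggregates the diary to one row per participant and variable: the mean
#' Likert score over days in flare (`mean_on`), over days out of flare
#' (`mean_off`), the entry counts behind each, and the difference feature
#' `diff = mean_on - mean_off` capturing the effect of a flare on that
#' variable (negative = worse during flare, since 1 is the least healthy
#' score). Days with an undefined flare state (flare petal unscored) are
#' excluded entirely; the flare petal itself is not a feature. `diff` is
#' present only when the participant has at least one scored entry on each
#' side, which is why per-variable sample sizes vary.
#'
#' @param diary a `flare_diary`.
#' @param threshold flare binarization threshold, see [derive_flare_state()].
#' @return data frame of class `flare_features`: `participant_id`,
#'   `variable`, `mean_on`, `mean_off` (in \[1,5\] or `NA`), `n_on`,
#'   `n_off`, `diff` (in \[-4,4\] or `NA`).
#' @export
flare_features <- function(diary, threshold = 3L) {
  stopifnot(inherits(diary, "flare_diary"))
  states <- flare_states(diary, threshold)
  d <- merge(diary[diary$variable != "flare", , drop = FALSE],
             states[c("participant_id", "date", "flare_on")],
             by = c("participant_id", "date"))
  d <- d[!is.na(d$flare_on), , drop = FALSE]
  if (nrow(d) == 0L) {
    out <- data.frame(participant_id = character(), variable = character(),
                      mean_on = numeric(), mean_off = numeric(),
                      n_on = integer(), n_off = integer(), diff = numeric())
    return(structure(out, class = c("flare_features", "data.frame")))
  }
  key <- paste(d$participant_id, d$variable, sep = "\r")
  first <- !duplicated(key)
  uk <- key[first]
  n_on <- as.integer(tapply(d$flare_on, key, sum)[uk])
  n_off <- as.integer(tapply(!d$flare_on, key, sum)[uk])
  sum_on <- as.numeric(tapply(d$score * d$flare_on, key, sum)[uk])
  sum_off <- as.numeric(tapply(d$score * !d$flare_on, key, sum)[uk])
  out <- data.frame(
    participant_id = d$participant_id[first],
    variable = d$variable[first],
    mean_on = ifelse(n_on >= 1L, sum_on / n_on, NA_real_),
    mean_off = ifelse(n_off >= 1L, sum_off / n_off, NA_real_),
    n_on = n_on, n_off = n_off,
    stringsAsFactors = FALSE
  )
  out$diff <- ifelse(out$n_on >= 1L & out$n_off >= 1L,
                     out$mean_on - out$mean_off, NA_real_)
  out <- out[order(out$participant_id, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("flare_features", "data.frame"))
}

#' Keep participants with enough diary data
#'
#' Eligibility for cluster analysis: participants with fewer than
#' `min_days` distinct entry dates are excluded. The filter only ever
#' removes participants, so raising `min_days` never adds anyone.
#'
#' @param diary a `flare_diary`.
#' @param min_days minimum number of distinct entry dates (default 10;
#'   i.e. "<10 days of data entry" is excluded, 10 itself is kept).
#' @return the filtered `flare_diary`, with attributes `n_before` and
#'   `n_after` recording the participant counts. Emits a warning when no
#'   participant survives.
#' @export
eligibility_filter <- function(diary, min_days = 10L) {
  stopifnot(inherits(diary, "flare_diary"))
  abort_if(!is_count(min_days) || min_days < 1, "min_days must be >= 1")
  days <- tapply(diary$date, diary$participant_id,
                 function(d) length(unique(d)))
  keep <- names(days)[days >= min_days]
  out <- diary[diary$participant_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "catalogue") <- attr(diary, "catalogue")
  attr(out, "n_before") <- length(days)
  attr(out, "n_after") <- length(keep)
  class(out) <- c("flare_diary", "data.frame")
  if (length(keep) == 0L) {
    warning("no participant has >= ", min_days, " days of data entry")
  }
  out
}

#' Difference-feature matrix for clustering
#'
#' Reshapes [flare_features()] output into a participants-by-variables
#' matrix of difference features.
#'
#' @param features a `flare_features` data frame.
#' @param variables character vector of variables to use, default
#'   [clustering_variables()].
#' @param complete drop participants with any missing difference feature
#'   (default `TRUE`; affinity propagation needs a complete matrix).
#' @return numeric matrix with participant ids as row names; attribute
#'   `n_dropped_incomplete` counts participants removed by `complete`.
#' @export
feature_matrix <- function(features, variables = clustering_variables(),
                           complete = TRUE) {
  stopifnot(inherits(features, "flare_features"))
  variables <- canonical_variables(variables)
  pids <- sort(unique(features$participant_id))
  M <- matrix(NA_real_, length(pids), length(variables),
              dimnames = list(pids, variables))
  sub <- features[features$variable %in% variables, , drop = FALSE]
  M[cbind(match(sub$participant_id, pids), match(sub$variable, variables))] <-
    sub$diff
  dropped <- 0L
  if (complete) {
    ok <- stats::complete.cases(M)
    dropped <- sum(!ok)
    M <- M[ok, , drop = FALSE]
  }
  attr(M, "n_dropped_incomplete") <- dropped
  M
}

#' Rescale difference features for clustering
#'
#' Column-wise min-max normalization onto \[-1, 1\]:
#' `x -> 2 * (x - min) / (max - min) - 1`, so each non-degenerate column
#' attains both -1 and +1. A constant column carries no clustering
#' information and is mapped to all zeros with a degeneracy flag. The
#' alternative `"maxabs"` scheme (`x -> x / max(|x|)`), which preserves the
#' sign and the zero point, is available behind the `method` switch.
#'
#' @param M numeric matrix (participants x features), no missing values.
#' @param method `"minmax"` (default) or `"maxabs"`.
#' @return object of class `normalized_features`: list with `matrix`
#'   (values in \[-1,1\], same dimnames as `M`), `col_min`, `col_max`
#'   (per-column provenance of the affine map) and `degenerate` (logical
#'   per column).
#' @export
normalize_features <- function(M, method = c("minmax", "maxabs")) {
  method <- match.arg(method)
  stopifnot(is.matrix(M), is.numeric(M))
  abort_if(anyNA(M),
           "feature matrix has missing values; apply eligibility_filter()/feature_matrix(complete = TRUE) first")
  lo <- apply(M, 2, min)
  hi <- apply(M, 2, max)
  degenerate <- hi == lo
  N <- M
  for (j in seq_len(ncol(M))) {
    if (degenerate[j]) {
      N[, j] <- 0
    } else if (method == "minmax") {
      N[, j] <- 2 * (M[, j] - lo[j]) / (hi[j] - lo[j]) - 1
    } else {
      N[, j] <- M[, j] / max(abs(M[, j]))
    }
  }
  structure(
    list(matrix = N, col_min = lo, col_max = hi, degenerate = degenerate,
         method = method),
    class = "normalized_features"
  )
}

#' Write the per-participant feature table to CSV
#'
#' Wide format: one row per participant with `<variable>_flare_on`,
#' `<variable>_flare_off`, `<variable>_diff` and, when `normalized` is
#' supplied, `<variable>_diff_norm` columns. Variable names are slugged
#' (spaces to underscores) for header safety.
#'
#' @param features a `flare_features` data frame.
#' @param path output path.
#' @param normalized optional `normalized_features` whose columns are added.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, normalized = NULL) {
  stopifnot(inherits(features, "flare_features"))
  slug <- function(v) gsub("[^a-z0-9]+", "_", tolower(v))
  pids <- sort(unique(features$participant_id))
  vars <- sort(unique(features$variable))
  out <- data.frame(participant_id = pids, stringsAsFactors = FALSE)
  for (v in vars) {
    sub <- features[features$variable == v, , drop = FALSE]
    i <- match(pids, sub$participant_id)
    out[[paste0(slug(v), "_flare_on")]] <- sub$mean_on[i]
    out[[paste0(slug(v), "_flare_off")]] <- sub$mean_off[i]
    out[[paste0(slug(v), "_diff")]] <- sub$diff[i]
  }
  if (!is.null(normalized)) {
    N <- normalized$matrix
    for (v in colnames(N)) {
      col <- rep(NA_real_, length(pids))
      col[match(rownames(N), pids)] <- N[, v]
      out[[paste0(slug(v), "_diff_norm")]] <- col
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
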