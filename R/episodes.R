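#' Segment flare days of one participant into episodes
#'
#' Core episode reconstruction. A flare episode is a maximal run of
#' flare-on days, with one bridging allowance: two flare-on days exactly two
#' calendar days apart are merged into a single episode when the intervening
#' day has no diary entry at all (the single missing day is absorbed into
#' the episode and counted in its duration). A recorded flare-off day — or a
#' day with an entry but no flare score — always separates episodes, and
#' gaps of two or more consecutive missing days are never bridged.
#'
#' @param entry_dates `Date` vector of all days on which the participant
#'   entered anything (any petal); defines what counts as a missing day.
#' @param flare_on logical vector aligned with `entry_dates`: the day's
#'   flare state (`NA` if the flare petal was not scored).
#' @return data frame with columns `start_date`, `end_date`,
#'   `duration_days` (calendar days, `end - start + 1`),
#'   `n_recorded_flare_days`, `bridged_gap_count`, sorted by `start_date`.
#' @seealso [segment_episodes()] for the whole-diary interface.
#' @export
segment_flare_days <- function(entry_dates, flare_on) {
  stopifnot(length(entry_dates) == length(flare_on))
  empty <- data.frame(
    start_date = as.Date(character()), end_date = as.Date(character()),
    duration_days = integer(), n_recorded_flare_days = integer(),
    bridged_gap_count = integer()
  )
  if (length(entry_dates) == 0L) return(empty)
  ord <- order(entry_dates)
  entry_dates <- entry_dates[ord]
  flare_on <- flare_on[ord]
  abort_if(anyDuplicated(entry_dates) > 0L, "duplicate entry dates")
  on_days <- entry_dates[!is.na(flare_on) & flare_on]
  if (length(on_days) == 0L) return(empty)

  entered <- as.integer(entry_dates)
  on <- as.integer(on_days)
  starts <- ends <- rec <- bridged <- integer(0)
  cur_start <- cur_end <- on[1]
  cur_rec <- 1L
  cur_bridge <- 0L
  for (d in on[-1]) {
    gap <- d - cur_end
    if (gap == 1L) {
      cur_end <- d
      cur_rec <- cur_rec + 1L
    } else if (gap == 2L && !((cur_end + 1L) %in% entered)) {
      cur_end <- d
      cur_rec <- cur_rec + 1L
      cur_bridge <- cur_bridge + 1L
    } else {
      starts <- c(starts, cur_start); ends <- c(ends, cur_end)
      rec <- c(rec, cur_rec); bridged <- c(bridged, cur_bridge)
      cur_start <- cur_end <- d
      cur_rec <- 1L
      cur_bridge <- 0L
    }
  }
  starts <- c(starts, cur_start); ends <- c(ends, cur_end)
  rec <- c(rec, cur_rec); bridged <- c(bridged, cur_bridge)
  data.frame(
    start_date = as.Date(starts, origin = "1970-01-01"),
    end_date = as.Date(ends, origin = "1970-01-01"),
    duration_days = as.integer(ends - starts + 1L),
    n_recorded_flare_days = rec,
    bridged_gap_count = bridged
  )
}

#' Reconstruct flare episodes for every participant in a diary
#'
#' Applies [segment_flare_days()] per participant. Episodes are never
#' truncated at the observation boundary; instead, episodes whose first or
#' last day coincides with the participant's first or last entry day are
#' flagged, since their true extent may be censored.
#'
#' @param diary a `flare_diary`.
#' @param threshold flare binarization threshold, see [derive_flare_state()].
#' @return data frame with one row per episode: `participant_id`,
#'   `start_date`, `end_date`, `duration_days`, `n_recorded_flare_days`,
#'   `bridged_gap_count`, `at_boundary` (logical), sorted by participant
#'   then start date.
#' @export
segment_episodes <- function(diary, threshold = 3L) {
  states <- flare_states(diary, threshold)
  pieces <- lapply(split(states, states$participant_id), function(s) {
    ep <- segment_flare_days(s$date, s$flare_on)
    if (nrow(ep) == 0L) return(NULL)
    ep$participant_id <- s$participant_id[1]
    ep$at_boundary <- ep$start_date == min(s$date) | ep$end_date == max(s$date)
    ep
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L) {
    return(data.frame(
      participant_id = character(), start_date = as.Date(character()),
      end_date = as.Date(character()), duration_days = integer(),
      n_recorded_flare_days = integer(), bridged_gap_count = integer(),
      at_boundary = logical()
    ))
  }
  out <- do.call(rbind, pieces)
  cols <- c("participant_id", "start_date", "end_date", "duration_days",
            "n_recorded_flare_days", "bridged_gap_count", "at_boundary")
  out <- out[order(out$participant_id, out$start_date), cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-participant flare frequency interval
#'
#' "One flare every X days". The default definition divides the
#' participant's observation span (last entry day minus first entry day,
#' plus one) by the number of episodes; the alternative `"onset_gap"`
#' definition averages the gaps between consecutive episode onsets and
#' needs at least two episodes. Participants with no episodes get `NA` and
#' are excluded from frequency summaries.
#'
#' @param diary a `flare_diary`.
#' @param episodes output of [segment_episodes()].
#' @param method `"span"` (default) or `"onset_gap"`.
#' @return data frame `participant_id`, `n_episodes`, `interval_days`.
#' @export
flare_frequency_intervals <- function(diary, episodes,
                                      method = c("span", "onset_gap")) {
  method <- match.arg(method)
  stopifnot(inherits(diary, "flare_diary"))
  pids <- sort(unique(diary$participant_id))
  n_ep <- vapply(pids, function(p) sum(episodes$participant_id == p), 0L)
  interval <- rep(NA_real_, length(pids))
  for (i in seq_along(pids)) {
    if (n_ep[i] == 0L) next
    if (method == "span") {
      d <- diary$date[diary$participant_id == pids[i]]
      interval[i] <- (as.numeric(max(d) - min(d)) + 1) / n_ep[i]
    } else if (n_ep[i] >= 2L) {
      on <- sort(episodes$start_date[episodes$participant_id == pids[i]])
      interval[i] <- mean(as.numeric(diff(on)))
    }
  }
  data.frame(participant_id = pids, n_episodes = as.integer(n_ep),
             interval_days = interval, row.names = NULL)
}

#' Cohort-level episode summary
#'
#' Pools episode durations over all episodes and frequency intervals over
#' participants with at least one episode. Standard deviations use the
#' unbiased (n-1) estimator and are `NA` when fewer than two values exist.
#'
#' @param episodes output of [segment_episodes()].
#' @param intervals output of [flare_frequency_intervals()], or `NULL` to
#'   skip the frequency block.
#' @return list of class `episode_summary` with `n_flares_total` and the
#'   mean/sd/min/max of durations and frequency intervals.
#' @export
summarize_episodes <- function(episodes, intervals = NULL) {
  mom <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      return(list(mean = NA_real_, sd = NA_real_, min = NA_real_,
                  max = NA_real_, n = 0L))
    }
    list(mean = mean(x), sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
         min = min(x), max = max(x), n = length(x))
  }
  dur <- mom(episodes$duration_days)
  freq <- mom(intervals$interval_days)
  structure(list(
    n_flares_total = nrow(episodes),
    duration_mean = dur$mean, duration_sd = dur$sd,
    duration_min = dur$min, duration_max = dur$max,
    frequency_interval_mean = freq$mean, frequency_interval_sd = freq$sd,
    frequency_interval_min = freq$min, frequency_interval_max = freq$max,
    n_participants_with_flare = freq$n
  ), class = "episode_summary")
}

#' @export
print.episode_summary <- function(x, ...) {
  cat(sprintf("%d flare episodes in %d participants\n", x$n_flares_total,
              x$n_participants_with_flare))
  cat(sprintf("  duration (days): mean %.2f, sd %.2f, range %s-%s\n",
              x$duration_mean, x$duration_sd, format(x$duration_min),
              format(x$duration_max)))
  cat(sprintf("  frequency (one flare every X days): mean %.2f, sd %.2f, range %s-%s\n",
              x$frequency_interval_mean, x$frequency_interval_sd,
              format(x$frequency_interval_min),
              format(x$frequency_interval_max)))
  invisible(x)
}

#' Write an episode table to CSV
#' @param episodes output of [segment_episodes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  out <- episodes
  out$start_date <- format(out$start_date, "%Y-%m-%d")
  out$end_date <- format(out$end_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
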