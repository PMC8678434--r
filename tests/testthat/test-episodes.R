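episodes_of <- function(pattern) {
  d <- pattern_diary(pattern)
  segment_episodes(d)
}

test_that("contiguous flare runs form single episodes", {
  ep <- episodes_of("FFFO")
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$duration_days, 3L)
  expect_equal(ep$n_recorded_flare_days, 3L)
  expect_equal(ep$bridged_gap_count, 0L)
})

test_that("one missing day between flare entries is bridged into the episode", {
  ep <- episodes_of("F.F")
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$duration_days, 3L)
  expect_equal(ep$n_recorded_flare_days, 2L)
  expect_equal(ep$bridged_gap_count, 1L)
})

test_that("two consecutive missing days are never bridged", {
  ep <- episodes_of("F..F")
  expect_equal(nrow(ep), 2L)
  expect_equal(ep$duration_days, c(1L, 1L))
})

test_that("a recorded flare-off day always separates episodes", {
  ep <- episodes_of("FOF")
  expect_equal(nrow(ep), 2L)
  # ... and so does an entry day without a flare score, one day apart
  ep2 <- episodes_of("FEF")
  expect_equal(nrow(ep2), 2L)
})

test_that("segmentation handles empty and flare-free diaries", {
  expect_equal(nrow(episodes_of("OOEO")), 0L)
  d <- pattern_diary("EEE")  # entries but no flare scores at all
  expect_equal(nrow(segment_episodes(d)), 0L)
})

test_that("episodes touching the observation boundary are kept and flagged", {
  ep <- episodes_of("FOOF")
  expect_equal(nrow(ep), 2L)
  expect_true(all(ep$at_boundary))
  ep2 <- episodes_of("OFFO")
  expect_false(any(ep2$at_boundary))
})

test_that("segmentation agrees with the adjacency-component oracle on random patterns", {
  set.seed(42)
  origin <- as.Date("2020-01-01")
  for (rep in 1:300) {
    len <- sample(3:14, 1)
    sym <- sample(c("F", "O", ".", "E"), len, replace = TRUE,
                  prob = c(0.4, 0.25, 0.25, 0.1))
    entered <- which(sym != ".")
    if (length(entered) == 0L) next
    dates <- origin + entered - 1L
    st <- ifelse(sym[entered] == "F", TRUE,
                 ifelse(sym[entered] == "O", FALSE, NA))
    got <- segment_flare_days(dates, st)
    want <- oracle_segment(dates, st)
    expect_equal(got, want, info = paste(sym, collapse = ""))
  }
})

test_that("episode invariants hold on synthetic cohorts", {
  co <- generate_cohort(cohort_config(n_participants = 15L), seed = 11L)
  ep <- segment_episodes(co$diary)
  st <- flare_states(co$diary)
  # partition: every recorded flare-on day in exactly one episode
  on_days <- st[!is.na(st$flare_on) & st$flare_on, ]
  hits <- mapply(function(p, d) {
    sum(ep$participant_id == p & ep$start_date <= d & ep$end_date >= d)
  }, on_days$participant_id, on_days$date)
  expect_true(all(hits == 1L))
  # no flare-off day inside any episode
  off_days <- st[!is.na(st$flare_on) & !st$flare_on, ]
  off_hits <- mapply(function(p, d) {
    sum(ep$participant_id == p & ep$start_date <= d & ep$end_date >= d)
  }, off_days$participant_id, off_days$date)
  expect_true(all(off_hits == 0L))
  # duration identity and bridge bound
  expect_equal(ep$duration_days,
               ep$n_recorded_flare_days + ep$bridged_gap_count)
  expect_true(all(ep$bridged_gap_count <= ep$n_recorded_flare_days - 1L))
  # idempotence: marking exactly the episode membership of each entry day
  # as the flare state and re-segmenting reproduces the same episodes
  for (p in unique(ep$participant_id)[1:5]) {
    sub <- ep[ep$participant_id == p, ]
    sp <- st[st$participant_id == p, ]
    in_ep <- vapply(sp$date, function(d) {
      any(sub$start_date <= d & sub$end_date >= d)
    }, TRUE)
    again <- segment_flare_days(sp$date, in_ep)
    expect_equal(nrow(again), nrow(sub))
    expect_equal(again$start_date, sub$start_date)
    expect_equal(again$end_date, sub$end_date)
  }
})

test_that("frequency intervals follow the span-over-episode-count definition", {
  d <- pattern_diary(paste0("F", strrep("O", 98), "F"))  # 100-day span
  ep <- segment_episodes(d)
  iv <- flare_frequency_intervals(d, ep)
  expect_equal(iv$n_episodes, 2L)
  expect_equal(iv$interval_days, 50)
  # single episode over the whole span
  d1 <- pattern_diary(paste0("F", strrep(".", 0), "F", strrep("O", 8)))
  iv1 <- flare_frequency_intervals(d1, segment_episodes(d1))
  expect_equal(iv1$interval_days, 10 / 1)
  # no episodes: undefined and excluded from summaries
  d0 <- pattern_diary("OOOOO")
  iv0 <- flare_frequency_intervals(d0, segment_episodes(d0))
  expect_true(is.na(iv0$interval_days))
  s <- summarize_episodes(segment_episodes(d0), iv0)
  expect_equal(s$n_flares_total, 0L)
  expect_true(is.na(s$frequency_interval_mean))
})

test_that("onset-gap frequency definition is available behind the switch", {
  d <- pattern_diary("FOOOOOOFOOOOF")  # onsets at days 1, 8, 13
  ep <- segment_episodes(d)
  iv <- flare_frequency_intervals(d, ep, method = "onset_gap")
  expect_equal(iv$interval_days, mean(c(7, 5)))
})

test_that("episode summaries use unbiased moments and honour denominators", {
  eps <- data.frame(
    participant_id = c("A", "A", "B"),
    start_date = as.Date("2020-01-01") + c(0, 10, 0),
    end_date = as.Date("2020-01-01") + c(0, 12, 4),
    duration_days = c(1L, 3L, 5L),
    n_recorded_flare_days = c(1L, 3L, 5L),
    bridged_gap_count = c(0L, 0L, 0L), at_boundary = FALSE
  )
  s <- summarize_episodes(eps)
  expect_equal(s$n_flares_total, 3L)
  expect_equal(s$duration_mean, 3)
  expect_equal(s$duration_sd, 2)
  expect_equal(c(s$duration_min, s$duration_max), c(1, 5))
  # single episode: sd undefined, reported as missing
  s1 <- summarize_episodes(eps[1, ])
  expect_true(is.na(s1$duration_sd))
})

test_that("generator durations propagate through segmentation at scale", {
  # geometric durations with mean 4 and no missingness: pooled duration
  # mean over ~2000 episodes stays within 0.2 of the configured mean
  set.seed(7)
  durs <- integer(0)
  while (length(durs) < 2000) {
    pr <- sample_flare_process(400L, 4, 10)
    durs <- c(durs, pr$episodes$duration_days)
  }
  expect_lt(abs(mean(durs[1:2000]) - 4), 0.2)
})
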