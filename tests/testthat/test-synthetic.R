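test_that("generation is deterministic given config and seed", {
  cfg <- cohort_config(n_participants = 6L)
  a <- generate_cohort(cfg, seed = 123L)
  b <- generate_cohort(cfg, seed = 123L)
  expect_identical(a$diary, b$diary)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cfg, seed = 124L)
  expect_false(identical(as.data.frame(a$diary), as.data.frame(c$diary)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(generate_cohort(cohort_config(n_participants = 3L), seed = 5L))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("every diary respects the data model contract", {
  co <- generate_cohort(cohort_config(n_participants = 10L), seed = 8L)
  d <- co$diary
  expect_s3_class(d, "flare_diary")
  expect_true(all(d$score %in% 1:5))
  # at most 10 variables per participant: 7 fixed symptoms + flare + 2 optional
  per <- tapply(d$variable, d$participant_id, function(v) length(unique(v)))
  expect_true(all(per <= 10L))
  opt <- tapply(d$variable, d$participant_id, function(v) {
    sum(unique(v) %in% petal_catalogue()$optional)
  })
  expect_true(all(opt <= 2L))
})

test_that("an impossible episode model is rejected", {
  expect_error(cohort_config(duration_mean = c(0.5, 3.5)), ">= 1")
  expect_error(sample_flare_process(10L, 0.2, 5), ">= 1")
})

test_that("zero flare probability propagates as an episode-free pipeline", {
  cfg <- cohort_config(n_participants = 4L, gap_mean = c(1e6, 1e6),
                       flare_fidelity = 1)
  co <- generate_cohort(cfg, seed = 2L)
  ep <- segment_episodes(co$diary)
  expect_equal(nrow(ep), 0L)
  s <- summarize_episodes(ep, flare_frequency_intervals(co$diary, ep))
  expect_equal(s$n_flares_total, 0L)
})

test_that("episode process matches its configured duration means", {
  # 2000 episodes per phenotype: empirical mean within 3 standard errors
  set.seed(606)
  for (z in 1:2) {
    mu <- c(7.2, 3.5)[z]
    durs <- numeric(0)
    while (length(durs) < 2000) {
      pr <- sample_flare_process(600L, mu, c(28.1, 31.8)[z])
      # drop window-truncated final episodes to avoid censoring bias
      eps <- pr$episodes
      keep <- eps$start_day + eps$duration_days - 1L < 600L
      durs <- c(durs, eps$duration_days[keep])
    }
    durs <- durs[1:2000]
    se <- sd(durs) / sqrt(2000)
    expect_lt(abs(mean(durs) - mu), 3 * se)
  }
})

test_that("latent flare state is recoverable from the flare petal", {
  co <- generate_cohort(cohort_config(n_participants = 12L), seed = 17L)
  # reconstruct per-day truth from the latent episodes
  st <- flare_states(co$diary)
  st <- st[!is.na(st$flare_on), ]
  eps <- co$truth$episodes
  fu <- co$truth$follow_up_days
  truth_state <- mapply(function(p, d) {
    any(eps$participant_id == p & eps$start_date <= d &
          eps$start_date + eps$duration_days - 1 >= d)
  }, st$participant_id, st$date)
  agree <- mean(st$flare_on == truth_state)
  expect_gte(agree, 0.99)
})

test_that("MCAR masking leaves difference features unbiased", {
  base <- cohort_config(n_participants = 120L, cluster_weights = c(1, 0.0001),
                        missing_day_prob = 0, missing_petal_prob = 0,
                        shift_sd = 0)
  masked <- cohort_config(n_participants = 120L, cluster_weights = c(1, 0.0001),
                          missing_day_prob = 0.3, missing_petal_prob = 0.1,
                          shift_sd = 0)
  mean_diff <- function(cfg, seed) {
    co <- generate_cohort(cfg, seed)
    f <- flare_features(co$diary)
    mean(f$diff[f$variable == "pain"], na.rm = TRUE)
  }
  d0 <- mean(vapply(1:4, function(s) mean_diff(base, s), 1))
  d1 <- mean(vapply(1:4, function(s) mean_diff(masked, s), 1))
  # both estimate the same attenuated pain shift; allow Monte-Carlo error
  expect_lt(abs(d0 - d1), 0.05)
})

test_that("baseline covariates respect their structural invariants", {
  co <- generate_cohort(cohort_config(n_participants = 200L), seed = 12L)
  b <- co$baseline
  smoke <- b[c("current_smoker", "ex_smoker", "never_smoker")]
  present <- !is.na(smoke$current_smoker)
  expect_true(all(rowSums(smoke[present, ]) == 1))
  both <- !is.na(b$female)
  expect_true(all(b$female[both] + b$male[both] == 1))
  # group-2 never smokes currently under the default model
  cur <- b$current_smoker[co$truth$cluster == 2]
  expect_true(all(cur %in% c(0, NA)))
})

test_that("the fixture suite writes the documented artefacts", {
  dir <- file.path(tempdir(), "fixtures-test")
  emit_fixture_suite(dir, seed = 5L)
  expect_true(file.exists(file.path(dir, "bridge_single_gap.csv")))
  bridge <- read_diary(file.path(dir, "bridge_single_gap.csv"))
  ep <- segment_episodes(bridge)
  expect_equal(ep$duration_days[1], 3L)
  expect_equal(ep$bridged_gap_count[1], 1L)
  two <- segment_episodes(read_diary(file.path(dir, "bridge_double_gap.csv")))
  expect_equal(nrow(two), 2L)
  manifest <- jsonlite::fromJSON(file.path(dir, "null_cohort", "manifest.json"))
  expect_equal(manifest$seed, 5L)
  null_vars <- manifest$variables
  expect_true(all(null_vars$shift1 == 0 & null_vars$shift2 == 0))
  dd <- utils::read.csv(file.path(dir, "duplicate_rows.csv"))
  expect_true(any(duplicated(dd[c("x", "y")])))
  # generated cohorts round-trip through the reader
  d <- read_diary(file.path(dir, "planted_cohort", "diary.csv"))
  expect_s3_class(d, "flare_diary")
})
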