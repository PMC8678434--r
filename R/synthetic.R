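# Default per-variable generative parameters. Baseline means are the
# flare-off Likert means of the two phenotype groups; shifts are the
# latent-scale change applied on flare days (negative = worse). The seven
# fixed symptom variables carry the planted cluster contrast; optional
# petals get a neutral 3.5 baseline and small cluster-specific shifts.
# Anti-inflammatory use is kept on the common 1-5 scale (baseline rescaled
# from its published 0-1 presentation; see the methods vignette).
default_variable_params <- function() {
  v <- rbind(
    data.frame(
      variable = c("pain", "fatigue", "sleep quality", "recommended exercise",
                   "mood", "anti-inflammatory use", "stress"),
      baseline_mean1 = c(3.777, 3.445, 3.328, 3.494, 3.302, 2.70, 3.977),
      baseline_mean2 = c(3.834, 3.666, 3.630, 3.934, 3.494, 2.80, 4.049),
      shift1 = c(-0.694, -0.368, -0.151, -0.274, -0.251, 0.131, -0.101),
      shift2 = c(-0.984, -1.111, -0.438, -0.422, -0.800, 0.128, -0.980)
    ),
    data.frame(
      variable = c("caffeine intake", "hot flushes", "adherence to medication",
                   "screen time", "confidence in self-management", "eyesight",
                   "hydration", "chest pain", "flare of psoriasis",
                   "impact of menstrual cycle", "red painful eyes",
                   "smoking habits", "blood in stool"),
      baseline_mean1 = 3.5, baseline_mean2 = 3.5,
      shift1 = c(-0.015, -0.408, -0.008, -0.124, -0.330, -0.077, -0.103,
                 -0.227, -0.024, -0.115, -0.094, 0.132, 0),
      shift2 = c(-0.122, -0.348, -0.032, -0.619, -0.779, -0.362, 0.046,
                 -0.956, 0, -0.399, 0.043, 0, 0.224)
    )
  )
  rownames(v) <- NULL
  v
}

# Baseline clinical covariate model: per-cluster normal means/sds for the
# continuous indices, Bernoulli probabilities for the binaries, and a
# three-category smoking multinomial.
default_baseline_params <- function() {
  list(
    continuous = data.frame(
      covariate = baseline_continuous(),
      mean1 = c(3.173, 3.680, 3.627, 0.618, 2.585, 1.906, 4.018, 8.060,
                3.640, 4.240),
      sd1 = c(2.069, 1.733, 2.568, 0.191, 0.663, 1.005, 2.057, 4.716,
              2.691, 2.722),
      mean2 = c(3.533, 3.852, 3.715, 0.659, 2.400, 1.600, 3.429, 7.935,
                4.000, 3.950),
      sd2 = c(2.082, 2.081, 2.214, 0.240, 0.940, 0.754, 2.420, 5.234,
              3.162, 2.964)
    ),
    binary = data.frame(
      covariate = c("employed", "female", "hla_b27_positive", "bdmard_ever",
                    "chronic_widespread_pain"),
      p1 = c(0.592, 0.354, 0.818, 0.427, 0.188),
      p2 = c(0.650, 0.303, 0.813, 0.515, 0.333)
    ),
    smoking = rbind(group1 = c(0.154, 0.431, 0.415),
                    group2 = c(0.000, 0.333, 0.667)),
    missing_prob = 0.15
  )
}

#' Synthetic cohort configuration
#'
#' Full parameterization of the generative model behind the synthetic
#' diary cohort: a two-component phenotype mixture, lognormal follow-up,
#' an alternating renewal flare process with shifted-geometric episode
#' durations and inter-episode gaps, latent-Gaussian Likert symptom scores
#' with cluster-specific flare shifts, MCAR missingness, and a baseline
#' covariate model. Defaults emulate the published cohort structure: a
#' 96:33 phenotype mixture, follow-up with mean about 157 days, a flare
#' roughly every 35 days with mean durations 7.2 vs 3.5 days, and the
#' per-cluster symptom shift and baseline profiles of the two groups.
#'
#' @param n_participants cohort size, default 129.
#' @param cluster_weights positive mixture weights, default `c(96, 33)`.
#' @param follow_up_meanlog,follow_up_sdlog lognormal number of logged
#'   diary days; the defaults give a mean of about 220 and sd of about
#'   190, the moments implied for the analysis-eligible cohort (the
#'   published whole-registry mean of about 157 days averages over the
#'   roughly one third of registrants who logged fewer than 10 days and
#'   enter no analysis; see the methods vignette).
#' @param follow_up_min,follow_up_max clamp for the logged-day count;
#'   the default minimum of 10 matches the eligibility cutoff.
#' @param duration_mean per-cluster mean flare duration in days
#'   (shifted-geometric), default `c(7.2, 3.5)`.
#' @param gap_mean per-cluster mean inter-episode gap in days, default
#'   `c(28.1, 31.8)` so that one flare cycle averages about 35 days.
#' @param duration_dispersion `NULL` for geometric durations, or a
#'   negative-binomial size parameter for heavier-tailed durations.
#' @param variables per-variable parameter table; see
#'   `flarediary:::default_variable_params()` for the expected columns.
#' @param daily_sd latent within-day noise sd (Likert points), default 0.5.
#' @param between_sd between-participant baseline sd, default 0.45.
#' @param shift_sd between-participant sd of the individual flare shift
#'   around the cluster shift, default 0.05 (planted phenotypes are
#'   internally homogeneous; see the methods vignette).
#' @param shared_daily_sd sd of an optional shared within-day factor added
#'   to every variable (models within-day symptom correlation); default 0.
#' @param threshold flare petal binarization threshold the cohort is
#'   generated to be consistent with, default 3.
#' @param flare_fidelity probability that the emitted flare petal score is
#'   on the correct side of `threshold`, default 0.995.
#' @param missing_day_prob probability a whole diary day is missing (MCAR),
#'   default 0.2.
#' @param missing_petal_prob probability an individual petal is unscored on
#'   an otherwise entered day, default 0.03.
#' @param informative_missingness extra day-missingness probability on
#'   flare days (0 = MCAR, the default); probes adherence bias.
#' @param baseline baseline covariate model; see
#'   `flarediary:::default_baseline_params()`.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 129L,
                          cluster_weights = c(96, 33),
                          follow_up_meanlog = 5.115,
                          follow_up_sdlog = 0.747,
                          follow_up_min = 10L, follow_up_max = 711L,
                          duration_mean = c(7.2, 3.5),
                          gap_mean = c(28.1, 31.8),
                          duration_dispersion = NULL,
                          variables = default_variable_params(),
                          daily_sd = 0.5, between_sd = 0.45,
                          shift_sd = 0.05, shared_daily_sd = 0,
                          threshold = 3L, flare_fidelity = 0.995,
                          missing_day_prob = 0.2,
                          missing_petal_prob = 0.03,
                          informative_missingness = 0,
                          baseline = default_baseline_params()) {
  abort_if(!is_count(n_participants) || n_participants < 1,
           "n_participants must be a positive integer")
  abort_if(length(cluster_weights) != 2L || any(cluster_weights <= 0),
           "cluster_weights must be two positive weights")
  abort_if(any(duration_mean < 1) || any(gap_mean < 1),
           "duration_mean and gap_mean must be >= 1 day")
  probs <- c(flare_fidelity, missing_day_prob, missing_petal_prob,
             informative_missingness)
  abort_if(any(probs < 0 | probs > 1), "probabilities must be in [0, 1]")
  abort_if(!all(c("variable", "baseline_mean1", "baseline_mean2", "shift1",
                  "shift2") %in% names(variables)),
           "variables table is missing required columns")
  variables$variable <- canonical_variables(variables$variable)
  abort_if(!setequal(variables$variable,
                     setdiff(all_variables(), "flare")),
           "variables table must cover every petal except 'flare'")
  structure(list(
    n_participants = as.integer(n_participants),
    cluster_weights = cluster_weights,
    follow_up = list(meanlog = follow_up_meanlog, sdlog = follow_up_sdlog,
                     min = follow_up_min, max = follow_up_max),
    duration_mean = duration_mean, gap_mean = gap_mean,
    duration_dispersion = duration_dispersion,
    variables = variables, daily_sd = daily_sd, between_sd = between_sd,
    shift_sd = shift_sd, shared_daily_sd = shared_daily_sd,
    threshold = as.integer(threshold), flare_fidelity = flare_fidelity,
    missing_day_prob = missing_day_prob,
    missing_petal_prob = missing_petal_prob,
    informative_missingness = informative_missingness,
    baseline = baseline
  ), class = "cohort_config")
}

# shifted-geometric (or negative-binomial) positive count with mean m
sample_lengths <- function(n, m, dispersion = NULL) {
  if (n == 0L) return(integer(0))
  if (m <= 1) return(rep(1L, n))
  if (is.null(dispersion)) {
    1L + stats::rgeom(n, prob = 1 / m)
  } else {
    1L + stats::rnbinom(n, size = dispersion, mu = m - 1)
  }
}

#' Sample one alternating flare/non-flare process
#'
#' Alternating renewal process over a follow-up window: off-gaps and flare
#' episodes alternate, both with shifted-geometric lengths (support >= 1
#' day) of the given means, starting in the non-flare state. With a
#' `dispersion` value, episode durations become shifted negative-binomial,
#' a heavier-tailed option for duration sds well above the mean.
#'
#' @param n_days window length in days.
#' @param duration_mean mean episode duration (days).
#' @param gap_mean mean inter-episode gap (days).
#' @param dispersion `NULL` (geometric) or negative-binomial size.
#' @return list: `state` (logical vector of length `n_days`, `TRUE` =
#'   in flare), `episodes` (data frame `start_day`, `duration_days` of the
#'   latent episodes, truncated at the window edge).
#' @export
sample_flare_process <- function(n_days, duration_mean, gap_mean,
                                 dispersion = NULL) {
  abort_if(!is_count(n_days) || n_days < 1, "n_days must be >= 1")
  abort_if(duration_mean < 1 || gap_mean < 1,
           "duration_mean and gap_mean must be >= 1 day")
  state <- logical(n_days)
  starts <- integer(0)
  durs <- integer(0)
  t <- 1L
  in_flare <- FALSE
  while (t <= n_days) {
    len <- sample_lengths(1L, if (in_flare) duration_mean else gap_mean,
                          if (in_flare) dispersion else NULL)
    if (in_flare) {
      end <- min(t + len - 1L, n_days)
      state[t:end] <- TRUE
      starts <- c(starts, t)
      durs <- c(durs, end - t + 1L)
    }
    t <- t + len
    in_flare <- !in_flare
  }
  list(state = state,
       episodes = data.frame(start_day = starts, duration_days = durs))
}

#' Generate a synthetic diary cohort
#'
#' Draws a full cohort from a [cohort_config()]: per participant, a cluster
#' label, a follow-up window, a latent alternating flare process, daily
#' latent-Gaussian scores per variable (baseline + individual offset +
#' flare shift + noise, rounded and clipped onto the 1-5 Likert scale), a
#' flare petal consistent with the latent state at the configured fidelity,
#' two optional petals, day- and petal-level missingness, and baseline
#' clinical covariates. Fully deterministic given `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list of class `synthetic_cohort`: `diary` (a `flare_diary`),
#'   `baseline` (a `baseline_table`), and `truth` with per-participant
#'   `cluster` (named integer vector), latent `episodes` (before
#'   missingness), `shifts` (participants x variables matrix of individual
#'   latent shifts) and `follow_up_days`; plus the `config` and `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  abort_if(!is_count(seed), "seed must be an integer")
  with_seed(seed, generate_cohort_impl(config, seed))
}

generate_cohort_impl <- function(config, seed) {
  n <- config$n_participants
  pids <- sprintf("P%03d", seq_len(n))
  vars <- config$variables
  nv <- nrow(vars)
  w <- config$cluster_weights / sum(config$cluster_weights)
  cluster <- sample(1:2, n, replace = TRUE, prob = w)
  names(cluster) <- pids

  # the lognormal models the number of days LOGGED; since whole-day
  # missingness thins the window, the observation window is inflated so
  # that the expected logged-day count matches the target distribution
  fu <- round(stats::rlnorm(n, config$follow_up$meanlog,
                            config$follow_up$sdlog))
  fu <- pmin(pmax(fu, config$follow_up$min), config$follow_up$max)
  window <- pmax(round(fu / (1 - config$missing_day_prob)), 1L)
  origin <- as.Date("2019-01-01")

  shifts <- matrix(NA_real_, n, nv, dimnames = list(pids, vars$variable))
  diary_pieces <- vector("list", n)
  truth_pieces <- vector("list", n)

  optional <- petal_catalogue()$optional
  thr <- config$threshold

  for (i in seq_len(n)) {
    z <- cluster[i]
    F <- window[i]
    proc <- sample_flare_process(F, config$duration_mean[z],
                                 config$gap_mean[z],
                                 config$duration_dispersion)
    if (nrow(proc$episodes) > 0L) {
      tp <- proc$episodes
      tp$participant_id <- pids[i]
      tp$start_date <- origin + tp$start_day - 1L
      truth_pieces[[i]] <- tp
    }

    base_v <- ifelse(rep(z, nv) == 1L, vars$baseline_mean1,
                     vars$baseline_mean2)
    shift_c <- ifelse(rep(z, nv) == 1L, vars$shift1, vars$shift2)
    b_i <- stats::rnorm(nv, 0, config$between_sd)
    s_i <- shift_c + stats::rnorm(nv, 0, config$shift_sd)
    shifts[i, ] <- s_i

    chosen <- sample(optional, 2L)
    use <- vars$variable %in% c(clustering_variables(), chosen)
    vuse <- which(use)
    k <- length(vuse)

    shared <- if (config$shared_daily_sd > 0) {
      stats::rnorm(F, 0, config$shared_daily_sd)
    } else {
      numeric(F)
    }
    # latent matrix: days x used variables
    lat <- matrix(base_v[vuse] + b_i[vuse], F, k, byrow = TRUE) +
      outer(proc$state, s_i[vuse]) + shared +
      matrix(stats::rnorm(F * k, 0, config$daily_sd), F, k)
    score <- pmin(pmax(as.integer(round(lat)), 1L), 5L)

    # flare petal: right side of the threshold with prob flare_fidelity
    ok <- stats::runif(F) < config$flare_fidelity
    side_on <- ifelse(ok, proc$state, !proc$state)
    lo <- sample.int(thr, F, replace = TRUE)
    hi <- thr + sample.int(5L - thr, F, replace = TRUE)
    flare_score <- ifelse(side_on, lo, hi)

    # missingness: whole days, then individual petals
    p_day <- config$missing_day_prob +
      config$informative_missingness * proc$state
    keep_day <- stats::runif(F) >= pmin(p_day, 1)
    day_idx <- which(keep_day)
    if (length(day_idx) == 0L) day_idx <- 1L  # ensure one entry per participant
    nd <- length(day_idx)

    sc <- matrix(score, F, k)[day_idx, , drop = FALSE]
    all_scores <- cbind(sc, flare_score[day_idx])
    var_names <- c(vars$variable[vuse], "flare")
    keep_petal <- matrix(
      stats::runif(nd * (k + 1L)) >= config$missing_petal_prob, nd, k + 1L
    )
    rows <- which(keep_petal, arr.ind = TRUE)
    diary_pieces[[i]] <- data.frame(
      participant_id = pids[i],
      date = origin + day_idx[rows[, 1]] - 1L,
      variable = var_names[rows[, 2]],
      score = all_scores[rows],
      stringsAsFactors = FALSE
    )
  }

  diary <- as_flare_diary(do.call(rbind, diary_pieces),
                          source = "synthetic cohort")
  truth_eps <- if (length(Filter(Negate(is.null), truth_pieces))) {
    out <- do.call(rbind, Filter(Negate(is.null), truth_pieces))
    out <- out[c("participant_id", "start_date", "start_day",
                 "duration_days")]
    rownames(out) <- NULL
    out
  } else {
    data.frame(participant_id = character(), start_date = as.Date(character()),
               start_day = integer(), duration_days = integer())
  }

  baseline <- generate_baseline(pids, cluster, config$baseline)

  structure(list(
    diary = diary, baseline = baseline,
    truth = list(cluster = cluster, episodes = truth_eps, shifts = shifts,
                 follow_up_days = stats::setNames(as.integer(fu), pids)),
    config = config, seed = seed
  ), class = "synthetic_cohort")
}

generate_baseline <- function(pids, cluster, bp) {
  n <- length(pids)
  out <- data.frame(participant_id = pids, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(bp$continuous))) {
    v <- bp$continuous$covariate[j]
    m <- ifelse(cluster == 1L, bp$continuous$mean1[j], bp$continuous$mean2[j])
    s <- ifelse(cluster == 1L, bp$continuous$sd1[j], bp$continuous$sd2[j])
    x <- stats::rnorm(n, m, s)
    x[stats::runif(n) < bp$missing_prob] <- NA_real_
    out[[v]] <- x
  }
  bin <- stats::setNames(
    lapply(seq_len(nrow(bp$binary)), function(j) {
      p <- ifelse(cluster == 1L, bp$binary$p1[j], bp$binary$p2[j])
      x <- as.numeric(stats::runif(n) < p)
      x[stats::runif(n) < bp$missing_prob] <- NA_real_
      x
    }),
    bp$binary$covariate
  )
  out$employed <- bin$employed
  out$female <- bin$female
  out$male <- 1 - bin$female                 # jointly missing, complementary
  out$hla_b27_positive <- bin$hla_b27_positive
  smoke_cat <- vapply(seq_len(n), function(i) {
    sample.int(3L, 1L, prob = bp$smoking[cluster[i], ])
  }, 1L)
  smoke_missing <- stats::runif(n) < bp$missing_prob
  out$current_smoker <- ifelse(smoke_missing, NA_real_,
                               as.numeric(smoke_cat == 1L))
  out$ex_smoker <- ifelse(smoke_missing, NA_real_,
                          as.numeric(smoke_cat == 2L))
  out$never_smoker <- ifelse(smoke_missing, NA_real_,
                             as.numeric(smoke_cat == 3L))
  out$bdmard_ever <- bin$bdmard_ever
  out$chronic_widespread_pain <- bin$chronic_widespread_pain
  structure(out, class = c("baseline_table", "data.frame"))
}

#' Write a synthetic cohort to disk
#'
#' Emits the canonical long diary CSV, the baseline covariate CSV and a
#' manifest JSON recording the full configuration and seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_diary(cohort$diary, file.path(dir, "diary.csv"))
  bl <- as.data.frame(cohort$baseline)
  utils::write.csv(bl, file.path(dir, "baseline.csv"), row.names = FALSE)
  cfg <- cohort$config
  manifest <- list(
    generator = "flarediary synthetic cohort",
    seed = cohort$seed,
    config = cfg[setdiff(names(cfg), "variables")],
    variables = cfg$variables
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

#' Emit the canonical small test fixtures
#'
#' Writes the named fixtures used throughout the test suite:
#' single-participant diaries exercising the single-missing-day bridge rule
#' (`bridge_single_gap.csv`, `bridge_double_gap.csv`,
#' `bridge_recorded_off.csv`), a duplicate-row clustering instance
#' (`duplicate_rows.csv`), a null-effect cohort with no planted shifts and
#' one phenotype (`null_cohort/`), and a cohort at the default planted
#' two-phenotype parameterization (`planted_cohort/`), each with its
#' manifest.
#'
#' @param dir output directory.
#' @param seed seed for the two generated cohorts.
#' @return `dir`, invisibly.
#' @export
emit_fixture_suite <- function(dir, seed = 20201L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  day <- function(k) as.Date("2019-06-01") + k - 1L
  mk <- function(dates, scores, file) {
    df <- data.frame(participant_id = "P001", date = day(dates),
                     variable = "flare", score = scores)
    write_diary(as_flare_diary(df), file.path(dir, file))
  }
  # flare-on / missing / flare-on: one bridged episode of duration 3
  mk(c(1, 3, 4), c(1, 2, 5), "bridge_single_gap.csv")
  # flare-on / 2 missing days / flare-on: two separate episodes
  mk(c(1, 4, 5), c(1, 2, 5), "bridge_double_gap.csv")
  # flare-on / recorded flare-off / flare-on: never merged
  mk(c(1, 2, 3), c(1, 5, 2), "bridge_recorded_off.csv")

  # feature-space instance with exactly duplicated rows (P001=P002, P004=P005)
  dup <- data.frame(
    participant_id = sprintf("P%03d", 1:6),
    x = c(0, 0, 0.1, 3, 3, 3.1), y = c(0, 0, 0.1, 0, 0, 0.1)
  )
  utils::write.csv(dup, file.path(dir, "duplicate_rows.csv"),
                   row.names = FALSE)

  null_cfg <- cohort_config(
    n_participants = 20L, cluster_weights = c(1, 1),
    variables = within(default_variable_params(), {
      shift2 <- shift1 <- 0
      baseline_mean2 <- baseline_mean1
    }),
    duration_mean = c(4.3, 4.3), gap_mean = c(31, 31), shift_sd = 0
  )
  write_cohort(generate_cohort(null_cfg, seed), file.path(dir, "null_cohort"))
  write_cohort(generate_cohort(cohort_config(n_participants = 30L), seed + 1L),
               file.path(dir, "planted_cohort"))
  invisible(dir)
}
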