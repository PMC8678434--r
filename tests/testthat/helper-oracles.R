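# Independent oracles and small fixture builders shared across tests.
# Each oracle is written directly from the definition it checks, using a
# different algorithmic route than the package implementation.

# --- diary builders -------------------------------------------------------

# one-participant diary from a day-pattern string over consecutive days:
#   "F" flare-on entry, "O" flare-off entry, "." no entry, "E" entry with
#   no flare score (pain only)
pattern_diary <- function(pattern, pid = "P001",
                          origin = as.Date("2020-01-01")) {
  sym <- strsplit(pattern, "")[[1]]
  rows <- list()
  for (i in seq_along(sym)) {
    d <- origin + i - 1L
    rows[[i]] <- switch(sym[i],
      "F" = data.frame(participant_id = pid, date = d,
                       variable = "flare", score = 2L),
      "O" = data.frame(participant_id = pid, date = d,
                       variable = "flare", score = 5L),
      "E" = data.frame(participant_id = pid, date = d,
                       variable = "pain", score = 3L),
      "." = NULL
    )
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(NULL)
  as_flare_diary(do.call(rbind, rows))
}

# --- episode segmentation oracle ------------------------------------------

# brute-force reimplementation of the bridge rule via pairwise adjacency
# and connected components: flare days d, d' belong to the same episode iff
# they are chained by links where |d - d'| == 1, or |d - d'| == 2 and the
# day between them has no diary entry.
oracle_segment <- function(entry_dates, flare_on) {
  ord <- order(entry_dates)
  entered <- as.integer(entry_dates[ord])
  st <- flare_on[ord]
  on <- entered[!is.na(st) & st]
  if (length(on) == 0L) {
    return(data.frame(start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      duration_days = integer(),
                      n_recorded_flare_days = integer(),
                      bridged_gap_count = integer()))
  }
  comp <- seq_along(on)
  link <- function(i, j) {
    ci <- comp[i]; cj <- comp[j]
    comp[comp == cj] <<- ci
  }
  for (i in seq_along(on)) {
    for (j in seq_along(on)) {
      if (i >= j) next
      gap <- on[j] - on[i]
      if (gap == 1L) link(i, j)
      if (gap == 2L && !((on[i] + 1L) %in% entered)) link(i, j)
    }
  }
  eps <- lapply(unique(comp), function(cc) {
    days <- on[comp == cc]
    data.frame(start = min(days), end = max(days), nrec = length(days))
  })
  eps <- do.call(rbind, eps)
  eps <- eps[order(eps$start), , drop = FALSE]
  data.frame(
    start_date = as.Date(eps$start, origin = "1970-01-01"),
    end_date = as.Date(eps$end, origin = "1970-01-01"),
    duration_days = as.integer(eps$end - eps$start + 1L),
    n_recorded_flare_days = eps$nrec,
    bridged_gap_count = as.integer(eps$end - eps$start + 1L - eps$nrec)
  )
}

# --- t-test formula oracles -----------------------------------------------

oracle_paired_t <- function(x, conf_level = 0.95) {
  n <- length(x)
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / (n - 1))
  se <- s / sqrt(n)
  tstat <- m / se
  df <- n - 1
  p <- 2 * stats::pt(-abs(tstat), df)
  crit <- stats::qt(1 - (1 - conf_level) / 2, df)
  list(estimate = m, t_stat = tstat, df = df, p_value = p,
       ci_low = m - crit * se, ci_high = m + crit * se)
}

oracle_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t_stat = tstat, df = df, p_value = p)
}

# --- clustering instance generator ----------------------------------------

# two well-separated planar blobs; `sep_ratio` = centre distance divided by
# the blob diameter (2 sd)
blob_instance <- function(n, sep_ratio = 4, spread = 0.5, seed = 1) {
  set.seed(seed)
  n1 <- ceiling(n / 2)
  n2 <- n - n1
  centre_dist <- sep_ratio * 2 * spread
  X <- rbind(
    cbind(rnorm(n1, 0, spread), rnorm(n1, 0, spread)),
    cbind(rnorm(n2, centre_dist, spread), rnorm(n2, 0, spread))
  )
  rownames(X) <- sprintf("p%02d", seq_len(n))
  list(X = X, truth = rep(1:2, c(n1, n2)))
}

# adjusted Rand index is taken from mclust (Suggests) in the tests that
# need it; skip-free because mclust ships with the test environment.
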