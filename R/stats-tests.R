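#' Paired t-test on per-participant difference features
#'
#' One-sample t-test of the per-participant differences (flare-on mean
#' minus flare-off mean) against zero, with a two-sided p-value and 95%
#' confidence interval — the paired test of flare-on vs flare-off scores.
#' Degenerate inputs are reported, never raised: with fewer than two
#' differences no inference is possible; with zero variance the test
#' collapses to `p = 1` (all differences zero) or the `p -> 0` limit
#' (constant non-zero difference).
#'
#' @param diffs numeric vector of per-participant differences (`NA` dropped).
#' @param conf_level confidence level, default 0.95.
#' @return list of class `paired_t_test`: `n`, `estimate`, `ci_low`,
#'   `ci_high`, `t_stat`, `df`, `p_value`, `degenerate`.
#' @export
paired_t_test <- function(diffs, conf_level = 0.95) {
  x <- diffs[!is.na(diffs)]
  n <- length(x)
  res <- list(n = n, estimate = NA_real_, ci_low = NA_real_,
              ci_high = NA_real_, t_stat = NA_real_, df = NA_real_,
              p_value = NA_real_, degenerate = TRUE, conf_level = conf_level)
  if (n >= 1L) res$estimate <- mean(x)
  if (n >= 2L) {
    res$df <- n - 1
    if (stats::sd(x) == 0) {
      res$ci_low <- res$ci_high <- res$estimate
      if (res$estimate == 0) {
        res$t_stat <- 0
        res$p_value <- 1
      } else {
        res$t_stat <- sign(res$estimate) * Inf
        res$p_value <- 0
      }
    } else {
      tt <- stats::t.test(x, conf.level = conf_level)
      res$t_stat <- unname(tt$statistic)
      res$p_value <- tt$p.value
      res$ci_low <- tt$conf.int[1]
      res$ci_high <- tt$conf.int[2]
      res$degenerate <- FALSE
    }
  }
  structure(res, class = "paired_t_test")
}

#' @export
print.paired_t_test <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: estimate %.3f, %d%% CI [%.3f, %.3f], t = %.3f, df = %s, p = %.4g, n = %d%s\n",
    x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high, x$t_stat,
    format(x$df), x$p_value, x$n, if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance two-sample t-test with Satterthwaite degrees of
#' freedom, used for all between-cluster comparisons (symptom means,
#' continuous baseline covariates, and 0/1 indicators, where it coincides
#' with an unpooled two-proportion z-test up to the df). Degenerate inputs
#' (a group with fewer than two values, or both groups constant) yield a
#' flagged result with an explanatory `reason` instead of an error.
#'
#' @param a,b numeric vectors (`NA` dropped per group).
#' @return list of class `welch_t_test`: group means/sds/ns, `t_stat`,
#'   `df`, `p_value`, `degenerate`, `reason`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  res <- list(
    mean_a = if (length(a)) mean(a) else NA_real_,
    mean_b = if (length(b)) mean(b) else NA_real_,
    sd_a = if (length(a) >= 2L) stats::sd(a) else NA_real_,
    sd_b = if (length(b) >= 2L) stats::sd(b) else NA_real_,
    n_a = length(a), n_b = length(b),
    t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
    degenerate = TRUE, reason = NA_character_
  )
  if (length(a) < 2L || length(b) < 2L) {
    res$reason <- "a group has fewer than 2 observations"
    return(structure(res, class = "welch_t_test"))
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    res$reason <- "both groups constant"
    res$df <- length(a) + length(b) - 2
    if (mean(a) == mean(b)) {
      res$t_stat <- 0
      res$p_value <- 1
    } else {
      res$t_stat <- sign(mean(a) - mean(b)) * Inf
      res$p_value <- 0
    }
    return(structure(res, class = "welch_t_test"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  res$t_stat <- unname(tt$statistic)
  res$df <- unname(tt$parameter)
  res$p_value <- tt$p.value
  res$degenerate <- FALSE
  structure(res, class = "welch_t_test")
}

#' @export
print.welch_t_test <- function(x, ...) {
  cat(sprintf(
    "Welch t-test: means %.3f vs %.3f (n = %d/%d), t = %.3f, df = %.2f, p = %.4g%s\n",
    x$mean_a, x$mean_b, x$n_a, x$n_b, x$t_stat, x$df, x$p_value,
    if (x$degenerate) paste0(" (degenerate: ", x$reason, ")") else ""
  ))
  invisible(x)
}

# catalogue-order, flare excluded: the reporting order for per-variable tables
table_variable_order <- function(catalogue = petal_catalogue()) {
  c(
    "pain", "fatigue", "sleep quality", "recommended exercise", "mood",
    "anti-inflammatory use", "stress",
    catalogue$optional
  )
}

#' Per-variable paired-test report
#'
#' One paired t-test per variable over the participants that have both a
#' flare-on and a flare-off mean for it (so `n` varies by variable).
#' Raw p-values are reported with a significance flag at `alpha`
#' (default 0.01); no multiple-testing correction is applied. Variables
#' with fewer than two paired participants yield an `NA` row rather than
#' an error.
#'
#' @param features a [flare_features()] data frame.
#' @param variables report order; defaults to the seven fixed symptom
#'   variables followed by the optional petals, restricted to variables
#'   present in `features`.
#' @param alpha significance convention for the `significant` flag.
#' @return data frame: `variable`, `estimate`, `p_value`, `ci_low`,
#'   `ci_high`, `n`, `significant`.
#' @export
build_table1 <- function(features, variables = NULL, alpha = 0.01) {
  stopifnot(inherits(features, "flare_features"))
  if (is.null(variables)) {
    variables <- intersect(table_variable_order(), unique(features$variable))
  } else {
    variables <- canonical_variables(variables)
  }
  rows <- lapply(variables, function(v) {
    d <- features$diff[features$variable == v]
    tt <- paired_t_test(d)
    data.frame(
      variable = v, estimate = tt$estimate, p_value = tt$p_value,
      ci_low = tt$ci_low, ci_high = tt$ci_high, n = tt$n,
      significant = !is.na(tt$p_value) && !tt$degenerate &&
        tt$p_value < alpha,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-cluster comparison tables
#'
#' Characterizes the clusters found by affinity propagation, mirroring the
#' three standard reports: difference features per cluster
#' (`differences`), flare-on and flare-off means per cluster (`means`),
#' and baseline covariates per cluster (`baseline`), each with Welch
#' t-test p-values between the two largest clusters. Inference on the
#' difference features is restricted to `test_variables` (by default the
#' clustering set, whose sample size equals the cluster size); other
#' variables are reported descriptively with `NA` p-values. Binary
#' covariates are compared as 0/1 indicators through the same Welch
#' machinery, or with a chi-square test when `binary_test = "chisq"`.
#' When `episodes` and the diary's cluster labels are supplied, episode
#' durations pooled within clusters are compared the same way
#' (`duration_welch`).
#'
#' @param features a [flare_features()] data frame.
#' @param labels named integer vector: cluster id per participant id.
#' @param baseline optional [read_baseline()] table.
#' @param episodes optional [segment_episodes()] table.
#' @param test_variables variables whose difference features get a Welch
#'   p-value; default [clustering_variables()].
#' @param min_n minimum per-group n for a non-degenerate comparison.
#' @param binary_test `"welch"` (default) or `"chisq"` for 0/1 covariates.
#' @return list of class `cluster_comparison`: data frames `differences`,
#'   `means`, `baseline` (or `NULL`), `duration_welch` (a
#'   [welch_t_test()] or `NULL`), plus `cluster_sizes`.
#' @export
compare_clusters <- function(features, labels, baseline = NULL,
                             episodes = NULL,
                             test_variables = clustering_variables(),
                             min_n = 2L,
                             binary_test = c("welch", "chisq")) {
  binary_test <- match.arg(binary_test)
  stopifnot(inherits(features, "flare_features"))
  abort_if(is.null(names(labels)), "labels must be named by participant_id")
  sizes <- sort(table(labels), decreasing = TRUE)
  abort_if(length(sizes) < 2L, "need at least two clusters to compare")
  g1 <- names(labels)[labels == names(sizes)[1]]
  g2 <- names(labels)[labels == names(sizes)[2]]
  test_variables <- canonical_variables(test_variables)

  welch_row <- function(a, b, test = TRUE) {
    w <- if (test && length(a[!is.na(a)]) >= min_n &&
             length(b[!is.na(b)]) >= min_n) welch_t_test(a, b) else NULL
    p <- if (!is.null(w) && !w$degenerate) w$p_value else NA_real_
    list(w = w, p = p)
  }

  vars <- intersect(table_variable_order(), unique(features$variable))
  diff_rows <- lapply(vars, function(v) {
    fv <- features[features$variable == v, , drop = FALSE]
    d1 <- fv$diff[fv$participant_id %in% g1]
    d2 <- fv$diff[fv$participant_id %in% g2]
    d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
    wr <- welch_row(d1, d2, test = v %in% test_variables)
    data.frame(
      variable = v,
      diff_group1 = if (length(d1)) mean(d1) else NA_real_, n_group1 = length(d1),
      diff_group2 = if (length(d2)) mean(d2) else NA_real_, n_group2 = length(d2),
      p_value = wr$p, stringsAsFactors = FALSE
    )
  })
  differences <- do.call(rbind, diff_rows)

  mean_rows <- lapply(c("on", "off"), function(side) {
    col <- if (side == "on") "mean_on" else "mean_off"
    do.call(rbind, lapply(intersect(test_variables, vars), function(v) {
      fv <- features[features$variable == v, , drop = FALSE]
      m1 <- fv[[col]][fv$participant_id %in% g1]
      m2 <- fv[[col]][fv$participant_id %in% g2]
      m1 <- m1[!is.na(m1)]; m2 <- m2[!is.na(m2)]
      wr <- welch_row(m1, m2)
      data.frame(
        side = paste0("flare_", side), variable = v,
        mean_group1 = if (length(m1)) mean(m1) else NA_real_,
        sd_group1 = if (length(m1) >= 2) stats::sd(m1) else NA_real_,
        n_group1 = length(m1),
        mean_group2 = if (length(m2)) mean(m2) else NA_real_,
        sd_group2 = if (length(m2) >= 2) stats::sd(m2) else NA_real_,
        n_group2 = length(m2),
        p_value = wr$p, stringsAsFactors = FALSE
      )
    }))
  })
  means <- do.call(rbind, mean_rows)

  baseline_tab <- NULL
  if (!is.null(baseline)) {
    covs <- c(baseline_continuous(), baseline_binary())
    is_bin <- covs %in% baseline_binary()
    baseline_tab <- do.call(rbind, lapply(seq_along(covs), function(i) {
      v <- covs[i]
      x1 <- baseline[[v]][baseline$participant_id %in% g1]
      x2 <- baseline[[v]][baseline$participant_id %in% g2]
      x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
      p <- NA_real_
      if (length(x1) >= min_n && length(x2) >= min_n) {
        if (is_bin[i] && binary_test == "chisq") {
          tab <- rbind(c(sum(x1), length(x1) - sum(x1)),
                       c(sum(x2), length(x2) - sum(x2)))
          p <- tryCatch(
            suppressWarnings(stats::chisq.test(tab)$p.value),
            error = function(e) NA_real_
          )
        } else {
          w <- welch_t_test(x1, x2)
          if (!w$degenerate) p <- w$p_value
        }
      }
      data.frame(
        covariate = v, binary = is_bin[i],
        mean_group1 = if (length(x1)) mean(x1) else NA_real_,
        sd_group1 = if (length(x1) >= 2) stats::sd(x1) else NA_real_,
        n_group1 = length(x1),
        mean_group2 = if (length(x2)) mean(x2) else NA_real_,
        sd_group2 = if (length(x2) >= 2) stats::sd(x2) else NA_real_,
        n_group2 = length(x2),
        p_value = p, stringsAsFactors = FALSE
      )
    }))
  }

  duration_welch <- NULL
  if (!is.null(episodes) && nrow(episodes) > 0L) {
    d1 <- episodes$duration_days[episodes$participant_id %in% g1]
    d2 <- episodes$duration_days[episodes$participant_id %in% g2]
    duration_welch <- welch_t_test(d1, d2)
  }

  structure(
    list(differences = differences, means = means, baseline = baseline_tab,
         duration_welch = duration_welch,
         cluster_sizes = as.integer(sizes),
         group1 = g1, group2 = g2),
    class = "cluster_comparison"
  )
}
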