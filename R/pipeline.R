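#' Pipeline configuration
#'
#' Configuration for the end-to-end analysis. Exactly one data source must
#' be given: paths to a diary CSV (plus optional baseline CSV), or a
#' [cohort_config()] for a synthetic cohort generated on the fly.
#'
#' @param diary_path,baseline_path input CSVs (`baseline_path` optional).
#' @param synthetic a [cohort_config()], mutually exclusive with
#'   `diary_path`.
#' @param threshold flare binarization threshold (1..5), default 3.
#' @param min_days cluster-analysis eligibility cutoff, default 10.
#' @param cluster_variables variables clustered on, default
#'   [clustering_variables()].
#' @param q,damping,max_iter,conv_window affinity propagation settings,
#'   see [affinity_propagation()].
#' @param alpha significance convention for reports, default 0.01.
#' @param frequency_method flare frequency definition, see
#'   [flare_frequency_intervals()].
#' @param normalization `"minmax"` or `"maxabs"`, see
#'   [normalize_features()].
#' @param out_dir output directory, or `NULL` for no files.
#' @param seed run seed (synthetic generation and AP tie-break jitter).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(diary_path = NULL, baseline_path = NULL,
                            synthetic = NULL, threshold = 3L,
                            min_days = 10L,
                            cluster_variables = clustering_variables(),
                            q = 0, damping = 0.9, max_iter = 1000L,
                            conv_window = 100L, alpha = 0.01,
                            frequency_method = c("span", "onset_gap"),
                            normalization = c("minmax", "maxabs"),
                            out_dir = NULL, seed = 1L) {
  abort_if(is.null(diary_path) == is.null(synthetic),
           "give exactly one of diary_path or synthetic")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "cohort_config"))
  structure(list(
    diary_path = diary_path, baseline_path = baseline_path,
    synthetic = synthetic, threshold = as.integer(threshold),
    min_days = as.integer(min_days),
    cluster_variables = canonical_variables(cluster_variables),
    q = q, damping = damping, max_iter = as.integer(max_iter),
    conv_window = as.integer(conv_window), alpha = alpha,
    frequency_method = match.arg(frequency_method),
    normalization = match.arg(normalization),
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' The JSON document mirrors the arguments of [pipeline_config()]; a
#' `synthetic` block holds [cohort_config()] arguments. Unknown fields are
#' errors.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  abort_if(!file.exists(path), "config file does not exist: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(pipeline_config)), "synthetic")
  extra <- setdiff(names(doc), c(known, "synthetic"))
  abort_if(length(extra) > 0L, "unknown config field(s): %s",
           paste(extra, collapse = ", "))
  if (!is.null(doc$synthetic)) {
    syn_known <- names(formals(cohort_config))
    syn_extra <- setdiff(names(doc$synthetic), syn_known)
    abort_if(length(syn_extra) > 0L, "unknown synthetic field(s): %s",
             paste(syn_extra, collapse = ", "))
    doc$synthetic <- do.call(cohort_config, doc$synthetic)
  }
  do.call(pipeline_config, doc)
}

#' Run the full flare analysis pipeline
#'
#' Executes every stage on one cohort: read or generate the diary, derive
#' flare states, segment episodes and summarize duration/frequency, build
#' flare-on/off features and the per-variable paired-test report, filter
#' for eligibility, normalize the difference features, cluster with
#' affinity propagation, and characterize the clusters (difference
#' features, flare-on/off means, baseline covariates, and a Welch
#' comparison of episode durations between clusters). Every filter logs
#' its before/after participant counts. With `out_dir` set, writes
#' `episodes.csv`, `features.csv`, `table1.csv`, `table2.csv`,
#' `table3.csv`, `table4.csv`, `labels.csv`, `report.json` and `run.log`;
#' all report files are byte-identical across reruns of the same config
#' and seed (wall-clock timestamps appear only in `run.log`).
#'
#' @param config a [pipeline_config()].
#' @return list of class `flare_run_report` with cohort counts, the
#'   episode summary, all tables, the clustering result and a structured
#'   log.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  logf <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    invisible(msg)
  }

  truth <- NULL
  baseline <- NULL
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic, seed = config$seed)
    diary <- cohort$diary
    baseline <- cohort$baseline
    truth <- cohort$truth
    logf("generated synthetic cohort: %d participants, seed %d",
         config$synthetic$n_participants, config$seed)
  } else {
    diary <- read_diary(config$diary_path)
    logf("read diary: %s", config$diary_path)
    if (!is.null(config$baseline_path)) {
      baseline <- read_baseline(config$baseline_path)
      logf("read baseline: %s", config$baseline_path)
    }
  }

  n_registered <- length(unique(diary$participant_id))
  states <- flare_states(diary, config$threshold)
  episodes <- segment_episodes(diary, config$threshold)
  with_flare <- unique(episodes$participant_id)
  logf("flare filter: %d -> %d participants with >= 1 flare episode",
       n_registered, length(with_flare))
  intervals <- flare_frequency_intervals(diary, episodes,
                                         config$frequency_method)
  ep_summary <- summarize_episodes(episodes, intervals)

  features <- flare_features(diary, config$threshold)
  table1 <- build_table1(features, alpha = config$alpha)

  eligible <- eligibility_filter(diary, config$min_days)
  logf("eligibility filter (>= %d entry days): %d -> %d participants",
       config$min_days, attr(eligible, "n_before"), attr(eligible, "n_after"))
  feat_elig <- flare_features(eligible, config$threshold)
  M <- feature_matrix(feat_elig, config$cluster_variables, complete = TRUE)
  logf("complete-case difference matrix: %d participants (%d dropped without both flare-on and flare-off data)",
       nrow(M), attr(M, "n_dropped_incomplete"))

  ap <- NULL
  comparison <- NULL
  labels <- NULL
  norm <- NULL
  if (nrow(M) >= 2L) {
    norm <- normalize_features(M, config$normalization)
    S <- build_similarity(norm$matrix, r = 2)
    ap <- affinity_propagation(
      S, q = config$q, damping = config$damping,
      max_iter = config$max_iter, conv_window = config$conv_window,
      seed = config$seed
    )
    labels <- stats::setNames(ap$cluster, rownames(M))
    logf("affinity propagation: %d clusters (sizes %s), %d iterations, %s",
         length(ap$exemplars), paste(sort(table(labels), decreasing = TRUE),
                                     collapse = "/"),
         ap$n_iterations,
         if (ap$converged) "converged" else "not converged")
    if (length(ap$exemplars) >= 2L) {
      comparison <- compare_clusters(
        feat_elig, labels, baseline = baseline, episodes = episodes,
        test_variables = config$cluster_variables
      )
    }
  } else {
    warning("fewer than 2 participants eligible for clustering; ",
            "cluster analysis skipped")
    logf("cluster analysis skipped: fewer than 2 eligible participants")
  }

  report <- structure(list(
    counts = list(
      n_registered = n_registered,
      n_with_flare = length(with_flare),
      n_eligible = attr(eligible, "n_after"),
      n_clustered = if (is.null(labels)) 0L else length(labels)
    ),
    episode_summary = ep_summary,
    table1 = table1,
    comparison = comparison,
    ap = ap, labels = labels, features = features,
    episodes = episodes, normalized = norm,
    truth = truth, config = config, log = log_lines,
    version = as.character(utils::packageVersion("flarediary"))
  ), class = "flare_run_report")

  if (!is.null(config$out_dir)) {
    write_run_report(report, config$out_dir)
  }
  report
}

# serialize the report to the output directory
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_episodes(report$episodes, file.path(dir, "episodes.csv"))
  write_features(report$features, file.path(dir, "features.csv"),
                 normalized = report$normalized)
  num <- function(df) {
    df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 10) else x)
    df
  }
  utils::write.csv(num(report$table1), file.path(dir, "table1.csv"),
                   row.names = FALSE)
  cmp <- report$comparison
  if (!is.null(cmp)) {
    utils::write.csv(num(cmp$differences), file.path(dir, "table2.csv"),
                     row.names = FALSE)
    utils::write.csv(num(cmp$means), file.path(dir, "table3.csv"),
                     row.names = FALSE)
    if (!is.null(cmp$baseline)) {
      utils::write.csv(num(cmp$baseline), file.path(dir, "table4.csv"),
                       row.names = FALSE)
    }
  }
  if (!is.null(report$ap)) {
    ids <- names(report$labels)
    utils::write.csv(data.frame(
      participant_id = ids, cluster_id = report$labels,
      is_exemplar = ids %in% ids[report$ap$exemplars]
    ), file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  }
  cfg <- report$config
  jsonlite::write_json(list(
    counts = report$counts,
    episode_summary = unclass(report$episode_summary),
    cluster_sizes = if (is.null(cmp)) NULL else cmp$cluster_sizes,
    ap = if (is.null(report$ap)) NULL else list(
      n_clusters = length(report$ap$exemplars),
      n_iterations = report$ap$n_iterations,
      converged = report$ap$converged,
      preference = report$ap$preference[1],
      net_similarity = report$ap$net_similarity
    ),
    duration_welch = if (is.null(cmp) || is.null(cmp$duration_welch)) NULL
      else unclass(cmp$duration_welch),
    config = list(
      threshold = cfg$threshold, min_days = cfg$min_days,
      cluster_variables = cfg$cluster_variables, q = cfg$q,
      damping = cfg$damping, max_iter = cfg$max_iter,
      conv_window = cfg$conv_window, alpha = cfg$alpha,
      frequency_method = cfg$frequency_method,
      normalization = cfg$normalization, seed = cfg$seed,
      synthetic = !is.null(cfg$synthetic)
    ),
    log = report$log,
    version = report$version
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE, null = "null")
  writeLines(paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), report$log),
             file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.flare_run_report <- function(x, ...) {
  cat("Flare diary analysis run\n")
  cat(sprintf("  participants: %d registered, %d with >= 1 flare, %d eligible, %d clustered\n",
              x$counts$n_registered, x$counts$n_with_flare,
              x$counts$n_eligible, x$counts$n_clustered))
  print(x$episode_summary)
  if (!is.null(x$ap)) print(x$ap)
  invisible(x)
}

#' Command-line entry point
#'
#' Thin argument-vector interface over the package functions, used by the
#' `flarediary-cli.R` script shipped in `inst/scripts/`. Subcommands:
#' `simulate` (write a synthetic cohort), `episodes`, `features`, `test`
#' (per-variable paired-test table), `cluster`, `run` (full pipeline) and
#' `fixtures`. Flags: `--config <json>`, `--seed <int>`, `--out <dir>`,
#' `--in <diary csv>`, `--threshold <1..5>`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: flarediary <simulate|episodes|features|test|cluster|run|fixtures>",
    "                  [--config cfg.json] [--in diary.csv] [--out dir]",
    "                  [--seed N] [--threshold N]",
    sep = "\n"
  )
  fail <- function(msg) {
    message(msg)
    message(usage)
    invisible(1L)
  }
  if (length(args) == 0L) return(fail("no subcommand given"))
  cmd <- args[1]
  args <- args[-1]
  opt <- list(seed = 1L, threshold = 3L, out = ".")
  given <- character(0)
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--") || i == length(args)) {
      return(fail(paste("bad argument:", key)))
    }
    val <- args[i + 1L]
    name <- sub("^--", "", key)
    if (!name %in% c("config", "in", "out", "seed", "threshold")) {
      return(fail(paste("unknown flag:", key)))
    }
    opt[[name]] <- if (name %in% c("seed", "threshold")) as.integer(val) else val
    given <- c(given, name)
    i <- i + 2L
  }
  get_diary <- function() {
    if (is.null(opt$`in`)) stop("--in <diary.csv> is required", call. = FALSE)
    read_diary(opt$`in`)
  }
  code <- tryCatch({
    switch(cmd,
      simulate = {
        write_cohort(generate_cohort(cohort_config(), seed = opt$seed),
                     opt$out)
      },
      fixtures = emit_fixture_suite(opt$out, seed = opt$seed),
      episodes = {
        write_episodes(segment_episodes(get_diary(), opt$threshold),
                       file.path(opt$out, "episodes.csv"))
      },
      features = {
        write_features(flare_features(get_diary(), opt$threshold),
                       file.path(opt$out, "features.csv"))
      },
      test = {
        t1 <- build_table1(flare_features(get_diary(), opt$threshold))
        utils::write.csv(t1, file.path(opt$out, "table1.csv"),
                         row.names = FALSE)
      },
      cluster = {
        d <- eligibility_filter(get_diary())
        M <- feature_matrix(flare_features(d, opt$threshold))
        ap <- affinity_propagation(
          build_similarity(normalize_features(M)$matrix),
          q = 0, seed = opt$seed
        )
        write_ap_result(ap, file.path(opt$out, "labels.csv"),
                        file.path(opt$out, "ap_log.json"))
      },
      run = {
        cfg <- if (!is.null(opt$config)) {
          read_pipeline_config(opt$config)
        } else {
          pipeline_config(synthetic = cohort_config(), seed = opt$seed)
        }
        # explicit CLI flags override config fields
        if ("out" %in% given || is.null(cfg$out_dir)) cfg$out_dir <- opt$out
        if ("seed" %in% given) cfg$seed <- opt$seed
        run_full_pipeline(cfg)
      },
      return(fail(paste("unknown subcommand:", cmd)))
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
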