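#' Negative-power Euclidean similarity matrix
#'
#' Builds the affinity propagation similarity matrix
#' `S[i, k] = -d(i, k)^r` from Euclidean distances between the rows of
#' `X`; the default `r = 2` (negative squared distance) is the standard
#' choice. The diagonal is left as `NA` until a preference is applied by
#' [preference_from_quantile()] or [affinity_propagation()].
#'
#' @param X numeric matrix (participants x features), no missing values.
#' @param r distance exponent, default 2.
#' @return symmetric n x n matrix with non-positive off-diagonal entries,
#'   `NA` diagonal, row/col names from `rownames(X)`.
#' @export
build_similarity <- function(X, r = 2) {
  stopifnot(is.matrix(X) || is.data.frame(X))
  X <- as.matrix(X)
  abort_if(anyNA(X),
           "feature matrix has missing values; complete cases are required (see eligibility_filter)")
  D <- as.matrix(stats::dist(X))
  S <- -(D^r)
  diag(S) <- NA_real_
  S
}

#' Shared preference from a quantile of the similarities
#'
#' The diagonal "preference" of the similarity matrix controls how many
#' exemplars emerge. A single shared value is used for all points: the
#' `q`-th quantile (linear interpolation between order statistics) of the
#' off-diagonal similarities. `q = 0` — the minimum similarity — is the
#' setting that minimizes the number of clusters; `q = 1` gives the
#' maximum.
#'
#' @param S similarity matrix from [build_similarity()].
#' @param q quantile in \[0, 1\].
#' @return scalar preference value.
#' @export
preference_from_quantile <- function(S, q = 0) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  abort_if(nrow(S) < 2L, "need at least 2 points")
  abort_if(!is.numeric(q) || length(q) != 1L || q < 0 || q > 1,
           "q must be a single value in [0, 1]")
  off <- S[row(S) != col(S)]
  unname(stats::quantile(off, probs = q, type = 7, na.rm = FALSE))
}

#' Net similarity of an exemplar set
#'
#' The objective affinity propagation approximately maximizes: each
#' non-exemplar contributes its similarity to the closest exemplar, each
#' exemplar its preference.
#'
#' @param S similarity matrix (diagonal ignored).
#' @param exemplars integer indices of the exemplar set.
#' @param preference scalar or length-n preference vector.
#' @return scalar net similarity.
#' @export
ap_net_similarity <- function(S, exemplars, preference) {
  n <- nrow(S)
  preference <- rep_len(preference, n)
  others <- setdiff(seq_len(n), exemplars)
  tot <- sum(preference[exemplars])
  if (length(others) > 0L) {
    sub <- S[others, exemplars, drop = FALSE]
    tot <- tot + sum(apply(sub, 1, max))
  }
  tot
}

#' Affinity propagation clustering
#'
#' From-scratch implementation of the responsibility/availability message
#' passing scheme. Responsibilities are updated as
#' `r(i,k) <- S(i,k) - max_{k' != k} (a(i,k') + S(i,k'))`, availabilities as
#' `a(i,k) <- min(0, r(k,k) + sum_{i' not in \{i,k\}} max(0, r(i',k)))` with
#' `a(k,k) <- sum_{i' != k} max(0, r(i',k))`; both are damped as
#' `new <- damping * old + (1 - damping) * new`. Points with
#' `r(k,k) + a(k,k) > 0` are exemplars; iteration stops when the exemplar
#' set is unchanged for `conv_window` consecutive iterations or at
#' `max_iter`. Each point is then labeled with its most similar exemplar
#' (exemplars label themselves).
#'
#' Exactly duplicated rows create symmetric message ties that can prevent
#' convergence; a deterministic, seeded jitter of magnitude
#' `1e-12 * range(S)` is therefore added to the similarities once
#' (disable with `jitter = FALSE` for exact-arithmetic comparisons).
#'
#' @param S similarity matrix from [build_similarity()] (diagonal may be
#'   `NA`; it is replaced by the preference).
#' @param preference scalar or length-n preference; when `NULL`, computed
#'   from `q` via [preference_from_quantile()].
#' @param q preference quantile, default 0 (fewest clusters).
#' @param damping message damping in \[0.5, 1), default 0.9.
#' @param max_iter iteration cap, default 1000.
#' @param conv_window iterations of unchanged exemplar set required for
#'   convergence, default 100.
#' @param jitter add the deterministic tie-breaking jitter (default TRUE).
#' @param seed seed for the jitter only; the algorithm itself is
#'   deterministic.
#' @param refine apply the standard final refinement: within each cluster,
#'   move the exemplar to the member maximizing the intra-cluster
#'   similarity sum and reassign until stable (default TRUE).
#' @return object of class `ap_result`: `exemplars` (integer indices),
#'   `labels` (exemplar index per point), `cluster` (dense 1..K ids in
#'   decreasing cluster-size order), `n_iterations`, `converged`,
#'   `net_similarity`, `preference`, and `ids` (row names of `S`).
#' @export
affinity_propagation <- function(S, preference = NULL, q = 0, damping = 0.9,
                                 max_iter = 1000L, conv_window = 100L,
                                 jitter = TRUE, seed = 1L, refine = TRUE) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  abort_if(damping < 0.5 || damping >= 1, "damping must be in [0.5, 1)")
  abort_if(!is_count(conv_window) || conv_window < 1,
           "conv_window must be >= 1")
  n <- nrow(S)
  ids <- rownames(S) %||% as.character(seq_len(n))
  if (n == 1L) {
    return(structure(list(
      exemplars = 1L, labels = 1L, cluster = 1L, n_iterations = 0L,
      converged = TRUE, net_similarity = 0, preference = preference %||% 0,
      ids = ids
    ), class = "ap_result"))
  }
  off <- S[row(S) != col(S)]
  abort_if(any(!is.finite(off)), "similarities must be finite")
  if (all(off == 0)) {
    # all points coincide: a single exemplar is optimal for any preference
    if (is.null(preference)) preference <- 0
    return(structure(list(
      exemplars = 1L, labels = rep(1L, n), cluster = rep(1L, n),
      n_iterations = 0L, converged = TRUE,
      net_similarity = rep_len(preference, n)[1],
      preference = preference, ids = ids
    ), class = "ap_result"))
  }

  W <- S
  scale <- 0
  if (jitter) {
    # non-positive symmetric jitter keeps off-diagonal similarities valid
    # (<= 0); a quantile-derived preference is taken from the jittered
    # matrix so that exact-duplicate degeneracies resolve toward fewer
    # exemplars rather than a zero-cost exemplar per duplicate
    rng <- max(off) - min(off)
    scale <- 1e-12 * if (rng > 0) rng else 1
    noise <- with_seed(seed, matrix(stats::runif(n * n), n, n))
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    W <- W - scale * noise
  }
  if (is.null(preference)) preference <- preference_from_quantile(W, q)
  pref <- rep_len(preference, n)
  diag(W) <- pref
  if (jitter) {
    diag(W) <- diag(W) - scale * with_seed(seed + 1L, stats::runif(n))
  }

  R <- A <- matrix(0, n, n)
  idx <- seq_len(n)
  exemplar_key <- ""
  stable <- 0L
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + W
    j1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(idx, j1)]
    AS[cbind(idx, j1)] <- -Inf
    m2 <- AS[cbind(idx, max.col(AS, ties.method = "first"))]
    Rnew <- W - m1
    Rnew[cbind(idx, j1)] <- W[cbind(idx, j1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    P <- pmax(R, 0)
    diag(P) <- 0
    sp <- colSums(P)                       # sum_{i' != k} max(0, r(i',k))
    Anew <- matrix(diag(R) + sp, n, n, byrow = TRUE) - P
    Anew[Anew > 0] <- 0
    diag(Anew) <- sp
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(R) + diag(A) > 0)
    key <- paste(ex, collapse = ",")
    if (length(ex) > 0L && key == exemplar_key) {
      stable <- stable + 1L
      if (stable >= conv_window) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
      exemplar_key <- key
    }
  }

  exemplars <- which(diag(R) + diag(A) > 0)
  if (length(exemplars) == 0L) {
    exemplars <- which.max(diag(R) + diag(A))  # best-effort fallback
    converged <- FALSE
  }
  Sx <- S
  diag(Sx) <- -Inf
  assign_to <- function(E) {
    lab <- E[max.col(Sx[, E, drop = FALSE], ties.method = "first")]
    lab[E] <- E
    lab
  }
  labels <- assign_to(exemplars)
  if (refine) {
    # final polish, as in mainstream implementations: within each cluster,
    # move the exemplar to the member maximizing the intra-cluster
    # similarity sum, then reassign; repeat until stable
    S0 <- S
    diag(S0) <- 0
    for (pass in 1:10) {
      new_ex <- vapply(exemplars, function(e) {
        mem <- which(labels == e)
        mem[which.max(colSums(S0[mem, mem, drop = FALSE]))]
      }, 1L)
      new_ex <- sort(unique(new_ex))
      if (identical(new_ex, exemplars)) break
      exemplars <- new_ex
      labels <- assign_to(exemplars)
    }
    labels <- assign_to(exemplars)
  }

  ord <- order(-tabulate(match(labels, exemplars), length(exemplars)),
               exemplars)
  cluster <- match(match(labels, exemplars), ord)

  structure(list(
    exemplars = exemplars, labels = labels, cluster = cluster,
    n_iterations = it, converged = converged,
    net_similarity = ap_net_similarity(S, exemplars, pref),
    preference = preference, ids = ids
  ), class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  k <- length(x$exemplars)
  cat(sprintf(
    "Affinity propagation: %d cluster%s (sizes %s), %d iteration%s, %s\n",
    k, if (k == 1) "" else "s",
    paste(table(x$cluster), collapse = "/"),
    x$n_iterations, if (x$n_iterations == 1) "" else "s",
    if (x$converged) "converged" else "NOT converged"
  ))
  cat(sprintf("  preference %.4g, net similarity %.4g\n",
              x$preference[1], x$net_similarity))
  invisible(x)
}

#' Brute-force optimal exemplar set
#'
#' Exhaustively enumerates every non-empty exemplar subset and returns the
#' one maximizing the net similarity — the exact optimum of the objective
#' affinity propagation approximates. Exponential in `n`, so refused for
#' `n > 12`; intended as a validation oracle for small instances. Exact
#' score ties are broken toward the lexicographically smallest index set.
#'
#' @param S similarity matrix (diagonal ignored).
#' @param preference scalar or length-n preference vector.
#' @return list: `exemplars` (integer indices), `net_similarity`.
#' @export
ap_exemplar_oracle <- function(S, preference) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  n <- nrow(S)
  abort_if(n > 12L, "oracle enumeration limited to n <= 12 (got n = %d)", n)
  best <- NULL
  best_score <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    E <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    sc <- ap_net_similarity(S, E, preference)
    better <- sc > best_score ||
      (sc == best_score && !is.null(best) && lex_less(E, best))
    if (better) {
      best_score <- sc
      best <- E
    }
  }
  list(exemplars = best, net_similarity = best_score)
}

# lexicographic order on integer index sets
lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

#' Write cluster labels and the run log
#'
#' Emits the labels CSV (`participant_id, cluster_id, is_exemplar`) and a
#' JSON run log (iterations, convergence, preference, net similarity).
#'
#' @param result an `ap_result`.
#' @param labels_path,log_path output paths (`NULL` to skip either).
#' @return invisibly, the labels data frame.
#' @export
write_ap_result <- function(result, labels_path = NULL, log_path = NULL) {
  stopifnot(inherits(result, "ap_result"))
  df <- data.frame(
    participant_id = result$ids,
    cluster_id = result$cluster,
    is_exemplar = seq_along(result$labels) %in% result$exemplars
  )
  if (!is.null(labels_path)) {
    utils::write.csv(df, labels_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(log_path)) {
    jsonlite::write_json(list(
      n = length(result$labels), n_clusters = length(result$exemplars),
      n_iterations = result$n_iterations, converged = result$converged,
      preference = result$preference[1],
      net_similarity = result$net_similarity
    ), log_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(df)
}
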