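# Best-arm identification over family profiles. Arms are families; pulling an
# arm means evaluating the unbiased J-score estimator on one sampled k-mer.
# Cost is accounted in "k-mer evaluations": one per batch element per active
# arm, and |N_k(q)| per family scored exactly.

new_search_trace <- function(winner, method, per_round_active, estimates,
                             exact_scores, t_used, evaluations,
                             winner_score, winner_score_exact) {
  structure(
    list(winner = winner, method = method,
         per_round_active = per_round_active, estimates = estimates,
         exact_scores = exact_scores, exact_scored = names(exact_scores),
         t_used = t_used, evaluations = as.integer(evaluations),
         winner_score = winner_score, winner_score_exact = winner_score_exact),
    class = "search_trace"
  )
}

check_profiles <- function(profiles, query_counts = NULL) {
  if (!length(profiles)) jb_invalid_input("at least one family profile is required")
  ids <- unname(vapply(profiles, function(p) p$family_id, character(1)))
  if (anyDuplicated(ids)) jb_invalid_input("family ids must be unique")
  ks <- vapply(profiles, function(p) p$k, integer(1))
  if (length(unique(ks)) != 1L) jb_invalid_input("profiles built with differing k")
  if (!is.null(query_counts) && query_counts$k != ks[1L]) {
    jb_invalid_parameter("query counted at a different k than the profiles")
  }
  ids
}

exact_scores_for <- function(query_counts, profiles, ids) {
  vapply(seq_along(profiles), function(i) {
    tryCatch(j_score_exact(query_counts, profiles[[i]]),
             jbandit_undefined_score = function(e) NA_real_)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(ids)
}

#' Exhaustive exact-J assignment (the oracle search)
#'
#' Scores the query exactly against every family and returns the argmax, with
#' ties broken by (score descending, family id ascending). Undefined scores
#' (query and family both without k-mers) never win unless all scores are
#' undefined. Charges `|N_k(q)|` k-mer evaluations per family. This is the
#' reference against which both bandit searches are validated.
#'
#' @param query_counts `kmer_counts` of the query.
#' @param profiles List of `family_profile` objects (unique ids, common k).
#' @return A `search_trace` whose `exact_scores` holds every family's score.
#' @export
exhaustive_argmax <- function(query_counts, profiles) {
  ids <- check_profiles(profiles, query_counts)
  scores <- exact_scores_for(query_counts, profiles, ids)
  ranked <- ids[order_score_desc_id_asc(ifelse(is.na(scores), -Inf, scores), ids)]
  winner <- ranked[1L]
  new_search_trace(
    winner = winner, method = "exact", per_round_active = list(ids),
    estimates = stats::setNames(numeric(0), character(0)),
    exact_scores = scores, t_used = NA_integer_,
    evaluations = length(ids) * query_counts$distinct,
    winner_score = scores[[winner]], winner_score_exact = TRUE
  )
}

#' Sequential-halving search for the best-scoring family
#'
#' Modified sequential halving: for `R` rounds, one shared batch of `B`
#' k-mers is drawn per round (so the per-arm estimates within a round are
#' correlated) and the running mean estimate of every active arm is updated;
#' the top `max(ceiling(|active|/2), T)` arms survive each round. After the
#' rounds, the `T` arms with the highest running means are scored exactly and
#' the best exact score wins. Total cost is at most `m*R*B + T*|N_k(q)|`
#' k-mer evaluations. When `m <= T` every arm reaches the exact-scoring step
#' regardless of the sampling rounds, so the rounds are skipped and the
#' search reduces to [exhaustive_argmax()].
#'
#' Uses the global RNG stream; callers wanting reproducibility seed it (the
#' assignment layer derives one substream per query from the master seed).
#'
#' @param query_counts `kmer_counts` of the query; must have at least one
#'   distinct k-mer.
#' @param profiles List of `family_profile` objects.
#' @param config A [bandit_config()]; uses `batch_fraction`, `rounds`,
#'   `survivors`.
#' @return A `search_trace`.
#' @export
sequential_halving <- function(query_counts, profiles, config = bandit_config()) {
  ids <- check_profiles(profiles, query_counts)
  if (query_counts$distinct < 1L) {
    jb_stop("query has no k-mers; use the root-family fallback", "jbandit_no_kmers")
  }
  m <- length(profiles)
  names(profiles) <- ids
  if (m <= config$survivors) {
    # every arm reaches the exact-scoring step anyway: skip the sampling
    # rounds and record the assignment as exact
    return(exhaustive_argmax(query_counts, profiles))
  }
  B <- batch_size_for(query_counts, config)
  jhat <- stats::setNames(numeric(m), ids)
  active <- ids
  per_round <- vector("list", config$rounds + 1L)
  per_round[[1L]] <- ids
  M <- 0
  for (r in seq_len(config$rounds)) {
    batch <- sample_kmer_batch(query_counts, B)
    est <- vapply(active, function(id) {
      j_score_batch_estimate(query_counts, profiles[[id]], batch)
    }, numeric(1))
    jhat[active] <- ((r - 1) * jhat[active] + est) / r
    M <- M + length(active) * B
    t <- min(length(active), max(ceiling(length(active) / 2), config$survivors))
    active <- active[order_score_desc_id_asc(jhat[active], active)][seq_len(t)]
    per_round[[r + 1L]] <- sort(active)
  }
  top <- active[order_score_desc_id_asc(jhat[active], active)]
  top <- top[seq_len(min(config$survivors, length(top)))]
  exact <- vapply(top, function(id) j_score_exact(query_counts, profiles[[id]]),
                  numeric(1))
  M <- M + length(top) * query_counts$distinct
  winner <- top[order_score_desc_id_asc(exact, top)][1L]
  new_search_trace(
    winner = winner, method = "halving", per_round_active = per_round,
    estimates = jhat, exact_scores = exact, t_used = NA_integer_,
    evaluations = M, winner_score = exact[[winner]], winner_score_exact = TRUE
  )
}

#' Batched upper-confidence-bound search for the best-scoring family
#'
#' Confidence-interval elimination: while fewer than `m` k-mers have been
#' consumed per arm and more than one arm is active, a shared batch is drawn,
#' running means are updated over all consumed k-mers, and every arm whose
#' upper confidence bound falls below the best arm's lower bound is
#' eliminated. The radius after `t` consumed k-mers is
#' `C = sigma * sqrt(2 * log(1/delta) / t)` (Hoeffding, for sigma-sub-Gaussian
#' single-k-mer evaluations). Per-round batches are clamped to the remaining
#' per-arm budget `m - t_used`, so each arm consumes at most `m` sampled
#' k-mers before any survivors are resolved by exact scoring — the accounting
#' under which the [theorem1_bound()] sample-complexity guarantee holds.
#'
#' With `delta = m^-3` the returned family is the true argmax with
#' probability at least `1 - 2/m`, within the Theorem-1 evaluation budget.
#'
#' @param query_counts `kmer_counts` of the query.
#' @param profiles List of `family_profile` objects.
#' @param config A [bandit_config()]; uses `batch_fraction` and `delta`
#'   (`NULL` means `m^-3`).
#' @param sigma Sub-Gaussian scale; defaults to the maximum of
#'   [sigma_upper_bound()] over the profiles.
#' @return A `search_trace` with `t_used` filled in.
#' @export
batched_ucb <- function(query_counts, profiles, config = bandit_config(),
                        sigma = NULL) {
  ids <- check_profiles(profiles, query_counts)
  if (query_counts$distinct < 1L) {
    jb_stop("query has no k-mers; use the root-family fallback", "jbandit_no_kmers")
  }
  m <- length(profiles)
  names(profiles) <- ids
  if (is.null(sigma)) {
    sigma <- max(vapply(profiles, sigma_upper_bound, numeric(1)))
  }
  delta <- resolve_delta(config, m)
  B <- batch_size_for(query_counts, config)
  jhat <- stats::setNames(numeric(m), ids)
  active <- ids
  per_round <- list(ids)
  t_used <- 0L
  M <- 0
  while (t_used < m && length(active) > 1L) {
    b <- min(B, m - t_used)
    batch <- sample_kmer_batch(query_counts, b)
    est <- vapply(active, function(id) {
      j_score_batch_estimate(query_counts, profiles[[id]], batch)
    }, numeric(1))
    jhat[active] <- (t_used * jhat[active] + b * est) / (t_used + b)
    C <- sigma * sqrt(2 * log(1 / delta) / (t_used + b))
    M <- M + length(active) * b
    t_used <- t_used + b
    keep <- jhat[active] + C >= max(jhat[active]) - C
    active <- active[keep]
    per_round[[length(per_round) + 1L]] <- sort(active)
  }
  if (length(active) == 1L) {
    winner <- active
    exact <- stats::setNames(numeric(0), character(0))
    winner_score <- if (t_used > 0L) jhat[[winner]] else NA_real_
    exact_flag <- FALSE
  } else {
    exact <- vapply(active, function(id) j_score_exact(query_counts, profiles[[id]]),
                    numeric(1))
    M <- M + length(active) * query_counts$distinct
    winner <- active[order_score_desc_id_asc(exact, active)][1L]
    winner_score <- exact[[winner]]
    exact_flag <- TRUE
  }
  new_search_trace(
    winner = winner, method = "ucb", per_round_active = per_round,
    estimates = jhat, exact_scores = exact, t_used = t_used,
    evaluations = M, winner_score = winner_score,
    winner_score_exact = exact_flag
  )
}

#' Sample-complexity bound for the batched UCB search
#'
#' Evaluates the guarantee on the total number of k-mer evaluations `M` used
#' by [batched_ucb()] when it returns the correct family:
#'
#' \deqn{M \le \sum_{h=1}^{m} \min\!\left(\frac{24\,\sigma^2}{\Delta_h^2}\log m + B,\; m + \ell\right)}
#'
#' where `Delta_h` is the J-score gap of arm `h` to the best arm (the best
#' arm's first branch is infinite, so it contributes `m + ell`), `sigma` the
#' sub-Gaussian scale, `B` the batch size, and `ell` an upper bound on the
#' cost of one exact scoring (e.g. the maximum sequence length). Natural
#' logarithm throughout.
#'
#' @param gaps Named nonnegative numeric vector of score gaps, one per family,
#'   with at least one zero entry (the best arm).
#' @param sigma Nonnegative sub-Gaussian scale.
#' @param B Positive integer batch size.
#' @param ell Positive integer exact-scoring cost bound.
#' @param m Number of arms; defaults to `length(gaps)`.
#' @return The bound (numeric scalar).
#' @examples
#' theorem1_bound(c(best = 0, rep(0.5, 15)), sigma = 1, B = 8, ell = 100)  # 1856
#' @export
theorem1_bound <- function(gaps, sigma, B, ell, m = length(gaps)) {
  if (!length(gaps) || any(gaps < 0)) {
    jb_invalid_input("`gaps` must be nonnegative with one entry per family")
  }
  if (!any(gaps == 0)) jb_invalid_input("`gaps` must contain a zero (best arm)")
  first <- ifelse(gaps == 0, Inf, 24 * sigma^2 / gaps^2 * log(m) + B)
  sum(pmin(first, m + ell))
}

#' Realized gap profile of a query against a family set
#'
#' Computes, by exhaustive exact scoring, the suboptimality gaps
#' `Delta_h = max_y J(q, y) - J(q, h)` together with the global sigma bound,
#' batch size and exact-scoring cost bound, packaged for [theorem1_bound()].
#'
#' @inheritParams batched_ucb
#' @param ell Exact-scoring cost bound; defaults to the query length.
#' @return List with `gaps`, `sigma`, `m`, `B`, `ell`.
#' @export
gap_profile <- function(query_counts, profiles, config = bandit_config(),
                        ell = query_counts$length) {
  ids <- check_profiles(profiles, query_counts)
  scores <- exact_scores_for(query_counts, profiles, ids)
  scores[is.na(scores)] <- 0
  list(gaps = max(scores) - scores,
       sigma = max(vapply(profiles, sigma_upper_bound, numeric(1))),
       m = length(profiles),
       B = batch_size_for(query_counts, config),
       ell = ell)
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf(
    "<search_trace> winner='%s' (method=%s, score=%s), %d evaluations, %d exact-scored\n",
    x$winner, x$method,
    if (is.na(x$winner_score)) "NA" else format(x$winner_score, digits = 4),
    x$evaluations, length(x$exact_scored)))
  invisible(x)
}
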