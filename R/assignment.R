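#' Build profiles for a set of families, optionally adding a root family
#'
#' The root family is the union of all backbone members across families; a
#' query sharing no k-mer with any family is assigned to it (the fallback
#' rule), and it also competes as an ordinary arm in the search. If the
#' family list already contains `root_id`, it is used as-is; otherwise a
#' synthetic root is appended from the concatenation of all members.
#'
#' @param families Named list: family id -> character vector of member
#'   sequences.
#' @param k k-mer length.
#' @param root_id Identifier of the root family (default `"ROOT"`).
#' @param add_root Whether to synthesize the root when absent.
#' @return Named list of `family_profile` objects.
#' @export
build_profiles <- function(families, k, root_id = "ROOT", add_root = TRUE) {
  if (!length(families) || is.null(names(families)) ||
      any(!nzchar(names(families)))) {
    jb_invalid_input("`families` must be a nonempty named list")
  }
  if (anyDuplicated(names(families))) jb_invalid_input("family ids must be unique")
  if (add_root && !(root_id %in% names(families))) {
    families[[root_id]] <- unname(unlist(families, use.names = FALSE))
  }
  profiles <- lapply(names(families), function(id) {
    build_family_profile(families[[id]], k = k, family_id = id)
  })
  stats::setNames(profiles, names(families))
}

shares_any_kmer <- function(query_counts, profiles) {
  if (query_counts$distinct < 1L) return(FALSE)
  qk <- names(query_counts$counts)
  for (p in profiles) {
    if (any(qk %in% names(p$summed_counts))) return(TRUE)
  }
  FALSE
}

#' Assign every query to its best-scoring family
#'
#' Runs the configured search (`exact`, `halving`, or `ucb`) for each query
#' against all family profiles. A query shorter than `k`, or sharing no k-mer
#' with any family, cannot be scored meaningfully and is assigned to the root
#' family with `method = "fallback"`, a score of `NA`, and zero evaluations.
#' Each query gets its own RNG substream derived from `config$seed` and the
#' query's position, so results are identical however the work is partitioned
#' across processes.
#'
#' @param queries Named character vector of query sequences (unique names).
#' @param profiles Named list of `family_profile` objects, e.g. from
#'   [build_profiles()]; must contain `root_family` if any query needs the
#'   fallback.
#' @param root_family Id of the root (fallback) family.
#' @param config A [bandit_config()].
#' @param threads Number of worker processes (forked; results are
#'   thread-count invariant).
#' @param trace_path Optional path: writes one JSON record per query (winner,
#'   evaluation count, per-round active-arm counts).
#' @return A data.frame with columns `query_id`, `family_id`, `score`,
#'   `method`, `evaluations`, `exact_score` — one row per query, input order.
#' @export
assign_all <- function(queries, profiles, root_family = "ROOT",
                       config = bandit_config(), threads = 1L,
                       trace_path = NULL) {
  if (!length(queries)) jb_invalid_input("no query sequences given")
  qids <- names(queries)
  if (is.null(qids) || any(!nzchar(qids))) {
    jb_invalid_input("queries must be a named character vector")
  }
  if (anyDuplicated(qids)) {
    jb_invalid_input(sprintf("duplicate query id(s): %s",
                             paste(unique(qids[duplicated(qids)]), collapse = ", ")))
  }
  check_profiles(profiles)
  pids <- vapply(profiles, function(p) p$family_id, character(1))
  names(profiles) <- pids

  one <- function(i) {
    qc <- count_kmers(queries[[i]], config$k)
    if (!shares_any_kmer(qc, profiles)) {
      if (!(root_family %in% pids)) {
        jb_stop(sprintf(
          "query '%s' shares no k-mer with any family and no root family '%s' is available",
          qids[i], root_family), "jbandit_configuration_error")
      }
      return(list(row = data.frame(
        query_id = qids[i], family_id = root_family, score = NA_real_,
        method = "fallback", evaluations = 0L, exact_score = FALSE,
        stringsAsFactors = FALSE),
        trace = list(query_id = qids[i], winner = root_family,
                     method = "fallback", evaluations = 0L,
                     active_counts = integer(0))))
    }
    set.seed(derive_seed(config$seed, i))
    tr <- switch(config$algorithm,
      exact = exhaustive_argmax(qc, profiles),
      halving = sequential_halving(qc, profiles, config),
      ucb = batched_ucb(qc, profiles, config))
    list(row = data.frame(
      query_id = qids[i], family_id = tr$winner, score = tr$winner_score,
      method = tr$method, evaluations = tr$evaluations,
      exact_score = tr$winner_score_exact, stringsAsFactors = FALSE),
      trace = list(query_id = qids[i], winner = tr$winner, method = tr$method,
                   evaluations = tr$evaluations,
                   active_counts = vapply(tr$per_round_active, length, integer(1))))
  }

  if (.Platform$OS.type == "windows") threads <- 1L  # no fork; same output
  res <- if (threads > 1L) {
    parallel::mclapply(seq_along(queries), one, mc.cores = threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_along(queries), one)
  }
  failed <- vapply(res, inherits, logical(1), "try-error")
  if (any(failed)) stop(attr(res[[which(failed)[1L]]], "condition"))

  if (!is.null(trace_path)) {
    lines <- vapply(res, function(r) {
      jsonlite::toJSON(r$trace, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, trace_path)
  }
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  rownames(out) <- NULL
  out
}

#' Write assignments as TSV
#'
#' One row per query in input order, header included, columns `query_id`,
#' `family_id`, `score` (`NA` for fallback assignments), `method`,
#' `evaluations`. Output is byte-identical across runs with the same seed.
#'
#' @param assignments Data.frame from [assign_all()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  cols <- c("query_id", "family_id", "score", "method", "evaluations")
  df <- assignments[, cols]
  df$score <- ifelse(is.na(df$score), "NA",
                     formatC(df$score, digits = 12, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
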