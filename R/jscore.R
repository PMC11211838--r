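#' Exact J-score between a query and a family
#'
#' The J-score is a weighted multiset Jaccard similarity between the k-mers of
#' a query `q` and the averaged k-mer multiset of a family `S`:
#'
#' \deqn{J(q, S) = \frac{\sum_{a \in N_k(q)} \min(c_q(a),\; c_S(a))}
#'                     {(|q| - k + 1) + \frac{1}{|S|}\sum_{s \in S}(|s| - k + 1)}}
#'
#' where `c_q(a)` is the multiplicity of k-mer `a` in the query, `c_S(a)` the
#' member-averaged multiplicity in the family, and `N_k(q)` the distinct
#' k-mers of the query. The denominator depends only on sequence lengths, so
#' only the numerator has to be estimated when sampling (see
#' [j_score_batch_estimate()]). The score lies in `[0, 1]`, and a query scored
#' against the singleton family containing itself scores exactly 0.5.
#'
#' Cost is one hash lookup per distinct query k-mer.
#'
#' @param query_counts `kmer_counts` of the query.
#' @param profile `family_profile` with the same `k`.
#' @return Numeric score in `[0, 1]`.
#' @examples
#' q <- count_kmers("ABABA", 2)
#' f <- build_family_profile(c("ABAB", "BABB"), 2)
#' j_score_exact(q, f)   # 2.5 / 7
#' @export
j_score_exact <- function(query_counts, profile) {
  check_k_match(query_counts, profile)
  den <- query_counts$total_kmers + profile$avg_kmer_total
  if (den <= 0) {
    jb_stop("J-score undefined: query and family both have zero k-mers",
            "jbandit_undefined_score")
  }
  if (!query_counts$distinct || !length(profile$summed_counts)) return(0)
  idx <- match(names(query_counts$counts), names(profile$summed_counts))
  hit <- !is.na(idx)
  if (!any(hit)) return(0)
  num <- sum(pmin(query_counts$counts[hit],
                  profile$summed_counts[idx[hit]] / profile$member_count))
  num / den
}

#' Sample a batch of k-mers uniformly from a query's distinct k-mer set
#'
#' Draws `B` k-mers i.i.d. with replacement, each distinct k-mer of the query
#' having equal probability `1/|N_k(q)|`. Sampling is over *distinct* k-mers,
#' not positions: the estimator's `|N_k(q)|/B` prefactor is unbiased only
#' under this scheme. Uses R's global RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param query_counts `kmer_counts` with at least one distinct k-mer.
#' @param B Positive integer batch size.
#' @return Character vector of length `B` (the batch).
#' @export
sample_kmer_batch <- function(query_counts, B) {
  if (!is.numeric(B) || length(B) != 1L || is.na(B) || B < 1) {
    jb_invalid_parameter("`B` must be a positive integer")
  }
  if (query_counts$distinct < 1L) {
    jb_stop("query has no k-mers to sample", "jbandit_no_kmers")
  }
  kmers <- names(query_counts$counts)
  kmers[sample.int(length(kmers), size = B, replace = TRUE)]
}

#' Unbiased batch estimate of the J-score
#'
#' For a batch `B = (a_1, ..., a_B)` drawn by [sample_kmer_batch()], returns
#'
#' \deqn{\tilde J = \frac{|N_k(q)|}{B} \cdot
#'   \frac{\sum_{a \in B} \min(c_q(a), c_S(a))}{(|q|-k+1) + \bar\ell_S}}
#'
#' an unbiased estimator of [j_score_exact()]: averaging the singleton-batch
#' estimate over every distinct k-mer of the query reproduces the exact score
#' as a finite identity. Each batch element counts as one "k-mer evaluation",
#' the cost unit of the bandit searches. Individual estimates may exceed 1;
#' only the exact score is bounded by 1.
#'
#' @param query_counts `kmer_counts` of the query the batch was drawn from.
#' @param profile `family_profile` with matching `k`.
#' @param batch Character vector of k-mers from the query's distinct set.
#' @return Numeric estimate (nonnegative).
#' @examples
#' q <- count_kmers("ABABA", 2)
#' f <- build_family_profile(c("ABAB", "BABB"), 2)
#' j_score_batch_estimate(q, f, "AB")   # 3/7
#' @export
j_score_batch_estimate <- function(query_counts, profile, batch) {
  check_k_match(query_counts, profile)
  if (!length(batch)) jb_invalid_parameter("`batch` must be nonempty")
  den <- query_counts$total_kmers + profile$avg_kmer_total
  if (den <= 0) {
    jb_stop("J-score undefined: query and family both have zero k-mers",
            "jbandit_undefined_score")
  }
  cq <- query_counts$counts[batch]
  if (anyNA(cq)) jb_invalid_input("batch contains k-mers absent from the query")
  cs <- profile$summed_counts[batch] / profile$member_count
  cs[is.na(cs)] <- 0
  (query_counts$distinct / length(batch)) * sum(pmin(as.numeric(cq), cs)) / den
}

check_k_match <- function(query_counts, profile) {
  stopifnot(inherits(query_counts, "kmer_counts"),
            inherits(profile, "family_profile"))
  if (query_counts$k != profile$k) {
    jb_invalid_parameter(sprintf(
      "k mismatch: query counted at k=%d, profile built at k=%d",
      query_counts$k, profile$k))
  }
  invisible(TRUE)
}
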