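#' Count the k-mers of a sequence as a multiset
#'
#' Enumerates every length-`k` substring of `x` and records its multiplicity.
#' A sequence of length `L` has `max(L - k + 1, 0)` k-mers counted with
#' repetition; a sequence shorter than `k` has none. Residues are used
#' literally: no reverse-complement canonicalization and no special handling
#' of ambiguity codes, so the same code path serves nucleotide and amino-acid
#' input.
#'
#' @param x A single character string of residues (already case-normalized and
#'   gap-free; [read_fasta()] performs both on input).
#' @param k Positive integer k-mer length.
#' @return An object of class `kmer_counts`: a list with elements `k`,
#'   `counts` (named integer vector, k-mer -> multiplicity, names sorted),
#'   `total_kmers` (`max(nchar(x) - k + 1, 0)`), `distinct` (number of
#'   distinct k-mers), and `length` (the sequence length).
#' @examples
#' count_kmers("ACGT", 2)$counts   # AC, CG, GT each once
#' count_kmers("AAAA", 2)$counts   # AA three times
#' @seealso [build_family_profile()], [j_score_exact()]
#' @export
count_kmers <- function(x, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    jb_invalid_parameter("`k` must be a positive integer")
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    jb_invalid_input("`x` must be a single character string")
  }
  k <- as.integer(k)
  len <- nchar(x)
  n <- len - k + 1L
  if (n < 1L) {
    counts <- integer(0)
  } else {
    kmers <- substring(x, seq_len(n), seq_len(n) + k - 1L)
    tab <- table(kmers)
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  structure(
    list(k = k, counts = counts, total_kmers = max(n, 0L),
         distinct = length(counts), length = len),
    class = "kmer_counts"
  )
}

#' Build the averaged k-mer profile of a sequence family
#'
#' A family profile stores the key-wise *sum* of the member k-mer multisets
#' together with the member count, so the averaged count of k-mer `a` in
#' family `S` is `summed_counts[a] / member_count` — kept as an exact
#' integer/denominator pair and divided only at scoring time. The profile also
#' carries the average number of k-mers per member (the family term of the
#' J-score denominator) and the sub-Gaussianity upper bound used by the UCB
#' search (see [sigma_upper_bound()]).
#'
#' @param members Character vector of member sequences (at least one).
#' @param k Positive integer k-mer length.
#' @param family_id Identifier for the family.
#' @return An object of class `family_profile`: list with `family_id`,
#'   `member_count`, `summed_counts` (named integer vector), `avg_kmer_total`,
#'   `sigma_bound`, and `k`.
#' @examples
#' p <- build_family_profile(c("ACGT", "ACGG"), k = 2, family_id = "f")
#' p$summed_counts            # AC:2 CG:2 GG:1 GT:1
#' p$avg_kmer_total           # 3
#' @export
build_family_profile <- function(members, k, family_id = "family") {
  if (length(members) < 1L) {
    jb_invalid_input("a family must contain at least one member sequence")
  }
  counted <- lapply(members, count_kmers, k = k)
  nm <- unlist(lapply(counted, function(cc) names(cc$counts)), use.names = FALSE)
  vv <- unlist(lapply(counted, function(cc) unname(cc$counts)), use.names = FALSE)
  if (length(nm)) {
    s <- rowsum(vv, nm)                       # sorts groups: deterministic
    summed <- stats::setNames(as.integer(s[, 1L]), rownames(s))
  } else {
    summed <- integer(0)
  }
  member_count <- length(members)
  avg_total <- sum(vapply(counted, function(cc) cc$total_kmers, integer(1))) /
    member_count
  sigma <- if (length(summed)) max(summed) / member_count / 2 else 0
  structure(
    list(family_id = family_id, member_count = member_count,
         summed_counts = summed, avg_kmer_total = avg_total,
         sigma_bound = sigma, k = as.integer(k)),
    class = "family_profile"
  )
}

#' Sub-Gaussianity upper bound for a family profile
#'
#' A single-k-mer score evaluation against family `S` takes values in
#' `[0, max_a c_S(a)]` (up to the fixed positive denominator), so half the
#' largest averaged k-mer count bounds its sub-Gaussian parameter. The batched
#' UCB search uses the maximum of this bound over all families as its global
#' sigma.
#'
#' @param profile A `family_profile`.
#' @return Nonnegative numeric: `max(summed_counts) / member_count / 2`, or 0
#'   for a profile with no k-mers.
#' @examples
#' sigma_upper_bound(build_family_profile("AAAA", k = 2))  # 1.5
#' @export
sigma_upper_bound <- function(profile) {
  stopifnot(inherits(profile, "family_profile"))
  if (!length(profile$summed_counts)) return(0)
  max(profile$summed_counts) / profile$member_count / 2
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("<kmer_counts> k=%d, length=%d, %d k-mers (%d distinct)\n",
              x$k, x$length, x$total_kmers, x$distinct))
  invisible(x)
}

#' @export
print.family_profile <- function(x, ...) {
  cat(sprintf(
    "<family_profile> '%s': %d member(s), k=%d, %d distinct k-mers, avg %.1f k-mers/member, sigma<=%.3g\n",
    x$family_id, x$member_count, x$k, length(x$summed_counts),
    x$avg_kmer_total, x$sigma_bound))
  invisible(x)
}
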