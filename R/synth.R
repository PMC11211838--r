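# Synthetic sequence families with known ground truth. Substitution-only
# evolution: a k-mer straddling no substituted site survives intact, so the
# expected fraction of query k-mers still matching its source family is
# (1 - rate)^k — enough structure to exercise every scoring and search path.

ALPHABETS <- list(
  dna = c("A", "C", "G", "T"),
  protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
)

random_sequence <- function(length, alphabet) {
  paste(sample(alphabet, length, replace = TRUE), collapse = "")
}

# i.i.d. substitutions at `rate`; a substituted site always changes residue.
mutate_sequence <- function(x, rate, alphabet) {
  if (rate <= 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    A <- length(alphabet)
    cur <- match(chars[hit], alphabet)
    # shift by 1..A-1 positions around the alphabet: never the same residue
    chars[hit] <- alphabet[((cur - 1L + sample.int(A - 1L, length(hit),
                                                   replace = TRUE)) %% A) + 1L]
  }
  paste(chars, collapse = "")
}

#' Generate synthetic families and queries with ground-truth labels
#'
#' Emulates the structure of a backbone decomposed into families: `m` family
#' ancestors are derived from one uniform random root sequence by i.i.d.
#' substitutions at rate `ancestor_divergence` (so ancestors of different
#' families are far apart), each family's members are independent copies of
#' its ancestor substituted at `within_family_rate`, and each query is a
#' uniformly chosen member of a uniformly chosen family substituted at
#' `query_rate`, with the source family recorded as the true label.
#' Substitutions only — no indels — so k-mer survival is analytically
#' predictable. Fully reproducible from `seed`.
#'
#' Defaults generate the package's standard benchmark condition: 32 families
#' of 8 members of length 1000, ancestors ~30% diverged, members 2% within
#' family, 200 queries at 5% substitution.
#'
#' @param m Number of families.
#' @param members_per_family Members per family.
#' @param seq_length Sequence length (all sequences equal length).
#' @param ancestor_divergence Substitution rate root -> family ancestor, in
#'   `[0, 1)`.
#' @param within_family_rate Substitution rate ancestor -> member.
#' @param query_rate Substitution rate member -> query.
#' @param n_queries Number of queries.
#' @param alphabet `"dna"` or `"protein"`.
#' @param seed RNG seed.
#' @return An object of class `synth_data`: list with `families` (named list
#'   of named member vectors), `queries` (named character vector), `truth`
#'   (data.frame `query_id`, `true_family`), and `params`.
#' @export
synthesize_families <- function(m = 32L, members_per_family = 8L,
                                seq_length = 1000L,
                                ancestor_divergence = 0.3,
                                within_family_rate = 0.02,
                                query_rate = 0.05, n_queries = 200L,
                                alphabet = c("dna", "protein"), seed = 1L) {
  alphabet <- match.arg(alphabet)
  rates <- c(ancestor_divergence, within_family_rate, query_rate)
  if (any(rates < 0) || any(rates >= 1)) {
    jb_invalid_parameter("substitution rates must lie in [0, 1)")
  }
  if (m < 1 || members_per_family < 1 || seq_length < 1 || n_queries < 1) {
    jb_invalid_parameter("sizes must be positive")
  }
  ab <- ALPHABETS[[alphabet]]
  set.seed(as.integer(seed) %% 2147483647)

  fam_ids <- sprintf("fam%0*d", nchar(as.character(m)), seq_len(m))
  root <- random_sequence(seq_length, ab)
  families <- stats::setNames(vector("list", m), fam_ids)
  for (h in seq_len(m)) {
    ancestor <- mutate_sequence(root, ancestor_divergence, ab)
    members <- vapply(seq_len(members_per_family), function(j) {
      mutate_sequence(ancestor, within_family_rate, ab)
    }, character(1))
    families[[h]] <- stats::setNames(
      members, sprintf("%s_s%d", fam_ids[h], seq_len(members_per_family)))
  }

  qids <- sprintf("q%0*d", nchar(as.character(n_queries)), seq_len(n_queries))
  src_fam <- sample.int(m, n_queries, replace = TRUE)
  src_mem <- sample.int(members_per_family, n_queries, replace = TRUE)
  queries <- vapply(seq_len(n_queries), function(i) {
    mutate_sequence(families[[src_fam[i]]][[src_mem[i]]], query_rate, ab)
  }, character(1))
  names(queries) <- qids

  structure(
    list(families = families, queries = queries,
         truth = data.frame(query_id = qids, true_family = fam_ids[src_fam],
                            stringsAsFactors = FALSE),
         params = list(m = m, members_per_family = members_per_family,
                       seq_length = seq_length,
                       ancestor_divergence = ancestor_divergence,
                       within_family_rate = within_family_rate,
                       query_rate = query_rate, n_queries = n_queries,
                       alphabet = alphabet, seed = seed)),
    class = "synth_data"
  )
}

#' Write a synthetic dataset as FASTA fixtures plus manifest and truth TSVs
#'
#' Writes one FASTA per family, `queries.fasta`, a `manifest.tsv`
#' (family_id, fasta_path, relative paths), and `truth.tsv` (query_id,
#' true_family) into `dir`.
#'
#' @param x A `synth_data` object.
#' @param dir Output directory (created if needed).
#' @return List of written paths (`manifest`, `queries`, `truth`,
#'   `family_fastas`), invisibly.
#' @export
write_synth_data <- function(x, dir) {
  stopifnot(inherits(x, "synth_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fam_paths <- character(0)
  for (id in names(x$families)) {
    p <- file.path(dir, paste0(id, ".fasta"))
    write_fasta(x$families[[id]], p)
    fam_paths[id] <- p
  }
  qpath <- file.path(dir, "queries.fasta")
  write_fasta(x$queries, qpath)
  mpath <- file.path(dir, "manifest.tsv")
  writeLines(c("family_id\tfasta_path",
               paste(names(x$families), basename(fam_paths), sep = "\t")),
             mpath)
  tpath <- file.path(dir, "truth.tsv")
  utils::write.table(x$truth, tpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(manifest = mpath, queries = qpath, truth = tpath,
                 family_fastas = fam_paths))
}

#' Rank agreement between two score orderings of the families
#'
#' Compares a candidate scoring of the families (e.g. an estimated J-score
#' ordering) against a reference scoring for one query. `d0` is 1 when the
#' reference's top family is also the candidate's top family; `dx` (for each
#' percentage `x`) is 1 when the reference's top family lies within the
#' candidate's top `ceiling(m * x / 100)` families. Spearman's rank
#' correlation (average ranks for ties) and its p-value measure how monotone
#' the relationship between the two scorings is; when either scoring is
#' constant across families the correlation is undefined and is set to 0 with
#' p-value 1 — the most adversarial convention when averaging over queries.
#'
#' @param reference Named numeric vector of reference scores.
#' @param candidate Named numeric vector of candidate scores (same names).
#' @param x_levels Numeric vector of percentages for `dx` (default 10).
#' @return An object of class `rank_agreement`: list with `d0`, `dx` (named
#'   by level), `spearman_rho`, `p_value`.
#' @export
rank_agreement <- function(reference, candidate, x_levels = 10) {
  if (length(reference) < 2L) jb_invalid_input("need at least two families")
  if (is.null(names(reference)) || is.null(names(candidate)) ||
      !setequal(names(reference), names(candidate)) ||
      length(reference) != length(candidate)) {
    jb_invalid_input("`reference` and `candidate` must share the same family ids")
  }
  candidate <- candidate[names(reference)]
  m <- length(reference)
  ref_top <- names(reference)[order_score_desc_id_asc(reference, names(reference))][1L]
  cand_order <- names(candidate)[order_score_desc_id_asc(candidate, names(candidate))]
  d0 <- as.numeric(cand_order[1L] == ref_top)
  dx <- vapply(x_levels, function(x) {
    top_n <- min(m, max(1L, ceiling(m * x / 100)))
    as.numeric(ref_top %in% cand_order[seq_len(top_n)])
  }, numeric(1))
  names(dx) <- paste0("d", x_levels)
  if (stats::sd(candidate) == 0 || stats::sd(reference) == 0) {
    rho <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(
      stats::cor.test(reference, candidate, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(d0 = d0, dx = dx, spearman_rho = rho, p_value = p),
            class = "rank_agreement")
}

#' @export
print.synth_data <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<synth_data> %d families x %d members, length %d (%s); %d queries at %.0f%% substitution\n",
    p$m, p$members_per_family, p$seq_length, p$alphabet, p$n_queries,
    100 * p$query_rate))
  invisible(x)
}

#' @export
print.rank_agreement <- function(x, ...) {
  cat(sprintf("<rank_agreement> d0=%g, %s, rho=%.3f (p=%.3g)\n",
              x$d0, paste(names(x$dx), "=", x$dx, collapse = ", "),
              x$spearman_rho, x$p_value))
  invisible(x)
}
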