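# Independent brute-force oracles: position-by-position k-mer scanning and an
# integer-rational J-score. Deliberately naive (quadratic loops, no hash
# reuse) so they share no code with the implementation under test.

DNA <- c("A", "C", "G", "T")
AMINO <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(len, alphabet = DNA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

oracle_count_kmers <- function(x, k) {
  counts <- integer(0)
  L <- nchar(x)
  if (L >= k) {
    for (i in seq_len(L - k + 1)) {
      a <- substr(x, i, i + k - 1)
      counts[a] <- (if (a %in% names(counts)) counts[[a]] else 0L) + 1L
    }
  }
  counts
}

# Exact rational J: multiply numerator and denominator through by |S| so all
# arithmetic stays in integers until the final division.
oracle_j_score <- function(q, members, k) {
  cq <- oracle_count_kmers(q, k)
  mc <- length(members)
  summed <- integer(0)
  for (s in members) {
    cs <- oracle_count_kmers(s, k)
    for (a in names(cs)) {
      summed[a] <- (if (a %in% names(summed)) summed[[a]] else 0L) + cs[[a]]
    }
  }
  num_mc <- 0
  for (a in names(cq)) {
    in_fam <- if (a %in% names(summed)) summed[[a]] else 0L
    num_mc <- num_mc + min(mc * cq[[a]], in_fam)
  }
  tq <- max(nchar(q) - k + 1, 0)
  st <- sum(vapply(members, function(s) max(nchar(s) - k + 1, 0), numeric(1)))
  den_mc <- mc * tq + st
  if (den_mc == 0) return(NA_real_)
  num_mc / den_mc
}

# Small random search instance: families of random sequences plus a query
# mutated off one member, so there is a meaningful best arm.
rand_instance <- function(m = 6, members = 3, len = 80, k = 6,
                          query_rate = 0.05, alphabet = DNA) {
  fams <- lapply(seq_len(m), function(h) {
    anc <- rand_seq(len, alphabet)
    vapply(seq_len(members), function(j) {
      chars <- strsplit(anc, "")[[1]]
      hit <- which(runif(len) < 0.02)
      chars[hit] <- sample(alphabet, length(hit), replace = TRUE)
      paste(chars, collapse = "")
    }, character(1))
  })
  names(fams) <- sprintf("f%02d", seq_len(m))
  src <- sample.int(m, 1)
  base <- fams[[src]][sample.int(members, 1)]
  chars <- strsplit(base, "")[[1]]
  hit <- which(runif(len) < query_rate)
  chars[hit] <- sample(alphabet, length(hit), replace = TRUE)
  query <- paste(chars, collapse = "")
  profiles <- lapply(names(fams), function(id) {
    build_family_profile(fams[[id]], k = k, family_id = id)
  })
  list(profiles = profiles, query = query, qc = count_kmers(query, k),
       true_family = names(fams)[src], families = fams)
}
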