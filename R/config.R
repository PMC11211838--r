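#' Configuration for the query-to-family search
#'
#' Bundles every tunable of the assignment pipeline. The defaults are the
#' configuration used throughout: `k = 20`, batch fraction `c = 0.2` (per
#' query, the batch size is `B = max(1, round(c * |q|))`), `R = 3` halving
#' rounds, `T = 10` survivors scored exactly, and a UCB failure probability
#' `delta = m^-3` (computed from the number of families at run time when left
#' `NULL`).
#'
#' @param k k-mer length (positive integer).
#' @param batch_fraction Fraction `c` in `(0, 1]` of the query length used as
#'   the per-round batch size.
#' @param rounds Number `R` of sampling rounds for sequential halving.
#' @param survivors Number `T` of top arms scored exactly at the end of
#'   sequential halving (also the floor of the halving schedule).
#' @param delta UCB failure probability in `(0, 1)`, or `NULL` for the
#'   `m^-3` default.
#' @param seed Master seed; per-query substreams are derived from it.
#' @param algorithm `"halving"` (default), `"ucb"`, or `"exact"`.
#' @return An object of class `bandit_config`.
#' @export
bandit_config <- function(k = 20L, batch_fraction = 0.2, rounds = 3L,
                          survivors = 10L, delta = NULL, seed = 0L,
                          algorithm = c("halving", "ucb", "exact")) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    jb_invalid_parameter("`k` must be a positive integer")
  }
  if (!is.numeric(batch_fraction) || length(batch_fraction) != 1L ||
      is.na(batch_fraction) || batch_fraction <= 0 || batch_fraction > 1) {
    jb_invalid_parameter("`batch_fraction` must lie in (0, 1]")
  }
  if (!is.numeric(rounds) || rounds < 1 || rounds != floor(rounds)) {
    jb_invalid_parameter("`rounds` must be a positive integer")
  }
  if (!is.numeric(survivors) || survivors < 1 || survivors != floor(survivors)) {
    jb_invalid_parameter("`survivors` must be a positive integer")
  }
  if (!is.null(delta) &&
      (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
       delta <= 0 || delta >= 1)) {
    jb_invalid_parameter("`delta` must lie in (0, 1) or be NULL")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    jb_invalid_parameter("`seed` must be a single integer")
  }
  structure(
    list(k = as.integer(k), batch_fraction = batch_fraction,
         rounds = as.integer(rounds), survivors = as.integer(survivors),
         delta = delta, seed = as.integer(seed), algorithm = algorithm),
    class = "bandit_config"
  )
}

# Per-query batch size B = max(1, round(c * |q|)).
batch_size_for <- function(query_counts, config) {
  max(1L, as.integer(round(config$batch_fraction * query_counts$length)))
}

# delta default: m^-3 in the number of arms.
resolve_delta <- function(config, m) {
  if (!is.null(config$delta)) config$delta else m^-3
}

#' @export
print.bandit_config <- function(x, ...) {
  cat(sprintf(
    "<bandit_config> algorithm=%s, k=%d, c=%.3g, R=%d, T=%d, delta=%s, seed=%d\n",
    x$algorithm, x$k, x$batch_fraction, x$rounds, x$survivors,
    if (is.null(x$delta)) "m^-3" else format(x$delta), x$seed))
  invisible(x)
}
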