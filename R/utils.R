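# Internal error helpers: every user-facing failure carries a condition class
# so callers (and the CLI) can distinguish bad parameters from bad data.

jb_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "jbandit_error"), call = call))
}

jb_invalid_parameter <- function(msg) jb_stop(msg, "jbandit_invalid_parameter")
jb_invalid_input <- function(msg) jb_stop(msg, "jbandit_invalid_input")
jb_data_error <- function(msg) jb_stop(msg, "jbandit_data_error")

# Deterministic ordering by (score desc, id asc) with C-locale id comparison,
# so ties break identically on every platform.
order_score_desc_id_asc <- function(scores, ids) {
  order(-scores, ids, method = "radix")
}

# Per-query RNG substream: derived from the master seed and the query index so
# that partitioning work across processes cannot change any result.
derive_seed <- function(seed, index) {
  base <- seed %% 2147483647
  as.integer((base + (index %% 2147483647) * 1000003) %% 2147483647)
}
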