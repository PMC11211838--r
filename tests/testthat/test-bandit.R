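test_that("exhaustive argmax matches brute-force scoring with deterministic ties", {
  set.seed(31)
  for (rep in 1:25) {
    inst <- rand_instance(m = 5, members = 2, len = 40, k = 4)
    tr <- exhaustive_argmax(inst$qc, inst$profiles)
    want <- vapply(names(inst$families), function(id) {
      oracle_j_score(inst$query, inst$families[[id]], 4)
    }, numeric(1))
    expect_equal(unname(tr$exact_scores[names(want)]), unname(want),
                 tolerance = 1e-12)
    best <- names(want)[order(-want, names(want), method = "radix")][1]
    expect_equal(tr$winner, best)
    expect_equal(tr$evaluations, length(inst$profiles) * inst$qc$distinct)
  }

  # identical families: lexicographically smallest id wins
  pa <- build_family_profile("ACGTACGT", 3, "b_fam")
  pb <- build_family_profile("ACGTACGT", 3, "a_fam")
  tr <- exhaustive_argmax(count_kmers("ACGTACGT", 3), list(pa, pb))
  expect_equal(tr$winner, "a_fam")

  # the family containing the query beats a disjoint family with score 0.5
  q <- count_kmers("ACGTACGTAC", 3)
  tr <- exhaustive_argmax(q, list(
    build_family_profile("ACGTACGTAC", 3, "self"),
    build_family_profile("TTTTTTTTTT", 3, "other")))
  expect_equal(tr$winner, "self")
  expect_equal(unname(tr$winner_score), 0.5)

  expect_error(exhaustive_argmax(q, list()), class = "jbandit_invalid_input")
})

test_that("sequential halving degenerates to the exhaustive argmax when T >= m", {
  set.seed(32)
  for (rep in 1:30) {
    inst <- rand_instance(m = sample(2:8, 1), members = 2, len = 60, k = 5)
    cfg <- bandit_config(k = 5, survivors = 10, seed = rep)
    tr <- sequential_halving(inst$qc, inst$profiles, cfg)
    ref <- exhaustive_argmax(inst$qc, inst$profiles)
    expect_identical(tr$winner, ref$winner)
    expect_equal(tr$evaluations, ref$evaluations)
    expect_equal(tr$method, "exact")
  }
})

test_that("sequential halving respects its evaluation budget and nested active sets", {
  set.seed(33)
  for (rep in 1:30) {
    m <- sample(12:40, 1)
    inst <- rand_instance(m = m, members = 2, len = 100, k = 6)
    cfg <- bandit_config(k = 6, batch_fraction = runif(1, 0.05, 0.5),
                         rounds = sample(1:4, 1), survivors = sample(2:8, 1))
    tr <- sequential_halving(inst$qc, inst$profiles, cfg)
    B <- max(1L, round(cfg$batch_fraction * inst$qc$length))
    expect_lte(tr$evaluations,
               m * cfg$rounds * B + cfg$survivors * inst$qc$distinct)
    # active sets shrink monotonically and contain the winner at the end
    sets <- tr$per_round_active
    for (i in seq_len(length(sets) - 1)) {
      expect_true(all(sets[[i + 1]] %in% sets[[i]]))
      expect_lte(length(sets[[i + 1]]), length(sets[[i]]))
    }
    expect_true(tr$winner %in% sets[[length(sets)]])
    expect_lte(length(tr$exact_scored), cfg$survivors)
    expect_true(tr$winner_score_exact)
  }
})

test_that("halving with a single family returns it after one exact scoring", {
  inst <- rand_instance(m = 1, members = 3, len = 50, k = 4)
  tr <- sequential_halving(inst$qc, inst$profiles, bandit_config(k = 4))
  expect_equal(tr$winner, inst$profiles[[1]]$family_id)
  expect_equal(tr$evaluations, inst$qc$distinct)
  expect_error(
    sequential_halving(count_kmers("AC", 4), inst$profiles,
                       bandit_config(k = 4)),
    class = "jbandit_no_kmers")
})

test_that("same seed and inputs give bit-identical traces", {
  inst <- local({set.seed(34); rand_instance(m = 20, members = 2, len = 80, k = 5)})
  cfg <- bandit_config(k = 5, survivors = 4)
  set.seed(99); t1 <- sequential_halving(inst$qc, inst$profiles, cfg)
  set.seed(99); t2 <- sequential_halving(inst$qc, inst$profiles, cfg)
  expect_identical(t1, t2)
  set.seed(99); u1 <- batched_ucb(inst$qc, inst$profiles, cfg)
  set.seed(99); u2 <- batched_ucb(inst$qc, inst$profiles, cfg)
  expect_identical(u1, u2)
})

test_that("batched UCB handles degenerate and zero-overlap arm sets", {
  # single arm: immediate return, no sampling
  inst <- rand_instance(m = 1, members = 2, len = 50, k = 4)
  tr <- batched_ucb(inst$qc, inst$profiles, bandit_config(k = 4))
  expect_equal(tr$winner, inst$profiles[[1]]$family_id)
  expect_equal(tr$evaluations, 0L)
  expect_equal(tr$t_used, 0L)

  # one family contains the query, all others share nothing: the matching
  # family wins on every seed (its estimates are exactly 0.5, others 0)
  q <- paste(rep("ACGT", 10), collapse = "")
  profiles <- c(list(build_family_profile(q, 5, "match")),
                lapply(1:4, function(i) {
                  build_family_profile(paste(rep("TGCA", 10), collapse = ""),
                                       5, paste0("null", i))
                }))
  qc <- count_kmers(q, 5)
  for (s in 1:10) {
    set.seed(s)
    tr <- batched_ucb(qc, profiles, bandit_config(k = 5))
    expect_equal(tr$winner, "match")
  }
})

test_that("UCB eliminates provably inferior arms when the radius is tight", {
  inst <- local({set.seed(35); rand_instance(m = 8, members = 2, len = 120,
                                             k = 6, query_rate = 0.02)})
  # tiny caller-supplied sigma makes the Hoeffding radius negligible, so the
  # single-survivor return path (no exact scoring) must trigger
  set.seed(36)
  tr <- batched_ucb(inst$qc, inst$profiles, bandit_config(k = 6), sigma = 1e-9)
  expect_equal(length(tr$per_round_active[[length(tr$per_round_active)]]), 1L)
  expect_equal(length(tr$exact_scored), 0L)
  expect_false(tr$winner_score_exact)
  expect_equal(tr$winner, inst$true_family)
  # radius shrinks the active set monotonically
  sets <- tr$per_round_active
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("UCB per-arm sampling is capped at m k-mers before exact resolution", {
  set.seed(37)
  for (rep in 1:10) {
    inst <- rand_instance(m = sample(4:12, 1), members = 2, len = 200, k = 6)
    tr <- batched_ucb(inst$qc, inst$profiles, bandit_config(k = 6))
    expect_lte(tr$t_used, length(inst$profiles))
  }
})

test_that("theorem1_bound evaluates the sample-complexity formula", {
  gaps <- c(best = 0, setNames(rep(0.5, 15), paste0("a", 1:15)))
  expect_equal(theorem1_bound(gaps, sigma = 1, B = 8, ell = 100), 1856)

  # huge gaps, tiny sigma: ~B per suboptimal arm plus m + ell for the best
  gaps2 <- c(best = 0, setNames(rep(1e6, 15), paste0("a", 1:15)))
  expect_equal(theorem1_bound(gaps2, sigma = 1e-9, B = 8, ell = 100),
               15 * 8 + 116, tolerance = 1e-6)

  # identical arms: every min picks m + ell
  gaps3 <- setNames(rep(0, 16), paste0("a", 1:16))
  expect_equal(theorem1_bound(gaps3, sigma = 1, B = 8, ell = 100), 16 * 116)

  expect_error(theorem1_bound(c(a = 0.1, b = 0.2), 1, 8, 100),
               class = "jbandit_invalid_input")
  expect_error(theorem1_bound(numeric(0), 1, 8, 100),
               class = "jbandit_invalid_input")
})

test_that("gap_profile reports exhaustive gaps with the best arm at zero", {
  inst <- local({set.seed(38); rand_instance(m = 6, members = 2, len = 80, k = 5)})
  gp <- gap_profile(inst$qc, inst$profiles, bandit_config(k = 5))
  expect_equal(min(gp$gaps), 0)
  expect_true(all(gp$gaps >= 0))
  expect_equal(gp$m, 6)
  expect_equal(gp$sigma,
               max(vapply(inst$profiles, sigma_upper_bound, numeric(1))))
})
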