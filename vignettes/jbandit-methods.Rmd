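---
title: "Methods: the J-score and bandit search for query-to-family assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the J-score and bandit search for query-to-family assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jbandit)
```

## The problem

Ensemble-of-profiles alignment pipelines split their input into *backbone*
sequences — aligned once, decomposed along a guide tree into nested *families*
— and *query* sequences, each of which must be routed to the single family
whose profile it matches best before being aligned into it. Scoring a query
against a profile HMM costs quadratic time in sequence length, and with
hundreds of families and thousands of queries this assignment step dominates
the whole pipeline. `jbandit` implements a cheap alignment-free surrogate for
that routing decision and two adaptive search strategies that avoid even
paying the full surrogate cost for most families.

## The J-score

For a sequence $s$, let $N_k(s)$ be its set of distinct $k$-mers and $c_s(a)$
the multiplicity of $k$-mer $a$ in $s$. For a family $S$ of sequences, counts
are averaged over the members, $c_S(a) = \frac{1}{|S|}\sum_{s\in S} c_s(a)$.
The similarity of query $q$ to family $S$ is

$$
J(q,S) \;=\; \frac{\sum_{a \in N_k(q)} \min\!\big(c_q(a),\, c_S(a)\big)}
 {(|q|-k+1) \;+\; \frac{1}{|S|}\sum_{s\in S}(|s|-k+1)} ,
$$

a weighted multiset Jaccard similarity in which family $k$-mers can occur a
rational number of times. Key properties, all enforced by tests:

* $0 \le J \le 1$, since the numerator is at most $|q|-k+1$;
* $J(q, \{q\}) = 1/2$ exactly (and exactly in double precision, because the
  numerator sums integers);
* the denominator depends on lengths only — no set union is needed, which is
  what makes unbiased sampling possible.

`family_profile` objects keep the integer *sum* of member counts together
with the member count as a separate divisor, so tests can compare against an
integer-rational oracle; floating division happens only at scoring time.
Members shorter than $k$ contribute zero (never negative) length terms.

Sequences are uppercased on read and gap characters (`-`, `.`) stripped,
since queries are handled unaligned. $k$-mers are literal substrings: there
is no reverse-complement canonicalization (amino-acid input makes it
ill-defined, and the score is a proxy for profile match, not strand-aware
genome distance), and ambiguity codes are counted as ordinary residues. This
keeps the multiset identities exact for any alphabet.

## Unbiased estimation

Let $P_q$ put equal mass on each *distinct* $k$-mer of the query. For a batch
$B = (a_1,\dots,a_B)$ drawn i.i.d. from $P_q$,

$$
\tilde J(q,S,B) \;=\; \frac{|N_k(q)|}{B}\,
 \frac{\sum_{a\in B}\min(c_q(a), c_S(a))}{(|q|-k+1)+\bar\ell_S}
$$

satisfies $\mathbb E[\tilde J] = J$ — a finite identity, not an asymptotic
one: averaging the singleton-batch estimate over every distinct $k$-mer of
the query reproduces the exact score to floating-point precision. The test
suite asserts this identity on random pairs, and it is the first quantity the
acceptance script recomputes. Sampling is over distinct $k$-mers, not
positions: the $|N_k(q)|/B$ prefactor is unbiased only under that scheme,
which is why the cheaper position-sampling variant is deliberately not
offered. Individual estimates may exceed 1; only the exact score is bounded.

The cost unit throughout is one *k-mer evaluation* — one summand of the
estimator. Exact scoring charges $|N_k(q)|$ evaluations per family.

## Search algorithms

Both searches treat families as bandit arms; pulling an arm is one k-mer
evaluation.

**Sequential halving** (the default). For $R$ rounds: draw *one* shared batch
of size $B$ per round (estimates across arms within a round are therefore
correlated — implemented as specified, and harmless since only ranks matter),
update each active arm's running mean, and keep the top
$\max(\lceil |S_{\text{active}}|/2\rceil, T)$ arms. After the rounds, the $T$
arms with the best running means are scored exactly and the best exact score
wins. Total cost is at most $mRB + T\,|N_k(q)|$ evaluations, asserted on
every trace in the test suite. Two boundary choices: the halving count uses
the ceiling and is capped at the active-set size; and when $m \le T$ the
sampling rounds are skipped entirely, because every arm reaches the
exact-scoring step regardless — the search then reduces to the exhaustive
exact argmax and is labelled `method = "exact"` in the output, which keeps
"halving with a huge `T`" and "exact" byte-identical.

**Batched UCB.** While fewer than $m$ k-mers have been consumed per arm and
more than one arm is active: draw a shared batch, update running means over
all consumed k-mers, and eliminate every arm whose upper confidence bound
falls below the leader's lower bound, with Hoeffding radius
$C = \sigma\sqrt{2\ln(1/\delta)/t}$ after $t$ consumed k-mers. The
sub-Gaussian scale is the preprocessing bound
$\sigma = \tfrac12\max_a c_S(a)$, maximized over families. Survivors are
resolved by exact scoring. Two numerical choices:

* *Radius reconstruction.* The radius is chosen so that
  $\exp(-tC^2/2\sigma^2) = \delta$; natural logarithm; the update after a
  batch of size $b$ uses $t_{\text{used}}+b$ consumed k-mers.
* *Budget clamping.* Each round's batch is clamped to
  $\min(B, m - t_{\text{used}})$, so an arm never consumes more than $m$
  sampled k-mers. This is the accounting under which the sample-complexity
  guarantee
  $M \le \sum_h \min\!\big(\tfrac{24\sigma^2}{\Delta_h^2}\ln m + B,\; m+\ell\big)$
  (with $\Delta_h$ the exact-score gap to the best arm) is provable: the
  per-survivor cost $m + \ell$ is covered by the bound's second branch
  precisely because consumption stops at $m$. Drawing full-size batches past
  the cap would void the audit whenever $B > m$.

`theorem1_bound()` evaluates the guarantee so every UCB run can be audited
against its realized gap profile; the test suite and the acceptance script do
exactly that on Monte-Carlo instances with $m=16$, $\delta = m^{-3}$.

Running means in both algorithms weight batch estimates by batch size, so
$\hat J_h$ is always the mean of all single-k-mer evaluations the arm has
consumed — one consistent rule for the equal-batch halving rounds and the
clamped UCB rounds.

**Ties and determinism.** Every selection (top-$t$, final argmax, exhaustive
argmax) breaks ties by score descending, then family id ascending under
C-locale ordering — deterministic and seed-independent. One master seed;
each query gets a substream derived from (seed, query index), so the
1-thread and 8-thread runs of `assign_all()` produce byte-identical TSVs.

## Fallback rule

A query shorter than $k$, or sharing no $k$-mer with *any* family, carries no
score signal; it is assigned to the *root* family — the family of all
backbone members — with `method = "fallback"` and zero evaluations. A query
sharing $k$-mers with some families simply scores 0 against the rest; the
fallback only fires when every score would be 0. The root is a first-class
family (id `ROOT` by default, overridable via the manifest's `#root=` line);
`build_profiles()` synthesizes it as the union of all members when absent,
and it competes in the search like any other arm (its per-member averaging
makes it a weak competitor except when nothing else matches).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 20 | k-mer length; 20 gives near-disjoint family k-mer sets for sequences of length ≥ several hundred on the 4-letter alphabet. For short sequences (length ~100, amino acids) a smaller `k` (≈10) is advisable, since queries must share length-`k` words with the backbone to score at all |
| `batch_fraction` (`c`) | 0.2 | per-query batch size `B = max(1, round(c·|q|))` |
| `rounds` (`R`) | 3 | halving rounds |
| `survivors` (`T`) | 10 | arms scored exactly at the end of halving; also the elimination floor |
| `delta` | `m^-3` | UCB failure probability; at this value the returned family is the true argmax with probability ≥ 1 − 2/m |
| `seed` | 0 | master seed for all sampling |

The zero-flag CLI defaults reproduce exactly this configuration.

## The synthetic-data generator

`synthesize_families()` emulates the structure this tool faces — families
derived from distinct ancestors, queries mutated off known members — with
substitutions only: one uniform random root sequence; family ancestors are
the root substituted i.i.d. at `ancestor_divergence` (a substituted site
always changes residue); members are the ancestor substituted at
`within_family_rate`; each query is a random member substituted at
`query_rate`, its source family recorded as ground truth. Substitution-only
evolution keeps k-mer survival analytically predictable — a query k-mer
survives with probability $(1-\text{rate})^k$ — which is what the tests'
separation arguments rely on.

The defaults (32 families × 8 members × length 1000, ancestors 30% diverged,
2% within-family, 200 queries at 5% substitution) are the package's standard
benchmark condition: large enough that family k-mer sets are essentially
disjoint at $k=20$ while queries retain ≈36% of their k-mers, so ground
truth is recoverable and the halving/exhaustive comparison is meaningful,
yet small enough to regenerate from a seed in seconds. The UCB audit uses a
separate condition (16 families × 4 members × length 300, 50% divergence,
10% query substitution): at $m=16$ the budget cap permits only 16 sampled
k-mers per arm, and the 10% rate keeps the realized gaps (≈0.1) in the
regime where every arm's bound term sits in its $m+\ell$ branch, so the
evaluation audit is exact rather than vacuous.

What the generator does **not** emulate: indels (so no length heterogeneity
within a family), rate variation across sites, realistic residue
composition, or fragmentary queries. Passing tests therefore demonstrate the
estimator identities, budgets and search correctness under clean
substitution divergence — not alignment quality on real data, where the
score is a proxy whose agreement with profile-HMM bit-scores must be judged
separately (the `rank_agreement()` statistics exist for exactly that kind of
comparison between two score orderings).

## Degenerate inputs and edge cases

* Query with no k-mers (`|q| < k`): no score is defined; the assignment
  layer routes to the fallback. The scoring functions raise classed errors
  (`jbandit_no_kmers`, `jbandit_undefined_score`) rather than inventing a 0.
* Family with all members shorter than `k`: a valid profile with empty
  counts, zero average length term, zero sigma.
* All-equal scores: lexicographically smallest family id wins, everywhere.
* Constant score vectors in `rank_agreement()`: Spearman's rho is undefined;
  it is set to 0 with p-value 1, the most adversarial convention when
  averaging agreement over many queries.
* `sigma = 0` with several arms sharing no k-mer with the query: the UCB
  radius collapses, elimination keeps only estimate-maximal arms, and any
  residual tie is resolved by exact scoring.

## Problem sizes used in the checks

The test suite and acceptance script regenerate everything from seeds at
these scales: 100 random pairs for the unbiasedness identity, 1000 fuzzed
pairs for the score bounds, 500 instances (lengths ≤ 30, both alphabets)
against the integer-rational brute-force oracle, 200 random instances for
the exhaustive-limit equivalence, 200 Monte-Carlo UCB instances at $m=16$,
and the 32-family benchmark with 200 queries for the default-configuration
regression (halving agrees with the exhaustive winner on ≥90% of queries;
exact-J recovers the true family on ≥95%). All complete in a few minutes on
one core.

## Known limitations

* The J-score is a proxy: it tracks profile match well when query and family
  share long exact words, and degrades for short sequences or large `k` on
  20-letter alphabets — the regime where the score is 0 for all families and
  the fallback dominates.
* The UCB budget cap of `m` sampled k-mers per arm means that for small `m`
  the algorithm nearly always defers to exact scoring of all arms; its
  advantage is asymptotic in `m`.
* Profiles are static; there is no support for adding members incrementally.
* Parallelism is fork-based (`parallel::mclapply`); on platforms without
  fork it falls back to serial execution semantics with identical output.
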