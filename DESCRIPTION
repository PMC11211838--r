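Package: jbandit
Title: Bandit-Accelerated k-mer Similarity Search for Query-to-Family Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns query sequences to the best-matching family of backbone
    sequences using the J-score, a weighted multiset Jaccard similarity over
    k-mers in which family k-mer counts are averaged over members. The exact
    score admits an unbiased estimator from uniformly sampled k-mers, which
    turns the argmax-over-families search into a best-arm identification
    problem. Two multi-armed-bandit search strategies are provided: a modified
    sequential-halving scheme with a final exact-scoring step, and a batched
    upper-confidence-bound scheme with Hoeffding confidence radii and a proven
    sample-complexity bound. Includes FASTA/manifest readers, a command-line
    driver, and a synthetic sequence-family generator with ground-truth labels
    for validation, along with rank-agreement statistics (top-1, top-x
    percent, Spearman correlation) for comparing score orderings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
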