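# Permutation enrichment: is the observed set of mis-splicing SNVs enriched
# for a deterministic property (motif match, gene-set membership) relative
# to random draws of the same size from a stated SNV universe?

#' Permutation enrichment test
#'
#' Draws `|observed|` SNVs without replacement from the universe
#' `n_permutations` times and counts predicate hits per draw; for motif
#' predicates identical flank sequences are de-duplicated before counting
#' (unique-sequence rule). The P value is the proportion of permutations
#' whose hit count is at least the observed count.
#'
#' @param observed_ids Ids of the observed SNV set (subset of the universe).
#' @param universe_ids Ids of the eligible SNV universe.
#' @param hits Named logical vector over `universe_ids`: does the SNV
#'   satisfy the predicate.
#' @param sequences Optional named character vector over `universe_ids`
#'   (e.g. the 11-mer flanks); when given, hit counting is over unique
#'   sequences.
#' @param n_permutations Number of random draws (default 100000).
#' @param seed Integer RNG seed, recorded in the result.
#' @param exhaustive Enumerate all `choose(|universe|, |observed|)` draws
#'   instead of sampling (exact P; only for small universes).
#' @return List of class `enrichment_result`: `observed_count`,
#'   `n_permutations`, `null_mean`, `null_q`, `p_value`, `p_lt_min`
#'   (`TRUE` when no permutation reached the observed count, in which case
#'   the P value is best reported as `< 1/n`), `seed`.
#' @export
permutation_enrichment <- function(observed_ids, universe_ids, hits,
                                   sequences = NULL, n_permutations = 100000L,
                                   seed = 1L, exhaustive = FALSE) {
  if (!all(observed_ids %in% universe_ids))
    stop("observed SNVs must be a subset of the universe")
  k <- length(observed_ids)
  if (k > length(universe_ids)) stop("observed set larger than universe")
  # integer-indexed internally: id lookups are hoisted out of the loop
  n_univ <- length(universe_ids)
  hit_i <- unname(hits[universe_ids])
  seq_i <- if (is.null(sequences)) NULL else {
    # unique-sequence rule: count distinct sequence codes among drawn hits
    as.integer(factor(unname(sequences[universe_ids])))
  }
  count_hits <- if (is.null(seq_i)) {
    function(idx) sum(hit_i[idx])
  } else {
    function(idx) length(unique(seq_i[idx[hit_i[idx]]]))
  }
  observed_count <- count_hits(match(observed_ids, universe_ids))
  if (exhaustive) {
    draws <- utils::combn(n_univ, k, simplify = FALSE)
    null_counts <- vapply(draws, count_hits, 0L)
    n_permutations <- length(draws)
  } else {
    set.seed(seed)
    null_counts <- vapply(seq_len(n_permutations), function(i)
      count_hits(sample.int(n_univ, k)), 0L)
  }
  n_ge <- sum(null_counts >= observed_count)
  structure(list(observed_count = observed_count,
                 n_permutations = n_permutations,
                 null_mean = mean(null_counts),
                 null_q = quantile(null_counts, c(0.025, 0.5, 0.975),
                                   names = FALSE),
                 p_value = n_ge / n_permutations,
                 p_lt_min = n_ge == 0L,
                 seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> observed=%d null_mean=%.2f p=%s (n=%d)\n",
              x$observed_count, x$null_mean,
              if (x$p_lt_min) paste0("<", format(1 / x$n_permutations))
              else format(x$p_value), x$n_permutations))
  invisible(x)
}

#' Exact test of an r x c contingency table
#'
#' Freeman-Halton generalisation of the Fisher exact test (network
#' algorithm). The direction of a "one-sided" r x c test is not
#' well-defined; the probability-mass P is returned.
#'
#' @param table Integer matrix.
#' @return P value.
#' @export
fisher_rxc <- function(table) {
  fisher.test(table)$p.value
}
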