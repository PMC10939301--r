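# Ranking stability under database subsampling: re-rank every
# strategy/threshold combination per miRNA against random subsets of the
# pair database and record where the full-database top combination lands.

#' Subsample a pair database
#'
#' Uniform sample without replacement of `floor(fraction * nrow(db))`
#' pairs, deterministic given `seed`. The global RNG state is untouched.
#'
#' @param db An [mtp_database()].
#' @param fraction Fraction of pairs to keep, in (0, 1].
#' @param seed Integer seed.
#' @return An [mtp_database()] with the sampled pairs (original row
#'   order).
#' @export
subsample_database <- function(db, fraction = 0.75, seed = 1L) {
  if (nrow(db) == 0L) stop("cannot subsample an empty database")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  k <- floor(fraction * nrow(db))
  idx <- withr::with_seed(seed, sample.int(nrow(db), k))
  out <- db[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mtp_database", "data.frame")
  out
}

#' Ranking robustness under database subsampling
#'
#' For each replicate `i` (seeded `base_seed + i`), a random fraction of
#' the database (default 75%) is kept, the specific odds ratios are
#' recomputed for every strategy/threshold combination from the cached
#' correlations (only the database changes), the combinations are
#' re-ranked, and the rank of the full-database top combination in the
#' replicate ranking is recorded per miRNA (`NA` if it fell below
#' significance). Replicates are independent of iteration order: replicate
#' `i` run alone gives the same result.
#'
#' @param cor_tables Named list of strategy correlation tables.
#' @param db Full [mtp_database()].
#' @param gene_ids Candidate gene set (per-miRNA universe gene side).
#' @param selections Full-database [select_top()] result.
#' @param fraction Subsample fraction, default 0.75.
#' @param n_reps Number of replicates, default 40.
#' @param base_seed Base seed; replicate `i` uses `base_seed + i`.
#' @param direction `"lower"` or `"higher"`.
#' @param alpha,fdr Passed to [rank_strategies_per_mirna()].
#' @param zero_correction Passed to [evaluate_specific()].
#' @return Data frame `mirna_id`, `replicate`, `rank_of_original_top`,
#'   `was_significant`, with `n_reps * nrow(selections)` rows.
#' @export
robustness_rankings <- function(cor_tables, db, gene_ids, selections,
                                fraction = 0.75, n_reps = 40L,
                                base_seed = 1L,
                                direction = c("lower", "higher"),
                                alpha = 0.05, fdr = FALSE,
                                zero_correction = TRUE) {
  direction <- match.arg(direction)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  rows <- list()
  for (rep_i in seq_len(n_reps)) {
    db_sub <- subsample_database(db, fraction, seed = base_seed + rep_i)
    spec <- evaluate_specific(cor_tables, db_sub, gene_ids,
                              mirna_ids = selections$mirna_id,
                              direction = direction,
                              zero_correction = zero_correction)
    for (i in seq_len(nrow(selections))) {
      sel <- selections[i, ]
      ranking <- rank_strategies_per_mirna(
        spec[spec$mirna_id == sel$mirna_id, , drop = FALSE],
        alpha = alpha, fdr = fdr)
      hit <- which(ranking$strategy == sel$strategy &
                     abs(ranking$threshold - sel$threshold) < 1e-9)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = sel$mirna_id, replicate = rep_i,
        rank_of_original_top = if (length(hit)) hit[1L] else NA_integer_,
        was_significant = length(hit) > 0L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
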