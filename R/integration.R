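# Selection-integration: per miRNA, rank the (strategy, threshold)
# combinations by specific odds ratio, keep significant ones, select the
# top, and emit the selected combination's detected pairs as the
# integrated mTP set.

#' Rank strategy/threshold combinations for one miRNA
#'
#' Drops combinations with a non-significant exact test (`p >= alpha`) or a
#' non-finite odds ratio, then sorts by odds ratio descending. Ties are
#' broken deterministically: stricter threshold first (higher |threshold|,
#' i.e. higher-confidence pairs), then canonical strategy order (see
#' [enumerate_strategies()]), then smaller p-value.
#'
#' @param evals Data frame of specific evaluations for one miRNA (rows of
#'   [evaluate_specific()]).
#' @param alpha Significance level for the exact-test filter (default
#'   0.05). No multiple-testing correction is applied by default; set
#'   `fdr = TRUE` to filter on Benjamini-Hochberg adjusted p-values across
#'   the miRNA's combinations instead.
#' @param fdr Apply Benjamini-Hochberg adjustment before filtering.
#' @return The significant rows, sorted, with a `rank` column prepended
#'   (possibly zero rows).
#' @export
rank_strategies_per_mirna <- function(evals, alpha = 0.05, fdr = FALSE) {
  p <- evals$p_value
  if (fdr) p <- stats::p.adjust(p, method = "BH")
  keep <- !is.na(p) & p < alpha & !is.na(evals$odds_ratio) &
    is.finite(evals$odds_ratio)
  out <- evals[keep, , drop = FALSE]
  if (nrow(out) > 0L) {
    strat_order <- match(out$strategy, enumerate_strategies()$name)
    o <- order(-out$odds_ratio, -abs(out$threshold), strat_order,
               out$p_value)
    out <- out[o, , drop = FALSE]
  }
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Select the top combination per miRNA
#'
#' @param spec_evals Data frame from [evaluate_specific()] covering one or
#'   more miRNAs.
#' @inheritParams rank_strategies_per_mirna
#' @return Data frame with one row per miRNA that has at least one
#'   significant combination: `mirna_id`, `strategy`, `threshold`,
#'   `odds_ratio`, `p_value`, `n_detected`, `n_overlap_db`. miRNAs with an
#'   empty ranking are absent (no targets found).
#' @export
select_top <- function(spec_evals, alpha = 0.05, fdr = FALSE) {
  rows <- list()
  for (m in unique(spec_evals$mirna_id)) {
    ranking <- rank_strategies_per_mirna(
      spec_evals[spec_evals$mirna_id == m, , drop = FALSE],
      alpha = alpha, fdr = fdr)
    if (nrow(ranking) == 0L) next
    top <- ranking[1L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      mirna_id = m, strategy = top$strategy, threshold = top$threshold,
      odds_ratio = top$odds_ratio, p_value = top$p_value,
      n_detected = top$a + top$b, n_overlap_db = top$a,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(mirna_id = character(0), strategy = character(0),
                      threshold = numeric(0), odds_ratio = numeric(0),
                      p_value = numeric(0), n_detected = integer(0),
                      n_overlap_db = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Integrate mTPs across miRNAs
#'
#' The integrated set is the union, over miRNAs, of the pairs detected by
#' each miRNA's selected (strategy, threshold) combination, annotated with
#' the pair correlation and database membership.
#'
#' @param selections Data frame from [select_top()].
#' @param cor_tables Named list of strategy correlation tables (as passed
#'   to [evaluate_specific()]).
#' @param db An [mtp_database()].
#' @param direction `"lower"` or `"higher"`.
#' @param db_only If `TRUE`, keep only pairs present in the database (the
#'   subset used for downstream functional analysis).
#' @return Data frame `mirna_id`, `gene_id`, `correlation`, `strategy`,
#'   `threshold`, `in_database`.
#' @export
integrate_mtps <- function(selections, cor_tables, db,
                           direction = c("lower", "higher"),
                           db_only = FALSE) {
  direction <- match.arg(direction)
  db_keys <- pair_key(db$mirna_id, db$gene_id)
  rows <- list()
  for (i in seq_len(nrow(selections))) {
    sel <- selections[i, ]
    ct <- cor_tables[[sel$strategy]]
    if (is.null(ct)) {
      stop("no correlation table for selected strategy '", sel$strategy, "'")
    }
    det <- detect_mtps(ct, sel$threshold, direction)
    pairs <- det$pairs[det$pairs$mirna_id == sel$mirna_id, , drop = FALSE]
    if (nrow(pairs) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      mirna_id = pairs$mirna_id, gene_id = pairs$gene_id,
      correlation = pairs$r, strategy = sel$strategy,
      threshold = sel$threshold,
      in_database = pair_key(pairs$mirna_id, pairs$gene_id) %in% db_keys,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame(mirna_id = character(0), gene_id = character(0),
                      correlation = numeric(0), strategy = character(0),
                      threshold = numeric(0), in_database = logical(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  if (db_only) out <- out[out$in_database, , drop = FALSE]
  rownames(out) <- NULL
  out
}
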