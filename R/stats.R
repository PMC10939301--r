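# Odds-ratio over-representation statistics. A detection set is compared
# with the pair database over a pair universe: the 2x2 table counts
#   a   = detected pairs that are in the database,
#   b   = detected pairs not in the database,
#   S_d = database pairs in the universe that were not detected,
#   R   = universe pairs neither detected nor in the database,
# and OR = (a/b) / (S_d/R) = (a*R)/(b*S_d). The overall scope pools all
# candidate miRNAs over the expressed-miRNA x expressed-gene universe; the
# specific scope restricts the universe to one miRNA's pairs with the
# candidate genes, which removes the bias introduced by miRNAs that are
# unevenly represented in the database.

#' Define a pair universe
#'
#' A Cartesian universe of miRNA x gene pairs, stored implicitly by its two
#' ID sets.
#'
#' @param mirna_ids,gene_ids Character vectors of unique IDs.
#' @return Object of class `pair_universe` with elements `mirnas`, `genes`,
#'   `size`.
#' @export
pair_universe <- function(mirna_ids, gene_ids) {
  mirna_ids <- unique(as.character(mirna_ids))
  gene_ids <- unique(as.character(gene_ids))
  structure(list(mirnas = mirna_ids, genes = gene_ids,
                 size = length(mirna_ids) * length(gene_ids)),
            class = "pair_universe")
}

#' Build the 2x2 contingency table for one detection set
#'
#' Database pairs outside the universe (unexpressed features) are excluded
#' before counting; detected pairs must all lie inside the universe.
#'
#' @param detected A [detect_mtps()] result, or a data frame with columns
#'   `mirna_id`, `gene_id`.
#' @param db An [mtp_database()].
#' @param universe A [pair_universe()].
#' @return Object of class `contingency_table`: list with integer fields
#'   `a`, `b`, `S_d`, `R` summing to `universe$size`.
#' @export
build_contingency <- function(detected, db, universe) {
  pairs <- if (inherits(detected, "detection_set")) detected$pairs else detected
  stopifnot(inherits(universe, "pair_universe"))
  inside <- pairs$mirna_id %in% universe$mirnas &
    pairs$gene_id %in% universe$genes
  if (any(!inside)) {
    stop("detected pair outside the universe: (",
         pairs$mirna_id[!inside][1L], ", ", pairs$gene_id[!inside][1L], ")")
  }
  db_u <- db$mirna_id %in% universe$mirnas & db$gene_id %in% universe$genes
  db_keys <- pair_key(db$mirna_id[db_u], db$gene_id[db_u])
  det_keys <- pair_key(pairs$mirna_id, pairs$gene_id)
  a <- sum(det_keys %in% db_keys)
  b <- length(det_keys) - a
  S_d <- length(db_keys) - a
  R <- universe$size - a - b - S_d
  structure(list(a = a, b = b, S_d = S_d, R = R),
            class = "contingency_table")
}

as_counts <- function(t) c(a = t$a, b = t$b, S_d = t$S_d, R = t$R)

#' Odds ratio of a 2x2 contingency table
#'
#' `OR = (a*R)/(b*S_d)`. With `zero_correction`, 0.5 is added to every cell
#' whenever any cell is zero (Haldane-Anscombe), which keeps the reported
#' OR finite at strict thresholds where `b` or `S_d` is routinely zero.
#' Returns `NA` when the universe is empty or contains no database pairs
#' (`a + S_d = 0`), where over-representation is undefined.
#'
#' @param t A `contingency_table` (or list with fields `a`, `b`, `S_d`,
#'   `R`).
#' @param zero_correction Apply the Haldane-Anscombe 0.5 correction when a
#'   cell is zero.
#' @return Positive real, `Inf`, or `NA`.
#' @export
odds_ratio <- function(t, zero_correction = TRUE) {
  cnt <- as_counts(t)
  if (sum(cnt) == 0 || (cnt[["a"]] + cnt[["S_d"]]) == 0) return(NA_real_)
  if (zero_correction && any(cnt == 0)) cnt <- cnt + 0.5
  num <- cnt[["a"]] * cnt[["R"]]
  den <- cnt[["b"]] * cnt[["S_d"]]
  if (den == 0) {
    if (num == 0) return(NA_real_)
    return(Inf)
  }
  num / den
}

#' One-sided Fisher's exact test for over-representation
#'
#' Exact p-value `P(X >= a)` under the hypergeometric null with the table's
#' margins (database pairs in the universe as successes, detected pairs as
#' draws). One-sided "greater" because the question is over-representation
#' of database pairs among detections; depletion is not penalized.
#'
#' @inheritParams odds_ratio
#' @return p-value in `[0, 1]`, or `NA` for an empty universe.
#' @export
fisher_exact_greater <- function(t) {
  cnt <- as_counts(t)
  n_univ <- sum(cnt)
  if (n_univ == 0) return(NA_real_)
  k_db <- cnt[["a"]] + cnt[["S_d"]]
  n_det <- cnt[["a"]] + cnt[["b"]]
  phyper(cnt[["a"]] - 1, k_db, n_univ - k_db, n_det, lower.tail = FALSE)
}

#' Benchmark metrics of a contingency table
#'
#' Treating database membership as ground truth: precision `a/(a+b)`,
#' recall `a/(a+S_d)`, specificity `R/(b+R)`, accuracy
#' `(a+R)/(a+b+S_d+R)`. Any 0/0 yields `NA`.
#'
#' @inheritParams odds_ratio
#' @return Named numeric vector `precision`, `recall`, `specificity`,
#'   `accuracy`.
#' @export
benchmark_metrics <- function(t) {
  cnt <- as_counts(t)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  c(precision = safe_div(cnt[["a"]], cnt[["a"]] + cnt[["b"]]),
    recall = safe_div(cnt[["a"]], cnt[["a"]] + cnt[["S_d"]]),
    specificity = safe_div(cnt[["R"]], cnt[["b"]] + cnt[["R"]]),
    accuracy = safe_div(cnt[["a"]] + cnt[["R"]], sum(cnt)))
}

eval_row <- function(t, zero_correction) {
  m <- benchmark_metrics(t)
  data.frame(a = t$a, b = t$b, S_d = t$S_d, R = t$R,
             odds_ratio = odds_ratio(t, zero_correction),
             p_value = fisher_exact_greater(t),
             precision = m[["precision"]], recall = m[["recall"]],
             specificity = m[["specificity"]], accuracy = m[["accuracy"]])
}

#' Overall (pooled) evaluation of every strategy/threshold combination
#'
#' One odds ratio, exact test and benchmark-metric set per (strategy,
#' threshold) over the pooled universe of all expressed-miRNA x
#' expressed-gene pairs.
#'
#' @param cor_tables Named list of [pair_correlations()] tables, one per
#'   strategy.
#' @param db An [mtp_database()].
#' @param universe The overall [pair_universe()] (expressed miRNAs x
#'   expressed genes).
#' @param direction `"lower"` or `"higher"`; sets the threshold grid.
#' @param zero_correction Passed to [odds_ratio()].
#' @return Data frame with one row per (strategy, threshold).
#' @export
evaluate_overall <- function(cor_tables, db, universe,
                             direction = c("lower", "higher"),
                             zero_correction = TRUE) {
  direction <- match.arg(direction)
  grid <- threshold_grid(direction)
  rows <- list()
  for (s in names(cor_tables)) {
    for (th in grid) {
      det <- detect_mtps(cor_tables[[s]], th, direction)
      t <- build_contingency(det, db, universe)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(strategy = s, threshold = th, stringsAsFactors = FALSE),
        eval_row(t, zero_correction))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-miRNA (specific) evaluation of every strategy/threshold combination
#'
#' For each miRNA the universe is its own pairs with the candidate genes,
#' so the same miRNA enters numerator and denominator of the odds ratio and
#' uneven database coverage across miRNAs cannot bias the comparison.
#'
#' @inheritParams evaluate_overall
#' @param gene_ids Candidate gene set (the gene side of each per-miRNA
#'   universe).
#' @param mirna_ids miRNAs to evaluate; defaults to all miRNAs present in
#'   the correlation tables.
#' @return Data frame with one row per (mirna_id, strategy, threshold).
#' @export
evaluate_specific <- function(cor_tables, db, gene_ids, mirna_ids = NULL,
                              direction = c("lower", "higher"),
                              zero_correction = TRUE) {
  direction <- match.arg(direction)
  grid <- threshold_grid(direction)
  if (is.null(mirna_ids)) {
    mirna_ids <- unique(unlist(lapply(cor_tables, function(ct) ct$mirna_id),
                               use.names = FALSE))
  }
  gene_ids <- unique(gene_ids)
  n_genes <- length(gene_ids)
  db_by_mirna <- split(db$gene_id, db$mirna_id)
  rows <- list()
  for (s in names(cor_tables)) {
    ct <- cor_tables[[s]]
    by_mirna <- split(seq_len(nrow(ct)), ct$mirna_id)
    for (m in mirna_ids) {
      idx <- by_mirna[[m]]
      r <- ct$r[idx]
      genes <- ct$gene_id[idx]
      db_genes <- intersect(db_by_mirna[[m]], gene_ids)
      k_db <- length(db_genes)
      in_db <- genes %in% db_genes
      for (th in grid) {
        det <- if (direction == "lower") !is.na(r) & r < th
               else !is.na(r) & r > th
        a <- sum(det & in_db)
        t <- structure(list(a = a, b = sum(det) - a, S_d = k_db - a,
                            R = n_genes - sum(det) - k_db + a),
                       class = "contingency_table")
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(mirna_id = m, strategy = s, threshold = th,
                     stringsAsFactors = FALSE),
          eval_row(t, zero_correction))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
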