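# The seven correlation strategies and threshold-based detection.
#
# A strategy pairs a gene-side representative (Cg = gene CPM, Eg = gene
# module eigengene, Hg = gene module hub) with a miRNA-side representative
# (Cm, Em, Hm). The two combinations that would correlate miRNA modules
# with individual gene CPM profiles (Cg_Em, Cg_Hm) are excluded: no prior
# study uses them and they are not part of the benchmarked set.

REP_KIND <- c(C = "cpm_feature", E = "eigengene", H = "hub")

#' Enumerate the seven correlation strategies
#'
#' @return Data frame with columns `name`, `gene_rep`, `mirna_rep`,
#'   `gene_kind`, `mirna_kind`, in canonical order: Cg_Cm, Eg_Cm, Hg_Cm,
#'   Eg_Em, Eg_Hm, Hg_Em, Hg_Hm.
#' @export
enumerate_strategies <- function() {
  gene_rep <- c("Cg", "Eg", "Hg", "Eg", "Eg", "Hg", "Hg")
  mirna_rep <- c("Cm", "Cm", "Cm", "Em", "Hm", "Em", "Hm")
  data.frame(
    name = paste(gene_rep, mirna_rep, sep = "_"),
    gene_rep = gene_rep,
    mirna_rep = mirna_rep,
    gene_kind = unname(REP_KIND[substr(gene_rep, 1L, 1L)]),
    mirna_kind = unname(REP_KIND[substr(mirna_rep, 1L, 1L)]),
    stringsAsFactors = FALSE
  )
}

#' Correlation threshold grid
#'
#' Anti-correlation mode (`"lower"`) uses the nine thresholds -0.90 to
#' -0.50 in steps of 0.05; positive mode (`"higher"`) uses 0.50 to 0.90.
#'
#' @param direction `"lower"` (anti-correlation) or `"higher"` (positive).
#' @return Numeric vector of thresholds, ordered strict to lenient for
#'   `"lower"` and lenient to strict for `"higher"` (i.e. always ascending).
#' @export
threshold_grid <- function(direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (direction == "lower") {
    round(seq(-0.90, -0.50, by = 0.05), 2L)
  } else {
    round(seq(0.50, 0.90, by = 0.05), 2L)
  }
}

#' Candidate miRNA-gene pairs
#'
#' The Cartesian product of the candidate miRNA set (DEMs by default in the
#' pipeline, or all expressed miRNAs) with the candidate gene set.
#'
#' @param mirna_ids,gene_ids Non-empty character vectors.
#' @return Data frame with columns `mirna_id`, `gene_id`; miRNAs vary
#'   slowest.
#' @export
candidate_pairs <- function(mirna_ids, gene_ids) {
  if (length(mirna_ids) == 0L) {
    stop("empty miRNA set; if no DEMs are available, use the expressed ",
         "miRNA set (mirna_set = \"expressed\")")
  }
  if (length(gene_ids) == 0L) stop("empty gene set")
  data.frame(
    mirna_id = rep(mirna_ids, each = length(gene_ids)),
    gene_id = rep(gene_ids, times = length(mirna_ids)),
    stringsAsFactors = FALSE
  )
}

#' Pairwise Pearson correlations under one strategy
#'
#' Correlates each candidate pair's gene-side and miRNA-side representative
#' profiles over the shared sample order. Under module strategies the
#' correlation is computed once per (gene representative, miRNA
#' representative) combination and broadcast to all member pairs. `r` is
#' `NA` when either feature lacks a representative (unassigned under a
#' module strategy, or its module was skipped) or a profile has zero
#' variance.
#'
#' @param gene_reps,mirna_reps [build_representatives()] maps for the
#'   strategy's representative kinds.
#' @param pairs Data frame from [candidate_pairs()].
#' @param strategy Strategy name (one of [enumerate_strategies()]`$name`).
#' @return Data frame with columns `mirna_id`, `gene_id`, `strategy`, `r`.
#' @export
pair_correlations <- function(gene_reps, mirna_reps, pairs, strategy) {
  stopifnot(inherits(gene_reps, "representative_map"),
            inherits(mirna_reps, "representative_map"))
  if (!identical(gene_reps$samples, mirna_reps$samples)) {
    stop("gene and miRNA matrices must share the same samples in the ",
         "same order")
  }
  gp <- gene_reps$feature_profile[pairs$gene_id]
  mp <- mirna_reps$feature_profile[pairs$mirna_id]
  r <- rep(NA_real_, nrow(pairs))
  ok <- !is.na(gp) & !is.na(mp)
  if (any(ok)) {
    gprof <- unique(gp[ok])
    mprof <- unique(mp[ok])
    # cor() yields NA for zero-variance profiles, which is the wanted
    # degenerate-profile behaviour.
    cmat <- suppressWarnings(
      cor(t(gene_reps$profiles[gprof, , drop = FALSE]),
          t(mirna_reps$profiles[mprof, , drop = FALSE]))
    )
    r[ok] <- cmat[cbind(match(gp[ok], gprof), match(mp[ok], mprof))]
  }
  data.frame(mirna_id = pairs$mirna_id, gene_id = pairs$gene_id,
             strategy = strategy, r = r, stringsAsFactors = FALSE)
}

#' Threshold-based mTP detection
#'
#' Keeps pairs whose correlation is strictly below the threshold
#' (`direction = "lower"`, anti-correlation) or strictly above it
#' (`direction = "higher"`, positive mode). Boundary values are excluded
#' and `NA` correlations are never detected.
#'
#' @param corr Correlation table from [pair_correlations()].
#' @param threshold A value from [threshold_grid()] for the direction.
#' @param direction `"lower"` or `"higher"`.
#' @return An object of class `detection_set`: list with `strategy`,
#'   `threshold`, `direction` and `pairs` (data frame `mirna_id`,
#'   `gene_id`, `r`).
#' @export
detect_mtps <- function(corr, threshold, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  grid <- threshold_grid(direction)
  if (!any(abs(grid - threshold) < 1e-9)) {
    stop("threshold ", threshold, " is not in the ", direction, " grid")
  }
  keep <- if (direction == "lower") {
    !is.na(corr$r) & corr$r < threshold
  } else {
    !is.na(corr$r) & corr$r > threshold
  }
  structure(list(
    strategy = unique(corr$strategy),
    threshold = threshold,
    direction = direction,
    pairs = corr[keep, c("mirna_id", "gene_id", "r")]
  ), class = "detection_set")
}

# Correlation tables for all seven strategies, building each representative
# map once. Returns a named list of correlation tables.
correlate_all_strategies <- function(gene_cpm, mirna_cpm, gene_modules,
                                     mirna_modules, pairs) {
  strategies <- enumerate_strategies()
  gene_maps <- list()
  mirna_maps <- list()
  for (k in unique(strategies$gene_kind)) {
    gene_maps[[k]] <- build_representatives(gene_cpm, gene_modules, k)
  }
  for (k in unique(strategies$mirna_kind)) {
    mirna_maps[[k]] <- build_representatives(mirna_cpm, mirna_modules, k)
  }
  out <- vector("list", nrow(strategies))
  names(out) <- strategies$name
  for (i in seq_len(nrow(strategies))) {
    out[[i]] <- pair_correlations(gene_maps[[strategies$gene_kind[i]]],
                                  mirna_maps[[strategies$mirna_kind[i]]],
                                  pairs, strategies$name[i])
  }
  out
}
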