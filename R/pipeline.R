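# Orchestration: in-memory analysis core, YAML/list config validation and
# the file-based pipeline behind the command-line interface.

#' Run the full strategy-comparison and selection-integration analysis
#'
#' Executes profiles -> strategies -> statistics -> selection-integration
#' (-> optional robustness) on in-memory inputs and returns all result
#' tables.
#'
#' @param genes,mirnas [expression_matrix()] objects over the same samples
#'   in the same order (counts or CPM; counts are CPM-normalized here).
#' @param gene_modules,mirna_modules Named character assignments
#'   (feature_id -> module_id; `"0"` = unassigned). Features absent from
#'   the assignment are treated as unassigned.
#' @param dems,degs Character vectors of differentially expressed miRNA /
#'   gene IDs (IDs not in the matrices are dropped with a warning).
#' @param db An [mtp_database()].
#' @param corr_type `"lower"` (anti-correlation, default) or `"higher"`
#'   (positive mode); chooses the threshold grid and detection direction.
#' @param mirna_set `"dem"` (default): candidate pairs use the DEMs;
#'   `"expressed"`: all miRNAs.
#' @param gene_set `"expressed"` (default) or `"deg"`: gene side of the
#'   candidate pairs and of the specific universes.
#' @param alpha Significance level for the exact-test filter.
#' @param fdr Filter on Benjamini-Hochberg adjusted p-values instead.
#' @param zero_correction Haldane-Anscombe correction for reported odds
#'   ratios (the exact test always uses the uncorrected table).
#' @param db_only Restrict `integrated_mtps` to database pairs.
#' @param robustness If `TRUE`, run the database-subsampling protocol.
#' @param robustness_fraction,robustness_reps Subsample fraction (default
#'   0.75) and replicate count (default 40).
#' @param seed Base seed for the robustness subsampling.
#' @return List of class `mtp_results` with `overall_eval`,
#'   `specific_eval`, `selection`, `integrated_mtps`, `robustness` (NULL
#'   unless requested), `cor_tables`, `universe`, `settings`.
#' @export
mtp_analysis <- function(genes, mirnas, gene_modules, mirna_modules,
                         dems, degs = character(0), db,
                         corr_type = c("lower", "higher"),
                         mirna_set = c("dem", "expressed"),
                         gene_set = c("expressed", "deg"),
                         alpha = 0.05, fdr = FALSE,
                         zero_correction = TRUE, db_only = FALSE,
                         robustness = FALSE, robustness_fraction = 0.75,
                         robustness_reps = 40L, seed = 1L) {
  corr_type <- match.arg(corr_type)
  mirna_set <- match.arg(mirna_set)
  gene_set <- match.arg(gene_set)
  stopifnot(inherits(genes, "expression_matrix"),
            inherits(mirnas, "expression_matrix"))
  if (!identical(sample_ids(genes), sample_ids(mirnas))) {
    stop("gene and miRNA matrices must share the same samples in the ",
         "same order")
  }
  if (!genes$normalized) genes <- cpm_normalize(genes)
  if (!mirnas$normalized) mirnas <- cpm_normalize(mirnas)
  dems <- filter_feature_set(dems, mirnas, role = "DEM")
  degs <- filter_feature_set(degs, genes, role = "DEG")

  cand_mirnas <- if (mirna_set == "dem") dems else feature_ids(mirnas)
  cand_genes <- if (gene_set == "deg") degs else feature_ids(genes)
  pairs <- candidate_pairs(cand_mirnas, cand_genes)

  cor_tables <- correlate_all_strategies(genes, mirnas, gene_modules,
                                         mirna_modules, pairs)

  overall_universe <- pair_universe(feature_ids(mirnas), cand_genes)
  overall <- evaluate_overall(cor_tables, db, overall_universe,
                              direction = corr_type,
                              zero_correction = zero_correction)
  specific <- evaluate_specific(cor_tables, db, cand_genes,
                                mirna_ids = cand_mirnas,
                                direction = corr_type,
                                zero_correction = zero_correction)
  selection <- select_top(specific, alpha = alpha, fdr = fdr)
  integrated <- integrate_mtps(selection, cor_tables, db,
                               direction = corr_type, db_only = db_only)
  robust <- NULL
  if (robustness && nrow(selection) > 0L) {
    robust <- robustness_rankings(cor_tables, db, cand_genes, selection,
                                  fraction = robustness_fraction,
                                  n_reps = robustness_reps,
                                  base_seed = seed,
                                  direction = corr_type, alpha = alpha,
                                  fdr = fdr,
                                  zero_correction = zero_correction)
  }
  structure(list(
    overall_eval = overall, specific_eval = specific,
    selection = selection, integrated_mtps = integrated,
    robustness = robust, cor_tables = cor_tables,
    universe = overall_universe,
    settings = list(corr_type = corr_type, mirna_set = mirna_set,
                    gene_set = gene_set, alpha = alpha, fdr = fdr,
                    zero_correction = zero_correction, db_only = db_only,
                    seed = seed)
  ), class = "mtp_results")
}

#' @export
print.mtp_results <- function(x, ...) {
  cat("<mtp_results>\n")
  cat(sprintf("  mode: %s; candidate miRNAs: %d; candidate genes: %d\n",
              x$settings$corr_type,
              length(unique(x$specific_eval$mirna_id)),
              length(x$universe$genes)))
  cat(sprintf("  miRNAs with a selected combination: %d\n",
              nrow(x$selection)))
  cat(sprintf("  integrated mTPs: %d (%d in database)\n",
              nrow(x$integrated_mtps), sum(x$integrated_mtps$in_database)))
  invisible(x)
}

config_defaults <- function() {
  list(genes = NULL, mirnas = NULL, gene_modules = NULL,
       mirna_modules = NULL, dems = NULL, degs = NULL, db = NULL,
       normalized = FALSE, lowercase_ids = FALSE,
       corr_type = "lower", mirna_set = "dem", gene_set = "expressed",
       alpha = 0.05, fdr = FALSE, zero_correction = TRUE,
       db_only = FALSE, robustness = FALSE, robustness_fraction = 0.75,
       robustness_reps = 40L, seed = 1L, out_dir = "mtpcor_results")
}

#' Validate a run configuration
#'
#' Accepts a YAML file path or a named list; fills defaults (alpha 0.05,
#' robustness fraction 0.75 with 40 replicates, grid chosen by
#' `corr_type`), rejects unknown keys and out-of-range values, and checks
#' that all referenced input files exist.
#'
#' @param config Path to a YAML config file, or a named list.
#' @return The completed config list (class `mtp_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  required <- c("genes", "mirnas", "gene_modules", "mirna_modules",
                "dems", "db")
  for (key in required) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
    if (!file.exists(cfg[[key]])) {
      stop("config key '", key, "': file not found: ", cfg[[key]])
    }
  }
  if (!is.null(cfg$degs) && !file.exists(cfg$degs)) {
    stop("config key 'degs': file not found: ", cfg$degs)
  }
  if (!cfg$corr_type %in% c("lower", "higher")) {
    stop("corr_type must be 'lower' or 'higher'")
  }
  if (!cfg$mirna_set %in% c("dem", "expressed")) {
    stop("mirna_set must be 'dem' or 'expressed'")
  }
  if (!cfg$gene_set %in% c("expressed", "deg")) {
    stop("gene_set must be 'expressed' or 'deg'")
  }
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(cfg$robustness_fraction > 0 && cfg$robustness_fraction <= 1)) {
    stop("robustness_fraction must be in (0, 1]")
  }
  if (cfg$robustness_reps < 1L) stop("robustness_reps must be >= 1")
  structure(cfg, class = c("mtp_config", "list"))
}

#' Run the file-based pipeline
#'
#' Reads all inputs named in the config, runs [mtp_analysis()] and writes
#' the result tables to `out_dir`. Per-stage counts are reported via
#' `message()`.
#'
#' @param config A config file path or list; see [validate_config()].
#' @return Invisibly, the [mtp_analysis()] results bundle.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  lc <- cfg$lowercase_ids
  genes <- read_expression_table(cfg$genes, kind = "gene",
                                 normalized = cfg$normalized,
                                 lowercase_ids = lc)
  mirnas <- read_expression_table(cfg$mirnas, kind = "mirna",
                                  normalized = cfg$normalized,
                                  lowercase_ids = lc)
  gene_modules <- read_module_assignment(cfg$gene_modules,
                                         lowercase_ids = lc)
  mirna_modules <- read_module_assignment(cfg$mirna_modules,
                                          lowercase_ids = lc)
  dems <- read_feature_list(cfg$dems, lowercase_ids = lc)
  degs <- if (is.null(cfg$degs)) character(0) else
    read_feature_list(cfg$degs, lowercase_ids = lc)
  db <- read_mtp_database(cfg$db, lowercase_ids = lc)
  message("inputs: ", nrow(genes$values), " genes, ",
          nrow(mirnas$values), " miRNAs, ", length(dems), " DEMs, ",
          nrow(db), " database pairs")
  results <- mtp_analysis(
    genes, mirnas, gene_modules, mirna_modules, dems, degs, db,
    corr_type = cfg$corr_type, mirna_set = cfg$mirna_set,
    gene_set = cfg$gene_set, alpha = cfg$alpha, fdr = cfg$fdr,
    zero_correction = cfg$zero_correction, db_only = cfg$db_only,
    robustness = cfg$robustness,
    robustness_fraction = cfg$robustness_fraction,
    robustness_reps = cfg$robustness_reps, seed = cfg$seed)
  message("selection: ", nrow(results$selection),
          " miRNA(s) with a significant combination; integrated mTPs: ",
          nrow(results$integrated_mtps))
  write_results_tables(results, cfg$out_dir)
  invisible(results)
}
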