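# Tabular input/output with strict validation. All files are plain TSV:
# tab-separated, UTF-8, '#' comment lines ignored, no quoting.

UNASSIGNED_MODULE <- "0"

#' Construct a validated expression matrix
#'
#' Wraps a numeric features x samples matrix together with its kind and
#' normalization state. All downstream functions require at least 3 samples
#' (Pearson correlation is degenerate below that), unique feature and sample
#' IDs, and finite non-negative values.
#'
#' @param values Numeric matrix, rows = features, columns = samples, with
#'   rownames and colnames set.
#' @param kind `"gene"` or `"mirna"`.
#' @param normalized Logical; `TRUE` if values are already CPM (or otherwise
#'   library-size normalized), `FALSE` for raw counts.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `kind`, `normalized`.
#' @export
expression_matrix <- function(values, kind = c("gene", "mirna"),
                              normalized = FALSE) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate feature ID: '", dup, "'")
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop("duplicate sample ID: '", dup, "'")
  }
  if (ncol(values) < 3L) {
    stop("at least 3 samples required (got ", ncol(values), ")")
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be >= 0")
  structure(list(values = values, kind = kind, normalized = normalized),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s: %d features x %d samples (%s)\n",
              x$kind, nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "counts"))
  invisible(x)
}

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# Shared TSV reader: no quoting, '#' comments, UTF-8.
read_tsv_raw <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, header = header, sep = "\t", quote = "",
             comment.char = "#", check.names = FALSE,
             colClasses = "character", blank.lines.skip = TRUE,
             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read an expression table from TSV
#'
#' Expects a header row of sample IDs and a first column of feature IDs.
#'
#' @param path Path to a TSV file.
#' @inheritParams expression_matrix
#' @param lowercase_ids If `TRUE`, lowercase all feature IDs at load time
#'   (ID matching elsewhere is exact and case-sensitive; miRNA nomenclature
#'   is inconsistent across databases, so normalization is explicit, never
#'   silent).
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, kind = c("gene", "mirna"),
                                  normalized = FALSE, lowercase_ids = FALSE) {
  kind <- match.arg(kind)
  tab <- read_tsv_raw(path, header = TRUE)
  if (ncol(tab) < 2L) stop("expression table needs >= 1 sample column: ", path)
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate feature ID in ", path, ": '",
         ids[duplicated(ids)][1L], "'")
  }
  num <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab)))
  )
  num <- matrix(num, nrow = nrow(tab),
                dimnames = list(ids, colnames(tab)[-1L]))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric value at feature '", ids[bad[1L]], "', sample '",
         colnames(num)[bad[2L]], "' in ", path)
  }
  if (lowercase_ids) rownames(num) <- tolower(rownames(num))
  expression_matrix(num, kind = kind, normalized = normalized)
}

#' Read a feature-to-module assignment table
#'
#' Two-column TSV (feature_id, module_id), no header. Module `"0"` is the
#' unassigned sentinel (the grey-module equivalent); features absent from
#' the file are treated as unassigned downstream. An empty file yields an
#' empty assignment.
#'
#' @inheritParams read_expression_table
#' @return Named character vector mapping feature_id to module_id.
#' @export
read_module_assignment <- function(path, lowercase_ids = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- read_pair_lines(path)
  if (length(lines$first) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  feat <- lines$first
  mod <- lines$second
  if (lowercase_ids) feat <- tolower(feat)
  # Consistent duplicates are collapsed; conflicting ones are an error.
  if (anyDuplicated(feat)) {
    for (f in unique(feat[duplicated(feat)])) {
      mods <- unique(mod[feat == f])
      if (length(mods) > 1L) {
        stop("feature '", f, "' assigned to multiple modules: ",
             paste(mods, collapse = ", "))
      }
    }
    keep <- !duplicated(feat)
    feat <- feat[keep]
    mod <- mod[keep]
  }
  stats::setNames(mod, feat)
}

# Parse a strict two-column TSV into its columns, reporting the (1-based,
# comment-inclusive) line number of any malformed row.
read_pair_lines <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  first <- character(0)
  second <- character(0)
  for (i in which(keep)) {
    parts <- strsplit(raw[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("malformed row at line ", i, " of ", path,
           ": expected 2 tab-separated columns, got ", length(parts))
    }
    first <- c(first, parts[[1L]])
    second <- c(second, parts[[2L]])
  }
  list(first = first, second = second)
}

#' Read a list of feature IDs (one per line)
#'
#' @inheritParams read_expression_table
#' @return Character vector of unique IDs.
#' @export
read_feature_list <- function(path, lowercase_ids = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8")
  ids <- trimws(raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))])
  if (lowercase_ids) ids <- tolower(ids)
  unique(ids)
}

#' Read a miRNA-target pair database
#'
#' Two-column TSV (mirna_id, gene_id), no header; any two-column pair table
#' (e.g. a multiMiR export) serves. Duplicate rows are allowed in the file
#' and de-duplicated, with a message reporting the count dropped.
#'
#' @inheritParams read_expression_table
#' @return An `mtp_database`: data frame with columns `mirna_id`, `gene_id`,
#'   unique rows.
#' @export
read_mtp_database <- function(path, lowercase_ids = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- read_pair_lines(path)
  db <- mtp_database(lines$first, lines$second,
                     lowercase_ids = lowercase_ids, quiet = FALSE)
  db
}

#' Construct a validated pair database
#'
#' @param mirna_id,gene_id Character vectors of equal length; non-empty IDs.
#' @param lowercase_ids Lowercase both ID columns.
#' @param quiet Suppress the dropped-duplicate message.
#' @return Data frame of class `mtp_database` with unique
#'   (`mirna_id`, `gene_id`) rows.
#' @export
mtp_database <- function(mirna_id = character(0), gene_id = character(0),
                         lowercase_ids = FALSE, quiet = TRUE) {
  mirna_id <- as.character(mirna_id)
  gene_id <- as.character(gene_id)
  if (length(mirna_id) != length(gene_id)) {
    stop("mirna_id and gene_id must have equal length")
  }
  if (any(!nzchar(mirna_id)) || any(!nzchar(gene_id))) {
    stop("pair database IDs must be non-empty strings")
  }
  if (lowercase_ids) {
    mirna_id <- tolower(mirna_id)
    gene_id <- tolower(gene_id)
  }
  key <- pair_key(mirna_id, gene_id)
  dup <- duplicated(key)
  if (any(dup) && !quiet) {
    message("dropped ", sum(dup), " duplicate pair(s)")
  }
  df <- data.frame(mirna_id = mirna_id[!dup], gene_id = gene_id[!dup],
                   stringsAsFactors = FALSE)
  class(df) <- c("mtp_database", "data.frame")
  df
}

pair_key <- function(mirna_id, gene_id) paste(mirna_id, gene_id, sep = "\x1f")

#' Restrict a feature set to the features present in an expression matrix
#'
#' DEG/DEM lists must be subsets of the corresponding matrix; violations are
#' dropped with a warning naming the role and count.
#'
#' @param ids Character vector of feature IDs.
#' @param expr An [expression_matrix()].
#' @param role Label used in the warning (e.g. `"DEM"`).
#' @return The IDs present in `expr`, in input order.
#' @export
filter_feature_set <- function(ids, expr, role = "feature") {
  present <- ids %in% feature_ids(expr)
  if (any(!present)) {
    warning(sum(!present), " ", role,
            " ID(s) absent from the expression matrix were dropped: ",
            paste(head(ids[!present], 5L), collapse = ", "),
            if (sum(!present) > 5L) ", ..." else "")
  }
  ids[present]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
}

#' Write the result tables of a pipeline run
#'
#' Writes `overall_eval.tsv`, `specific_eval.tsv`, `selection.tsv`,
#' `integrated_mtps.tsv` and `robustness.tsv` to `out_dir`. Empty components
#' produce headers-only files, so the output layout is fixed.
#'
#' @param results A results bundle as returned by [mtp_analysis()].
#' @param out_dir Output directory; created if missing.
#' @return Invisibly, the paths written.
#' @export
write_results_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  schemas <- list(
    overall_eval = c("strategy", "threshold", "a", "b", "S_d", "R",
                     "odds_ratio", "p_value"),
    specific_eval = c("mirna_id", "strategy", "threshold", "a", "b", "S_d",
                      "R", "odds_ratio", "p_value", "precision", "recall",
                      "specificity", "accuracy"),
    selection = c("mirna_id", "strategy", "threshold", "odds_ratio",
                  "p_value", "n_detected", "n_overlap_db"),
    integrated_mtps = c("mirna_id", "gene_id", "correlation", "strategy",
                        "threshold", "in_database"),
    robustness = c("mirna_id", "replicate", "rank_of_original_top",
                   "was_significant")
  )
  files <- c(overall_eval = "overall_eval.tsv",
             specific_eval = "specific_eval.tsv",
             selection = "selection.tsv",
             integrated_mtps = "integrated_mtps.tsv",
             robustness = "robustness.tsv")
  paths <- character(0)
  for (name in names(files)) {
    df <- results[[name]]
    cols <- schemas[[name]]
    if (is.null(df) || nrow(df) == 0L) {
      df <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(cols)), cols))
    } else {
      missing_cols <- setdiff(cols, colnames(df))
      if (length(missing_cols)) {
        stop("results$", name, " lacks column(s): ",
             paste(missing_cols, collapse = ", "))
      }
      df <- df[, cols, drop = FALSE]
    }
    path <- file.path(out_dir, files[[name]])
    write_tsv(df, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
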