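# Representative expression profiles: per-feature CPM rows, module
# eigengenes (first PC of the standardized member matrix, WGCNA convention)
# and module hub profiles (member with maximal |kME|).

#' Counts-per-million normalization
#'
#' Scales every sample column to counts per million mapped reads:
#' `value[i, j] / colsum[j] * 1e6`. Within-sample rank order of features is
#' preserved.
#'
#' @param counts An [expression_matrix()] with `normalized = FALSE`.
#' @return The CPM-normalized [expression_matrix()] (`normalized = TRUE`).
#' @export
cpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$normalized) stop("matrix is already normalized")
  libsize <- colSums(counts$values)
  if (any(libsize == 0)) {
    stop("zero-sum sample column: '",
         colnames(counts$values)[libsize == 0][1L], "'")
  }
  cpm <- sweep(counts$values, 2L, libsize, "/") * 1e6
  expression_matrix(cpm, kind = counts$kind, normalized = TRUE)
}

module_members <- function(expr, assignment, module_id) {
  if (identical(module_id, UNASSIGNED_MODULE)) {
    stop("module '", UNASSIGNED_MODULE,
         "' is the unassigned sentinel and has no representative profile")
  }
  members <- names(assignment)[assignment == module_id]
  members <- intersect(members, feature_ids(expr))
  if (length(members) == 0L) {
    stop("module '", module_id,
         "' has no members present in the expression matrix")
  }
  members
}

# Row standardization with population sd (divisor n), the PCA convention
# used for eigengene computation. Zero-variance rows come back as NA rows.
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  (x - mu) / sd_pop
}

#' Module eigengene
#'
#' The first principal component of the module's member x sample matrix
#' after per-feature standardization (mean 0, population sd 1 across
#' samples). The returned vector has unit Euclidean norm and its sign is
#' oriented so that its Pearson correlation with the mean standardized
#' member profile is non-negative; if that correlation is numerically zero
#' or undefined (an exactly balanced module), the first non-zero entry is
#' made positive. Constant member
#' profiles are dropped with a warning before the PCA.
#'
#' @param expr An [expression_matrix()] (typically CPM).
#' @param assignment Named character vector feature_id -> module_id.
#' @param module_id Module to summarize; the unassigned sentinel `"0"` is
#'   rejected.
#' @return Named numeric vector over samples, unit norm.
#' @export
module_eigengene <- function(expr, assignment, module_id) {
  members <- module_members(expr, assignment, module_id)
  x <- expr$values[members, , drop = FALSE]
  z <- standardize_rows(x)
  constant <- !stats::complete.cases(z)
  if (any(constant)) {
    warning("module '", module_id, "': dropped ", sum(constant),
            " constant member profile(s)")
    z <- z[!constant, , drop = FALSE]
  }
  if (nrow(z) == 0L) {
    stop("module '", module_id, "': all member profiles are constant")
  }
  v <- svd(z, nu = 0L, nv = 1L)$v[, 1L]
  v <- orient_eigengene(v, colMeans(z))
  stats::setNames(v, sample_ids(expr))
}

orient_eigengene <- function(v, mean_profile) {
  r <- suppressWarnings(cor(v, mean_profile))
  # an exactly balanced module (e.g. two anti-correlated members) leaves
  # the first PC orthogonal to the mean profile; fall back to a fixed rule
  if (!is.na(r) && abs(r) > 1e-10) {
    if (r < 0) v <- -v
  } else {
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1L]] < 0) v <- -v
  }
  v
}

#' Module hub profile
#'
#' The CPM profile of the module's hub feature: the member with the highest
#' absolute correlation with the module eigengene (|kME|, the standard
#' module-membership hubness score). Ties are broken by lexicographically
#' smallest feature ID. Published module workflows rarely pin the hub
#' definition down in print; max-|kME| is the documented convention here.
#'
#' @inheritParams module_eigengene
#' @return Named numeric vector over samples (the hub member's expression
#'   row), with attribute `hub_id`.
#' @export
module_hub_profile <- function(expr, assignment, module_id) {
  members <- module_members(expr, assignment, module_id)
  eg <- module_eigengene(expr, assignment, module_id)
  kme <- suppressWarnings(
    apply(expr$values[members, , drop = FALSE], 1L, cor, y = eg)
  )
  score <- abs(kme)
  score[is.na(score)] <- -Inf  # constant members can never be hub
  best <- max(score)
  hub <- sort(members[score == best])[1L]
  out <- expr$values[hub, ]
  attr(out, "hub_id") <- hub
  out
}

#' Build a representative-profile map
#'
#' Maps features to the profile the chosen representative kind assigns them:
#' their own CPM row (`cpm_feature`), or their module's eigengene or hub
#' profile (shared by all module members). Features in the unassigned module
#' `"0"` (or absent from the assignment) are present in the map only for
#' `cpm_feature`. Modules whose summary cannot be computed (all-constant
#' members) are skipped with a warning and their members excluded.
#'
#' @inheritParams module_eigengene
#' @param rep_kind `"cpm_feature"`, `"eigengene"` or `"hub"`.
#' @return An object of class `representative_map`: list with `profiles`
#'   (profile x sample matrix), `feature_profile` (named character mapping
#'   feature_id to a row of `profiles`) and `kind`.
#' @export
build_representatives <- function(expr, assignment,
                                  rep_kind = c("cpm_feature", "eigengene",
                                               "hub")) {
  rep_kind <- match.arg(rep_kind)
  samples <- sample_ids(expr)
  if (rep_kind == "cpm_feature") {
    profiles <- expr$values
    feature_profile <- stats::setNames(feature_ids(expr), feature_ids(expr))
  } else {
    mods <- setdiff(unique(assignment[names(assignment) %in%
                                        feature_ids(expr)]),
                    UNASSIGNED_MODULE)
    mods <- sort(mods)
    profiles <- matrix(numeric(0), nrow = 0L, ncol = length(samples),
                       dimnames = list(NULL, samples))
    feature_profile <- character(0)
    for (m in mods) {
      prof <- tryCatch(
        switch(rep_kind,
               eigengene = module_eigengene(expr, assignment, m),
               hub = module_hub_profile(expr, assignment, m)),
        error = function(e) {
          warning("skipping module '", m, "': ", conditionMessage(e))
          NULL
        })
      if (is.null(prof)) next
      profiles <- rbind(profiles, matrix(as.numeric(prof), nrow = 1L,
                                         dimnames = list(m, samples)))
      members <- module_members(expr, assignment, m)
      feature_profile <- c(feature_profile, stats::setNames(rep(m,
        length(members)), members))
    }
  }
  structure(list(profiles = profiles, feature_profile = feature_profile,
                 kind = rep_kind, samples = samples),
            class = "representative_map")
}
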