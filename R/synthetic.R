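# Seeded synthetic datasets with planted miRNA -> target regulation.
#
# Co-expression is induced by shared latent Gaussian sample factors: each
# module has a latent profile, members load on it, and log-expression is
# the loaded latent plus feature noise, exponentiated around a lognormal
# baseline abundance. Regulation is planted either at the feature level
# (each target's profile couples directly to its regulator miRNA) or at the
# module level (a whole target module couples only through its latent, so
# the module eigengene carries the signal while individual member profiles
# are noisy) - the two architectures under which individual-profile (Cg_Cm)
# and eigengene (Eg_Cm) strategies are respectively optimal.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a small paired expression study: 12 samples, 500
#' genes in 5 co-expression modules, 60 miRNAs in 3 modules, 3 regulator
#' miRNAs (the DEM set) with 15 planted targets each, repressive coupling
#' of -0.9 on the latent scale, 80% of planted pairs present in the pair
#' database plus 1500 random decoy pairs (about 5% of the 60 x 500 pair
#' universe, echoing the density of predicted-target databases).
#'
#' @param n_samples,n_genes,n_mirnas Dimensions of the study.
#' @param n_gene_modules,n_mirna_modules Number of co-expression modules
#'   (10% of features are left unassigned, module `"0"`).
#' @param n_regulator_mirnas Number of regulator miRNAs (these form the
#'   DEM list).
#' @param targets_per_regulator Planted targets per regulator.
#' @param coupling Signed latent-scale coupling in `[-1, 1]`; negative =
#'   repression (anti-correlation), 0 = null data with no planted pairs.
#' @param db_truth_fraction Share of planted pairs included in the
#'   database.
#' @param db_decoy_count Random non-planted pairs added to the database.
#' @param regulation `"feature"` (targets couple individually to the
#'   regulator) or `"module"` (dedicated target modules couple through
#'   their latent only).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 12L, n_genes = 500L,
                             n_mirnas = 60L, n_gene_modules = 5L,
                             n_mirna_modules = 3L,
                             n_regulator_mirnas = 3L,
                             targets_per_regulator = 15L,
                             coupling = -0.9, db_truth_fraction = 0.8,
                             db_decoy_count = 1500L,
                             regulation = c("feature", "module"),
                             seed = 1L) {
  regulation <- match.arg(regulation)
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas),
              n_gene_modules = as.integer(n_gene_modules),
              n_mirna_modules = as.integer(n_mirna_modules),
              n_regulator_mirnas = as.integer(n_regulator_mirnas),
              targets_per_regulator = as.integer(targets_per_regulator),
              coupling = coupling,
              db_truth_fraction = db_truth_fraction,
              db_decoy_count = as.integer(db_decoy_count),
              regulation = regulation, seed = as.integer(seed))
  with(cfg, {
    if (n_samples < 3L) stop("n_samples must be >= 3")
    if (min(n_genes, n_mirnas, n_gene_modules, n_mirna_modules,
            n_regulator_mirnas, targets_per_regulator) < 1L) {
      stop("all counts must be positive")
    }
    if (abs(coupling) > 1) stop("|coupling| must be <= 1")
    if (db_truth_fraction < 0 || db_truth_fraction > 1) {
      stop("db_truth_fraction must be in [0, 1]")
    }
    if (db_decoy_count < 0) stop("db_decoy_count must be >= 0")
    if (n_regulator_mirnas > n_mirnas) stop("more regulators than miRNAs")
    if (targets_per_regulator > n_genes) {
      stop("targets_per_regulator exceeds n_genes")
    }
    if (n_regulator_mirnas * targets_per_regulator > floor(0.9 * n_genes)) {
      stop("too many planted targets for the assigned gene pool")
    }
    if (regulation == "module" && n_gene_modules <= n_regulator_mirnas) {
      stop("module regulation needs n_gene_modules > n_regulator_mirnas")
    }
  })
  structure(cfg, class = "synthetic_config")
}

# log-scale sd of the structured signal; kept mild so that latent-scale
# correlations survive exponentiation and CPM scaling with limited
# attenuation (the generator's contract is that observed pair correlations
# track the configured coupling).
SYN_SIGMA <- 0.3
SYN_MODULE_LOADING <- 0.8          # member loading on its module latent
SYN_TARGET_MODULE_LOADING <- 0.3   # feature-level targets' module loading
# Module-level regulation means individual members are noisy reporters of
# the aggregate signal: their loading is set low enough that single-profile
# correlations sit at or below the detection grid while the eigengene,
# which averages member noise away, sits well above it.
SYN_MODULE_PRESET_LOADING <- 0.55
# Regulated modules in the module preset are this many times larger than
# the planted target set (co-expressed non-targets are the usual cost of
# module-level strategies; they also make the sample eigengene estimable
# at small n).
SYN_PRESET_MODULE_MULTIPLIER <- 4L
SYN_UNASSIGNED_FRACTION <- 0.1

#' Generate a seeded synthetic dataset
#'
#' @param config A [synthetic_config()].
#' @return List with elements `genes` and `mirnas`
#'   ([expression_matrix()]s of count-like values), `gene_modules` and
#'   `mirna_modules` (named character assignments; unassigned = `"0"`),
#'   `dems`, `degs` (character vectors), `db` ([mtp_database()]), `truth`
#'   (list with `planted_pairs` data frame of `mirna_id`, `gene_id`,
#'   `sign`, plus `regulators` and `config`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  ns <- cfg$n_samples
  samples <- sprintf("S%02d", seq_len(ns))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  mirnas <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  regulators <- mirnas[seq_len(cfg$n_regulator_mirnas)]
  c0 <- abs(cfg$coupling)
  csign <- sign(cfg$coupling)
  planted <- cfg$coupling != 0

  # --- gene module layout ---------------------------------------------
  n_unassigned <- round(SYN_UNASSIGNED_FRACTION * cfg$n_genes)
  assigned_genes <- genes[seq_len(cfg$n_genes - n_unassigned)]
  gene_mod_names <- sprintf("GM%d", seq_len(cfg$n_gene_modules))
  if (planted && cfg$regulation == "module") {
    # Dedicated regulated modules first, background modules take the rest.
    # Each regulated module is larger than the planted target set: the
    # module as a whole is co-expressed with (and repressed by) the
    # regulator, but only `targets_per_regulator` of its members are true
    # database targets - the usual situation when a miRNA drives a
    # co-expression module through a subset of direct targets.
    mod_size <- min(SYN_PRESET_MODULE_MULTIPLIER * cfg$targets_per_regulator,
                    length(assigned_genes) %/% (cfg$n_regulator_mirnas + 1L))
    mod_size <- max(mod_size, cfg$targets_per_regulator)
    n_regmod <- cfg$n_regulator_mirnas * mod_size
    regmod_genes <- assigned_genes[seq_len(n_regmod)]
    rest <- assigned_genes[-seq_len(n_regmod)]
    gm <- c(rep(gene_mod_names[seq_len(cfg$n_regulator_mirnas)],
                each = mod_size),
            gene_mod_names[cfg$n_regulator_mirnas +
              1L + (seq_along(rest) - 1L) %%
              (cfg$n_gene_modules - cfg$n_regulator_mirnas)])
    gene_assign <- stats::setNames(gm, c(regmod_genes, rest))
    # planted targets: a random subset of each regulated module
    target_genes <- unlist(lapply(seq_len(cfg$n_regulator_mirnas),
      function(i) {
        members <- regmod_genes[(i - 1L) * mod_size + seq_len(mod_size)]
        sample(members, cfg$targets_per_regulator)
      }))
    target_of <- stats::setNames(
      rep(regulators, each = cfg$targets_per_regulator), target_genes)
  } else {
    gene_assign <- stats::setNames(
      gene_mod_names[1L + (seq_along(assigned_genes) - 1L) %%
                       cfg$n_gene_modules],
      assigned_genes)
    if (planted) {
      n_target <- cfg$n_regulator_mirnas * cfg$targets_per_regulator
      target_genes <- sample(assigned_genes, n_target)
      target_of <- stats::setNames(
        rep(regulators, each = cfg$targets_per_regulator), target_genes)
    } else {
      target_of <- stats::setNames(character(0), character(0))
    }
  }

  # --- latent sample factors ------------------------------------------
  u <- matrix(rnorm(cfg$n_regulator_mirnas * ns), ncol = ns,
              dimnames = list(regulators, samples))
  z <- matrix(rnorm(cfg$n_gene_modules * ns), ncol = ns,
              dimnames = list(gene_mod_names, samples))
  if (planted && cfg$regulation == "module") {
    # target-module latents couple to their regulator
    for (i in seq_len(cfg$n_regulator_mirnas)) {
      z[i, ] <- csign * c0 * u[i, ] + sqrt(1 - c0^2) * rnorm(ns)
    }
  }

  # --- gene signals on the log scale ----------------------------------
  gsig <- matrix(rnorm(cfg$n_genes * ns), ncol = ns,
                 dimnames = list(genes, samples))  # iid noise baseline
  for (g in assigned_genes) {
    k <- gene_assign[[g]]
    if (planted && cfg$regulation == "feature" && g %in% names(target_of)) {
      a <- SYN_TARGET_MODULE_LOADING
      b <- c0
      if (a^2 + b^2 > 1) a <- 0  # very strong coupling leaves no room
      res <- sqrt(max(0, 1 - a^2 - b^2))
      gsig[g, ] <- a * z[k, ] + b * csign * u[target_of[[g]], ] +
        res * rnorm(ns)
    } else {
      loading <- if (planted && cfg$regulation == "module" &&
                     g %in% names(target_of)) {
        SYN_MODULE_PRESET_LOADING
      } else {
        SYN_MODULE_LOADING
      }
      gsig[g, ] <- loading * z[k, ] + sqrt(1 - loading^2) * rnorm(ns)
    }
  }

  # --- miRNA module layout and signals --------------------------------
  other_mirnas <- setdiff(mirnas, regulators)
  n_mir_unassigned <- round(SYN_UNASSIGNED_FRACTION * length(other_mirnas))
  assigned_mirnas <- other_mirnas[seq_len(length(other_mirnas) -
                                            n_mir_unassigned)]
  mir_mod_names <- sprintf("MM%d", seq_len(cfg$n_mirna_modules))
  mirna_assign <- stats::setNames(
    mir_mod_names[1L + (seq_along(assigned_mirnas) - 1L) %%
                    cfg$n_mirna_modules],
    assigned_mirnas)
  w <- matrix(rnorm(cfg$n_mirna_modules * ns), ncol = ns,
              dimnames = list(mir_mod_names, samples))
  msig <- matrix(rnorm(cfg$n_mirnas * ns), ncol = ns,
                 dimnames = list(mirnas, samples))
  msig[regulators, ] <- u  # regulator profiles are their own latents
  for (m in assigned_mirnas) {
    msig[m, ] <- SYN_MODULE_LOADING * w[mirna_assign[[m]], ] +
      sqrt(1 - SYN_MODULE_LOADING^2) * rnorm(ns)
  }

  # --- exponentiate to count-like values ------------------------------
  to_counts <- function(sig) {
    mu <- rnorm(nrow(sig), mean = log(200), sd = 1)
    round(exp(mu + SYN_SIGMA * sig), 4L)
  }
  gene_expr <- expression_matrix(to_counts(gsig), kind = "gene",
                                 normalized = FALSE)
  mirna_expr <- expression_matrix(to_counts(msig), kind = "mirna",
                                  normalized = FALSE)

  # --- planted truth and database -------------------------------------
  if (planted) {
    planted_pairs <- data.frame(
      mirna_id = unname(target_of), gene_id = names(target_of),
      sign = csign, stringsAsFactors = FALSE)
    planted_pairs <- planted_pairs[order(planted_pairs$mirna_id,
                                         planted_pairs$gene_id), ]
    rownames(planted_pairs) <- NULL
  } else {
    planted_pairs <- data.frame(mirna_id = character(0),
                                gene_id = character(0), sign = numeric(0),
                                stringsAsFactors = FALSE)
  }
  n_truth <- round(cfg$db_truth_fraction * nrow(planted_pairs))
  truth_idx <- if (n_truth > 0) sort(sample.int(nrow(planted_pairs),
                                                n_truth)) else integer(0)
  db_mirna <- planted_pairs$mirna_id[truth_idx]
  db_gene <- planted_pairs$gene_id[truth_idx]
  planted_keys <- pair_key(planted_pairs$mirna_id, planted_pairs$gene_id)
  # decoys: uniform over the non-planted complement of the pair universe
  n_decoys <- 0L
  seen <- character(0)
  while (n_decoys < cfg$db_decoy_count) {
    need <- cfg$db_decoy_count - n_decoys
    idx <- sample.int(cfg$n_mirnas * cfg$n_genes, min(2L * need + 10L,
                      cfg$n_mirnas * cfg$n_genes))
    mi <- mirnas[1L + (idx - 1L) %/% cfg$n_genes]
    gi <- genes[1L + (idx - 1L) %% cfg$n_genes]
    keys <- pair_key(mi, gi)
    ok <- !(keys %in% planted_keys) & !(keys %in% seen) & !duplicated(keys)
    take <- which(ok)[seq_len(min(need, sum(ok)))]
    db_mirna <- c(db_mirna, mi[take])
    db_gene <- c(db_gene, gi[take])
    seen <- c(seen, keys[take])
    n_decoys <- n_decoys + length(take)
  }
  db <- mtp_database(db_mirna, db_gene)

  list(genes = gene_expr, mirnas = mirna_expr,
       gene_modules = gene_assign, mirna_modules = mirna_assign,
       dems = regulators,
       degs = sort(names(target_of)),
       db = db,
       truth = list(planted_pairs = planted_pairs,
                    regulators = regulators, config = cfg))
}

#' Generate a null dataset (no planted regulation)
#'
#' Forces `coupling = 0`: no planted pairs, database made of decoys only.
#' Used for type-I-error and p-value calibration checks.
#'
#' @inheritParams generate_dataset
#' @return As [generate_dataset()]; `truth$planted_pairs` has zero rows.
#' @export
null_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  config$coupling <- 0
  generate_dataset(config)
}

#' Write a synthetic dataset to TSV inputs
#'
#' Writes the pipeline's input files (`genes.tsv`, `mirnas.tsv`,
#' `gene_modules.tsv`, `mirna_modules.tsv`, `dems.txt`, `degs.txt`,
#' `mtp_db.tsv`) plus `truth.tsv` to a directory.
#'
#' @param dataset A [generate_dataset()] bundle.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the named vector of paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_expr <- function(em, path) {
    df <- data.frame(feature_id = rownames(em$values), em$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, path)
  }
  paths <- c(genes = file.path(out_dir, "genes.tsv"),
             mirnas = file.path(out_dir, "mirnas.tsv"),
             gene_modules = file.path(out_dir, "gene_modules.tsv"),
             mirna_modules = file.path(out_dir, "mirna_modules.tsv"),
             dems = file.path(out_dir, "dems.txt"),
             degs = file.path(out_dir, "degs.txt"),
             db = file.path(out_dir, "mtp_db.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_expr(dataset$genes, paths[["genes"]])
  write_expr(dataset$mirnas, paths[["mirnas"]])
  write_assign <- function(assign, path) {
    df <- data.frame(feature_id = names(assign), module_id = unname(assign),
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, fileEncoding = "UTF-8")
  }
  write_assign(dataset$gene_modules, paths[["gene_modules"]])
  write_assign(dataset$mirna_modules, paths[["mirna_modules"]])
  writeLines(dataset$dems, paths[["dems"]])
  writeLines(dataset$degs, paths[["degs"]])
  write.table(dataset$db, paths[["db"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  write_tsv(dataset$truth$planted_pairs, paths[["truth"]])
  invisible(paths)
}
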