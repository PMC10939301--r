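test_that("exactly seven strategies in canonical order, exclusions honored", {
  s <- enumerate_strategies()
  expect_identical(nrow(s), 7L)
  expect_identical(s$name, c("Cg_Cm", "Eg_Cm", "Hg_Cm", "Eg_Em", "Eg_Hm",
                             "Hg_Em", "Hg_Hm"))
  # miRNA-module x gene-CPM combinations are not part of the set
  expect_false(any(c("Cg_Em", "Cg_Hm") %in% s$name))
  expect_identical(s$gene_kind[s$name == "Eg_Cm"], "eigengene")
  expect_identical(s$mirna_kind[s$name == "Hg_Hm"], "hub")
})

test_that("threshold grids are the nine 0.05-spaced values per direction", {
  expect_equal(threshold_grid("lower"), seq(-0.90, -0.50, by = 0.05))
  expect_equal(threshold_grid("higher"), seq(0.50, 0.90, by = 0.05))
  expect_length(threshold_grid("lower"), 9L)
  expect_length(threshold_grid("higher"), 9L)
})

test_that("candidate pairs are the Cartesian product", {
  p <- candidate_pairs(paste0("m", 1:3), paste0("g", 1:100))
  expect_identical(nrow(p), 300L)
  expect_identical(nrow(candidate_pairs("m1", "g1")), 1L)
  expect_error(candidate_pairs(character(0), "g1"), "expressed")
  expect_error(candidate_pairs("m1", character(0)), "empty gene set")
})

test_that("pair correlations match the direct-formula oracle", {
  g <- make_expr(rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1),
                       g3 = c(2, 2, 2, 2)), "gene")
  m <- make_expr(rbind(m1 = c(1, 2, 3, 4), m2 = c(2, 1, 4, 3)), "mirna")
  greps <- build_representatives(g, character(0), "cpm_feature")
  mreps <- build_representatives(m, character(0), "cpm_feature")
  pairs <- candidate_pairs(c("m1", "m2"), c("g1", "g2", "g3"))
  ct <- pair_correlations(greps, mreps, pairs, "Cg_Cm")
  r_of <- function(mi, gi) ct$r[ct$mirna_id == mi & ct$gene_id == gi]
  expect_equal(r_of("m1", "g1"), 1)       # identical profiles
  expect_equal(r_of("m1", "g2"), -1)      # perfect anti-correlation
  expect_equal(r_of("m2", "g1"),
               pearson_oracle(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_true(is.na(r_of("m1", "g3")))    # zero-variance gene profile
})

test_that("missing representatives yield NA and sample mismatch errors", {
  g <- make_expr(rbind(g1 = c(1, 2, 3, 4), g2 = c(9, 7, 5, 1)), "gene")
  m <- make_expr(rbind(m1 = c(4, 3, 2, 1)), "mirna")
  # g2 unassigned: absent from the eigengene map
  greps <- build_representatives(g, c(g1 = "M1", g2 = "0"), "eigengene")
  mreps <- build_representatives(m, character(0), "cpm_feature")
  pairs <- candidate_pairs("m1", c("g1", "g2"))
  ct <- pair_correlations(greps, mreps, pairs, "Eg_Cm")
  expect_false(is.na(ct$r[ct$gene_id == "g1"]))
  expect_true(is.na(ct$r[ct$gene_id == "g2"]))

  m2 <- m
  colnames(m2$values) <- c("S2", "S1", "S3", "S4")
  mreps2 <- build_representatives(m2, character(0), "cpm_feature")
  expect_error(pair_correlations(greps, mreps2, pairs, "Eg_Cm"),
               "same samples")
})

test_that("correlations are invariant to a shared sample permutation", {
  set.seed(13)
  gv <- matrix(rexp(5 * 8, 0.01), nrow = 5)
  mv <- matrix(rexp(2 * 8, 0.01), nrow = 2)
  perm <- sample(8)
  mk <- function(v, kind) make_expr(v, kind)
  pairs <- candidate_pairs(c("m1", "m2"), paste0("g", 1:5))
  ct1 <- pair_correlations(
    build_representatives(mk(gv, "gene"), character(0), "cpm_feature"),
    build_representatives(mk(mv, "mirna"), character(0), "cpm_feature"),
    pairs, "Cg_Cm")
  gp <- gv[, perm]; colnames(gp) <- paste0("S", 1:8)
  mp <- mv[, perm]; colnames(mp) <- paste0("S", 1:8)
  ct2 <- pair_correlations(
    build_representatives(mk(gp, "gene"), character(0), "cpm_feature"),
    build_representatives(mk(mp, "mirna"), character(0), "cpm_feature"),
    pairs, "Cg_Cm")
  expect_equal(ct1$r, ct2$r, tolerance = 1e-12)
})

test_that("detection uses strict inequalities and nests across the grid", {
  ct <- data.frame(mirna_id = "m1", gene_id = paste0("g", 1:4),
                   strategy = "Cg_Cm",
                   r = c(-0.95, -0.85, -0.90, NA),
                   stringsAsFactors = FALSE)
  det <- detect_mtps(ct, -0.90, "lower")
  expect_identical(det$pairs$gene_id, "g1")  # boundary -0.90 excluded, NA never
  det2 <- detect_mtps(ct, -0.85, "lower")
  expect_setequal(det2$pairs$gene_id, c("g1", "g3"))
  expect_true(all(det$pairs$gene_id %in% det2$pairs$gene_id))

  ct_hi <- data.frame(mirna_id = "m1", gene_id = "g1", strategy = "Cg_Cm",
                      r = 0.95, stringsAsFactors = FALSE)
  expect_identical(nrow(detect_mtps(ct_hi, 0.90, "higher")$pairs), 1L)
  expect_error(detect_mtps(ct, -0.4, "lower"), "grid")

  # nesting property on random correlations, both directions
  set.seed(31)
  big <- data.frame(mirna_id = "m1", gene_id = paste0("g", 1:500),
                    strategy = "Cg_Cm", r = runif(500, -1, 1),
                    stringsAsFactors = FALSE)
  for (dir in c("lower", "higher")) {
    grid <- threshold_grid(dir)
    strict_first <- if (dir == "lower") grid else rev(grid)
    prev <- NULL
    for (th in strict_first) {
      cur <- detect_mtps(big, th, dir)$pairs$gene_id
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("singleton gene modules make Eg_Cm equal Cg_Cm", {
  set.seed(23)
  gv <- matrix(rexp(6 * 10, 0.01), nrow = 6)
  g <- make_expr(gv, "gene")
  m <- make_expr(matrix(rexp(2 * 10, 0.01), nrow = 2), "mirna")
  singleton <- stats::setNames(paste0("M", 1:6), paste0("g", 1:6))
  pairs <- candidate_pairs(c("m1", "m2"), paste0("g", 1:6))
  mreps <- build_representatives(m, character(0), "cpm_feature")
  r_cg <- pair_correlations(
    build_representatives(g, character(0), "cpm_feature"), mreps,
    pairs, "Cg_Cm")$r
  r_eg <- pair_correlations(
    build_representatives(g, singleton, "eigengene"), mreps,
    pairs, "Eg_Cm")$r
  # eigengene of a singleton is the z-scored profile: same correlation,
  # same sign under the orientation convention
  expect_equal(r_cg, r_eg, tolerance = 1e-10)
})
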