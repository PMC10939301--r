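test_that("contingency tables count the four pair classes", {
  u <- pair_universe(paste0("m", 1:10), paste0("g", 1:100))
  expect_identical(u$size, 1000L)
  # 20 detections, 15 database pairs in universe, overlap 5
  det <- data.frame(
    mirna_id = rep("m1", 20),
    gene_id = paste0("g", 1:20), stringsAsFactors = FALSE)
  db <- mtp_database(rep(c("m1", "m2"), c(5, 10)),
                     paste0("g", c(1:5, 21:30)))
  t <- build_contingency(det, db, u)
  expect_identical(as.integer(c(t$a, t$b, t$S_d, t$R)),
                   c(5L, 15L, 10L, 970L))

  t0 <- build_contingency(det[0, ], db, u)
  expect_identical(as.integer(c(t0$a, t0$b, t0$S_d, t0$R)),
                   c(0L, 0L, 15L, 985L))

  db_out <- mtp_database("mX", "gX")  # disjoint from universe
  t1 <- build_contingency(det, db_out, u)
  expect_identical(as.integer(c(t1$a, t1$b, t1$S_d, t1$R)),
                   c(0L, 20L, 0L, 980L))

  bad <- data.frame(mirna_id = "mX", gene_id = "g1",
                    stringsAsFactors = FALSE)
  expect_error(build_contingency(bad, db, u), "outside the universe")
})

test_that("odds ratio is the cross-product with Haldane correction", {
  expect_equal(odds_ratio(ct(5, 15, 10, 970), zero_correction = FALSE),
               (5 * 970) / (15 * 10))  # 32.333...
  expect_equal(odds_ratio(ct(5, 15, 10, 970)), 4850 / 150)
  expect_equal(odds_ratio(ct(10, 90, 90, 810)), 1.0)  # independence
  expect_equal(odds_ratio(ct(5, 0, 10, 100)),
               (5.5 * 100.5) / (0.5 * 10.5))  # 105.2857...
  expect_true(is.na(odds_ratio(ct(0, 0, 0, 0))))
  # universe without database pairs: over-representation undefined
  expect_true(is.na(odds_ratio(ct(0, 10, 0, 90))))
  expect_identical(odds_ratio(ct(5, 0, 10, 100), zero_correction = FALSE),
                   Inf)
})

test_that("a transposed table changes the benchmark metrics (transposition guard)", {
  # both the cross-product odds ratio and the hypergeometric tail are
  # algebraically symmetric under swapping b and S_d (the hypergeometric
  # is symmetric in draws and successes), so neither can catch a
  # transposed table; precision and recall, which assign the two margins
  # different roles, must differ on an asymmetric table
  asym <- ct(4, 2, 8, 100)
  swapped <- ct(4, 8, 2, 100)
  expect_equal(odds_ratio(asym), odds_ratio(swapped))
  expect_equal(fisher_exact_greater(asym), fisher_exact_greater(swapped))
  m1 <- benchmark_metrics(asym)
  m2 <- benchmark_metrics(swapped)
  expect_false(isTRUE(all.equal(m1[["precision"]], m2[["precision"]])))
  expect_equal(m1[["precision"]], m2[["recall"]])  # roles swap exactly
})

test_that("one-sided exact test matches enumeration on worked examples", {
  expect_equal(fisher_exact_greater(ct(3, 1, 1, 3)), 34 / 140,
               tolerance = 1e-12)
  expect_equal(fisher_exact_greater(ct(0, 5, 7, 20)), 1.0)  # P(X >= 0)
  expect_equal(fisher_exact_greater(ct(1, 0, 0, 1)), 0.5)
  expect_true(is.na(fisher_exact_greater(ct(0, 0, 0, 0))))
  # random tables against both the enumeration oracle and fisher.test
  set.seed(77)
  for (i in 1:30) {
    cnt <- as.integer(rmultinom(1, size = sample(4:40, 1), prob = rep(1, 4)))
    tt <- ct(cnt[1], cnt[2], cnt[3], cnt[4])
    p <- fisher_exact_greater(tt)
    expect_equal(p, fisher_oracle(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-10)
    m <- matrix(c(cnt[1], cnt[3], cnt[2], cnt[4]), 2)
    expect_equal(p, stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-8)
  }
})

test_that("benchmark metrics follow their definitions", {
  m <- benchmark_metrics(ct(5, 15, 10, 970))
  expect_equal(unname(m), c(0.25, 1 / 3, 970 / 985, 975 / 1000))
  perfect <- benchmark_metrics(ct(7, 0, 0, 93))
  expect_equal(unname(perfect[c("precision", "recall")]), c(1, 1))
  empty <- benchmark_metrics(ct(0, 0, 10, 90))
  expect_true(is.na(empty[["precision"]]))
  expect_equal(empty[["recall"]], 0)
})

test_that("overall evaluation covers the 7 x 9 grid and handles no detections", {
  set.seed(3)
  ds <- generate_dataset(synthetic_config(n_samples = 8, n_genes = 60,
                                          n_mirnas = 12, n_gene_modules = 2,
                                          n_mirna_modules = 2,
                                          n_regulator_mirnas = 2,
                                          targets_per_regulator = 4,
                                          db_decoy_count = 40, seed = 4))
  res <- analyze_dataset(ds)
  expect_identical(nrow(res$overall_eval), 63L)
  expect_setequal(unique(res$overall_eval$strategy),
                  enumerate_strategies()$name)
  # regulators are unassigned in the miRNA module table, so Em/Hm
  # strategies have no detections for DEM pairs: degenerate tables give
  # a = 0 and p = 1, never a significant OR
  em_rows <- res$specific_eval[res$specific_eval$strategy == "Eg_Em", ]
  expect_true(all(em_rows$a == 0))
})

test_that("specific tables partition the overall table", {
  set.seed(8)
  ds <- generate_dataset(synthetic_config(n_samples = 8, n_genes = 60,
                                          n_mirnas = 10, n_gene_modules = 2,
                                          n_mirna_modules = 2,
                                          n_regulator_mirnas = 2,
                                          targets_per_regulator = 4,
                                          db_decoy_count = 40, seed = 8))
  # candidate miRNA set = all expressed, so specific universes partition
  # the overall universe
  res <- analyze_dataset(ds, mirna_set = "expressed")
  for (s in c("Cg_Cm", "Eg_Cm")) {
    for (th in c(-0.9, -0.6)) {
      ov <- res$overall_eval
      sp <- res$specific_eval
      a_overall <- ov$a[ov$strategy == s & abs(ov$threshold - th) < 1e-9]
      a_specific <- sum(sp$a[sp$strategy == s &
                               abs(sp$threshold - th) < 1e-9])
      expect_identical(a_specific, a_overall)
    }
  }
})

test_that("a miRNA absent from the database has undefined specific ORs", {
  g <- make_expr(rbind(g1 = c(1, 5, 2, 8), g2 = c(8, 2, 5, 1)), "gene")
  m <- make_expr(rbind(m1 = c(8, 4, 7, 1)), "mirna")
  pairs <- candidate_pairs("m1", c("g1", "g2"))
  ctab <- pair_correlations(
    build_representatives(g, character(0), "cpm_feature"),
    build_representatives(m, character(0), "cpm_feature"), pairs, "Cg_Cm")
  db <- mtp_database("mOther", "g1")
  sp <- evaluate_specific(list(Cg_Cm = ctab), db, c("g1", "g2"))
  expect_true(all(is.na(sp$odds_ratio)))
})
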