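test_that("housekeeping normalization matches the closed form and filters", {
  cm <- count_matrix(rbind(HK1 = c(100, 400), G1 = c(50, 60)),
                     c("A", "B"), "HK1")
  nn <- normalize_counts(cm, min_avg_count = 100)
  expect_equal(nn$report$scale_factors$scale_factor, c(2, 0.5))
  # already-equal geometric means: identity
  cm2 <- count_matrix(rbind(HK1 = c(500, 500), G1 = c(5, 9)),
                      c("A", "B"), "HK1")
  expect_equal(normalize_counts(cm2)$report$scale_factors$scale_factor,
               c(1, 1))
  # a low-abundance reference gene is excluded by the >450 filter
  cm3 <- count_matrix(rbind(HK1 = c(800, 900), HK2 = c(280, 320),
                            G1 = c(5, 9)),
                      c("A", "B"), c("HK1", "HK2"))
  expect_equal(normalize_counts(cm3)$report$retained_housekeeping, "HK1")
  expect_error(normalize_counts(count_matrix(rbind(HK1 = c(10, 20),
                                                   G1 = c(1, 2)),
                                             c("A", "B"), "HK1")),
               "average count")
})

test_that("normalization equalizes housekeeping geomeans and is idempotent", {
  g <- gen_count_matrix(n_genes = 100, n_hk = 10, n_per_group = 3, seed = 20)
  nn <- normalize_counts(g$cm)
  hk <- nn$report$retained_housekeeping
  gm <- apply(nn$counts$counts[hk, ], 2, function(v) exp(mean(log(v))))
  expect_lt(diff(range(gm)) / mean(gm), 1e-9)
  nn2 <- normalize_counts(nn$counts)
  expect_equal(nn2$counts$counts, nn$counts$counts, tolerance = 1e-12)
})

test_that("DE calls follow the p-value and fold-change gates", {
  set.seed(21)
  base <- matrix(2^rnorm(40 * 8, 8, 0.1), 40, 8)
  rownames(base) <- paste0("g", 1:40)
  # plant a clear up gene and a clear down gene
  base[1, 5:8] <- base[1, 5:8] * 2
  base[2, 5:8] <- base[2, 5:8] * 0.4
  # significant but small fold change -> ns
  base[3, 5:8] <- base[3, 5:8] * 1.2
  cm <- count_matrix(base, rep(c("A", "B"), each = 4), character())
  de <- select_de(cm)
  expect_equal(de$call[1], "up")
  expect_equal(de$call[2], "down")
  expect_lt(de$p_value[3], 0.05)
  expect_equal(de$call[3], "ns")
  # identical groups: FC = 1 and ns everywhere, p = 1 for constants
  cst <- count_matrix(matrix(5, 3, 4, dimnames = list(paste0("g", 1:3))),
                      rep(c("A", "B"), each = 2), character())
  dc <- select_de(cst)
  expect_true(all(dc$fold_change == 1))
  expect_true(all(dc$p_value == 1))
  expect_true(all(dc$call == "ns"))
  expect_error(select_de(count_matrix(matrix(1, 2, 2),
                                      c("A", "B"), character())),
               ">= 2 samples")
})

test_that("swapping the groups mirrors up and down calls with reciprocal FC", {
  g <- gen_count_matrix(n_genes = 150, n_hk = 5, n_per_group = 4,
                        de_fraction = 0.1, fc = 2.5, seed = 22)
  cm <- normalize_counts(g$cm)$counts
  de_ab <- select_de(cm)
  swapped <- count_matrix(cm$counts, factor(cm$groups,
                                            levels = rev(levels(cm$groups))),
                          cm$housekeeping_ids)
  de_ba <- select_de(swapped)
  expect_setequal(de_ab$gene_id[de_ab$call == "up"],
                  de_ba$gene_id[de_ba$call == "down"])
  expect_equal(de_ab$fold_change, 1 / de_ba$fold_change, tolerance = 1e-12)
})

test_that("per-gene p-values match stats::t.test", {
  set.seed(23)
  a <- matrix(rnorm(20 * 3, 8), 20)
  b <- matrix(rnorm(20 * 4, 8.3), 20, 4)
  wt <- organoidquant:::welch_t_rows(a, b, var_equal = TRUE)
  ref <- vapply(1:20, function(i)
    t.test(b[i, ], a[i, ], var.equal = TRUE)$p.value, numeric(1))
  expect_equal(wt$p_value, ref, tolerance = 1e-12)
  wtw <- organoidquant:::welch_t_rows(a, b, var_equal = FALSE)
  refw <- vapply(1:20, function(i)
    t.test(b[i, ], a[i, ])$p.value, numeric(1))
  expect_equal(wtw$p_value, refw, tolerance = 1e-12)
})

test_that("average-linkage clustering matches the brute-force oracle", {
  # identical profiles merge first at distance 0
  m <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 1, 0, 2))
  cl <- cluster_profiles(m)
  expect_equal(cl$merge_heights[1], 0, tolerance = 1e-12)
  # perfectly anti-correlated profiles sit at distance 2
  anti <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(cluster_profiles(anti)$merge_heights, 2, tolerance = 1e-12)
  expect_error(cluster_profiles(rbind(c(1, 1, 1), c(1, 2, 3))),
               "zero-variance")
  # random matrices up to 8 leaves against the O(n^3) reference
  set.seed(24)
  for (n in c(3, 5, 8)) {
    for (rep in 1:5) {
      m <- matrix(rnorm(n * 6), n, 6)
      cl <- cluster_profiles(m)
      expect_equal(sort(cl$merge_heights),
                   sort(oracle_average_linkage(1 - cor(t(m)))),
                   tolerance = 1e-9)
    }
  }
})

test_that("relative expression follows 2^-dCt and its scaling laws", {
  ct <- tibble::tibble(sample_label = "s1",
                       gene_id = c("ATP5O", "G"),
                       ct_value = c(20, 25))
  re <- relative_expression(ct)
  expect_equal(re$rel_expr, 2^-5)
  # equal Ct of the two isoforms -> ratio exactly 1
  ct2 <- tibble::tibble(sample_label = "s1",
                        gene_id = c("ATP5O", "MAPT-4R", "MAPT-3R"),
                        ct_value = c(20, 24, 24))
  re2 <- relative_expression(ct2, ratios = list("4R/3R" = c("MAPT-4R",
                                                            "MAPT-3R")))
  expect_equal(re2$rel_expr[re2$gene_id == "4R/3R"], 1)
  # a -1 cycle shift across all genes doubles every relative expression
  ct3 <- ct; ct3$ct_value[2] <- 24
  expect_equal(relative_expression(ct3)$rel_expr, 2 * re$rel_expr)
  expect_error(relative_expression(tibble::tibble(sample_label = "s1",
                                                  gene_id = "G",
                                                  ct_value = 25)),
               "missing")
})

test_that("control QC reports linearity and background without gating", {
  set.seed(25)
  conc <- c(128, 32, 8, 2, 0.5, 0.125)
  pos <- sapply(1:3, function(s) conc * 20 * runif(1, 0.9, 1.1))
  neg <- matrix(rpois(24, 4), 8, 3)
  qc <- qc_controls(pos, neg, conc)
  expect_true(all(qc$pos_r_squared > 0.99))
  expect_true(all(qc$neg_background > 0))
})
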