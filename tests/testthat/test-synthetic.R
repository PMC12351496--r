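test_that("generators are pure functions of parameters and seed", {
  a <- gen_tube_phantom(3, snr = 10, seed = 30)
  b <- gen_tube_phantom(3, snr = 10, seed = 30)
  expect_identical(unclass(a$stack), unclass(b$stack))
  expect_identical(a$truth$fragments, b$truth$fragments)
  c1 <- gen_calcium_movie(n_cells = 4, duration_s = 60,
                          image_shape = c(48L, 48L), seed = 31)
  c2 <- gen_calcium_movie(n_cells = 4, duration_s = 60,
                          image_shape = c(48L, 48L), seed = 31)
  expect_identical(unclass(c1$movie), unclass(c2$movie))
  d1 <- gen_count_matrix(n_genes = 30, n_hk = 4, seed = 32)
  d2 <- gen_count_matrix(n_genes = 30, n_hk = 4, seed = 32)
  expect_identical(d1$cm$counts, d2$cm$counts)
  tre <- tibble::tibble(sample_label = "s", gene_id = "G", rel_expr = 0.5)
  expect_identical(gen_ct_table(tre, ct_noise_sd = 0.2, seed = 33)$ct,
                   gen_ct_table(tre, ct_noise_sd = 0.2, seed = 33)$ct)
  # the caller's RNG stream is not disturbed
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_puncta_image(5, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("truth records describe the noise-free phantoms exactly", {
  g <- gen_puncta_image(n_objects = 10, snr = Inf, seed = 34)
  expect_equal(g$truth$coverage, mean(g$truth$mask))
  expect_equal(g$truth$n_objects, 10)
  gt <- gen_tube_phantom(2, snr = Inf, seed = 35)
  expect_equal(nrow(gt$truth$fragments), 2)
  expect_true(all(gt$truth$fragments$length_um >= 3 - 1e-9 &
                    gt$truth$fragments$length_um <= 8 + 1e-9))
  gc <- gen_coloc_pair(overlap_fraction = 0.3, seed = 36)
  expect_equal(gc$truth$overlap_fraction,
               sum(gc$truth$mask_a & gc$truth$mask_b) / sum(gc$truth$mask_a))
  expect_gt(gc$truth$overlap_fraction, 0.25)
  gm <- gen_calcium_movie(n_cells = 4, duration_s = 60,
                          image_shape = c(48L, 48L), seed = 37)
  expect_true(all(gm$truth$events$time_s >= 0 &
                    gm$truth$events$time_s <= 60))
  expect_true(all(gm$truth$events$amplitude > 0))
  gcm <- gen_count_matrix(n_genes = 50, n_hk = 6, de_fraction = 0.2,
                          seed = 38)
  expect_false(any(gcm$truth$de$gene_id %in% gcm$truth$housekeeping_ids))
})

test_that("degenerate generator settings behave as documented", {
  expect_error(gen_puncta_image(coverage_target = 0.6), "0.5")
  g0 <- gen_tube_phantom(0, seed = 39)
  expect_equal(g0$truth$n_fragments, 0)
  res <- suppressWarnings(analyze_neurites3d(
    g0$stack, tube_enhance_params(gaussian_sigma_px = 1,
                                  frangi_scale_px = 2)))
  expect_equal(res$n_fragments, 0)
  # zero event rate: nothing to detect
  gz <- gen_calcium_movie(n_cells = 4, rate_per_min = 0, duration_s = 60,
                          image_shape = c(48L, 48L), snr = 20, seed = 40)
  expect_equal(nrow(gz$truth$events), 0)
  res <- analyze_calcium(gz$movie)
  expect_equal(nrow(res$events), 0)
})

test_that("library-size-free count phantoms normalize to the identity", {
  g <- gen_count_matrix(n_genes = 40, n_hk = 6, lib_sd = 0, seed = 41)
  # library factors all 1 still leaves sampling noise in the HK geomeans,
  # so build the exact-identity case directly
  m <- matrix(rep(c(600, 700, 800), each = 4), 3, 4, byrow = TRUE)
  rownames(m) <- c("HK1", "HK2", "G1")
  cm <- count_matrix(m, rep(c("A", "B"), 2), c("HK1", "HK2"))
  nn <- normalize_counts(cm)
  expect_equal(nn$counts$counts, cm$counts, tolerance = 1e-12)
  expect_true(all(g$truth$library_factors == 1))
})

test_that("Ct table generation inverts through relative_expression", {
  tre <- tibble::tibble(sample_label = rep(c("s1", "s2"), each = 2),
                        gene_id = rep(c("MAPT-4R", "MAPT-3R"), 2),
                        rel_expr = c(0.5, 0.25, 0.8, 0.4))
  g <- gen_ct_table(tre, ct_noise_sd = 0, seed = 42)
  re <- relative_expression(g$ct,
                            ratios = list("4R/3R" = c("MAPT-4R", "MAPT-3R")))
  got <- re[re$gene_id %in% c("MAPT-4R", "MAPT-3R"), ]
  merged <- dplyr::inner_join(got, tre, by = c("sample_label", "gene_id"))
  expect_equal(merged$rel_expr.x, merged$rel_expr.y, tolerance = 1e-12)
  expect_equal(re$rel_expr[re$gene_id == "4R/3R"], c(2, 2),
               tolerance = 1e-12)
})

test_that("truth JSON is versioned, validated, and round-trips", {
  dir <- withr::local_tempdir()
  g <- gen_tube_phantom(2, snr = 10, seed = 43)
  f <- file.path(dir, "truth.json")
  write_truth(g$truth, f)
  back <- read_truth(f)
  expect_equal(back$schema_version, 1L)
  expect_equal(back$n_fragments, 2)
  expect_equal(back$fragments$length_um, g$truth$fragments$length_um,
               tolerance = 1e-12)
  bad <- g$truth; bad$fragments <- NULL
  expect_error(write_truth(bad, f), "missing field")
  jsonlite::write_json(list(a = 1), f)
  expect_error(read_truth(f), "versioned")
})
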