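test_that("zproject_mean averages the centred planes", {
  arr <- array(0, c(3, 4, 4))
  arr[1, , ] <- 1; arr[2, , ] <- 2; arr[3, , ] <- 3
  st <- image_stack3d(arr / 3)
  expect_equal(unique(as.numeric(zproject_mean(st, 3))), 2 / 3)
  # n = Z = 1 is the identity
  st1 <- image_stack3d(array(runif(16), c(1, 4, 4)))
  expect_equal(as.numeric(zproject_mean(st1, 1)), as.numeric(unclass(st1)[1, , ]))
  expect_error(zproject_mean(st, 0), ">= 1")
  expect_error(zproject_mean(st, 5), "exceeds")
  # random 20-plane stack equals the brute-force per-pixel mean
  set.seed(2)
  arr <- array(runif(24 * 6 * 6), c(24, 6, 6))
  st <- image_stack3d(arr)
  expect_equal(as.numeric(zproject_mean(st, 20)),
               as.numeric(oracle_zproject(arr, 3:22)))
})

test_that("median filter matches the brute-force sliding-window median", {
  set.seed(3)
  for (img in list(matrix(rep(c(0, 1), 18), 6, 6),          # checkerboard
                   matrix(runif(15 * 11), 15, 11))) {
    expect_equal(organoidquant:::median_filter2d(img, 5L),
                 oracle_median2d(img, 5L))
  }
})

test_that("H-minima suppresses only minima shallower than H", {
  x <- matrix(0.5, 21, 21)
  x[5, 5] <- 0.48       # depth 0.02 < H
  x[15, 15] <- 0.40     # depth 0.10 > H
  hm <- hminima(x, 0.05)
  expect_equal(hm[5, 5], 0.5)                 # shallow minimum removed
  expect_equal(hm[15, 15], 0.45)              # deep minimum survives (depth reduced by H)
  expect_true(all(hm >= x - 1e-12))
  # constant image is returned unchanged
  expect_equal(hminima(matrix(0.3, 5, 5), 0.05), matrix(0.3, 5, 5))
})

test_that("preprocess2d applies the chain deterministically and stays in [0,1]", {
  # constant image: background equals the constant, subtraction floors at 0
  const <- image2d(matrix(0.4, 64, 64))
  out <- preprocess2d(const)
  expect_true(all(out == 0))
  set.seed(4)
  img <- image2d(matrix(runif(128 * 128), 128, 128))
  o1 <- preprocess2d(img)
  o2 <- preprocess2d(img)
  expect_identical(unclass(o1), unclass(o2))
  expect_gte(min(o1), 0)
  expect_lte(max(o1), 1)
  expect_error(preprocess2d(image2d(matrix(2, 4, 4) / 1.5)), "normalized")
  expect_error(preprocess2d_params(median_size_px = 4), "odd")
  expect_error(preprocess2d_params(hminima_depth = 1.5), "0, 1")
})

test_that("Otsu matches exhaustive between-class-variance search", {
  # half zeros, half ones: threshold strictly inside (0, 1), 8 foreground
  img <- matrix(c(rep(0, 8), rep(1, 8)), 4, 4)
  m <- binarize_otsu(img)
  thr <- attr(m, "threshold")
  expect_true(thr > 0 && thr < 1)
  expect_equal(sum(m), 8)
  # constant image: empty foreground plus warning, never an error
  expect_warning(mc <- binarize_otsu(matrix(0.5, 4, 4)), "constant")
  expect_equal(sum(mc), 0)
  # bimodal mixture: >= 99% of the high-mode pixels end up foreground
  set.seed(5)
  lab <- rbinom(4096, 1, 0.5)
  v <- ifelse(lab == 1, rnorm(4096, 0.8, 0.05), rnorm(4096, 0.2, 0.05))
  v <- pmin(pmax(v, 0), 1)
  mm <- binarize_otsu(matrix(v, 64, 64))
  expect_gte(mean(mm[lab == 1]), 0.99)
  # exhaustive-search equivalence on random images
  set.seed(6)
  for (i in 1:25) {
    v <- matrix(runif(256), 16, 16)
    expect_equal(otsu_threshold(v), oracle_otsu(v))
  }
})

test_that("coverage and colocalization metrics satisfy their identities", {
  ones <- matrix(1, 10, 10)
  res <- coverage(ones == 1, ones)
  expect_equal(res$area_fraction, 1)
  expect_equal(res$integrated_density, 100)
  empty <- coverage(ones == 0, ones)
  expect_equal(c(empty$area_fraction, empty$integrated_density), c(0, 0))
  expect_error(coverage(matrix(TRUE, 2, 2), ones), "shapes differ")
  # colocalization: identical masks reproduce the mask's own coverage;
  # disjoint masks give zero; area metrics are symmetric
  set.seed(7)
  a <- matrix(runif(100) > 0.7, 10, 10)
  b <- matrix(runif(100) > 0.6, 10, 10)
  img <- matrix(runif(100), 10, 10)
  expect_equal(colocalize(a, a, img), coverage(a, img))
  expect_equal(colocalize(a, !a, img)$area_fraction, 0)
  expect_equal(colocalize(a, b, img)$area_fraction,
               colocalize(b, a, img)$area_fraction)
})

test_that("area metrics are monotone under mask growth", {
  set.seed(8)
  img <- matrix(runif(400), 20, 20)
  small <- matrix(runif(400) > 0.8, 20, 20)
  big <- small | matrix(runif(400) > 0.8, 20, 20)
  expect_gte(coverage(big, img)$area_fraction,
             coverage(small, img)$area_fraction)
  expect_gte(coverage(big, img)$integrated_density,
             coverage(small, img)$integrated_density)
})

test_that("objects_in_path counts and measures objects inside the region", {
  m <- matrix(FALSE, 30, 30)
  m[5, 3:12] <- TRUE          # 10-px bar
  m[20, 10:19] <- TRUE        # second 10-px bar
  path <- matrix(TRUE, 30, 30)
  st <- objects_in_path(m, path, pixel_size_um = 0.1)
  expect_equal(st$n_objects, 2)
  expect_equal(st$objects$length_um, c(1, 1), tolerance = 1e-9)
  # single-pixel object has the 1-px minimum length
  m1 <- matrix(FALSE, 10, 10); m1[5, 5] <- TRUE
  st1 <- objects_in_path(m1, matrix(TRUE, 10, 10), 0.065)
  expect_equal(st1$objects$length_um, 0.065)
  # restriction to the path mask
  path2 <- matrix(FALSE, 30, 30); path2[1:10, ] <- TRUE
  expect_equal(objects_in_path(m, path2, 0.1)$n_objects, 1)
  expect_error(objects_in_path(m, matrix(FALSE, 30, 30), 0.1), "empty")
  expect_warning(st0 <- objects_in_path(matrix(FALSE, 5, 5),
                                        matrix(TRUE, 5, 5), 0.1),
                 "no objects")
  expect_equal(st0$mean_length_um, 0)
})

test_that("planted bar phantoms are counted and measured through thresholding", {
  g <- gen_puncta_image(n_objects = 12, shape = "bar",
                        bar_length_px_range = c(18, 25), snr = 20, seed = 6)
  mask <- binarize_otsu(g$image)
  st <- objects_in_path(mask, matrix(TRUE, nrow(mask), ncol(mask)), 0.065)
  expect_equal(st$n_objects, 12)
  expect_lt(abs(st$mean_length_um / mean(g$truth$lengths_um) - 1), 0.1)
})
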