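# small cylinder/sphere phantoms for the enhancement stage
make_cylinder <- function(d = c(24, 40, 40), radius = 3, axis_z = 12) {
  arr <- array(0, d)
  for (x in 4:(d[3] - 3))
    for (y in 1:d[2])
      for (z in 1:d[1]) {
        if ((y - 20)^2 + (z - axis_z)^2 <= radius^2) arr[z, y, x] <- 1
      }
  arr
}

make_sphere <- function(d = c(24, 40, 40), radius = 6) {
  arr <- array(0, d)
  ctr <- c(12, 20, 20)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3])
    if (sum((c(z, y, x) - ctr)^2) <= radius^2) arr[z, y, x] <- 1
  arr
}

test_that("vesselness enhances tubes and suppresses blobs", {
  p <- tube_enhance_params(gaussian_sigma_px = 1, frangi_scale_px = 3,
                           background_ball_radius_px = 12)
  cyl <- image_stack3d(0.8 * make_cylinder())
  v <- enhance_tubes(cyl, p)
  on_axis <- unclass(v)[12, 20, 10:30]
  off <- unclass(v)[4, 5, 10:30]
  expect_gte(median(on_axis), 10 * max(median(off), 1e-6))
  # sphere: axis response not elevated over background by more than 2x
  sph <- image_stack3d(0.8 * make_sphere())
  vs <- enhance_tubes(sph, p)
  centre <- unclass(vs)[12, 20, 20]
  tube_ref <- median(on_axis)
  expect_lt(centre, 0.5 * tube_ref)
  # constant stack -> all-zero response
  const <- image_stack3d(array(0.3, c(8, 10, 10)))
  expect_true(all(unclass(enhance_tubes(const, p)) == 0))
  # Z < 3 is rejected (Hessian undefined)
  expect_error(enhance_tubes(image_stack3d(array(0.1, c(2, 10, 10))), p),
               "Z >= 3")
})

test_that("thinning yields one-voxel curves and preserves homotopy", {
  bar <- array(FALSE, c(5, 7, 44)); bar[2:4, 3:5, 3:42] <- TRUE
  skel <- organoidquant:::cpp_thin3d(as.logical(bar), dim(bar))
  dim(skel) <- dim(bar)
  lab <- organoidquant:::label_components(skel, 26L)
  expect_equal(attr(lab, "n_labels"), 1L)
  # no 2x2x2 solid block survives (one voxel wide)
  solid <- FALSE
  for (z in 1:4) for (y in 1:6) for (x in 1:43)
    if (all(skel[z:(z + 1), y:(y + 1), x:(x + 1)])) solid <- TRUE
  expect_false(solid)
  # two disjoint bars -> two skeleton components
  two <- array(FALSE, c(5, 16, 30))
  two[2:4, 2:4, 3:27] <- TRUE
  two[2:4, 12:14, 3:27] <- TRUE
  sk2 <- organoidquant:::cpp_thin3d(as.logical(two), dim(two))
  dim(sk2) <- dim(two)
  expect_equal(attr(organoidquant:::label_components(sk2, 26L), "n_labels"), 2L)
  # random blobs: component count unchanged by thinning
  set.seed(9)
  rnd <- organoidquant:::gaussian_smooth(array(runif(20 * 30 * 30), c(20, 30, 30)), 2) > 0.52
  before <- attr(organoidquant:::label_components(rnd, 26L), "n_labels")
  skr <- organoidquant:::cpp_thin3d(as.logical(rnd), dim(rnd))
  dim(skr) <- dim(rnd)
  after <- attr(organoidquant:::label_components(skr, 26L), "n_labels")
  expect_equal(after, before)
  expect_true(all(rnd[skr]))  # skeleton contained in the mask
})

test_that("fragment lengths follow the anisotropic step-sum closed form", {
  p <- array(FALSE, c(3, 3, 52)); p[2, 2, 2:51] <- TRUE
  st <- fragment_stats(p, c(0.2, 0.133, 0.133))
  expect_equal(st$n_fragments, 1)
  expect_equal(st$fragments$length_um, 49 * 0.133, tolerance = 1e-9)
  expect_equal(st$volume_um3, prod(dim(p)) * prod(c(0.2, 0.133, 0.133)))
  # deleting one voxel splits the path and removes two incident steps
  p2 <- p; p2[2, 2, 26] <- FALSE
  st2 <- fragment_stats(p2, c(0.2, 0.133, 0.133))
  expect_equal(st2$n_fragments, 2)
  expect_equal(sum(st2$fragments$length_um),
               st$fragments$length_um - 2 * 0.133, tolerance = 1e-9)
  # empty skeleton: zero fragments, zero mean, warning flag
  expect_warning(st0 <- fragment_stats(array(FALSE, c(3, 3, 3)),
                                       c(0.2, 0.1, 0.1)))
  expect_equal(st0$n_fragments, 0)
  expect_equal(st0$mean_length_um, 0)
  # z-step weighting: a pure z path uses dz
  pz <- array(FALSE, c(12, 3, 3)); pz[2:11, 2, 2] <- TRUE
  expect_equal(fragment_stats(pz, c(0.2, 0.133, 0.133))$fragments$length_um,
               9 * 0.2, tolerance = 1e-9)
})

test_that("fragment count is invariant to axis permutation and rescaling", {
  g <- gen_tube_phantom(4, snr = Inf, seed = 11)
  p <- tube_enhance_params(gaussian_sigma_px = 1, frangi_scale_px = 2)
  res <- analyze_neurites3d(g$stack, p)
  skel <- attr(res, "skeleton")
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    lab <- organoidquant:::label_components(aperm(skel, perm), 26L)
    expect_equal(attr(lab, "n_labels"), res$n_fragments)
  }
  half <- image_stack3d(unclass(g$stack) * 0.5,
                        voxel_size_um = attr(g$stack, "voxel_size_um"))
  expect_equal(analyze_neurites3d(half, p)$n_fragments, res$n_fragments)
})

test_that("noise-free phantom recovery is exact in count and close in length", {
  g <- gen_tube_phantom(5, snr = Inf, seed = 47)
  p <- tube_enhance_params(gaussian_sigma_px = 1, frangi_scale_px = 2)
  res <- analyze_neurites3d(g$stack, p)
  expect_equal(res$n_fragments, g$truth$n_fragments)
  expect_lt(abs(res$mean_length_um / mean(g$truth$fragments$length_um) - 1),
            0.15)
})
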