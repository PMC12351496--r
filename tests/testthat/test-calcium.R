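# a clean normalized transient on a flat baseline
clean_kernel_trace <- function(tau_r, tau_d, amp, rate = 4, pre = 20,
                               len_s = 20, post = 10) {
  tt <- seq(0, len_s, by = 1 / rate)
  kp <- organoidquant:::kernel_peak_value(tau_r, tau_d)
  y <- amp * (1 - exp(-tt / tau_r)) * exp(-tt / tau_d) / kp
  c(rep(0, pre), y, rep(0, post))
}

test_that("activity map responds to change and nothing else", {
  static <- calcium_movie(array(0.3, c(10, 16, 16)))
  expect_true(all(unclass(activity_map(static, Inf)) == 0))
  # one blinking pixel dominates the unfiltered map
  arr <- array(0.1, c(10, 16, 16))
  arr[seq(1, 9, 2), 8, 9] <- 0.9
  m <- activity_map(calcium_movie(arr), Inf)
  expect_equal(which(unclass(m) == max(m), arr.ind = TRUE)[1, ],
               c(row = 8, col = 9))
})

test_that("cell detection respects the separation rule and floors", {
  m <- matrix(0, 32, 32)
  m[10, 10] <- 1; m[10, 13] <- 0.8    # 3 px apart
  m[25, 25] <- 0.9
  rois <- detect_cells(image2d(m, 1), min_separation_px = 5, k_mad = 3)
  expect_equal(nrow(rois), 2)          # the higher of the close pair wins
  expect_true(any(rois$y == 10 & rois$x == 10))
  expect_false(any(rois$x == 13))
  # flat map: no cells
  expect_equal(nrow(detect_cells(image2d(matrix(0.2, 16, 16), 1))), 0)
})

test_that("ROI edits are reproducible and renumbered", {
  m <- matrix(0, 32, 32); m[10, 10] <- 1; m[25, 25] <- 0.9
  rois <- detect_cells(image2d(m, 1), k_mad = 3)
  ed <- apply_roi_edits(rois, list(remove = 1L,
                                   add = list(list(y = 5L, x = 6L))))
  expect_equal(nrow(ed), nrow(rois))
  expect_true(any(ed$y == 5 & ed$x == 6))
  expect_equal(ed$roi_id, seq_len(nrow(ed)))
})

test_that("dF/F0 normalization recovers steps and is scale invariant", {
  # a +10% step on a constant baseline plateaus at 0.10
  arr <- array(0.3, c(240, 12, 12))
  arr[121:240, , ] <- 0.33
  mv <- calcium_movie(arr)
  rois <- structure(tibble::tibble(roi_id = 1L, y = 6L, x = 6L),
                    radius_px = 3L,
                    class = c("roi_set", class(tibble::tibble())))
  tr <- extract_and_normalize(mv, rois)
  # the running baseline absorbs a permanent step after ~half a window,
  # so the plateau is read just after the step
  expect_equal(median(tr$dff[130:155, 1]), 0.10, tolerance = 1e-6)
  expect_equal(median(tr$dff[10:100, 1]), 0, tolerance = 1e-9)
  # constant trace -> identically zero
  tr0 <- extract_and_normalize(calcium_movie(array(0.2, c(100, 12, 12))), rois)
  expect_true(all(abs(tr0$dff) < 1e-12))
  # multiplying the movie by c > 0 leaves dF/F0 unchanged
  tr2 <- extract_and_normalize(calcium_movie(arr * 2), rois)
  expect_equal(tr2$dff, tr$dff, tolerance = 1e-12)
})

test_that("transient detection applies the 2% amplitude rule", {
  # flat trace: nothing
  expect_equal(nrow(detect_transients(rep(0, 100), 4)), 0)
  # 5% event detected exactly once; 1% event rejected
  x5 <- clean_kernel_trace(0.5, 2, 0.05)
  expect_equal(nrow(detect_transients(x5, 4)), 1)
  x1 <- clean_kernel_trace(0.5, 2, 0.01)
  expect_equal(nrow(detect_transients(x1, 4)), 0)
  # event count is non-increasing in the threshold
  set.seed(10)
  x <- clean_kernel_trace(0.5, 2, 0.4)
  x <- x + rnorm(length(x), 0, 0.01)
  counts <- vapply(c(0.02, 0.1, 0.3, 0.5), function(th)
    nrow(detect_transients(x, 4, amplitude_threshold = th,
                           noise_floor_k = 0)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("kinetics fits recover noiseless kernels and fall back gracefully", {
  for (pars in list(c(0.5, 2, 0.05), c(3, 2, 0.4))) {
    x <- clean_kernel_trace(pars[1], pars[2], pars[3])
    ev <- detect_transients(x, 4)
    f <- fit_transient(x, ev[1, ], 4)
    expect_true(f$fit_ok)
    expect_lt(abs(f$rise_time_s / pars[1] - 1), 0.05)
    expect_lt(abs(f$decay_time_s / pars[2] - 1), 0.05)
    expect_lt(abs(f$amplitude / pars[3] - 1), 0.05)
  }
  # a 3 s rise lands above the 1.5 s classification cut
  x <- clean_kernel_trace(3, 2, 0.4)
  ev <- detect_transients(x, 4)
  expect_gt(fit_transient(x, ev[1, ], 4)$rise_time_s, 1.5)
  # degenerate 2-point rise: fit_ok FALSE, amplitude falls back to raw peak
  short <- c(0, 0, 0.05, 0.04, 0.03, 0.02, 0.01, 0, 0)
  f <- fit_transient(short, list(onset_idx = 2L, peak_idx = 3L,
                                 offset_idx = 8L), 4)
  expect_false(f$fit_ok)
  expect_equal(f$amplitude, 0.05)
})

test_that("classification uses a strict 1.5 s median rise cut", {
  rois <- structure(tibble::tibble(roi_id = 1:4, y = 1:4, x = 1:4),
                    radius_px = 4L,
                    class = c("roi_set", class(tibble::tibble())))
  ev <- tibble::tibble(
    roi_id = c(1L, 1L, 2L, 3L, 4L),
    onset_idx = 1L, peak_idx = 2L, offset_idx = 3L, amplitude = 0.3,
    rise_time_s = c(1.0, 1.2, 2.0, 1.5, NA),
    decay_time_s = 2, fit_ok = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    peak_time_s = c(10, 50, 20, 30, 40))
  cells <- classify_cells(ev, rois, duration_s = 300)
  expect_equal(cells$cell_class, c("fast", "slow", "slow", "slow"))
  # monotone: inflating every rise time never turns a slow cell fast
  ev2 <- ev; ev2$rise_time_s <- ev2$rise_time_s + 1
  cells2 <- classify_cells(ev2, rois, 300)
  expect_false(any(cells2$cell_class == "fast" & cells$cell_class == "slow"))
})

test_that("network metrics and synchrony follow their closed forms", {
  rois <- structure(tibble::tibble(roi_id = 1:10, y = 1:10, x = 1:10),
                    radius_px = 4L,
                    class = c("roi_set", class(tibble::tibble())))
  mk_events <- function(times) tibble::tibble(
    roi_id = 1:10, onset_idx = 1L, peak_idx = 2L, offset_idx = 3L,
    amplitude = 0.3, rise_time_s = 1, decay_time_s = 2, fit_ok = TRUE,
    peak_time_s = times)
  cells <- classify_cells(mk_events(rep(100.2, 10)), rois, 300)
  # all peaks in one bin -> synchrony 1
  expect_equal(network_metrics(cells, mk_events(rep(100.2, 10)), 300)$synchrony, 1)
  # peaks in 10 distinct bins -> 0.1
  expect_equal(network_metrics(cells, mk_events(seq(10, 100, by = 10)), 300)$synchrony,
               0.1)
  # zero active cells -> all-zero metrics with a warning
  slowcells <- cells; slowcells$cell_class <- "slow"
  expect_warning(z <- network_metrics(slowcells, mk_events(rep(1, 10)), 300))
  expect_equal(z$synchrony, 0)
  expect_equal(z$active_fraction, 0)
})

test_that("synchrony of Poisson trains matches the brute-force definition", {
  set.seed(12)
  diffs <- replicate(60, {
    trains <- lapply(1:20, function(i) sort(runif(rpois(1, 5), 0, 300)))
    active <- which(lengths(trains) > 0)
    rois <- structure(tibble::tibble(roi_id = seq_along(trains),
                                     y = 1L, x = 1L), radius_px = 4L,
                      class = c("roi_set", class(tibble::tibble())))
    ev <- dplyr::bind_rows(lapply(active, function(i)
      tibble::tibble(roi_id = i, onset_idx = 1L, peak_idx = 2L,
                     offset_idx = 3L, amplitude = 0.3, rise_time_s = 1,
                     decay_time_s = 2, fit_ok = TRUE,
                     peak_time_s = trains[[i]])))
    cells <- classify_cells(ev, rois, 300)
    got <- network_metrics(cells, ev, 300, sync_bin_s = 1)$synchrony
    want <- oracle_synchrony(trains[active], 1, length(active))
    got - want
  })
  expect_equal(mean(abs(diffs)), 0, tolerance = 1e-12)
})

test_that("a small movie runs end to end deterministically", {
  g <- gen_calcium_movie(n_cells = 5, rate_per_min = 2, snr = 8,
                         duration_s = 120, image_shape = c(64L, 64L),
                         seed = 15)
  r1 <- analyze_calcium(g$movie)
  r2 <- analyze_calcium(g$movie)
  expect_identical(r1$events, r2$events)     # bit-identical event tables
  expect_equal(nrow(r1$rois), 5)
  expect_s3_class(glance(r1), "tbl_df")
  expect_equal(tidy(r1), r1$events)
})
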