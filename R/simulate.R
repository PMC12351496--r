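# Synthetic-data generators.  Every generator is a pure function of
# (parameters, seed) and returns the data together with a ground-truth
# record describing the noise-free phantom exactly, so the pipelines can
# be validated end to end without any raw microscopy data.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  force(seed)  # before the RNG snapshot: the seed may itself be a draw
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Generate a 3D tube phantom with known centerline lengths
#'
#' Smooth random 3D curves (gentle quadratic bend) are dilated to tubes
#' of the given radius, blurred with a Gaussian PSF, and overlaid with
#' Gaussian noise at the stated SNR (`(peak signal - background) /
#' noise SD`).  Curves are placed by rejection sampling with a minimum
#' pairwise separation and a margin from the volume faces; the truth
#' records each fragment's exact centerline length.
#'
#' @param n_fragments Number of tubes.
#' @param length_um_range Range of centerline lengths (um).
#' @param tube_radius_px Tube radius in (lateral) pixels.
#' @param volume_shape `(Z, Y, X)` voxels.
#' @param voxel_size_um `(dz, dy, dx)` um.
#' @param snr Signal-to-noise ratio; `Inf` for noise-free.
#' @param seed RNG seed.
#' @param min_separation_um Minimum distance between curve centerlines.
#' @return List with `stack` ([image_stack3d]) and `truth` (list:
#'   `n_fragments`, tibble `fragments` with `length_um`, `snr`, `seed`).
#' @export
gen_tube_phantom <- function(n_fragments, length_um_range = c(3, 8),
                             tube_radius_px = 2,
                             volume_shape = c(32L, 160L, 160L),
                             voxel_size_um = c(0.2, 0.133, 0.133),
                             snr = Inf, seed = 1,
                             min_separation_um = 1.2) with_seed(seed, {
  d <- as.integer(volume_shape)
  vs <- as.numeric(voxel_size_um)
  ext_um <- d * vs                       # physical extents (z, y, x)
  margin_um <- c(2 * vs[1], (tube_radius_px + 4) * vs[2],
                 (tube_radius_px + 4) * vs[3])
  curves <- list()
  tries <- 0
  while (length(curves) < n_fragments) {
    tries <- tries + 1
    if (tries > 500 * max(n_fragments, 1))
      stop("cannot place tubes without overlap; lower n_fragments",
           call. = FALSE)
    L <- runif(1, length_um_range[1], length_um_range[2])
    # direction mostly lateral (thin z extent), gentle curvature
    az <- runif(1, 0, 2 * pi)
    dirv <- c(runif(1, -0.15, 0.15), sin(az), cos(az))
    dirv <- dirv / sqrt(sum(dirv^2))
    perp <- c(0, -dirv[3], dirv[2]); perp <- perp / sqrt(sum(perp^2))
    curv <- runif(1, -0.04, 0.04)        # 1/um, gentle bend
    p0 <- c(runif(1, margin_um[1], ext_um[1] - margin_um[1]),
            runif(1, margin_um[2], ext_um[2] - margin_um[2]),
            runif(1, margin_um[3], ext_um[3] - margin_um[3]))
    s <- seq(0, L, by = 0.05)
    pts <- t(vapply(s, function(si)
      p0 + si * dirv + (curv * si^2 / 2) * perp, numeric(3)))
    inside <- all(pts[, 1] > margin_um[1] & pts[, 1] < ext_um[1] - margin_um[1] &
                  pts[, 2] > margin_um[2] & pts[, 2] < ext_um[2] - margin_um[2] &
                  pts[, 3] > margin_um[3] & pts[, 3] < ext_um[3] - margin_um[3])
    if (!inside) next
    clash <- FALSE
    for (cv in curves) {
      dmin <- min(vapply(seq_len(nrow(pts)), function(i)
        min(sqrt(colSums((t(cv$pts) - pts[i, ])^2))), numeric(1)))
      if (dmin < min_separation_um + 2 * tube_radius_px * vs[3]) {
        clash <- TRUE; break
      }
    }
    if (clash) next
    len <- sum(sqrt(rowSums(diff(pts)^2)))
    curves[[length(curves) + 1]] <- list(pts = pts, length_um = len)
  }
  # render: binary dilation of the centerline to the tube radius
  # (distances in um), then PSF blur and noise
  arr <- array(0, d)
  r_um <- tube_radius_px * vs[3]
  for (cv in curves) {
    vox <- sweep(cv$pts, 2, vs, `/`)     # voxel coordinates (z, y, x)
    rz <- ceiling(r_um / vs[1]); rl <- ceiling(r_um / vs[2])
    for (i in seq_len(nrow(vox))) {
      cz <- vox[i, 1]; cy <- vox[i, 2]; cx <- vox[i, 3]
      iz <- max(1, floor(cz - rz)):min(d[1], ceiling(cz + rz) + 1)
      iy <- max(1, floor(cy - rl)):min(d[2], ceiling(cy + rl) + 1)
      ix <- max(1, floor(cx - rl)):min(d[3], ceiling(cx + rl) + 1)
      dz2 <- ((iz - 0.5 - cz) * vs[1])^2
      dy2 <- ((iy - 0.5 - cy) * vs[2])^2
      dx2 <- ((ix - 0.5 - cx) * vs[3])^2
      dist2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
      sub <- arr[iz, iy, ix, drop = FALSE]
      sub[dist2 <= r_um^2] <- 1
      arr[iz, iy, ix] <- sub
    }
  }
  arr <- gaussian_smooth(arr, 0.8)
  peak <- max(arr, 0.01)
  sig <- 0.7 * arr / peak
  if (is.finite(snr)) sig <- sig + rnorm(length(sig), 0, 0.7 / snr)
  stack <- image_stack3d(pmin(pmax(sig, 0), 1), voxel_size_um = vs)
  truth <- list(kind = "tube_phantom", n_fragments = length(curves),
                fragments = tibble::tibble(
                  fragment_id = seq_along(curves),
                  length_um = vapply(curves, `[[`, numeric(1), "length_um")),
                tube_radius_px = tube_radius_px, snr = snr, seed = seed)
  list(stack = stack, truth = truth)
})

# place non-overlapping discs/bars; used by the puncta generator
place_objects <- function(n_objects, shape, image_shape, radius_px_range,
                          bar_length_px_range, bar_width_px, coverage_target,
                          forbidden = NULL) {
  d <- image_shape
  mask <- matrix(FALSE, d[1], d[2])
  objs <- list()
  tries <- 0
  done <- function() {
    if (!is.null(coverage_target)) mean(mask) >= coverage_target
    else length(objs) >= n_objects
  }
  while (!done()) {
    tries <- tries + 1
    if (tries > 20000) break
    # a 2-px clearance ring keeps neighbouring objects separable after
    # the PSF blur, so the planted object count stays the ground truth
    mar <- 2
    if (shape == "spot") {
      r <- runif(1, radius_px_range[1], radius_px_range[2])
      cy <- runif(1, r + mar + 2, d[1] - r - mar - 2)
      cx <- runif(1, r + mar + 2, d[2] - r - mar - 2)
      iy <- floor(cy - r - mar):ceiling(cy + r + mar)
      ix <- floor(cx - r - mar):ceiling(cx + r + mar)
      d2 <- outer((iy - cy)^2, (ix - cx)^2, `+`)
      sel <- d2 <= r^2
      sel_clear <- d2 <= (r + mar)^2
      obj <- list(y = cy, x = cx, radius_px = r, length_px = 2 * r)
    } else {
      L <- runif(1, bar_length_px_range[1], bar_length_px_range[2])
      th <- runif(1, 0, pi)
      w <- bar_width_px / 2
      half <- L / 2
      cy <- runif(1, half + w + mar + 2, d[1] - half - w - mar - 2)
      cx <- runif(1, half + w + mar + 2, d[2] - half - w - mar - 2)
      iy <- floor(cy - half - w - mar):ceiling(cy + half + w + mar)
      ix <- floor(cx - half - w - mar):ceiling(cx + half + w + mar)
      gy <- outer(iy - cy, rep(1, length(ix)))
      gx <- outer(rep(1, length(iy)), ix - cx)
      u <- gy * sin(th) + gx * cos(th)       # along the bar
      v <- -gy * cos(th) + gx * sin(th)      # across
      sel <- abs(u) <= half & abs(v) <= w
      sel_clear <- abs(u) <= half + mar & abs(v) <= w + mar
      obj <- list(y = cy, x = cx, angle = th, bar_px = L,
                  length_px = L + bar_width_px)
    }
    sub <- mask[iy, ix, drop = FALSE]
    blocked <- any(sub & sel_clear)
    if (!is.null(forbidden))
      blocked <- blocked || any(forbidden[iy, ix][sel_clear])
    if (blocked) next
    sub[sel] <- TRUE
    mask[iy, ix] <- sub
    objs[[length(objs) + 1]] <- obj
  }
  list(mask = mask, objects = objs)
}

#' Generate a 2D puncta / mitochondria phantom
#'
#' Round spots or bar-shaped objects on a dark background with an exactly
#' known foreground mask; the truth records coverage and per-object
#' end-to-end lengths.  `coverage_target`, when given, adds objects until
#' that area fraction is reached (it must be <= 0.5: denser fields are
#' not realistic and placement degenerates).
#'
#' @param n_objects Number of objects (ignored when `coverage_target` is
#'   set).
#' @param shape `"spot"` or `"bar"`.
#' @param coverage_target Optional target area fraction in (0, 0.5].
#' @param image_shape `(Y, X)` pixels.
#' @param pixel_size_um Pixel size.
#' @param radius_px_range Spot radius range.
#' @param bar_length_px_range,bar_width_px Bar geometry (end-to-end
#'   length is bar length + width).
#' @param snr Signal-to-noise ratio.
#' @param seed RNG seed.
#' @return List with `image` ([image2d]), `truth` (mask, coverage,
#'   objects tibble).
#' @export
gen_puncta_image <- function(n_objects = 40, shape = c("spot", "bar"),
                             coverage_target = NULL,
                             image_shape = c(256L, 256L),
                             pixel_size_um = 0.065,
                             radius_px_range = c(5, 12),
                             bar_length_px_range = c(10, 30),
                             bar_width_px = 3, snr = 20,
                             seed = 1) with_seed(seed, {
  shape <- match.arg(shape)
  if (!is.null(coverage_target) && coverage_target > 0.5)
    stop("coverage_target > 0.5 is not supported", call. = FALSE)
  pl <- place_objects(n_objects, shape, as.integer(image_shape),
                      radius_px_range, bar_length_px_range, bar_width_px,
                      coverage_target)
  img <- render_mask(pl$mask, snr)
  objs <- dplyr::bind_rows(lapply(pl$objects, tibble::as_tibble))
  truth <- list(kind = "puncta", mask = pl$mask, coverage = mean(pl$mask),
                n_objects = length(pl$objects),
                objects = objs,
                lengths_um = if (nrow(objs)) objs$length_px * pixel_size_um
                             else numeric(0),
                snr = snr, seed = seed)
  list(image = image2d(img, pixel_size_um = pixel_size_um), truth = truth)
})

# soft-edge rendering of a binary mask with additive noise at given SNR
render_mask <- function(mask, snr) {
  sig <- gaussian_smooth(mask * 1.0, 0.8)
  sig <- 0.7 * sig / max(sig, 0.01)
  if (is.finite(snr)) sig <- sig + rnorm(length(sig), 0, 0.7 / snr)
  matrix(pmin(pmax(sig, 0), 1), nrow(mask), ncol(mask))
}

#' Generate a two-channel phantom with a planted mask overlap
#'
#' Channel A is a spot phantom; channel B reuses a subset of A's objects
#' (chosen to cover approximately `overlap_fraction` of A's area) and
#' adds fresh objects disjoint from A.  The truth records the exact
#' overlap fraction of the noise-free masks.
#'
#' @param overlap_fraction Target `|A and B| / |A|`.
#' @param n_objects Objects per channel.
#' @inheritParams gen_puncta_image
#' @return List with `image_a`, `image_b`, `truth` (`mask_a`, `mask_b`,
#'   `overlap_fraction`).
#' @export
gen_coloc_pair <- function(overlap_fraction = 0.3, n_objects = 40,
                           image_shape = c(256L, 256L),
                           pixel_size_um = 0.065,
                           radius_px_range = c(5, 12), snr = 20,
                           seed = 1) with_seed(seed, {
  pa <- place_objects(n_objects, "spot", as.integer(image_shape),
                      radius_px_range, NULL, NULL, NULL)
  mask_a <- pa$mask
  # greedily reuse objects of A until ~overlap_fraction of A's area
  area_a <- sum(mask_a)
  mask_b <- matrix(FALSE, nrow(mask_a), ncol(mask_a))
  got <- 0
  for (obj in sample(pa$objects)) {
    if (got / area_a >= overlap_fraction) break
    r <- obj$radius_px
    iy <- floor(obj$y - r):ceiling(obj$y + r)
    ix <- floor(obj$x - r):ceiling(obj$x + r)
    sel <- outer((iy - obj$y)^2, (ix - obj$x)^2, `+`) <= r^2
    sub <- mask_b[iy, ix, drop = FALSE]
    sub[sel] <- TRUE
    mask_b[iy, ix] <- sub
    got <- sum(mask_b & mask_a)
  }
  pb <- place_objects(max(0, n_objects - length(pa$objects)), "spot",
                      as.integer(image_shape), radius_px_range, NULL, NULL,
                      NULL, forbidden = mask_a | mask_b)
  mask_b <- mask_b | pb$mask
  truth <- list(kind = "coloc_pair", mask_a = mask_a, mask_b = mask_b,
                overlap_fraction = sum(mask_a & mask_b) / sum(mask_a),
                snr = snr, seed = seed)
  list(image_a = image2d(render_mask(mask_a, snr), pixel_size_um),
       image_b = image2d(render_mask(mask_b, snr), pixel_size_um),
       truth = truth)
})

#' Generate a synthetic calcium movie with known events
#'
#' Cells are flat-top fluorescent discs placed with a minimum separation;
#' each cell fires a Poisson event train (a configurable fraction of
#' events is drawn from one shared network train, controlling synchrony),
#' events are rendered with the kernel `A (1 - e^(-t/tau_r)) e^(-t/tau_d)`
#' scaled so its peak dF/F0 equals the drawn amplitude, an optional
#' exponential bleaching drift is applied, and Gaussian noise is added at
#' the stated SNR (`(cell brightness - background) / noise SD`, per pixel
#' per frame).
#'
#' @param n_cells Number of cells.
#' @param rate_per_min Mean event rate per cell (events/min).
#' @param tau_r_s,tau_d_s Kernel rise and decay time constants (s).
#' @param amp_mean,amp_sd Event peak dF/F0 distribution (truncated below
#'   at `0.4 * amp_mean` so the design amplitude scale is respected).
#' @param shared_event_fraction Fraction of each cell's events taken from
#'   the shared train (1 = fully synchronous network).
#' @param drift Fractional fluorescence decay over the whole movie
#'   (bleaching), 0 to disable.
#' @param snr Signal-to-noise ratio; `Inf` for noise-free.
#' @param duration_s,frame_rate_hz Movie length and sampling (300 s at
#'   4 Hz by default).
#' @param image_shape `(Y, X)` pixels (128 x 128 desk-scale default).
#' @param min_separation_px Minimum distance between cell centres.
#' @param seed RNG seed.
#' @return List with `movie` ([calcium_movie]) and `truth` (cell centres,
#'   per-cell event times/amplitudes, kinetics, rates, shared fraction).
#' @export
gen_calcium_movie <- function(n_cells = 20, rate_per_min = 1, tau_r_s = 0.5,
                              tau_d_s = 2, amp_mean = 0.4, amp_sd = 0.1,
                              shared_event_fraction = 0, drift = 0,
                              snr = 10, duration_s = 300, frame_rate_hz = 4,
                              image_shape = c(128L, 128L),
                              min_separation_px = 14,
                              seed = 1) with_seed(seed, {
  d <- as.integer(image_shape)
  n_t <- round(duration_s * frame_rate_hz)
  margin <- 8
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < n_cells) {
    tries <- tries + 1
    if (tries > 20000)
      stop("cannot place cells with the requested separation", call. = FALSE)
    p <- c(round(runif(1, margin, d[1] - margin)),
           round(runif(1, margin, d[2] - margin)))
    if (nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >=
            min_separation_px))
      centers <- rbind(centers, p)
  }
  # event trains: shared network train + per-cell own trains
  min_gap_s <- 6
  draw_train <- function(rate) {
    n <- rpois(1, rate * duration_s / 60)
    sort(runif(n, 5, duration_s - 15))
  }
  thin_gaps <- function(tt) {
    if (length(tt) < 2) return(tt)
    keep <- c(TRUE, diff(tt) >= min_gap_s)
    tt[keep]
  }
  shared <- draw_train(rate_per_min)
  cell_events <- lapply(seq_len(n_cells), function(i) {
    own <- draw_train(rate_per_min * (1 - shared_event_fraction))
    adopted <- shared[runif(length(shared)) < shared_event_fraction]
    tt <- thin_gaps(sort(c(own, adopted)))
    amp <- pmax(0.4 * amp_mean, rnorm(length(tt), amp_mean, amp_sd))
    tibble::tibble(time_s = tt, amplitude = amp)
  })
  # per-cell dF/F0 traces from the kernel (peak-normalized)
  tgrid <- (seq_len(n_t) - 1) / frame_rate_hz
  kp <- kernel_peak_value(tau_r_s, tau_d_s)
  traces <- vapply(cell_events, function(ev) {
    f <- numeric(n_t)
    for (j in seq_len(nrow(ev))) {
      dt <- tgrid - ev$time_s[j]
      on <- dt >= 0
      f[on] <- f[on] + ev$amplitude[j] *
        (1 - exp(-dt[on] / tau_r_s)) * exp(-dt[on] / tau_d_s) / kp
    }
    f
  }, numeric(n_t))
  b0 <- 0.05; s_base <- 0.3
  bleach <- if (drift > 0) exp(log(1 - drift) * tgrid / duration_s) else
    rep(1, n_t)
  # flat-top cell profile so the ROI-mean dF/F0 equals the planted one
  r_flat <- 5.5
  movie <- array(0, c(n_t, d[1], d[2]))
  bgframe <- matrix(b0, d[1], d[2])
  prof_list <- list()
  for (i in seq_len(n_cells)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    iy <- max(1, cy - 8):min(d[1], cy + 8)
    ix <- max(1, cx - 8):min(d[2], cx + 8)
    dist2 <- outer((iy - cy)^2, (ix - cx)^2, `+`)
    prof <- exp(-(dist2 / r_flat^2)^4)
    bgframe[iy, ix] <- bgframe[iy, ix] * (1 - prof)
    prof_list[[i]] <- list(iy = iy, ix = ix, prof = prof)
  }
  for (t in seq_len(n_t)) movie[t, , ] <- bgframe
  for (i in seq_len(n_cells)) {
    pl <- prof_list[[i]]
    amp_t <- s_base * (1 + traces[, i]) * bleach     # T
    patch <- outer(amp_t, as.numeric(pl$prof))       # T x P
    movie[, pl$iy, pl$ix] <- movie[, pl$iy, pl$ix] +
      array(patch, c(n_t, length(pl$iy), length(pl$ix)))
  }
  if (is.finite(snr))
    movie <- movie + rnorm(length(movie), 0, (s_base - b0) / snr)
  movie <- pmin(pmax(movie, 0), 1)
  truth <- list(kind = "calcium", centers = tibble::tibble(
                  cell_id = seq_len(n_cells),
                  y = centers[, 1], x = centers[, 2]),
                events = dplyr::bind_rows(
                  lapply(seq_len(n_cells), function(i) {
                    ev <- cell_events[[i]]; ev$cell_id <- i; ev
                  })),
                tau_r_s = tau_r_s, tau_d_s = tau_d_s,
                rate_per_min = rate_per_min,
                shared_event_fraction = shared_event_fraction,
                drift = drift, snr = snr, duration_s = duration_s,
                frame_rate_hz = frame_rate_hz, seed = seed)
  list(movie = calcium_movie(movie, frame_rate_hz), truth = truth)
})

#' Generate a count matrix with planted differential expression
#'
#' Gene base means are log-normal; housekeeping genes are split into a
#' high-abundance majority (passing the average-count filter, mirroring
#' the 7-of-10 reference genes retained in the published panel) and a
#' low-abundance minority that the filter should exclude.  Sample library
#' sizes vary (so normalization is non-trivial); planted DE genes get a
#' multiplicative fold change in group B.  `family = "nb"` draws
#' negative-binomial counts with the given dispersion; `"lognormal"`
#' draws log-normal counts (normal log-counts, useful for null
#' calibration studies).
#'
#' @param n_genes Endogenous genes (760 in the published panel).
#' @param n_hk Housekeeping genes (10).
#' @param n_per_group Samples per group.
#' @param de_fraction Fraction of endogenous genes planted as DE.
#' @param fc Fold change of planted DE genes (B over A; half the planted
#'   genes get `1/fc`).
#' @param dispersion NB dispersion (1/size).
#' @param family `"nb"` or `"lognormal"`.
#' @param sdlog Log-normal noise SD (family `"lognormal"`).
#' @param lib_sd SD of log library-size factors.
#' @param seed RNG seed.
#' @return List with `cm` (a [count_matrix] holding both groups) and
#'   `truth` (planted DE tibble, housekeeping ids, library factors).
#' @export
gen_count_matrix <- function(n_genes = 760L, n_hk = 10L, n_per_group = 4L,
                             de_fraction = 0, fc = 3, dispersion = 0.1,
                             family = c("nb", "lognormal"), sdlog = 0.35,
                             lib_sd = 0.15, seed = 1) with_seed(seed, {
  family <- match.arg(family)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  hk_ids <- sprintf("HK%02d", seq_len(n_hk))
  n_hi <- ceiling(0.7 * n_hk)
  hk_mu <- c(runif(n_hi, 800, 3000), runif(n_hk - n_hi, 80, 350))
  mu <- rlnorm(n_genes, meanlog = log(300), sdlog = 1.0)
  n_s <- 2L * n_per_group
  groups <- rep(c("A", "B"), each = n_per_group)
  libf <- rlnorm(n_s, 0, lib_sd)
  n_de <- round(de_fraction * n_genes)
  de_idx <- if (n_de) sample.int(n_genes, n_de) else integer(0)
  fc_gene <- rep(1, n_genes)
  if (n_de) {
    up <- seq_len(n_de) <= ceiling(n_de / 2)
    fc_gene[de_idx] <- ifelse(up, fc, 1 / fc)
  }
  mu_all <- c(mu, hk_mu)                       # genes then housekeeping
  fc_all <- c(fc_gene, rep(1, n_hk))
  m <- matrix(0, n_genes + n_hk, n_s)
  for (s in seq_len(n_s)) {
    mm <- mu_all * libf[s] * (if (groups[s] == "B") fc_all else 1)
    m[, s] <- if (family == "nb")
      rnbinom(length(mm), mu = mm, size = 1 / dispersion)
    else rlnorm(length(mm), meanlog = log(mm), sdlog = sdlog)
  }
  rownames(m) <- c(gene_ids, hk_ids)
  colnames(m) <- paste0(groups, rep(seq_len(n_per_group), 2))
  cm <- count_matrix(m, groups, hk_ids)
  truth <- list(kind = "counts",
                de = tibble::tibble(gene_id = gene_ids[de_idx],
                                    fold_change = fc_gene[de_idx]),
                housekeeping_ids = hk_ids,
                hk_above_filter = hk_ids[hk_mu > 450],
                library_factors = libf, dispersion = dispersion,
                family = family, seed = seed)
  list(cm = cm, truth = truth)
})

#' Generate a qPCR Ct table from known relative expressions
#'
#' `Ct_gene = Ct_ref - log2(rel_expr) + noise`; the reference gene rows
#' get `Ct_ref + noise`.
#'
#' @param true_rel_expr Tibble with `sample_label`, `gene_id`,
#'   `rel_expr` (> 0).
#' @param ref_gene Reference gene id (ATP5O).
#' @param ct_ref Reference Ct level (cycles).
#' @param ct_noise_sd Gaussian Ct noise SD (cycles).
#' @param seed RNG seed.
#' @return List with `ct` (tibble as read by [read_ct_table()]) and
#'   `truth` (the input table).
#' @export
gen_ct_table <- function(true_rel_expr, ref_gene = "ATP5O", ct_ref = 20,
                         ct_noise_sd = 0, seed = 1) with_seed(seed, {
  tre <- tibble::as_tibble(true_rel_expr)
  stopifnot(all(tre$rel_expr > 0))
  genes <- tre |>
    dplyr::mutate(ct_value = ct_ref - log2(.data$rel_expr) +
                    rnorm(dplyr::n(), 0, ct_noise_sd)) |>
    dplyr::select("sample_label", "gene_id", "ct_value")
  samples <- unique(tre$sample_label)
  refs <- tibble::tibble(sample_label = samples, gene_id = ref_gene,
                         ct_value = ct_ref +
                           rnorm(length(samples), 0, ct_noise_sd))
  list(ct = dplyr::bind_rows(refs, genes), truth = list(
    kind = "ct_table", rel_expr = tre, ref_gene = ref_gene,
    ct_noise_sd = ct_noise_sd, seed = seed))
})

# ---------------------------------------------------------------------------
# ground-truth serialization (versioned schema, validated on write)

truth_required_fields <- list(
  tube_phantom = c("n_fragments", "fragments"),
  puncta = c("coverage", "n_objects"),
  coloc_pair = c("overlap_fraction"),
  calcium = c("centers", "events", "tau_r_s", "tau_d_s"),
  counts = c("de", "housekeeping_ids"),
  ct_table = c("rel_expr", "ref_gene"))

#' Write / read a ground-truth record as JSON
#'
#' The schema is versioned; required fields per record kind are validated
#' on write.  Matrices (phantom masks) are omitted from the JSON.
#'
#' @param truth A generator `truth` list.
#' @param path JSON file.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth <- function(truth, path) {
  kind <- truth$kind
  req <- truth_required_fields[[kind]]
  if (is.null(req)) stop("unknown truth kind: ", kind, call. = FALSE)
  missing <- setdiff(req, names(truth))
  if (length(missing))
    stop("truth record missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  slim <- truth[!vapply(truth, is.matrix, logical(1)) |
                  names(truth) %in% c("centers")]
  slim$schema_version <- 1L
  jsonlite::write_json(slim, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(tr$schema_version))
    stop("not a versioned truth record", call. = FALSE)
  tr
}
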