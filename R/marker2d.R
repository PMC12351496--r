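# 2D fluorescence marker quantification: mean z-projection, the
# median / background / H-minima / CLAHE preprocessing chain, Otsu
# binarization, and area/intensity readouts (marker coverage, synaptic
# colocalization, mitochondria along a neurite path).

#' Parameters of the 2D preprocessing chain
#'
#' @param median_size_px Odd median-filter window (5 in the published
#'   chain; stated there as a "sigma", but a median filter has a size).
#' @param hminima_depth Depth `H` of the H-minima denoise on the
#'   normalized scale (published value 0.05).
#' @param clahe_clip CLAHE clip limit as a fraction of the tile histogram.
#' @param clahe_tile_px CLAHE tile size in pixels.
#' @param background_method Background-level estimator:
#'   `"histogram_peak_offset"` finds the intensity-histogram mode and
#'   takes the first intensity beyond it where counts drop under
#'   `background_peak_fraction` of the mode count; `"triangle"` uses the
#'   triangle geometric method.
#' @param background_peak_fraction Drop-off fraction for the peak-offset
#'   method, in (0, 1).
#' @return A `preprocess2d_params` list.
#' @export
preprocess2d_params <- function(median_size_px = 5L, hminima_depth = 0.05,
                                clahe_clip = 0.01, clahe_tile_px = 64L,
                                background_method = c("histogram_peak_offset",
                                                      "triangle"),
                                background_peak_fraction = 0.5) {
  median_size_px <- as.integer(median_size_px)
  if (median_size_px < 1L || median_size_px %% 2L == 0L)
    stop("median_size_px must be odd and >= 1", call. = FALSE)
  if (hminima_depth < 0 || hminima_depth > 1)
    stop("hminima_depth must be in [0, 1]", call. = FALSE)
  if (background_peak_fraction <= 0 || background_peak_fraction >= 1)
    stop("background_peak_fraction must be in (0, 1)", call. = FALSE)
  structure(list(median_size_px = median_size_px,
                 hminima_depth = hminima_depth,
                 clahe_clip = clahe_clip,
                 clahe_tile_px = as.integer(clahe_tile_px),
                 background_method = match.arg(background_method),
                 background_peak_fraction = background_peak_fraction),
            class = "preprocess2d_params")
}

#' Mean z-projection of a stack
#'
#' Averages `n_planes` consecutive planes centred on the stack midpoint
#' (20 planes in the published analysis of 60x organoid sections).
#'
#' @param stack An [image_stack3d].
#' @param n_planes Number of planes to average (`1 <= n_planes <= Z`).
#' @return An [image2d] with the stack's lateral pixel size.
#' @export
zproject_mean <- function(stack, n_planes = 20L) {
  stopifnot(inherits(stack, "image_stack3d"))
  n_planes <- as.integer(n_planes)
  z <- dim(stack)[1]
  if (n_planes < 1L) stop("n_planes must be >= 1", call. = FALSE)
  if (n_planes > z)
    stop("n_planes exceeds the number of planes (", z, ")", call. = FALSE)
  start <- (z - n_planes) %/% 2L + 1L
  sel <- start:(start + n_planes - 1L)
  proj <- apply(unclass(stack)[sel, , , drop = FALSE], c(2, 3), mean)
  image2d(proj, pixel_size_um = attr(stack, "voxel_size_um")[3])
}

# background level from the intensity histogram (256 bins)
estimate_background <- function(v, method, peak_fraction) {
  n_bins <- 256L
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  if (method == "histogram_peak_offset") {
    mode_bin <- which.max(counts)
    cutoff <- peak_fraction * counts[mode_bin]
    after <- which(counts < cutoff)
    after <- after[after > mode_bin]
    bg_bin <- if (length(after)) after[1] else mode_bin
    edges[bg_bin + 1L]
  } else {  # triangle: largest perpendicular distance from the peak-to-
            # tail chord of the histogram
    mode_bin <- which.max(counts)
    nz <- which(counts > 0)
    tail_bin <- max(nz)
    if (tail_bin <= mode_bin) return(edges[mode_bin + 1L])
    ks <- mode_bin:tail_bin
    # line from (mode_bin, peak) to (tail_bin, 0)
    x1 <- mode_bin; y1 <- counts[mode_bin]; x2 <- tail_bin; y2 <- 0
    d <- abs((y2 - y1) * ks - (x2 - x1) * counts[ks] + x2 * y1 - y2 * x1)
    edges[ks[which.max(d)] + 1L]
  }
}

#' The published 2D preprocessing chain
#'
#' Applies, in order: median filtering, background removal (histogram
#' shape-based level beyond the distribution peak, subtracted and clamped
#' at zero), the H-minima transform (H = 0.05), and CLAHE.  Input and
#' output are on the normalized `[0, 1]` scale.
#'
#' @param img An [image2d] (values in `[0, 1]`).
#' @param params A [preprocess2d_params()] list.
#' @return The processed [image2d].
#' @export
preprocess2d <- function(img, params = preprocess2d_params()) {
  stopifnot(inherits(img, "image2d"))
  assert_normalized(img)
  px <- attr(img, "pixel_size_um")
  x <- unclass(as.matrix(img))

  x <- log_stage("median", list(size = params$median_size_px),
                 median_filter2d(x, params$median_size_px))

  bg <- estimate_background(as.numeric(x), params$background_method,
                            params$background_peak_fraction)
  x <- log_stage("background", list(level = signif(bg, 4)),
                 pmax(x - bg, 0))

  x <- log_stage("hminima", list(h = params$hminima_depth),
                 hminima(x, params$hminima_depth))

  if (max(x) - min(x) > 0) {
    nx_t <- max(2L, round(nrow(x) / params$clahe_tile_px))
    ny_t <- max(2L, round(ncol(x) / params$clahe_tile_px))
    lim <- max(1, params$clahe_clip * 256)
    x <- log_stage("clahe", list(nx = nx_t, ny = ny_t, limit = lim),
                   EBImage::clahe(x, nx = nx_t, ny = ny_t, bins = 256L,
                                  limit = lim))
    x <- pmin(pmax(as.matrix(x), 0), 1)
  }
  image2d(x, pixel_size_um = px)
}

#' Coverage metrics of a segmentation mask
#'
#' Area fraction and integrated signal density (ISD) of a binary mask
#' over a field of view.  ISD is the sum of *raw* (pre-equalization)
#' intensities under the mask: CLAHE destroys intensity linearity, so the
#' mask from the processed image is applied back to the raw image.
#'
#' @param mask Logical matrix (foreground = `TRUE`).
#' @param raw_img Raw intensity image, same shape.
#' @return One-row tibble: `area_fraction`, `integrated_density`,
#'   `n_foreground_px`.
#' @export
coverage <- function(mask, raw_img) {
  mask <- as.array(mask)
  raw <- unclass(as.array(raw_img))
  if (!identical(dim(mask), dim(raw)))
    stop("mask and image shapes differ", call. = FALSE)
  n_fg <- sum(mask)
  tibble::tibble(
    area_fraction = n_fg / length(mask),
    integrated_density = if (n_fg) sum(raw[mask]) else 0,
    n_foreground_px = as.integer(n_fg))
}

#' Mask colocalization of two markers
#'
#' Overlap (pixelwise AND) of two segmentation masks, quantified with the
#' same coverage metrics; used for pre/postsynaptic marker pairs
#' (e.g. VGluT1 x PSD95).  Symmetric in the masks for the area metrics.
#'
#' @param mask_a,mask_b Logical matrices, same shape.
#' @param raw_img_a Raw image of the first channel (for ISD).
#' @return One-row tibble as in [coverage()].
#' @export
colocalize <- function(mask_a, mask_b, raw_img_a) {
  if (!identical(dim(as.array(mask_a)), dim(as.array(mask_b))))
    stop("mask shapes differ", call. = FALSE)
  coverage(as.array(mask_a) & as.array(mask_b), raw_img_a)
}

#' Count and measure objects inside a neurite path
#'
#' Replaces the manual freehand tracing step: a `path_mask` delimits the
#' neurite (axonal) region, the marker mask is restricted to it, connected
#' components (8-connectivity) are the objects (e.g. mitochondria), and
#' each object's length is its extent along its principal axis in
#' micrometres (minimum one pixel).  The per-path mean mirrors the
#' "lengths averaged for each axon" readout.
#'
#' @param mask Logical marker mask.
#' @param path_mask Logical region-of-interest mask, same shape, non-empty.
#' @param pixel_size_um Pixel size in micrometres.
#' @return An `object_stats` list: tibble `objects` (`object_id`, `n_px`,
#'   `length_um`), `n_objects`, `mean_length_um`, `empty` flag.
#' @export
objects_in_path <- function(mask, path_mask, pixel_size_um) {
  mask <- as.array(mask); path_mask <- as.array(path_mask)
  if (!identical(dim(mask), dim(path_mask)))
    stop("mask and path_mask shapes differ", call. = FALSE)
  if (!any(path_mask))
    stop("path_mask is empty", call. = FALSE)
  m <- mask & path_mask
  lab <- label_components(m, 8L)
  n <- attr(lab, "n_labels")
  lengths_um <- numeric(n)
  n_px <- integer(n)
  if (n > 0) {
    idx <- which(m, arr.ind = TRUE)
    labs <- lab[m]
    for (o in seq_len(n)) {
      pts <- idx[labs == o, , drop = FALSE]
      n_px[o] <- nrow(pts)
      lengths_um[o] <- object_axis_length_px(pts) * pixel_size_um
    }
  }
  empty <- n == 0
  if (empty) warning("no objects inside the path", call. = FALSE)
  structure(list(
    objects = tibble::tibble(object_id = seq_len(n), n_px = n_px,
                             length_um = lengths_um),
    n_objects = n,
    mean_length_um = if (empty) 0 else mean(lengths_um),
    empty = empty), class = "object_stats")
}

# extent of a pixel set along its principal axis, in pixels (min 1)
object_axis_length_px <- function(pts) {
  if (nrow(pts) == 1) return(1)
  ctr <- scale(pts, scale = FALSE)
  cv <- crossprod(ctr) / nrow(pts)
  ax <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  proj <- ctr %*% ax
  (max(proj) - min(proj)) + 1
}

#' @export
print.object_stats <- function(x, ...) {
  cat("<object_stats> ", x$n_objects, " objects, mean length ",
      signif(x$mean_length_um, 4), " um\n", sep = "")
  invisible(x)
}

#' Full 2D marker quantification of one field of view
#'
#' Runs the complete chain on a stack or image: mean z-projection (for
#' stacks), preprocessing, Otsu binarization, and coverage on the raw
#' projection.
#'
#' @param x An [image_stack3d] or [image2d].
#' @param params A [preprocess2d_params()].
#' @param n_planes Planes for the projection (stacks only).
#' @return One-row tibble with the coverage metrics plus the Otsu
#'   threshold used.
#' @export
quantify_markers2d <- function(x, params = preprocess2d_params(),
                               n_planes = 20L) {
  raw <- if (inherits(x, "image_stack3d")) {
    zproject_mean(x, min(n_planes, dim(x)[1]))
  } else x
  proc <- preprocess2d(raw, params)
  mask <- binarize_otsu(proc)
  res <- coverage(mask, raw)
  res$otsu_threshold <- attr(mask, "threshold")
  res
}
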