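# Lightweight calibrated containers.  Pixel data stay as plain numeric
# arrays (images do not fit a data-frame surface); every derived result
# type is a tibble or carries tibbles.

#' Calibrated 2D fluorescence image
#'
#' Wraps a numeric matrix of non-negative intensities together with the
#' physical pixel size.  Intensities are kept on a normalized `[0, 1]`
#' scale throughout the package (integer TIFF data are divided by the
#' dtype maximum on read).
#'
#' @param pixels Numeric matrix (y, x) of non-negative intensities.
#' @param pixel_size_um Physical pixel size in micrometres. The defaults
#'   used in practice are 0.065 for a 100x and 0.108 for a 60x oil
#'   objective with a 6.5 um camera pixel.
#' @param channel_names Optional character vector naming the channel(s).
#' @return An `image2d` object (numeric matrix with calibration attributes).
#' @export
image2d <- function(pixels, pixel_size_um = 0.065, channel_names = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1)
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive real", call. = FALSE)
  if (any(pixels < 0, na.rm = TRUE))
    stop("image intensities must be non-negative", call. = FALSE)
  structure(pixels,
            pixel_size_um = pixel_size_um,
            channel_names = channel_names,
            class = c("image2d", "matrix", "array"))
}

#' Calibrated 3D fluorescence stack
#'
#' A Z x Y x X array of non-negative intensities with anisotropic voxel
#' size. Axis order is (z, y, x), 0.2 um z-step by default (spinning-disk
#' confocal acquisition).
#'
#' @param voxels Numeric array with `dim` of length 3, ordered (z, y, x).
#' @param voxel_size_um Numeric length-3 `(dz, dy, dx)` in micrometres.
#' @return An `image_stack3d` object.
#' @export
image_stack3d <- function(voxels, voxel_size_um = c(0.2, 0.065, 0.065)) {
  voxels <- as.array(voxels)
  storage.mode(voxels) <- "double"
  if (length(dim(voxels)) != 3)
    stop("voxels must be a 3D (z, y, x) array", call. = FALSE)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3 || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("voxel_size_um must be three positive reals (dz, dy, dx)",
         call. = FALSE)
  if (any(voxels < 0, na.rm = TRUE))
    stop("voxel intensities must be non-negative", call. = FALSE)
  structure(voxels,
            voxel_size_um = voxel_size_um,
            class = c("image_stack3d", "array"))
}

#' Calcium-imaging movie
#'
#' A T x H x W array of non-negative intensities sampled at a fixed frame
#' rate (4 Hz, 5 min in the source acquisitions).
#'
#' @param frames Numeric array with `dim` of length 3, ordered (t, y, x).
#' @param frame_rate_hz Sampling rate in Hz.
#' @return A `calcium_movie` object with a derived `duration_s` attribute.
#' @export
calcium_movie <- function(frames, frame_rate_hz = 4) {
  frames <- as.array(frames)
  storage.mode(frames) <- "double"
  if (length(dim(frames)) != 3)
    stop("frames must be a 3D (t, y, x) array", call. = FALSE)
  if (dim(frames)[1] < 2)
    stop("a movie needs at least two frames", call. = FALSE)
  stopifnot(is.numeric(frame_rate_hz), length(frame_rate_hz) == 1)
  if (!is.finite(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be positive", call. = FALSE)
  if (any(frames < 0, na.rm = TRUE))
    stop("movie intensities must be non-negative", call. = FALSE)
  structure(frames,
            frame_rate_hz = frame_rate_hz,
            duration_s = dim(frames)[1] / frame_rate_hz,
            class = c("calcium_movie", "array"))
}

#' Gene-by-sample count matrix with group and housekeeping annotation
#'
#' @param counts Numeric gene x sample matrix of non-negative counts with
#'   gene rownames and sample colnames.
#' @param groups Factor or character vector, one group label per sample
#'   (e.g. CTRL / MUT).
#' @param housekeeping_ids Character vector of reference gene ids, a
#'   subset of `rownames(counts)`.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, groups, housekeeping_ids = character()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop("one group label per sample is required", call. = FALSE)
  housekeeping_ids <- as.character(housekeeping_ids)
  missing_hk <- setdiff(housekeeping_ids, rownames(counts))
  if (length(missing_hk))
    stop("housekeeping gene(s) not in the count matrix: ",
         paste(missing_hk, collapse = ", "), call. = FALSE)
  structure(list(counts = counts, groups = groups,
                 housekeeping_ids = housekeeping_ids),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples; groups: ",
      paste(levels(x$groups), table(x$groups), sep = ":", collapse = ", "),
      "; ", length(x$housekeeping_ids), " housekeeping genes\n", sep = "")
  invisible(x)
}

#' @export
print.image2d <- function(x, ...) {
  cat("<image2d> ", nrow(x), " x ", ncol(x), " px, pixel ",
      attr(x, "pixel_size_um"), " um, range [",
      signif(min(x), 3), ", ", signif(max(x), 3), "]\n", sep = "")
  invisible(x)
}

#' @export
print.image_stack3d <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size_um")
  cat("<image_stack3d> ", d[1], " z x ", d[2], " y x ", d[3], " x px, voxel ",
      paste(vs, collapse = " x "), " um\n", sep = "")
  invisible(x)
}

#' @export
print.calcium_movie <- function(x, ...) {
  d <- dim(x)
  cat("<calcium_movie> ", d[1], " frames of ", d[2], " x ", d[3], " px at ",
      attr(x, "frame_rate_hz"), " Hz (", attr(x, "duration_s"), " s)\n",
      sep = "")
  invisible(x)
}

# internal: check an image/stack is on the normalized [0, 1] scale
assert_normalized <- function(x, what = "image") {
  if (min(x) < 0 || max(x) > 1 + 1e-9)
    stop(what, " must be normalized to [0, 1]", call. = FALSE)
  invisible(TRUE)
}
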