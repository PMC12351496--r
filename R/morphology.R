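# R-side wrappers around the compiled morphology kernels.

# connected-component labeling; mask is a logical matrix / 3D array
label_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  if (is.null(connectivity))
    connectivity <- if (length(d) == 2) 8L else 26L
  lab <- cpp_label(as.logical(mask), as.integer(d), as.integer(connectivity))
  n <- attr(lab, "n_labels")
  dim(lab) <- d
  attr(lab, "n_labels") <- n
  lab
}

#' Suppress shallow local minima (H-minima transform)
#'
#' Raises every regional minimum whose depth is below `h` to its
#' surrounding pass level, by grayscale reconstruction-by-erosion of
#' `img + h` constrained above `img` (8-connectivity).  Used as a denoise
#' stage: texture shallower than `h` on the normalized `[0, 1]` scale is
#' flattened, deeper structure is untouched.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param h Minimum depth in `[0, 1]` for a regional minimum to survive.
#' @return Numeric matrix, same shape, clamped to `[0, 1]`.
#' @export
hminima <- function(img, h) {
  stopifnot(h >= 0, h <= 1)
  x <- unclass(as.matrix(img))
  if (h == 0) return(x)
  rec <- cpp_reconstruct_erode(as.numeric(x + h), as.numeric(x),
                               as.integer(dim(x)))
  dim(rec) <- dim(x)
  # a fully flat image has no pass level: the reconstruction stalls at
  # img + h everywhere; return the input unchanged in that case
  if (min(rec - x) >= h - 1e-12) return(x)
  pmin(pmax(rec, 0), 1)
}

# grayscale opening with an axis-aligned box (separable running min/max);
# radius is per-axis half-width in voxels
box_opening <- function(x, radius) {
  d <- dim(x)
  r <- as.integer(rep_len(radius, length(d)))
  er <- cpp_box_extreme(as.numeric(x), as.integer(d), r, TRUE)
  op <- cpp_box_extreme(er, as.integer(d), r, FALSE)
  dim(op) <- d
  op
}

# 2D median filter with an odd square window (size x size), replicated
# border
median_filter2d <- function(img, size = 5L) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L)
    stop("median window size must be odd and >= 1", call. = FALSE)
  if (size == 1L) return(unclass(as.matrix(img)))
  cpp_median_filter2d(unclass(as.matrix(img)), (size - 1L) %/% 2L)
}

# separable Gaussian smoothing along every axis of a 2D/3D array,
# replicate-padded borders; sigma per axis (voxels)
gaussian_smooth <- function(x, sigma) {
  d <- dim(x)
  sigma <- rep_len(sigma, length(d))
  out <- x
  for (ax in seq_along(d)) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# convolve a 2D/3D array with a 1D kernel along axis `ax` (replicate pad)
convolve_axis <- function(x, k, ax) {
  d <- dim(x)
  r <- (length(k) - 1L) %/% 2L
  perm <- c(ax, setdiff(seq_along(d), ax))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  # replicate-pad along the filtered axis
  mpad <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
  f <- stats::filter(mpad, rev(k), method = "convolution", sides = 2)
  f <- f[(r + 1L):(r + dp[1]), , drop = FALSE]
  dim(f) <- dp
  aperm(f, order(perm))
}

# strict 8-neighbourhood local maxima of a matrix (ties broken toward the
# first raster occurrence by requiring >= over earlier and > over later
# neighbours is overkill: plateau handling is done by the greedy
# min-separation step downstream, so >= against all neighbours suffices)
local_maxima2d <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  ok <- matrix(TRUE, ny, nx)
  for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2:(ny + 1)) + di, (2:(nx + 1)) + dj]
    ok <- ok & (m >= nb)
  }
  ok & is.finite(m)
}
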