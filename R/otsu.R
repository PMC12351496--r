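#' Otsu threshold on a fixed 256-bin histogram
#'
#' Finds the intensity cut that maximizes the between-class variance of
#' the histogram of `x` (256 bins over `[0, 1]`).  Candidate thresholds
#' are the bin upper edges; foreground is *strictly above* the returned
#' threshold (ties go to background, a deterministic tie-break).
#'
#' @param x Numeric vector/matrix/array of intensities in `[0, 1]`.
#' @param n_bins Number of histogram bins (fixed at 256 in the pipelines).
#' @return The threshold (scalar).  `NA` for a constant input.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite intensities", call. = FALSE)
  if (min(v) < 0 || max(v) > 1 + 1e-9)
    stop("intensities must be in [0, 1]", call. = FALSE)
  if (max(v) - min(v) <= 0) return(NA_real_)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  # class means from exact per-bin intensity sums, so the result equals
  # an exhaustive search over the 256 candidate cuts on the raw values
  sums <- vapply(split(v, factor(bin, levels = seq_len(n_bins))), sum, 0)
  w0 <- cumsum(counts) / length(v)
  mu <- cumsum(sums) / length(v)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  # between-class variance for cuts after bin k = 1..n_bins-1
  k <- seq_len(n_bins - 1L)
  bcv <- (mu_t * w0[k] - mu[k])^2 / (w0[k] * w1[k])
  bcv[!is.finite(bcv)] <- -Inf
  best <- which.max(bcv)
  edges[best + 1L]                     # upper edge of the best cut bin
}

#' Binarize an image or stack by Otsu's method
#'
#' @param x An [image2d], [image_stack3d], or plain numeric array in
#'   `[0, 1]`.
#' @param n_bins Histogram bins (256).
#' @return Logical mask of the same shape (`TRUE` = foreground).  A
#'   constant input yields an all-background mask with a warning rather
#'   than an error, so degenerate fields of view do not abort a batch.
#' @export
binarize_otsu <- function(x, n_bins = 256L) {
  arr <- unclass(as.array(x))
  thr <- otsu_threshold(arr, n_bins)
  if (is.na(thr)) {
    warning("constant image: Otsu undefined, returning empty foreground",
            call. = FALSE)
    mask <- array(FALSE, dim(arr))
  } else {
    mask <- arr > thr
  }
  attr(mask, "threshold") <- thr
  mask
}
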