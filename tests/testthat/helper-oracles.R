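# Independent brute-force oracles used to validate the fast
# implementations.  They are deliberately naive.

# exhaustive Otsu: try every one of the 256 candidate cuts, computing the
# between-class variance directly from the raw pixel values
oracle_otsu <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  best <- NA_real_
  best_bcv <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    cut <- edges[k + 1L]
    lo <- v[v <= cut]
    hi <- v[v > cut]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bcv > best_bcv + 1e-15) {
      best_bcv <- bcv
      best <- cut
    }
  }
  best
}

# direct sliding-window median with replicated borders
oracle_median2d <- function(img, size) {
  r <- (size - 1L) %/% 2L
  ny <- nrow(img); nx <- ncol(img)
  out <- img
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ii <- pmin(pmax((i - r):(i + r), 1L), ny)
    jj <- pmin(pmax((j - r):(j + r), 1L), nx)
    out[i, j] <- median(img[ii, jj])
  }
  out
}

# direct per-pixel mean over selected planes
oracle_zproject <- function(arr, planes) {
  acc <- arr[planes[1], , ]
  for (p in planes[-1]) acc <- acc + arr[p, , ]
  acc / length(planes)
}

# naive O(n^3) agglomerative average linkage on a distance matrix
oracle_average_linkage <- function(d) {
  n <- nrow(d)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      ma <- members[[active[a]]]; mb <- members[[active[b]]]
      dd <- mean(d[ma, mb])
      if (dd < best_d - 1e-12) {
        best_d <- dd; best <- c(a, b)
      }
    }
    heights <- c(heights, best_d)
    new_members <- c(members[[active[best[1]]]], members[[active[best[2]]]])
    members[[length(members) + 1]] <- new_members
    active <- c(active[-best], length(members))
  }
  heights
}

# brute-force synchrony with the same definition as network_metrics:
# max over bins of the number of distinct cells peaking in the bin,
# over the number of active cells
oracle_synchrony <- function(event_times_by_cell, bin_s, n_active) {
  bins <- unlist(lapply(event_times_by_cell, function(tt) floor(tt / bin_s)))
  cells <- rep(seq_along(event_times_by_cell),
               lengths(event_times_by_cell))
  if (!length(bins)) return(0)
  co <- tapply(cells, bins, function(x) length(unique(x)))
  max(co) / n_active
}

# match detected events to planted ones by cell and peak time
match_events <- function(det, truth_events, tol_s = 3) {
  tp <- 0
  for (i in seq_len(nrow(det))) {
    te <- truth_events[truth_events$cell_id == det$cell_id[i], ]
    if (nrow(te) && any(abs(te$time_s - det$peak_time_s[i]) < tol_s))
      tp <- tp + 1
  }
  tp
}

# map detected ROIs to ground-truth cells (NA when > tol_px away)
map_rois_to_cells <- function(rois, centers, tol_px = 4) {
  vapply(seq_len(nrow(rois)), function(i) {
    d2 <- (centers$y - rois$y[i])^2 + (centers$x - rois$x[i])^2
    if (min(d2) <= tol_px^2) centers$cell_id[which.min(d2)] else NA_integer_
  }, integer(1))
}
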