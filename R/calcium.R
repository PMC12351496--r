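# Calcium-imaging pipeline: activity-map cell detection, dF/F0 trace
# extraction, transient detection with exponential kinetics, fast/slow
# classification at tau* = 1.5 s, and network-level metrics.

#' Cumulative frame-difference activity map
#'
#' Sums the absolute frame-to-frame difference over the movie and removes
#' high-frequency spatial noise by multiplying the 2D Fourier transform
#' with a Gaussian low-pass of the given cutoff (cycles/pixel).  Active
#' cells appear as smooth bright blobs.
#'
#' @param movie A [calcium_movie] (`T >= 2`).
#' @param lowpass_cutoff Gaussian cutoff in cycles/pixel (0.1 default);
#'   `Inf` disables filtering.
#' @return An [image2d] activity map (non-negative).
#' @export
activity_map <- function(movie, lowpass_cutoff = 0.1) {
  stopifnot(inherits(movie, "calcium_movie"))
  d <- dim(movie)
  if (d[1] < 2) stop("need at least two frames", call. = FALSE)
  arr <- unclass(movie)
  m <- apply(abs(arr[-1, , , drop = FALSE] - arr[-d[1], , , drop = FALSE]),
             c(2, 3), sum)
  if (is.finite(lowpass_cutoff)) {
    fy <- fft_freq(nrow(m)); fx <- fft_freq(ncol(m))
    g <- exp(-outer(fy^2, fx^2, `+`) / (2 * lowpass_cutoff^2))
    m <- Re(fft(fft(m) * g, inverse = TRUE)) / length(m)
  }
  image2d(pmax(m, 0), pixel_size_um = 1)
}

# DFT sample frequencies in cycles per sample
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

#' Detect cell positions on an activity map
#'
#' Local maxima above an adaptive floor (`median + k_mad * MAD`) are
#' accepted greedily in descending map value, enforcing a minimum
#' pairwise separation; of two peaks closer than that, the higher one
#' wins.
#'
#' @param map [image2d] from [activity_map()].
#' @param min_separation_px Minimum pairwise centre distance.
#' @param n_max Keep at most this many ROIs.
#' @param radius_px ROI disk radius used downstream.
#' @param k_mad Floor stringency in MAD units.
#' @return A `roi_set`: tibble (`roi_id`, `y`, `x`) with attribute
#'   `radius_px`.  May be empty.
#' @export
detect_cells <- function(map, min_separation_px = 6L, n_max = Inf,
                         radius_px = 4L, k_mad = 5) {
  m <- unclass(as.matrix(map))
  floor_v <- median(m) + k_mad * stats::mad(m)
  cand <- which(local_maxima2d(m) & m > floor_v, arr.ind = TRUE)
  centers <- matrix(numeric(0), 0, 2)
  if (nrow(cand)) {
    ord <- order(m[cand], decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      p <- cand[i, ]
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >=
              min_separation_px)) {
        centers <- rbind(centers, p)
        if (nrow(centers) >= n_max) break
      }
    }
  }
  rois <- tibble::tibble(roi_id = seq_len(nrow(centers)),
                         y = as.integer(centers[, 1]),
                         x = as.integer(centers[, 2]))
  structure(rois, radius_px = as.integer(radius_px),
            class = c("roi_set", class(rois)))
}

#' Apply a reproducible ROI edits record
#'
#' Manual curation of false or missed detections is captured as a JSON
#' file (or list) with `add` (list of `{y, x}` centres) and `remove`
#' (roi ids), so curated analyses re-run identically.
#'
#' @param rois A `roi_set` from [detect_cells()].
#' @param edits List or path to a JSON file.
#' @return The edited `roi_set` (ids re-numbered consecutively).
#' @export
apply_roi_edits <- function(rois, edits) {
  if (is.character(edits)) edits <- jsonlite::read_json(edits,
                                                        simplifyVector = TRUE)
  radius <- attr(rois, "radius_px")
  out <- tibble::as_tibble(rois)
  if (!is.null(edits$remove) && length(edits$remove))
    out <- out[!(out$roi_id %in% edits$remove), ]
  if (!is.null(edits$add)) {
    add <- as.data.frame(edits$add)
    if (nrow(add))
      out <- dplyr::bind_rows(out,
                              tibble::tibble(roi_id = NA_integer_,
                                             y = as.integer(add$y),
                                             x = as.integer(add$x)))
  }
  out$roi_id <- seq_len(nrow(out))
  structure(out, radius_px = radius, class = c("roi_set", class(out)))
}

#' Extract and normalize dF/F0 traces
#'
#' Per ROI: the raw trace is the mean intensity inside the ROI disk, the
#' baseline F0 is a running percentile (10th by default) over a sliding
#' window (30 s), dF/F0 = (F - F0)/F0, then a centred moving average
#' (0.75 s = 3 frames at 4 Hz) smooths the trace.  Traces where F0 is not
#' strictly positive anywhere are flagged invalid.
#'
#' @param movie A [calcium_movie].
#' @param rois A `roi_set`.
#' @param baseline_window_s,baseline_percentile Running-percentile
#'   baseline parameters.
#' @param smooth_window_s Moving-average window in seconds.
#' @return A `dff_traces` object: `dff` (T x n matrix), `f0`, `raw`,
#'   `valid`, `frame_rate_hz`, `rois`, `smooth_window_frames`.
#' @export
extract_and_normalize <- function(movie, rois, baseline_window_s = 30,
                                  baseline_percentile = 0.1,
                                  smooth_window_s = 0.75) {
  stopifnot(inherits(movie, "calcium_movie"))
  rate <- attr(movie, "frame_rate_hz")
  d <- dim(movie)
  n_t <- d[1]
  flat <- matrix(unclass(movie), nrow = n_t)  # T x (H*W), column-major (y,x)
  radius <- attr(rois, "radius_px")
  disk <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  disk <- disk[disk$dy^2 + disk$dx^2 <= radius^2, ]
  n_roi <- nrow(rois)
  raw <- matrix(0, n_t, max(n_roi, 0))
  for (r in seq_len(n_roi)) {
    ys <- rois$y[r] + disk$dy
    xs <- rois$x[r] + disk$dx
    ok <- ys >= 1 & ys <= d[2] & xs >= 1 & xs <= d[3]
    raw[, r] <- rowMeans(flat[, ys[ok] + (xs[ok] - 1) * d[2], drop = FALSE])
  }
  w <- round(baseline_window_s * rate)
  if (w %% 2 == 0) w <- w + 1
  w <- min(w, n_t)
  # the percentile is taken over a 1-s pre-smoothed trace so shot noise
  # does not drag the baseline below the true resting fluorescence
  pre <- max(1L, round(rate)); if (pre %% 2 == 0) pre <- pre + 1L
  f0 <- apply(raw, 2, function(v)
    zoo::rollapply(moving_average(v, pre), width = w, FUN = quantile,
                   probs = baseline_percentile, names = FALSE,
                   partial = TRUE, align = "center"))
  f0 <- matrix(f0, nrow = n_t)
  valid <- apply(f0, 2, function(v) all(v > 0))
  dff <- matrix(0, n_t, n_roi)
  dff[, valid] <- (raw[, valid, drop = FALSE] - f0[, valid, drop = FALSE]) /
    f0[, valid, drop = FALSE]
  sw <- max(1L, round(smooth_window_s * rate))
  if (sw %% 2 == 0) sw <- sw + 1L
  dff_raw <- dff
  if (sw > 1) dff <- apply(dff, 2, moving_average, w = sw)
  dff <- matrix(dff, nrow = n_t)
  # the smoothed trace drives detection; kinetics are fitted on the
  # unsmoothed one (the moving average would bias the rise time)
  structure(list(dff = dff, dff_raw = dff_raw, f0 = f0, raw = raw,
                 valid = valid, frame_rate_hz = rate, rois = rois,
                 smooth_window_frames = sw),
            class = "dff_traces")
}

# centred moving average with replicated ends
moving_average <- function(v, w) {
  r <- (w - 1L) %/% 2L
  pad <- c(rep(v[1], r), v, rep(v[length(v)], r))
  as.numeric(stats::filter(pad, rep(1 / w, w), sides = 2))[(r + 1):(r + length(v))]
}

#' @export
print.dff_traces <- function(x, ...) {
  cat("<dff_traces> ", ncol(x$dff), " ROIs x ", nrow(x$dff), " frames at ",
      x$frame_rate_hz, " Hz (", sum(x$valid), " valid)\n", sep = "")
  invisible(x)
}

#' Detect calcium transients in a dF/F0 trace
#'
#' A transient starts where both the trace value and its slope increase,
#' peaks at a local maximum, and ends where the slope turns from negative
#' to flat (or the maximum onset-offset interval is reached).  The event
#' amplitude is the peak dF/F0 relative to the trace value at onset
#' (identical to the raw peak on a clean baseline, robust to residual
#' baseline offset otherwise); candidate peaks below the amplitude
#' threshold (2% dF/F0 by default) are discarded and accepted events do
#' not overlap (higher peaks win).
#'
#' @param values Numeric dF/F0 trace (already smoothed).
#' @param frame_rate_hz Sampling rate.
#' @param amplitude_threshold Minimum peak dF/F0 (default 0.02).
#' @param max_event_s Maximum onset-to-offset interval in seconds.
#' @param noise_floor_k Multiplier of the robust trace-noise estimate
#'   (MAD of first differences) below which peaks are never accepted;
#'   the effective threshold is `max(amplitude_threshold, noise_floor_k *
#'   sigma_hat)`, so on clean traces the stated absolute threshold
#'   governs while noisy traces do not flood the event list.
#' @return Tibble of events: `onset_idx`, `peak_idx`, `offset_idx`,
#'   `amplitude` (peak dF/F0), ordered by onset.
#' @export
detect_transients <- function(values, frame_rate_hz = 4,
                              amplitude_threshold = 0.02, max_event_s = 10,
                              noise_floor_k = 10) {
  x <- as.numeric(values)
  n <- length(x)
  empty <- tibble::tibble(onset_idx = integer(), peak_idx = integer(),
                          offset_idx = integer(), amplitude = numeric())
  if (n < 3) return(empty)
  max_f <- max(2L, round(max_event_s * frame_rate_hz))
  sigma_hat <- 1.4826 * median(abs(diff(x))) / sqrt(2)
  thr <- max(amplitude_threshold, noise_floor_k * sigma_hat)
  slack <- 0.25 * thr                   # tolerated counter-slope wiggle
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                 x[2:(n - 1)] >= x[3:n], FALSE)
  peaks <- which(is_peak)
  if (!length(peaks)) return(empty)
  peaks <- peaks[order(x[peaks], decreasing = TRUE)]
  taken <- rep(FALSE, n)
  ev <- list()
  for (p in peaks) {
    if (taken[p]) next
    # onset: walk back down the rising edge to its foot; a short wiggle
    # budget tolerates single-frame noise dips without wandering off
    # along the flat baseline
    on <- p
    wiggle <- 0L
    while (on > 1 && p - on < max_f && !taken[on - 1]) {
      if (x[on - 1] < x[on]) {
        wiggle <- 0L
      } else if (x[on - 1] <= x[on] + slack && wiggle < 2L) {
        wiggle <- wiggle + 1L
      } else break
      on <- on - 1
    }
    seg <- on:min(on + 3L, p)
    on <- seg[which.min(x[seg])]
    amp <- x[p] - x[on]
    if (amp < thr) next
    # offset: walk forward along the decay until the slope turns back up
    off <- p
    wiggle <- 0L
    while (off < n && off - on < max_f && !taken[off + 1] &&
           x[off] - x[on] >= 0.05 * amp) {
      if (x[off + 1] < x[off]) {
        wiggle <- 0L
      } else if (x[off + 1] <= x[off] + slack && wiggle < 2L) {
        wiggle <- wiggle + 1L
      } else break
      off <- off + 1
    }
    ev[[length(ev) + 1]] <- c(on, p, off, amp)
    taken[on:off] <- TRUE
  }
  if (!length(ev)) return(empty)
  ev <- do.call(rbind, ev)
  ord <- order(ev[, 1])
  tibble::tibble(onset_idx = as.integer(ev[ord, 1]),
                 peak_idx = as.integer(ev[ord, 2]),
                 offset_idx = as.integer(ev[ord, 3]),
                 amplitude = ev[ord, 4])
}

# peak value of the normalized transient kernel (1 - e^(-t/tr)) e^(-t/td)
kernel_peak_value <- function(tau_r, tau_d) {
  tp <- tau_r * log(1 + tau_d / tau_r)
  (1 - exp(-tp / tau_r)) * exp(-tp / tau_d)
}

#' Fit exponential kinetics to one transient
#'
#' Least-squares fit of `A (1 - exp(-(t - t0)/tau_r)) exp(-(t - t0)/tau_d)`
#' over the event window; the reported amplitude is the fitted peak
#' dF/F0, `rise_time_s = tau_r`, `decay_time_s = tau_d`.  When a segment
#' has fewer than 3 points, the fit fails to converge, or the residual
#' norm exceeds `tol` times the peak, `fit_ok` is `FALSE` and the
#' amplitude falls back to the raw peak value.
#'
#' @param values dF/F0 trace.
#' @param event One-row event (as from [detect_transients()]) or a list
#'   with `onset_idx`, `peak_idx`, `offset_idx`.
#' @param frame_rate_hz Sampling rate.
#' @param tol Relative residual tolerance for `fit_ok`.
#' @param pre_frames Pre-onset context included in the fit window (the
#'   detected onset sits partway up a slow rise, so the free start time
#'   `t0` needs room to slide back; clipped at the previous event).
#' @param smooth_window_frames When `values` is a moving-average-smoothed
#'   trace, the same window length here convolves the model with that
#'   average so the smoothing does not bias the fitted kinetics.
#' @param tr_range,td_range Box constraints on the time constants (s).
#'   Rise constants beyond the observable event window (capped at 10 s
#'   by default) are not identifiable, so the default caps keep single
#'   noisy events from sliding along the rise/decay trade-off ridge.
#' @return One-row tibble: event indices plus `amplitude`, `rise_time_s`,
#'   `decay_time_s`, `fit_ok`.
#' @export
fit_transient <- function(values, event, frame_rate_hz = 4, tol = 0.25,
                          pre_frames = 8L, smooth_window_frames = 1L,
                          tr_range = c(1e-3, 20), td_range = c(1e-3, 60)) {
  x <- as.numeric(values)
  on <- event$onset_idx; pk <- event$peak_idx; off <- event$offset_idx
  raw_peak <- x[pk] - x[on]
  fallback <- tibble::tibble(onset_idx = on, peak_idx = pk, offset_idx = off,
                             amplitude = raw_peak, rise_time_s = NA_real_,
                             decay_time_s = NA_real_, fit_ok = FALSE)
  if (pk - on + 1 < 3 || off - pk + 1 < 3) return(fallback)
  ext <- max(1L, on - as.integer(pre_frames))
  # local baseline from the samples nearest the onset: the wider
  # pre-window can still carry the previous transient's tail
  b <- median(x[max(ext, on - 2L):on])
  idx <- ext:off
  t <- (idx - ext) / frame_rate_hz
  y <- x[idx] - b
  t0s <- (on - ext) / frame_rate_hz
  tr0 <- max((pk - on) / frame_rate_hz / 2, 0.8 / frame_rate_hz)
  td0 <- max((off - pk) / frame_rate_hz / 2, 1 / frame_rate_hz)
  a0 <- raw_peak / kernel_peak_value(tr0, td0)
  # model: transient kernel, convolved with the same moving average as
  # the data when the trace is smoothed
  sw <- max(1L, as.integer(smooth_window_frames))
  offs <- (seq_len(sw) - (sw + 1) / 2) / frame_rate_hz
  # b1 absorbs the slow tilt the running-percentile baseline leaves in
  # the local window (it biases the rise constant upward otherwise)
  kfun <- function(t, A, tr, td, t0, b1) {
    out <- 0
    for (o in offs) {
      u <- pmax(t + o - t0, 0)
      out <- out + A * (1 - exp(-u / tr)) * exp(-u / td)
    }
    out / sw + b1 * t
  }
  # t0 absorbs the offset between the window start and the true transient
  # start
  clamp <- function(v, r) min(max(v, r[1]), r[2])
  starts <- list(
    list(A = a0, tr = clamp(tr0, tr_range), td = clamp(td0, td_range),
         t0 = t0s + 0.1, b1 = 0),
    list(A = a0, tr = clamp(tr0, tr_range), td = clamp(td0, td_range),
         t0 = t0s, b1 = 0),
    list(A = 1.5 * a0, tr = clamp(1.5 * tr0, tr_range),
         td = clamp(0.7 * td0, td_range), t0 = t0s + 0.05, b1 = 0),
    list(A = a0, tr = clamp(2 / frame_rate_hz, tr_range),
         td = clamp(2, td_range), t0 = t0s + 0.1, b1 = 0))
  t0_hi <- t0s + max(3, 2 * (pk - on) / frame_rate_hz)
  fit <- fit_kernel_ls(t, y, kfun, starts,
                       lower = c(A = 0, tr = tr_range[1], td = td_range[1],
                                 t0 = 0, b1 = -0.05),
                       upper = c(A = Inf, tr = tr_range[2], td = td_range[2],
                                 t0 = t0_hi, b1 = 0.05))
  if (is.null(fit)) return(fallback)
  cf <- fit$coef
  amp_fit <- cf[["A"]] * kernel_peak_value(cf[["tr"]], cf[["td"]])
  ok <- is.finite(amp_fit) && amp_fit > 0 &&
    fit$resid_norm <= tol * max(raw_peak, 1e-12)
  if (!ok) return(fallback)
  tibble::tibble(onset_idx = on, peak_idx = pk, offset_idx = off,
                 amplitude = amp_fit, rise_time_s = cf[["tr"]],
                 decay_time_s = cf[["td"]], fit_ok = TRUE)
}

# least-squares kernel fit tried from several starts; the best-deviance
# converged fit wins (the LM optimizer can stall or report a singular
# gradient from an unlucky initialization)
fit_kernel_ls <- function(t, y, kfun, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(
        y ~ kfun(t, A, tr, td, t0, b1), start = st, lower = lower,
        upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300))),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || stats::deviance(fit) < stats::deviance(best)))
      best <- fit
  }
  if (is.null(best)) return(NULL)
  list(coef = coef(best),
       resid_norm = sqrt(mean(stats::residuals(best)^2)))
}

# detect + fit all events of all traces; returns tibble with roi_id.
# Detection runs on the display-smoothed trace; the kinetics fit uses a
# slightly wider moving average (with the model convolved to match), the
# noise/identifiability sweet spot for both fast and slow kernels.
detect_and_fit_events <- function(traces, amplitude_threshold = 0.02,
                                  max_event_s = 10, noise_floor_k = 10,
                                  fit_smooth_window_s = 1.25) {
  rate <- traces$frame_rate_hz
  wf <- max(1L, round(fit_smooth_window_s * rate))
  if (wf %% 2 == 0) wf <- wf + 1L
  out <- lapply(seq_len(ncol(traces$dff)), function(r) {
    if (!traces$valid[r]) return(NULL)
    v <- traces$dff[, r]
    ev <- detect_transients(v, rate, amplitude_threshold, max_event_s,
                            noise_floor_k)
    if (!nrow(ev)) return(NULL)
    vf <- if (!is.null(traces$dff_raw))
      moving_average(traces$dff_raw[, r], wf) else v
    wfit <- if (!is.null(traces$dff_raw)) wf else traces$smooth_window_frames
    prev_off <- c(0L, ev$offset_idx[-nrow(ev)])
    fitted <- dplyr::bind_rows(lapply(seq_len(nrow(ev)), function(i)
      fit_transient(vf, ev[i, ], rate,
                    pre_frames = max(0L, min(8L, ev$onset_idx[i] -
                                               prev_off[i] - 1L)),
                    smooth_window_frames = wfit)))
    fitted$roi_id <- traces$rois$roi_id[r]
    fitted
  })
  ev <- dplyr::bind_rows(out)
  if (!nrow(ev))
    ev <- tibble::tibble(onset_idx = integer(), peak_idx = integer(),
                         offset_idx = integer(), amplitude = numeric(),
                         rise_time_s = numeric(), decay_time_s = numeric(),
                         fit_ok = logical(), roi_id = integer())
  ev$peak_time_s <- (ev$peak_idx - 1) / rate
  dplyr::relocate(ev, "roi_id")
}

#' Classify cells as fast (neuronal) or slow
#'
#' A cell is *fast* iff the median rise time of its fitted transients is
#' strictly below `tau_star_s` (1.5 s); cells at exactly the threshold,
#' with no events, or with no successful fits are *slow*.  Slow signals
#' (internal stores, non-neuronal cells) are excluded from the network
#' metrics.
#'
#' @param events Event tibble from [detect_and_fit_events()] (or any
#'   tibble with `roi_id`, `rise_time_s`, `fit_ok`).
#' @param rois The `roi_set` the events came from.
#' @param duration_s Movie duration in seconds (for event rates).
#' @param tau_star_s Rise-time threshold in seconds.
#' @return Tibble of cells: `roi_id`, `n_events`, `event_rate_per_min`,
#'   `median_rise_s`, `mean_amplitude`, `cell_class`.
#' @export
classify_cells <- function(events, rois, duration_s, tau_star_s = 1.5) {
  base <- tibble::tibble(roi_id = rois$roi_id)
  if (nrow(events)) {
    per <- events |>
      dplyr::group_by(.data$roi_id) |>
      dplyr::summarise(
        n_events = dplyr::n(),
        median_rise_s = median(.data$rise_time_s[.data$fit_ok]),
        mean_amplitude = mean(.data$amplitude),
        .groups = "drop")
  } else {
    per <- tibble::tibble(roi_id = integer(), n_events = integer(),
                          median_rise_s = numeric(),
                          mean_amplitude = numeric())
  }
  cells <- dplyr::left_join(base, per, by = "roi_id")
  cells$n_events[is.na(cells$n_events)] <- 0L
  cells$event_rate_per_min <- cells$n_events / (duration_s / 60)
  cells$cell_class <- ifelse(
    !is.na(cells$median_rise_s) & cells$median_rise_s < tau_star_s,
    "fast", "slow")
  cells
}

#' Network-level activity metrics
#'
#' Only fast cells with at least one event ("active" cells) enter the
#' frequency, amplitude and synchrony summaries; the active fraction uses
#' all detected ROIs as denominator.  Synchrony is the peak co-activation
#' fraction: the maximum, over time bins, of the number of distinct
#' active cells with an event peak in the same bin, divided by the number
#' of active cells (`"mean"` averages the per-bin fraction over bins that
#' contain at least one event instead).
#'
#' @param cells Tibble from [classify_cells()].
#' @param events Event tibble (with `roi_id`, `peak_time_s`).
#' @param duration_s Movie duration (s).
#' @param sync_bin_s Synchrony bin width (s).
#' @param sync_method `"peak"` (default) or `"mean"` co-activation.
#' @return One-row tibble: `n_cells_total`, `n_active_fast`,
#'   `active_fraction`, `mean_frequency_per_min`, `mean_amplitude`,
#'   `synchrony`.
#' @export
network_metrics <- function(cells, events, duration_s, sync_bin_s = 1,
                            sync_method = c("peak", "mean")) {
  sync_method <- match.arg(sync_method)
  n_total <- nrow(cells)
  active <- cells[cells$cell_class == "fast" & cells$n_events > 0, ]
  n_active <- nrow(active)
  if (n_active == 0) {
    warning("no active fast cells: network metrics are zero", call. = FALSE)
    return(tibble::tibble(n_cells_total = n_total, n_active_fast = 0L,
                          active_fraction = 0, mean_frequency_per_min = 0,
                          mean_amplitude = 0, synchrony = 0))
  }
  ev <- events[events$roi_id %in% active$roi_id, ]
  bins <- floor(ev$peak_time_s / sync_bin_s)
  co <- tapply(ev$roi_id, bins, function(ids) length(unique(ids)))
  sync <- if (sync_method == "peak") max(co) / n_active
          else mean(co) / n_active
  tibble::tibble(
    n_cells_total = n_total,
    n_active_fast = n_active,
    active_fraction = n_active / n_total,
    mean_frequency_per_min = mean(active$event_rate_per_min),
    mean_amplitude = mean(ev$amplitude),
    synchrony = sync)
}

#' Full calcium-imaging analysis of one movie
#'
#' Activity map, cell detection (with optional reproducible manual
#' edits), dF/F0 extraction, transient detection and kinetics, fast/slow
#' classification, and network metrics.
#'
#' @param movie A [calcium_movie].
#' @param config The `calcium` group of [default_config()] (any subset of
#'   its fields).
#' @param edits Optional ROI edits (list or JSON path), see
#'   [apply_roi_edits()].
#' @return A `calcium_result`: list with `map`, `rois`, `traces`,
#'   `events`, `cells`, `metrics`.  [tidy()] returns the event table,
#'   [glance()] the network metrics.
#' @export
analyze_calcium <- function(movie, config = list(), edits = NULL) {
  cfg <- default_config()$calcium
  cfg[names(config)] <- config
  map <- activity_map(movie, cfg$lowpass_cutoff)
  rois <- detect_cells(map, min_separation_px = cfg$min_separation_px,
                       radius_px = cfg$roi_radius_px, k_mad = cfg$detect_k_mad)
  if (!is.null(edits)) rois <- apply_roi_edits(rois, edits)
  traces <- extract_and_normalize(movie, rois,
                                  baseline_window_s = cfg$baseline_window_s,
                                  baseline_percentile = cfg$baseline_percentile,
                                  smooth_window_s = cfg$smooth_window_s)
  events <- detect_and_fit_events(traces, cfg$amplitude_threshold,
                                  cfg$max_event_s, cfg$noise_floor_k,
                                  cfg$fit_smooth_window_s)
  duration <- attr(movie, "duration_s")
  cells <- classify_cells(events, rois, duration, cfg$tau_star_s)
  metrics <- suppressWarnings(
    network_metrics(cells, events, duration, cfg$sync_bin_s))
  structure(list(map = map, rois = rois, traces = traces, events = events,
                 cells = cells, metrics = metrics),
            class = "calcium_result")
}

#' @export
print.calcium_result <- function(x, ...) {
  cat("<calcium_result> ", nrow(x$rois), " ROIs, ", nrow(x$events),
      " events; active fraction ", signif(x$metrics$active_fraction, 3),
      ", synchrony ", signif(x$metrics$synchrony, 3), "\n", sep = "")
  invisible(x)
}
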