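# TIFF / CSV / YAML i/o.  Calibration lives in legends and lab notebooks,
# not in the files, so it is always supplied (or defaulted) by the caller;
# a YAML sidecar read by the CLI can override TIFF resolution tags.

#' Read a TIFF image, stack, or movie
#'
#' Reads a single- or multi-page TIFF (or an ordered series of TIFF files)
#' into a calibrated container.  Integer data are normalized to `[0, 1]`
#' by the TIFF reader (division by the dtype maximum); axis order is
#' normalized to (z or t, y, x).
#'
#' @param path A TIFF file, a directory of TIFF files (read in sorted
#'   order), or a character vector of TIFF paths.
#' @param kind One of `"auto"`, `"image2d"`, `"stack"`, `"movie"`.  With
#'   `"auto"`, a single page becomes an [image2d] and multiple pages a
#'   stack; movies must be requested explicitly.
#' @param pixel_size_um,voxel_size_um,frame_rate_hz Calibration; see
#'   [image2d], [image_stack3d], [calcium_movie].
#' @param channel For multi-channel pages, the channel index to keep.
#' @return An [image2d], [image_stack3d] or [calcium_movie].
#' @export
read_image <- function(path, kind = c("auto", "image2d", "stack", "movie"),
                       pixel_size_um = 0.065,
                       voxel_size_um = c(0.2, 0.065, 0.065),
                       frame_rate_hz = 4, channel = 1L) {
  kind <- match.arg(kind)
  paths <- path
  if (length(path) == 1 && dir.exists(path))
    paths <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
  if (!length(paths) || !all(file.exists(paths)))
    stop("cannot read TIFF input: ", paste(path, collapse = ", "),
         call. = FALSE)
  pages <- list()
  for (p in paths) {
    pg <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pg)) pg <- list(pg)
    pages <- c(pages, pg)
  }
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3) m <- m[, , channel]
    m
  })
  if (kind == "auto") kind <- if (length(pages) == 1) "image2d" else "stack"
  if (kind == "image2d") {
    if (length(pages) != 1)
      stop("multi-page input cannot be a single 2D image", call. = FALSE)
    return(image2d(pages[[1]], pixel_size_um = pixel_size_um))
  }
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  if (kind == "stack") image_stack3d(arr, voxel_size_um = voxel_size_um)
  else calcium_movie(arr, frame_rate_hz = frame_rate_hz)
}

#' Write an image, stack, or movie to (multi-page) TIFF
#'
#' @param x An [image2d], [image_stack3d] or [calcium_movie] (values in
#'   `[0, 1]`).
#' @param path Output file.
#' @param bits Bits per sample; 8 or 16 write integer TIFF (round-trip
#'   exact for data quantized on that grid), 32 writes float.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, bits = 16L) {
  if (inherits(x, "image2d")) {
    pages <- list(unclass(x))
  } else {
    d <- dim(x)
    pages <- lapply(seq_len(d[1]), function(i) {
      m <- unclass(x)[i, , ]
      dim(m) <- d[2:3]
      m
    })
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read a gene x sample count matrix from CSV
#'
#' Expected layout: a `gene_id` column followed by one column per sample;
#' an optional annotation row with `gene_id == "group"` carries the group
#' label of each sample (otherwise pass `groups`).
#'
#' @param path CSV file.
#' @param housekeeping_ids Declared reference genes; all must be present.
#' @param groups Optional group labels (overrides any annotation row).
#' @return A [count_matrix].
#' @export
read_counts <- function(path, housekeeping_ids = character(), groups = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    stop("count CSV needs a gene_id column", call. = FALSE)
  grow <- df$gene_id == "group"
  if (is.null(groups)) {
    if (!any(grow))
      stop("no group annotation row and no groups argument", call. = FALSE)
    groups <- as.character(unlist(df[which(grow)[1], -1]))
  }
  df <- df[!grow, , drop = FALSE]
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "double"
  rownames(counts) <- df$gene_id
  missing_hk <- setdiff(housekeeping_ids, rownames(counts))
  if (length(missing_hk))
    stop("declared housekeeping gene(s) missing from ", path, ": ",
         paste(missing_hk, collapse = ", "), call. = FALSE)
  count_matrix(counts, groups, housekeeping_ids)
}

#' Write a [count_matrix] to CSV (with a group annotation row)
#'
#' @param cm A [count_matrix].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  header <- data.frame(gene_id = "group",
                       as.list(setNames(as.character(cm$groups),
                                        colnames(cm$counts))),
                       check.names = FALSE)
  body <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                     check.names = FALSE)
  write.csv(rbind(header, body), path, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table from CSV
#'
#' @param path CSV with columns `sample_label`, `gene_id`, `ct_value`.
#' @return A tibble with those columns.
#' @export
read_ct_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_label", "gene_id", "ct_value")
  if (!all(need %in% names(df)))
    stop("Ct CSV needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$ct_value)))
    stop("non-finite Ct values", call. = FALSE)
  tibble::as_tibble(df[need])
}

#' Default analysis configuration
#'
#' One nested list holding every tunable of the four pipelines, with the
#' published value wherever the source protocol states one.  Serializes
#' round-trip-identical through YAML ([write_config()] / [read_config()]).
#'
#' @return A named list of parameter groups.
#' @export
default_config <- function() {
  list(
    markers2d = list(
      n_planes = 20L,
      median_size_px = 5L,
      hminima_depth = 0.05,
      clahe_clip = 0.01,
      clahe_tile_px = 64L,
      background_method = "histogram_peak_offset",
      background_peak_fraction = 0.5
    ),
    neurite3d = list(
      gaussian_sigma_px = 3,
      frangi_scale_px = 10,
      frangi_alpha = 0.5,
      frangi_beta = 0.5,
      frangi_gamma = NA,          # NA -> half the maximum Hessian norm
      background_ball_radius_px = NA,  # NA -> 2 * frangi_scale_px
      deconvolve = FALSE,
      deconv_sigma_px = 2,
      min_voxels = 1L
    ),
    calcium = list(
      frame_rate_hz = 4,
      lowpass_cutoff = 0.1,
      detect_k_mad = 5,
      min_separation_px = 6L,
      roi_radius_px = 4L,
      baseline_window_s = 30,
      baseline_percentile = 0.1,
      smooth_window_s = 0.75,
      fit_smooth_window_s = 1.25,
      amplitude_threshold = 0.02,
      noise_floor_k = 10,
      max_event_s = 10,
      tau_star_s = 1.5,
      sync_bin_s = 1
    ),
    expression = list(
      min_avg_count = 450,
      alpha = 0.05,
      fc_up = 1.5,
      fc_down = 0.66,
      log_scale_tests = TRUE,
      ref_gene = "ATP5O"
    )
  )
}

#' @rdname default_config
#' @param config A configuration list.
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (grp in names(base))
    if (!is.null(cfg[[grp]]))
      base[[grp]][names(cfg[[grp]])] <- cfg[[grp]]
  base
}

# one structured record per pipeline stage (printed when
# options(organoidquant.verbose = TRUE))
log_stage <- function(stage, params = list(), expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- force(expr)
  if (isTRUE(getOption("organoidquant.verbose"))) {
    ps <- if (length(params))
      paste(names(params), vapply(params, function(p)
        paste(format(p), collapse = ","), ""), sep = "=", collapse = " ")
    else ""
    message(sprintf("[%s] %s elapsed=%.2fs", stage, ps,
                    proc.time()[["elapsed"]] - t0))
  }
  value
}
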