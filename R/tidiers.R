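# broom-style tidiers for the result objects

#' @export
tidy.de_table <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.de_table <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 n_up = sum(x$call == "up"),
                 n_down = sum(x$call == "down"),
                 alpha = attr(x, "alpha"),
                 fc_up = attr(x, "fc_up"),
                 fc_down = attr(x, "fc_down"))
}

#' @export
tidy.calcium_result <- function(x, ...) x$events

#' @export
glance.calcium_result <- function(x, ...) x$metrics

#' @export
tidy.skeleton_stats <- function(x, ...) x$fragments

#' @export
glance.skeleton_stats <- function(x, ...) {
  tibble::tibble(n_fragments = x$n_fragments,
                 mean_length_um = x$mean_length_um,
                 volume_um3 = x$volume_um3)
}

#' @export
tidy.object_stats <- function(x, ...) x$objects

#' @export
glance.object_stats <- function(x, ...) {
  tibble::tibble(n_objects = x$n_objects,
                 mean_length_um = x$mean_length_um)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  m <- x$tree$merge
  tibble::tibble(merge = seq_len(nrow(m)), left = m[, 1], right = m[, 2],
                 height = x$merge_heights)
}

#' @export
tidy.normalization_report <- function(x, ...) x$scale_factors

#' @export
glance.normalization_report <- function(x, ...) {
  tibble::tibble(n_retained_housekeeping = length(x$retained_housekeeping),
                 min_avg_count = x$min_avg_count)
}
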