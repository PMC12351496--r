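# NanoString-style count normalization, fold-change differential
# expression, average-linkage/Pearson clustering, and qPCR relative
# expression (2^-dCt).

geometric_mean <- function(x) exp(mean(log(x)))

#' Housekeeping geometric-mean normalization
#'
#' Retains the declared housekeeping genes whose cross-sample mean count
#' exceeds `min_avg_count` (450 in the published analysis, which kept 7
#' of 10 reference genes), computes each sample's geometric mean over the
#' retained set, and rescales every sample so those geometric means are
#' equal (to the grand geometric mean).
#'
#' @param cm A [count_matrix].
#' @param min_avg_count Average-count filter for reference genes.
#' @return List with `counts` (the normalized [count_matrix]) and
#'   `report` (a `normalization_report`: `retained_housekeeping`, tibble
#'   `scale_factors`, `min_avg_count`).
#' @export
normalize_counts <- function(cm, min_avg_count = 450) {
  stopifnot(inherits(cm, "count_matrix"))
  hk <- cm$housekeeping_ids
  if (!length(hk))
    stop("no housekeeping genes declared", call. = FALSE)
  avg <- rowMeans(cm$counts[hk, , drop = FALSE])
  retained <- hk[avg > min_avg_count]
  if (!length(retained))
    stop("no housekeeping gene passes the average count > ", min_avg_count,
         " filter", call. = FALSE)
  gm <- unname(apply(cm$counts[retained, , drop = FALSE], 2, geometric_mean))
  if (any(gm <= 0))
    stop("zero housekeeping counts: geometric mean undefined", call. = FALSE)
  grand <- geometric_mean(gm)
  sf <- grand / gm
  norm <- sweep(cm$counts, 2, sf, `*`)
  report <- structure(list(
    retained_housekeeping = retained,
    scale_factors = tibble::tibble(sample = colnames(cm$counts),
                                   hk_geomean = gm, scale_factor = sf),
    min_avg_count = min_avg_count), class = "normalization_report")
  list(counts = count_matrix(norm, cm$groups, cm$housekeeping_ids),
       report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("<normalization_report> ", length(x$retained_housekeeping),
      " housekeeping genes retained (average count > ", x$min_avg_count,
      "); scale factors ",
      paste(signif(x$scale_factors$scale_factor, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# vectorized per-gene two-sided t-tests on the rows of two matrices;
# pooled-variance (Student) by default — at n ~ 3 per group the Welch
# approximation is markedly conservative and breaks null calibration
welch_t_rows <- function(a, b, var_equal = TRUE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(ma))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tt <- (mb - ma) / sqrt(se2)
  p <- 2 * pt(-abs(tt), df)
  # both groups constant: equal means -> p = 1 by convention
  degen <- se2 == 0
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  list(statistic = tt, df = df, p_value = p)
}

#' Differential-expression selection by t-test and fold change
#'
#' Per-gene two-sided t-tests between groups A and B (on
#' `log2(x + 1)` of the normalized counts by default) combined with a
#' linear fold-change gate: a gene is called *up* iff `p <= alpha` and
#' `FC >= fc_up`, *down* iff `p <= alpha` and `FC <= fc_down`, otherwise
#' *ns*.  The fold change is the ratio of group means on the linear
#' scale, B over A.  No multiple-testing correction is applied (matching
#' the published selection); an optional BH-FDR column can be added.
#'
#' @param cm_a,cm_b [count_matrix] objects with identical genes (already
#'   normalized), or a single [count_matrix] for `cm_a` with exactly two
#'   group levels and `cm_b = NULL`.
#' @param alpha P-value cutoff (0.05).
#' @param fc_up,fc_down Fold-change cutoffs (1.5 and 0.66).
#' @param log_scale Run the t-tests on `log2(x + 1)` (default) or on the
#'   linear counts.
#' @param var_equal Pooled-variance Student t (default, matching the
#'   common spreadsheet "multiple t-tests" and exactly calibrated at
#'   small n); `FALSE` for Welch.
#' @param add_fdr Add a `p_adj` Benjamini-Hochberg column (off to match
#'   the published lists).
#' @return A `de_table`: tibble with `gene_id`, `mean_a`, `mean_b`,
#'   `fold_change`, `p_value`, `call` (`up`/`down`/`ns`).
#' @export
select_de <- function(cm_a, cm_b = NULL, alpha = 0.05, fc_up = 1.5,
                      fc_down = 0.66, log_scale = TRUE, add_fdr = FALSE,
                      var_equal = TRUE) {
  if (is.null(cm_b)) {
    stopifnot(inherits(cm_a, "count_matrix"))
    lev <- levels(cm_a$groups)
    if (length(lev) != 2)
      stop("need exactly two groups", call. = FALSE)
    a <- cm_a$counts[, cm_a$groups == lev[1], drop = FALSE]
    b <- cm_a$counts[, cm_a$groups == lev[2], drop = FALSE]
  } else {
    a <- cm_a$counts; b <- cm_b$counts
    if (!identical(rownames(a), rownames(b)))
      stop("gene sets differ between groups", call. = FALSE)
  }
  if (ncol(a) < 2 || ncol(b) < 2)
    stop("need >= 2 samples per group", call. = FALSE)
  ta <- if (log_scale) log2(a + 1) else a
  tb <- if (log_scale) log2(b + 1) else b
  wt <- welch_t_rows(ta, tb, var_equal = var_equal)
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  fc <- mean_b / mean_a
  fc[mean_a == 0 & mean_b == 0] <- 1
  call <- rep("ns", nrow(a))
  sig <- wt$p_value <= alpha
  call[sig & fc >= fc_up] <- "up"
  call[sig & fc <= fc_down] <- "down"
  out <- tibble::tibble(gene_id = rownames(a), mean_a = mean_a,
                        mean_b = mean_b, fold_change = fc,
                        p_value = wt$p_value, call = call)
  if (add_fdr) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  structure(out, alpha = alpha, fc_up = fc_up, fc_down = fc_down,
            class = c("de_table", class(out)))
}

#' Average-linkage hierarchical clustering on Pearson distance
#'
#' Profiles (rows) are clustered agglomeratively with average linkage on
#' the distance `d = 1 - Pearson r` (in `[0, 2]`), the combination used
#' for the published heat maps.  Ties break deterministically toward the
#' lowest leaf index.
#'
#' @param m Numeric matrix, one profile per row (each with positive
#'   variance), `>= 2` rows.
#' @return A `cluster_result`: list with the `hclust` tree, `distance`
#'   matrix, `merge_heights`, and `leaf_order` for heat-map rendering.
#' @export
cluster_profiles <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need >= 2 profiles", call. = FALSE)
  v <- apply(m, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance profile: Pearson correlation undefined",
         call. = FALSE)
  d <- 1 - cor(t(m))
  tree <- hclust(as.dist(d), method = "average")
  structure(list(tree = tree, distance = d,
                 merge_heights = tree$height,
                 leaf_order = tree$order),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$leaf_order), " leaves, merge heights ",
      paste(signif(x$merge_heights, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' qPCR relative expression (2^-dCt) and isoform ratios
#'
#' Relative expression of each gene in each sample is `2^-(Ct_gene -
#' Ct_ref)` with ATP5O as the default reference; isoform ratios
#' (e.g. 4R/3R tau) are ratios of relative expressions, i.e.
#' `2^-(Ct_4R - Ct_3R)`.
#'
#' @param ct Tibble/data frame with `sample_label`, `gene_id`,
#'   `ct_value` (see [read_ct_table()]).
#' @param ref_gene Reference (housekeeping) gene id, present in every
#'   sample.
#' @param ratios Optional named list of `c(numerator, denominator)` gene
#'   pairs, e.g. `list("4R/3R" = c("MAPT-4R", "MAPT-3R"))`.
#' @return Tibble with `sample_label`, `gene_id`, `rel_expr` rows and,
#'   when `ratios` are requested, extra rows whose `gene_id` is the ratio
#'   name.
#' @export
relative_expression <- function(ct, ref_gene = "ATP5O", ratios = NULL) {
  ct <- tibble::as_tibble(ct)
  stopifnot(all(c("sample_label", "gene_id", "ct_value") %in% names(ct)))
  ref <- ct[ct$gene_id == ref_gene, c("sample_label", "ct_value")]
  names(ref)[2] <- "ct_ref"
  samples <- unique(ct$sample_label)
  if (!all(samples %in% ref$sample_label))
    stop("reference gene ", ref_gene, " missing for sample(s): ",
         paste(setdiff(samples, ref$sample_label), collapse = ", "),
         call. = FALSE)
  out <- ct[ct$gene_id != ref_gene, ] |>
    dplyr::left_join(ref, by = "sample_label") |>
    dplyr::mutate(rel_expr = 2^-(.data$ct_value - .data$ct_ref)) |>
    dplyr::select("sample_label", "gene_id", "rel_expr")
  if (!is.null(ratios)) {
    wide <- tidyr::pivot_wider(out, names_from = "gene_id",
                               values_from = "rel_expr")
    for (nm in names(ratios)) {
      pair <- ratios[[nm]]
      if (!all(pair %in% names(wide)))
        stop("ratio ", nm, " needs genes ", paste(pair, collapse = ", "),
             call. = FALSE)
      out <- dplyr::bind_rows(out, tibble::tibble(
        sample_label = wide$sample_label, gene_id = nm,
        rel_expr = wide[[pair[1]]] / wide[[pair[2]]]))
    }
  }
  out
}

#' Positive/negative control QC report
#'
#' Linearity of positive-control counts against their design
#' concentrations (R^2) and a background flag per sample (any endogenous
#' signal below negative-control mean + 2 SD would be indistinguishable
#' from background).  Reported only; no gating is applied.
#'
#' @param pos Numeric matrix of positive-control counts (controls x
#'   samples), with design concentrations `conc`.
#' @param neg Numeric matrix of negative-control counts.
#' @param conc Design concentrations of the positive controls.
#' @return Tibble per sample: `pos_r_squared`, `neg_background`.
#' @export
qc_controls <- function(pos, neg, conc) {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  r2 <- apply(pos, 2, function(v) cor(log2(v + 1), log2(conc))^2)
  bg <- apply(neg, 2, function(v) mean(v) + 2 * sd(v))
  tibble::tibble(sample = colnames(pos) %||% seq_along(r2),
                 pos_r_squared = r2, neg_background = bg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
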