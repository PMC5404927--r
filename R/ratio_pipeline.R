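#' Keep confidently detected protein groups
#'
#' Applies the detection filter used throughout the SILAC analysis: drops
#' contaminant and reverse-database hits and requires at least two unique,
#' sequenced peptides per protein group. Row order is preserved and the
#' filter is idempotent.
#'
#' @param records Protein-group record tibble from [read_protein_groups()]
#'   (one replicate).
#' @param min_unique_peptides Minimum unique peptide count. Default 2.
#' @return Filtered tibble of the same shape.
#' @export
filter_detected <- function(records, min_unique_peptides = 2L) {
  dplyr::filter(records,
                !.data$is_contaminant,
                !.data$is_reverse,
                .data$unique_peptides >= min_unique_peptides)
}

#' Normalize SILAC ratios to a soluble reference subset
#'
#' For each ratio kind independently (H/L, H/M, and M/L for reporting), the
#' median of the raw ratios over detected reference-subset members is
#' computed; every protein's raw ratio is divided by that median and
#' log2-transformed. After normalization the median log2 ratio of the
#' detected reference members is exactly 0 for each ratio kind, anchoring
#' the ratio scale to proteins expected to show no specific enrichment.
#' Missing ratios stay missing.
#'
#' @param records Detected protein-group records from one replicate (after
#'   [filter_detected()]), with raw (unnormalized) ratios.
#' @param reference Identifier set of reference (e.g. soluble mitochondrial
#'   matrix) proteins; matched against [record_key()].
#' @param case_fold Passed to [record_key()].
#' @return A ratio table tibble with columns `protein_id` (the set-operation
#'   key), `accession`, `log2_hl`, `log2_hm`, `log2_ml`, `replicate_id`, and
#'   attributes `reference_median` (named vector of the three raw-ratio
#'   medians) and `normalized = TRUE`.
#' @export
normalize_to_reference <- function(records, reference, case_fold = TRUE) {
  key <- record_key(records, case_fold = case_fold)
  in_ref <- key %in% (if (case_fold) toupper(reference) else reference)
  med <- vapply(c(hl = "ratio_hl", hm = "ratio_hm", ml = "ratio_ml"),
                function(col) {
                  vals <- records[[col]][in_ref]
                  vals <- vals[!is.na(vals)]
                  if (length(vals) == 0) NA_real_ else stats::median(vals)
                }, numeric(1))
  for (kind in c("hl", "hm")) {
    if (!is.finite(med[[kind]])) {
      stop("no detected reference member carries an ", toupper(kind),
           " ratio; cannot normalize", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    protein_id = key,
    accession = records$protein_id,
    log2_hl = log2(records$ratio_hl / med[["hl"]]),
    log2_hm = log2(records$ratio_hm / med[["hm"]]),
    log2_ml = if (is.finite(med[["ml"]])) log2(records$ratio_ml / med[["ml"]]) else NA_real_,
    replicate_id = records$replicate_id
  )
  attr(out, "reference_median") <- med
  attr(out, "normalized") <- TRUE
  out
}

#' Join two replicate ratio tables into a complete-case paired table
#'
#' Keeps exactly the proteins that possess both H/L and H/M ratios in both
#' replicates; all downstream cutoff analysis runs on this paired table.
#'
#' @param table1,table2 Normalized ratio tables from
#'   [normalize_to_reference()] with distinct `replicate_id`s.
#' @return Tibble with one row per retained protein: `protein_id`,
#'   `log2_hl_r1`, `log2_hm_r1`, `log2_ml_r1`, `log2_hl_r2`, `log2_hm_r2`,
#'   `log2_ml_r2`, plus attribute `replicates` recording the two ids in
#'   column order.
#' @export
join_replicates <- function(table1, table2) {
  r1 <- unique(table1$replicate_id)
  r2 <- unique(table2$replicate_id)
  if (length(r1) != 1 || length(r2) != 1 || r1 == r2) {
    stop("join_replicates() needs two tables with distinct replicate ids",
         call. = FALSE)
  }
  sel <- function(tab, suffix) {
    tab <- dplyr::distinct(tab, .data$protein_id, .keep_all = TRUE)
    dplyr::select(tab, "protein_id",
                  !!paste0("log2_hl_", suffix) := "log2_hl",
                  !!paste0("log2_hm_", suffix) := "log2_hm",
                  !!paste0("log2_ml_", suffix) := "log2_ml")
  }
  out <- dplyr::inner_join(sel(table1, "r1"), sel(table2, "r2"), by = "protein_id")
  out <- dplyr::filter(out,
                       !is.na(.data$log2_hl_r1), !is.na(.data$log2_hm_r1),
                       !is.na(.data$log2_hl_r2), !is.na(.data$log2_hm_r2))
  attr(out, "replicates") <- c(r1, r2)
  out
}

#' Replicate-to-replicate coefficient of determination
#'
#' R-squared of the ordinary least-squares fit of replicate-2 log2 ratios on
#' replicate-1 log2 ratios, the standard reproducibility summary for paired
#' ratiometric experiments.
#'
#' @param paired Paired ratio table from [join_replicates()].
#' @param ratio_kind `"hl"` or `"hm"`.
#' @return R-squared (scalar in \[0, 1\]).
#' @export
replicate_correlation <- function(paired, ratio_kind = c("hl", "hm")) {
  ratio_kind <- match.arg(ratio_kind)
  x <- paired[[paste0("log2_", ratio_kind, "_r1")]]
  y <- paired[[paste0("log2_", ratio_kind, "_r2")]]
  if (length(x) < 3) stop("need at least 3 paired proteins", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one replicate; R^2 undefined", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Scatter plot of paired log2 ratios with cutoff quadrants
#'
#' Reproduces the standard two-dimensional ratio scatter (log2 H/M against
#' log2 H/L for one replicate), coloring curated true positives, proteins
#' lacking prior annotation, and all others, with dashed cutoff lines when
#' supplied.
#'
#' @param paired Paired ratio table from [join_replicates()].
#' @param replicate 1 or 2 (which replicate's values to plot).
#' @param tp_set,unannotated_set Optional identifier sets to color.
#' @param cutoff_hl,cutoff_hm Optional dashed cutoff lines.
#' @return A ggplot object.
#' @export
plot_ratio_scatter <- function(paired, replicate = 1, tp_set = NULL,
                               unannotated_set = NULL,
                               cutoff_hl = NULL, cutoff_hm = NULL) {
  suf <- paste0("_r", replicate)
  df <- tibble::tibble(
    log2_hl = paired[[paste0("log2_hl", suf)]],
    log2_hm = paired[[paste0("log2_hm", suf)]],
    class = "other"
  )
  if (!is.null(unannotated_set)) {
    df$class[paired$protein_id %in% unannotated_set] <- "unannotated"
  }
  if (!is.null(tp_set)) df$class[paired$protein_id %in% tp_set] <- "true positive"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_hl, y = .data$log2_hm,
                                        color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(values = c(
      "true positive" = "forestgreen", "unannotated" = "firebrick",
      "other" = "grey30")) +
    ggplot2::labs(x = bquote(log[2] * "(H/L)"), y = bquote(log[2] * "(H/M)"),
                  color = NULL) +
    ggplot2::theme_classic()
  if (!is.null(cutoff_hl)) p <- p + ggplot2::geom_vline(xintercept = cutoff_hl, linetype = "dashed")
  if (!is.null(cutoff_hm)) p <- p + ggplot2::geom_hline(yintercept = cutoff_hm, linetype = "dashed")
  p
}
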