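#' Build a true/false-positive class specification for cutoff selection
#'
#' Encodes which curated lists define the true-positive and false-positive
#' classes for each proteome/ratio-axis combination:
#'
#' * `OMM` + `hl`: TP = curated outer-mitochondrial-membrane proteins,
#'   FP = soluble mitochondrial matrix reference proteins.
#' * `OMM` + `hm`: TP = curated OMM proteins, FP = all detected proteins
#'   lacking any prior mitochondrial annotation (complement of the
#'   mitochondrial annotation union).
#' * `ERM` + `hl`: TP = curated ER-membrane proteins, FP = matrix reference
#'   proteins (the H/L classes are shared between proteomes, only the TP
#'   list changes).
#' * `ERM` + `hm`: TP = curated ERM proteins, FP = all detected proteins not
#'   on the curated ERM list (complement of the TP list).
#'
#' @param proteome_kind `"OMM"` or `"ERM"`.
#' @param ratio_kind `"hl"` or `"hm"`.
#' @param tp_set Curated true-positive identifier set for this proteome.
#' @param matrix_set Soluble-matrix reference identifier set (H/L axis FP).
#' @param mito_annotation Union of prior mitochondrial annotation
#'   (required for `OMM` + `hm`).
#' @return A `roc_class_spec` list: `proteome_kind`, `ratio_kind`, `tp_set`,
#'   `fp_set`, `fp_is_complement`.
#' @export
build_class_spec <- function(proteome_kind = c("OMM", "ERM"),
                             ratio_kind = c("hl", "hm"),
                             tp_set, matrix_set = NULL, mito_annotation = NULL) {
  proteome_kind <- match.arg(proteome_kind)
  ratio_kind <- match.arg(ratio_kind)
  if (length(tp_set) == 0) stop("true-positive list is missing", call. = FALSE)
  if (ratio_kind == "hl") {
    if (is.null(matrix_set)) stop("matrix reference list is missing", call. = FALSE)
    fp_set <- matrix_set
    fp_is_complement <- FALSE
  } else if (proteome_kind == "OMM") {
    if (is.null(mito_annotation)) stop("mitochondrial annotation union is missing", call. = FALSE)
    fp_set <- mito_annotation
    fp_is_complement <- TRUE
  } else {
    fp_set <- tp_set
    fp_is_complement <- TRUE
  }
  if (!fp_is_complement && length(intersect(tp_set, fp_set)) > 0) {
    stop("true- and false-positive classes overlap", call. = FALSE)
  }
  structure(list(proteome_kind = proteome_kind, ratio_kind = ratio_kind,
                 tp_set = tp_set, fp_set = fp_set,
                 fp_is_complement = fp_is_complement),
            class = "roc_class_spec")
}

#' ROC curve over observed score thresholds
#'
#' Sweeps every distinct observed score as a candidate cutoff. A protein is
#' counted above a threshold `t` when its score is `>= t`. The
#' true-positive rate at `t` is the fraction of detected true positives
#' above `t`; the false-positive rate likewise over detected false
#' positives. When the class specification marks the FP class as a
#' complement, the false positives are the scored proteins *not* in the
#' stored set.
#'
#' @param scores Tibble with columns `protein_id` and `score` (one row per
#'   detected protein), or a named numeric vector.
#' @param spec An `roc_class_spec` from [build_class_spec()], or a list with
#'   elements `tp_set`, `fp_set`, `fp_is_complement`.
#' @return An `roc_result` object: tibble `sweep` (`threshold`, `tpr`,
#'   `fpr`, `j`, descending thresholds), `chosen_cutoff`, `max_j`,
#'   `n_tp_detected`, `n_fp_detected`.
#' @export
roc_curve <- function(scores, spec) {
  if (!is.data.frame(scores)) {
    scores <- tibble::tibble(protein_id = names(scores), score = as.numeric(scores))
  }
  scores <- dplyr::filter(scores, !is.na(.data$score))
  is_tp <- scores$protein_id %in% spec$tp_set
  is_fp <- if (isTRUE(spec$fp_is_complement)) {
    !(scores$protein_id %in% spec$fp_set)
  } else {
    scores$protein_id %in% spec$fp_set
  }
  n_tp <- sum(is_tp)
  n_fp <- sum(is_fp)
  if (n_tp == 0) stop("no detected true positives among scored proteins", call. = FALSE)
  if (n_fp == 0) stop("no detected false positives among scored proteins", call. = FALSE)
  thresholds <- sort(unique(scores$score), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) sum(is_tp & scores$score >= t) / n_tp, numeric(1))
  fpr <- vapply(thresholds, function(t) sum(is_fp & scores$score >= t) / n_fp, numeric(1))
  sweep <- tibble::tibble(threshold = thresholds, tpr = tpr, fpr = fpr,
                          j = tpr - fpr)
  best <- which(sweep$j == max(sweep$j))[1]  # descending order => largest threshold
  structure(list(sweep = sweep,
                 chosen_cutoff = sweep$threshold[best],
                 max_j = sweep$j[best],
                 n_tp_detected = n_tp,
                 n_fp_detected = n_fp,
                 spec = spec[c("proteome_kind", "ratio_kind", "fp_is_complement")]),
            class = "roc_result")
}

#' Select the ratio cutoff from an ROC sweep
#'
#' Returns the threshold maximizing TPR minus FPR (the Youden-style
#' criterion). Ties are broken toward the largest threshold, i.e. the most
#' stringent cutoff. The `reported` value truncates the exact cutoff toward
#' zero at two decimal places, matching how such cutoffs are conventionally
#' printed; downstream filtering should use the exact value.
#'
#' @param roc An `roc_result` from [roc_curve()].
#' @return Tibble with one row: `cutoff` (exact), `reported` (truncated to 2
#'   decimals), `max_j`.
#' @export
select_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  tibble::tibble(cutoff = roc$chosen_cutoff,
                 reported = trunc2(roc$chosen_cutoff),
                 max_j = roc$max_j)
}

trunc2 <- function(x) trunc(x * 100) / 100

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC sweep over", nrow(x$sweep), "observed thresholds\n")
  cat(sprintf("  detected TP: %d, detected FP: %d%s\n", x$n_tp_detected,
              x$n_fp_detected,
              if (isTRUE(x$spec$fp_is_complement)) " (complement class)" else ""))
  cat(sprintf("  chosen cutoff: %.4f (TPR - FPR = %.4f)\n",
              x$chosen_cutoff, x$max_j))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$sweep

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(chosen_cutoff = x$chosen_cutoff, max_j = x$max_j,
                 n_tp_detected = x$n_tp_detected, n_fp_detected = x$n_fp_detected,
                 n_thresholds = nrow(x$sweep))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve plot
#'
#' @param object An `roc_result`.
#' @param ... Ignored.
#' @return A ggplot object with the ROC curve and the chosen cutoff marked.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  chosen <- dplyr::filter(object$sweep, .data$threshold == object$chosen_cutoff)
  ggplot2::ggplot(object$sweep, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(data = chosen, color = "firebrick", size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_classic()
}
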