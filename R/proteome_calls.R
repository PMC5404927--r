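#' Apply dual ratio cutoffs and intersect replicates into a final proteome
#'
#' A protein enters the final proteome exactly when its log2(H/L) and
#' log2(H/M) values meet or exceed the corresponding cutoffs in *both*
#' replicates. Proteins passing H/L in both replicates but failing H/M in at
#' least one are recorded as "dual-labeled": comparably biotinylated by the
#' targeted and the cytosolic construct, hence excluded for lack of spatial
#' specificity.
#'
#' @param paired Paired ratio table from [join_replicates()].
#' @param cutoffs Tibble with columns `replicate`, `cutoff_hl`, `cutoff_hm`
#'   (one row per replicate; replicate labels 1 and 2 refer to the first and
#'   second table given to [join_replicates()]).
#' @param proteome_kind `"OMM"`, `"ERM"` or any label carried into reports.
#' @param use_truncated Filter on the printed two-decimal truncation of the
#'   cutoffs instead of their exact values. Default `FALSE` (exact).
#' @return A `proteome_call` object: tibble `calls` with the four pass flags
#'   plus `member` and `dual_labeled` logicals per protein, `members`
#'   (sorted identifier vector), `dual_labeled` (identifier vector),
#'   `cutoffs`, `proteome_kind`.
#' @export
apply_cutoffs <- function(paired, cutoffs, proteome_kind = "OMM",
                          use_truncated = FALSE) {
  stopifnot(all(c("replicate", "cutoff_hl", "cutoff_hm") %in% names(cutoffs)))
  if (!setequal(cutoffs$replicate, c(1, 2))) {
    stop("cutoffs must cover replicates 1 and 2", call. = FALSE)
  }
  cut_of <- function(rep, kind) {
    v <- cutoffs[[paste0("cutoff_", kind)]][cutoffs$replicate == rep]
    if (use_truncated) trunc2(v) else v
  }
  calls <- tibble::tibble(
    protein_id = paired$protein_id,
    log2_hl_r1 = paired$log2_hl_r1, log2_hm_r1 = paired$log2_hm_r1,
    log2_hl_r2 = paired$log2_hl_r2, log2_hm_r2 = paired$log2_hm_r2,
    pass_hl_r1 = paired$log2_hl_r1 >= cut_of(1, "hl"),
    pass_hm_r1 = paired$log2_hm_r1 >= cut_of(1, "hm"),
    pass_hl_r2 = paired$log2_hl_r2 >= cut_of(2, "hl"),
    pass_hm_r2 = paired$log2_hm_r2 >= cut_of(2, "hm")
  )
  calls <- dplyr::mutate(calls,
    member = .data$pass_hl_r1 & .data$pass_hm_r1 & .data$pass_hl_r2 & .data$pass_hm_r2,
    dual_labeled = .data$pass_hl_r1 & .data$pass_hl_r2 &
      !(.data$pass_hm_r1 & .data$pass_hm_r2))
  structure(list(
    proteome_kind = proteome_kind,
    calls = calls,
    members = sort(calls$protein_id[calls$member]),
    dual_labeled = sort(calls$protein_id[calls$dual_labeled]),
    cutoffs = cutoffs
  ), class = "proteome_call")
}

#' Dual-labeled exclusion set of a proteome call
#'
#' Proteins that pass the H/L cutoff in both replicates (strongly
#' biotinylated by the targeted construct relative to the untagged control)
#' yet fail the H/M cutoff in at least one replicate (comparably
#' biotinylated by the cytosolic construct). Disjoint from the member set by
#' construction.
#'
#' @param call A `proteome_call` from [apply_cutoffs()].
#' @return Sorted identifier vector.
#' @export
dual_labeled_set <- function(call) {
  stopifnot(inherits(call, "proteome_call"))
  call$dual_labeled
}

#' Intersect two proteome calls and rank by combined enrichment
#'
#' Set intersection of the two member lists, annotated with a combined
#' enrichment score: the sum over the two proteomes of the protein's mean
#' log2(H/M) across replicates. Rows are sorted by descending score, so the
#' protein most strongly and consistently enriched in both compartments
#' ranks first.
#'
#' @param a,b `proteome_call` objects keyed by the same identifier
#'   convention.
#' @param score `"sum_of_means"` (default; sum of per-proteome mean
#'   log2(H/M)) or `"sum_all"` (sum of all four log2(H/M) values).
#' @return Tibble `protein_id`, `mean_hm_a`, `mean_hm_b`,
#'   `combined_enrichment`, sorted by descending score (ties by id).
#' @export
intersect_proteomes <- function(a, b, score = c("sum_of_means", "sum_all")) {
  stopifnot(inherits(a, "proteome_call"), inherits(b, "proteome_call"))
  score <- match.arg(score)
  common <- intersect(a$members, b$members)
  mean_hm <- function(call, ids) {
    idx <- match(ids, call$calls$protein_id)
    (call$calls$log2_hm_r1[idx] + call$calls$log2_hm_r2[idx]) / 2
  }
  out <- tibble::tibble(
    protein_id = common,
    mean_hm_a = mean_hm(a, common),
    mean_hm_b = mean_hm(b, common)
  )
  mult <- if (score == "sum_all") 2 else 1
  out$combined_enrichment <- mult * (out$mean_hm_a + out$mean_hm_b)
  dplyr::arrange(out, dplyr::desc(.data$combined_enrichment), .data$protein_id)
}

#' @export
print.proteome_call <- function(x, ...) {
  cat(sprintf("%s proteome call: %d paired proteins, %d members, %d dual-labeled\n",
              x$proteome_kind, nrow(x$calls), length(x$members),
              length(x$dual_labeled)))
  invisible(x)
}

#' @method tidy proteome_call
#' @export
tidy.proteome_call <- function(x, ...) x$calls

#' @method glance proteome_call
#' @export
glance.proteome_call <- function(x, ...) {
  tibble::tibble(proteome_kind = x$proteome_kind,
                 n_paired = nrow(x$calls),
                 n_members = length(x$members),
                 n_dual_labeled = length(x$dual_labeled))
}
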