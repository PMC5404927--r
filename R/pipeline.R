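#' Run the full ratiometric SILAC analysis for one proteome
#'
#' Orchestrates the stages end to end: detection filtering, reference-median
#' normalization, replicate pairing, per-replicate ROC cutoff selection on
#' both ratio axes, dual-cutoff proteome calling with replicate
#' intersection, and (optionally) annotation metrics. Stage counts are
#' logged via `message()` so a run can be audited against expected numbers.
#'
#' Inputs may be given as in-memory tibbles/vectors or as file paths
#' (protein-group TSVs, identifier lists, catalog TSV), which are read with
#' the `tables_io` readers.
#'
#' @param replicate1,replicate2 Protein-group record tibbles (or TSV paths)
#'   for the two replicates.
#' @param reference Identifier set (or list-file path) of reference
#'   (soluble matrix) proteins used for normalization and as the H/L
#'   false-positive class.
#' @param tp_set Curated true-positive identifier set (or path).
#' @param proteome_kind `"OMM"` or `"ERM"`.
#' @param catalog Optional annotation catalog tibble (or TSV path); required
#'   for the OMM H/M false-positive class (complement of the `mito`
#'   annotation union) and for annotation metrics.
#' @param mito_compartment Catalog compartment whose union defines prior
#'   mitochondrial annotation. Default `"mito"`.
#' @param dialect Column dialect for reading protein-group TSVs.
#' @param use_truncated Filter on two-decimal truncated cutoffs. Default
#'   `FALSE`.
#' @param verbose Emit stage-count messages. Default `TRUE`.
#' @return List with `call` (the `proteome_call`), `cutoffs` (tibble:
#'   `replicate`, `cutoff_hl`, `cutoff_hm`, `reported_hl`, `reported_hm`,
#'   `max_j_hl`, `max_j_hm`), `rocs` (nested list of `roc_result`s by
#'   replicate and axis), `paired` (the paired ratio table), `correlations`
#'   (R-squared per axis), and `counts` (stage-count tibble).
#' @export
run_silac_analysis <- function(replicate1, replicate2, reference, tp_set,
                               proteome_kind = c("OMM", "ERM"),
                               catalog = NULL, mito_compartment = "mito",
                               dialect = maxquant_dialect(),
                               use_truncated = FALSE, verbose = TRUE) {
  proteome_kind <- match.arg(proteome_kind)
  say <- function(...) if (verbose) message(sprintf(...))
  load_records <- function(x, rep_id) {
    if (is.character(x)) read_protein_groups(x, dialect, replicate_id = rep_id) else x
  }
  load_set <- function(x, name) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) read_id_set(x, name) else x
  }
  reps <- list(load_records(replicate1, 1L), load_records(replicate2, 2L))
  reference <- load_set(reference, "reference")
  tp_set <- load_set(tp_set, "curated_tp")
  if (is.character(catalog) && length(catalog) == 1) {
    catalog <- read_annotation_catalog(catalog)
  }
  mito_annotation <- if (!is.null(catalog)) {
    catalog_set(catalog, mito_compartment)
  } else NULL

  detected <- purrr::map(reps, filter_detected)
  say("%s: detected %d / %d proteins (replicate 1), %d / %d (replicate 2)",
      proteome_kind, nrow(detected[[1]]), nrow(reps[[1]]),
      nrow(detected[[2]]), nrow(reps[[2]]))
  tables <- purrr::map(detected, normalize_to_reference, reference = reference)
  paired <- join_replicates(tables[[1]], tables[[2]])
  say("%s: %d proteins with both ratios in both replicates", proteome_kind,
      nrow(paired))

  spec_hl <- build_class_spec(proteome_kind, "hl", tp_set = tp_set,
                              matrix_set = reference)
  spec_hm <- build_class_spec(proteome_kind, "hm", tp_set = tp_set,
                              matrix_set = reference,
                              mito_annotation = mito_annotation)
  rocs <- list()
  cutoff_rows <- list()
  for (rep_i in 1:2) {
    suf <- paste0("_r", rep_i)
    roc_hl <- roc_curve(tibble::tibble(protein_id = paired$protein_id,
                                       score = paired[[paste0("log2_hl", suf)]]),
                        spec_hl)
    roc_hm <- roc_curve(tibble::tibble(protein_id = paired$protein_id,
                                       score = paired[[paste0("log2_hm", suf)]]),
                        spec_hm)
    sel_hl <- select_cutoff(roc_hl)
    sel_hm <- select_cutoff(roc_hm)
    rocs[[rep_i]] <- list(hl = roc_hl, hm = roc_hm)
    cutoff_rows[[rep_i]] <- tibble::tibble(
      replicate = rep_i,
      cutoff_hl = sel_hl$cutoff, cutoff_hm = sel_hm$cutoff,
      reported_hl = sel_hl$reported, reported_hm = sel_hm$reported,
      max_j_hl = sel_hl$max_j, max_j_hm = sel_hm$max_j)
    say("%s replicate %d: cutoffs log2(H/L) >= %.2f, log2(H/M) >= %.2f",
        proteome_kind, rep_i, sel_hl$reported, sel_hm$reported)
  }
  cutoffs <- purrr::list_rbind(cutoff_rows)
  call <- apply_cutoffs(paired, cutoffs, proteome_kind = proteome_kind,
                        use_truncated = use_truncated)
  say("%s: final proteome %d proteins, %d dual-labeled excluded",
      proteome_kind, length(call$members), length(call$dual_labeled))
  counts <- tibble::tibble(
    stage = c("input_r1", "input_r2", "detected_r1", "detected_r2", "paired",
              "final", "dual_labeled"),
    n = c(nrow(reps[[1]]), nrow(reps[[2]]), nrow(detected[[1]]),
          nrow(detected[[2]]), nrow(paired), length(call$members),
          length(call$dual_labeled)))
  list(call = call, cutoffs = cutoffs, rocs = rocs, paired = paired,
       correlations = c(hl = replicate_correlation(paired, "hl"),
                        hm = replicate_correlation(paired, "hm")),
       counts = counts)
}

#' Intersect two proteome calls into a ranked contact-candidate report
#'
#' Thin wrapper over [intersect_proteomes()] that logs the result size; the
#' top-ranked row is the protein with the highest combined enrichment
#' across the two compartments.
#'
#' @param call_a,call_b `proteome_call` objects.
#' @param verbose Emit a message. Default `TRUE`.
#' @return Ranked intersection tibble (see [intersect_proteomes()]).
#' @export
run_intersection <- function(call_a, call_b, verbose = TRUE) {
  out <- intersect_proteomes(call_a, call_b)
  if (verbose) {
    message(sprintf("%s x %s intersection: %d proteins%s",
                    call_a$proteome_kind, call_b$proteome_kind, nrow(out),
                    if (nrow(out) > 0) paste0("; top-ranked ", out$protein_id[1])
                    else ""))
  }
  out
}
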