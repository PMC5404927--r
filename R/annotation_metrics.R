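#' Assign a protein to one sub-compartment by priority
#'
#' When a protein carries several sub-compartment annotations it is assigned
#' to the first label of the priority list whose set contains it, e.g.
#' `OMM > IMS > IMM > matrix` for mitochondria or
#' `ER > Golgi > PM` for the secretory pathway.
#'
#' @param ids Character vector of protein identifiers.
#' @param catalog Annotation catalog tibble (`compartment`, `id`).
#' @param priority Ordered character vector of compartment labels.
#' @return Character vector: the assigned label per protein, or `NA` when
#'   the protein is in none of the priority sets.
#' @export
assign_subcompartment <- function(ids, catalog, priority) {
  missing <- setdiff(priority, unique(catalog$compartment))
  if (length(missing) > 0) {
    stop("priority label '", missing[1], "' not present in catalog", call. = FALSE)
  }
  out <- rep(NA_character_, length(ids))
  for (label in rev(priority)) {
    out[ids %in% catalog$id[catalog$compartment == label]] <- label
  }
  out
}

#' Annotation specificity of a proteome
#'
#' Fraction of proteome members carrying prior compartment annotation,
#' the same fraction over a background universe (e.g. the whole detected or
#' human proteome), and a single-assignment sub-compartment breakdown using
#' [assign_subcompartment()] priorities.
#'
#' @param proteome Identifier vector (final proteome members).
#' @param annotation_union Identifier set: union of prior annotation for the
#'   compartment.
#' @param background Identifier vector over which the baseline fraction is
#'   computed.
#' @param catalog Optional annotation catalog for the sub-compartment
#'   breakdown.
#' @param priority Optional ordered labels for the breakdown.
#' @return A `specificity_report`: list with `n_total`, `n_annotated`,
#'   `fraction_annotated`, `percent_annotated` (rounded to whole percent),
#'   `baseline_fraction`, and tibble `subcompartment_counts`
#'   (`compartment`, `n`) over proteins with at least one sub-annotation.
#' @export
specificity <- function(proteome, annotation_union, background = NULL,
                        catalog = NULL, priority = NULL) {
  proteome <- unique(proteome)
  if (length(proteome) == 0) stop("empty proteome", call. = FALSE)
  if (!is.null(background) && !all(proteome %in% background)) {
    warning("proteome is not contained in the background universe", call. = FALSE)
  }
  n_total <- length(proteome)
  n_annotated <- sum(proteome %in% annotation_union)
  baseline <- if (is.null(background)) NA_real_ else {
    mean(unique(background) %in% annotation_union)
  }
  sub <- NULL
  if (!is.null(catalog) && !is.null(priority)) {
    lab <- assign_subcompartment(proteome, catalog, priority)
    lab <- lab[!is.na(lab)]
    sub <- tibble::tibble(compartment = factor(lab, levels = priority)) |>
      dplyr::count(.data$compartment, .drop = FALSE, name = "n") |>
      dplyr::mutate(compartment = as.character(.data$compartment))
  }
  structure(list(
    n_total = n_total,
    n_annotated = n_annotated,
    fraction_annotated = n_annotated / n_total,
    percent_annotated = round(100 * n_annotated / n_total),
    baseline_fraction = baseline,
    subcompartment_counts = sub
  ), class = "specificity_report")
}

#' Coverage of a curated list by a proteome
#'
#' Fraction of a curated list of well-established compartment residents that
#' the final proteome recovered — the depth-of-coverage metric.
#'
#' @param proteome Identifier vector (final proteome members).
#' @param curated Non-empty identifier set of established residents.
#' @return Tibble with `n_curated`, `n_recovered`, `coverage`,
#'   `percent` (rounded to whole percent).
#' @export
coverage <- function(proteome, curated) {
  curated <- unique(curated)
  if (length(curated) == 0) stop("curated list is empty", call. = FALSE)
  n_rec <- sum(curated %in% proteome)
  tibble::tibble(n_curated = length(curated), n_recovered = n_rec,
                 coverage = n_rec / length(curated),
                 percent = round(100 * n_rec / length(curated)))
}

#' Orphan members of a proteome
#'
#' Proteome members lacking any prior compartment annotation: candidate
#' novel residents (or residual false positives).
#'
#' @param proteome Identifier vector.
#' @param annotation_union Identifier set of prior annotation.
#' @return Sorted identifier vector.
#' @export
orphan_set <- function(proteome, annotation_union) {
  sort(setdiff(unique(proteome), annotation_union))
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("specificity: %d/%d annotated (%d%%)", x$n_annotated, x$n_total,
              x$percent_annotated))
  if (!is.na(x$baseline_fraction)) {
    cat(sprintf("; background %d%%", round(100 * x$baseline_fraction)))
  }
  cat("\n")
  invisible(x)
}

#' @method tidy specificity_report
#' @export
tidy.specificity_report <- function(x, ...) {
  if (is.null(x$subcompartment_counts)) {
    tibble::tibble(compartment = character(), n = integer())
  } else {
    x$subcompartment_counts
  }
}

#' @method glance specificity_report
#' @export
glance.specificity_report <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_annotated = x$n_annotated,
                 fraction_annotated = x$fraction_annotated,
                 percent_annotated = x$percent_annotated,
                 baseline_fraction = x$baseline_fraction)
}
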