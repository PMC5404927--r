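#' Default column-name mapping for MaxQuant proteinGroups tables
#'
#' Maps the internal field names used throughout the package to the column
#' headers of a MaxQuant `proteinGroups.txt` export. Ratio columns target the
#' *unnormalized* protein SILAC ratios; normalization to a reference subset
#' is performed downstream by [normalize_to_reference()]. Override any entry
#' to read other dialects.
#'
#' @return Named character vector mapping internal names
#'   (`protein_id`, `gene_symbol`, `unique_peptides`, `ratio_hl`, `ratio_hm`,
#'   `ratio_ml`, `is_contaminant`, `is_reverse`) to expected column headers.
#' @export
#' @examples
#' maxquant_dialect()
maxquant_dialect <- function() {
  c(
    protein_id     = "Majority protein IDs",
    gene_symbol    = "Gene names",
    unique_peptides = "Unique peptides",
    ratio_hl       = "Ratio H/L",
    ratio_hm       = "Ratio H/M",
    ratio_ml       = "Ratio M/L",
    is_contaminant = "Potential contaminant",
    is_reverse     = "Reverse"
  )
}

#' Read a protein-group quantification table
#'
#' Parses a tab-separated protein-group table (MaxQuant `proteinGroups`
#' dialect by default) into one row per protein group with the SILAC ratio
#' triplet, unique-peptide count and QC flags. Blank or non-finite ratio
#' cells become `NA` (absence of a ratio is never coerced to zero). Flag
#' columns are treated as set when the cell is non-empty (MaxQuant writes
#' `"+"`). `protein_id` keeps the first accession of the semicolon-separated
#' majority-ID group; set operations downstream key on `gene_symbol` when
#' present, else on this accession (see [record_key()]).
#'
#' @param path Path to a tab-separated table with a header row.
#' @param dialect Named character vector mapping internal field names to
#'   column headers; see [maxquant_dialect()].
#' @param replicate_id Integer replicate label attached to every record.
#' @return A tibble with columns `protein_id`, `gene_symbol`,
#'   `unique_peptides`, `ratio_hl`, `ratio_hm`, `ratio_ml`,
#'   `is_contaminant`, `is_reverse`, `replicate_id`.
#' @export
read_protein_groups <- function(path, dialect = maxquant_dialect(),
                                replicate_id = 1L) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  required <- c("protein_id", "unique_peptides", "ratio_hl", "ratio_hm",
                "is_contaminant", "is_reverse")
  for (field in required) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("protein-group table is missing mandatory column '",
           if (is.null(col)) field else col, "'", call. = FALSE)
    }
  }
  get_col <- function(field, default = NA_character_) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  tibble::tibble(
    protein_id      = first_accession(get_col("protein_id")),
    gene_symbol     = first_accession(get_col("gene_symbol")),
    unique_peptides = parse_count_col(get_col("unique_peptides"), dialect[["unique_peptides"]]),
    ratio_hl        = parse_ratio_col(get_col("ratio_hl"), dialect[["ratio_hl"]]),
    ratio_hm        = parse_ratio_col(get_col("ratio_hm"), dialect[["ratio_hm"]]),
    ratio_ml        = parse_ratio_col(get_col("ratio_ml"), dialect[["ratio_ml"]]),
    is_contaminant  = flag_col(get_col("is_contaminant", "")),
    is_reverse      = flag_col(get_col("is_reverse", "")),
    replicate_id    = as.integer(replicate_id)
  )
}

first_accession <- function(x) {
  out <- stringr::str_trim(stringr::str_split_i(x, ";", 1))
  out[is.na(out)] <- ""
  out
}

flag_col <- function(x) {
  x <- stringr::str_trim(ifelse(is.na(x), "", x))
  x != ""
}

parse_ratio_col <- function(x, colname) {
  x <- stringr::str_trim(x)
  x[x %in% c("", "NaN", "NA", "nan")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop("non-numeric value in column '", colname, "' at row ", bad[1],
         ": '", x[bad[1]], "'", call. = FALSE)
  }
  out[!is.finite(out)] <- NA_real_
  out
}

parse_count_col <- function(x, colname) {
  out <- parse_ratio_col(x, colname)
  out[is.na(out)] <- 0
  as.integer(out)
}

#' Identifier key for set operations
#'
#' Returns the identifier each protein record contributes to curated-list and
#' annotation set operations: the gene symbol when present, otherwise the
#' first majority accession. Case folding to uppercase is on by default so
#' that hand-curated gene lists match regardless of capitalization.
#'
#' @param records Protein-group record tibble (see [read_protein_groups()]).
#' @param case_fold Uppercase identifiers before matching? Default `TRUE`.
#' @return Character vector of identifiers, one per row of `records`.
#' @export
record_key <- function(records, case_fold = TRUE) {
  key <- ifelse(!is.na(records$gene_symbol) & records$gene_symbol != "",
                records$gene_symbol, records$protein_id)
  if (case_fold) key <- toupper(key)
  key
}

#' Read a curated identifier list
#'
#' Reads a plain-text identifier list: either one identifier per line, or a
#' two-column (set name, identifier) tab/whitespace-separated file from which
#' the rows matching `name` are taken (all rows if the file is one-column).
#' Lines starting with `#` are skipped. Identifiers are whitespace-trimmed,
#' de-duplicated and, by default, uppercased.
#'
#' @param path Path to the list file.
#' @param name Label for the set (used in error messages and reports).
#' @param case_fold Uppercase identifiers? Default `TRUE`.
#' @return Character vector of unique identifiers with attribute `"name"`.
#' @export
read_id_set <- function(path, name = basename(path), case_fold = TRUE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  if (length(lines) == 0) {
    stop("identifier list '", name, "' is empty", call. = FALSE)
  }
  parts <- stringr::str_split(lines, "[\t ]+")
  two_col <- all(lengths(parts) >= 2)
  ids <- if (two_col) {
    keep <- purrr::map_chr(parts, 1) == name
    if (!any(keep)) keep <- rep(TRUE, length(parts))  # single foreign set name
    purrr::map_chr(parts[keep], 2)
  } else {
    purrr::map_chr(parts, 1)
  }
  id_set(ids, name = name, case_fold = case_fold)
}

#' Construct an identifier set
#'
#' @param ids Character vector of identifiers (trimmed, de-duplicated).
#' @param name Set label.
#' @param case_fold Uppercase identifiers? Default `TRUE`.
#' @return Character vector of unique identifiers with attribute `"name"`.
#' @export
id_set <- function(ids, name = "set", case_fold = TRUE) {
  ids <- stringr::str_trim(as.character(ids))
  ids <- ids[!is.na(ids) & ids != ""]
  if (case_fold) ids <- toupper(ids)
  ids <- unique(ids)
  if (length(ids) == 0) stop("identifier set '", name, "' is empty", call. = FALSE)
  structure(ids, name = name)
}

#' Read an annotation catalog
#'
#' Reads a two-column tab-separated file (`compartment_label`, `identifier`,
#' no header required; a header row whose first field is
#' `"compartment_label"` is skipped) into a catalog tibble. A protein may
#' belong to several compartments.
#'
#' @param path Path to the two-column TSV.
#' @param case_fold Uppercase identifiers? Default `TRUE`.
#' @return Tibble with columns `compartment` and `id`, de-duplicated.
#' @export
read_annotation_catalog <- function(path, case_fold = TRUE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  parts <- stringr::str_split(lines, "\t")
  if (any(lengths(parts) < 2)) {
    stop("annotation catalog must have two tab-separated columns", call. = FALSE)
  }
  out <- tibble::tibble(
    compartment = purrr::map_chr(parts, 1),
    id = purrr::map_chr(parts, 2)
  )
  out <- dplyr::filter(out, .data$compartment != "compartment_label")
  if (case_fold) out$id <- toupper(out$id)
  dplyr::distinct(out)
}

#' Extract one compartment's identifier set from a catalog
#'
#' @param catalog Catalog tibble from [read_annotation_catalog()].
#' @param compartment Compartment label to extract.
#' @return Identifier set (see [id_set()]).
#' @export
catalog_set <- function(catalog, compartment) {
  ids <- catalog$id[catalog$compartment == compartment]
  if (length(ids) == 0) {
    stop("catalog has no compartment '", compartment, "'", call. = FALSE)
  }
  id_set(ids, name = compartment, case_fold = FALSE)
}

#' Read an iTRAQ per-protein ratio table
#'
#' Reads a tab-separated table of isobaric-tag IP-MS quantifications with
#' list-valued ratio cells: `protein_id`, `unique_quantified_peptides`,
#' `ratios_116_114`, `ratios_117_115` (delimiter-separated positive ratio
#' observations; empty cell means no observations), and optional
#' `is_contaminant` / `is_reverse` flag columns.
#'
#' @param path Path to the TSV.
#' @param delim Delimiter inside ratio-list cells. Default `";"`.
#' @return Tibble with list-columns `ratios_116_114`, `ratios_117_115`
#'   (numeric vectors) plus the scalar columns above.
#' @export
read_itraq_table <- function(path, delim = ";") {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  need <- c("protein_id", "unique_quantified_peptides", "ratios_116_114", "ratios_117_115")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("iTRAQ table is missing column '", missing[1], "'", call. = FALSE)
  }
  parse_list <- function(x) {
    purrr::map(x, function(cell) {
      cell <- stringr::str_trim(ifelse(is.na(cell), "", cell))
      if (cell == "") return(numeric(0))
      vals <- as.numeric(stringr::str_split_1(cell, stringr::fixed(delim)))
      if (anyNA(vals)) stop("non-numeric ratio in iTRAQ cell: '", cell, "'", call. = FALSE)
      if (any(vals <= 0)) stop("non-positive ratio in iTRAQ cell: '", cell, "'", call. = FALSE)
      vals
    })
  }
  tibble::tibble(
    protein_id = raw$protein_id,
    unique_quantified_peptides = parse_count_col(raw$unique_quantified_peptides,
                                                 "unique_quantified_peptides"),
    ratios_116_114 = parse_list(raw$ratios_116_114),
    ratios_117_115 = parse_list(raw$ratios_117_115),
    is_contaminant = if ("is_contaminant" %in% names(raw)) flag_col(raw$is_contaminant) else FALSE,
    is_reverse = if ("is_reverse" %in% names(raw)) flag_col(raw$is_reverse) else FALSE
  )
}

#' Read traced organelle contours
#'
#' Reads a CSV of traced 2-D organelle contours in nanometre coordinates:
#' columns `contour_id`, `organelle` (`"mito"` or `"er"`), `er_class`
#' (`"rough"`, `"smooth"` or `"unclassified"`; ignored for mitochondria),
#' `closed` (logical), `point_index`, `x_nm`, `y_nm` and optionally
#' `condition_label`. Points are ordered by `point_index` within each
#' contour. Mitochondrial contours must be closed with at least 3 points;
#' consecutive duplicate points are rejected.
#'
#' @param path Path to the CSV.
#' @return Contour tibble (one row per point) sorted by contour and index.
#' @export
read_contours <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    contour_id = readr::col_character(),
    organelle = readr::col_character(),
    er_class = readr::col_character(),
    closed = readr::col_logical(),
    point_index = readr::col_integer(),
    x_nm = readr::col_double(),
    y_nm = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  if (!"condition_label" %in% names(raw)) raw$condition_label <- ""
  out <- dplyr::arrange(raw, .data$contour_id, .data$point_index)
  validate_contours(out)
  out
}

validate_contours <- function(contours) {
  stopifnot(all(contours$organelle %in% c("mito", "er")))
  by_id <- split(contours, contours$contour_id)
  for (ct in by_id) {
    n <- nrow(ct)
    closed <- ct$closed[1]
    if (ct$organelle[1] == "mito" && !closed) {
      warning("mitochondrial contour '", ct$contour_id[1], "' is not closed",
              call. = FALSE)
    }
    if (n < 2 || (closed && n < 3)) {
      stop("contour '", ct$contour_id[1], "' has too few points", call. = FALSE)
    }
    d <- sqrt(diff(ct$x_nm)^2 + diff(ct$y_nm)^2)
    if (any(d == 0)) {
      stop("contour '", ct$contour_id[1], "' has consecutive duplicate points",
           call. = FALSE)
    }
  }
  invisible(contours)
}

#' Write a deterministic report file
#'
#' Serializes any of the pipeline's tabular or structured results with
#' deterministic row order (sorted by the first identifier-like column) and
#' fixed float rendering, so identical inputs produce byte-identical files.
#' Result objects (`roc_result`, `proteome_call`, `eb_prior`,
#' `contact_report`) are flattened via their [generics::tidy()] method for
#' TSV output and serialized structurally for JSON.
#'
#' @param x A tibble/data frame or a package result object.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- if (is.data.frame(x)) sort_report(x) else unclass_deep(x)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(path))
  }
  tab <- if (is.data.frame(x)) x else generics::tidy(x)
  tab <- sort_report(tab)
  num <- vapply(tab, is.numeric, logical(1)) & !vapply(tab, is.integer, logical(1))
  tab[num] <- lapply(tab[num], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  })
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

sort_report <- function(tab) {
  key <- intersect(c("protein_id", "id", "contour_id", "mito_id"), names(tab))
  if (length(key) > 0) tab <- dplyr::arrange(tab, dplyr::across(dplyr::all_of(key)))
  tab
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(sort_report(tibble::as_tibble(x)))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (!is.null(attr(x, "name"))) attr(x, "name") <- NULL
  x
}

#' Re-read a TSV report written by [write_report()]
#'
#' @param path Path to the TSV report.
#' @return Tibble with numeric columns restored.
#' @export
read_report_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         na = "NA")
  tibble::as_tibble(out)
}
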