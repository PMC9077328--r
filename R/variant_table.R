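# Default column names of a gnomAD v2 per-gene CSV export.
default_column_map <- function() {
  list(
    hgvs_p = "Protein Consequence",
    vep_annotation = "VEP Annotation",
    clinvar_significance = "ClinVar Clinical Significance",
    allele_count = "Allele Count",
    allele_number = "Allele Number",
    allele_frequency = "Allele Frequency",
    chromosome = "Chromosome",
    genomic_position = "Position",
    ref = "Reference",
    alt = "Alternate"
  )
}

MANDATORY_COLUMNS <- c(
  "hgvs_p", "vep_annotation",
  "allele_count", "allele_number", "allele_frequency"
)

#' Read a gnomAD-style variant CSV export
#'
#' Reads a per-gene population variant table (gnomAD v2 export dialect:
#' RFC-4180 CSV, UTF-8, header row), parses the HGVS protein consequence of
#' every row, and returns one record per parseable row. Rows whose protein
#' consequence is empty or not a simple substitution are skipped and counted;
#' rows with `allele_number = 0` or an allele frequency outside `[0, 1]` are
#' rejected defensively, also with a count. Missing allele frequencies are
#' recomputed as allele count / allele number.
#'
#' @param path Path to the CSV file.
#' @param protein_id Optional identifier attached to every record.
#' @param column_map Named list overriding the default gnomAD column names,
#'   e.g. `list(hgvs_p = "HGVS Consequence")`. Names as in
#'   `missensemap:::default_column_map()`.
#' @return A tibble of variant records with columns `protein_id`, `hgvs_p`,
#'   `ref_aa`, `position`, `alt_aa`, `vep_annotation`,
#'   `clinvar_significance` (all-`NA` when the export has no ClinVar column),
#'   `allele_count`, `allele_number`, `allele_frequency`, and the genomic
#'   locus columns (`chromosome`, `genomic_position`, `ref`, `alt`) when
#'   present in the export. A parse report (row, skip and reject counts) is
#'   attached as attribute `"parse_report"`; retrieve it with
#'   [parse_report()].
#' @seealso [filter_neutral_missense()], [write_variant_table()]
#' @export
read_variant_table <- function(path, protein_id = NA_character_,
                               column_map = list()) {
  if (!file.exists(path)) {
    mm_io_error(sprintf("variant table not found: %s", path))
  }
  cmap <- utils::modifyList(default_column_map(), as.list(column_map))
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE),
    error = function(e) mm_io_error(sprintf("cannot read %s: %s", path,
                                            conditionMessage(e)))
  )
  missing <- vapply(MANDATORY_COLUMNS,
                    function(f) !(cmap[[f]] %in% names(raw)), logical(1))
  if (any(missing)) {
    mm_config_error(sprintf(
      "mandatory column(s) missing from %s: %s", path,
      paste(unlist(cmap[MANDATORY_COLUMNS[missing]]), collapse = ", ")))
  }

  has_clinvar <- cmap$clinvar_significance %in% names(raw)
  parsed <- parse_hgvs_p(raw[[cmap$hgvs_p]])

  rec <- tibble(
    protein_id = protein_id,
    hgvs_p = parsed$hgvs_p,
    ref_aa = parsed$ref_aa,
    position = parsed$position,
    alt_aa = parsed$alt_aa,
    vep_annotation = raw[[cmap$vep_annotation]],
    clinvar_significance = if (has_clinvar) {
      raw[[cmap$clinvar_significance]]
    } else {
      NA_character_
    },
    allele_count = suppressWarnings(as.integer(raw[[cmap$allele_count]])),
    allele_number = suppressWarnings(as.integer(raw[[cmap$allele_number]])),
    allele_frequency = suppressWarnings(as.numeric(raw[[cmap$allele_frequency]]))
  )
  for (f in c("chromosome", "genomic_position", "ref", "alt")) {
    if (cmap[[f]] %in% names(raw)) rec[[f]] <- raw[[cmap[[f]]]]
  }

  n_rows <- nrow(rec)
  keep_cons <- parsed$valid
  n_skipped <- sum(!keep_cons)

  rec <- rec[keep_cons, , drop = FALSE]
  rec$allele_frequency <- ifelse(
    is.na(rec$allele_frequency) & !is.na(rec$allele_count) &
      !is.na(rec$allele_number) & rec$allele_number > 0L,
    rec$allele_count / rec$allele_number,
    rec$allele_frequency
  )
  bad_allele <- is.na(rec$allele_number) | rec$allele_number <= 0L |
    is.na(rec$allele_frequency) |
    rec$allele_frequency < 0 | rec$allele_frequency > 1
  n_rejected <- sum(bad_allele)
  if (n_rejected > 0L) {
    warn(sprintf("%d row(s) rejected: allele_number = 0 or allele frequency outside [0, 1]",
                 n_rejected))
  }
  rec <- rec[!bad_allele, , drop = FALSE]

  attr(rec, "parse_report") <- list(
    path = path,
    n_rows = n_rows,
    n_records = nrow(rec),
    n_skipped_consequence = n_skipped,
    n_rejected_allele = n_rejected,
    has_clinvar_column = has_clinvar
  )
  rec
}

#' Write variant records back to a gnomAD-style CSV
#'
#' Re-emits records read by [read_variant_table()] (possibly filtered, or
#' audited with a `retained` column) using the default gnomAD export column
#' names, so outputs of a run are themselves valid inputs.
#'
#' @param records Variant-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  cmap <- default_column_map()
  out <- tibble(
    `Protein Consequence` = records$hgvs_p,
    `VEP Annotation` = records$vep_annotation,
    `ClinVar Clinical Significance` = records$clinvar_significance,
    `Allele Count` = records$allele_count,
    `Allele Number` = records$allele_number,
    `Allele Frequency` = records$allele_frequency
  )
  for (f in c("chromosome", "genomic_position", "ref", "alt")) {
    if (f %in% names(records)) out[[cmap[[f]]]] <- records[[f]]
  }
  if ("retained" %in% names(records)) out$retained <- records$retained
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Retrieve the report attached to a parsed or filtered table
#'
#' @param x An object returned by [read_variant_table()] (attribute
#'   `"parse_report"`), [filter_neutral_missense()] (`"filter_report"`) or
#'   [aggregate_by_residue()] (`"aggregation_report"`).
#' @return A named list of counts, or `NULL` when no report is attached.
#' @export
parse_report <- function(x) {
  attr(x, "parse_report", exact = TRUE) %||%
    attr(x, "filter_report", exact = TRUE) %||%
    attr(x, "aggregation_report", exact = TRUE)
}
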