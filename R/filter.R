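#' Construct a neutral-missense filter policy
#'
#' The policy keeps variants whose VEP consequence is missense and whose
#' ClinVar clinical significance is absent, benign-class, or otherwise not in
#' the excluded set. The default excluded classes are pathogenic, likely
#' pathogenic, conflicting interpretations of pathogenicity, and uncertain
#' significance, so that only plausibly neutral missense variation remains.
#'
#' Matching is case-insensitive after trimming and collapsing internal
#' whitespace. Multi-valued ClinVar cells (e.g. `"Benign/Likely benign"`) are
#' split on `/` and `;` and the record is excluded if any token matches an
#' excluded class.
#'
#' @param required_vep Accepted VEP annotation strings. Both
#'   `"missense_variant"` (gnomAD export) and `"missense"` are accepted by
#'   default.
#' @param excluded_clinvar ClinVar significance classes to exclude.
#' @param keep_unannotated_clinvar Keep records with no ClinVar annotation
#'   (default `TRUE`).
#' @return An object of class `mm_filter_policy`.
#' @export
filter_policy <- function(required_vep = c("missense_variant", "missense"),
                          excluded_clinvar = c(
                            "pathogenic",
                            "likely pathogenic",
                            "conflicting interpretations of pathogenicity",
                            "uncertain significance"
                          ),
                          keep_unannotated_clinvar = TRUE) {
  required_vep <- canon_label(required_vep)
  if (length(required_vep) == 0L || all(required_vep == "")) {
    mm_argument_error("`required_vep` must be a non-empty set of annotations")
  }
  structure(
    list(
      required_vep = required_vep,
      excluded_clinvar = canon_label(excluded_clinvar),
      keep_unannotated_clinvar = isTRUE(keep_unannotated_clinvar)
    ),
    class = "mm_filter_policy"
  )
}

# TRUE where the ClinVar cell hits an excluded class (any token of a
# multi-valued cell counts)
clinvar_excluded <- function(x, policy) {
  unannotated <- is.na(x) | trimws(x) == ""
  tokens <- str_split(canon_label(x), "\\s*[/;]\\s*")
  hit <- vapply(tokens, function(tk) any(tk %in% policy$excluded_clinvar),
                logical(1))
  ifelse(unannotated, !policy$keep_unannotated_clinvar, hit)
}

#' Filter variant records to neutral missense variants
#'
#' Applies the neutral-missense policy: keep records whose VEP annotation is
#' in the accepted set and whose ClinVar significance is not in the excluded
#' set (records without a ClinVar entry are kept by default). Records whose
#' parsed consequence is synonymous (`ref_aa == alt_aa`) are also removed, so
#' every retained record is a genuine substitution. Input order is preserved
#' and the operation is idempotent.
#'
#' @param records Variant-record tibble from [read_variant_table()].
#' @param policy A [filter_policy()]; the default implements the standard
#'   neutral-missense rules.
#' @param audit If `TRUE`, return all input rows with a logical `retained`
#'   column instead of dropping rows.
#' @param dedupe If `TRUE`, collapse duplicate rows (identical genomic locus
#'   when present, else identical consequence + allele statistics) before
#'   filtering. Off by default: exports are taken as-is.
#' @return The retained records (or the audited full table), with a
#'   `"filter_report"` attribute counting removals per rule:
#'   `n_input`, `removed_vep`, `removed_no_vep_annotation` (subset of
#'   `removed_vep` with an empty annotation cell), `removed_clinvar`,
#'   `removed_synonymous`, `n_duplicates_collapsed`, `n_retained`.
#' @examples
#' tbl <- tibble::tibble(
#'   protein_id = "P1", hgvs_p = "p.Arg5Cys", ref_aa = "R", position = 5L,
#'   alt_aa = "C", vep_annotation = "missense_variant",
#'   clinvar_significance = NA_character_, allele_count = 1L,
#'   allele_number = 1000L, allele_frequency = 1e-3
#' )
#' filter_neutral_missense(tbl)
#' @export
filter_neutral_missense <- function(records, policy = filter_policy(),
                                    audit = FALSE, dedupe = FALSE) {
  if (!inherits(policy, "mm_filter_policy")) {
    mm_argument_error("`policy` must be created with filter_policy()")
  }
  n_dup <- 0L
  if (isTRUE(dedupe) && nrow(records) > 0L) {
    key_cols <- if (all(c("chromosome", "genomic_position", "ref", "alt") %in%
                        names(records))) {
      c("chromosome", "genomic_position", "ref", "alt")
    } else {
      c("hgvs_p", "allele_count", "allele_number")
    }
    before <- nrow(records)
    records <- dplyr::distinct(records, dplyr::across(dplyr::all_of(key_cols)),
                               .keep_all = TRUE)
    n_dup <- before - nrow(records)
  }

  no_vep <- is.na(records$vep_annotation) |
    trimws(records$vep_annotation) == ""
  vep_ok <- canon_label(records$vep_annotation) %in% policy$required_vep
  clin_bad <- clinvar_excluded(records$clinvar_significance, policy)
  synonymous <- !is.na(records$ref_aa) & !is.na(records$alt_aa) &
    records$ref_aa == records$alt_aa

  retained <- vep_ok & !clin_bad & !synonymous

  report <- list(
    n_input = nrow(records),
    removed_vep = sum(!vep_ok),
    removed_no_vep_annotation = sum(no_vep & !vep_ok),
    removed_clinvar = sum(vep_ok & clin_bad),
    removed_synonymous = sum(vep_ok & !clin_bad & synonymous),
    n_duplicates_collapsed = n_dup,
    n_retained = sum(retained)
  )

  out <- if (isTRUE(audit)) {
    dplyr::mutate(records, retained = retained)
  } else {
    records[retained, , drop = FALSE]
  }
  attr(out, "parse_report") <- NULL
  attr(out, "filter_report") <- report
  out
}
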