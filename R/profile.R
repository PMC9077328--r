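# Right-closed upper edges of frequency bins 1..5; bin 6 ends at 1.
BIN_EDGES <- c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1)

#' Assign allele frequencies to visualization bins
#'
#' Allele frequencies are compressed on a base-10 log scale into 6 bins, one
#' per decade: bin k covers `(10^(k-6), 10^(k-5)]`, with every frequency at or
#' below `1e-5` (including those below `1e-6`) in bin 1 and `af = 1` in
#' bin 6. Intervals are half-open on the left and closed on the right, so
#' exact powers of ten sit in the lower bin (`1e-4` is in bin 2) and `af = 1`
#' is binnable.
#'
#' @param af Numeric vector of allele frequencies in `(0, 1]`.
#' @return Integer vector of bin indices in `1..6`.
#' @examples
#' assign_frequency_bin(c(1e-7, 1e-4, 1))
#' @export
assign_frequency_bin <- function(af) {
  if (length(af) == 0L) return(integer(0))
  if (anyNA(af) || any(af <= 0 | af > 1)) {
    mm_argument_error("allele frequencies must lie in (0, 1] and be non-missing")
  }
  findInterval(af, BIN_EDGES, left.open = TRUE) + 1L
}

new_residue_profile <- function(aggregates, protein_id, protein_length,
                                report = list()) {
  vp <- nrow(aggregates) / protein_length
  structure(
    aggregates,
    protein_id = protein_id,
    protein_length = as.integer(protein_length),
    vp = vp,
    aggregation_report = report,
    class = c("residue_profile", class(tibble()))
  )
}

#' Aggregate filtered variants per residue
#'
#' Builds a per-residue profile from filtered (neutral missense) variant
#' records. Multiple variants at the same residue are multiallelic
#' observations of disjoint events, so their allele frequencies are summed
#' (capped at 1, since frequencies are probabilities). Each variable residue
#' gets a log10 frequency bin via [assign_frequency_bin()], and the
#' whole-protein variant density Vp is the number of variable residue
#' positions divided by the protein length.
#'
#' Records with `allele_frequency = 0` are dropped (log-scale binning is
#' undefined at 0) and records whose position exceeds `protein_length` are
#' skipped; both with warnings counted in the aggregation report.
#'
#' @param records Filtered variant-record tibble.
#' @param protein_length Length of the canonical protein sequence (residues).
#' @param protein_id Optional identifier; defaults to the records' id.
#' @return A `residue_profile`: a tibble with one row per variable residue
#'   (`position`, `summed_af`, `n_variants`, `bin_index`, ordered by
#'   position) carrying attributes `protein_id`, `protein_length`, `vp` and
#'   an `aggregation_report`. Access Vp with `vp()` or [glance()].
#' @examples
#' recs <- tibble::tibble(
#'   position = c(50L, 50L, 7L), allele_frequency = c(1e-5, 2e-5, 1e-3)
#' )
#' prof <- aggregate_by_residue(recs, protein_length = 100)
#' vp(prof)
#' @export
aggregate_by_residue <- function(records, protein_length, protein_id = NULL) {
  protein_length <- check_scalar_count(protein_length, "protein_length")
  protein_id <- protein_id %||%
    (if ("protein_id" %in% names(records)) records$protein_id[1] else NA_character_) %||%
    NA_character_

  af <- records$allele_frequency
  pos <- records$position
  zero_af <- !is.na(af) & af == 0
  out_of_range <- !is.na(pos) & (pos > protein_length | pos < 1L)
  n_zero <- sum(zero_af)
  n_oor <- sum(out_of_range & !zero_af)
  if (n_zero > 0L) {
    warn(sprintf("%d record(s) with allele_frequency = 0 dropped before aggregation", n_zero))
  }
  if (n_oor > 0L) {
    warn(sprintf("%d record(s) with position outside 1..%d skipped", n_oor, protein_length))
  }
  keep <- !zero_af & !out_of_range & !is.na(pos) & !is.na(af)

  agg <- tibble(position = as.integer(pos[keep]), af = af[keep]) |>
    dplyr::group_by(position) |>
    dplyr::summarise(raw_sum = sum(af), n_variants = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(position)
  n_capped <- sum(agg$raw_sum > 1)
  agg <- agg |>
    dplyr::mutate(summed_af = pmin(raw_sum, 1)) |>
    dplyr::mutate(bin_index = if (dplyr::n() > 0) assign_frequency_bin(summed_af) else integer(0)) |>
    dplyr::select(position, summed_af, n_variants, bin_index)
  if (n_capped > 0L) {
    warn(sprintf("summed allele frequency capped at 1 for %d residue(s)", n_capped))
  }

  new_residue_profile(
    agg, protein_id, protein_length,
    report = list(
      n_records = nrow(records),
      n_used = sum(keep),
      n_zero_af_dropped = n_zero,
      n_out_of_range_skipped = n_oor,
      n_capped = n_capped
    )
  )
}

#' Whole-protein missense variant density
#'
#' @param profile A `residue_profile`.
#' @return Vp: variable residue positions / protein length.
#' @export
vp <- function(profile) {
  stopifnot(inherits(profile, "residue_profile"))
  attr(profile, "vp", exact = TRUE)
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf(
    "<residue_profile> %s: length %d, %d variable position(s), Vp = %.4g\n",
    attr(x, "protein_id") %||% "?", attr(x, "protein_length"), nrow(x),
    attr(x, "vp")
  ))
  NextMethod()
}

#' Write / read a residue profile as TSV
#'
#' The profile table (`position`, `summed_af`, `n_variants`, `bin_index`) is
#' written as TSV, with `protein_id`, `protein_length` and `vp` preserved in
#' leading `# key=value` comment lines so the file round-trips exactly.
#'
#' @param profile A `residue_profile`.
#' @param path Output (or input) TSV path.
#' @return `write_profile_tsv()` returns `path` invisibly;
#'   `read_profile_tsv()` returns the reconstructed `residue_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "residue_profile"))
  hdr <- c(
    sprintf("# protein_id=%s", attr(profile, "protein_id") %||% "NA"),
    sprintf("# protein_length=%d", attr(profile, "protein_length")),
    sprintf("# vp=%s", format(attr(profile, "vp"), digits = 17))
  )
  body <- strsplit(readr::format_tsv(as_tibble(profile)), "\n", fixed = TRUE)[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  if (!file.exists(path)) mm_io_error(sprintf("profile not found: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- str_match(hdr, "^#\\s*([a-z_]+)=(.*)$")
  meta <- stats::setNames(as.list(kv[, 3]), kv[, 2])
  body <- lines[!grepl("^#", lines)]
  tab <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         col_types = "idii", progress = FALSE,
                         show_col_types = FALSE)
  tab <- as_tibble(as.data.frame(tab))  # drop reader metadata attributes
  pid <- meta$protein_id
  if (is.null(pid) || identical(pid, "NA")) pid <- NA_character_
  new_residue_profile(tab, pid, as.integer(meta$protein_length))
}
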