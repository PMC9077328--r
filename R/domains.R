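#' Read a domain-boundary table
#'
#' Domain boundaries are user-defined (InterPro or literature coordinates on
#' the canonical sequence) and supplied as a plain-text file with one domain
#' per line: `name start end`, whitespace- or tab-delimited, 1-based
#' inclusive coordinates. Lines beginning with `#` and blank lines are
#' ignored. Overlapping or nested domains are permitted (e.g. JmjN and JmjC
#' scored separately).
#'
#' @param path Path to the text file.
#' @return A tibble `name`, `start`, `end` in file order.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) mm_io_error(sprintf("domain file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    return(tibble(name = character(0), start = integer(0), end = integer(0)))
  }
  parts <- str_split(trimws(lines[keep]), "\\s+")
  res <- purrr::map2(parts, keep, function(p, ln) {
    if (length(p) != 3L) {
      mm_format_error(sprintf("line %d: expected 'name start end', got %d field(s)",
                              ln, length(p)))
    }
    start <- suppressWarnings(as.integer(p[2]))
    end <- suppressWarnings(as.integer(p[3]))
    if (is.na(start) || is.na(end) ||
        p[2] != as.character(start) || p[3] != as.character(end)) {
      mm_format_error(sprintf("line %d: non-integer domain bounds '%s %s'",
                              ln, p[2], p[3]))
    }
    if (start < 1L || start > end) {
      mm_format_error(sprintf("line %d: invalid interval %d..%d (need 1 <= start <= end)",
                              ln, start, end))
    }
    tibble(name = p[1], start = start, end = end)
  })
  dplyr::bind_rows(res)
}

#' Compute per-domain Vd/Vp depletion ratios
#'
#' For each domain, Vd is the density of variable residue positions within
#' the domain (distinct positions carrying at least one retained missense
#' variant, divided by domain length) and Vp the same density over the whole
#' protein. The ratio Vd/Vp compares the domain's missense variation to the
#' protein average: values below 1 indicate missense depletion, a classic
#' signature of functional constraint. Densities count distinct variable
#' positions, not variant records, so multiallelic residues are not
#' double-counted. A domain spanning the whole protein has ratio exactly 1.
#'
#' @param profile A `residue_profile` from [aggregate_by_residue()].
#' @param domains Tibble `name`, `start`, `end` (see [read_domain_table()]),
#'   1-based inclusive, all within the protein length.
#' @return A tibble with one row per domain, in input order: `name`, `start`,
#'   `end`, `domain_length`, `variable_in_domain`, `vd`,
#'   `variable_in_protein`, `protein_length`, `vp`, `vdvp_ratio` (`NA` with
#'   `undefined = TRUE` when Vp is 0) and `vdvp_label` (ratio printed to two
#'   decimals, as conventionally reported above 1D plots).
#' @examples
#' recs <- tibble::tibble(position = 1:10, allele_frequency = 1e-4)
#' prof <- aggregate_by_residue(recs, protein_length = 100)
#' compute_vdvp(prof, tibble::tibble(name = "D1", start = 1L, end = 20L))
#' @export
compute_vdvp <- function(profile, domains) {
  stopifnot(inherits(profile, "residue_profile"))
  L <- attr(profile, "protein_length")
  if (nrow(domains) > 0L) {
    bad <- domains$start < 1L | domains$end > L | domains$start > domains$end
    if (any(bad)) {
      mm_argument_error(sprintf(
        "domain(s) outside 1..%d or inverted: %s", L,
        paste(domains$name[bad], collapse = ", ")))
    }
  }
  n_var <- nrow(profile)
  vp_val <- attr(profile, "vp")
  pos <- profile$position

  out <- domains |>
    dplyr::rowwise() |>
    dplyr::mutate(
      domain_length = end - start + 1L,
      variable_in_domain = sum(pos >= start & pos <= end)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      vd = variable_in_domain / domain_length,
      variable_in_protein = n_var,
      protein_length = L,
      vp = vp_val,
      undefined = vp_val == 0,
      vdvp_ratio = ifelse(undefined, NA_real_, vd / vp_val),
      vdvp_label = ifelse(undefined, "NA", sprintf("%.2f", vdvp_ratio))
    )
  out
}

#' Write Vd/Vp results as TSV
#'
#' Ratios are printed to two decimals in `vdvp_label` with full precision
#' retained in `vdvp_ratio`.
#'
#' @param results Tibble from [compute_vdvp()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_vdvp_tsv <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}
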