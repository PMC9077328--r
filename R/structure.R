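#' Load a protein structure (PDB or mmCIF)
#'
#' Parses a structure file into a per-residue index used for mapping variant
#' profiles. Format is auto-detected from the extension (`.pdb`/`.ent` vs
#' `.cif`/`.mmcif`), falling back to content sniffing (`data_`/`loop_`
#' blocks mark mmCIF). For predicted models the B-factor column holds the
#' per-residue pLDDT confidence score.
#'
#' @param path Path to a PDB or mmCIF file.
#' @return A `structure_model`: list with `path`, `format`, `chains`, and
#'   `residues` — a tibble (`chain`, `resno`, `insert`, `has_ca`,
#'   `b_factor`), `b_factor` taken from the C-alpha atom when present.
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) mm_io_error(sprintf("structure not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  fmt <- if (ext %in% c("pdb", "ent")) {
    "pdb"
  } else if (ext %in% c("cif", "mmcif")) {
    "cif"
  } else {
    head_lines <- readLines(path, n = 20L, warn = FALSE)
    if (any(grepl("^(data_|loop_|_atom_site\\.)", head_lines))) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (fmt == "cif") {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
    },
    error = function(e) {
      mm_format_error(sprintf("cannot parse structure %s as %s: %s",
                              path, fmt, conditionMessage(e)))
    }
  )
  atoms <- as_tibble(parsed$atom)
  if (nrow(atoms) == 0L) {
    mm_format_error(sprintf("no atoms parsed from %s", path))
  }
  residues <- atoms |>
    dplyr::filter(type %in% c("ATOM", "HETATM")) |>
    dplyr::group_by(chain, resno, insert) |>
    dplyr::summarise(
      has_ca = any(elety == "CA"),
      b_factor = if (any(elety == "CA")) b[elety == "CA"][1] else b[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(chain, resno)

  structure(
    list(
      path = path,
      format = fmt,
      chains = sort(unique(residues$chain)),
      residues = residues
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s (%s): %d chain(s), %d residue(s)\n",
              x$path, x$format, length(x$chains), nrow(x$residues)))
  invisible(x)
}

#' Map a residue profile onto a structure chain
#'
#' Resolves every profile position to a residue of one chain using a constant
#' numbering offset (structure residue number = profile position + offset).
#' Positions absent from the chain, lacking a C-alpha atom (spheres are drawn
#' at C-alpha), or — when `plddt_min` is set — with a pLDDT at or below the
#' threshold, are reported as unmapped with a reason; the mapping is total
#' over profile positions. For predicted models the conventional cut-off is
#' `plddt_min = 70` (above it the backbone is generally correct).
#'
#' Chains containing insertion codes are not addressable by a constant
#' integer offset and are rejected: silent mis-mapping is worse than failure.
#'
#' @param profile A `residue_profile`.
#' @param model A `structure_model` from [load_structure()].
#' @param chain Chain identifier in the model.
#' @param offset Integer numbering offset (default 0).
#' @param plddt_min If set, residues with `b_factor <= plddt_min` are masked.
#' @return A `structure_annotation`: list with `chain`, `offset`,
#'   `plddt_min`, `structure_path`, `mapped` (tibble `position`, `resno`,
#'   `bin_index`, `summed_af`, `n_variants`), `unmapped` (tibble `position`,
#'   `reason` in `absent_residue` / `no_ca` / `plddt_below_threshold`), and
#'   empty pathogenic slots filled by [overlay_pathogenic()].
#' @export
map_profile <- function(profile, model, chain, offset = 0L,
                        plddt_min = NULL) {
  stopifnot(inherits(profile, "residue_profile"),
            inherits(model, "structure_model"))
  if (!chain %in% model$chains) {
    mm_argument_error(sprintf("chain '%s' not in structure (chains: %s)",
                              chain, paste(model$chains, collapse = ", ")))
  }
  offset <- as.integer(offset)
  res <- model$residues[model$residues$chain == chain, , drop = FALSE]
  if (any(!is.na(res$insert) & res$insert != "")) {
    mm_argument_error(sprintf(
      "chain '%s' contains insertion codes; integer-offset mapping would be ambiguous",
      chain))
  }

  status <- resolve_positions(profile$position, res, offset, plddt_min)
  mapped_idx <- which(is.na(status))

  structure(
    list(
      chain = chain,
      offset = offset,
      plddt_min = plddt_min,
      structure_path = model$path,
      mapped = tibble(
        position = profile$position[mapped_idx],
        resno = profile$position[mapped_idx] + offset,
        bin_index = profile$bin_index[mapped_idx],
        summed_af = profile$summed_af[mapped_idx],
        n_variants = profile$n_variants[mapped_idx]
      ),
      unmapped = tibble(
        position = profile$position[!is.na(status)],
        reason = status[!is.na(status)]
      ),
      pathogenic_mapped = tibble(position = integer(0), label = character(0),
                                 resno = integer(0)),
      pathogenic_unmapped = tibble(position = integer(0), label = character(0),
                                   reason = character(0))
    ),
    class = "structure_annotation"
  )
}

# NA = mapped; otherwise the unmapped reason. Shared by profile and
# pathogenic mapping so both obey identical rules.
resolve_positions <- function(positions, chain_residues, offset, plddt_min) {
  target <- positions + offset
  idx <- match(target, chain_residues$resno)
  reason <- rep(NA_character_, length(positions))
  reason[is.na(idx)] <- "absent_residue"
  ok <- !is.na(idx)
  no_ca <- ok & !chain_residues$has_ca[idx]
  reason[no_ca] <- "no_ca"
  if (!is.null(plddt_min)) {
    low <- ok & !no_ca & chain_residues$b_factor[idx] <= plddt_min
    reason[low] <- "plddt_below_threshold"
  }
  reason
}

#' Overlay externally curated pathogenic variants
#'
#' Pathogenic variant positions (e.g. ClinVar pathogenic or published
#' disease variants, in profile/UniProt coordinates) are resolved with the
#' same mapping rules as the neutral profile — same chain, offset and pLDDT
#' mask — and rendered in a style visually distinct from the six neutral
#' frequency bins. Unmappable positions are reported, never fatal.
#'
#' @param annotation A `structure_annotation` from [map_profile()].
#' @param pathogenic Tibble with columns `position`, `label` (see
#'   [read_pathogenic_table()]).
#' @param model The `structure_model` the annotation was produced from.
#' @return The annotation with `pathogenic_mapped` / `pathogenic_unmapped`
#'   filled in.
#' @export
overlay_pathogenic <- function(annotation, pathogenic, model) {
  stopifnot(inherits(annotation, "structure_annotation"),
            inherits(model, "structure_model"))
  if (nrow(pathogenic) == 0L) return(annotation)
  res <- model$residues[model$residues$chain == annotation$chain, ,
                        drop = FALSE]
  status <- resolve_positions(pathogenic$position, res, annotation$offset,
                              annotation$plddt_min)
  ok <- is.na(status)
  annotation$pathogenic_mapped <- tibble(
    position = as.integer(pathogenic$position[ok]),
    label = pathogenic$label[ok],
    resno = as.integer(pathogenic$position[ok]) + annotation$offset
  )
  annotation$pathogenic_unmapped <- tibble(
    position = as.integer(pathogenic$position[!ok]),
    label = pathogenic$label[!ok],
    reason = status[!ok]
  )
  annotation
}

#' Read a pathogenic-variant position list
#'
#' Plain-text TSV with columns `position` and `label` (header optional;
#' lines beginning `#` ignored).
#'
#' @param path Input path.
#' @return Tibble `position`, `label`.
#' @export
read_pathogenic_table <- function(path) {
  if (!file.exists(path)) mm_io_error(sprintf("pathogenic list not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(tibble(position = integer(0), label = character(0)))
  }
  if (grepl("^position\\b", lines[1], ignore.case = TRUE)) lines <- lines[-1]
  parts <- str_split(trimws(lines), "\\s+", n = 2)
  tibble(
    position = vapply(parts, function(p) {
      v <- suppressWarnings(as.integer(p[1]))
      if (is.na(v)) mm_format_error(sprintf("bad pathogenic position '%s'", p[1]))
      v
    }, integer(1)),
    label = vapply(parts, function(p) if (length(p) > 1) p[2] else "", character(1))
  )
}

#' Write the position-mapping report
#'
#' One row per profile (and pathogenic) position with its mapping status, so
#' masked or missing residues are auditable.
#'
#' @param annotation A `structure_annotation`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mapping_report <- function(annotation, path) {
  rep <- dplyr::bind_rows(
    dplyr::mutate(annotation$mapped[, c("position", "resno")],
                  status = "mapped", reason = NA_character_,
                  class = "neutral"),
    dplyr::mutate(annotation$unmapped, status = "unmapped",
                  resno = NA_integer_, class = "neutral"),
    dplyr::mutate(annotation$pathogenic_mapped[, c("position", "resno")],
                  status = "mapped", reason = NA_character_,
                  class = "pathogenic"),
    dplyr::mutate(annotation$pathogenic_unmapped[, c("position", "reason")],
                  status = "unmapped", resno = NA_integer_,
                  class = "pathogenic")
  ) |>
    dplyr::arrange(class, position) |>
    dplyr::select(class, position, resno, status, reason)
  readr::write_tsv(rep, path, progress = FALSE)
  invisible(path)
}
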