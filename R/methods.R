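#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a residue profile
#'
#' @param x A `residue_profile`.
#' @param ... Unused.
#' @return A plain tibble of per-residue aggregates: `protein_id`,
#'   `position`, `summed_af`, `n_variants`, `bin_index`.
#' @method tidy residue_profile
#' @export
tidy.residue_profile <- function(x, ...) {
  dplyr::mutate(as_tibble(x),
                protein_id = attr(x, "protein_id") %||% NA_character_,
                .before = 1)
}

#' One-row summary of a residue profile
#'
#' @param x A `residue_profile`.
#' @param ... Unused.
#' @return Tibble with `protein_id`, `protein_length`, `n_variable_positions`,
#'   `n_variants`, `vp`.
#' @method glance residue_profile
#' @export
glance.residue_profile <- function(x, ...) {
  tibble(
    protein_id = attr(x, "protein_id") %||% NA_character_,
    protein_length = attr(x, "protein_length"),
    n_variable_positions = nrow(x),
    n_variants = sum(x$n_variants),
    vp = attr(x, "vp")
  )
}

#' Tidy a structure annotation
#'
#' @param x A `structure_annotation`.
#' @param ... Unused.
#' @return One row per profile and pathogenic position with `class`
#'   (neutral/pathogenic), `position`, `resno`, `status` and `reason`.
#' @method tidy structure_annotation
#' @export
tidy.structure_annotation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$mapped[, c("position", "resno", "bin_index")],
                  status = "mapped", reason = NA_character_,
                  class = "neutral"),
    dplyr::mutate(x$unmapped, status = "unmapped", resno = NA_integer_,
                  bin_index = NA_integer_, class = "neutral"),
    dplyr::mutate(x$pathogenic_mapped[, c("position", "resno")],
                  status = "mapped", reason = NA_character_,
                  bin_index = NA_integer_, class = "pathogenic"),
    dplyr::mutate(x$pathogenic_unmapped[, c("position", "reason")],
                  status = "unmapped", resno = NA_integer_,
                  bin_index = NA_integer_, class = "pathogenic")
  ) |>
    dplyr::select(class, position, resno, bin_index, status, reason) |>
    dplyr::arrange(class, position)
}

#' One-row summary of a structure annotation
#'
#' @param x A `structure_annotation`.
#' @param ... Unused.
#' @return Tibble with chain, offset, pLDDT threshold and mapping counts.
#' @method glance structure_annotation
#' @export
glance.structure_annotation <- function(x, ...) {
  tibble(
    chain = x$chain,
    offset = x$offset,
    plddt_min = x$plddt_min %||% NA_real_,
    n_mapped = nrow(x$mapped),
    n_unmapped = nrow(x$unmapped),
    n_pathogenic_mapped = nrow(x$pathogenic_mapped),
    n_pathogenic_unmapped = nrow(x$pathogenic_unmapped)
  )
}

#' @export
print.structure_annotation <- function(x, ...) {
  cat(sprintf(
    "<structure_annotation> chain %s, offset %+d: %d mapped, %d unmapped, %d pathogenic\n",
    x$chain, x$offset, nrow(x$mapped), nrow(x$unmapped),
    nrow(x$pathogenic_mapped)
  ))
  invisible(x)
}
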