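#' Sphere style for the six frequency bins
#'
#' Encoding used by the emitted viewer scripts: sphere radius and shade of
#' blue both increase with the allele-frequency bin, so common variants are
#' large and dark, rare ones small and light. Pathogenic overlays use a
#' contrasting colour (red by default). Only monotonicity is semantically
#' meaningful; the exact values are configurable.
#'
#' @param radii Six positive, non-decreasing sphere radii in Angstrom.
#' @param colors 6 x 3 matrix of RGB values in `[0, 1]`, one row per bin
#'   (default: light-to-dark blue ramp).
#' @param pathogenic_color Length-3 RGB vector for pathogenic spheres.
#' @param pathogenic_radius Sphere radius for pathogenic positions.
#' @return A `style_spec` object.
#' @export
style_spec <- function(radii = c(0.8, 1.2, 1.6, 2.0, 2.4, 2.8),
                       colors = NULL,
                       pathogenic_color = c(0.85, 0.1, 0.1),
                       pathogenic_radius = 2.0) {
  if (length(radii) != 6L || any(radii <= 0) || is.unsorted(radii)) {
    mm_argument_error("`radii` must be 6 positive non-decreasing values")
  }
  if (is.null(colors)) {
    ramp <- grDevices::colorRampPalette(c("#C6DBEF", "#08306B"))(6)
    colors <- t(grDevices::col2rgb(ramp) / 255)
  }
  colors <- as.matrix(colors)
  if (!all(dim(colors) == c(6L, 3L)) || any(colors < 0 | colors > 1)) {
    mm_argument_error("`colors` must be a 6 x 3 matrix of RGB values in [0, 1]")
  }
  if (length(pathogenic_color) != 3L ||
      any(pathogenic_color < 0 | pathogenic_color > 1)) {
    mm_argument_error("`pathogenic_color` must be 3 RGB values in [0, 1]")
  }
  if (length(pathogenic_radius) != 1L || pathogenic_radius <= 0) {
    mm_argument_error("`pathogenic_radius` must be a single positive value")
  }
  structure(
    list(radii = as.numeric(radii), colors = unname(colors),
         pathogenic_color = as.numeric(pathogenic_color),
         pathogenic_radius = as.numeric(pathogenic_radius)),
    class = "style_spec"
  )
}

#' Emit a PyMOL command script for an annotated structure
#'
#' Writes a `.pml` script that loads the structure, shows a grey cartoon,
#' and draws C-alpha spheres for every mapped variable residue: one named
#' selection per non-empty frequency bin (`af_bin1` .. `af_bin6`, residues
#' in ascending order) plus a `pathogenic` selection when pathogenic
#' positions are overlaid. Sphere radius and colour come from the
#' [style_spec()]. Output is a pure function of its inputs — byte-identical
#' across runs — so scripts can be diffed and versioned.
#'
#' @param annotation A `structure_annotation` from [map_profile()] (and
#'   optionally [overlay_pathogenic()]).
#' @param style A [style_spec()].
#' @param out Output path for the `.pml` file.
#' @return `out`, invisibly.
#' @export
emit_viewer_script <- function(annotation, style = style_spec(), out) {
  stopifnot(inherits(annotation, "structure_annotation"),
            inherits(style, "style_spec"))
  lines <- c(
    "# missensemap viewer script",
    sprintf("load %s, struct", annotation$structure_path),
    "hide everything, struct",
    "show cartoon, struct",
    "color gray80, struct",
    "set sphere_quality, 2"
  )
  mapped <- annotation$mapped
  for (k in sort(unique(mapped$bin_index))) {
    resnos <- sort(mapped$resno[mapped$bin_index == k])
    sel <- sprintf("af_bin%d", k)
    rgb <- style$colors[k, ]
    lines <- c(
      lines,
      sprintf("set_color %s_col, [%.3f, %.3f, %.3f]", sel,
              rgb[1], rgb[2], rgb[3]),
      sprintf("select %s, struct and chain %s and resi %s and name CA",
              sel, annotation$chain, paste(resnos, collapse = "+")),
      sprintf("show spheres, %s", sel),
      sprintf("alter %s, vdw=%.2f", sel, style$radii[k]),
      sprintf("color %s_col, %s", sel, sel)
    )
  }
  if (nrow(annotation$pathogenic_mapped) > 0L) {
    resnos <- sort(unique(annotation$pathogenic_mapped$resno))
    rgb <- style$pathogenic_color
    lines <- c(
      lines,
      sprintf("set_color pathogenic_col, [%.3f, %.3f, %.3f]",
              rgb[1], rgb[2], rgb[3]),
      sprintf("select pathogenic, struct and chain %s and resi %s and name CA",
              annotation$chain, paste(resnos, collapse = "+")),
      "show spheres, pathogenic",
      sprintf("alter pathogenic, vdw=%.2f", style$pathogenic_radius),
      "color pathogenic_col, pathogenic"
    )
  }
  lines <- c(lines, "rebuild", "deselect")
  con <- tryCatch(file(out, "wb"),
                  error = function(e) mm_io_error(sprintf("cannot write %s", out)),
                  warning = function(e) mm_io_error(sprintf("cannot write %s", out)))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(out)
}
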