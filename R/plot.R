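#' 1D plot of missense variants along a protein sequence
#'
#' Draws the linear analogue of the structure annotation: one tick per
#' variable residue position along a 1..protein_length axis, a thin baseline
#' bar for the full sequence, coloured rectangles for user-supplied domains,
#' and (optionally) each domain's Vd/Vp ratio printed above it — ratios
#' below 1 flag missense-depleted domains at a glance. Tick height is
#' uniform by default (position is the message); `scale_by_bin = TRUE`
#' optionally scales height with the allele-frequency bin.
#'
#' @param profile A `residue_profile`.
#' @param domains Optional tibble `name`, `start`, `end`.
#' @param vdvp Optional result of [compute_vdvp()] for the same domains;
#'   required for labels when `show_vdvp_labels = TRUE`.
#' @param show_vdvp_labels Print `Vd/Vp` two-decimal labels above domains.
#' @param scale_by_bin Scale tick height by frequency bin (default uniform).
#' @param domain_colors Optional named vector of fills, `name -> colour`.
#' @param pathogenic_marks Optional tibble `position`, `label`; drawn as red
#'   downward ticks with labels.
#' @return A ggplot object; render to file with [write_figure()].
#' @export
plot_linear <- function(profile, domains = NULL, vdvp = NULL,
                        show_vdvp_labels = TRUE, scale_by_bin = FALSE,
                        domain_colors = NULL, pathogenic_marks = NULL) {
  stopifnot(inherits(profile, "residue_profile"))
  L <- attr(profile, "protein_length")
  if (!is.null(domains) && nrow(domains) > 0L &&
      (any(domains$start < 1L) || any(domains$end > L))) {
    mm_argument_error("domain rectangles exceed the 1..protein_length axis")
  }

  marks <- as_tibble(profile)
  marks$height <- if (scale_by_bin) 0.15 + 0.55 * marks$bin_index / 6 else 0.55

  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = tibble(xmin = 1, xmax = L),
      ggplot2::aes(xmin = xmin, xmax = xmax, ymin = -0.03, ymax = 0.03),
      fill = "grey55"
    )
  if (nrow(marks) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = marks,
      ggplot2::aes(x = position, xend = position, y = 0.05, yend = 0.05 + height),
      linewidth = 0.3, colour = "#2166AC"
    )
  }
  if (!is.null(domains) && nrow(domains) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = domains,
      ggplot2::aes(xmin = start, xmax = end, ymin = -0.16, ymax = 0.16,
                   fill = name),
      colour = "grey20", alpha = 0.85
    ) +
      ggplot2::geom_text(
        data = domains,
        ggplot2::aes(x = (start + end) / 2, y = -0.27, label = name),
        size = 2.8
      )
    if (!is.null(domain_colors)) {
      p <- p + ggplot2::scale_fill_manual(values = domain_colors)
    }
    if (isTRUE(show_vdvp_labels) && !is.null(vdvp) && nrow(vdvp) > 0L) {
      p <- p + ggplot2::geom_text(
        data = vdvp,
        ggplot2::aes(x = (start + end) / 2, y = 0.85, label = vdvp_label),
        size = 3, fontface = "bold"
      )
    }
  }
  if (!is.null(pathogenic_marks) && nrow(pathogenic_marks) > 0L) {
    p <- p +
      ggplot2::geom_segment(
        data = pathogenic_marks,
        ggplot2::aes(x = position, xend = position, y = -0.05, yend = -0.45),
        linewidth = 0.4, colour = "#B2182B"
      ) +
      ggplot2::geom_text(
        data = pathogenic_marks,
        ggplot2::aes(x = position, y = -0.52, label = label),
        size = 2.5, colour = "#B2182B"
      )
  }
  p +
    ggplot2::scale_x_continuous(limits = c(0, L + 1), expand = c(0.01, 0)) +
    ggplot2::scale_y_continuous(limits = c(-0.6, 1.0)) +
    ggplot2::labs(
      x = "Residue position",
      title = attr(profile, "protein_id") %||% NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      axis.title.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank(),
      legend.position = "none"
    )
}

#' @rdname plot_linear
#' @param object A `residue_profile` (for `autoplot`).
#' @param ... Passed on to [plot_linear()].
#' @method autoplot residue_profile
#' @export
autoplot.residue_profile <- function(object, ...) {
  plot_linear(object, ...)
}

#' Write a plot to SVG or PNG
#'
#' Format is chosen from the output extension; SVG uses the cairo vector
#' device so figures remain editable (e.g. in Inkscape).
#'
#' @param plot A ggplot object.
#' @param out Output path ending in `.svg` or `.png`.
#' @param width,height Figure size in inches.
#' @param dpi Raster resolution (PNG only).
#' @return `out`, invisibly.
#' @export
write_figure <- function(plot, out, width = 9, height = 3, dpi = 150) {
  ext <- tolower(tools::file_ext(out))
  if (!ext %in% c("svg", "png")) {
    mm_argument_error("output format must be .svg or .png")
  }
  dev <- if (ext == "svg") grDevices::svg else grDevices::png
  tryCatch(
    ggplot2::ggsave(out, plot = plot, device = dev, width = width,
                    height = height, units = "in", dpi = dpi),
    error = function(e) {
      if (!dir.exists(dirname(out))) {
        mm_io_error(sprintf("cannot write figure to %s", out))
      }
      stop(e)
    }
  )
  invisible(out)
}
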