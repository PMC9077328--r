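# Allele number used for synthetic exports; roughly the full gnomAD v2
# exome call set, so allele counts round to plausible integers.
SYNTH_ALLELE_NUMBER <- 251496L

NEUTRAL_CLINVAR <- c("", "Benign", "Likely benign", "Benign/Likely benign")
EXCLUDED_CLINVAR <- c(
  "Pathogenic", "Likely pathogenic",
  "Conflicting interpretations of pathogenicity", "Uncertain significance"
)

#' Specification for a synthetic variant table
#'
#' Describes the generative model behind a gnomAD-style export with known
#' ground truth: each residue is independently variable with its region's
#' density (a depleted region models a constrained domain), allele
#' frequencies are drawn log-uniform so every frequency decade is populated,
#' and realistic contamination is added — rows with excluded ClinVar classes,
#' non-missense rows, and multiallelic residues carrying a second
#' substitution.
#'
#' Default densities sit in the 0.29–0.42 band typical of well-covered human
#' proteins in population exome data; default contamination fractions mirror
#' the small pathogenic/uncertain fraction (about 1.5%) such exports carry.
#'
#' @param protein_length Protein length in residues.
#' @param density_background Per-residue probability of being variable
#'   outside depleted regions.
#' @param depleted_regions Optional tibble `start`, `end`, `density`
#'   (optionally `name`) overriding the background density inside regions.
#' @param af_log10_range `c(lo, hi)` with `-7 <= lo < hi <= 0`; allele
#'   frequencies are `10^U(lo, hi)` before rounding to an integer allele
#'   count out of 251,496 alleles.
#' @param fraction_pathogenic Fraction of output rows carrying an excluded
#'   ClinVar class (filtered out downstream).
#' @param fraction_non_missense Fraction of output rows with synonymous or
#'   stop-gained VEP annotation (filtered out downstream).
#' @param multiallelic_rate Fraction of variable residues that receive a
#'   second, distinct substitution.
#' @param sampling `"stratified"` (default): each region contributes exactly
#'   `round(region_length * density)` variable positions, drawn uniformly
#'   without replacement, so the realised per-region density is the nominal
#'   one and recovery tests measure the pipeline, not sampling noise.
#'   `"bernoulli"`: each residue is independently variable with its region's
#'   density, for binomial-variance checks.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An `mm_synthetic_spec` object.
#' @export
synthetic_spec <- function(protein_length,
                           density_background = 0.35,
                           depleted_regions = NULL,
                           af_log10_range = c(-6.5, 0),
                           fraction_pathogenic = 0.015,
                           fraction_non_missense = 0.05,
                           multiallelic_rate = 0.1,
                           sampling = c("stratified", "bernoulli"),
                           seed = 1L) {
  sampling <- match.arg(sampling)
  protein_length <- check_scalar_count(protein_length, "protein_length")
  if (density_background < 0 || density_background > 1) {
    mm_argument_error("`density_background` must lie in [0, 1]")
  }
  if (!is.null(depleted_regions) && nrow(depleted_regions) > 0L) {
    r <- depleted_regions
    if (!all(c("start", "end", "density") %in% names(r))) {
      mm_argument_error("`depleted_regions` needs columns start, end, density")
    }
    if (any(r$start < 1L | r$end > protein_length | r$start > r$end)) {
      mm_argument_error("depleted regions must lie within 1..protein_length")
    }
    if (any(r$density < 0 | r$density > 1)) {
      mm_argument_error("region densities must lie in [0, 1]")
    }
    if (!"name" %in% names(r)) {
      depleted_regions$name <- sprintf("region_%d", seq_len(nrow(r)))
    }
  }
  if (length(af_log10_range) != 2L || af_log10_range[1] < -7 ||
      af_log10_range[2] > 0 || af_log10_range[1] >= af_log10_range[2]) {
    mm_argument_error("`af_log10_range` must be c(lo, hi) with -7 <= lo < hi <= 0")
  }
  if (fraction_pathogenic < 0 || fraction_non_missense < 0 ||
      fraction_pathogenic + fraction_non_missense >= 1) {
    mm_argument_error("contamination fractions must be >= 0 and sum to < 1")
  }
  if (multiallelic_rate < 0 || multiallelic_rate >= 1) {
    mm_argument_error("`multiallelic_rate` must lie in [0, 1)")
  }
  structure(
    list(
      protein_length = protein_length,
      density_background = density_background,
      depleted_regions = depleted_regions,
      af_log10_range = as.numeric(af_log10_range),
      fraction_pathogenic = fraction_pathogenic,
      fraction_non_missense = fraction_non_missense,
      multiallelic_rate = multiallelic_rate,
      sampling = sampling,
      seed = as.integer(seed)
    ),
    class = "mm_synthetic_spec"
  )
}

draw_af <- function(n, range) {
  af <- 10^stats::runif(n, range[1], range[2])
  ac <- pmax(1L, as.integer(round(af * SYNTH_ALLELE_NUMBER)))
  list(ac = ac, an = rep(SYNTH_ALLELE_NUMBER, n), af = ac / SYNTH_ALLELE_NUMBER)
}

AA20 <- setdiff(unname(AA_3TO1), "*")

# uniform draw over AA20 excluding, per element, the residues in ...
draw_aa_excluding <- function(n, ...) {
  taboo <- list(...)
  out <- sample(AA20, n, replace = TRUE)
  repeat {
    bad <- Reduce(`|`, lapply(taboo, function(t) out == t), rep(FALSE, n))
    if (!any(bad)) break
    out[bad] <- sample(AA20, sum(bad), replace = TRUE)
  }
  out
}

#' Generate a gnomAD-style variant table with ground truth
#'
#' Draws a synthetic per-gene variant export from an [synthetic_spec()]
#' generative model, together with a ground-truth sidecar recording, for
#' every truly variable residue, its region, neutral variant count and
#' expected post-filter summed allele frequency. The sidecar exactly
#' predicts what the filter + aggregation pipeline recovers from the CSV, so
#' every downstream module can be tested end-to-end without real downloads.
#'
#' @param spec An `mm_synthetic_spec`.
#' @param csv Optional path; when given the variant table is written as CSV
#'   in the gnomAD export dialect (byte-identical for identical specs).
#' @param sidecar Optional path for the ground-truth TSV.
#' @return A list: `variants` (tibble in export column layout), `truth`
#'   (tibble `position`, `region`, `n_neutral_variants`, `summed_af`),
#'   `spec`, and the file paths when written.
#' @export
generate_variant_table <- function(spec, csv = NULL, sidecar = NULL) {
  stopifnot(inherits(spec, "mm_synthetic_spec"))
  withr::with_seed(spec$seed, {
    L <- spec$protein_length
    dens <- rep(spec$density_background, L)
    region <- rep("background", L)
    regs <- spec$depleted_regions
    if (!is.null(regs)) {
      for (i in seq_len(nrow(regs))) {
        span <- regs$start[i]:regs$end[i]
        dens[span] <- regs$density[i]
        region[span] <- regs$name[i]
      }
    }
    pos <- if (spec$sampling == "bernoulli") {
      which(stats::runif(L) < dens)
    } else {
      unlist(lapply(split(seq_len(L), region), function(span) {
        k <- round(length(span) * dens[span[1]])
        sort(sample(span, k))
      }), use.names = FALSE)
    }
    pos <- sort(as.integer(pos))
    n_pos <- length(pos)

    ref <- if (n_pos) sample(AA20, n_pos, replace = TRUE) else character(0)
    alt <- draw_aa_excluding(n_pos, ref)
    second <- if (n_pos) which(stats::runif(n_pos) < spec$multiallelic_rate) else integer(0)
    alt2 <- draw_aa_excluding(length(second), ref[second], alt[second])

    neutral <- tibble(
      position = c(pos, pos[second]),
      ref_aa = c(ref, ref[second]),
      alt_aa = c(alt, alt2)
    )
    dr <- draw_af(nrow(neutral), spec$af_log10_range)
    neutral$allele_count <- dr$ac
    neutral$allele_number <- dr$an
    neutral$allele_frequency <- dr$af
    neutral$vep <- "missense_variant"
    neutral$clinvar <- sample(NEUTRAL_CLINVAR, nrow(neutral), replace = TRUE,
                              prob = c(0.85, 0.07, 0.05, 0.03))

    n_neutral <- nrow(neutral)
    denom <- 1 - spec$fraction_pathogenic - spec$fraction_non_missense
    total <- n_neutral / denom
    n_path <- round(spec$fraction_pathogenic * total)
    n_nm <- round(spec$fraction_non_missense * total)

    contam <- function(n) {
      p <- sample.int(L, n, replace = TRUE)
      r <- sample(AA20, n, replace = TRUE)
      a <- draw_aa_excluding(n, r)
      d <- draw_af(n, spec$af_log10_range)
      tibble(position = p, ref_aa = r, alt_aa = a, allele_count = d$ac,
             allele_number = d$an, allele_frequency = d$af)
    }
    path_rows <- contam(n_path)
    if (n_path > 0L) {
      path_rows$vep <- "missense_variant"
      path_rows$clinvar <- sample(EXCLUDED_CLINVAR, n_path, replace = TRUE)
    } else {
      path_rows$vep <- character(0); path_rows$clinvar <- character(0)
    }
    nm_rows <- contam(n_nm)
    if (n_nm > 0L) {
      syn <- stats::runif(n_nm) < 0.5
      nm_rows$vep <- ifelse(syn, "synonymous_variant", "stop_gained")
      nm_rows$alt_aa <- ifelse(syn, nm_rows$ref_aa, "*")
      nm_rows$clinvar <- ""
    } else {
      nm_rows$vep <- character(0); nm_rows$clinvar <- character(0)
    }

    rows <- dplyr::bind_rows(neutral, path_rows, nm_rows)
    rows <- rows[sample.int(nrow(rows)), , drop = FALSE]

    variants <- tibble(
      `Protein Consequence` = format_hgvs_p(rows$ref_aa, rows$position,
                                            rows$alt_aa),
      `VEP Annotation` = rows$vep,
      `ClinVar Clinical Significance` = rows$clinvar,
      `Allele Count` = rows$allele_count,
      `Allele Number` = rows$allele_number,
      `Allele Frequency` = rows$allele_frequency
    )

    truth <- neutral |>
      dplyr::group_by(position) |>
      dplyr::summarise(
        n_neutral_variants = dplyr::n(),
        summed_af = min(1, sum(allele_frequency)),
        .groups = "drop"
      ) |>
      dplyr::mutate(region = region[position], .after = position) |>
      dplyr::arrange(position)

    out <- list(variants = variants, truth = truth, spec = spec)
    if (!is.null(csv)) {
      readr::write_csv(variants, csv, progress = FALSE)
      out$csv <- csv
    }
    if (!is.null(sidecar)) {
      readr::write_tsv(truth, sidecar, progress = FALSE)
      out$sidecar <- sidecar
    }
    out
  })
}

#' Write an ideal poly-alanine helix as a toy PDB structure
#'
#' Emits a C-alpha trace of an ideal helix (1.5 Angstrom rise and 100 degree
#' twist per residue, radius 2.28 Angstrom, giving consecutive C-alpha
#' distances of about 3.8 Angstrom) — enough structure for mapping and
#' viewer-script tests without real coordinates. The B-factor column is
#' filled from `plddt_profile` when given, emulating a predicted model.
#'
#' @param n_residues Number of residues.
#' @param plddt_profile Optional numeric vector of length `n_residues`
#'   written to the B-factor column (default 99.99 everywhere).
#' @param chain Chain identifier (single character).
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
generate_toy_structure <- function(n_residues, plddt_profile = NULL,
                                   chain = "A", path) {
  n_residues <- check_scalar_count(n_residues, "n_residues")
  b <- plddt_profile %||% rep(99.99, n_residues)
  if (length(b) != n_residues) {
    mm_argument_error("`plddt_profile` must have one value per residue")
  }
  i <- seq_len(n_residues)
  theta <- (i - 1) * 100 * pi / 180
  x <- 2.28 * cos(theta)
  y <- 2.28 * sin(theta)
  z <- 1.5 * (i - 1)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    i, chain, i, x, y, z, 1.00, b
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
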