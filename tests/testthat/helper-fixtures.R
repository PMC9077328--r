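# One-letter -> three-letter table kept independent of the package internals
# so fixtures and oracles do not lean on the code under test.
AA13 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
  `*` = "Ter"
)

hgvs_of <- function(ref, pos, alt) {
  sprintf("p.%s%d%s", AA13[ref], pos, AA13[alt])
}

# quick variant-record tibble in the shape read_variant_table() returns
rec_tbl <- function(position, af = rep(1e-4, length(position)),
                    vep = "missense_variant", clinvar = NA_character_,
                    ref = "A", alt = "V", an = 100000L,
                    protein_id = "P1") {
  n <- length(position)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  tibble::tibble(
    protein_id = protein_id,
    hgvs_p = hgvs_of(ref, position, alt),
    ref_aa = ref,
    position = as.integer(position),
    alt_aa = alt,
    vep_annotation = rep_len(vep, n),
    clinvar_significance = rep_len(clinvar, n),
    allele_count = as.integer(round(af * an)),
    allele_number = rep_len(as.integer(an), n),
    allele_frequency = af
  )
}

# write a gnomAD-style CSV from plain field vectors
write_fixture_csv <- function(path, consequence, vep,
                              clinvar = NULL,
                              ac = rep(1L, length(consequence)),
                              an = rep(100000L, length(consequence)),
                              af = ac / an) {
  df <- data.frame(
    `Protein Consequence` = consequence,
    `VEP Annotation` = vep,
    `Allele Count` = ac,
    `Allele Number` = an,
    `Allele Frequency` = af,
    check.names = FALSE
  )
  if (!is.null(clinvar)) df[["ClinVar Clinical Significance"]] <- clinvar
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# independent parse-back of the emitted PyMOL script: named list of sorted
# residue-number vectors, one per `select` line
parse_pml_selections <- function(path) {
  lines <- readLines(path)
  sel <- grep("^select ", lines, value = TRUE)
  out <- list()
  for (s in sel) {
    name <- sub("^select ([^,]+),.*$", "\\1", s)
    resi <- sub(".*resi ([0-9+]+).*", "\\1", s)
    out[[name]] <- sort(as.integer(strsplit(resi, "+", fixed = TRUE)[[1]]))
  }
  out
}

# minimal mmCIF writer driven by fixed-column parsing of a CA-trace PDB,
# for PDB/mmCIF equivalence checks
pdb_to_mmcif <- function(pdb_path, cif_path) {
  lines <- grep("^ATOM", readLines(pdb_path), value = TRUE)
  hdr <- c(
    "data_toy", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
    ))
  )
  rows <- vapply(seq_along(lines), function(i) {
    l <- lines[[i]]
    atom <- trimws(substr(l, 13, 16))
    res <- trimws(substr(l, 18, 20))
    chain <- substr(l, 22, 22)
    resno <- trimws(substr(l, 23, 26))
    x <- trimws(substr(l, 31, 38)); y <- trimws(substr(l, 39, 46))
    z <- trimws(substr(l, 47, 54))
    occ <- trimws(substr(l, 55, 60)); b <- trimws(substr(l, 61, 66))
    elem <- trimws(substr(l, 77, 78))
    paste("ATOM", i, elem, atom, ".", res, chain, "1", resno, "?",
          x, y, z, occ, b, "?", resno, res, chain, atom, "1")
  }, character(1))
  writeLines(c(hdr, rows), cif_path)
  cif_path
}

# brute-force per-position aggregation oracle (loop, no dplyr)
oracle_aggregate <- function(positions, afs, protein_length) {
  upos <- sort(unique(positions[positions >= 1 & positions <= protein_length]))
  data.frame(
    position = upos,
    summed_af = vapply(upos, function(p) min(1, sum(afs[positions == p])),
                       numeric(1)),
    n_variants = vapply(upos, function(p) sum(positions == p), numeric(1))
  )
}

# brute-force Vd/Vp oracle from first principles: densities of distinct
# variable positions
oracle_vdvp <- function(variable_positions, protein_length, start, end) {
  upos <- unique(variable_positions)
  vin <- sum(upos >= start & upos <= end)
  vd <- vin / (end - start + 1)
  vp <- length(upos) / protein_length
  if (vp == 0) NA_real_ else vd / vp
}

# sample one integer from lo..hi without the scalar-sample() pitfall
sample_between <- function(lo, hi) {
  if (lo == hi) lo else sample(lo:hi, 1)
}
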