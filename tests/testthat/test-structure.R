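make_profile <- function(positions, af = rep(1e-4, length(positions)), L = 100L) {
  aggregate_by_residue(rec_tbl(positions, af = af), L)
}

test_that("a toy PDB round-trips through structure loading", {
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(3, path = f)
  mod <- load_structure(f)
  expect_equal(mod$chains, "A")
  expect_equal(nrow(mod$residues), 3L)
  expect_true(all(mod$residues$has_ca))
})

test_that("PDB and mmCIF of the same content index residues identically", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(5, plddt_profile = c(90, 65, 90, 80, 71), path = pdb)
  cif <- withr::local_tempfile(fileext = ".cif")
  pdb_to_mmcif(pdb, cif)
  m1 <- load_structure(pdb)
  m2 <- load_structure(cif)
  expect_equal(m1$format, "pdb")
  expect_equal(m2$format, "cif")
  expect_equal(
    as.data.frame(m1$residues[, c("chain", "resno", "has_ca", "b_factor")]),
    as.data.frame(m2$residues[, c("chain", "resno", "has_ca", "b_factor")])
  )
})

test_that("a residue lacking a C-alpha atom is flagged and excluded from mapping", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   2.280   0.000  1.00 90.00           C",
    "ATOM      2  N   ALA A   2      -2.245   0.396   1.500  1.00 90.00           N",
    "ATOM      3  CA  ALA A   3       1.000   1.000   3.000  1.00 90.00           C",
    "END"
  ), f)
  mod <- load_structure(f)
  expect_equal(mod$residues$has_ca, c(TRUE, FALSE, TRUE))
  ann <- map_profile(make_profile(1:3, L = 3L), mod, "A")
  expect_equal(ann$mapped$position, c(1L, 3L))
  expect_equal(ann$unmapped$reason, "no_ca")
})

test_that("numbering offset arithmetic targets the right residues", {
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(10, path = f)
  mod <- load_structure(f)
  ann <- map_profile(make_profile(10, L = 20L), mod, "A", offset = -5L)
  expect_equal(ann$mapped$resno, 5L)
  ann0 <- map_profile(make_profile(10, L = 20L), mod, "A", offset = 0L)
  expect_equal(ann0$mapped$resno, 10L)
})

test_that("pLDDT masking excludes low-confidence residues with a reason", {
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(10, plddt_profile = c(90, 65, rep(90, 8)), path = f)
  mod <- load_structure(f)
  prof <- make_profile(c(1, 2), L = 10L)
  ann <- map_profile(prof, mod, "A", plddt_min = 70)
  expect_equal(ann$mapped$position, 1L)
  expect_equal(ann$unmapped$reason, "plddt_below_threshold")
  # threshold is strict: pLDDT exactly at the cut-off is masked
  f70 <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(2, plddt_profile = c(70, 70.01), path = f70)
  ann70 <- map_profile(make_profile(1:2, L = 2L), load_structure(f70), "A",
                       plddt_min = 70)
  expect_equal(ann70$mapped$position, 2L)
  # without a threshold the same profile maps fully
  ann_off <- map_profile(prof, mod, "A")
  expect_equal(nrow(ann_off$unmapped), 0L)
})

test_that("every profile position lands in exactly one of mapped/unmapped", {
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(30, plddt_profile = rep(c(90, 60, 80), 10), path = f)
  mod <- load_structure(f)
  prof <- make_profile(c(1, 5, 12, 28, 40, 55), L = 60L)
  ann <- map_profile(prof, mod, "A", plddt_min = 70)
  got <- sort(c(ann$mapped$position, ann$unmapped$position))
  expect_equal(got, sort(prof$position))
  expect_length(intersect(ann$mapped$position, ann$unmapped$position), 0)
})

test_that("unknown chains and insertion-coded chains are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(3, path = f)
  mod <- load_structure(f)
  expect_error(map_profile(make_profile(1), mod, "B"),
               class = "mm_argument_error")

  fi <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   2.280   0.000  1.00 90.00           C",
    "ATOM      2  CA  ALA A   1A      1.000   1.000   1.500  1.00 90.00           C",
    "END"
  ), fi)
  modi <- load_structure(fi)
  err <- expect_error(map_profile(make_profile(1), modi, "A"),
                      class = "mm_argument_error")
  expect_match(conditionMessage(err), "insertion")
})

test_that("viewer scripts define one selection per non-empty bin, parse-back exact", {
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(50, path = f)
  mod <- load_structure(f)
  # three positions forced into bin 4, two into bin 1, one into bin 6
  prof <- make_profile(c(10, 20, 30, 40, 45, 50),
                       af = c(5e-3, 5e-3, 5e-3, 5e-6, 5e-6, 1), L = 50L)
  ann <- map_profile(prof, mod, "A")
  out <- withr::local_tempfile(fileext = ".pml")
  emit_viewer_script(ann, style_spec(), out)
  sels <- parse_pml_selections(out)
  expect_setequal(names(sels), c("af_bin1", "af_bin4", "af_bin6"))
  expect_equal(sels$af_bin4, c(10L, 20L, 30L))
  expect_equal(sels$af_bin1, c(40L, 45L))
  expect_equal(sels$af_bin6, 50L)
  # brute-force expectation: selections reproduce {position + offset} per bin
  for (k in unique(prof$bin_index)) {
    expect_equal(sels[[paste0("af_bin", k)]],
                 sort(prof$position[prof$bin_index == k]))
  }
})

test_that("script emission is deterministic: identical inputs, identical bytes", {
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(20, path = f)
  mod <- load_structure(f)
  ann <- map_profile(make_profile(c(3, 7, 11), L = 20L), mod, "A")
  o1 <- withr::local_tempfile(fileext = ".pml")
  o2 <- withr::local_tempfile(fileext = ".pml")
  emit_viewer_script(ann, style_spec(), o1)
  emit_viewer_script(ann, style_spec(), o2)
  expect_identical(readBin(o1, "raw", file.size(o1)),
                   readBin(o2, "raw", file.size(o2)))
})

test_that("an empty annotation emits load and base representation only", {
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(5, path = f)
  mod <- load_structure(f)
  ann <- map_profile(make_profile(integer(0), L = 5L), mod, "A")
  out <- withr::local_tempfile(fileext = ".pml")
  emit_viewer_script(ann, style_spec(), out)
  lines <- readLines(out)
  expect_length(grep("^select ", lines), 0L)
  expect_length(grep("^load ", lines), 1L)
  expect_true(any(grepl("^show cartoon", lines)))
})

test_that("default style radii are non-decreasing and bin colours darken", {
  st <- style_spec()
  expect_length(st$radii, 6L)
  expect_true(all(diff(st$radii) >= 0))
  # monotone darkening: luminance decreases with bin index
  lum <- st$colors %*% c(0.299, 0.587, 0.114)
  expect_true(all(diff(as.numeric(lum)) < 0))
  expect_error(style_spec(radii = c(3, 2, 1, 1, 1, 1)),
               class = "mm_argument_error")
})

test_that("pathogenic overlay maps with the same rules and renders distinctly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(50, plddt_profile = c(rep(90, 41), 60, rep(90, 8)),
                         path = f)
  mod <- load_structure(f)
  prof <- make_profile(c(10, 20), L = 60L)
  ann <- map_profile(prof, mod, "A", plddt_min = 70)
  patho <- tibble::tibble(position = c(42L, 15L, 55L),
                          label = c("masked", "ok", "absent"))
  ann2 <- overlay_pathogenic(ann, patho, mod)
  expect_equal(ann2$pathogenic_mapped$position, 15L)
  expect_setequal(ann2$pathogenic_unmapped$reason,
                  c("plddt_below_threshold", "absent_residue"))
  out <- withr::local_tempfile(fileext = ".pml")
  emit_viewer_script(ann2, style_spec(), out)
  sels <- parse_pml_selections(out)
  expect_equal(sels$pathogenic, 15L)

  # empty overlay leaves the annotation unchanged
  ann3 <- overlay_pathogenic(ann, patho[0, ], mod)
  expect_equal(ann3, ann)
})

test_that("the mapping report lists every position with status and reason", {
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(10, plddt_profile = c(rep(90, 9), 60), path = f)
  mod <- load_structure(f)
  ann <- map_profile(make_profile(c(1, 10, 15), L = 20L), mod, "A",
                     plddt_min = 70)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_mapping_report(ann, out)
  rep <- read.delim(out)
  expect_equal(sort(rep$position), c(1L, 10L, 15L))
  expect_equal(rep$status[rep$position == 1], "mapped")
  expect_equal(rep$reason[rep$position == 10], "plddt_below_threshold")
  expect_equal(rep$reason[rep$position == 15], "absent_residue")
})

test_that("consecutive C-alpha distances of the toy helix are near 3.8 Angstrom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(25, path = f)
  xyz <- bio3d::read.pdb(f)$atom[, c("x", "y", "z")]
  d <- sqrt(rowSums(diff(as.matrix(xyz))^2))
  expect_true(all(abs(d - 3.8) < 0.3))
})
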