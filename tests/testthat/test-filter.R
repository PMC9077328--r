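test_that("the stated consequence/significance rules retain exactly the neutral missense record", {
  recs <- dplyr::bind_rows(
    rec_tbl(1, vep = "missense_variant", clinvar = NA),
    rec_tbl(2, vep = "missense_variant", clinvar = "Pathogenic"),
    rec_tbl(3, vep = "missense_variant", clinvar = "Uncertain significance"),
    rec_tbl(4, vep = "synonymous_variant", clinvar = NA),
    rec_tbl(5, vep = "stop_gained", clinvar = NA)
  )
  out <- filter_neutral_missense(recs)
  expect_equal(out$position, 1L)
  rep <- parse_report(out)
  expect_equal(rep$n_input, 5L)
  expect_equal(rep$removed_vep, 2L)
  expect_equal(rep$removed_clinvar, 2L)
  expect_equal(rep$n_retained, 1L)
})

test_that("all four excluded ClinVar classes are removed; benign classes kept", {
  classes <- c("Pathogenic", "Likely pathogenic",
               "Conflicting interpretations of pathogenicity",
               "Uncertain significance")
  recs <- rec_tbl(seq_along(classes), clinvar = classes)
  expect_equal(nrow(filter_neutral_missense(recs)), 0L)
  kept <- rec_tbl(1:3, clinvar = c("Benign", "Likely benign", NA))
  expect_equal(nrow(filter_neutral_missense(kept)), 3L)
})

test_that("ClinVar matching is case/whitespace-insensitive and token-wise on multi-valued cells", {
  recs <- rec_tbl(1:4, clinvar = c(
    "  PATHOGENIC ", "Benign/Likely benign",
    "Benign/Pathogenic", "benign; likely   pathogenic"
  ))
  out <- filter_neutral_missense(recs)
  expect_equal(out$position, 2L)
})

test_that("both 'missense' and 'missense_variant' annotations are accepted", {
  recs <- rec_tbl(1:3, vep = c("missense", "missense_variant", "Missense"))
  expect_equal(nrow(filter_neutral_missense(recs)), 3L)
})

test_that("records without any VEP annotation are excluded and reported", {
  recs <- rec_tbl(1:2, vep = c(NA, "missense_variant"))
  out <- filter_neutral_missense(recs)
  expect_equal(out$position, 2L)
  expect_equal(parse_report(out)$removed_no_vep_annotation, 1L)
})

test_that("keep_unannotated_clinvar = FALSE drops records without ClinVar entries", {
  recs <- rec_tbl(1:2, clinvar = c(NA, "Benign"))
  pol <- filter_policy(keep_unannotated_clinvar = FALSE)
  expect_equal(filter_neutral_missense(recs, pol)$position, 2L)
})

test_that("parsed-synonymous consequences never survive even with a missense label", {
  recs <- rec_tbl(1:2, ref = "G", alt = c("G", "V"))
  out <- filter_neutral_missense(recs)
  expect_equal(out$position, 2L)
  expect_true(all(out$ref_aa != out$alt_aa))
})

test_that("filtering is idempotent and order-equivariant", {
  spec <- synthetic_spec(400, seed = 11L)
  f <- withr::local_tempfile(fileext = ".csv")
  generate_variant_table(spec, csv = f)
  recs <- read_variant_table(f)
  once <- filter_neutral_missense(recs)
  twice <- filter_neutral_missense(once)
  strip <- function(x) {
    attr(x, "filter_report") <- NULL
    as.data.frame(x)
  }
  expect_equal(strip(twice), strip(once))
  expect_true(nrow(once) < nrow(recs))

  perm <- withr::with_seed(1, sample.int(nrow(recs)))
  out_perm <- filter_neutral_missense(recs[perm, ])
  expect_equal(
    dplyr::arrange(as.data.frame(out_perm), hgvs_p, allele_count),
    dplyr::arrange(as.data.frame(once), hgvs_p, allele_count)
  )
  # input order preserved: retained rows appear in their original order
  expect_equal(once$hgvs_p, recs$hgvs_p[recs$hgvs_p %in% once$hgvs_p])
})

test_that("every retained record satisfies the policy predicates on independent re-check", {
  spec <- synthetic_spec(400, seed = 23L)
  f <- withr::local_tempfile(fileext = ".csv")
  generate_variant_table(spec, csv = f)
  out <- filter_neutral_missense(read_variant_table(f))
  excluded <- c("pathogenic", "likely pathogenic",
                "conflicting interpretations of pathogenicity",
                "uncertain significance")
  for (i in seq_len(nrow(out))) {
    expect_true(tolower(out$vep_annotation[i]) %in% c("missense", "missense_variant"))
    cv <- out$clinvar_significance[i]
    if (!is.na(cv)) {
      toks <- tolower(trimws(strsplit(cv, "[/;]")[[1]]))
      expect_false(any(toks %in% excluded))
    }
  }
})

test_that("audit mode preserves every row and flags retention consistently", {
  recs <- rec_tbl(1:4, vep = c("missense_variant", "stop_gained",
                               "missense_variant", "missense_variant"),
                  clinvar = c(NA, NA, "Pathogenic", "Benign"))
  aud <- filter_neutral_missense(recs, audit = TRUE)
  expect_equal(nrow(aud), 4L)
  expect_equal(aud$retained, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(
    as.data.frame(dplyr::select(aud[aud$retained, ], -retained)),
    as.data.frame(filter_neutral_missense(recs))
  )
})

test_that("duplicate rows are kept by default and collapsed only on request", {
  recs <- dplyr::bind_rows(rec_tbl(5, af = 1e-4), rec_tbl(5, af = 1e-4))
  expect_equal(nrow(filter_neutral_missense(recs)), 2L)
  dd <- filter_neutral_missense(recs, dedupe = TRUE)
  expect_equal(nrow(dd), 1L)
  expect_equal(parse_report(dd)$n_duplicates_collapsed, 1L)
})

test_that("empty input filters to empty output with all-zero report", {
  out <- filter_neutral_missense(rec_tbl(integer(0)))
  expect_equal(nrow(out), 0L)
  rep <- parse_report(out)
  expect_true(all(unlist(rep) == 0L))
})
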