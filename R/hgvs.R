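# Three-letter -> one-letter amino-acid code, including the stop codon (Ter).
AA_3TO1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Ter = "*"
)

AA_1TO3 <- stats::setNames(names(AA_3TO1), unname(AA_3TO1))

#' Parse HGVS protein-consequence strings
#'
#' Parses simple substitution consequences in HGVS `p.` notation
#' (e.g. `"p.Arg123Cys"`) into one-letter reference residue, 1-based
#' position and one-letter alternate residue. Non-substitution consequences
#' (frameshifts, deletions, duplications, insertions, extensions, `p.Met1?`,
#' `p.=`) are reported as typed parse failures rather than errors, so a whole
#' column can be parsed in one call and unparseable rows counted.
#'
#' @param x Character vector of HGVS `p.` strings. Surrounding parentheses
#'   (`p.(Arg123Cys)`) are tolerated.
#' @return A tibble with one row per input: `hgvs_p`, `ref_aa`, `position`,
#'   `alt_aa`, `valid` (logical) and `reason` (`NA` when valid; otherwise one
#'   of `"empty"`, `"no_p_prefix"`, `"non_substitution"`, `"malformed"`).
#'   `Ter` maps to `"*"`. Synonymous forms such as `p.Gly10Gly` parse
#'   successfully; they are removed later by the VEP-annotation filter.
#' @examples
#' parse_hgvs_p(c("p.Arg123Cys", "p.Met1?", "p.Gly10Gly"))
#' @export
parse_hgvs_p <- function(x) {
  x <- as.character(x)
  n <- length(x)
  out <- tibble(
    hgvs_p = x,
    ref_aa = NA_character_,
    position = NA_integer_,
    alt_aa = NA_character_,
    valid = FALSE,
    reason = NA_character_
  )
  if (n == 0L) return(out)

  trimmed <- trimws(x)
  empty <- is.na(trimmed) | trimmed == ""
  out$reason[empty] <- "empty"

  no_prefix <- !empty & !startsWith(trimmed, "p.")
  out$reason[no_prefix] <- "no_p_prefix"

  body <- sub("^p\\.", "", trimmed)
  body <- sub("^\\((.*)\\)$", "\\1", body)

  # explicit non-substitution HGVS forms
  nonsub <- !empty & !no_prefix & (
    str_detect(body, "fs|del|dup|ins|ext") |
      str_detect(body, "[?=]")
  )
  out$reason[nonsub] <- "non_substitution"

  todo <- !empty & !no_prefix & !nonsub
  m <- str_match(body[todo], "^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$")
  ref3 <- m[, 2]
  alt3 <- m[, 4]
  known <- !is.na(ref3) & ref3 %in% names(AA_3TO1) & alt3 %in% names(AA_3TO1)
  pos <- suppressWarnings(as.integer(m[, 3]))
  ok <- known & !is.na(pos) & pos >= 1L

  idx <- which(todo)
  out$ref_aa[idx[ok]] <- unname(AA_3TO1[ref3[ok]])
  out$position[idx[ok]] <- pos[ok]
  out$alt_aa[idx[ok]] <- unname(AA_3TO1[alt3[ok]])
  out$valid[idx[ok]] <- TRUE
  out$reason[idx[!ok]] <- "malformed"
  out
}

# one-letter (ref, pos, alt) -> "p.Arg123Cys"; used by serialization and the
# synthetic generator
format_hgvs_p <- function(ref_aa, position, alt_aa) {
  sprintf("p.%s%d%s", AA_1TO3[ref_aa], as.integer(position), AA_1TO3[alt_aa])
}
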