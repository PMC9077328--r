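#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stringr str_squish str_to_lower str_match str_detect str_split
NULL

# classed conditions so the CLI can map failures to distinct exit codes
mm_config_error <- function(msg, ...) {
  abort(msg, class = "mm_config_error", ...)
}

mm_data_error <- function(msg, ...) {
  abort(msg, class = "mm_data_error", ...)
}

mm_format_error <- function(msg, ...) {
  abort(msg, class = c("mm_format_error", "mm_data_error"), ...)
}

mm_argument_error <- function(msg, ...) {
  abort(msg, class = c("mm_argument_error", "mm_config_error"), ...)
}

mm_io_error <- function(msg, ...) {
  abort(msg, class = "mm_io_error", ...)
}

# canonical form used for annotation matching: trimmed, lower-case,
# internal whitespace collapsed
canon_label <- function(x) {
  str_squish(str_to_lower(as.character(x)))
}

check_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) ||
      x != as.integer(x) || x < min) {
    mm_argument_error(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
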