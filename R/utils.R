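#' @importFrom rlang abort .data %||%
#' @importFrom dplyr %>%
NULL

#' Normalize a term to its dictionary lookup key
#'
#' Matching throughout the package is exact on a lightly normalized key:
#' case-folded, internal whitespace runs collapsed to single spaces, and
#' leading/trailing whitespace stripped. Punctuation is preserved so that
#' chemical names differing only by brackets, commas or hyphens are not
#' merged.
#'
#' @param x Character vector of terms.
#' @return Character vector of keys, same length as `x`.
#' @examples
#' norm_key("  Bacterial   Infections ")
#' @export
norm_key <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

# Split a key into whitespace tokens.
key_tokens <- function(key) {
  if (is.na(key) || !nzchar(key)) return(character())
  strsplit(key, " ", fixed = TRUE)[[1]]
}

stop_input <- function(msg) rlang::abort(msg, class = "didkit_input_error")
stop_validation <- function(msg) rlang::abort(msg, class = "didkit_validation_error")
stop_config <- function(msg) rlang::abort(msg, class = "didkit_config_error")
stop_format <- function(msg) rlang::abort(msg, class = "didkit_format_error")
stop_consistency <- function(msg) rlang::abort(msg, class = "didkit_consistency_error")

# TSV field escaping for the DID dialect: free text may contain tabs and
# newlines, which would break the flat layout. Escaped on write, restored
# on read; backslash itself is escaped so the transform is invertible.
escape_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_field <- function(x) {
  # scan character-wise only when a backslash is present (rare in practice)
  needs <- grepl("\\", x, fixed = TRUE)
  x[needs] <- vapply(x[needs], unescape_one, character(1), USE.NAMES = FALSE)
  x
}

unescape_one <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "\\" && i < n) {
      nxt <- chars[[i + 1L]]
      out <- c(out, switch(nxt,
        "t" = "\t", "n" = "\n", "r" = "\r", "\\" = "\\",
        paste0("\\", nxt)
      ))
      i <- i + 2L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop_input(sprintf("input file does not exist: %s", path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required_cols, names(tab))
  if (length(missing)) {
    stop_format(sprintf("file %s is missing required column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  tab
}
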