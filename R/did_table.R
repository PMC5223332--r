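# Canonical column inventory of the flat DID table. Names are descriptive;
# the letter tags mirror the originating spreadsheet columns for
# traceability and are embedded in the on-disk header as "name(letter)".
did_column_letters <- c(
  source_id = "B", raw_drug_name = "D",
  cas_number = "E", cas_authority = "F", cas_match_type = "G",
  drug_preferred_pt = "H", authority_matches = "I-AC",
  drug_cui = "AD", drug_cui_match_type = "AE",
  subtype_leaf = "AN", subtype_root = "AO", subtype_polarity = "AP",
  entire_value = "AQ", target = "AR", target_equals_entire = "AS",
  ind_match_quality = "AT", ind_entry_term = "AU",
  ind_preferred_term = "AV", ind_cui = "AW", ind_entry_status = "AX",
  ind_semantic_types = "AY", ind_phenotypic = "AZ",
  remap_outcome = "BA", compound_index = "BB",
  init_entry_term = "BD", init_preferred_term = "BE",
  init_cui = "BF", init_semantic_types = "BG"
)

# columns that may be absent in legacy exports of the published subset
did_optional_columns <- c("init_entry_term", "init_preferred_term",
                          "init_cui", "init_semantic_types")

did_key_of <- function(rows) {
  paste(rows$source_id, rows$raw_drug_name, rows$target,
        dplyr::coalesce(rows$ind_cui, ""), sep = "\r")
}

#' Summarize first subtype annotations per entire value
#'
#' Helper building the `subtype_annotations` input of [assemble_did()]: one
#' row per unique entire value carrying its first (cue-order) subtype
#' annotation.
#'
#' @param entire_values Character vector.
#' @inheritParams tag_subtypes
#' @return Tibble with columns `entire_value`, `subtype_leaf`,
#'   `subtype_root`, `subtype_polarity`.
#' @export
subtype_table <- function(entire_values, cues = default_subtype_cues(),
                          rollup = default_subtype_rollup()) {
  vals <- unique(entire_values)
  anns <- lapply(vals, function(v) tag_subtypes(v, cues, rollup)[1, ])
  dplyr::bind_rows(anns) %>%
    dplyr::transmute(
      entire_value = vals,
      subtype_leaf = .data$leaf,
      subtype_root = .data$root,
      subtype_polarity = .data$polarity
    )
}

#' Assemble parsed pairs and normalizations into the flat DID table
#'
#' Joins the per-stage outputs — parsed pairs, drug normalizations
#' ([normalize_drugs()]), indication mappings ([normalize_indications()]),
#' and subtype annotations ([subtype_table()]) — into one row per (pair x
#' indication mapping component). The table is keyed on the quadruplet
#' (source, raw drug name, target, indication CUI): duplicate quadruplets
#' collapse keeping the highest-quality indication match, and rows are
#' sorted by (source, raw drug name, target).
#'
#' @param pairs Parsed-pairs tibble from the ingest adapters.
#' @param drug_norms Tibble from [normalize_drugs()], covering every raw
#'   drug name in `pairs`.
#' @param indication_maps Tibble from [normalize_indications()], covering
#'   every target in `pairs`.
#' @param subtype_annotations Optional tibble from [subtype_table()].
#' @return A `did_table` tibble; see the package vignette for the column
#'   inventory.
#' @export
assemble_did <- function(pairs, drug_norms, indication_maps,
                         subtype_annotations = NULL) {
  pairs <- tibble::as_tibble(pairs)
  if (!nrow(pairs)) return(new_did_table(empty_did()))

  missing_drugs <- setdiff(pairs$raw_drug_name, drug_norms$raw_name)
  if (length(missing_drugs)) {
    stop_consistency(sprintf(
      "pairs reference raw drug name(s) without a normalization: %s",
      paste(utils::head(missing_drugs, 5), collapse = ", ")
    ))
  }
  missing_inds <- setdiff(pairs$target, indication_maps$target)
  if (length(missing_inds)) {
    stop_consistency(sprintf(
      "pairs reference target(s) without an indication mapping: %s",
      paste(utils::head(missing_inds, 5), collapse = ", ")
    ))
  }
  if (is.null(subtype_annotations)) {
    subtype_annotations <- tibble::tibble(
      entire_value = character(), subtype_leaf = character(),
      subtype_root = character(), subtype_polarity = character()
    )
  }

  rows <- pairs %>%
    dplyr::left_join(dplyr::rename(drug_norms, raw_drug_name = "raw_name"),
                     by = "raw_drug_name") %>%
    dplyr::inner_join(indication_maps, by = "target",
                      relationship = "many-to-many") %>%
    dplyr::left_join(subtype_annotations, by = "entire_value") %>%
    dplyr::transmute(
      source_id = .data$source_id,
      raw_drug_name = .data$raw_drug_name,
      cas_number = .data$cas_number,
      cas_authority = .data$cas_authority,
      cas_match_type = .data$cas_match_type,
      drug_preferred_pt = .data$preferred_pt,
      authority_matches = .data$authority_matches,
      drug_cui = .data$cui,
      drug_cui_match_type = .data$cui_match_type,
      subtype_leaf = .data$subtype_leaf,
      subtype_root = .data$subtype_root,
      subtype_polarity = .data$subtype_polarity,
      entire_value = .data$entire_value,
      target = .data$target,
      target_equals_entire = .data$target_equals_entire,
      ind_match_quality = .data$ind_match_quality,
      ind_entry_term = .data$ind_entry_term,
      ind_preferred_term = .data$ind_preferred_term,
      ind_cui = .data$ind_cui,
      ind_entry_status = .data$ind_entry_status,
      ind_semantic_types = .data$ind_semantic_types,
      ind_phenotypic = .data$ind_phenotypic,
      remap_outcome = .data$remap_outcome,
      compound_index = .data$compound_index,
      init_entry_term = .data$init_entry_term,
      init_preferred_term = .data$init_preferred_term,
      init_cui = .data$init_cui,
      init_semantic_types = .data$init_semantic_types
    )

  # collapse duplicate quadruplets, best indication match quality first
  rows <- rows[order(match_precedence(rows$ind_match_quality),
                     rows$source_id), , drop = FALSE]
  rows <- rows[!duplicated(did_key_of(rows)), , drop = FALSE]
  rows <- rows[order(rows$source_id, rows$raw_drug_name, rows$target,
                     dplyr::coalesce(rows$ind_cui, "")), , drop = FALSE]
  new_did_table(rows)
}

empty_did <- function() {
  cols <- names(did_column_letters)
  out <- tibble::as_tibble(
    stats::setNames(rep(list(character()), length(cols)), cols)
  )
  out$target_equals_entire <- logical()
  out$ind_phenotypic <- logical()
  out$compound_index <- integer()
  out[names(did_column_letters)]
}

new_did_table <- function(rows) {
  rows <- tibble::as_tibble(rows)[names(did_column_letters)]
  class(rows) <- c("did_table", class(rows))
  rows
}

#' @export
print.did_table <- function(x, ...) {
  cat(sprintf("<did_table> %d rows, %d sources, %d unique raw drug names\n",
              nrow(x), dplyr::n_distinct(x$source_id),
              dplyr::n_distinct(x$raw_drug_name)))
  NextMethod()
}

#' Validate DID table invariants
#'
#' Checks quadruplet uniqueness, the `target_equals_entire` flag against
#' string equality, and that populated CUIs are nonempty.
#'
#' @param rows A `did_table`.
#' @return `rows`, invisibly, if valid.
#' @export
validate_did <- function(rows) {
  key <- did_key_of(rows)
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop_validation(sprintf(
      "duplicate quadruplet key(s): %s",
      paste(utils::head(gsub("\r", " | ", dup), 3), collapse = "; ")
    ))
  }
  bad_flag <- which(rows$target_equals_entire != (rows$target == rows$entire_value))
  if (length(bad_flag)) {
    stop_validation(sprintf("target_equals_entire flag inconsistent at row(s) %s",
                            paste(utils::head(bad_flag, 5), collapse = ", ")))
  }
  if (any(!is.na(rows$ind_cui) & !nzchar(rows$ind_cui))) {
    stop_validation("populated indication CUI must be nonempty")
  }
  invisible(rows)
}

did_header <- function(cols) {
  sprintf("%s(%s)", cols, did_column_letters[cols])
}

#' Write a DID table to its TSV dialect
#'
#' UTF-8 TSV; the header names each field with its spreadsheet column letter
#' in parentheses (e.g. `target(AR)`). Tabs, newlines and backslashes inside
#' fields are escaped (`\\t`, `\\n`, `\\r`, `\\\\`) and restored by
#' [read_did()]; missing values are written as empty fields; the boolean
#' flags are written `Y`/`N`. Byte output is deterministic for a given row
#' list.
#'
#' @param rows A `did_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_did <- function(rows, path) {
  rows <- tibble::as_tibble(rows)[names(did_column_letters)]
  ser <- lapply(names(did_column_letters), function(col) {
    v <- rows[[col]]
    if (is.logical(v)) {
      ifelse(is.na(v), "", ifelse(v, "Y", "N"))
    } else if (is.numeric(v)) {
      ifelse(is.na(v), "", format(v, scientific = FALSE, trim = TRUE))
    } else {
      ifelse(is.na(v), "", escape_field(v))
    }
  })
  lines <- c(
    paste(did_header(names(did_column_letters)), collapse = "\t"),
    if (nrow(rows)) do.call(paste, c(ser, sep = "\t"))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a DID table from its TSV dialect
#'
#' Inverse of [write_did()]. In legacy mode the pre-remap block (columns
#' BD-BL of the published layout) may be absent and is filled with missing
#' values; unrecognized extra columns are ignored.
#'
#' @param path Path to a DID TSV.
#' @param legacy Accept files missing the optional pre-remap block.
#' @return A `did_table`.
#' @export
read_did <- function(path, legacy = FALSE) {
  if (!file.exists(path)) stop_input(sprintf("input file does not exist: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop_format("empty DID file (missing header)")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  canon <- sub("\\([^)]*\\)$", "", header)

  required <- setdiff(names(did_column_letters),
                      if (legacy) did_optional_columns else character())
  missing <- setdiff(required, canon)
  if (length(missing)) {
    stop_format(sprintf("DID header mismatch; missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }

  body <- lines[-1]
  cells <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(cells)
  # trailing empty fields are dropped by strsplit; pad back out
  cells <- lapply(cells, function(x) c(x, rep("", length(header) - length(x))))
  if (any(nf > length(header))) {
    stop_format(sprintf("row(s) with too many fields at line(s) %s",
                        paste(utils::head(which(nf > length(header)) + 1L, 5),
                              collapse = ", ")))
  }
  mat <- if (length(cells)) do.call(rbind, cells) else
    matrix(character(), ncol = length(header))
  colnames(mat) <- canon

  out <- empty_did()[0, ]
  get_col <- function(col) {
    if (col %in% canon) {
      v <- unescape_field(mat[, col])
      ifelse(nzchar(v), v, NA_character_)
    } else {
      rep(NA_character_, nrow(mat))
    }
  }
  vals <- lapply(names(did_column_letters), get_col)
  names(vals) <- names(did_column_letters)
  out <- tibble::as_tibble(vals)
  out$target_equals_entire <- out$target_equals_entire == "Y"
  out$ind_phenotypic <- out$ind_phenotypic == "Y"
  out$compound_index <- as.integer(out$compound_index)

  rows <- new_did_table(out)
  key <- did_key_of(rows)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_validation(sprintf(
      "duplicate quadruplet at line %d: %s",
      dup[[1]] + 1L, gsub("\r", " | ", key[dup[[1]]])
    ))
  }
  rows
}
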