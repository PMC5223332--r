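#' @title Parsed drug-indication pairs and filter accounting
#' @description Every source adapter returns a list with two elements:
#'   `pairs`, a tibble of parsed pairs with columns `source_id`,
#'   `raw_drug_name`, `entire_value` (the raw source's whole indication
#'   value), `target` (a term/phrase within or based on the entire value,
#'   denoting one indication concept), and `target_equals_entire`; and
#'   `report`, a `filter_report` tallying how many candidate pairs entered,
#'   survived filtering, and parsed into targets, with per-rule removal
#'   counts.
#' @name ingest
NULL

new_filter_report <- function(initial, filtered, parsed, per_rule_removed) {
  structure(
    list(
      initial = as.integer(initial),
      filtered = as.integer(filtered),
      parsed = as.integer(parsed),
      per_rule_removed = per_rule_removed
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> initial %d -> filtered %d -> parsed %d\n",
              x$initial, x$filtered, x$parsed))
  if (length(x$per_rule_removed)) {
    for (nm in names(x$per_rule_removed)) {
      cat(sprintf("  removed by %s: %d\n", nm, x$per_rule_removed[[nm]]))
    }
  }
  invisible(x)
}

empty_pairs <- function() {
  tibble::tibble(
    source_id = character(), raw_drug_name = character(),
    entire_value = character(), target = character(),
    target_equals_entire = logical()
  )
}

#' Default relation allowlist and role blocklist for pair-style sources
#'
#' Seeded with the canonical indication relations of drug reference
#' terminologies (`may_treat`, `may_prevent`, ...) and the non-indication
#' role objects that contaminate chemical-ontology exports (`metabolite`,
#' `prodrug`, `epitope`). Both are plain character vectors a caller can
#' extend or replace.
#'
#' @return Character vector.
#' @export
default_relation_allowlist <- function() {
  c("may_treat", "may_prevent", "may_diagnose",
    "has_mechanism_of_action", "has_physiological_effect",
    "therapeutic", "has_role", "indicated_for")
}

#' @rdname default_relation_allowlist
#' @export
default_role_blocklist <- function() {
  c("metabolite", "prodrug", "epitope", "solvent", "reagent", "food additive")
}

#' Default tokens signalling a combination (multi-ingredient) product name
#' @return Character vector of tokens searched case-insensitively in the
#'   drug-name field.
#' @export
default_combination_tokens <- function() {
  c(" and ", "/", " + ", ", combinations", " with ", " w/ ")
}

is_combination_name <- function(name, tokens = default_combination_tokens()) {
  low <- stringr::str_to_lower(name)
  vapply(low, function(s) any(stringr::str_detect(s, stringr::fixed(tokens))),
         logical(1), USE.NAMES = FALSE)
}

# empty, purely numeric, or a bare letter+digits code
is_ill_formed_name <- function(name) {
  name <- trimws(name)
  !nzchar(name) | grepl("^[0-9]+$", name) | grepl("^[A-Za-z][0-9]+$", name)
}

#' Ingest a pair-style source (controlled drug/indication relation lists)
#'
#' Records whose relation name is not on the allowlist, or whose indication
#' term is on the role blocklist (matched under [norm_key()]), are dropped and
#' tallied. Survivors become parsed pairs with `target = entire_value`;
#' duplicates on (drug, entire value) collapse.
#'
#' @param records Tibble with columns `source_id`, `drug`, `relation`,
#'   `indication_term` (the on-disk pair-source TSV layout).
#' @param relation_allowlist,role_blocklist Character vectors; see
#'   [default_relation_allowlist()].
#' @return `list(pairs = <tibble>, report = <filter_report>)`.
#' @export
ingest_pair_source <- function(records,
                               relation_allowlist = default_relation_allowlist(),
                               role_blocklist = default_role_blocklist()) {
  records <- tibble::as_tibble(records)
  needed <- c("source_id", "drug", "relation", "indication_term")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop_input(paste("pair-style records missing column(s):",
                     paste(missing, collapse = ", ")))
  }
  initial <- nrow(records)
  if (!initial) {
    return(list(pairs = empty_pairs(),
                report = new_filter_report(0L, 0L, 0L, integer())))
  }

  bad_rel <- !records$relation %in% relation_allowlist
  blocked <- norm_key(records$indication_term) %in% norm_key(role_blocklist) & !bad_rel
  keep <- records[!bad_rel & !blocked, , drop = FALSE]
  dup <- duplicated(keep[c("source_id", "drug", "indication_term")])
  keep <- keep[!dup, , drop = FALSE]

  pairs <- tibble::tibble(
    source_id = keep$source_id,
    raw_drug_name = keep$drug,
    entire_value = keep$indication_term,
    target = keep$indication_term,
    target_equals_entire = TRUE
  )
  report <- new_filter_report(
    initial, nrow(pairs), nrow(dplyr::distinct(pairs[c("source_id", "raw_drug_name", "target")])),
    c(relation_filter = sum(bad_rel), role_blocklist = sum(blocked),
      duplicate = sum(dup))
  )
  list(pairs = pairs, report = report)
}

#' Ingest a hierarchy-style source (ATC-like classification levels)
#'
#' Each level of the classification is viewed as a separate candidate
#' indication for the drug. Identical terms repeated at nested levels (e.g.
#' the same class name at codes B01 and B01A) collapse to one pair.
#' Combination and ill-formed drug names are dropped with their whole level
#' lists.
#'
#' @param records Tibble with columns `source_id`, `drug`, `level_code`,
#'   `level_term` — one row per hierarchy level, ordered root to leaf within
#'   each drug.
#' @param combination_tokens Tokens flagging multi-ingredient names; see
#'   [default_combination_tokens()].
#' @return `list(pairs, report)`; see [ingest_pair_source()].
#' @export
ingest_hierarchy_source <- function(records,
                                    combination_tokens = default_combination_tokens()) {
  records <- tibble::as_tibble(records)
  needed <- c("source_id", "drug", "level_code", "level_term")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop_input(paste("hierarchy-style records missing column(s):",
                     paste(missing, collapse = ", ")))
  }
  if (any(is.na(records$level_term) | !nzchar(trimws(records$level_term)))) {
    stop_input("hierarchy record with an empty level term")
  }
  initial <- nrow(records)
  if (!initial) {
    return(list(pairs = empty_pairs(),
                report = new_filter_report(0L, 0L, 0L, integer())))
  }

  combo <- is_combination_name(records$drug, combination_tokens)
  ill <- is_ill_formed_name(records$drug) & !combo
  keep <- records[!combo & !ill, , drop = FALSE]
  dup <- duplicated(keep[c("source_id", "drug", "level_term")])
  keep <- keep[!dup, , drop = FALSE]

  pairs <- tibble::tibble(
    source_id = keep$source_id,
    raw_drug_name = keep$drug,
    entire_value = keep$level_term,
    target = keep$level_term,
    target_equals_entire = TRUE
  )
  report <- new_filter_report(
    initial, nrow(pairs), nrow(dplyr::distinct(pairs[c("source_id", "raw_drug_name", "target")])),
    c(combination = sum(combo), ill_formed = sum(ill), redundant_level = sum(dup))
  )
  list(pairs = pairs, report = report)
}

#' Ingest a free-text source (label-style records with an indications section)
#'
#' Drops combination products and records whose indications text reaches the
#' tractability cutoff (length >= `max_len` characters after newlines are
#' converted to single spaces; the default keeps texts of up to 539
#' characters). Records sharing the same (generic name, text) but differing
#' only by trade name, dosage, formulation, or supplier collapse to one.
#' If an indication dictionary is supplied, each surviving text is parsed
#' into one or more targets with [split_targets()]; otherwise the whole text
#' is carried as a single target and parsing can be done later.
#'
#' @param records Tibble with columns `source_id`, `generic_name`,
#'   `trade_name`, `dosage`, `supplier`, `indications_text`.
#' @param max_len Integer tractability cutoff; texts with
#'   `nchar >= max_len` are dropped.
#' @param indication_dict Optional `concept_dictionary` used to parse texts
#'   into targets.
#' @inheritParams ingest_hierarchy_source
#' @return `list(pairs, report)`; `report$parsed` counts unique (drug,
#'   target) pairs after splitting.
#' @export
ingest_freetext_source <- function(records, max_len = 540L,
                                   indication_dict = NULL,
                                   combination_tokens = default_combination_tokens()) {
  if (length(max_len) != 1L || is.na(max_len) || max_len < 0) {
    stop_config("max_len must be a nonnegative integer")
  }
  records <- tibble::as_tibble(records)
  needed <- c("source_id", "generic_name", "indications_text")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop_input(paste("free-text records missing column(s):",
                     paste(missing, collapse = ", ")))
  }
  initial <- nrow(records)
  if (!initial) {
    return(list(pairs = empty_pairs(),
                report = new_filter_report(0L, 0L, 0L, integer())))
  }

  text <- stringr::str_replace_all(records$indications_text, "[\r\n]+", " ")
  combo <- is_combination_name(records$generic_name, combination_tokens)
  overlong <- nchar(text) >= max_len & !combo
  keep <- records[!combo & !overlong, , drop = FALSE]
  keep$entire_value <- text[!combo & !overlong]
  dup <- duplicated(keep[c("source_id", "generic_name", "entire_value")])
  keep <- keep[!dup, , drop = FALSE]

  filtered_pairs <- tibble::tibble(
    source_id = keep$source_id,
    raw_drug_name = keep$generic_name,
    entire_value = keep$entire_value
  )
  if (is.null(indication_dict)) {
    pairs <- dplyr::mutate(filtered_pairs,
                           target = .data$entire_value,
                           target_equals_entire = TRUE)
  } else {
    pairs <- tidyr::unnest(
      dplyr::mutate(
        filtered_pairs,
        split = purrr::map(.data$entire_value, split_targets, dict = indication_dict)
      ),
      "split"
    )
  }
  report <- new_filter_report(
    initial,
    nrow(filtered_pairs),
    nrow(dplyr::distinct(pairs[c("source_id", "raw_drug_name", "target")])),
    c(combination = sum(combo), overlong = sum(overlong),
      redundant_variant = sum(dup))
  )
  list(pairs = pairs, report = report)
}

#' Parse an indication text into target terms
#'
#' Deterministic approximation of manual target extraction: the text is split
#' into sentences on `.` and `;`, then scanned left to right with greedy
#' longest dictionary matching — at each word position the longest word
#' n-gram whose [norm_key()] is an indexed dictionary term is emitted as a
#' target and the scan resumes after it. Matches never overlap and appear in
#' text order. If no dictionary term occurs anywhere, the whole value is
#' returned as its own target.
#'
#' @param entire_value Nonempty string.
#' @param dict An indication `concept_dictionary`.
#' @return Tibble with columns `target` and `target_equals_entire` (at least
#'   one row).
#' @export
split_targets <- function(entire_value, dict) {
  if (length(entire_value) != 1L || is.na(entire_value) || !nzchar(entire_value)) {
    stop_input("entire_value must be a single nonempty string")
  }
  keys <- unique(dict$terms$key)
  max_n <- max(c(1L, lengths(strsplit(keys, " ", fixed = TRUE))))

  sentences <- strsplit(entire_value, "[.;]")[[1]]
  found <- character()
  for (sent in sentences) {
    words <- strsplit(stringr::str_squish(sent), " ", fixed = TRUE)[[1]]
    words <- words[nzchar(words)]
    # token surface with edge punctuation stripped, for matching
    clean <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", words)
    i <- 1L
    while (i <= length(words)) {
      hit_len <- 0L
      for (n in rev(seq_len(min(max_n, length(words) - i + 1L)))) {
        cand <- norm_key(paste(clean[i:(i + n - 1L)], collapse = " "))
        if (nzchar(cand) && cand %in% keys) {
          hit_len <- n
          break
        }
      }
      if (hit_len > 0L) {
        found <- c(found, paste(clean[i:(i + hit_len - 1L)], collapse = " "))
        i <- i + hit_len
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(found)) {
    return(tibble::tibble(target = entire_value, target_equals_entire = TRUE))
  }
  found <- unique(found)
  tibble::tibble(target = found, target_equals_entire = found == entire_value)
}

#' Read raw source files in the three on-disk layouts
#'
#' Thin TSV readers for the pair, hierarchy and free-text source layouts
#' (UTF-8, header row required); they validate the column set and return the
#' record tibble expected by the matching `ingest_*` adapter.
#'
#' @param path Path to the source TSV.
#' @return A tibble of raw records.
#' @export
read_pair_source <- function(path) {
  read_tsv_strict(path, c("source_id", "drug", "relation", "indication_term"))
}

#' @rdname read_pair_source
#' @export
read_hierarchy_source <- function(path) {
  read_tsv_strict(path, c("source_id", "drug", "level_code", "level_term"))
}

#' @rdname read_pair_source
#' @export
read_freetext_source <- function(path) {
  read_tsv_strict(path, c("source_id", "generic_name", "trade_name", "dosage",
                          "supplier", "indications_text"))
}
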