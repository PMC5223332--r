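#' Render an entry term for display
#'
#' For readability in the flat table, preferred (`P`) entry terms are shown
#' in proper case — the first letter of each whitespace-delimited word
#' capitalized, the rest lowercased — and non-preferred synonyms (`S`) fully
#' lowercased. The rendering is a projection: applying it twice equals
#' applying it once.
#'
#' @param term The entry term.
#' @param status `"P"` or `"S"`.
#' @return The rendered string.
#' @examples
#' render_entry_term("bacterial infections", "P")
#' render_entry_term("Hypertensive Disease", "S")
#' @export
render_entry_term <- function(term, status) {
  if (!status %in% c("P", "S")) stop_input("status must be P or S")
  if (is.na(term)) return(NA_character_)
  if (status == "S") return(stringr::str_to_lower(term))
  words <- strsplit(term, " ", fixed = TRUE)[[1]]
  words <- ifelse(
    nzchar(words),
    paste0(toupper(substring(words, 1L, 1L)),
           tolower(substring(words, 2L))),
    words
  )
  paste(words, collapse = " ")
}

unmapped_indication <- function(target) {
  structure(
    list(
      target = target,
      entry_term = NA_character_, entry_status = NA_character_,
      preferred_term = NA_character_, cui = NA_character_,
      semantic_types = character(), phenotypic = FALSE,
      match_quality = "UNMAPPED", initial = NULL, compound_index = NA_integer_
    ),
    class = "indication_mapping"
  )
}

#' Map an indication target to a concept, preferring phenotypic types
#'
#' Exact-key lookup of the target against the indication dictionary. Among
#' candidates, one with a phenotypic semantic type is preferred; then
#' P-status beats S-status; remaining ties break on the smallest concept
#' identifier. Unmatched targets yield an `UNMAPPED` mapping.
#'
#' @param target Nonempty target term/phrase.
#' @param dict The indication `concept_dictionary`.
#' @param scheme A `semantic_scheme`.
#' @return An `indication_mapping`: a list with fields `target`,
#'   `entry_term` (display-rendered), `entry_status`, `preferred_term`,
#'   `cui`, `semantic_types`, `phenotypic`, `match_quality`, `initial`
#'   (pre-remap block, `NULL` until a remap occurs), `compound_index`.
#' @export
map_indication <- function(target, dict, scheme) {
  if (length(target) != 1L || is.na(target) || !nzchar(trimws(target))) {
    stop_input("target must be a single nonempty string")
  }
  hits <- lookup_term(dict, target)
  if (!nrow(hits)) return(unmapped_indication(target))
  hits$phenotypic <- vapply(hits$semantic_types, is_phenotypic, logical(1),
                            scheme = scheme)
  hits <- hits[order(!hits$phenotypic, hits$status != "P", hits$concept_id), ,
               drop = FALSE]
  best <- hits[1, ]
  structure(
    list(
      target = target,
      entry_term = render_entry_term(best$matched_term, best$status),
      entry_status = best$status,
      preferred_term = render_entry_term(best$preferred_term, "P"),
      cui = best$concept_id,
      semantic_types = best$semantic_types[[1]],
      phenotypic = best$phenotypic,
      match_quality = if (best$status == "P") "PT_EXACT" else "SYNONYM",
      initial = NULL, compound_index = NA_integer_
    ),
    class = "indication_mapping"
  )
}

#' @export
print.indication_mapping <- function(x, ...) {
  cat(sprintf("<indication_mapping> %s -> %s (%s, %s, phenotypic=%s)\n",
              x$target, x$cui %||% NA, x$preferred_term %||% NA,
              x$match_quality, x$phenotypic))
  invisible(x)
}

#' Remap a non-phenotypic indication mapping to its phenotypic concept
#'
#' Therapeutic-class concepts (e.g. an "Anti-Bacterial Agents" mapping) are
#' traded for the disease-level concept they imply (e.g. "Bacterial
#' Infections") when the remap table provides one, unifying raw data that
#' encode to either. The pre-remap mapping is preserved in the `initial`
#' block and the final match quality becomes `QUASI_SYNONYM` (lexical
#' precision was traded for terminological reduction). Non-phenotypic
#' mappings without a remap entry stay where they are ("stuck").
#'
#' @param mapping An `indication_mapping` from [map_indication()].
#' @param remap A `remap_table`.
#' @param dict,scheme Dictionary and scheme used to resolve remap targets.
#' @return `list(mapping = <final indication_mapping>, outcome = one of
#'   "ALREADY_PHENOTYPIC", "REMAPPED", "STUCK", "UNMAPPED")`. The final
#'   mapping is a fixed point: remapping it again leaves it unchanged.
#' @export
remap_phenotype <- function(mapping, remap, dict, scheme) {
  stopifnot(inherits(mapping, "indication_mapping"))
  if (mapping$match_quality == "UNMAPPED") {
    return(list(mapping = mapping, outcome = "UNMAPPED"))
  }
  if (isTRUE(mapping$phenotypic)) {
    return(list(mapping = mapping, outcome = "ALREADY_PHENOTYPIC"))
  }
  hit <- remap$to_concept_id[remap$from_concept_id == mapping$cui]
  if (!length(hit)) {
    return(list(mapping = mapping, outcome = "STUCK"))
  }
  to <- dict$entries[dict$entries$concept_id == hit[[1]], , drop = FALSE]
  if (!nrow(to)) {
    stop_config(sprintf("remap target %s is absent from the dictionary", hit[[1]]))
  }
  final <- mapping
  final$initial <- list(
    entry_term = mapping$entry_term, entry_status = mapping$entry_status,
    preferred_term = mapping$preferred_term, cui = mapping$cui,
    semantic_types = mapping$semantic_types
  )
  final$entry_term <- render_entry_term(to$preferred_term, "P")
  final$entry_status <- "P"
  final$preferred_term <- render_entry_term(to$preferred_term, "P")
  final$cui <- to$concept_id
  final$semantic_types <- to$semantic_types[[1]]
  final$phenotypic <- is_phenotypic(scheme, final$semantic_types)
  final$match_quality <- "QUASI_SYNONYM"
  list(mapping = final, outcome = "REMAPPED")
}

#' Map a target that may need several concepts to cover it
#'
#' If the whole target matches a single concept, a singleton mapping is
#' returned (no compound index). Otherwise the target is partitioned into
#' maximal dictionary-matchable spans (leftmost-longest over words), each
#' span mapped and phenotypically remapped, and components indexed 1..k.
#' Uncovered residue between spans is dropped. A target with no matchable
#' span yields a singleton `UNMAPPED` mapping.
#'
#' @inheritParams map_indication
#' @param remap A `remap_table` applied to every component.
#' @return A list of `indication_mapping` objects (components carry
#'   `compound_index` only when more than one concept was needed).
#' @export
compound_map <- function(target, dict, scheme, remap) {
  whole <- map_indication(target, dict, scheme)
  if (whole$match_quality != "UNMAPPED") {
    return(list(remap_phenotype(whole, remap, dict, scheme)$mapping))
  }
  spans <- split_targets(target, dict)
  spans <- spans$target[!spans$target_equals_entire]
  if (!length(spans)) {
    return(list(whole))
  }
  maps <- lapply(spans, function(sp) {
    m <- remap_phenotype(map_indication(sp, dict, scheme), remap, dict, scheme)$mapping
    m$target <- target  # components keep the original target (column AR)
    m
  })
  if (length(maps) > 1L) {
    for (i in seq_along(maps)) maps[[i]]$compound_index <- i
  }
  maps
}

indication_mapping_row <- function(m, outcome) {
  init <- m$initial
  tibble::tibble(
    target = m$target,
    compound_index = m$compound_index,
    ind_match_quality = m$match_quality,
    ind_entry_term = m$entry_term,
    ind_entry_status = m$entry_status,
    ind_preferred_term = m$preferred_term,
    ind_cui = m$cui,
    ind_semantic_types = if (length(m$semantic_types)) {
      paste(m$semantic_types, collapse = ";")
    } else NA_character_,
    ind_phenotypic = m$phenotypic,
    remap_outcome = outcome,
    init_entry_term = if (is.null(init)) NA_character_ else init$entry_term,
    init_preferred_term = if (is.null(init)) NA_character_ else init$preferred_term,
    init_cui = if (is.null(init)) NA_character_ else init$cui,
    init_semantic_types = if (is.null(init) || !length(init$semantic_types)) {
      NA_character_
    } else paste(init$semantic_types, collapse = ";")
  )
}

#' Normalize a vector of indication targets to a flat table
#'
#' Driver over [map_indication()], [remap_phenotype()] and [compound_map()]:
#' one output row per (unique target, component).
#'
#' @param targets Character vector of targets (duplicates collapsed).
#' @inheritParams compound_map
#' @param compound Should multi-concept covering be attempted for targets
#'   that do not match as a whole? Default `TRUE`.
#' @return A tibble with columns `target`, `compound_index`,
#'   `ind_match_quality`, `ind_entry_term`, `ind_entry_status`,
#'   `ind_preferred_term`, `ind_cui`, `ind_semantic_types`,
#'   `ind_phenotypic`, `remap_outcome`, and the pre-remap block
#'   `init_entry_term`, `init_preferred_term`, `init_cui`,
#'   `init_semantic_types`.
#' @export
normalize_indications <- function(targets, dict, scheme, remap,
                                  compound = TRUE) {
  targets <- unique(targets)
  rows <- lapply(targets, function(tg) {
    if (compound) {
      maps <- compound_map(tg, dict, scheme, remap)
      dplyr::bind_rows(lapply(maps, function(m) {
        outcome <- if (m$match_quality == "UNMAPPED") {
          "UNMAPPED"
        } else if (!is.null(m$initial)) {
          "REMAPPED"
        } else if (m$phenotypic) "ALREADY_PHENOTYPIC" else "STUCK"
        indication_mapping_row(m, outcome)
      }))
    } else {
      res <- remap_phenotype(map_indication(tg, dict, scheme), remap, dict, scheme)
      indication_mapping_row(res$mapping, res$outcome)
    }
  })
  dplyr::bind_rows(rows)
}
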