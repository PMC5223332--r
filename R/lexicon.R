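#' Define a terminology authority
#'
#' An authority is a named synonym dictionary (e.g. a chemical registry or a
#' metathesaurus) together with its precedence rank used when several
#' dictionaries disagree on the preferred term for the same concept. Rank 1 is
#' the most preferred.
#'
#' @param name Short identifier string, e.g. `"ChemIDplus"`.
#' @param rank Positive integer; 1 = most preferred.
#' @return An object of class `did_authority`.
#' @seealso [authority_ranking()] for building a whole ranked configuration.
#' @export
authority <- function(name, rank) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_input("authority name must be a single nonempty string")
  }
  rank <- as.integer(rank)
  if (is.na(rank) || rank < 1L) stop_input("authority rank must be a positive integer")
  structure(list(name = name, rank = rank), class = "did_authority")
}

#' @export
print.did_authority <- function(x, ...) {
  cat(sprintf("<authority> %s (rank %d)\n", x$name, x$rank))
  invisible(x)
}

#' Build a ranked authority configuration
#'
#' @param names Character vector of authority names, most preferred first
#'   (ranks are assigned 1, 2, ...), or a named integer vector of explicit
#'   ranks (`c(ChemIDplus = 1, ChEBI = 2)`). Equal explicit ranks are allowed;
#'   ties at resolution time are broken on the lexicographically smallest
#'   concept identifier.
#' @return A tibble with columns `name` and `rank`.
#' @examples
#' authority_ranking(c("ChemIDplus", "ChEBI", "DrugBank", "eVOC", "CTD"))
#' @export
authority_ranking <- function(names) {
  if (is.numeric(names)) {
    rk <- tibble::tibble(name = base::names(names), rank = as.integer(names))
  } else {
    rk <- tibble::tibble(name = as.character(names), rank = seq_along(names))
  }
  if (anyNA(rk$name) || any(!nzchar(rk$name)) || anyDuplicated(rk$name)) {
    stop_input("authority names must be unique nonempty strings")
  }
  if (anyNA(rk$rank) || any(rk$rank < 1L)) stop_input("ranks must be positive integers")
  rk
}

new_concept_dictionary <- function(authority_name, rank, entries, terms) {
  structure(
    list(
      authority = authority(authority_name, rank),
      entries = entries,
      terms = terms
    ),
    class = "concept_dictionary"
  )
}

#' Build a concept dictionary from a term table
#'
#' The term table holds one row per (concept, term) pair, the same layout as
#' the dictionary TSV on disk (see [load_dictionary()]). Each concept must
#' have exactly one preferred (`P`) term; any number of synonym (`S`) rows may
#' follow. A CAS-style registry number and semantic-type codes may be given on
#' any row of a concept and are pooled per concept.
#'
#' @param rows A data frame with columns `concept_id`, `term`, `status`
#'   (`"P"` or `"S"`), and optionally `cas_number` and `semantic_types`
#'   (semicolon-separated type codes).
#' @param authority A [authority()] object, or an authority name (rank 1 is
#'   then assumed).
#' @return A `concept_dictionary`: entries (one row per concept, with
#'   `preferred_term`, `cas_number`, list-column `semantic_types`) plus a term
#'   index keyed by [norm_key()].
#' @export
dictionary_from_rows <- function(rows, authority) {
  if (is.character(authority)) authority <- authority(authority, 1L)
  rows <- tibble::as_tibble(rows)
  needed <- c("concept_id", "term", "status")
  missing <- setdiff(needed, names(rows))
  if (length(missing)) {
    stop_format(paste("dictionary rows missing column(s):", paste(missing, collapse = ", ")))
  }
  if (!"cas_number" %in% names(rows)) rows$cas_number <- NA_character_
  if (!"semantic_types" %in% names(rows)) rows$semantic_types <- NA_character_
  rows$line <- seq_len(nrow(rows)) + 1L  # +1: header occupies line 1 on disk

  bad_status <- rows[!rows$status %in% c("P", "S"), ]
  if (nrow(bad_status)) {
    stop_validation(sprintf(
      "unknown status code(s) %s at line(s) %s (expected P or S)",
      paste(unique(bad_status$status), collapse = ", "),
      paste(bad_status$line, collapse = ", ")
    ))
  }
  blank <- rows[is.na(rows$term) | !nzchar(trimws(rows$term)) |
                  is.na(rows$concept_id) | !nzchar(trimws(rows$concept_id)), ]
  if (nrow(blank)) {
    stop_validation(sprintf("blank concept_id or term at line(s) %s",
                            paste(blank$line, collapse = ", ")))
  }
  dup <- rows[duplicated(rows[c("concept_id", "term")]), ]
  if (nrow(dup)) {
    stop_validation(sprintf(
      "duplicate (concept_id, term) row(s) for %s at line(s) %s",
      paste(unique(dup$concept_id), collapse = ", "),
      paste(dup$line, collapse = ", ")
    ))
  }
  n_p <- tapply(rows$status == "P", rows$concept_id, sum)
  off <- names(n_p)[n_p != 1L]
  if (length(off)) {
    stop_validation(sprintf(
      "concept(s) %s must have exactly one P-status (preferred) term",
      paste(off, collapse = ", ")
    ))
  }

  entries <- rows %>%
    dplyr::group_by(.data$concept_id) %>%
    dplyr::summarise(
      preferred_term = .data$term[.data$status == "P"][1],
      cas_number = {
        cas <- unique(.data$cas_number[!is.na(.data$cas_number) & nzchar(.data$cas_number)])
        if (length(cas) > 1L) {
          stop_validation(sprintf("concept %s carries conflicting CAS numbers: %s",
                                  .data$concept_id[1], paste(cas, collapse = ", ")))
        }
        if (length(cas)) cas else NA_character_
      },
      semantic_types = list(sort(unique(unlist(
        strsplit(.data$semantic_types[!is.na(.data$semantic_types)], ";", fixed = TRUE)
      )))),
      .groups = "drop"
    )

  terms <- rows %>%
    dplyr::transmute(
      concept_id = .data$concept_id,
      term = .data$term,
      status = .data$status,
      key = norm_key(.data$term)
    )

  new_concept_dictionary(authority$name, authority$rank, entries, terms)
}

#' Load a concept dictionary from a delimited-text file
#'
#' The dictionary format is a project-defined TSV (UTF-8, header required)
#' with columns `concept_id`, `term`, `status` (`P`|`S`), optional
#' `cas_number`, and optional `semantic_types` (semicolon-separated codes) —
#' one row per (concept, term) pair. Native metathesaurus release formats are
#' deliberately not parsed; export to this layout first.
#'
#' @param path Path to the TSV file.
#' @inheritParams dictionary_from_rows
#' @return A `concept_dictionary`; see [dictionary_from_rows()].
#' @export
load_dictionary <- function(path, authority) {
  rows <- read_tsv_strict(path, c("concept_id", "term", "status"))
  dictionary_from_rows(rows, authority)
}

#' @export
print.concept_dictionary <- function(x, ...) {
  cat(sprintf(
    "<concept_dictionary> %s (rank %d): %d concepts, %d indexed terms\n",
    x$authority$name, x$authority$rank, nrow(x$entries), nrow(x$terms)
  ))
  invisible(x)
}

#' Look up a term in a concept dictionary
#'
#' Matching is exact and case-insensitive on the normalized key (see
#' [norm_key()]): all concepts whose preferred term or any synonym equals the
#' query under the key are returned.
#'
#' @param dict A `concept_dictionary`.
#' @param term Query string.
#' @return A tibble with zero or more rows and columns `concept_id`,
#'   `matched_term`, `status`, `preferred_term`, `cas_number`,
#'   `semantic_types` (list-column).
#' @export
lookup_term <- function(dict, term) {
  stopifnot(inherits(dict, "concept_dictionary"))
  if (length(term) != 1L || is.na(term) || !nzchar(trimws(term))) {
    stop_input("lookup query must be a single nonempty string")
  }
  key <- norm_key(term)
  hits <- dict$terms[dict$terms$key == key, , drop = FALSE]
  out <- dplyr::inner_join(
    dplyr::rename(hits, matched_term = "term"),
    dict$entries,
    by = "concept_id"
  )
  dplyr::select(out, "concept_id", "matched_term", "status",
                "preferred_term", "cas_number", "semantic_types")
}

#' Resolve conflicting preferred terms across ranked authorities
#'
#' When several dictionaries supply a preferred term for the same underlying
#' concept (typically keyed by a shared CAS number), the candidate from the
#' highest-ranked (lowest rank number) authority wins. Ties between equally
#' ranked authorities are broken deterministically on the lexicographically
#' smallest concept identifier.
#'
#' @param candidates A data frame with columns `authority`, `concept_id`,
#'   `preferred_term` — one row per candidate authority.
#' @param ranking A ranking tibble from [authority_ranking()].
#' @return A list with elements `preferred_term`, `authority`, `concept_id`.
#' @examples
#' rk <- authority_ranking(c("ChemIDplus", "ChEBI"))
#' cands <- tibble::tibble(
#'   authority = c("ChEBI", "ChemIDplus"),
#'   concept_id = c("103-90-2", "103-90-2"),
#'   preferred_term = c("paracetamol", "Acetaminophen")
#' )
#' rank_resolve(cands, rk)
#' @export
rank_resolve <- function(candidates, ranking) {
  candidates <- tibble::as_tibble(candidates)
  if (!nrow(candidates)) stop_input("rank_resolve needs at least one candidate")
  unknown <- setdiff(candidates$authority, ranking$name)
  if (length(unknown)) {
    stop_config(sprintf("candidate authority not in ranking: %s",
                        paste(unknown, collapse = ", ")))
  }
  cand <- dplyr::left_join(candidates, ranking, by = c(authority = "name"))
  cand <- cand[order(cand$rank, cand$concept_id, cand$authority), , drop = FALSE]
  list(
    preferred_term = cand$preferred_term[[1]],
    authority = cand$authority[[1]],
    concept_id = cand$concept_id[[1]]
  )
}

#' Load or construct a semantic-type scheme
#'
#' A scheme assigns each semantic-type code a position in the type tree
#' (dotted tree number), a label, and a flag saying whether the type denotes a
#' phenotype — a disease or another biological condition, process, or
#' function. The phenotypic flag partitions the scheme and drives the
#' preference for disease-level indication encoding.
#'
#' @param path Path to a TSV with columns `type_code`, `tree_number`, `label`,
#'   `phenotypic` (0 or 1).
#' @return A tibble of class `semantic_scheme`.
#' @seealso [default_semantic_scheme()]
#' @export
load_semantic_scheme <- function(path) {
  tab <- read_tsv_strict(path, c("type_code", "tree_number", "label", "phenotypic"))
  scheme_from_rows(tab)
}

scheme_from_rows <- function(tab) {
  tab <- tibble::as_tibble(tab)
  tab$phenotypic <- as.logical(as.integer(tab$phenotypic))
  if (anyDuplicated(tab$type_code)) {
    stop_validation("semantic-type codes must be unique in a scheme")
  }
  if (anyNA(tab$phenotypic)) stop_validation("phenotypic flag must be 0 or 1")
  class(tab) <- c("semantic_scheme", class(tab))
  tab
}

#' Default semantic-type scheme
#'
#' A compact scheme covering the type-tree regions that matter for indication
#' encoding. Phenotypic types span diseases and abnormalities (the `B2.2.1.2`
#' pathologic-function subtree) and biologic functions (the `A2.2`
#' physiologic-function subtree); the non-phenotypic exemplars are chemical
#' and pharmacologic substance types such as "Pharmacologic Substance"
#' (A1.4.1.1.1) and "Antibiotic" (A1.4.1.1.1.1). The scheme is data, not
#' code: supply your own via [load_semantic_scheme()] to change the
#' partition.
#'
#' @return A `semantic_scheme` tibble.
#' @export
default_semantic_scheme <- function() {
  scheme_from_rows(tibble::tribble(
    ~type_code, ~tree_number,     ~label,                                ~phenotypic,
    "T047",     "B2.2.1.2.1",     "Disease or Syndrome",                 1,
    "T046",     "B2.2.1.2",       "Pathologic Function",                 1,
    "T048",     "B2.2.1.2.1.1",   "Mental or Behavioral Dysfunction",    1,
    "T191",     "B2.2.1.2.1.2",   "Neoplastic Process",                  1,
    "T184",     "B2.2.1.2.2",     "Sign or Symptom",                     1,
    "T037",     "B2.2.1.2.4",     "Injury or Poisoning",                 1,
    "T039",     "A2.2",           "Physiologic Function",                1,
    "T040",     "A2.2.1",         "Organism Function",                   1,
    "T042",     "A2.2.2",         "Organ or Tissue Function",            1,
    "T043",     "A2.2.3",         "Cell Function",                       1,
    "T044",     "A2.2.4",         "Molecular Function",                  1,
    "T061",     "B1.3.1.3",       "Therapeutic or Preventive Procedure", 1,
    "T121",     "A1.4.1.1.1",     "Pharmacologic Substance",             0,
    "T195",     "A1.4.1.1.1.1",   "Antibiotic",                          0,
    "T109",     "A1.4.1.2",       "Organic Chemical",                    0,
    "T167",     "A1.4.3",         "Substance",                           0
  ))
}

#' Test whether a set of semantic types is phenotypic
#'
#' @param scheme A `semantic_scheme`.
#' @param type_codes Character vector of type codes (possibly empty).
#' @return `TRUE` iff at least one code is flagged phenotypic in the scheme.
#' @export
is_phenotypic <- function(scheme, type_codes) {
  if (!length(type_codes)) return(FALSE)
  any(type_codes %in% scheme$type_code[scheme$phenotypic])
}

#' Load or construct a phenotype remap table
#'
#' Maps therapeutic-class concepts (e.g. "Anti-Bacterial Agents") to the
#' disease-level phenotypic concept they imply (e.g. "Bacterial Infections").
#' The table must be idempotent: a remap target never itself remaps further.
#'
#' @param path Path to a TSV with columns `from_concept_id`, `to_concept_id`.
#' @return A tibble of class `remap_table`.
#' @export
load_remap_table <- function(path) {
  tab <- read_tsv_strict(path, c("from_concept_id", "to_concept_id"))
  remap_from_rows(tab)
}

#' @rdname load_remap_table
#' @param rows A data frame with columns `from_concept_id`, `to_concept_id`.
#' @export
remap_from_rows <- function(rows) {
  tab <- tibble::as_tibble(rows)[c("from_concept_id", "to_concept_id")]
  if (anyDuplicated(tab$from_concept_id)) {
    stop_validation("remap table maps a source concept more than once")
  }
  chain <- intersect(tab$to_concept_id, tab$from_concept_id)
  chain <- setdiff(chain, tab$from_concept_id[tab$from_concept_id == tab$to_concept_id])
  if (length(chain)) {
    stop_validation(sprintf(
      "remap table is not idempotent: target(s) %s remap further",
      paste(chain, collapse = ", ")
    ))
  }
  class(tab) <- c("remap_table", class(tab))
  tab
}

#' Validate a remap table against a dictionary and scheme
#'
#' Checks that every remap target resolves in the dictionary and carries at
#' least one phenotypic semantic type.
#'
#' @param remap A `remap_table`.
#' @param dict The indication `concept_dictionary`.
#' @param scheme A `semantic_scheme`.
#' @return `remap`, invisibly, if valid; otherwise a configuration error.
#' @export
validate_remap <- function(remap, dict, scheme) {
  for (cid in unique(remap$to_concept_id)) {
    hit <- dict$entries[dict$entries$concept_id == cid, ]
    if (!nrow(hit)) {
      stop_config(sprintf("remap target %s is absent from the dictionary", cid))
    }
    if (!is_phenotypic(scheme, hit$semantic_types[[1]])) {
      stop_config(sprintf("remap target %s has no phenotypic semantic type", cid))
    }
  }
  invisible(remap)
}
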