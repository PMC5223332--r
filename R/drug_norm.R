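#' Match-quality types
#'
#' Every mapping from a raw name to a standard-vocabulary entry is typed by
#' quality: `PT_EXACT` (key-equal to the preferred term), `SYNONYM`
#' (key-equal to a non-preferred synonym), `QUASI_SYNONYM` (near-equivalent,
#' differing by a minor chemical modifier such as "anhydrous", or an
#' indication remapped across semantic types), `NARROWER` / `BROADER`
#' (raw-to-standard directionality: a raw salt/derivative/formulation name is
#' NARROWER than the parent standard term), and `UNMAPPED`. The order
#' returned is the within-authority precedence used when several entries
#' match.
#'
#' @return Character vector of the six type labels, most exact first.
#' @export
match_types <- function() {
  c("PT_EXACT", "SYNONYM", "QUASI_SYNONYM", "NARROWER", "BROADER", "UNMAPPED")
}

match_precedence <- function(type) {
  match(type, match_types())
}

#' Default salt/formulation and quasi-synonym modifier lexicons
#'
#' Trailing tokens that mark a raw drug name as a salt, derivative, or
#' formulation of a parent compound (driving NARROWER/BROADER typing), and
#' modifiers that leave the name a near-equivalent of the standard term
#' (driving QUASI_SYNONYM typing). Both are configuration, not code.
#'
#' @return Character vector of lower-case tokens.
#' @export
default_salt_lexicon <- function() {
  c("hydrochloride", "fumarate", "sodium", "sulfate", "maleate", "tartrate",
    "acetate", "mesylate", "besylate", "hydrate", "dihydrate", "phosphate",
    "citrate", "succinate", "potassium", "calcium", "bromide", "nitrate")
}

#' @rdname default_salt_lexicon
#' @export
default_quasi_lexicon <- function() {
  c("anhydrous", "monohydrate", "racemic", "hemihydrate")
}

#' Classify the quality of one raw-name-to-entry match
#'
#' @param raw_name Raw drug/chemical name (nonempty).
#' @param matched_term The dictionary term it was matched to, or `NA` if no
#'   match was found (then `UNMAPPED` is returned).
#' @param status `"P"` or `"S"`: the matched term's status in its entry.
#' @param salt_lexicon,quasi_lexicon Modifier token sets; see
#'   [default_salt_lexicon()].
#' @return One of [match_types()].
#' @examples
#' classify_drug_match("arformoterol fumarate", "Arformoterol", "P")
#' classify_drug_match("cidofovir anhydrous", "Cidofovir", "P")
#' @export
classify_drug_match <- function(raw_name, matched_term, status = "P",
                                salt_lexicon = default_salt_lexicon(),
                                quasi_lexicon = default_quasi_lexicon()) {
  if (length(raw_name) != 1L || is.na(raw_name) || !nzchar(trimws(raw_name))) {
    stop_input("raw_name must be a single nonempty string")
  }
  if (is.na(matched_term)) return("UNMAPPED")
  rk <- key_tokens(norm_key(raw_name))
  mk <- key_tokens(norm_key(matched_term))
  if (identical(rk, mk)) {
    return(if (identical(status, "P")) "PT_EXACT" else "SYNONYM")
  }
  modifiers <- c(salt_lexicon, quasi_lexicon)
  if (length(rk) > length(mk) && identical(rk[seq_along(mk)], mk)) {
    extra <- rk[-seq_along(mk)]
    if (all(extra %in% quasi_lexicon)) return("QUASI_SYNONYM")
    if (all(extra %in% modifiers)) return("NARROWER")
  } else if (length(mk) > length(rk) && identical(mk[seq_along(rk)], rk)) {
    extra <- mk[-seq_along(rk)]
    if (all(extra %in% quasi_lexicon)) return("QUASI_SYNONYM")
    if (all(extra %in% modifiers)) return("BROADER")
  }
  "UNMAPPED"
}

# Best match of one raw name within a single dictionary. Tries exact key
# lookup first; failing that, strips trailing modifier tokens off the raw
# name (salt variant -> NARROWER/QUASI), then looks for dictionary terms
# that extend the raw name by trailing modifier tokens (-> BROADER).
match_in_dictionary <- function(raw_name, dict, salt_lexicon, quasi_lexicon) {
  none <- tibble::tibble(
    authority = dict$authority$name, concept_id = NA_character_,
    matched_term = NA_character_, status = NA_character_,
    match_type = "UNMAPPED", preferred_term = NA_character_,
    cas_number = NA_character_
  )
  classify_hits <- function(hits) {
    if (!nrow(hits)) return(NULL)
    hits$match_type <- vapply(seq_len(nrow(hits)), function(i) {
      classify_drug_match(raw_name, hits$matched_term[i], hits$status[i],
                          salt_lexicon, quasi_lexicon)
    }, character(1))
    hits <- hits[hits$match_type != "UNMAPPED", , drop = FALSE]
    if (!nrow(hits)) return(NULL)
    hits <- hits[order(match_precedence(hits$match_type),
                       hits$status != "P", hits$concept_id), , drop = FALSE]
    best <- hits[1, , drop = FALSE]
    tibble::tibble(
      authority = dict$authority$name, concept_id = best$concept_id,
      matched_term = best$matched_term, status = best$status,
      match_type = best$match_type, preferred_term = best$preferred_term,
      cas_number = best$cas_number
    )
  }

  hit <- classify_hits(lookup_term(dict, raw_name))
  if (!is.null(hit)) return(hit)

  modifiers <- c(salt_lexicon, quasi_lexicon)
  toks <- key_tokens(norm_key(raw_name))
  if (length(toks) > 1L) {
    for (k in seq_len(length(toks) - 1L)) {
      tail_toks <- toks[(length(toks) - k + 1L):length(toks)]
      if (!all(tail_toks %in% modifiers)) break
      stem <- paste(toks[seq_len(length(toks) - k)], collapse = " ")
      hit <- classify_hits(lookup_term(dict, stem))
      if (!is.null(hit)) return(hit)
    }
  }

  # BROADER direction: a dictionary term = raw name + trailing modifier(s)
  raw_key <- paste(toks, collapse = " ")
  cand <- dict$terms[startsWith(dict$terms$key, paste0(raw_key, " ")), , drop = FALSE]
  if (nrow(cand)) {
    ok <- vapply(cand$key, function(k) {
      extra <- key_tokens(substring(k, nchar(raw_key) + 2L))
      length(extra) > 0L && all(extra %in% modifiers)
    }, logical(1))
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand)) {
      hits <- dplyr::inner_join(dplyr::rename(cand, matched_term = "term"),
                                dict$entries, by = "concept_id")
      hit <- classify_hits(hits)
      if (!is.null(hit)) return(hit)
    }
  }
  none
}

#' Normalize one raw drug/chemical name across ranked dictionaries
#'
#' Queries every dictionary, keeping each authority's best match under the
#' precedence PT_EXACT > SYNONYM > QUASI_SYNONYM > NARROWER > BROADER. The
#' CAS-style registry number is taken from the highest-ranked authority that
#' supplies one; the CUI comes from the designated metathesaurus-style
#' dictionary; the preferred PT is resolved across authorities with
#' [rank_resolve()].
#'
#' @param raw_name Raw drug/chemical name.
#' @param dicts List of `concept_dictionary` objects (at least one).
#' @param ranking Authority ranking from [authority_ranking()]; defaults to
#'   the dictionaries' own ranks.
#' @param salt_lexicon,quasi_lexicon Modifier lexicons; see
#'   [default_salt_lexicon()].
#' @param umls_authority Name of the dictionary whose concept identifiers are
#'   CUI-style; `NULL` if none.
#' @return A list of class `drug_normalization` with fields `raw_name`,
#'   `per_authority` (tibble, one row per dictionary), `cas_number`,
#'   `cas_authority`, `cas_match_type`, `cui`, `cui_match_type`,
#'   `preferred_pt`, `pt_authority`.
#' @export
normalize_drug <- function(raw_name, dicts, ranking = NULL,
                           salt_lexicon = default_salt_lexicon(),
                           quasi_lexicon = default_quasi_lexicon(),
                           umls_authority = "UMLS") {
  if (!length(dicts)) stop_input("at least one dictionary is required")
  if (is.null(ranking)) {
    ranking <- tibble::tibble(
      name = vapply(dicts, function(d) d$authority$name, character(1)),
      rank = vapply(dicts, function(d) d$authority$rank, integer(1))
    )
  }
  per <- dplyr::bind_rows(lapply(dicts, match_in_dictionary, raw_name = raw_name,
                                 salt_lexicon = salt_lexicon,
                                 quasi_lexicon = quasi_lexicon))

  mapped <- per[per$match_type != "UNMAPPED", , drop = FALSE]

  cas_number <- NA_character_
  cas_authority <- NA_character_
  cas_match_type <- NA_character_
  with_cas <- mapped[!is.na(mapped$cas_number), , drop = FALSE]
  if (nrow(with_cas)) {
    with_cas <- dplyr::left_join(with_cas, ranking, by = c(authority = "name"))
    with_cas <- with_cas[order(with_cas$rank, with_cas$concept_id), , drop = FALSE]
    cas_number <- with_cas$cas_number[[1]]
    cas_authority <- with_cas$authority[[1]]
    cas_match_type <- with_cas$match_type[[1]]
  }

  cui <- NA_character_
  cui_match_type <- NA_character_
  if (!is.null(umls_authority)) {
    urow <- mapped[mapped$authority == umls_authority, , drop = FALSE]
    if (nrow(urow)) {
      cui <- urow$concept_id[[1]]
      cui_match_type <- urow$match_type[[1]]
    }
  }

  preferred_pt <- NA_character_
  pt_authority <- NA_character_
  if (nrow(mapped)) {
    res <- rank_resolve(
      mapped[c("authority", "concept_id", "preferred_term")], ranking
    )
    preferred_pt <- res$preferred_term
    pt_authority <- res$authority
  }

  structure(
    list(
      raw_name = raw_name, per_authority = per,
      cas_number = cas_number, cas_authority = cas_authority,
      cas_match_type = cas_match_type,
      cui = cui, cui_match_type = cui_match_type,
      preferred_pt = preferred_pt, pt_authority = pt_authority
    ),
    class = "drug_normalization"
  )
}

#' @export
print.drug_normalization <- function(x, ...) {
  cat(sprintf("<drug_normalization> %s\n", x$raw_name))
  cat(sprintf("  CAS: %s (%s, %s)  CUI: %s  preferred PT: %s\n",
              x$cas_number %||% NA, x$cas_authority %||% NA,
              x$cas_match_type %||% NA, x$cui %||% NA, x$preferred_pt %||% NA))
  invisible(x)
}

pack_authority_matches <- function(per) {
  per <- per[per$match_type != "UNMAPPED", , drop = FALSE]
  if (!nrow(per)) return(NA_character_)
  paste(sprintf("%s=%s:%s", per$authority, per$concept_id, per$match_type),
        collapse = ";")
}

#' Normalize a vector of raw drug names to a flat table
#'
#' Vectorized driver over [normalize_drug()]: one output row per unique raw
#' name, with the per-authority matches packed into a single
#' `authority_matches` column (`authority=concept:MATCH_TYPE;...`).
#'
#' @param raw_names Character vector (duplicates are collapsed).
#' @inheritParams normalize_drug
#' @return A tibble with columns `raw_name`, `cas_number`, `cas_authority`,
#'   `cas_match_type`, `cui`, `cui_match_type`, `preferred_pt`,
#'   `pt_authority`, `authority_matches`.
#' @export
normalize_drugs <- function(raw_names, dicts, ranking = NULL,
                            salt_lexicon = default_salt_lexicon(),
                            quasi_lexicon = default_quasi_lexicon(),
                            umls_authority = "UMLS") {
  raw_names <- unique(raw_names)
  rows <- lapply(raw_names, function(nm) {
    dn <- normalize_drug(nm, dicts, ranking, salt_lexicon, quasi_lexicon,
                         umls_authority)
    tibble::tibble(
      raw_name = dn$raw_name, cas_number = dn$cas_number,
      cas_authority = dn$cas_authority, cas_match_type = dn$cas_match_type,
      cui = dn$cui, cui_match_type = dn$cui_match_type,
      preferred_pt = dn$preferred_pt, pt_authority = dn$pt_authority,
      authority_matches = pack_authority_matches(dn$per_authority)
    )
  })
  dplyr::bind_rows(rows)
}
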