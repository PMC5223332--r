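#' Terminological reduction
#'
#' TR = (N + X) / U, where N is the number of unique normalized identifiers
#' among the mapped names, X the number of unique raw names left
#' unnormalized, and U the number of unique original raw names. TR = 1 means
#' normalization merged nothing; lower values indicate stronger unification.
#'
#' @param raw_names Character vector of raw names (duplicates collapsed).
#' @param mapping Named character vector (or list) mapping each raw name to
#'   its normalized identifier, with `NA` for names that remain
#'   unnormalized. Must be defined for every raw name.
#' @return A list of class `tr_result` with fields `n_normalized` (N),
#'   `n_unnormalized` (X), `n_unique_raw` (U), and `tr`.
#' @examples
#' tr(c("a", "b", "c", "d"), c(a = "c1", b = "c1", c = "c1", d = "c1"))
#' @export
tr <- function(raw_names, mapping) {
  raw_names <- unique(raw_names)
  if (!length(raw_names)) stop_input("raw_names must be nonempty")
  mapping <- unlist(mapping)
  if (!all(raw_names %in% names(mapping))) {
    stop_input("mapping must be defined (possibly NA) for every raw name")
  }
  ids <- mapping[raw_names]
  u <- length(raw_names)
  x <- sum(is.na(ids))
  n <- length(unique(ids[!is.na(ids)]))
  structure(
    list(n_normalized = n, n_unnormalized = x, n_unique_raw = u,
         tr = (n + x) / u),
    class = "tr_result"
  )
}

#' @export
print.tr_result <- function(x, ...) {
  cat(sprintf("<tr_result> N=%d X=%d U=%d TR=%.4f\n",
              x$n_normalized, x$n_unnormalized, x$n_unique_raw, x$tr))
  invisible(x)
}

# normalized identity spaces used throughout the metrics:
#   drug: CAS number, else CUI, else the raw name itself (unnormalized)
#   indication: final CUI, else the raw target itself
drug_norm_id <- function(rows, id = c("either", "cas", "cui")) {
  id <- match.arg(id)
  switch(id,
    cas = rows$cas_number,
    cui = rows$drug_cui,
    either = dplyr::coalesce(rows$cas_number, rows$drug_cui)
  )
}

entity_ids <- function(rows, entity = c("drug", "indication", "pair"),
                       stage = c("raw", "normalized")) {
  entity <- match.arg(entity)
  stage <- match.arg(stage)
  drug <- if (stage == "raw") rows$raw_drug_name else
    dplyr::coalesce(drug_norm_id(rows), rows$raw_drug_name)
  ind <- if (stage == "raw") rows$target else
    dplyr::coalesce(rows$ind_cui, rows$target)
  switch(entity,
    drug = drug,
    indication = ind,
    pair = paste(drug, ind, sep = "\r")
  )
}

entity_incidence <- function(rows, entity, stage) {
  dplyr::distinct(tibble::tibble(
    source_id = rows$source_id,
    id = entity_ids(rows, entity, stage)
  ))
}

#' Terminological reduction computed from a DID table
#'
#' @param rows A `did_table`.
#' @param entity `"drug"` or `"indication"`.
#' @param id For drugs, which identifier counts as "normalized": a CAS
#'   number (`"cas"`), a CUI (`"cui"`), or either (`"either"`, default).
#' @return A `tr_result`; see [tr()].
#' @export
did_tr <- function(rows, entity = c("drug", "indication"),
                   id = c("either", "cas", "cui")) {
  entity <- match.arg(entity)
  id <- match.arg(id)
  if (entity == "drug") {
    tab <- dplyr::distinct(tibble::tibble(raw = rows$raw_drug_name,
                                          norm = drug_norm_id(rows, id)))
  } else {
    tab <- dplyr::distinct(tibble::tibble(raw = rows$target,
                                          norm = rows$ind_cui))
  }
  # a raw name maps to at most one normalized id by construction; guard anyway
  tab <- tab[!duplicated(tab$raw), , drop = FALSE]
  tr(tab$raw, stats::setNames(tab$norm, tab$raw))
}

#' Per-source coverage of unique normalized entities
#'
#' For each source, the number of unique normalized drugs, indications, and
#' drug-indication pairs it contributes, with percentages relative to the
#' global unique totals (columns need not sum to 100: shared entities count
#' for every source carrying them).
#'
#' @param rows A nonempty `did_table`.
#' @param stage `"normalized"` (default) or `"raw"`.
#' @return A tibble with one row per source: `source_id`, `n_drug`,
#'   `pct_drug`, `n_indication`, `pct_indication`, `n_pair`, `pct_pair`;
#'   attribute `totals` holds the global unique counts.
#' @export
coverage <- function(rows, stage = c("normalized", "raw")) {
  stage <- match.arg(stage)
  if (!nrow(rows)) stop_input("coverage needs a nonempty table")
  out <- NULL
  totals <- integer()
  for (entity in c("drug", "indication", "pair")) {
    inc <- entity_incidence(rows, entity, stage)
    tot <- dplyr::n_distinct(inc$id)
    per <- inc %>%
      dplyr::count(.data$source_id, name = "n") %>%
      dplyr::mutate(pct = 100 * .data$n / tot)
    names(per)[2:3] <- paste0(c("n_", "pct_"), entity)
    out <- if (is.null(out)) per else dplyr::full_join(out, per, by = "source_id")
    totals[[entity]] <- tot
  }
  out <- out[order(out$source_id), , drop = FALSE]
  attr(out, "totals") <- totals
  out
}

#' Source overlap scores
#'
#' For each source, the mean over its unique entities of the number of
#' distinct sources containing that entity (the source itself always counts,
#' so every score is at least 1 and at most the number of sources). The
#' pooled `"All"` row is the mean over the union of unique entities, each
#' counted once.
#'
#' @param rows A `did_table` with at least one source.
#' @param entity `"drug"`, `"indication"`, or `"pair"`.
#' @param stage `"raw"` or `"normalized"`.
#' @return Tibble with columns `source_id` (per-source rows then `"All"`)
#'   and `score`.
#' @export
overlap <- function(rows, entity = c("drug", "indication", "pair"),
                    stage = c("raw", "normalized")) {
  entity <- match.arg(entity)
  stage <- match.arg(stage)
  if (!nrow(rows)) stop_input("overlap needs a nonempty table")
  inc <- entity_incidence(rows, entity, stage)
  sharing <- inc %>% dplyr::count(.data$id, name = "n_sources")
  per <- inc %>%
    dplyr::inner_join(sharing, by = "id") %>%
    dplyr::group_by(.data$source_id) %>%
    dplyr::summarise(score = mean(.data$n_sources), .groups = "drop") %>%
    dplyr::arrange(.data$source_id)
  dplyr::bind_rows(per, tibble::tibble(source_id = "All",
                                       score = mean(sharing$n_sources)))
}

#' All overlap scores of a table, wide
#'
#' Convenience wrapper running [overlap()] for every entity at one stage.
#'
#' @inheritParams overlap
#' @return Tibble with columns `source_id`, `drug`, `indication`, `pair`.
#' @export
overlap_stats <- function(rows, stage = c("raw", "normalized")) {
  stage <- match.arg(stage)
  out <- NULL
  for (entity in c("drug", "indication", "pair")) {
    sc <- overlap(rows, entity, stage)
    names(sc)[2] <- entity
    out <- if (is.null(out)) sc else dplyr::full_join(out, sc, by = "source_id")
  }
  out
}

#' Overlap change scores
#'
#' Element-wise difference `normalized - raw` between two overlap score
#' tables covering identical sources (e.g. a raw score of 1.00 and a
#' normalized score of 2.21 give a change of 1.21).
#'
#' @param raw_stats,normalized_stats Tibbles with a `source_id` column and
#'   identical numeric score columns, as returned by [overlap()] or
#'   [overlap_stats()].
#' @return A tibble of the same shape holding the differences.
#' @export
overlap_change <- function(raw_stats, normalized_stats) {
  if (!setequal(raw_stats$source_id, normalized_stats$source_id) ||
      !identical(sort(names(raw_stats)), sort(names(normalized_stats)))) {
    stop_consistency("overlap tables must cover identical sources and columns")
  }
  normalized_stats <- normalized_stats[
    match(raw_stats$source_id, normalized_stats$source_id),
    names(raw_stats), drop = FALSE
  ]
  out <- raw_stats
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- normalized_stats[num] - raw_stats[num]
  out
}

#' Zipf distribution of entity sharing counts
#'
#' Histogram over unique entities of the number of sources sharing each:
#' bin k holds the number of unique entities contributed by exactly k
#' sources. The counts sum to the number of unique entities at that stage.
#'
#' @inheritParams overlap
#' @return Tibble with columns `k` (1..number of sources) and `count`.
#' @export
zipf <- function(rows, entity = c("drug", "indication", "pair"),
                 stage = c("raw", "normalized")) {
  entity <- match.arg(entity)
  stage <- match.arg(stage)
  if (!nrow(rows)) stop_input("zipf needs a nonempty table")
  inc <- entity_incidence(rows, entity, stage)
  s <- dplyr::n_distinct(inc$id)
  n_src <- dplyr::n_distinct(inc$source_id)
  sharing <- inc %>% dplyr::count(.data$id, name = "n_sources")
  hist <- sharing %>% dplyr::count(.data$n_sources, name = "count")
  out <- tibble::tibble(k = seq_len(n_src)) %>%
    dplyr::left_join(hist, by = c(k = "n_sources")) %>%
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  stopifnot(sum(out$count) == s)
  out
}

#' Richness: indications per drug and drugs per indication
#'
#' Per source, the mean number of unique indications paired with each of its
#' unique drugs, and the mean number of unique drugs paired with each of its
#' unique indications, in the chosen identity space.
#'
#' @inheritParams overlap
#' @return Tibble with columns `source_id`, `indications_per_drug`,
#'   `drugs_per_indication`.
#' @export
richness <- function(rows, stage = c("raw", "normalized")) {
  stage <- match.arg(stage)
  if (!nrow(rows)) stop_input("richness needs a nonempty table")
  tab <- dplyr::distinct(tibble::tibble(
    source_id = rows$source_id,
    drug = entity_ids(rows, "drug", stage),
    ind = entity_ids(rows, "indication", stage)
  ))
  tab %>%
    dplyr::group_by(.data$source_id) %>%
    dplyr::summarise(
      indications_per_drug = dplyr::n() / dplyr::n_distinct(.data$drug),
      drugs_per_indication = dplyr::n() / dplyr::n_distinct(.data$ind),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$source_id)
}
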