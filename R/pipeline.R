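#' Compute the full metrics bundle of a DID table
#'
#' Runs every integration metric on an assembled table and returns them in
#' the same structure as [expected_metrics()], so pipeline output and
#' ground-truth oracle can be compared element by element.
#'
#' @param rows A nonempty `did_table`.
#' @return A list with `tr_drug`, `tr_indication`, `overlap_raw`,
#'   `overlap_normalized`, `overlap_change`, `coverage`, `zipf` (per entity
#'   and stage), `richness_raw`, `richness_normalized`.
#' @export
did_metrics <- function(rows) {
  oraw <- overlap_stats(rows, "raw")
  onorm <- overlap_stats(rows, "normalized")
  zipf_out <- list()
  for (entity in c("drug", "indication", "pair")) {
    for (stage in c("raw", "normalized")) {
      zipf_out[[paste(entity, stage, sep = "_")]] <- zipf(rows, entity, stage)
    }
  }
  cov <- coverage(rows, "normalized")
  attr(cov, "totals") <- NULL
  list(
    tr_drug = unclass(did_tr(rows, "drug", "either")),
    tr_indication = unclass(did_tr(rows, "indication")),
    overlap_raw = oraw,
    overlap_normalized = onorm,
    overlap_change = overlap_change(oraw, onorm),
    coverage = cov,
    zipf = zipf_out,
    richness_raw = richness(rows, "raw"),
    richness_normalized = richness(rows, "normalized")
  )
}

#' Run the full DID construction pipeline from a directory of files
#'
#' Expects the canonical file layout written by [emit_sources()]: the ranked
#' drug dictionaries (`dict_drug_chemid.tsv` rank 1 and `dict_drug_umls.tsv`
#' rank 2), the typed indication dictionary, remap table, semantic scheme,
#' and up to three raw source files (pair, hierarchy, free-text layouts).
#' Ingests each present source with its adapter, normalizes drugs across the
#' ranked dictionaries and indications with phenotypic remapping, tags
#' subtypes, assembles the deduplicated flat table, and computes the metrics
#' bundle.
#'
#' @param dir Directory holding the files.
#' @return A list with elements `did` (the `did_table`), `reports` (one
#'   `filter_report` per ingested source style), `drug_norms`,
#'   `indication_maps`, and `metrics` (see [did_metrics()]).
#' @export
run_pipeline <- function(dir) {
  p <- function(f) file.path(dir, f)
  chemid <- load_dictionary(p("dict_drug_chemid.tsv"), authority("ChemIDplus", 1L))
  umls <- load_dictionary(p("dict_drug_umls.tsv"), authority("UMLS", 2L))
  ind_dict <- load_dictionary(p("dict_indications.tsv"), authority("UMLS_IND", 1L))
  scheme <- load_semantic_scheme(p("scheme.tsv"))
  remap <- load_remap_table(p("remap.tsv"))
  validate_remap(remap, ind_dict, scheme)

  pairs <- list()
  reports <- list()
  if (file.exists(p("source_pair.tsv"))) {
    res <- ingest_pair_source(read_pair_source(p("source_pair.tsv")))
    pairs$pair <- res$pairs
    reports$pair <- res$report
  }
  if (file.exists(p("source_hierarchy.tsv"))) {
    res <- ingest_hierarchy_source(read_hierarchy_source(p("source_hierarchy.tsv")))
    pairs$hierarchy <- res$pairs
    reports$hierarchy <- res$report
  }
  if (file.exists(p("source_freetext.tsv"))) {
    res <- ingest_freetext_source(read_freetext_source(p("source_freetext.tsv")),
                                  indication_dict = ind_dict)
    pairs$freetext <- res$pairs
    reports$freetext <- res$report
  }
  all_pairs <- dplyr::bind_rows(pairs)
  if (!nrow(all_pairs)) stop_input(sprintf("no source records found under %s", dir))

  drug_norms <- normalize_drugs(all_pairs$raw_drug_name,
                                dicts = list(chemid, umls),
                                umls_authority = "UMLS")
  ind_maps <- normalize_indications(unique(all_pairs$target), ind_dict,
                                    scheme, remap)
  subs <- subtype_table(all_pairs$entire_value)
  did <- assemble_did(all_pairs, drug_norms, ind_maps, subs)
  validate_did(did)

  list(did = did, reports = reports, drug_norms = drug_norms,
       indication_maps = ind_maps, metrics = did_metrics(did))
}
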