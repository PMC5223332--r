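# Shared in-code fixtures: a tiny CAS-style registry, a rival dictionary
# disagreeing on the preferred term, a metathesaurus-style drug dictionary
# with a broad class, and a typed indication dictionary with a remap pair.

chemid_fixture <- function() {
  dictionary_from_rows(
    tibble::tribble(
      ~concept_id, ~term,            ~status, ~cas_number, ~semantic_types,
      "103-90-2",  "Acetaminophen",  "P",     "103-90-2",  "T109",
      "103-90-2",  "paracetamol",    "S",     "103-90-2",  "T109",
      "50-78-2",   "Aspirin",        "P",     "50-78-2",   "T109",
      "67346-49-0", "Arformoterol",  "P",     "67346-49-0", "T109",
      "113852-37-2", "Cidofovir",    "P",     "113852-37-2", "T109"
    ),
    authority("ChemIDplus", 1L)
  )
}

chebi_fixture <- function() {
  dictionary_from_rows(
    tibble::tribble(
      ~concept_id,   ~term,          ~status, ~cas_number, ~semantic_types,
      "CHEBI:46195", "paracetamol",  "P",     "103-90-2",  "T109",
      "CHEBI:15365", "acetylsalicylic acid", "P", "50-78-2", "T109",
      "CHEBI:15365", "aspirin",      "S",     "50-78-2",   "T109"
    ),
    authority("ChEBI", 2L)
  )
}

umls_drug_fixture <- function() {
  dictionary_from_rows(
    tibble::tribble(
      ~concept_id, ~term,           ~status, ~cas_number, ~semantic_types,
      "C0000970",  "Acetaminophen", "P",     NA,          "T121",
      "C0000970",  "paracetamol",   "S",     NA,          "T121",
      "C0003204",  "Antiseptics",   "P",     NA,          "T121"
    ),
    authority("UMLS", 3L)
  )
}

indication_fixture <- function() {
  dictionary_from_rows(
    tibble::tribble(
      ~concept_id, ~term,                   ~status, ~cas_number, ~semantic_types,
      "C0279516",  "Anti-Bacterial Agents", "P",     NA,          "T195",
      "C0279516",  "antibacterial agent",   "S",     NA,          "T195",
      "C0004623",  "Bacterial Infections",  "P",     NA,          "T047",
      "C2266959",  "Cephalosporins",        "P",     NA,          "T195",
      "C0020538",  "Hypertensive Disease",  "P",     NA,          "T047",
      "C0020538",  "hypertension",          "S",     NA,          "T047",
      "C0002962",  "Angina Pectoris",       "P",     NA,          "T047",
      "C0002962",  "angina",                "S",     NA,          "T047",
      "C0027497",  "Nausea",                "P",     NA,          "T184",
      "C0042963",  "Vomiting",              "P",     NA,          "T184",
      "C0030193",  "Pain",                  "P",     NA,          "T047"
    ),
    authority("UMLS_IND", 1L)
  )
}

remap_fixture <- function() {
  remap_from_rows(tibble::tibble(
    from_concept_id = "C0279516", to_concept_id = "C0004623"
  ))
}

write_dict_tsv <- function(rows, path = withr::local_tempfile(fileext = ".tsv",
                                                              .local_envir = parent.frame())) {
  readr::write_tsv(rows, path, progress = FALSE, na = "")
  path
}

# random printable strings, salted with the characters that stress the DID
# TSV dialect (tabs, newlines, backslashes, quotes)
random_nasty_string <- function(min_len = 1L, max_len = 12L) {
  pool <- c(letters, LETTERS, 0:9, " ", "\t", "\n", "\\", "\"", "'", ",",
            ";", "(", ")", "-")
  n <- sample(min_len:max_len, 1)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

random_did_rows <- function(n) {
  mk <- function() random_nasty_string()
  chr_with_na <- function(p) {
    v <- as.character(replicate(n, mk()))
    v[stats::runif(n) < p] <- NA_character_
    v
  }
  tibble::tibble(
    source_id = replicate(n, mk()),
    raw_drug_name = replicate(n, mk()),
    cas_number = chr_with_na(0.3),
    cas_authority = rep("ChemIDplus", n),
    cas_match_type = sample(match_types(), n, replace = TRUE),
    drug_preferred_pt = replicate(n, mk()),
    authority_matches = replicate(n, mk()),
    drug_cui = sprintf("C%06d", sample.int(1e6, n)),
    drug_cui_match_type = sample(match_types(), n, replace = TRUE),
    subtype_leaf = replicate(n, mk()),
    subtype_root = replicate(n, mk()),
    subtype_polarity = sample(c("NEGATIVE", "POSITIVE", "UNKNOWN"), n, TRUE),
    entire_value = replicate(n, mk()),
    target = sprintf("t%03d %s", seq_len(n), replicate(n, mk())),
    target_equals_entire = sample(c(TRUE, FALSE), n, TRUE),
    ind_match_quality = sample(match_types(), n, replace = TRUE),
    ind_entry_term = replicate(n, mk()),
    ind_preferred_term = replicate(n, mk()),
    ind_cui = sprintf("C%06d", sample.int(1e6, n)),
    ind_entry_status = sample(c("P", "S"), n, TRUE),
    ind_semantic_types = sample(c("T047", "T121;T195", NA), n, TRUE),
    ind_phenotypic = sample(c(TRUE, FALSE), n, TRUE),
    remap_outcome = sample(c("ALREADY_PHENOTYPIC", "REMAPPED", "STUCK"), n, TRUE),
    compound_index = ifelse(stats::runif(n) < 0.2, sample.int(3, n, TRUE),
                            NA_integer_),
    init_entry_term = chr_with_na(0.5),
    init_preferred_term = NA_character_,
    init_cui = chr_with_na(0.5),
    init_semantic_types = NA_character_
  )
}
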