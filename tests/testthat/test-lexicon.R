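test_that("load_dictionary builds a term index and reports malformed input", {
  path <- write_dict_tsv(tibble::tibble(
    concept_id = c("103-90-2", "103-90-2"),
    term = c("Acetaminophen", "paracetamol"),
    status = c("P", "S"),
    cas_number = c("103-90-2", "103-90-2"),
    semantic_types = c("T109", "T109")
  ))
  d <- load_dictionary(path, authority("ChemIDplus", 1L))
  expect_equal(nrow(d$entries), 1L)
  expect_equal(nrow(d$terms), 2L)
  expect_equal(d$entries$preferred_term, "Acetaminophen")

  # header-only file -> empty dictionary
  empty_path <- write_dict_tsv(tibble::tibble(
    concept_id = character(), term = character(), status = character()
  ))
  expect_equal(nrow(load_dictionary(empty_path, "X")$entries), 0L)

  # conflicting redefinition of a concept (two P rows) names the ID
  bad <- write_dict_tsv(tibble::tibble(
    concept_id = c("1-1-1", "1-1-1"), term = c("foo", "bar"),
    status = c("P", "P")
  ))
  expect_error(load_dictionary(bad, "X"), "1-1-1",
               class = "didkit_validation_error")

  # duplicated (concept, term) row
  dup <- write_dict_tsv(tibble::tibble(
    concept_id = c("1-1-1", "1-1-1"), term = c("foo", "foo"),
    status = c("P", "S")
  ))
  expect_error(load_dictionary(dup, "X"), class = "didkit_validation_error")

  # unknown status code, with line number
  odd <- write_dict_tsv(tibble::tibble(
    concept_id = "1-1-1", term = "foo", status = "Q"
  ))
  expect_error(load_dictionary(odd, "X"), "line",
               class = "didkit_validation_error")

  expect_error(load_dictionary(tempfile(), "X"), class = "didkit_input_error")
})

test_that("lookup is exact, case-insensitive, and whitespace-tolerant", {
  d <- chemid_fixture()
  hit <- lookup_term(d, "PARACETAMOL")
  expect_equal(hit$concept_id, "103-90-2")
  expect_equal(hit$status, "S")

  hit_p <- lookup_term(d, "acetaminophen")
  expect_equal(hit_p$status, "P")

  expect_equal(nrow(lookup_term(d, "zzz-nonexistent")), 0L)
  expect_error(lookup_term(d, "   "), class = "didkit_input_error")

  # invariance of the result under case and surrounding whitespace
  for (q in c("Aspirin", "  aspirin ", "ASPIRIN", "aSpIrIn")) {
    expect_equal(lookup_term(d, q)$concept_id, "50-78-2")
  }
})

test_that("every dictionary indexes at least one term per entry", {
  dicts <- list(chemid_fixture(), chebi_fixture(), umls_drug_fixture(),
                indication_fixture())
  for (d in dicts) {
    expect_gte(nrow(d$terms), nrow(d$entries))
    # the index covers every preferred term
    expect_true(all(norm_key(d$entries$preferred_term) %in% d$terms$key))
  }
})

test_that("rank_resolve picks the highest-ranked authority deterministically", {
  rk <- authority_ranking(c("ChemIDplus", "ChEBI", "DrugBank", "eVOC", "CTD"))
  cands <- tibble::tibble(
    authority = c("ChEBI", "ChemIDplus"),
    concept_id = c("CHEBI:46195", "103-90-2"),
    preferred_term = c("paracetamol", "acetaminophen")
  )
  res <- rank_resolve(cands, rk)
  expect_equal(res$preferred_term, "acetaminophen")
  expect_equal(res$authority, "ChemIDplus")

  # invariant under permutation of candidate order
  res2 <- rank_resolve(cands[2:1, ], rk)
  expect_equal(res, res2)

  single <- rank_resolve(tibble::tibble(authority = "CTD", concept_id = "c9",
                                        preferred_term = "x"), rk)
  expect_equal(single$preferred_term, "x")
  expect_equal(single$authority, "CTD")

  # equal explicit ranks: smallest concept_id wins
  rk_tie <- authority_ranking(c(A = 1, B = 1))
  tie <- rank_resolve(tibble::tibble(
    authority = c("A", "B"), concept_id = c("zz", "aa"),
    preferred_term = c("from_a", "from_b")
  ), rk_tie)
  expect_equal(tie$preferred_term, "from_b")

  expect_error(
    rank_resolve(tibble::tibble(authority = "Mystery", concept_id = "1",
                                preferred_term = "x"), rk),
    class = "didkit_config_error"
  )
})

test_that("remap tables are idempotent and validated against the dictionary", {
  rm <- remap_fixture()
  # a remap target never remaps further
  expect_false(any(rm$to_concept_id %in% rm$from_concept_id))
  expect_silent(validate_remap(rm, indication_fixture(),
                               default_semantic_scheme()))

  # chained table rejected
  expect_error(
    remap_from_rows(tibble::tibble(from_concept_id = c("a", "b"),
                                   to_concept_id = c("b", "c"))),
    class = "didkit_validation_error"
  )
  # target missing from dictionary
  expect_error(
    validate_remap(
      remap_from_rows(tibble::tibble(from_concept_id = "C0279516",
                                     to_concept_id = "C9999999")),
      indication_fixture(), default_semantic_scheme()
    ),
    class = "didkit_config_error"
  )
  # non-phenotypic target
  expect_error(
    validate_remap(
      remap_from_rows(tibble::tibble(from_concept_id = "C0004623",
                                     to_concept_id = "C2266959")),
      indication_fixture(), default_semantic_scheme()
    ),
    class = "didkit_config_error"
  )
})

test_that("semantic scheme partitions types into phenotypic and not", {
  sch <- default_semantic_scheme()
  expect_false(any(duplicated(sch$type_code)))
  expect_true(is_phenotypic(sch, "T047"))
  expect_false(is_phenotypic(sch, "T195"))
  expect_true(is_phenotypic(sch, c("T195", "T047")))
  expect_false(is_phenotypic(sch, character()))

  # roundtrip through the scheme TSV layout
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- tibble::as_tibble(sch)
  out$phenotypic <- as.integer(out$phenotypic)
  readr::write_tsv(out, path, progress = FALSE)
  expect_equal(tibble::as_tibble(load_semantic_scheme(path)),
               tibble::as_tibble(sch))
})
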