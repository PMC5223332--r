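ind_world <- function() {
  list(dict = indication_fixture(), scheme = default_semantic_scheme(),
       remap = remap_fixture())
}

test_that("map_indication prefers phenotypic candidates and records the entry", {
  iw <- ind_world()
  m <- map_indication("antibacterial agent", iw$dict, iw$scheme)
  expect_equal(m$cui, "C0279516")
  expect_false(m$phenotypic)
  expect_equal(m$entry_status, "S")
  expect_equal(m$match_quality, "SYNONYM")
  expect_equal(m$entry_term, "antibacterial agent")

  m2 <- map_indication("bacterial infections", iw$dict, iw$scheme)
  expect_equal(m2$cui, "C0004623")
  expect_true(m2$phenotypic)
  expect_equal(m2$match_quality, "PT_EXACT")
  expect_equal(m2$entry_term, "Bacterial Infections")

  m3 <- map_indication("zq-unknown-condition", iw$dict, iw$scheme)
  expect_equal(m3$match_quality, "UNMAPPED")
  expect_true(is.na(m3$cui))

  # a phenotypic candidate beats a non-phenotypic one on the same key
  tied <- dictionary_from_rows(tibble::tribble(
    ~concept_id, ~term, ~status, ~cas_number, ~semantic_types,
    "C1", "shared term", "P", NA, "T121",
    "C2", "disease form", "P", NA, "T047",
    "C2", "shared term", "S", NA, "T047"
  ), "X")
  expect_equal(map_indication("shared term", tied, iw$scheme)$cui, "C2")
})

test_that("phenotypic remapping unifies class terms and preserves the initial block", {
  iw <- ind_world()
  m <- map_indication("antibacterial agent", iw$dict, iw$scheme)
  res <- remap_phenotype(m, iw$remap, iw$dict, iw$scheme)
  expect_equal(res$outcome, "REMAPPED")
  expect_equal(res$mapping$cui, "C0004623")
  expect_equal(res$mapping$preferred_term, "Bacterial Infections")
  expect_equal(res$mapping$match_quality, "QUASI_SYNONYM")
  expect_equal(res$mapping$initial$cui, "C0279516")
  expect_true(res$mapping$phenotypic)

  stuck <- remap_phenotype(map_indication("cephalosporins", iw$dict, iw$scheme),
                           iw$remap, iw$dict, iw$scheme)
  expect_equal(stuck$outcome, "STUCK")
  expect_equal(stuck$mapping$cui, "C2266959")
  expect_false(stuck$mapping$phenotypic)

  phen <- map_indication("bacterial infections", iw$dict, iw$scheme)
  res2 <- remap_phenotype(phen, iw$remap, iw$dict, iw$scheme)
  expect_equal(res2$outcome, "ALREADY_PHENOTYPIC")
  expect_identical(res2$mapping, phen)

  un <- remap_phenotype(map_indication("nothing here", iw$dict, iw$scheme),
                        iw$remap, iw$dict, iw$scheme)
  expect_equal(un$outcome, "UNMAPPED")

  # remap target missing from dictionary is a configuration error
  bad <- remap_from_rows(tibble::tibble(from_concept_id = "C0279516",
                                        to_concept_id = "C404"))
  expect_error(remap_phenotype(m, bad, iw$dict, iw$scheme),
               class = "didkit_config_error")
})

test_that("remap_phenotype is idempotent for every outcome", {
  iw <- ind_world()
  targets <- c("antibacterial agent", "cephalosporins", "bacterial infections",
               "hypertension", "zq-unknown")
  for (tg in targets) {
    once <- remap_phenotype(map_indication(tg, iw$dict, iw$scheme),
                            iw$remap, iw$dict, iw$scheme)
    twice <- remap_phenotype(once$mapping, iw$remap, iw$dict, iw$scheme)
    expect_identical(twice$mapping, once$mapping, info = tg)
  }
})

test_that("entry-term rendering is a case projection", {
  expect_equal(render_entry_term("bacterial infections", "P"),
               "Bacterial Infections")
  expect_equal(render_entry_term("Hypertensive Disease", "S"),
               "hypertensive disease")
  expect_equal(render_entry_term("pain", "P"), "Pain")
  for (term in c("mIxEd CaSe TeRm", "single", "TWO WORDS")) {
    for (st in c("P", "S")) {
      once <- render_entry_term(term, st)
      expect_identical(render_entry_term(once, st), once)
    }
  }
  expect_error(render_entry_term("x", "Q"), class = "didkit_input_error")
})

test_that("compound mapping covers multi-concept targets with indexed components", {
  iw <- ind_world()
  maps <- compound_map("nausea and vomiting", iw$dict, iw$scheme, iw$remap)
  expect_length(maps, 2L)
  expect_equal(vapply(maps, `[[`, character(1), "cui"),
               c("C0027497", "C0042963"))
  expect_equal(vapply(maps, `[[`, integer(1), "compound_index"), 1:2)

  single <- compound_map("nausea", iw$dict, iw$scheme, iw$remap)
  expect_length(single, 1L)
  expect_true(is.na(single[[1]]$compound_index))

  fallback <- compound_map("entirely unknown words", iw$dict, iw$scheme, iw$remap)
  expect_length(fallback, 1L)
  expect_equal(fallback[[1]]$match_quality, "UNMAPPED")
})

test_that("every mapped final CUI resolves in the dictionary", {
  iw <- ind_world()
  targets <- c("antibacterial agent", "cephalosporins", "bacterial infections",
               "nausea and vomiting", "angina", "made up thing")
  tab <- normalize_indications(targets, iw$dict, iw$scheme, iw$remap)
  mapped <- tab$ind_cui[!is.na(tab$ind_cui)]
  expect_true(all(mapped %in% iw$dict$entries$concept_id))
  # a remap never leaves the table with more non-phenotypic rows
  expect_lte(sum(!tab$ind_phenotypic & tab$ind_match_quality != "UNMAPPED"),
             sum(!is.na(tab$init_cui)) +
               sum(tab$remap_outcome == "STUCK", na.rm = TRUE))
})

test_that("the stuck fraction after remapping matches the generator's plan", {
  for (seed in c(3L, 17L)) {
    w <- build_world(world_spec(seed = seed, nonphenotypic_rate = 0.5,
                                stuck_rate = 0.4))
    targets <- unique(w$truth$records$raw_target)
    tab <- normalize_indications(targets, w$indication_dict, w$scheme, w$remap)
    # oracle: the generator knows which initial concepts have no remap
    truth <- unique(w$truth$records[c("raw_target", "ind_cui_initial",
                                      "ind_cui_final")])
    merged <- dplyr::inner_join(tab, truth, by = c(target = "raw_target"))
    expect_equal(merged$ind_cui, merged$ind_cui_final)
    planned_stuck <- merged$ind_cui_initial == merged$ind_cui_final &
      !merged$ind_phenotypic
    expect_equal(merged$remap_outcome == "STUCK", planned_stuck)
    # final non-phenotypic proportion never exceeds the initial one
    init_nonphen <- sum(!is.na(merged$init_cui)) + sum(planned_stuck)
    expect_lte(sum(!merged$ind_phenotypic), init_nonphen)
  }
})
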