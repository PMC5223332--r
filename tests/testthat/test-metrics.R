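test_that("tr follows its closed forms", {
  all_one <- tr(letters[1:4], stats::setNames(rep("c1", 4), letters[1:4]))
  expect_equal(all_one$tr, 0.25)
  expect_equal(all_one$n_normalized, 1L)
  expect_equal(all_one$n_unnormalized, 0L)

  inj <- tr(letters[1:4], stats::setNames(paste0("c", 1:4), letters[1:4]))
  expect_equal(inj$tr, 1.0)

  half_unmapped <- tr(c("a", "b"), c(a = "c1", b = NA))
  expect_equal(half_unmapped$tr, 1.0)  # X counts toward the numerator

  expect_error(tr(character(), c(a = "c1")), class = "didkit_input_error")
  expect_error(tr(c("a", "b"), c(a = "c1")), class = "didkit_input_error")
})

test_that("tr is scale-free under duplication of raw names", {
  set.seed(99)
  names <- sprintf("n%03d", 1:50)
  mapping <- stats::setNames(
    ifelse(stats::runif(50) < 0.2, NA, sprintf("c%02d", sample.int(20, 50, TRUE))),
    names
  )
  once <- tr(names, mapping)
  doubled <- tr(c(names, names), mapping)
  expect_identical(once, doubled)
})

test_that("coverage counts per-source unique entities against global totals", {
  a <- list(
    pairs = tibble::tibble(
      source_id = c("s1", "s1", "s1"),
      raw_drug_name = c("paracetamol", "paracetamol", "aspirin"),
      entire_value = c("hypertension", "angina", "hypertension"),
      target = c("hypertension", "angina", "hypertension"),
      target_equals_entire = TRUE
    )
  )
  dicts <- list(chemid_fixture(), chebi_fixture(), umls_drug_fixture())
  iw <- list(dict = indication_fixture(), scheme = default_semantic_scheme(),
             remap = remap_fixture())
  did <- assemble_did(a$pairs,
                      normalize_drugs(a$pairs$raw_drug_name, dicts),
                      normalize_indications(a$pairs$target, iw$dict, iw$scheme,
                                            iw$remap))
  cov <- coverage(did)
  expect_equal(nrow(cov), 1L)
  expect_equal(cov$pct_drug, 100)
  expect_equal(cov$pct_indication, 100)
  expect_equal(cov$pct_pair, 100)

  # two sources sharing everything both cover 100%
  two <- did
  two2 <- did
  two2$source_id <- "s2"
  both <- dplyr::bind_rows(two, two2)
  cov2 <- coverage(both)
  expect_equal(cov2$pct_drug, c(100, 100))
  expect_equal(cov2$pct_pair, c(100, 100))
})

test_that("overlap scores are bounded, count self, and match a brute-force recount", {
  # source with fully private entities scores exactly 1.00
  w <- build_world(world_spec(seed = 31L, share_fraction = 0))
  d <- withr::local_tempdir()
  emit_sources(w, d)
  rows <- run_pipeline(d)$did

  for (entity in c("drug", "indication", "pair")) {
    for (stage in c("raw", "normalized")) {
      sc <- overlap(rows, entity, stage)
      expect_true(all(sc$score >= 1))
      expect_true(all(sc$score <= dplyr::n_distinct(rows$source_id)))
    }
  }

  # brute-force recount on a seeded 4-source world
  w4 <- build_world(world_spec(n_sources = 4L, share_fraction = 0.5, seed = 13L))
  d4 <- withr::local_tempdir()
  emit_sources(w4, d4)
  rows4 <- run_pipeline(d4)$did
  for (stage in c("raw", "normalized")) {
    inc <- unique(data.frame(
      s = rows4$source_id,
      id = if (stage == "raw") rows4$raw_drug_name else
        ifelse(is.na(rows4$cas_number),
               ifelse(is.na(rows4$drug_cui), rows4$raw_drug_name, rows4$drug_cui),
               rows4$cas_number)
    ))
    share <- sapply(split(inc$s, inc$id), function(s) length(unique(s)))
    got <- overlap(rows4, "drug", stage)
    for (src in unique(inc$s)) {
      mine <- unique(inc$id[inc$s == src])
      expect_equal(got$score[got$source_id == src],
                   mean(as.numeric(share[mine])))
    }
    expect_equal(got$score[got$source_id == "All"], mean(as.numeric(share)))
  }
})

test_that("overlap change is elementwise and rejects mismatched sources", {
  raw <- tibble::tibble(source_id = c("a", "b", "All"), score = c(1, 2, 1.5))
  norm <- tibble::tibble(source_id = c("b", "a", "All"), score = c(3, 2, 2.5))
  ch <- overlap_change(raw, norm)
  expect_equal(ch$score, c(1, 1, 1))

  expect_equal(overlap_change(raw, raw)$score, c(0, 0, 0))
  expect_error(overlap_change(raw, norm[1:2, ]),
               class = "didkit_consistency_error")
})

test_that("zipf histograms conserve unique-entity totals", {
  w <- build_world(world_spec(n_sources = 3L, seed = 8L))
  d <- withr::local_tempdir()
  emit_sources(w, d)
  rows <- run_pipeline(d)$did
  for (entity in c("drug", "indication", "pair")) {
    for (stage in c("raw", "normalized")) {
      z <- zipf(rows, entity, stage)
      n_unique <- length(unique(
        didkit:::entity_ids(rows, entity, stage)
      ))
      expect_equal(sum(z$count), n_unique)
      expect_equal(nrow(z), dplyr::n_distinct(rows$source_id))
    }
  }

  # tiny worked case: 2 sources, 1 shared and 2 private entities
  toy <- tibble::tibble(
    source_id = c("s1", "s1", "s2", "s2"),
    raw_drug_name = c("shared", "only1", "shared", "only2"),
    cas_number = NA_character_, drug_cui = NA_character_,
    target = "pain", ind_cui = "C1"
  )
  toy_full <- dplyr::bind_cols(
    toy,
    tibble::as_tibble(
      setNames(
        lapply(setdiff(names(didkit:::empty_did()), names(toy)),
               function(x) rep(NA_character_, nrow(toy))),
        setdiff(names(didkit:::empty_did()), names(toy))
      )
    )
  )
  z <- zipf(toy_full, "drug", "raw")
  expect_equal(z$count, c(2L, 1L))
})

test_that("richness averages satisfy the pair-count identity", {
  w <- build_world(world_spec(seed = 21L))
  d <- withr::local_tempdir()
  emit_sources(w, d)
  rows <- run_pipeline(d)$did
  for (stage in c("raw", "normalized")) {
    r <- richness(rows, stage)
    expect_true(all(r$indications_per_drug >= 1))
    expect_true(all(r$drugs_per_indication >= 1))
    for (src in r$source_id) {
      sub <- rows[rows$source_id == src, ]
      pairs <- unique(paste(didkit:::entity_ids(sub, "drug", stage),
                            didkit:::entity_ids(sub, "indication", stage),
                            sep = "\r"))
      drugs <- unique(didkit:::entity_ids(sub, "drug", stage))
      expect_equal(
        r$indications_per_drug[r$source_id == src] * length(drugs),
        length(pairs)
      )
    }
  }

  # worked example: drugs A (3 indications) and B (1) average 2.0
  toy <- tibble::tibble(
    source_id = "s", raw_drug_name = c("A", "A", "A", "B"),
    cas_number = NA_character_, drug_cui = NA_character_,
    target = c("i1", "i2", "i3", "i4"), ind_cui = NA_character_
  )
  toy_full <- dplyr::bind_cols(
    toy,
    tibble::as_tibble(
      setNames(
        lapply(setdiff(names(didkit:::empty_did()), names(toy)),
               function(x) rep(NA_character_, nrow(toy))),
        setdiff(names(didkit:::empty_did()), names(toy))
      )
    )
  )
  r <- richness(toy_full, "raw")
  expect_equal(r$indications_per_drug, 2)
  expect_equal(r$drugs_per_indication, 1)
})
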