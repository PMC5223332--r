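pair_records <- function(...) {
  tibble::tribble(~source_id, ~drug, ~relation, ~indication_term, ...)
}

test_that("pair adapter applies relation allowlist and role blocklist", {
  recs <- pair_records(
    "src", "drugA", "has_role", "metabolite",
    "src", "drugA", "may_treat", "hypertension",
    "src", "drugA", "may_treat", "hypertension",
    "src", "drugB", "related_to", "hypertension"
  )
  res <- ingest_pair_source(recs,
                            relation_allowlist = c("may_treat", "may_prevent",
                                                   "has_role"),
                            role_blocklist = c("metabolite", "prodrug", "epitope"))
  expect_equal(res$report$initial, 4L)
  expect_equal(res$report$per_rule_removed[["role_blocklist"]], 1L)
  expect_equal(res$report$per_rule_removed[["relation_filter"]], 1L)
  expect_equal(res$report$per_rule_removed[["duplicate"]], 1L)
  expect_equal(nrow(res$pairs), 1L)
  expect_true(all(res$pairs$target_equals_entire))
  # single-concept controlled values: parsed = filtered
  expect_equal(res$report$parsed, res$report$filtered)

  emptied <- ingest_pair_source(pair_records())
  expect_equal(nrow(emptied$pairs), 0L)
  expect_equal(emptied$report$initial, 0L)
})

test_that("hierarchy adapter collapses repeated nested terms and drops bad names", {
  recs <- tibble::tribble(
    ~source_id, ~drug, ~level_code, ~level_term,
    "atc", "drugX", "B01", "Antithrombotic Agents",
    "atc", "drugX", "B01A", "Antithrombotic Agents",
    "atc", "drugX", "B01AC", "Platelet aggregation inhibitors",
    "atc", "drugY, combinations", "C01", "Cardiac Therapy",
    "atc", "X123", "C02", "Antihypertensives",
    "atc", "drugZ", "D01", "Antifungals"
  )
  res <- ingest_hierarchy_source(recs)
  expect_equal(res$report$initial, 6L)
  expect_equal(res$report$per_rule_removed[["redundant_level"]], 1L)
  expect_equal(res$report$per_rule_removed[["combination"]], 1L)
  expect_equal(res$report$per_rule_removed[["ill_formed"]], 1L)
  x_pairs <- res$pairs[res$pairs$raw_drug_name == "drugX", ]
  expect_equal(nrow(x_pairs), 2L)
  expect_setequal(x_pairs$target, c("Antithrombotic Agents",
                                    "Platelet aggregation inhibitors"))
  # single-level record with a unique term contributes exactly one pair
  expect_equal(sum(res$pairs$raw_drug_name == "drugZ"), 1L)

  expect_error(
    ingest_hierarchy_source(tibble::tibble(source_id = "a", drug = "d",
                                           level_code = "B01", level_term = "")),
    class = "didkit_input_error"
  )
})

freetext_records <- function(texts, drugs = sprintf("drug%02d", seq_along(texts)),
                             trade = toupper(drugs)) {
  tibble::tibble(
    source_id = "dm", generic_name = drugs, trade_name = trade,
    dosage = "10 mg", supplier = "acme", indications_text = texts
  )
}

test_that("free-text adapter enforces the tractability boundary exactly", {
  t539 <- strrep("a", 539)
  t540 <- strrep("a", 540)
  res <- ingest_freetext_source(freetext_records(c(t539, t540)))
  expect_equal(res$report$per_rule_removed[["overlong"]], 1L)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(nchar(res$pairs$entire_value), 539L)

  # length measured after newline-to-space conversion
  with_newlines <- paste(strrep("a", 269), strrep("b", 270), sep = "\n")
  expect_equal(
    ingest_freetext_source(freetext_records(with_newlines))$report$per_rule_removed[["overlong"]],
    1L
  )
  expect_error(ingest_freetext_source(freetext_records("x"), max_len = -1),
               class = "didkit_config_error")
})

test_that("free-text adapter collapses label variants and combination products", {
  recs <- dplyr::bind_rows(
    freetext_records("For use in hypertension.", drugs = "drugA", trade = "BRAND1"),
    freetext_records("For use in hypertension.", drugs = "drugA", trade = "BRAND2"),
    freetext_records("For pain.", drugs = "drugA and drugB")
  )
  res <- ingest_freetext_source(recs)
  expect_equal(res$report$per_rule_removed[["redundant_variant"]], 1L)
  expect_equal(res$report$per_rule_removed[["combination"]], 1L)
  expect_equal(nrow(res$pairs), 1L)
})

test_that("split_targets performs greedy leftmost-longest extraction", {
  dict <- indication_fixture()
  got <- split_targets("treatment of hypertension and angina", dict)
  expect_equal(got$target, c("hypertension", "angina"))
  expect_false(any(got$target_equals_entire))

  whole <- split_targets("hypertension", dict)
  expect_equal(whole$target, "hypertension")
  expect_true(whole$target_equals_entire)

  none <- split_targets("for oral use only", dict)
  expect_equal(none$target, "for oral use only")
  expect_true(none$target_equals_entire)

  # multi-word term wins over nothing; matches are in text order and
  # non-overlapping
  got2 <- split_targets("anti-bacterial agents; then hypertension.", dict)
  expect_equal(got2$target, c("anti-bacterial agents", "hypertension"))
})

test_that("split_targets agrees with a brute-force all-substrings matcher", {
  dict <- indication_fixture()
  keys <- unique(dict$terms$key)
  brute <- function(value) {
    # enumerate every word n-gram per sentence, then replay the greedy
    # leftmost-longest selection over the match set
    out <- character()
    for (sent in strsplit(value, "[.;]")[[1]]) {
      words <- strsplit(gsub("\\s+", " ", trimws(sent)), " ")[[1]]
      words <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", words)
      words <- words[nzchar(words)]
      n <- length(words)
      if (!n) next
      cand <- list()
      for (i in seq_len(n)) for (j in i:n) {
        phrase <- paste(words[i:j], collapse = " ")
        if (norm_key(phrase) %in% keys) cand[[length(cand) + 1L]] <- c(i, j)
      }
      i <- 1L
      while (i <= n) {
        here <- Filter(function(ij) ij[1] == i, cand)
        if (length(here)) {
          best <- here[[which.max(vapply(here, function(ij) ij[2], numeric(1)))]]
          out <- c(out, paste(words[best[1]:best[2]], collapse = " "))
          i <- best[2] + 1L
        } else {
          i <- i + 1L
        }
      }
    }
    unique(out)
  }

  values <- c(
    "treatment of hypertension and angina",
    "bacterial infections. nausea and vomiting",
    "angina pectoris with nausea; hypertensive disease",
    "anti-bacterial agents for bacterial infections",
    "no match here at all",
    "Pain"
  )
  for (v in values) {
    got <- split_targets(v, dict)
    expected <- brute(v)
    if (!length(expected)) expected <- v
    expect_equal(got$target, expected, info = v)
  }
})

test_that("adapters are deterministic and satisfy filter accounting", {
  set.seed(42)
  w <- build_world(world_spec(seed = 11L))
  for (nm in c("pair", "hierarchy", "freetext")) {
    recs <- w$sources[[nm]]
    res1 <- switch(nm,
      pair = ingest_pair_source(recs),
      hierarchy = ingest_hierarchy_source(recs),
      freetext = ingest_freetext_source(recs)
    )
    res2 <- switch(nm,
      pair = ingest_pair_source(recs),
      hierarchy = ingest_hierarchy_source(recs),
      freetext = ingest_freetext_source(recs)
    )
    expect_identical(res1$pairs, res2$pairs)
    rep <- res1$report
    expect_lte(rep$filtered, rep$initial)
    expect_equal(sum(rep$per_rule_removed) + rep$filtered, rep$initial)
  }
})
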