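#' Specify a synthetic drug-indication world
#'
#' The generator emulates the statistical structure of a multi-source
#' drug-indication corpus: several sources naming the same underlying drugs
#' via preferred terms, synonyms, salt/hydrate variants and unregistered
#' code names; indications phrased either as disease terms or as
#' therapeutic-class terms that need phenotypic remapping; nested hierarchy
#' levels with deliberately repeated terms; and free-text indication
#' sections of varying length, some exceeding the tractability cutoff.
#' Every emitted raw string carries a ground-truth concept assignment, which
#' makes the world an oracle for every pipeline stage.
#'
#' Defaults restate the corpus conditions the generator emulates:
#' about 30% of indication encodings are initially non-phenotypic
#' (`nonphenotypic_rate`), a tenth of those have no disease-level concept to
#' remap to and stay "stuck" (`stuck_rate`), 37% of free-text records are
#' intractably long (`freetext_overlong_rate`), sources share a minority of
#' their concept pools (`share_fraction`), and a source carries about three
#' indications per drug (`indications_per_drug_mean`).
#'
#' @param n_sources Number of sources (styles cycle pair, hierarchy,
#'   free-text).
#' @param n_drug_concepts,n_indication_concepts Concept pool sizes.
#' @param synonyms_per_concept Synonyms per concept besides the preferred
#'   term.
#' @param salt_variant_rate Probability that a source names a drug by a salt
#'   variant of the preferred term (a NARROWER match by construction).
#' @param unmappable_rate Probability that a source names a drug by an
#'   unregistered code name resolvable in no dictionary.
#' @param nonphenotypic_rate Fraction of indication concepts expressed as
#'   therapeutic-class (non-phenotypic) concepts.
#' @param stuck_rate Fraction of non-phenotypic concepts with no phenotypic
#'   remap target.
#' @param share_fraction Fraction of each concept pool shared by all
#'   sources; the rest is split privately.
#' @param indications_per_drug_mean Mean indications per drug within a
#'   source (1 + Poisson(mean - 1)).
#' @param freetext_overlong_rate Probability that a free-text record's
#'   indications section reaches the 540-character cutoff.
#' @param seed Integer seed; identical spec and seed give an identical
#'   world.
#' @return A validated list of class `world_spec`.
#' @export
world_spec <- function(n_sources = 3L,
                       n_drug_concepts = 40L,
                       n_indication_concepts = 30L,
                       synonyms_per_concept = 2L,
                       salt_variant_rate = 0.15,
                       unmappable_rate = 0.05,
                       nonphenotypic_rate = 0.3,
                       stuck_rate = 0.1,
                       share_fraction = 0.3,
                       indications_per_drug_mean = 3,
                       freetext_overlong_rate = 0.37,
                       seed = 1L) {
  spec <- list(
    n_sources = as.integer(n_sources),
    n_drug_concepts = as.integer(n_drug_concepts),
    n_indication_concepts = as.integer(n_indication_concepts),
    synonyms_per_concept = as.integer(synonyms_per_concept),
    salt_variant_rate = salt_variant_rate,
    unmappable_rate = unmappable_rate,
    nonphenotypic_rate = nonphenotypic_rate,
    stuck_rate = stuck_rate,
    share_fraction = share_fraction,
    indications_per_drug_mean = indications_per_drug_mean,
    freetext_overlong_rate = freetext_overlong_rate,
    seed = as.integer(seed)
  )
  rates <- c("salt_variant_rate", "unmappable_rate", "nonphenotypic_rate",
             "stuck_rate", "share_fraction", "freetext_overlong_rate")
  for (r in rates) {
    v <- spec[[r]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_validation(sprintf("%s must be a single value in [0, 1]", r))
    }
  }
  counts <- c("n_sources", "n_drug_concepts", "n_indication_concepts")
  for (ct in counts) {
    if (is.na(spec[[ct]]) || spec[[ct]] < 1L) {
      stop_validation(sprintf("%s must be a positive integer", ct))
    }
  }
  if (spec$synonyms_per_concept < 0L) {
    stop_validation("synonyms_per_concept must be nonnegative")
  }
  if (spec$indications_per_drug_mean < 1) {
    stop_validation("indications_per_drug_mean must be at least 1")
  }
  if (is.na(spec$seed)) stop_validation("seed must be an integer")
  structure(spec, class = "world_spec")
}

#' @export
print.world_spec <- function(x, ...) {
  cat(sprintf(
    "<world_spec> %d sources, %d drug / %d indication concepts, seed %d\n",
    x$n_sources, x$n_drug_concepts, x$n_indication_concepts, x$seed
  ))
  invisible(x)
}

# Pronounceable syllable grammar; every word is globally unique within a
# world, so no generated term can partially collide with another (greedy
# longest-match extraction is then exact by construction).
make_namer <- function() {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vows <- c("a", "e", "i", "o", "u")
  used <- new.env(parent = emptyenv())
  word <- function() {
    repeat {
      n_syl <- sample(2:4, 1)
      w <- paste0(sample(cons, n_syl, replace = TRUE),
                  sample(vows, n_syl, replace = TRUE), collapse = "")
      if (is.null(used[[w]])) {
        used[[w]] <- TRUE
        return(w)
      }
    }
  }
  function(n_words = 1L) {
    paste(vapply(seq_len(n_words), function(i) word(), character(1)),
          collapse = " ")
  }
}

# sample() without the 1:n surprise on length-1 numeric pools
resample <- function(x, size = 1L, ...) {
  x[sample.int(length(x), size, ...)]
}

source_styles <- function(n_sources) {
  styles <- rep(c("pair", "hierarchy", "freetext"), length.out = n_sources)
  tibble::tibble(
    source_id = sprintf("%s_%02d", styles, seq_len(n_sources)),
    style = styles
  )
}

# split pool indices into a shared block plus per-source private blocks
split_pool <- function(n, n_sources, share_fraction) {
  idx <- sample.int(n)
  n_shared <- round(share_fraction * n)
  shared <- idx[seq_len(n_shared)]
  private <- vector("list", n_sources)
  rest <- if (n_shared < n) idx[(n_shared + 1L):n] else integer()
  for (i in seq_along(rest)) {
    s <- ((i - 1L) %% n_sources) + 1L
    private[[s]] <- c(private[[s]], rest[[i]])
  }
  lapply(seq_len(n_sources), function(s) sort(c(shared, private[[s]])))
}

#' Build a synthetic world with ground truth
#'
#' Generates the concept pools, the ranked drug dictionaries (a CAS-style
#' registry covering every drug concept and a metathesaurus-style dictionary
#' supplying CUIs), the typed indication dictionary, the phenotype remap
#' table and semantic scheme, and a full per-source emission plan (including
#' the noise that the ingest filters must remove). All randomness is drawn
#' here under the spec's seed; [emit_sources()] is deterministic
#' serialization.
#'
#' @param spec A [world_spec()].
#' @return A list of class `did_world` with elements `spec`, `drug_dicts`,
#'   `indication_dict`, `remap`, `scheme`, `sources` (raw record tibbles per
#'   style), and `truth` (clean ground-truth records plus planned noise
#'   counts).
#' @export
build_world <- function(spec) {
  if (!inherits(spec, "world_spec")) spec <- do.call(world_spec, spec)
  set.seed(spec$seed %% .Machine$integer.max)
  namer <- make_namer()
  salts <- default_salt_lexicon()

  ## ---- drug concepts and dictionaries ----
  n_d <- spec$n_drug_concepts
  drug <- tibble::tibble(
    idx = seq_len(n_d),
    cas = sprintf("%04d-%02d-%d", 1000L + seq_len(n_d), seq_len(n_d) %% 100L,
                  seq_len(n_d) %% 10L),
    dcui = sprintf("D%06d", seq_len(n_d)),
    pt = vapply(seq_len(n_d), function(i) namer(1L), character(1))
  )
  drug$synonyms <- lapply(seq_len(n_d), function(i) {
    if (spec$synonyms_per_concept == 0L) character() else
      vapply(seq_len(spec$synonyms_per_concept), function(j) namer(1L),
             character(1))
  })
  # a minority of concepts get an alternative preferred term in the
  # metathesaurus-style dictionary, exercising ranked conflict resolution
  drug$alt_pt <- ifelse(stats::runif(n_d) < 0.3,
                        vapply(seq_len(n_d), function(i) namer(1L), character(1)),
                        NA_character_)

  chemid_rows <- dplyr::bind_rows(lapply(seq_len(n_d), function(i) {
    tibble::tibble(
      concept_id = drug$cas[[i]],
      term = c(drug$pt[[i]], drug$synonyms[[i]]),
      status = c("P", rep("S", length(drug$synonyms[[i]]))),
      cas_number = drug$cas[[i]],
      semantic_types = "T109"
    )
  }))
  umls_drug_rows <- dplyr::bind_rows(lapply(seq_len(n_d), function(i) {
    p <- if (is.na(drug$alt_pt[[i]])) drug$pt[[i]] else drug$alt_pt[[i]]
    syn <- setdiff(unique(c(drug$pt[[i]], drug$synonyms[[i]])), p)
    tibble::tibble(
      concept_id = drug$dcui[[i]],
      term = c(p, syn),
      status = c("P", rep("S", length(syn))),
      cas_number = NA_character_,
      semantic_types = "T121"
    )
  }))
  drug_dicts <- list(
    dictionary_from_rows(chemid_rows, authority("ChemIDplus", 1L)),
    dictionary_from_rows(umls_drug_rows, authority("UMLS", 2L))
  )

  ## ---- indication concepts, scheme, remap ----
  scheme <- default_semantic_scheme()
  n_i <- spec$n_indication_concepts
  nonphen <- stats::runif(n_i) < spec$nonphenotypic_rate
  ind <- tibble::tibble(
    idx = seq_len(n_i),
    cui = sprintf("C%06d", seq_len(n_i)),
    nonphen = nonphen,
    pt = vapply(seq_len(n_i), function(i) namer(sample(1:2, 1)), character(1)),
    stype = ifelse(nonphen, "T121", "T047")
  )
  ind$synonyms <- lapply(seq_len(n_i), function(i) {
    if (spec$synonyms_per_concept == 0L) character() else
      vapply(seq_len(spec$synonyms_per_concept),
             function(j) namer(sample(1:2, 1)), character(1))
  })
  # remap targets: fresh phenotypic partner concepts for the remappable
  # fraction of the non-phenotypic pool
  remappable <- which(ind$nonphen & stats::runif(n_i) >= spec$stuck_rate)
  partner <- tibble::tibble(
    cui = sprintf("C%06d", n_i + seq_along(remappable)),
    pt = vapply(seq_along(remappable), function(i) namer(1L), character(1)),
    stype = "T047",
    for_idx = remappable
  )
  ind$final_cui <- ind$cui
  ind$final_cui[remappable] <- partner$cui

  ind_rows <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(seq_len(n_i), function(i) {
      tibble::tibble(
        concept_id = ind$cui[[i]],
        term = c(ind$pt[[i]], ind$synonyms[[i]]),
        status = c("P", rep("S", length(ind$synonyms[[i]]))),
        cas_number = NA_character_,
        semantic_types = ind$stype[[i]]
      )
    })),
    tibble::tibble(
      concept_id = partner$cui, term = partner$pt, status = "P",
      cas_number = NA_character_, semantic_types = partner$stype
    )
  )
  indication_dict <- dictionary_from_rows(ind_rows, authority("UMLS_IND", 1L))
  remap <- remap_from_rows(tibble::tibble(
    from_concept_id = ind$cui[remappable],
    to_concept_id = partner$cui
  ))

  ## ---- per-source emission plan ----
  src <- source_styles(spec$n_sources)
  drug_pools <- split_pool(n_d, spec$n_sources, spec$share_fraction)
  ind_pools <- split_pool(n_i, spec$n_sources, spec$share_fraction)

  alias_of <- function(di) {
    # how a source names drug concept di: PT/synonym, salt variant, or an
    # unregistered code name
    u <- stats::runif(1)
    if (u < spec$unmappable_rate) {
      list(alias = paste0(toupper(namer(1L)), "-", sample(100:999, 1)),
           mapped = FALSE, variant = "unmappable")
    } else if (u < spec$unmappable_rate + spec$salt_variant_rate) {
      list(alias = paste(drug$pt[[di]], sample(salts, 1)), mapped = TRUE,
           variant = "salt")
    } else {
      opts <- c(drug$pt[[di]], drug$synonyms[[di]])
      list(alias = sample(opts, 1), mapped = TRUE, variant = "plain")
    }
  }
  surface_of <- function(ii) {
    sample(c(ind$pt[[ii]], ind$synonyms[[ii]]), 1)
  }

  truth_records <- list()
  sources <- list(pair = NULL, hierarchy = NULL, freetext = NULL)
  planned <- list(overlong = 0L, pair_noise = 0L, combination = 0L,
                  ill_formed = 0L, redundant_level = 0L,
                  redundant_variant = 0L)
  indication_counts <- list()

  for (s in seq_len(spec$n_sources)) {
    sid <- src$source_id[[s]]
    style <- src$style[[s]]
    d_pool <- drug_pools[[s]]
    i_pool <- ind_pools[[s]]
    # idiosyncratic phrasing bias: pair-style sources favor disease terms,
    # hierarchy-style sources favor class terms needing remap
    w <- rep(1, length(i_pool))
    if (style == "pair") w[!ind$nonphen[i_pool]] <- 3
    if (style == "hierarchy") w[ind$nonphen[i_pool]] <- 3

    recs <- list()
    for (di in d_pool) {
      al <- alias_of(di)
      k <- min(1L + stats::rpois(1, spec$indications_per_drug_mean - 1),
               length(i_pool))
      picked <- resample(i_pool, k, prob = w)
      surfaces <- vapply(picked, surface_of, character(1))
      indication_counts[[length(indication_counts) + 1L]] <-
        tibble::tibble(source_id = sid, drug_idx = di, k = k)

      overlong <- style == "freetext" &&
        stats::runif(1) < spec$freetext_overlong_rate
      if (!overlong) {
        truth_records[[length(truth_records) + 1L]] <- tibble::tibble(
          source_id = sid,
          raw_drug = al$alias,
          drug_cas = if (al$mapped) drug$cas[[di]] else NA_character_,
          drug_cui = if (al$mapped) drug$dcui[[di]] else NA_character_,
          raw_target = surfaces,
          ind_cui_initial = ind$cui[picked],
          ind_cui_final = ind$final_cui[picked]
        )
      } else {
        planned$overlong <- planned$overlong + 1L
      }
      recs[[length(recs) + 1L]] <- list(
        drug_idx = di, alias = al$alias, picked = picked,
        surfaces = surfaces, overlong = overlong
      )
    }

    if (style == "pair") {
      rows <- dplyr::bind_rows(lapply(recs, function(r) {
        tibble::tibble(source_id = sid, drug = r$alias,
                       relation = sample(c("may_treat", "may_prevent"), 1),
                       indication_term = r$surfaces)
      }))
      # noise: blocklisted role objects and off-allowlist relations
      n_noise <- stats::rbinom(1, length(recs), 0.2)
      if (n_noise > 0) {
        noise <- tibble::tibble(
          source_id = sid,
          drug = vapply(sample(recs, n_noise, replace = TRUE),
                        function(r) r$alias, character(1)),
          relation = sample(c("has_role", "related_to"), n_noise, replace = TRUE),
          indication_term = sample(c("metabolite", "prodrug", "epitope"),
                                   n_noise, replace = TRUE)
        )
        # off-allowlist relations are dropped by the relation rule even with
        # a clean term; blocklisted terms by the role rule
        noise$indication_term[noise$relation == "related_to"] <- "well tolerated"
        planned$pair_noise <- planned$pair_noise + n_noise
        rows <- dplyr::bind_rows(rows, noise)
      }
      sources$pair <- dplyr::bind_rows(sources$pair, rows)
    } else if (style == "hierarchy") {
      rows <- dplyr::bind_rows(lapply(recs, function(r) {
        base <- paste0(sample(LETTERS, 1), sprintf("%02d", sample(1:99, 1)))
        codes <- vapply(seq_along(r$picked), function(l) {
          paste0(base, paste(rep("A", l - 1L), collapse = ""))
        }, character(1))
        lev <- tibble::tibble(source_id = sid, drug = r$alias,
                              level_code = codes, level_term = r$surfaces)
        # deliberate repetition of a term at the adjacent nested level
        if (stats::runif(1) < 0.3) {
          dup <- lev[nrow(lev), ]
          dup$level_code <- paste0(dup$level_code, "A")
          planned$redundant_level <<- planned$redundant_level + 1L
          lev <- dplyr::bind_rows(lev, dup)
        }
        lev
      }))
      n_combo <- stats::rbinom(1, length(recs), 0.1)
      if (n_combo > 0) {
        combo <- tibble::tibble(
          source_id = sid,
          drug = vapply(seq_len(n_combo), function(i) {
            paste(drug$pt[[resample(d_pool)]], "and",
                  drug$pt[[resample(d_pool)]])
          }, character(1)),
          level_code = "X01",
          level_term = vapply(resample(i_pool, n_combo, replace = TRUE),
                              surface_of, character(1))
        )
        planned$combination <- planned$combination + n_combo
        rows <- dplyr::bind_rows(rows, combo)
      }
      n_ill <- stats::rbinom(1, length(recs), 0.1)
      if (n_ill > 0) {
        ill <- tibble::tibble(
          source_id = sid,
          drug = sprintf("X%03d", sample(100:999, n_ill)),
          level_code = "X02",
          level_term = vapply(resample(i_pool, n_ill, replace = TRUE),
                              surface_of, character(1))
        )
        planned$ill_formed <- planned$ill_formed + n_ill
        rows <- dplyr::bind_rows(rows, ill)
      }
      sources$hierarchy <- dplyr::bind_rows(sources$hierarchy, rows)
    } else {
      rows <- dplyr::bind_rows(lapply(recs, function(r) {
        listed <- if (length(r$surfaces) == 1L) r$surfaces else
          paste(paste(r$surfaces[-length(r$surfaces)], collapse = ", "),
                "and", r$surfaces[length(r$surfaces)])
        text <- sprintf("Indicated for the treatment of %s.", listed)
        if (r$overlong) {
          pad <- paste(rep("See full prescribing information for details.",
                           ceiling(600 / 45)), collapse = " ")
          text <- paste(text, pad)
          stopifnot(nchar(text) >= 540L)
        }
        tibble::tibble(
          source_id = sid, generic_name = r$alias,
          trade_name = toupper(substr(r$alias, 1, 6)),
          dosage = paste0(sample(c(5, 10, 25, 50), 1), " mg"),
          supplier = "synthetica", indications_text = text
        )
      }))
      # redundant label variants: same generic and text, new trade name
      n_dup <- stats::rbinom(1, nrow(rows), 0.2)
      if (n_dup > 0) {
        dup <- rows[sample.int(nrow(rows), n_dup), , drop = FALSE]
        dup$trade_name <- paste0(dup$trade_name, "-XR")
        overl <- nchar(gsub("[\r\n]+", " ", dup$indications_text)) >= 540L
        planned$redundant_variant <- planned$redundant_variant +
          sum(!overl)
        planned$overlong <- planned$overlong + sum(overl)
        rows <- dplyr::bind_rows(rows, dup)
      }
      sources$freetext <- dplyr::bind_rows(sources$freetext, rows)
    }
  }

  records <- dplyr::distinct(dplyr::bind_rows(truth_records))
  truth <- list(
    records = records,
    name_map = dplyr::distinct(tibble::tibble(
      raw = records$raw_drug, concept = records$drug_cas
    )),
    remap_pairs = tibble::tibble(from_concept_id = ind$cui[remappable],
                                 to_concept_id = partner$cui),
    indication_counts = dplyr::bind_rows(indication_counts),
    planned = planned
  )

  structure(
    list(spec = spec, drug_dicts = drug_dicts,
         indication_dict = indication_dict, remap = remap, scheme = scheme,
         sources = sources, truth = truth),
    class = "did_world"
  )
}

#' @export
print.did_world <- function(x, ...) {
  cat(sprintf(
    "<did_world> seed %d: %d sources, %d clean ground-truth records\n",
    x$spec$seed, x$spec$n_sources, nrow(x$truth$records)
  ))
  invisible(x)
}

dict_to_rows <- function(dict) {
  dplyr::left_join(
    dplyr::select(dict$terms, "concept_id", "term", "status"),
    dplyr::mutate(
      dict$entries,
      semantic_types = vapply(.data$semantic_types, function(st) {
        if (length(st)) paste(st, collapse = ";") else NA_character_
      }, character(1))
    ) %>% dplyr::select("concept_id", "cas_number", "semantic_types"),
    by = "concept_id"
  )
}

#' Serialize a synthetic world to files
#'
#' Writes the dictionaries, remap table, semantic scheme and the three raw
#' source files (pair, hierarchy, free-text layouts) as UTF-8 TSVs in `dir`.
#' Purely deterministic: all randomness was drawn in [build_world()].
#'
#' @param world A `did_world` from [build_world()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
emit_sources <- function(world, dir) {
  stopifnot(inherits(world, "did_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    drug_chemid = file.path(dir, "dict_drug_chemid.tsv"),
    drug_umls = file.path(dir, "dict_drug_umls.tsv"),
    indications = file.path(dir, "dict_indications.tsv"),
    remap = file.path(dir, "remap.tsv"),
    scheme = file.path(dir, "scheme.tsv"),
    pair = file.path(dir, "source_pair.tsv"),
    hierarchy = file.path(dir, "source_hierarchy.tsv"),
    freetext = file.path(dir, "source_freetext.tsv")
  )
  readr::write_tsv(dict_to_rows(world$drug_dicts[[1]]), paths$drug_chemid,
                   progress = FALSE)
  readr::write_tsv(dict_to_rows(world$drug_dicts[[2]]), paths$drug_umls,
                   progress = FALSE)
  readr::write_tsv(dict_to_rows(world$indication_dict), paths$indications,
                   progress = FALSE)
  readr::write_tsv(tibble::as_tibble(world$remap), paths$remap, progress = FALSE)
  sch <- tibble::as_tibble(world$scheme)
  sch$phenotypic <- as.integer(sch$phenotypic)
  readr::write_tsv(sch, paths$scheme, progress = FALSE)
  if (!is.null(world$sources$pair)) {
    readr::write_tsv(world$sources$pair, paths$pair, progress = FALSE)
  }
  if (!is.null(world$sources$hierarchy)) {
    readr::write_tsv(world$sources$hierarchy, paths$hierarchy, progress = FALSE)
  }
  if (!is.null(world$sources$freetext)) {
    readr::write_tsv(world$sources$freetext, paths$freetext, progress = FALSE)
  }
  invisible(paths)
}

## ---- analytic expected metrics (ground-truth twin of the metrics module) ----

# base-R recounts from the ground-truth record table, independent of the
# pipeline code path
expected_overlap_table <- function(inc) {
  ids <- unique(inc$id)
  sharing <- tapply(inc$source_id, inc$id, function(s) length(unique(s)))
  per_src <- sort(unique(inc$source_id))
  score <- vapply(per_src, function(s) {
    mine <- unique(inc$id[inc$source_id == s])
    mean(as.numeric(sharing[mine]))
  }, numeric(1))
  tibble::tibble(
    source_id = c(per_src, "All"),
    score = c(score, mean(as.numeric(sharing[ids])))
  )
}

expected_zipf_table <- function(inc) {
  sharing <- tapply(inc$source_id, inc$id, function(s) length(unique(s)))
  n_src <- length(unique(inc$source_id))
  counts <- vapply(seq_len(n_src), function(k) sum(sharing == k), integer(1))
  tibble::tibble(k = seq_len(n_src), count = counts)
}

truth_incidence <- function(rec, entity, stage) {
  drug <- if (stage == "raw") rec$raw_drug else
    ifelse(is.na(rec$drug_cas), rec$raw_drug, rec$drug_cas)
  indn <- if (stage == "raw") rec$raw_target else rec$ind_cui_final
  id <- switch(entity, drug = drug, indication = indn,
               pair = paste(drug, indn, sep = "\r"))
  unique(tibble::tibble(source_id = rec$source_id, id = id))
}

#' Analytic expected metrics from ground truth
#'
#' Computes every integration metric directly from the world's ground-truth
#' record table by set arithmetic in base R — independently of the ingest,
#' normalization, assembly and metrics code paths — so it can serve as the
#' oracle in pipeline-equivalence tests.
#'
#' @param world A `did_world`.
#' @return A list with elements `tr_drug`, `tr_indication` (each N/X/U/tr),
#'   `overlap_raw`, `overlap_normalized`, `overlap_change` (wide tibbles as
#'   in [overlap_stats()]), `coverage`, `zipf` (nested by entity and
#'   stage), `richness_raw`, `richness_normalized`.
#' @export
expected_metrics <- function(world) {
  rec <- world$truth$records
  if (!nrow(rec)) stop_input("world has no ground-truth records")

  # drug TR over unique raw names
  name_map <- unique(rec[c("raw_drug", "drug_cas")])
  u <- length(unique(name_map$raw_drug))
  x <- sum(is.na(name_map$drug_cas))
  n <- length(unique(name_map$drug_cas[!is.na(name_map$drug_cas)]))
  tr_drug <- list(n_normalized = n, n_unnormalized = x, n_unique_raw = u,
                  tr = (n + x) / u)

  tgt_map <- unique(rec[c("raw_target", "ind_cui_final")])
  ui <- length(unique(tgt_map$raw_target))
  xi <- sum(is.na(tgt_map$ind_cui_final))
  ni <- length(unique(tgt_map$ind_cui_final[!is.na(tgt_map$ind_cui_final)]))
  tr_ind <- list(n_normalized = ni, n_unnormalized = xi, n_unique_raw = ui,
                 tr = (ni + xi) / ui)

  wide <- function(stage) {
    out <- NULL
    for (entity in c("drug", "indication", "pair")) {
      sc <- expected_overlap_table(truth_incidence(rec, entity, stage))
      names(sc)[2] <- entity
      out <- if (is.null(out)) sc else merge(out, sc, by = "source_id",
                                             sort = FALSE)
    }
    tibble::as_tibble(out)
  }
  overlap_raw <- wide("raw")
  overlap_norm <- wide("normalized")
  ochange <- overlap_raw
  for (col in c("drug", "indication", "pair")) {
    ochange[[col]] <- overlap_norm[[col]][
      match(ochange$source_id, overlap_norm$source_id)] - ochange[[col]]
  }

  cov <- NULL
  for (entity in c("drug", "indication", "pair")) {
    inc <- truth_incidence(rec, entity, "normalized")
    tot <- length(unique(inc$id))
    cnt <- tapply(inc$id, inc$source_id, length)
    per <- tibble::tibble(source_id = names(cnt), n = as.integer(cnt),
                          pct = 100 * as.integer(cnt) / tot)
    names(per)[2:3] <- paste0(c("n_", "pct_"), entity)
    cov <- if (is.null(cov)) per else merge(cov, per, by = "source_id",
                                            sort = FALSE)
  }
  cov <- tibble::as_tibble(cov[order(cov$source_id), ])

  zipf_out <- list()
  for (entity in c("drug", "indication", "pair")) {
    for (stage in c("raw", "normalized")) {
      zipf_out[[paste(entity, stage, sep = "_")]] <-
        expected_zipf_table(truth_incidence(rec, entity, stage))
    }
  }

  rich <- function(stage) {
    drug <- if (stage == "raw") rec$raw_drug else
      ifelse(is.na(rec$drug_cas), rec$raw_drug, rec$drug_cas)
    indn <- if (stage == "raw") rec$raw_target else rec$ind_cui_final
    tab <- unique(tibble::tibble(source_id = rec$source_id, drug = drug,
                                 ind = indn))
    per_src <- sort(unique(tab$source_id))
    tibble::tibble(
      source_id = per_src,
      indications_per_drug = vapply(per_src, function(s) {
        sub <- tab[tab$source_id == s, ]
        nrow(sub) / length(unique(sub$drug))
      }, numeric(1)),
      drugs_per_indication = vapply(per_src, function(s) {
        sub <- tab[tab$source_id == s, ]
        nrow(sub) / length(unique(sub$ind))
      }, numeric(1))
    )
  }

  list(
    tr_drug = tr_drug, tr_indication = tr_ind,
    overlap_raw = overlap_raw, overlap_normalized = overlap_norm,
    overlap_change = ochange, coverage = cov, zipf = zipf_out,
    richness_raw = rich("raw"), richness_normalized = rich("normalized")
  )
}
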