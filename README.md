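# didkit

Tools for building and analyzing an integrated **drug–indication database
(DID)** from heterogeneous sources.

## The problem

Drug–indication knowledge is scattered across resources with incompatible
shapes: controlled relation lists (`drug — may_treat — disease`), ATC-style
classification hierarchies whose levels convey therapeutic classes, and
free-text product labels with an indications section. The same drug appears
under preferred terms, synonyms, salt/hydrate variants, trade names, or
company codes; the same indication appears either as a disease term
("Bacterial Infections") or as a therapeutic-class term ("Anti-Bacterial
Agents") that merely implies the disease. `didkit` is for informaticians who
need to merge such sources into one deduplicated flat table with
language-neutral concept identifiers, and to quantify how well the merge
worked.

## What it does

- **Ingest** adapters for the three source styles, applying the standard
  filtering rules (relation allowlists and role blocklists, combination and
  ill-formed drug names, redundant nested hierarchy terms, label variants
  differing only by trade name/dosage/supplier, free-text sections at or
  beyond the 540-character tractability cutoff) with full per-rule
  accounting.
- **Drug name normalization** to CAS-style and CUI-style identifiers across
  ranked synonym dictionaries (`ChemIDplus > ChEBI > DrugBank > eVOC > CTD`
  is the classic ranking), typing each match as `PT_EXACT`, `SYNONYM`,
  `QUASI_SYNONYM` ("cidofovir anhydrous" : "Cidofovir"), `NARROWER`
  ("arformoterol fumarate" : "Arformoterol"; directionality raw-to-standard),
  `BROADER`, or `UNMAPPED`.
- **Indication normalization** with a semantic-type preference for
  *phenotypes* (diseases and other biological conditions, processes and
  functions), and a remap table that unifies class-term encodings with their
  disease-level concept (e.g. C0279516 "Anti-Bacterial Agents" →
  C0004623 "Bacterial Infections"); class terms with no phenotypic
  counterpart stay "stuck".
- **Subtype tagging** of lexical cues (prefix "anti-", suffix "-lytic", head
  nouns like "agonist", keywords like "treatment of") rolled up a leaf →
  lexical root → polarity hierarchy.
- **Assembly** of the unique-quadruplet table keyed on (source, raw drug
  name, raw indication target, indication CUI), with a deterministic,
  escaped TSV dialect (`write_did()` / `read_did()`).
- **Integration metrics.** Terminological reduction
  `TR = (N + X) / U`, where `N` = unique normalized identifiers, `X` =
  unique raw names left unnormalized, `U` = unique raw names (lower =
  stronger unification); per-source coverage; overlap scores (mean number
  of sources sharing each unique entity, within each source's coverage,
  with change = normalized − raw); Zipf sharing distributions; and richness
  (indications per drug, drugs per indication).
- **A synthetic-world generator** (`world_spec()`, `build_world()`,
  `emit_sources()`) with analytic expected metrics (`expected_metrics()`)
  that serves as a ground-truth oracle for every stage, since the real
  corpora are licensed or proprietary.

## Worked example

```r
library(didkit)

world <- build_world(world_spec(seed = 1))
dir <- tempfile()
emit_sources(world, dir)        # dictionaries, remap, scheme, 3 raw sources
res <- run_pipeline(dir)

res$did
#> <did_table> 178 rows, 3 sources, 49 unique raw drug names

res$metrics$tr_drug$tr
#> [1] 0.8163265
```

A drug TR of 0.82 means normalization reduced the 49 unique raw drug names
(aliases, salt variants, and a few unregistered code names) to 36 concepts
plus 4 names that stayed unmapped: (36 + 4) / 49 ≈ 0.82. The pooled drug
overlap score rises from 1.10 (raw strings, mostly private to each source)
to 1.35 after normalization — each unique drug is now shared by 1.35 sources
on average — and

```r
res$metrics$overlap_change
#> # A tibble: 4 × 4
#>   source_id     drug indication   pair
#>   <chr>        <dbl>      <dbl>  <dbl>
#> 1 freetext_03  0.364      0.207 0.0513
#> 2 hierarchy_02 0.524      0.343 0.0448
#> 3 pair_01      0.409      0.385 0.0417
#> 4 All          0.248      0.160 0.0230
```

shows normalization raising sharing for all three entity kinds — here the
drug-name effect dominates because the generated sources alias drugs through
synonyms and salt variants, while the indication effect comes from the
phenotypic remapping of class terms. Every number above
can be checked against `expected_metrics(world)`, which recomputes the
metrics from the generator's ground truth by independent set arithmetic.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

builds a seeded synthetic world, serializes it, runs the complete pipeline
from the files (ingest → normalize → remap → assemble → metrics), verifies
exact agreement with the ground-truth oracle, prints a summary, and writes
the JSON results file.

## Layout

- `R/` — lexicon, ingest, drug/indication normalization, subtypes, DID
  table, metrics, synthetic world, pipeline driver
- `tests/testthat/` — unit, property, and acceptance suites
- `vignettes/did-construction.Rmd` — the methods vignette: model,
  parameters, numerical choices, limitations
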