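---
title: "Constructing and evaluating an integrated drug-indication database"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and evaluating an integrated drug-indication database}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(didkit)
```

## The model

`didkit` builds a drug–indication database (DID): a flat table of unique
quadruplets (source, raw drug/chemical name, raw indication target,
indication concept identifier). The construction has four stages, each a
module with an explicit contract:

1. **Parsing and filtering.** Source records arrive in one of three shapes —
   controlled (drug, relation, term) pairs, classification hierarchies where
   every level is a candidate indication, and free-text label records. Each
   adapter converts records to parsed pairs carrying the raw *entire value*
   and the *target* term denoting one indication concept, and tallies what
   the filters removed and why.
2. **Drug name normalization.** Every raw name is looked up in ranked
   synonym dictionaries; per-authority best matches are typed by quality
   (exact preferred term, synonym, quasi-synonym, narrower/broader with
   raw-to-standard directionality). A CAS-style registry number is taken
   from the highest-ranked authority supplying one, a CUI from the
   metathesaurus-style dictionary, and conflicts between authorities'
   preferred terms are resolved by rank.
3. **Indication normalization.** Targets are exact-key mapped to concepts
   with a preference for *phenotypic* semantic types (diseases and other
   biological conditions, processes, functions). Non-phenotypic mappings —
   typically therapeutic-class terms — are remapped through a curated table
   to the disease concept they imply; the pre-remap mapping is preserved and
   the final match is typed quasi-synonym, making the precision trade
   explicit. Classes with no phenotypic counterpart stay "stuck".
4. **Assembly and metrics.** Rows are joined, deduplicated on the
   quadruplet key, and measured: terminological reduction
   `TR = (N + X)/U`; per-source coverage; overlap (mean number of sources
   sharing each unique entity, computed within each source's coverage, with
   a pooled "All" row over the union); Zipf sharing histograms; richness.

### Assumptions

- Identity is purely terminological: two names refer to the same drug iff
  they key-match entries of the same concept (no structure comparison).
- Matching is exact on a normalized key — case-folded, whitespace-squashed,
  punctuation preserved. Punctuation is kept because chemical nomenclature
  distinguishes names that differ only by brackets or commas; folding them
  would over-merge.
- The remap table is *data*, not code: class-to-disease mappings are
  curation products and cannot be derived algorithmically. The package
  ships fixtures and accepts user tables; `validate_remap()` enforces that
  targets exist, are phenotypic, and that the table is idempotent.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| free-text tractability cutoff | keep < 540 characters | the conventional boundary for label sections considered parseable; measured after newlines become spaces |
| authority ranking | order given by the dictionaries' ranks | rank 1 wins CAS/preferred-term conflicts; ties break on smallest concept id for determinism |
| salt lexicon | hydrochloride, fumarate, sodium, ... | trailing tokens marking a salt/derivative (NARROWER raw-to-standard) |
| quasi lexicon | anhydrous, monohydrate, racemic, hemihydrate | modifiers leaving a name a near-equivalent |
| combination tokens | " and ", "/", " + ", ", combinations", " with " | a name containing one is a multi-ingredient product |
| subtype cue/rollup tables | seeded with treat/prevent/anti/-lytic/agonist/... | deliberately incomplete configuration; prefix cues require ≥ 3 characters after the prefix so "anti" does not fire on "ant..." words |

Within one authority, when several entries match a name, precedence is
PT_EXACT > SYNONYM > QUASI_SYNONYM > NARROWER > BROADER, then P-status,
then smallest concept id — exactness first, determinism always. For
indications, a phenotypic candidate beats a non-phenotypic one before
status is considered.

## The synthetic world

Real DID corpora are built from licensed and proprietary sources, so the
package carries its own stated world: `build_world()` draws, under one
seed, drug concepts with preferred terms, synonyms, salt variants
(`salt_variant_rate = 0.15`) and unregistered code names
(`unmappable_rate = 0.05`, emulating company codes); indication concepts
split phenotypic/non-phenotypic (`nonphenotypic_rate = 0.3`, matching the
roughly 30% initial non-phenotypic encodings seen in practice) with remap
partners for all but a `stuck_rate = 0.1` fraction (so ~3% of encodings
stay non-phenotypic after remapping); three source styles with
idiosyncratic phrasing (pair sources favor disease terms, hierarchies favor
class terms, free text embeds "treatment of X and Y" sentences);
`share_fraction = 0.3` of each concept pool shared across sources;
`indications_per_drug_mean = 3`; and `freetext_overlong_rate = 0.37`
(the observed share of intractably long label sections). Every emitted raw
string has exactly one ground-truth assignment, and generated words are
globally unique, so greedy longest-match target extraction is exact by
construction.

`expected_metrics()` recomputes every metric from the ground-truth records
by base-R set arithmetic — a code path disjoint from the pipeline — and the
acceptance suite requires *exact* agreement over a grid of 10 seeds × 3
specifications.

What a green grid does establish: the ingest filters, alias resolution,
phenotypic remapping, quadruplet deduplication and all metric definitions
are mutually consistent and deterministic. What it does not establish:
performance on real vocabulary data, where names collide across concepts,
extraction needs more than exact dictionary matching, and curation quality
dominates. Absolute corpus statistics (row counts, the published 91/85/84%
drug and 57% indication TR values) depend on licensed inputs and manual
curation and are therefore out of scope; only printed worked arithmetic
(overlap change = normalized − raw) is asserted against published cells.

## Numerical and design choices

- **Tie-breaks** are all lexicographic-smallest (concept ids, source order)
  — reproducibility over any notion of preference the data cannot support.
- **Rounding**: metrics are kept at full precision; two-decimal rounding is
  presentation only.
- **Length boundary**: texts of exactly 540 characters are dropped, 539
  kept; both published phrasings ("< 540", "> 539") agree on this.
- **Degenerate inputs**: empty record sets yield empty outputs with zeroed
  reports; a target matching nothing passes through as its own target and
  an UNMAPPED mapping; unknown subtype leaves roll up to themselves with
  polarity UNKNOWN.
- **Compound targets**: when no single concept covers a target, maximal
  leftmost-longest dictionary spans are mapped as components 1..k and
  uncovered residue is dropped (compound rows are rare — about 1% in
  practice — and no principled residue rule exists).
- **Dedup collapse** keeps the best indication match quality; the paper
  states quadruplet uniqueness but not the collapse rule.
- **TR for drugs** is reported for CAS-based, CUI-based, or combined
  normalization (`did_tr(..., id =)`), mirroring the three published
  variants.
- The TSV dialect escapes tabs, newlines and backslashes so free-text
  entire values survive a write/read roundtrip byte-identically; header
  names embed the originating spreadsheet column letters (`target(AR)`)
  instead of replicating a 60-column positional layout.
- The generator's `synonyms_per_concept` counts synonyms *besides* the
  preferred term; an injective world (TR = 1) is therefore
  `synonyms_per_concept = 0` with zero variant rates.

## Worked micro-example

```{r}
dict <- dictionary_from_rows(tibble::tribble(
  ~concept_id, ~term,                   ~status, ~cas_number, ~semantic_types,
  "C0279516",  "Anti-Bacterial Agents", "P",     NA,          "T195",
  "C0279516",  "antibacterial agent",   "S",     NA,          "T195",
  "C0004623",  "Bacterial Infections",  "P",     NA,          "T047"
), "UMLS_IND")
remap <- remap_from_rows(tibble::tibble(
  from_concept_id = "C0279516", to_concept_id = "C0004623"
))
m <- map_indication("antibacterial agent", dict, default_semantic_scheme())
remap_phenotype(m, remap, dict, default_semantic_scheme())$mapping
```

The class term maps exactly to its class concept and is then traded for the
disease concept, with the initial mapping preserved in the pre-remap block.

## Known limitations

- No fuzzy or statistical matching: a name absent from every dictionary is
  UNMAPPED, period. Real pipelines supplement this with curation.
- Trade names resolve only through dictionary synonymy; there is no
  heuristic trade-name stripping.
- Subtype tagging is lexical and unguarded beyond the prefix-length rule
  ("antigen" needs cue-table curation, not code).
- The combination-product detector is token-based; names legitimately
  containing "and" would be over-filtered.
- Percentage-style published table values are not recomputable from
  synthetic data and are not asserted anywhere; the package reproduces the
  *definitions*, verified against its own ground truth.
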