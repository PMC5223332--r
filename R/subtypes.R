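#' Default indication-subtype cue table
#'
#' Lexical cues marking the subtype of a drug-indication relation in the raw
#' entire value: therapeutic/pharmacologic class prefixes ("*Anti*diabetic"),
#' suffixes ("Anxio*lytic*"), head nouns ("beta-adrenergic *agonist*"), and
#' free keywords ("treatment of ..."). `KEYWORD` cues match at token starts,
#' and the annotation leaf is the full matched token (so "treat" found in
#' "treatment" yields leaf "treatment"); `PREFIX`/`SUFFIX`/`HEAD_NOUN` cues
#' report their own leaf label. The tables are deliberately configuration,
#' not code: the shipped defaults are seed material, incomplete by nature.
#'
#' @return Tibble with columns `kind` (`PREFIX`, `SUFFIX`, `HEAD_NOUN`,
#'   `KEYWORD`), `surface`, `leaf`.
#' @export
default_subtype_cues <- function() {
  tibble::tribble(
    ~kind,      ~surface,     ~leaf,
    "KEYWORD",  "treat",      "",
    "KEYWORD",  "prevent",    "",
    "KEYWORD",  "manage",     "",
    "KEYWORD",  "diagnos",    "",
    "KEYWORD",  "inhibit",    "",
    "KEYWORD",  "carcinogen", "",
    "KEYWORD",  "mutagen",    "",
    "PREFIX",   "anti",       "anti",
    "SUFFIX",   "lytic",      "lytic",
    "HEAD_NOUN", "agonist",    "agonist",
    "HEAD_NOUN", "antagonist", "antagonist",
    "HEAD_NOUN", "activator",  "activator",
    "HEAD_NOUN", "activators", "activator",
    "HEAD_NOUN", "adjunct",    "adjunct"
  )
}

#' Default subtype rollup table
#'
#' Rolls leaf subtype forms up a three-level hierarchy: surface leaf (e.g.
#' "treatment") to lexical root ("treat") to polarity — NEGATIVE for
#' inhibitory/therapeutic relations, POSITIVE for causative ones, UNKNOWN
#' where the direction is undecided (e.g. diagnosis).
#'
#' @return Tibble with columns `leaf`, `root`, `polarity`.
#' @export
default_subtype_rollup <- function() {
  neg <- function(root, leaves) tibble::tibble(leaf = leaves, root = root, polarity = "NEGATIVE")
  pos <- function(root, leaves) tibble::tibble(leaf = leaves, root = root, polarity = "POSITIVE")
  unk <- function(root, leaves) tibble::tibble(leaf = leaves, root = root, polarity = "UNKNOWN")
  dplyr::bind_rows(
    neg("treat", c("treat", "treats", "treating", "treatment")),
    neg("prevent", c("prevent", "prevents", "preventing", "prevention")),
    neg("manage", c("manage", "manages", "managing", "management")),
    neg("inhibit", c("inhibit", "inhibits", "inhibiting", "inhibition", "inhibitor")),
    neg("anti", "anti"),
    neg("lytic", "lytic"),
    neg("antagonist", "antagonist"),
    pos("carcinogen", c("carcinogen", "carcinogenic")),
    pos("mutagen", c("mutagen", "mutagenic")),
    pos("agonist", "agonist"),
    pos("activator", c("activator", "activation")),
    unk("adjunct", "adjunct"),
    unk("diagnose", c("diagnose", "diagnoses", "diagnosing", "diagnosis", "diagnostic"))
  )
}

#' Roll a leaf subtype form up to its lexical root and polarity
#'
#' @param leaf Leaf form (lower case).
#' @param table Rollup tibble (`leaf`, `root`, `polarity`); see
#'   [default_subtype_rollup()]. A leaf absent from the table (also after a
#'   plural-`s` fallback) passes through with polarity `UNKNOWN`.
#' @return `list(root =, polarity =)`.
#' @examples
#' rollup_subtype("treating")
#' @export
rollup_subtype <- function(leaf, table = default_subtype_rollup()) {
  row <- table[table$leaf == leaf, , drop = FALSE]
  if (!nrow(row) && grepl("s$", leaf)) {
    row <- table[table$leaf == sub("s$", "", leaf), , drop = FALSE]
  }
  if (!nrow(row)) return(list(root = leaf, polarity = "UNKNOWN"))
  list(root = row$root[[1]], polarity = row$polarity[[1]])
}

# one token, lower-cased, edge punctuation stripped
tokenize_lower <- function(x) {
  toks <- strsplit(stringr::str_to_lower(x), "[[:space:]]+")[[1]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Tag indication subtypes in a raw entire value
#'
#' Case-insensitive scan of the raw entire value against the cue table.
#' `KEYWORD` cues match a token start and report the full token as the leaf;
#' `PREFIX` cues match a token start provided at least 3 characters remain
#' after the prefix (so "anti" does not fire on "ant..." words); `SUFFIX`
#' cues match token ends; `HEAD_NOUN` cues match whole tokens. Each matching
#' cue yields one annotation, duplicates on the same leaf collapse, and a
#' value matching no cue yields a single `UNKNOWN` annotation.
#'
#' @param entire_value The raw entire value string.
#' @param cues Cue tibble; see [default_subtype_cues()].
#' @param rollup Rollup tibble; see [default_subtype_rollup()].
#' @return Tibble with columns `leaf`, `root`, `polarity`; never empty.
#' @examples
#' tag_subtypes("treatment of hypertension")
#' tag_subtypes("Antidiabetic")
#' @export
tag_subtypes <- function(entire_value, cues = default_subtype_cues(),
                         rollup = default_subtype_rollup()) {
  if (!nrow(cues)) stop_input("cue table must be nonempty")
  toks <- tokenize_lower(entire_value)
  leaves <- character()
  for (i in seq_len(nrow(cues))) {
    kind <- cues$kind[[i]]
    surf <- stringr::str_to_lower(cues$surface[[i]])
    if (kind == "KEYWORD") {
      hit <- toks[startsWith(toks, surf)]
      leaves <- c(leaves, hit)
    } else if (kind == "PREFIX") {
      hit <- toks[startsWith(toks, surf) & nchar(toks) >= nchar(surf) + 3L]
      if (length(hit)) leaves <- c(leaves, cues$leaf[[i]])
    } else if (kind == "SUFFIX") {
      hit <- toks[endsWith(toks, surf) & nchar(toks) > nchar(surf)]
      if (length(hit)) leaves <- c(leaves, cues$leaf[[i]])
    } else if (kind == "HEAD_NOUN") {
      if (surf %in% toks) leaves <- c(leaves, cues$leaf[[i]])
    } else {
      stop_input(sprintf("unknown cue kind: %s", kind))
    }
  }
  leaves <- unique(leaves[nzchar(leaves)])
  if (!length(leaves)) {
    return(tibble::tibble(leaf = NA_character_, root = NA_character_,
                          polarity = "UNKNOWN"))
  }
  rolled <- lapply(leaves, rollup_subtype, table = rollup)
  tibble::tibble(
    leaf = leaves,
    root = vapply(rolled, `[[`, character(1), "root"),
    polarity = vapply(rolled, `[[`, character(1), "polarity")
  )
}
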