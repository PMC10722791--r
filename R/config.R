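#' Mapping configuration
#'
#' All tunable vocabulary and thresholds used by the preprocessing rules and
#' the mapping cascade, in one list. Every list can be extended (or replaced)
#' either by arguments here or by a plain key-value config file read with
#' [read_config()].
#'
#' @param max_d Maximum edit distance accepted by the spelling-correction
#'   stages (both epithet-only and whole-string). Default 3, matching the
#'   hardest typo load the mapper is expected to recover from.
#' @param dropout_keywords Word-blocks that mark a query as carrying no
#'   taxonomic information about itself (typically the name names the host,
#'   not the entity); such queries short-circuit to a 90-range status code.
#' @param part_terms Latin materia-medica part terms (and conjunctions)
#'   removed before declension reconstruction.
#' @param infra_abbrev Nomenclatural abbreviations recognised during
#'   semantic screening.
#' @param preserve_first_char Logical; the synthetic typo injector never
#'   alters the first character when this is `TRUE` (default), keeping the
#'   genus-block pruning stage exercised.
#' @param declension_table Named list: genitive suffix -> character vector of
#'   candidate nominative suffixes.
#' @return A list of class `taxmap_config`.
#' @export
taxmap_config <- function(max_d = 3L,
                          dropout_keywords = c("virus", "viroid", "phytoplasma",
                                               "endosymbiont", "phage"),
                          part_terms = c("herba", "radix", "cortex", "folium",
                                         "flos", "fructus", "semen", "rhizoma",
                                         "et"),
                          infra_abbrev = c("sp.", "spp.", "var.", "subsp.",
                                           "ssp.", "f.", "cv.", "cf.", "aff."),
                          preserve_first_char = TRUE,
                          declension_table = list(
                            "ae"   = c("a", "e"),
                            "i"    = c("us", "um", "is"),
                            "is"   = c("is", "e", "s"),
                            "orum" = c("um", "us"),
                            "arum" = c("a"),
                            "us"   = c("us")
                          )) {
  stopifnot(is.numeric(max_d), max_d >= 0)
  structure(
    list(
      max_d = as.integer(max_d),
      dropout_keywords = tolower(dropout_keywords),
      part_terms = tolower(part_terms),
      infra_abbrev = tolower(infra_abbrev),
      preserve_first_char = isTRUE(preserve_first_char),
      declension_table = declension_table
    ),
    class = "taxmap_config"
  )
}

#' Read a key-value configuration file
#'
#' Lines of the form `key = value` (or `key<TAB>value`); `#` starts a
#' comment. List-valued keys (`dropout_keywords`, `part_terms`,
#' `infra_abbrev`) take comma-separated values and *extend* the defaults.
#' `max_d` and `preserve_first_char` replace the defaults.
#'
#' @param path Path to the config file.
#' @param base Configuration to extend; defaults to [taxmap_config()].
#' @return A `taxmap_config` list.
#' @export
read_config <- function(path, base = taxmap_config()) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    m <- stringr::str_match(ln, "^([A-Za-z_]+)\\s*(?:=|\t)\\s*(.+)$")
    if (is.na(m[1, 1])) abort(paste0("config: cannot parse line: ", ln))
    key <- m[1, 2]
    val <- stringr::str_trim(m[1, 3])
    if (key %in% c("dropout_keywords", "part_terms", "infra_abbrev")) {
      extra <- tolower(stringr::str_trim(strsplit(val, ",")[[1]]))
      base[[key]] <- unique(c(base[[key]], extra[nzchar(extra)]))
    } else if (key == "max_d") {
      base$max_d <- as.integer(val)
    } else if (key == "preserve_first_char") {
      base$preserve_first_char <- tolower(val) %in% c("true", "1", "yes")
    } else {
      abort(paste0("config: unknown key '", key, "'"))
    }
  }
  base
}

# Rank tiers for nearest-taxon mapping: species < genus < family < order <
# class < phylum < kingdom < domain. Intermediate ranks collapse onto the
# tier of the nearest canonical rank; unranked ancestors inherit the tier of
# the nearest ranked descendant during the lineage walk.
rank_tier_table <- c(
  "subspecies" = 1L, "varietas" = 1L, "variety" = 1L, "forma" = 1L,
  "form" = 1L, "strain" = 1L, "subvariety" = 1L, "species" = 1L,
  "species group" = 2L, "species subgroup" = 2L,
  "subgenus" = 2L, "genus" = 2L,
  "subtribe" = 3L, "tribe" = 3L, "subfamily" = 3L, "family" = 3L,
  "superfamily" = 4L, "suborder" = 4L, "order" = 4L, "superorder" = 5L,
  "infraclass" = 5L, "subclass" = 5L, "class" = 5L, "superclass" = 6L,
  "subphylum" = 6L, "phylum" = 6L, "division" = 6L,
  "subkingdom" = 7L, "kingdom" = 7L,
  "superkingdom" = 8L, "domain" = 8L, "realm" = 8L
)

rank_tier <- function(rank) {
  tier <- unname(rank_tier_table[tolower(rank)])
  tier
}

# status codes produced when a nearest-taxon hit lands on a given tier
tier_status <- function(tier) {
  ifelse(is.na(tier), 18L, 9L + pmin(tier, 8L))
}

dropout_status <- function(keyword, config) {
  base <- match(keyword, config$dropout_keywords)
  if (is.na(base)) 99L else 89L + pmin(base, 9L)
}

#' Status code glossary
#'
#' The full table of mapping status codes, as a tibble. Ranges follow the
#' cascade stages: 0-5 exact, 6/8 cross-reference synonym recursion, 10-18
#' lineage-based nearest taxon (by rank tier), 20-22 epithet-only spelling
#' correction, 30-34 whole-string correction (declension first), 40-43
#' strain/abbreviation routing, 90-99 rule-based dropout, 100 partial,
#' 1000 unmapped.
#'
#' @return A tibble with columns `status_code`, `stage`, `meaning`.
#' @export
status_codes <- function() {
  tibble::tribble(
    ~status_code, ~stage, ~meaning,
    0L,    "exact",      "raw string equals a canonical name",
    1L,    "exact",      "raw string equals a synonym",
    2L,    "exact",      "canonical name after simple correction",
    3L,    "exact",      "synonym after simple correction",
    4L,    "exact",      "case-insensitive variant of an indexed name",
    5L,    "exact",      "exact hit on several distinct taxa (homonym)",
    6L,    "recursive",  "unique taxon via synonyms of a match in another reference",
    8L,    "recursive",  "several taxa via synonyms of matches in other references",
    10L,   "nearest",    "nearest taxon at species tier",
    11L,   "nearest",    "nearest taxon at genus tier",
    12L,   "nearest",    "nearest taxon at family tier",
    13L,   "nearest",    "nearest taxon at order tier",
    14L,   "nearest",    "nearest taxon at class tier",
    15L,   "nearest",    "nearest taxon at phylum tier",
    16L,   "nearest",    "nearest taxon at kingdom tier",
    17L,   "nearest",    "nearest taxon at domain tier",
    18L,   "nearest",    "nearest taxon at unranked/other tier",
    20L,   "epithet",    "epithet correction, unique canonical name",
    21L,   "epithet",    "epithet correction, unique synonym",
    22L,   "epithet",    "epithet correction, tie across distinct taxa",
    30L,   "whole",      "Latin declension reconstruction, unique taxon",
    31L,   "whole",      "Latin declension reconstruction, several taxa",
    32L,   "whole",      "whole-string correction, unique canonical name",
    33L,   "whole",      "whole-string correction, unique synonym",
    34L,   "whole",      "whole-string correction, tie across distinct taxa",
    40L,   "strain",     "strain-coded name, nearest species/genus container",
    41L,   "strain",     "'cf.' query, higher taxon of the stripped match",
    42L,   "strain",     "'aff.' query, higher taxon of the stripped match",
    43L,   "strain",     "genus-only query ('X sp.'), genus container",
    90L,   "dropout",    "dropout keyword: virus",
    91L,   "dropout",    "dropout keyword: viroid",
    92L,   "dropout",    "dropout keyword: phytoplasma",
    93L,   "dropout",    "dropout keyword: endosymbiont",
    94L,   "dropout",    "dropout keyword: phage",
    95L,   "dropout",    "hybrid mark",
    99L,   "dropout",    "content-free input or configured extra keyword",
    100L,  "partial",    "prefix word-blocks matched a taxon",
    1000L, "unmapped",   "no stage produced a mapping"
  )
}

valid_status_codes <- function() {
  c(0:5, 6L, 8L, 10:18, 20:24, 30:36, 40:49, 90:99, 100L, 1000L)
}

multi_match_codes <- function() c(5L, 8L, 22L, 31L, 34L)
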