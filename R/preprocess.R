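# Input-name preprocessing: rule-based simplification, semantic screening,
# Latin declension candidates and vernacular substitution. All functions are
# pure: flags and normal forms depend only on the input string and the
# configuration.

fold_name <- function(x) stringr::str_to_lower(x)

first_block <- function(x) {
  vapply(strsplit(x, " ", fixed = TRUE), function(w) {
    if (length(w) == 0) "" else w[[1]]
  }, character(1))
}

#' Simplify a raw name string
#'
#' Applies the rule-based simple corrections that reduce a query to the most
#' basic form found in taxonomic references: parenthesised spans are removed,
#' trailing authority word-blocks are dropped, stray punctuation and
#' whitespace are collapsed.
#'
#' The authority rule: starting from the third word-block, the first block
#' that begins with an uppercase letter, is a single-letter abbreviation with
#' a period (e.g. `"L."`), or is `"&"`, and every block after it, is dropped.
#' The first two word-blocks (the binomial) are never dropped.
#'
#' @param raw Character vector of raw name strings.
#' @return Character vector of simplified strings.
#' @examples
#' simple_correct("Panax ginseng C.A.Mey.")
#' simple_correct("Actinidia deliciosa (A.Chev.) C.F.Liang & A.R.Ferguson")
#' @export
simple_correct <- function(raw) {
  vapply(as.character(raw), simple_correct_one, character(1), USE.NAMES = FALSE)
}

simple_correct_one <- function(raw) {
  if (is.na(raw)) abort("simple_correct: NA input", class = "taxmapr_content_free")
  x <- stringr::str_trim(raw)
  if (!nzchar(x)) abort("simple_correct: content-free input", class = "taxmapr_content_free")
  # parenthesised spans (innermost-out, so nesting unwinds)
  repeat {
    x2 <- gsub("\\([^()]*\\)", " ", x)
    if (identical(x2, x)) break
    x <- x2
  }
  # unmatched parens and punctuation that never appears in indexed names
  x <- gsub("[]()[{}`\"',;:]", " ", x)
  x <- stringr::str_squish(x)
  toks <- strsplit(x, " ", fixed = TRUE)[[1]]
  if (length(toks) > 2) {
    # authority word-blocks: capitalised names (they contain lowercase
    # letters, unlike strain/isolate codes), single-letter abbreviations
    # ("L."), and "&" joins
    drop_from <- which(
      (grepl("^[A-Z]", toks) & grepl("[a-z]", toks) & !grepl("[0-9]", toks)) |
        grepl("^[A-Za-z]\\.$", toks) | toks == "&"
    )
    drop_from <- drop_from[drop_from >= 3]
    if (length(drop_from) > 0) toks <- toks[seq_len(min(drop_from) - 1)]
  }
  out <- paste(toks, collapse = " ")
  if (!nzchar(out)) abort("simple_correct: content-free input", class = "taxmapr_content_free")
  out
}

is_year_token <- function(tok) {
  grepl("^[0-9]{4}$", tok) & suppressWarnings(as.integer(tok)) >= 1700 &
    suppressWarnings(as.integer(tok)) <= 2099
}

#' Semantic screening of a simplified name
#'
#' Detects word-blocks that change how a query is routed through the mapping
#' cascade: strain-like alphanumeric codes (digit-bearing tokens that are not
#' plausible description years), the similarity abbreviations `cf.` and
#' `aff.`, hybrid marks, dropout keywords (`virus`, `phytoplasma`, ...) and
#' genus-only forms (a bare generic epithet or `"<Genus> sp."`).
#'
#' @param normalized A string produced by [simple_correct()].
#' @param config A [taxmap_config()].
#' @return Character vector of flags, possibly empty; dropout flags are
#'   `"dropout:<keyword>"`.
#' @examples
#' screen_semantics("Streptomyces sp. ABC-123")
#' screen_semantics("Rubia cf. cordifolia")
#' @export
screen_semantics <- function(normalized, config = taxmap_config()) {
  toks <- strsplit(normalized, " ", fixed = TRUE)[[1]]
  ftoks <- fold_name(toks)
  flags <- character(0)
  hit <- ftoks[ftoks %in% config$dropout_keywords]
  if (length(hit) > 0) flags <- c(flags, paste0("dropout:", hit[[1]]))
  if (any(grepl("×", toks)) || any(ftoks == "x" & seq_along(toks) > 1) ||
      any(ftoks == "hybrid")) {
    flags <- c(flags, "hybrid")
  }
  if (any(ftoks %in% c("cf.", "cf"))) flags <- c(flags, "confer")
  if (any(ftoks %in% c("aff.", "aff"))) flags <- c(flags, "affinis")
  digit_toks <- toks[grepl("[0-9]", toks)]
  if (length(digit_toks) > 0 && !all(is_year_token(digit_toks))) {
    flags <- c(flags, "strain_like")
  }
  if (length(toks) == 1 || any(ftoks %in% c("sp.", "spp.", "sp", "spp"))) {
    flags <- c(flags, "genus_only")
  }
  if (any(ftoks %in% config$part_terms)) flags <- c(flags, "declension_candidate")
  flags
}

apply_suffix <- function(block, config) {
  cands <- block
  fb <- fold_name(block)
  for (suf in names(config$declension_table)) {
    if (stringr::str_ends(fb, suf) && nchar(fb) > nchar(suf)) {
      stem <- substr(block, 1, nchar(block) - nchar(suf))
      cands <- c(cands, paste0(stem, config$declension_table[[suf]]))
    }
  }
  unique(cands)
}

#' Nominative-form candidates for a Latin-inflected name
#'
#' Reconstructs possible canonical (nominative) forms from a name written in
#' the genitive style common in materia-medica sources (e.g. "Glycyrrhizae
#' radix"). Part terms (herba, radix, cortex, ...) and conjunctions are
#' removed; every remaining word-block is expanded through the declension
#' table; the output is the deduplicated Cartesian combination of the
#' per-block candidate sets. The part-term-stripped original is always
#' included.
#'
#' @param word_blocks Character vector of word-blocks (one name, tokenised).
#' @param config A [taxmap_config()].
#' @return Character vector of candidate canonical name strings (possibly
#'   empty when nothing survives part-term removal).
#' @examples
#' latin_candidates(c("Glycyrrhizae", "radix"))
#' @export
latin_candidates <- function(word_blocks, config = taxmap_config()) {
  keep <- word_blocks[!(fold_name(word_blocks) %in% config$part_terms)]
  if (length(keep) == 0) return(character(0))
  per_block <- lapply(keep, apply_suffix, config = config)
  combos <- expand.grid(per_block, stringsAsFactors = FALSE)
  unique(apply(combos, 1, paste, collapse = " "))
}

#' Read a vernacular-name map
#'
#' Two-column TSV (vernacular name, scientific name); `#` starts a comment
#' line. Keys are case-folded.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: folded vernacular -> scientific name.
#' @export
read_vernacular_map <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) return(setNames(character(0), character(0)))
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  if (any(!nzchar(parts[, 2]))) abort("vernacular map: lines must have two tab-separated columns")
  setNames(stringr::str_trim(parts[, 2]), fold_name(stringr::str_trim(parts[, 1])))
}

#' Substitute a curated vernacular name
#'
#' Whole-string, case-folded lookup against a curated vernacular -> scientific
#' name map; unmatched inputs pass through unchanged.
#'
#' @param raw Raw input string.
#' @param vmap Named character vector as returned by [read_vernacular_map()],
#'   or `NULL`.
#' @return List with elements `name` (possibly substituted string) and
#'   `applied` (logical).
#' @export
apply_vernacular <- function(raw, vmap = NULL) {
  if (is.null(vmap) || length(vmap) == 0) {
    return(list(name = raw, applied = FALSE))
  }
  key <- fold_name(stringr::str_trim(raw))
  if (key %in% names(vmap)) {
    list(name = unname(vmap[[key]]), applied = TRUE)
  } else {
    list(name = raw, applied = FALSE)
  }
}

# Full preprocessing of one raw query into the structure the cascade uses.
name_query <- function(raw, config = taxmap_config(), vernacular = NULL) {
  vern <- apply_vernacular(raw, vernacular)
  normalized <- tryCatch(
    simple_correct(vern$name),
    taxmapr_content_free = function(e) ""
  )
  blocks <- if (nzchar(normalized)) strsplit(normalized, " ", fixed = TRUE)[[1]] else character(0)
  flags <- if (nzchar(normalized)) screen_semantics(normalized, config) else character(0)
  list(
    raw = raw,
    input = vern$name,
    normalized = normalized,
    word_blocks = blocks,
    flags = flags,
    vernacular_applied = vern$applied
  )
}
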