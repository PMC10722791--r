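# The six-stage mapping cascade. Each query is resolved against a target
# reference, consulting every loaded reference for synonym recursion and
# lineage-aware nearest-taxon assignment. Stage order: exact matching ->
# cross-reference recursion / nearest taxon -> rule-based dropout ->
# epithet-only edit-distance correction -> whole-string correction (Latin
# declension first) -> partial mapping. See status_codes() for the code
# table.

match_result <- function(status_code, taxon_ids = character(0),
                         matched_name = NA_character_,
                         matched_rank = NA_character_,
                         distance = 0L, stage = NA_character_) {
  list(status_code = as.integer(status_code), taxon_ids = taxon_ids,
       matched_name = matched_name, matched_rank = matched_rank,
       distance = as.integer(distance), stage = stage)
}

ranks_of <- function(ref, taxon_ids) {
  vapply(taxon_ids, function(id) {
    n <- ref_node(ref, id)
    if (is.null(n)) NA_character_ else n$rank
  }, character(1), USE.NAMES = FALSE)
}

#' Exact matching of a query against one reference
#'
#' Tries the raw string, then its case-folded form, then the
#' simple-corrected form against the reference's name index (canonical
#' names and synonyms). Canonical hits shadow synonym hits on the same key;
#' several distinct taxa on one key yield the homonym code.
#'
#' @param query A raw name string or the result of an internal
#'   preprocessing step.
#' @param ref A `taxmap_reference`.
#' @param config A [taxmap_config()].
#' @return A match-result list (`status_code`, `taxon_ids`, `matched_name`,
#'   `matched_rank`, `distance`, `stage`); status 1000 when nothing matches.
#' @export
exact_match <- function(query, ref, config = taxmap_config()) {
  q <- if (is.character(query)) query else query$input
  normalized <- if (is.character(query)) {
    tryCatch(simple_correct_one(q), taxmapr_content_free = function(e) "")
  } else {
    query$normalized
  }
  try_key <- function(key, raw_equal_code, fallback_code) {
    hits <- ref_lookup(ref, key)
    if (nrow(hits) == 0) return(NULL)
    canon <- hits[!hits$is_synonym, ]
    use <- if (nrow(canon) > 0) canon else hits
    ids <- sort(unique(use$taxon_id))
    is_syn <- all(use$is_synonym)
    if (length(ids) > 1) {
      return(match_result(5L, ids, use$display[[1]],
                          paste(unique(ranks_of(ref, ids)), collapse = "|"),
                          stage = "exact"))
    }
    code <- if (any(use$display == q)) raw_equal_code + is_syn else fallback_code + is_syn
    if (code %in% c(4L, 5L) && is_syn) code <- 4L  # case-insensitive variant, synonym or not
    match_result(code, ids, use$display[[1]], ranks_of(ref, ids), stage = "exact")
  }
  res <- try_key(fold_name(stringr::str_trim(q)), 0L, 4L)
  if (!is.null(res)) return(res)
  if (nzchar(normalized) && fold_name(normalized) != fold_name(stringr::str_trim(q))) {
    res <- try_key(fold_name(normalized), 2L, 2L)
    if (!is.null(res)) {
      if (res$status_code %in% c(0L, 1L)) res$status_code <- res$status_code + 2L
      return(res)
    }
  }
  match_result(1000L, stage = "exact")
}

#' Cross-reference synonym recursion
#'
#' For a query that matched exactly in at least one non-target reference but
#' not in the target, tries the canonical name and all synonyms of every
#' matched node against the target's name index. A unique target taxon gets
#' status 6, several distinct taxa status 8.
#'
#' @param matched_nodes A list of node rows (one-row tibbles) matched in
#'   other references.
#' @param target_ref The target `taxmap_reference`.
#' @return A match-result list; status 1000 when recursion finds nothing.
#' @export
recursive_match <- function(matched_nodes, target_ref) {
  hit_ids <- character(0)
  hit_name <- NA_character_
  for (node in matched_nodes) {
    cand_names <- c(node$canonical_name, node$synonyms[[1]])
    for (nm in cand_names) {
      hits <- ref_lookup(target_ref, fold_name(nm))
      if (nrow(hits) > 0) {
        if (is.na(hit_name)) hit_name <- hits$display[[1]]
        hit_ids <- c(hit_ids, hits$taxon_id)
      }
    }
  }
  hit_ids <- sort(unique(hit_ids))
  if (length(hit_ids) == 0) return(match_result(1000L, stage = "recursive"))
  code <- if (length(hit_ids) == 1) 6L else 8L
  match_result(code, hit_ids, hit_name,
               paste(unique(ranks_of(target_ref, hit_ids)), collapse = "|"),
               stage = "recursive")
}

# domain label of a node: canonical name of its highest-rank named ancestor
# at kingdom/domain tier; falls back to the first lineage element.
domain_label <- function(ref, node) {
  lin <- node$lineage[[1]]
  lranks <- node$lineage_ranks[[1]]
  if (!is.na(rank_tier(node$rank)) && rank_tier(node$rank) >= 7L) {
    return(node$canonical_name)
  }
  if (length(lin) == 0) return(NA_character_)
  tiers <- rank_tier(lranks)
  top <- which(!is.na(tiers) & tiers >= 7L)
  pick <- if (length(top) > 0) top[[1]] else 1L
  n <- ref_node(ref, lin[[pick]])
  if (is.null(n)) NA_character_ else n$canonical_name
}

# choose among homonymic target taxa the one whose domain agrees with the
# source node's domain; ties and misses fall back to the lowest taxon id.
pick_domain_consistent <- function(ids, target_ref, source_domain) {
  if (length(ids) == 1 || is.na(source_domain)) return(sort(ids)[[1]])
  doms <- vapply(sort(ids), function(id) {
    n <- ref_node(target_ref, id)
    if (is.null(n)) NA_character_ else domain_label(target_ref, n)
  }, character(1))
  agree <- names(doms)[!is.na(doms) & fold_name(doms) == fold_name(source_domain)]
  if (length(agree) > 0) agree[[1]] else sort(ids)[[1]]
}

#' Lineage-based nearest-taxon mapping
#'
#' Walks the lineage of a node matched in another reference from tip to
#' root, trying each ancestor's canonical name (then synonyms) against the
#' target reference. The first (lowest-rank) resolvable ancestor is
#' returned, with a status code keyed to its rank tier (10 species ... 17
#' domain, 18 unranked). When an ancestor name is a homonym in the target,
#' the candidate whose own kingdom/domain label agrees with the source
#' lineage is preferred, so cross-domain hemihomonyms never capture the
#' query.
#'
#' @param matched_nodes List of node rows matched in other references.
#' @param source_refs List of the `taxmap_reference`s those nodes came from
#'   (parallel to `matched_nodes`).
#' @param target_ref The target reference.
#' @return A match-result list; status 1000 when no ancestor resolves.
#' @export
nearest_taxon <- function(matched_nodes, source_refs, target_ref) {
  best <- NULL
  best_tier <- Inf
  for (i in seq_along(matched_nodes)) {
    node <- matched_nodes[[i]]
    src <- source_refs[[i]]
    src_domain <- domain_label(src, node)
    lin <- node$lineage[[1]]
    lranks <- node$lineage_ranks[[1]]
    # tip-to-root ancestor walk; unranked ancestors inherit the tier of the
    # nearest ranked descendant (start from the node's own tier)
    inherited <- rank_tier(node$rank)
    for (j in rev(seq_along(lin))) {
      anc <- ref_node(src, lin[[j]])
      if (is.null(anc)) next
      tier <- rank_tier(lranks[[j]])
      if (is.na(tier)) tier <- inherited else inherited <- tier
      cand_names <- c(anc$canonical_name, anc$synonyms[[1]])
      hit_made <- FALSE
      for (nm in cand_names) {
        hits <- ref_lookup(target_ref, fold_name(nm))
        if (nrow(hits) == 0) next
        id <- pick_domain_consistent(unique(hits$taxon_id), target_ref, src_domain)
        hit_node <- ref_node(target_ref, id)
        hit_tier <- rank_tier(hit_node$rank)
        eff_tier <- if (!is.na(hit_tier)) hit_tier else if (!is.na(tier)) tier else 9L
        if (eff_tier < best_tier) {
          best_tier <- eff_tier
          best <- match_result(tier_status(if (eff_tier <= 8) eff_tier else NA),
                               id, hit_node$canonical_name, hit_node$rank,
                               stage = "nearest")
        }
        hit_made <- TRUE
        break
      }
      if (hit_made) break  # first resolvable ancestor is the lowest rank for this node
    }
  }
  if (is.null(best)) match_result(1000L, stage = "nearest") else best
}

#' Candidate pool for epithet-only correction
#'
#' Names in the reference sharing the query's first word-block, narrowed by
#' length (|difference| <= `max_d`) and character composition (multiset
#' difference <= 2 * `max_d`).
#'
#' @param query Normalized query string.
#' @param ref A `taxmap_reference`.
#' @param max_d Maximum edit distance under consideration.
#' @return The matching slice of the reference's indexed-name table.
#' @export
candidate_pool <- function(query, ref, max_d = 3L) {
  fb <- first_block(fold_name(query))
  ids <- ref$genus_index[[fb]]
  if (is.null(ids)) return(ref$names_tbl[0, ])
  pool <- ref$names_tbl[ref$names_tbl$first_block == fb, ]
  qf <- fold_name(query)
  keep <- abs(nchar(pool$folded) - nchar(qf)) <= max_d &
    .charcomp_diff(qf, pool$folded) <= 2L * max_d
  pool[keep, ]
}

best_distance_match <- function(query, pool, max_d, codes) {
  # codes = c(unique_canonical, unique_synonym, tie)
  if (nrow(pool) == 0) return(match_result(1000L))
  qf <- fold_name(query)
  d <- .osa_pool_dist(qf, pool$folded, as.integer(max_d))
  ok <- d <= max_d
  if (!any(ok)) return(match_result(1000L))
  dmin <- min(d[ok])
  winners <- pool[d == dmin, ]
  ids <- sort(unique(winners$taxon_id))
  if (length(ids) > 1) {
    return(match_result(codes[[3]], ids, winners$display[[1]],
                        NA_character_, distance = dmin))
  }
  w <- winners[order(winners$is_synonym), ][1, ]
  code <- if (w$is_synonym) codes[[2]] else codes[[1]]
  match_result(code, ids, w$display, NA_character_, distance = dmin)
}

#' Epithet-only spelling correction
#'
#' Damerau-Levenshtein correction restricted to names sharing the query's
#' first word-block (the genus bucket). The minimal-distance candidate
#' within `max_d` wins; ties across distinct taxa are reported under the
#' tie code.
#'
#' @inheritParams candidate_pool
#' @return A match-result list with status 20/21/22, or 1000 when no
#'   candidate is within `max_d`.
#' @export
correct_epithet <- function(query, ref, max_d = 3L) {
  pool <- candidate_pool(query, ref, max_d)
  res <- best_distance_match(query, pool, max_d, c(20L, 21L, 22L))
  if (res$status_code != 1000L) {
    res$matched_rank <- paste(unique(ranks_of(ref, res$taxon_ids)), collapse = "|")
    res$stage <- "epithet"
  }
  res
}

#' Whole-string correction with Latin declension reconstruction
#'
#' First tries the declension candidates of the query as exact hits in the
#' target (status 30 unique / 31 several taxa), then falls back to
#' whole-string Damerau-Levenshtein over the target's full indexed-name
#' list, pruned by length and character composition (status 32/33/34).
#'
#' @inheritParams candidate_pool
#' @param config A [taxmap_config()].
#' @return A match-result list; status 1000 when both routes fail.
#' @export
correct_whole <- function(query, ref, max_d = 3L, config = taxmap_config()) {
  blocks <- strsplit(query, " ", fixed = TRUE)[[1]]
  cands <- setdiff(latin_candidates(blocks, config), query)
  decl_ids <- character(0)
  decl_name <- NA_character_
  for (cand in cands) {
    hits <- ref_lookup(ref, fold_name(cand))
    if (nrow(hits) > 0) {
      if (is.na(decl_name)) decl_name <- hits$display[[1]]
      decl_ids <- c(decl_ids, hits$taxon_id)
    }
  }
  decl_ids <- sort(unique(decl_ids))
  if (length(decl_ids) > 0) {
    code <- if (length(decl_ids) == 1) 30L else 31L
    return(match_result(code, decl_ids, decl_name,
                        paste(unique(ranks_of(ref, decl_ids)), collapse = "|"),
                        stage = "whole"))
  }
  qf <- fold_name(query)
  pool <- ref$names_tbl
  keep <- abs(nchar(pool$folded) - nchar(qf)) <= max_d
  pool <- pool[keep, ]
  res <- best_distance_match(query, pool, max_d, c(32L, 33L, 34L))
  if (res$status_code != 1000L) {
    res$matched_rank <- paste(unique(ranks_of(ref, res$taxon_ids)), collapse = "|")
    res$stage <- "whole"
  }
  res
}

# strip strain/abbreviation tokens, keeping plausible name word-blocks
strain_residue <- function(blocks, config) {
  keep <- !grepl("[0-9]", blocks) &
    !(fold_name(blocks) %in% config$infra_abbrev) &
    !grepl("^[A-Z0-9-]{2,}$", blocks)  # all-caps isolate codes
  blocks[keep]
}

#' Routing for strain-coded, cf./aff. and genus-only queries
#'
#' Strips strain tokens and nomenclatural abbreviations, exact-matches the
#' remaining binomial (or generic epithet) and returns a species- or
#' genus-level container: status 40 for strain-like queries, 41/42 for
#' cf./aff. (which return a higher taxon of the stripped match, honouring
#' the abbreviation's meaning), 43 for genus-only forms. Edit-distance
#' correction is deliberately bypassed: strain codes are string-similar but
#' taxonomically unrelated.
#'
#' @param query A preprocessed query (list from the internal preprocessor) or
#'   a raw string.
#' @param target_ref The target reference.
#' @param config A [taxmap_config()].
#' @return A match-result list; status 1000 when the residue is unmappable.
#' @export
strain_nearest <- function(query, target_ref, config = taxmap_config()) {
  if (is.character(query)) query <- name_query(query, config)
  blocks <- strain_residue(query$word_blocks, config)
  code <- if ("confer" %in% query$flags) 41L
          else if ("affinis" %in% query$flags) 42L
          else if ("strain_like" %in% query$flags) 40L
          else 43L
  want_parent <- code %in% c(41L, 42L)
  try_seqs <- list()
  if (length(blocks) >= 1) try_seqs <- c(try_seqs, list(blocks))
  if (length(blocks) > 1) try_seqs <- c(try_seqs, list(blocks[[1]]))
  for (bl in try_seqs) {
    key <- fold_name(paste(bl, collapse = " "))
    hits <- ref_lookup(target_ref, key)
    if (nrow(hits) == 0) next
    ids <- sort(unique(hits$taxon_id))
    id <- ids[[1]]
    node <- ref_node(target_ref, id)
    if (want_parent) {
      # the abbreviation asserts similarity, not identity: report a higher
      # taxon from the match's lineage
      lin <- node$lineage[[1]]
      if (length(lin) > 0) {
        parent <- ref_node(target_ref, lin[[length(lin)]])
        if (!is.null(parent)) node <- parent
      }
    }
    return(match_result(code, node$taxon_id, node$canonical_name, node$rank,
                        stage = "strain"))
  }
  match_result(1000L, stage = "strain")
}

#' Partial mapping on prefix word-blocks
#'
#' Drops the final word-block repeatedly and exact-matches each prefix
#' against the target; the longest matching prefix wins (status 100). When
#' every prefix fails the query is unmapped (status 1000).
#'
#' @param query Normalized query string.
#' @param target_ref The target reference.
#' @return A match-result list.
#' @export
partial_map <- function(query, target_ref) {
  blocks <- strsplit(query, " ", fixed = TRUE)[[1]]
  if (length(blocks) > 1) {
    for (len in rev(seq_len(length(blocks) - 1))) {
      key <- fold_name(paste(blocks[seq_len(len)], collapse = " "))
      hits <- ref_lookup(target_ref, key)
      if (nrow(hits) > 0) {
        id <- sort(unique(hits$taxon_id))[[1]]
        node <- ref_node(target_ref, id)
        return(match_result(100L, id, node$canonical_name, node$rank,
                            stage = "partial"))
      }
    }
  }
  match_result(1000L, stage = "partial")
}

empty_other <- function() {
  tibble::tibble(reference = character(0), status_code = integer(0),
                 taxon_ids = character(0), matched_name = character(0))
}

record_row <- function(q, target, res, other = empty_other()) {
  tibble::tibble(
    query = q$raw,
    normalized = q$normalized,
    flags = list(q$flags),
    vernacular_applied = q$vernacular_applied,
    target = target,
    status_code = res$status_code,
    taxon_ids = list(res$taxon_ids),
    taxon_id = if (length(res$taxon_ids) > 0) res$taxon_ids[[1]] else NA_character_,
    matched_name = res$matched_name,
    matched_rank = res$matched_rank,
    distance = res$distance,
    stage = res$stage %||% NA_character_,
    other_matches = list(other)
  )
}

#' Map one scientific-name string to a target reference
#'
#' Runs the full cascade for a single raw query: vernacular substitution,
#' simple correction and semantic screening, then exact matching,
#' cross-reference synonym recursion, lineage-based nearest-taxon mapping,
#' rule-based dropout, epithet-only and whole-string edit-distance
#' correction (with Latin declension reconstruction), and partial mapping.
#' Every input yields exactly one record with one status code; best exact
#' matches in the non-target references are carried along in
#' `other_matches`.
#'
#' @param raw Raw name string.
#' @param refset A `taxmap_refset`.
#' @param target Name of the target reference within `refset`.
#' @param vernacular Optional vernacular map ([read_vernacular_map()]).
#' @return One-row tibble (see [map_names()] for the column set).
#' @examples
#' \dontrun{
#' map_name("Panax ginseng C.A.Mey.", refset, target = "ncbi")
#' }
#' @export
map_name <- function(raw, refset, target, vernacular = NULL) {
  config <- refset$config
  if (!target %in% names(refset$references)) {
    abort(paste0("target reference '", target, "' is not loaded"),
          class = "taxmapr_config_error")
  }
  query <- name_query(raw, config, vernacular)
  target_ref <- refset$references[[target]]
  if (!nzchar(query$normalized)) {
    return(record_row(query, target, match_result(99L, stage = "dropout")))
  }
  dropout <- grep("^dropout:", query$flags, value = TRUE)
  if (length(dropout) > 0) {
    kw <- sub("^dropout:", "", dropout[[1]])
    return(record_row(query, target,
                      match_result(dropout_status(kw, config), stage = "dropout")))
  }
  if ("hybrid" %in% query$flags) {
    return(record_row(query, target, match_result(95L, stage = "dropout")))
  }
  # exact matching in every reference (also feeds the other-matches columns)
  ex <- lapply(refset$references, exact_match, query = query, config = config)
  other <- purrr::map_dfr(setdiff(names(ex), target), function(rn) {
    r <- ex[[rn]]
    tibble::tibble(reference = rn, status_code = r$status_code,
                   taxon_ids = paste(r$taxon_ids, collapse = "|"),
                   matched_name = r$matched_name)
  })
  if (nrow(other) == 0) other <- empty_other()
  if (ex[[target]]$status_code != 1000L) {
    return(record_row(query, target, ex[[target]], other))
  }
  matched_elsewhere <- names(ex)[vapply(ex, function(r) r$status_code != 1000L, logical(1))]
  matched_elsewhere <- setdiff(matched_elsewhere, target)
  if (length(matched_elsewhere) > 0) {
    nodes <- list()
    srcs <- list()
    for (rn in matched_elsewhere) {
      ref <- refset$references[[rn]]
      for (id in ex[[rn]]$taxon_ids) {
        n <- ref_node(ref, id)
        if (!is.null(n)) {
          nodes <- c(nodes, list(n))
          srcs <- c(srcs, list(ref))
        }
      }
    }
    res <- recursive_match(nodes, target_ref)
    if (res$status_code == 1000L) res <- nearest_taxon(nodes, srcs, target_ref)
    if (res$status_code != 1000L) return(record_row(query, target, res, other))
  }
  # genus-only routing only applies to explicit "<Genus> sp." forms; a bare
  # unmatched single word-block is more likely a damaged name and belongs to
  # the correction stages
  explicit_sp <- any(fold_name(query$word_blocks) %in% c("sp.", "spp.", "sp", "spp"))
  special <- intersect(c("confer", "affinis", "strain_like"), query$flags)
  if (length(special) > 0 || explicit_sp) {
    res <- strain_nearest(query, target_ref, config)
    if (res$status_code != 1000L) return(record_row(query, target, res, other))
  } else {
    res <- correct_epithet(query$normalized, target_ref, config$max_d)
    if (res$status_code != 1000L) return(record_row(query, target, res, other))
    res <- correct_whole(query$normalized, target_ref, config$max_d, config)
    if (res$status_code != 1000L) return(record_row(query, target, res, other))
  }
  record_row(query, target, partial_map(query$normalized, target_ref), other)
}

#' Map a batch of scientific names
#'
#' Data-frame-first batch variant of [map_name()]: takes a data frame with a
#' name column (or a bare character vector) and returns one mapping record
#' per input row.
#'
#' @param data Data frame with a column of raw name strings, or a character
#'   vector.
#' @param refset A `taxmap_refset`.
#' @param target Name of the target reference.
#' @param name_col Column holding the names (default `"name"`).
#' @param vernacular Optional vernacular map.
#' @return Tibble with columns `query`, `normalized`, `flags`,
#'   `vernacular_applied`, `target`, `status_code`, `taxon_ids` (list),
#'   `taxon_id` (first id), `matched_name`, `matched_rank`, `distance`,
#'   `stage`, `other_matches` (list of per-reference best exact matches).
#' @export
map_names <- function(data, refset, target, name_col = "name",
                      vernacular = NULL) {
  nms <- if (is.data.frame(data)) {
    if (!name_col %in% names(data)) {
      abort(paste0("column '", name_col, "' not found in data"))
    }
    data[[name_col]]
  } else {
    as.character(data)
  }
  purrr::map_dfr(nms, map_name, refset = refset, target = target,
                 vernacular = vernacular)
}
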