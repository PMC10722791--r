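# Standardisation and integration of species-compound occurrence tables:
# names are mapped to the target reference, structures are canonicalised by
# an injected normaliser, and identical standardised pairs from different
# sources are merged with their support (number of independent source
# databases) recorded.

species_level_unique <- function(rec) {
  if (rec$status_code %in% multi_match_codes()) return(FALSE)
  if (length(rec$taxon_ids[[1]]) != 1) return(FALSE)
  rank <- rec$matched_rank
  if (is.na(rank)) return(FALSE)
  tier <- rank_tier(rank)
  !is.na(tier) && tier <= 1L
}

#' Integrate species-compound pair tables
#'
#' Maps every distinct name through the full cascade against the target
#' reference, keeps pairs whose name resolves uniquely at species level or
#' better, canonicalises structures through `structure_normalizer`, and
#' merges identical (taxon, structure) pairs across sources, unioning the
#' source labels. Pairs that fail name mapping, map above species level,
#' map ambiguously, or whose structure fails normalisation are excluded and
#' counted, never fatal.
#'
#' @param pair_tables Named list of per-source data frames with columns
#'   `name` and `structure`.
#' @param refset A `taxmap_refset`.
#' @param target Target reference name.
#' @param structure_normalizer Function string -> canonical string (an
#'   injected contract; identity by default). Return `NA` or signal an
#'   error to reject a structure.
#' @param vernacular Optional vernacular map used during name mapping.
#' @return List of class `taxmap_np`: `pairs` (tibble `taxon_id`,
#'   `canonical_name`, `structure`, `sources`, `support`), `excluded`
#'   (tibble `reason`, `n`), `n_input` (total input pair rows).
#' @export
integrate_pairs <- function(pair_tables, refset, target,
                            structure_normalizer = identity,
                            vernacular = NULL) {
  stopifnot(is.list(pair_tables), !is.null(names(pair_tables)))
  long <- purrr::imap_dfr(pair_tables, function(tbl, src) {
    if (nrow(tbl) == 0) return(tibble::tibble(source = character(0),
                                              name = character(0),
                                              structure = character(0)))
    tibble::tibble(source = src, name = tbl$name, structure = tbl$structure)
  })
  if (nrow(long) == 0) {
    return(structure(list(
      pairs = tibble::tibble(taxon_id = character(0), canonical_name = character(0),
                             structure = character(0), sources = character(0),
                             support = integer(0)),
      excluded = tibble::tibble(reason = character(0), n = integer(0)),
      n_input = 0L), class = "taxmap_np"))
  }
  distinct_names <- unique(long$name)
  recs <- lapply(distinct_names, function(nm) {
    map_name(nm, refset, target, vernacular = vernacular)
  })
  names(recs) <- distinct_names
  keep_tax <- vapply(recs, function(r) {
    if (species_level_unique(r)) r$taxon_id else NA_character_
  }, character(1))
  long$taxon_id <- unname(keep_tax[long$name])
  long$norm_structure <- vapply(long$structure, function(s) {
    tryCatch({
      out <- structure_normalizer(s)
      if (is.null(out) || length(out) != 1 || is.na(out)) NA_character_ else as.character(out)
    }, error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  name_failed <- is.na(long$taxon_id)
  struct_failed <- !name_failed & is.na(long$norm_structure)
  kept <- long[!name_failed & !struct_failed, ]
  canon_of <- function(ids) {
    ref <- refset$references[[target]]
    vapply(ids, function(id) ref_node(ref, id)$canonical_name, character(1),
           USE.NAMES = FALSE)
  }
  pairs <- kept |>
    dplyr::group_by(taxon_id = .data$taxon_id, structure = .data$norm_structure) |>
    dplyr::summarise(
      sources = paste(sort(unique(.data$source)), collapse = "|"),
      support = dplyr::n_distinct(.data$source),
      .groups = "drop"
    ) |>
    dplyr::mutate(canonical_name = canon_of(.data$taxon_id), .after = "taxon_id") |>
    dplyr::arrange(.data$taxon_id, .data$structure)
  excluded <- tibble::tibble(
    reason = c("name_not_species_level_unique", "structure_normalization_failed",
               "merged_duplicates"),
    n = c(sum(name_failed), sum(struct_failed),
          nrow(kept) - nrow(pairs))
  )
  structure(list(pairs = pairs, excluded = excluded, n_input = nrow(long)),
            class = "taxmap_np")
}

#' @export
print.taxmap_np <- function(x, ...) {
  cat("<taxmap_np> ", nrow(x$pairs), " unified pairs from ", x$n_input,
      " input rows\n", sep = "")
  invisible(x)
}

#' Support histogram of unified pairs
#'
#' @param np A `taxmap_np` from [integrate_pairs()], or its `pairs` tibble.
#' @return Tibble: `support`, `n`; `sum(n)` equals the number of unified
#'   pairs.
#' @export
support_histogram <- function(np) {
  pairs <- if (inherits(np, "taxmap_np")) np$pairs else np
  pairs |>
    dplyr::count(.data$support, name = "n") |>
    dplyr::arrange(.data$support)
}

#' Write the unified pair table and exclusion report
#'
#' @param np A `taxmap_np`.
#' @param path Output TSV path for the unified pairs; the exclusion report
#'   goes to `<path>.exclusions.tsv`.
#' @return Invisibly, the two paths.
#' @export
write_np_report <- function(np, path) {
  readr::write_tsv(np$pairs, path, progress = FALSE)
  excl_path <- paste0(path, ".exclusions.tsv")
  readr::write_tsv(np$excluded, excl_path, progress = FALSE)
  invisible(c(path, excl_path))
}
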