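# Cross-reference discrepancy diagnostics: canonical/synonym disputes,
# hemihomonyms (one name in several domains of life), rank disagreements and
# reference-overlap counts. All functions compare names after case-folding
# (and the parsers have already stripped authority text), consistent with
# the mapper.

# long table of every indexed name across the set
all_names_long <- function(refset) {
  purrr::map_dfr(refset$references, function(ref) {
    tbl <- ref$names_tbl
    node_idx <- match(tbl$taxon_id, ref$nodes$taxon_id)
    tibble::tibble(
      reference = ref$name,
      name = tbl$folded,
      display = tbl$display,
      taxon_id = tbl$taxon_id,
      is_synonym = tbl$is_synonym,
      rank = ref$nodes$rank[node_idx],
      domain = vapply(node_idx, function(i) {
        domain_label(ref, ref$nodes[i, ])
      }, character(1))
    )
  })
}

#' Classify canonical names as universal, disputed or unique
#'
#' Every canonical name in the set is classified: *disputed* when it also
#' appears as a synonym of some taxon (in another reference or within the
#' same one), *universal* when it appears as a canonical name in at least
#' two references and never as a synonym, *unique* when a single reference
#' knows it at all.
#'
#' @param refset A `taxmap_refset` with at least two references (with a
#'   single reference only intra-reference disputes are defined and a
#'   warning is issued).
#' @return Tibble with one row per canonical name: `name`, one `role_<ref>`
#'   column per reference (`canonical`/`synonym`/`both`/`absent`),
#'   `classification`, `domains`, `ranks`.
#' @export
canonical_status_classify <- function(refset) {
  long <- all_names_long(refset)
  single_ref <- length(refset$references) < 2
  if (single_ref) {
    warn("single reference loaded: only intra-reference disputes are defined")
  }
  roles <- long |>
    dplyr::group_by(.data$name, .data$reference) |>
    dplyr::summarise(
      role = dplyr::case_when(
        any(!.data$is_synonym) & any(.data$is_synonym) ~ "both",
        any(!.data$is_synonym) ~ "canonical",
        TRUE ~ "synonym"
      ),
      .groups = "drop"
    )
  canon_names <- unique(roles$name[roles$role %in% c("canonical", "both")])
  per_name <- roles |>
    dplyr::filter(.data$name %in% canon_names) |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      n_canonical = sum(.data$role %in% c("canonical", "both")),
      any_synonym = any(.data$role %in% c("synonym", "both")),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      classification = dplyr::case_when(
        .data$any_synonym ~ "disputed",
        single_ref ~ NA_character_,
        .data$n_canonical >= 2 ~ "universal",
        TRUE ~ "unique"
      )
    )
  extras <- long |>
    dplyr::filter(.data$name %in% canon_names) |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      domains = paste(sort(unique(stats::na.omit(.data$domain))), collapse = "|"),
      ranks = paste(sort(unique(stats::na.omit(.data$rank))), collapse = "|"),
      .groups = "drop"
    )
  wide <- roles |>
    dplyr::filter(.data$name %in% canon_names) |>
    tidyr::pivot_wider(names_from = "reference", values_from = "role",
                       names_prefix = "role_", values_fill = "absent")
  per_name |>
    dplyr::select("name", "classification") |>
    dplyr::left_join(wide, by = "name") |>
    dplyr::left_join(extras, by = "name") |>
    dplyr::arrange(.data$name)
}

#' Scan for hemihomonyms
#'
#' Names (canonical or synonym) borne by taxa in at least two distinct
#' top-rank lineages (kingdom/domain labels) anywhere in the set. Identical
#' names inside one domain (e.g. two congeneric species) are not reported.
#'
#' @param refset A `taxmap_refset`.
#' @return Tibble: `name`, `domains` (sorted, pipe-joined), `n_domains`,
#'   `references`.
#' @export
hemihomonym_scan <- function(refset) {
  all_names_long(refset) |>
    dplyr::filter(!is.na(.data$domain)) |>
    dplyr::distinct(.data$name, domain = fold_name(.data$domain), .data$reference) |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      domains = paste(sort(unique(.data$domain)), collapse = "|"),
      n_domains = dplyr::n_distinct(.data$domain),
      references = paste(sort(unique(.data$reference)), collapse = "|"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_domains >= 2) |>
    dplyr::arrange(.data$name)
}

#' Scan for rank disagreements
#'
#' Canonical names whose bearer taxa carry at least two distinct rank
#' labels, reported separately for disagreements observable inside one
#' reference (`scope = "within"`) and only across references
#' (`scope = "cross"`).
#'
#' @param refset A `taxmap_refset`.
#' @return Tibble: `name`, `scope`, `ranks`, `references`.
#' @export
rank_disagreement_scan <- function(refset) {
  canon <- all_names_long(refset) |>
    dplyr::filter(!.data$is_synonym) |>
    dplyr::distinct(.data$name, .data$reference, .data$rank)
  within <- canon |>
    dplyr::group_by(.data$name, .data$reference) |>
    dplyr::filter(dplyr::n_distinct(.data$rank) >= 2) |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      scope = "within",
      ranks = paste(sort(unique(.data$rank)), collapse = "|"),
      references = paste(sort(unique(.data$reference)), collapse = "|"),
      .groups = "drop"
    )
  cross <- canon |>
    dplyr::group_by(.data$name) |>
    dplyr::filter(dplyr::n_distinct(.data$rank) >= 2) |>
    dplyr::summarise(
      scope = "cross",
      ranks = paste(sort(unique(.data$rank)), collapse = "|"),
      references = paste(sort(unique(.data$reference)), collapse = "|"),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$name %in% within$name)
  dplyr::bind_rows(within, cross) |> dplyr::arrange(.data$name)
}

#' Canonical-name overlap counts across references
#'
#' For every canonical name in the union, counts in how many references it
#' appears as a canonical name, then tabulates names per multiplicity. The
#' counts sum to the size of the union.
#'
#' @param refset A `taxmap_refset`.
#' @return Tibble: `multiplicity` (1..number of references), `n`.
#' @export
overlap_counts <- function(refset) {
  canon <- all_names_long(refset) |>
    dplyr::filter(!.data$is_synonym) |>
    dplyr::distinct(.data$name, .data$reference)
  canon |>
    dplyr::count(.data$name, name = "multiplicity") |>
    dplyr::count(.data$multiplicity, name = "n") |>
    dplyr::arrange(.data$multiplicity)
}

#' Write the per-name diagnostic report
#'
#' @param refset A `taxmap_refset`.
#' @param path Output TSV path.
#' @return The classification tibble, invisibly.
#' @export
write_diagnostics_report <- function(refset, path) {
  tbl <- canonical_status_classify(refset)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(tbl)
}
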