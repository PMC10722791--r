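# Tidier and plotting methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a reference set into its node table
#'
#' @param x A `taxmap_refset`.
#' @param ... Unused.
#' @return Tibble with one row per accepted taxon across all references:
#'   `reference`, `taxon_id`, `canonical_name`, `rank`, `parent_id`,
#'   `status`, `n_synonyms`, `depth`.
#' @export
tidy.taxmap_refset <- function(x, ...) {
  purrr::map_dfr(x$references, function(ref) {
    tibble::tibble(
      reference = ref$name,
      taxon_id = ref$nodes$taxon_id,
      canonical_name = ref$nodes$canonical_name,
      rank = ref$nodes$rank,
      parent_id = ref$nodes$parent_id,
      status = ref$nodes$status,
      n_synonyms = lengths(ref$nodes$synonyms),
      depth = lengths(ref$nodes$lineage)
    )
  })
}

#' One-row summary of a reference set
#'
#' @param x A `taxmap_refset`.
#' @param ... Unused.
#' @return Tibble: `n_references`, `n_taxa`, `n_indexed_names`,
#'   `n_synonyms`, `n_valid_names` (size of the pooled valid-name list).
#' @export
glance.taxmap_refset <- function(x, ...) {
  tibble::tibble(
    n_references = length(x$references),
    n_taxa = sum(vapply(x$references, function(r) nrow(r$nodes), integer(1))),
    n_indexed_names = sum(vapply(x$references, function(r) nrow(r$names_tbl), integer(1))),
    n_synonyms = sum(vapply(x$references, function(r) sum(r$names_tbl$is_synonym), integer(1))),
    n_valid_names = length(ls(x$valid_names))
  )
}

#' Tidy an integrated pair set
#'
#' @param x A `taxmap_np`.
#' @param ... Unused.
#' @return The unified pair tibble.
#' @export
tidy.taxmap_np <- function(x, ...) x$pairs

#' One-row summary of an integrated pair set
#'
#' @param x A `taxmap_np`.
#' @param ... Unused.
#' @return Tibble: `n_input`, `n_unified`, `n_excluded`, `n_species`,
#'   `n_structures`.
#' @export
glance.taxmap_np <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_unified = nrow(x$pairs),
    n_excluded = sum(x$excluded$n),
    n_species = dplyr::n_distinct(x$pairs$taxon_id),
    n_structures = dplyr::n_distinct(x$pairs$structure)
  )
}

#' Bar chart of the pair-support histogram
#'
#' @param object A `taxmap_np`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.taxmap_np <- function(object, ...) {
  h <- support_histogram(object)
  ggplot2::ggplot(h, ggplot2::aes(x = factor(.data$support), y = .data$n)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "Supporting source databases", y = "Species-compound pairs",
                  title = "Degree of support of unified pairs") +
    ggplot2::theme_minimal()
}

#' Bar chart of mapping outcomes by cascade stage
#'
#' @param records Mapping records from [map_names()].
#' @return A ggplot object.
#' @export
plot_status_summary <- function(records) {
  summary <- records |>
    dplyr::count(.data$stage, .data$status_code)
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$status_code), y = .data$n,
                               fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Status code", y = "Queries", fill = "Stage",
                  title = "Mapping outcomes") +
    ggplot2::theme_minimal()
}

#' Bar chart of canonical-name overlap across references
#'
#' @param refset A `taxmap_refset`.
#' @return A ggplot object.
#' @export
plot_overlap <- function(refset) {
  ggplot2::ggplot(overlap_counts(refset),
                  ggplot2::aes(x = factor(.data$multiplicity), y = .data$n)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = "References containing the name", y = "Canonical names",
                  title = "Canonical-name overlap") +
    ggplot2::theme_minimal()
}
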