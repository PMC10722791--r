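# Reference-dump parsing and indexing. Two dialects are supported: NCBI
# taxdump (names.dmp + nodes.dmp, fields separated by "\t|\t") and
# Darwin-Core-style taxon tables (the common core of CoL / EoL / GBIF
# checklist exports). Both are reduced to one node model: accepted taxa with
# synonyms attached, ranks, and materialised root->parent lineages.

DWC_REQUIRED <- c("taxonID", "scientificName", "taxonRank",
                  "parentNameUsageID", "acceptedNameUsageID", "taxonomicStatus")

NCBI_SYNONYM_CLASSES <- c("synonym", "equivalent name", "includes",
                          "genbank synonym")

# lenient authority stripping for names coming out of reference files
strip_authority <- function(x) {
  vapply(x, function(nm) {
    tryCatch(simple_correct_one(nm), taxmapr_content_free = function(e) stringr::str_squish(nm))
  }, character(1), USE.NAMES = FALSE)
}

read_dmp <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

walk_lineages <- function(ids, parent_of) {
  # iterative parent-chain walk with memoisation; cycles are a structural error
  done <- new.env(parent = emptyenv())
  for (id in ids) {
    if (!is.null(done[[id]])) next
    stack <- character(0)
    cur <- id
    anc <- character(0)
    repeat {
      if (!is.null(done[[cur]])) {
        anc <- c(done[[cur]], cur)  # cur resolved earlier; it is stack-top's parent
        break
      }
      if (cur %in% stack) {
        abort(paste0("cyclic parent chain involving taxon '", cur, "'"),
              class = "taxmapr_structural_error")
      }
      stack <- c(stack, cur)
      p <- parent_of[[cur]]
      if (is.null(p) || length(p) != 1 || is.na(p) || !nzchar(p) ||
          identical(p, cur) || is.null(parent_of[[p]])) {
        # cur is the root, or its parent is missing from this reference
        anc <- character(0)
        break
      }
      cur <- p
    }
    for (i in rev(seq_along(stack))) {
      done[[stack[[i]]]] <- anc
      anc <- c(anc, stack[[i]])
    }
  }
  lapply(ids, function(id) done[[id]])
}

finalize_nodes <- function(tbl) {
  parent_of <- as.list(setNames(tbl$parent_id, tbl$taxon_id))
  lin <- walk_lineages(tbl$taxon_id, parent_of)
  rank_of <- setNames(tbl$rank, tbl$taxon_id)
  tbl$lineage <- lin
  tbl$lineage_ranks <- lapply(lin, function(ids) unname(rank_of[ids]))
  tbl
}

parse_ncbi_taxdump <- function(files) {
  if (is.null(files$names) || is.null(files$nodes)) {
    abort("ncbi-taxdump dialect needs both 'names' and 'nodes' files",
          class = "taxmapr_dialect_error")
  }
  nd <- read_dmp(files$nodes)
  if (any(lengths(nd) < 3)) {
    abort("nodes.dmp: missing column 'rank' (need tax_id | parent | rank)",
          class = "taxmapr_dialect_error")
  }
  nm <- read_dmp(files$names)
  if (any(lengths(nm) < 4)) {
    abort("names.dmp: missing column 'name class' (need tax_id | name | unique | class)",
          class = "taxmapr_dialect_error")
  }
  nodes <- tibble::tibble(
    taxon_id = vapply(nd, `[[`, character(1), 1),
    parent_id = vapply(nd, `[[`, character(1), 2),
    rank = vapply(nd, `[[`, character(1), 3)
  )
  nodes$parent_id[nodes$parent_id == nodes$taxon_id] <- NA_character_
  names_tbl <- tibble::tibble(
    taxon_id = vapply(nm, `[[`, character(1), 1),
    name = vapply(nm, `[[`, character(1), 2),
    class = vapply(nm, `[[`, character(1), 4)
  )
  sci <- names_tbl[names_tbl$class == "scientific name", ]
  canon <- setNames(sci$name, sci$taxon_id)
  syn <- names_tbl[names_tbl$class %in% NCBI_SYNONYM_CLASSES, ]
  syn$name <- strip_authority(syn$name)
  dropped <- sum(!(syn$taxon_id %in% nodes$taxon_id))
  syn <- syn[syn$taxon_id %in% nodes$taxon_id, ]
  syn_by <- split(syn$name, syn$taxon_id)
  keep <- nodes$taxon_id %in% names(canon)
  dropped <- dropped + sum(!keep)
  nodes <- nodes[keep, ]
  nodes$canonical_name <- unname(canon[nodes$taxon_id])
  nodes$status <- "accepted"
  nodes$synonyms <- lapply(nodes$taxon_id, function(id) {
    unique(syn_by[[id]] %||% character(0))
  })
  nodes <- finalize_nodes(nodes)
  attr(nodes, "dropped") <- dropped
  nodes
}

parse_dwc_taxon <- function(files) {
  path <- if (is.list(files)) files[[1]] else files[[1]]
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(DWC_REQUIRED, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("dwc-taxon table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "taxmapr_dialect_error")
  }
  tbl$scientificName <- strip_authority(tbl$scientificName)
  status <- fold_name(dplyr::coalesce(tbl$taxonomicStatus, "accepted"))
  is_syn <- grepl("synonym|misapplied", status)
  acc <- tbl[!is_syn, ]
  syn <- tbl[is_syn, ]
  dropped <- sum(!(syn$acceptedNameUsageID %in% acc$taxonID) |
                   is.na(syn$acceptedNameUsageID))
  syn <- syn[!is.na(syn$acceptedNameUsageID) &
               syn$acceptedNameUsageID %in% acc$taxonID, ]
  syn_by <- split(syn$scientificName, syn$acceptedNameUsageID)
  nodes <- tibble::tibble(
    taxon_id = acc$taxonID,
    parent_id = acc$parentNameUsageID,
    rank = dplyr::coalesce(fold_name(acc$taxonRank), "no rank"),
    canonical_name = acc$scientificName,
    status = ifelse(grepl("doubtful", fold_name(dplyr::coalesce(acc$taxonomicStatus, ""))),
                    "doubtful", "accepted"),
    synonyms = lapply(acc$taxonID, function(id) unique(syn_by[[id]] %||% character(0)))
  )
  nodes <- nodes[!is.na(nodes$canonical_name) & nzchar(nodes$canonical_name), ]
  nodes <- finalize_nodes(nodes)
  attr(nodes, "dropped") <- dropped
  nodes
}

#' Parse a taxonomic reference dump
#'
#' Reads a reference in one of the supported dialects and returns the
#' unified node table: accepted taxa with synonyms attached to their
#' accepted target and lineages materialised by walking parent links.
#' Synonym records whose accepted target is missing are dropped and counted
#' (see the `dropped` attribute).
#'
#' @param dialect `"ncbi-taxdump"` or `"dwc-taxon"`.
#' @param files For `ncbi-taxdump`, a list with elements `names` and `nodes`
#'   (paths); for `dwc-taxon`, a single path (plain or gzipped TSV).
#' @return A tibble with columns `taxon_id`, `parent_id`, `rank`,
#'   `canonical_name`, `status`, `synonyms` (list), `lineage` (list,
#'   root to parent), `lineage_ranks` (list); attribute `dropped` counts
#'   discarded records.
#' @export
parse_reference <- function(dialect = c("ncbi-taxdump", "dwc-taxon"), files) {
  dialect <- match.arg(dialect)
  if (!is.list(files)) files <- as.list(files)
  if (dialect == "ncbi-taxdump" && (is.null(files$names) || is.null(files$nodes))) {
    abort("ncbi-taxdump dialect needs both 'names' and 'nodes' files",
          class = "taxmapr_dialect_error")
  }
  for (f in files) {
    if (!file.exists(f)) abort(paste0("reference file not found: ", f),
                               class = "taxmapr_config_error")
  }
  switch(dialect,
         "ncbi-taxdump" = parse_ncbi_taxdump(files),
         "dwc-taxon" = parse_dwc_taxon(files))
}

#' Build the name and genus indexes for a node table
#'
#' The name index maps every case-folded canonical name and synonym to the
#' taxa bearing it; the genus index maps the case-folded first word-block of
#' every indexed name to the taxa whose names start with it. Values are
#' sorted by taxon id for determinism.
#'
#' @param nodes Node tibble from [parse_reference()].
#' @return List with `name_index` and `genus_index` (environments) and
#'   `names_tbl`, the long table of indexed names (columns `display`,
#'   `folded`, `first_block`, `taxon_id`, `is_synonym`).
#' @export
build_indexes <- function(nodes) {
  n_syn <- lengths(nodes$synonyms)
  names_tbl <- tibble::tibble(
    display = c(nodes$canonical_name, unlist(nodes$synonyms)),
    taxon_id = c(nodes$taxon_id, rep(nodes$taxon_id, n_syn)),
    is_synonym = c(rep(FALSE, nrow(nodes)), rep(TRUE, sum(n_syn)))
  )
  names_tbl$folded <- fold_name(names_tbl$display)
  names_tbl$first_block <- first_block(names_tbl$folded)
  names_tbl <- dplyr::arrange(names_tbl, .data$taxon_id, .data$is_synonym)
  name_index <- new.env(parent = emptyenv(), size = max(16L, nrow(names_tbl)))
  rows_by_key <- split(seq_len(nrow(names_tbl)), names_tbl$folded)
  for (k in names(rows_by_key)) name_index[[k]] <- rows_by_key[[k]]
  genus_index <- new.env(parent = emptyenv())
  ids_by_block <- lapply(split(names_tbl$taxon_id, names_tbl$first_block),
                         function(ids) sort(unique(ids)))
  for (k in names(ids_by_block)) {
    if (nzchar(k)) genus_index[[k]] <- ids_by_block[[k]]
  }
  list(name_index = name_index, genus_index = genus_index, names_tbl = names_tbl)
}

new_reference <- function(name, nodes) {
  idx <- build_indexes(nodes)
  node_rows <- new.env(parent = emptyenv(), size = max(16L, nrow(nodes)))
  for (i in seq_len(nrow(nodes))) node_rows[[nodes$taxon_id[[i]]]] <- i
  structure(
    list(name = name, nodes = nodes, names_tbl = idx$names_tbl,
         name_index = idx$name_index, genus_index = idx$genus_index,
         node_rows = node_rows, dropped = attr(nodes, "dropped") %||% 0L),
    class = "taxmap_reference"
  )
}

ref_node <- function(ref, taxon_id) {
  i <- ref$node_rows[[taxon_id]]
  if (is.null(i)) NULL else ref$nodes[i, ]
}

# exact lookup of a folded name key; returns the matching slice of names_tbl
ref_lookup <- function(ref, folded_key) {
  rows <- ref$name_index[[folded_key]]
  if (is.null(rows)) return(ref$names_tbl[0, ])
  ref$names_tbl[rows, ]
}

#' Load several references into one reference set
#'
#' @param config A data frame (or tibble) with columns `reference` (unique
#'   name), `dialect`, and `paths` (list-column: for `ncbi-taxdump` a named
#'   list with `names`/`nodes`, otherwise a single path).
#' @param mapping_config A [taxmap_config()] attached to the set.
#' @return A `taxmap_refset`: named references, each with indexes, plus the
#'   pooled valid-name list (every name recognised in at least one
#'   reference).
#' @export
load_reference_set <- function(config, mapping_config = taxmap_config()) {
  stopifnot(is.data.frame(config), nrow(config) >= 1)
  if (anyDuplicated(config$reference)) {
    abort("duplicate reference names in configuration",
          class = "taxmapr_config_error")
  }
  refs <- purrr::pmap(config, function(reference, dialect, paths, ...) {
    new_reference(reference, parse_reference(dialect, paths))
  })
  names(refs) <- config$reference
  new_refset(refs, mapping_config)
}

new_refset <- function(refs, mapping_config = taxmap_config()) {
  valid <- new.env(parent = emptyenv())
  for (r in refs) {
    for (k in unique(r$names_tbl$folded)) valid[[k]] <- TRUE
  }
  structure(
    list(references = refs, valid_names = valid, config = mapping_config),
    class = "taxmap_refset"
  )
}

#' @export
print.taxmap_refset <- function(x, ...) {
  cat("<taxmap_refset> ", length(x$references), " reference(s)\n", sep = "")
  for (r in x$references) {
    cat("  ", r$name, ": ", nrow(r$nodes), " taxa, ",
        nrow(r$names_tbl), " indexed names\n", sep = "")
  }
  invisible(x)
}

name_is_valid <- function(refset, folded_key) {
  isTRUE(refset$valid_names[[folded_key]])
}

#' Pooled valid-name list
#'
#' Every case-folded name (canonical or synonym) recognised in at least one
#' loaded reference.
#'
#' @param refset A `taxmap_refset`.
#' @return Sorted character vector.
#' @export
valid_names <- function(refset) {
  sort(ls(refset$valid_names))
}

# ---- preprocessed reference caches -----------------------------------------

join_pipe <- function(x) vapply(x, paste, character(1), collapse = "|")
split_pipe <- function(x) {
  lapply(x, function(s) if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]])
}

#' Write the preprocessed cache files for a reference
#'
#' Serialises the parsed node table (`<name>_node_dict.tsv`) and genus index
#' (`<name>_genus_dict.tsv`) so later runs can skip raw-dump parsing. The
#' serialisation round-trips exactly through [read_reference_cache()].
#'
#' @param ref A `taxmap_reference`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_reference_cache <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  node_path <- file.path(dir, paste0(ref$name, "_node_dict.tsv"))
  genus_path <- file.path(dir, paste0(ref$name, "_genus_dict.tsv"))
  flat <- tibble::tibble(
    taxon_id = ref$nodes$taxon_id,
    canonical_name = ref$nodes$canonical_name,
    rank = ref$nodes$rank,
    parent_id = dplyr::coalesce(ref$nodes$parent_id, ""),
    status = ref$nodes$status,
    synonyms = join_pipe(ref$nodes$synonyms),
    lineage = join_pipe(ref$nodes$lineage),
    lineage_ranks = join_pipe(ref$nodes$lineage_ranks)
  )
  readr::write_tsv(flat, node_path, progress = FALSE)
  blocks <- sort(ls(ref$genus_index))
  genus <- tibble::tibble(
    first_block = blocks,
    taxon_ids = vapply(blocks, function(b) paste(ref$genus_index[[b]], collapse = "|"),
                       character(1))
  )
  readr::write_tsv(genus, genus_path, progress = FALSE)
  invisible(c(node_path, genus_path))
}

#' Reload a reference from its cache files
#'
#' @param name Reference name (the cache file prefix).
#' @param dir Directory holding the cache files.
#' @return A `taxmap_reference` equal to the one that was cached.
#' @export
read_reference_cache <- function(name, dir) {
  node_path <- file.path(dir, paste0(name, "_node_dict.tsv"))
  if (!file.exists(node_path)) {
    abort(paste0("no cache for reference '", name, "' in ", dir),
          class = "taxmapr_config_error")
  }
  flat <- readr::read_tsv(node_path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  nodes <- tibble::tibble(
    taxon_id = flat$taxon_id,
    parent_id = ifelse(is.na(flat$parent_id) | !nzchar(flat$parent_id),
                       NA_character_, flat$parent_id),
    rank = flat$rank,
    canonical_name = flat$canonical_name,
    status = flat$status,
    synonyms = split_pipe(flat$synonyms),
    lineage = split_pipe(flat$lineage),
    lineage_ranks = split_pipe(flat$lineage_ranks)
  )
  new_reference(name, nodes)
}

#' Download a reference dump (helper)
#'
#' Thin wrapper over [utils::download.file()] for fetching reference dumps;
#' never needed for testing, which runs entirely on generated fixtures.
#'
#' @param url Source URL.
#' @param destfile Destination path.
#' @return The destination path, invisibly.
#' @export
download_reference <- function(url, destfile) {
  utils::download.file(url, destfile, mode = "wb", quiet = TRUE)
  invisible(destfile)
}
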