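# Shared test helpers: an independent recursive edit-distance oracle and
# small handmade reference fixtures written in both dialects.

# Independent oracle for the restricted Damerau-Levenshtein distance: the
# textbook recursive definition (memoised, but still the plain recursion on
# suffix lengths), kept free of the DP implementation it checks.
osa_oracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(x, y) {
    key <- paste(x, y, sep = "\r")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    nx <- nchar(x)
    ny <- nchar(y)
    v <- if (nx == 0) {
      ny
    } else if (ny == 0) {
      nx
    } else {
      cx <- substr(x, nx, nx)
      cy <- substr(y, ny, ny)
      cost <- if (cx == cy) 0L else 1L
      best <- min(rec(substr(x, 1, nx - 1), y) + 1L,
                  rec(x, substr(y, 1, ny - 1)) + 1L,
                  rec(substr(x, 1, nx - 1), substr(y, 1, ny - 1)) + cost)
      if (nx > 1 && ny > 1 &&
          substr(x, nx, nx) == substr(y, ny - 1, ny - 1) &&
          substr(x, nx - 1, nx - 1) == substr(y, ny, ny)) {
        best <- min(best, rec(substr(x, 1, nx - 2), substr(y, 1, ny - 2)) + 1L)
      }
      best
    }
    memo[[key]] <- v
    v
  }
  rec(a, b)
}

# all strings of length 0..n over an alphabet
all_strings <- function(n, alphabet = c("a", "c", "g", "t")) {
  acc <- list("")
  level <- ""
  for (i in seq_len(n)) {
    level <- as.vector(outer(level, alphabet, paste0))
    acc[[i + 1]] <- level
  }
  unlist(acc)
}

# write a tiny NCBI-style taxdump; nodes: tibble(taxon_id, parent, rank,
# name, synonyms = list of chr)
write_test_taxdump <- function(nodes, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  writeLines(sprintf("%s\t|\t%s\t|\t%s\t|", nodes$taxon_id, nodes$parent, nodes$rank),
             nodes_path)
  nm <- sprintf("%s\t|\t%s\t|\t\t|\tscientific name\t|", nodes$taxon_id, nodes$name)
  for (i in seq_len(nrow(nodes))) {
    for (s in nodes$synonyms[[i]]) {
      nm <- c(nm, sprintf("%s\t|\t%s\t|\t\t|\tsynonym\t|", nodes$taxon_id[[i]], s))
    }
  }
  writeLines(nm, names_path)
  list(names = names_path, nodes = nodes_path)
}

write_test_dwc <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "Taxon.tsv")
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

td_nodes <- function(...) {
  tbl <- tibble::tribble(...)
  if (!"synonyms" %in% names(tbl)) tbl$synonyms <- rep(list(character(0)), nrow(tbl))
  tbl
}

# kiwifruit-style two-reference set: the "col" reference holds the
# subspecies-style canonical with the other form as synonym; the "ncbi"
# reference holds the species-style canonical. Both share genus + kingdom.
make_kiwi_refset <- function(with_synonym = TRUE, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ncbi <- td_nodes(
    ~taxon_id, ~parent, ~rank, ~name,
    "1", "1", "no rank", "root",
    "2", "1", "kingdom", "Viridiplantae",
    "3", "2", "genus", "Actinidia",
    "4", "3", "species", "Actinidia deliciosa"
  )
  ncbi_paths <- write_test_taxdump(ncbi, dir = file.path(dir, "ncbi"))
  col <- tibble::tibble(
    taxonID = c("C1", "C2", "C3", "C4", if (with_synonym) "C5"),
    scientificName = c("root", "Plantae", "Actinidia", "Actinidia chinensis deliciosa",
                       if (with_synonym) "Actinidia deliciosa"),
    taxonRank = c("no rank", "kingdom", "genus", "species", if (with_synonym) "species"),
    parentNameUsageID = c("", "C1", "C2", "C3", if (with_synonym) ""),
    acceptedNameUsageID = c("", "", "", "", if (with_synonym) "C4"),
    taxonomicStatus = c("accepted", "accepted", "accepted", "accepted",
                        if (with_synonym) "synonym")
  )
  col_path <- write_test_dwc(col, dir = file.path(dir, "col"))
  load_reference_set(tibble::tibble(
    reference = c("ncbi", "col"),
    dialect = c("ncbi-taxdump", "dwc-taxon"),
    paths = list(ncbi_paths, col_path)
  ))
}

# hemihomonym target: genus "Agathis" as a conifer (Plantae) and a wasp
# (Animalia); source reference holds the plant species "Agathis ovata".
make_hemi_refset <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  target <- td_nodes(
    ~taxon_id, ~parent, ~rank, ~name,
    "1", "1", "no rank", "root",
    "2", "1", "kingdom", "Plantae",
    "3", "1", "kingdom", "Animalia",
    "4", "2", "genus", "Agathis",
    "5", "3", "genus", "Agathis",
    "6", "5", "species", "Agathis tibialis"
  )
  target_paths <- write_test_taxdump(target, dir = file.path(dir, "target"))
  src <- td_nodes(
    ~taxon_id, ~parent, ~rank, ~name,
    "1", "1", "no rank", "root",
    "2", "1", "kingdom", "Plantae",
    "3", "2", "genus", "Agathis",
    "4", "3", "species", "Agathis ovata"
  )
  src_paths <- write_test_taxdump(src, dir = file.path(dir, "src"))
  load_reference_set(tibble::tibble(
    reference = c("target", "src"),
    dialect = c("ncbi-taxdump", "ncbi-taxdump"),
    paths = list(target_paths, src_paths)
  ))
}

# standard small generated set shared by several test files
make_generated_refset <- function(n_species = 30, seed = 42, ...) {
  spec <- fixture_spec(n_species = n_species, n_genera = 6, synonym_rate = 0.3,
                       shared_fraction = 0.5, seed = seed, ...)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  out <- generate_fixture_set(spec, c(refA = "ncbi-taxdump", refB = "dwc-taxon"), dir)
  list(refset = load_reference_set(out$config), truth = out$truth,
       config = out$config, dir = dir, spec = spec)
}
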