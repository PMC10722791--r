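test_that("a minimal taxdump parses into accepted nodes with lineages", {
  nodes <- td_nodes(
    ~taxon_id, ~parent, ~rank, ~name,
    "1", "1", "no rank", "root",
    "2", "1", "genus", "Rubia",
    "3", "2", "species", "Rubia cordifolia"
  )
  nodes$synonyms[[3]] <- "Rubia munjista"
  paths <- write_test_taxdump(nodes)
  parsed <- parse_reference("ncbi-taxdump", paths)
  expect_identical(nrow(parsed), 3L)
  sp <- parsed[parsed$taxon_id == "3", ]
  expect_identical(sp$canonical_name, "Rubia cordifolia")
  expect_identical(sp$synonyms[[1]], "Rubia munjista")
  # lineage is the hand-walked parent chain root -> genus
  expect_identical(sp$lineage[[1]], c("1", "2"))
  expect_identical(sp$lineage_ranks[[1]], c("no rank", "genus"))
  expect_true(is.na(parsed$parent_id[parsed$taxon_id == "1"]))
})

test_that("DwC synonym rows attach to their accepted target", {
  rows <- tibble::tibble(
    taxonID = c("A", "B"),
    scientificName = c("Actinidia chinensis deliciosa", "Actinidia deliciosa"),
    taxonRank = c("species", "species"),
    parentNameUsageID = c("", ""),
    acceptedNameUsageID = c("", "A"),
    taxonomicStatus = c("accepted", "synonym")
  )
  parsed <- parse_reference("dwc-taxon", write_test_dwc(rows))
  expect_identical(nrow(parsed), 1L)
  expect_identical(parsed$taxon_id, "A")
  expect_true("Actinidia deliciosa" %in% parsed$synonyms[[1]])
})

test_that("empty tables, missing columns, cycles and orphans are handled", {
  empty <- tibble::tibble(taxonID = character(0), scientificName = character(0),
                          taxonRank = character(0), parentNameUsageID = character(0),
                          acceptedNameUsageID = character(0), taxonomicStatus = character(0))
  expect_identical(nrow(parse_reference("dwc-taxon", write_test_dwc(empty))), 0L)
  bad <- tibble::tibble(taxonID = "A", scientificName = "Aus bus")
  expect_error(parse_reference("dwc-taxon", write_test_dwc(bad)),
               regexp = "taxonRank", class = "taxmapr_dialect_error")
  cyc <- td_nodes(
    ~taxon_id, ~parent, ~rank, ~name,
    "1", "2", "genus", "Aus",
    "2", "1", "species", "Aus bus"
  )
  expect_error(parse_reference("ncbi-taxdump", write_test_taxdump(cyc)),
               class = "taxmapr_structural_error")
  # synonym pointing to a missing accepted id is dropped and counted
  orphan <- tibble::tibble(
    taxonID = c("A", "B"), scientificName = c("Aus bus", "Aus cus"),
    taxonRank = c("species", "species"), parentNameUsageID = c("", ""),
    acceptedNameUsageID = c("", "ZZZ"), taxonomicStatus = c("accepted", "synonym"))
  parsed <- parse_reference("dwc-taxon", write_test_dwc(orphan))
  expect_identical(nrow(parsed), 1L)
  expect_identical(attr(parsed, "dropped"), 1L)
  expect_error(parse_reference("ncbi-taxdump", list(names = "nope.dmp")),
               class = "taxmapr_dialect_error")
  expect_error(parse_reference("dwc-taxon", "no/such/file.tsv"),
               class = "taxmapr_config_error")
})

test_that("indexes cover every canonical name and synonym", {
  gen <- make_generated_refset()
  for (ref in gen$refset$references) {
    tbl <- ref$names_tbl
    for (i in seq_len(nrow(tbl))) {
      hits <- taxmapr:::ref_lookup(ref, tbl$folded[[i]])
      expect_true(tbl$taxon_id[[i]] %in% hits$taxon_id)
      fb <- tbl$first_block[[i]]
      expect_true(tbl$taxon_id[[i]] %in% ref$genus_index[[fb]])
    }
    # genus-index values sorted for determinism
    for (k in ls(ref$genus_index)) {
      expect_identical(ref$genus_index[[k]], sort(ref$genus_index[[k]]))
    }
  }
})

test_that("lineages equal the brute-force parent chain", {
  gen <- make_generated_refset()
  for (ref in gen$refset$references) {
    nodes <- ref$nodes
    parent_of <- stats::setNames(nodes$parent_id, nodes$taxon_id)
    for (i in seq_len(nrow(nodes))) {
      chain <- character(0)
      cur <- nodes$taxon_id[[i]]
      repeat {
        p <- parent_of[[cur]]
        if (is.na(p)) break
        chain <- c(p, chain)
        cur <- p
      }
      expect_identical(nodes$lineage[[i]], chain)
      # no node is its own ancestor; aligned rank labels
      expect_false(nodes$taxon_id[[i]] %in% nodes$lineage[[i]])
      expect_identical(length(nodes$lineage[[i]]), length(nodes$lineage_ranks[[i]]))
    }
  }
})

test_that("the pooled valid-name list is the union across references", {
  gen <- make_generated_refset()
  expected <- sort(unique(unlist(lapply(gen$refset$references,
                                        function(r) r$names_tbl$folded))))
  expect_identical(valid_names(gen$refset), expected)
})

test_that("reference-set configuration errors are reported", {
  gen <- make_generated_refset()
  cfg <- gen$config
  dup <- dplyr::bind_rows(cfg, cfg[1, ])
  expect_error(load_reference_set(dup), class = "taxmapr_config_error")
  bad <- cfg
  bad$paths[[1]] <- list(names = "missing.dmp", nodes = "missing2.dmp")
  expect_error(load_reference_set(bad), class = "taxmapr_config_error")
})

test_that("caches round-trip the parsed reference exactly", {
  gen <- make_generated_refset()
  dir <- withr::local_tempdir()
  for (ref in gen$refset$references) {
    write_reference_cache(ref, dir)
    back <- read_reference_cache(ref$name, dir)
    expect_identical(back$nodes$taxon_id, ref$nodes$taxon_id)
    expect_identical(back$nodes$canonical_name, ref$nodes$canonical_name)
    expect_identical(back$nodes$rank, ref$nodes$rank)
    expect_identical(back$nodes$parent_id, ref$nodes$parent_id)
    expect_identical(back$nodes$lineage, ref$nodes$lineage)
    expect_identical(back$nodes$synonyms, ref$nodes$synonyms)
  }
})
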