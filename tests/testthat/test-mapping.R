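test_that("exact matching distinguishes raw, corrected and case-folded hits", {
  refset <- make_kiwi_refset()
  ncbi <- refset$references$ncbi
  r <- exact_match("Actinidia deliciosa", ncbi)
  expect_identical(r$status_code, 0L)
  expect_identical(r$taxon_ids, "4")
  expect_identical(exact_match("actinidia deliciosa", ncbi)$status_code, 4L)
  r2 <- exact_match("Actinidia deliciosa (A.Chev.) C.F.Liang", ncbi)
  expect_identical(r2$status_code, 2L)
  expect_identical(r2$taxon_ids, "4")
  expect_identical(exact_match("Nonexistens nomen", ncbi)$status_code, 1000L)
  # raw synonym hit in the DwC reference
  col <- refset$references$col
  expect_identical(exact_match("Actinidia deliciosa", col)$status_code, 1L)
  expect_identical(exact_match("Actinidia deliciosa", col)$taxon_ids, "C4")
})

test_that("synonym recursion maps the subspecies-style name into the other reference", {
  refset <- make_kiwi_refset()
  r <- map_name("Actinidia chinensis deliciosa", refset, "ncbi")
  expect_identical(r$status_code, 6L)
  expect_identical(r$taxon_id, "4")
  expect_identical(r$stage, "recursive")
  # the record carries the best matches from the other references
  om <- r$other_matches[[1]]
  expect_identical(om$reference, "col")
  expect_identical(om$status_code, 0L)
})

test_that("without the synonym link the query degrades to genus-level nearest mapping", {
  refset <- make_kiwi_refset(with_synonym = FALSE)
  r <- map_name("Actinidia chinensis deliciosa", refset, "ncbi")
  expect_identical(r$status_code, 11L)  # genus tier
  expect_identical(r$taxon_id, "3")
  expect_identical(r$matched_rank, "genus")
  expect_identical(r$stage, "nearest")
})

test_that("recursion reports several target taxa under the multi-match code", {
  dir <- withr::local_tempdir()
  target <- td_nodes(
    ~taxon_id, ~parent, ~rank, ~name,
    "1", "1", "no rank", "root",
    "2", "1", "species", "Aus bus",
    "3", "1", "species", "Aus cus"
  )
  srcA <- td_nodes(~taxon_id, ~parent, ~rank, ~name, "1", "1", "species", "Aus dus")
  srcA$synonyms[[1]] <- "Aus bus"
  srcB <- td_nodes(~taxon_id, ~parent, ~rank, ~name, "1", "1", "species", "Aus dus")
  srcB$synonyms[[1]] <- "Aus cus"
  refset <- load_reference_set(tibble::tibble(
    reference = c("target", "A", "B"),
    dialect = "ncbi-taxdump",
    paths = list(write_test_taxdump(target, file.path(dir, "t")),
                 write_test_taxdump(srcA, file.path(dir, "a")),
                 write_test_taxdump(srcB, file.path(dir, "b")))))
  r <- map_name("Aus dus", refset, "target")
  expect_identical(r$status_code, 8L)
  expect_setequal(r$taxon_ids[[1]], c("2", "3"))
})

test_that("nearest mapping picks the domain-consistent hemihomonym genus", {
  refset <- make_hemi_refset()
  r <- map_name("Agathis ovata", refset, "target")
  expect_identical(r$stage, "nearest")
  expect_identical(r$status_code, 11L)
  expect_identical(r$taxon_id, "4")  # the Plantae genus, not the wasp
})

test_that("candidate pools are pruned by genus block, length and composition", {
  refset <- make_generated_refset()$refset
  ref <- refset$references$refA
  sp <- ref$nodes[ref$nodes$rank == "species", ]
  nm <- sp$canonical_name[[1]]
  pool <- candidate_pool(nm, ref, max_d = 3)
  expect_true(fold_long <- all(pool$first_block == taxmapr:::first_block(tolower(nm))))
  expect_true(all(abs(nchar(pool$folded) - nchar(tolower(nm))) <= 3))
  # a name 10 characters longer than every pool member is excluded
  long_query <- paste0(nm, "abcdefghij")
  expect_false(tolower(nm) %in% candidate_pool(long_query, ref, 3)$folded)
  expect_identical(nrow(candidate_pool("Zz nothing", ref, 3)), 0L)
})

test_that("epithet correction finds the closest name and reports ties", {
  dir <- withr::local_tempdir()
  nodes <- td_nodes(
    ~taxon_id, ~parent, ~rank, ~name,
    "1", "1", "no rank", "root",
    "2", "1", "genus", "Rubia",
    "3", "2", "species", "Rubia cordifolia",
    "4", "2", "species", "Rubia tinctorum",
    "5", "2", "species", "Rubia peregrina"
  )
  refset <- load_reference_set(tibble::tibble(
    reference = "r", dialect = "ncbi-taxdump",
    paths = list(write_test_taxdump(nodes, dir))))
  ref <- refset$references$r
  r <- correct_epithet("Rubia cordifolai", ref)
  expect_identical(r$status_code, 20L)
  expect_identical(r$taxon_ids, "3")
  expect_identical(r$distance, 1L)
  expect_identical(correct_epithet("Rubia zzzzzzzzzzz", ref)$status_code, 1000L)
  # tie between two equidistant taxa
  dir2 <- withr::local_tempdir()
  tie <- td_nodes(
    ~taxon_id, ~parent, ~rank, ~name,
    "1", "1", "no rank", "root",
    "2", "1", "species", "Aus bicolor",
    "3", "1", "species", "Aus tricolor"
  )
  refset2 <- load_reference_set(tibble::tibble(
    reference = "r", dialect = "ncbi-taxdump",
    paths = list(write_test_taxdump(tie, dir2))))
  rt <- correct_epithet("Aus bricolor", refset2$references$r)
  expect_identical(rt$status_code, 22L)
  expect_setequal(rt$taxon_ids, c("2", "3"))
})

test_that("whole-string correction runs declension reconstruction first", {
  dir <- withr::local_tempdir()
  nodes <- td_nodes(
    ~taxon_id, ~parent, ~rank, ~name,
    "1", "1", "no rank", "root",
    "2", "1", "genus", "Glycyrrhiza",
    "3", "2", "species", "Glycyrrhiza uralensis"
  )
  refset <- load_reference_set(tibble::tibble(
    reference = "r", dialect = "ncbi-taxdump",
    paths = list(write_test_taxdump(nodes, dir))))
  ref <- refset$references$r
  r <- correct_whole("Glycyrrhizae radix", ref)
  expect_identical(r$status_code, 30L)
  expect_identical(r$taxon_ids, "2")
  full <- map_name("Glycyrrhizae radix", refset, "r")
  expect_identical(full$status_code, 30L)
  expect_identical(full$stage, "whole")
  # whole-string edit distance rescues a corrupted genus block
  r2 <- correct_whole("Glycyrrhizb uralensis", ref)
  expect_identical(r2$status_code, 32L)
  expect_identical(r2$taxon_ids, "3")
  expect_identical(correct_whole("qqqq zzzz", ref)$status_code, 1000L)
})

test_that("strain, cf., aff. and genus-only queries bypass edit-distance correction", {
  dir <- withr::local_tempdir()
  nodes <- td_nodes(
    ~taxon_id, ~parent, ~rank, ~name,
    "1", "1", "no rank", "root",
    "2", "1", "genus", "Streptomyces",
    "3", "1", "genus", "Bacillus",
    "4", "3", "species", "Bacillus subtilis",
    "5", "1", "genus", "Rubia",
    "6", "5", "species", "Rubia cordifolia"
  )
  refset <- load_reference_set(tibble::tibble(
    reference = "r", dialect = "ncbi-taxdump",
    paths = list(write_test_taxdump(nodes, dir))))
  r <- map_name("Streptomyces sp. ABC-123", refset, "r")
  expect_identical(r$status_code, 40L)
  expect_identical(r$taxon_id, "2")
  # cf. returns a higher taxon within the match's lineage
  r2 <- map_name("Rubia cf. cordifolia", refset, "r")
  expect_identical(r2$status_code, 41L)
  expect_identical(r2$taxon_id, "5")
  # aff. takes priority over the year token and also returns the parent
  r3 <- map_name("Bacillus aff. subtilis 1997", refset, "r")
  expect_identical(r3$status_code, 42L)
  expect_identical(r3$taxon_id, "3")
  r4 <- map_name("Rubia sp.", refset, "r")
  expect_identical(r4$status_code, 43L)
  expect_identical(r4$taxon_id, "5")
})

test_that("dropout keywords and hybrids short-circuit with no taxon", {
  refset <- make_kiwi_refset()
  r <- map_name("Tobacco mosaic virus", refset, "ncbi")
  expect_identical(r$status_code, 90L)
  expect_identical(length(r$taxon_ids[[1]]), 0L)
  r2 <- map_name("Mentha x piperita", refset, "ncbi")
  expect_identical(r2$status_code, 95L)
  expect_identical(length(r2$taxon_ids[[1]]), 0L)
})

test_that("partial mapping falls back to prefix word-blocks", {
  refset <- make_kiwi_refset()
  r <- map_name("Actinidia totallywrongword", refset, "ncbi")
  expect_identical(r$status_code, 100L)
  expect_identical(r$taxon_id, "3")
  r2 <- map_name("Actinidia deliciosa extraneous trailing words", refset, "ncbi")
  expect_identical(r2$status_code, 100L)
  expect_identical(r2$taxon_id, "4")
  expect_identical(map_name("xyzzy", refset, "ncbi")$status_code, 1000L)
})

test_that("vernacular substitution feeds the cascade", {
  refset <- make_kiwi_refset()
  vmap <- c("kiwifruit" = "Actinidia deliciosa")
  r <- map_name("kiwifruit", refset, "ncbi", vernacular = vmap)
  expect_identical(r$status_code, 0L)
  expect_identical(r$taxon_id, "4")
  expect_true(r$vernacular_applied)
})

test_that("every canonical name and synonym maps soundly in its own reference", {
  gen <- make_generated_refset()
  for (rn in names(gen$refset$references)) {
    ref <- gen$refset$references[[rn]]
    canon <- ref$nodes[ref$nodes$rank %in% c("species", "genus", "kingdom"), ]
    recs <- map_names(canon$canonical_name, gen$refset, rn)
    expect_true(all(recs$status_code == 0L))
    expect_identical(recs$taxon_id, canon$taxon_id)
    expect_true(all(recs$stage == "exact"))
    syn_rows <- which(lengths(ref$nodes$synonyms) > 0)
    if (length(syn_rows) > 0) {
      syn_recs <- map_names(unlist(ref$nodes$synonyms[syn_rows]), gen$refset, rn)
      expect_true(all(syn_recs$status_code == 1L))
    }
  }
})

test_that("mapping is total with a single valid status code per input", {
  gen <- make_generated_refset()
  withr::with_seed(21, {
    garbage <- replicate(40, paste(
      sample(c(letters, LETTERS, 0:9, ".", "(", ")", "-", " "), sample(1:25, 1),
             replace = TRUE), collapse = ""))
  })
  inputs <- c(garbage, "", "   ", "(only parens)", "Rubia sp.", "x", "1234")
  recs <- map_names(inputs, gen$refset, "refA")
  expect_identical(nrow(recs), length(inputs))
  expect_true(all(recs$status_code %in% taxmapr:::valid_status_codes()))
  for (i in seq_len(nrow(recs))) {
    ids <- recs$taxon_ids[[i]]
    code <- recs$status_code[[i]]
    if (code %in% c(90:99, 1000L)) {
      expect_identical(length(ids), 0L)
    } else {
      expect_gte(length(ids), 1L)
    }
    if (length(ids) > 1) expect_true(code %in% taxmapr:::multi_match_codes())
  }
})

test_that("typo injection recovers the planted taxon across typo loads", {
  gen <- make_generated_refset(n_species = 40, seed = 7)
  sp <- gen$refset$references$refA$nodes
  sp <- sp[sp$rank == "species", ]
  for (k in 0:3) {
    tt <- generate_typo_table(sp[, c("canonical_name", "taxon_id")], k, seed = 100 + k)
    recs <- map_names(tt$corrupted, gen$refset, "refA")
    ok <- recs$status_code %in% c(0L, 4L) |
      (recs$stage %in% c("epithet", "whole") &
         !recs$status_code %in% taxmapr:::multi_match_codes())
    correct <- ok & recs$taxon_id == tt$taxon_id
    expect_identical(mean(correct), 1)
    expect_true(all(recs$distance <= k))
  }
})

test_that("batch mapping accepts data frames and name columns", {
  refset <- make_kiwi_refset()
  df <- tibble::tibble(name = c("Actinidia deliciosa", "xyzzy"))
  recs <- map_names(df, refset, "ncbi")
  expect_identical(recs$status_code, c(0L, 1000L))
  df2 <- tibble::tibble(input = "Actinidia deliciosa")
  expect_identical(map_names(df2, refset, "ncbi", name_col = "input")$status_code, 0L)
  expect_error(map_names(df2, refset, "ncbi"), regexp = "column")
  expect_error(map_name("Aus", refset, "nope"), class = "taxmapr_config_error")
})
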