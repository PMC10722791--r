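test_that("fixture generation is deterministic and round-trips through the parser", {
  spec <- fixture_spec(n_species = 12, n_genera = 4, synonym_rate = 0.5, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  o1 <- generate_fixture_set(spec, c(r = "ncbi-taxdump"), d1)
  o2 <- generate_fixture_set(spec, c(r = "ncbi-taxdump"), d2)
  for (f in c("r_names.dmp", "r_nodes.dmp")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  parsed <- parse_reference("ncbi-taxdump", o1$config$paths[[1]])
  truth <- o1$truth
  expect_identical(sum(parsed$rank == "species"), 12L)
  # parsed node set equals the generator's ground truth exactly
  expect_identical(parsed$taxon_id, truth$taxon_id)
  expect_identical(parsed$canonical_name, truth$canonical_name)
  expect_identical(parsed$rank, truth$rank)
  for (i in seq_len(nrow(parsed))) {
    syn <- truth$synonym[[i]]
    expect_identical(parsed$synonyms[[i]],
                     if (is.na(syn)) character(0) else syn)
  }
})

test_that("both dialect writers produce parseable, equivalent references", {
  spec <- fixture_spec(n_species = 10, n_genera = 3, synonym_rate = 0.4,
                       shared_fraction = 1, seed = 3)
  dir <- withr::local_tempdir()
  out <- generate_fixture_set(spec, c(n = "ncbi-taxdump", d = "dwc-taxon"), dir)
  refset <- load_reference_set(out$config)
  a <- refset$references$n$nodes
  b <- refset$references$d$nodes
  expect_setequal(a$canonical_name, b$canonical_name)
  expect_setequal(unlist(a$synonyms), unlist(b$synonyms))
  expect_identical(sort(unique(a$rank)), sort(unique(b$rank)))
})

test_that("generated names keep the promised pairwise separation", {
  spec <- fixture_spec(n_species = 15, n_genera = 5, synonym_rate = 0.4, seed = 11)
  dir <- withr::local_tempdir()
  out <- generate_fixture_set(spec, c(r = "ncbi-taxdump"), dir)
  parsed <- parse_reference("ncbi-taxdump", out$config$paths[[1]])
  nms <- unique(c(parsed$canonical_name, unlist(parsed$synonyms)))
  # the fixed structural labels (root/kingdoms) are not generated names
  nms <- setdiff(nms, c("root", "Plantae", "Animalia", "Bacteria"))
  for (i in seq_along(nms)) {
    for (j in seq_len(i - 1)) {
      if (nchar(nms[[i]]) > 3 && nchar(nms[[j]]) > 3) {
        expect_gte(damerau_levenshtein(tolower(nms[[i]]), tolower(nms[[j]])), 7L)
      }
    }
  }
})

test_that("planted hemihomonym pairs are found by the scanner", {
  spec <- fixture_spec(n_species = 10, n_genera = 4, hemihomonym_pairs = 1, seed = 13)
  dir <- withr::local_tempdir()
  out <- generate_fixture_set(spec, c(r = "ncbi-taxdump"), dir)
  refset <- load_reference_set(out$config)
  h <- hemihomonym_scan(refset)
  expect_identical(nrow(h), 1L)
  expect_identical(h$n_domains, 2L)
})

test_that("impossible fixture specs are rejected", {
  expect_error(fixture_spec(n_species = 5, n_genera = 2, hemihomonym_pairs = 3),
               class = "taxmapr_spec_error")
  expect_error(fixture_spec(n_species = 5, n_genera = 2, hemihomonym_pairs = 1,
                            domains = c(Plantae = 1)),
               class = "taxmapr_spec_error")
  expect_error(fixture_spec(n_species = 2, n_genera = 5))
})

test_that("typo injection stays within the requested distance", {
  expect_identical(inject_typos("Rubia cordifolia", 0), "Rubia cordifolia")
  withr::with_seed(17, {
    for (i in 1:60) {
      k <- sample(0:3, 1)
      nm <- paste(sample(letters, sample(8:16, 1), replace = TRUE), collapse = "")
      corrupted <- inject_typos(nm, k)
      expect_lte(osa_oracle(nm, corrupted), k)
      if (k > 0) expect_identical(substr(corrupted, 1, 1), substr(nm, 1, 1))
    }
  })
  expect_identical(inject_typos("Rubia cordifolia", 2, seed = 5),
                   inject_typos("Rubia cordifolia", 2, seed = 5))
  d <- damerau_levenshtein("Rubia cordifolia", inject_typos("Rubia cordifolia", 1, seed = 9))
  expect_lte(d, 1L)
})

test_that("near-duplicate injection breaks the separation on request", {
  spec <- fixture_spec(n_species = 12, n_genera = 3, near_duplicate_rate = 0.5,
                       seed = 23)
  dir <- withr::local_tempdir()
  out <- generate_fixture_set(spec, c(r = "ncbi-taxdump"), dir)
  parsed <- parse_reference("ncbi-taxdump", out$config$paths[[1]])
  sp <- parsed$canonical_name[parsed$rank == "species"]
  expect_gt(length(sp), 12)
  dmin <- Inf
  for (i in seq_along(sp)) {
    for (j in seq_len(i - 1)) {
      dmin <- min(dmin, damerau_levenshtein(tolower(sp[[i]]), tolower(sp[[j]])))
    }
  }
  expect_lte(dmin, 2L)
})

test_that("NP pair tables honour the planned support and perturbation settings", {
  gen <- make_generated_refset()
  plan <- c("1" = 3, "2" = 1, "4" = 1)
  npgen <- generate_np_pairs(gen$refset, "refA", support_plan = plan,
                             typo_rate = 0, seed = 5)
  expect_identical(length(npgen$tables), 4L)
  occ <- dplyr::bind_rows(npgen$tables, .id = "src")
  # with no perturbation every name is an exact canonical string
  sp_names <- gen$refset$references$refA$nodes$canonical_name
  expect_true(all(occ$name %in% sp_names))
  counts <- dplyr::count(npgen$truth, support)
  expect_identical(stats::setNames(counts$n, counts$support),
                   stats::setNames(as.integer(plan), names(plan)))
  # a pair planted in all sources appears in every table
  quad <- npgen$truth[npgen$truth$support == 4, ]
  hits <- vapply(npgen$tables, function(t) quad$structure %in% t$structure, logical(1))
  expect_true(all(hits))
  # declension-style perturbation round-trips through whole-string correction
  ga <- grep("a$", gen$refset$references$refA$nodes$canonical_name[
    gen$refset$references$refA$nodes$rank == "genus"], value = TRUE)
  if (length(ga) > 0) {
    q <- paste0(sub("a$", "ae", ga[[1]]), " radix")
    r <- map_name(q, gen$refset, "refA")
    expect_identical(r$status_code, 30L)
    expect_identical(r$matched_name, ga[[1]])
  }
})
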