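# Synthetic-data generators: miniature taxonomic references in both dialects,
# seeded typo injection, and species-compound pair tables with a planned
# cross-source overlap. The generators are ground truth by construction:
# every downstream accuracy measurement on fixtures has an exact expected
# value.

CONSONANTS <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v")
VOWELS <- c("a", "e", "i", "o", "u")

random_word <- function(n_syllables) {
  paste0(paste0(sample(CONSONANTS, n_syllables, replace = TRUE),
                sample(VOWELS, n_syllables, replace = TRUE)), collapse = "")
}

cap_first <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

# rejection-sample words whose pairwise distance to every accepted name is
# at least min_dist (bounded distance keeps this cheap)
gen_separated <- function(n, existing, min_dist, syllables = 4:6, cap = FALSE,
                          ending = NULL) {
  out <- character(0)
  pool <- existing
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 200000L) abort("fixture generator: cannot satisfy name-separation constraint")
    w <- random_word(sample(syllables, 1))
    if (!is.null(ending)) w <- paste0(substr(w, 1, nchar(w) - 1), ending)
    if (cap) w <- cap_first(w)
    if (length(pool) == 0 ||
        all(.osa_pool_dist(fold_name(w), fold_name(pool), min_dist - 1L) >= min_dist)) {
      out <- c(out, w)
      pool <- c(pool, w)
    }
  }
  out
}

#' Specification for a synthetic reference fixture
#'
#' @param n_species Number of species.
#' @param n_genera Number of genera (species are distributed round-robin).
#' @param domains Named numeric vector of top-rank (kingdom) labels with
#'   proportions; genera are assigned to domains by largest remainder.
#' @param synonym_rate Probability that a species carries one synonym.
#' @param hemihomonym_pairs Number of genus names planted in two different
#'   domains at once.
#' @param shared_fraction Fraction of species present in every generated
#'   reference when a multi-reference set is emitted; the rest are split
#'   round-robin as reference-unique species.
#' @param near_duplicate_rate Fraction of species that receive a deliberate
#'   near-duplicate sibling (epithet within edit distance 2), breaking the
#'   default pairwise separation.
#' @param min_dist Minimum pairwise edit distance between generated names
#'   (default `2 * max_d + 1 = 7`, so up to `max_d` typos are always
#'   uniquely recoverable).
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   files.
#' @return A list of class `taxmap_fixture_spec`.
#' @export
fixture_spec <- function(n_species = 50L, n_genera = 10L,
                         domains = c(Plantae = 0.5, Animalia = 0.3, Bacteria = 0.2),
                         synonym_rate = 0.2, hemihomonym_pairs = 0L,
                         shared_fraction = 1, near_duplicate_rate = 0,
                         min_dist = 7L, seed = 1L) {
  stopifnot(n_species >= 1, n_genera >= 1, n_genera <= n_species,
            all(domains >= 0), sum(domains) > 0,
            synonym_rate >= 0, synonym_rate <= 1,
            shared_fraction >= 0, shared_fraction <= 1,
            near_duplicate_rate >= 0, near_duplicate_rate <= 1)
  if (hemihomonym_pairs > n_genera) {
    abort("more hemihomonym pairs than genera", class = "taxmapr_spec_error")
  }
  if (length(domains) < 2 && hemihomonym_pairs > 0) {
    abort("hemihomonym pairs need at least two domains", class = "taxmapr_spec_error")
  }
  structure(
    list(n_species = as.integer(n_species), n_genera = as.integer(n_genera),
         domains = domains / sum(domains), synonym_rate = synonym_rate,
         hemihomonym_pairs = as.integer(hemihomonym_pairs),
         shared_fraction = shared_fraction,
         near_duplicate_rate = near_duplicate_rate,
         min_dist = as.integer(min_dist), seed = as.integer(seed)),
    class = "taxmap_fixture_spec"
  )
}

# largest-remainder apportionment of n items over named proportions
apportion <- function(n, props) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# in-memory taxonomy shared by all emitted references
build_taxonomy <- function(spec) {
  withr::with_seed(spec$seed, {
    domains <- names(spec$domains)
    genus_domain_counts <- apportion(spec$n_genera, spec$domains)
    # fixed structural names take part in the separation constraint too;
    # genus names get a first-declension ending so the Latin-genitive test
    # forms (-ae) are always constructible
    genus_names <- gen_separated(spec$n_genera, c("root", domains), spec$min_dist,
                                 cap = TRUE, ending = "a")
    genus_domain <- rep(domains, genus_domain_counts)
    all_names <- c("root", domains, genus_names)
    # species epithets: separation enforced on the full binomial
    sp_genus <- rep(seq_len(spec$n_genera), length.out = spec$n_species)
    sp_names <- character(spec$n_species)
    for (i in seq_len(spec$n_species)) {
      repeat {
        ep <- random_word(sample(4:6, 1))
        full <- paste(genus_names[[sp_genus[[i]]]], ep)
        if (all(.osa_pool_dist(fold_name(full), fold_name(all_names),
                               spec$min_dist - 1L) >= spec$min_dist)) {
          sp_names[[i]] <- full
          all_names <- c(all_names, full)
          break
        }
      }
    }
    # synonyms: fresh separated binomials
    has_syn <- stats::runif(spec$n_species) < spec$synonym_rate
    syn_names <- rep(NA_character_, spec$n_species)
    if (any(has_syn)) {
      fresh <- gen_separated(sum(has_syn), all_names, spec$min_dist, cap = TRUE)
      eps <- gen_separated(sum(has_syn), character(0), 1L)
      syns <- paste(fresh, eps)
      syn_names[has_syn] <- syns
      all_names <- c(all_names, syns)
    }
    # hemihomonym genera: one genus name planted in two domains, one species each
    hemi <- NULL
    if (spec$hemihomonym_pairs > 0) {
      hg <- gen_separated(spec$hemihomonym_pairs, all_names, spec$min_dist, cap = TRUE)
      all_names <- c(all_names, hg)
      hemi <- purrr::map_dfr(seq_len(spec$hemihomonym_pairs), function(i) {
        doms <- sample(domains, 2)
        eps <- gen_separated(2L, all_names, spec$min_dist)
        tibble::tibble(genus = hg[[i]], domain = doms,
                       species = paste(hg[[i]], eps))
      })
      all_names <- c(all_names, hemi$species)
    }
    # near-duplicate siblings (distance <= 2 on the epithet)
    dup <- NULL
    n_dup <- floor(spec$near_duplicate_rate * spec$n_species)
    if (n_dup > 0) {
      pick <- sort(sample(spec$n_species, n_dup))
      dup <- purrr::map_dfr(pick, function(i) {
        ep <- strsplit(sp_names[[i]], " ")[[1]][[2]]
        ep2 <- inject_typos(ep, sample(1:2, 1), preserve_first = FALSE)
        tibble::tibble(genus_i = sp_genus[[i]],
                       species = paste(genus_names[[sp_genus[[i]]]], ep2))
      })
      dup <- dup[!fold_name(dup$species) %in% fold_name(all_names), ]
    }
    list(domains = domains, genus_names = genus_names, genus_domain = genus_domain,
         sp_genus = sp_genus, sp_names = sp_names, syn_names = syn_names,
         hemi = hemi, dup = dup)
  })
}

# assemble a node tibble for one reference containing a species subset
taxonomy_nodes <- function(tax, sp_keep, include_hemi_species = TRUE) {
  rows <- list()
  nid <- 0L
  nxt <- function() {
    nid <<- nid + 1L
    as.character(nid)
  }
  root_id <- nxt()
  rows[[length(rows) + 1]] <- tibble::tibble(
    taxon_id = root_id, parent_id = NA_character_, rank = "no rank",
    canonical_name = "root", synonym = NA_character_, domain = NA_character_)
  dom_ids <- setNames(character(length(tax$domains)), tax$domains)
  for (d in tax$domains) {
    dom_ids[[d]] <- nxt()
    rows[[length(rows) + 1]] <- tibble::tibble(
      taxon_id = dom_ids[[d]], parent_id = root_id, rank = "kingdom",
      canonical_name = d, synonym = NA_character_, domain = d)
  }
  genus_ids <- character(length(tax$genus_names))
  for (g in seq_along(tax$genus_names)) {
    genus_ids[[g]] <- nxt()
    rows[[length(rows) + 1]] <- tibble::tibble(
      taxon_id = genus_ids[[g]], parent_id = dom_ids[[tax$genus_domain[[g]]]],
      rank = "genus", canonical_name = tax$genus_names[[g]],
      synonym = NA_character_, domain = tax$genus_domain[[g]])
  }
  for (i in sp_keep) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      taxon_id = nxt(), parent_id = genus_ids[[tax$sp_genus[[i]]]],
      rank = "species", canonical_name = tax$sp_names[[i]],
      synonym = tax$syn_names[[i]],
      domain = tax$genus_domain[[tax$sp_genus[[i]]]])
  }
  if (!is.null(tax$hemi)) {
    for (i in seq_len(nrow(tax$hemi))) {
      gid <- nxt()
      d <- tax$hemi$domain[[i]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon_id = gid, parent_id = dom_ids[[d]], rank = "genus",
        canonical_name = tax$hemi$genus[[i]], synonym = NA_character_, domain = d)
      if (include_hemi_species) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          taxon_id = nxt(), parent_id = gid, rank = "species",
          canonical_name = tax$hemi$species[[i]], synonym = NA_character_, domain = d)
      }
    }
  }
  if (!is.null(tax$dup) && nrow(tax$dup) > 0) {
    for (i in seq_len(nrow(tax$dup))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon_id = nxt(), parent_id = genus_ids[[tax$dup$genus_i[[i]]]],
        rank = "species", canonical_name = tax$dup$species[[i]],
        synonym = NA_character_,
        domain = tax$genus_domain[[tax$dup$genus_i[[i]]]])
    }
  }
  dplyr::bind_rows(rows)
}

write_ncbi_dialect <- function(flat, dir, reference) {
  names_path <- file.path(dir, paste0(reference, "_names.dmp"))
  nodes_path <- file.path(dir, paste0(reference, "_nodes.dmp"))
  node_lines <- sprintf("%s\t|\t%s\t|\t%s\t|",
                        flat$taxon_id,
                        ifelse(is.na(flat$parent_id), flat$taxon_id, flat$parent_id),
                        flat$rank)
  name_lines <- sprintf("%s\t|\t%s\t|\t\t|\tscientific name\t|",
                        flat$taxon_id, flat$canonical_name)
  syn <- flat[!is.na(flat$synonym), ]
  if (nrow(syn) > 0) {
    name_lines <- c(name_lines,
                    sprintf("%s\t|\t%s\t|\t\t|\tsynonym\t|", syn$taxon_id, syn$synonym))
  }
  readr::write_lines(node_lines, nodes_path)
  readr::write_lines(name_lines, names_path)
  list(names = names_path, nodes = nodes_path)
}

write_dwc_dialect <- function(flat, dir, reference) {
  path <- file.path(dir, paste0(reference, "_Taxon.tsv"))
  acc <- tibble::tibble(
    taxonID = flat$taxon_id, scientificName = flat$canonical_name,
    taxonRank = flat$rank, parentNameUsageID = dplyr::coalesce(flat$parent_id, ""),
    acceptedNameUsageID = "", taxonomicStatus = "accepted")
  syn <- flat[!is.na(flat$synonym), ]
  if (nrow(syn) > 0) {
    acc <- dplyr::bind_rows(acc, tibble::tibble(
      taxonID = paste0("s", syn$taxon_id), scientificName = syn$synonym,
      taxonRank = "species", parentNameUsageID = "",
      acceptedNameUsageID = syn$taxon_id, taxonomicStatus = "synonym"))
  }
  readr::write_tsv(acc, path, progress = FALSE)
  path
}

#' Generate one synthetic reference on disk
#'
#' Emits a structurally valid miniature taxonomy (single root, lineage
#' kingdom -> genus -> species) in the requested dialect. Generated names
#' are pronounceable Latin-like strings with pairwise edit distance at
#' least `spec$min_dist` unless near-duplicates are requested; planted
#' hemihomonym genus pairs and synonyms are included per the spec.
#'
#' @param spec A [fixture_spec()].
#' @param dialect `"ncbi-taxdump"` or `"dwc-taxon"`.
#' @param dir Output directory.
#' @param reference Reference name used as the file prefix.
#' @return List with `paths` (suitable for [parse_reference()]/
#'   [load_reference_set()]) and `truth`, the ground-truth node table.
#' @export
generate_reference_fixture <- function(spec, dialect = c("ncbi-taxdump", "dwc-taxon"),
                                       dir, reference = "ref1") {
  dialect <- match.arg(dialect)
  out <- generate_fixture_set(spec, setNames(dialect, reference), dir)
  list(paths = out$config$paths[[1]], truth = out$truth)
}

#' Generate a multi-reference fixture set
#'
#' Builds one underlying taxonomy, then emits each requested reference in
#' its dialect: a `shared_fraction` of the species appear in every
#' reference, the rest are dealt round-robin as reference-unique species.
#' All genera and kingdoms appear in every reference, so lineage-based
#' nearest mapping is always exercised for unshared species.
#'
#' @param spec A [fixture_spec()].
#' @param dialects Named character vector: reference name -> dialect.
#' @param dir Output directory.
#' @return List with `config` (tibble ready for [load_reference_set()]) and
#'   `truth` (tibble: `reference`, `taxon_id`, `canonical_name`, `rank`,
#'   `domain`, `synonym`, `shared`).
#' @export
generate_fixture_set <- function(spec, dialects, dir) {
  stopifnot(length(dialects) >= 1, !is.null(names(dialects)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tax <- build_taxonomy(spec)
  n_shared <- round(spec$shared_fraction * spec$n_species)
  shared_idx <- seq_len(n_shared)
  rest <- setdiff(seq_len(spec$n_species), shared_idx)
  owner <- rep(seq_along(dialects), length.out = length(rest))
  truth <- list()
  config <- list()
  for (r in seq_along(dialects)) {
    rn <- names(dialects)[[r]]
    sp_keep <- sort(c(shared_idx, rest[owner == r]))
    # hemihomonym genus pairs go into every reference, but their species
    # only into the first one, so the domain-aware nearest-mapping path is
    # exercised when they are queried against the other references
    flat <- taxonomy_nodes(tax, sp_keep,
                           include_hemi_species = (r == 1 || length(dialects) == 1))
    paths <- switch(dialects[[r]],
                    "ncbi-taxdump" = write_ncbi_dialect(flat, dir, rn),
                    "dwc-taxon" = write_dwc_dialect(flat, dir, rn),
                    abort(paste0("unknown dialect: ", dialects[[r]])))
    config[[length(config) + 1]] <- tibble::tibble(
      reference = rn, dialect = dialects[[r]], paths = list(paths))
    truth[[length(truth) + 1]] <- dplyr::mutate(
      flat, reference = rn,
      shared = .data$canonical_name %in% tax$sp_names[shared_idx])
  }
  list(config = dplyr::bind_rows(config), truth = dplyr::bind_rows(truth))
}

#' Inject typographical errors into a name
#'
#' Applies `k` edit operations drawn uniformly from substitution, insertion,
#' deletion and adjacent transposition at uniform positions (alphabet
#' a-z). The first character is never altered by default, so the
#' genus-block pruning stage of the corrector stays exercised. The edit
#' distance between original and corrupted string never exceeds `k`.
#'
#' @param name Input string (length must exceed `k`).
#' @param k Number of edit operations (>= 0).
#' @param seed Optional integer seed for reproducible corruption.
#' @param preserve_first Keep the first character untouched (default TRUE).
#' @return The corrupted string.
#' @export
inject_typos <- function(name, k, seed = NULL, preserve_first = TRUE) {
  stopifnot(k >= 0, nchar(name) > k)
  run <- function() {
    s <- strsplit(name, "")[[1]]
    lo <- if (preserve_first) 2L else 1L
    for (i in seq_len(k)) {
      op <- sample(c("sub", "ins", "del", "tra"), 1)
      n <- length(s)
      if (op == "sub") {
        p <- sample(seq(lo, n), 1)
        s[[p]] <- sample(letters, 1)
      } else if (op == "ins") {
        p <- sample(seq(lo, n + 1L), 1)
        s <- append(s, sample(letters, 1), after = p - 1L)
      } else if (op == "del" && n > lo) {
        p <- sample(seq(lo, n), 1)
        s <- s[-p]
      } else if (op == "tra" && n > lo) {
        p <- sample(seq(lo, n - 1L), 1)
        s[c(p, p + 1L)] <- s[c(p + 1L, p)]
      }
    }
    paste(s, collapse = "")
  }
  # interacting operations (e.g. an edit inside a transposed pair) can
  # realise a distance above k under the restricted distance; resample
  # until the corrupted string is genuinely within k edits
  run_checked <- function() {
    for (tries in 1:100) {
      out <- run()
      if (damerau_levenshtein(name, out) <= k) return(out)
    }
    name
  }
  if (!is.null(seed)) withr::with_seed(seed, run_checked()) else run_checked()
}

#' Build a typo test table from canonical names
#'
#' @param names_tbl Data frame with columns `canonical_name` and `taxon_id`.
#' @param k Number of typos per name.
#' @param seed Integer seed.
#' @return Tibble: `corrupted`, `original`, `taxon_id`, `k`.
#' @export
generate_typo_table <- function(names_tbl, k, seed = 1L) {
  withr::with_seed(seed, {
    tibble::tibble(
      corrupted = vapply(names_tbl$canonical_name, inject_typos, character(1),
                         k = k, USE.NAMES = FALSE),
      original = names_tbl$canonical_name,
      taxon_id = names_tbl$taxon_id,
      k = as.integer(k)
    )
  })
}

#' Generate species-compound pair tables with a planned support structure
#'
#' Draws species from the target reference and synthetic structure strings,
#' assigns each pair a support level from `support_plan`, and writes the
#' pair into that many randomly chosen source tables. Occurrences are
#' optionally perturbed with one typo at `typo_rate`, so integration still
#' recovers the planned support exactly on separation-guaranteed fixtures.
#' `n_genus_only` extra pairs carry `"<Genus> sp."` names (mappable only at
#' genus level) and `n_unmappable` carry garbage names; both are planned
#' exclusions.
#'
#' @param refset A `taxmap_refset`.
#' @param target Target reference name.
#' @param support_plan Named integer vector: support level -> number of
#'   pairs (e.g. `c("1" = 3, "2" = 1, "4" = 1)`).
#' @param sources Character vector of source-database labels (at least the
#'   maximum planned support).
#' @param typo_rate Probability that an occurrence is written with one typo.
#' @param n_genus_only,n_unmappable Planned exclusions (support 1 each).
#' @param seed Integer seed.
#' @return List: `tables` (named list of per-source tibbles with `name`,
#'   `structure`), `truth` (tibble: `taxon_id`, `structure`, `support`).
#' @export
generate_np_pairs <- function(refset, target, support_plan = c("1" = 6, "2" = 3, "3" = 1),
                              sources = c("srcA", "srcB", "srcC", "srcD"),
                              typo_rate = 0.1, n_genus_only = 0L,
                              n_unmappable = 0L, seed = 1L) {
  support_levels <- as.integer(names(support_plan))
  stopifnot(all(support_levels >= 1), max(support_levels) <= length(sources))
  target_ref <- refset$references[[target]]
  species <- target_ref$nodes[target_ref$nodes$rank == "species", ]
  n_pairs <- sum(support_plan)
  withr::with_seed(seed, {
    sp_pick <- species[sample(nrow(species), n_pairs, replace = TRUE), ]
    structure_str <- sprintf("C1CCCCC1N%04d", sample(9999, n_pairs))
    support <- rep(support_levels, support_plan)
    tables <- setNames(lapply(sources, function(s) {
      tibble::tibble(name = character(0), structure = character(0))
    }), sources)
    for (i in seq_len(n_pairs)) {
      chosen <- sample(sources, support[[i]])
      for (s in chosen) {
        nm <- sp_pick$canonical_name[[i]]
        if (stats::runif(1) < typo_rate) nm <- inject_typos(nm, 1L)
        tables[[s]] <- dplyr::bind_rows(tables[[s]],
                                        tibble::tibble(name = nm, structure = structure_str[[i]]))
      }
    }
    if (n_genus_only > 0) {
      gen <- target_ref$nodes[target_ref$nodes$rank == "genus", ]
      gpick <- gen[sample(nrow(gen), n_genus_only, replace = TRUE), ]
      for (i in seq_len(n_genus_only)) {
        s <- sample(sources, 1)
        tables[[s]] <- dplyr::bind_rows(tables[[s]], tibble::tibble(
          name = paste(gpick$canonical_name[[i]], "sp."),
          structure = sprintf("C1CCCCC1X%04d", i)))
      }
    }
    if (n_unmappable > 0) {
      for (i in seq_len(n_unmappable)) {
        s <- sample(sources, 1)
        tables[[s]] <- dplyr::bind_rows(tables[[s]], tibble::tibble(
          name = paste(random_word(4), random_word(4)),
          structure = sprintf("C1CCCCC1Z%04d", i)))
      }
    }
    truth <- tibble::tibble(taxon_id = sp_pick$taxon_id,
                            structure = structure_str, support = support) |>
      dplyr::group_by(.data$taxon_id, .data$structure) |>
      dplyr::summarise(support = max(.data$support), .groups = "drop")
    list(tables = tables, truth = truth)
  })
}
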