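# taxmapr

Multi-reference scientific-name mapping for taxonomic and natural-product
data.

## The problem

Scientific names are the universal label for species yet a poor database
key. The major checklists (Catalogue of Life, Encyclopedia of Life, GBIF,
NCBI Taxonomy) disagree on which form of a name is accepted — kiwifruit is
*Actinidia chinensis deliciosa* in one checklist and *Actinidia deliciosa*
in another — identical names are reused across nomenclatural codes
(hemihomonyms), and real sources add typos, strain codes ("*Streptomyces*
sp. ABC-123"), vernacular names and Latin-inflected drug names
("Glycyrrhizae radix"). Anyone integrating biodiversity or natural-product
occurrence data — where every record is a (species name, compound) pair —
needs those strings resolved to stable taxon identifiers first.

`taxmapr` maps raw name strings to taxon identifiers in a chosen reference
while consulting several references simultaneously, so synonymy and
phylogenetic lineage recorded in one checklist can rescue queries absent
from another.

## The method

Each query is normalised (vernacular substitution, authority and
parenthetical stripping, semantic screening) and pushed through a six-stage
cascade, stopping at the first success; every outcome carries a status code:

| Stage | Codes | Idea |
|---|---|---|
| Exact match | 0–5 | raw / simplified / case-folded hit on canonical names and synonyms |
| Synonym recursion | 6, 8 | names of a taxon matched in *another* reference tried against the target |
| Nearest taxon | 10–18 | lineage walked tip-to-root; first ancestor resolvable in the target, rank-tier coded; homonymic ancestors resolved by kingdom/domain agreement |
| Strain / cf. / aff. routing | 40–43 | strain codes bypass spelling correction; the stripped binomial's species or genus container is returned |
| Spelling correction | 20–24, 30–36 | restricted Damerau–Levenshtein (d ≤ 3) over the genus bucket, then whole-string with Latin declension reconstruction (−ae → −a, −i → −us/−um/−is, …) |
| Partial / dropout | 100, 1000, 90–99 | longest matching prefix; keyword queries (virus, phytoplasma, …) halt with no taxon |

The correction distance is the restricted Damerau–Levenshtein distance
(insertions, deletions, substitutions, adjacent transpositions), computed in
C++ over a candidate pool pruned by shared first word-block, length
difference ≤ d and character-multiset difference ≤ 2d.

## Worked example

The package ships deterministic generators for miniature references in both
supported dialects (NCBI taxdump and Darwin-Core taxon tables), so the whole
system runs with no downloads:

```r
library(taxmapr)
library(dplyr)

spec <- fixture_spec(n_species = 40, n_genera = 8, synonym_rate = 0.25,
                     shared_fraction = 0.5, seed = 2024)
dir <- tempfile("refs")
fx <- generate_fixture_set(spec, c(ncbi = "ncbi-taxdump", col = "dwc-taxon"), dir)
refset <- load_reference_set(fx$config)
glance(refset)
#> # A tibble: 1 × 5
#>   n_references n_taxa n_indexed_names n_synonyms n_valid_names
#>          <int>  <int>           <int>      <int>         <int>
#> 1            2     84              94         10            59

sp <- refset$references$col$nodes |> filter(rank == "species")
queries <- c(
  sp$canonical_name[[1]],                          # clean canonical name
  inject_typos(sp$canonical_name[[2]], 2, seed = 9),  # two planted typos
  paste(sp$canonical_name[[3]], "DSM-1042"),       # strain-coded
  "Tobacco mosaic virus")                          # host name, no signal
map_names(queries, refset, target = "col") |>
  select(query, status_code, taxon_id, matched_name, distance, stage)
#> # A tibble: 4 × 6
#>   query                        status_code taxon_id matched_name  distance stage
#>   <chr>                              <int> <chr>    <chr>            <int> <chr>
#> 1 Dopobitenofa popobuvefiri              0 13       Dopobitenofa…        0 exact
#> 2 Mopaturotifa guroleseipus             20 14       Mopaturotifa…        2 epit…
#> 3 Modusipa torebasise DSM-1042          40 15       Modusipa tor…        0 stra…
#> 4 Tobacco mosaic virus                  90 <NA>     <NA>                 0 drop…
```

Row 1 is an exact canonical hit (status 0). Row 2 carried two typos and was
recovered by epithet-only correction at distance 2 (status 20). Row 3 was
recognised as strain-coded and routed to its species container without any
spelling correction (status 40). Row 4 names the host of a virus, carries no
taxonomic signal about itself, and is dropped with no taxon (status 90).
`status_codes()` prints the full code table.

Other entry points: `canonical_status_classify()`, `hemihomonym_scan()`,
`rank_disagreement_scan()` and `overlap_counts()` quantify disagreements
between loaded references; `integrate_pairs()` + `support_histogram()`
standardise and merge species-compound tables from several source databases;
`run_batch()` (and the thin `inst/cli/taxmapr` script) provide file-in,
file-out batch mapping with caches and logs.

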