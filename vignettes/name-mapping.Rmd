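---
title: "Mapping scientific names across taxonomic references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping scientific names across taxonomic references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxmapr)
library(dplyr)
```

## The problem

Scientific names are the lingua franca for biological species, but they make
poor database identifiers: names are revised as taxonomy moves, the major
checklists (Catalogue of Life, Encyclopedia of Life, GBIF, NCBI Taxonomy)
disagree about which form of a name is the accepted one, identical names are
legitimately reused across nomenclatural codes (hemihomonyms such as the
conifer genus *Agathis* and the braconid wasp genus *Agathis*), and
real-world sources — ethnobotanical literature, natural-product occurrence
databases, legacy spreadsheets — contribute typos, strain codes, vernacular
names and Latin-inflected drug names ("Glycyrrhizae radix"). `taxmapr`
resolves such strings to taxon identifiers in a chosen reference while
consulting all loaded references at once, so that synonymy and lineage
information recorded in one checklist can rescue a query that is absent from
another.

## The mapping cascade

Each query is preprocessed (vernacular substitution from a curated map,
rule-based simplification that removes authority strings and parenthesised
spans, then semantic screening for strain codes, `cf.`/`aff.`, hybrid marks,
dropout keywords and genus-only forms) and then pushed through six stages,
stopping at the first success:

1. **Exact matching** (status 0–5): the raw string, its case-folded form and
   its simplified form against the target's name index (canonical names and
   synonyms). A key carried by several distinct taxa yields the homonym
   code 5.
2. **Synonym recursion** (6/8): if the query matched exactly in another
   reference but not the target, the canonical name and all synonyms of the
   matched taxon are tried against the target; one taxon gives 6, several
   give 8.
3. **Nearest-taxon mapping** (10–18): a query that is a valid name somewhere
   is never spell-corrected. Instead the matched node's lineage is walked
   tip-to-root and the first ancestor resolvable in the target is returned,
   with the status keyed to its rank tier (10 species … 17 domain). When an
   ancestor name is a homonym in the target, the candidate whose
   kingdom/domain label agrees with the source lineage wins, so
   cross-domain hemihomonyms never capture the query.
4. **Rule-based routing/dropout**: strain-coded and `cf.`/`aff.` queries
   bypass edit-distance correction entirely (strain codes are string-similar
   but taxonomically meaningless); the stripped binomial or genus is
   resolved instead (40–43, with `cf.`/`aff.` deliberately returning a
   higher taxon of the match). Queries built around keywords such as
   *virus* or *phytoplasma* name the host, not the entity, and halt with
   90–99 and no taxon; hybrids likewise (95).
5. **Edit-distance correction** (20–24, then 30–36): restricted
   Damerau-Levenshtein distance (insertions, deletions, substitutions,
   adjacent transpositions), first over the genus bucket — names sharing the
   query's first word-block, pruned by length difference and character
   multiset difference before any distance is computed — then over the whole
   valid-name list with the same pruning. Whole-string correction first
   tries Latin declension reconstruction: part terms (*radix*, *herba*,
   *cortex*, …) are removed and genitive suffixes expanded to nominative
   candidates (`-ae → -a/-e`, `-i → -us/-um/-is`, …), whose exact hits get
   status 30/31.
6. **Partial mapping** (100/1000): prefix word-blocks are tried
   longest-first; a hit gives 100, exhaustion 1000.

`status_codes()` prints the full table. The ranges are fixed by the cascade
design; the per-code assignment inside each range is this package's own and
is stable.

```{r codes}
status_codes()
```

## Parameters that matter

* `max_d` (default **3** edits) bounds both correction stages. Three edits
  is the heaviest typo load the cascade is designed to recover, and the
  candidate-pool pruning (length difference ≤ `max_d`, character-multiset
  difference ≤ `2·max_d`) is derived from it.
* The **dropout keyword** and **part-term** lists default to the common
  cases (virus, viroid, phytoplasma, endosymbiont, phage; herba, radix,
  cortex, folium, flos, fructus, semen, rhizoma, et) and are extensible via
  `taxmap_config()` or a key-value config file.
* The **year heuristic**: a digit token is a description year only if it is
  a 4-digit number in 1700–2099; any other digit-bearing token marks the
  query strain-like.
* The **authority rule** drops, from the third word-block onward, capitalised
  blocks that contain lowercase letters (authors), single-letter
  abbreviations with a period ("L."), and `&`. All-caps/digit-bearing blocks
  are kept — they are isolate codes, not authors. The first two word-blocks
  are never dropped, so binomials survive.
* The **rank-tier order** for nearest mapping is species < genus < family <
  order < class < phylum < kingdom < domain; intermediate ranks collapse
  onto these tiers and unranked ancestors inherit the tier of the nearest
  ranked descendant.

## Design choices made where the design was open

* **Exact-match code table**: 0/1 raw canonical/synonym, 2/3 after
  simplification, 4 case-insensitive variant, 5 exact multi-taxon. Multiple
  taxon ids are reported only under the designated multi-match codes (5, 8,
  22, 31, 34); everywhere else a deterministic single id (lowest
  reference-local id) is returned — partial mapping on a homonymic prefix is
  the one place this bites, and silent arbitrariness seemed worse than a
  documented deterministic rule.
* **Whole-string correction pool**: not restricted to the query's first
  word-block, because a typo may sit in the generic epithet itself and the
  epithet-only stage already covers the same-genus bucket. Both canonical
  names and synonyms are searched, consistent with the pooled valid-name
  list used for exact matching.
* **Genus-only routing**: only explicit `"<Genus> sp."` forms are routed to
  the genus container (status 43). A bare unmatched single word-block is
  more likely a damaged name (e.g. a binomial whose space was lost) and is
  sent through the correction stages instead.
* **Declension table**: the suffix table (`-ae`, `-i`, `-is`, `-orum`,
  `-arum`, `-us`) covers the standard noun declensions seen in
  materia-medica names. It is declared in `taxmap_config()` and makes no
  claim of completeness; unknown suffixes leave the block unchanged.
* **Flag priority** is dropout > hybrid > `cf.`/`aff.` > strain-like >
  genus-only: a dropout keyword means the query carries no taxonomic signal
  at all, so nothing downstream should run.

## The synthetic-data generators

Because no gold-standard corpus of erroneous scientific names exists, the
package ships generators that construct ground truth by design.

`generate_fixture_set()` emits miniature references (NCBI-taxdump and
Darwin-Core dialects) over a single taxonomy: one root, kingdoms, genera,
species. Names are pronounceable Latin-like strings kept at pairwise edit
distance ≥ `2·max_d + 1 = 7` by rejection sampling, so after injecting up to
`max_d` typos the original is provably the unique nearest name and every
recovery measurement has an exact expected value. Generated genus names take
a first-declension `-a` ending so genitive (`-ae`) test forms are always
constructible. Planted structure includes synonyms (default rate 0.2),
cross-domain hemihomonym genus pairs (whose species are emitted only in the
first reference, so the domain-aware nearest-mapping path is actually
exercised), a configurable fraction of species shared across references,
and — only on request — near-duplicate siblings within edit distance 2 that
deliberately break the separation guarantee (`near_duplicate_rate`; 0.005 is
used in the stress checks, reflecting that near-identical epithets are rare
but real).

`inject_typos()` applies `k` operations drawn uniformly from substitution,
insertion, deletion and adjacent transposition at uniform positions
(alphabet a–z). The first character is preserved by default so the
genus-bucket pruning stage stays in play rather than being trivially
bypassed. Because interacting operations can realise a restricted-DL
distance above `k`, the injector verifies the realised distance and
resamples when needed — the contract `distance(original, corrupted) ≤ k`
always holds.

`generate_np_pairs()` builds species-compound occurrence tables across 2–4
synthetic source databases with a *planned* support histogram (how many
sources carry each pair), optional single-typo perturbation of the name
occurrences, and planned exclusions (genus-only names, garbage names), so
the integration pipeline can be checked for exact histogram recovery and
count conservation.

What the fixtures deliberately do **not** emulate: authority strings inside
reference files, infraspecific ranks, the rank-ladder irregularities of real
checklists, non-Latin scripts, and the sheer scale of the real databases
(millions of names, where hash-index memory and tie frequencies behave
differently). Passing the fixture suite therefore demonstrates the
correctness of the algorithms under controlled conditions, not
database-scale accuracy figures.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which every code path (all cascade stages, both dialects,
multi-reference recursion, hemihomonym disambiguation) is exercised with
stable statistics: 500-species references for typo recovery (k = 0–3),
40 hemihomonym genus pairs (80 planted species) for domain consistency with
a seeded random-choice null, 100 planned pairs for integration. Distances
are computed in C++ with a band bound (`max_d + 1` means "too far"), and all
randomness flows from a single user seed through deterministic offsets, so
identical seeds give byte-identical fixtures and results.

Degenerate inputs are defined, not errors: empty or punctuation-only strings
get the content-free code 99; every input yields exactly one record and one
status code.

## Known limitations

* Nomenclatural authorship is stripped, never parsed; author/year homonyms
  within one code cannot be separated.
* No phonetic matching: errors beyond `max_d` edits that sound alike
  ("Koeleria"/"Celeria") are out of reach by design.
* Synonym recursion is one step deep (canonical ↔ synonym of a matched
  node), not transitive closure over chains of references.
* EoL-style rows lacking parent pointers keep a truncated lineage; rows
  whose accepted target is missing are dropped and counted.
* The integration pipeline treats structure canonicalisation as an injected
  contract; chemistry is out of scope here.
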