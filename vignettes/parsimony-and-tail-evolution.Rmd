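---
title: "Parsimony analysis and the evolution of the dromaeosaurid tail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony analysis and the evolution of the dromaeosaurid tail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caudotheca)
```

## The problem

Dromaeosaurid theropods carry a distinctive tail skeleton: in most species
the distal caudal vertebrae are encased in a bundle of bony rods — greatly
elongated prezygapophyses and chevron (hemal arch) processes — for which
the term *caudotheca* is used. Two departures from this condition matter
phylogenetically: unenlagiines lack the sheath entirely, and the giant
dromaeosaurines *Utahraptor* and *Achillobator* show a *hemicaudotheca*,
prezygapophyses elongated but extending little more than one centrum
length. Whether the hemicaudotheca is a precursor of the full sheath or a
secondary reduction is a question about character history on a phylogeny,
and answering it requires (i) a parsimony analysis of a large discrete
morphological matrix and (ii) parsimony mapping of tabulated caudal
characters onto the resulting tree. This package implements both stages as
reusable, tested functions, together with a simulator that makes every
stage verifiable without external data.

## Parsimony machinery

**Scoring.** A character is a per-taxon state *set*: singletons, polymorphic
cells (`{01}`), missing (`?`, the full set) and inapplicable (`-`). Two
scorers are implemented and cross-checked against each other and against
external oracles in the tests: a bitmask Fitch kernel (C++) for unordered
characters on binary trees, and a Sankoff dynamic program (R) that handles
ordered (linear-cost) characters, polytomies, and all ancestral-state work.
Polymorphic cells are treated as uncertainty — any member state may be
assigned — rather than charged extra steps; inapplicable cells are scored
as missing by default, with `gap_as_state = TRUE` available where the
inapplicable condition should count as evidence. These conventions are the
defaults of the standard search programs for this kind of matrix, and they
are what make printed ensemble statistics reproducible.

**Step bounds and homoplasy indices.** For each character the minimum
conceivable length `m` (on any tree) and maximum `g` (the star-tree length)
are computed with ambiguity resolved in the direction that favors the bound:
`m` minimizes the number of observed states (a minimum hitting set over the
cell sets; for ordered characters, the narrowest covering state window) and
`g` maximizes the modal state frequency (for ordered characters, the best
median state). The ensemble indices are CI = M/S, HI = 1 − CI,
RI = (G − S)/(G − M), RC = CI·RI. Parsimony-uninformative characters are
**included** in the ensemble sums by default: that is the convention under
which the printed CI/HI pair of the reference analyses sums to exactly 1,
and `include_uninformative = FALSE` exposes the alternative.

**Search.** `heuristic_search()` runs seeded random addition-sequence
replicates (ties in the stepwise placement broken by a fixed enumeration
order of insertion edges) followed by branch swapping. TBR is the default
neighborhood, mirroring the default of the reference search program; SPR
and NNI are provided and are verified to be nested subsets of TBR. Swapping
is breadth-first over a visited set keyed on canonical tree strings,
keeping every tree of length ≤ the current best and restarting from
improvements. Per-replicate seeds are drawn from the master seed by one
`sample.int()` call, so runs are reproducible and replicates independent.
`exhaustive_search()` enumerates all `(2n−5)!!` topologies (refused above 9
taxa by default) and serves as the exact oracle throughout the test suite;
on every tested instance the heuristic attains the exact optimum.

**Counting trees: the collapse rule.** How many "distinct"
most-parsimonious trees a search reports depends on a convention the
analyses themselves rarely state: whether binary resolutions whose extra
edges have no character support are counted separately. The package's
default (`collapse = "min"`) collapses internal branches whose minimum
optimized length over all most-parsimonious reconstructions is zero, then
deduplicates by bipartition sets; `collapse = "never"` keeps all binary
resolutions. Because published tree counts depend on this unstated
convention, lengths, consensus topology and statistics are the reliable
quantities; counts are reported under the configured rule but treated as
secondary.

**Support.** `decay_index()` computes Bremer support as
`L(¬clade) − S_min` by a converse-constraint search: candidate trees
containing the clade are penalized out of consideration during both
stepwise addition and swapping. On small instances this is verified to
equal the value obtained by enumerating all topologies and binning by
clade presence. `decay_table()` runs one constrained search per internal
bipartition of the strict consensus; every consensus clade necessarily has
decay ≥ 1.

**Ancestral states.** `optimize_states()` resolves the set of
most-parsimonious reconstructions exactly by a preorder pass over the
Sankoff cost tables. The two classical conventions differ only in
tie-breaking: ACCTRAN prefers a change on the current (rootward) branch,
DELTRAN prefers the parent's state; remaining ties go to the lowest state
label, and the root takes its lowest-label optimal state. Both modes are
verified to achieve the per-character minimum change count and to be
members of the brute-force set of optimal assignments; across differing
reconstructions ACCTRAN's changes always sit at or above DELTRAN's in the
tree. `synapomorphy_list()` reports the stem-branch changes of a clade with
a `both` / `ACCTRAN-only` / `DELTRAN-only` support flag, mirroring how
apomorphy tables are reported.

## The coelurosaurian matrix

The full published character-taxon matrix (≥ 307 characters, including two
pelvic-girdle characters added in its latest revision) is distributed
upstream only as word-processor supplementary files. The package therefore
defines a canonical plain-text transcription (NEXUS `DATA` block with
`SYMBOLS`/`MISSING`/`GAP`, optional `ASSUMPTIONS` `TYPESET` marking ordered
characters; a template ships in `inst/extdata/`) and automates everything
downstream of transcription. All characters default to unordered, matching
the conventions of the source analyses; an assumptions block can override
per character. With a transcription in place, `run_analysis()` reproduces
the full workflow — search, statistics, consensus, decay, synapomorphies —
and the reduced rerun after deletion of fragmentary deinonychosaurian
terminals; without it, those specific reruns are the only part of the
package that cannot execute, and the corresponding acceptance tests fail
with an explanatory message rather than being skipped.

## The tail module

`tail_table()` ships the printed tabulation of coelurosaurian caudal
skeletons: caudal count NC, last transverse-process-bearing caudal TP,
first elongated centrum E, first caudotheca contributor PZ, first caudal
contacted by the sheath C, twofold mid-caudal elongation, and presence of
an abrupt transition point. Values are parsed as intervals: `">10"` becomes
[11, ∞), `"24-26"` a closed range (one reversed range in the printed table
is normalized), `"36 (+4)"` spans the preserved count and the
estimate-inclusive total, and `"approx. 30"` is taken at face value with an
approximation flag. `?` is unknown; `-` is inapplicable — the distinction
matters, because inapplicable PZ and C *is* the observation that no
caudotheca exists.

`encode_tail_characters()` discretizes the records into seven unordered
characters: the caudotheca (absent / hemicaudotheca / caudotheca), the
transition point (none / type 1, the ornithomimid condition with
prezygapophyseal elongation / type 2, the paravian condition with centrum
elongation), twofold elongation, binned NC (≤24, 25–30, >30), binned TP
(≤6, 7–12, ≥13), and two-state codings of PZ (contributor at or before the
6th caudal vs farther back) and C (sheath reaching the 3rd–4th caudal vs
the 6th or beyond). Bin edges are package choices: the NC bins separate the
short-tailed condition from the eudromaeosaurian re-elongation while
leaving boundary-straddling intervals ambiguous (they encode as state
sets, or as missing when they span all bins), and the TP/PZ/C cutoffs are
the microraptorian-vs-eudromaeosaurian contrasts stated with the
tabulation. Taxa with a hemicaudotheca but no table row (*Utahraptor*,
*Achillobator*, and the newly described *Yurgovuchia*, whose diagnosis
states the condition) are injected from a separate side table so the
printed-table transcription stays pristine.

The mapping tree (`coelurosaur_tree()`) is assembled in code from the
analysis's stated consensus relationships, restricted to taxa with tail
data plus the hemicaudothecate dromaeosaurines: unenlagiines basal within
Dromaeosauridae, Microraptoria sister to Eudromaeosauria, and
*Bambiraptor*, velociraptorines and *Deinonychus* as successive sister
groups of the dromaeosaurine clade, with polytomies where relationships
are unresolved. It is a derived reference object, not data; the isolated
tail skeleton UMNH VP 20209 is deliberately not attached (its position is
open) and is instead handled by `classify_tail_condition()`. Mapping the
seven characters recovers the expected transitions, notably the single
origin of the caudotheca on the branch uniting microraptorians and
eudromaeosaurs followed by its reduction to a hemicaudotheca *inside* that
clade, and the reversal of twofold centrum elongation within
Eudromaeosauria.

`classify_tail_condition()` deviates deliberately from a rule keyed on TP
alone: the tabulated eudromaeosaurs span TP = 6 (*Bambiraptor*) to TP > 12
(*Tsaagan*), so transverse-process extent cannot separate the two patterns
by itself. Classification is keyed on the caudotheca geometry — C ≤ 4 with
PZ ≤ 6 is microraptorian, C ≥ 5 with PZ ≥ 7 eudromaeosaurian — with TP as a
secondary consistency check and interval logic throughout; values that
straddle a boundary return `indeterminate` rather than a guess. Under the
conservative assumption of four missing proximal caudals,
`infer_caudotheca_position(4, 3)` bounds the new tail skeleton's sheath at
the 7th caudal (first contributor no farther cranial than the 8th), which
places it in the eudromaeosaurian pattern.

## The simulator

`simulate_tree()` draws uniform unrooted topologies (or Yule trees) and
`evolve_characters()` runs a symmetric Mk-style change process — per
branch, a character changes with a fixed probability to a uniformly chosen
other state (±1 for ordered characters). Symmetry keeps the parsimony
target well-defined for recovery tests. `degrade_matrix()` adds uniform
missingness, taxon-concentrated missingness for designated fragmentary
terminals (the fossil regime whose deletion the reduced analysis studies),
and polymorphic cells, recording the ground-truth mask. `clean = TRUE`
engineers one cleanly marking binary character per internal edge, so the
generating tree is the unique most-parsimonious tree with CI = 1 — the
fixture used for end-to-end identities.

What the simulator does **not** emulate: correlated characters, ordered
multistate asymmetries, rate heterogeneity across lineages, or the
non-random anatomical structure of real fossil missingness (whole body
regions absent together). Passing recovery tests therefore demonstrate the
correctness of the machinery, not the reliability of parsimony on real
matrices.

## Numerical choices and limitations

Exhaustive enumeration is capped at 9 taxa (135,135 topologies) and the
constraint penalty is additive and large (1e7) rather than a hard filter,
so constrained searches can traverse violating regions. Duplicate columns
are compressed with weights before scoring. Test and script problem sizes
(5–10 taxa, tens of characters, 20–50 instance batches; the synthetic
acceptance analysis uses 16 taxa × 200 characters with 5 replicates) were
chosen so the full suite exercises every code path in a few minutes while
the exact oracles remain feasible. Known limitations: the heuristic search
carries no optimality guarantee on large matrices (the published replicate
count of 1000 is available as configuration but not the default); island
counts are a connectivity approximation over replicate tree sets; and
reported MPT counts inherit the collapse-rule caveat above.
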