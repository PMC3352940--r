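# caudotheca

Maximum-parsimony phylogenetics for discrete morphological matrices, with a
dedicated module for the evolution of the dromaeosaurid tail skeleton.

The package is aimed at systematists working with fossil character-taxon
matrices: a few hundred unordered multistate characters, polymorphic cells,
and heavy missing data concentrated on fragmentary terminals. It
reimplements, as tested and reusable R functions, the complete workflow of
a parsimony study of Coelurosauria: matrix parsing, tree search, homoplasy
statistics, clade support, apomorphy mapping, and the tracing of caudal
(tail) characters — including the bony sheath of elongated prezygapophyses
and chevron processes called the *caudotheca*, and its reduced counterpart,
the *hemicaudotheca* — across the phylogeny.

## The model

For a character with cell state sets `x_i` on the leaves of a tree `T`, the
parsimony length is the minimum number of state changes over all
internal-node assignments,

    s(T) = min over assignments  sum over edges (u,v)  c(a_u, a_v)

with unit change costs for unordered characters (Fitch) and linear
(Manhattan) costs for ordered ones (Sankoff). Missing and inapplicable
cells constrain nothing; polymorphic cells are uncertainty sets. The tree
length is `S = sum_i s_i`, and the ensemble homoplasy indices are

    CI = M / S        (consistency index,  M = sum of per-character minima)
    HI = 1 - CI       (homoplasy index)
    RI = (G - S) / (G - M)   (retention index, G = star-tree maxima)
    RC = CI * RI      (rescaled consistency index)

Most-parsimonious trees are found by random addition-sequence replicates
followed by TBR (or SPR/NNI) branch swapping that retains all equally short
trees; small instances can be solved exactly by enumeration of all
`(2n-5)!!` topologies. Bremer support (decay) of a clade is
`L(not clade) - S_min`, computed by rerunning the search while rejecting
every tree containing the clade. ACCTRAN and DELTRAN resolve ambiguous
reconstructions rootward and tipward respectively; both always realize the
minimum change count.

## Worked example

A fossil-style simulated matrix (10 taxa, 60 three-state characters, 15%
missing cells plus two fragmentary terminals masked at 80%):

```r
library(caudotheca)

cfg <- simulation_config(n_taxa = 10, n_char = 60, seed = 7, rate = 0.1,
                         missing_fraction = 0.15, fragmentary_count = 2,
                         fragmentary_missing = 0.8)
m <- degrade_matrix(evolve_characters(simulate_tree(10, seed = 7), cfg), cfg)

res <- heuristic_search(m, search_config(replicates = 10, seed = 1))
res
#> search_result: best length 74, 33 tree(s) (71 binary resolutions)
#>   10 replicates, tbr swapping, 1 island(s)
homoplasy_stats(m, res$trees[[1]])
#> homoplasy_stats over 60 characters (including uninformative)
#>   S = 74, M = 60, G = 99
#>   CI = 0.8108  HI = 0.1892  RI = 0.6410  RC = 0.5198
```

The 33 equally short trees disagree so thoroughly (the two fragmentary
terminals attach almost anywhere) that the strict consensus is unresolved
and no clade earns a decay index. Deleting the fragmentary terminals — the
reduced analysis — resolves the consensus and produces positive support,
the behavior that motivates rerunning fossil analyses without fragmentary
material:

```r
red <- prune_taxa(m, attr(m, "fragmentary_taxa"))
res2 <- heuristic_search(red, search_config(replicates = 10, seed = 1))
res2
#> search_result: best length 72, 7 tree(s) (7 binary resolutions)
decay_table(red, res2, search_config(replicates = 5, seed = 1))
#>      clade size decay
#> 2    t3,t6    2     4
#> 1 t2,t4,t5    3     2
```

The tail module works from the bundled tabulation of coelurosaurian caudal
skeletons:

```r
tt <- tail_table()
table(classify_tail_condition(tt))
#>            acaudothecate eudromaeosaurian-pattern            indeterminate
#>                       22                        5                        1
#>   microraptorian-pattern
#>                        3

infer_caudotheca_position(4, 3)   # four missing proximal caudals,
#> first_contributing     cranial_extent   # sheath from the 3rd preserved
#>                  8                  7

ch <- map_tail_changes(coelurosaur_tree(), encode_tail_characters(tt))
subset(ch, character == "caudotheca")[, c("from", "to", "acctran", "deltran")]
#>   from to acctran deltran
#> 1    2  1    TRUE    TRUE   # caudotheca reduced to hemicaudotheca
#> 2    0  2    TRUE    TRUE   # caudotheca gained
```

The two caudotheca changes show the sheath being gained once (on the branch
uniting microraptorians and eudromaeosaurs) and later *reduced* to a
hemicaudotheca inside that clade — so the intermediate-looking condition of
the giant dromaeosaurines is a secondary reversal, not a precursor.

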