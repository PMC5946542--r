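# mitorder

Comparative analysis of mitochondrial gene-order rearrangements in
snakes: arrangement typing, rearrangement-feature detection, event-path
inference between arrangements, and parsimony mapping of arrangements
onto a phylogeny to count independent rearrangement events and localize
hotspots.

## Who this is for

Researchers comparing annotated mitogenomes across a clade who want to
go beyond "the gene order differs": to classify genomes into discrete
arrangement types, name the rearrangement events that separate them, and
ask how often each derived state arose independently on a given tree.
The package is organized around snake mitogenomes — the richest known
system of vertebrate mitogenome rearrangement, with eleven described
arrangement types — but the machinery (circular canonicalization,
rule-based detectors, Fitch/DELTRAN reconstruction) is generic.

## The core ideas

**Typing rule.** A genome arrangement is the circular, strand-aware
sequence of its annotated features; two genomes belong to the same type
iff they have the same components in the same circular order, with
feature lengths abstracted. Comparisons use the canonical key — the
lexicographically minimal rotation of the token string — so the rule is
rotation-invariant, symmetric and transitive. The one deliberate
exception: the type whose only published diagnostic is control-region
length asymmetry (III-E) is separated from its token-identical base
type by a CR length-ratio threshold (max/min > 1.2).

**Event inference.** The difference between two arrangements is
decomposed deterministically into atomic events: token multiset
differences (LOSS; INSERTION of non-coding blocks; PSEUDOGENIZATION;
DUPLICATION), neighbor changes on shared single-copy genes
(TRANSLOCATION, with a minimal-explanation search that prefers mobile
tRNAs), and control-region asymmetry appearing across the threshold
(CR_ASYMMETRY).

**Parsimony mapping.** Tip states (arrangement types, or binary
presence characters such as "carries pseudo-Pro") are reconstructed
with Fitch parsimony; ambiguous ancestral sets are resolved DELTRAN
(transformations delayed tipward), under which independent origins of a
derived state are the edges into it. Roots can be constrained by
outgroup knowledge — e.g. OL-present, since lizards retain the
light-strand replication origin — or held indeterminate (`UNKNOWN`) for
the arrangement character.

## Worked example

Generate an annotated genome of the colubrid/homalopsid pseudo-Pro
arrangement (Type III-C), classify it, and run the bundled 65-taxon
study fixture through the census:

```r
library(mitorder)
library(dplyr)

registry <- arrangement_registry()

rec <- generate_record("III-C", seed = 1, registry = registry)
rec$order[[1]]
#> <mt_order> circular, 41 tokens
#>   F,12S,V,16S,ND1,I,-P*,CR:1100,L2,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,
#>   COX2,K,ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100

classify_order(rec$order[[1]], registry)
#> [1] "III-C"
```

The token string reads linearly from tRNA-Phe: a `-` prefix marks
L-strand genes, `:n` carries lengths in bp, and `-P*` is the degenerate
tRNA-Pro copy sitting immediately 5' of the control region in the
ND1..ND2 segment — the diagnostic feature of this type.

```r
fx <- build_fixture_set(seed = 1, registry = registry)
type_census(classify_records(fx$records, registry))
#>    type      n
#>  1 I         2
#>  2 II        3
#>  3 III      30
#>  4 III-A     1
#>  5 III-B    13
#>  6 III-B1    1
#>  7 III-C    11
#>  8 III-D     1
#>  9 III-E     1
#> 10 III-F     1
#> 11 III-G     1
```

Eleven distinct types across 65 genomes: the two blind-snake types (I,
II, both OL-less), the dominant alethinophidian duplicate-CR type III,
the viperid III-B with its III-B1 variant, the widespread III-C, and
the four singleton types. Downstream:

```r
# independent origins of III-C on the fixture tree (DELTRAN)
cl <- classify_records(fx$records, registry)
st <- setNames(ifelse(cl$type == "III-C", "present", "absent"), cl$taxon_id)
fit <- fitch_reconstruct(fx$tree, st, root_state = "absent")
count_origins(resolve_states(fit), "present")
#> [1] 6

# hotspot census over the registry's diagnostic events
hotspot_census(registry)
#>   locus    n_types
#> 1 CR-flank       7
#> 2 WANCY          3
#> 3 other          3
```

Seven of the eleven types carry at least one rearrangement at the
control regions or their immediate flanks — the CR-flank hotspot — and
`derivation_graph()` reproduces the derivation structure
(`UNKNOWN → {I, II, III}`, `III →` its seven derivatives,
`III-B → III-B1`) with per-edge event lists.

`tidy()`/`glance()` methods expose reconstructions as tibbles, and
`autoplot()`/`plot_gene_order()` draw censuses and linear gene-order
maps.

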