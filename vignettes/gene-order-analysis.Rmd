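---
title: "Comparative analysis of snake mitogenome gene orders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of snake mitogenome gene orders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorder)
library(dplyr)
```

## The problem

Vertebrate mitochondrial genomes are small circular molecules carrying a
nearly fixed complement of 37 genes (22 tRNAs, 2 rRNAs, 13 protein-coding
genes), a control region (CR) and, in most lineages, a light-strand
replication origin (OL) embedded in the WANCY tRNA cluster
(Trp-Ala-Asn-OL-Cys-Tyr). Snakes deviate from the typical arrangement more
than most vertebrate groups: blind snakes have lost the OL, and
alethinophidian snakes carry a duplicated control region with a
translocated tRNA-Leu(UUR). Layered on top of that base arrangement are
lineage-specific translocations, pseudogenes (notably a degenerate
tRNA-Pro copy, written `P*`), duplicated functional genes, large
non-coding insertions, and pronounced length asymmetry between the two
control-region copies.

`mitorder` treats each annotated genome as a circular, strand-aware token
sequence and answers four questions:

1. **Typing** — which *arrangement type* does a genome belong to? Two
   genomes are the same arrangement exactly when they share the same
   components in the same circular order; feature lengths are abstracted.
2. **Feature detection** — which rearrangement features does a genome
   carry (OL presence, CR count and asymmetry, translocations,
   pseudogenes, NC insertions, extra gene copies), and at which hotspot
   locus (WANCY cluster, CR flanks, elsewhere)?
3. **Event paths** — what minimal list of atomic events (loss,
   translocation, duplication, pseudogenization, insertion, CR
   asymmetry) converts one arrangement into another?
4. **Phylogenetic mapping** — given a rooted tree, how often did each
   derived state arise or disappear independently (Fitch parsimony with
   DELTRAN-style resolution), and what derivation graph over types does
   the reconstruction imply?

## Circular canonicalization

A circular order has no natural starting point, so all comparisons go
through a canonical key: the lexicographically minimal rotation of the
token-identity string. Token identity is the triple (name, strand,
pseudo-ness); `P*` never equals `P`, and a gene moved to the opposite
strand changes the arrangement (inversions, although absent from the
known snake types, must not silently collapse). Keys are
rotation-invariant by construction, giving a hashable form of the
identity rule:

```{r}
ord <- parse_order_string("F,12S,V,16S,ND1,I,CR:1100,L2,-Q,M")
substr(canonical_key(ord), 1, 40)
```

For display, `linearize()` rotates an order to start at tRNA-Phe (falling
back to 12S), the two anchors that sit outside every rearranged locus in
the known types. Under anchor duplication the rotation with the smallest
token sequence is chosen, keeping the operation deterministic and
idempotent.

## The type registry

The registry ships the eleven reference arrangements (I, II, III,
III-A...III-G) with their derivation parents. Diagnostic events are not
hand-coded: they are recomputed at registry build time by
`infer_event_path()` against each type's parent order, so the printed
diagnostics always agree with the event machinery. For the three basal
types (I, II, III) the true ancestor is indeterminate; the canonical
squamate order serves purely as the baseline for *describing* their
events, without any claim that it is the actual ancestor.

```{r}
registry <- arrangement_registry()
tidyr::unnest(select(registry, label, parent, events), events) |>
  select(label, parent, kind, subject)
```

One design point deserves emphasis. Type III-E is token-identical to
Type III: its sole published diagnostic is the strongly asymmetric pair
of control regions (2878 bp and 4110 bp). A purely token-level rule would
merge it with III, so the registry marks III-E with an asymmetry flag and
classification promotes a III-keyed record to III-E when its CR length
ratio exceeds the threshold. Type III-F does not need this treatment: its
342 bp non-coding insertion between ND5 and ND6 is a token-level
difference, and we treat the insertion as the primary diagnostic with CR
asymmetry as corroborating evidence.

## Tunable parameters

* **NC threshold, 50 bp** (`pipeline_config()$nc_threshold_bp`). GenBank
  parsing turns unannotated gaps at or above this size into explicit `NC`
  tokens. Typical intergenic spacers in snake mitogenomes are under
  ~30 bp while the smallest diagnostic insertion is 342 bp; 50 bp
  separates the regimes with a wide margin on both sides. How
  sub-threshold spacers were treated in earlier typing work is not
  documented, so the threshold is exposed in the configuration rather
  than buried.
* **CR asymmetry ratio, 1.2** (`cr_asymmetry_ratio`). Concertedly
  evolving CR duplicates are nearly identical in length (ratio ≈ 1.0);
  the smallest diagnostic asymmetry is 4110/2878 ≈ 1.43. The threshold
  1.2 splits the regimes and is exposed in the configuration.
* **Anchor, tRNA-Phe** with 12S fallback: both are universally present
  and outside all rearranged loci.
* **Resolution mode, DELTRAN** (see below); `"acctran"` is available
  behind a flag.

## Translocation calls and their tie-break

A gene is a translocation candidate when it occurs exactly once in both
orders and *both* of its circular neighbors differ. Tokens absent from
either order are deleted before flanks are compared, so one insertion or
loss does not cascade into spurious calls on its neighbors. A subtlety:
moving gene X past a neighbor is formally indistinguishable from moving
the neighbor, so the detector searches for the smallest candidate subset
whose removal reconciles the two circles, preferring tRNAs (the mobile
elements of mitogenome evolution) over rRNA/protein genes when several
minimal explanations tie. This is what makes the Lys translocation in
Type III-A come out as "K moved to 5' of ATP6" rather than "ATP8 moved".

## Event-path inference

`infer_event_path(parent, child)` decomposes an arrangement difference in
a fixed category order: (1) token multiset differences become LOSS,
INSERTION (non-coding), PSEUDOGENIZATION (pseudo tokens) and DUPLICATION
(second copies) events, with new occurrences identified by their
neighborhoods; (2) neighbor comparison on shared single-copy tokens
yields TRANSLOCATION events; (3) a CR length ratio crossing the
asymmetry threshold yields CR_ASYMMETRY. Alphabetical ordering within
categories makes the decomposition deterministic. The decomposition is
descriptive — it does not attempt to reconstruct tandem
duplication/random loss intermediates, which the data cannot resolve.

## Parsimony mapping

`fitch_reconstruct()` computes bottom-up Fitch state sets on a rooted
tree; the change count equals the number of empty intersections, which is
the exact parsimony score on binary trees. Two deliberate generalizations:

* **Polytomies** are handled by iterated pairwise intersection over the
  children in newick order. This is deterministic and never
  overestimates; on discordant polytomies it can undercount relative to
  exact parsimony (property-tested against an exhaustive oracle). The
  bundled fixture tree keeps its one soft polytomy inside a clade that is
  uniform for every analyzed character, so no headline count touches the
  discrepancy.
* **Root constraints.** `root_state` forces the root. For the OL
  character the root is constrained to `present`: OL presence is the
  outgroup condition in squamates (lizards retain it), and without the
  constraint parsimony would prefer a single OL gain inside snakes over
  the two independent losses in the blind-snake lineages. The constraint
  charges one extra change when the bottom-up root set excludes the
  forced state. For the arrangement-type character the root is forced to
  the placeholder `UNKNOWN`: the ancestral snake arrangement is left
  indeterminate rather than asserted.

`resolve_states()` turns Fitch sets into one state per node. DELTRAN
(keep the parent's state whenever possible, i.e. delay transformations
tipward) is the default because the headline counts — six independent
origins of III-C, seven of pseudo-Pro presence — are parallel-gain
readings of the data. Two refinements: when the parent carries the
out-of-alphabet `UNKNOWN` placeholder and a node's set is still
ambiguous, the placeholder propagates (the ancestral condition remains
indeterminate instead of being forced to an arbitrary alphabet member);
and the `"acctran"` mode is a simple acceleration heuristic (prefer a
non-parental state at ambiguous nodes), logged for comparison rather
than a full MPR-set ACCTRAN.

`count_origins()`/`count_losses()` then count state-changing edges. With
DELTRAN on a binary presence character, origins equal the number of
maximal presence subtrees.

`derivation_graph()` collects the distinct (parent state, child state)
transitions of the resolved tree into a directed acyclic graph over type
labels, annotating edges out of `UNKNOWN` with the child type's stored
diagnostic events and concrete edges via `infer_event_path()`. A dataset
containing a single arrangement yields a one-node graph: one observed
state carries no transition evidence, so no edge out of the indeterminate
root is reported.

## The synthetic fixture

The package ships no sequence data. Instead, `generate_record()` builds a
fully annotated record for any registry type: the token sequence is the
type's reference order; diagnostic CR/NC lengths come from the registry
(2878/4110 for III-E, 342 for III-F, 5702 for III-G); all other lengths
are typical vertebrate gene sizes with a small seeded jitter. The same
seed gives byte-identical output (including GenBank emission); lengths
never affect typing.

`build_fixture_set()` loads a **synthetic** 65-taxon, 14-family study
panel (`snake_taxa_synthetic.tsv`, `snake_tree_synthetic.nwk`): real
snake species names, a topology that follows the published family-level
relationships (Leptotyphlopidae basal, Scolecophidia paraphyletic, the
caenophidian ladder Acrochordidae → Xenodermatidae → Viperidae →
Homalopsidae → Elapidae → Colubridae), and per-tip type assignments
constructed so that the published headline counts are recomputable: 11
distinct types; III-C in six independent clusters across Colubridae and
Homalopsidae; pseudo-Pro additionally in the III-B1 viperid; the three
singleton colubrid types each attached next to a Type III lineage. The
fixture emulates arrangement structure only — it contains no nucleotide
evolution, no heteroplasmy, no concerted-evolution dynamics, and its
species-to-type map is a constructed stand-in, not a transcription of
the published per-species table. Passing tests therefore demonstrate
that the pipeline recovers the published counts from data *with the
published structure*, not that any particular real species carries a
particular arrangement.

`perturb()` applies one atomic event to a record and is the driver for
the closure property test: `infer_event_path(x, perturb(x, e))` must
recover exactly `[e]`. The random event generator constrains
destinations to unique junctions away from the source neighborhood,
because an adjacent-swap event is genuinely ambiguous (moving X past Y
equals moving Y past X) and no detector can be expected to resolve it.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GenBank's 1-based
  inclusive intervals are converted at the boundary.
* tRNA-Leu/Ser isoacceptors without an annotated anticodon are assigned
  from flanking genes (Leu(CUN) beside Ser(AGY)/ND5; Ser(UCN) beside
  COX1/Asp) and the inference is reported as a message.
* An empty order string, an unknown symbol, a duplicate taxon id, a
  missing anchor, an unlabeled tip, or two OL tokens are hard errors;
  overlapping GenBank features are permitted and reported.
* CR asymmetry with unknown lengths is reported as `FALSE` with a
  caveat message rather than guessed.
* `NEW-k` labels for unregistered arrangements are issued in input
  order and recorded with their canonical keys, so novel-type discovery
  is reproducible.

## Problem sizes and limitations

The bundled analyses are desk-scale: the full 65-genome pipeline
(generation, typing, feature detection, three parsimony characters,
derivation graph) runs in seconds, and the property suite uses 500
random rotations, 200 random ≤8-tip trees against the exhaustive oracle,
and 100 random perturbation closures. The exhaustive oracle refuses
trees beyond 12 tips by design.

Known limitations: no nucleotide-level annotation or sequence-similarity
confirmation of pseudogene identity (annotations are consumed, not
produced); no inversion handling beyond strand-aware identity; no
likelihood or Bayesian ancestral-state models; no TDRL scenario
enumeration between arbitrary orders; linear or fragmented assemblies
are out of scope.
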