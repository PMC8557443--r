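---
title: "Orthology inference from gene trees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthology inference from gene trees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(phylortho)
```

## The problem

Given a gene family's phylogeny — a tree whose leaves are genes labeled
with their species of origin — a biologist curating the family asks two
questions of every internal node: does it represent a *speciation* (its
descendants diverged when their species did) or a *duplication* (a gene
copy number change within a genome)? The answers partition the leaves into
**orthogroups**: clusters of genes descending from a single ancestral gene
at the root of the tree. Orthogroups are the working unit of comparative
genomics — they carry gene names across species, define gene families, and
anchor analyses of family expansion and loss. Manual tree inspection scales
poorly; this package automates it while keeping every intermediate
(event calls, pairs, supports) inspectable.

The only required input is a NEWICK gene tree with species-prefixed leaf
labels (e.g. `Hsap_NKX2-2`, delimiter and field configurable). No species
tree is needed: the method reads the taxonomic signal directly from the
gene tree's topology.

## The method

**1. Species-overlap event calling.** For an internal node with child
subtrees carrying species sets $L$ and $R$, the overlap score is the
Jaccard index

$$ s = \frac{|L \cap R|}{|L \cup R|}, $$

and the node is a duplication when $s$ strictly exceeds the overlap
threshold (default 0), a speciation otherwise. The intuition: subtrees
that share species must have arisen by duplication within a genome, while
a clean species split is what a speciation leaves behind. At threshold 0
any shared species flags a duplication; raising the threshold tolerates
small-scale tree inaccuracies at the cost of less granular calls. The
strict inequality matters: it keeps species-disjoint bipartitions as
speciations at threshold 0. At a polytomy the score is the maximum over
all unordered child pairs (conservative: one overlapping pair marks the
whole node), and ortholog pairs are emitted only across child pairs at or
below the threshold. A pair of genes is **orthologous** iff the MRCA of
the two leaves is a speciation node.

**2. Graph clustering.** Ortholog pairs form an undirected graph over all
genes, weighted by the support of the pair's MRCA (missing supports count
as 1; weighting can be disabled). Edges below `min_support` are pruned
(edges exactly at the threshold are kept). The graph is partitioned with
Markov clustering (MCL): self-loops of weight 1 are added, columns are
normalized, and expansion (matrix squaring) alternates with inflation
(elementwise power `inflation`, then renormalization) until convergence;
clusters are read off the attractor rows. Inflation (default 1.6)
controls granularity; the remaining MCL settings (expansion 2, loop
weight 1, `max_iter` 100, tolerance 1e-6 on the sup norm, prune cutoff
1e-5) are conventional and configurable through `mcl()`. MCL rather than
connected components matters in practice: a single misplaced gene can
bridge two families with a spurious edge or two, and the random-walk flow
cuts such weak bridges while leaving densely connected clusters whole.
Isolated genes become singleton orthogroups so the output always covers
every leaf. Orthogroup ids (`OG0`, `OG1`, ...) are assigned by decreasing
size with ties broken by the lexicographically smallest member — outputs
are byte-reproducible.

**3. Rooting.** Event calling needs a rooted tree. Three modes:
`keep` (trust the input rooting), `midpoint`, and `iterative`. For
`iterative`, every edge of the unrooted topology is scored by the smallest
achievable maximum root-to-tip distance when the root is placed optimally
on that edge — the best-scoring edge hosts the classical midpoint root and
the runners-up are natural "second-best midpoint" candidates (ties broken
by preorder edge index). The top `iter_n` (default 10) candidates are each
tried in full (events, pairs, clustering) and the root minimizing the
orthogroup count wins, ties going to the lower rank. This is an implicit
parsimony criterion on ancestral gene copies, and it rescues trees where
a long internal branch would capture the plain midpoint: on the quartet
`(A_a1:10,B_b1:1,(A_a2:1,B_b2:1):1);` midpoint rooting yields 3
orthogroups, the iterative root 2. Because the candidate list always
contains the midpoint root, the iterative count can never exceed the
midpoint count. When the optimal position falls exactly on a node, the
root attaches with a zero-length edge, keeping the tree strictly rooted.
Trees without branch lengths error unless `unit_lengths = TRUE`.

Node supports are properties of unrooted bipartitions, not of node
numbers, so rerooting carries them by split lookup: each internal node of
the rerooted tree recovers the support recorded for its leaf bipartition
(the new root, which is not a bipartition, gets none). When a rooted
binary input carries two (possibly conflicting) root-child labels for the
same split, the value attached to the clade identical to the keyed side
wins.

**4. Supports.** Bootstrap percentages (detected by any value > 1) are
rescaled to $[0,1]$; posteriors pass through. A missing support is
*trusted* (treated as 1) wherever one is consumed — pruning, weighting,
annotation gating — but is always *reported* as `NA`, never imputed. The
package therefore runs identically on trees with no supports at all.

**5. Annotation.** Given a dictionary mapping reference gene ids to names,
each gene is annotated with the names of the reference genes it pairs
with; the annotation support is the support of the pair MRCA closest to
the root (the deepest node the annotation rests on). Orthogroups are named
by the unique, natural-sorted (`NKX2-2` before `NKX2-8` before `NKX2-10`)
names of the reference genes they contain, joined with `/`. Unnamed
orthogroups then receive propagated labels: ascend from the orthogroup's
MRCA toward the root and, at the first node passing the
`min_annot_support` gate whose descendants include members of named
orthogroups, take `like:` plus the union of those orthogroups' names. The
label aggregates *all* named orthogroups under the connecting ancestor
(not just the nearest one), matching the composite `A/B` format; the gate
controls the greediness of the propagation, and lowering it can only add
labels, never remove one.

**6. Pair-level relationships.** Relative to the event calls and the
clustering, a gene pair is an *ortholog* (speciation MRCA), *in-paralog*
(duplication MRCA, same orthogroup) or *out-paralog* (duplication MRCA,
different orthogroups). Note this in/out distinction is operationalized by
orthogroup co-membership, not by the classical definition relative to a
species pair — the two coincide when orthogroups sit at the root scope but
the co-membership reading is what the clustering defines. After pruning,
tree and graph can disagree; ortholog pairs split across orthogroups are
reported as orthologs with `same_orthogroup = FALSE`, since both facts are
informative.

## The simulator and what it does (not) emulate

`simulate_gene_tree()` provides ground truth: `k` gene copies start at the
root of a species tree; along each species branch of length $t$ every
lineage accrues duplications as a Poisson process of rate $\lambda$ and
survives the branch with probability $e^{-\mu t}$; every lineage bifurcates
at species-tree speciations; extinct subtrees are pruned and unifurcations
suppressed. Each surviving root copy defines one true orthogroup, and the
generating event of every internal node is logged — an independent oracle
for the event classifier. Loss is resolved per branch rather than at
mid-branch death times: the truth partition and event log are what the
simulator exists for, not waiting-time realism. `assign_supports()` draws
per-node supports from event-specific Beta distributions (default
Beta(9, 1) for both event classes, i.e. a well-resolved tree; skewed
settings inject weak nodes to exercise pruning and gating).

What the simulator does *not* emulate: incomplete lineage sorting,
horizontal transfer, alignment/inference error (tip misplacement is
emulated separately and bluntly by `randomize_tips()`, which permutes a
random fraction of leaf labels while keeping topology, lengths and
supports). Passing the simulation-based tests therefore shows the
*pipeline logic* is correct under the duplication-loss model, not that
real trees — with their correlated, branch-length-dependent errors — will
be classified this well.

## Benchmarking machinery

`score_families()` compares predicted orthogroups with disjoint reference
families: *best* mode matches each family to the single orthogroup
maximizing the F-score (ties: larger intersection, then smaller
orthogroup, then id); *majority* mode unions all orthogroups in which the
family holds a strict majority of members, a more inclusive metric that
typically raises recall. Scoring uses complete orthogroups by default;
when reference families cover only a curated subset of the tree, the
`universe` argument drops uncovered genes from the predictions before any
counting (they then contribute neither false positives nor majority
votes). Majority-mode recall provably cannot fall below best-mode recall
*when the best-matched orthogroup retains its majority* (the union is then
a superset); without that condition rare counterexamples exist, so the
package asserts the conditional statement and checks the aggregate
tendency empirically. `weighted_mean_scores()` weights family means by
family size; `adjusted_rand_index()` is the standard pair-counting
chance-corrected similarity (two degenerate identical partitions score 1
by convention).

## Study conditions used by the validation suite

Chosen once, as the package's own experimental design:

- **Perfect recovery**: 100 random species trees of 4–8 species
  (`ape::rtree`), $\lambda \in \{0, 0.3, 0.6\}$, $\mu = 0$, $k = 1$;
  pipeline at threshold 0, inflation 1.6, no pruning, input rooting.
  Expected: precision = recall = 1 and ARI = 1 against truth for every
  tree — without loss, every true orthogroup is a clade and every
  spurious bridge is absent.
- **Oracle equivalence**: 200 simulated trees of ≤ 30 leaves; events and
  pair sets must match a brute-force per-pair MRCA oracle exactly.
- **MCL reference behavior**: all 278 clique-union graphs on ≤ 6 nodes at
  inflations 1.2/1.6/2.0 must equal connected components; the
  3-clique–bridge and K4 fixtures must match clusterings frozen from an
  independent MCL implementation.
- **Rooting parsimony**: 50 simulated trees with one internal branch
  stretched 20-fold; the iterative root's orthogroup count may never
  exceed the midpoint count.
- **Misplacement robustness**: one ~200-gene tree (fixed balanced
  8-species unit-branch species tree, $k = 20$ root copies as families,
  $\lambda = 0.1$; first seed yielding 150–260 genes), corrupted at
  fractions 0/0.05/0.1/0.2 with 20 seeds each. Expected: mean precision
  and recall both fall monotonically and recall falls much faster — the
  clusters stay pure while misplaced genes fall out of them.

These problem sizes keep the whole suite within a couple of minutes on one
CPU while leaving each property's failure modes plenty of room to show up.

## A worked example

```{r}
fit <- orthogroups("((A_x1:1,B_y1:1)0.9:1,(A_x2:1,B_y2:1)0.8:1);",
                   root = "keep")
fit
membership_table(fit)
pairs_table(fit)
```

The root is a duplication (both children contain species A and B), the two
cherries are speciations, so there are two ortholog pairs and MCL returns
two orthogroups. Pruning at `min_support = 0.85` removes the 0.8 edge and
splits its cherry into singletons:

```{r}
length(orthogroups("((A_x1:1,B_y1:1)0.9:1,(A_x2:1,B_y2:1)0.8:1);",
                   root = "keep", min_support = 0.85)$orthogroups$clusters)
```

And against simulated truth:

```{r}
sp <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
sim <- simulate_gene_tree(sp, dup_rate = 0.5, loss_rate = 0, seed = 42)
fit <- orthogroups(sim$tree, root = "keep")
score_families(truth_families(sim), fit$orthogroups)
```

## Numerical and degenerate-input choices

- MCL convergence: sup-norm change < 1e-6, or a warning and the last
  iterate after 100 iterations; entries < 1e-5 are pruned each step.
  Nodes that lose all mass numerically (not observed in practice) become
  singletons rather than being dropped.
- Ties everywhere are broken deterministically (preorder edge index for
  root candidates, lower rank for equal orthogroup counts, smallest member
  for cluster ids, lowest cluster index for equal attractor mass), so a
  fixed input yields byte-identical outputs.
- 2-leaf trees cannot be represented unrooted; their single candidate
  halves the one edge.
- Single-species trees are legal: every node is a duplication, every gene
  a singleton orthogroup.
- An empty ingroup intersection yields an all-unassigned result with a
  warning, not an error.
- The simulator reports total extinction as a flagged empty result
  (`extinct = TRUE`) so callers can re-seed deliberately instead of
  looping silently.

## Known limitations

- Orthogroup truth and calls are defined at the tree's root scope; finer
  scopes come from `ingroup =` restriction, not from a scope parameter on
  the event caller.
- The in/out-paralog labels follow orthogroup co-membership (above), which
  differs subtly from the classical species-pair-relative definition.
- Annotation support takes the *deepest* qualifying node; when several
  nodes on the walk-up path qualify, a better-supported shallower node is
  not preferred.
- Tip randomization permutes labels rather than re-grafting subtrees, so
  corrupted trees keep their exact shape; real inference error is gentler
  and branch-length-correlated.
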