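---
title: "Prioritizing bridge protein pairs between two interacting cell types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing bridge protein pairs between two interacting cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppibridge)
```

## The problem

When two cell types communicate — an oligodendrocyte and the immune cell
attacking it, a tumor cell and a T-cell — the conversation runs through
*contact proteins*: membrane and secreted proteins that appear in curated
ligand–receptor pairs whose partner is present in the other cell's proteome.
Among the many intercellular contact-protein interactions, a few pairs sit at
the crossroads: each of their proteins is important for its own cell's
intracellular protein–protein interaction (PPI) network, and together they
touch a large share of the intercellular interactions. `ppibridge` calls such
pairs **bridges** and prioritizes them in two steps: a network-pruning score
that collapses each intracellular network into per-contact-protein
importance values, and an exact integer program that selects the cheapest
set of intercellular pairs covering a tunable fraction of the intercellular
interactions.

## Intracellular importance score (IIS)

Each cell's network is an undirected simple graph. After contact proteins
are identified from a ligand–receptor table and degree-0 proteins are
removed, each protein receives a PageRank centrality `PR` (damping 0.85,
power iteration, L1 convergence threshold 0.001 — the defaults of the common
desktop network-analysis tools, so scores are comparable), or optionally an
unnormalized Brandes betweenness. The contact protein \(i\) is then scored

\[
\mathrm{IIS}_i \;=\; \sum_{j \in NC_i} \frac{PR_j}{d_{ij}}
          \;+\; \sum_{k \in C_i \setminus \{i\}} \frac{PR_k}{d_{ik}},
\]

where \(NC_i\) are the non-contact proteins reachable from \(i\) and
\(C_i\) the other contact proteins reachable from \(i\). The two distance
terms deliberately use two different pruned graphs:

* distances \(d_{ij}\) to non-contact proteins are measured after deleting
  every contact–contact edge, so a contact protein cannot borrow importance
  through a shortcut over another contact protein;
* distances \(d_{ik}\) between contact proteins are measured on the induced
  subgraph of the contact proteins only.

Distances are unit-weight breadth-first-search hop counts; an unreachable
protein contributes nothing (in particular, a contact protein reachable only
through non-contact proteins contributes nothing to the second term). The
self term is excluded, since \(d_{ii} = 0\). Because PPI networks are
small-world, most proteins sit within a few hops of each other; dividing
centrality by distance on the pruned graphs is what spreads the scores
apart. The additive terms are kept per contributor, so the top score
contributors of any contact protein can be reported
(`top_contributors()`).

Centrality itself is computed on the full intracellular network, before
pruning: the pruning changes distances only, not importance.

### Normalization

Raw IIS values are divided by the per-cell maximum and floored at
`iis_floor` (default `1e-9`). Max-scaling is used rather than min–max: a
min–max scheme maps the weakest contact protein to 0, which would make any
pair containing it infinitely expensive downstream. The floor keeps contact
proteins with zero intracellular importance — for instance a contact protein
whose only interactions are intercellular — selectable at a very high but
finite cost.

## The bridge selection program

The intercellular network is bipartite: edges \(E\) connect contact
proteins of cell 1 to contact proteins of cell 2. Only connected pairs are
candidates, so the candidate pair set \(P\) equals \(E\). Pair
\(i = (u, v)\) costs

\[ s_i = \frac{1}{\widehat{\mathrm{IIS}}_1(u) + \widehat{\mathrm{IIS}}_2(v)}, \]

the inverse of the summed normalized scores, and *covers* interaction
\(j = (a, b)\) iff \(u = a\) or \(v = b\) — a shared endpoint on the same
cell side (matching is cell-respecting: one symbol occurring in both cells
denotes two different proteins). With binaries \(x_i\) (pair selected) and
\(y_j\) (edge covered) the program is

\[
\min \sum_{i \in P} x_i s_i \quad \text{s.t.} \quad
x_i c_{ij} \le y_j,\;\;
\sum_{j \in E} y_j \ge \alpha |E|,\;\;
y_j \le \sum_{i \in P} x_i c_{ij} .
\]

At \(\alpha = 1\) this is the NP-complete *set cover with pairs* problem;
smaller \(\alpha\) (default grid 0.1, 0.2, 0.4, 0.6, 0.8) asks for a
smaller, more focused selection. The coverage requirement is integerized as
\(\lceil \alpha|E| \rceil\), computed as `ceiling(alpha * n - 1e-9)` so
binary floating-point overshoot (`0.1 * 30` is slightly above 3 in double
arithmetic) cannot inflate the target.

### The exact solver and determinism

`solve_bridges()` is an exact branch-and-bound optimizer written for this
model. Only the \(x\) variables are branched on; \(y\) is implied by
\(x\) and reconstructed for the returned solution, which therefore
satisfies all three constraint families. Pairs are explored in descending
coverage-per-cost order; a partial selection is pruned when the remaining
pairs cannot reach the coverage target, or when its cost plus a fractional
covering bound (fill the missing coverage greedily from the best-ratio
remaining pairs, last pair taken fractionally) exceeds the incumbent.
`brute_force_bridges()` enumerates all \(2^{|P|}\) subsets (guarded to
\(|P| \le 20\)) and serves as the independent oracle: the test suite checks
objective *and* selected-set agreement on hundreds of random instances.

Instances of this problem routinely have many alternative optima (pairs
sharing an endpoint often have identical coverage sets, and symmetric
scores produce identical costs). Output is made reproducible by a fixed
tie-break applied identically in both solvers: among selections within
`1e-9` of the optimal cost, prefer fewer pairs, then the lexicographically
smallest sorted index set in the canonical pair order (pairs sorted by cell-1
then cell-2 protein). The reported selection is therefore deterministic
across platforms and independent of search order. The number reported for a
given \(\alpha\) should be read as "a smallest-cost selection", not "the
unique answer".

## Pair-level ranking (OIS)

Independently of the optimizer, every candidate pair gets an overall
importance score

\[ \mathrm{OIS}_i = \frac{\deg_c(i)}{\max_k \deg_c(k)} +
   \frac{1/s_i}{\max_k 1/s_k} \in (0, 2], \]

the sum of its max-normalized coverage degree and max-normalized pair
score. `compute_ois()` sorts descending with lexicographic tie-breaks. The
optimizer evaluates pairs *collectively* (it prefers complementary
coverage); the OIS evaluates them individually, and the two views are
complementary.

## Evaluation against a random baseline

Given an annotation list (e.g. proteins already associated with a disease),
`association_rate()` reports the annotated fraction of the *distinct*
cell-tagged proteins in a selection — a protein in several selected pairs
counts once, and the same symbol in the two cells counts twice.
`random_baseline()` draws the same number of *pairs* uniformly without
replacement from the candidate set, `repetitions` times (default 10 000),
and averages the same rate; `baseline_expectation()` computes the exact
expectation by enumerating all draws on small instances, and the test suite
requires the Monte-Carlo mean to sit within three standard errors of it.
Sampling pairs rather than proteins mirrors what the optimizer actually
chooses among.

## The synthetic interactome generator

Real inputs at publication scale require dated snapshots of interaction
databases, curated proteomes and literature annotation, none of which this
package downloads. `generate_interactome()` instead produces a desk-scale
two-cell instance with the structural features the method relies on, with
every default chosen once as a realistic miniature:

* intracellular topology: preferential attachment with exact edge counts
  (duplicates resampled), giving the hub-dominated degree distribution of
  PPI networks; an Erdős–Rényi alternative is available;
* sizes: 60 and 50 proteins with 180 and 150 edges (average degree ~6, in
  the range of curated PPI compilations), 25 % contact-eligible proteins,
  40 intercellular edges;
* planted ground truth: 2 bridge proteins per cell are wired to the cell's
  12 highest-degree non-contact hubs and 6 fellow contacts (raising both
  IIS terms) and receive several intercellular edges (raising coverage
  degree). The planting is the operational definition of "should be found":
  recovery tests check that the planted proteins reach the top IIS quartile
  and that the \(\alpha = 0.1\) selection's proteins are planted at a rate
  above the random baseline in at least 90 % of seeds.

What the generator does **not** emulate: identifier noise and cross-database
mapping, weighted or directed interactions, correlated false edges,
expression-level effects, and publication-scale sizes (thousands of nodes).
Passing tests therefore demonstrate algorithmic correctness and the
direction of the enrichment effect, not performance claims on real curated
networks.

## Numerical and design choices

* Self-loop PPI rows are dropped (distances and coverage assume simple
  graphs); the protein itself is kept as a node.
* Ligand–receptor orientation is ignored; both orientations are matched
  against both proteomes, since all edges are undirected.
* A contact protein that loses all intracellular edges is dropped from the
  intracellular network but kept in the intercellular network with raw IIS
  0 (→ floor after normalization), so every intercellular edge remains
  coverable.
* PageRank convergence is the total L1 change per synchronous sweep; the
  degree-0 (dangling) case redistributes mass uniformly. Betweenness is
  unnormalized; since the IIS enters the pipeline only through per-cell
  max-normalization, a global scaling of the centrality has no downstream
  effect.
* Pipeline TSV outputs print numbers via a fixed `%.12g` format, and
  provenance records exclude timestamps, so identical configuration and
  seed produce byte-identical files.
* Test and acceptance problem sizes — up to 40 proteins per cell for oracle
  comparisons, 14 candidate pairs for exhaustive enumeration, 50 seeds for
  recovery runs — were chosen so each property is exercised at a size where
  the independent oracles are exact and fast.

## Limitations

The exact solver's worst case is exponential; it is comfortable at the
hundreds-of-pairs scale with small coverage targets, but publication-scale
instances (thousands of pairs at high \(\alpha\)) would need a commercial
MILP backend behind the same interface. Identifier mapping between
namespaces (UniProt vs. gene symbol) is out of scope: inputs must share one
namespace. The method scores topology only; it knows nothing about
expression levels or interaction confidence weights.
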