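---
title: "Homology-index lineages: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-index lineages: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homolineage)
```

## The model

`homolineage` treats divergence between two proteins as a one-dimensional
quantity, the homology index

$$\mathrm{HI} \;=\; \min\!\Big(1,\; \frac{2\,(p/100)\,L_a}{L_q + L_s}\Big),$$

where $p$ is the percent identity of the pairwise alignment, $L_a$ its
length in columns and $L_q$, $L_s$ the two sequence lengths. HI counts
identical aligned residues relative to the mean sequence length: it is 1
exactly for a full-length identical match, discounts partial-coverage hits,
and needs only the fields of one line of tabular search output (the
standard 12 columns plus `qlen` and `slen`), so precomputed all-vs-all
search results can be streamed in without re-alignment. For desk-scale
inputs the internal aligner (`alignPair()`) computes the same quantity with
Smith–Waterman local alignment under BLOSUM62 and affine gaps (open 11,
extend 1, the classical protein-search defaults). Pairs whose best local
alignment scores at or below zero get HI 0. When both a precomputed table
and sequences are available, the table is authoritative.

Under neutral substitution HI decays monotonically with divergence time,
so thresholding the HI graph at successive values replays divergence
history backwards. Three modelling commitments follow:

* **Grouping is single linkage.** A homologous group at threshold $t$ is a
  connected component of the graph restricted to edges $\mathrm{HI} \ge t$.
  Single linkage is the only clustering rule for which "the group at
  threshold $t$" is well defined for every $t$ simultaneously and the
  groups are nested across thresholds, which is what makes the lineage
  chart and the dendrogram two views of the same object
  (`groupsAtThreshold()` / `hiDendrogram()` agree at every cut; this is an
  enforced cross-module invariant, not a coincidence).
* **Hit symmetrisation by maximum.** Search output is asymmetric (both
  directions, multiple HSPs); `buildHIGraph()` keeps the maximum HI per
  unordered pair — the strongest evidence, monotone under adding hits.
* **Events from count dynamics.** Between adjacent lineage-chart points
  with a gene-count drop, a divergence event is inferred; a simultaneous
  species-count drop makes it orthologous, an unchanged species count
  paralogous. The rule is applied literally; orthologous events whose
  departing set also contained copies of species that stayed are flagged
  `mixed` rather than split into sub-events.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `majorFrac` (`classifyEvents`) | 0.25 | an event is *major* when at least this fraction of the group departs; chosen so that "two main groups" vs "a few genes peeling off" fall on opposite sides |
| `edgeHiThreshold` (`buildNetwork`) | 0.3 | minimum HI for a reciprocal best match to count towards $N_S$ |
| `minCI` (network exports) | 0.05 | display cut for edge lists; the full matrix stays in the object |
| `t` (`highlightOrthologs`) | 0.8 | HI threshold above which a species counts as carrying an ortholog of the focal gene |
| `nRandom` (`rfPercentile`) | 1000 | Monte-Carlo null size; the standard error of a percentile near 50 is $\approx 1.6$ points at this size |
| `flagFrac` (`duplicationSignature`) | 0.5 | fraction of a species' charted genes that must share a paralogous interval to flag genome-level duplication |

All thresholds live on the HI scale in $[0,1]$. Seeds are mandatory
wherever randomness enters (the percentile null, the simulator), and every
pipeline output records its seed and thresholds in a comment header, so
reruns are byte-identical.

## The CI network

For two genomes with $N_C$ and $N_D$ genes sharing $N_S$ matched genes,
$\mathrm{CI} = 2N_S/(N_C+N_D)$ is the harmonic mean of the coverage ratios
$N_S/N_C$ and $N_S/N_D$ — the F-measure of the correspondence. $N_S$ is
defined here as the number of *reciprocal best match* pairs with HI at or
above `edgeHiThreshold`, which makes the correspondence one-to-one and the
F-measure reading exact; a direction-averaged hit count is available as
`method = "hit"` for the looser reading.

## Trees and the RF percentile

The orthology tree for a focal gene takes, per species, the gene with
maximum HI to the focal gene (ties broken by smallest gene ID; the focal
species is always represented by the focal gene itself, whose self-HI
is 1), then builds the single-linkage dendrogram over the representatives
on $d = 1 - \mathrm{HI}$ and relabels leaves by species. Taxonomy trees
come from an NCBI-style parent/child node table, pruned to the species of
interest with unary nodes suppressed; polytomies are preserved, never
resolved by guesswork.

Discordance is the unrooted Robinson–Foulds distance (symmetric difference
of non-trivial bipartitions; a multifurcating tree contributes only the
bipartitions it resolves). Because RF grows with the leaf count, the
package reports alongside it the percentile of the observed distance in a
null of uniformly random unrooted binary topologies on the same leaves —
sampled by sequential random edge addition, which is exactly uniform — with
$\ge$-counting so that **high percentile means more similar than random**;
an observed RF of 0 always scores 100.

## What the simulator emulates

`simulateFamily()` produces a protein family with a fully known history:

* a random species tree built coalescent-style (uniformly random pair
  joins). Merge heights are *evenly spaced* up to `treeHeight`
  (default 0.5 substitutions/site, placing the deepest divergence near
  HI 0.4 where local alignment is still reliable). Even spacing is a
  deliberate testbed choice: under Kingman-coalescent waiting times the
  shallow internodes crowd into gaps of $10^{-3}$–$10^{-2}$
  substitutions/site, far below the per-pair identity noise floor
  ($\mathrm{sd} \approx \sqrt{p(1-p)/L} \approx 0.013$–$0.03$ at $L=300$),
  so no method could resolve the true event order there and recovery
  checks would measure noise, not correctness;
* duplications grafted onto named branches at a chosen relative time
  (default: one duplication halfway up the terminal branch of `sp1`);
* sequences evolved by per-site Poisson substitution with uniform
  replacement over the 20 amino acids and **no indels**, giving the
  closed-form identity decay
  $p(T) = e^{-T} + (1 - e^{-T})/20$ for a path of $T$ expected
  substitutions per site (`expectedHI()`), so every merge height has an
  analytic expectation;
* synthetic taxonomic families from a single-linkage cut of the species
  tree at half its height, so family counts in lineage charts are
  exercised.

Validation in the test suite runs 50 replicates at 8 species, one
duplication and 300 residues — large enough for stable precision/recall
estimates, small enough that the all-vs-all alignment of each family runs
in under a second. What passing these checks does **not** show: behaviour
under indels and alignment-coverage loss, rate heterogeneity across sites
or lineages, domain shuffling, horizontal transfer, or the truncated,
non-exhaustive hit lists of capped real search runs (the reader records
per-query hit counts so users can detect the latter).

## Numerical choices and degenerate inputs

* Distinct edge HI values are the exact threshold set of a sweep; ties are
  processed atomically at their value. Chart points are change points
  only, so an event interval `(t_low, t_high]` brackets — but need not
  pinpoint — the underlying merge; simulator scoring therefore matches
  expected events by interval containment, not point distance.
* Dendrogram cuts use `cutree(h = 1 - t + 1e-9)`: the epsilon keeps
  merges at exactly HI $= t$ inside the group (the subgraph rule is
  $\ge t$) without crossing the next distinct threshold.
* Pairs with no recorded similarity are treated as HI 0 ($d = 1$) when a
  dendrogram needs a complete distance matrix.
* `alignPair()` on a pair with no positive-scoring local alignment
  returns HI 0 with `aln_len = 0` — the one place the "alignment length
  $\ge 1$" invariant is relaxed, since no alignment exists.
* Empty inputs degrade gracefully: an empty hit list gives an empty
  graph; a focal gene with no homologous species yields an empty-tree
  signal (`NULL` with a message) rather than a one-leaf tree; RF requires
  at least 4 shared leaves (fewer admit no non-trivial bipartition).
* Representative and best-match ties are always broken lexicographically
  by gene ID, making every output deterministic.

## Known limitations

Single linkage chains: one spurious high-HI edge can bridge two groups.
The max-collapse of hits makes this conservative but not immune. The RF
percentile's null is topology-uniform, not an empirical gene-family null.
Species-tree recovery from a single family is noise-limited — with 300
residues, adjacent deep merges separated by $\approx 0.05$ HI flip in a
few percent of replicates even in clean simulations; longer sequences or
multi-family consensus are the remedies. Horizontal transfer is not
modelled or detected, though untraceably sparse lineage charts are a hint
users can follow up. At RefSeq scale the internal aligner is not
appropriate; use precomputed tabular search output.
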