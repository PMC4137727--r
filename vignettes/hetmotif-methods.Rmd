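---
title: "Colored motif analysis of drug-disease-gene association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colored motif analysis of drug-disease-gene association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetmotif)
```

## The problem

Literature mining produces millions of subject–predicate–object assertions
("predications") relating diseases, drugs and genes, each backed by one or
more PubMed ids. Individually these associations are noisy — extraction
precision from abstracts is far from perfect — and collectively they are far
too numerous to inspect. hetmotif implements a network view of such data:
the assertions become an undirected, typed association network, and the
signal is sought not in single edges but in *network motifs* — small colored
subgraph patterns that occur significantly more often than expected under a
structure-preserving null model. The matches of significant motifs are then
aggregated into a core network whose neighborhood structure supports three
kinds of inference: prioritizing candidate disease genes, inferring disease
relationships, and flagging drug-repositioning leads.

## The data model

Every record is one assertion: subject id and type, predicate, object id
and type, source PMID. Three entity types exist (`disease`, `drug`, `gene`),
so the undirected network has six edge *layers*, one per unordered pair of
endpoint types. Identity is the case-folded, whitespace-trimmed id token; no
concept-resolution is attempted, because the input ids are already
vocabulary-level tokens.

The filtering chain mirrors how a high-confidence snapshot is built from a
noisy extraction:

1. **Deduplication** — the same pair asserted under many PMIDs and in both
   argument orders collapses to one association with a support count.
   Self-associations are dropped (the network is simple).
2. **Drug whitelist** — drug-containing layers are restricted to an
   approved-drug list; for drug-drug associations *both* endpoints must be
   approved, which is the strict reading of restricting associations to
   approved drugs.
3. **Derived lists** — the genes and diseases of interest are those that
   co-occur with surviving approved drugs; gene-gene, disease-disease and
   disease-gene associations must have both endpoints on the corresponding
   derived list.
4. **Stoplist** — generic terms ("gene", "protein", ...) are removed by
   exact-token, case-insensitive matching. Substring matching is
   deliberately avoided so that e.g. "proteinase" is never deleted by a
   "protein" entry.

The stage order (whitelist, derived lists, stoplist) is the pipeline's
audit-trail contract; the four operations are exposed individually and
compose in any order if a different regime is wanted.

## The motif model

All connected three-node induced subgraphs are classified into colored
isomorphism classes: 10 triangles (one per multiset of three types) and 18
open paths (3 centre types × 6 unordered leaf-type pairs), 28 classes in
all. Three-node patterns are the smallest informative motifs and the
building blocks of larger ones; larger motifs are out of scope.

Counting uses sparse matrix algebra rather than triple enumeration. With
adjacency matrix $A$ and per-type index sets, colored triangle counts are
sums of $(A_{s_1 s_3} A_{s_3 s_2}) \odot A_{s_1 s_2}$ with a divisor of 1,
2 or 6 for 0, 2 or 3 repeated types; path counts come from per-node
neighbor-type tallies $M = A T$ (pairs $\binom{M_{va}}{2}$ or
$M_{va}M_{vb}$ summed over centres $v$) minus the triangles counted among
those neighbor pairs. Match *enumeration* — needed to build the core
network — walks each edge (triangles, with a total-order guard so every
triple appears once) and each centre's open neighbor pairs (paths, centred
uniquely). Census counts and enumerated matches are checked against each
other and against a brute-force classification over all $\binom{n}{3}$
triples in the test suite.

Every distinct node set counts, and overlapping matches all count — the
full-enumeration convention of standard motif tools — because overlap is
exactly what the core-network aggregation exploits later.

## The null model and significance

The null ensemble randomizes edges while preserving the typed structure:
double-edge swaps confined within each layer preserve per-layer edge counts
and every node's per-layer degree, so motif excess cannot be an artifact of
degree structure. Cross-type layers are rewired as directed bipartite
graphs (tail = first endpoint type), which restricts the swap to the
side-respecting variant; same-type layers use the ordinary undirected swap.
The default is 100 attempted swaps per edge, a standard mixing allowance;
layers with fewer than two edges cannot be swapped and pass through
unchanged. A weaker null that preserves only per-layer edge counts (free
endpoint resampling within the right types) is available as
`mode = "layer_count"` for sensitivity analysis.

For each pattern with real count $N_\mathrm{real}$ and null counts across
$R$ replicates with mean $\bar N_\mathrm{rand}$ and population standard
deviation $\sigma_\mathrm{rand}$:

$$Z = \frac{N_\mathrm{real} - \bar N_\mathrm{rand}}{\sigma_\mathrm{rand}},
\qquad
p = \frac{\#\{r : N_\mathrm{rand}^{(r)} \ge N_\mathrm{real}\}}{R}.$$

A pattern is called a motif when $N_\mathrm{real} \ge 5$ and $p \le 0.05$.
Choices worth stating explicitly:

* the **population** (not sample) standard deviation is used, the
  convention of standard motif tools; the difference is negligible at
  hundreds of replicates;
* the empirical $p$ counts ties **against** significance
  ($\ge$, the convention of standard motif tools). This matters more than
  it may look: under the exact degree-preserving null, some path-pattern
  counts are almost invariant (they are determined by the degree sequences
  up to a triangle correction), so their null distributions are nearly
  constant. Counting only strict exceedances would give every replicate of
  such a pattern $p \approx 0$ and break calibration — the test suite
  checks that a null replicate treated as "real" is flagged in at most
  $\sim\alpha$ of trials, and only the $\ge$ convention passes it. The
  strict variant remains available as `inequality = "greater"`;
* when $\sigma_\mathrm{rand} = 0$ the z-score is undefined (`NA`) but the
  pattern can still be significant through $p$ and the count floor;
* no multiple-testing adjustment is applied across the 28 patterns by
  default, reproducing the traditional procedure; `bonferroni = TRUE`
  divides $\alpha$ by the number of patterns for the conservative variant.

The default ensemble size is 1000 replicates; the examples and tests here
use 100–200, which is ample for $p \le 0.05$ decisions on strong signals
(the planted-recovery and calibration properties below hold at 200).
All randomness flows from one root seed from which per-replicate sub-seeds
are drawn once, so an ensemble is reproducible from a single integer.

## Core network, degree structure, hubs

The core network is the union of the induced edges of every match of every
significant pattern, with per-edge and per-node provenance (which patterns
contributed). It is by construction a subgraph of the input and shrinks
monotonically as patterns are removed from the significant set.

Degree distributions per entity type are summarised as histogram + CCDF
with a power-law exponent fitted by maximum likelihood with a
Kolmogorov–Smirnov scan over the lower cutoff (`igraph::fit_power_law`,
plfit implementation; the discrete estimator is applied automatically to
integer degrees). Log-log regression on binned histograms is deliberately
not used — it is known to be biased. No formal test of scale-freeness is
made beyond the exponent fit and the CCDF plot. Hubs are reported as the
top-$k$ nodes by degree with lexicographic tie-breaks; the descriptive
"fewer than 10 links" cutoff separating the low-degree mass from hubs is
echoed in reports but plays no algorithmic role.

## Neighborhood analytics

Three operators turn significant motifs into hypotheses:

* `pattern_subnetwork()` — the induced subgraph on all nodes in any match
  of one pattern, with per-layer edge counts. Induced means *all*
  associations among participating nodes are included, not only match
  edges, matching how such subnetworks are sized in practice. Whether
  cross-match co-occurrence edges should count is genuinely ambiguous; the
  induced reading is implemented and recorded here.
* `shared_neighbors()` / `prioritize_candidates()` — guilt-by-association:
  the typed neighborhoods of two anchors are partitioned into shared and
  exclusive sets; candidates for the target are the source-exclusive
  neighbors, ranked by how many target-type nodes support them (adjacent to
  both candidate and target), then lexicographically. The paper-level
  method prioritizes but never ranks; the ranking rule is package plumbing
  and is recorded in the output's `ranking_rule` attribute.
* `ego_subnetwork()` — the induced subgraph within a hop radius, for
  first-neighbor views around hub drugs or diseases.

## The synthetic data generator

There is no public snapshot of the source knowledge base, so the package
carries a generator that emulates the *shape* of the input stream with full
ground truth. The reference conditions, fixed once as defaults:

* 300 diseases, 100 drugs, 300 genes;
* a ~2,000-edge background with per-layer sizes in the proportions of a
  filtered literature snapshot (disease-drug dominant: 1310; disease-gene
  510; disease-disease 40; drug-gene 90; gene-gene 50; drug-drug 6);
* endpoint sampling weights drawn from a power law with exponent 2.5
  (heavy-tailed degrees; `degree_model = "uniform"` switches this off);
* mean redundancy 2.5 records per unique association, with random argument
  order and sequential synthetic PMIDs;
* 40% of background drugs whitelisted; 25 generic contaminant terms wired
  into the stream;
* optional planted motif matches on reserved nodes.

Planted matches are wired on nodes untouched by background sampling, so a
planted path can never be closed into a triangle by accident. Reserved
drugs are whitelisted and every reserved disease/gene is tethered to one
whitelisted background drug, so planted structures survive the whitelist
and derived-list filters by construction; planted counts are therefore
guaranteed *lower bounds* on census counts (background wiring can create
additional matches of the same pattern). The manifest records per-layer
record and unique-association counts, expected survivors after every
filtering stage (computed by plain set logic, independently of the
pipeline's own operations), the derived lists, and the planted triples; the
pipeline's stage counts are audited against it exactly.

What the generator does **not** emulate: real term distributions, UMLS
typing, extraction errors correlated with entity frequency, or
inter-layer degree correlations. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration on networks with
realistic size, sparsity and tail behaviour — not performance on any real
literature snapshot.

## Numerical and design choices

* Canonical edge order is lexicographic on id tokens; deduplication and all
  exports are deterministic.
* Type conflicts (one id seen as both gene and disease) abort graph
  construction rather than coerce, because node color is load-bearing for
  motif classification.
* Isolated nodes are excluded — they cannot join motifs and would distort
  entity counts.
* Pattern keys are stable strings (`tri:...` with sorted types,
  `path:center=...;leaves=...` with sorted leaves) used across censuses,
  significance tables and provenance.
* Significance tables sort by z descending with undefined z last.
* The problem sizes used in the shipped tests (graphs up to ~2,200 edges,
  ensembles of 100–200 replicates, 20-seed recovery sweeps, n = 5,000
  degree sequences) were chosen as the smallest scales at which the
  statistical properties under test are stable.

## Known limitations

* Only three-node motifs; larger patterns are out of scope by design.
* Predicate semantics and direction are discarded — the method operates on
  the co-association structure only.
* The empirical p-value has resolution 1/R; with R = 1000 the smallest
  non-zero p is 0.001 and ties at zero are common among strong motifs.
* The weaker `layer_count` null is a sensitivity tool, not the default
  inference: it confounds degree effects with motif signal.
* Functional-enrichment follow-up of candidate genes requires external
  knowledge bases and is not part of the package.

## A compact worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(
  planted = data.frame(pattern = pattern_tri(c("disease", "disease", "gene")),
                       count = 30)
)
dat <- generate_predications(cfg)
run <- run_pipeline(dat$records, dat$whitelist, dat$stoplist,
                    n_networks = 200, seed = 2)
run
tidy(run$significance)
glance(run$significance)
autoplot(run$significance)
```
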