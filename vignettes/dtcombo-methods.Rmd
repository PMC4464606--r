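---
title: "Methods and design notes for dtcombo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for dtcombo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtcombo)
library(tibble)
```

`dtcombo` bundles two analysis engines that share nothing but file
formats: a similarity-weighted network recommender for drug–target
interaction (DTI) prediction with an ontology-based significance screen,
and a pathway-reachability engine that proposes near-minimal druggable
target sets for a user gene list. This vignette explains the models, the
parameters that matter, the numerical choices, and what the bundled
synthetic generators do and do not tell you about real data.

## The DT-Hybrid recommender

### Model

A DTI network is a bipartite graph: binary adjacency `a` with drugs as
rows and targets as columns, every entity having at least one
interaction (isolated entities cannot be scored — a zero degree would
put a zero in a denominator — so the loader only ever builds networks
from edge lists, where they cannot occur).

Scores come from two-step resource spreading. Each target holds one
unit of resource; it spreads to the drugs touching it, then back to
targets. Collapsing both steps gives `R = W a` with the drug-side
transfer matrix

$$W_{ij} = \frac{S_{ij}}{k(d_i)^{1-\lambda}\, k(d_j)^{\lambda}}
  \sum_l \frac{a_{il}\, a_{jl}}{k(t_l)}.$$

Two published degree normalizations are the endpoints of `lambda_hybrid`:
at λ = 1 the spread is mass-conserving (every column of `W` sums to 1
when `S` is all ones, and the total score equals the interaction count);
at λ = 0 it is the heat-spreading average. The two regimes are exact
transposes of each other (`W(λ) = W(1-λ)ᵀ` under all-ones `S`), which the
test suite exploits as a free invariant.

The similarity weight `S` is where domain knowledge enters:

$$S = \alpha\, S^D + (1-\alpha)\, \tilde S, \qquad
  \tilde S_{ij} = \frac{\sum_{l,s} a_{il}\, a_{js}\, S^T_{ls}}
                      {k(d_i)\, k(d_j)},$$

with `S^D` a supplied drug–drug similarity (chemical fingerprints,
sequence identity — computed outside this package and read from file)
and `S̃` the drug similarity induced by projecting a target–target
similarity `S^T` through the interaction profiles. Note `S̃`'s diagonal
is a drug's own target-profile coherence and is deliberately *not*
forced to 1: a drug whose targets are mutually dissimilar transfers
less, including to itself. Omitting either similarity input replaces it
with all-ones, recovering plain hybrid network-based inference.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `lambda_hybrid` | 0.5 | degree-normalization exponent; 1 = mass-conserving, 0 = heat-spreading |
| `alpha_mix` | 0.4 | weight of the supplied drug similarity vs. the target-induced one |
| `top_n` | 20 | candidate predictions retained per drug |

No authoritative values exist for λ and α in this setting, so the
defaults are the package's own choice, made once: the mid-range hybrid
λ = 0.5 (neither endpoint is uniformly better in the recommender
literature), and α = 0.4 to lean slightly on the induced similarity,
which is always available and always on the same scale, whereas supplied
similarities vary in provenance. Sensitivity to both is smooth — they
enter multiplicatively — and both are exposed everywhere, including the
CLI.

Ranking excludes validated pairs (they are not predictions), sorts by
score descending, and breaks ties by target identifier so output is
reproducible byte for byte.

## The ontology screen

Predicted targets are scored against what the drug is already known to
do. Terms of a Gene Ontology-style DAG are compared by node distance:
`sim = 1/(1+d)` with `d` the shortest path ignoring edge direction,
after every root of the (possibly multi-namespace) DAG is attached to
one dummy root. The augmentation is what makes all distances finite;
direction must be ignored because two siblings are mutually unreachable
along directed `is_a` edges. The transform `1/(1+d)` is bounded,
monotone and parameter-free; because the downstream subset selection
only uses the *ordering* of correlations (thresholds sweep observed
values), any strictly decreasing transform of `d` would select identical
subsets — the choice affects the reported correlation values, not which
targets are flagged.

A candidate's *correlation* with a drug is the maximum term similarity
between any of its annotation terms and any term of the drug's validated
targets. Unannotated entities get correlation 0, which keeps them out of
low-p subsets rather than letting missing annotation masquerade as
evidence. Annotations are used as given — they are not propagated to
ancestor terms first; with propagation, correlations would rise
uniformly (every pair gains ancestral matches) but the selection would
again shift only where propagation changes the correlation ordering.

For each drug the candidate subsets `M(θ) = {corr ≥ θ}` are swept over
the candidates' distinct correlation values (any θ between two observed
values yields the same subset, so the sweep is exhaustive). With `m` the
number of targets in the network, `q` the number with correlation ≥ θ,
and `k = |M|`, the subset's p-value is

$$p = \binom{q}{k} \Big/ \binom{m}{k},$$

the chance that `k` targets drawn at random from the network all clear
the threshold. It is computed in log space (`lchoose`) so large `m` does
not overflow. The subset with minimal `p` is reported; ties prefer the
larger subset, then the smaller threshold. Two readings of `q` are
possible: counting ties (`≥ θ`) guarantees `k ≤ q` and `p ∈ (0,1]`;
counting strictly (`> θ`) can make `q < k`, collapsing `p` to an
uninformative 0 whenever the threshold equals the subset's own minimum.
The tie-inclusive count is the default; `strict = TRUE` exposes the
other reading for comparison. Similarly, `m` is the full network target
count, not the per-drug candidate count — under the per-drug reading
every threshold would give `q = k` and the sweep would degenerate to
`p = 1/C(k,k)`-style constants. Reported p-values are raw by design; no
multiple-testing correction is applied, and no adjusted column exists.

## The pathway engine

Pathway input is a SIF-like edge table (source, interaction type,
target, directedness flag, pathway id). Loading unions the pathway sets
of parallel edges, drops self-loops, and forces complex-to-constituent
edges undirected (membership in a complex has no direction); all other
directions are kept as given. Entity collapse then renames nodes through
an optional user mapping (sub-units, compartment-tagged copies) and
folds case, dropping any self-loops the collapse creates. Collapsing is
idempotent and input-order invariant, both tested.

The index stores, for every ordered pair within `max_len = 9` edges, the
directed shortest distance and **one** shortest path — the
lexicographically smallest node sequence — with each path edge carrying
the union of pathway ids it appears in. One path rather than all keeps
the index linear in pairs; the lexicographic tie-break makes serialized
output deterministic. Distances are unweighted edge counts. The bound of
9 is the indexing horizon that keeps all-pairs storage tractable while
comfortably exceeding typical signalling cascade depths; it is
configurable. Distances are computed by breadth-first search (via
igraph); the test suite re-derives every stored distance with an
independent queue-based BFS written in plain R, and verifies that
*omitted* pairs are genuinely farther than the bound.

### Combination queries

The query orientation is target → gene: a drug perturbs its target and
the effect propagates downstream to the user's genes. Distance 0 means
the gene itself is the drug target (the "direct" end of the
direct–indirect range). Both query windows default to `[0, 9]`, the full
indexed range.

The pair filter exists because the result is meant to seed *combinations*:
with two or more candidates, a candidate with no partner inside the pair
range cannot participate in any combination and is pruned; a lone
candidate is kept, since a single-target answer has no pair constraint.
Pair distance is the smaller of the two directed distances — combination
partners need not lie on a common directed path. The compatible-pair
list is part of the result, so callers preferring to drop only pairs can
do so.

The greedy minimum-cover step runs after the pair filter, on the
filtered candidates: repeatedly take the candidate covering the most
uncovered genes, breaking ties by the smaller total distance to the
newly covered genes (closer action, fewer intermediaries), then by
identifier. The classic harmonic bound
`|greedy| ≤ H(max set size) · |optimum|` holds and is verified against
an exhaustive optimum on every fixture and on random set systems.

## Synthetic data: what it emulates, what it does not

`gen_dti_case()` plants the assumption the recommender exploits —
similar drugs hit similar targets — as literal block structure: drugs
and targets are partitioned into co-modules, interactions are dense
within a block (probability `density = 0.35`, a typical sparse-DTI
regime once blocks are taken into account) and rare across
(`noise = 0.1` of the within rate); similarities are 0.9 within / 0.1
across with ±0.05 jitter. Ten percent of within-block interactions are
held out (never orphaning an entity) as recoverable ground truth. The
acceptance check asks only that held-out pairs rank far above a uniform
baseline (permutation p < 0.01) — a deliberately weak claim. Passing it
shows the machinery recovers planted signal; it says nothing about AUC
on real pharmacology, where similarity matrices are noisier, blocks
overlap, and degree distributions are heavy-tailed.

`gen_ontology_case()` builds complete trees, giving every term pair a
closed-form distance that serves as an oracle. Real GO is a DAG with
multiple parents, where `1/(1+d)` still works but tree intuition (unique
paths) does not; no test depends on tree-ness except through the oracle.

`gen_pathway_case()` builds a layered targets → intermediates → genes
graph with known distances, a compartment-suffixed duplicate node to
exercise collapsing, and undirected complex edges among the first layer
so candidate pairs stay mutually reachable. Its expected output is
computed by an independent brute-force companion (plain BFS plus
exhaustive cover enumeration) bundled beside the generator. Real pathway
networks are far less regular; the fixture tests correctness of
composition, not realism.

All generators are pure functions of their arguments including the seed.

## Numerical and degenerate-input choices

- Hypergeometric p-values via `exp(lchoose(q,k) - lchoose(m,k))`;
  `k = 0` returns 1 exactly.
- Missing similarity entries default to 0 and missing diagonals to 1,
  which is neutral under the α-mixing scheme and keeps matrices valid;
  asymmetric inputs are symmetrized with the entrywise maximum and a
  warning when the directions disagree by more than 1e-6.
- Similarity validation tolerates asymmetry up to 1e-9 after loading.
- Empty ontology: augmentation yields a DAG containing only the dummy
  root. A dummy-root identifier colliding with an existing term is fatal.
- Drugs with no candidates produce an empty, flagged significance result
  rather than an error; genes absent from the index are reported as
  unreachable rather than dropped silently.
- DTI-layer identifiers are opaque and case-sensitive; pathway-layer
  names are canonicalized to upper case, because entity collapse is the
  one place the method itself merges name variants.

Test problem sizes (random instances of up to 15×15 for the recommender
oracle, graphs of up to 200 nodes for the index oracle, 60×80 with 4
blocks for recovery) were chosen so each property runs in seconds while
still exercising non-trivial structure; all are parameters of the
generators, not limits of the implementation.

## Known limitations

- Scoring is dense linear algebra: fine for thousands of drugs/targets,
  not engineered for millions of interactions.
- The index stores all reachable ordered pairs; beyond ~10⁴ nodes its
  memory footprint, not CPU, is the constraint.
- Similarity computation (chemical, sequence) is out of scope: matrices
  are inputs.
- Cross-namespace gene identifier translation is not provided; gene
  lists must use the same vocabulary as the pathway network, up to case.
- The significance screen conditions on annotation quality: sparsely
  annotated target spaces drive correlations to 0 and p-values to 1,
  which is conservative but uninformative.
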