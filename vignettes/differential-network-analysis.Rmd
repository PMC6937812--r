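---
title: "Differential regulatory networks and in-silico phenotype reversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential regulatory networks and in-silico phenotype reversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgrnet)
```

## The problem

A disease and a healthy condition of the same tissue — for example a
patient-derived organoid line carrying a pathogenic mutation and its
isogenic control — usually differ in the expression of hundreds of genes.
Most of those changes are passengers. The question this package addresses
is which small set of genes, if forced back to its healthy activity,
would drag the rest of the dysregulated expression program along with it.

The approach treats each phenotype as a Boolean steady state of a gene
regulatory network. Starting from (i) a two-group expression contrast and
(ii) a prior-knowledge network (PKN) of signed, directed gene–gene
interactions, the pipeline:

1. calls differentially expressed genes (DEGs) with a
   Benjamini–Hochberg-corrected significance filter and a strict
   fold-change filter,
2. discretizes each DEG into a disease state and a healthy state
   (up in disease ⇒ active in disease, inactive in healthy),
3. restricts the PKN to DEGs, infers signs for interactions of unknown
   regulatory effect, and prunes, separately per phenotype, the
   interactions that are incompatible with that phenotype's expression
   program — yielding two phenotype-specific networks,
4. enumerates signed elementary circuits and identifies differential
   regulators, whose union forms the perturbation candidate set,
5. exhaustively simulates all 1–4-gene clamped perturbations of the
   diseased network under synchronous Boolean dynamics and ranks them by
   how many dysregulated genes they revert to the healthy state, and
6. optionally tests gene lists (e.g. the up-regulated network genes) for
   over-representation in user-supplied GMT gene sets.

## Models and rules

### DEG calling and discretization

For an expression matrix the default contrast is a Welch unequal-variance
test on `log2(x + 1)` values with the fold change computed as
`log2((mean_disease + 1) / (mean_control + 1))`. The pseudocount (+1,
configurable) keeps zero-expression genes finite. Genes with zero
variance in both groups are resolved by the limit of the statistic:
p = 1 for equal means, p = 0 otherwise — this is what makes noise-free
simulated data behave sensibly. The test is deliberately replaceable:
any externally produced three-column table (gene, log2fc, pvalue) is
accepted instead.

A gene is a DEG iff its BH-adjusted q-value is `<= alpha` (inclusive)
and `|log2fc|` is strictly greater than `lfc_threshold`. BH correction
is applied to all tested genes before the fold-change filter; the order
does not affect q-values, only the tested set. Discretization keeps only
DEGs: since a DEG's fold change is nonzero by construction, its disease
state is `log2fc > 0` and its healthy state the negation.

### Sign resolution and pruning

PKN interactions of unknown regulatory effect are signed once, from the
disease states: activation if source and target share a state, inhibition
otherwise. Both phenotype networks share this single signed PKN; a
per-phenotype resolution would be equally defensible but would make the
two networks incomparable edge-by-edge, which the differential-regulator
stage needs.

Pruning uses local Boolean-consistency semantics — target ON iff some
activator is ON and no inhibitor is ON, with inhibitor dominance. Under
the steady state `s` of one phenotype, an edge `u → v` is removed iff

* it is an inhibition with `s(u) = 1` and `s(v) = 1` (an active inhibitor
  contradicts an active target), or
* it is an activation with `s(u) = 1`, `s(v) = 0`, and no inhibition
  in-edge of `v` has an active source (an active activator of an
  inactive target that nothing dominates).

Edges with inactive sources are never removed: an inactive regulator is
simply silent, and such edges are what lets the two networks share
topology (and hence common circuits). The rule is asymmetric between the
phenotypes — the same PKN generally yields networks of different size.
This concrete rule is this package's reconstruction of "compatibility
with the discretized expression program"; a post-pruning audit
(`audit_network()`) re-checks every retained edge and is run by the
pipeline on every build. Parallel edges with conflicting recorded signs
are kept as distinct edges — curated interaction databases do contain
both mechanisms for one pair.

### Elementary circuits

An elementary circuit is a directed cycle with distinct intermediate
nodes; its sign is the parity of its inhibition count (even ⇒ positive).
Circuits matter because their existence is a necessary condition for a
stable steady state, and genes on positive circuits are natural switches
between phenotypes. Enumeration is a Johnson-style blocked DFS rooted at
each node in increasing id order over the subgraph of not-smaller ids,
so each circuit appears exactly once, canonically rotated to its
smallest gene id. Directed circuits are not merged with their reversals,
and parallel edges of different sign give distinct circuits.

Counts can grow factorially with network size, so enumeration is capped
at `max_circuit_length = 12` by default (configurable, `Inf` to disable)
with a warning when the cap truncates anything. Because a truncated
subtree might still contain a cycle, blocking is suppressed along
truncated branches; the bounded search is therefore exact up to the cap.

### Boolean dynamics and reversion scoring

Updates are synchronous: every non-clamped node with at least one
regulator moves to `OR(activators) AND NOT OR(inhibitors)`. Two
boundary conventions needed fixing:

* nodes without regulators hold their state (they are inputs);
* a node regulated only by inhibitors treats the activator clause as
  satisfied — active unless inhibited. Without this default such nodes
  would switch off permanently and a two-gene negative feedback loop
  could never oscillate, which contradicts the qualitative behaviour the
  circuit analysis is built on.

Deterministic synchronous iteration from the disease state, with the
perturbed genes clamped at their healthy values, must enter a cycle; the
first repeated state closes the attractor (a fixpoint is a cycle of
length 1; `step_cap = 10000` guards memory). A gene counts as
**reverted** iff it is not clamped, its disease and healthy states
differ, and its state equals the healthy state in *every* attractor
state — oscillating genes never count, a deliberately conservative
choice. Clamped genes are forced rather than reverted and are excluded
from the score (a `count_clamped` switch includes them for users who
prefer the inclusive reading). The disease state need not be a fixpoint
of the pruned network, so the empty perturbation's `baseline_score` is
always reported; rankings should be read relative to it.

`rank_combinations()` is exhaustive over all combinations of size 1 to
`max_combo` (default 4) and sorts by score (descending), then combo size
(ascending — parsimony wins ties), then lexicographically; it refuses
candidate sets above `candidate_cap` (default 25, ~15k simulations)
rather than silently running for hours. Asynchronous update schedules
are a known alternative and are out of scope here.

### Over-representation

Enrichment is the standard upper-tail hypergeometric test per gene set
with BH correction across sets (the same step-up implementation as the
DEG stage). The universe defaults to the genes actually tested for
differential expression, not the union of the GMT — the background
should be what could have been called, not what an annotation file
happens to mention.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | BH-adjusted significance threshold (inclusive) |
| `lfc_threshold` | 1 | strict absolute log2 fold-change threshold |
| `pseudocount` | 1 | offset in fold change and log transform |
| `kept_categories` | Transcription regulation, Binding | PKN interaction categories retained |
| `max_circuit_length` | 12 | elementary-circuit enumeration cap |
| `max_combo` | 4 | largest perturbation combination |
| `top_k` | 10 | ranking length emitted |
| `candidate_cap` | 25 | refuse larger candidate sets |
| `step_cap` | 10000 | Boolean iteration guard |

All of them live in `pipeline_config()` and round-trip through a YAML
file.

## The synthetic-data generator

No public substitute exists for a proprietary curated interaction
database, and this package's validation should not depend on one. The
generator therefore builds complete, ground-truth-known inputs:

* `generate_pkn()` samples a simple signed digraph uniformly over
  loop-free ordered pairs (a degree-skewed sampler is available behind a
  flag, default off — uniform sampling is the simplest model that
  exercises every code path), assigns true signs, optionally plants a
  few short circuits among the DEGs, and masks a chosen fraction of
  signs as "unknown" in the emitted network while the truth keeps them.
* `generate_states()` assigns each gene a Boolean disease state; planted
  DEGs flip state between phenotypes, other genes do not.
* `make_consistent()` re-signs each edge so it survives pruning in both
  phenotypes; the one impossible case (a non-DEG source active in both
  phenotypes pointing at a DEG, whose required sign differs between
  phenotypes) is rewired to a non-DEG target.
* `plant_decoys()` converts a fraction of edges whose endpoints are both
  active in disease into inhibitions — exactly the configuration the
  pruning rule removes — giving the pruning stage known true negatives.
* `generate_expression()` draws multiplicative log-normal noise around a
  positive baseline (FPKM-like), disease means shifted by
  `2^(+/- lfc_magnitude)` for DEGs, mean-corrected so group-mean ratios
  hit the planted fold change in expectation.

Defaults are chosen as a compact but fully-featured study: 80 genes, 40
DEGs, |log2FC| = 2, noise sigma 0.2, 6 replicates per group (a typical
organoid-pool design), a 240-edge PKN with 25% masked signs, 30%
inhibitions, three planted 3-cycles and 10% decoys. The DEG-recovery
validation scenario is larger — 1,000 genes with 100 planted DEGs — to
make sensitivity and realized FDR meaningful; both run in seconds.

What the generator does *not* emulate: correlated transcriptome-wide
noise, library-size or length biases, count overdispersion, hub-dominated
(scale-free) PKN topology by default, or biologically structured decoys.
Passing the planted-truth tests therefore demonstrates correctness of
the algorithms under the stated model, not robustness to every artefact
of real RNA-seq data.

## Numerical and degenerate-input choices

* Welch test: zero variance in both groups ⇒ p ∈ {0, 1} by the limit of
  the statistic (above); this is exact, not a numerical fudge.
* BH: step-up with `q = min(1, cummin(p·m/rank))` in sorted order,
  returned in input order; permutation-equivariant by construction.
* Gene identifiers are opaque, case-sensitive strings; all canonical
  orders are plain lexicographic sorts.
* Empty cases degrade gracefully: no DEGs ⇒ empty networks, no circuits
  ⇒ candidates reduce to differential regulators, empty candidate set ⇒
  empty ranking with a warning.
* Everything downstream of the DE table is deterministic; the config
  seed exists for the generator and for reproducibility bookkeeping, and
  identical config + seed gives byte-identical output files (no
  timestamps in outputs).

## Validation problem sizes

The shipped test suite validates: BH against the direct step-up formula
on 1,000 random vectors; DEG recovery (sensitivity ≥ 0.9, realized
FDR ≤ 0.1) on the 1,000-gene scenario and exact recovery at zero noise;
the pruning rule against an independent edge-by-edge audit on 200 random
instances plus planted-consistent and pure-decoy networks; circuit
enumeration against brute-force simple-path search on 100 random
digraphs of ≤ 10 nodes; attractors against a full transition-graph
oracle on 100 random networks of ≤ 12 nodes; the analytic perturbation
cases (chains, stars, binomial combination counts, tie ordering); exact
hypergeometric sums; and byte-level determinism of the end-to-end run.
These sizes keep the whole suite under a minute on a laptop while being
large enough that the oracles, not luck, carry the evidence.

## Known limitations

* The pruning rule is a documented reconstruction of steady-state
  compatibility; other differential-network formalisms (e.g. ones with
  threshold or majority semantics) would retain different edge sets.
* Synchronous updates are one convention; asynchronous schedules can
  change attractors and therefore scores.
* Exhaustive 1–4-gene search is binomial in the candidate count; beyond
  ~25 candidates a screening step (tighter DEG thresholds, category
  filters) is required.
* Unknown signs are resolved from the disease states and shared by both
  networks; interactions whose true mechanism differs between phenotypes
  are outside the model.
* Enrichment is one-sided over-representation only.
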