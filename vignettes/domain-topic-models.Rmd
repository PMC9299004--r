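---
title: "Domain-topic models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-topic models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`domtopics` treats a corpus as a bipartite incidence graph: each document
is a node connected to the distinct terms it contains (term repetitions
within a document are discarded, so the model sees binary incidence) and,
separately, to its metadata values.  Clustering this graph clusters both
sides at once: documents gather into **domains** — sets of texts sharing
a similar usage of terms — and terms gather into **topics** — sets of
terms sharing a similar presence across documents.

The clustering model is the nested, degree-corrected, non-overlapping
stochastic block model (SBM).  Degree correction matters because the two
sides of a document–term graph have very different degree statistics:
term frequencies are fat-tailed while the number of distinct terms per
document fluctuates around a mean.  A degree-corrected model attributes
heterogeneous degrees to the nodes rather than inventing blocks to
explain them.  The nested variant recursively groups blocks into
superblocks, and the multigraph of edge counts between blocks at each
level is itself modelled by an SBM one level up, producing a multi-scale
description whose depth and block counts are inferred, not chosen.

Fitting minimises the **description length** (DL) of the graph: the
information cost of the graph given the model plus the cost of the model
parameters themselves.  `description_length()` evaluates, in nats,

* the microcanonical degree-corrected likelihood of the simple bipartite
  graph given level-1 blocks, degrees and block pair counts,
  $\sum_r \ln e_r! - \sum_{rs} \ln e_{rs}! - \sum_i \ln k_i!$ (all block
  pairs cross sides; there are no within-block edges in a bipartite,
  type-pure state);
* a uniform prior over degree sequences given the block degree totals,
  $\sum_r \ln \left(\!\!\binom{n_r}{e_r}\!\!\right)$ with
  $\left(\!\!\binom{n}{m}\!\!\right) = \binom{n+m-1}{m}$;
* a partition prior per node type and per level,
  $\ln \binom{n-1}{B-1} + \ln n! - \sum_r \ln n_r!$;
* the nested edge-matrix prior: at each level the block multigraph's
  counts are described given the grouping one level up,
  $\sum_{RS} \ln \left(\!\!\binom{m_R m_S}{e_{RS}}\!\!\right)$, closing
  at the top with a single block per side.

Because parameter costs are counted, adding blocks only pays when the
edge structure genuinely supports them: on structureless random graphs
the minimum-DL state is a single block per side, which is what the test
suite and `scripts/acceptance.R` verify (single level-1 block per side on
50×50 Bernoulli graphs in 10/10 seeds).  Blocks are *type-pure* by
construction — moves and merges only ever combine nodes of the same side
— which matches the semantics (domains are sets of documents, topics
sets of terms) and costs nothing, since bipartite edges never favour
mixed blocks.

We work with the single best-known fit rather than posterior averages,
and with non-overlapping blocks; both choices trade a small amount of
statistical nuance for a representation in which every document belongs
to exactly one domain at each level, which is what tables, maps and
period analyses consume.

## The search

The optimiser (C++, `src/sbm_optimize.cpp`) runs an agglomerative
heuristic interleaved with single-node Metropolis sweeps:

1. start from singletons (every node its own block);
2. per stage, run `sweeps` sweeps at each inverse temperature in `betas`
   (default `c(1, Inf)`; `Inf` is greedy descent), with
   neighbour-of-neighbour informed proposals;
3. merge blocks down by the factor `sigma` (default 1.5), choosing each
   block's best partner among `n_candidates` sampled candidates;
4. repeat until one block per side remains, tracking the best state seen
   anywhere along the trajectory;
5. restore the best state and polish with greedy sweeps;
6. repeat everything `n_restarts` times (default 5) and keep the global
   best; equal-DL states resolve to the first found under the seeded
   stream, so identical seeds give byte-identical models.

Upper levels are fitted greedily on the block multigraph with the same
engine (multiset-coefficient likelihood instead of the degree-corrected
one); a level is kept only when it encodes the matrix below more cheaply
than the flat closure it replaces, and growth is capped at `max_levels`
(default 10).  `refine_dtm()` continues sweeps from an existing state and
returns the better of old and new, so its DL is monotone and zero sweeps
is exactly a no-op.

On graphs small enough to enumerate (up to 6+6 nodes, Bell(6)² ≈ 41k
type-pure flat partitions), the search attains the exhaustive minimum DL
in 20/20 random graphs; this is rechecked by `scripts/acceptance.R` at
every run, with the enumeration evaluated by the independent R
implementation of the DL rather than the C++ search path.

## Chained models

A fitted domain hierarchy can be *chained* to any metadata dimension:
`fit_chained()` builds the document–metadata graph, transposes the
nested document blocks onto it and holds them immutable at every level,
so only the metadata side is partitioned (its partition prior is the
only model cost that varies; the document side is conditioned on).
Years chain into periods, countries into country groups.  The metadata
hierarchy is given the same depth as the document hierarchy, with
collapsed single-block levels where no statistically significant
distinction exists.  Years are treated as categorical: when recovered
periods come out chronologically contiguous, that is evidence in the
data, not a constraint of the model — and `period_summary()` reports the
contiguity of each block rather than assuming it.  Sub-corpus
re-chaining (e.g. periods of a single domain group) is the same
operation after `subset_graph()`; document blocks absent from the
restriction are dropped with their relative order preserved so labels
remain comparable.

## Characterising blocks

Let $p_{dt}$ be the fraction of domain $d$'s document–term edges landing
in level-1 topic $t$ (`topic_usage()`).  Superdomains aggregate their
descendants' counts, so $p_{dt} > 0$ implies $p_{d^+t} > 0$ for every
ancestor $d^+$ — which keeps specificity finite.

**Nested specificity** asks which topics distinguish a domain from the
larger wholes containing it:
$$\hat S_{dt} = \frac{1}{|d^+ \supset d|} \sum_{d^+ \supset d}
  p_{dt} \log\frac{p_{dt}}{p_{d^+t}},$$
the expectation-weighted pointwise relative entropy averaged over the
ladder of strict ancestors (up to and including the top-level block, the
domain itself excluded).  Summed over topics, each ladder term is a KL
divergence, hence $\sum_t \hat S_{dt} \ge 0$.

**Nested commonality** asks which topics are specific to *all* immediate
subdomains of a domain:
$$\hat C^*_{dt} = \frac{1}{|d^+ \supset d|}\sum_{d^+ \supset d}
  \frac{1}{|d^- \subset d|}\sum_{d^- \subset d}
  \log\frac{p_{d^-t}}{p_{d^+t}},
  \qquad
  \hat C_{dt} = \Big(\tfrac{1}{|d^-\subset d|}\sum_{d^-} p_{d^-t}\Big)
  \hat C^*_{dt}.$$
It reaches $-\infty$ when a topic is missing from a subdomain while
present in others — an informative signal, deliberately not smoothed
away: no pseudocounts are used anywhere.  Two zero conventions are
applied: $0\log(0/q) = 0$ in the specificity, and $\hat C_{dt} = 0$ when
the topic is absent from *all* subdomains (the weight factor vanishes,
so the $0 \cdot (-\infty)$ limit resolves to 0; the $-\infty$ value is
reserved for topics that are present somewhere but missing from some
subdomain).  Natural logarithms are used throughout; the base only
rescales scores and the interfaces consume ranks.

Both measures transpose to any pair of block types (characteristic
domains of a topic or of a period) and to elements instead of blocks
(characteristic terms of a domain), via `block_scores(...,
granularity = "element")`.

## Tables, maps, bump charts

`domain_topic_table()` renders a focal domain's subtree: commonality-
selected topics for domains above level 1, specificity-selected topics
for level-1 domains.  Topic selection uses the *half-sum rule*: order
scores decreasingly and keep the smallest prefix whose cumulative score
reaches half the sum of positive scores (a prefix hitting exactly half
qualifies).  Term selection within a topic uses the *half-max rule*:
keep values strictly greater than half the maximum; when every value is
non-positive the single best term is shown so no topic renders empty.
The asymmetry is deliberate: distinct topics have distinct connectivity
patterns, so enough topics are kept to cover most of their weight, while
terms within a topic share a pattern and only the strongest contributors
are informative.

`map_export()` produces the data behind the two-sided interactive map:
both hierarchies with block heights proportional to volume (document
counts for domains, term-usage counts for topics; children sum exactly
to their parent), and a per-level colour relevance normalised so each
level's strongest block is 1.  Without a selection, relevance is the
volume share; with a selection, the opposite side's relevance becomes
the fraction of each block's edges landing in the selected block — for
a selected level-1 topic $t$ this is exactly $p(t|d)$ per domain.  The
export also carries per-domain document lists, a per-year histogram
(restricted to the selected domain when one is selected) and a
term-to-topic search index.  `write_map_html()` wraps the JSON in a
small self-contained viewer; the JSON is the stable, tested interface
and the viewer is a convenience.

`bump_chart_data()` crosses domains at one level with the periods of a
year-chained model: absolute volume is documents per year averaged
within the period, relative volume is the domain's share of the period's
documents, and ranks order domains within each period by absolute
volume, ties broken by label index.  `prevalence_change()` is the
within-period share difference between two periods — shares, not counts,
so corpus growth does not masquerade as domain growth.

Blocks are labelled `L{level}{kind}{index}` with kinds `D`, `T`, `P`
(domain, topic, metadata/period).  Within a level, topic indices start
at 0 and domain indices continue from the highest topic index, so the
two ranges never collide.

## The synthetic generator

`planted_spec()` / `generate_corpus()` define the study conditions under
which every claim above is tested, without any external dataset.
Documents are split evenly over planted domains; each domain draws terms
through a characteristic mixture over planted topics; each draw is, with
probability `epsilon`, replaced by a uniform draw over the whole
vocabulary (emulating the stop-word-like background a real corpus
carries, which the model isolates into its own topics); term sets are
deduplicated, matching the binary incidence the model consumes.

Defaults implement a strong-signal regime: 300 documents, 60 terms, 3
domains, 4 topics, `epsilon = 0.05`, and a mixture in which each domain
*owns* one topic exclusively (weight 0.75) with the remaining weight
spread over shared topics; 25 negative-binomial draws per document leave
at least 15 distinct terms each after deduplication.  Under these
conditions the fitted level-1 partitions recover the planted labels with
median adjusted Rand index 1.0 over 20 seeds on both sides, which is
what the acceptance suite asserts.  Year metadata, when requested,
drifts across domains through planted eras (each domain draws its year
from its era with probability `era_weight = 0.9`), giving the chained
model a recoverable two-period structure.

What the generator deliberately does **not** emulate: within-document
term burstiness, fat-tailed vocabulary growth (Heaps/Zipf behaviour),
correlated multi-field metadata, or drifting vocabularies.  Passing the
planted-recovery tests therefore demonstrates correctness of the
inference machinery under the model's own assumptions, not performance
on real corpora; on real data, block counts and depths are whatever the
MDL objective supports.

## Numerical choices and problem sizes

All description lengths are in nats and computed with `lgamma`; the
C++ incremental bookkeeping is recomputed from scratch at every stage
boundary to prevent drift, and the final model DL is always re-evaluated
by the independent R implementation.  Ties in DL resolve to the first
state found under the seeded stream.  Degenerate inputs: a graph with a
single document and term yields one domain, one topic, one level; empty
documents are dropped (with a warning) before fitting since an isolated
node cannot be placed; metadata-less documents stay in the doc–term
graph but are omitted from that field's chained graph.

Test and acceptance problem sizes were chosen to exercise every property
at desk scale: 300–360-node fits (sub-second each), 20-seed recovery
batches, 10-seed non-overfitting and period-recovery batches,
20 exhaustively enumerated graphs of up to 6+6 nodes, and 100 randomised
small hierarchies for the measure oracles.  The full suite runs in about
a minute on one CPU.

## Known limitations

* The search is a heuristic: global optimality is only guaranteed where
  enumeration can check it.  Restarts and sweeps are exposed in
  `fit_config()` for harder instances.
* Upper levels are fitted greedily given the level below; cross-level
  joint moves are not attempted (refits of level 1 under the nested
  prior are available through `refine_dtm()`).
* Overlapping blocks, posterior averaging over partitions, weighted or
  layered variants, and directed graphs are out of scope by design.
* The dense block-pair count matrix bounds practical problem sizes to
  roughly 10^4 nodes per side; corpora of that size fit comfortably,
  but the implementation targets desk-scale analysis, not web-scale.
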