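---
title: "Methods: ADME screening, bipartite network statistics and the contribution score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ADME screening, bipartite network statistics and the contribution score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The problem

Multi-herb medicines act through many components hitting many protein
targets at once, so a single-compound, single-target analysis cannot say
which constituents matter or whether two herbs in a formula act
synergistically. The system-pharmacology workflow implemented here
answers those questions for a two-herb formula in four steps: filter the
raw component inventory down to pharmacokinetically plausible "active"
components, assemble the bipartite component–target (C–T) network those
components span, score each component's contribution to the network, and
test the target set for association with diseases and pathways. The
packaged example is Zhi-zhu Wan (ZZW), a classical pairing of Zhishi
(immature *Citrus* fruit, flavonoid-rich) and Baizhu (*Atractylodes*
root, lactone-rich) used for functional dyspepsia; its published
62-component and 133-target tables ship under `inst/extdata`.

## ADME screening

A component passes the screen when all four criteria hold:

* oral bioavailability **OB ≥ 30 %** (inclusive — a component at exactly
  30 passes);
* Caco-2 permeability **Caco-2 > −0.4** (strict: values at or below the
  threshold are treated as non-permeable);
* drug-likeness **DL ≥ 0.18**, with a per-herb override table defaulting
  to **DL ≥ 0.14 for Baizhu**, whose characteristic lactones sit just
  under the general threshold;
* gastrointestinal absorption class **GI = high**.

The inclusive/strict reading of each inequality follows the criteria as
conventionally stated; boundary cases are unit-tested. Failures are
reported per component in the fixed order OB, CACO2, DL, GI so decision
tables are comparable across runs.

Screens of real inventories routinely keep a handful of components that
fail the automatic criteria because they are abundant, bioactive marker
compounds (for ZZW: atractylone, synephrine and the four flavanone
glycosides hesperidin, naringin, narirutin and neohesperidin). This is
modelled as an explicit `whitelist` in `screening_criteria()` rather
than by loosening thresholds, so the automatic decision and the manual
retention stay distinguishable in the output. On the packaged table the
default criteria fail exactly those six components; whitelisting them
reproduces the published 62-component active set.

DL itself is defined as the Tanimoto similarity
$T(A,B) = A\cdot B / (|A|^2 + |B|^2 - A\cdot B)$ between a component's
molecular-descriptor vector $A$ and the average descriptor vector $B$ of
known drugs. The reference vector $B$ depends on a drug-database average
that is not reproducible from published material, so DL is consumed as
an input column; `tanimoto_similarity()` implements the formula for
users who supply their own descriptor vectors. For binary substructure
fingerprints the set form $|a \wedge b| / |a \vee b|$ is used instead
(`pairwise_similarity_summary()`); a pair of all-zero fingerprints has
no defined similarity and is scored 0 with a warning. The default
fingerprint length is 61 bits, matching the substructure profile used
for the packaged formula, but is configurable because published
fingerprint lengths vary.

## Property comparison between herbs

`compare_property()` is a two-sided two-sample Student's *t*-test with
pooled variance (the classical form; Welch's unequal-variance test is
available behind `welch = TRUE`). Degenerate input with zero variance in
both groups returns $t = 0, p = 1$ when the means agree and is an error
otherwise, since the statistic is undefined there. The sign of $t$
always matches the sign of the difference in group means.

## Bipartite networks

`build_bipartite()` stores a *simple* bipartite graph: duplicate
predicted interactions collapse to a single edge, which is how network
viewers compute the degree figures usually reported. Declared but
isolated nodes are kept with degree 0 — important when a network is
reported as "133 targets" even though a particular edge sample touches
fewer. Mean degrees are kept at full precision in `summary()`; rounding
to one decimal (e.g. 650 edges / 133 targets → 4.9) happens only in
reporting code, never in the stored values.

Per-herb subnetworks restrict to edges whose component belongs to the
herb; their edge sets partition the merged network's edges whenever
every component carries a herb label (property-tested). Shared targets
between two herbs are the right-side nodes with at least one incident
edge in each subnetwork. Degree rankings break ties by node id so output
is deterministic. Networks export to SIF and GraphML (with `side` and
`herb` node attributes) for Cytoscape; both formats round-trip through
the package's readers.

## The contribution score

For component $i$ in the merged C–T network with $T_{edge}$ edges,
component degree $C_i$, per-herb subnetwork degrees $C_{Ai}$ and
$C_{Bi}$, and target degrees $P_j$:

$$\omega_i = C_i / T_{edge}, \qquad
  A_i = \omega_i + \left|\frac{C_{Ai} + C_{Bi}}{C_{Ai} - C_{Bi}}\right|, \qquad
  CS(i) = C_i \cdot A_i \cdot \sum_{j \in \mathrm{targets}(i)} P_j.$$

Scores are reported as percentages of the total and cumulatively down
the ranking (CS descending, ties by id), which yields the familiar
"top $k$ components carry $x\%$ of the formula's contribution" curve.

Three interpretation choices were genuinely open and are resolved as
follows:

* **The affinity index is a per-component constant.** The index is
  written with a target subscript but contains no target-dependent
  quantity, so it is computed once per component and applied to every
  incident target.
* **$\omega$ is the component's share of all edges.** The "component
  edges over total edges" ratio is read as (degree of component $i$) /
  (total edges of the merged network), consistent with $\omega$ being
  indexed by component.
* **The inner sum runs over the component's own targets.** Summing
  $P_j$ over *all* proteins would multiply every component by the same
  global constant and destroy the ranking differences the score exists
  to create. Both behaviours are available (`sum_over = "incident"`
  (default) or `"all"`), so the sensitivity of a ranking to this reading
  can be checked directly.

When the two herbs' component sets are disjoint — as in any formula
where each component belongs to one herb — one of $C_{Ai}, C_{Bi}$ is
zero and the ratio term is identically 1, so $A_i = \omega_i + 1$ (this
identity is property-tested on random two-herb networks). The
denominator can only vanish with $C_{Ai} = C_{Bi} > 0$, i.e. for data
where a component is shared between herbs. That case must still be
defined: the default `policy = "floor"` floors the denominator at 1
(the ratio term becomes $C_{Ai}+C_{Bi}$), and `"error"` and `"skip"`
are available for users who prefer to be told or to drop the term.

Correctness is anchored by an independent brute-force evaluator that
recomputes every score by direct edge enumeration; the two routes agree
to 1e-12 on an exhaustive sweep of small adjacency patterns (all 2×4 and
3×3 bipartite masks) and on seeded random 5×5 and larger two-herb
networks. A full enumeration of every bipartite graph on 5+5 nodes
(2^25 graphs) adds nothing over the exhaustive small masks plus random
sampling and is not attempted. Published CS percentages for the packaged
formula (e.g. the cumulative share of the top components) depend on the
study's full 650-edge list, which was never published; they are
therefore *not* regression targets. The package instead guarantees
formula fidelity via the oracle, percentage closure
($\sum CS\% = 100 \pm 10^{-9}$), and a planted-hub recovery test (a
component wired to every target, with correspondingly high-degree
targets, must rank first).

## Over-representation analysis

Association between the active components' target set and a disease (or
pathway) is the hypergeometric upper tail: for a universe of $N$ genes,
$K$ of them annotated to the disease, a query set of $n$ targets and an
observed overlap $k$,

$$P = P(X \ge k) = 1 - \sum_{i=0}^{k-1}
     \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

significant at $P < 0.05$. The sum is evaluated in log space
(`lchoose` plus log-sum-exp) and clamped to $[0,1]$, so it is stable for
database-sized universes; it agrees with exact enumeration to 1e-12 for
all parameter combinations with $N \le 30$ and with `phyper` elsewhere.
$k = 0$ gives $P = 1$ exactly (empty sum), and $P$ is non-increasing in
$k$. The raw $p$ is primary — mirroring common practice for disease
ranking — and a Benjamini–Hochberg column is always included for users
who want multiplicity control. Whether a database's $N$ counts genes or
gene–disease pairs varies between sources, so `universe_size` is an
explicit argument; the default is the number of distinct genes seen in
the annotation map and query.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, deterministic
given their arguments plus a mandatory seed (the ambient RNG stream is
saved and restored, so calling a generator never perturbs a user's
session-level reproducibility).

**Component tables.** `zhishi_profile()` / `baizhu_profile()` copy the
published per-herb property means (MW 393.39 vs 252.67, OB 28.94 vs
37.76, Caco-2 −0.20 vs 0.69, DL 0.41 vs 0.20, MLogP 0.15 vs 2.10, nHAcc
7.67 vs 2.95, nHDon 3.50 vs 1.54, TPSA 51.65 vs 120.45 — the TPSA pair
is taken at face value even though the source text's wording around it
is internally inconsistent). Dispersions are not part of any published
summary; the defaults (MW 120, OB 20, Caco-2 0.8, DL 0.18, MLogP 1.5,
TPSA 45; Poisson counts for the H-bond properties) were chosen once so
that the reported between-herb differences are detectable at the
surveyed sample sizes of 150 and 128 components — e.g. the MW difference
of ~141 g/mol against an SD of 120 gives a *t* around 10 — while
identical profiles stay calibrated under the null (≥ 90 % of seeds give
p > 0.05 at n = 100 per group, verified by Monte Carlo in the test
suite). Continuous properties are normal draws clamped to their natural
ranges (MW ≥ 50, OB/TPSA ≥ 0, DL ∈ [0,1]). The generator plants no
correlation structure *between* properties and no multimodality (real
herb inventories mix chemical classes); tests passing on this data show
the statistics behave as designed, not that any particular real herb
pair differs.

**Networks.** `gen_bipartite_edges()` draws a simple bipartite graph
with an exact edge count in which every component has degree ≥ 1 (each
component receives one uniform target, then the remaining edges are
sampled uniformly without replacement from the unused pairs);
`cover_right = TRUE` additionally guarantees every target at least one
edge, for emulating networks whose reported node counts include all
targets. Degree distributions are therefore near-uniform, unlike the
heavy-tailed degrees of real C–T networks; rankings on synthetic
networks exercise the bookkeeping, and the planted-hub test covers the
heavy-tail regime explicitly.

**Annotations.** `gen_annotation_universe()` plants one annotation with
an exact query overlap $k$ among uniformly drawn decoys, giving a
ground-truth enrichment the ranking must recover at rank 1.

## Problem sizes and numerical choices

The test suite and the acceptance script run the study-sized
configurations directly — a 61-component × 133-target network with 650
edges, a 24-pathway × 84-target network with 353 edges, 62 fingerprints
(1891 pairs), 150 + 128 component draws, a 1000-gene annotation universe
with 50 decoys — plus 200 random smaller networks for the percentage
closure property; the whole suite completes in well under a minute.
Tolerances: 1e-12 wherever two exact computations are compared (oracle
equivalence, complement identities), 1e-9 for the floating-point sum of
percentages. Ties anywhere in a ranking are broken by id so every output
is reproducible byte for byte; the pipeline report isolates the
timestamp in a single JSON field for the same reason.

## Known limitations

* OB, Caco-2, DL and GI values are consumed, not predicted; the package
  contains no structure-based property models and no database clients.
* The contribution score is a topological measure; it knows nothing of
  binding affinities or expression context, and its published
  percentages for the example formula cannot be checked without the
  unpublished edge list.
* The affinity index is defined for at most two herbs. Formulas with
  three or more herbs would need a generalisation of the
  $C_{Ai}/C_{Bi}$ ratio that the source formulation does not provide.
* Enrichment treats annotations as flat gene sets; ontology structure
  (term nesting, gene-set overlap) is ignored.
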