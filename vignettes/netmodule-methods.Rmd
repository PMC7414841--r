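---
title: "Methods: network proximity, module detection, and drug perturbation"
author: "netmodule authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network proximity, module detection, and drug perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmodule)
```

# The model

`netmodule` treats a disease as a connected neighborhood of the
protein–protein interactome and a drug as a set of target proteins
whose graph distance to that neighborhood predicts pharmacological
relevance. The package chains six analyses; each is summarized below
together with its assumptions, tunable parameters, and the numerical
choices that are not forced by the mathematics.

## Closest proximity and its null model

For disease proteins $S$, drug targets $T$, and the unweighted
shortest-path metric $d(s,t)$,
$$d_c(S,T) \;=\; \frac{1}{|T|}\sum_{t\in T}\min_{s\in S} d(s,t).$$
Only genes present in the network enter the computation (unmapped genes
are dropped and logged up front, before any analysis); a target with no
path to any disease protein is excluded from the average rather than
assigned an infinite distance, which keeps $d_c$ finite on fragmented
networks, and the same exclusion is applied inside the null model so
observed and reference distances are computed under identical rules.

Significance comes from a degree-preserving randomization: all nodes
are partitioned into ascending degree bins (greedy accumulation of
whole degree classes until a bin holds at least `minBinSize` nodes,
default **100**, trailing remainder merged), and a random stand-in for
a gene set draws, per member, one node from that member's bin without
replacement. Both $S$ and $T$ are randomized by default — the
`randomize = "targets"` mode holds $S$ fixed for users who prefer to
randomize only the drug side. With reference mean $\bar d$ and SD
$\sigma_d$ over `nRandom` draws (default **1000**; the package's
synthetic studies use 300),
$$z_c = \frac{d_c - \bar d}{\sigma_d},$$
with the one-sided P value from the standard-normal lower tail (the
empirical lower-tail rank is also reported as a diagnostic, since the
null is discrete and can be skewed on small graphs). Classification
uses the conventional quantiles: $z_c \le -1.645$ significant
($P<0.05$), $z_c \le -1.282$ probable ($P<0.10$), both boundaries
inclusive. A null with zero SD (e.g. a disease set covering the whole
graph) is flagged degenerate: $z$ is `NA`, the classification
`not_proximal`, and a warning is raised rather than dividing by zero.

## DIAMOnD module detection

Given the current module of size $s_0$ in a network of $N$ nodes, a
candidate with degree $k$ and $k_s$ links into the module has
connectivity p-value
$$p(k,k_s) = \sum_{i=k_s}^{\min(k,s_0)}
  \frac{\binom{s_0}{i}\binom{N-s_0}{k-i}}{\binom{N}{k}},$$
computed with `stats::phyper`. Each iteration absorbs the candidate
with the smallest $p$; only nodes adjacent to the module ($k_s \ge 1$)
are eligible, and $N$ stays the full network size throughout. Two
choices the algorithm statement leaves open are made deterministic
here: ties in $p$ are broken by the lexicographically smallest gene
symbol, and the optional seed weight $\alpha$ (default **1**, i.e.
unweighted) inflates seed links, candidate degree, module size, and
universe consistently by $(\alpha-1)$ per seed link/gene, which keeps
the hypergeometric arguments within bounds for any $\alpha \ge 1$.

## Validation and the stopping rule

DIAMOnD ranks the entire network, so the module boundary must come
from orthogonal evidence. A ranked gene is a *hit* when it belongs to
the union of the validation sources. At iteration $i$ a window of
width $w$ (default: the seed-set size, giving windows comparable to
the seed set) covers $[i-\lfloor w/2\rfloor,\, i+\lfloor w/2\rfloor]$,
truncated — never padded — at the ends. The window statistic is a
one-sided binomial tail of the window hit count against the
interactome-wide background hit rate; this is simple, calibrated (at
the true background rate, fewer than ~5% of windows are significant at
0.05, the binomial's discreteness making it conservative), and
directly interpretable. A Fisher 2×2 alternative testing the window
against the rest of the ranking is available via `mode = "fisher"`.

"No further significant gain" is operationalized explicitly: the stop
is the **last significant window before the first run of `patience`
consecutive non-significant windows** (patience default = window
width). With no such run the last significant window is returned; with
no significant window at all, 0 with a warning. The rule is monotone
in the threshold: a stricter p-threshold never stops later.

## Enrichment, the map, and perturbation

Over-representation of a query set in annotation terms is the
hypergeometric upper tail; the EASE variant recomputes it after
deleting one overlapping gene (floored at zero overlap, where the tail
is 1), a deliberately conservative penalty against single-gene
artifacts. The published significance triple is applied strictly:
$p < 0.01$, overlap $> 3$, fold enrichment $> 1.5$. No
multiple-testing correction is applied on this default path because
the filter operates on raw p-values; a Benjamini–Hochberg column is
available behind `adjust = TRUE`. The enrichment map connects two
terms when their Jaccard coefficient strictly exceeds **0.1**
("overlap by more than 10%"); a coefficient of exactly 0.1 creates no
edge. Per-drug perturbation runs the same proximity z against each map
node's gene set; a node is perturbed at $z \le -1.282$, and nodes with
degenerate nulls are excluded from the ratio's denominator.

## Attack vulnerability

Random-failure curves delete nodes in uniformly random order and track
the LCC after every single removal (exact grid, one point per node),
normalized by the **intact LCC** rather than the node count — a network
that starts fragmented is judged against what was actually connected.
Internally the trajectory is computed by reverse percolation with a
union–find, so a full curve costs near-linear time instead of $n$
component recomputations; a test cross-checks it against stepwise
recomputation with igraph. Targeted attack removes a drug's perturbed
nodes simultaneously (the sequential variant is
`targetedAttackCurve`). The half-collapse fraction is the smallest
removed fraction at which the mean curve is $\le 0.5$; a curve that
never crosses returns 1.0 with a warning.

## ssGSEA

Per sample, genes are ranked by expression (average ranks on ties;
walk order deterministic via gene-name tie-break), and the score is
the integrated difference between the weighted in-set ECDF (weights
$\mathrm{rank}^\tau$, default $\tau = 0.25$, the single-sample
convention) and the uniform out-of-set ECDF. Scores are therefore
invariant to any strictly increasing per-sample transform and
column-independent; at $\tau = 0$ the score is exactly antisymmetric
under rank reversal. No cross-sample normalization is applied — paired
analyses compare raw ES within a cohort, and `pairedDelta` reports
$\Delta ES = ES_{after} - ES_{before}$ per subject with group labels
(e.g. clinical improver flags) passed through untouched, never
computed.

# The synthetic study

The generator emulates the shape of a real interactome study: a
preferential-attachment backbone (heavy-tailed degrees, connected;
chosen over a configuration model for connectivity by default) with
**1,000 nodes** and attachment **m = 2**; a planted module of **60
genes** receiving extra within-module edges with probability **0.15**
per pair, making the module clearly denser than background, as disease
modules are observed to be; **25 seed genes** inside the module;
**3 proximal drugs** targeting module genes directly (`dNear = 0`, the
$d_c \approx 0$ regime occupied by significantly proximal drugs) and
**3 distal drugs** targeting nodes at distance ≥ 2, **5 targets each**
(a typical multi-target kinase-inhibitor scale); **20 gene-set terms**
of size 10–40, of which 30% draw 60% of their members from the module;
and paired expression for **20 subjects** with log-scale noise SD
**0.3** and a treatment shift of **1** applied to the enriched sets in
the "after" samples of the 50% improver subjects. All stage seeds are
derived from one master seed via named substreams, so any stage can be
regenerated independently and `writeBundle` output is byte-identical
across reruns.

What the generator does **not** emulate: biological gene identity (all
symbols are synthetic tokens), edge noise or study-bias structure in
the interactome, correlated expression between genes, non-Gaussian
microarray noise, or partial treatment response. Passing tests
therefore demonstrate that the algorithms recover planted structure
under clean, favorable conditions — not that any particular real drug
or disease conclusion is reproduced. The recovery experiments report
proximity to the planted module gene set itself (the set the drug
strata are defined against); with real curated disease genes the
observed set is a noisy subset and separations will be weaker.

Problem sizes in the test suite are chosen for tight feedback:
1,000-node graphs with 300-draw nulls for calibration and separation,
145-gene modules (120 non-seed) for stopping-rule recovery, windows of
25 with patience 25, exhaustive oracles on graphs of up to 30 nodes
(distances), 200 nodes (module detection), and universes of up to 50
genes (enrichment tails).

# Known limitations

- Gene symbols are opaque, case-sensitive strings; no alias
  resolution. Genes absent from the network are dropped and logged,
  before all computations.
- The degree-binning scheme (ascending greedy, merge-last) is one of
  several reasonable operationalizations of "same degree
  distribution"; very coarse bins on small graphs make the null
  conservative.
- The normal approximation for the one-sided P assumes an
  approximately Gaussian reference distribution; on very small or very
  dense graphs the empirical rank (reported alongside) is the safer
  quantity.
- Window significance treats hits as independent draws, which ignores
  the ranking's serial dependence; the patience mechanism absorbs most
  of the resulting jitter but the stop can shift by roughly half a
  window width.
- The perturbation ratio depends on the enrichment map's term
  collection; with few terms the ratio is coarse (steps of
  $1/n_{nodes}$).
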