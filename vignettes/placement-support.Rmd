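---
title: "Least-squares phylogenetic placement and its support values"
author: "lspplace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Least-squares phylogenetic placement and its support values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`lspplace` inserts an aligned query sequence $q$ onto a fixed backbone tree
$T$ with $n$ leaves by solving the least-squares phylogenetic placement
(LSPP) problem: choose an edge $e$, an attachment position $x$ along that
edge, and a pendant branch length $p$ minimizing

$$\sum_{i=1}^{n} w_{qi}\,\bigl(\delta_{qi} - d_{qi}(T)\bigr)^2,$$

where $\delta_{qi}$ is the corrected sequence distance between $q$ and
backbone leaf $i$, $d_{qi}(T)$ is the path distance through the tree once
$q$ is attached, and $w_{qi} = \delta_{qi}^{-2}$ by default (the
Fitch–Margoliash weighting, which discounts long, high-variance distances;
exponents 0 and 1 are also available). For a candidate edge $e = (u, v)$
with length $\ell_e$, leaves proximal to $u$ see
$d_{qi} = p + x + c_i(u)$ and leaves distal past $v$ see
$d_{qi} = p + (\ell_e - x) + c_i(v)$, with $c_i(\cdot)$ the fixed path
length from the edge endpoint to leaf $i$. For each edge this is a
two-variable quadratic: the package solves the $2 \times 2$ normal
equations in closed form and projects onto the constraints $p \ge 0$,
$0 \le x \le \ell_e$ by clamping each active constraint in turn and
re-minimizing the free coordinate, keeping the feasible candidate with the
smallest objective (the standard NNLS-style treatment of a two-variable
box-constrained quadratic). The pendant constraint can be switched off.

Every edge is fitted exhaustively, $O(n)$ per edge and $O(n^2)$ per query.
A dynamic program can solve the same problem in linear time; the exhaustive
fit was chosen because it is the unambiguous definition of the optimum at
desk scale (backbones up to a few thousand leaves) and doubles as an oracle
should a faster solver be added later. Ties in the objective are broken by
the smallest edge number so results are reproducible. References whose
distance is invalid (saturated or with no shared ungapped site) get weight
zero; a query is rejected only if fewer than two usable distances remain.
Because an observed distance can be exactly zero (identical sequences),
distances are floored at $10^{-6}$ before being raised to a negative power
for weighting.

# Distances

For DNA the corrected distance is the JC69 transform of the normalized
Hamming distance $h$ computed over sites where neither sequence is gapped:
$\delta = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}h)$, the inverse of
$h = \tfrac{3}{4}(1 - e^{-4t/3})$. The transform is undefined at
$h \ge 3/4$; such pairs are *flagged invalid and excluded from the
objective* rather than capped, because capping would inject arbitrary
large distances into a least-squares fit. Saturation counts are reported
in the placement diagnostics. Ambiguity codes (N, R, Y, ..., X for amino
acids) are treated as gaps: only core-alphabet characters count as
observed. Sequences are uppercased on input.

For amino acids the Scoredist estimator is provided: the BLOSUM62 score of
the pair over mutually ungapped sites is normalized between the expected
score of two random sequences (Robinson–Robinson residue frequencies) and
the upper-limit score (mean of the two self-scores), then log-corrected
and scaled, $d = -\ln(\sigma_n/\sigma_{un}) \times 100 \times c$. The
calibration coefficient defaults to $c = 1.3$, the FastTree-2 convention,
so that distances are on the same scale as FastTree-2 branch lengths; the
original publication's $c = 1.13$ is selectable. A pair whose normalized
score is non-positive is reported at the documented maximum distance
(default 1000). Note the $\times 100$ percentage scaling inherited from
the Scoredist definition.

# Support estimation

All four support methods share one principle: generate $B$ replicate
distance vectors for the query, place each replicate, and report the
fraction of valid replicate placements choosing each edge as that edge's
support. Replicates that yield fewer than two usable distances are dropped
from the denominator and counted in the diagnostics (an alternative would
be to count them as incorrect; dropping was chosen because a replicate
with no usable signal carries no information about the edge choice).

**Fast bootstrapping.** Site resampling is encoded once per run in an
integer matrix $H$ of dimension $(B+1) \times L$: row 0 is all ones (the
original alignment) and each subsequent row counts how many times each
site was drawn when sampling $L$ sites with replacement. Per query, a
single pass over the alignment builds two $L \times n$ binary matrices:
$V$ (site ungapped in both query and reference, and mismatching) and $G$
(site ungapped in both). Replicate mismatch counts are then the matrix
product $P = HV$ and replicate valid-site counts are $L' = HG$, so
$h = P / L'$ elementwise, with no further string operations. Computing
$L'$ by the same product as $P$ keeps the whole replicate pipeline in one
formulation. The result is bit-exact equal to materializing every
resampled alignment and re-counting, which the test suite verifies against
an independently written string-resampling oracle. $H$ is shared by all
queries, as is the tree geometry, so the per-query cost is two matrix
products plus $B$ vectorized placements.

**Slow bootstrapping** materializes each replicate alignment and, before
placing, re-estimates the backbone branch lengths on the fixed topology
from the resampled backbone sequences: all pairwise JC69 distances are fit
to the tree path lengths by non-negative weighted least squares (weights
$\delta^{-2}$), solved with an established NNLS routine on the
pair-by-edge incidence system. With re-estimation disabled, slow
bootstrapping reproduces the fast pipeline's edge choices replicate by
replicate, which is tested. Pairs with no shared ungapped site or
saturated distances are excluded from the refit; the refit aborts if more
than half the pairs are unusable. For amino-acid alignments the slow path
computes replicate distances with Scoredist on the materialized
replicates; branch-length re-estimation is DNA-only (it fits JC69
distances) and must be switched off there.

**Subsampling** draws $b$ of the $L$ sites *without* replacement
(indicator matrix $S$, shared across queries; row 0 all ones by analogy
with $H$), computes $h_b = (SV)/(SG)$, and applies the variance
correction $h_{corr} = \sqrt{b/n}\,(h_b - h_n) + h_n$ around the
full-alignment value $h_n$, with $n = L$ the total number of sites and
$b = \mathrm{round}(L^{0.9})$ by default (R's round-half-even). Corrected
values below zero are clamped to zero and values at or above $3/4$ are
flagged invalid, as the JC69 domain requires. One property worth knowing:
because the $b$ sites are drawn without replacement from the $n$ observed
sites, the subsample estimator carries the finite-population factor, and
the corrected replicate variance is the bootstrap variance times
$(n-b)/(n-1)$ — about $0.54$ at the default $b = n^{0.9}$ with $n = 2000$,
where $b/n \approx 0.46$ is far from the $b/n \to 0$ regime in which the
$\sqrt{b/n}$ scaling is exact. The test suite checks the empirical ratio
against this sampling-theory value. Practitioners who want
variance-matched replicates at moderate $L$ should prefer bootstrapping;
subsampling is provided for its robustness properties and lower per-site
cost.

**Parametric sampling** models each query–reference distance
independently: with $l$ mutually ungapped sites and observed Hamming
fraction $\hat h$, replicate counts are drawn as
$x \sim \mathrm{Binomial}(l, \hat h)$ or its Poisson approximation
$x \sim \mathrm{Poisson}(\hat h l)$, then transformed back through JC69.
Distances between pairs that share tree-path segments are in truth
correlated; this independence assumption is a known simplification, kept
deliberately (modeling the covariance would require knowing the placement
in the first place), and is the main reason parametric support is less
well calibrated than the nonparametric methods. Saturated references are
excluded before sampling; a draw with $x/l \ge 3/4$ is flagged invalid.
Parametric draws are seeded per query from the run seed and a stable hash
of the query id, so results do not depend on query order or worker count.

The default replicate count is $B = 100$.

# Evaluation of support quality

Given a truth table (each query's pruning edge), a placement is *correct*
when its highest-support edge equals the true edge exactly, ties again
broken by the smaller edge number. Four summaries are computed:

* **Calibration** — top placements are binned by support percentage into
  left-inclusive bins ($[0,10), \dots, [90,100)$, with $\{100\}$ its own
  bin), and the fraction correct per bin is compared with the bin
  midpoint; e.g. a calibrated method is right about 45% of the time in
  its 40–50% bin. The MSE against the midpoints is occupancy-weighted by
  default (an unweighted mode exists); empty bins are excluded.
* **ROC/AUROC** — for each integer threshold $T \in \{0,\dots,100\}$, a
  correct placement with support $\ge T$ counts as a true positive and an
  incorrect one with support $\ge T$ as a false positive; the area under
  the recall-vs-FPR sweep is computed by the trapezoid rule anchored at
  the origin. Single-class inputs report AUROC as undefined.
* **ECDF** — right-continuous empirical CDFs of top-placement support,
  separately for correct and incorrect placements.
* **Top-k accuracy** — the fraction of queries whose true edge is among
  the $k$ highest-support edges, $k = 1..10$.

# The synthetic generator

The generator produces the conditions under which the pipeline is tested:
a random unrooted binary topology with exponential branch lengths
(default mean 0.05 substitutions/site, a moderately diverged single-gene
backbone), sequences evolved site-independently under JC69 from a uniform
root, a random subset of leaves pruned out as queries (suppressing
degree-2 nodes, including a degree-2 root, and summing merged branch
lengths) with each query's true attachment edge recorded, and optionally
fragmentary queries that keep one contiguous window of non-gap characters
(default 200) and gap the rest. The truth edge is resolved
combinatorially, by matching the leaf bipartition of the merged edge, so
it is independent of the placement code it is used to test.

The standard study scenario — used by the test suite and by
`scripts/acceptance.R` — is a 300-leaf simulation with $L = 2000$ sites
from which 200 leaves are pruned as queries, leaving a 100-leaf backbone,
with $B = 100$ fast-bootstrap replicates. These sizes keep the full run
around half a minute while leaving enough queries for stable ROC and
calibration estimates.

What the simulator does *not* emulate: rate variation across sites or
lineages, non-JC substitution processes, indels (fragments are made by
masking, not read simulation), alignment error, or model misspecification
between the distance estimator and the generating process. Passing tests
therefore demonstrate the correctness of the machinery and the behavior
of support under the method's own model assumptions — not accuracy on
hard real data, where distance-based placement is known to degrade with
high rates, sparse taxon sampling, and biased missing data.

# Numerical and design choices

* Edge numbers are assigned by depth-first post-order over the tree as
  read, 0-based; the numbering is reproduced identically when the Newick
  output is re-read, as jplace consumers require. Placements are written
  in jplace v3 with fields `edge_num`, `support`,
  `least_squares_error`, `distal_length`, `pendant_length`, rows sorted
  by decreasing support; jplace is used because it is the de facto
  placement interchange format.
* All randomness flows through explicit seeds; generator stages and
  parametric draws derive stable sub-seeds (run seed plus a hash of the
  query id), making multi-worker runs reproducible.
* Degenerate inputs are errors, not warnings: ragged FASTA, missing or
  negative branch lengths, duplicate ids, a query with fewer than two
  usable distances, a subsample size outside $[1, L]$, an already
  saturated $\hat h$ handed to the parametric sampler.
* The objective value is clamped at zero from below to absorb
  floating-point negatives of order $10^{-16}$.
* `BLOSUM62` is taken from the Biostrings data object; the expected
  random score uses the Robinson–Robinson frequencies. Both constants are
  fixed, with only the calibration coefficient exposed.

# Known limitations

Placement cost is quadratic in the backbone size per query, which is fine
up to a few thousand leaves but well short of the sub-linear heuristics
used by large-scale placement tools; candidate filtering and clustering
heuristics are out of scope. Amino-acid support is available through the
slow (materialized) path only, since the $V/G$ mismatch formulation
applies to any alphabet but Scoredist does not decompose into per-site
counts. The parametric samplers ignore distance covariance, and the
subsample correction under-disperses at the default $b$ as described
above, both documented behaviors of the underlying procedures rather than
implementation artifacts.
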