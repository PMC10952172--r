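---
title: "Co-occurrence networks from survey data: models, nulls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence networks from survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocnet)
```

## The problem

A survey asks each participant to list the social groups they identify with
(up to 10) and, next to each group, the behaviours its members typically
perform. The scientific questions are relational: which identities tend to
co-occur *within* people, which behaviours are shared *between* identities,
and whether identities that co-occur also share behaviours. coocnet treats
these questions with the machinery of animal social-network analysis, where
the same formal situation — repeated samples of group co-membership with
very uneven sampling effort — has a mature toolkit.

Three networks are built from the same long-format data
(`participant_id, identity, behaviour`):

* **identity-by-identity** — samples are participants, items are identities;
* **behaviour-by-identity** — samples are (participant, identity) entries,
  items are behaviours;
* **identity-by-behaviour** — samples are behaviour labels aggregated over
  the population, items are identities.

Each construction yields a binary samples-by-items *occurrence matrix*, the
"group-by-individual" matrix of the animal literature: co-membership of a
sample is taken as evidence of association.

## The association index

For items $A$ and $B$, with $x$ the number of samples containing both,
$y_A$ and $y_B$ the numbers containing only one, the edge weight is the
Simple Ratio Index

$$ w_{AB} \;=\; \frac{x}{x + y_A + y_B}, $$

the proportion of samples containing either item in which both appear. It
corrects for the fact that frequently reported items co-occur often by
chance alone. The classical SRI has a fourth denominator term for "both
seen in the same sampling period but not together"; here a sample *is* a
single response list, so that term is structurally zero. Pairs whose
denominator is zero (possible in the derived matrices when a node shares no
samples with another) are assigned weight 0 with a warning — absence of
information is treated as absence of association for the structural
metrics.

Rarely mentioned items say little at the population level, so analyses run
on *filtered* networks keeping only nodes observed **more than three times**
(strictly; `min_count = 3`). The filter uses each occurrence matrix's own
column totals, which is why the three networks filter to different node
sets even though two of them share the identity vocabulary.

## Structural description

* **Density** $= 2E / (n(n-1))$ over realized (positive-weight) edges.
* **CV of edge weights** — SD/mean over all unordered dyads *including
  zeros* by default. The permutation null varies the zero dyads too, so
  excluding them would compare differently shaped dyad sets; the
  nonzero-only variant is available (`include_zeros = FALSE`) and the
  choice is recorded in every report.
* **Weighted betweenness** — Freeman betweenness with fractional credit
  across tied shortest paths. Two weight conventions are exposed because
  association weights are similarities while shortest-path algorithms
  expect costs. The default `weight_mode = "cost"` passes weights directly
  as path lengths, matching the behaviour of the graph libraries whose
  output such survey analyses conventionally report; `"similarity_reciprocal"`
  uses $1/w$ and is the semantically cleaner choice. Both are computed by
  igraph and are verified in the test suite against an exhaustive
  path-enumeration oracle on small graphs.
* **Communities and modularity** — walktrap (4-step random walks, weighted)
  cut at the maximum-modularity level, components handled independently;
  modularity is the weighted Newman score
  $Q = \sum_c \left( w^{in}_c / W - (s_c / 2W)^2 \right)$, implemented
  in-package and cross-checked against igraph. $Q \in [-0.5, 1]$; two equal
  disjoint cliques split correctly give $Q = 0.5$.

## The permutation null

Non-randomness is assessed with datastream (Bejder-type) permutations: the
occurrence matrix is randomized by 2×2 *checkerboard swaps*
$\left[\begin{smallmatrix}1&0\\0&1\end{smallmatrix}\right] \to
\left[\begin{smallmatrix}0&1\\1&0\end{smallmatrix}\right]$, which hold
fixed (1) the number of samples, (2) the number of items per sample and
(3) each item's total count, while shuffling who reports what. After each
block of swaps the SRI network is recomputed; the observed CV of edge
weights is compared with its null distribution (elevated CV indicates
structured association), and every dyad's observed weight is compared with
its own null distribution to classify *preferred* ($p_{upper} \le .025$)
and *avoided* ($p_{lower} \le .025$) pairs at the two-tailed level
$\alpha = .95$. Proportions use the $(k+1)/(n+1)$ convention, and ties
count toward both tails (conservative). Defaults: 10,000 recorded
permutations.

### Why the chain uses trial swaps

Two chain kernels are implemented. The classic sequential convention
retries uniformly drawn 2×2 proposals until one is swappable, so every
step moves. That kernel's stationary distribution is *not* uniform over
the margin-fixed matrices: it weights each matrix by its number of
swappable submatrices (the swap/trial-swap distinction of Artzy-Randrup &
Stone). On matrices with heavy-tailed column totals — exactly what
Zipf-like label popularity produces — the bias is not academic: in our
calibration simulations it inflated the global test's type-I error and
the dyadic flag rate to roughly 20%. The default kernel therefore performs
*trial swaps*: each step is a single uniform proposal, applied only when it
is a checkerboard. This kernel is symmetric, hence exactly uniform over
the null's state space, and calibration simulations recover the nominal
levels. Step counts scale with the data (one proposal per incidence
between recorded samples, 20 per incidence of burn-in) so that acceptance
behaviour, not wall-clock convention, sets the effective swap rate. The
sequential kernel remains available (`kernel = "swap"`) for comparison
with older analyses.

The chain asserts row and column totals after every recorded permutation
(`check_margins = TRUE`), and a matrix with no swappable submatrix is
reported as frozen rather than silently returned.

### Conservatism of the dyadic test

The dyadic null distributions are discrete (co-occurrence counts are
integers) and ties are counted in both tails, so the realized two-tailed
flag rate under the null sits *below* the nominal 5% — around 3% in our
simulations at study scale. This is the standard behaviour of
preferred/avoided-associate tests and errs on the side of fewer false
positives; it should be kept in mind when comparing dyad counts across
studies.

## Mantel correlation

The identity-by-identity and identity-by-behaviour networks share identity
nodes; their correlation is Pearson's $r$ between the vectorized upper
triangles of the two weight matrices restricted to the shared node set,
with a two-tailed permutation $p$ obtained by simultaneously relabelling
the rows and columns of one matrix (10,000 relabelings by default,
$(k+1)/(n+1)$ convention). All dyads, including observed zeros, enter the
correlation.

## The synthetic generator

`generate_survey()` emulates the reference survey's marginal statistics:
286 participants; identities per participant from a discretized truncated
normal on 1–10 moment-matched to mean 5.20, SD 1.95; behaviours per
identity (for entries with any behaviours) likewise matched to mean 2.06,
SD 1.26 on 1–10; an identity entry lists no behaviours with probability
0.19, the value implied by the reported behaviours-per-person mean of 8.65
($5.20 \times 2.06 \times 0.81 \approx 8.7$); vocabularies of 138 identity
and 83 behaviour labels with Zipf popularity. The Zipf exponents (1.0 for
identities, 1.6 for behaviours) were chosen once so that the
more-than-three filter retains node counts of the same order as the
reference networks; only mean/SD/mode/range and vocabulary sizes are
reported quantities, so the distribution family and tail exponents are
modelling choices, stated here.

Identity sets are drawn by **conditional Poisson (maximum-entropy)
sampling**: a participant reporting $k$ identities receives each
$k$-subset $S$ with probability $\propto \prod_{j \in S} w_j$. This is the
crucial design decision of the generator: under this design the incidence
matrix, conditional on its margins, is *uniform* — exactly the null
hypothesis of the datastream permutation test — so the generator's
structureless mode is a genuine null for calibration. A sequential
weighted draw without replacement, the intuitive alternative, does *not*
have this property; it injects margin-conditional structure that the
permutation test correctly flags (we measured ~20% type-I error before
adopting conditional Poisson sampling). The exact $O(Vk)$
elementary-symmetric-polynomial algorithm is exposed as `sample_cps()`.

Planted structure deliberately breaks conditional uniformity:

* **blocks** — a participant affiliates with at most one block
  (probability `rate`); affiliation multiplies block members' sampling
  weights by `boost`, producing elevated within-block co-report;
* **preferred dyads** — the pair is forced jointly into the identity set
  with probability `effect` (default 0.1, i.e. ~29 forced co-reports at
  study scale);
* **avoided dyads** — the pair is never allowed to co-occur;
* **behaviour overlap** — behaviour draws mix a shared pool (weight
  `behaviour_overlap`, default 0.7) with an identity-specific shuffled
  pool, giving identities distinguishable behavioural profiles.

What the generator does **not** emulate: the free-text messiness of real
responses (labels arrive pre-coded), demographic covariates, participant
drop-out, and any dependence of behaviour counts on identity popularity.
Passing calibration and power tests on synthetic data therefore
demonstrates the statistical machinery, not the qualitative coding
pipeline that real survey data additionally require.

## Numerical and degenerate-input choices

* Labels are whitespace-normalized and case-folded at ingestion; duplicate
  triples collapse; identity-less rows are dropped with a warning; more
  than 10 identities per participant warns but keeps the data.
* Mode statistics resolve ties to the smallest value.
* Tie detection in permutation tails and the CV comparison uses an
  absolute tolerance of $10^{-12}$ on weights in $[0,1]$.
* Networks with fewer than 2 nodes (density), fewer than 2 dyads (CV),
  fewer than 3 nodes (betweenness) or fewer than 3 shared nodes (Mantel)
  raise degenerate-input errors rather than returning NA.
* Walktrap runs per connected component; isolated nodes become singleton
  modules; the partition is the maximum-modularity dendrogram cut.

## Problem sizes used in the shipped simulations

The packaged tests and the acceptance script run: calibration on 200
structureless surveys (286 participants, 30-identity vocabulary, 1,000
permutations each); power on 100 replicates per planted-dyad scenario and
50 replicates of the two-block recovery scenario; oracle comparisons on
100 random occurrence matrices and exhaustive path enumeration up to 7
nodes. These sizes give binomial standard errors of ~1.5 percentage points
on calibration rates while keeping the default runs desk-scale.

## Known limitations

* The dyadic test's discreteness makes it conservative (see above); no
  mid-p correction is applied.
* The identity-by-behaviour construction aggregates behaviours over the
  population, so its sample count equals the behaviour vocabulary; with
  dense behaviour sharing this matrix can approach saturation, where the
  permutation null has little room to move and per-dyad tests lose power.
* Betweenness under `weight_mode = "cost"` treats strong associations as
  long paths; it is reported for comparability, with the reciprocal mode
  available where interpretability matters.
* The Mantel permutation assumes node exchangeability under the null; it
  does not condition on the networks' margins.
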