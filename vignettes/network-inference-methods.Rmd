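---
title: "Bayesian model averaging for regulatory network inference: models, search, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian model averaging for regulatory network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmanet)
```

## The inference problem

Given an expression matrix over genes and samples, we want a weighted
directed graph in which an edge $j \to i$ states that gene $j$ regulates
gene $i$, with a weight that is a posterior probability rather than an
arbitrary score. Each target gene $i$ poses a variable-selection problem:
which subset $H$ of the other genes best predicts it under the linear
model

$$X_i = \beta_0 + \sum_{h \in H} \beta_h X_h + \epsilon_i,
  \qquad \epsilon_i \sim N(0, \sigma^2_\epsilon)?$$

For time-series data the lag-1 form is used instead: expression at time
$t-1$ predicts expression at time $t$, giving $R(T-1)$ stacked regression
rows from $R$ replicates of $T$ time points. Replicates are pooled into
one regression; that pooling is what lets the sample count $n$ grow with
$R$ and anchors the upper end of the $g$ search interval below.

With more candidate regulators than samples, many subsets fit almost
equally well, and committing to a single one misstates the evidence.
Bayesian model averaging instead scores many candidate models and defines
the edge weight $j \to i$ as the *posterior inclusion probability*: the
summed posterior weight of all retained models containing $j$. Those
weights are what `scan_target()` and `infer_network()` return.

## Scoring a model: Zellner's g-prior

Each model is scored by the g-prior marginal likelihood, expressed as a
log Bayes factor against the intercept-only null model:

$$\log p(D \mid M, g) = \tfrac{n-1-k}{2}\,\log(1+g)
  \;-\; \tfrac{n-1}{2}\,\log\!\left(1 + g\,(1-R^2)\right),$$

with $k$ the model size and $R^2$ its coefficient of determination. The
single parameter $g$ controls shrinkage: the first term penalizes model
size, the second rewards fit, and the null model scores exactly zero.
The score is scale-free in the data because both response and predictors
are standardized (centered, unit variance) when the design is built.
Centering alone would suffice for the score; the response is scaled too
because it leaves $R^2$, the score, and every downstream weight
unchanged while making regression coefficients directly comparable
across targets.

A model's prior is independent-inclusion Bernoulli: candidate $j$ enters
with probability $\pi_j$. With no prior knowledge the default is
$\pi = 1/p$ over $p$ candidates, i.e. one expected regulator per target.
Real regulatory networks have about as many edges as genes, and this
choice also behaves correctly in the degenerate direction: on pure-noise
data the null model dominates and no regulator reaches inclusion 0.5.
(A $1/\sqrt{p}$ default was considered and rejected: at small $p$ it puts
prior mass near 0.5 per candidate and promotes spurious regulators from
noise.) Informative priors from external data replace $\pi_j$ per edge
and are clamped to $[10^{-6}, 1-10^{-6}]$ so that a prior file containing
exact 0 or 1 cannot make a model impossible or mandatory.

$g$ is chosen to maximize the *total* posterior mass of the retained
model set over the interval $[1, n]$. The maximization runs Brent's
method inside a bracket located by a deterministic 64-point scan of the
mass curve. Interior maxima are polished by Brent root-finding on the
analytic derivative of the log total mass: function-comparison line
search alone localizes an optimum only to about the square root of
machine precision, which is too loose for the exact oracle equivalences
the test suite asserts. Boundary maxima are returned as-is.

## Searching the model space

The number of candidate models is $2^p$; the scan explores only the
neighborhood of good models. Starting from the null model at $g_0 = n$,
every model currently in *Occam's window* — within a factor $1/\mathrm{OR}$
of the best model's posterior — proposes all single-variable additions
and removals. New models inside the window are admitted and expanded in
turn; the pass repeats until no new model appears. Then $g$ is optimized
on the retained set, all models are rescored, and the window is
re-applied. The odds ratio OR (default $10^4$, flag `--or`) trades
breadth for time: 100, 1000 and 10 000 are the typical settings, and the
widest is the most accurate. A `rescan` option repeats scan-then-optimize
until the window is stable; the single pass is the default because one
pass is the normative behavior and the rescan rarely changes small
problems.

Candidates are ranked before the scan: by prior probability when
informative priors are supplied (ties by absolute correlation with the
response), otherwise by absolute Pearson correlation (ties by index).
`max_candidates` truncates the ranking, mirroring the common triage of a
genome-scale candidate list to its top 100.

Two engineering pieces make the scan cheap:

* **Incremental Cholesky regression.** The factor of
  $X^\top X$ restricted to the member columns is bordered by one
  row/column on addition and repaired with Givens rotations on removal,
  so each neighbor costs $O(k^2)$ instead of the $O(k^3)$
  refactorization. $X^\top X$, $X^\top y$ and $y^\top y$ are precomputed
  once per target. If a factorization fails numerically, a ridge jitter
  of $10^{-10}\cdot\mathrm{trace}/k$ is added to the diagonal and the
  factorization retried once; exactly collinear proposals are skipped as
  degenerate and never enter the window. Tests compare the update path
  against dense refactorization at relative tolerance $10^{-8}$,
  appropriate for double-precision accumulation at these sizes.

* **A constant-space visited-model filter.** Each candidate variable gets
  a fixed 32-bit MurmurHash3 code; a model's signature is the XOR of its
  members' codes, so stepping to a neighbor updates the signature with
  one XOR. The signature plus the model size address a single bit in a
  64 × 65 326 bit table (522 608 bytes): column = (hash mod $2^{16}$)
  mod 65 326, row = hash bits 20–21 (0-based, a convention locked by unit
  tests) joined with the size mod 16. Sizes map to different rows because
  XOR folding alone would collide systematically on same-signature sets
  of different composition. Bits are never cleared, so no model is ever
  re-evaluated (no false negatives); an aliased bit can skip an
  unvisited model, which only narrows the search slightly and, at the
  observed occupancy, happens for under 2% of proposals. One filter is
  allocated per target and reset between targets so the error rate does
  not accumulate across a run. On small problems the filter provably
  changes nothing: the suite compares it against an exact hash set.

Every target's scan is independent, so `infer_network()` distributes
targets over forked workers; the merge is deterministic and the output is
identical for any worker count.

## Post-processing: transitive reduction

Linear regression cannot distinguish direct regulation from a strong
two-step chain, so the inferred graph contains shortcut edges. Treating
each weight as an independent probability, the probability of a path is
the product of its edge weights; with distances $d = -\log w$ the best
indirect explanation is a shortest path. A direct edge is removed when
some indirect path (two or more edges) in the *original* graph is
strictly shorter. Decisions are simultaneous against the unmodified
input, which makes the pass order-independent; sequential removal would
depend on edge order. Exact ties keep the direct edge (removal requires a
*better* indirect path). The Dijkstra search from each edge's source
drops the direct edge itself and prunes any frontier beyond the direct
distance, so searches on sparse high-weight graphs terminate quickly.
One pass is the normative post-processing step; because removals are
judged against the original graph, a second pass can occasionally remove
more, and `iterate = TRUE` runs to a fixed point for users who want
that closure.

## Evaluation

`evaluate_network()` sweeps a threshold over every distinct predicted
weight (ties enter together; universe pairs with no prediction enter at
weight 0) and accumulates TP/FP/FN/TN over a universe of ordered
non-self gene pairs. AUROC is the trapezoid area over (FPR, recall).
AUPR uses step interpolation,
$\sum_i (r_i - r_{i-1})\,p_i$ — the convention for sparse-network
evaluation, where linear interpolation of precision would flatter a
method. The universe is explicit (or derived from the gene set) because
restricting it — for example to pairs with known regulators — changes
every count; tests pin both areas on a hand-enumerated toy ranking
(AUPR $= 5/6$, AUROC $= 0.75$).

## The synthetic generator

`sample_network()` draws each ordered non-self pair independently with
probability `density` and a coefficient uniform on $\pm[0.5, 0.9]$,
rescaling the matrix to spectral radius 0.9 if it exceeds it;
`simulate_expression()` runs the stable VAR(1) dynamics
$x_t = A x_{t-1} + \epsilon$, $\epsilon \sim N(0, 0.2^2)$ by default,
from standard-normal initial states, replicate-major. The defaults — 10
genes, density 0.15, 6 time points, 20 replicates — emulate benchmark
time-series network-inference sets of the 10-gene scale.

The generator matches the inference model on purpose: recovery on these
fixtures isolates the estimator (search, scoring, dedupe, reduction) from
model misspecification, so a failure is attributable. The flip side
limits what passing says about real data: real regulatory dynamics are
nonlinear and non-Gaussian with measurement noise, unmodeled latent
regulators, and far fewer effective replicates; near-perfect AUPR on
these fixtures is expected and is a correctness check, not a performance
claim.

## Numerical conventions and edge cases

* Comparisons between the incremental and dense regression paths use
  relative tolerance $10^{-8}$; standardization invariants hold to
  $10^{-10}$.
* Constant (zero-variance) candidate columns are dropped and recorded;
  constant targets are skipped with a warning and the network simply
  lacks their in-edges.
* Lagged designs need $T \ge 2$ and at least 3 usable rows — with fewer,
  unit-variance standardization is not defined.
* Proposals whose size would reach $n - 1$ are not scored (the score
  requires $n > k + 1$).
* Model-set ties in the window are broken deterministically (smaller
  model first, then lexicographic members) so runs are reproducible
  bit-for-bit at a fixed seed; the seed feeds only the filter's hash
  codes and the synthetic generator.
* Missing values are not imputed: any non-finite cell is a hard read
  error naming the offending row and column.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated data:
500 random add/remove walks (up to 30 columns, 200 rows) for the
regression oracle; 50 exhaustively enumerated problems of up to 12
candidates for the windowed-BMA oracle at OR $\in \{100, 10^4\}$;
$10^5$ random models for the filter's error rates; 200 random digraphs
of up to 12 nodes against a simple-path-enumeration oracle for the
reduction; and ten 10-gene VAR(1) networks for end-to-end recovery.
These sizes make every oracle exact or exhaustive while keeping the
whole suite fast enough to run routinely.

## Known limitations

* The linear lag-1 model shares the usual blind spots: contemporaneous
  regulation, nonlinear activation, and unobserved confounders are
  outside the model class, and the reported inclusion probabilities are
  conditional on that class.
* Occam's-window search is greedy: a model inside the final window is
  found only if reachable by single-variable steps from other window
  models. In practice (and exhaustively verified on small problems) the
  retained windows coincide with full enumeration, but no guarantee
  exists for adversarial designs.
* The bit filter trades a bounded false-"seen" rate for constant memory;
  on very long scans the rate grows with occupancy. The table size is
  fixed by design.
* Transitive reduction assumes path independence when multiplying edge
  probabilities; overlapping evidence violates that assumption and can
  over-prune dense, high-weight graphs.
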