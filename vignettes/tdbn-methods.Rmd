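---
title: "Time-delay Boolean networks: model, inference, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-delay Boolean networks: model, inference, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdbnet)
```

## The model

A classical Boolean network updates every gene deterministically: gene $i$
at time $t+1$ equals $f_i$ applied to the time-$t$ states of its input
genes. Real regulatory events are neither noise-free nor instantaneous: a
regulator may switch on and its target may only respond some time later.
The time-delay Boolean network keeps binary states but relaxes determinism
through two kinds of pairwise relation between a Boolean function $f$ (on
at most $K$ input genes) and a target gene $v'$:

* **Prerequisite** ($f \succ v'$): the on-state of $f$ at time $t$ is
  *necessary* for the on-state of $v'$ at time $t+1$. If $f(x) = 0$ the
  target is forced off; if $f(x) = 1$ the target is free — the delayed
  activation may or may not have arrived. The symmetric form $f \succ
  \bar v'$ (prerequisite of the dual) forces the target *on* when $f$ is
  off. Duals of functions are never needed as a fourth form: a
  dual-function prerequisite can always be rewritten as a plain-function
  prerequisite, so the representation above is canonical.
* **Similarity** ($f \sim v'$): the target's next state equals $f(x)$ —
  the classical deterministic update, kept as a special case.

Each gene carries at most one relation; unregulated genes are free. One
input state can therefore have up to $2^n$ possible successors, and the
data the method consumes are independent *transition pairs* (state at $t$,
state at $t+1$), not trajectories.

The worked example used throughout the package (`tdbn_example3()`) has
three genes: $(v_1 \lor v_3) \succ v_1'$, $(v_1 \land v_3) \succ v_2'$ and
$v_2 \sim v_3'$.

```{r example}
net <- tdbn_example3()
net
possible_outputs(net, c(1, 0, 1))
```

## Count tables and the noiseless algorithm

For a target $v_i'$ and an ordered input pair $(v_j, v_h)$ the transition
sample is summarised by a $2 \times 4$ table counting the eight joint
patterns $(v_j, v_h, v_i')$; cells are indexed with the first input as the
most significant bit and the output bit last. Each of the eight *basic
relationships* forbids exactly one cell: forbidding $(c, 1)$ says the
OR-form function that vanishes exactly at input pattern $c$ is a
prerequisite of the target; forbidding $(c, 0)$ says the same function is a
prerequisite of the dual. With noise-free data, a basic relationship is
*consistent* when its forbidden cell has count zero.

Consistent basics are combined with AND: the prerequisite-to-target
functions conjoin to $f_L$, the prerequisite-to-dual functions to $f_R$.
Only $f_L$ (or only $f_R$) yields a prerequisite relation; when both exist
and $\overline{f_R} \equiv f_L$ the target is pinned to the function value
— a similarity; when both exist otherwise, the evidence is contradictory
and no relation is emitted; conjunctions that collapse to a constant are
vacuous. Because a low-order relation casts *marginal shadows* into every
tuple that shares its support (the AND relation above forces $v_2' = 0$
whenever $v_1 = 0$, visible in pair $(v_1, v_2)$ as the shadow $v_1 \succ
v_2'$), the per-target combination conjoins the consistent basics of *all*
canonical tuples; the shadows reinforce the full relation rather than
compete with it. When every assignment of every $K$-subset appears in the
inputs together with all possible outputs, this reconstruction is unique
and exact, which the test suite verifies on enumerated samples from random
networks.

## Noise: the misclassified multinomial and the EM p-score

Binarized expression data carry misclassification: each observed bit —
input and output alike — is assumed flipped independently with probability
$p < 0.5$. A count table is then a multinomial on $2^{k+1}$ cells whose
true probabilities $q$ are smeared by the flip kernel
$P(\text{obs } a \mid \text{true } c) = p^{d(c,a)} (1-p)^{(k+1)-d(c,a)}$,
with $d$ the Hamming distance between cell indices. Zero counts are no
longer trustworthy, so each basic relationship becomes a *hypothesis*
$q_c = 0$ about one forbidden cell, and its plausibility is measured by the
smallest flip probability able to reconcile the hypothesis with the
observed table: the **p-score**, the maximum-likelihood estimate of $p$
under the constraint.

The likelihood is maximised by EM over the latent *splitting counts* (true
cell, observed cell). The E-step distributes each observed count over true
cells proportionally to $q_c\, p^{d}(1-p)^{(k+1)-d}$; the M-step has closed
forms $q_c = \sum_a \hat m_{ca} / N$ and
$p = \sum_{c,a} d(c,a)\, \hat m_{ca} / ((k{+}1) N)$. Numerical choices:

* initial $q$ is the smoothed frequency vector $(n + 0.5)$ renormalised
  after zeroing the forbidden cell, and $p_0 = 0.02$ — a strictly interior
  start that keeps every observable cell probability positive; degenerate
  user-supplied starts are detected and replaced;
* convergence at relative log-likelihood change below $10^{-8}$ or 2000
  iterations; because the EM converges linearly, its $p$-updates form a
  near-geometric sequence at the stopping point, so the estimate is
  Aitken-extrapolated past it, $q$ is reconverged at the extrapolated $p$
  (a concave subproblem), and the refinement is kept only when it improves
  the likelihood. The observed-data log-likelihood is monotone
  non-decreasing across the whole trace and is asserted in tests on every
  run;
* the joint likelihood can be multimodal, with a spurious mode at the
  identifiability boundary: when a fit lands at $p \ge 0.3$, a coarse
  profile scan (fixed-$p$ maximisation over $q$ is concave, hence
  reliable) checks for a better interior basin and the EM restarts there
  if one exists;
* $p$ is confined to $[0, 0.5)$; beyond $0.5$ the flip model is
  unidentifiable by symmetry. The constrained M-step preserves EM
  monotonicity. A forbidden cell whose observed count is already zero
  needs no noise: the score is exactly 0 and $q$ equals the observed
  frequencies;
* the unconstrained model is never fitted — without a forbidden cell,
  $p = 0$ with $q$ at the observed frequencies is always a perfect fit,
  so only the $2^{k+1}$ constrained hypotheses are scored.

A boundary case worth knowing: on a perfectly uniform table every
hypothesis is maximally implausible and the profile likelihood becomes a
near-flat ridge rising toward $p \to 0.5$; the EM then crawls along the
ridge and reports a large score near the cap rather than an interior
maximum. Tests cross-check the EM against an independent
profile-likelihood grid search (step $10^{-3}$ in $p$, inner fixed-$p$
maximisation over $q$) on random tables, where the maximum is interior.

## Threshold selection and assembly

All $\binom{n}{K} \cdot n \cdot 2^{K+1}$ hypotheses are scored; small
scores indicate plausible relationships. The *maximum compatibility
criterion* chooses the score threshold admitting the maximum number of
relationships that are jointly conflict-free. A selection conflicts when,
for some target, the conjunction of the selected basics' functions (L and
R sides separately, over the union of their tuples) reduces to a function
on more than $K$ genes, collapses to a constant, or the two sides coexist
while being neither dual-equivalent nor jointly satisfiable.

One design point deserves emphasis: feasibility is **not monotone** in the
threshold. Marginal shadows of one true relation enter the ranking at
slightly different scores, and a partially admitted shadow set can
transiently conjoin to a function on more than $K$ genes that collapses
back to the true support once the remaining shadows join. Stopping at the
first conflicting score would therefore truncate the selection far too
early — typically at the second shadow of any AND-type relation — and
reconstruct almost nothing. The implementation instead evaluates every
candidate threshold (the distinct scores and the absolute cap, default
0.5, the identifiability bound) and keeps the largest whose strictly-below
selection is conflict-free; ties at the conflicting admission are excluded
all-or-none. Optional known-biology seeding (`must_include`) lower-bounds
the threshold so externally trusted relationships are never dropped.
Assembly then combines the selected basics per target exactly as in the
noiseless algorithm.

```{r pipeline}
tr <- add_noise(simulate(net, 100, seed = 7), 0.05)
fit <- tdbn_infer(tr, K = 2)
fit
```

## What the generator emulates, and what it does not

`simulate()` reproduces the study conditions of the simulation experiment:
input states uniform and independent on $\{0,1\}^n$, each free output bit
an independent fair coin, and `add_noise()` flipping every input and
output bit independently with probability $p$ (both sides are corrupted;
the misclassification model treats rows and columns of the wiring diagram
symmetrically). The headline configuration is the three-gene network with
$m = 100$ samples and $p = 0.05$; per-gene independent choice among free
outcomes coincides with a uniform choice over the joint possible-output
set because the freedom is product-form.

Real expression time courses differ in ways the generator deliberately
does not model: consecutive time points are autocorrelated rather than
independent, binarization thresholds induce gene-specific asymmetric error
rates rather than one symmetric $p$, inputs within an experiment are far
from uniform, and regulation need not be representable with indegree
$\le K$. Passing the simulation-based tests therefore demonstrates
correctness of the inference machinery under the stated model, not
performance on arrays; the binarization utilities (`binarize_log_ratio`,
thresholding log-ratios strictly above zero, and `binarize_trend`, coding
within-experiment increases, with exact ties mapped to off in both) are
provided to bridge to such data.

## Stochastic performance at the study conditions

Replicate experiments (fixed seeds, 200 replicates) at $m = 100$,
$p = 0.05$ on the three-gene example characterise what the method can and
cannot do at this sample size. The true forbidden cell attains its row's
minimum score in essentially all replicates (99%), and the replicate
distributions of the true-cell scores centre near the generating $p$. But
exact whole-network recovery requires every true shadow to outscore every
spurious hypothesis; that clean gap occurs in roughly two fifths of
replicates, and even a clairvoyant threshold choice recovers the exact
network in only about half of them at this $m$. The package's threshold
rule recovers it in about 40%. These rates rise steeply with $m$ (the
noise-free identification probability is driven by input-coverage
probabilities that approach 1 exponentially), which the
`identification_probability()` experiments in the test suite exercise
directly.

## Problem sizes and other choices

* Input tuple length is capped (`options(tdbnet.kmax = 3)` by default):
  tables have $2^{k+1}$ cells and tuple enumeration grows as $n^K$, and
  the bounded-indegree assumption is what makes identification tractable
  at all.
* Tables are built for ascending tuples only; reversing a tuple permutes
  the two middle columns, so nothing is lost.
* Network equivalence is decided semantically — per target, the
  possible-output sets are compared over all assignments of the union of
  reduced supports — making it insensitive to input order, dummy inputs,
  and syntactic differences between relations imposing identical
  constraints.
* Reported experiments use 200 replicates for the three-gene pipeline, 50
  replicates for consistency checks at $m = 5000$, and 50 paired trials
  for the eight-gene identification-probability curves; these sizes give
  stable estimates of the quantities asserted while keeping the default
  test run fast.
* Unresolvable targets (conflicting irreducible constraints in incomplete
  noise-free data) are reported as unregulated with a warning — never
  guessed.

## Limitations

The method scores hypotheses per table and does not pool the flip
probability across tables, though the model says it is shared; pooling
would shrink score variance but is not part of the procedure implemented
here. Conflict-freedom certifies only compatibility with *some*
indegree-$K$ network, so a spurious hypothesis that happens to be
absorbable can survive selection in noisy replicates. Scores carry no
sampling-error calibration (no confidence intervals or multiple-testing
control); they are MLEs used for ranking. Finally, inference of $K$
itself, probabilistic rule mixtures, and attractor analysis are out of
scope.
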