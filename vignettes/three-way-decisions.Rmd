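---
title: "Three-way decisions with probabilistic rough sets: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-way decisions with probabilistic rough sets: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threeway)
```

## The decision model

A binary classifier that must answer on every object will make avoidable
errors on objects it knows little about.  Three-way decisions add a third
option — defer — and tie it to the structure of the evidence: objects are
grouped into equivalence classes (identical values on the available
attributes), each class carries a conditional concept probability
$P(C\mid[x])$, and two thresholds $0 \le \beta < \alpha \le 1$ split the
universe into an accept region ($P \ge \alpha$), a reject region
($P \le \beta$) and a deferred boundary in between.  The comparisons are
exactly $\ge$ and $\le$, so a class sitting on a threshold goes to the
decisive region; `probabilistic_regions()` applies them with a `1e-12`
guard against floating-point representation error only.  $\beta = \alpha$
is rejected at construction because the accept and reject regions would
overlap at equality.

The package deliberately keeps the Pawlak model (`pawlak_regions()`) as a
separate qualitative implementation — block containment and disjointness,
no probabilities — rather than as the $(1, 0)$ special case.  The
equivalence of the two routes is then a meaningful property that the test
suite checks on random tables instead of a definition.

Assumptions worth stating: the concept is binary ($C$ versus its
complement; multi-label problems are handled one-vs-rest), the
information function is total (missing cells are rejected at load), and
attributes are categorical at partitioning time — continuous features
pass through an explicit discretization step first.

## Threshold learning

**ITRS.** The total uncertainty
$\Delta(\alpha,\beta) = \sum_R P(R)\,\delta_R$ weighs each region's
conditional uncertainty by its probability mass.  $\delta_R$ is the
Shannon entropy (base 2, bits) or the Gini coefficient of
$\{P(C\mid R), P(C^c\mid R)\}$.  Two conventions make $\Delta$ well
behaved: $0\log 0 = 0$, and an empty region ($P(R)=0$, $P(C\mid R)$
undefined) contributes $\delta_R = 0$, which keeps $\Delta$ continuous as
a region empties.  A trisection only changes when a threshold crosses a
block probability, so $\Delta$ is piecewise constant and the distinct
block probabilities augmented with $\{0, 1\}$ are a sufficient, exact
candidate grid.  We therefore search that grid exhaustively rather than
running the gradient-style continuous search sometimes suggested for this
objective: at the scale of equivalence-class profiles the candidate set
is tiny, and exhaustive search is exact and deterministic.  A uniform
dense grid (default step 0.01) is retained purely as a cross-check, and
the suite verifies the two agree to `1e-9` on hundreds of random tables.
Ties among minimizers are broken to the largest $\alpha$, then the
smallest $\beta$ — the most conservative optimum, so a fully consistent
table returns the Pawlak pair $(1,0)$.  A partition offering no valid
pair is flagged degenerate and returns $(1,0)$.

**GTRS.** Games are two-player: player 1 may lower $\alpha$ by one of the
configured steps (or stay), player 2 may raise $\beta$ likewise.  Profiles
whose joint move violates $0 \le \beta < \alpha \le 1$ get payoff
$-\infty$ for both and are never reported as equilibria.  The payoff
forms are this package's own definitions (the general GTRS literature
leaves them to the application): for the uncertainty games the immediate
player receives one minus the size-weighted mean uncertainty of
POS ∪ NEG (zero when both are empty) and the deferred player
$1 - \delta_B$ (one when the boundary is empty); for the
accuracy–generality game the players receive the raw accuracy and
generality of the perturbed trisection, with an undefined accuracy
(empty immediate regions) scored $(0, 0)$ and flagged.  They are plain
functions, so alternative forms can be slotted in.

Pure-strategy Nash equilibria are found by exhaustive best-response
checking; among several equilibria the selection is deterministic:
maximal payoff sum, then minimal total threshold movement, then
lexicographic strategy order.  The repeated game starts at $(1, 0)$ — the
Pawlak model is the natural origin, and starting there makes every later
trisection a relaxation of it — with default steps $\{0.05, 0.10\}$, and
stops when the selected profile is (stay, stay), when its payoff sum
improves on the stay profile's by less than $\varepsilon = 10^{-6}$, when
the next thresholds would be infeasible, or at the iteration cap
(default 50), which guarantees termination.  A game without a pure
equilibrium falls back to the stay profile and stops, so progress is
never built on an unstable profile.

## Iterative refinement under evolving features

When a new feature arrives, `refine_with_new_feature()` first scores the
prior regions by precision, $Q_P = P(C \mid POS)$ and
$Q_N = P(C^c \mid NEG)$ (other quality notions — risk, cost, accuracy —
would slot into the same interface).  If both clear their floors
(defaults $c_1 = c_2 = 0.9$), only the deferred objects are re-trisected:
the old boundary is treated as the whole universe — including for the
region probabilities $P(R)$ used by the learners — thresholds are learned
on that reduced table, and the new positive/negative sub-regions are
merged into the prior ones.  The updated boundary is the sub-boundary
computed inside the old one; a literal subtraction of the old boundary
from the new would always be empty, so the merge is the only reading
consistent with the rest of the procedure.  An empty region has undefined
precision, and undefined quality fails any positive floor: an empty
positive region carries no evidence that past decisions were adequate, so
the full-recompute branch is taken.  Both branches preserve the
invariants checked on every call: on the boundary branch the returned
POS/NEG are supersets of the prior ones and the boundary is nested; at
every stage the three regions partition the universe.

Note that the nesting guarantee belongs to the algorithm, not to the
probabilistic model: with $\alpha < 1$ a full recomputation on more
attributes can shrink the positive region, which is why the monotone
boundary property is asserted only for the Pawlak model.

## Evaluation

Accuracy is the correct fraction among decided objects and generality the
decided fraction of the universe; an empty immediate region makes
accuracy undefined, and it is returned as `NA` with a flag — never
silently zero.  Held-out objects are matched to the training block with
the identical value signature and inherit its decision; an unseen
signature defers, since an unseen value combination is precisely the
"insufficient evidence" case the third option exists for.  Test accuracy
counts only decided test objects and test generality the decided
fraction, mirroring the two definitions.  Cross-validation stratifies
folds by decision label from a required seed; discretization edges,
thresholds and regions are all fitted on the training part only, and the
train-fitted bin edges clamp out-of-range held-out values to the outer
bins.  Folds with no decided test object are excluded from the accuracy
mean and counted.  Because both training tables and fold assignment are
functions of explicit seeds, every reported number is reproducible.

Continuous attributes are binned by equal-frequency quantiles into at
most 5 bins by default: quantile edges avoid the empty blocks that
equal-width edges produce on the skewed count features typical of
annotation data (interactor counts, domain counts).  Both the policy and
the bin count are explicit arguments, and the learned edges persist with
the table.

## The synthetic generator

`generate_table()` emulates the structure of an annotation problem with
evolving evidence: a latent binary concept at prevalence $\pi$ (default
0.4), feature groups released cumulatively, and label noise (default
0.05, a plausible rate of wrong annotations).  Each categorical feature
has one concept-positive level, one concept-negative level and shared
background levels (default cardinality 4, hence two background levels).
With probability equal to its informativeness a value is drawn from the
concept-conditional support, otherwise uniformly from the background —
equivalently, the two concept-conditional distributions are overlapping
multinomials whose overlap is one minus the informativeness.  This
construction has two properties that make the benchmark behave like the
phenomenon it models: any block containing a concept-revealing value is
pure in the latent concept regardless of informativeness (so the
*quality* of decided objects is set by the label noise and stays flat as
features accrue), while the *fraction* of objects whose signature is
all-background — hence deferred — shrinks geometrically as more features
arrive.  More information means more decisions at similar accuracy,
which is the headline behaviour the acceptance suite asserts over the
five learners.

The default evolving benchmark uses 1000 objects and four releases of
one feature each with informativeness 0.2/0.4/0.6/0.8.  One feature per
release is a deliberate choice: with four 4-level features the signature
space (256) stays well populated at $n = 1000$, so held-out signatures
are usually seen in training; releasing several features at once would
make most signatures singletons and the held-out evaluation would
collapse into wholesale deferment for every model alike.  Ground truth
(latent concept, flipped labels, level roles) is returned alongside the
table, never embedded in it.

What the generator does **not** emulate: the marginal distributions of
real annotation features (power-law interactor counts, molecular
weights), correlations between features, objects arriving over time
(only features evolve), or hierarchical label structure.  Passing the
benchmark therefore demonstrates the machinery — partitioning, threshold
learning, refinement, seeded evaluation — under controlled conditions,
not performance on any real proteome.

## Problem sizes and runtime

The test suite works at desk scale: random tables of 8–40 objects for
the oracle-equivalence checks (200 tables against a 0.01 dense grid for
ITRS, 500 random games up to 5×5 against brute-force best-response
enumeration for the Nash solver), and the full benchmark — 10 generator
seeds × 5 models × 4 cumulative feature sets × 10-fold CV — for the
trend property.  The complete suite runs in about a minute on one core;
block statistics are computed with vectorized signature grouping, which
is what keeps two thousand model fits cheap.

## Known limitations

- Concepts are binary; multi-class trisections would need the
  multi-category uncertainty measures this package does not implement.
- Only pure-strategy equilibria of 2-player games are considered; a game
  without one simply stops the learning loop.
- The GTRS payoff forms, while standard in spirit (uncertainty balance,
  accuracy–generality trade-off), are local definitions; learned
  thresholds depend on them as well as on the step sizes and stopping
  rule, so GTRS results should be read as one member of a family.
- Equivalence-class matching generalizes only to seen signatures;
  with many fine-grained attributes most held-out objects defer.  That
  is honest behaviour, but it means feature sets should be kept coarse
  (or discretized) relative to the sample size.
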