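---
title: "Methods: score-based DAG discovery with a linear-Gaussian BIC"
author: "dagclimb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: score-based DAG discovery with a linear-Gaussian BIC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dagclimb)
```

## The model

`dagclimb` assumes the data are draws from a recursive linear-Gaussian
structural model: a directed acyclic graph (DAG) over the observed
variables in which every node is a linear function of its parents plus
independent Gaussian noise,

$$ X_i = \beta_0 + \sum_{X_j \in Pa(X_i)} \beta_j X_j + \varepsilon_i,
   \qquad \varepsilon_i \sim N(0, \sigma_i^2). $$

Three assumptions matter in practice: all relationships are linear and
acyclic (no feedback loops), disturbances are mutually independent (no
latent confounders), and all variables are continuous and complete-case.
Inputs are z-scored (mean 0, sample SD 1 with denominator $n-1$), so
every coefficient reported anywhere in the package is a standardized
effect: the expected SD change in the child per SD of the parent.

## The score

Each node's local fit is scored by

$$ \mathrm{BIC}(X_i, Pa(X_i)) =
   -\frac{n}{2}\Big[\ln(2\pi) + 1 + \ln\frac{RSS_i}{n}\Big]
   - \frac{k_i+2}{2}\ln n, $$

the maximized Gaussian log-likelihood of the regression minus a penalty
counting $k_i$ slopes, the intercept and the residual variance
($k_i + 2$ parameters per node). Natural logarithms throughout; the
search *maximizes* this quantity (larger, i.e. less negative, is
better). The graph score is the sum of local scores, which makes the
score decomposable: a single-edge change re-scores only the one or two
nodes whose parent sets changed. Local scores are memoized in a cache
keyed by the node and its sorted parent set; cached and cache-free
totals are bit-identical.

Two consequences worth knowing:

* **Score equivalence.** DAGs with the same skeleton and the same
  v-structures (Markov-equivalent graphs) have identical scores on any
  data. The search therefore returns *one member* of an equivalence
  class; the orientation of non-collider edges is decided by the
  constraints and the deterministic move order, not by the data. The
  test suite verifies equality across all 25 three-node DAGs.
* **Penalty arithmetic.** Adding one parent raises the penalty by
  exactly $\tfrac{1}{2}\ln n$, so an edge enters only when its partial
  correlation $\rho$ satisfies roughly
  $n\,\hat\rho^2 > \ln n$ — about $|\hat\rho| > 0.041$ at $n = 5000$.

Numerical choices: all regressions use QR least squares, never the
normal equations, because aggregated behavioral factors can be nearly
collinear; a rank-deficient design is an error naming the collinear
parents. A residual variance below $10^{-12}$ (perfect collinearity) has
no finite log-likelihood and errors by default; `clamp = TRUE` clamps it
to the floor for exploratory runs only, since silent clamping can
fabricate arbitrarily dominant scores.

## The search

`hill_climb()` is greedy steepest ascent from the empty graph. Each
iteration enumerates all legal moves — additions of absent,
non-forbidden, non-cycle-creating edges; removals; reversals whose
reversed direction is not forbidden and keeps the graph acyclic —
computes each move's score delta from the affected local terms only, and
applies the single best move if it improves the total by more than
`epsilon` ($10^{-9}$ by default, a guard against float-noise
oscillation). The search stops at a local optimum or at
`max_iterations` (default $10p^2$; hitting the cap returns the partial
result with a warning recorded in the trace).

Determinism was a design goal. Moves are ordered additions → removals →
reversals, lexicographically within class, and a candidate replaces the
incumbent best move only when it wins by more than `epsilon`. The last
rule matters more than it looks: the two orientations of a first edge
are score-equivalent, so in exact arithmetic they tie, but in floating
point they differ by ~$10^{-12}$. Letting that noise pick the winner
makes results platform-dependent and — worse — can steer the greedy
search into a poorer basin (an early backwards edge can make a spurious
shortcut edge look locally attractive). With the epsilon-tie rule, ties
resolve to the first move in the deterministic order, and chain
benchmarks recover the exact generating DAG in 98 of 100 seeds.

Acyclicity of a candidate addition $u \to v$ is checked incrementally by
reachability (is $u$ reachable from $v$?), which is property-tested
against a full topological sort.

Expert knowledge enters as a blacklist. `default_constraints()` encodes
exactly two domain rules: the outcome is a sink (no outgoing edges), and
the polygenic score cannot point into aggregated parental factors.
Nothing else is forbidden — deliberately: the genetic score may affect
the outcome, and edges from parental factors *into* the polygenic score
are allowed because they proxy the parents' own genotypes (passive
gene-environment correlation), not an action on the child's DNA.

## Effect quantification

The learned DAG is quantified by per-equation OLS. For a recursive
linear model with independent disturbances and no latent variables, the
equation-wise OLS estimates *are* the maximum-likelihood path
coefficients, so no joint covariance fit is needed; standard errors come
from the classical OLS covariance and two-sided p-values from the $t$
distribution with $n - k - 1$ degrees of freedom (exact at small $n$,
indistinguishable from normal at study sizes; SE differences against a
full-information fit are $O(k/n)$).

Total effects of a source on the target are computed twice and must
agree to $10^{-10}$: as the sum over all directed pathways (enumerated
breadth-first, shortest paths first, lexicographic within length) of the
product of edge coefficients, and as the corresponding entry of
$(I - B)^{-1} - I$, where $B$ is the direct-effect matrix —
nilpotent for a DAG, so the inverse is the finite series
$B + B^2 + \dots + B^p$. Indirect effect is total minus direct,
identically.

## Bootstrap stability and model comparison

`bootstrap_dags()` re-runs the *whole* learn-and-fit procedure
(re-standardize, hill climb, path model) on `B` resamples of the $n$
rows drawn with replacement (default `B = 100`). For each directed edge
it records the appearance frequency (denominator `B`; failed resamples
contribute no appearances and are counted separately) and the 2.5th and
97.5th percentiles of its coefficient across the resamples *in which the
edge was learned*. Conditioning on presence is a deliberate convention —
an absent edge has no coefficient — but it inherits the usual
selective-inference caveat: intervals for rarely-selected edges are
conditional quantities, not marginal confidence intervals. Edge identity
is direction-sensitive throughout ($X \to Y$ and $Y \to X$ are tallied
separately), matching how edge reversals are discussed as distinct
outcomes.

Reporting uses a frequency filter, boundary-inclusive at the
conventional 0.40. An effect is flagged *consistent* when the full-data
coefficient falls inside its bootstrap interval (closed interval).
Per-resample seeds are drawn up-front from the master seed, so summaries
are bit-reproducible and independent of execution order.

`compare_edge_sets()` compares two learned models (e.g. an
ancestry-restricted subgroup against the full sample) by directed-edge
intersection: Jaccard overlap $|A \cap B| / |A \cup B|$ plus the
fraction of each model's edges that are shared. Two empty edge sets
compare as fully overlapping.

### A caveat on noise frequencies

Bootstrap resamples are dependent through the original sample. When the
original draw happens to contain a spurious correlation just below the
BIC entry threshold $\sqrt{\ln n / n}$ — an event that is not rare,
since that threshold sits only two-to-three null standard errors
($1/\sqrt{n}$) from zero — a substantial fraction of resamples push it
over, and the deterministic tie-break concentrates all appearances on
one orientation. Frequencies of a few tenths for a single spurious edge
are therefore possible on pure noise, though such edges stay below the
0.40 reporting filter (which the test suite asserts). The operational
guarantee is *no spurious edge gets reported*, not *every spurious
frequency is tiny* — a distinction to keep in mind when reading
unfiltered bootstrap tables.

## Preprocessing

Collinear questionnaire scales are collapsed before structure learning:
agglomerative hierarchical clustering with average linkage on the
distance $1 - |r|$, cut so clusters merge only while the linkage
distance stays at or below $1 - t$; the absolute-correlation threshold
$t$ defaults to 0.7 (configurable). Average linkage is the standard
choice for variable clustering and is monotone in the cutoff; a variable
with no $|r| \ge t$ neighbor stays a singleton. Each multi-variable
cluster is replaced by its first principal component; the variance it
explains is the leading eigenvalue of the cluster's correlation matrix
over the cluster size — for two variables exactly $(1 + |r|)/2$, so a
pair correlated at 0.832 yields 91.6%. Eigenvector sign is arbitrary, so
components are oriented to a positive loading sum (ties broken by the
first variable's loading), making factor scores deterministic across
platforms; flipping every input of a cluster flips its factor exactly.

For predictor screening, `lmg_importance()` decomposes the regression
$R^2$ into per-predictor LMG shares — the average incremental $R^2$ over
all orderings of the predictors. It is computed exactly via subset
enumeration with ordering weights $s!(p-s-1)!/p!$, algebraically
identical to averaging the $p!$ orderings but needing only $2^p$
regressions; $p$ is capped at 12 (screening in this workflow operates on
a few dozen variables at most, after which enumeration is exact and
cheap — no sampling fallback is provided).

Missing data are handled once, at ingest: `read_variable_table()` drops
incomplete rows and every downstream operation rejects missing values.

## The synthetic generators

`simulate_sem()` draws from an arbitrary user-specified linear-Gaussian
SEM in topological order, with optional automatic solving of noise
variances so every node has unit marginal variance (coefficients then
read directly as standardized effects). Sample covariances converge to
the analytic $(I-B)^{-1} D (I-B)^{-\top}$, which the tests check at
$n = 100\,000$.

`make_study_like()` is the benchmarking fixture: eight variables —
three interlinked parental substance-use factors (Tobacco, Drug,
Alcohol), two parental-problem factors (EmoIssues, Behavioral), somatic
complaints, a child polygenic score (PRS) and the externalizing outcome
(External) — with direct effects on the outcome of 0.33 (Alcohol), 0.20
(EmoIssues), 0.10 (Behavioral) and 0.07 (PRS). The non-outcome
coefficients (substance-use interlinks around 0.2–0.5, substance-to-
problem paths of 0.15–0.5) were chosen once so that all variables keep
unit variance, total substance-use effects land in the tenths, and the
polygenic score stays nearly orthogonal to the parental factors: a weak
Behavioral → PRS edge of 0.03 creates a small passive gene-environment
correlation while keeping the marginal outcome-on-PRS slope within 0.02
of the direct 0.07 (a larger 0.05 edge would push the marginal slope to
0.089, blurring the direct/marginal distinction the fixture is meant to
illustrate). The generator emulates the correlation structure and
effect-size regime of real family-behavior data, not its marginal
distributions: real T-scores are skewed, floor-censored and measured
with error, none of which is modeled. Recovery results on this fixture
therefore demonstrate correctness of the machinery under the model's own
assumptions, not robustness to their violation.

`make_correlated_blocks()` draws block-equicorrelated Gaussians for
exercising the clustering and aggregation steps, erroring when the
implied correlation matrix is not positive definite.

## Problem sizes used by the test suite

Chosen as comfortable desk-scale workloads: structure-recovery batteries
use 3-variable chains at $n = 5000$ over 100 seeds; effect recovery uses
the 8-variable fixture at $n = 10\,000$ over 20 seeds; bootstrap
batteries use $B = 100$ resamples (bivariate strong-edge case over 10
seeds, and the full 8-variable fixture at $n = 5000$ over 10 seeds);
score equivalence enumerates all 25 three-node DAGs; the covariance
convergence check runs once at $n = 100\,000$.

## Known limitations

* Only one member of a Markov equivalence class is identifiable from
  data; undirected-in-the-class edges are oriented by constraints and
  deterministic ordering. No CPDAG output is provided.
* Acyclicity excludes feedback (e.g. child-to-parent effects), and
  independent disturbances exclude latent confounding.
* Greedy search finds a local optimum; there is no tabu list and no
  random restarting. On three-node problems it attains the exhaustive
  optimum in ≥ 95% of seeded trials.
* Bootstrap coefficient intervals are conditional on edge selection (see
  above), and frequencies of borderline spurious edges can be
  non-negligible even on pure noise.
* LMG is exact-enumeration only, capped at 12 predictors.
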