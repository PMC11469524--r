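---
title: "Steady-state MRA network inference: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state MRA network inference: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mranet)
```

## The model

`mranet` infers directed, signed, semi-quantitative signaling networks from
systematic perturbation experiments. The data are steady-state log2 fold
changes of phospho-protein readouts versus an unperturbed solvent control,
measured under combinations of a receptor stimulus and small-molecule kinase
inhibitors. The framework is Modular Response Analysis (MRA): the observable
global response of the network to a perturbation vector $p$ is

$$ R = -r^{-1} p, $$

where $r$ is the local response matrix. Its off-diagonal entry $r_{ij}$ — the
local response coefficient of the edge $j \to i$ — is the direct steady-state
change of node $i$ per unit change of node $j$ with the rest of the network
held fixed. $|r| > 1$ amplifies, $|r| < 1$ dampens, and the sign encodes
activation versus inhibition. The diagonal is normalized to $-1$, the
standard MRA convention. A node in this package represents the measured
phospho-signal of its protein (pGSK3 rather than GSK3 enzyme activity); edge
signs are whatever the data support.

Perturbations enter in two ways:

* **Stimulation.** The stimulus (e.g. receptor crosslinking) is an explicit
  network node $s$ with a perturbation entry of 1; the stimulation strength
  is absorbed into the outgoing coefficients of $s$. Stimulus nodes have no
  incoming edges.
* **Inhibition.** A kinase inhibitor on node $k$ has a twofold action on
  what $k$ transmits to its targets: a basal negative offset $l_k < 0$, and
  a dampening of the propagated signal by $e^{l_k} \in (0, 1)$. Concretely,
  node $k$ transmits $\tilde{x}_k = e^{l_k} x_k + l_k$ instead of $x_k$;
  the inhibited node's own measured response is not directly altered. Both
  limits are reproduced: with no upstream signal the targets see
  $r_{jk} l_k$, and under stimulation the propagated component is scaled by
  $e^{l_k}$. Where an inhibitor is known to perturb the phospho-signal of
  its own target (allosteric AKT inhibitors, covalent Btk inhibitors), that
  readout is masked in every condition containing the inhibitor.

All modeling is in log2 fold-change space, matching the data; no base
conversion is applied. The steady-state assumption reflects measurement at a
quasi-stationary time point after stimulation.

## Structural identifiability: coefficient paths

Real designs measure and perturb only a subset of nodes, so not every
coefficient is identifiable on its own. The response of readout $m$ to a
perturbation at $u$ decomposes (in loop-free networks) into products of edge
coefficients along the simple paths $u \to m$, times the inhibitor factors
described above. `buildMonomialMatrix()` enumerates these monomials as
integer exponent vectors over the raw symbols — edge coefficients $r$,
inhibitor offsets $l_k$, and dampening factors $\exp(l_k)$, the latter two
tracked separately because the two inhibitor actions leave distinct
fingerprints in the data. `reduceToIdentifiablePaths()` then selects a
maximal linearly independent subset by exact integer (fraction-free)
Gaussian elimination, preferring the shortest monomials as pivots so that
the resulting *coefficient paths* keep readable names such as
`r_H_A*r_B_H`. Factor order within a name follows the topological order of
the factor's source node, ties broken lexicographically, which keeps names
stable across runs and node orderings. Because the gradient of a monomial
$l^{\beta} e^{\gamma l}$ with respect to $l$ is $\beta/l + \gamma$, the rank
computation combines the two columns of each inhibitor into one with fixed
integer weights (a Schwartz–Zippel argument); the path count therefore never
exceeds the number of underlying parameters.

Two caveats are intrinsic to this enumeration and are handled explicitly:

* **Feedback loops** make responses rational, not polynomial, in the
  coefficients.
* **Parallel paths** that always co-occur inside one response (an
  unperturbed, unmeasured branching node) can make the monomial count
  overstate what the data constrain.

`verifyRank()` therefore evaluates the analytic Jacobian of all simulated
responses with respect to the log-magnitude parameters at random generic
parameter points and compares its numerical rank (singular values above
$10^{-8}$ of the largest) with the symbolic path count. On tree networks
with study-shaped condition sets the two provably agree, and the test suite
asserts this on random trees. Whenever they disagree, the numerical rank is
authoritative: it supplies the identifiable-parameter count used in the
reduced chi-square and in all likelihood-ratio tests. The package's own
B-cell-receptor fixture is an example: its RAF–MEK–ERK feedback loop and
its parallel receptor-proximal routes make the numerical rank (30) differ
slightly from the monomial count (31), and the degrees of freedom follow
the numerical value.

## Fitting

`fitModel()` minimizes the weighted sum of squared residuals

$$ \mathrm{WSSR} = \sum \left( \frac{\text{data} - \text{model}}{\text{error}} \right)^2 $$

over all non-missing cells, with per-cell standard errors from the replicate
measurements. Goodness of fit is the reduced chi-square
$X_r = \mathrm{WSSR}/(N - k)$ with $N$ the number of data points and $k$ the
identifiable-parameter count; $X_r \approx 1$ indicates a noise-level fit.

Numerical choices, all configurable:

* **Optimizer.** Damped least squares (Levenberg–Marquardt via
  `minpack.lm::nls.lm`) with an analytic Jacobian. Differentiating the
  steady state $A x = b$ gives $dx = A^{-1}(db - dA\,x)$; for an edge
  $k \to j$ the right-hand side has a single nonzero entry $-\tilde{x}_k$
  at row $j$, so the full Jacobian assembles from one matrix inverse per
  condition.
* **Parameterization.** The optimizer works on the raw parameters (edge
  coefficients unconstrained, inhibitor strengths in $[-20, -10^{-4}]$).
  The objective depends on them only through the identifiable combinations,
  so the optimum and all reported statistics equal those of a fit over path
  values; path values are read off as monomials of the raw optimum.
* **Multi-start.** 100 Latin-hypercube restarts by default; edge starting
  values log-uniform in magnitude over $[0.01, 100]$ with random sign,
  inhibitor starts uniform in $[-5, -0.01]$. The search is three-stage:
  every restart runs up to 200 iterations; the 5 best endpoints are
  polished to convergence (relative function tolerance $10^{-8}$, cap 1000
  iterations); finally a deterministic sign-refinement sweep flips one edge
  coefficient of the best fit at a time, re-optimizes briefly, and keeps
  improvements. Wrong-sign local optima on weakly constrained edges are
  the dominant multimodality of this objective — a network-scale fit can
  sit severalfold above the global optimum with every restart
  sign-trapped — and the sweep escapes them at a cost linear in the edge
  count. A plateau warning is emitted if fewer than two restarts reach the
  returned optimum (after refinement, possibly none do).
* **Error floor.** Per-cell standard errors are floored at 0.05 log2 units
  to prevent infinite weights from vanishing replicate scatter.
* **Missing cells** (masked readouts, empty cells) are dropped from both
  the WSSR and the data-point count.

For cross-model comparison, `refitWithFixedInhibitors()` clamps the
inhibitor strengths to common values — both systems received the same doses,
so differences should be attributed to the wiring — and refits the remaining
coefficients; clamped parameters are excluded from the identifiable count.

## Greedy structure adaptation

`adaptNetwork()` iterates fit → adapt → consistency check:

1. **Removal scan.** Each edge is removed in turn and the model refitted;
   the likelihood-ratio statistic $\Delta\mathrm{WSSR}$ is referred to
   $\chi^2(\Delta k)$ with $\Delta k$ the change in *identifiable*
   parameters (an edge absorbed in a path costs no degrees of freedom).
   Edges with $p > 0.05$ are removal candidates, most superfluous first.
2. **Addition scan** (only when no removal is upheld): every absent ordered
   pair — excluding self-loops and edges into stimulus nodes — is tried;
   additions with $p < 0.05$ are candidates, most significant first. No
   multiple-testing correction is applied across candidates, matching the
   stated thresholds of the original procedure.
3. **Consistency gate.** The data are split: stimulated conditions train
   the model, unstimulated inhibitor conditions are held out. Each
   candidate model simulates the held-out conditions and is scored by the
   error reduction versus the all-zero null model (unperturbed control),
   $100 \cdot (\mathrm{WSSR}_{\text{null}} - \mathrm{WSSR}_{\text{sim}}) /
   \mathrm{WSSR}_{\text{null}}$. "Not significantly worse" is
   operationalized as a tolerance of 2 percentage points (configurable) on
   this score relative to the previous accepted step. A candidate is upheld
   only if it passes the gate *and* does not increase the reduced
   chi-square; the second condition makes the documented monotonicity of
   the fit statistic across accepted steps structural rather than
   empirical. Candidates are tried in rank order until one is upheld; one
   structural change is made per iteration; the loop stops when no
   candidate is upheld. Pure simplifications ($\Delta k = 0$,
   $\Delta\mathrm{WSSR} < 10^{-6}$) are upheld without consulting the gate.

The full trace — every candidate tried, its p-value, fit statistics before
and after, consistency score, and the accept/reject decision — is returned
and serialized, so a run is auditable and replayable. Seeds for every scan
derive deterministically from the master seed: identical inputs give
identical traces.

Two behaviors of this greedy procedure are worth knowing. First,
structurally equivalent candidates exist: if a node's transmitted signal
feeds only sink readouts, an addition onto one sink can be
fit-indistinguishable from an addition onto another (the analogue of a
crosstalk onto an unobserved kinase being identifiable only jointly with
that kinase's outgoing link). The scan then ranks them identically, and the
lexicographic tie-break decides. Second, with ~20 candidate additions tested
at $\alpha = 0.05$ per scan and no correction, roughly one spurious
candidate per scan is expected on null data; the gate rejects some but not
all of these, so final networks may carry an extra noise-supported edge
alongside the correctly recovered changes. The structure-recovery study in
the test suite therefore scores whether the planted changes are recovered,
and the type-I calibration study checks the 5% rate directly.

## Uncertainty: profile likelihood

`profileLikelihood()` steps one coefficient path away from its optimum in
both directions, re-optimizing all other free parameters at each step, until
the WSSR crosses $\mathrm{WSSR}_{\text{fit}} + \chi^2_{1, 1-\alpha}$ (3.841
at $\alpha = 0.05$, pointwise, 1 df). The path monomial is constrained by
eliminating one of its raw factors — an edge coefficient appearing in few
other paths is preferred, and an inhibitor strength whose dampening factor
is also part of the path is never eliminated (no closed form) — with the
chain rule applied to the Jacobian. Stepping is adaptive: the initial step
is 10% of the estimate's magnitude (floor 0.01), doubled until the threshold
is bracketed, then bisected until the WSSR is within $10^{-3}$ of the
threshold. If the path value exceeds $10^4$ in magnitude without crossing,
that direction is flagged `ni` (non-identifiable): a change can be
compensated by the other coefficients. The $10^4$ bound is this package's
default, chosen far outside any plausible coefficient magnitude.

`compareModels()` flags a shared path as significantly different when the
95% pointwise CIs of any pair of models are disjoint (`ni` directions count
as unbounded, hence never disjoint on that side); paths present in only some
models are listed as individual links, not flagged. `consensusNetwork()`
votes edges across fitted models (default: present in at least 3), and bins
each coefficient into five states: amplification ($r > 1$), dampening to
neutral relay ($0 < r < 1$), no link ($r = 0$), attenuating to neutral
inhibition ($-1 < r < 0$), enforced inhibition ($r < -1$). The boundary
values $|r| = 1$ are assigned to the neutral-side bins and $|r| < 10^{-9}$
counts as no link, since the defining intervals are open. `composePath()`
multiplies coefficients along a path, so two inhibitory links in series
yield an overall positive response.

## The synthetic-data generator

`bcrDesignFixture()` packages a literature-style B-cell-receptor network
(20 nodes, 25 edges, stimulus node BCR) and the emulated perturbation
design: 8 inhibitors (JNK, MEK, PI3K, Btk, AKT, mTORC1, IKK, p38), each
with and without stimulation, plus stimulation alone — 17 conditions over
14 phospho-readouts, with the AKT and Btk self-readouts masked. The
topology is a representative encoding of a curated starting network and is
deliberately packaged as an editable CSV rather than an authoritative
reconstruction. A `"dlbcl"` variant emulates chronically active signaling:
no stimulated condition and no receptor-proximal stimulus node.

`generateGroundTruth()` draws edge coefficients log-uniform in magnitude
over $[0.3, 3]$ — spanning dampening and amplifying regimes around neutral
relay, the range where fitted coefficients of this kind of data typically
land — and inhibitor strengths uniform in $[-3, -0.5]$ (a twofold to
twentyfold dampening of propagated signal). Signs default to activating,
with known negative feedback (ERK onto RAF in the fixture) set negative;
draws whose feedback products destabilize the steady state are rejected and
resampled. `generateDataset()` simulates the noiseless responses, draws
$n = 3$ independent Gaussian replicates per cell in log2 space (default
noise 0.2 log2 units, homoscedastic per readout; per-readout noise vectors
are supported since real antibody panels differ), and returns the replicate
mean with the empirical standard error of the mean — so SEM-based weighting
is exercised exactly as in a replicated bead-based ELISA experiment. For
calibration studies the generator can instead store the known
$\sigma/\sqrt{n}$ as the error (`errorType = "known"`): with $n = 3$ the
empirical SEM makes the squared weighted residual so heavy-tailed that its
mean does not exist, and a reduced chi-square near 1 is only a meaningful
expectation when the weights match the true noise.

What the generator does *not* emulate: saturation and other nonlinearities
of real dose–response curves, correlated antibody noise, batch effects, and
the possibility that the true biology is far from steady state. Passing
tests on these synthetic data therefore demonstrate the correctness and
calibration of the inference machinery under the model's own assumptions,
not the adequacy of those assumptions for any particular experiment.

## Problem sizes in the test suite

The suite calibrates the reduced chi-square on the full 20-node fixture
(10 replicate simulations, 100 restarts each), and uses six-node networks
for recovery and adaptation studies (20 seeded datasets for parameter and
structure recovery) and a four-node chain for the 100-run profile-likelihood
coverage study. The structure-recovery study uses an acyclic six-node start
network: feedback loops multiply local optima in every candidate refit of a
scan, and disentangling optimizer failures from statistical ones is not what
that study measures — loop handling is exercised by the fixture-scale
calibration study and the rank cross-checks instead.

## Known limitations

* Steady-state changes only; no dynamics or time courses.
* The monomial enumeration covers simple paths; loop-induced
  identifiability is caught numerically, not named symbolically.
* Greedy adaptation finds a local optimum of structure space and inherits
  the uncorrected multiple-testing behavior described above.
* No Bayesian posterior, bootstrap CIs, or regularized structure learning.
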