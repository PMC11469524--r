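# mranet

Semi-quantitative signaling-network inference from systematic perturbation
data by steady-state Modular Response Analysis (MRA).

## The problem

Intracellular signaling networks — kinase cascades with feedback and
crosstalk, such as the pathways downstream of the B cell receptor — are
probed experimentally by perturbing nodes (receptor stimulation,
small-molecule kinase inhibitors) and measuring the steady-state change of
phospho-protein readouts as log2 fold changes versus a solvent control.
`mranet` turns such condition-by-readout matrices into a directed, signed,
semi-quantitative network: which node acts on which, how strongly, and with
what uncertainty. It is written for systems biologists analyzing
perturbation panels (bead-based ELISA, reverse-phase protein arrays) and
for methodologists studying perturbation-based network reconstruction.

## The model

MRA relates the observable global response matrix *R* to the local response
matrix *r* through

    R = -r⁻¹ p

where the off-diagonal entry `r[i, j]` (named `r_<i>_<j>`, target first) is
the direct strength of edge `j → i` — |r| > 1 amplifies, |r| < 1 dampens,
the sign encodes activation vs. inhibition — and *p* encodes the
perturbations: stimulated nodes receive a unit entry, while an inhibitor on
node *k* replaces what *k* transmits by `exp(l_k)·x_k + l_k` with strength
`l_k < 0` (a basal negative offset plus a dampening of propagated signal).
Because real designs measure and perturb only a subset of nodes, the
package first derives the structurally identifiable *coefficient paths*
(products such as `r_H_A*r_B_H`) by exact Gaussian elimination over the
response monomials, cross-checked against the numerical rank of the
response Jacobian. Fitting is weighted least squares (Latin-hypercube
multi-start Levenberg–Marquardt with analytic Jacobian); goodness of fit is
the reduced chi-square `WSSR / (N - k)` with *k* the identifiable-parameter
count. On top sit greedy likelihood-ratio structure adaptation gated by a
held-out consistency check, profile-likelihood confidence intervals,
cross-dataset structure transfer, and consensus core-network extraction
with five-state coefficient binning. A synthetic-data generator emulating a
B-cell-receptor perturbation panel (8 inhibitors × ±stimulation, 14
readouts, n = 3 replicates) makes every stage testable end to end.

See the methods vignette (`vignettes/mranet-methods.Rmd`) for the full
model, assumptions, and design choices.

## Worked example

Generate a ground-truth model on the packaged B-cell-receptor design,
simulate a noisy perturbation dataset, and fit the true structure:

```r
library(mranet)

fx <- bcrDesignFixture()        # literature-style network + study design
fx$network
#> SignalingNetwork with 20 nodes and 25 edges
#>   stimuli: BCR

truth <- generateGroundTruth(fx$network, fx$design, seed = 7,
  negativeEdges = data.frame(source = "ERK", target = "RAF"))
dat <- generateDataset(truth, noiseSd = 0.2, seed = 8)
dat
#> PerturbationDataset: 17 conditions x 14 readouts (n = 3 replicates); 4 missing cells

fit <- fitModel(fx$network, fx$design, dat, nStarts = 50, seed = 1)
fit
#> MRAFit: WSSR = 487.509 on 234 data points, 30 identifiable parameters
#>   reduced chi-square = 2.39 | restarts converged: 0 / 50

head(round(pathValues(fit), 3))
#>        r_SYK_BCR      r_ZAP70_BCR  l_AKT*r_BAD_AKT l_AKT*r_GSK3_AKT
#>            2.869            0.686           -0.951           -3.220
#>  l_Btk*r_JNK_Btk l_IKK*r_NFkB_IKK
#>           -0.834           -7.244

profileLikelihood(fit, dat, pathName = "r_SYK_BCR")
#>        path estimate lower upper niLower niUpper
#> 1 r_SYK_BCR     2.87  2.82  2.91   FALSE   FALSE
```

The 234 data points are the 17 × 14 measurements minus the four masked
cells (the AKT and Btk inhibitors act on their own readouts). The fitted
coefficient paths are the identifiable combinations: `r_SYK_BCR` is the
stimulus-to-SYK response, `l_AKT*r_BAD_AKT` couples the AKT inhibitor
strength to the AKT→BAD edge — inhibitor strengths only ever appear
multiplied by an outgoing coefficient of their target. The reduced
chi-square of 2.4 rather than ~1 reflects the weighting by *empirical*
replicate SEMs (heavy-tailed at n = 3); weighting by the known noise
(`generateDataset(..., errorType = "known")`) calibrates it to ≈1, which is
what the acceptance script measures. "Converged 0 / 50" means the final
deterministic sign-refinement stage improved on every raw restart. The
profile-likelihood CI is tight because `r_SYK_BCR` is pinned directly by
the stimulated SYK response; the simulation's true value here is 2.92,
just outside this particular pointwise 95% interval — the coverage study
in the test suite confirms the nominal 95% rate over 100 simulations.

Structure adaptation, transfer, comparison and consensus follow the same
pattern; `adaptNetwork()` returns the final fit plus a replayable trace of
every candidate tried. A thin command-line wrapper
(`inst/scripts/mranet`, subcommands `generate fit simulate adapt profile
compare transfer consensus`) exposes the same pipeline to shell users.

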