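---
title: "Models and methods in SumoNMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in SumoNMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SumoNMR)
```

This vignette records the mathematical models, the default parameter
choices and why they were made, and the numerical decisions behind each
analysis stage. It makes no empirical claims beyond what the test suite
and `scripts/acceptance.R` compute.

## Chemical-shift perturbations and interface calling

For each residue the combined amide CSP is the weighted Euclidean shift
distance

$$\mathrm{CSP} = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N / 5)^2},$$

with the conventional nitrogen scaling of 5 reflecting the ~5-fold wider
<sup>15</sup>N shift range (`weightedShiftDistance()`, adjustable via
`nitrogenWeight`). Peaks between titration points are matched by nearest
weighted distance within a gate (default 0.15 ppm); an assignment in
which two moving peaks claim the same target is an error, not a silent
choice, because it indicates the gate is too wide for the spectrum.

Interface residues are those with CSP strictly greater than
mean + `sdMultiplier`&nbsp;&times;&nbsp;SD (default multiplier 2). The SD
is the *population* SD by default (`sdType = "population"`): the profile
is the complete set of observed residues, not a sample from a larger one.
Residues whose peaks broaden beyond detection are in intermediate
exchange; their CSP is undefined, so they are excluded from the
mean/SD statistics and reported separately rather than imputed.

## The 1:1 binding model and the Kd fit

With total protein $P_t$, total ligand $L_t$ and dissociation constant
$K_d$, mass balance gives the bound fraction of protein as the root of a
quadratic:

$$f_b = \frac{(P_t + L_t + K_d) - \sqrt{(P_t + L_t + K_d)^2 - 4 P_t L_t}}
             {2 P_t}.$$

`boundFraction()` evaluates the algebraically equivalent conjugate form
$2 L_t / \big(s + \sqrt{s^2 - 4 P_t L_t}\big)$ with $s = P_t + L_t + K_d$,
which avoids the catastrophic cancellation of the textbook form when
$K_d \gg P_t, L_t$ (the difference of two nearly equal large numbers).
This is what lets the closed form agree with an independent root-finding
equilibrium solver to $10^{-10}$ relative across a wide log-spaced grid
(see `test-acceptance.R`).

In fast exchange the observed CSP is $\mathrm{CSP}_{max} \cdot f_b$. For
fixed $K_d$ this model is *linear* in the per-residue amplitudes
$\mathrm{CSP}_{max}$, so `fitKd()` profiles them out in closed form
($\hat a_r = \sum_i f_i y_{ri} / \sum_i f_i^2$, clamped at zero) and
minimises the profiled sum of squares over the single parameter
$\log K_d$ with `stats::optimize` on $[10^{-4}, 10^{6}]$ µM
(tolerance $10^{-10}$). A 1-D bounded search cannot fail to converge and
has no starting-value sensitivity, unlike a joint multi-parameter
nonlinear fit.

### Uncertainty: bootstrap interval construction

Uncertainties come from a seeded nonparametric bootstrap over the
non-zero titration points (default 500 resamples). With typical designs
only 4–5 such points exist, so the bootstrap distribution of $K_d$ is
strongly skewed, and the plain percentile interval under-covers: its
upper bound tracks the skewed point estimate. `fitKd()` therefore
reports the **basic (reversed-percentile) interval computed on the log
scale**, $\exp\!\big(2\log\hat K_d - q_{1-\alpha/2, \alpha/2}\big)$,
which reflects the quantiles about the estimate (the standard remedy for
this skew) and keeps both bounds positive. The acceptance suite checks
calibration directly: 95% intervals must cover the generating $K_d$ in
at least 90 of 100 seeded replicates at 0.005 ppm noise.

## <sup>15</sup>N relaxation

T1 and T2 decays are fit per residue as $I(t) = I_0 e^{-t/T}$ by
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) in intensity
space — a log transform would be undefined at the near-zero and negative
intensities that noisy long delays produce. Starting values are
deterministic ($I_0$ = first intensity, $T$ = delay nearest $I_0/e$).
Fits with $T \le 0$ or $T > 100 \times$ the longest delay are flagged as
non-decaying (`ok = FALSE`) rather than reported: such a $T$ is not
measurable on the grid. Default delay grids span 0.002–0.4 s (T1) and
0.002–0.2 s (T2), bracketing typical backbone values for small proteins.

The heteronuclear NOE is the ratio of saturated to unsaturated peak
intensity, with first-order error propagation of a common spectral noise
level. `flexibilityProfile()` flags residues with hetNOE &lt; 0.5 as
flexible and &le; 0 as highly flexible — the conventional cutoffs for
large-amplitude ps–ns motion; T1/T2 are reported alongside but the call
is driven by the hetNOE, the most direct ps–ns probe.

## Ensemble superposition and disorder

`kabsch()` computes the optimal least-squares rotation by singular value
decomposition with the determinant (reflection) correction, so the
returned matrix is always a proper rotation. Degenerate (collinear)
point sets are an error. `superposeToMean()` iterates superposition onto
the evolving mean structure to convergence ($10^{-6}$ Å change in mean
RMSD); this removes the arbitrariness of picking a reference model.
Backbone selection is N, CA, C. Ensemble spread is summarised as
RMSD-to-mean (default) or mean pairwise RMSD, and disorder as
per-residue RMSF about the mean. `alignSuperpose()` handles ensembles of
different constructs: it pairs residues by global sequence alignment,
superposes on the paired Cα, and iteratively prunes pairs deviating more
than `pruneCutoff` (default 2 Å) beyond the current RMSD.

Distance restraints are classed by sequence separation $|i - j|$: short
(&le; 1), medium (2–4), long (&ge; 5); the partition always sums to the
total.

## Sequence motifs and alignment

`scanSumoConsensus()` reports every &psi;-K-x-E window with &psi; in
{L, I, V} by default; `psiSet` accepts the extended literature set
(adding M, F). The acceptor lysine is position 2 of the motif.
`scanSim()` implements an operational SIM rule (versioned "sim-1" in its
output so results are traceable to the rule): a 4-residue core with
&ge; 3 residues from {V, I, L}, whose two flanking 4-residue windows
(clipped at the termini) together contain &ge; 2 residues from
{D, E, S}; overlapping qualifying cores merge into one hit. The
thresholds encode the motif's defining features — a short branched
hydrophobic strand in an acidic/serine context — while remaining a
deliberately simple, auditable rule rather than a trained predictor.
`kToR()` produces the lysine-free control construct; a consensus rescan
of its output is empty by construction.

Global alignment uses `Biostrings::pairwiseAlignment` with BLOSUM62 and
affine gaps (opening 10, extension 0.5, so a gap of length $L$ costs
$10 + 0.5L$). Percent identity is reported under an explicit denominator
convention — all alignment columns (default) or the shorter ungapped
sequence — because the two can differ by several points on divergent
pairs.

## Synthetic-data generators: scope

All generators are seeded through `withSeed()`, which saves and restores
the caller's random state, and exist to exercise the analysis code with
known ground truth:

- `simulateTitration()` moves each interface peak by
  $f_b \cdot \Delta\delta_{max}$ per axis plus Gaussian noise
  (`noiseSd`, in ppm on the proton axis; nitrogen noise is scaled by the
  weight). Defaults: $P_t = 50$ µM, ligand ratios 0–5, true $K_d = 31$
  µM — a moderate-affinity regime in which the quadratic and
  hyperbolic isotherms visibly differ, so the fit is genuinely tested.
  Designated broadened residues are deleted above a bound-fraction
  cutoff rather than attenuated: the analysis models presence/absence
  only.
- `simulateRelaxation()` / `simulateHetNoe()` add Gaussian intensity
  noise to exact decays/ratios on the default grids.
- `simulateEnsemble()` builds a self-avoiding Cα random walk (3.8 Å
  spacing) with idealised N/CA/C/O placement and adds per-region
  Gaussian coordinate noise (larger in designated flexible tails). It
  validates superposition and RMSF code; it is not a physical model of
  protein structure.
- `simulateRestraints()` draws residue pairs uniformly; only the
  sequence-separation bookkeeping is meaningful.

## Limitations

Single-site 1:1 binding in fast exchange; no lineshape or
intermediate-exchange modelling beyond peak disappearance. Bootstrap
intervals require at least a handful of titration points to be
meaningful. Mono-exponential relaxation only; no spectral-density or
model-free analysis. The SIM scanner is a rule, not a predictor, and
will not match divergent motifs. All default parameters are
overridable through the design constructors and `defaultConfig()`.
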