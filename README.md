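# SumoNMR

Tools for analysing NMR studies of SUMO-family proteins and their binding
partners: chemical-shift-perturbation (CSP) titrations with quadratic 1:1
binding fits, <sup>15</sup>N relaxation (T1, T2, heteronuclear NOE) and
flexibility calls, NMR structure-ensemble superposition and disorder
statistics, and sequence-level scans for SUMOylation consensus sites
(&psi;-K-x-E) and SUMO-interacting motifs (SIMs). Seeded synthetic-data
generators for every data type make the full pipeline testable end to end
without instrument data.

## Scientific background

SUMO (small ubiquitin-like modifier) proteins are covalently attached to
lysines of substrate proteins and are also read out non-covalently through
SIMs. Two NMR experiments dominate the characterisation of such systems:

- **CSP titrations.** A <sup>15</sup>N-labelled protein is titrated with
  unlabelled ligand; each residue's amide peak moves by
  CSP = sqrt(&Delta;&delta;H&sup2; + (&Delta;&delta;N/5)&sup2;).
  Residues with CSP above mean + 2&middot;SD map the binding interface,
  and the CSP-versus-ligand curves fit the quadratic 1:1 binding
  isotherm to give a dissociation constant Kd. Peaks that broaden out of
  detection (intermediate exchange) are excluded from the statistics and
  reported separately.
- **<sup>15</sup>N relaxation.** Mono-exponential T1/T2 decays and the
  heteronuclear NOE report per-residue backbone dynamics; hetNOE below
  0.5 flags flexible residues and values at or below zero flag
  large-amplitude disorder, typical of SUMO's N-terminal tail.

On the structural side, NMR ensembles are superposed by Kabsch
least-squares rotation (iteratively, to the evolving mean structure) and
summarised by RMSD and per-residue RMSF; distance restraints are
partitioned into short-, medium- and long-range by sequence separation.

## Worked example

Simulate a titration of a 90-residue protein (true Kd 31 &micro;M,
interface at residues 40&ndash;44, 0.005 ppm peak noise), call the
interface, and fit Kd:

```r
library(SumoNMR)

design <- titrationDesign(noiseSd = 0.005, seed = 7)
ts <- simulateTitration(design)
ts
#> TitrationSeries with 6 points
#>   [P]t (uM): 50, 50, 50, 50, 50, 50
#>   [L]t (uM): 0, 12.5, 25, 50, 100, 250
#>   peaks per point: 90, 90, 90, 90, 90, 90

call <- callInterface(cspProfile(ts))
call
#> InterfaceCall: threshold 0.1139 ppm (mean 0.01734 + 2 x SD 0.04826)
#>   interface residues: 40, 41, 42, 43, 44
#>   broadened (excluded from stats): none

fit <- fitKd(ts, residues = 40:44, nBoot = 500, seed = 7)
fit
#> BindingFit (shared mode)
#>   Kd = 30.03 uM (boot se 3.76, 95% CI 26.72..52.86, 500 resamples)
#>   residues fit: 5  RMS residual: 0.00385 ppm
```

The interface call recovers exactly the five planted residues, and the
fitted Kd (30.0 &micro;M, 95% CI 26.7&ndash;52.9) covers the generating
value of 31 &micro;M. Sequence scans on the bundled reference peptides:

```r
scanSumoConsensus(referencePeptides()[["substrate"]])
#>             kind start end matchedText anchorLysine
#> 1 sumo_consensus     3   6        IKQE            4
#> 2 sumo_consensus     8  11        IKPE            9

scanSim(referencePeptides()[["PML_SIM"]])
#>   kind start end matchedText  rule
#> 1  sim     7  12      RVVVIS sim-1
```

## Running the tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "SumoNMR",
                               load_package = "installed")'
```

The suite validates every analysis routine against independent oracle
implementations (equilibrium root-finding vs the closed form, grid-search
decay fits, rotation-grid superposition, brute-force alignment and motif
scans) in `tests/testthat/helper-oracles.R`, plus an end-to-end block in
`tests/testthat/test-acceptance.R`.

## Limitations

The binding model assumes a single 1:1 site in fast exchange for shifted
peaks; intermediate-exchange residues are modelled only as
presence/absence. Relaxation fits are per-residue mono-exponentials with
no model-free analysis. The synthetic ensemble generator produces
self-avoiding C&alpha; traces with idealised backbone geometry, intended
for validating superposition and disorder statistics rather than as
physically realistic structures. See the vignette for the full model and
parameter rationale.
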