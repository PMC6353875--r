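# csptitr

Quantitative analysis of protein–ligand NMR titrations followed by
¹H–¹⁵N HSQC spectroscopy, for weak (millimolar-scale) interactions such
as histone-tail peptides binding chromatin reader domains.

Given assigned amide peak lists across a titration, the package

- computes per-residue weighted chemical shift perturbations (CSPs),
  Δδ = √(Δδ_H² + (0.20 Δδ_N)²);
- classifies significantly perturbed residues against a trimmed
  threshold: mean + 1.0 SD (and a 1.5 SD upper tier) computed after
  removing the top 10% of CSPs, excluding unassigned and
  exchange-broadened resonances;
- fits each significant residue's trajectory to the one-site isotherm
  with explicit ligand depletion,
  Δδ = Δδ_max ((L+P+K_d) − √((L+P+K_d)² − 4PL)) / (2P),
  by bounded Levenberg–Marquardt least squares;
- aggregates per-residue K_d values into a global affinity with a
  one-pass 2-SD outlier exclusion, reporting a lower limit ("> x mM")
  when the titration is underdetermined by lack of saturation, and "NB"
  when no residue shows a perturbation above noise;
- maps significance tiers onto a helix/loop region annotation of the
  construct, and exports ambiguous interaction restraints for
  data-driven docking;
- implements a strand-aware "within 150 bp" genomic peak co-occurrence
  criterion for comparing ChIP-seq modification maps;
- ships seeded synthetic generators (titrations and BED peak pairs)
  with ground truth, so the whole pipeline is testable end to end.

## Worked example

A synthetic titration of a 0.1 mM protein with a peptide of true
K_d = 0.3 mM, molar ratios 0–32, realistic 0.005 ppm peak-position
noise:

```r
library(csptitr)

sim <- simulateTitration(trueKd = 0.3, proteinConc = 0.1,
                         noiseSd = 0.005, seed = 11)
out <- runTitrationPipeline(sim$series)
#> csp: 84 residues, 0 broadened, 0 proline
#> significance: trimmed 9 of 84; mean 0.01444, SD 0.02783; thresholds 0.04227 / 0.05619 ppm
#> fitting 17 significant residues
#> global Kd 0.3 +/- 0.027 mM (16 used, 1 excluded by the 2-SD rule)

out$globalKd
#> GlobalKd: 0.3 +/- 0.027 mM
#>   16 residues used, 1 excluded (2-SD rule)
```

The log traces every rule application: 9 = ceil(0.10 × 84) residues
trimmed before the threshold statistics; 17 residues above
mean + 1 SD enter fitting; one per-residue K_d deviated from the
candidate mean by ≥ 2 SD and was excluded; the global value is the mean
± SD over the 16 retained residues and recovers the simulated truth.

A non-binding control (peaks move only by noise) reports `NB`:

```r
nb <- simulateTitration(binderFraction = 0, noiseSd = 0.005, seed = 3)
runTitrationPipeline(nb$series, verbose = FALSE)$label
#> [1] "NB"
```

The peak-overlap criterion:

```r
ps <- simulatePeakSets(nA = 200, nB = 200, sharedFraction = 0.5,
                       jitterBp = 150, seed = 3)
overlapPeaks(ps$a, ps$b, maxGap = 150)
#> OverlapSummary (maxGap 150 bp, strand-aware):
#>   A: 200 peaks, 100 with a partner in B (50.0%)
#>   B: 200 peaks, 100 with a partner in A (50.0%)
#>   qualifying pairs: 100
```

File-based workflows (`readTitration()` on a YAML design plus TSV or
Sparky-style peak lists, `readBed()`, `runTitrationPipelineConfig()`)
and a thin CLI (`inst/scripts/csptitr-cli.R` with `run`, `csp`,
`overlap`, `simulate`, `simulate-beds` subcommands) wrap the same
functions. See the vignette `vignettes/csp-titration-methods.Rmd` for
the model, the rule definitions, and every tunable parameter.

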