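---
title: "Quantifying weak protein–peptide binding from HSQC titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying weak protein-peptide binding from HSQC titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csptitr)
```

## The measurement and the model

A ¹H–¹⁵N HSQC spectrum shows one peak per non-proline backbone amide.
When a ligand is titrated into an isotopically labelled protein under fast
exchange, peaks of residues at or near the binding surface drift from the
apo position toward the bound position in proportion to the fraction of
protein bound. `csptitr` quantifies that drift and turns it into a
dissociation constant.

Two equations carry the whole analysis. The **weighted CSP** combines the
proton and nitrogen shift changes of one amide into a single perturbation,

$$\Delta\delta = \sqrt{(\Delta\delta_H)^2 + (w\,\Delta\delta_N)^2},$$

with $w = 0.20$ (the conventional compensation for the ~5-fold larger ¹⁵N
shift dispersion; `nitrogenWeight` is configurable but uniform — no
residue-type-specific weights). The **binding isotherm** is the exact
single-site solution with ligand depletion,

$$\Delta\delta = \Delta\delta_{max}\,
 \frac{(L + P + K_d) - \sqrt{(L + P + K_d)^2 - 4 P L}}{2 P},$$

where $L$ and $P$ are *total* ligand and protein concentrations (mM).
The depletion form matters because these are weak, mM-scale interactions
measured at 0.05–0.10 mM protein: bound ligand is a non-negligible part
of the total, and the hyperbolic approximation $L/(L+K_d)$ would bias
$K_d$ upward. `isotherm()` is the closed form of the smaller quadratic
root; the test suite verifies it against a numerically solved root to
1e-10 relative and against the hyperbola in the trace-protein limit
($P = 10^{-9} K_d$, agreement 1e-6).

## From peak lists to CSPs

Input is one assigned peak list per titration point (canonical TSV or a
Sparky-like export; an `NA` sentinel marks a peak broadened beyond
detection) plus a YAML design giving concentrations. Identity across
points is by assigned residue number, never nearest-neighbour matching,
so crossing trajectories cannot be mis-threaded. The first point must be
apo; differences are taken point-minus-apo; `csp_traj[1]` is identically
zero.

Three statuses partition the residues: `assigned`, `proline` (no amide),
and `broadened` — absent at some non-apo point, with the trajectory kept
only *before* the first absence (a reappearing peak stays undefined, as
its assignment there is not trustworthy). Broadened residues are excluded
from both the significance statistics and the fits, but reported, since
disappearance itself is evidence of intermediate-exchange binding.

The quantity classified and fitted is the **endpoint CSP**, apo versus
the final titration point (for broadened residues, the last defined
point). The alternative — the highest point common to all residues —
would discard saturation information for the well-behaved majority.

## The significance rule

The classification population is the endpoint CSP of assigned,
non-broadened residues (at least 5 required). The
$\lceil 0.10\,n \rceil$ largest values are trimmed; the mean and sample
(n−1) SD of the remainder set two thresholds, mean + 1.0 SD and
mean + 1.5 SD; every residue in the population — including the trimmed
ones, which are the strongest binders — is classified against them with
strict `>`. Choices the rule's usual verbal statement leaves open, fixed
here once: `ceiling` for the trim count (at least one residue is always
trimmed), sample rather than population SD, strict inequalities, and
trim-boundary ties broken by residue number so output is deterministic.
With a zero-variance population the thresholds collapse onto the common
value and strict `>` classifies nothing, which is the sensible degenerate
answer. The suite checks the whole rule against an independent
sort-slice-recompute oracle on 1000 random populations and checks scale
equivariance and insensitivity to unassigned/broadened padding.

## Fitting and aggregation

Each significant residue's trajectory is fit for $(K_d,
\Delta\delta_{max})$ by Levenberg–Marquardt least squares with positivity
bounds (`minpack.lm`), started at $K_{d,0}$ = median non-zero ligand
concentration and $\Delta\delta_{max,0}$ = 1.2 × the largest observed
CSP — scale-aware starts that converge across the mM range without
tuning. Standard errors come from the fit covariance and are reported
but deliberately not used as aggregation weights: the global value is an
unweighted average of per-residue point estimates.

Aggregation applies a **one-pass** 2-SD rule: mean and SD over all
candidate $K_d$, removal of residues deviating by ≥ 2 SD, mean/SD
recomputed over the remainder. No iterative re-trimming — the rule is a
single application. Two triggers convert the result into a lower-limit
form "> min $K_d$": half or more of the candidates excluded, or more
than half of them unsaturated. The literal ≥ 50%-excluded trigger is
nearly impossible to trip with a symmetric 2-SD criterion; in practice
lack of saturation is what makes an affinity underdetermined, so both
triggers are implemented and the saturation one does the real work. A
titration is *saturated* when the fitted fraction bound at the final
point reaches `saturationCutoff` (default 0.8; the field invokes "lack
of saturation" without a number, so the cutoff is exposed).

One numerical guard: when all candidate $K_d$ are equal, SD = 0 and the
literal ≥ 2-SD rule would exclude *every* residue. No exclusion is
applied when the SD is below 1e-8 relative to the mean — this also keeps
noiseless validation runs (optimizer jitter ~1e-10) out of the
degenerate branch.

## The no-binding call

A purely relative mean + 1 SD threshold cannot by itself return "no
significant residues" on real (noisy) data: some fraction of a
pure-noise population always sits in the upper tail. What distinguishes
a non-binder experimentally is that even its largest perturbations are
within measurement noise. The pipeline therefore applies a
**detectability floor**: a residue enters fitting only if it is
significant *and* its endpoint CSP exceeds `minCSP` (default 0.03 ppm,
several times the ~0.005 ppm precision of peak-position measurement).
When no residue passes, or fewer than two fits converge, the run reports
**NB** and never reaches aggregation. The floor is a detection-limit
statement, not part of the statistical rule, which is why it lives in
the pipeline and not in `classifySignificance()`.

## The synthetic generator

`simulateTitration()` emulates exactly the structure the analysis
assumes: a minority of binder residues (default 20% of 84 assigned
residues, matching the size of an assigned-backbone dataset for a small
helical domain) sharing one true $K_d$, each with its own
$\Delta\delta_{max}$ (uniform on 0.05–0.25 ppm, the observed scale of
specific peptide-binding CSPs) and a random fixed 2-D direction — linear
trajectories, i.e. fast exchange; per-dimension Gaussian noise (default
0.005 ppm) at every point including apo; optional broadening that
removes binder peaks while the fraction bound is inside a window
(default 0.3–0.7), mimicking intermediate-exchange disappearance at
partial saturation. Default design: 0.1 mM protein, ratios
0, 1, 2, 4, 8, 16, 32. Geometry and noise use separate seeds so
replicates can share one ground truth.

What it does **not** emulate — and therefore what passing tests do not
show about real data: peak overlap and mis-assignment, exchange-regime
shape changes short of disappearance, per-point dilution (supported in
the design file but not simulated), baseline drift, or correlated noise.
Parameter-recovery results here are a correctness statement about the
estimator, not an accuracy claim for any particular spectrometer
dataset.

`simulatePeakSets()` plants a known fraction of one BED set within a
bounded gap of the other, on the anchor's strand, giving ground truth
for the overlap criterion below.

## Region mapping and restraints

`classifyRegions()` counts classified residues per region of a
3-column annotation. The shipped default describes the SRM–SANT1
construct (residues 141–251): SRM 141–158, linker 159–167, α1 168–178,
α1–α2 loop 179–220, α2 221–230, α2–α3 loop 231–236, α3 237–247,
C-term 248–251. The helix ranges come from chemical-shift-based
secondary-structure analysis; the SRM C-terminal boundary is inferred
from the construct starts and is overridable.

`buildRestraints()` turns a tier (default ≥ 1 SD) into the active set of
the protein and pairs it with a user-supplied peptide active set, as
ambiguous one-to-many interaction restraints — the standard form for
CSP-derived docking input, since a CSP says "this residue is at or near
the interface", not which partner atom it touches. Effective-distance
bounds default to 0–2.0 Å per common practice and are configurable. No
passive residues are emitted by default. An explicit override exists for
manually curated lists.

## Genomic peak co-occurrence

`overlapPeaks()` implements: same chromosome, compatible strand, gap ≤
`maxGap` (default 150 bp), where the gap of touching intervals is 0
(BED half-open convention; inputs are converted to 1-based `GRanges`
internally and the engine is `GenomicRanges::findOverlaps`). Strand
compatibility treats `.`/`*` as matching anything — ChIP-seq peaks are
usually unstranded, so a literal same-strand reading would void all
overlaps; a `strict` mode demands identical strands. Counts are
peak-wise, not merged-region-wise. The suite checks the implementation
against an O(n²) brute-force reference on random peak sets, including
the gap = 150 versus 151 boundary.

## Problem sizes and determinism

The validation suite runs, per property: 10⁴ random isotherm draws
against the quadratic-root oracle; 1000 random significance populations
(n = 5–200) against brute force; 500 random BED pairs (n ≤ 200) against
the quadratic-time reference; and 200 noisy titration replicates
(σ = 0.005 ppm, truth 0.3 mM) for which the median recovered global
$K_d$ must fall within 20% of truth. These sizes give stable
pass/fail behaviour at interactive runtimes. All simulation is
explicitly seeded; pipeline outputs are byte-identical across re-runs
on identical inputs.

## Known limitations

Single-site model only — no cooperativity, no two-site fits, and no
global shared-$K_d$ fit across residues (the global value is an average
of independent per-residue fits, matching how such titrations are
conventionally summarized). Exchange regime is reduced to a
present/absent flag. Concentrations are taken from the design file
verbatim; any dilution correction must be expressed there via per-point
`protein_conc` overrides. The significance rule is descriptive, not a
hypothesis test; no multiplicity machinery is attached, on purpose.
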