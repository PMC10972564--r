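---
title: "Methods: two-state conformation-selection analysis by HDX-MS and NMR"
author: "ConfSel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-state conformation-selection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConfSel)
```

## The problem and the model

Active (dual-phosphorylated, "2P") ERK2 interconverts between two global
conformers, R and L, on the millisecond timescale (exchange rate
constant $k_{ex} \approx 300\,\mathrm{s^{-1}}$). The R state is
associated with a catalytically productive ATP-binding mode; the L state
resembles the unphosphorylated ("0P") enzyme, which populates L
exclusively. The apoenzyme R:L populations are 80:20 at 25&nbsp;°C and
50:50 at 5&nbsp;°C for 2P-ERK2, and 0:100 for 0P-ERK2. ATP-competitive
inhibitors can display *conformation selection*: binding preferentially
to, and trapping, one pre-existing conformer, which shifts the
population equilibrium and changes the mobility of regions far from the
binding pocket (the DFG motif, strand β9, the *P*+1 segment, helix αF).

ConfSel implements the two solution readouts of this behaviour and a
forward model that generates data with exactly the statistical structure
the analysis assumes, so every stage is testable without any
experimental download:

* **HDX-MS**: peptide-level deuterium-uptake time courses, the
  in-exchange correction, and the per-segment difference statistic
  $\mathrm{dAUC} = \sum_t (\mathrm{HDX}_{apo} -
  \mathrm{HDX}_{inhibitor})_t$ over the nine labeling times, followed by
  ranking and a threshold classification of the inhibitor panel.
* **NMR**: slow-exchange methyl HMQC peak pairs
  ($\Delta\omega \gg k_{ex}$), whose volumes are proportional to the
  state populations ($\hat p_R = V_R/(V_R+V_L)$), and combined
  chemical-shift perturbations
  $\Delta\delta = \sqrt{\Delta\delta_H^2 + (0.25\,\Delta\delta_C)^2}$
  used to categorise methyl probes.
* **Structural geometry**: Kabsch superposition on a C-terminal-domain
  Cα selection (residues 109–141, 205–245, 272–310), per-residue RMSD
  without local refit, and halogen-to-tyrosine-ring-centroid distances.

## The uptake forward model

Each exchange-competent backbone amide $i$ (every residue except the
peptide's first and all prolines) exchanges as a single exponential at
the population-weighted rate

$$k_{obs,i} = p_R \frac{k_{int,i}}{P_{R,i}} +
             p_L \frac{k_{int,i}}{P_{L,i}},$$

the fast-ensemble limit of two-state exchange: $k_{ex} = 300\,
\mathrm{s^{-1}}$ exceeds every observable amide rate on the labeling
grid (the earliest time point is 30 s) by orders of magnitude, so each
amide sees the ensemble-averaged protection. Peptide uptake is

$$u(t) = f_{lab}\, f_{bx} \sum_i \left(1 - e^{-k_{obs,i} t}\right),$$

which is non-decreasing in $t$ and bounded by
$f_{lab} f_{bx} N_{exch}$.

Intrinsic rates $k_{int}$ use the standard acid/base/water-catalysed
form with nearest-neighbour side-chain modifiers on the dominant
base-catalysed term, so rates scale tenfold per pD unit in the
physiological regime. The neighbour-factor table is the package's own
parameterisation: it reproduces the realistic spread (roughly
0.5–10 s⁻¹ at pD 7.2, 25 °C) and the qualitative sequence effects of
published reference-rate tables without copying any of them verbatim —
none of the analysis depends on their absolute accuracy.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| labeling fraction $f_{lab}$ | 0.9 | — | 54 µL D₂O added to 6 µL protein |
| back-exchange factor $f_{bx}$ | 0.75 | — | typical survival for a cooled LC setup; constant across peptides |
| time grid | 0.5–180 | min | 9 points: 0.5, 1, 3, 8, 16, 30, 60, 90, 180 |
| in-exchange window | 30 s at 1/100 rate | — | quench-handling deuteration, a small constant per-peptide offset |
| $P_R$, $P_L$ (allosteric regions) | 150, 30 | — | see calibration below |
| $P$ (contact regions) | 20 | — | state-independent steric baseline |
| $k_{ex}$ | 300 | s⁻¹ | measured exchange rate; justifies ensemble averaging |

### Inhibitor classes and calibration

The generator's ground-truth panel has 17 compounds (13 R-selective, 3
exchange-retaining, 1 intermediate), plus BVD523 (R-selective), ATG017
(exchange-retaining), and the references VTX11e (R-selective) and
GDC0994 (exchange-retaining). Class effects are:

* **R-selective** — bound $p_R = 1$; allosteric-region protection
  ×20 (2P only).
* **Exchange-retaining** — apo populations; contact-region protection
  ×20 only.
* **Intermediate** — bound $p_R = 0.9$; allosteric protection ×5.

All compounds protect contact regions ×20 (nucleotide-pocket
occlusion), and in the 0P form every compound retains the pure-L
ensemble, so allosteric protection never applies there.

The baseline allosteric protection factors are the one genuinely free
pair. The classifier's combined score for the intermediate compound is
governed by the log-rate separations between apo, intermediate-bound,
and R-selective-bound amides; for $P_R/P_L$ near 3–5 the intermediate
lands near 0.42–0.44 on the min–max-normalised scale across the
realistic intrinsic-rate range, comfortably inside the intermediate
band. $P_R = 150$, $P_L = 30$ was fixed on that analysis, and the
default noiseless panel then reproduces the 13/3/1 cluster counts and
14 R-selective compounds of 19 surveyed end to end:

```{r classify}
tab <- simulatePanel()
dauc <- daucTable(tab, list(DFG_161_168 = c(161L, 168L),
                            P1_191_198 = c(191L, 198L)))
cls <- classifyPanel(dauc)
table(cls$label[!cls$is_reference])
```

### The classification rule

The published analysis separates clusters visually in the dAUC–dAUC
plane. ConfSel replaces this with a deterministic, scale-free rule:
per-segment min–max normalisation across the panel (anchored in
practice by the VTX11e and GDC0994 references), the mean of the DFG and
*P*+1 normalised scores, and thresholds at 0.4/0.6. Because
normalisation is affine-invariant, classification is unchanged by any
affine rescaling of the dAUC values; the thresholds are exposed as
parameters. Ranks (average-tie) are exported alongside raw dAUC, since
either could be used for display.

## The NMR peak model

Slow-exchange reporters (I72, L220, L242) carry R- and L-state peaks
whose ppm gap is checked against the slow-exchange condition at
construction ($\Delta\omega / k_{ex} > 10$ at a 900 MHz field, with the
¹³C dimension scaled by the gyromagnetic ratio). Noiseless volumes are
exactly $p_R$ and $p_L$ (unit total), so the volume-ratio estimator is
exact at zero noise and unbiased to first order under volume noise.
Volume noise is additive Gaussian, clamped at zero; peaks that are
structurally absent (broadened, or a state with zero population) yield
no volume rather than noise — one cannot integrate a peak that is not
there. Pairs whose total volume falls below 5&nbsp;% of the probe's apo
volume are flagged broadened and excluded from estimation.

Chemical-shift responses encode the published probe phenomenology:
R-state reporters (I196, I345) move proportionally to the population
shift $\Delta p_R$ the inhibitor induces; left-side reporters (L26,
L105, L155, L161) move by a fixed vector set by the left-side
substituent (tetrahydropyran vs pyrazole); first-shell contacts (I82,
L154) broaden under every inhibitor; second-shell contacts (V12, V37,
I101) broaden under all but the amidopyrrole-scaffold compounds
(VTX11e, BVD523). Probe categorisation uses point-biserial correlation
(threshold 0.8) between $\Delta\delta$ and the class indicator, with a
0.02 ppm minimum dynamic range so flat probes are never classified.

## Structural geometry

Coordinates are parsed with bio3d; hydrogens are dropped and the
highest-occupancy alternate location kept. Superposition is the Kabsch
algorithm (SVD of the cross-covariance with determinant sign
correction, so reflections are never returned); per-residue RMSDs are
computed after the single global C-domain fit, with no local refit, and
with the atom subset (all-heavy / side-chain / Cα) exposed because the
convention behind published per-residue values is ambiguous. The
halogen–π measure is the distance from the halogen to the unweighted
centroid of the six tyrosine ring carbons, the convention consistent
with the published 3.3–3.5 Å contacts. Author residue numbering is
used throughout, with a configurable per-structure offset because
expression tags shift numbering across deposited entries.

Tests verify the superposition against a brute-force Euler-angle
search and bio3d's independent least-squares fit on constructed
clouds, recovery of known rigid transforms to below $10^{-9}$ Å, and
rigid-transform invariance of every distance. The checks against
deposited ERK2 entries (5UMO/2ERK catalytic-residue RMSDs, 6OPK/6GDQ
halogen–π distances) fetch coordinates from the PDB at run time and
therefore require network access; all the geometry they exercise is
oracle-tested offline on constructed fixtures.

## Isotope envelopes and centroids

Envelopes are the peptide's natural-abundance isotopologue distribution
(built by convolution from its elemental composition) convolved with a
binomial distribution of deuterons over the exchangeable amides. Peaks
are laid on a uniform grid spaced by the ²H–¹H mass difference
(1.00628 Da divided by the charge) — the increment relevant to
deuteration — with the natural-abundance fine structure composited onto
that grid. The approximation mislocates ¹³C satellites by ~3 mDa, far
below anything the analysis reads, and buys an exact identity: the
envelope centroid shifts by exactly $N p \times 1.00628$ Da, verified
in the tests against exhaustive enumeration of all $2^N$ deuteration
states for $N \le 8$. Centroids are intensity-weighted means on the
neutral scale (m/z decharged with the proton mass), making uptake
charge-independent. Negative uptake and negative corrected values are
preserved with a warning, never clamped, because clamping would bias
dAUC.

## What the generator does and does not emulate

The generator reproduces the statistical structure the analysis relies
on: population-weighted exchange under saturating binding (1:1.2
enzyme:inhibitor), region-specific protection, a 90&nbsp;% labeling
plateau, a constant in-exchange offset, replicate scatter, and
slow-exchange peak volumes. It does not emulate EX1/bimodal envelopes,
peptide-dependent back-exchange, overlapping peptides, retention-time
effects, lineshape or relaxation physics, or titration behaviour below
saturation. Passing tests therefore demonstrate correctness of the
analysis pipeline under the stated model, not robustness of the
published conclusions to those unmodeled effects.

## Numerical and design choices

* Replicates are corrected first and then averaged; the two operations
  commute for a constant control, so the order is immaterial.
* With zero noise every generator output is deterministic and
  seed-independent; with noise, seeds are explicit everywhere and the
  caller's RNG state is never touched.
* Degenerate min–max normalisation (all dAUC equal in a segment) maps
  all scores to 0.5 with a warning rather than failing.
* Ties in ranking take the average rank.
* The label-recovery property test uses 200 noisy panels at 0.1 Da
  noise restricted to the two classified segments; the acceptance
  script uses 20 seeds for population recovery and the full default
  panel (5 peptides × 22 conditions × 2 forms) for classification —
  problem sizes at which the whole suite runs in about a minute.

## Known limitations

* Protection factors and class effect sizes are generator choices, not
  inferences about ERK2; only their qualitative pattern is anchored in
  the published regional behaviour.
* The peptide sequences outside the three published reporter segments
  are composition-plausible placeholders.
* The categorisation rule needs at least two inhibitors on each side
  of an indicator; probes broadened under all but one or two compounds
  (the amidopyrrole exemptions) remain unclassified rather than being
  forced into a category.
* Population estimates assume volumes strictly proportional to
  populations; differential relaxation between states is not modeled.
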