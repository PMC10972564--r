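# ConfSel

Conformation-selection analysis of ATP-competitive kinase inhibitors by
HDX-MS and NMR, built around the two-state (R/L) exchange behaviour of
ERK2.

Active, dual-phosphorylated ERK2 interconverts between two global
conformers — R, associated with productive ATP binding, and L,
resembling the unphosphorylated enzyme — with apoenzyme R:L populations
of 80:20 at 25 °C (50:50 at 5 °C; the unphosphorylated enzyme is pure
L). Some ATP-competitive inhibitors trap the R state when they bind;
others leave the equilibrium untouched. ConfSel is for analysts of
hydrogen-deuterium-exchange mass spectrometry (HDX-MS) and methyl-NMR
data who want to quantify and classify that behaviour:

* **dAUC statistic** — per peptide segment, the summed corrected-uptake
  difference over the labeling time grid,
  `dAUC = Σ_t (HDX_apo − HDX_inhibitor)_t`, with ranking and a
  scale-free min–max threshold classifier that labels each compound
  R-state-selective, exchange-retaining, or intermediate.
* **Population estimation** — for methyl probes in slow exchange
  (Δω ≫ k_ex ≈ 300 s⁻¹), both conformers give resolved peaks and
  `p̂_R = V_R / (V_R + V_L)`; combined chemical-shift perturbations
  `Δδ = sqrt(Δδ_H² + (0.25 Δδ_C)²)` categorise probes as R-state
  reporters, left-side reporters, or broadened contacts.
* **Forward simulator** — a fully specified generator for uptake tables
  and peak tables (population-weighted amide exchange, region-specific
  protection, in-exchange offsets, seeded noise) so the whole pipeline
  is testable end to end without any experimental data.
* **Structural geometry** — Kabsch superposition on a C-domain Cα
  selection, per-residue RMSD, and halogen-to-ring-centroid distances
  from PDB/mmCIF files.

## Worked example

Estimate apoenzyme populations from simulated slow-exchange peak pairs
(2 % volume noise), then classify the default inhibitor panel:

```r
library(ConfSel)

apo <- simulateHmqcPeakPairs(defaultMethylProbes()[c("I72", "L220", "L242")],
                             ConformerModel(pR = 0.8), noiseSd = 0.02,
                             seed = 1)
estimatePopulations(peakPairs(apo), volumeNoiseSd = 0.02)
#>   probe_id       p_R uncertainty
#> 1      I72 0.7945072  0.01655969
#> 2     L220 0.7715650  0.01585257
#> 3     L242 0.8145888  0.01687416

tab  <- simulatePanel()                      # noiseless default panel
dauc <- daucTable(tab, list(DFG_161_168 = c(161L, 168L),
                            P1_191_198 = c(191L, 198L)))
cls  <- classifyPanel(dauc)
table(cls$label[!cls$is_reference])
#>     EXCHANGE INTERMEDIATE  R_SELECTIVE
#>            4            1           14

cls[cls$inhibitor_id %in% c("#1", "#5", "VTX11e", "GDC0994"), ]
#>    inhibitor_id score_DFG_161_168 score_P1_191_198 combined_score        label
#> 1            #1         0.4086032        0.4330697      0.4208365 INTERMEDIATE
#> 5            #5         1.0000000        1.0000000      1.0000000  R_SELECTIVE
#> 20       VTX11e         1.0000000        1.0000000      1.0000000  R_SELECTIVE
#> 21      GDC0994         0.0000000        0.0000000      0.0000000     EXCHANGE
```

The three slow-exchange reporters recover the 80:20 ensemble to within
the propagated uncertainty. On the noiseless panel the classifier
separates 14 R-state-selective compounds (13 panel compounds plus
BVD523) from 4 exchange-retaining ones, with compound #1 intermediate —
its combined score of 0.42 sits between the 0.4/0.6 thresholds.

The full pipeline (simulate → uptake → dAUC → classify → NMR →
report), with CSV outputs and a seed/parameter-hash provenance block:

```r
runPipeline(defaultRunConfig())
```

or from a shell, `Rscript inst/scripts/run_pipeline.R --out results/`.

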