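# amyloidIMS

Analysis of native ESI-IMS–MS screens of amyloid peptide aggregation and
its inhibition by small molecules.

Amyloidogenic peptides (amyloid-β, hIAPP) assemble through transient
oligomers into fibrils, and the oligomers — not the fibrils — are the
species most implicated in toxicity. Native electrospray ionisation with
travelling-wave ion mobility mass spectrometry separates co-populated
oligomers by mass-to-charge ratio *and* drift time, preserves non-covalent
peptide–ligand complexes, and therefore supports a fast plate-format screen
for aggregation inhibitors. This package provides the complete analysis
chain for such screens, for mass spectrometrists and chemical biologists
running (or simulating) them:

* **Species assignment** — match centroided peaks to oligomer order *n*,
  charge *z* and ligand count *l* via
  *m/z* = (*nM* + *lM*<sub>L</sub> + *z m*<sub>H</sub>)/*z*, resolving
  *m/z*-degenerate ions (dimer⁴⁺ vs trimer⁶⁺ and their whole families) by
  drift time.
* **CCS calibration** — the standard travelling-wave protocol: corrected
  drift *t*′ = *t* − *c*·√(*m/z*)/1000, reduced cross section
  Ω′ = Ω/(*z*·√(1/*m* + 1/*m*<sub>gas</sub>)), power law Ω′ = *A t*′<sup>*B*</sup>
  fitted on log scales to calibrants of known drift-tube CCS.
* **Oligomer growth models** — isotropic (σ<sub>n</sub> = σ<sub>1</sub>·n<sup>2/3</sup>),
  linear (σ<sub>n</sub> = *a n* + *k*, fibril-like) and fixed-density
  spherical (ρ = 0.44 Da/Å³, parameter-free) fits to the CCS-vs-*n* series,
  compared by AICc.
* **Binding-mode classification** — each screened compound is called
  **specific** (binomial ligand-adduct distribution), **non-specific**
  (truncated-Poisson distribution), **colloidal** (ligand self-multimer
  series) or **negative** (spectrum unchanged), with oligomer-depletion
  metrics reported alongside.
* **Synthetic spectra** — a generator that plants oligomer ladders, charge
  envelopes, drift times from a chosen growth law and all four binding
  signatures, so the whole pipeline is testable without instrument data.

## Worked example

Simulate the 20-compound focused screen (compounds 3 and 16 planted
specific, 9 colloidal, 15 and 17 non-specific, the rest negative), then
assign and classify every well against the apo reference:

```r
library(amyloidIMS)

sc     <- defaultScenario(noiseCv = 0.05, seed = 1)   # Met-Abeta40, oligomers 1..6
plate  <- focusedScreenPlate()
report <- runScreen(simulateScreen(plateFromTable(plate), sc),
                    simulateApo(sc), abeta40Spec(), plate,
                    calibration = sc@calibration, seed = 1)
modeCounts(report)
#>     specific non_specific    colloidal     negative
#>            2            2            1           15
subset(reportTable(report), mode != "negative")[, 1:5]
#>    compound_id well         mode bound_fraction       margin
#> 3            3   A3     specific      0.3316399  0.009471612
#> 9            9   A9    colloidal      0.3616868 -0.037318346
#> 15          15   B3 non_specific      0.3512603 -0.004945000
#> 16          16   B4     specific      0.3420283  0.012958268
#> 17          17   B5 non_specific      0.3517579 -0.005281812
```

Every planted mode is recovered. `bound_fraction` is the share of peptide
ion current carried by ligand-bound ions; `margin` is Poisson rss minus
binomial rss on the pooled adduct profile (positive ⇒ binomial, i.e.
specific). The two specific hits also show oligomer depletion — the
largest observed oligomer drops from hexamer to trimer (`max_n_holo` vs
`max_n_apo` in the full table), the signature of an inhibitor acting on
early assembly.

The apo assignment also yields the CCS-vs-*n* series and the growth-model
comparison:

```r
apoAsg <- assignSpectrum(simulateApo(sc), abeta40Spec(),
                         calibration = sc@calibration)
fitGrowth(oligomerCcsSeries(apoAsg, abeta40Spec(), sc@calibration), 4461)
#> GrowthFit [isotropic] (selected) rss=1.57772e-30 aicc=-419.48
#>   params: sigma_monomer=680
#> GrowthFit [linear] rss=0.00701882 aicc=-32.5055
#>   params: a=328.082 k=377.424
#> GrowthFit [spherical] rss=0.200711 aicc=-20.3859
#>   params: rho=0.44
#> Selected model: isotropic
```

recovering the scenario's planted isotropic law (σ₁ = 680 Å²) exactly. The
ungapped core-motif comparison between the amyloidogenic segments of hIAPP
and amyloid-β:

```r
motifIdentitySimilarity("NNFGAIL", "SNKGAII")
#>   identity similarity
#>         57         86
```

A thin command-line front end over the same functions ships in
`inst/scripts/amyloidims` (subcommands `simulate`, `assign`, `fit-growth`,
`classify`, `screen`, `compare`, `motif`).

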