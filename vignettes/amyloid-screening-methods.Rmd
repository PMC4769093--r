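---
title: "Models and methods: oligomer assignment, CCS calibration and binding-mode classification"
author: "amyloidIMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: oligomer assignment, CCS calibration and binding-mode classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloidIMS)
```

# The problem

Amyloidogenic peptides such as amyloid-β (Aβ40) and human islet amyloid
polypeptide (hIAPP) assemble through transient, lowly populated oligomers
into fibrils. Native electrospray ionisation coupled to travelling-wave ion
mobility mass spectrometry (ESI-IMS–MS) can watch this process directly: it
separates ions by mass-to-charge ratio *and* by drift time through a buffer
gas, which reports on shape via the rotationally averaged collision cross
section (CCS). Because soft ionisation preserves non-covalent complexes, a
small molecule added to the peptide leaves a characteristic fingerprint in
the spectrum, and a plate of compounds can be screened for aggregation
inhibitors in minutes per well.

This package implements the complete analysis chain for such a screen:

1. assignment of centroided peaks to oligomer / charge / ligand-adduct
   species, using drift time to resolve m/z-degenerate ions;
2. calibration of travelling-wave drift times to CCS;
3. fitting and comparison of oligomer growth models (CCS versus oligomer
   order);
4. classification of each compound's binding mode as specific,
   non-specific, colloidal or negative;
5. a synthetic-spectrum generator so that every stage can be exercised,
   end to end, without instrument data.

# Species arithmetic and m/z degeneracy

In positive mode an oligomer of order $n$ carrying $l$ ligand adducts and
$z$ protons appears at

$$ m/z \;=\; \frac{n M + l M_L + z\,m_H}{z}, $$

with $M$ the peptide monomer mass, $M_L$ the ligand mass and
$m_H = 1.007276$ Da. Average masses are used throughout: at 4.4 kDa and
above, oligomer isotope envelopes are not resolved on a
quadrupole-time-of-flight instrument, and all reference masses in this
field are quoted as averages. The electron mass is neglected; at the 50 ppm
matching tolerance this is three orders of magnitude below the noise.

The relation is invariant under $(n, z, l) \mapsto (kn, kz, kl)$: the
dimer$^{4+}$ and trimer$^{6+}$ ions of any peptide share one m/z exactly,
as do all $n = z$ species with the singly protonated monomer. These
*degeneracy families* are the reason IMS matters: members of a family have
different CCS per charge and therefore different drift times.

# Travelling-wave CCS calibration

Travelling-wave mobility has no closed-form drift-to-CCS relation, so the
instrument is calibrated with species of known drift-tube CCS (classically
denatured cytochrome c, ubiquitin, lysozyme and tryptic peptides). The
package implements the standard protocol:

* corrected drift $t_d' = t_d - c\sqrt{m/z}/1000$, removing the
  m/z-dependent, mobility-independent transit (EDC delay, instrument
  constant $c$, default 1.41 in instrument-native units);
* reduced CCS $\Omega' = \Omega / \big(z \sqrt{1/m + 1/m_{gas}}\big)$,
  removing charge and reduced-mass factors (nitrogen drift gas, 28.0134
  Da);
* power law $\Omega' = A\,t_d'^{\,B}$ fitted by least squares of
  $\ln \Omega'$ on $\ln t_d'$, with $r^2$ reported.

`estimateCcs()` applies the law; `invertCcs()` is its exact inverse and is
what the synthetic generator uses to turn a "true" CCS into a drift time.
Estimate∘invert is an identity to numerical precision, which the test suite
asserts at $10^{-9}$ relative. The calibrants shipped in
`inst/extdata/calibrants_synthetic.csv` are synthetic (generated exactly
from a known law) because literature drift-tube values are not
redistributable data; they exercise the code paths, not the instrument.

# Oligomer growth models

Three idealised laws describe CCS versus oligomer order $n$:

* **isotropic**: $\sigma_n = \sigma_{monomer}\, n^{2/3}$ — growth equal in
  all dimensions;
* **linear**: $\sigma_n = a n + k$ — growth in one dimension, $a$ the cross
  section a monomer adds within a fibril, $k$ the fibril cap;
* **spherical**: a perfect sphere of protein-typical density
  $\rho = 0.44$ Da/Å$^3$; volume $nM/\rho$, radius $(3V/4\pi)^{1/3}$,
  cross section $\pi r^2$. With the density fixed this law has *no free
  parameters*.

`fitGrowth()` fits all three and selects by small-sample corrected AICc,
counting 1, 2 and 0 parameters respectively (or 1 for the spherical law
when the density is fitted). Two numerical choices matter and are the
package's own:

* **Log-scale residuals (default).** CCS uncertainty is a relative
  reproducibility, i.e. multiplicative. On the log scale the error variance
  is constant and the Gaussian AICc is the matching criterion; on the
  absolute scale large-$n$ points would dominate the fit and the criterion
  would be mis-specified. On the log scale the isotropic law is linear with
  a closed-form scale; the linear law is fitted by Nelder–Mead from the
  ordinary-regression start; an exact fit short-circuits the optimiser.
  `logResiduals = FALSE` restores plain least squares.
* **Ties break toward parsimony.** A noiseless spherical series is *also*
  an exact isotropic series (both scale as $n^{2/3}$), so both fits reach
  zero residual; the zero-parameter spherical law wins the tie, as it
  should.

The models are genuinely confusable in realistic corners: for a 4.46 kDa
monomer the fixed-density spherical curve happens to run within a few
percent of the linear law $250n + 380$, and a binomial adduct distribution
approaches a Poisson as sites increase at fixed mean occupancy (see below).
The test suite probes both limits rather than hiding them.

# Species assignment and degeneracy resolution

`assignSpectrum()` drops peaks below 0.5% of the base peak (noise floor),
matches each remaining peak against the full theoretical grid
($n \le n_{max}$, $z$ in the charge range, $l \le l_{max}$, ligand
self-multimers $j \le j_{max}$ at charge 1–2) within a 50 ppm tolerance,
and resolves multi-candidate peaks by drift time: each candidate's CCS is
predicted from a growth prior, converted to a drift through the calibration
inverse, and the nearest candidate wins, ties breaking toward smaller $n$
(parsimony). Without a calibration, degenerate peaks are honestly reported
as unassigned with a degeneracy flag.

The growth prior is chosen in this order:

1. an explicit prior passed by the caller (e.g. a fitted
   `GrowthModelComparison`);
2. a prior **anchored on the spectrum's own unambiguous peaks**: peaks
   matching exactly one grid species carry label-independent CCS
   information, and their estimated CCS values fix the CCS-versus-$n$ law
   (full model comparison with anchors at ≥ 3 orders, closed-form isotropic
   scale below that);
3. a spherical-seeded isotropic fallback
   ($\sigma_{monomer}$ from the fixed-density sphere at $n = 1$, scaled
   $n^{2/3}$) when no anchor exists.

The anchoring step is load-bearing: a fixed fallback prior whose monomer
CCS is ~20% below the true value mis-resolves entire degeneracy families.
In a screen, `runScreen()` assigns the apo reference first (its undepleted
oligomer ladder provides anchors), fits the growth law to the apo CCS
series, and reuses that prior for every holo spectrum — ligand-bound
spectra are often oligomer-depleted and may contain *no* unambiguous peak.
Adducted monomer CCS values are scaled by
$((M + lM_L)/M)^{2/3}$: the adduct adds volume, not shape.

# Binding-mode classification

For each compound the ligand-adduct count distribution is read off the
monomer charge states (the species on which adduct counts are annotated in
this field; higher oligomers of these peptides are not observed to bind).
Per-charge profiles over $l = 0..l_{max}$ are normalised and pooled by an
intensity-weighted mean. Two families are fitted to the pooled profile:

* **binomial** — specific binding at $N$ equivalent sites with occupancy
  $p$; $N$ is searched over $1..l_{max}$, $\hat p = \bar l / N$ in closed
  form;
* **truncated Poisson** — non-specific adduction during ionisation; the
  rate matches the truncated mean (the maximum-likelihood condition),
  found by root search, and the pmf is renormalised over the finite
  support so the comparison is between proper distributions.

The verdict cascade is:

1. **colloidal** if ligand self-multimer assignments at ≥ 2 multimer orders
   carry > 2% of base-peak intensity — self-association contaminates the
   adduct profile, so this check comes first;
2. **negative** if the bound fraction (peptide ion current with $l \ge 1$)
   is below 5% — deliberately low, because specific inhibitors that bind
   through hydrophobic contacts can show weak gas-phase binding yet fully
   inhibit fibrillation;
3. otherwise **specific** versus **non-specific** by which family leaves
   the smaller residual sum of squares on the normalised profile.

The residual comparison (rather than a likelihood-ratio test) is a
deliberate choice: the mapping from ion counts to measured intensity is
unknown, so a counting likelihood would be fictitious, while residuals on
normalised profiles are well defined. The margin (Poisson rss − binomial
rss) is always reported so users can impose their own cutoff, and the
binomial → Poisson confusability limit ($N$ large, $p$ small at fixed
$Np$) is asserted as a shrinking-margin trend in the tests. Oligomer
depletion (largest observed order and oligomer fraction of peptide ion
current, holo versus apo) is reported alongside every verdict as auxiliary
evidence for inhibition: a "positive" call in practice combines specific
binding with depletion of higher-order oligomers.

All thresholds (50 ppm, 0.5% floor, 2% colloid, 5% binding) are
`assignmentConfig()` parameters; none of them is printed in the primary
literature, and the defaults are engineering choices documented here.

# The synthetic-spectrum generator

`simulateApo()` emulates the apo condition of a screen: one peak per
populated (order, charge) pair, intensity = oligomer abundance × charge
weight × multiplicative lognormal noise (unit mean, CV-parameterised),
drift time from the truth growth model's CCS pushed through the inverse
calibration. `simulateHolo()` plants a binding signature: binomial or
truncated-Poisson splitting of monomer charge-state intensity across
adduct counts (conserving each charge state's ion current), geometric
(ratio 0.7) ligand-multimer and peptide+ligand series for colloidal
aggregators, depletion of oligomers above a cutoff for specific binders,
and byte-identical apo output for negatives. `simulateScreen()` derives a
per-compound seed from the plate seed and the compound id by a 31-bit
string hash, so any single well can be regenerated in isolation.

The default study conditions (chosen once, as a realistic desk-scale
emulation, and used by all acceptance-level tests) are: Met-Aβ40 at average
mass 4461.0 Da; oligomers 1–6 with abundances 0.55 / 0.18 / 0.11 / 0.07 /
0.05 / 0.04; two charge states per order (monomer 3+/4+), including the
co-populated dimer$^{4+}$/trimer$^{6+}$ degenerate pair; isotropic truth
with a 680 Å$^2$ monomer CCS (a literature-plausible Aβ40 value); a fixed
synthetic calibration ($A = 550$, $B = 0.55$, EDC 1.41, N$_2$); intensity
noise CV 0.05; specific binders with $N = 2$, $p = 0.3$ and complete
depletion above trimer; non-specific binders with rate 1; colloidal
aggregators with multimers $j = 2..5$ entering at 30% of base peak. The
20-compound plate of `focusedScreenPlate()` plants compounds 3 and 16
specific, 9 colloidal, 15 and 17 non-specific, the remainder negative,
with an hIAPP column that differs only in compounds 3 (non-specific) and 9
(negative); its ligand masses are evenly spaced synthetic stand-ins
(228.2–488.5 Da) because no reusable mass table exists for the screened
series.

What the generator does *not* emulate — isotope structure, chemical
background, detector saturation, drift-time jitter, in-source dissociation
— bounds what the recovery tests show: they validate the analysis chain
against its own forward model under realistic intensity noise, not against
instrument physics. Drift times in particular are noiseless by
construction, so degeneracy resolution is tested for logical correctness,
and its robustness margin to drift error is the gap between family members
(~20% in drift), not a measured instrument property.

# Worked example

```{r example, eval = FALSE}
sc <- defaultScenario(noiseCv = 0.05, seed = 1)
plate <- focusedScreenPlate()
report <- runScreen(simulateScreen(plateFromTable(plate), sc),
                    simulateApo(sc), abeta40Spec(), plate,
                    calibration = sc@calibration, seed = 1)
modeCounts(report)
#>     specific non_specific    colloidal     negative
#>            2            2            1           15
```

Problem sizes throughout (12-peak apo spectra, 20-compound plates, 100
replicates per Monte-Carlo study) are the package's chosen desk-scale
defaults; all statistics reported by `scripts/acceptance.R` are recomputed
from scratch at run time under these conditions.

# Known limitations

* Single peptide per sample; mixed-target screens are out of scope.
* No dissociation-constant estimation: a titration series, not a
  single-ratio screen, would be required.
* Hydrophobically driven binders can be under-called (weak gas-phase
  binding); the 5% threshold mitigates but cannot remove this, and
  orthogonal solution assays remain advisable.
* mzML ingestion is an extension point; the supported interchange format
  is the three-column centroided peak-list CSV.
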