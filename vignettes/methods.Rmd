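---
title: "Models and methods behind pepstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pepstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepstruct)
```

pepstruct implements the desk calculations used when short designed
peptides — here modelled on a GPCR TMH7–H8 elbow fragment and a
β-arrestin finger-loop fragment — are characterised by circular dichroism
and solution NMR. This vignette records the models, their assumptions,
the tunable parameters, and the design decisions taken where the
methodology left genuine choices open.

## CD helicity

Raw ellipticity in millidegrees is normalised per peptide bond:
$[\theta](\lambda) = \theta_{mdeg}(\lambda) / (10\,C\,l\,n)$ with molar
concentration $C$, path length $l$ in cm and $n$ residues. We treat
$[\theta]$ as **mean-residue** molar ellipticity; per-molecule
normalisation is sometimes seen, but only the per-residue convention is
consistent with the $+3000 / -36000$ endpoints of the 222 nm estimator
below, so it is adopted as a package decision and recorded here rather
than presented as an external fact.

Helix content comes from the classical single-wavelength affine
estimator

$$\%\,helix = 100\cdot\frac{3000 - [\theta]_{222}}{39000},$$

i.e. $[\theta]_{222} = +3000$ for pure coil and $-36000$ for full helix.
The estimator is exactly affine and strictly decreasing; values outside
$[0, 100]$ are returned unclamped with a range flag so that pathological
inputs remain visible. For table reproduction the percentage is also
rounded half-away-from-zero to integer (base R's round-half-even would
shift printed cells); the unrounded value is always retained.

Two further choices are deliberately conservative:

* **Smoothing** is a moving-window least-squares polynomial
  (Savitzky–Golay-style; window 11 points, degree 3, both configurable),
  with windows shrinking symmetrically at the ends so no extrapolated
  points are produced. Instrument vendors ship proprietary "adaptive"
  smoothers whose details are unpublished; a polynomial smoother is a
  transparent, testable stand-in (it reproduces constants and straight
  lines exactly). Smoothing is **off by default** for the 222 nm
  estimator input — a single-wavelength read-out should not silently
  depend on a filter.
* **Shape classification** uses coarse features only: a random-coil call
  requires the global minimum in 195–200 nm without a 208/222 nm double
  minimum; a helical call requires local minima within ±3 nm of 208 and
  222 nm plus a positive band below 195 nm. Anything else is `other`.
  No multi-basis deconvolution (CONTIN/CDSSTR-style) is attempted: the
  workflow this package supports uses only the single-wavelength
  estimator.

## Secondary shifts and two-state helix populations

Secondary shifts are $\Delta\delta(i) = \delta_{obs}(i) -
\delta_{coil}(aa_i)$. The random-coil reference must be *named* for
results to be reproducible, so every profile records its reference-set
identifier. The default set (`wishart1995`) is the Wishart-style table
for unstructured peptides; sequence-neighbour and temperature/pH
corrections are off by default because the supported workflow gives no
evidence of using them. Nothing downstream depends on the absolute coil
values so long as the same set is used for real and synthetic tables —
the Δδ arithmetic is exactly invertible, which the suite asserts to
machine precision.

**Segment detection.** A residue is helical when
$\Delta\delta_{H\alpha} < -0.05$ ppm (the coil band $|\Delta\delta| \le
0.05$ ppm is conformationally uninformative). Helical segments are
maximal runs of at least 3 such consecutive residues; a single interior
residue at or above the band terminates a run. The run-length and
breaker rules are not standardised anywhere; these values are the ones
that resolve a helix–hinge–helix elbow (e.g. spans 394–402 and 404–408
split by a breaker at 403) into two segments rather than one, and the
scanner is verified against a brute-force enumeration of all maximal
qualifying runs on random profiles.

**Populations.** The two-state helix–coil model reads a segment-averaged
deviation as a linear interpolation between 0 (coil) and the full-helix
limiting shift: $-0.39$ ppm for Hα and $+3.1$ ppm for Cα, so
$\%\,helix = 100\,\overline{\Delta\delta}/\Delta\delta_{limit}$. These
two limits are calibration constants of the package, chosen as the pair
that reproduces the published (Δδ, %) conversions we validate against to
±1 point (the residual point is attributable to two-decimal rounding of
the printed averages). Uncertainties are propagated from per-measurement
errors of 0.01 ppm (¹H) and 0.1 ppm (¹³C):
$100\cdot\sigma_\nu/|\Delta\delta_{limit}|$, giving ≈2.6% for Hα and
≈3.2% for Cα. Note the Cα figure: a often-quoted ≈7% error for
Cα-derived populations is **not** what these numbers propagate to; the
package reports the formula-propagated value and leaves the discrepancy
visible rather than adopting an unexplained constant.

The combined estimate is the mean of the two integer-rounded
percentages with uncertainty equal to half their absolute difference
(the population SD of a pair) — the convention used when both columns
are averaged into one table cell.

## Chemical-shift-perturbation interface mapping

Free-vs-mixture differences are combined per residue as
$$\Delta\delta_w = \sqrt{\Delta\delta_{H\alpha}^2 +
\Delta\delta_{HN}^2 + \Delta\delta_{C\alpha}^2/4}.$$
The amide nucleus in this formula is read as the backbone amide proton
HN (the alternative reading, an "Hα of the NH group", is not a standard
nucleus and was rejected). Missing nuclei contribute zero but are
recorded as absent in the component table, so proline (no HN) and
overlapped resonances never silently inflate or deflate a residue's
$\Delta\delta_w$; a residue sharing no nucleus between the two tables is
omitted, never zero-filled.

"Significant" perturbation has no standard quantitative definition, so
the default policy is data-driven: flag residues above mean + 1·SD of
the profile, floored at 0.02 ppm (a flat profile flags nothing); a fixed
cutoff policy is available, and the policy string is embedded in every
exported active-residue list.

**Detection limit.** The suite checks exact recovery of injected
perturbations on synthetic mixtures. With the default ¹³C measurement
noise (0.1 ppm), the quarter-weighted Cα term gives the background
$\Delta\delta_w$ a half-normal tail of scale ≈0.05 ppm, and the
mean+1·SD threshold is crossed by pure noise in a few percent of
profiles when injections are only marginally above 3× the background SD
(≈0.1 ppm). Exact set recovery becomes reliable for injections of
several tenths of a ppm; the acceptance suite injects
(0.25, 0.25, 0.50) ppm on (Hα, HN, Cα) — $\Delta\delta_w \approx 0.43$
ppm — and requires exact recovery across 200 seeded replicates. Users
mapping weaker interfaces should prefer the fixed-cutoff policy with a
threshold informed by their own noise floor.

## Ensemble geometry

Superposition is the closed-form least-squares (Kabsch/SVD) solution
over a named atom selection (default backbone N, CA, C), constrained to
proper rotations; the returned RMSD is verified against an independent
quaternion-search oracle. Helix axes are the dominant principal axis of
a segment's CA coordinates, sign-fixed so the projection of (last CA −
first CA) is positive, i.e. axes are **directed N→C**. Directed axes are
essential: with undirected axes every angle folds into [0°, 90°] and
obtuse elbow angles (~94–97°) would be unrepresentable. The inter-helix
angle is $\arccos$ of the dot product of the two directed axes,
averaged per model across the ensemble.

The principal-axis fit was chosen over local rotational (Kahn-style)
axis fitting for robustness on very short helices, and `rms_to_axis`
exposes fit quality. Its known weaknesses are documented rather than
hidden: for a discrete helix the principal axis of a finite window tilts
slightly with window phase (different windows of the same ideal helix
disagree by up to a few degrees), and for a 5-residue segment under
0.2 Å coordinate jitter the per-model angle noise is several degrees —
which near 0° folds into a positive bias, since angles cannot be
negative. The angle-recovery validation therefore uses nine-residue
segments, where the estimator is in its stable regime; the 94° elbow
construction with its native 9+5-residue spans is validated separately
at its 3° tolerance.

The Ramachandran summary uses deliberately coarse rectangular φ/ψ
regions (α, β and left-handed-α cores, with a 20° "allowed" margin) —
enough to separate helical ensembles from nonsense, not a substitute for
a proper validation service. PDB handling honours ATOM / MODEL / ENDMDL
/ TER records only, rejects alternate locations other than blank/'A',
and ignores occupancies.

The published elbow-peptide ensembles themselves (the 94° ± 15° and 75°
± 30° statistics) are **not** desk-reproducible — no coordinate
deposition accompanies them — so coordinate ensembles are treated
strictly as *inputs* here; the geometry module is validated on
synthetic constructions with known ground truth instead.

## Peptide properties

Masses are computed at the element level: residue formulas summed, plus
water, then caps applied as formula edits (acetyl +C₂H₂O, amide −OH+NH₂)
on IUPAC average and monoisotopic scales. This reproduces the two
reference capped-peptide masses to within 0.02 Da. Net charge is the
standard Henderson–Hasselbalch sum; capped termini contribute no
terminal charges. The pKa scale defaults to the EMBOSS set (a Lehninger
set is included, and individual values can be overridden) since the
original design screening used an external webserver whose internals are
not public. The isoelectric point is found by bisection to 1e-4 pH
units and is reported as undefined when the charge never crosses zero.

## Synthetic data: what it does and does not emulate

The generators provide ground truth for every estimator:

* **Shift tables** follow the two-state model exactly:
  $\delta_{obs} = \delta_{coil} + f_i\,\Delta\delta_{limit} +
  \mathcal{N}(0, \sigma_\nu)$ with $\sigma_H = 0.01$, $\sigma_C = 0.1$
  ppm — the stated measurement errors, which are the *study conditions*
  of all recovery tests. Noise is independent across residues and
  nuclei. Real spectra add what this omits: peak overlap, assignment
  ambiguity, nearest-neighbour sequence effects on coil values, and
  exchange broadening.
* **Mixture tables** add specified per-residue offsets plus fresh noise
  and record the injected ground truth, enabling exact-recovery checks.
* **CD spectra** are smooth two-Gaussian-family basis curves anchored at
  222 nm to the estimator's endpoints, carrying only the canonical
  features (197 nm coil minimum; 208/222 nm helical minima; positive
  band below 195 nm). They make no claim to reproduce real band
  intensities away from 222 nm.
* **Coordinate ensembles** are ideal α-helices (φ = −57°, ψ = −47°,
  standard bond geometry, built by internal-coordinate chain extension)
  hinged at a prescribed inter-axis angle, with optional per-model
  random rigid motions and isotropic Gaussian jitter. The hinge residue
  geometry is left distorted on purpose — the hinge is disordered in the
  motif being modelled — and side chains are absent.

Passing the recovery tests therefore demonstrates that the estimators
are correct *under their own model assumptions* at realistic noise; it
does not demonstrate robustness to the unmodelled features of real
spectra listed above.

## Numerical conventions and problem sizes

Ties in integer rounding go away from zero. Degenerate inputs error
with classed conditions (`degeneracy_error`, `coverage_error`, …) rather
than returning silently wrong numbers: superposition needs ≥ 3 paired
atoms, an axis fit ≥ 4 CAs, classification a 190–260 nm window. All
generators are bit-reproducible under a fixed seed. The validation suite
uses 500 random profiles for the segment-detection oracle, 200
replicates per helix fraction for population recovery, 20-model
ensembles at five constructed angles for geometry, 50 random 10-atom
pairs for the superposition oracle and 200 replicates for CSP recovery —
sizes chosen so the full suite runs in well under a minute while keeping
binomial wiggle in the ≥95% recovery checks negligible.

## Known limitations

* Ballesteros–Weinstein labels are user-supplied configuration; the
  package computes nothing from them.
* The CD estimator is single-wavelength; no spectral deconvolution.
* HN shifts carry no helix dependence in the simulator, so HN-only CSP
  scenarios are less realistic than Hα/Cα ones.
* The random-coil set ships as a single named table; users with
  neighbour-corrected or temperature-corrected references can register
  their own via `random_coil_table(name, values)`.
* No docking: the pipeline deliberately stops at the exported
  active-residue restraint list.
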