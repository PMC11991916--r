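---
title: "Quantitative modelling of prohibitin ring complexes in mitochondrial cristae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative modelling of prohibitin ring complexes in mitochondrial cristae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitobell)
```

## Scope and scientific background

Prohibitin 1 and prohibitin 2 (PHB1/PHB2) are SPFH-family scaffold proteins
of the mitochondrial inner membrane. In human U2OS cells they assemble into
membrane-embedded, bell-shaped complexes of 11 alternating PHB1 and PHB2
subunits that sit predominantly on crista membranes (CMs) rather than the
inner boundary membrane (IBM). `mitobell` implements the quantitative
analysis layer around that structural picture:

1. a **stereology module** that turns cell-level measurements (molecules
   per cell, mitochondrial network length, crista spacing, void fraction,
   tubule diameter) into complexes-per-crista and membrane-coverage
   estimates, with Monte-Carlo uncertainty propagation;
2. a **ring-assembly module** that builds parametric n-fold cyclic
   assemblies of alternating subunits inside the measured bell envelope;
3. a **crosslink-restraint module** that maps crosslinking
   mass-spectrometry (XL-MS) residue pairs onto such assemblies under a
   Cα–Cα distance constraint and uses self-links to discriminate subunit
   arrangements;
4. a **subtomogram-averaging simulator** — a desk-scale analog of the
   cryo-ET processing chain — with synthetic bell densities, a missing
   wedge, exhaustive in-plane alignment, rotational symmetry detection and
   Fourier shell correlation (FSC);
5. **synthetic-data generators** that plant ground truth so that every
   stage is testable without external downloads.

Wet-lab steps (imaging, knock-ins, blotting), real tomographic
reconstruction, structure prediction and density-guided fitting are out of
scope; inputs such as network length or crista spacing are taken as given.

## The stereological abundance model

All derived quantities are compositions of elementary ratios. With total
prohibitin molecules $M$, molecules per ring $m$, CM-localized fraction
$f$, network length $L$ (µm), raw inter-crista spacing $s$ (nm) and void
fraction $v$:

$$
N_\text{rings} = \frac{M}{m}, \qquad
s^\ast = \frac{s}{1 - v}, \qquad
N_\text{cristae} = \frac{1000\,L}{s^\ast}, \qquad
N_\text{per crista} = \frac{N_\text{rings}\, f}{N_\text{cristae}}.
$$

Membrane areas use the circular-crista model: one CM disc has area
$\pi (d/2)^2$ at tubule inner diameter $d$; a lamellar crista has two
opposing membranes, so the total area doubles. A ring of diameter $d_r$
occupies $\pi (d_r/2)^2$, and coverage is the ratio of total ring footprint
to total crista membrane area, in percent. The CM:IBM concentration
enrichment converts a localization fraction $f$ into a per-unit-length
density ratio, $\frac{f}{1-f}\,\rho$, where $\rho$ is the IBM:CM length
ratio.

The default parameters are the measured study values: PHB1
$(3.38 \pm 0.23)\times 10^6$ and PHB2 $(3.46 \pm 0.15)\times 10^6$
molecules per cell, a $1082 \pm 360$ µm network, $74 \pm 15$ nm raw
spacing, $21 \pm 8\%$ voids, a 75–84% CM fraction, a 564 nm tubule inner
diameter, a 20 nm ring diameter, 32 molecules per 16-dimer ring, 11
subunits per bell complex and an IBM:CM ratio of 0.64.

```{r}
report <- run_quant_pipeline(default_study_params())
report
```

Design choices worth making explicit:

* **CM fraction.** No single localization fraction is reported, only the
  75–84% range; the pipeline default is its midpoint, 0.795, which
  reproduces both the $1.7 \times 10^5$ CM-ring count and the ~43
  complexes per crista.
* **Rounding.** All internal arithmetic is unrounded; only the print
  method applies presentation rounding (3 significant figures for ring
  counts, integer part for cristae, nearest integer for per-crista counts,
  2 significant figures for percentages). One consequence: the widely
  quoted 11,510 cristae is the integer part of $1082000/94$ with the
  *rounded* 94 nm spacing, whereas the unrounded chain gives 11,551 —
  a 0.36% difference that the report keeps; tests accept both readings.
* **Complexes per crista.** The ~43 value is derived as
  $M / 11 \times f / N_\text{cristae}$, which reproduces it to < 0.2%;
  this derivation is recorded in the JSON report as an assumption.

### Monte-Carlo uncertainty propagation

Only point estimates are published for the derived chain, while the inputs
carry standard deviations. `monte_carlo_intervals()` draws each measured
input independently from a normal with its (value, sd) — no covariance
information exists — truncated to its validity domain by clipping
(fractions to $[0, 0.999]$, lengths to positive), re-runs the chain per
draw and reports central quantile intervals. With all sd = 0 the intervals
degenerate exactly to the point estimates; a fixed seed reproduces the
intervals bit for bit. The default 10,000 draws run in about a second.

## The alternating ring builder

The assembly convention is fixed: the symmetry axis is +z with the bell
top toward +z (the intermembrane-space side, matching the averaging
convention of aligning particles along z); rotation is counter-clockwise
viewed from +z; chain indexing is 0-based and residue numbering 1-based.
Chain $k$ carries the subunit named by the strict alternation
A,B,A,B,…, translated to the placement radius along +x and rotated by
$2\pi k/n$. For odd $n$ the wrap-around pair is forced homotypic:
$C_{11}$ with two alternating identities yields exactly one A–A (6A/5B
start) or B–B (5A/6B start) interface. Both arrangements are first-class;
neither is preferred a priori — discriminating them is the crosslink
module's job.

The synthetic subunit generator emits a CA trace with a membrane anchor at
the bilayer interface and an arm leaning inward toward the narrowed top,
jittered by ±1 Å under a fixed seed. It is constructed so the assembled
ring respects the measured envelope: maximal CA radial extent at most the
95.1 Å base radius and CA z-span at most the 84.0 Å bell height. The
default placement radius is the base radius minus an 8 Å subunit margin
and is exposed as a parameter, since only the envelope is measured. The
sequence-segment net-charge helper uses the simplest charge model
consistent with the reported coiled-coil segment charges: K/R = +1,
D/E = −1, histidine neutral, termini ignored.

## Crosslink-restraint mapping

A crosslink is in agreement with the structure when its shortest
admissible Cα–Cα distance is **at most 30 Å (inclusive)** — the empirical
upper bound for common crosslinkers. Policy decisions, recorded in the
exported metadata:

* **Admissible chain pairs.** Self-links (same protein, same residue,
  diagnostic of homomeric contacts) require *distinct* chains of the same
  identity — a residue cannot crosslink to itself within one chain. All
  other links minimize over every ordered identity-matching chain pair,
  including the same chain, which covers the intra-subunit reading.
* **Ambiguity margin.** The "shortest distance, allowing a 2 Å
  difference" mapping rule is implemented as ambiguity *reporting*: the
  minimum remains the assigned distance, and every chain pair within 2 Å
  of it is listed as a co-candidate assignment.
* **Deduplication.** Tables are collapsed to unique unordered residue
  pairs per study; the same convention drives the cross-study overlap
  histogram.

The discriminating logic of self-links follows from the geometry: in an
alternating $C_{11}$ ring, same-identity chains are adjacent only at the
single homotypic interface; elsewhere they are at least two steps apart.
At the bell-top radius the adjacent-chain chord is ~25 Å (< 30 Å) while
the two-step chord is ~48 Å (> 30 Å), so an A-self-link is satisfiable in
the 6A/5B arrangement and violated in 5A/6B, and symmetrically for B.
`arrangement_test()` evaluates both assemblies; the synthetic generator
plants self-links only on residues whose sole sub-cutoff same-identity
contact is the homotypic adjacency, so the discrimination is exact by
construction.

## The subtomogram-averaging simulator

The simulator reproduces the logic, not the scale, of tomographic
processing. Its forward model: particles are in-plane rotations (uniform
over 360°) and continuous x/y shifts (uniform within ±`max_shift` voxels)
of a template, resampled bilinearly in one pass, degraded by a hard
Fourier-domain missing wedge and white Gaussian noise. Restricting the
search to in-plane angles mirrors the z-axis pre-alignment step of the
real workflow; a full 3D orientation search is out of scope. The wedge
half-angle defaults to 30° (a ±60° tilt range); the true tilt geometry is
unstated, so it is a free parameter.

The synthetic bell is a smooth truncated-cone shell running from the
190.2 Å base diameter to the 89.0 Å top over an 84.0 Å height, atop a
radially tapered bilayer patch, with an `n_fold`-periodic azimuthal
modulation representing subunits (uniform when `n_fold = 1`). Density is
strictly zero outside the envelope plus a 3-sigma shell margin.

**Alignment** is exhaustive: every grid angle × integer shift is scored by
real-space cross-correlation of the transformed reference against each
particle, with the reference initialized as the unaligned mean and one
refinement pass against the first-pass average. Because the wedge is fixed
in the laboratory frame while the reference rotates, the rotated reference
is wedge-filtered before scoring; without this the wedge imprint biases
the angular search toward zero. One identifiability caveat: with a
$C_{11}$-symmetric template the absolute angle is defined only up to the
32.7° period *and* a global reference phase within that period (the
average that serves as reference locks onto an arbitrary phase). Recovery
is therefore assessed on angles after removing the circular-mean offset
within the symmetry period; at low noise ≥ 90% of angles land within one
search step.

**Symmetry detection** samples density on rings across radii
(15–95% of the half-box) and all heights, computes azimuthal Fourier power
per order, and normalizes by total sampled ring energy, so each value is
the energy fraction carried by that order. The argmax over orders ≥ 2 is
the detected symmetry. An azimuthally uniform volume leaves only
grid-anisotropy residuals (≲ $10^{-5}$ of the energy, concentrated at
order 4 multiples), orders of magnitude below a real modulation signal
(~$10^{-2}$), which is why the uniform-volume check is phrased as an
absolute energy-fraction bound rather than a ratio between near-zero
numbers.

**FSC** correlates Fourier coefficients shell by shell (width one
frequency voxel) and reads the resolution at the first downward crossing
of the 0.143 threshold, linearly interpolated between shells; a curve that
never crosses reports the Nyquist resolution (2 × voxel size). Identical
volumes give FSC = 1 in every shell to within $10^{-10}$.

**Numerical choices.** All rotations are bilinear per z-slice, implemented
as sparse matrices shared across slices and particles. Interpolation
smoothing bounds several contracts: a synthetic $C_{11}$ bell rotated by
360/11° correlates ≥ 0.99 with itself; $C_n$ symmetrization of that bell
correlates ≥ 0.999 with the input at 4 Å voxels (≥ 0.995 at 5.5 Å), and
applying the symmetrizer twice correlates ≥ 0.999 with applying it once.
These are correlation-based contracts because a strict elementwise
tolerance is unattainable under repeated linear resampling — each
application smooths slightly — while correlation isolates the structural
statement from the benign smoothing.

**Problem sizes.** Simulations use 64-voxel grids at 4 Å (module checks at
48 voxels / 5.5 Å), stacks of 12–24 particles, 10–20 search angles and
±1–2 voxel shifts; alignment-based properties use 5–10 seeds per
condition. These sizes keep the whole validation suite on a laptop scale
while leaving every statistical margin comfortable (e.g. symmetry
detection is correct in 20/20 trials at SNR 0.5). The real study's
resolutions (28.1/18.3/16.3 Å from 817 particles) are properties of real
data and are deliberately not reproduction targets.

**Particle densities.** Tomogram scenes are homogeneous Poisson point
processes — only mean ± sd densities are reported, and a Poisson model is
the minimal-assumption generator with an unbiased `count/volume`
estimator. Group comparisons use the two-sided two-sample Student's
t-test on per-tomogram densities (pooled variance); at wild-type-like
(743 µm⁻³) versus knockdown-like (257 µm⁻³) densities and n = 10 scenes
per group the test detects the difference in ≥ 95% of repetitions, and
its type-I error at equal densities stays near the nominal 5%.

## What the synthetic data do and do not show

The generators emulate the *structure* of the real inputs — measured
parameter sets with uncertainties, XL-MS pair lists with
satisfied/violated/self fractions and cross-study overlap, bell-shaped
densities with wedge and noise — under planted, machine-readable ground
truth. They do not emulate peptide-level identification noise, conformational
heterogeneity, CTF effects, per-tilt dose weighting or non-Poisson particle
clustering. Passing tests therefore demonstrate correctness of the
computational chain under the stated forward models, not performance on
raw experimental data.

## Known limitations

* The stereology model treats cristae as full circular discs of the
  tubule inner diameter and rings as non-overlapping flat footprints.
* Monte-Carlo draws are independent; any correlation among measured
  inputs would change interval widths (not the point estimates).
* The alignment search is in-plane only and the wedge is a hard mask;
  resolutions from the simulator are comparable only within the
  simulator.
* Net-charge computation ignores termini and histidine protonation.
* mmCIF output covers the minimal `atom_site` loop needed for coordinate
  exchange; PDB I/O goes through bio3d.
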