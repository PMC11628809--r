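---
title: "Models and methods behind membranekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind membranekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranekit)
```

membranekit implements the analysis chain used to relate lipid bilayer
thickness and composition to the activity of an intramembrane protease:
solid-state NMR lineshape processing, the mean-torque projection of chain
order onto leaflet thickness, cleavage kinetics, and membrane observables
computed from particle trajectories. This vignette explains each model, its
assumptions, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Deuterium powder spectra and dePakeing

A chain-perdeuterated phospholipid in a fluid bilayer undergoes fast axially
symmetric reorientation, so each labelled carbon produces a Pake doublet
whose 90°-orientation (horn-to-horn) splitting is

$$\Delta\nu_{90,i} = \tfrac{3}{4}\,\chi_Q\, c_i\, |S_{CD,i}|,$$

with $\chi_Q$ the static quadrupolar coupling constant, $c_i$ the coupling
reduction of the site (1 for methylenes, 1/3 for the fast-rotating terminal
methyl), and $S_{CD,i}$ the segmental order parameter. We take
$\chi_Q = 167$ kHz, the literature value for aliphatic C–D bonds; it is an
explicit argument (`chi_q`) everywhere it enters. The forward model
(`simulate_quadrupolar_powder`) bins the exact orientation distribution
($\cos\theta$ uniform) into the frequency grid analytically, weights sites
by deuteron multiplicity, convolves with a Gaussian line broadening, and
normalises to unit integral. On a symmetric grid the output is exactly
mirror-symmetric.

dePakeing (`depake`) inverts the powder superposition into the 0°-oriented
sub-spectrum, where each doublet collapses to a sharp pair at twice its
horn offset. We discretise the powder kernel on a uniform symmetric grid
and solve a non-negative least-squares problem with a second-difference
(Tikhonov) smoothness penalty. This choice is deterministic, noise-tolerant
and directly testable against the forward model; the regularisation
strength `lambda` (default `5e-4`, scaled by the kernel norm) and the grid
size (default 513 points) are exposed. When the Gaussian broadening of the
acquisition is known (simulated spectra carry it in their metadata) it is
included in the kernel, so the inversion simultaneously deconvolves the
lineshape; with unknown broadening the inversion still works, with slightly
smeared oriented peaks. Grossly asymmetric input (relative symmetry
residual above 0.2) triggers a recorded warning; an all-zero spectrum is an
error.

The smoothed order profile (`extract_smoothed_order_profile`) follows the
classical equal-area-per-deuteron construction: the oriented half-spectrum
is integrated from the smallest to the largest splitting and partitioned
into windows of 3 deuterons for the methyl and 2 per methylene; each
site's splitting is the area-weighted mean frequency of its window, and
larger splittings are assigned to lower carbon indices (the plateau). Ties
and residual inversions are resolved by a weighted pool-adjacent-violators
pass, so the reported magnitude profile is monotone non-increasing from
plateau to methyl. Because the methyl's threefold coupling reduction is
inverted at this spectral layer, the stored profile is chain-referenced at
every carbon; order parameters are stored with the physical negative sign.

*What the round trip shows.* With a 12-carbon profile (plateau
$|S| = 0.21$, tapering to 0.05), 0.5 kHz broadening and peak signal-to-noise
50, simulate → dePake → extract recovers every $S_{CD}$ within ±0.015
(typically ±0.01). That validates the numerical chain, not the spectrometer:
real spectra add $T_2$ effects, baseline errors and partial orientation
that the generator does not emulate.

## Mean-torque projection and thickness regressions

The first-order mean-torque model maps a segmental order parameter onto
the mean travel of that segment along the bilayer normal:

$$\langle\cos\beta\rangle = \tfrac12\Bigl(1 + \sqrt{\tfrac{-8 S_{CD} - 1}{3}}\Bigr),
\qquad S_{CD} \le -\tfrac18 .$$

For weakly ordered segments ($-\tfrac18 < S_{CD} < 0$) the first-order
expression has no real solution; we fall back on the second-moment estimate
$\langle\cos\beta\rangle \approx \sqrt{\langle\cos^2\beta\rangle}$ with
$\langle\cos^2\beta\rangle = (1+4|S_{CD}|)/3$. The two branches do not join
continuously at $-1/8$ (0.5 vs $\sqrt{0.5}$); this is a property of the
documented fallback, asserted in the tests so a silent change of convention
is caught. Fluid-phase methylene orders sit well inside the first-order
branch, where the closed form agrees with an independent Boltzmann
quadrature oracle (solve for the torque strength reproducing
$\langle\cos^2\beta\rangle$, then integrate $\langle\cos\beta\rangle$) to
better than 0.02 over $S_{CD} \in [-0.45, -0.15]$.

The projected chain length sums segments at the all-trans projected repeat
$l_{cc} = 1.27$ Å (half the 2.54 Å two-carbon repeat), the methyl
counting as one segment with its chain-referenced order, so the all-trans
limit $l_c = 1.27\,\text{Å} \times n_\text{segments}$ is exact. Only the
first-order model is implemented; higher-order corrections are out of
scope and flagged in the result (`model_order`). The package reports
$l_c$ (leaflet) and leaves doubling to hydrophobic thickness to the caller,
since headgroup offsets are a separate modelling decision.

Thickness-versus-cholesterol calibration (`fit_thickness_model`) is
ordinary least squares of $l_c$ on cholesterol mol %; its `predict` method
is the documented bridge from a kinetics sample's measured cholesterol
content to its leaflet thickness.

## Phosphorus-31 CSA lineshapes

Under fast axial rotation the ³¹P shift of a lamellar-phase lipid is
axially symmetric: $\nu(\theta) = \sigma_{iso} + \tfrac{\Delta\sigma}{3}
(3\cos^2\theta - 1)$, with edges at $\sigma_{iso} + 2\Delta\sigma/3$
(0°) and $\sigma_{iso} - \Delta\sigma/3$ (90°, the intensity maximum under
the $\sin\theta$ weight). $\Delta\sigma$ is stored negative for lamellar
phospholipids; reports quote the span $|\Delta\sigma|$. The decomposition
(`fit_multicomponent`) models a spectrum as one or two powder patterns plus
an optional isotropic line and fits spans, isotropic shifts, Gaussian
broadenings and fractions by Levenberg–Marquardt least squares. Fractions
live on the probability simplex through a stick-breaking map with $n-1$
free fractions in $[0,1]$ — a hard constraint, not a penalty. Components
are returned sorted by span; two powder spans within 1 ppm raise a
degeneracy warning. The orientation distribution is an ideal spherical
powder; partially oriented (deformed-vesicle) lineshapes are out of scope,
and structured residuals are the symptom to look for. The broadening
kernel is Gaussian; $\sigma_{iso}$ floats by default.

## Cleavage kinetics

Progress curves of a FRET-quenched transmembrane substrate follow
$I(t) = I_{max} - I_0\,e^{-t/\tau}$ under pseudo-first-order cleavage.
`fit_single_exponential` fits unweighted residuals (no weighting scheme is
assumed for plate-reader noise), initialised from a log-linearised tail
with a provisional plateau 5% above the observed maximum. Curves without a
rising trend (Spearman $\rho < 0.2$) are rejected; a fitted $\tau$ beyond
100× the observation window is flagged unreliable. `normalize_tau` builds
the $\tau/\tau_0$ table against a reference sample (the protease in the
thinnest cholesterol-free membrane), with first-order error propagation
and an exact unit entry for the reference. `trend_fits` fits both a
straight line and the decay $y = A\,e^{-(x - x_0)/d}$ ($x_0$ pinned to the
smallest thickness so the amplitude is interpretable); point exclusions
are explicit caller masks recorded in the output — never automatic —
because any such exclusion is an interpretive choice, not a statistical
one.

## Trajectory observables

All trajectory operations assume an orthorhombic box with the bilayer
normal along z and angstrom coordinates; minimum-image distances are used
throughout.

**Order parameters** implement
$S_{CD} = \tfrac12\langle 3\cos^2\theta_z - 1\rangle$ over C–H bonds,
molecules and frames, with atoms matched by name patterns. Explicit
hydrogens are required; the synthetic generator provides them, and for
united-atom inputs a reconstruction step would be needed (not included).

**Annular classification** labels a lipid annular when its minimum
heavy-atom distance to any protein heavy atom is ≤ `cutoff`. No cutoff is
canonical; the default is 6 Å (first-shell contact) and every composition
report carries a sensitivity table at {5, 6, 7} Å plus the cutoff used.
Annulus composition is reported both as means of per-frame percentages and
as pooled-lipid percentages, since the two averages differ when annulus
size fluctuates.

**Headgroup orientation** histograms the P→N vector angle to +z per lipid,
reflecting lower-leaflet vectors so both leaflets share one convention;
the histogram is normalised to unit area.

**Helix tilt** takes the principal axis of per-residue backbone centroids
after a one-helical-turn (3.6-residue) moving average; without the
smoothing, the phase–height coupling of the helical winding leans a raw
principal axis by 1–2°. Tilt is folded to [0°, 90°].

**Pair distributions** are standard distinct-pair cross-RDFs on half-open
bins $[r, r+\Delta r)$, normalised by ideal-gas shell volume and mean pair
density; both this and the annular classifier are verified against
brute-force explicit-image oracles, exactly, on random frames.

**Bending modulus.** The midplane height field is the mean of the two
leaflet surfaces, each a per-cell average of reference-atom z on an
$N \times N$ grid with periodic nearest-neighbour filling of empty cells.
With $\hat h_q = \mathrm{FFT}(h)/N^2$, the spectrum is
$S_u(q) = A\,\langle|\hat h_q|^2\rangle$, the normalisation under which
the Helfrich–Canham prediction $S_u(q) = k_BT/(k_c q^4 + \gamma q^2)$
holds with $k_c$ in $k_BT$ units and lengths in nm. Modes are binned by
exact magnitude — each bin averages modes of identical $|q|$ — which
avoids the shallow-slope bias that fixed-width annular bins introduce in
small boxes. The fit is weighted linear regression of $1/S_u$ on $q^4$
(and $q^2$ when tension is floated) with inverse-variance weights
$n_\text{modes} S_u^2$; the default window keeps the four smallest
non-zero magnitudes, the long-wavelength regime where the continuum
theory applies. A non-positive fitted $k_c$ is an error, pointing at the
window. Absolute agreement with any particular simulation study is not
claimable because the per-area versus per-mode normalisation convention
varies across the literature; the package's convention is validated
self-consistently against its own sampler, which draws surfaces from the
stationary Helfrich distribution with the same convention.

## Synthetic generators: what they emulate, and what they do not

Every generator is a pure function of its parameters and a seed, and
embeds its ground truth in the output metadata. Defaults are chosen to
match the study conditions the package targets: 12-carbon (DLPC-like)
chains with plateau order 0.21 (the cholesterol-free fluid phase, giving
$l_c \approx 9.8$ Å), 0.5 kHz line broadening, SNR 50 spectra; cleavage
curves with $\tau = 600$ s sampled over a 3τ window at 2% noise; two
CSA powder patterns at spans 44.3/32.6 ppm with fractions 91/8% plus 1%
isotropic; Helfrich surfaces at $k_c = 20\,k_BT$ on 64×64 grids over a
25 nm box; and bilayer patches of 49–81 lipids per leaflet at 8 Å lattice
spacing.

The toy bilayer is a geometric stand-in, not a physical lipid system:
all-trans chains with ideal tetrahedral hydrogens whose director wobbles
about the normal with a von Mises–Fisher distribution of concentration
$\kappa$, chosen because the expected methylene order has the closed form
$E[S_{CD}] = -\tfrac12\bigl(1 - 3L(\kappa)/\kappa\bigr)$ with $L$ the
Langevin function (`scd_expected_vmf`). That makes the order-parameter
estimator testable without molecular dynamics, which is the point: every
consumer analysis is a geometric functional, so geometric fixtures with
known truth are sufficient to validate the estimators. They say nothing
about force fields, sampling convergence or real lipid disorder; passing
tests certify the analysis chain, not any simulation.

## Problem sizes and determinism

The validation suite runs at desk scale by design: 1025-point spectra with
a 513-point inversion grid, 200 Monte-Carlo kinetics replicates, 500
Helfrich frames per rigidity on 64×64 grids, 100-seed oracle-equality
sweeps on ≤ 300-particle frames, and 2–5 frame bilayer stacks of ≤ 81
lipids per leaflet. All randomness flows through explicit seeds (workflow
stage seeds derive from the single config seed), so every pipeline output
is exactly reproducible from its configuration.

## Known limitations

- The dePake inversion assumes an ideal spherical powder; partially
  oriented vesicle lineshapes bias extracted splittings.
- Profile recovery degrades when splittings approach the linewidth: with
  1 kHz broadening and a plateau order near 0.1 the methyl splitting
  (~1 kHz) is no longer resolvable and per-carbon errors grow to a few
  hundredths — a physical resolution limit, not a numerical one.
- Exact numerical agreement with any specific legacy dePakeing program is
  not claimable; the algorithm is validated against its own forward model.
- Only the first-order mean-torque model is provided.
- ³¹P fitting supports at most two powder components plus one isotropic
  line; vesicle-deformation lineshape modelling is out of scope.
- Trajectory readers cover multi-frame PDB natively (and single-frame
  PDB/DCD via bio3d); compressed trajectory formats require prior
  conversion.
- The bending modulus uses the fixed-normal height-spectrum route only; no
  local-normal correction, lipid-tilt or splay estimators.
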