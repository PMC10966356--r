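---
title: "Predicting far-UV CD spectra with coupled atomic oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting far-UV CD spectra with coupled atomic oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdosc)
```

## The model

Circular dichroism in the far UV arises from chiral coupling between
electronic oscillators. In the classical coupled-oscillator picture,
each site $i$ of a protein carries a complex, wavelength-dependent
polarizability $\alpha_i(\lambda)$ — imaginary part absorption, real
part dispersion — and a unit induced-dipole direction $e_i$. `cdosc`
implements the second-order coupling term as the working model of the
molar ellipticity:

$$\theta(\lambda) \;=\; -\sum_{i \ne j}
  \mathrm{Im}\!\left[\alpha_i \alpha_j\right] C_{ij}\, G_{ij},
\qquad
C_{ij} = K\,\frac{(e_i \times e_j)\cdot(r_j - r_i)}{\lambda^2},
\qquad
G_{ij} = \frac{e_i\cdot e_j - 3\,(e_i\cdot e_{ij})(e_j\cdot e_{ij})}{r_{ij}^{3}},$$

with $K = 1.426468\times10^{26}$, $r_{ij}$ the inter-dipole distance,
$e_{ij}$ the unit separation vector, and $\theta = 3298.21\,
\Delta\epsilon$ converting to molar CD. $C_{ij}$ is the
chirality-sensitive factor (a scalar triple product: it vanishes for
coplanar arrangements and changes sign under reflection); $G_{ij}$ is
the geometry-only dipole–dipole interaction. Both are symmetric, and
the sum runs over *ordered* pairs $i \ne j$ — twice the unordered sum.
That factor of two is a fixed convention here; it is absorbed by the
overall scale of the polarizability library, which is the only place
physical units enter (only products $\alpha_i\alpha_j C_{ij} G_{ij}$
are observable). No distance cutoff is applied by default: the $1/r^3$
kernel is long-ranged and truncating it measurably distorts spectra.

The assumptions worth keeping in mind: one conformation per input
(first MODEL of a multi-model file), isotropic scalar polarizabilities,
and a mean-field selection of one 21-curve polarizability set for the
whole protein. Higher-order coupling terms, absorbance prediction and
anisotropic polarizability tensors are out of scope.

## From structure to spectrum

`read_pdb()` parses ATOM/HETATM records by fixed columns, resolves
alternate locations (highest occupancy, ties toward `'A'`), keeps
HETATM records only for D-amino acids and MSE, and skips waters.
Hydrogens are used when present but never rebuilt for the forward model
— structures without hydrogens simply contribute no H sites, a
documented limitation.

**Dipole directions.** The published record this model derives from
does not pin the orientation convention of $e_i$, so the package
declares a default — each atom's dipole points along the bond to its
heaviest covalently bonded neighbor (ties broken by atom-name order),
with a logged residue-centroid fallback for unbonded atoms — and keeps
it configurable (`assign_dipole_directions(s, rule = <function>)`).
Covalent topology comes from a YAML template shipped with the package.

**Secondary structure.** Residues are collapsed into four groups:
α-helix (H), β-strand (E), coil (C) and other (O: turns, isolated
bridges and the rest). The built-in assigner combines backbone
hydrogen-bond energetics — the electrostatic model with partial
charges on N–H and C=O, amide hydrogens rebuilt from the preceding
peptide plane, bonds accepted below −0.5 kcal/mol — with a
right-handed $\varphi/\psi$ gate for helices, so a mirror-image
(left-handed) helix is *not* classed H even though its hydrogen-bond
distances are mirror-invariant. All constants live in `ss_config()`.
Bit-compatibility with the reference STRIDE program on real PDB
entries is not claimed for the re-implementation; for that purpose the
ingestion readers `read_stride()` / `read_dssp()` plus `apply_ss()`
are first-class, and the four-group collapse (H/G/I → H, E/B → E,
C → C, rest → O) is applied to external files identically.

**Atom typing and blending.** The 21 atom types (variants of H, C, N,
O, S by backbone/side-chain role and residue class) are data, not
code: a YAML table maps (element, role, class) to a label, because the
authentic selection rules are not fully published; users can supply
their own table. For a query protein with secondary-structure content
$(p_a, p_b, p_c, p_o)$, each library base entry $i$ gets the weight

$$c_{bi} = \frac{100}{c_t}\exp\!\big(-50\,(|a_i-p_a|+|b_i-p_b|+|c_i-p_c|+|o_i-p_o|)\big),$$

group curves get fixed equal weights summing to `group_mass` (default
0.1), and $c_t$ is chosen so that *all* weights sum to one — the
normalization role is stated for $c_t$; making the full weight vector
a convex combination is this package's concrete choice, as is applying
the group weights after that normalization. The exponential decay rate
50 makes the blend effectively nearest-neighbors in content space: an
L1 content distance of 0.1 already suppresses an entry by $e^{-5}$.

**D-residues.** Atoms of D-amino-acid residues (detected from the
signed volume of (N−CA, C−CA, CB−CA), or forced by D residue names)
use $\alpha^* = -\mathrm{Re}\,\alpha + i\,\mathrm{Im}\,\alpha$. A
consequence worth stating explicitly, and regression-tested: for an
all-D protein built as the *exact mirror* of an all-L one, the
geometric sign flip of $C_{ij}$ and the polarizability flip compensate,
so the predicted spectrum equals the L-form spectrum; the mirror alone
(without the flip) negates it. This is a property of the second-order
term, where the two sign changes enter an even number of times.

## Metrics and normalization

Model/experiment closeness uses the normalized absolute deviation
$\hat\Delta_\theta = \sum_i|\theta_i^{exp}-\theta_i^{mod}| /
\sum_i|\theta_i^{exp}|$ over the overlapping grid (linear
interpolation, no extrapolation): 0 is a perfect match, 0.1 a 10%
deviation. The quadratic NRMSD is provided as an alternative; the
absolute form is preferred for robustness to outlying points. Model
spectra are normalized to experiment by the single positive factor
$\sum|\theta^{exp}|/\sum|\theta^{mod}|$ — absolute-mass matching, not
least squares, which other CD tools use; the CLI reports NAD both raw
and after normalization since published deviations are typically the
normalized ones.

## The training side

The optical activity $o(\lambda)$ has $\mathrm{Im}\,o = \theta$;
its real part is recovered by a discrete Kramers–Kronig transform
(`kk_real_part()`), implemented with the Maclaurin alternating-point
scheme on a uniform $1/\lambda$ grid (resampled at ≥ 4× the input
density). Band-limited data make the transform biased: with the
default zero tail the recovered dispersive part of an in-band
Lorentzian is off by ~3% RMS on the 188–244 nm band alone, and a
forward-then-inverse round trip on a wide (150–320 nm) grid carries
~10% RMS error from the slowly decaying dispersive tails. A
damped-oscillator tail extrapolation (`extension = list(mode =
"lorentz")`) fits the in-band absorptive profile and reduces the
one-way bias below 1% in the tested configuration.

Per protein, the mean polarizability solves $\alpha_p^2 = -o_p /
\langle\sum_{ij} C_{ij} G_{ij}\rangle_\Omega$. The rotational average
$\langle\cdot\rangle_\Omega$ over beam orientations is computed by the
invariance shortcut: $C_{ij}$ and $G_{ij}$ are rotation-invariant
scalars, so the average equals the unrotated sum —
`rotational_average_CG()` exists to verify exactly that, with seeded
random rotations. The complex square root takes the branch continuous
in $\lambda$, anchored so $\mathrm{Im}\,\alpha_p \ge 0$ at the
dominant absorption band (physical absorption sign); the source
record is silent on the branch, so this is declared here.

Atomic curves are then assembled per type $a$ from non-negative
coefficients, real and imaginary parts separately:
$\mathrm{Re}\,\alpha_a = \sum_p k_{ap}\,\mathrm{Re}\,\alpha_p$ and
$\mathrm{Im}\,\alpha_a = \sum_p k'_{ap}\,\mathrm{Im}\,\alpha_p$.
(Read literally as a single real sum, the combination could not yield
a complex polarizability and every spectrum would vanish; the
two-part reading is the one consistent with a working model, and
non-negative $k'$ keeps absorption physical.) The coefficients are
learned by simulated annealing: log-space Gaussian single-coordinate
proposals (positivity by construction), geometric cooling from an
initial temperature of 5% of the starting objective, objective = mean
NAD over the corpus (switchable to NRMSD), seeded and fully
deterministic. Initialization is uniform $k = 1/P$ followed by a
deterministic global rescale over a log grid, which exploits the
$\alpha \to s\alpha$, $\theta \to s^2\theta$ homogeneity. At zero
temperature the chain is greedy and the accepted objective is
non-increasing — a tested invariant, as is non-negativity along the
chain.

## Synthetic data: what it covers and what it does not

All tests run without downloads. `make_helix()` / `make_strand()`
build poly-alanine chains from ideal internal coordinates (helix
$\varphi,\psi = -57.8°, -47°$: 1.5 Å rise, 3.8 Å CA–CA; strand
$-120°, +120°$), with an antiparallel partner placed by a calibrated
rigid offset that puts interior residues at sheet hydrogen-bond
geometry. `make_lorentzian_library()` generates complex curves
$\alpha(\nu) = A/(\nu_0^2-\nu^2-i g \nu)$, $\nu = 1/\lambda$ — the
damped-oscillator form whose real/imaginary parts are Kramers–Kronig
consistent analytically, which is what makes it the right ground
truth for transform tests. Defaults (the package's study conditions,
fixed once): 3 types, centers 205/215/225 nm, widths 8–10 nm — bands
kept inside 188–244 nm so the band-limited transform bias stays small
— and peak amplitudes giving helix-sized fixtures molar ellipticities
of order $10^4$ deg·cm²·dmol⁻¹. Spectral noise is additive Gaussian
on $\theta$ with sd = `noise_sd` × peak amplitude, roughly how
synchrotron-radiation CD noise behaves locally; no baseline-drift
model.

The recovery corpus (`make_synthetic_corpus()`) is five poly-alanine
helices of 8–16 residues typed by element (C/N/O), with noise-free
spectra from the known 3-type library. On this corpus the
simulated-annealing fit reaches mean NAD ≈ 0.02 within 4000–6000
iterations (seconds of CPU). The corpus is deliberately homogeneous:
with one shared curve set serving structurally diverse proteins, the
mean-field model is not generally identifiable from a handful of
spectra — distinct type curves can trade off against each other while
leaving every forward spectrum unchanged — so recovery on mixed
helix/strand corpora is *not* claimed. Passing tests demonstrate the
machinery (transform, extraction, optimization, determinism), not that
a real 100+-protein training run is reproduced; real spectra add
instrument noise, baseline error, conformational averaging and
non-ideal geometry that these fixtures do not emulate.

## Numerical choices and edge cases

* Wavelength grid: 188–244 nm at 1 nm (the granularity of displayed
  synchrotron CD spectra); spectra on other grids are interpolated
  onto the overlap, never extrapolated.
* Problem sizes in the shipped tests: fixtures of 4–20 residues
  (20–100 atoms), corpora of 2–5 proteins, chains of 400–6000 Monte
  Carlo iterations — sizes at which every oracle (naive double loop,
  analytic Lorentzian, hand-evaluated formulas) is exact and fast.
* Pair kernel: coincident atoms raise a singular-geometry error;
  the $i = j$ diagonal is excluded by definition.
* Fewer than two atoms: zero spectrum with a warning.
* Chains shorter than three usable residues: all coil, with a warning.
* Ties and fallbacks (altloc, dipole neighbors, unmatched atom types)
  are deterministic and logged, so repeated runs are bit-identical.
* Floating-point outputs are written at fixed precision
  (wavelength %.1f, ellipticity %.6e) for stable diffs.

## Known limitations

Hydrogen-free crystal structures contribute no H oscillators (no
reconstruction); the dipole-direction convention is a declared
stand-in; exact STRIDE compatibility requires ingesting STRIDE output;
the shipped 21-type table is a documented reconstruction, not the
authors' trained selection; and the synthetic library's absolute scale
is arbitrary — only NAD-style normalized comparisons are meaningful
across libraries.
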