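---
title: "Ensemble modeling of flexible proteins against SAXS data"
author: "saxsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble modeling of flexible proteins against SAXS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A protein with flexible linkers or disordered tails does not adopt a single
conformation in solution, so a single predicted or crystallographic model —
however accurate for the folded parts — can disagree badly with solution
scattering data. Small-angle X-ray scattering (SAXS) measures the time and
ensemble average over all conformations present, which makes it the natural
experiment to test conformational hypotheses against, but it cannot by
itself resolve individual structures.

`saxsens` bridges the two: starting from one atomic model whose flexible
segments are known (or detectable from per-residue confidence values such
as AlphaFold's pLDDT), it generates a large pool of stereochemically valid
conformers by Monte Carlo torsion sampling, computes each conformer's
scattering observables, and selects a small weighted ensemble whose summed
profiles best match the experimental data under a non-negativity
constraint. The result is a set of representative models with percent
contributions — either genuinely populated conformers or a proxy for a
continuum of transient states; the method cannot distinguish the two, and
the search is not exhaustive.

## Observables

**Pair-distance distribution.** For atoms with electron counts $Z_i$ at
distance $r_{ij}$, every unordered pair contributes weight $Z_i Z_j$ to the
bin containing $r_{ij}$. Bins are uniform, left-closed/right-open
$[k\Delta r, (k+1)\Delta r)$ with $\Delta r = 1$ Å by default, starting at
$r = 0$; curves are reported at left bin edges and moments are evaluated at
bin centers. The histogram is rescaled so its area equals the structure's
molecular mass in Da, which puts curves from different structures on a
common, physically meaningful scale. Self-terms are excluded. The
electron-product weighting approximates the X-ray contrast of a dry
structure; `weighting = "uniform"` is available for testing.

**Scattering intensity.** The Debye equation gives the exact orientational
average for a rigid atom set,
$$I(q) = \sum_i \sum_j f_i(q)\, f_j(q)\, \frac{\sin(q r_{ij})}{q r_{ij}},$$
with $\sin(x)/x \to 1$ as $x \to 0$. The default `point` mode uses
$f_i = Z_i$ (q-independent point scatterers); `cromer_mann` mode uses
4-Gaussian form factors. This is a **vacuum** calculation: no excluded
volume, no hydration shell. Absolute intensities are therefore not
comparable to solvent-corrected calculators, but the fitting stages only
ever use intensities up to a fitted scale (or fitted weights), where the
vacuum approximation is a reasonable stand-in. External calculators can be
plugged into the pipeline as `function(structure, qGrid)` and their output
flows through the same interpolation and scaling contract.

**Radius of gyration** is computed three ways and cross-checked in the
test suite: from coordinates ($R_g^2 = \sum w_i |x_i - \bar x|^2 / \sum
w_i$, electron-weighted by default), from the P(r) second moment
($R_g^2 = \int r^2 P\, dr / 2\int P\, dr$, at bin centers), and from the
Guinier slope of the Debye curve at $qR_g < 0.5$. On rigid structures the
three agree within 0.5 Å (binning) and 2 % (Guinier curvature)
respectively.

**Fit quality.** A calculated curve is scaled to the experimental one by
the SD-weighted least-squares factor
$c = \sum(I_e I_c/\sigma^2) / \sum(I_c^2/\sigma^2)$, and reported with
$n\chi^2 = \frac{1}{N-1}\sum\left((I_e - cI_c)/\sigma\right)^2$ (one
fitted parameter) and the unweighted RMSD. When the experimental curve has
no SDs, $\sigma \equiv 1$. Ensemble fits report
$n\chi^2$ with an $N - m$ denominator, $m$ being the number of
positive-weight models, since the weights themselves absorb the scale.

## Conformer generation

Flexible regions are maximal runs of at least `minRun = 5` consecutive
residues with confidence strictly below the threshold (default 60; a
residue exactly at the threshold is rigid — "below" is read strictly).
Runs touching the termini count: a disordered tail is a region. Manual
ranges pass through the same validation.

Each Monte Carlo trial draws one flexible residue, one of $\varphi/\psi$,
and a rotation uniform in $[-30°, +30°]$ (the `maxAngle` default). The
rotation is applied to the full rigid subtree on the C-terminal side of
the bond: for $\varphi$, everything past C$\alpha$ including the side
chain; for $\psi$, the carbonyl O plus all later residues. Rotating whole
subtrees is what makes the sampler exactly bond-geometry-preserving: bond
lengths and 1–3 distances are conserved to machine precision across the
entire pool, a property the tests assert at 1e-8 Å.

A trial is accepted iff it is clash-free: no pair of selected atoms
(default basis: heavy atoms) in different residues and at least 3 covalent
bonds apart sits closer than $0.8 (r_i^{vdW} + r_j^{vdW})$, strictly. The
scaled-van-der-Waals cutoff is the common hard-sphere convention; the
basis can be restricted to backbone atoms or extended to hydrogens when
present. Acceptance is purely steric — no force field. The `temperature`
parameter (default 300 K) is accepted for interface parity and is inert
unless a user-supplied torsion-energy callback is configured, in which
case a Metropolis test at that temperature applies; in this pipeline the
selection pressure comes from the SAXS fit, not from sampler energetics.

Rejected trials keep walking from the rejected coordinates; after
`returnAfterFails = 20` consecutive rejections the working coordinates
reset to the last accepted frame. This reading makes the reset counter
meaningful (a chain that reverted on every rejection would never need
one). Accepted frames are superposed on the starting structure over a
rigid alignment range (validated to not intersect any flexible region)
and stored under their 1-based trial index, so every downstream report
can be traced back to the original run. Identical seeds give
bit-identical pools.

A torsion drawn at a position where it is undefined (the first residue's
$\varphi$, the last residue's $\psi$) counts as a rejected trial; this
can only occur when a flexible region touches a terminus.

## Pool reduction and augmentation

Computing profiles for tens of thousands of frames is wasteful, so the
accepted pool is strided: positions `offset+1, offset+1+stride, ...`,
keeping `floor((N-offset-1)/stride)+1` frames. Representativeness is
judged by overlaying unit-mass Rg histograms of the full and reduced
pools; the total-variation distance is reported as an advisory metric
with no hard threshold — the choice of stride and offset stays with the
user. After preselection, the `k` frames flanking each preselected frame
(in the original accepted-pool ordering) can be added back,
`k ≤ floor(stride/2)`, to recover neighbours the stride skipped.

## Ensemble selection

Given per-model profiles as columns of $A$ and the experimental curve
$b$, the weights solve
$$\min_w \|W(Aw - b)\|_2 \quad \text{s.t. } w \ge 0,$$
with $W = \mathrm{diag}(1/\sigma)$ when SD weighting is requested and SDs
exist. The solver is the Lawson–Hanson active-set algorithm, which
terminates at the exact KKT point: the weighted residual is orthogonal to
every positive-weight column, and the dual is non-positive on every
zero-weight column. The implementation normalizes columns to unit 2-norm
internally (the problem is scale-equivariant) — without this, active-set
iterations on near-duplicate columns such as adjacent trajectory frames
can stall. Ties between duplicate columns resolve to the lowest column
index, deterministically. Columns enter unscaled (beyond the internal
normalization, which is undone on exit): per-column pre-scaling to the
experimental curve would make the weights non-identifiable.

Only strictly positive weights are reported, as percents totalling 100.
P(r) fits run unweighted by default and additionally SD-weighted when the
experimental P(r) carries SDs; both selections contribute to the
preselected set. The ensemble radius of gyration is
$R_g = \sqrt{\sum (p_i/100) R_{g,i}^2}$, and reconstructed curves carry
pointwise propagated SDs $\sqrt{\sum (w_i \sigma_i)^2}$ when per-model
SDs exist.

## The synthetic data generator

`buildToyChain()` constructs a poly-alanine chain (N, C$\alpha$, C, O,
C$\beta$ per residue) with ideal geometry (N–C$\alpha$ 1.458 Å,
C$\alpha$–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å, C$\alpha$–C$\beta$
1.521 Å, trans peptide) in an extended $\varphi/\psi = -139°/135°$
conformation, emulating a two-domain protein joined by a flexible linker:
domain residues carry confidence 90, linker residues 40, mirroring the
high/low pLDDT contrast of predicted structures. The chain is glycine-free
(every non-terminal residue has both torsions), clash-free under the
default basis, and its bond lengths match the constants to 1e-6 Å.

`makeSyntheticExperiment()` mixes the Debye I(q) and mass-normalized P(r)
of chosen conformers with known weights and applies multiplicative
Gaussian noise, $I_{exp} = \sum w_i I_i \cdot (1+\epsilon)$,
$\epsilon \sim N(0, \text{noise}^2)$; the SD columns equal the applied
noise scale, so SD-weighted fitting is exercised against an honest error
model. With zero noise the generating weights are exactly recoverable,
which is the self-consistency backbone of the test suite.

What the generator does **not** emulate: real side chains and their
packing, hydration-shell contrast, inter-point noise correlation from
detector binning, q-dependent error growth, and imperfect background
subtraction. Passing tests therefore demonstrate the correctness of the
machinery — geometry, profiles, reduction, selection — not that any real
protein's ensemble would be recovered this cleanly.

**Well-separated conformers.** Mixture recovery under noise is limited by
profile collinearity, not by Rg differences: two conformers 10 Å apart in
Rg can still have I(q) columns correlated at 0.999, in which case a 1 %
noise level moves tens of percent between them. This is intrinsic to
SAXS (it is why ensemble methods report representative, not unique,
models). The generator therefore operationalizes "well separated" with
`pickSeparatedModels()`: greedy farthest-point sampling on unit-normalized
profiles, applied to a pool large enough to be diverse (2000 trials in
the shipped tests). Under those conditions 1 %-noise mixtures of five
conformers are recovered within a few percentage points.

## Numerical choices and problem sizes

* P(r) bins: left edges reported, centers used for moments; area
  normalization exact to 1e-6 relative.
* Interpolation onto the experimental grid is piecewise linear and
  refuses extrapolation. The internal Debye calculator evaluates directly
  on the experimental grid (interpolation is an identity there); external
  calculators are computed on their own grid and interpolated.
* Covalent topology for the clash exclusions is inferred once from the
  starting coordinates (heavy–heavy < 1.9 Å, X–H < 1.3 Å, same or
  adjacent residues) — valid because torsion moves never change bonded
  geometry.
* Superposition uses the SVD (Kabsch) route with a reflection guard; the
  tests cross-check against an independent quaternion closed form.
* Degenerate NNLS inputs (duplicate columns) resolve by ascending column
  order; all-zero columns never enter.
* Test/acceptance problem sizes: 50-residue chains (250 atoms),
  2000-trial Monte Carlo runs, stride 10, 150–201-point q grids. These
  run the full pipeline in well under a minute while leaving every
  contract (geometry conservation, KKT certificates, exact noiseless
  recovery) checkable at tight tolerances.

## Known limitations

* Single chain, no prosthetic groups, no glycans; no repair of broken
  input models.
* Vacuum Debye intensities: no hydration shell or excluded-volume term —
  adequate for weight fitting, not for absolute-scale comparison with
  solvent-aware calculators, which can be plugged in instead.
* Hard-sphere acceptance only; no Ramachandran prior beyond what clash
  rejection induces, no side-chain sampling, no crankshaft or concerted
  moves.
* The ensemble is representative, not unique or exhaustive: different
  pools, calculators or weighting choices select different model subsets
  of similar fit quality, and near-collinear conformers can trade weight
  under noise.
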