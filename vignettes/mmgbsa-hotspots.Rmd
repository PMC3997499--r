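---
title: "Per-residue MM-GB/SA decomposition and interface hot spots"
author: "HotspotGBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-residue MM-GB/SA decomposition and interface hot spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HotspotGBSA)
```

## The model

HotspotGBSA implements an end-point ("single trajectory") MM-GB/SA
analysis of a protein--protein dimer.  For a complex AB evaluated on a
conformational ensemble, the effective binding energy of one frame is

$$\Delta G_\mathrm{eff} \;=\; E_\mathrm{elec}^\mathrm{inter}
 + E_\mathrm{vdW}^\mathrm{inter}
 + \big[G_\mathrm{GB}(AB) - G_\mathrm{GB}(A) - G_\mathrm{GB}(B)\big]
 + \gamma \big[\mathrm{SASA}(AB) - \mathrm{SASA}(A) - \mathrm{SASA}(B)\big],$$

where both monomers are evaluated on the unchanged complex coordinates
of the same frame.  Because the monomer geometries are identical to
their geometry in the complex, all intramolecular bonded and nonbonded
terms cancel exactly and are never computed; what remains are the
inter-partner Coulomb and Lennard-Jones sums (no cutoff, solute
dielectric 1, Lorentz--Berthelot combination) and the change in
solvation free energy.  Configurational entropy is deliberately not
part of the effective energy.

The polar solvation term is a generalized Born model of the OBC-II
family: effective Born radii come from the pairwise-descreening (HCT)
integral over reduced intrinsic radii $\tilde\rho_i = \rho_i - 0.09$ Å,
rescaled through
$R_i^{-1} = \tilde\rho_i^{-1} - \tanh(\alpha\Psi - \beta\Psi^2 +
\gamma\Psi^3)/\rho_i$ with $(\alpha,\beta,\gamma) = (1.0,\,0.8,\,4.85)$,
and the energy is the canonical interpolation
$f_\mathrm{GB} = \sqrt{r^2 + R_iR_j\exp(-r^2/4R_iR_j)}$ with a
Debye--Hückel factor $\exp(-\kappa f_\mathrm{GB})$ inside the
dielectric term.  At 298 K, $\kappa = \sqrt{0.10806\, I}$ per Å with
the ionic strength $I$ in mol/L; the default is 0.1 M.  Some codes
scale $\kappa$ by 0.73 to mimic finite ion size; the unscaled form is
used here and `gbOptions(kappa_scale=)` makes the choice explicit.
Intrinsic radii follow the mbondi2 convention (element radii, with
1.3 Å for hydrogens bonded to nitrogen).

The nonpolar term is $\gamma\cdot\mathrm{SASA}$ with
$\gamma = 0.0072$ kcal/mol/Å$^2$.  Areas are Shrake--Rupley with a
1.4 Å probe over the intrinsic GB radii, hydrogens included.

## Per-residue decomposition

`decomposeResidues()` attributes every term of
$\Delta G_\mathrm{eff}$ to residues: inter-partner pair energies are
split half/half between the two residues they touch (the GB cross
terms likewise), GB self terms belong to their own atom, and the
solvation contributions are complex-minus-monomer differences on
identical coordinates.  Summing the residue rows of any frame
reproduces that frame's total exactly; the test suite asserts this to
$10^{-6}$ kcal/mol and the observed error is at rounding level.
Ensemble statistics are the arithmetic frame mean and the standard
error of the mean ($s/\sqrt{n}$; undefined and reported `NA` for a
single frame).

Classification is rule-based and row-local.  A residue is **hot** when
its mean contribution is strictly below $-2$ kcal/mol.  It is **cold**
when it lies in the interface but contributes only marginally:
operationally, mean relative burial $\ge 0.05$ and
$|\Delta G| \le 1$ kcal/mol.  Both cutoffs are exposed in
`spotThresholds()`; the interface rule needs a number where practice
is usually qualitative, and 0.05 relative burial is a deliberately
permissive membership test.  The burial baseline itself,
$\mathrm{rb} = (\mathrm{SASA}_\mathrm{mono} -
\mathrm{SASA}_\mathrm{cplx})/\mathrm{SASA}_\mathrm{mono}$, is also a
(deliberately crude) predictor: ranking by burial marks essentially
every interface residue, which is exactly why the energy-based
decomposition is the primary tool.

`alanineScan()` truncates a side chain beyond C$\beta$ on the fixed
ensemble coordinates (no re-minimization), re-protonates and
re-parameterizes the mutant, and recomputes the full effective energy;
$\Delta\Delta G = \Delta G_\mathrm{eff}(\mathrm{mut}) -
\Delta G_\mathrm{eff}(\mathrm{wt})$, so destabilizing mutations are
positive.  No incremental shortcut is taken -- each mutant is a
complete evaluation -- which keeps the scan directly comparable to a
two-evaluation oracle.  Glycine (no C$\beta$) and proline (backbone
ring) are excluded, the standard scanning convention.

## Parameterization choices

Per-atom charges and Lennard-Jones parameters are a bundled
transcription of a fixed-charge all-atom protein force field of the
Amber ff99SB family; each residue template's charges sum exactly to
its formal charge.  Protonation states are fixed defaults appropriate
near pH 7.5: histidine neutral (N$\varepsilon$ tautomer),
aspartate/glutamate deprotonated, lysine/arginine protonated,
cysteine reduced.  Chain termini are zwitterionic and are implemented
as charge patches on the standard templates (the ammonium hydrogens
carry the amide-hydrogen charge, the carboxylate oxygens $-0.8055$ e,
with the residual placed on N and C so the total stays at the exact
sum of formal charges).  Hydrogens are built at ideal geometry from
local rules (tetrahedral/trigonal completion, staggered rotors,
anti-periplanar hydroxyls); existing hydrogens are never moved.

## Numerical design

Three properties are made *exact* rather than approximate:

* **Rigid-motion invariance.**  All analytic terms are invariant by
  construction; sphere-sampled SASA is not, so the quadrature point
  set is oriented in the canonical principal-axis frame of the
  complex.  The set itself (a low-discrepancy quarter-sphere seed
  orbited by 180° flips about the frame axes) is invariant under the
  frame's sign ambiguities, so rotating or translating the input
  changes no energy term beyond floating-point noise.
* **C2 symmetry.**  For a dimer built as an exact two-fold image, the
  symmetry operation is one of the flips under which the point set is
  invariant; per-chain profiles therefore agree to ~1e-13 rather than
  to quadrature tolerance.
* **Non-interacting limit.**  Monomer SASA reuses the complex's
  frame, so complex-minus-monomer areas cancel identically when the
  partners are far apart, and $\Delta G_\mathrm{eff} \to 0$.

Other numerical choices: 960 sphere points by default (rounded up to
a multiple of 4; the isolated-atom area is then exact to ~0.5%, and a
five-atom cluster agrees with a 10,000-point evaluation to better
than 0.5 Å$^2$ per atom), distances in Å, energies in kcal/mol,
charges in elementary units, Coulomb constant 332.0637 kcal Å/mol/e².
Born radii are strictly positive because the tanh rescaling is
bounded; salt screening lowers the polar solvation energy of charged
solutes monotonically, which is asserted as a property test.

## What the synthetic data emulate -- and what they do not

The generators exist so that every pipeline stage has a desk-scale,
fully characterized input:

* `buildIdealHelix()` / `buildHelixDimer()` produce ideal α-helices
  (φ = −57°, ψ = −47°; one template rotamer per side chain, chi-1
  clash relief on a 10° grid) and two-helix dimers, optionally as
  exact C2 images.
* `buildStickyDimer()` engineers one deliberately dominant interface
  residue.  A design note: an isolated, solvent-exposed ion pair is
  *not* a usable "sticky" construct under GB -- the desolvation
  penalty compensates the Coulomb attraction almost exactly (we
  measured net contributions between −0.6 and +1 kcal/mol across
  feasible Arg--Glu geometries).  This mirrors the well-known
  observation that interface hot spots are predominantly bulky
  residues combining hydrophobic contact with directional polar
  interactions.  The default preset therefore uses a tryptophan whose
  indole N--H hydrogen-bonds a charged glutamate carboxylate while
  the ring packs into a leucine groove; its mean contribution is
  about −3 kcal/mol, comfortably past the −2 hot threshold, and it is
  recovered rank-1.  `core_a = "R"` builds the literal ion-pair
  variant, which still dominates the inter-partner electrostatic pair
  ledger and is used to test exactly that.
* `jitterEnsemble()` applies i.i.d. Gaussian coordinate noise with a
  fixed seed (frame 1 is the input).  This is *not* dynamics: it has
  no Boltzmann weighting, no correlated motions, no side-chain
  rearrangement.  It validates estimators -- means, SEMs,
  conservation, symmetry -- not conformational physics.  Passing
  tests on jittered ensembles therefore demonstrate correctness of
  the energy function and bookkeeping, and say nothing about whether
  a short ensemble reproduces hot-spot sets observed on long MD of
  real domains.
* `synthMeltingCurve()` and `synthSecStandards()` generate Boltzmann
  sigmoids (optional post-peak aggregation decay) and log-linear SEC
  standards; defaults mirror a 25--95 °C ramp at 0.5 °C steps and the
  classic lysozyme-to-apoferritin standard set.

Problem sizes used throughout the tests and the acceptance script --
helices of 8--30 residues per chain, ensembles of 3--20 frames, 100
noisy melting curves -- were chosen as the smallest systems on which
the asserted properties are non-trivial.

## Assay-side analytics

`tmFromDerivative()` smooths the fluorescence with a centered moving
average (default 5 points), takes centered finite differences,
requires the positive-slope peak to exceed 3× the median absolute
derivative (otherwise "no transition detected"), and refines the peak
with a local quadratic fit over ±4 points; on noise-free sigmoids the
midpoint is recovered exactly, and at 2% amplitude noise the bias and
RMSE over 100 seeded curves are about 0.04 °C and 0.3 °C.
`tmSigmoidFit()` fits the four-parameter Boltzmann model over the
pre-aggregation region (up to the smoothed maximum), initialized from
the derivative estimate.  `secCalibrate()`/`predictMw()` implement the
standards-based log-linear molecular-weight calibration.  Sequence
properties use average residue masses plus one water, and the
5500/1490/125 extinction rule with cystine pairs counted as
`floor(nCys/2)`.

`identitySimilarity()` uses a global pairwise alignment (BLOSUM62,
gap open 10, extend 0.5): identity counts identical aligned columns
over gap-free columns, similarity additionally counts positive
substitution scores.  A progressive multiple aligner would give
slightly different percentages; pairwise alignment was chosen for
determinism and self-containment, and comparisons against published
multiple-alignment percentages should be read with a few points of
slack.  The bundled Hsp90 C-terminal-domain fragments (human
P07900 561--697, yeast P02829 540--677, E. coli P0A6Z3 510--624) are
offline transcriptions; the yeast and E. coli entries are approximate,
which shifts percentages computed from them by several points, while
the human fragment is anchored at all residues with documented roles
(H640, I642, S658, T669, L672, P681, Q682, I688, Y689, I692, L696).

## A worked example

```{r example, eval = FALSE}
d <- buildStickyDimer()
ens <- buildHydrogens(d$ensemble)
sys <- assignParameters(ens, part = d$partition)
ensm <- jitterEnsemble(ens, sigma = 0.15, n_frames = 5, seed = 42)
sysm <- new("ParameterizedSystem", ensemble = ensm,
            params = atomParams(sys), partition = d$partition)

rt <- decomposeResidues(sysm)
report <- classifySpots(rt, spotThresholds(), relativeBurial(sysm))
report
exportReport(report, "hotspots.tsv")

alanineScan(sysm, data.frame(chain = "B", resno = 10), frames = 1L)
```

## Known limitations

* Fixed protonation; no pKa prediction, no tautomer search.
* Single-trajectory end point only: no separate monomer ensembles, no
  explicit solvent, no Poisson--Boltzmann cross-check, no entropy.
* The hydrogen builder places ideal geometry; it does not optimize
  hydrogen-bond networks.
* Jittered pseudo-ensembles are statistical stand-ins, not
  conformational sampling (see above).
* PDB is the only structure format (multi-MODEL files as ensembles);
  no mmCIF or binary trajectories.
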