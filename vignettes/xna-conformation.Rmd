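---
title: "Conformational analysis of DNA and xeno-nucleic-acid duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational analysis of DNA and xeno-nucleic-acid duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xnageom)
library(dplyr)
```

## What this package measures, and why

Engineered polymerases can copy DNA templates into synthetic genetic
polymers (xeno-nucleic acids, XNAs) whose sugar-phosphate backbones differ
from DNA's. Two such polymers drive the design of this package: TNA
(alpha-L-threose nucleic acid, threofuranose sugars joined by 3'->2'
phosphodiester linkages, a five-atom backbone repeat) and its phosphonate
variant pTNA, in which a methylene is inserted between the 3' oxygen and
the phosphorus, restoring a six-atom repeat but abolishing stable duplex
formation with DNA in solution. Crystal structures of polymerase-bound
extension products let one ask precisely *how* these backbones differ from
DNA inside an active site. The quantities that answer it are conformational:

* **Sugar pucker.** A furanose ring's five endocyclic torsions
  $\nu_0,\dots,\nu_4$ follow, to good approximation, the pseudorotation
  series
  $$\nu_j = \nu_{max}\,\cos\!\big(P + 144^\circ (j-2)\big),$$
  so two numbers summarize the ring: the phase $P$ (which atom puckers out
  of plane; C3'-endo near 18 deg typifies A-form helices, C2'-endo near
  162 deg B-form) and the amplitude $\nu_{max}$ (how puckered). We invert
  the series with the atan2 form
  $P = \operatorname{atan2}\{(\nu_4+\nu_1)-(\nu_3+\nu_0),\,
  2\nu_2(\sin 36^\circ + \sin 72^\circ)\}$, which stays well-conditioned
  where $\nu_2 \approx 0$ (P near 90/270 deg), and recover
  $\nu_{max} = |\nu_2 / \cos P|$ (from the numerator term instead when
  $\cos P$ is small).
* **Backbone torsions and chi.** Each chemistry declares its own named
  torsions over its repeat unit in the registry; forcing DNA's
  alpha--zeta alphabet onto a five- or six-atom repeat with different atom
  inventories would mislabel bonds. We keep the convention that *delta* is
  the sugar-coupled torsion (about C4'-C3' for DNA, about C3'-C2' for the
  threose chemistries) because that is the torsion whose covariance with
  the glycosidic angle chi separates A-form from B-form geometry. TNA's
  five-bond repeat therefore declares alpha, beta, delta, epsilon, zeta
  (no gamma-analog bond exists); pTNA's six-bond repeat restores a gamma.
* **P-P spacing.** The distance between consecutive bridging phosphorus
  atoms (phosphate or phosphonate) along a strand — the most direct
  geometric signature of repeat-unit length.
* **Base-pair geometry.** Heavy-atom donor-acceptor distances of the
  canonical Watson-Crick hydrogen bonds, and the six intra-pair
  (shear, stretch, stagger, buckle, propeller, opening) plus six step
  (shift, slide, rise, tilt, roll, twist) rigid-body parameters computed
  from fitted base reference frames.
* **Superposition.** Kabsch least-squares rigid fits: global C-alpha
  alignment with iterative outlier rejection for protein comparisons, and
  local all-heavy-atom fits on a named residue subset for active-site
  overlays.

## Chemistry registry

Residue codes map to chemistries through a registry
(`default_registry()`), which records, per chemistry, the ring atoms, the
ordered backbone path starting at the bridging phosphorus, the linkage
donor (O3' for DNA, O2' for the 3'->2' threose chemistries), the named
torsion definitions (with symbolic references that resolve across
chemistry junctions, so a DNA primer extended with pTNA measures its
junction torsions correctly), and the glycosidic quadruples
(O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines). Backbone
neighbors are established by covalent proximity (donor to phosphorus
under 2.0 A — refined P-O and C-C bonds are shorter than 1.9 A), not by
residue numbering, with a relaxed 1-3 fallback when a phosphorus itself is
unmodelled. The registry is user-extensible and serializable
(`write_registry()` / `read_registry()`): ligand codes for non-standard
nucleotides vary between depositions and must be read from the files being
analysed, so the shipped TNA/pTNA codes (`TA`..`PC`) are the generator's
own synthetic codes, not claims about any deposition.

## Base reference frames and pair/step parameters

Each observed base is least-squares fitted (Kabsch, ring atoms only) to an
embedded idealized planar geometry expressed in a standard base-fixed
frame; the fitted rigid transform *is* the base's frame. Intra-pair
parameters flip the second strand's frame 180 degrees about its x-axis and
then read the six descriptors off the relative transform; step parameters
do the same between consecutive pair mid-frames. The "middle" frame is
reached by rotating halfway along the relative rotation's geodesic
(half-rotation interpolation), and the rotational descriptors are the
relative rotation vector expressed in that mid-frame — positive twist is
right-handed. This construction is exactly invertible, which the duplex
generator exploits: building from a parameter vector and re-measuring
returns the input to ~1e-13, so round-trip tests check the full build +
detect + fit + decompose pipeline, not a shared code path (the builder
composes frames forward; the analyzer fits frames from coordinates and
decomposes). With both bases placed from the same embedded geometries, an
ideal pair yields heavy-atom H-bond distances of 2.87-3.05 A, inside the
canonical hydrogen-bonding range.

Watson-Crick pairs are detected by complementarity plus geometry: all
canonical heavy-atom H-bonds at most 3.5 A (configurable), no distance
below a 2.0 A clash floor, and roughly antiparallel base planes (frame
z-axes with negative dot product), which rejects stacked or parallel
arrangements that pass the distance screen. Distances alone match how
heavy-atom contacts are reported crystallographically; no angular term is
used.

## The synthetic-structure generator

Every test input is generated in code; nothing is downloaded.

**Rings at prescribed pucker.** `make_furanose()` embeds the five ring
atoms by constrained least squares: three internal angles and two chain
torsions are free, bond lengths are *restrained* to idealized
small-molecule values (C-C 1.525 A, C-O 1.420 A). The pseudorotation
series is not exactly closable on a fixed-length five-ring — at
$\nu_{max} = 45$ deg the best fixed-length ring misses some torsion
targets by up to ~0.75 deg — so the lengths are allowed to flex by up to
a few hundredths of an Angstrom (observed at most 0.04 A over the full
wheel), bringing the worst achieved-vs-target torsion error to ~0.26 deg.
The achieved torsions are attached to the output as the test oracle, and
an embedding that misses its targets by more than 0.5 deg raises an error
rather than returning an approximation.

**Duplexes at prescribed parameters.** `make_duplex()` propagates pair
mid-frames by the step parameters (inverting the analyzer's construction
exactly), splits each mid-frame into two base frames by the intra-pair
parameters, attaches sugars at the requested pucker and chi by rigidly
gluing the embedded ring onto the base's glycosidic bond, adds the
chemistry's substituents with tetrahedral geometry (the threose 2'/3'
substituents trans, as in a threo-diol; the DNA arrangement
beta-D-2'-deoxyribose), and finally places each bridging phosphorus to
satisfy both linkage bonds simultaneously (for pTNA, the phosphonate P
and its methylene are solved together as a two-atom bridge; like a
terminal phosphate, they belong to the linkage and are absent from
unlinked termini). Strand 2 runs antiparallel by construction.

Defaults are the package's standard study conditions, chosen once:
idealized B-form steps (twist 36 deg, rise 3.4 A, all else zero), ideal
pair geometry (all six intra-pair parameters zero), C2'-endo DNA sugars
(P = 162, nu_max = 38) with anti chi = -105 deg, and north-region threose
sugars (P = 20, nu_max = 35, chi = -120 deg) reflecting the C3'-endo to
C4'-exo range reported for polymerase-bound threose nucleotides.

**What the generator does and does not emulate.** It reproduces the
*statistical structure the analysis assumes*: correct connectivity across
chemistry junctions, exact target torsions/parameters, Gaussian coordinate
noise (`perturb()`, seed-reproducible), and a random-walk C-alpha cloud at
the canonical 3.8 A spacing for superposition tests. It does not emulate
crystallographic reality: no energy minimization or sterics beyond
bond-length sanity, no solvent, ions or B-factor-weighted noise, no
sequence-dependent helical variation, and backbone torsions that follow
from rigid substituent placement rather than relaxed conformers. Passing
tests therefore demonstrate that the *measurements* are correct and
internally consistent, not that the generator's geometry matches any
particular crystal structure; measurements on real data inherit whatever
coordinate error the refinement left in the model.

## Numerical choices and degenerate inputs

* Angles live in (-180, 180]; phases in [0, 360); angular comparisons use
  the shortest signed difference (the reported "delta drop" between
  consecutive residues is such a difference).
* Dihedrals with coincident or collinear points are errors, not NaNs.
* Rings flatter than nu_max = 5 deg are flagged degenerate; the phase is
  then reported as undefined and classification is refused — below
  crystallographic coordinate error, conformer labels are noise.
* Conformer labels use the 20-state wheel (18-degree bins, envelopes
  centered at 18 + 36k deg, twists between them); a coarser
  `envelope` column gives the nearest pure envelope state, the loose
  family label common in prose. Quadrants: north [315, 45), east, south,
  west. Half-open bins; the A/B-form delta boundary at 110 deg belongs to
  the B region.
* A/B-form chi/delta boxes default to conventional fiber-diffraction-style
  rectangles (A: delta 55-110, chi -190 to -138 mod 360; B: delta 110-175,
  chi -140 to -70) and are configuration, since qualitative A/B statements
  in the literature rarely print boundaries.
* Kabsch excludes reflections by determinant correction; mirror-image
  sets keep a positive-determinant rotation and a nonzero RMSD.
* Outlier rejection (default 5 rounds, threshold 2.0 x current RMSD,
  both configurable) stops at an RMSD floor of 1e-6 A: once the retained
  set fits essentially perfectly, a proportional threshold would reject
  atoms on floating-point jitter. Published protein RMSDs rarely state
  their rejection settings, so comparisons against them should quote
  both the with-rejection and no-rejection values (`max_rounds = 0`
  reduces exactly to the plain fit).
* Altloc resolution keeps the highest-occupancy conformer, ties broken by
  label (A first), matching common practice when a single conformation is
  analysed; the discarded alternates are listed in a report, and residue
  counts are conserved.

## Problem sizes

The shipped tests and the acceptance script use deliberately small
problems — duplexes of 1-10 base pairs, 100-residue C-alpha clouds,
100-ring pucker grids, 50 step-parameter round trips, 100 outlier-recovery
trials — sizes at which every oracle is exact and the whole suite runs in
well under a minute on one core. All scale linearly in atoms except pair
detection, which is quadratic in strand length and still instantaneous at
duplex scales of interest.

## Limitations

* Pair detection covers canonical Watson-Crick pairs only; wobble and
  Hoogsteen taxonomies are out of scope, as are stacking energetics,
  helical-axis curvature and groove geometry.
* Pseudorotation uses the Altona-Sundaralingam parameterization
  exclusively (no Cremer-Pople coordinates, no six-membered rings), and
  nu_max is reported as an absolute value.
* The mmCIF writer emits a minimal canonical `atom_site` loop (author
  numbering mirrored into the label fields); it is meant for round-trips
  and overlays, not for redepositing models.
* Analysing deposited structures with non-standard nucleotide codes
  requires adding those codes to the registry first; the package
  deliberately refuses to guess chemistry from an unknown code in strict
  mode.
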