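---
title: "Methods: membrane-bound helical peptide and bilayer observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-bound helical peptide and bilayer observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memhelix)
```

## Scope and model system

`memhelix` analyses ensembles of an amphipathic helical peptide bound to a
lipid bilayer. The built-in defaults describe the islet amyloid
polypeptide (IAPP) 1–25 fragment — sequence `KCNTATCATQRLANFLVHSSNNFGA`,
with the S20G variant substituting glycine at position 20 — in a mixed
DOPC/DOPS membrane (88:40, the ~7:3 neutral-to-anionic ratio of β-cell
membranes). The fragment's disulfide loop (Cys2–Cys7) keeps residues 1–4
disordered; the membrane-binding helix spans residues 5–25 with a
characteristic hinge at His18. All internal coordinates are Angstrom;
file formats that use nm (GRO) are converted at the I/O boundary only.

Because production MD trajectories of such systems are rarely portable,
the package pairs every analysis with a seeded generator that constructs
inputs with known ground truth. Analyses are validated by closing the
loop: build a structure with a stated property, measure it back.

## Secondary structure and helicity

Secondary structure uses the classic electrostatic hydrogen-bond model:
for donor N–H of residue *i* and acceptor C=O of residue *j*
(`|i − j| ≥ 2`),

$$E = 27.888\left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}}\right)\ \mathrm{kcal/mol},$$

with a bond when `E < −0.5` kcal/mol. Amide hydrogens absent from
united-atom structures are rebuilt 1.0 Å from N along the direction
opposing the bisector of (C′ᵢ₋₁→N) and (Cα→N). Two consecutive n-turns
(n = 3, 4, 5) make a minimal helix (codes G, H, I, assigned in priority
H > G > I); simple bridge patterns give E; turn neighbourhoods give T;
everything else is C. Bends (S) and full ladder bookkeeping are out of
scope — only the helix/strand/coil distinction that helicity consumes is
promised, and the assignment is tested for exact agreement with an
independent brute-force reimplementation on noisy helices.

Helicity of a residue is the fraction of frames carrying a helical code.
The helical set defaults to {H, G, I} — the three classes a DSSP-style
assignment plots as helix — and is configurable; chain termini are never
helical.

## The kink angle and conformational families

The hinge statistic is the angle between two Cα chord vectors, Cα13→Cα17
and Cα19→Cα23 (one helical turn before and after His18), reported per
frame in [0°, 180°], histogrammed in 10° bins (midpoints 5°, 15°, …), and
classified into *compact* (< 60°) and *L-shaped* (≥ 60°) families. The
60° boundary is the midpoint between the 40° and 90° populations the
mutant exhibits and is a reported, configurable parameter.

A geometric point that matters for interpretation: an *unkinked* ideal
α-helix does not give 0°. Each i→i+4 Cα chord is tilted ~15° off the
helix axis (chord rise ~6 Å, perpendicular offset `2R·sin(200°)` with
R ≈ 2.3 Å), and the two chords sit 240° apart in helical phase, so a
straight helix subtends

```{r}
as.numeric(interhelical_angle(build_ideal_helix()))
```

degrees. The wild type's ~20° population is therefore what an essentially
straight helix with thermal noise looks like in this statistic. For the
same reason the kink generator does **not** bend about an axis
perpendicular to the pre-hinge helix axis (which could never produce
target angles below the ~24° baseline); it rotates the post-hinge rigid
body about the normal of the plane spanned by the two chord vectors,
through the hinge Cα. That moves the second chord within the plane and
controls the subtended angle exactly, for any target in (0°, 180°); the
achieved angle is verified to 0.1°. A target of 0 (or `NULL`) is treated
as "no kink" and returns the helix unchanged.

## Immersion depth

For a residue, `D_im` is the z-distance from the mean phosphorus z of the
interfacial leaflet to the geometric centre (unweighted, no mass
weighting) of its side-chain heavy atoms (Cα for glycine), signed so that
positive means toward the bilayer core. The sign is pinned by the
embedding convention: a helix centre placed 7 Å below the upper-leaflet
phosphate plane reads back `D_im = +7`. Frames should first pass through
`recenter_membrane()`, which makes molecules whole across the z boundary
and centres the mean phosphorus z at `box_z/2`; leaflets are then split
at the midrange of the phosphorus z values (robust to unequal leaflet
populations after lipids are deleted around an embedded peptide, where a
median would collapse onto the fuller plane).

## Hydrogen bonds and contacts

A hydrogen bond requires donor–acceptor distance < 3.5 Å **and** an
H–D–A angle < 30° with the vertex at the donor. Both thresholds are
strict inequalities, distances are minimum-image, and the vertex-at-donor
convention is stated explicitly because several analysis codes place the
vertex at the hydrogen instead. Which atoms can donate or accept is a
plain-text chemistry table shipped under `inst/extdata/` (N/O donors with
their hydrogen names, N/O acceptors, thiol S) that users can replace.
Occupancy of a pair specification (e.g. Leu16 main chain against Ser20
side chain) counts frames with at least one qualifying triple in either
direction; both pair-level occupancy and per-block time series are
reported, since a residue pair can form several simultaneous D/A
combinations.

Side-chain contacts use the same strict-`<` rule at 4.5 Å over side-chain
heavy atoms (Cα for Gly); head-group contacts count distinct lipids with
any head-group heavy atom within 4.5 Å of any peptide heavy atom. Block
averaging divides a frame series into `ceiling(n/n_blocks)`-sized
contiguous blocks (tail may be shorter); the size-weighted mean of block
means equals the global mean to machine precision.

## NMR observables

The ³J(HN–Hα) coupling uses the Vuister–Bax Karplus form

$$^3J(\varphi) = A\cos^2(\varphi - 60^\circ) + B\cos(\varphi - 60^\circ) + C$$

with A = 6.51, B = −1.76, C = 1.60 Hz. The −60° phase offset is exposed
as a parameter; with these coefficients the curve passes through 1.60 Hz
at φ = 150°, 6.35 Hz at φ = 60°, and its β-region maximum 9.87 Hz at
φ = −120°, and stays below 6 Hz across the canonical helical range
[−70°, −45°]. Ensemble profiles average the *per-frame* J (what NMR
measures under fast exchange), not J of the mean φ; the alternative is
available behind a flag. Spread is estimated as the SD across five
contiguous windows of the analysed range by default.

Secondary shifts are Δδ = δ − δ_rc per residue against a packaged
random-coil Hα table keyed by residue type (editable TSV); upfield
(negative) Hα shifts are flagged helix-consistent. Shift *prediction* is
out of scope — predicted or experimental tables are consumed as delimited
text — and profile agreement is quantified as the fraction of shared
residues within ±0.2 ppm.

## Bilayer observables

**Area per lipid** partitions each leaflet's xy plane into an
`n × n` grid (default 100; at least 8) and assigns every cell to the
xy-nearest minimum-image phosphorus of that leaflet, ties broken by
lowest lipid index; a lipid's area is its cell count times the cell area,
so per-leaflet areas sum to the box area *exactly*, every frame. With a
protein present, its heavy atoms within 5 Å (z) of the leaflet's
phosphorus range compete for cells, mirroring protein-aware grid
partitioning. Exact per-lipid equality on a perfect lattice requires a
grid commensurate with the lattice (the tests use 96 cells over an 8×8
lattice); incommensurate grids split boundary cells asymmetrically at the
±0.5-cell level.

**Thickness** is the per-cell z-difference between the nearest upper- and
lower-leaflet phosphorus (the P–P distance from top to bottom leaflet),
averaged over cells and frames.

**Order parameters** use the united-atom local frame: for interior carbon
*i*, the molecular z-axis is the unit C(i−1)→C(i+1) vector, y ⊥ z in the
three-carbon plane, x the plane normal; with θ against the bilayer normal
(box z, a slab-geometry assumption — no local-normal estimation for
curved membranes), `S_ab = ⟨(3cosθ_a cosθ_b − δ_ab)/2⟩` and the reported,
positive-for-ordered quantity is `S_cd = −(2/3)S_xx − (1/3)S_yy`. For
ideal tetrahedral geometry this equals the explicit average of
−(3cos²θ_CH−1)/2 over both reconstructed hydrogens (tested to 1e-6). The
generator's straight pseudo-chains make the three-carbon plane
degenerate; there the axially symmetric limit `S_cd = S_zz/2` applies,
giving the closed form `(3cos²τ − 1)/4` for chains tilted by τ: 0.5 when
aligned with the normal, 0 at the magic angle (54.74°), −0.25 at 90°.

**RDF** histograms minimum-image reference–target distances, normalised
by exact shell volumes and the whole-box target density (the documented
convention; "bulk" is ambiguous in slab systems, so the density in use is
reported). The coordination number integrates `ρ·g(r)·4πr²dr` with the
same shell volumes; at 3 Å around phosphates against water oxygens this
is the hydration number.

## Synthetic generators

All generators are pure functions of (specification, seed): identical
inputs give bit-identical systems, and the RNG state of the caller is
never disturbed.

- **Helix builder**: sequential internal-coordinate (NeRF) placement with
  standard backbone geometry (N–Cα 1.458 Å, Cα–C′ 1.525 Å, C′–N 1.329 Å,
  ω = 180°), φ/ψ = (−57°, −47°) inside the helical span and an arbitrary
  but fixed coil (−80°, 80°) for the N-terminal loop (the disulfide bond
  itself is not modelled — geometry only). Side chains are single
  centroid beads at canonical Cα–centroid distances per residue type;
  glycine has none, so its "side chain" is the Cα atom everywhere
  downstream. Consecutive Cα distances come out at 3.80 Å and the rise at
  ~1.5 Å/residue, and `backbone_dihedrals()` recovers the build torsions.
  Tests that need ring-atom contacts (Phe15/Phe23) add two extra beads
  around the centroid.
- **Slab bilayer**: per leaflet, lipids on a (jittered) square lattice
  with spacing √A_L — defaults 64 lipids per leaflet, A_L = 64 Å², i.e. a
  64 × 64 Å box with the 38 Å phosphorus-plane separation inside an 80 Å
  box, mirroring the study system's dimensions; straight bead chains
  descend toward the midplane at the spec tilt with seeded random
  azimuths; SPC-like water fills the remaining volume at 0.0334 Å⁻³;
  species (DOPC/DOPS at the requested counts) are placed randomly per
  leaflet. No physics is modelled — the geometry is exactly what the
  analyses consume.
- **Embedding**: the helix axis is rotated into the membrane plane,
  rolled so the buried set (Thr9/Leu12/Leu16/Ser20) faces the core and
  the exposed set (Gln10/Asn14/His18) the solvent (grid search over roll
  angles, error if unsatisfiable), translated so the helical-span Cα
  centre sits the requested 7 Å below the leaflet's mean phosphorus z,
  and lipids with any bead within 1.5 Å of the peptide are deleted (count
  recorded).
- **Charge accounting**: `neutralize()` returns the monovalent
  counterion count for a composition (88 DOPC + 40 DOPS → 40 cations); a
  `mode` switch covers net-positive compositions with anions instead.

## What the synthetic data does and does not show

The generators emulate the *geometry* of the study conditions — sizes,
compositions, placements, noise — not their physics. Gaussian coordinate
noise has no correlations, so helicity stays uniformly high where a real
trajectory would fray at the termini; pseudo-lipids have no headgroup
structure, so hydration numbers characterise the slab model rather than a
real solvated membrane; and the two-family mutant ensembles are built,
not sampled from a free-energy surface. Passing tests therefore
demonstrate that the *analyses* are correct (they read back constructed
truth and agree with brute-force oracles), not that any simulation result
is reproduced. Quantities that only a production trajectory can supply —
equilibrium lipid areas, the occupancy of a particular hydrogen bond, the
agreement fraction between predicted and measured shifts — are exercised
here on constructed ensembles whose true value is known by design, so the
measurement machinery is validated even though no dynamics is run.

## Numerical choices and problem sizes

- Strict `<` at every cutoff; boundary tests at exact floating-point
  representable distances, with angle boundaries probed at ±0.001° to
  avoid transcendental round-off flakiness.
- Minimum-image wrapping folds displacements into (−L/2, L/2]; only
  orthorhombic boxes are supported in periodic analyses (triclinic input
  is refused at read time).
- Circular (not linear) SD, `sqrt(−2 ln R̄)`, for dihedral spread to
  avoid wrap artefacts near ±180°.
- Grid ownership ties break to the lowest lipid index; APL grids below
  8×8 are refused.
- Kink targets are met by direct in-plane rotation and verified to 0.1°.
- Default test problem sizes: ensembles of 100–500 frames of the 124-atom
  peptide, 32–128-lipid slabs, 10⁴ orientations for isotropic order
  checks, 5 000 target atoms × 10 frames for RDF uniformity — the whole
  suite runs in about half a minute.

## Replicates and the analysis drivers

Replicate trajectories (the study design is several independent runs from
one start) are aggregated with an unweighted mean and the *sample*
standard deviation (n − 1); a `--sem`-style switch is deliberately left
out of the data model and applied where plotted. `run_pipeline()` chains
helicity, kink-angle, coupling and hinge-flexibility stages over the
replicas, records every parameter and seed in a YAML manifest, proceeds
past stage failures (recording them), and writes TSV tables whose comment
headers carry the producing parameters. The numbered scripts under
`analysis/` are thin narrative drivers over these functions.

## Known limitations

- No XTC/TRR reader exists in this R environment; trajectories arrive as
  DCD or multi-model PDB.
- The simplified Kabsch–Sander assignment does not reproduce full DSSP
  output (no bends, no bridge-partner bookkeeping beyond ladder
  detection).
- Bilayer analyses assume a flat slab with the normal along z; curved or
  undulating membranes are out of scope, as are Voronoi areas, electron
  density profiles, and any energetic H-bond scoring outside the
  secondary-structure module.
- Comparisons against a deposited NMR ensemble require those coordinates
  at run time; the test suite exercises the same operations on a
  synthetic helix-kink-helix model built to an 85° axis angle between its
  two helices instead.
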