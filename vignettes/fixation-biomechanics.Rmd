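---
title: "Methods: desk-scale finite element comparison of angle-fracture fixation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale finite element comparison of angle-fracture fixation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model: what is being
simulated, which choices were genuinely open and how they were decided,
which numerical conventions are in force, and what the passing test suite
does and does not demonstrate about real mandibles.

## What the pipeline simulates

Unilateral post-canine chewing on a mandible with a plated angle fracture.
Four treatment arms (Champy vs biplanar fixation × chewing ipsilateral vs
contralateral to the fracture) are compared against the unfractured
control under identical material properties, muscle recruitment and
boundary conditions. The quantities of interest are those used clinically
and in the comparative-biomechanics literature to argue about fixation
rigidity and the bone-healing environment: interfragmentary displacement
(IFD, percentage change in fracture-gap node-pair distances; an optimal
healing window around 10 % is cited in the orthopedic literature),
principal strain extremes in the hardware and at the bone–implant
interface, sectional moment profiles along the corpus, and
strain-difference maps against the control.

## The synthetic mandible

Subject-specific CT geometry is replaced by a parameterized swept solid
([`mandible_spec()`]): a rectangular cross-section (default 8 × 14 mm)
swept along a semicircular dental arch (radius 15 mm), straight corpus
(35 mm per side), a mitered 90° gonial corner, and a vertical ramus
(30 mm) ending in the condyle. A cortical shell (2 mm default) wraps a
trabecular core; tooth blocks sit on the occlusal surface at normalized
arc positions (defaults approximate P3–M3, with P3–M1 as the bite teeth).
The lattice is split into six tetrahedra per hex cell (Kuhn split), so
all region interfaces conform: bone–bone and bone–tooth tie constraints
are realized exactly by shared nodes. The intact mesh is exactly
mirror-symmetric about the midsagittal plane, which the tests exploit
(left-chew and right-chew solutions must be mirror images to solver
precision).

What this emulates: the structural logic of the mandible — two condyles,
a dental arch between bite point and fracture, an angle region where the
masseteric sling inserts, stiff teeth on a cortical/trabecular corpus.
What it does not: real cross-sectional geometry (thin flaring ramus,
curved condylar neck, alveolar bone), heterogeneous orthotropic cortical
properties, the periodontal ligament, or sub-millimeter mesh resolution
at screw holes. Consequences of these gaps are taken up under
*Limitations*.

Default problem size: about 13 000 tetrahedra / 3 200 nodes, chosen so
the whole six-arm study solves in well under a minute on one CPU; the
verification battery uses meshes from one tetrahedron up to a
30 000-element cantilever.

## Fracture and hardware

The fracture is a 0.2 mm planar cut at the angle, realized on the
conforming cross-section plane nearest the requested plane (default: the
mitered gonial-corner plane; the obliquity is configurable through
`fracture_spec()`). Nodes on the plane are duplicated into anterior and
posterior faces displaced half a gap each, which yields an exact planar
gap and a clean registry of matched node pairs for the contact solver and
the IFD statistic. The registry normal points anterior → posterior.

Plates are straight 26.1 × 2.5 × 1 mm titanium strips spanning the
fracture perpendicular to its plane, offset 0.1 mm from the bone surface:
one on the superior border (Champy), plus one on the inferolateral
surface (biplanar). Screws are not meshed; each screw site ties the
plate-underside nodes within a screw radius (4.2 mm diameter) to their
nearest cortical nodes as equal-displacement constraints, two screws per
fragment per plate. The remaining plate underside is paired with the bone
as frictional contact, like the fracture faces.

## Loading

Muscle force magnitudes follow EMG × PCSA × 30 N/cm². The subject-specific
EMG and PCSA values behind the original in vivo work are not part of this
package; the defaults are deliberate placeholders at macaque scale
(PCSA 1.5–4.5 cm² per muscle; working side EMG 1.0, balancing side 0.6)
and are configurable per muscle. With these defaults the healthy model's
trimmed cortical principal strains land in the range reported by in vivo
macaque gauge work during chewing (roughly 150–700 microstrain), which is
the calibration a physiologist would check first.

Muscle geometry is anatomically stylized and was settled on anatomical
grounds, not by tuning to outcomes:

* the masseter/pterygoid insertion patches sit on the angle predominantly
  *posterior* to the fracture line (the position of the masseteric sling
  relative to a fracture below M3);
* the deep masseter's origin anchor gives it a near-vertical line of
  action with a lateral component (its zygomatic origin) — the classic
  driver of lateral "wishboning" of the corpus;
* bone nodes under a plate footprint are removed from insertion patches:
  plate placement elevates the periosteum and muscle off the plated
  strip, and leaving point loads on screw-tied nodes would contaminate
  the interface-strain statistic with applied-load artifacts;
* the condylar constraint set is the posterosuperior facet of the ramus
  end cap, not the whole cross-section: the condyle contacts the fossa
  over a small articular patch, and clamping the full section would lock
  the posterior fragment rotationally and suppress fracture motion.

Boundary conditions: working condyle fixed in x, y, z; balancing condyle
fixed in y (anteroposterior) and z (superoinferior) with mediolateral
translation free; chewing-side premolar/first-molar occlusal nodes fixed
in all directions (bite force is a reaction, not an input). Forces that
would fall on constrained DOFs are zeroed with a warning.

## Numerical choices

* **Elements.** Constant-strain tetrahedra with the closed-form isotropic
  stiffness; exact for uniform-strain patch tests (asserted at 1e-10) and
  monotonically convergent from below in bending (the cantilever
  verification reaches beam theory within 10 % at 80 × 8 × 8 cells).
* **Ties.** Node-cluster merging by union-find and a sparse indicator
  transformation; keeps the reduced operator symmetric and makes tie
  equivalence exact (two tied blocks equal one merged block to 1e-10).
* **Dirichlet conditions.** Row/column elimination, not penalty, so
  reactions are exact and global equilibrium closes to 1e-8 relative.
* **Contact.** Small-sliding node-pair penalty springs on the matched
  fracture pairs and plate–bone pairs. Normal penalty defaults to 100 ×
  the mean stiffness diagonal at the contact nodes (penetration stays
  orders of magnitude below the 1e-3 mm tolerance without conditioning
  collapse). A pair activates when its normal gap closes; the tangential
  force is capped by the Coulomb bound |f_t| ≤ μ f_n with slipping pairs
  carrying a secant tangential stiffness μ f_n/|s| (radial return), which
  keeps the operator positive definite and the outer active-set loop a
  stable fixed-point iteration. Convergence requires a stationary
  active/stick set and a relative displacement change below 1e-8;
  non-convergence is reported, never hidden, and post-processing refuses
  unconverged solutions.
* **Strain recovery.** Element strains are averaged into nodal tensors
  volume-weighted *before* eigendecomposition (principal values of the
  averaged tensor); the alternative convention (averaging principal
  values) changes extremes by a few percent on coarse meshes. Principal
  values use the closed-form trigonometric solution, verified against a
  dense eigensolver at 1e-12.
* **Trimming.** "Largest" strains exclude the top and bottom 5 % of
  sorted values (sort-and-slice; with n values, k = floor(0.05 n) cut per
  tail). A two-standard-deviation exclusion is available via
  `method = "sd"` — the two rules are numerically different, and the
  percentile rule is the default because it is the operative description
  of the tabulated comparisons this package mirrors.
* **IFD mode.** The per-pair distribution is binned into 1 %-wide
  integer-centered bins; the mode is the center of the fullest bin, first
  bin on ties; the mean is reported alongside because "average (mode)"
  phrasing in the comparative literature is ambiguous.
* **Section moments.** Free-body balance: the action transmitted onto the
  anterior side of a cut equals minus the sum of external forces and
  reactions on that side, with moments about the section centroid. This
  captures element, tie and contact transmission without enumerating the
  interface, closes equilibrium exactly at end stations, and matches
  P·d on a cantilever within discretization error. Local axes: sweep
  tangent (AP twist), global vertical, and their cross product (sagittal
  bending about the mediolateral axis).
* **Difference maps.** Undeformed-coordinate nearest-neighbor matching of
  bone nodes (hardware excluded), so the map is geometric rather than
  index-based; a distance threshold guards against incompatible meshes.
* **Degenerate inputs.** Specs are validated with diagnostics naming the
  offending field (zero cortical thickness, too-coarse discretization to
  host node sets or distinct tooth blocks, fracture planes that miss the
  angle region, gaps wider than the local element size, plates that do
  not span the fracture).

## Determinism

The generator, solver and statistics are fully deterministic for a fixed
spec; the seed is recorded in every configuration hash and output bundle,
and two runs of the same configuration produce bit-identical CSV tables.

## What the passing tests show — and what they do not

The verification suite demonstrates that the solver solves the stated
elasticity/contact problem correctly (patch exactness, beam convergence,
energy and equilibrium closure, complementarity, Coulomb bound,
tied-interface limit). The pipeline tests demonstrate the comparative
findings on the idealized geometry: Champy allows roughly an order of
magnitude more fracture-gap motion than biplanar, contralateral chewing
moves the fracture more than ipsilateral within each technique (with the
Champy motion concentrated at the inferior border), the single plate
carries higher trimmed strains than either biplanar plate, and the
biplanar model's global strain field stays closest to the unfractured
control. None of this certifies magnitudes for real mandibles: the
idealized section is stockier than a real corpus, so fracture motions
stay in the few-percent-of-gap range and the gap never actually closes
under these loads, whereas subject-specific models report gap closure and
opening beyond 50 %.

## Limitations

* **Interface strain concentration.** With 2 mm cells and screw ties
  spread over the 4.2 mm screw footprint, the transmitted load at a screw
  site dilutes over several nodes; bone–implant interface strain extremes
  are therefore of the same order as ambient bone strain, and comparisons
  between techniques at the interface reflect *where* each plate sits in
  the ambient strain field (the inferolateral plate occupies the
  highest-strain border) at least as much as the load path through the
  construct. Resolving screw-hole concentration physics would need
  sub-millimeter local meshing, which is outside this package's
  desk-scale envelope.
* **No gap closure.** Because fracture motions are small relative to the
  0.2 mm gap on this geometry, the fracture contact stays open in the
  default arms and compressive load crosses through the plates; the
  contact machinery is exercised (and verified) on dedicated block
  models.
* Isotropic cortical bone (configurable E, default 17 GPa) instead of
  mapped orthotropy; trabecular tissue at 10 GPa fills the whole core.
* Muscle recruitment is a two-level working/balancing table, not
  subject-specific EMG traces; origins are anchor points, not cranial
  surfaces.
* Single static load step; no dynamics, no geometric or material
  nonlinearity, no bone-healing model.
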