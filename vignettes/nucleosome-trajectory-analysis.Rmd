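---
title: "Methods: nucleosome trajectory analysis with nuctraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome trajectory analysis with nuctraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuctraj)
```

`nuctraj` quantifies how histone tail truncation affects nucleosome
structure in molecular dynamics (MD) trajectories. This vignette explains
the models and procedures, the tunable parameters, the synthetic-data
generator that stands in for production MD at desk scale, and the
numerical and design choices a maintainer should know about.

## The order parameter R_T

The central statistic compares a tail-truncated simulation with an intact
one. For any selection of atoms — a histone monomer's core backbone, a
structural domain such as the H2A α3 helix or the docking domain
(residues 100–119), or a segment of nucleosomal DNA — each trajectory
frame is superposed onto a common reference by weighted least squares
(Kabsch, SVD with the determinant correction that excludes reflections),
fitting on the histone core backbone (N, CA, C, O) with tail residues
excluded, and the RMSD of the selection is recorded per frame. The order
parameter is the ratio of time-averaged RMSDs,

$$ R_T = \frac{\langle \mathrm{RMSD}_\mathrm{truncated}\rangle}
               {\langle \mathrm{RMSD}_\mathrm{intact}\rangle}, $$

with $R_T > 1$ read as destabilization of the selection. Two readings of
the definition are possible (ratio of time averages vs time average of
per-frame ratios); `nuctraj` implements the ratio of time averages, which
is the natural reading of "RMSD averaged over the entire trajectory", and
the per-frame series are retained in the output tables so the alternative
can be formed externally. The two references used for the truncated and
intact RMSD series must be mutually aligned (zero RMSD) for the ratio to
be meaningful; this is the caller's contract, checked nowhere downstream.

`order_parameter_RT()` attaches a delta-method standard error that treats
frames as independent. MD frames are autocorrelated, so on real
trajectories this SE is optimistic and should be read as a lower bound;
on the stationary synthetic trajectories used for validation it is exact.

**Flagging.** The pipeline monitors ~50 selections at once and flags a
selection destabilized only when `R_T > 1.1` *and* `R_T − 1 > 4·SE`. The
effect-size floor is needed because all selections share one global
superposition: a large genuine displacement of one domain perturbs the
fitted frame and inflates every other selection's RMSD by a few percent —
statistically significant at tiny SEs, but not a destabilization signal.
The 1.1 floor is the edge of the stationary null band (synthetic
intact/intact pairs stay within [0.9, 1.1]); four SEs controls the
family-wise error over the monitored selections. The bare `R_T > 1`
reading is reported alongside for every selection. When a specific domain
is known or suspected to move, the cleaner protocol is to exclude it from
the fit selection, which removes the spillover entirely; the test suite
demonstrates both protocols.

## Fluctuation profiles

B-factors are computed as $B = (8\pi^2/3)\,\langle |r_i - \langle
r_i\rangle|^2\rangle$ over a frame window (the pipeline uses the second
half of the run, so that the profile reflects the equilibrated regime of
the synthetic generator's stationary statistics). Frames are superposed
onto the window-mean structure and the mean recomputed, iterated twice —
removing rigid-body drift without privileging any single frame. With $N$
fitted atoms the superposition absorbs six rigid degrees of freedom and
biases the mean-squared fluctuation down by a factor of roughly
$1 - 2/N$; for profiles over thousands of atoms this is negligible, and
for small synthetic systems with no rigid-body motion `fit_sel = NULL`
skips the superposition and recovers the closed form $B = 8\pi^2\sigma^2$
exactly.

## Secondary structure

Assignment follows the Kabsch–Sander hydrogen-bond-energy rules: the
backbone NH···O=C bond energy is
$E = 0.42\cdot0.20\cdot332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol, a bond exists when $E < -0.5$ kcal/mol, and any inter-atomic
distance below 0.5 Å caps the energy at −9.9 kcal/mol (flagged). Amide
hydrogens, absent from crystal structures and from the synthetic
generator, are reconstructed 1.00 Å from N along the preceding C=O
direction; chain breaks (C–N > 2.5 Å) and prolines donate no bond. The
code set is the minimal one that matters here: helices from consecutive
n-turns (G: n→n+3, H: n→n+4, I: n→n+5, retained for fidelity even though
π-helix is rare), strand E from parallel/antiparallel bridge patterns
(isolated bridges are folded into E rather than kept as a separate B
code), hydrogen-bonded turns T, bends S (CA-trace kink > 70°), with the
deterministic priority H > E > G > I > T > S and coil elsewhere. On an
ideal (φ, ψ) = (−57°, −47°) 12-residue helix the assignment matches a
reference implementation of the same rules (H at residues 2–11), and a
two-strand fixture reproduces the reference's bridge positions. Helix
propensity is the per-residue fraction of frames assigned H.

## DNA geometry

Backbone dihedrals α(O3′-P-O5′-C5′) through ζ(C3′-O3′-P-O5′) are signed
torsions in (−180°, 180°]; dihedrals whose neighbouring atoms are missing
(termini) are `NA`, never zero. BI/BII substates use the wrapped ε−ζ
difference with the field-standard convention BI when ε−ζ < 0 (strictly),
BII otherwise; the boundary at exactly zero goes to BII by the strict
rule.

Base-pair and step geometry rest on embedded standard-reference-frame
base coordinates (the convention used by helical-parameter programs,
with an idealised sugar–phosphate template shared by all four nucleotides
so that a uniform fibre duplex is exactly sequence-independent in its
backbone). A base's frame is the least-squares superposition of these
standard ring coordinates onto the observed ring atoms; the strand II
frame is flipped 180° about its x axis, so an ideal Watson–Crick pair
gives coincident frames; the pair frame is the quaternion mid-rotation of
the two. Step parameters come from the symmetric mid-step decomposition:
the roll–tilt angle Γ between the two pair z-axes is split evenly about
the hinge, twist is measured about the common z, roll and tilt are
Γcos φ and Γsin φ with φ the hinge-to-mid-frame-y angle, and the
translation expressed in the mid-step triad gives shift/slide/rise. A
duplex generated with twist 36° and rise 3.38 Å is recovered to numerical
precision, and all parameters are invariant under rigid motion.

Groove widths use the phosphate–phosphate definition: natural cubic
splines are threaded through each strand's P atoms (parameterised by
base-pair position; strand II mapped through the pairing), and at each
step the minor and major widths are the closest approach between the two
splines within a ±1.5-step window around the canonical cross-strand
offsets (−3 steps for the minor groove, +3 for the major, the offsets at
which the cross-strand P–P separation of ideal B-DNA is minimal/maximal
in the expected 12–18 Å range). The 2-D minimisation is multi-start
L-BFGS-B (the distance surface can hold two shallow minima). Widths are
`NA` where fewer than two phosphates flank the window — all of a 4-bp
duplex, and the terminal steps of any duplex. Base pairing is always
taken from the topology (default i ↔ n+1−i), never inferred from
geometry: nucleosomal DNA is known to harbour occasional non-Watson–Crick
pairings, and silent geometric pairing would misassign exactly those.

## Interactions and electrostatics

Hydrogen bonds use geometric criteria — donor–acceptor ≤ 3.5 Å and
D–H···A angle ≥ 150° by default. These defaults are deliberately explicit
and configurable: analysis tools differ, and published H-bond counts
rarely state their criterion. Donors are N/O atoms with an attached
hydrogen (≤ 1.25 Å); selections without polar atoms yield empty results,
not errors. The detachment criterion classifies a frame as detached when
its minimum inter-group distance strictly exceeds the intact-trajectory
mean plus one standard deviation ("greater than"); at-threshold frames
are in contact. Contact maps record, per residue pair across an
interface, the distance between the two closest atoms (equivalently the
sum of each atom's distance to their midpoint), with a 3 Å close-contact
cutoff; on a trajectory the map is computed on the frame-averaged
structure after superposing every frame onto the first.

Interaction energies are a minimal self-contained nonbonded model: 12-6
Lennard-Jones (well depth ε, combined geometrically; minimum-distance
radius from additive rmin/2) plus Coulomb (332.0636 q₁q₂/r kcal/mol),
optionally modulated by the smooth switching function between stated
radii. Parameters are supplied by the caller as a table — force-field
files are not bundled, and validation uses synthetic parameters against
exhaustive pairwise sums.

The potential map accumulates $q\,\mathrm{erf}(\beta r)/r$ per point
charge on a regular grid — the long-range (smoothed) component of an
Ewald decomposition, evaluated by direct summation (no periodic images by
default; an FFT evaluation would be an optimisation with the same
contract on non-periodic systems). Defaults are 1 Å spacing and β = 0.25
Å⁻¹. Conversion to Volts assumes vacuum permittivity (14.399645 V per
e/Å) — a displayed-units choice, not a solvation model; as β → ∞ the
kernel approaches the bare Coulomb potential (relative error < 10⁻⁶ for
βr > 6). Grids are written in OpenDX scalar-field format (z-fastest).

## The synthetic generator: what it does and does not emulate

No trajectory data accompany the study conditions this package targets —
production runs were ~100 ns of all-atom MD on ~200,000-atom solvated
systems, far beyond desk scale. The generator therefore emulates the
*statistical structure* the analyses consume, with known ground truth:

* `make_ideal_helix()` — poly-alanine backbones with exact φ/ψ (NeRF
  construction, standard bond geometry).
* `make_bdna_duplex()` — fibre-model B-DNA with uniform twist/rise.
* `make_toy_nucleosome()` — a 147-bp duplex bent onto a left-handed
  superhelix (defaults: radius 41.9 Å, pitch 25.9 Å, 1.67 wraps — the
  crystallographic particle dimensions; helical register one turn per
  10.5 bp; dyad at bp 74) plus eight ideal-helix pseudo-histones labelled
  A–H with the real tail, helix-domain and docking-domain residue ranges,
  and SHL boundaries every helical turn (14 segments for 147 bp).
* `make_harmonic_trajectory()` — frames are the reference plus
  independent per-coordinate Gaussian noise of scale σ (default depends
  on the experiment; 0.3 Å reproduces sub-Å backbone RMSDs typical of a
  stable core), optionally with per-selection scales and a progressive
  rigid displacement of one domain emulating destabilization. Output is
  bit-reproducible under a fixed seed.

Harmonic (frame-independent) noise was chosen over Langevin-style
correlated dynamics deliberately: it is stationary, analytically
checkable (B = 8π²σ², RMSD concentration, normal detachment tails), and
sufficient for every property the analyses assert. What passing tests on
this generator do **not** show: behaviour under time-correlated,
anharmonic, multi-state dynamics; force-field realism; solvent and ion
effects; sequence-dependent DNA fine structure; or the biological
findings of any particular MD study (e.g. which arginine contacts rewire
on tail truncation). They do show that, given trajectories with a known
fluctuation structure, the statistics computed are the ones defined, to
stated precision.

## Numerical choices and degenerate inputs

* Kabsch fits require ≥ 3 non-collinear points; collinear sets are an
  error (the rotation about the line is undetermined).
* Torsions are undefined for collinear triples (error) and returned in
  (−180°, 180°]; the trans boundary maps to +180°.
* Altloc handling keeps the highest-occupancy conformer; zero-occupancy
  atoms are kept (nucleosome tails have occupancy zero in the crystal yet
  are physically present). Copy labels 1/2 follow chain order in the
  file and can be overridden in the topology — deposited structures
  differ in which chain letter is which copy.
* Tail truncation errors on a partially absent residue range (a numbering
  mismatch must not truncate silently) but treats an entirely absent
  range as already truncated, making the operation idempotent.
* R_T is undefined (error) when the intact mean RMSD is zero.
* The trajectory text dialect stores `frame time x y z` rows; multi-model
  PDB round-trips at the format's 3-decimal precision.

## Problem sizes used in validation

The shipped validation exercises the package at sizes chosen to finish in
seconds to a couple of minutes while leaving Monte-Carlo error well below
the asserted tolerances: closed-form B-factor recovery uses 40 atoms ×
10⁴ frames (2% tolerance; observed error ~0.1%), R_T ratio recovery uses
the ~2,500-atom core backbone × 10³ frames (5% tolerance; observed
~0.1%), destabilization localisation uses backbone-only models × 250
frames with a 0→4 Å linear displacement profile, and detachment tails use
5 × 10³ frames. Oracle-equivalence checks (hydrogen bonds, minimum
distances, contact maps, nonbonded energies, Kabsch RMSD) are exact on
≤ 50-atom random instances.

## Known limitations

* The delta-method SE on R_T ignores frame autocorrelation; on real MD
  output, block averaging or effective-sample-size corrections should be
  applied before reading the significance guard literally.
* Groove widths implement only the P–P spline definition; curves-based
  definitions are out of scope.
* The nonbonded model has no bonded terms, no PME reciprocal sum with
  periodic images, and no dielectric model; it is an interface-energy
  diagnostic, not a force field.
* Binary MD formats (DCD/XTC) are not core; conversion to multi-model
  PDB or the text table is expected upstream.
* The Kabsch–Sander implementation pins the original rules; later DSSP
  revisions (polyproline II, extended bridge bookkeeping) are not
  reproduced.
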