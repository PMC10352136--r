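---
title: "Helical lattice analysis of membrane tubule coats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical lattice analysis of membrane tubule coats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coatlattice)
library(dplyr)
```

## The problem

Sorting-nexin BAR-domain complexes such as ESCPE-1 (SNX1–SNX5) remodel
endosomal membranes into narrow tubules and coat them with a helical protein
lattice. In cryo-electron tomography, subtomogram averaging of such coats
starts not from densities but from *coordinates*: a traced tube centerline
and a table of particle poses (position, orientation, cross-correlation
score) refined against an average. `coatlattice` implements the
coordinate-level computations of that workflow as reusable, tested
functions:

1. **Tube-axis geometry** — arc-length parametrized centerline splines with
   rotation-minimizing local frames, and cylinder *unrolling* of particles
   into `(s, u)` surface coordinates.
2. **Helix parametrization** — radius, strand pitch, number of helical
   starts and handedness of the coat of each tube.
3. **Subboxing** — helix-guided pose generation, azimuth-corrected so each
   subvolume's x axis points along the strand, plus cross-correlation-driven
   deduplication and rigid recentring.
4. **Outlier exclusion** — the four-criterion QC (extreme radius, extreme
   angle, missing neighbor, low cross-correlation).
5. **Neighborhood analysis** — pooled relative poses of lattice neighbors
   in each particle's frame, density peaks by k-means, and the lattice
   parameters $a$, $b$, $\alpha$, radius and inter-particle relative angle.
6. **Coat model metrics** — helical symmetry expansion of an asymmetric
   unit, Taubin circle fits for BAR-dimer curvature, and Shrake–Rupley
   solvent-accessible surface areas with interface burial.

Because raw tilt series cannot be reprocessed at desk scale, the package
ships a first-class synthetic generator whose defaults encode the study
conditions; every estimator is validated by recovery of known ground truth.

## The helix model

A coat with $n$ starts consists of $n$ helical strands winding a cylinder
of radius $R$ (Å), offset from one another by $2\pi/n$ in azimuth. One
strand rises by the pitch $P$ per full turn; the *lead angle* between a
strand and the circumferential direction satisfies
$\tan\theta = P / (2\pi R)$. Subunits repeat along each strand at spacing
$a$, so consecutive particles are related by an axial rise
$a\sin\theta$ and an azimuthal twist $a\cos\theta / R$ — the symmetry
operators used for coat expansion. Adjacent strands are bridged by the
second lattice vector $b$ at angle $\alpha$ to $a$ on the unrolled surface.

### Wrapping a lattice onto a cylinder

The generator does not choose pitch and starts independently: a physical
coat is one 2D lattice wrapped onto a cylinder, which requires the
circumference vector to be a lattice vector,

$$\mathbf{C} = k\,\mathbf{A} + n\,\mathbf{B}, \qquad |\mathbf{C}| = 2\pi R ,$$

with integers $k$ (along-strand wraps) and $n$ (the number of starts).
Given the lattice ($a$, $b$, $\alpha$) and a start class $n$, the generator
picks the $k$ whose circumference best matches the target shell radius and
applies a small isotropic strain (under 4% for the default geometry) so all
classes reach the same radius. Two consequences mirror what is seen in real
coats: the lattice parameters barely differ between start classes, while
the lead angle — and with it the relative angle between consecutive
particles, $a\cos\theta/R$ — adapts to the class.

The description of each tube is completed by a phase: the azimuth of strand 0 at
$s = 0$ is drawn uniformly per tube, since nothing in the data constrains
it.

## Generator defaults (the study conditions)

| Parameter | Default | Why |
|---|---|---|
| membrane radius | 140 Å | 28 nm outer-leaflet diameter |
| coat offset | 18.5 Å | half of the 3.7 nm protein coat |
| starts distribution | 5.6 / 31.7 / 27.2 / 36.1 % for 1–4 | observed per-tube frequencies (normalized to sum 1) |
| tube lengths | log-normal, mean 4,660 Å, s.d. 2,240 Å, truncated to [1,570, 15,520] Å | only summary statistics are reported |
| handedness | +1 | right-handed coats |
| lattice $a$, $b$, $\alpha$ | 57 Å, 65 Å, 70° | no spacings are printed for this coat; values chosen at the scale of a BAR-dimer lattice with $a < b <$ both diagonals, so the along-strand repeat is the shortest lattice vector (an assumption the start detector documents) |
| positional / angular noise | 5 Å, 5° | coordinate scatter typical of subtomogram alignment at ~10 Å resolution |
| dropout / decoys | 5% / 5% | exercise the QC criteria without dominating the lattice |
| cc scores | true ~ N(0.3, 0.05), decoys ~ N(0.1, 0.05), clipped to (0, 1] | arbitrary but documented; QC uses per-tube ranks, not absolute values |

Axes lie in the xy plane with uniform in-plane orientation, gentle in-plane
curvature (radius ≥ 50,000 Å) and a 20 Å out-of-plane undulation — enough
to exercise the frame transport without approaching the "extreme curvature"
exclusion regime.

What the generator does **not** emulate: missing-wedge anisotropy, CTF
effects, per-tomogram defocus gradients, membrane deformation away from a
cylinder, and spatially correlated alignment errors. Passing recovery tests
on this generator therefore validates the *geometry and bookkeeping* of the
pipeline, not its robustness to every artifact of real tomograms.

## Numerical choices

**Axis splines and frames.** Natural cubic splines through the control
points, reparametrized by arc length on a 1 Å grid; local frames by
rotation-minimizing (double-reflection) parallel transport seeded with a
fixed normal at $s = 0$. Frenet frames are avoided because torsion flips
them on near-straight tubes. The azimuth zero is the transported normal;
positive azimuth is right-handed about the tangent. Closest-point lookup
uses a two-stage (coarse stride, then local) search with a tangent-space
foot-point refinement, and raises an error naming the particle when a point
is nearly equidistant from two distant axis segments.

**Orientations.** Intrinsic Z–X–Z Euler angles in degrees (Dynamo-style
`tdrot/tilt/narot` semantics) everywhere in serialized tables;
matrix↔Euler round trips are exact to 1e−9 away from the gimbal
degeneracy, where the convention `psi = 0` is applied.

**Start detection.** The dominant along-strand direction is the mode of a
2° circular histogram of nearest-neighbor vector orientations in the
unrolled plane, sharpened by an iterated circular mean and a principal-axis
fit. The lead angle and start count are then refined together by maximizing
the circular concentration $\left|\,\overline{e^{2\pi i n v / V}}\,\right|$
of the perpendicular row coordinate $v$ wrapped at the full-turn row period
$V = 2\pi R \sin\theta$, over candidate $n = 1..6$ and a fine $\theta$
grid. The grid step adapts to the tube length: the dephasing rate is
dominated by the wrap count $v/V$ times $\cot\theta$, so long tubes need —
and get — finer steps. This replaces a simpler "median spacing of sorted
projections" row-spacing rule, which is fragile under dropout and noise;
ties in the start count resolve to the smallest candidate, which also makes
the noise-free case (where $n$ and its multiples score identically) exact.
Clouds whose best concentration stays below 0.25 are declared lattice-free.

**Neighborhood analysis.** The default cutoff is $1.3 \times \max(a_{\rm
est}, d_\perp)$, which for the default geometry admits the six first-shell
peak families ($\pm a$, $\pm b$, $\pm(b-a)$) and excludes $\pm(a+b)$;
k-means (`stats::kmeans`, 50 seeded restarts, best inertia) locates the
peaks. Centro-symmetric pairs are matched on tangent-plane components —
curvature makes both members of a pair sag radially by
$R(1 - \cos\Delta\beta)$, so 3D sum-norms never cancel — and every
centroid is *unbent* onto the cylinder surface before lattice vectors are
measured, removing the chord-versus-arc bias. The lattice angle is
reported on the canonical branch $\alpha \in (0°, 90°]$: the same lattice
is described by $(\alpha, \mathbf{b})$ and $(180° - \alpha, -\mathbf{b})$.
With k-means on noisy, partially overlapping clusters the recovered vector
lengths carry a small truncation bias (≲ 2 Å at 5 Å noise); the bias is
common to all start classes, which is why between-class comparisons are
much tighter than absolute recovery.

**Pipeline order.** simulate → tube filters (minimum length 1,600 Å,
curvature radius above 10× the tube radius) → helix fit → subbox →
snap → dedup (8 px) → QC → dedup (17 px) → neighborhood → lattice. The
*snap* stage is this package's coordinate-level stand-in for local
subvolume alignment: subbox poses, generated on the fitted helix at the
estimated strand phase, adopt the pose and score of the nearest observed
particle (within half an along-strand spacing), and the 8 px deduplication
then collapses poses that converged onto the same subunit. The strand
phase is estimated from the circular mean of the wrapped row coordinate;
without it, subbox strands would sit at an arbitrary azimuth offset from
the data.

**QC.** Thresholds are declared package defaults (radius ±20%, angle 30°,
neighbor tolerance 0.5 a, cc percentile 5) — validated by recovery on
labelled synthetic data, not taken from any publication. The expected
along-strand neighbor positions follow the curved strand on the fitted
helix; stepping along the straight particle tangent would miss true sites
by the curvature sag (~10 Å at the default geometry). The
cross-correlation criterion is a per-tube percentile, so it always trims
the lowest-scoring tail; strand-terminal sides beyond the tube end are
treated as satisfied. A particle is excluded iff it carries at least one
flag.

**Structure metrics.** SASA uses a deterministic Fibonacci point template
(960 points) on probe-expanded spheres (probe 1.4 Å; radii C 1.70, N 1.55,
O 1.52, S 1.80 Å), accurate to ~1% against the analytic two-sphere
formula. Interface burial is the two-sided sum
${\rm SASA}(A) + {\rm SASA}(B) - {\rm SASA}(AB)$; the polar fraction counts
nitrogen and oxygen contributions, a definition-dependent convention (S is
counted apolar). Curvature circles are Taubin algebraic fits after
projection onto the best-fit plane; the intended input is the Cα trace of
a BAR-domain dimer.

## Problem sizes

The validation suite runs at sizes chosen to give tight statistics while
remaining desk-scale: 2,000 noiseless tubes for start-frequency recovery
(binomial 95% bands at that n), 50 noisy tubes for the diameter, 30 tubes
per start class through the full pipeline for lattice invariance, and
10,000 draws for distribution checks. Unit tests use shorter tubes
(1,600–3,200 Å) so each runs in seconds.

## Known limitations

* The start detector assumes the along-strand repeat is the shortest
  lattice vector; for lattices where a lateral vector is shorter, the
  "strand" it reports would be that lateral family.
* Lattice-vector recovery by k-means carries a noise-dependent shrinkage
  of order 1–2 Å; use the between-class contrasts, or noiseless
  calibrations, when absolute spacings matter.
* `fit_curvature_circle` fits a single arc; strongly S-shaped backbones
  violate its model.
* Deduplication is performed per tube; coordinates of different tubes are
  never compared.
* Interface areas depend on the burial definition (two-sided here), the
  radius set and the point density; the reported polar fraction inherits
  all three.
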