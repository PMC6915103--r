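---
title: "Modelling cochlear-implant current spread with cochleafield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cochlear-implant current spread with cochleafield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cochleafield models the electric field produced by a cochlear implant in the
inner ear and what that field does along auditory nerve fibers. This
vignette is the package's methods account: the physical model and its
assumptions, the synthetic geometry and why it looks the way it does, the
numerical choices, and what the package deliberately does not attempt.

## The physical model

On the time scale of a stimulation pulse the tissue is treated as a purely
resistive volume conductor (quasi-static approximation; permittivity
neglected). The potential $V$ satisfies

$$\nabla \cdot (-\sigma \nabla V) = 0$$

with a piecewise-constant conductivity $\sigma$ per tissue compartment
(S/m): scalp 0.33, skull 0.013, brain 0.2, bony labyrinth 0.013, cochlear
canal (perilymph/endolymph) 1.43, auditory nerve 0.3333. The silicone
carrier of the electrode array is a perfect insulator and is represented as
a *void* — its elements are excluded from the conduction domain. For an
ideal insulator this is identical to a zero-conductivity material and it
keeps the stiffness matrix well conditioned.

Stimulation is monopolar and current-controlled: one contact pair injects a
prescribed total current (default 1 mA) and the return path is a distant
extracochlear ground patch held at 0 V. All other contact pairs are metal
left floating: each is an equipotential surface with zero net current.
Discretely, each contact patch is condensed to a single unknown (all its
nodes share one degree of freedom) and the prescribed total current enters
the right-hand side of that unknown; this is the weak form of a
total-normal-current condition and handles active and floating contacts
identically, only the load differing. The condensed system is symmetric
positive definite and solved by sparse Cholesky factorization; the
factorization is cached on the mesh and reused across stimuli, which makes
an all-contacts voltage-spread matrix essentially the cost of one solve.
Net patch currents are evaluated as the stiffness residual summed over
patch nodes — the consistent discrete flux — so charge conservation holds
to solver precision rather than to surface-quadrature accuracy.

Each MED-EL-style contact *pair* is merged into a single electrical patch
(one band around the carrier): the stimulation protocol drives pairs as
units, and nothing in a purely resistive model distinguishes the two pads
of a shorted pair.

## The synthetic cochlea

No imaging data ship with the package; the geometry is an analytic, tapered
Archimedean spiral chosen so that the pipeline's algorithms — which are
geometry-agnostic — can be exercised under controlled conditions.

* The **lamina edge curve** (outer edge of the osseous spiral lamina, where
  peripheral axons synapse) is a spiral of 2.5 turns whose in-plane radius
  tapers by 72 % from base to apex, uniformly scaled so its total arclength
  equals 25.003 mm.
* The **cochlear canal** is a tube around a centerline offset radially
  outward from the lamina edge, with radius tapering from 0.9 mm at the
  base to 0.45 mm at the apex. The two scalae are merged into one duct; the
  basilar partition is out of scope.
* The **electrode carrier** (radius 0.3 mm) follows the duct to an
  insertion depth of 720°, offset toward the scala-tympani side of the duct
  below 270° and toward the scala-vestibuli side above it, blending over
  ±10° — a parameterized translocation, not a replica of any particular
  insertion trauma. Twelve contact bands sit at 2.4 mm centre-to-centre
  spacing along the carrier, the most apical 0.8 mm from the tip; contact
  radius is 0.18 mm, represented at mesh resolution as a one-band ring.
* The **modiolar nerve** consists of a trunk cylinder (radius 0.65 mm)
  around the spiral axis, truncated at the nerve base plane z = −2.5 mm, a
  thin nerve sleeve following the lamina edge, and the connection between
  them. With `microstructures = TRUE` (the detailed, "ORI"-style variant)
  that connection is 10 discrete tubular channels of radius 0.3 mm — the
  porous Rosenthal's-canal microstructure through which fibers must thread
  in bundles; the rest of the modiolar envelope is bone. With
  `microstructures = FALSE` ("SIM"-style) the entire envelope is solid
  nerve. Both variants are labeled by the same deterministic implicit
  functions, so they are element-for-element identical outside the
  modiolar envelope. The paper-style channel count, radius and tortuosity
  are unknown quantities; the defaults (10 straight channels of 0.3 mm
  radius) are assumptions, exposed as parameters.
* The **head** is reduced to concentric brain/skull/scalp shells (radii
  9/11/13 mm) around the cochlear block. Its only role is to carry the
  return current to the extracochlear ground patch (a 10 mm-radius cap on
  the outer surface); a smaller-than-life head shortens that return path,
  which raises absolute potentials and decay rates relative to a full head
  but leaves every within-cochlea contrast intact.

What the generator does *not* emulate: real scalae separated by the basilar
membrane and organ of Corti, non-uniform base-to-apex fiber density, soma
packing in Rosenthal's canal, blood vessels, and patient-specific anatomy.
Tests passing on this geometry therefore validate the *algorithms* (solver
contracts, path optimality, filter and derivative identities, the
detailed-vs-simplified contrast mechanism), not anatomical accuracy.

## Meshing

Meshes are built on a graded tensor-product lattice: uniform spacing
(default 0.3 mm) in a box around the cochlear block, geometrically
coarsening (factor 1.6) out to the scalp shell. Each box is split into six
tetrahedra along a consistent diagonal (Kuhn/Freudenthal decomposition,
conforming across boxes), and each tetrahedron is labeled by evaluating the
implicit geometry at its centroid. This trades smooth boundaries for three
properties the study design needs: determinism (the detailed/simplified
toggle acts on an identical element set, so variant comparisons are never
confounded by remeshing), robustness (no surface intersection or repair
steps can fail), and O(1) point location (inside a Kuhn-split box the
containing tetrahedron follows from the ordering of the fractional
coordinates, with closed-form barycentric coordinates). Staircase
boundaries converge to the true geometry at first order; the mesh-volume
and potential-convergence tests quantify this on analytic fixtures. When
the detailed variant is meshed, the lattice spacing is capped at the
channel radius so every modiolar channel is resolved by at least two
elements across its diameter.

For the analytic point-source verification the lattice would be the wrong
tool — a staircase sphere perturbs the boundary at O(h) — so
`mesh_concentric_spheres()` maps a cube lattice radially onto exactly
spherical inner and outer boundaries ("spider-web" construction). With
current $I$ on the inner sphere and the outer sphere grounded the exact
solution is $V(r) = \frac{I}{4\pi\sigma}(1/r - 1/R)$, which reduces to the
free-space point source for $r \ll R$.

## Fiber reconstruction

Fibers are reconstructed exactly as a mesh-constrained shortest-path
problem:

1. 400 seed points, evenly spaced by arclength and including both
   endpoints, on the lamina edge curve (synaptic endings);
2. a matching end curve obtained by projecting the lamina curve onto the
   nerve base plane, uniformly shrinking it about the trunk axis until its
   maximal radial extent is 90 % of the trunk radius, and rotating it by
   45° — the spiral "wrap" that gives basal fibers a tangential course.
   The 90 % rule is this package's reproducible reading of "shrunk to fit";
   pairs are matched by arclength rank;
3. snapping both points of each pair to the nearest auditory-nerve mesh
   node (exact ties broken toward the lowest node id);
4. Dijkstra's algorithm over the edge graph of the nerve compartment with
   Euclidean edge weights (no curvature penalty — smoothing is the
   refinement pass's job). Equal-distance relaxations keep the smaller
   predecessor id, so paths are deterministic. The search is implemented
   in C++; tests check it against exhaustive path enumeration on tiny
   meshes and against an independent graph library.

Because paths can only use nerve-compartment edges, every fiber vertex lies
inside the auditory nerve by construction — the guarantee that spline
interpolation through a porous modiolus cannot give. In the detailed
variant, fibers between channels travel along the lamina sleeve to the
nearest channel and thread it in bundles.

The optional refinement pass extracts the compartment within a tube
(default radius 3 lattice spacings) around a coarse path, remeshes it at a
quarter of the parent spacing, and re-runs the search between the snapped
endpoints. The fine lattice is oriented along the path's endpoint *chord*:
a lattice path can only be as short as the best edge directions available,
and an axis-aligned fine lattice would keep a direction-dependent
metrication error that no amount of refinement removes. With chord
alignment the refined graph contains edges parallel to the dominant fiber
direction, and on a straight tube the refined path reaches the chord within
the tested 2 %. On strongly curved fibers the chord direction is only
globally right, so refinement there smooths the trajectory (finer steps)
more than it shortens it. Refinement is single-pass; iterating it is
possible but not done by default.

The soma is annotated at 1.5 mm arclength from the synaptic ending (the
average spiral-ganglion peripheral-axon length) with a 20 µm diameter;
vertices are classified peripheral/soma/central accordingly.

## Activation analysis

The potential sampled along a fiber is low-pass filtered before
differentiation: raw lattice-sampled potentials carry element-scale kinks
that a real myelinated fiber, integrating over its length constant, would
never see. The kernel is the steady-state cable Green's function — the
unit-area two-sided exponential $g(x) = e^{-|x|/\lambda}/(2\lambda)$ — with

$$\lambda = \sqrt{\rho_m a / (2 \rho_i)}, \qquad
\rho_m = 80 \times 1\ \mathrm{k\Omega\,cm^2},\ \rho_i = 0.05\
\mathrm{k\Omega\,cm},\ a = 1\ \mu m,$$

giving $\lambda \approx 2.83$ mm. Discrete convolution uses trapezoidal
quadrature on the native (uneven) vertex spacing with per-sample kernel
renormalization, so the DC gain is exactly one and the fiber endpoints need
no special casing. Filtering is applied once to $V$, before both derivative
orders; the two-sided symmetric kernel is the natural choice for a passive
cable read-out in space.

Derivatives use the uneven-spacing finite differences natural to
polyline-sampled data: a forward difference for $V'$ (undefined at the last
node) and, at interior nodes,

$$V''_k \approx \frac{(V_{k+1}-V_k)/|r_{k,k+1}| - (V_k-V_{k-1})/|r_{k-1,k}|}{|r_{k-1,k+1}|/2},$$

where $|r|$ are inter-vertex chord distances. Undefined endpoint values are
flagged `NA`, never zero-filled — a zero second derivative is a physical
statement, not a missing value. The activating function
$f = \frac{d}{4\rho_i c} V''$ uses configurable fiber diameter and
per-length membrane capacity (defaults: $d = 2 \mu m$; $c$ from a
1 µF/cm² specific capacity divided by the 80 myelin layers). These scale
constants do not shift where $f$ peaks or changes sign, which is all the
package's comparisons use.

Decay rates fit $20\log_{10}(|V|/\max|V|)$ against lamina arclength on one
side of the stimulating contact, excluding a 1 mm near-field gap where the
profile is dominated by the contact geometry rather than the far-field
slope; the rate is reported as positive dB/mm of decline with its $R^2$ and
fit window.

Detailed-vs-simplified comparisons sample both fields at the *same* fiber
coordinates (fibers traced in the detailed variant). The relative
difference of potential is normalized by the per-fiber maximum of the
detailed potential — "RD" needs a denominator, and the per-fiber peak keeps
fibers of different depth comparable. Reported per fiber: max |RD| of $V$
in percent, the ratios of derivative extrema (detailed/simplified),
arclength segments where the second derivatives have opposite sign (exact
sign comparison by default; a relative floor is available to ignore
numerical zeros), and the convergence arclength beyond which the
second-derivative RD stays below 5 %.

## Telemetry emulation

The voltage-spread protocol records, for each stimulating contact, the
voltage at every other contact at the plateau of the anodic phase of a
biphasic pulse at 50 µA. A purely resistive model has no pulse dynamics, so
the simulated measurement is simply the spread-matrix entry at that
amplitude; pulse shape is metadata. Synthetic cohorts (default 16 ears)
apply a per-subject lognormal scale and per-entry lognormal noise, both
unit-mean with a configurable coefficient of variation (default 0.3 — the
measured spreads span a broad range across subjects, and a multiplicative
model is the natural first description of anatomy- and impedance-driven
scale differences), plus missing electrodes drawn preferentially at the
basal end of the array, where partially extracochlear contacts are
deactivated in practice. Masking is per electrode (whole row and column,
with a recorded reason), matching how clinics deactivate contacts.
Comparison statistics exclude the stimulating contact itself: the model
carries no electrode–tissue interface impedance, so self-recordings are not
comparable. Entries are diagonal-`NA` CSV matrices with a JSON sidecar;
values are written at full precision so round trips are bit-exact.

## Problem sizes and tolerances

The default study conditions used by the test suite and the acceptance
script: 0.3 mm lattice spacing (≈ 380 k elements, ≈ 70 k nodes), one 1 mA
stimulus per variant on pair 3, 400 fibers, λ = 2.83 mm. The analytic
sphere fixture uses 10 and 16 cells per half-axis; the straight-duct
fixtures use 0.2–0.4 mm spacing. Iterative tolerances do not arise — the
direct Cholesky solve is exact to machine precision, which is why the
net-current contracts are tested at 0.1 % and met at ~1e-13. Potentials are
linear in the injected current and inversely proportional to a global
conductivity scale; both are tested as exact identities.

## Known limitations

* The geometry is parametric, not anatomical; absolute potentials, fiber
  lengths and decay rates depend on the scaled-down head and the merged
  single-duct canal and should be read as qualitative.
* Staircase boundaries limit geometric fidelity to first order in the
  lattice spacing; contact patches are mesh-resolution bands rather than
  0.18 mm discs.
* No electrode–tissue interface impedance, no capacitive or dispersive
  tissue behaviour, no multi-compartment ionic cable model — the activating
  function marks candidate polarization sites; it does not predict spike
  thresholds.
* Refinement shortens straight fiber sections toward the geodesic but only
  smooths strongly curved ones; an anisotropic or unstructured remesher
  would be needed to do better.
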