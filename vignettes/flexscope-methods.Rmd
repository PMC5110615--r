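---
title: "flexscope: models, solvers and synthetic scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flexscope: models, solvers and synthetic scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

flexscope simulates a flexible endoscope as an inextensible, incompressible
Cosserat elastic rod interacting with rigid anatomy and mass–spring soft
tissue, and scores recorded runs with the standard surgical skill metrics
(task time, economy of movement, tissue forces, diathermy targeting).  This
vignette is the package's own account of the models, the numerical choices
behind them, and what the synthetic test scenes do and do not establish.

## The discrete Cosserat rod

The rod is a chain of $n$ centreline mass points $r_i \in \mathbb{R}^3$ with
a unit quaternion material frame $q_j$ *between* each pair of neighbouring
points; the frame's columns are the directors $(d_1, d_2, d_3)$, with $d_3$
nominally following the centreline tangent.  At each interior junction the
discrete Darboux vector

$$\Omega_k = \frac{2}{\ell}\,\mathrm{vec}\!\left(\bar q_k \otimes q_{k+1}\right)$$

measures the rotation rate of the frame along the rod: components 1–2 are
bending strains, component 3 the twist rate.  The elastic energy combines
bend and twist in one quadratic form plus a penalty that couples frames to
the centreline:

$$V = \sum_k \tfrac12 (\Omega_k - \Omega^0_k)^{\!\top} K\, (\Omega_k -
\Omega^0_k)\,\ell + \sum_j \tfrac12 k_c\, \lvert d_3(q_j) - t_j \rvert^2
\ell, \qquad K = \mathrm{diag}(E I_1,\, E I_2,\, G J).$$

Because a single energy couples bending and twisting, twist converts into
bend and vice versa — the looping behaviour characteristic of endoscopes in
open cavities, exercised by a regression test (a doubly clamped pre-bent rod
twisted by $4\pi$ buckles out of plane by more than 10 % of its length).

The intrinsic Darboux target $\Omega^0$ doubles as the actuation channel:
the steerable tip is commanded by writing $(\kappa_{\max} w_{ud},
\kappa_{\max} w_{lr}, 0)$ into the last `m_tip` junctions, so the unloaded
tip settles into a circular arc.  The default `m_tip = 10` with full-wheel
articulation of 210 degrees matches a standard gastroscope bending section.

**Forces and torques.** Generalized forces are the exact negative gradient of
$V$: analytic expressions are verified against central finite differences of
the energy to $10^{-5}$ relative (in practice $\sim 10^{-9}$).  The
quaternion gradient is converted to a body-frame torque by
$\tau = \tfrac12 \mathrm{vec}(\bar q \otimes (-\partial V/\partial q))$ —
the torque conjugate to a body-frame rotation, which is what the
finite-difference oracle requires.

**Frame inertia.** The frames are quasi-static carriers of orientation: the
physical rotational inertia of a thin rod element is so small that explicit
integration would demand sub-microsecond steps.  The default therefore uses
a stabilizing inertia scaled to the step, $I_{rot} = 32\,\Delta t^2\,(K_{\max}/\ell
+ k_c \ell)$, placing the stiffest rotational mode at $\omega\,\Delta t
\approx 0.25$.  Equilibria — and therefore every static benchmark — are
unaffected; only the rotational relaxation time scale is regularized.  An
explicit `rotational_inertia` can override this.

**Unit norm.** Frame quaternions are renormalized every step rather than
constrained by a penalty; norms stay within $10^{-9}$ of 1 by construction.

## The hybrid constraint solver

Each step performs:

1. a semi-implicit (symplectic Euler) prediction under gravity, elastic
   forces/torques and linear/angular velocity damping;
2. `n_iterations` sweeps of
   a. a **global** solve of the inextensibility chain: the distance
      constraints' Jacobians form a tri-diagonal system $J W J^{\top}
      \lambda = c$ (each constraint only shares points with its
      neighbours), solved all-at-once by Gaussian elimination with partial
      pivoting (LAPACK `dgtsv`), then positions corrected by $\Delta r =
      -W J^{\top} \lambda$;
   b. **local** projection of collision constraints with a Coulomb friction
      approximation, processed proximal to distal: each contacted point is
      pushed out along the contact normal by its penetration depth and its
      tangential drift since the start of the step is cancelled up to the
      friction cone $\lvert \Delta t \rvert \le \mu \lvert \Delta n \rvert$;
3. velocities rederived from the realized displacement over $\Delta t$, and
   frame quaternions renormalized.

The solver operates at the position level (a projection method).  The
hybrid architecture — global banded solve first, local contact projection
second, optionally repeated — fixes the ordering but not whether the
constraints act on velocities or positions; projection is the simpler
choice and matches the local, immediate character of the contact
treatment.
Elements joining two *prescribed* (driven) points are excluded from the
global system — their constraint is satisfied by the drive itself and its
row would be identically zero; the remaining constraints split into
independent contiguous tri-diagonal blocks because the coupling term through
a zero-inverse-mass point vanishes.

In contact-free flight two sweeps keep the relative element elongation below
$10^{-6}$ per step; an insertion experiment over 60 000 steps accumulates
axial error only through the contact projections that follow the last global
solve, which is what the compression benchmark measures.

**Base reaction.** The axial force/torque fed back to the haptic channel is
the total force the rod transmits to the prescribed base points: gravity,
elastic forces and the accumulated constraint-chain tension
$\lambda/\Delta t^2$, projected on the feed axis.  A rod hanging at
equilibrium reports its total weight to within 2 %.

**Stretch-penalty baseline.** For benchmarking, the original treatment of
centreline stretch is retained as a variant: element forces $E_s A\,
\epsilon$ along the axis replace the global solve (contact handling is
identical).  `max_stable_stretch_modulus()` finds the largest $E_s$ stable
at the scripted 1 ms step by log-space bisection over *full* insertion runs;
a run counts as unstable if the solver detects divergence, any point
velocity exceeds 0.5 m/s at the end, or any element is stretched beyond
50 %.  (Short probes were found to accept stiffnesses that only blow up at
deeper insertion; velocity alone accepted rods that had burst out of the
channel and come quietly to rest.)

## Collision detection

Triangle meshes carry an AABB bounding volume hierarchy built by recursive
median split of the face list along the longest axis of the node's box
(ties broken by face index, leaves of at most 4 faces) — fully
deterministic.  Deformable surfaces are *refitted* bottom-up without
re-partitioning.  Narrow phase is the exact point–triangle closest-point
test; rod points collide as spheres of the rod radius, one contact per
(point, mesh) at the nearest surface point, with the normal pointing from
the surface point toward the rod point (this makes two-sided walls behave
correctly without relying on winding).  BVH queries are tested for exact
agreement with exhaustive narrow-phase sweeps.  Region-of-interest
filtering keeps only meshes whose AABB intersects the sphere of remaining
insertable length around the port.  Rod self-collision is not modelled.

## Soft tissue

Deformable bodies are tetrahedral mass–spring systems: springs on the unique
tet edges with length-normalized stiffness $k_s = k_{base}/\ell_0$ and
damping $k_d = 2\zeta\sqrt{k_s m_{red}}$, node masses lumped from adjacent
tet volumes at tissue density (1000 kg/m³), semi-implicit Euler integration.
Spring forces are equal-and-opposite, so free bodies conserve linear
momentum to machine precision.  Pinned nodes copy a driver pose exactly
(grasper jaws, clips, the assistant's retraction); severing marks springs
dead (they never revive, and removing a stretched spring cannot increase the
remaining energy); connective segments accumulate diathermy exposure while
the pedal is active and the tip is within the burn radius, and die at their
threshold — every alive segment in range accumulates simultaneously, and a
frame counts as on-target if at least one was in range.

Vessels (cystic duct and artery) are spring chains with pinned ends;
"cutting between clips" severs chain springs between the two clip-pinned
nodes.  MSM parameters are stand-ins tuned for stability and plausible
behaviour, not identified against tissue data; no parameter-recovery claim
is made.

## The synthetic scenes

Nothing is downloaded: all geometry is generated programmatically from a
seed.

**Compression channel.** The rod inextensibility benchmark inserts a
256-point rod (1 mm elements, 255 mm total) into a seeded tortuous rigid
tube over a 60 s linear ramp at the 1 ms step.  The channel design is part
of the benchmark's definition and was arrived at deliberately:

* it winds in the *horizontal plane only* (alternating bends of fixed
  amplitude with seeded jitter, 5 mm bore against a 2 mm rod radius).  A
  channel that also undulates vertically superimposes a height-dependent
  axial tension ($T + \rho g z$ constant along a frictionless channel) that
  is insensitive to friction and dwarfs the mechanism of interest; in the
  planar channel gravity only presses the rod onto the tube floor, and the
  axial load comes from sliding friction and bend reactions along the
  winding path — compression aggravated by contact, which is the phenomenon
  the benchmark isolates;
* fixed-amplitude alternating bends keep the total tortuosity (hence the
  axial load) comparable across seeds, while the shape itself varies;
* the friction coefficient (0.025, lubricated sliding) sets the magnitude
  of that load and was chosen so the stretch-penalty baseline at its
  largest stable stiffness compresses by roughly 6 %, the regime the
  benchmark contrasts; the hard-constraint rod is insensitive to this
  choice and stays near $10^{-3}$ %.

At full insertion more than half of the inserted points are in wall
contact (typically ~80 %).  The same scenario, switched to the penalty
variant, is the second half of the benchmark.

**Toy abdomen.** A simplified trans-gastric scene laid out along the feed
axis: straight entry tube (oesophagus stand-in), spherical stomach chamber
with entry and viscerotomy holes, the glowing viscerotomy ring on its far
wall, and an outer cavity containing a concave liver patch, an ellipsoidal
gallbladder (programmatic tet mesh) suspended from the liver bed by eight
burnable connective segments, and the two vessel chains with two clip
markers and a cut marker each.  A keyframed "expert" control stream
completes the three procedure tasks (navigate through the ring;
clip-clip-cut each vessel; burn the segments and extract the grasped
gallbladder back through the ring plane), including one deliberate second
of off-target diathermy so the targeting metric is exercised.  The hybrid
procedure's laparoscopic retraction by an assistant is modelled as two
persistent pins on the gallbladder, released when the endoscopic grasper
takes hold.

What these scenes do **not** show: real anatomy geometry or tissue
parameters, rod–tissue two-way coupling (tissues deform through tool
interactions, while the rod treats meshes as rigid obstacles), viscerotomy
creation/closure, self-collision, or haptic-hardware behaviour.  Passing
the suite demonstrates the solver's contracts and the metric pipeline, not
clinical fidelity.

## Metrics

Runs are recorded as versioned JSON Lines trajectories (the upstream
format was an unspecified binary; JSON Lines is portable and diffable) and
replayed deterministically: identical trajectories yield byte-identical
CSV.  Per task the suite reports completion time, tip path length in cm
(economy of movement), max/mean tissue and haptic forces, max/mean
commanded shaft velocity and acceleration (central differences of the
commanded insertion signal), clip distance (mm, mean over the task's clip
events) and clip angle (degrees against the local vessel tangent, 90° is
ideal), clip/cut counts, instrument protrusion (metres), and the diathermy
summary with `pct_non_target = 100 * off / (on + off)` (0 when diathermy
was never activated).  A Mann–Whitney U test (exact permutation for groups
of ≤ 8, normal approximation with tie and continuity correction otherwise)
is provided for group comparisons of such metrics.

## Numerical choices and problem sizes

* Default solver: $\Delta t = 1$ ms, 2 sweeps, $\mu = 0.3$, distance
  tolerance $10^{-6}$ — repeats beyond the first sweep are cheap and
  optional.
* Statics benchmarks run stiff parameter sets at reduced steps
  (cantilever: 76 points at 8 µs; torsion: statics only on 201 points);
  the scene runs 100 points at 0.5 ms with 20 Hz controls; the compression
  benchmark is always the full 256-point, 60 000-step schedule.
* Degenerate inputs (coincident points, zero-area triangles, singular
  systems, malformed mesh files) raise errors rather than warnings;
  divergence detection names the offending quantity.
* All generators consume an explicit seed and restore the caller's RNG
  stream; identical state, configuration and seed give bit-identical
  trajectories.

## Known limitations

Anisotropic cross-sections, material nonlinearity and plasticity are out of
scope; the rod has no self-collision; contact is sampled at the mass points
(no continuous collision detection), so very thin obstacles require
commensurate steps; tissue acts on the rod only through markers and tools,
not through two-way contact forces; and the endoscope's mechanical
parameters are placeholders for values that would be identified empirically
against a physical instrument.
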