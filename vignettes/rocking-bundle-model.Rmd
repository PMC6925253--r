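---
title: "A coarse-grained rocking-bundle model of ion-coupled transporter gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained rocking-bundle model of ion-coupled transporter gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

LeuT-fold secondary transporters alternate between an outward-facing (OF)
and an inward-facing (IF) state, a transition well described as a rigid-body
*rocking* of one four-helix bundle against the other. A single conserved
cation site (the Na2 site) sits at the interface of the two bundles, formed
by the TM1 and TM8 helices — one from each bundle. `rockbundle` asks, on a
desk-scale model that can be simulated exhaustively: **what does occupying
an inter-bundle ion site do to the OF state and to the OF ↔ IF transition?**

The package reproduces, as testable properties of a coarse model, the three
qualitative findings reported for this transporter class:

1. ion binding stabilizes the OF conformation (smaller inter-bundle motion,
   tighter site geometry);
2. ion binding couples the motions of the two bundles (stronger
   residue-correlation network across the interface);
3. ion binding raises the effective barrier of the OF ↔ IF transition
   (reproducibly more nonequilibrium work to drive it).

It is a model study, not a fit to any particular protein: the value of the
toy is that every claim can be checked against exact references and
independent oracles.

## The model

### Geometry

`build_toy_transporter()` lays out `2H` ideal helices of C-alpha beads
(12 residues each by default; rise 0.8, wiggle radius 1.6 model units,
100°/residue) in two bundles
related by a pseudo-two-fold axis. Each bundle carries one *site helix*
close to the central axis — the TM8 analogue on the moving bundle (bundle 1)
and the TM1 analogue on the fixed bundle (bundle 2). Five ion-site beads
(an i, i+3, i+4 triplet on the TM8 analogue and an i, i+3 pair on the TM1
analogue, all facing the interface) surround the ion pseudo-particle within
3.0 model units in the OF reference. Loops between consecutive helices of a
bundle are 2 jittered particles each; they belong to no bundle but ride
with the moving bundle during the rocking so the references stay free of
steric clashes.

The IF reference is generated by rotating bundle 1 by the rocking angle
(default 25°) about a y-direction axis passing *above* the ion site (1.9
model units below the periplasmic helix ends; (0, 0, 2.5) for the default
geometry). The pivot choice matters: an axis through the site region leaves
the site inter-helix distances nearly invariant — there is then no distance
range to steer over — whereas the elevated pivot pulls the site open
(4.13 → 5.28 model units) and moves both gate radii of gyration well clear
of a 10% completion tolerance (cytoplasmic 2.99 → 4.12, periplasmic
2.17 → 1.91). Gate tags (3 beads each) are the most inward-facing residues
of the bottom (cytoplasmic) and top (periplasmic) thirds of the site
helices; by construction the rocking closes the periplasmic gate and opens
the cytoplasmic one, and the builder fails hard if that ordering is
violated. The substrate-site probe pairs live on the upper portions of the
two site helices — the toy's core, whose geometry the bound ion holds
together; pairing with the peripheral helices would probe the floppy rim
instead.

One convention to note: descriptions of this transporter family label the
bundles inconsistently. The package fixes its own convention — *bundle 1 is
the moving bundle* (carries the TM8 analogue), bundle 2 is held fixed
(carries the TM1 analogue).

### Energy model

`build_energy_model()` assembles, in reduced units (kT ≡ 1, lengths
"Å-like"):

$$V(x) = -\tfrac{1}{\beta}\ln\!\big(e^{-\beta V_{OF}(x)} + e^{-\beta V_{IF}(x)}\big) + V_{excl}(x) + V_{ion}(x)$$

* $V_{OF}, V_{IF}$: harmonic elastic networks (cutoff 8, spring constant 1)
  built on the two references, each exactly zero at its own reference. The
  cutoff sets how strongly the elastic network alone anchors the two
  bundles to each other; 8 model units leaves the interface loose enough
  that the *apo* protein genuinely wanders away from the OF reference on
  simulated timescales — the behaviour the bound-vs-apo comparisons probe —
  while each bundle stays internally rigid.
* log-sum-exp mixing with $\beta_{mix} = 2$: a smooth double-basin surface
  with a single barrier-height knob. Exponential mixing was chosen over
  eigenvalue mixing because it is simpler, smooth everywhere, and its
  gradient is a convex combination of the basin gradients. At the defaults
  the basin-to-basin strain is ≈ 50–60 kT, so unbiased runs stay in their
  starting basin on the timescales simulated here.
* $V_{excl}$: soft pairwise repulsion below 2.0 model units (stiffness 25).
  The builder guarantees a 2.2-unit clearance in the references, so both
  references are genuine minima.
* $V_{ion}$: five harmonic distance restraints (k = 200 in reduced
  energy/length², a label echoing the restraint stiffness used for this
  site in atomistic work) between the ion particle and the five site beads,
  rest lengths from the OF reference. "Ion-bound" means the ion particle is
  present with restraints active; "apo" means the particle is absent.

Because the IF geometry pulls the site apart, the restraints cannot all be
satisfied there: at the IF reference the bound model's ion term is ≈ 190 kT
with the ion still at its OF position, relaxing to ≈ 16 kT once the ion
settles into the best compromise the broken site allows. That asymmetry —
rest lengths from the OF reference, exactly as the restraint scheme
prescribes — is the mechanistic source of every bound-vs-apo contrast
below.

### Dynamics

`run_equilibrium()` and `run_steered()` integrate overdamped
(Euler–Maruyama) Langevin dynamics in compiled code. First-order dynamics
was chosen over thermostatted Newtonian MD deliberately: for a C-alpha toy
the inertial dynamics adds cost without substance, and the work bookkeeping
is integrator-agnostic. Defaults Δt = 0.002, friction 1: the stiffest terms
(the k = 200 restraints) then have kΔt/γ = 0.4, comfortably inside the
stability region, which the divergence guard (abort above 10⁸ energy, with
the offending step index) verifies at run time.

## Collective variables

`colvars` implements the four CV kinds used to monitor and drive the
transition — centroid distances, radii of gyration, RMSD after optimal
(Kabsch) superposition, and orientation angles from the quaternion
key-matrix eigenproblem (canonicalized to w ≥ 0; angles in degrees in
[0, 180]). All are pure R and are cross-checked in the tests against the
compiled engine implementations and against independent oracles
(rotation-matrix angles, brute-force centroid arithmetic). Two conventions:

* "Center of mass" means centroid: the toy has no masses, so uniform (or
  user-supplied) weights replace the backbone-atom masses a structural
  analysis would use.
* The orientation CV of a *segment* (TM1e/TM1i/TM8e/TM8i, splitting each
  helix evenly with the extra residue extracellular) is the rotation-angle
  magnitude of the optimal superposition against a reference frame. For
  steering, the reference is the OF structure and each schedule runs from 0
  to the angle that segment turns through in the IF reference. The angle
  pins how *far* a segment has rotated but not about which axis. That
  freedom is deliberate: it is what lets an orientation-only drive comply
  locally without carrying the bundle into the IF basin (the protocol
  contrast the steered suite exists to exhibit). The alternative —
  measuring the misorientation against the IF reference and driving it to
  zero, which pins the full orientation — proved so effective on this
  smooth double-basin surface that *every* protocol completed, erasing the
  distinction between good and poor CV sets.

Orientation-CV forces are analytic: first-order eigenvector perturbation
of the 4×4 key-matrix eigenproblem (a finite-difference evaluation through
the eigenproblem is retained conceptually as the reference the
gradient-check tests compare against); distance, Rg and RMSD forces are
analytic throughout. A gradient-check test compares every kind against
finite differences of the R implementations.

## Steering protocols and work

`protocol_catalog()` builds the protocol family explored for the
transition, named after the structural elements they drive:

| protocol | CVs | expected outcome |
|---|---|---|
| `d_theta` | 2 site C-alpha pair distances + 4 segment orientations | completes, least work |
| `theta_only` | the 4 orientations | does not complete reliably |
| `d_only` | the 2 distances | does not complete |
| `rmsd_18` | RMSD of both site helices to IF | drives the helices, not the gates |
| `rg_theta` | site Rg + 4 orientations | partial |

The "d" coordinate follows the site definition as *two* C-alpha pair
distances spanning the site (low pair, high pair) rather than one mean
distance: two distances at different heights pin the relative placement of
the helices, which one scalar cannot.

Bias centers move linearly over `duration` steps (default 20,000), followed
by a restrained hold at the final centers (36,000 steps — the window in
which the thermally activated basin switch happens for the ion-bound arm)
and a bias-free relaxation segment (12,000 steps) over which completion is
judged, mirroring the restrained-equilibrium-then-unrestrained verification
stages such protocols use. Force constants: 300 per distance (the drive
must out-pull the k = 200 ion restraints in the bound arm), 0.3 deg⁻² per
orientation. Work is accumulated at each center update as
$W \mathrel{+}= U(x_t, c_{t+1}) - U(x_t, c_t)$ — exact for stepwise
schedules, with no quadrature error. `recompute_work()` re-derives the
total from a stride-1 trajectory through the pure-R CVs and must agree with
the online sum to 1e-10, which ties the compiled and interpreted code paths
together.

Completion is judged from the gate radii of gyration averaged over the
unrestrained relaxation segment (falling back to the hold segment, then to
the last 10% of frames): both gates within 10% of their IF values *and*
moved in the right directions. One gate in tolerance is "partial",
mirroring how such transitions are scored. Judging on the free segment
matters for the bound arm: right after the switch the ion still holds a
strained arrangement of the broken site that relaxes only once the bias is
off. (On much longer timescales the bound IF state slowly re-compresses
the site — the ion pulling the broken site back together — which is also
why the bound transition is scored on the relaxation window rather than on
an arbitrarily long follow-up.)

`jarzynski_estimate()` ($-kT\ln\langle e^{-W/kT}\rangle$ with a bootstrap
SE) validates the bookkeeping on a dragged two-particle trap. One point of
care: a harmonic trap on a 3-D interparticle *distance* does not have a
center-independent free energy — the radial Jacobian contributes
$-2kT\ln r$ — so the tests compare the estimator against the exact
quadrature of the radial partition function (≈ −1.30 kT for the test
geometry) rather than against zero.

## Trajectory analyses

* `correlation_matrix()` aligns every frame on bundle 2 (the held-fixed
  bundle — aligning on everything would fold the rocking motion into the
  fluctuations) and normalizes displacement covariances. A `nodes` argument
  selects the particles analysed, so a static alignment anchor never
  produces the zero-variance error reserved for genuinely degenerate input.
* `contact_mask()` (cutoff 8.0, occupancy 0.75 — declared defaults, not
  inferences from any particular study) filters the network;
  `build_network()` weights edges by $-\ln|C|$, so |C| lets
  anti-correlated pairs couple too. Paths are found by a deterministic
  Dijkstra (lexicographic tie-breaks) and verified against exhaustive
  enumeration on small fixtures.
* `interbundle_coupling_score()` averages |C| over contact edges linking
  the two site helices across bundles — the quantity the bound-vs-apo
  coupling comparison reports.
* `bundle_relative_rmsd()` measures one bundle against a reference after
  fitting on the other bundle (rigid-body motion) or on itself (internal
  distortion); superposition optimality guarantees mean(self-fit) ≤
  mean(other-fit).
* `ensemble_summary()` uses Freedman–Diaconis binning, fixed so outputs
  are reproducible.

## Study conditions and problem sizes

The defaults of `default_config()` *are* the study conditions: the
2-helix-per-bundle, 12-residue-per-helix transporter (48 helix beads + 4
loop particles + ion), 25° rocking, 150,000-step equilibrium runs per
condition, and 10 seed-paired steered replicas per condition for the work
comparison (paired seeds for variance reduction; one-sided paired Wilcoxon
at 0.05, which turns "reproducibly lower" into an assertable claim). These
sizes give stable contrasts on a single CPU in minutes. The geometric and
energetic constants were settled during model construction — the pivot
placement, cutoff and helix length jointly determine whether the
architecture expresses the ion-coupling phenomenology at all (a pivot
through the site gives the ion no leverage; a stiffer interface never
wanders) — and were frozen before the acceptance properties were asserted.

## What the toy does and does not show

The generator emulates the *statistical structure* of the real problem: two
quasi-rigid bundles, an ion site built on OF geometry that breaks along the
transition, gates whose compactness reports the state. Passing tests
therefore show that the analysis machinery measures what it claims and that
the qualitative ion-coupling logic follows from that architecture. They do
not show anything about absolute energetics: work values are in kT of a
reduced model and are comparable only within the toy (atomistic kcal/mol
magnitudes are out of scope by design); there is no membrane, solvent,
side-chain packing, or substrate; and the ion restraints are permanent, so
spontaneous unbinding events are outside the model. The toy's basins are
harmonic networks — anharmonic effects appear only through the basin mixing
and excluded volume.

## Known limitations

* Orientation-angle bias forces are finite-difference; near 0° and 180° the
  angle is non-smooth, which the schedules avoid by never resting at
  exactly 0 with a large force constant.
* The steered "completes in all replicas" behaviour of `d_theta` is a
  property of the default conditions; much stiffer or softer force
  constants change the verdict table, as force-constant tuning does in any
  steered-simulation study. The basin switch in the bound arm is thermally
  activated during the hold, so a drastically shortened hold turns
  completions into partials.
* The apo transition at these conditions costs almost no work (its barrier
  is near-thermal once the interface is loose enough to wander); the
  bound-vs-apo work comparison is therefore dominated by the ion term, by
  design.
* `run_protocol_suite()` records per-replica failures rather than
  aborting, but makes no attempt to re-seed failed replicas.
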