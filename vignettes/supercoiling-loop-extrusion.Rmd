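---
title: "Supercoiling-driven loop extrusion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supercoiling-driven loop extrusion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(supercoilex)
```

# The physical model

`supercoilex` simulates a TAD-sized 10-nm chromatin fibre as a twistable
worm-like chain and asks whether transcription-generated supercoiling can
drive cohesin-handcuff loop extrusion. The fibre is a closed ring of beads,
one bead per σ = 10 nm ≈ 400 bp (the default system, 300 beads, is a
120-kb domain). Energy terms, in reduced units (length σ, energy kT):

* **Bonds**: finitely extensible (FENE) springs centred at l₀ = 1 σ with
  extensibility limit r_max = 1.5 σ and stiffness k = 200 kT/σ². The
  centred form keeps the energy minimum exactly at l₀; the stiffness is
  chosen so the divergent walls sit five thermal standard deviations from
  the mean and bonds cannot cross (mean bond length stays within 2% of
  1 σ — a tested invariant).
* **Bending**: harmonic in the joint angle, k_b = kT·L_p/l₀ with
  L_p = 50 nm, the persistence length of the 10-nm fibre. The discrete-WLC
  expectation for this stiffness is ⟨cos θ⟩ = 0.824, i.e. an effective
  L_p of ≈ 52 nm; the dynamics recovers ≈ 48–53 nm depending on the
  replica seeds (tested at 50 ± 10%).
* **Twist**: each bond carries a material angle θ_b measured against a
  reference director that is parallel-transported in time; the joint twist
  φ_j = θ_j − θ_{j−1} + m_j (m_j the reference twist of the bent backbone)
  enters E = Σ C/(2l₀)(φ_j − φ₀_j)² with C = kT·L_t, L_t = 75 nm — the
  torsional persistence length used for supercoiled DNA, appropriate for
  fibres receiving fresh negative supercoiling (a tenfold lower value is
  the `supp_low_twist` sensitivity scenario). With this bookkeeping the
  discrete Călugăreanu–White identity Lk = Tw + Wr holds exactly for the
  polygonal curve, and its conservation over 10⁵-step trajectories (drift
  < 0.05 turns) is the package's sharpest correctness test: it exercises
  the frame transport, the twist forces and the Gauss-sum writhe together.
* **Twist–bend coupling**: the gradient of the reference twist with
  respect to bead positions (curvature-binormal form) converts torsional
  stress into writhe. Its sign and magnitude are pinned by a
  zero-temperature test: a uniformly overtwisted ring must relax downhill
  in energy by writhing with the handedness of its linking difference.
* **Excluded volume**: WCA repulsion with per-pair contact distance equal
  to the sum of bead radii; fibre–fibre pairs with a bead in a phantom
  region are exempt (strand passage).

## Topoisomerase and transcription emulation

Transcription is represented topologically. An *active swivel* advances
the intrinsic twist offset φ₀ of its joint at a set rate (turns per τ),
forcing the flanking segments to rotate against each other — the combined
action of RNA polymerase and the TOP1 ahead of it, which leaves net
negative supercoiling behind. Count-exact bookkeeping (the injected_R
counter) makes ΔLk accounting verifiable: |Δ(Tw+Wr)| equals the counter to
within 0.05 turns. With the `barrier` flag the joint transmits no twist
and drives only its lower-index flank — a continuously transcribing
polymerase acting as a topological barrier, which produces hemi-coiled
plectonemes (one flank supercoiled, the other torsionally silent).

TAD borders carry a *passive swivel* (zero twist stiffness: free local
relaxation, the nucleosome-scale action of TOP2B) flanked by a 3-bead
*phantom region* (no fibre–fibre excluded volume: intersegmental passage).
Passage events are detected post hoc as ±2-turn jumps of the
linking-number deficit.

## The cohesin handcuff

Two 15-bead rings sharing one bead (29 beads total), bead diameter 1 σ on
a centre-line circle of diameter 3.5 σ: external diameter 45 nm, mean
inner aperture 25 nm — wide enough for one 10-nm fibre, too narrow for the
35-nm CTCF obstacle. Rigidity is maintained by a harmonic restraint
network (neighbours, second neighbours, diametric partners, shared bead,
and an all-pairs frame across both rings; k = 60 kT/σ²) plus weak dihedral
restraints (0.5 kT/rad²) biasing the figure-eight towards planarity. Under
thermal motion the ring diameters hold their tolerances (outer 45 nm ± 5%,
aperture 25 nm ± 10%, both tested), while the figure-eight as a whole
fluctuates with a superposition RMSD of ≈ 0.3 σ, most of it the hinge
between the two rings. That compliance is deliberate: enforcing strict
coplanarity with stiff dihedrals makes the pinched loop at the handcuff
throat so expensive that, in simulations, the loop is expelled and the
handcuff translocates along the fibre instead of extruding; with the
compliant hinge the rings splay slightly and the growing plectoneme pushes
them apart as intended — a stiffness scan showed no value that keeps the
whole figure rigid below 0.2 σ and still extrudes. Construction numbers
(29/15/1 beads, 45/25 nm) are exact.

Threading is detected geometrically (fibre bead nearest the ring centre,
inside the 1.25 σ aperture radius and within ±1 σ of the ring plane, ties
to the lowest index); the conduction block is smeared over ±2 beads around
the detected bead so that frame-to-frame flicker of the nearest-bead choice
cannot open the joint. Threaded beads carry 10× translational drag and cohesin
beads 2×, the paper-level drag rules. One mapping decision is ours: in a
scalar-twist representation, fibre axial rotation is an internal
coordinate that excluded volume cannot touch, so the steric blocking of
crankshaft rotation by a tight ring — the physical reason a handcuff
limits axial rotation of the enclosed chromatin — is imposed directly as
a large rotational-drag factor (default 1000×) on the bonds at a threaded
bead. Without it, twist conduction simply drains the injected supercoiling
through two 10× joints out of ~75, and no localization or pushing occurs;
with it, supercoiling accumulates between the rings, which is the
mechanism under study. The factor is configurable
(`threaded_rot_block`).

## CTCF rule

A CTCF site is a 3.5 σ obstacle bead tethered concentrically to a border
bead. When a ring centre comes within `contact_dist` (3.5 σ): convergent
orientation anchors the ring (three tethers to the obstacle at their
current lengths) — one ring per CTCF site, since one exposed C-terminus
makes one contact; divergent orientation dissociates the whole handcuff
after `dwell` (5 τ) of continuous contact, removing all its restraints,
excluded volume and drag couplings.

# Dynamics and numerical choices

Overdamped Euler–Maruyama: positions move by F·dt/γ plus Gaussian noise
of variance 2kT·dt/γ per coordinate with γ the bead's effective drag;
material angles likewise against γ_r (default 0.33 kT·τ, the no-slip
cylinder estimate for a 10-nm fibre segment). Defaults: dt = 5×10⁻⁴ τ —
chosen so the radius at which the FENE wall's local stiffness exceeds the
explicit scheme's 2γ/dt stability bound is thermally unreachable (≈ 25 kT)
— with a per-step deterministic-displacement cap of 0.05 σ as a backstop
inside divergent walls (inactive at moderate forces); neighbour list with
1.5 σ skin rebuilt every 20 steps; threading/CTCF bookkeeping every 20
steps; bond over-extension aborts the run with a diagnostic rather than
propagating a corrupted topology.

The swivel rate default is 0.005 turns/τ for the 300-bead system: slow
enough that writhe conversion (measured relaxation ≈ 1–2 turns per 500 τ
at this size) keeps pace with injection, so the fibre responds
quasi-statically as in the depicted experiments. Scaled 150-bead versions
of the mechanism scenarios — used by the test suite so each run stays in
the minutes range — double the rate to 0.01 turns/τ, matching the ~4×
faster relaxation of the half-size system, and run to injected counts of
5–35 rotations depending on the scenario. Problem sizes used by the tests:
100-bead linear fibres for persistence-length recovery (4–8 replicas ×
2.5×10⁵ steps), 150-bead TADs for the mechanism properties, the full
300-bead system for the acceptance computation of the injection
experiment.

Initial states are built deterministically: fibres as exact rings or rods,
handcuff threading as a pinched double-lobe configuration (the enclosed
arc bulges as one near-circular lobe, the rest as the other, tilted
.18 rad apart), followed by a short zero-temperature settle that removes
construction overlaps. For equilibrium measurements the linear fibre can
instead be drawn directly from the discrete-WLC Boltzmann distribution
(`sample_thermal_fiber()`), avoiding the ~340 τ relaxation of a straight
rod.

# What the scenarios emulate — and what they do not

The scenario generator reproduces the study conditions: a circular 120-kb
domain whose two borders (diametrically opposite beads, passive swivel +
phantom cluster each) delimit the TAD arc containing the supercoil source;
a handcuff threaded around the source; optionally CTCF obstacles. Two
further loading details reflect the biology of the initial state. First,
the transcription machinery at the swivel is itself represented as a
neutral 30-nm obstacle: rings cannot slide past the polymerase, so the
handcuff cannot lose its supercoil source to an early fluctuation (without
this, runs are bistable — in roughly half of them the unpressurized loop
slips off the source and extrusion never starts). Second, handcuffs load
at a crossing made by transcription-induced supercoiling, so the nascent
loop starts with two turns of negative twist (`preload_turns`),
compensated in the outer arc so the total linking number is untouched. The
fibre is generic — no sequence, no nucleosome-scale structure, no
chromatin-state heterogeneity; CTCF sites are only orientation flags; and
cohesin loading/unloading kinetics beyond the orientation rule are out of
scope. Passing mechanism tests therefore demonstrate the physical
mechanism (supercoiling accumulates between rings, plectonemes push rings
to borders, orientation decides loop stability) in this idealized setting,
not quantitative agreement with experimental Hi-C of real chromosomes.

Two observations from the simulations are worth knowing when reading
outputs. First, the nascent loop initially shrinks for a few hundred τ —
loop-closure entropy favours eliminating the smaller lobe — until enough
torsional stress accumulates to buckle and push; the monotone-growth
property is therefore asserted from the post-collapse minimum onward.
Second, the loop-extent observable (contour distance between threaded
beads through the arc containing the swivel) flips to the complementary
arc in frames where both rings sit momentarily on the same side of the
source; time-series measures fold extents at half the fibre length.
Third, in the CTCF-free extrusion scenario nothing holds the rings at the
borders after they arrive, so "the loop grows to the whole TAD" is
asserted on the maximum of the smoothed extent (the arrival), and the
supercoiling-localization fraction is writhe-weighted and measured before
border arrival, where border topoisomerase activity legitimately relaxes
whatever reaches it.

# Known limitations

* Twist noise and transport are exact for the scalar-angle representation,
  but steric coupling between axial rotation and excluded volume does not
  emerge and is imposed through the threaded-joint rotational block.
* The explicit integrator slightly inflates stiff-mode variances (a few
  per cent on bond lengths; the recovered persistence length runs ≈ 5–8%
  below the discrete-WLC expectation).
* Phantom-region passages make linking number genuinely non-conserved at
  borders (that is their purpose); the `lk_deficit` diagnostic therefore
  reports dissipation, not error, in bordered scenarios.
* Writhe relaxation is slow at full size: the 300-bead figure experiments
  are minutes-long; the tests use the sanctioned 150-bead scaled systems.
* The divergent-CTCF scenario removes the handcuff entirely on
  dissociation; re-loading of fresh handcuffs is not modelled.
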