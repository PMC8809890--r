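---
title: "A reduced model of proton-transfer-coupled c-ring rotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced model of proton-transfer-coupled c-ring rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonmotor)
```

## The system and the question

The membrane-embedded F~o~ motor of ATP synthase converts a transmembrane
electrochemical proton gradient into rotation of its c-ring.  Each of the
ten c-subunits carries one essential carboxylate (a glutamate in most
bacteria and in yeast mitochondria) that picks up a proton from the
positively charged, acidic side (IMS/periplasm) through one half-channel of
the stator a-subunit, carries it almost a full turn through the lipid, and
releases it into the other half-channel toward the matrix.  An essential
arginine between the two half-channels prevents direct proton leakage.
Glutamate-to-aspartate substitution at the proton-carrying site shortens the
side chain by one methylene group and lowers its pKa; constructs carrying
one or two such substitutions in a genetically fused ring slow ATP synthesis
the more the two mutated subunits are separated, which suggests that
neighbouring subunits cooperate.  `protonmotor` implements a reduced model
of this machine to ask how such cooperation arises from the kinetics of
proton exchange.

## The reduced model

The package deliberately replaces the full protein with a rigid planar
rotor: ten protonatable sites on a circle of radius 2.5 nm, a stator with
the two relay carboxylates (aE162 toward the matrix at −36°, aE223 toward
the IMS at +36°) and the gate arginine aR176 (at 0°, defining the x-axis)
on a circle of radius 3.3 nm, and a single rotational degree of freedom
φ.  All observables treated here — rotation, proton flux, stage
durations, duration sharing — live on this coordinate.  The radii make the
aligned site–relay distance 0.8 nm, equal to the glutamate transfer offset
distance, so the distance factor reaches its cap exactly at closest
approach.

The total energy is a sum of four terms:

* **Screened Coulomb**, `q_i q_j B exp(-d/λ_D)/d` over deprotonated
  carboxylates (−1) and the arginine (+1), with `B = 2 kT·nm`,
  `λ_D = 1 nm` and a 0.3 nm distance floor.  The functional form and
  strength of the electrostatics in the antecedent atomistic treatment are
  not published; these are declared assumptions of this package, sized so
  that the arginine–carboxylate attraction is a ~1 kT well.
* **Membrane burial penalty**: each deprotonated c-site outside the ±72°
  a-facing window pays `eps_mem = 8 kT` (the membrane forbids buried
  charge in practice while keeping Monte Carlo moves ergodic).  The window
  edge is smoothed over 2° so the torque exists everywhere.
* **Protonation free energy**: site occupancy carries
  `ln(10)·(pH_ref − pKa) kT` plus the electrostatic work of moving a
  proton from the reservoir to the site's depth.  Half of the 150 mV
  potential is dropped between either bulk and the ring level
  (`psi_fraction_at_ring = 0.5`); the true profile across the
  half-channels is unknown and this is a declared assumption.  At the
  defaults the full driving force is
  `ln(10)·ΔpH + eΔψ = 2.30 + 5.84 = 8.14 kT` per proton.
* An optional smooth periodic **background** term standing in for all
  non-electrostatic protein energetics; identically zero by default.

## Proton moves and the hybrid cycle

Each round consists of one Metropolis sweep over all proton channels
followed by a block of overdamped Langevin steps of φ (production profile:
6000 rounds × 10^5 steps, 60,000 saved frames).  Channels are the ten
c-site ↔ aE162 and ten c-site ↔ aE223 pairs plus the two reservoir
exchanges (IMS ↔ aE223, aE162 ↔ matrix); there are no direct c-site ↔
c-site hops.  A channel is attempted with probability

`w = f(r) · g(θ) · h(R176)`

with `f(r) = min(1, exp(-A(r − r0)))`, a Gaussian orientation factor
`g(θ)` (center 0°, width 30°; the structural values behind this factor are
not published, and the width is chosen to confine transfer to roughly ±15°
of alignment), and a hard gate `h` that allows matrix-relay exchange only
on the matrix side of the arginine and IMS-relay exchange only on the IMS
side.  `w` is evaluated identically for both directions of a pair and the
move is accepted with `min(1, exp(-ΔV))`, so detailed balance holds and a
gradient-free system (pH 7/7, 0 mV) shows no net flux or rotation — both
are tested.

Wild-type sites use `A = 2.5 /nm`, `r0 = 0.8 nm`, `pKa = 8.0`; aspartate
sites use `A = 9.0 /nm`, `r0 = 0.6 nm`, `pKa = 7.0` (shorter side chain,
no reorientation toward the relay, intrinsically lower and less upshifted
pKa).  The sensitivity variants `A = 2.5` and `pKa = 7.8` for aspartate are
plain overrides.

**Relay pKa.** The pKa of the two relay glutamates is not published for
the antecedent model.  This package sets both to 8.0, equal to the c-site
glutamate: buried carboxylates at this interface are pKa-upshifted (the
structure-based estimates shipped in `table3_fixture()` reach 8.03), and
matching donor and acceptor makes every c-site ↔ relay hop thermoneutral,
so the relays neither trap protons nor interpose a chemical barrier.  With
a barrier there (e.g. relay pKa 7.0, a +2.3 kT release step), the ring
frequently passes a protonated site through the window without releasing
it, and the strict 10-protons-per-turn stoichiometry of the machine is
lost.  The choice is a model decision made on these grounds; both values
remain configurable (`pKa_aE223`, `pKa_aE162`).

## Why the motor turns, and why it is tightly coupled

A deprotonated site cannot leave the ±72° window (8 kT wall), so it
ratchets the ring; it is also weakly attracted to the arginine.  Release is
only possible left of the arginine and uptake only right of it, and both
are thermodynamically downhill only in the forward order (IMS → aE223 →
site → aE162 → matrix dissipates 8.14 kT).  In steady rotation two or
three window-facing sites are deprotonated at a time; each 36° advance is
one release plus one uptake, giving ten matrix-delivered protons per full
turn.  `net_proton_count()` reports *net* reservoir fluxes (forward minus
reverse successes) because equilibrium back-exchange at the relays —
perfectly legitimate microscopically — would otherwise inflate the gross
counts by a few protons per thousand rounds without any rotation.

## Time scales and the desk profile

The model has no absolute clock (the antecedent MD step is not mapped to
physical time); everything is reported in MD steps and frames.  `D_rot`
and `dt` are calibrated so that a production-profile wild-type run covers
a few net turns: the default `D_rot·dt` gives ~3° of free angular
diffusion per round, and a 36° step costs a few hundred rounds of
diffusion plus the Monte Carlo waits.  The `"desk"` profile (1000 rounds ×
10^4 steps) multiplies `dt` by 100 so that a wild-type run still covers
~3–5 net turns in about two seconds of computation; all tests and the
examples below use it.  For stoichiometry checks the package uses a longer
desk ensemble (3000 rounds, ≥10 net turns per run, seeds 1–5) because the
protons-per-turn ratio converges as 1/turns; this is the problem size used
by the acceptance script.

Numerical details: Euler–Maruyama integration with per-step angular noise
≈ 0.1°, far below the 2° membrane edge smoothing, so the wall is resolved;
a fresh random channel permutation each sweep avoids order bias; all
randomness flows through R's RNG so a seed fixes the full trajectory
bit-for-bit.  The initial state protonates everything except c-sites
strictly between the relays and is configurable; relaxation from an
all-protonated start is tested.

## Trajectory observables

* **Velocity** uses the last time the cumulative angle equals a multiple
  of 360° (linear interpolation between frames); partial turns of an
  asymmetric mutant ring would otherwise bias the estimate.  Runs that
  never complete a turn report an undefined velocity and are excluded
  (with a count) from ensemble summaries.
* **Stage durations** per subunit and transport cycle: release (first
  c→aE162 trial to its success), deprotonated rotation (release success to
  first aE223→c trial — "arrival at the uptake angle" is operationalized
  by the first admissible uptake attempt, keeping all three boundaries
  event-defined), uptake (first trial to success), and resting.  Transient
  re-protonation from the matrix relay before any uptake trial restarts
  the release clock at the release that finally sticks.
* **Duration sharing**: the overlap of two subunits' uptake-stage interval
  sets, normalized by the smaller total (symmetric and scale-free, in
  [0, 1]).

In wild-type desk runs the mean stages are a few hundred frames of release
and deprotonated rotation and a few frames of uptake, uniform across
subunits.  An aspartate site inverts this: its uptake stage grows by
orders of magnitude (small `f(r)` cap of 0.165, +2.3 kT uptake step), the
ring stalls with the mutated site at the IMS relay, and in the adjacent
double mutant the two prolonged uptake waits overlap — the mechanism by
which neighbouring mutations hurt less than distant ones.

## The biochemical pipeline and its generators

The data-reduction functions mirror a luciferase/ACMA bench workflow:
baseline-subtracted synthesis slope (90 s before / 50 s after the NADH
addition), four-step ATP calibration (5 s windows, 20 s spacing), specific
activity with first-order error propagation, LDAO expression
normalization, ACMA quench at 3 min against the post-FCCP plateau, DCCD
sensitivity, pooled two-sample t-tests from printed summary statistics
(the printed "±" values are treated as standard deviations — the choice
that reproduces the reported p-values given the replicate counts; figure
error bars are standard errors), and the distance–activity regression.
P-values are two-sided throughout; no multiplicity adjustment is applied
because the reference analysis reports raw pairwise p-values.

The synthetic generators produce Gaussian activity replicates (lognormal
optional) at the reference means/SDs/counts, piecewise-linear luminescence
traces, exponential ACMA quench/recovery traces, and scripted event logs.
They emulate the *arithmetic structure* of the instrument records — known
slopes, step heights and quench depths under Gaussian noise — not
instrument artifacts (photobleaching, mixing dead time, drift), so passing
recovery tests demonstrates correctness of the reduction pipeline, not
robustness to real-instrument pathology.

```{r, eval = FALSE}
tr <- run_trajectory(fo_sim_config(profile = "desk", seed = 1))
summary(tr)
plot(tr)
ens <- run_ensemble(fo_sim_config(profile = "desk", seed = 1, mutant = "ef"),
                    n_replicates = 10)
ensemble_summary(ens, overlap_pair = c("e", "f"))
```

## Known limitations

The rigid one-coordinate rotor has no internal protein elasticity, no
lipid or F~1~/b-subunit coupling, and no absolute time scale, so absolute
stage durations and velocities are not comparable to atomistic results —
only their ratios, orderings and stoichiometries are meaningful.  The
electrostatic constants, the membrane penalty, the potential profile
across the half-channels, the orientation-factor width and the relay pKa
are declared assumptions where the antecedent literature is silent; each
is a single configurable parameter.  Mutant activity percentages from
bench assays are not reproduced quantitatively by this reduced model and
are covered instead by the ordering and sharing properties above.
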