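---
title: "Methods: quantifying the ion atmosphere around nucleic acid duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the ion atmosphere around nucleic acid duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionscape)
```

## The problem

Nucleic acid duplexes are polyanions: a 12-bp duplex with 22 phosphate
groups carries a net formal charge of −22 e, and its solution structure is
inseparable from the cloud of mobile counterions (Na⁺, K⁺, Mg²⁺) and
co-ions (Cl⁻) that screens it.  Molecular-dynamics trajectories resolve
this ion atmosphere in full spatial and temporal detail, but extracting
interpretable numbers from them requires a consistent set of estimators:
where the ions sit (distribution functions), how completely they
neutralize the duplex (charge accumulation), which atoms hold them
(occupancy), for how long (residence times), and how mobile they remain
(diffusion coefficients).  `ionscape` implements that analysis stack for
B-DNA, A-RNA and the left-handed Z-DNA/Z-RNA forms of CG-alternating
duplexes, together with synthetic generators that make every estimator
testable by parameter recovery.

All distances are in Å, times in ps (residence times reported in ns),
concentrations in mol/L, occupancies in percent.  Boxes are orthorhombic;
all pair distances use the minimum-image convention.

## Coordinate frame: the helical axis

Cylindrical statistics need an axis.  Each base pair contributes a
reference center: per strand, the midpoint of C1′ and a base reference
nitrogen — N9 for purines and, following the literal axis convention, N4
for cytosines (`pyrimidine_ref = "N4"`); the glycosidic alternative N1 is
available as `pyrimidine_ref = "N1"`.  The pair center is the midpoint of
the two strand points, and the global axis of a frame is the
total-least-squares line (first principal component) through the pair
centers.  Curvature is deliberately not modeled: bent frames still receive
a straight global axis, and the largest center-to-line distance is
reported as a bend diagnostic (`max_residual`).

The two conventions differ geometrically.  The glycosidic (N1) reference
is symmetric under the pair dyad, so for the ideal synthetic builds the N1
centers are exactly collinear and all phosphorus atoms sit at a constant
cylindrical radius; the N4 reference displaces each center ~0.9 Å toward
the major groove, which for an alternating CG duplex traces a narrow helix
around the true axis (visible as `max_residual` ≈ 1.2 Å on an ideal
build).  Geometric regression tests therefore use N1; the user-facing
default remains the literal N4 convention.

## Distribution estimators

**Cylindrical distribution function (CDF).**  Ion concentration in
cylindrical shells of width `dr` (default 0.5 Å) around the axis,

$$c(r) = \frac{\langle n(r, r + \Delta r) \rangle}{N_A \, \pi (r_2^2 - r_1^2) \, h},$$

in mol/L.  The axial height *h* defaults to the fitted axial extent of the
duplex (ions beyond the duplex ends are excluded); `axial = "box"` uses
the full box height instead — the choice matters for far-field values and
both are supported because either reading is defensible.  Profiles should
extend to ≥ 30 Å, which is why a box of ~82 Å is the natural simulation
setting; a radius beyond half the smallest box edge is recorded as a
warning in the result rather than an error.  The binned profile integrates
exactly to the mean in-cylinder ion count (a conservation identity the
tests check to 10⁻⁹ relative).

**Radial distribution function.**  For a set of site atoms,

$$g(r) = \frac{\langle n_{\text{pairs}}(r, r + \Delta r)\rangle}
{n_{\text{sites}} \, \rho_{\text{bulk}} \, \tfrac{4}{3}\pi (r_2^3 - r_1^3)},$$

with ρ_bulk taken from the whole-box species count — parameter-free and
consistent with profiles that decay to the bulk concentration, as opposed
to a fitted far-field plateau.  Default bin width 0.1 Å resolves the
~0.1 Å peak shifts that distinguish binding modes (first-shell contact at
~2.3–2.4 Å for Na⁺, water-mediated binding near 4.5 Å, hexahydrated Mg²⁺
at ~4.1 Å).

`first_peak()` reports the highest bin of the first contiguous
above-threshold run (default threshold 1.5 on g); a maximum in the very
first bin has no rising flank and is classified "no peak" — this makes the
locator robust to bin noise on a rising edge while keeping "first, not
tallest" semantics.  `coordination_number()` integrates ρ_bulk·g over
spherical shells and equals direct neighbor counting by construction.

**Charge accumulation.**  The cumulative ionic charge (counterions plus
co-ions) within cylindrical radius r, normalized by |net duplex charge|
(22 e for the dodecamer).  Ion formal charges come from the species label;
a species without a defined charge is an error rather than a silent zero.

**Per-bin uncertainty** for all binned estimators is the standard error
over frame-block means (default block 1 ns) because consecutive frames are
autocorrelated; with a single block the error is reported as `NA`.

## Occupancy and residence kinetics

A site (atom or region group) is *occupied* when at least one ion of the
species is within the cutoff of at least one member atom.  Direct cutoffs
default to 3.0 Å (Na⁺), 3.5 Å (K⁺) and 5.0 Å (hexahydrated Mg²⁺), with
6.0 Å for water-mediated binding; all overridable.  Occupancy is 100 ×
mean of the binary trace.  Group (region) occupancy is the union over
member atoms — the only aggregation consistent with "at least one ion
bound", and an ion near two atoms contributes to both sites.  Because the
6 Å criterion is implied by the 3 Å one, occupancy at 6 Å ≥ occupancy at
3 Å always — asserted as a property test on every synthetic run.  The
default analysis window discards the leading 1/6 of a trajectory (the
data-collection convention for 120 ns runs analysed over their last
100 ns).  Sequence tables report the second strand 5′→3′, i.e. reversed
spatial order, so converged distributions show mirror symmetry between
strand blocks.

**Residence time.**  The occupancy autocorrelation is computed on a lag
grid of 10 ps to 1 ns in 10 ps steps,

$$C(t) = \langle p(t_0)\, p(t_0 + t) \rangle_{t_0} / C(0),$$

averaging over all valid origins (this removes the trivial (T−t)/T edge
factor a raw double sum would carry; the normalization is immaterial once
C is divided by C(0)).  τ_R comes from a weighted log-linear least-squares
fit.  Two refinements matter and are the package's own documented choices:

1. *Plateau subtraction.*  For a stationary occupancy trace C(t)/C(0)
   decays to the mean occupancy ⟨p⟩, not to zero, and with rate
   k_on + k_off rather than k_off.  Fitting the raw curve therefore
   overestimates τ_R at any appreciable occupancy.  By default the trace
   mean is subtracted before the fit and the fitted rate is rescaled by
   (1 − ⟨p⟩), which makes τ_R estimate the mean bound duration 1/k_off
   *exactly* for a two-state Markov process at any occupancy.
   `plateau = "none"` restores the literal reading.
2. *Fit restriction.*  Lags where the subtracted correlation has decayed
   below 20% of its first-lag value carry no kinetic signal; including
   them (even down-weighted) produced a systematic +13–20% bias at
   τ\* = 0.25 ns in recovery studies.  The frozen estimator fits only the
   initial decay, weighted by the subtracted correlation.  Re-estimated
   over four disjoint 20-seed batches at τ\* ∈ {0.25, 0.5, 2, 8} ns, all
   batch medians fell within ±7% of truth.

Censoring: when C(lag_max)/C(0) > 0.9 no decay is resolvable on the grid
and the result is flagged instead of fitted.  Note that for τ\* = 8 ns
and a 1 ns lag grid the expected terminal ratio is ≈ 0.885 for *any*
on/off rate ratio, so occasional censoring there reflects the grid, not
the estimator.

**Binding distances** average, over frames with at least one bound ion,
the distance of the nearest bound ion (default window: the trailing 10 ns
equivalent).  Frames without a bound ion are excluded; a site never bound
in the window yields an `undefined` flag, not an error.

**Pockets ("ion traps").**  A pocket is a maximal run of frames in which
one ion stays within the direct cutoff of ≥ `min_sites` duplex O/N atoms
simultaneously; the reported member set is the intersection over the run,
so membership implies per-frame occupancy of every member.  This captures
the four-atom C-O2/C-O2′ trap geometry characteristic of Z-RNA minor
grooves as well as O6/N4 major-groove bridges.

## Conformational descriptors

χ is the O4′–C1′–N9–C4 (purine) / O4′–C1′–N1–C2 (pyrimidine) torsion,
classified anti for χ ∈ (−180°, −90°] ∪ (90°, 180°], syn otherwise, with
a configurable ±10° intermediate band around the boundaries.  Sugar pucker
uses the pseudorotation treatment of the five endocyclic torsions: phase P
(36° sectors name the conformers, C3′-endo at P ≈ 18°, C2′-endo at
P ≈ 162°) and amplitude τ_m; amplitudes below 1° are flagged undefined
rather than classified.  `ring_from_pucker()` inverts the estimator
numerically (two puckering degrees of freedom solved against the estimator
itself), so generation → estimation round-trips to well under 0.5°, which
the tests assert over a grid of phases.

## Diffusion

Einstein estimator on unwrapped coordinates: MSD over all time origins,
D = slope/6 over a fit window of [10%, 50%] of the maximum lag — late
enough to avoid short-time artifacts, early enough to keep origin
statistics.  Because a straight line fitted to a parabola over that window
still yields a high R², the non-diffusive flag is based on the log–log
slope α of the MSD (|α − 1| > 0.3 flags the fit; ballistic motion gives
α = 2).  Unwrapping requires per-step displacements below 0.45 box per
axis — from wrapped input a jump of half a box is mathematically
undetectable, so the guard is a practical proxy that errors with a
suggestion to sample finer.  A distance-from-duplex filter for "bulk"
ions is deliberately not applied by default.

## The synthetic world

The generators stand in for undeposited MD trajectories; their defaults
*are* the stated experimental regime, chosen once:

* **Duplex builder** — (CG)₆ dodecamer by default, any even-length
  alternating CG sequence; B (twist +36°, rise 3.38 Å), A (+32.7°,
  2.81 Å), Z (−9°/−51° alternating, rise 3.7 Å); χ: B −112°, A −160°,
  Z-G +60° (syn), Z-C −150°; pucker: B C2′-endo, A C3′-endo, Z C3′-endo-G
  / C2′-endo-C; amplitude 38°.  Bases are fused regular polygons, sugars
  are generated from the pseudorotation target, backbones placed by
  internal coordinates, pairs propagated rigidly along z in an 82 Å box.
  The build guarantees topology (24 residues, 22 phosphates, −22 e),
  handedness, χ/pucker classes, O2′ presence for RNA and approximate
  groove geometry — *not* crystallographic accuracy, base-pair
  propeller/buckle, backbone continuity across steps (each residue carries
  its own idealized phosphate), or sequence generality beyond C/G.
* **Telegraph simulator** — alternating exponential unbound/bound
  durations (rates k_on, k_off), bound positions jittered σ = 0.5 Å about
  the site and truncated at the direct cutoff, unbound positions uniform
  outside it, so the ground-truth event list and the distance criterion
  agree frame-for-frame (an identity the tests assert).  Recovery studies
  use k_on = k_off — 50% occupancy, matching the strongly occupied
  left-handed-form sites — and traces of 200 τ\*, giving ~100 bound
  episodes per trace; shorter traces leave the 20-seed median too noisy to
  certify a 10% recovery bound.
* **Brownian simulator** — overdamped Euler–Maruyama, per-axis step
  σ = √(2 D Δt), optional Gaussian wells (U in kT, drift −D ∇U Δt).
* **Hydration-shell sampler** — n_shell first-shell "water oxygens" at
  Gaussian(d₀, σ) radii (defaults d₀ = 2.43 Å, the measured Na⁺–water
  first-shell distance; σ = 0.05 Å), pairwise overlaps < 2 Å rejected,
  bulk points at water density 0.0334 Å⁻³ outside 1.5 d₀.

A green test against these generators establishes estimator correctness —
counting, normalization, kinetic recovery — under known ground truth.  It
does *not* establish force-field realism: the generators have no
water structure beyond the first shell, no ion–ion correlations, no
sequence-dependent elasticity, and the duplex never moves.  Conclusions
about real ion atmospheres still require real trajectories; the package's
claim is that, given such trajectories, its numbers mean what they say.

## Numerical choices and degenerate inputs

Atom names are normalized across PDB dialects (`O5'`/`O5′`/`O5*`,
`O1P`→`OP1`).  Formal charges are template-based (−1 per phosphate, ion
charges by species label) — the analysis uses formal, not partial,
charges throughout.  Triclinic boxes are rejected.  Zero ions of a species
yield an all-zero CDF but an error for g(r) (whose normalization divides
by the bulk density).  An all-zero occupancy trace is an error for
residence estimation ("site never occupied"); an all-ones trace is
censored.  Flat sugar rings and peakless profiles return flagged results,
not exceptions.  All generators consume a mandatory seed and one RNG
stream: identical spec + seed is bit-identical, and the report runner
hashes its configuration into every output header so reruns can be
verified byte-for-byte.

## Known limitations

No local (per-step) helical axis or helicoidal parameter suite (twist,
roll, rise, inclination, x-displacement, propeller) — those belong to
dedicated structure tools; no triclinic boxes; no binary trajectory
formats (multi-model PDB and XYZ-with-sidecar only); no explicit
water-bridge topology for mediated binding (distance-defined only); no
finite-size corrections to D; formal charges only.  The Z-form builder
idealizes the zig-zag backbone with alternating twists but a uniform
rise.
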