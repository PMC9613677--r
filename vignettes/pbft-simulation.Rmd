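---
title: "Methods: cellular-level Monte Carlo for proton boron fusion therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cellular-level Monte Carlo for proton boron fusion therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbftcell)
```

## The model

`pbftcell` asks a microdosimetric question: when a proton beam crosses a
boron-loaded monolayer cell culture, how much extra energy do the
p + ¹¹B → 3α fusion alphas deposit in the cytoplasm and nucleus of the
cells, compared with the alphas that protons make anyway by nuclear
reactions on ¹⁶O, ¹⁴N and ¹²C?

The geometry is deliberately idealized: an `n × n` monolayer of
rectangular-parallelepiped cells at 100% confluence — shared faces, no
interstitial gaps — each cell of side `lcell` and thickness `tcell` with
a cubic nucleus of side `lnuc` at its centre; a buffer slab of thickness
`tbuffer` and the cells' footprint on top; everything inside an ambient
air sphere of radius `airad`. The beam travels along −z; z = 0 is the
buffer/cell interface, so depth in the cell layer runs from 0 to
−`tcell`. Cells and nuclei share one composition (1.27 g/cm³; H 10.64%,
O 74.5%, C 9.04%, N 3.21%, P 2.61% by weight), the buffer is water-like
(1.00 g/cm³; H 11.1%, O 88.9%). Boron is mixed in as natural boron at a
mass concentration in ppm: the boron weight fraction becomes
`ppm × 1e-6`, the other fractions are rescaled by the complement, and
the density is held fixed — the stated mixing rule for this system. Only
¹¹B (80.1 atom %) feeds the fusion channel. A consequence worth noting:
because the density does not change, the geometric and mass-equivalent
thickness of a boron-loaded buffer coincide, so no separate
"equivalent-thickness correction" switch is needed when comparing
loaded and unloaded buffers.

Boron placement follows three cytoplasm modes: none (`cytob = 0`), all
(`cytob = 1`), or random (`cytob = 2`), where each cell is boron-filled
when its uniform(0,1) draw falls below a threshold (default 0.5; the
threshold is exposed as `bthresh` because nothing forces the canonical
value). Draws are consumed in row-major cell order, and — a detail that
matters for paired comparisons — they are consumed in *every* mode, so
two runs differing only in the boron mode keep all downstream random
numbers aligned. A nucleus carries boron only when `nuclb = 1` *and* its
own cell's cytoplasm does.

## Transport

Protons are stepped with a condensed-history scheme. The step is the
minimum of (i) the distance to the next region boundary, (ii) the path
over which the proton loses 5% of its energy (`max_frac_eloss`), and
(iii) the axial tally bin width inside the buffer. Continuous energy
loss uses range–energy inversion, `E' = R⁻¹(R(E) − ρΔs)`, which is
exact within the continuous-slowing-down approximation whatever the
step size; energy bookkeeping therefore telescopes exactly, and the
per-history balance `E_source + ΣQ = Σdeposits + Σescapes` holds to
machine precision (the test tolerance of 1e-4 MeV is generous).

Stopping powers are first-order Bethe (no shell or density-effect
corrections) with ICRU-style mean excitation energies, combined over
elements by Bragg additivity; below 1 MeV per nucleon each elemental
term continues as a power law matched in value and log-slope at the
boundary. For protons in water this lands within ~1% of standard
tabulations over 1–100 MeV (25 MeV range: 0.626 g/cm² here vs 0.623
tabulated). For alphas the missing effective-charge correction makes
the model overestimate stopping below ~1 MeV/u, so fusion-alpha ranges
come out short (15 µm at 3.76 MeV in cell medium, vs ~25 µm from
evaluated data). This compresses alpha tracks but preserves every
qualitative property the package asserts (full containment of
low-energy alphas in a nucleus, sub-50 µm ranges, exact energy
conservation). A user-supplied two-column stopping table per material
and species overrides the analytic model when more fidelity is wanted.
Ranges are tabulated once per (material, species) on an 800-node log
grid by cumulative quadrature of 1/S and inverted by log-log
interpolation; the tabulation agrees with a fine-step Euler slowing
oracle to better than 0.5%.

Reactions fire with probability `1 − exp(−Σ_tot Δs)`, with cross
sections evaluated at the step midpoint energy (second-order accurate)
and the reaction placed at the step midpoint; the channel is drawn
proportionally to its macroscopic cross section, and every channel
consumes the proton. The channel set:

* **p + ¹¹B → 3α** (Q = +8.682 MeV): the excitation function is a
  compact effective table with the 675 keV resonance (1.2 b peak) and a
  slowly decaying tail above 10 MeV. Products use the fixed energies
  3.76 MeV + 2 × 2.46 MeV — the sequential ⁸Be picture with fixed
  product energies is the model adopted here, in preference to full
  three-body phase space; the entrance-channel energy dependence is
  deliberately ignored, and the event's energy ledger charges the
  difference to the reaction Q so conservation still closes.
* **¹⁶O(p,α)¹³N** (Q = −5.218 MeV): opens at 5.66 MeV by default. The
  figure of record for this threshold is 5.66 MeV while two-body
  kinematics from mass tables gives ≈5.55 MeV; the opening is a
  configurable parameter rather than a silently "corrected" constant.
  The embedded table carries resonance-region values of tens of mb and
  continues into an inclusive alpha-production tail of ~0.25 b at tens
  of MeV, standing in for the many-channel alpha yield a full nuclear
  cascade model would produce.
* **¹⁴N(p,α)¹¹C** (threshold 3.13 MeV) and an effective
  **¹²C(p,α)⁹B** channel (threshold 8.19 MeV), built the same way.
* a generic **(p,n)** counter on ¹⁶O (threshold 10 MeV): neutron births
  are counted, their energy is booked as escaping, and neutrons are
  never transported.

Two-body channels give the alpha
`KE = (E_p + Q) · m_res/(m_α + m_res)`; the residual recoil (¹³N, ¹¹C,
⁹B) is deposited locally and the radioisotope production counted —
decay is out of scope. Emission is isotropic. A hydrogen-only builtin
medium provides the null control: with no target nuclides present, no
alphas can be produced, which the test suite asserts end to end.

Alphas travel in straight lines (their lateral scattering is small on
these scales) with the same range-inversion slowing, stepped at the
axial bin width inside buffer and cells so depth profiles resolve 1 µm
bins. Protons by default also travel straight, which keeps the
depth-dose analytic — the Bragg peak of a monoenergetic beam lands at
the CSDA range by construction, and the suite checks it to 2%. An
optional Highland small-angle multiple-scattering model
(`scattering = TRUE`) adds Gaussian deflections per step for users who
want lateral spread in track maps; it is off by default so the
transport oracles stay exact.

Transport cutoffs are 0.1 MeV (protons) and 0.05 MeV (alphas), residual
energy deposited locally. Boxes are half-open `[min, max)` on every
axis, so every face has a unique owner and point location is
deterministic; after each step the particle is nudged 1e-6 µm along its
direction to cross the boundary cleanly (the associated unaccounted
path is ~1e-6 µm per step, energetically invisible).

## Random numbers

One R stream, seeded from `seed`, drives boron assignment (row-major)
and source sampling (exactly three uniforms per history, whatever the
source type). All in-flight decisions — reaction firing, channel
choice, emission angles, scattering — come from a counter-based hash
keyed by (seed, batch, history, step, purpose). Every history is an
independent substream, runs are bit-reproducible, and paired scenarios
at the same seed share common random numbers *per history*: a boron and
a normal arm see identical histories except where boron physically
intervenes. This is what makes paired enhancement factors stable at
modest statistics — the ratio estimator's variance collapses because
the two arms' event sets are nearly identical by construction, rather
than independent draws.

## Tallies and statistics

Batches (`maxbch` × `maxcas` histories) provide the uncertainty model:
every tally is stored per batch and summarized as batch mean ± standard
error, normalized per source particle so no separate fluence estimate
is needed. Scored quantities: energy deposition per region (cytoplasm
and nucleus of every cell, buffer, ambient) and species (proton, alpha,
residual recoils); the axial alpha profile over the cell layer (30 bins
of 1 µm by default — fine enough to resolve structure, coarse enough to
fill at realistic statistics); a buffer depth-dose (bins of
`max(tbuffer/100, 25 µm)`, which also caps proton steps so deposition
is localized to better than half a bin); alpha hit counts; reaction and
radioisotope counters.

A **hit** is one (alpha track, subdomain) pair — a track scores once in
every cell nucleus or cytoplasm it enters or is born in, however many
segments it leaves there. This is the standard fluence-like convention;
since nothing fixes the multiplicity rule otherwise, single-counting
was chosen and is applied consistently in the engine and in the
segment-walking recount. Repeated runs at different seeds are
summarized as (lower, average, upper), and both raw counts and
per-source-particle rates are reported, since a raw count is only
meaningful at a stated history number.

The **enhancement factor** divides total alpha energy deposition in the
cell array between paired boron and normal runs. Two estimators are
provided: `"pooled"` (default) divides the batch means and propagates
the paired batch covariance by the delta method; `"batchwise"` averages
per-batch ratios, dropping (and flagging) batches with a zero
denominator. The pooled form is the default because single batches of a
rare-event tally can legitimately be empty while the pooled totals are
not; with common random numbers the two agree to several decimals. A
vanishing pooled denominator is flagged as undefined rather than
patched — it genuinely occurs, e.g. for a 25 MeV beam under 5000 µm of
buffer with no boron.

The **energy fraction** `D_α/(D_α + D_p)` excludes residual-recoil
deposition from both terms: it compares the two transported species.

## The SOBP builder

`build_sobp(e_max, nsobp, medium)` picks `nsobp` energies whose CSDA
ranges are equally spaced across the modulation interval (default: from
75% of the distal range to the distal range) and solves a non-negative
least-squares problem for weights that flatten the summed depth-dose
there. The per-beam depth-dose is the CSDA deposition profile smeared
by a Gaussian range-straggling kernel of width 1.2% of the range — the
textbook magnitude for protons in water. The smearing is essential to
the *weighting* model: a superposition of unsmeared CSDA peaks is a
comb, not a plateau. With 20–25 energy points the plateau is flat to a
fraction of a percent and the distal 50% edge sits at the CSDA range of
the top energy (checked to 3%). The Monte Carlo engine itself does not
simulate energy-loss straggling, so a simulated SOBP depth-dose is
spikier than the analytic design curve at sub-bin resolution; the
acceptance-level quantity (the entrance enhancement factor) does not
depend on this.

## Study conditions and problem sizes

The canonical scenario is a 20 × 20 array (400 cells) of
30 × 30 × 30 µm³ cells with 10 µm nuclei, buffers of 1000 or 5000 µm,
beam energies of 25, 35 and 70 MeV, a 0.30 mm disk source (half the
array side, so corner cells sit outside the direct beam), 100 ppm boron
in cytoplasm, nucleus and — for SOBP comparisons — buffer, and an
80 MeV SOBP with the cell layer at 1e-4, 4, 4.5 and 4.8 cm depth.
Defaults in `simulation_config()` encode these values; `maxcas`/
`maxbch` default to 10⁴ × 10, a package choice since no canonical
history count exists. The test suite and the acceptance script scale
runs to what one CPU handles comfortably: the paired SOBP-entrance
enhancement factor uses 10 batches of 25 000 histories per arm, enough
for a few dozen alpha-producing events per arm — ample for a
common-random-number ratio, though far below what independent-arm
estimation would need; property checks use 10³–10⁴ histories.

## What the simulator does and does not show

Passing tests demonstrate internal consistency (conservation,
determinism, analytic-oracle agreement) and the physics the embedded
data encode: alpha production without boron above the oxygen threshold,
its absence below, fusion-alpha yields that only matter near the Bragg
peak, and an enhancement factor of ~1 at the entrance of a high-energy
SOBP. They do not validate absolute yields: the high-energy tails of
the channel tables are effective inclusive values (a full intranuclear
cascade would distribute alpha energies and multiplicities
differently), alpha ranges are compressed at low energy, energy-loss
straggling and (by default) lateral proton scattering are absent, and
neutron and photon dose are out of scope entirely. Real cell cultures
add curved geometries, heterogeneous boron uptake and chemistry that
rectangular cells with uniform ppm loading cannot capture. The package
is a framework for controlled comparisons — boron on versus off, layer
depth, beam energy — not a predictor of absolute clinical dose.
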