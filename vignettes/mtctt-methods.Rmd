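---
title: "Models and methods behind mtctt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtctt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mtctt)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The system

Microtubules are hollow polymers of αβ-tubulin dimers: 13 protofilaments
(head-to-tail rows of dimers) arranged side by side with a 3-start lateral
monomer helix. The α-tubulin C-terminal tail (αCTT, residues 438–451,
`DSVEGEGEEEGEEY`) is disordered and carries eight acidic side chains (D438
plus seven glutamates at 441, 443, 445, 446, 447, 449, 450). The tail's
acidic residues form transient salt bridges with four clusters of basic
residues on the tubulin body — two *trans* clusters on the β-tubulin of
the neighbouring dimer toward the minus end on the same protofilament
(site 1: R390/R391/K392; site 2: K174/R380/R213/K379/R306) and two *cis*
clusters on the tail's own α-tubulin (site 3: K311/R308/K338/R339; site 4:
K112/R123/R156/K163/K430). Two published summaries of these clusters
disagree on the site-3 count ("five basic residues" vs. a four-residue
list); the explicit residue list is taken as authoritative here.

A tail whose C-terminal residues are bound to the body is *inaccessible*
to readers of the tyrosinated tail tip. The nucleotide state of the
lattice (GDP: compacted, dimer repeat ≈ 81–82 Å, untwisted; GTP: expanded,
≈ 83–84 Å, supertwisted) modulates which sites are active: site-2 and
site-4 contacts are characteristic of the GDP lattice and nearly absent in
the GTP lattice.

## 2. Lattice construction

Coordinate convention: the microtubule axis is +z, the minus end toward
−z, so "toward the minus end" means decreasing ring index; within a dimer
the α monomer occupies the minus-proximal half. Tubulin residue numbers
follow author numbering.

`build_ring()` replicates a dimer template by the helical symmetry of an
N-protofilament, S-start lattice: protofilament *p* is rotated by
*p*·360/N degrees about the axis and raised by *p*·S·(repeat/2)/N. After N
steps the accumulated rise is S·repeat/2 — 1.5 dimers for the 13/3
default — so the lateral α/β register breaks at the wrap from the last
protofilament to the first. We model the standard B-lattice with that
single seam and record it at the pf 12 → pf 0 wrap; real reconstructions
inherit their seam from the template and never need this rule, but a
testable explicit convention is required for synthetic models.

`stack_rings()` translates copies of the ring by the dimer repeat
(rotating by the supertwist when nonzero), giving the 3-ring, 39-dimer
reference fragment. `apply_periodic_box()` declares an axial box of
exactly `n_rings × dimer_repeat` (246 Å for the GDP defaults); afterwards
every distance in the package uses the minimum-image convention along z.
A supertwisted lattice cannot be made periodic — the protofilaments would
not line up with their axial image — so GTP-geometry models stay finite
and the builder refuses the box with an explanatory error.

Defaults: dimer repeat 82.0 Å (GDP) and 83.5 Å (GTP), the midpoints of the
compacted/expanded ranges; supertwist 0°/dimer (GDP) and 0.2°/dimer (GTP,
magnitude configurable — the true value for an expanded lattice is not
printed anywhere we rely on, so it is a free parameter whose only role
here is to trigger the finite-box path); fixture radius 115 Å from the
axis.

`graft_tails()` attaches a bead-per-residue chain (3.8 Å spacing, the
Cα–Cα virtual bond length) to the anchor residue 437 of every α subunit,
initialised fully extended radially with a small seeded angular jitter.
Fully extended is a deliberate, reproducible start far from any bound
state: equilibration is then visible as a rising inaccessibility curve. A
clash with body atoms (< 2 Å) triggers regrowth with fresh jitter up to a
bounded retry count. β-tails are grafted only when the user supplies a
β-tail definition (no reference sequence ships with the package) and are
excluded from analysis by default.

## 3. Salt-bridge criteria

The operational definition of a salt bridge is a distance cutoff on
charged-group atoms: in atomistic mode, minimum distance over Glu OE1/OE2
or Asp OD1/OD2 against Lys NZ or Arg NE/NH1/NH2, cutoff 4.0 Å (the common
structural-biology convention); in coarse-grained mode, bead–bead distance
with cutoff 6.0 Å (one bead ≈ side-chain centroid; the looser value
absorbs the lost side-chain geometry). Both are configuration keys, not
measured quantities. Ties at exactly the cutoff count as contacts (≤). A
residue pair yields at most one record per frame, carrying the minimum
group distance.

Eligible tail residues are the acidic set D438 + 7 Glu. The C-terminal
main-chain carboxylate of Y451 is an opt-in group
(`include_cterm_carboxylate`), because the two published phrasings of the
qualifying set — "glutamates E445–E450" versus "E445 to Y451" — disagree;
the package defaults to the explicit glutamate list and exposes the
alternative as a flag. Trans partners are restricted to the same
protofilament; lateral-neighbour contacts are out of scope. In finite
models the minus-end ring has no trans partner, and those tails are
excluded from trans-site statistics (in periodic models every tail
resolves via the ring wrap).

## 4. Accessibility statistics

*Interaction rate* (residue × site matrix): the fraction of analysed
frames in which that residue forms ≥ 1 salt bridge with that site, pooled
over all tails. The pooled definition saturates quickly when many tails
are simulated — with 39 tails a per-tail occupancy of 0.1 pools to
1 − 0.9³⁹ ≈ 0.98 — so a per-tail variant (`per_tail = TRUE`) and an
events-per-ns estimator (maximal runs of consecutive bound frames divided
by trajectory time) are provided. One consequence worth stating plainly:
under pooling, the *global* arg-max cell of the matrix is an unstable
statistic (several cells sit near 1), and in the coarse-grained surrogate
it can fall either on E441/E443–site 1 or on a C-terminal–site 2/4 cell
depending on the seed. The robust, tested pattern is row-wise: E441 and
E443 interact overwhelmingly with site 1, and the C-terminal residues'
site-2/site-4 rates collapse under the GTP preset.

*Inaccessibility series*: per frame, a tail is inaccessible iff it has ≥ 1
contact whose tail residue is in the qualifying set (any site); the series
is the instantaneous fraction of inaccessible tails. We interpret the
fraction as instantaneous (not cumulative) because it is reported "as a
function of time" and should track equilibration; a cumulative ever-bound
variant is available behind `cumulative = TRUE`. Optional smoothing is a
centered running mean with truncated edges; window 0 is the identity, and a
window equal to the series length is allowed (it degenerates to the global
mean); only `window > length` is a parameter error.

*Replicates*: independent trajectories of one condition are aggregated by
truncating to the shortest series and averaging per frame position — no
interpolation, because replicate time grids are commensurate by
construction — plus an unweighted time-averaged scalar per replicate.

## 5. The coarse-grained simulator

The sampler is a surrogate for atomistic MD, built to reproduce the binary
salt-bridge bookkeeping of the analysis, not the physics of electrostatics
in solvent. Each tail is a 14-bead chain (one bead per residue) tethered
at residue 437:

* bonds: harmonic, `E = ½k(d − b₀)²` with `b₀ = 3.8 Å` and
  `k = 20 kT/Å²` — stiff enough that bond-length fluctuations (σ ≈ 0.22 Å)
  never approach the 1.5 Å integrity bound, soft enough for an efficient
  single-bead acceptance rate (~0.37 at the default 0.6 Å step);
* wall: a hard cylinder at the lattice surface radius (115 Å); moves
  placing any bead inside are rejected. Body atoms other than site beads
  are not represented;
* site attraction: a square well per (acidic bead, site bead) pair —
  −ε_s when within 6 Å, else 0 — with minimum-image distances in periodic
  models. Temperature is kT = 1.

Moves: per sweep, one trial displacement per bead (uniform cube, ±0.6 Å),
and every 10th sweep one pivot per tail (rotate the chain downstream of a
random bead about a uniformly random axis and angle; bond lengths are
invariant under the pivot, so only wall and attraction terms enter the
Metropolis ratio). Both satisfy detailed balance; the suite verifies that
a free 5-bond chain reproduces the exact bead-spring equilibrium
(uniform bond directions, bond lengths from p(l) ∝ l² exp(−k(l−b₀)²/2))
by a two-sample KS test at 10⁴ samples.

The GDP preset uses well depths ε = (2.0, 2.0, 1.5, 1.5) kT for sites
1–4; the GTP preset zeroes ε₂ and ε₄ and changes nothing else, so the
presets form a controlled contrast. These depths are calibration constants
of this package, not published quantities. Both presets run on the
periodic GDP-geometry lattice by default: the accessibility contrast is
carried entirely by the well depths, which keeps the comparison free of
geometric confounds (a finite supertwisted lattice can be configured
instead).

`time_per_sweep` (default 0.01 ns) is a labelling convention so outputs
carry a time axis; it has no dynamical meaning.

### Fixture geometry and calibration

The synthetic pseudo-dimer places beads only for the residues the analysis
needs: the anchor, the 17 site residues, and a few filler beads. Site
beads are deliberately buried *below* the wall surface (sites 1/3 at
r ≈ 109.5–109.8 Å, sites 2/4 at 111.6 Å, wall at 115 Å), for two reasons.
First, a tail bead can then only approach a site from outside the wall, so
the zero-attraction proximity baseline is small (mean inaccessibility
≈ 0.005 at ε = 0, versus the ≤ 0.05 the design targets); placing site
beads at the surface made nearness-by-chance so common that the baseline
was 0.18 and both presets saturated near 1. Second, burial shrinks the
bound-state volume (a spherical cap of the 6 Å well beyond the wall), so
the fixed ε values land in the moderate-occupancy regime where the
GDP/GTP contrast is visible: across seeds the GDP preset equilibrates to a
second-half mean inaccessibility of roughly 0.3–0.5 and the GTP preset to
roughly 0.1–0.3, with GDP > GTP in every tested seed pair. Sites 1/3 are
buried slightly deeper than 2/4 so that the preset contrast (which lives
in sites 2/4) dominates the shared background. Axially, site 1 sits just
below the anchor at the longitudinal interface (reachable by E441/E443,
whose short tether gives them the highest local concentration there),
site 2 distal on the β body, and the cis sites at intermediate and distal
offsets above the anchor. These geometric choices were fixed once, from
the baseline/saturation diagnostics above, before the acceptance checks
were formulated, and are not tuned per seed.

### What the generator does and does not emulate

It emulates: tethered-chain entropy against a wall, site-specific
short-range attraction, the multiplicity of acidic residues and site
residues, periodic boundary effects, and the nucleotide contrast as a
well-depth contrast. It does not emulate: explicit electrostatics or ionic
strength, solvent, tail–tail interactions, body flexibility, real
kinetics (MC "time" is not physical), or the βCTT. Consequently, passing
tests show that the analysis pipeline correctly measures what a controlled
generator produces — the direction and mechanism of the GDP/GTP contrast —
not that the coarse model reproduces atomistic contact statistics; in
particular the published absolute inaccessibility levels (tens of percent
after hundreds of ns) are expressly out of scope.

## 6. Numerical and interface choices

* Problem sizes: the reference system is 13 pf × 3 rings = 39 tails; the
  default run is 10⁴ sweeps (1000 frames at stride 10), which the
  behavioural checks use as-is. Oracle comparisons use a 4 pf × 2 ring
  model (288 atoms per frame) so the O(n²) brute force stays instant.
* Determinism: every stochastic operation takes a seed, runs in a private
  RNG scope (the caller's RNG state is restored), and is bit-reproducible;
  the MC kernel draws from R's RNG so C++ and R stay on one stream.
* I/O: PDB via bio3d (coordinates round-trip at the format's 3-decimal
  precision); XYZ is written at full double precision and is the default
  trajectory format; CSVs print doubles with `%.17g` so read-back is
  exact. Config files are YAML (flat sections, every default echoed back
  explicitly; unknown keys error with a spelling suggestion). The
  `manifest.yaml` written by `run_pipeline()` suffices to reproduce every
  artifact byte-for-byte.
* Degenerate inputs: single-ring finite models have no trans partners and
  refuse simulation; empty contact sets yield all-zero statistics rather
  than errors; a frame whose eligible residues lack their charged-group
  atoms raises a structured error naming them.

## 7. Known limitations

* The CG energy surface is a surrogate; none of its constants are
  physical measurements, and outputs must not be quoted as force-field
  results.
* The pooled interaction-rate matrix saturates at high tail counts (see
  §4); use the per-tail flag for discriminative comparisons.
* Site definitions, the tail sequence and partner rules are specific to
  the α-tubulin tail on a 13-pf B-lattice; other protofilament numbers
  build correctly, but the seam convention and site lists may not apply.
* No binary trajectory readers (DCD/XTC) in this release; convert to
  multi-model PDB or XYZ first.
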