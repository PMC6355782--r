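---
title: "Methods: trajectory analysis of nanoparticle aggregation in lipid bilayers"
author: "memlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of nanoparticle aggregation in lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memlens)
```

## The scientific problem

Fullerenes (C60) partition into lipid bilayers and, above a concentration
threshold, aggregate there. Whether they disperse or cluster depends on the
saturation of the lipid acyl chains, and the mechanism is thermodynamic: the
balance between the entropic and enthalpic components of the
fullerene-fullerene potential of mean force flips between fully saturated
(DPPC-like) and unsaturated (DOPC/POPC-like) matrices. Establishing that from
coarse-grained trajectories requires a chain of analyses — membrane
dimensions, density profiles, cluster statistics, radial distribution
functions, Boltzmann inversion, finite-difference thermodynamic
decomposition, and diffusion estimates. `memlens` implements that chain as a
reusable, tested pipeline, together with synthetic generators whose output
has closed-form ground truths, so every stage can be verified without any
molecular-dynamics engine.

## Data model

A `cg_trajectory` couples a bead topology (one row per bead: molecule,
species, group label, mass) with frames of coordinates in nm, orthorhombic
box edges and times in ns. Group labels (`lipid_head`, `lipid_glycerol`,
`lipid_tail`, `double_bond`, `fullerene`, `water`, `other`) come from an
explicit YAML topology map keyed by bead name — never inferred from naming
conventions, because coarse-grained bead names vary between lipids. Units
follow the GRO convention throughout: nm, amu, ns, kJ/mol, with
`kB = 0.0083145` kJ/(mol K). Internally beads are indexed from 0; 1-based
indices appear only at file boundaries.

Only orthorhombic boxes are supported; triclinic input is rejected at parse
time. All distances are minimum-image. Centers of mass under periodic
boundaries use the circular-mean construction (each coordinate mapped to an
angle, mass-weighted mean direction, mapped back), which is exact for
molecules split across the boundary as long as the molecule is small
compared to the box — true for a 16-bead fullerene cage by a wide margin.

## Membrane observables

* **Area per lipid**: `Lx*Ly / (n_lipids/2)` per frame; mean and SD over
  frames. SDs over frames are the error convention for all dimension
  observables.
* **Volume per lipid**: `(V_box - N_water * v_w - n_np * v_np) / n_lipids`.
  The water bead volume `v_w` is a calibration constant (default 0.12 nm^3);
  `v_np` defaults to 0, so the default output is the lipid+particle
  composite volume. Both are configuration items because the subtraction
  convention is not standardized in the field.
* **Density profiles**: per frame, z is measured relative to the
  circular-mean center of all lipid beads (a drifting slab stays centred),
  wrapped to `[-Lz/2, Lz/2)`, histogrammed per group as mass, divided by the
  bin volume and averaged over frames. Default bin width 0.1 nm resolves the
  three-region layering of nanoparticles in unsaturated bilayers without
  noise domination. The profile integral times the box area recovers each
  group's total mass to 1% for any binning — a standing test.
* **Bilayer thickness**: distance between the two head-group density peaks,
  each refined by quadratic interpolation through the maximum bin and its
  neighbours. Peak-to-peak is this package's convention (chosen because it
  is robust at high nanoparticle load and matches what phosphate-peak
  profiles display); Luzzati-style conventions are out of scope.
* **Area compressibility**: `K_A = kB*T*<A>/Var(A)` from total box-area
  fluctuations, with uncertainty from block averaging over 5 contiguous
  blocks — area fluctuations are time-correlated, so a naive SE would be
  optimistic. Offered in kJ/(mol nm^2) and mN/m (1 kJ/(mol nm^2) =
  1.6606 mN/m).

## Cluster statistics

Two particles are clustered when their center-of-mass minimum-image distance
is strictly below the cutoff, 1.30 nm by default (the established criterion
for coarse-grained fullerenes). Clusters are connected components; neighbour
search uses a cell list with cell edge at least the cutoff, falling back to
all-pairs below 64 particles, and both paths are asserted identical to an
independent O(N^2) oracle in the tests. The distance is the full 3D distance,
not its in-plane projection — the literal reading of the criterion — and the
choice is recorded here because it propagates to the RDFs. The per-frame
series reports largest-cluster size and the fraction of particles in it; the
analysis window is a trailing fraction of the trajectory (default the last
half), the usual equilibrated-tail practice.

## Pair structure and free energy

The center-of-mass RDF accumulates minimum-image pair distances into 0.02-nm
bins up to `min(half-box, 3.5)` nm. Three normalization modes are exposed:

* `raw_histogram` — plain counts (not invertible to a free energy: the
  additive constant is undefined, and `free_energy_profile()` rejects it);
* `shell_normalized` — counts over the ideal-gas shell expectation
  `n_pairs * 4 pi r^2 dr / V`, the textbook g(r), exact in bulk 3D;
* `plateau_normalized` (default) — the shell-normalized curve rescaled so
  its mean over a plateau window (default 2.5-3.2 nm) is 1.

The plateau mode exists because in thin-film geometry the effective bulk
density entering the shell normalization is ambiguous, yet Boltzmann
inversion needs a declared zero. Dividing out the shell volume first removes
the trivial r^2 geometry (without it, an inverted profile is off by
`-kB*T*ln(r^2/r_plateau^2)`, several kJ/mol at contact distances); the
plateau rescale then absorbs the unknown density into the additive constant.
Every output header records the mode and window. Differences of dG between
bins, and the first-to-second-minimum gap ddG, are independent of that
convention, and the tests assert it.

Free energies are `dG(r) = -kB*T*ln g(r)` per bin. Bins with `g = 0` are
masked as undefined rather than clamped — clamping would fabricate values.
Minima are located as the lowest defined bin in each search window
(defaults 0.85-1.25 nm for the contact pair, 1.30-1.75 nm for the
lipid-bead-separated pair), refined by 3-point quadratic interpolation; the
windows bracket the two physical classes of minima but are configurable so
the result under test is not hard-coded.

Second-shell splitting — the bifurcation of the RDF's second peak into two
sub-peaks, a short-range-order signature familiar from metallic glasses — is
detected as at least two local maxima in a window (default 1.30-2.20 nm),
each with topographic prominence at least 2% of the window maximum,
separated by a local minimum. For two equal Gaussians of width `s` the dip
exists only for separations above `2s`, and the prominence threshold shifts
the flip point to a value computable in closed form; the tests scan
separations and check the detector flips within one bin of that analytic
point.

The inter-pair axis density selects, per frame, particle pairs at a chosen
separation (within a tolerance, default 0.05 nm), sets up a local axis at
the pair midpoint, and histograms beads within a 0.5-nm-radius cylinder by
axial coordinate, normalized per qualifying pair instance. It is the
observable that shows a lipid bead sitting between the particles of a
solvent-separated pair at ~1.5 nm, and its absence at contact (~1.0 nm).

## Entropy/enthalpy decomposition

With free-energy profiles at three temperatures (defaults 283/298/313 K) on
a shared grid and a shared normalization convention,

* `-T dS(r) = T dG/dT ~ (T / 2 dT) * (G(T+dT) - G(T-dT))`,
* `dH(r) = dG(r) + T dS(r)`,

evaluated bin-wise. The central difference has zero truncation error for G
affine in T (asserted to machine precision), and the closure
`-TdS + dH = dG` holds exactly wherever all inputs are defined; masks
propagate. All three profiles must use the same mode and plateau window —
mixing conventions would inject spurious temperature dependence into the
derivative. The decomposition is evaluated on matched r-grids; values at
the minima located on the central profile are reported alongside the full
curves. One degenerate case worth recording: feeding the *same* samples
under three temperature labels yields the same g(r) at each label, so
`G(T) = -kB*T*ln g` is linear through the origin and the decomposition
correctly reports a purely entropic profile (`-TdS = dG`, `dH = 0`).

## Diffusion

MSD uses all time origins at stride 1 (the lowest-variance standard
estimator), computed per particle and axis with the exact FFT
(Wiener-Khinchin) algorithm, restricted to lags up to half the trajectory;
the per-lag standard error is taken across particles, the independent units.
`D = slope/(2d)` from a least-squares fit over a lag window, `d = 2`
lateral, `d = 1` normal. The default window is fractions 0.1-0.5 of the
maximum lag, a conventional compromise for real membrane data whose short
lags are contaminated by local cage rattling. For the package's own
estimator-recovery checks on purely Brownian synthetic data the fit window
is set to short lags (fractions 0.002-0.1) instead: a Brownian signal has no
short-time artefact to avoid, and long lags carry few independent
displacement segments, so the short-lag window is where the information is
(relative errors drop from ~5% to ~2% at 64 particles and 10^4 frames). A
fit with r^2 below 0.9 triggers a confinement warning — expected for the
membrane-normal direction, where the MSD saturates and the fitted number
must be read as an effective short-time coefficient. Ensemble center-of-mass
drift removal is off by default and exposed as a flag, so toggling it is
auditable.

## The synthetic generators

The generators define the study conditions under which the pipeline is
verified:

* **Slab membrane** — two leaflets of four-bead lipids (head bead at
  +/- half the head separation, three tail beads inward at 0.47 nm spacing,
  the second tail bead labelled `double_bond` for unsaturated species) on a
  jittered square lattice (Gaussian jitter, sigma 0.05 nm), plus optional
  water beads outside the slab. Area per lipid and head separation are
  exact by construction, which closes the loop: the membrane metrics must
  recover them (APL to 0.01 nm^2, thickness to 0.1 nm). Optional Gaussian
  box-area fluctuations give the compressibility estimator a known target.
* **Metropolis sampler** — single-particle moves under a
  truncated-and-shifted 12-6 pair potential (default cutoff 1.2 nm, the
  conventional coarse-grained cutoff; analytic minimum at `2^(1/6) sigma`)
  plus an optional layering field w(z): harmonic (`z`-variance `kB*T/k` in
  closed form) or a three-well cosine, `A*cos(3 pi z/h)` for `|z| < h/2`,
  which mimics the three-region compartmentalization of unsaturated
  bilayers for demonstration purposes. Lipid beads are frozen scaffolding —
  the analyses need labels and geometry, not lipid dynamics. Burn-in is a
  fixed first half of the sweeps; frames are recorded on a stride; the
  acceptance rate is logged and warned on outside 0.1-0.9 (dilute systems
  accept nearly everything, which is expected). In the dilute two-particle
  limit the recorded configurations obey `g(r) = exp(-u/kBT)` exactly,
  giving the Boltzmann-inversion chain a closed-form target.
* **Brownian walkers** — non-interacting overdamped updates
  `x <- x + sqrt(2 D dt) eta`, wrapped, with the true unwrapped path kept as
  an attribute so unwrapping is checked against exact bookkeeping, and an
  error if a step could break the half-box unwrapping contract.

All generators are deterministic given the spec seed (byte-identical
output), which the tests assert on written files.

What the generators deliberately do not emulate: lipid self-assembly or
dynamics, pressure coupling, undulations, hydrodynamics, or any claim of
coarse-grained force-field fidelity. Passing tests therefore demonstrate the
*estimators* are correct on data with known structure — not that the physics
of a particular force field is reproduced. Applying the pipeline to real
trajectories is exactly the same code path via `read_trajectory()`.

## Numerical choices

* Quadratic (3-point) interpolation for all peak and minimum positions:
  sub-bin precision without smoothing assumptions; falls back to the bin
  center at grid edges or non-concave neighbourhoods.
* RDF bin width 0.02 nm; z-profile bin width 0.1 nm; defaults only.
* Strict `<` at the cluster cutoff (ties are measure-zero but the contract
  is fixed); cell edge >= cutoff guarantees cell lists see every pair.
* `g = 0` bins masked, never clamped; undefinedness propagates through the
  decomposition.
* Unwrapping accumulates minimum-image frame-to-frame displacements and
  refuses displacements of half a box or more, naming the frame and bead.
* Block averaging (5 blocks) for compressibility errors; SD over frames for
  dimension observables.

## Problem sizes used in the checks

The test-suite and acceptance-script runs use desk-scale systems chosen so
each statistical bound sits several standard errors from its threshold:
2-particle dilute runs of 8x10^6 sweeps for the PMF recovery (max error
~0.1 kJ/mol against a 0.2 kJ/mol band); 64-particle ideal-gas runs of
4x10^4 sweeps for the g = 1 null; 64 Brownian walkers for 10^4 frames per
diffusion constant; 32-particle matched-density pairs of runs at 3x10^5
sweeps for the dispersion-to-aggregation contrast (per-run SE ~0.03 against
an ensemble largest-cluster gap of ~0.17, so five paired seeds are
sign-consistent); 512-lipid slabs for the geometry closed loop. Full-scale
coarse-grained membrane simulations (hundreds of microseconds) are the
domain of an MD engine and out of scope here; the headline literature
numbers from such simulations (dimerization free energies of a few kJ/mol,
minima at 1.0/1.5 nm, large saturated-bilayer clusters) are targets for
users with such trajectories, not quantities this package's generators can
produce.

## Known limitations

* Orthorhombic boxes only; no triclinic support.
* Thickness is peak-to-peak only; undulation corrections and per-leaflet
  asymmetry are not implemented.
* The normal-direction diffusion coefficient in a membrane is an effective
  short-time number; the package warns rather than models confinement.
* The Metropolis sampler is for generating verification data, not for
  production sampling of dense interacting systems (no cell lists in the
  energy loop, single-particle moves only).
* Plateau normalization assumes the plateau window genuinely samples the
  structureless tail; for very small boxes or strong long-range structure
  the window must be moved, and the output header always says where it was.
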