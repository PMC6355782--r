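# memlens

Trajectory analysis of nanoparticle aggregation in coarse-grained lipid
bilayers.

Fullerenes taken up by a lipid membrane either stay dispersed or aggregate,
depending on the saturation of the lipid tails, and the switch is
thermodynamic: the entropy/enthalpy balance of the fullerene–fullerene
potential of mean force flips between saturated and unsaturated matrices.
`memlens` is an R package for the full analysis chain that establishes such
results from coarse-grained membrane trajectories:

* membrane dimensions — area per lipid, volume per lipid, bilayer thickness
  (head-peak to head-peak), and the area compressibility
  `K_A = k_B T ⟨A⟩ / Var(A)` from box-area fluctuations;
* mass density profiles along the bilayer normal, per bead group;
* cluster statistics under the center-of-mass criterion
  `r_ij < 1.30 nm` (minimum image, connected components, cell-list
  accelerated);
* radial distribution functions g(r) of particle centers of mass with
  explicit normalization conventions for thin-film geometry, and their
  Boltzmann inversion `ΔG(r) = −k_B T ln g(r)`;
* location of the contact (~1.0 nm) and lipid-separated (~1.5 nm) free-energy
  minima, their gap ΔΔG, and detection of second-peak splitting of the RDF
  (a short-range-order signature);
* entropy/enthalpy decomposition from profiles at three temperatures,
  `−TΔS = (T/2ΔT)(G(T+ΔT) − G(T−ΔT))`, `ΔH = ΔG + TΔS`, exact for G affine
  in T and closing bin-wise by construction;
* lateral and normal diffusion coefficients from all-origin mean-squared
  displacements, `D = slope/(2d)`;
* deterministic synthetic generators (slab membranes, Metropolis particle
  sampling under a 12-6 potential plus a layering field, Brownian walkers)
  whose observables have closed-form ground truths, so every estimator is
  verifiable end to end.

Inputs are multi-frame GRO-dialect trajectories plus a YAML topology map
assigning each bead name a group (`lipid_head`, `lipid_tail`, `double_bond`,
`fullerene`, `water`, ...) and mass. Analysis functions take the trajectory
first and return tibbles, so calls chain with the pipe; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()` methods.

## Worked example

Sample two particles from a known truncated-shifted 12-6 potential
(ε = 2 kJ/mol, σ = 0.9 nm, cutoff 1.2 nm) and recover it by Boltzmann
inversion — the dilute limit where `g(r) = exp(−u/k_B T)` exactly:

```r
library(memlens)

spec <- synthetic_spec(
  n_particles = 2, box = c(6.6, 6.6, 6.6),
  pair_potential = list(epsilon = 2.0, sigma = 0.9, cutoff = 1.2),
  temperature = 298, seed = 42,
  sampler = list(mode = "metropolis", n_steps = 4e6,
                 step_size = 1.2, frame_stride = 2))

traj <- sample_particles_mc(spec)
#> Metropolis acceptance rate: 0.989 (4000000 sweeps, 1000000 frames)

pd  <- com_rdf(traj, bin_width = 0.02, r_max = 3.2, mode = "plateau_normalized")
fep <- free_energy_profile(pd, temperature = 298)
locate_minima(fep)
#> # A tibble: 1 × 5
#>   r_min1 dG_min1 r_min2 dG_min2    ddG
#>    <dbl>   <dbl>  <dbl>   <dbl>  <dbl>
#> 1   1.04  -0.803   1.43  -0.109 -0.693
```

The recovered contact minimum sits at the analytic `2^(1/6)·σ = 1.010 nm`
well position with depth `−ε − u(cutoff) = −0.830 kJ/mol` (the printed
−0.803 at 1.04 nm is within the run's sampling error; across the inversion
window 0.9–2.0 nm the profile deviates from the true potential by at most
0.17 kJ/mol here). `ddG < 0` means the contact pair is favoured over the
separated pair. For scale, thermal energy `thermal_energy(298)` is
2.478 kJ/mol — about 2.5 kJ/mol.

Membrane side, the generator→analysis loop closes on the geometry it was
given (512 lipids at 0.64 nm² per lipid, head planes 4 nm apart, 2000 water
beads of 0.12 nm³):

```r
mspec <- synthetic_spec(n_lipids = 512, box = c(12.8, 12.8, 10),
                        target_apl = 0.64, head_separation = 4.0,
                        n_waters = 2000, seed = 42)
mtraj <- generate_slab_membrane(mspec, n_frames = 10)
membrane_dimensions(mtraj)
#> # A tibble: 1 × 7
#>     apl apl_sd   vpl vpl_sd thickness    ka n_frames
#>   <dbl>  <dbl> <dbl>  <dbl>     <dbl> <dbl>    <int>
#> 1  0.64      0  2.73      0         4    NA       10
```

(`ka` needs a fluctuating box area and at least 100 frames; `apl` is
0.64 nm², `vpl` = (12.8·12.8·10 − 2000·0.12)/512 = 2.73 nm³, thickness
4.0 nm.)

A YAML-driven sweep over systems (generate → metrics → cluster → RDF → PMF →
minima → split → MSD) is available as `run_pipeline()`, and a thin CLI over
the same functions ships in `inst/cli/memlens`
(`memlens generate|apl|vpl|thickness|density|ka|cluster|rdf|pmf|minima|split|pairaxis|msd|diffusion|run`).

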