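test_that("fixed seed gives byte-identical generator output", {
  spec <- synthetic_spec(n_particles = 8, box = c(6, 6, 6), seed = 31,
                         sampler = list(mode = "metropolis", n_steps = 400,
                                        step_size = 0.5, frame_stride = 10))
  t1 <- suppressWarnings(suppressMessages(sample_particles_mc(spec)))
  t2 <- suppressWarnings(suppressMessages(sample_particles_mc(spec)))
  expect_identical(t1$coords, t2$coords)

  f1 <- withr::local_tempfile(fileext = ".gro")
  f2 <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(t1, f1); write_trajectory(t2, f2)
  expect_identical(readLines(f1), readLines(f2))

  bspec <- synthetic_spec(n_particles = 4, box = c(8, 8, 8), seed = 5,
                          sampler = list(mode = "brownian", n_frames = 50))
  expect_identical(simulate_brownian(bspec)$coords, simulate_brownian(bspec)$coords)
})

test_that("spec validation rejects inconsistent membrane geometry", {
  expect_error(synthetic_spec(n_lipids = 512, box = c(10, 10, 10), target_apl = 0.64),
               "1%", class = "memlens_spec_error")
  expect_error(synthetic_spec(n_lipids = 511, box = c(12.8, 12.8, 10)),
               "even", class = "memlens_spec_error")
  expect_error(synthetic_spec(n_lipids = 128, box = c(6.4, 6.4, 3),
                              target_apl = 0.64, head_separation = 4),
               "Lz", class = "memlens_spec_error")
})

test_that("slab generator builds the geometry its spec states", {
  spec <- synthetic_spec(n_lipids = 512, box = c(12.8, 12.8, 12),
                         target_apl = 0.64, head_separation = 4.0,
                         unsaturated = TRUE, n_waters = 500, seed = 2)
  traj <- generate_slab_membrane(spec, n_frames = 3)
  comp <- topology_composition(traj$topology)
  expect_equal(comp$n_molecules[comp$species == "DOPC"], 512)
  expect_equal(comp$beads_per_molecule[comp$species == "DOPC"], 4)
  expect_equal(comp$n_molecules[comp$species == "W"], 500)
  expect_true("double_bond" %in% traj$topology$group)

  # head beads sit on two planes head_separation apart
  heads <- traj$topology$group == "lipid_head"
  z <- traj$coords[heads, 3, 1]
  expect_equal(sort(unique(round(z - 6, 6))), c(-2, 2))
})

test_that("harmonic layering field gives the closed-form Gaussian z-density", {
  k <- 2.478  # kB*298/k = 1 nm^2
  spec <- synthetic_spec(n_particles = 24, box = c(8, 8, 14),
                         pair_potential = list(epsilon = 0, sigma = 0.9, cutoff = 1.2),
                         layering_field = list(form = "harmonic", k = k),
                         temperature = 298, seed = 17,
                         sampler = list(mode = "metropolis", n_steps = 3e4,
                                        step_size = 0.8, frame_stride = 5))
  traj <- suppressMessages(suppressWarnings(sample_particles_mc(spec)))
  z <- as.numeric(traj$coords[, 3, ]) - 7
  expect_equal(mean(z), 0, tolerance = 0.05)
  expect_equal(var(z), kB * 298 / k, tolerance = 0.05)
  # Gaussian shape: fourth moment / variance^2 = 3
  expect_equal(mean(z^4) / var(z)^2, 3, tolerance = 0.15)
})

test_that("equilibrium sampling is reversible: coarse z-state fluxes balance", {
  # bin a harmonically confined particle into 3 z-states and compare
  # empirical i->j vs j->i transition counts (detailed balance makes the
  # equilibrium flux matrix symmetric) and occupancies vs Boltzmann weights
  spec <- synthetic_spec(n_particles = 1, box = c(6, 6, 12),
                         pair_potential = list(epsilon = 0, sigma = 0.9, cutoff = 1.2),
                         layering_field = list(form = "harmonic", k = 2.478),
                         temperature = 298, seed = 23,
                         sampler = list(mode = "metropolis", n_steps = 6e4,
                                        step_size = 0.8, frame_stride = 1))
  traj <- suppressMessages(suppressWarnings(sample_particles_mc(spec)))
  z <- as.numeric(traj$coords[1, 3, ]) - 6
  state <- cut(z, c(-Inf, -0.5, 0.5, Inf), labels = FALSE)
  trans <- table(factor(head(state, -1), 1:3), factor(tail(state, -1), 1:3))
  for (i in 1:2) for (j in (i + 1):3) {
    nij <- trans[i, j]; nji <- trans[j, i]
    if (nij + nji > 0) {
      expect_lt(abs(nij - nji) / sqrt(nij + nji), 4)  # flux symmetry within noise
    }
  }
  # occupancy of the central state matches the Gaussian integral (bound set
  # by the autocorrelation-aware standard error, about 0.011 here)
  p_center_theory <- stats::pnorm(0.5) - stats::pnorm(-0.5)
  expect_lt(abs(mean(state == 2) - p_center_theory), 0.04)
})

test_that("Brownian generator honors D = 0, the lateral mask and the step guard", {
  static <- synthetic_spec(n_particles = 5, box = c(8, 8, 8), seed = 1,
                           diffusion_constant = 0,
                           sampler = list(mode = "brownian", n_frames = 10))
  traj <- simulate_brownian(static)
  expect_true(all(traj$coords == array(traj$coords[, , 1], dim(traj$coords))))

  lat <- synthetic_spec(n_particles = 5, box = c(8, 8, 8), seed = 1,
                        diffusion_constant = 0.02, lateral_only = TRUE,
                        sampler = list(mode = "brownian", n_frames = 200))
  ltraj <- simulate_brownian(lat)
  un <- unwrap_trajectory(ltraj)
  mz <- msd(un, axes = "z")
  expect_lt(max(abs(mz$msd)), 1e-10)

  big <- synthetic_spec(n_particles = 2, box = c(2, 2, 2), seed = 1,
                        diffusion_constant = 5, dt = 1,
                        sampler = list(mode = "brownian", n_frames = 5))
  expect_error(simulate_brownian(big), "box/4", class = "memlens_spec_error")
})

test_that("acceptance-rate bookkeeping warns outside [0.1, 0.9]", {
  spec <- synthetic_spec(n_particles = 2, box = c(8, 8, 8), seed = 3,
                         pair_potential = list(epsilon = 0, sigma = 0.9, cutoff = 1.2),
                         sampler = list(mode = "metropolis", n_steps = 200,
                                        step_size = 0.5, frame_stride = 10))
  expect_warning(suppressMessages(sample_particles_mc(spec)), "acceptance rate")
})
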